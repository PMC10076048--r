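# Handcrafted supervision signals: consecutive pose flow (CPF), reference
# pose flow (RPF), and the decoupling of a flow field into magnitude and
# orientation components (F = M * O).

#' Pose flow container
#'
#' A per-frame, per-joint 3D displacement field with the same `T x J x 3`
#' shape as its source sequence.
#'
#' @param vectors numeric `T x J x 3` array of displacements (meters).
#' @param kind `"cpf"`, `"rpf"`, or `"recomposed"`.
#' @return An object of class `pose_flow`.
#' @export
pose_flow <- function(vectors, kind = c("rpf", "cpf", "recomposed")) {
  if (!is.array(vectors) || length(dim(vectors)) != 3L || dim(vectors)[3] != 3L)
    stop("vectors must be a T x J x 3 array")
  if (!all(is.finite(vectors))) stop("flow vectors must be finite")
  structure(list(vectors = vectors, kind = match.arg(kind)),
            class = "pose_flow")
}

#' Magnitude flow container
#'
#' The scalar field of per-frame, per-joint flow magnitudes (Euclidean norms,
#' meters); always nonnegative.
#'
#' @param alpha numeric `T x J` matrix, `alpha >= 0`.
#' @return An object of class `magnitude_flow`.
#' @export
magnitude_flow <- function(alpha) {
  if (!is.matrix(alpha)) stop("alpha must be a T x J matrix")
  if (!all(is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be finite and nonnegative")
  structure(list(alpha = alpha), class = "magnitude_flow")
}

#' Orientation flow container
#'
#' The unit-vector field of per-frame, per-joint flow directions. Where the
#' motion magnitude is (numerically) zero the orientation is undefined: those
#' entries carry a zero vector and `valid_mask` is `FALSE` there; losses skip
#' them.
#'
#' @param units numeric `T x J x 3` array: unit vectors where valid, zero
#'   elsewhere.
#' @param valid_mask logical `T x J` matrix.
#' @return An object of class `orientation_flow`.
#' @export
orientation_flow <- function(units, valid_mask) {
  if (!is.array(units) || length(dim(units)) != 3L || dim(units)[3] != 3L)
    stop("units must be a T x J x 3 array")
  if (!is.matrix(valid_mask) || !identical(dim(valid_mask), dim(units)[1:2]))
    stop("valid_mask must be a T x J logical matrix")
  structure(list(units = units, valid_mask = valid_mask),
            class = "orientation_flow")
}

#' Reference pose of a sequence
#'
#' The temporal mean pose: a more stable comparison target than any single
#' (noisy) frame.
#'
#' @param seq a [pose_sequence].
#' @return A `J x 3` matrix, the elementwise mean over frames.
#' @export
reference_pose <- function(seq) {
  co <- seq$coords
  apply(co, c(2, 3), mean)
}

#' Reference pose flow (RPF)
#'
#' The displacement of every frame from the sequence's reference pose (its
#' temporal mean): `F_t = P_t - mean_t(P)`. By construction the flow sums to
#' zero over time for every joint and axis.
#'
#' @param seq a [pose_sequence].
#' @return A [pose_flow] of kind `"rpf"`, shape `T x J x 3`.
#' @export
compute_rpf <- function(seq) {
  co <- seq$coords
  TT <- dim(co)[1]
  ref <- reference_pose(seq)
  refarr <- aperm(array(ref, dim = c(dim(ref), TT)), c(3, 1, 2))
  pose_flow(co - refarr, kind = "rpf")
}

#' Consecutive pose flow (CPF)
#'
#' Frame-to-frame displacements `F_t = P_{t+1} - P_t`. The last row is
#' repeated so the flow keeps the sequence's frame count.
#'
#' @param seq a [pose_sequence] with at least 2 frames.
#' @return A [pose_flow] of kind `"cpf"`, shape `T x J x 3`.
#' @export
compute_cpf <- function(seq) {
  co <- seq$coords
  TT <- dim(co)[1]
  if (TT < 2L) stop("consecutive pose flow needs T >= 2 frames")
  d <- co[2:TT, , , drop = FALSE] - co[1:(TT - 1), , , drop = FALSE]
  pose_flow(d[c(seq_len(TT - 1L), TT - 1L), , , drop = FALSE], kind = "cpf")
}

#' Decouple a pose flow into magnitude and orientation
#'
#' Factorizes `F = M * O`: per entry, the magnitude is the Euclidean norm
#' `alpha = |F|` and the orientation is the unit vector `F / alpha`. Entries
#' with `alpha <= eps` have undefined orientation: they get a zero unit
#' vector and are marked invalid; the magnitude is kept as computed. The
#' `eps` guard keeps the factorization numerically differentiable away from
#' zero motion.
#'
#' @param flow a [pose_flow] (or bare `T x J x 3` array).
#' @param eps zero-motion threshold (default `1e-8` meters).
#' @return A list with components `magnitude` ([magnitude_flow]) and
#'   `orientation` ([orientation_flow]).
#' @export
decouple <- function(flow, eps = 1e-8) {
  v <- if (inherits(flow, "pose_flow")) flow$vectors else flow
  if (eps <= 0) stop("eps must be > 0")
  alpha <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = dim(v)[1])
  valid <- alpha > eps
  denom <- ifelse(valid, alpha, 1)
  units <- v / array(denom, dim = dim(v))
  units <- units * array(as.numeric(valid), dim = dim(v))
  list(magnitude = magnitude_flow(alpha),
       orientation = orientation_flow(units, valid))
}

#' Recompose a pose flow from magnitude and orientation
#'
#' The inverse of [decouple()] wherever the magnitude exceeds the zero-motion
#' threshold: `F = alpha * unit`, elementwise per frame and joint.
#'
#' @param m a [magnitude_flow].
#' @param o an [orientation_flow] of matching shape.
#' @param kind kind tag for the resulting [pose_flow].
#' @return A [pose_flow].
#' @export
recompose <- function(m, o, kind = "recomposed") {
  if (!identical(dim(m$alpha), dim(o$units)[1:2]))
    stop("shape error: magnitude and orientation disagree")
  pose_flow(o$units * array(m$alpha, dim = dim(o$units)), kind = kind)
}

#' Decoupled reference pose flow of a sequence
#'
#' The composite supervision signal: reference pose flow ([compute_rpf()])
#' factorized by [decouple()]. This is the ground-truth pair the decoupled
#' flow networks reconstruct.
#'
#' @param seq a [pose_sequence].
#' @param eps zero-motion threshold.
#' @return A list with `magnitude` and `orientation` components.
#' @export
pdf_of_sequence <- function(seq, eps = 1e-8) {
  decouple(compute_rpf(seq), eps = eps)
}
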