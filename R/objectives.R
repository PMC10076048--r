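# Loss functions for the four model variants, plus the adaptive
# homoscedastic-uncertainty combination that replaces hand-tuned term
# weights.
#
# Convention: "MSE" is the mean of squared element differences (not the sum,
# not the root), so reported losses are comparable across batch sizes and
# sequence lengths.

#' Fixed loss-term weights
#'
#' @param w1,w2,w3,w4 nonnegative weights for the magnitude, orientation, and
#'   constraint terms (defaults all 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w1 = 1, w2 = 1, w3 = 1, w4 = 1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Learnable uncertainty parameters
#'
#' One log-variance per weighted loss term: `s_k = log(delta_k^2)`, the
#' unconstrained parameterization of the per-task homoscedastic uncertainty
#' `delta_k`. Learned jointly with the network weights in adaptive mode.
#'
#' @param s numeric vector of log-variances (default `c(0, 0)`, i.e.
#'   `delta = 1`).
#' @return An object of class `uncertainty_params`.
#' @export
uncertainty_params <- function(s = c(0, 0)) {
  if (!is.numeric(s) || any(!is.finite(s))) stop("s must be finite numeric")
  structure(list(s = as.numeric(s)), class = "uncertainty_params")
}

#' Loss breakdown
#'
#' Bundles the raw per-term losses with the weights used and the combined
#' total; the total always equals the weighted sum of the terms.
#'
#' @param terms named numeric vector of raw (unweighted) term values.
#' @param weights named numeric vector of the weights applied, same names.
#' @param total combined scalar; defaults to `sum(weights * terms)`.
#' @param s optional uncertainty log-variances used (adaptive mode).
#' @return An object of class `loss_breakdown`.
#' @export
loss_breakdown <- function(terms, weights = NULL, total = NULL, s = NULL) {
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(terms)),
                                                   names(terms))
  if (is.null(total)) total <- sum(weights * terms)
  structure(list(total = total, terms = terms, weights = weights, s = s),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown total=%.6g | %s>\n", x$total,
              paste(sprintf("%s=%.6g", names(x$terms), x$terms),
                    collapse = ", ")))
  invisible(x)
}

#' Mean squared error
#'
#' @param a,b numeric arrays of identical shape.
#' @return Mean over all elements of the squared differences.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("shape error: mse inputs differ in shape")
  mean((a - b)^2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pose / flow reconstruction losses
#'
#' MSE between a target and its reconstruction, on flattened arrays. For the
#' baseline autoencoder the total loss is the mean of its two decoders' pose
#' losses.
#'
#' @param P,P_hat pose arrays (or [pose_sequence] objects) of equal shape.
#' @return MSE scalar.
#' @export
loss_pose <- function(P, P_hat) {
  a <- if (inherits(P, "pose_sequence")) P$coords else P
  b <- if (inherits(P_hat, "pose_sequence")) P_hat$coords else P_hat
  mse(a, b)
}

#' @rdname loss_pose
#' @param F_,F_hat flow arrays (or [pose_flow] objects) of equal shape.
#' @export
loss_flow <- function(F_, F_hat) {
  a <- if (inherits(F_, "pose_flow")) F_$vectors else F_
  b <- if (inherits(F_hat, "pose_flow")) F_hat$vectors else F_hat
  mse(a, b)
}

#' Normalized cosine distance between orientation fields
#'
#' Per entry `(1 - dot(o, o_hat)) / 2`, averaged over the entries where the
#' *target* orientation is valid (nonzero motion); undefined-orientation
#' entries of the target are excluded. Since both fields are unit vectors
#' where valid, the result lies in `[0, 1]`: 0 for parallel, 1/2 for
#' orthogonal, 1 for antiparallel fields.
#'
#' @param o target [orientation_flow] (its `valid_mask` selects the entries).
#' @param o_hat predicted [orientation_flow].
#' @return Scalar in `[0, 1]`.
#' @export
orientation_distance <- function(o, o_hat) {
  if (!identical(dim(o$units), dim(o_hat$units)))
    stop("shape error: orientation fields differ in shape")
  valid <- o$valid_mask
  if (!any(valid)) stop("undefined loss: target has no valid orientation entries")
  dots <- apply(o$units * o_hat$units, seq_len(length(dim(o$units)) - 1L), sum)
  mean(((1 - dots) / 2)[valid])
}

#' Explicit-network loss
#'
#' `w1 * MSE(M, M_hat) + w2 * cosine-distance(O, O_hat)`: magnitude
#' reconstruction plus normalized orientation cosine distance.
#'
#' @param M,O target [magnitude_flow] / [orientation_flow].
#' @param M_hat,O_hat predictions of the same shapes.
#' @param w a [loss_weights] (only `w1`, `w2` used).
#' @return A [loss_breakdown] with terms `magnitude`, `orientation`.
#' @export
loss_explicit <- function(M, O, M_hat, O_hat, w = loss_weights()) {
  terms <- c(magnitude = mse(M$alpha, M_hat$alpha),
             orientation = orientation_distance(O, O_hat))
  loss_breakdown(terms, c(magnitude = w$w1, orientation = w$w2))
}

#' Implicit-network loss
#'
#' Explicit-style flow terms on the derived flows, plus the decoder-agreement
#' constraint `w3 * MSE(P_M_hat, P_O_hat)` that drives the two generated
#' pose-like variables together.
#'
#' @param M,O target flows; `M_hat_M`, `O_hat_O` flows derived from the two
#'   decoder outputs.
#' @param P_hat_M,P_hat_O the decoders' pose-like outputs.
#' @param w a [loss_weights] (`w1`, `w2`, `w3` used).
#' @return A [loss_breakdown] with terms `magnitude`, `orientation`,
#'   `constraint`.
#' @export
loss_implicit <- function(M, O, M_hat_M, O_hat_O, P_hat_M, P_hat_O,
                          w = loss_weights()) {
  terms <- c(magnitude = mse(M$alpha, M_hat_M$alpha),
             orientation = orientation_distance(O, O_hat_O),
             constraint = mse(P_hat_M, P_hat_O))
  loss_breakdown(terms, c(magnitude = w$w1, orientation = w$w2,
                          constraint = w$w3))
}

#' Generalized-network loss
#'
#' As the implicit loss, but each decoder output is constrained to
#' reconstruct the original pose sequence:
#' `w3 * MSE(P_M_hat, P) + w4 * MSE(P_O_hat, P)`, adding shape information to
#' the motion supervision.
#'
#' @inheritParams loss_implicit
#' @param P the original (normalized) pose array.
#' @return A [loss_breakdown] with terms `magnitude`, `orientation`,
#'   `pose_M`, `pose_O`.
#' @export
loss_generalized <- function(M, O, M_hat_M, O_hat_O, P_hat_M, P_hat_O, P,
                             w = loss_weights()) {
  terms <- c(magnitude = mse(M$alpha, M_hat_M$alpha),
             orientation = orientation_distance(O, O_hat_O),
             pose_M = mse(P_hat_M, P),
             pose_O = mse(P_hat_O, P))
  loss_breakdown(terms, c(magnitude = w$w1, orientation = w$w2,
                          pose_M = w$w3, pose_O = w$w4))
}

#' Adaptive multi-task combination with homoscedastic uncertainty
#'
#' Combines raw term losses as
#' `sum_k [ exp(-s_k) * L_k / 2 + s_k / 2 ]` with `s_k = log(delta_k^2)`.
#' Substituting recovers `sum_k L_k / (2 delta_k^2) + log(prod_k delta_k)`:
#' the negative Gaussian log-likelihood with per-task homoscedastic
#' uncertainty, whose minimization learns the relative task weights instead
#' of hand-tuning them. For fixed `L_k > 0` the optimum satisfies
#' `exp(s_k) = L_k`.
#'
#' @param term_values named numeric vector of raw term losses.
#' @param u an [uncertainty_params] with one `s` entry per term.
#' @return Combined scalar loss.
#' @export
adaptive_combine <- function(term_values, u) {
  s <- u$s
  if (length(s) != length(term_values))
    stop("config error: need one uncertainty parameter per loss term")
  sum(0.5 * exp(-s) * term_values + 0.5 * s)
}
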