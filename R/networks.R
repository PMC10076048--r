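# Encoder / dual-decoder models. One shared LSTM encoder compresses a
# normalized pose sequence (frames flattened to T x 3J) into a fixed-length
# latent code Z (the action representation); two decoders tile Z over time,
# run it through an LSTM, and map each step through a linear layer.
#
# Variants:
#   baseline - both decoders reconstruct the pose sequence itself
#   pdf_e    - decoders emit the magnitude field and the orientation field
#              of the reference pose flow directly (explicit)
#   pdf_i    - decoders emit pose-like variables; flows are derived from them
#              by reference-flow decoupling, with a decoder-agreement
#              constraint (implicit)
#   pdf_g    - as pdf_i, but the constraint is reconstruction of the original
#              pose sequence (generalized: motion + shape)

#' Build an encoder/dual-decoder model
#'
#' @param variant one of `"baseline"`, `"pdf_e"`, `"pdf_i"`, `"pdf_g"`.
#' @param J number of joints (default 25).
#' @param T_frames fixed sequence length after normalization (default 50).
#' @param hidden_dim latent code length C (default 256).
#' @param num_layers encoder LSTM layers, 1 (default) or 2 (enhanced).
#' @param seed integer seed for weight initialization.
#' @param eps zero-motion threshold used when flows are derived inside the
#'   model.
#' @param magnitude_activation for `pdf_e` only: `"identity"` (default)
#'   leaves the magnitude head unconstrained; `"softplus"` forces positive
#'   magnitudes.
#' @return An object of class `pdf_model` with fields `variant`, `spec`, and
#'   `params` (a flat named list of weight arrays).
#' @export
build_model <- function(variant = c("baseline", "pdf_e", "pdf_i", "pdf_g"),
                        J = 25L, T_frames = 50L, hidden_dim = 256L,
                        num_layers = 1L, seed = 0L, eps = 1e-8,
                        magnitude_activation = c("identity", "softplus")) {
  variant <- match.arg(variant)
  magnitude_activation <- match.arg(magnitude_activation)
  if (!num_layers %in% c(1L, 2L)) stop("num_layers must be 1 or 2")
  if (hidden_dim < 1L) stop("hidden_dim must be >= 1")
  D <- as.integer(J) * 3L
  out_M <- if (variant == "pdf_e") as.integer(J) else D
  out_O <- D
  params <- withr_seed(seed, {
    p <- list()
    enc1 <- lstm_init(D, hidden_dim)
    p$enc1_W <- enc1$W; p$enc1_U <- enc1$U; p$enc1_b <- enc1$b
    if (num_layers == 2L) {
      enc2 <- lstm_init(hidden_dim, hidden_dim)
      p$enc2_W <- enc2$W; p$enc2_U <- enc2$U; p$enc2_b <- enc2$b
    }
    dM <- lstm_init(hidden_dim, hidden_dim)
    p$dM_W <- dM$W; p$dM_U <- dM$U; p$dM_b <- dM$b
    fM <- linear_init(hidden_dim, out_M)
    p$dM_fcW <- fM$W; p$dM_fcb <- fM$b
    dO <- lstm_init(hidden_dim, hidden_dim)
    p$dO_W <- dO$W; p$dO_U <- dO$U; p$dO_b <- dO$b
    fO <- linear_init(hidden_dim, out_O)
    p$dO_fcW <- fO$W; p$dO_fcb <- fO$b
    p
  })
  structure(list(
    variant = variant,
    spec = list(J = as.integer(J), T_frames = as.integer(T_frames),
                input_dim = D, hidden_dim = as.integer(hidden_dim),
                num_layers = as.integer(num_layers), out_M = out_M,
                out_O = out_O, eps = eps,
                magnitude_activation = magnitude_activation),
    params = params,
    seed = as.integer(seed)
  ), class = "pdf_model")
}

# evaluate expr with a locally-seeded RNG, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.pdf_model <- function(x, ...) {
  cat(sprintf("<pdf_model %s: J=%d, T=%d, C=%d, %d encoder layer(s), %d parameters>\n",
              x$variant, x$spec$J, x$spec$T_frames, x$spec$hidden_dim,
              x$spec$num_layers, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] object.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- input coercion -------------------------------------------------------

# Flatten pose coordinates to the per-frame vector the encoder consumes:
# T x (3J), joint index varying fastest within each axis block.
flatten_frames <- function(coords) {
  d <- dim(coords)
  matrix(coords, nrow = d[1], ncol = d[2] * 3L)
}

unflatten_frames <- function(mat, J) {
  array(mat, dim = c(nrow(mat), J, 3L))
}

# Accepts a pose_sequence, a T x D matrix, a B x T x D array, a list of
# pose_sequences, or a dataset_handle; returns a B x T x D array plus whether
# the input was a single sequence.
as_input_batch <- function(x, model) {
  D <- model$spec$input_dim
  TT <- model$spec$T_frames
  single <- FALSE
  if (inherits(x, "dataset_handle")) x <- x$sequences
  if (inherits(x, "pose_sequence")) {
    x <- list(x); single <- TRUE
  }
  if (is.list(x)) {
    mats <- lapply(x, function(s) flatten_frames(s$coords))
    X <- array(0, dim = c(length(mats), TT, D))
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      if (!identical(dim(m), c(TT, as.integer(D))))
        stop(sprintf("shape error: sequence %d is %dx%d, model expects %dx%d (normalize first)",
                     i, nrow(m), ncol(m), TT, D))
      X[i, , ] <- m
    }
    return(list(X = X, single = single))
  }
  if (is.matrix(x)) {
    if (!identical(dim(x), c(TT, as.integer(D))))
      stop(sprintf("shape error: input is %dx%d, model expects %dx%d",
                   nrow(x), ncol(x), TT, D))
    X <- array(0, dim = c(1L, TT, D))
    X[1, , ] <- x
    return(list(X = X, single = TRUE))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != TT || dim(x)[3] != D)
      stop(sprintf("shape error: batch is %dx%dx%d, model expects BxTxD = ?x%dx%d",
                   dim(x)[1], dim(x)[2], dim(x)[3], TT, D))
    return(list(X = x, single = FALSE))
  }
  stop("unsupported input type for model forward")
}

# ---- forward passes -------------------------------------------------------

enc_params <- function(model, layer) {
  pre <- paste0("enc", layer, "_")
  list(W = model$params[[paste0(pre, "W")]],
       U = model$params[[paste0(pre, "U")]],
       b = model$params[[paste0(pre, "b")]])
}

dec_params <- function(model, which) {
  pre <- paste0("d", which, "_")
  list(lstm = list(W = model$params[[paste0(pre, "W")]],
                   U = model$params[[paste0(pre, "U")]],
                   b = model$params[[paste0(pre, "b")]]),
       fcW = model$params[[paste0(pre, "fcW")]],
       fcb = model$params[[paste0(pre, "fcb")]])
}

encoder_forward <- function(model, X) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  Xm <- stack_bt(X)
  f1 <- lstm_forward(enc_params(model, 1L), Xm, B, TT)
  last <- t_rows(TT, B)
  if (model$spec$num_layers == 2L) {
    f2 <- lstm_forward(enc_params(model, 2L), f1$H, B, TT)
    list(z = f2$H[last, , drop = FALSE], Xm = Xm, f1 = f1, f2 = f2)
  } else {
    list(z = f1$H[last, , drop = FALSE], Xm = Xm, f1 = f1, f2 = NULL)
  }
}

# tile the latent code at every decoder time step (stacked layout)
tile_latent <- function(z, TT) {
  z[rep(seq_len(nrow(z)), TT), , drop = FALSE]
}

decoder_forward <- function(model, which, z) {
  TT <- model$spec$T_frames
  B <- nrow(z)
  dp <- dec_params(model, which)
  Xdm <- tile_latent(z, TT)
  fw <- lstm_forward(dp$lstm, Xdm, B, TT)
  Ym <- fw$H %*% dp$fcW + matrix(dp$fcb, B * TT, ncol(dp$fcW), byrow = TRUE)
  list(Y = unstack_bt(Ym, B, TT), Xdm = Xdm, fw = fw)
}

# Raw forward through encoder and both decoders, keeping every cache needed
# for the backward pass.
model_forward_raw <- function(model, X) {
  enc <- encoder_forward(model, X)
  dM <- decoder_forward(model, "M", enc$z)
  dO <- decoder_forward(model, "O", enc$z)
  list(z = enc$z, enc = enc, dM = dM, dO = dO)
}

#' Encode sequences to latent action representations
#'
#' Runs the encoder and returns its final-step hidden output: the fixed
#' length latent code Z used as the action representation. Deterministic
#' given weights and input.
#'
#' @param model a [build_model()] object.
#' @param x a normalized [pose_sequence], a `T x 3J` matrix, a `B x T x 3J`
#'   array, a list of sequences, or a [dataset_handle].
#' @return A length-C vector for a single sequence, otherwise a `B x C`
#'   matrix.
#' @export
encode <- function(model, x) {
  inp <- as_input_batch(x, model)
  z <- encoder_forward(model, inp$X)$z
  if (inp$single) drop(z) else z
}

#' Decode a latent code through one decoder
#'
#' The code is tiled to every time step, run through the decoder LSTM, and
#' mapped per frame by the linear output layer.
#'
#' @param model a [build_model()] object.
#' @param z a length-C vector or `B x C` matrix of latent codes.
#' @param which `"M"` or `"O"`: which decoder head to use.
#' @return A `T x output_dim` matrix (or `B x T x output_dim` array for a
#'   batch of codes) of raw decoder outputs.
#' @export
decode <- function(model, z, which = c("M", "O")) {
  which <- match.arg(which)
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$spec$hidden_dim)
    stop(sprintf("shape error: code length %d, model expects %d",
                 ncol(z), model$spec$hidden_dim))
  Y <- decoder_forward(model, which, z)$Y
  if (single) matrix(Y[1, , ], nrow = dim(Y)[2]) else Y
}

softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# magnitude head activation and its derivative
mag_activate <- function(model, raw) {
  if (model$spec$magnitude_activation == "softplus") softplus(raw) else raw
}
mag_activate_grad <- function(model, raw) {
  if (model$spec$magnitude_activation == "softplus") sigmoid(raw) else raw * 0 + 1
}

# normalize raw decoder vectors (B,T,J,3) to unit length, eps-guarded
unitize4 <- function(V, eps) {
  n <- batch_alpha4(V)
  m <- pmax(n, eps)
  U <- V / array(m, dim = dim(V))
  list(U = U, n = n, m = m)
}

#' Baseline forward pass: dual pose reconstruction
#'
#' Both decoders emit `T x 3J` pose reconstructions from the shared latent
#' code.
#'
#' @param model a `pdf_model` with `variant == "baseline"`.
#' @param x model input (see [encode()]).
#' @return For a single sequence, a list with `P_a` and `P_b` (`T x 3J`
#'   matrices); for a batch, `B x T x 3J` arrays.
#' @export
forward_baseline <- function(model, x) {
  if (model$variant != "baseline")
    stop("usage error: forward_baseline needs a baseline-variant model")
  inp <- as_input_batch(x, model)
  fwd <- model_forward_raw(model, inp$X)
  if (inp$single) {
    TT <- model$spec$T_frames
    list(P_a = matrix(fwd$dM$Y[1, , ], nrow = TT),
         P_b = matrix(fwd$dO$Y[1, , ], nrow = TT))
  } else {
    list(P_a = fwd$dM$Y, P_b = fwd$dO$Y)
  }
}

#' Explicit forward pass: direct magnitude and orientation reconstruction
#'
#' The magnitude decoder emits a `T x J` field of (unconstrained, or softplus
#' positive) magnitudes; the orientation decoder emits `T x J` 3-vectors that
#' are normalized to unit length (eps-guarded), so every output entry is a
#' valid orientation.
#'
#' @param model a `pdf_model` with `variant == "pdf_e"`.
#' @param x model input (see [encode()]).
#' @return For a single sequence, a list with `magnitude`
#'   ([magnitude_flow]-like: field `alpha`, possibly negative when the head is
#'   unconstrained) and `orientation` (an [orientation_flow] with all-true
#'   mask). For a batch, raw arrays `alpha` (`B x T x J`) and `units`
#'   (`B x T x J x 3`).
#' @export
forward_explicit <- function(model, x) {
  if (model$variant != "pdf_e")
    stop("usage error: forward_explicit needs a pdf_e-variant model")
  inp <- as_input_batch(x, model)
  fwd <- model_forward_raw(model, inp$X)
  J <- model$spec$J; TT <- model$spec$T_frames
  B <- dim(inp$X)[1]
  alpha <- array(mag_activate(model, fwd$dM$Y), dim = c(B, TT, J))
  V <- array(fwd$dO$Y, dim = c(B, TT, J, 3L))
  un <- unitize4(V, model$spec$eps)
  if (inp$single) {
    list(magnitude = structure(list(alpha = matrix(alpha[1, , ], nrow = TT)),
                               class = "magnitude_flow"),
         orientation = orientation_flow(array(un$U[1, , , ], dim = c(TT, J, 3L)),
                                        matrix(TRUE, TT, J)))
  } else {
    list(alpha = alpha, units = un$U)
  }
}

#' Implicit / generalized forward pass
#'
#' Both decoders emit pose-like `T x 3J` variables. The magnitude field is
#' derived from the first decoder's output and the orientation field from the
#' second's, in each case by reference-flow decoupling of the emitted
#' sequence. The derivation is part of the computation graph: training
#' differentiates through it.
#'
#' @param model a `pdf_model` with `variant` `"pdf_i"` or `"pdf_g"`.
#' @param x model input (see [encode()]).
#' @return For a single sequence, a list with `P_M`, `P_O` (`T x 3J`
#'   matrices), `magnitude` ([magnitude_flow]) and `orientation`
#'   ([orientation_flow]). For a batch, arrays `P_M`, `P_O`, `alpha`,
#'   `units`, `valid_mask`.
#' @export
forward_implicit <- function(model, x) {
  if (!model$variant %in% c("pdf_i", "pdf_g"))
    stop("usage error: forward_implicit needs a pdf_i or pdf_g model")
  inp <- as_input_batch(x, model)
  fwd <- model_forward_raw(model, inp$X)
  J <- model$spec$J; TT <- model$spec$T_frames
  B <- dim(inp$X)[1]
  PM <- array(fwd$dM$Y, dim = c(B, TT, J, 3L))
  PO <- array(fwd$dO$Y, dim = c(B, TT, J, 3L))
  FM <- batch_rpf4(PM)
  FO <- batch_rpf4(PO)
  alpha <- batch_alpha4(FM)
  dec <- batch_unit4(FO, model$spec$eps)
  if (inp$single) {
    list(P_M = matrix(fwd$dM$Y[1, , ], nrow = TT),
         P_O = matrix(fwd$dO$Y[1, , ], nrow = TT),
         magnitude = magnitude_flow(matrix(alpha[1, , ], nrow = TT)),
         orientation = orientation_flow(array(dec$U[1, , , ], dim = c(TT, J, 3L)),
                                        matrix(dec$valid[1, , ], nrow = TT)))
  } else {
    list(P_M = fwd$dM$Y, P_O = fwd$dO$Y, alpha = alpha, units = dec$U,
         valid_mask = dec$valid)
  }
}

# ---- batched flow helpers (B x T x J x 3) ---------------------------------

# reference pose flow of a batch of pose arrays: subtract the temporal mean
batch_rpf4 <- function(P) {
  d <- dim(P)
  M <- colMeans(aperm(P, c(2, 1, 3, 4)))           # B x J x 3
  P - aperm(array(M, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

batch_alpha4 <- function(F4) {
  d <- dim(F4)
  a <- sqrt(F4[, , , 1, drop = FALSE]^2 + F4[, , , 2, drop = FALSE]^2 +
              F4[, , , 3, drop = FALSE]^2)
  array(a, dim = d[1:3])
}

batch_unit4 <- function(F4, eps) {
  alpha <- batch_alpha4(F4)
  valid <- alpha > eps
  denom <- ifelse(valid, alpha, 1)
  U <- F4 / array(denom, dim = dim(F4))
  U <- U * array(as.numeric(valid), dim = dim(F4))
  list(U = U, alpha = alpha, valid = valid)
}
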