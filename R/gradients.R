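# Analytic gradients: loss-side gradients with respect to the raw decoder
# outputs for every variant, chained through the decoders and encoder by
# exact BPTT. These power training; finite-difference checks in the test
# suite pin them down.

# Supervision targets for a flattened batch X (B x T x 3J): the original
# poses plus the decoupled reference pose flow fields.
variant_targets <- function(X, J, eps = 1e-8) {
  d <- dim(X)
  P4 <- array(X, dim = c(d[1], d[2], J, 3L))
  F4 <- batch_rpf4(P4)
  dec <- batch_unit4(F4, eps)
  list(P = X, alpha = dec$alpha, units = dec$U, mask = dec$valid)
}

# Gradient of the masked orientation cosine distance w.r.t. the flow field
# F4 from which the predicted unit vectors were derived.
#   loss contribution: sum over target-valid entries of (1 - <o, u>)/2 / Nv
# u = F/|F| where |F| > eps, else 0 (zero-gradient there).
orientation_grad_wrt_flow <- function(F4, pred, t_units, t_mask, coef) {
  nv <- sum(t_mask)
  mask4 <- array(as.numeric(t_mask), dim = dim(F4))
  dU <- -coef * t_units * mask4 / (2 * nv)
  U <- pred$U
  UdU <- U[, , , 1, drop = FALSE] * dU[, , , 1, drop = FALSE] +
    U[, , , 2, drop = FALSE] * dU[, , , 2, drop = FALSE] +
    U[, , , 3, drop = FALSE] * dU[, , , 3, drop = FALSE]
  UdU <- array(UdU, dim = dim(F4)[1:3])
  inv <- ifelse(pred$valid, 1 / pred$alpha, 0)
  inv4 <- array(inv, dim = dim(F4))
  (dU - U * array(UdU, dim = dim(F4))) * inv4
}

# orientation loss value (batched arrays, masked by target validity)
orientation_loss_value <- function(pred_U, t_units, t_mask) {
  nv <- sum(t_mask)
  if (nv == 0) stop("undefined loss: target has no valid orientation entries")
  dots <- pred_U[, , , 1, drop = FALSE] * t_units[, , , 1, drop = FALSE] +
    pred_U[, , , 2, drop = FALSE] * t_units[, , , 2, drop = FALSE] +
    pred_U[, , , 3, drop = FALSE] * t_units[, , , 3, drop = FALSE]
  dots <- array(dots, dim = dim(pred_U)[1:3])
  sum(((1 - dots) / 2)[t_mask]) / nv
}

# Per-variant loss and its gradient w.r.t. the two raw decoder outputs.
# `coef` are the multipliers actually applied to each raw term (fixed
# weights, or 0.5 * exp(-s) in adaptive mode).
loss_and_output_grads <- function(model, X, fwd, targets, coef) {
  variant <- model$variant
  eps <- model$spec$eps
  J <- model$spec$J
  d <- dim(X)
  YM <- fwd$dM$Y; YO <- fwd$dO$Y
  if (variant == "baseline") {
    N <- length(YM)
    terms <- c(pose_M = mean((YM - X)^2), pose_O = mean((YO - X)^2))
    dYM <- coef[["pose_M"]] * 2 * (YM - X) / N
    dYO <- coef[["pose_O"]] * 2 * (YO - X) / N
    return(list(terms = terms, dYM = dYM, dYO = dYO))
  }
  if (variant == "pdf_e") {
    alpha_hat <- mag_activate(model, YM)
    N <- length(alpha_hat)
    L_mag <- mean((alpha_hat - targets$alpha)^2)
    dYM <- coef[["magnitude"]] * 2 * (alpha_hat - targets$alpha) / N *
      mag_activate_grad(model, YM)
    V <- array(YO, dim = c(d[1], d[2], J, 3L))
    un <- unitize4(V, eps)
    L_ori <- orientation_loss_value(un$U, targets$units, targets$mask)
    # d(units)/d(raw): projector through the eps-guarded normalization
    nv <- sum(targets$mask)
    mask4 <- array(as.numeric(targets$mask), dim = dim(V))
    dU <- -coef[["orientation"]] * targets$units * mask4 / (2 * nv)
    UdU <- array(un$U[, , , 1, drop = FALSE] * dU[, , , 1, drop = FALSE] +
                   un$U[, , , 2, drop = FALSE] * dU[, , , 2, drop = FALSE] +
                   un$U[, , , 3, drop = FALSE] * dU[, , , 3, drop = FALSE],
                 dim = dim(V)[1:3])
    guarded <- un$n > eps
    inv <- ifelse(guarded, 1 / un$m, 1 / eps)
    dV <- (dU - un$U * array(UdU * as.numeric(guarded), dim = dim(V))) *
      array(inv, dim = dim(V))
    return(list(terms = c(magnitude = L_mag, orientation = L_ori),
                dYM = dYM, dYO = array(dV, dim = d)))
  }
  # pdf_i / pdf_g: flows derived from pose-like decoder outputs
  PM4 <- array(YM, dim = c(d[1], d[2], J, 3L))
  PO4 <- array(YO, dim = c(d[1], d[2], J, 3L))
  FM <- batch_rpf4(PM4)
  FO <- batch_rpf4(PO4)
  predM <- batch_unit4(FM, eps)
  predO <- batch_unit4(FO, eps)
  N <- length(predM$alpha)
  L_mag <- mean((predM$alpha - targets$alpha)^2)
  dalpha <- coef[["magnitude"]] * 2 * (predM$alpha - targets$alpha) / N
  dFM <- predM$U * array(dalpha, dim = dim(FM))  # zero where alpha <= eps
  dYM <- array(batch_rpf4(dFM), dim = d)         # projector is self-adjoint
  L_ori <- orientation_loss_value(predO$U, targets$units, targets$mask)
  dFO <- orientation_grad_wrt_flow(FO, predO, targets$units, targets$mask,
                                   coef[["orientation"]])
  dYO <- array(batch_rpf4(dFO), dim = d)
  if (variant == "pdf_i") {
    Nc <- length(YM)
    L_con <- mean((YM - YO)^2)
    dcon <- 2 * (YM - YO) / Nc
    dYM <- dYM + coef[["constraint"]] * dcon
    dYO <- dYO - coef[["constraint"]] * dcon
    terms <- c(magnitude = L_mag, orientation = L_ori, constraint = L_con)
  } else {
    Nc <- length(YM)
    L_pm <- mean((YM - X)^2)
    L_po <- mean((YO - X)^2)
    dYM <- dYM + coef[["pose_M"]] * 2 * (YM - X) / Nc
    dYO <- dYO + coef[["pose_O"]] * 2 * (YO - X) / Nc
    terms <- c(magnitude = L_mag, orientation = L_ori,
               pose_M = L_pm, pose_O = L_po)
  }
  list(terms = terms, dYM = dYM, dYO = dYO)
}

# names and count of weighted terms per variant
variant_term_names <- function(variant) {
  switch(variant,
         baseline = c("pose_M", "pose_O"),
         pdf_e = c("magnitude", "orientation"),
         pdf_i = c("magnitude", "orientation", "constraint"),
         pdf_g = c("magnitude", "orientation", "pose_M", "pose_O"))
}

# fixed-weight coefficients for a variant (baseline averages its 2 decoders)
variant_fixed_coefs <- function(variant, w) {
  switch(variant,
         baseline = c(pose_M = 0.5, pose_O = 0.5),
         pdf_e = c(magnitude = w$w1, orientation = w$w2),
         pdf_i = c(magnitude = w$w1, orientation = w$w2, constraint = w$w3),
         pdf_g = c(magnitude = w$w1, orientation = w$w2, pose_M = w$w3,
                   pose_O = w$w4))
}

# Backpropagate output gradients through both decoders and the encoder.
model_backward <- function(model, X, fwd, dYM, dYO) {
  TT <- model$spec$T_frames
  B <- dim(X)[1]
  grads <- lapply(model$params, function(p) p * 0)
  dz <- matrix(0, B, model$spec$hidden_dim)
  bgroup <- rep(seq_len(B), TT)
  for (which in c("M", "O")) {
    pre <- paste0("d", which, "_")
    dp <- dec_params(model, which)
    dec <- if (which == "M") fwd$dM else fwd$dO
    dYm <- stack_bt(if (which == "M") dYM else dYO)
    dHm <- dYm %*% t(dp$fcW)
    bk <- lstm_backward(dp$lstm, dec$Xdm, dec$fw, dHm)
    grads[[paste0(pre, "W")]] <- bk$dW
    grads[[paste0(pre, "U")]] <- bk$dU
    grads[[paste0(pre, "b")]] <- bk$db
    grads[[paste0(pre, "fcW")]] <- crossprod(dec$fw$H, dYm)
    grads[[paste0(pre, "fcb")]] <- colSums(dYm)
    # the latent code feeds every decoder time step
    dz <- dz + rowsum(bk$dX, bgroup, reorder = TRUE)
  }
  # encoder: gradient enters only at the final hidden output of the top layer
  last <- t_rows(TT, B)
  if (model$spec$num_layers == 2L) {
    dH2 <- matrix(0, B * TT, model$spec$hidden_dim)
    dH2[last, ] <- dz
    bk2 <- lstm_backward(enc_params(model, 2L), fwd$enc$f1$H, fwd$enc$f2, dH2)
    grads$enc2_W <- bk2$dW; grads$enc2_U <- bk2$dU; grads$enc2_b <- bk2$db
    bk1 <- lstm_backward(enc_params(model, 1L), fwd$enc$Xm, fwd$enc$f1,
                         bk2$dX)
  } else {
    dH1 <- matrix(0, B * TT, model$spec$hidden_dim)
    dH1[last, ] <- dz
    bk1 <- lstm_backward(enc_params(model, 1L), fwd$enc$Xm, fwd$enc$f1, dH1)
  }
  grads$enc1_W <- bk1$dW; grads$enc1_U <- bk1$dU; grads$enc1_b <- bk1$db
  grads
}

# Full training-objective evaluation: loss breakdown, parameter gradients,
# and (adaptive mode) gradients of the uncertainty log-variances.
model_loss_and_grads <- function(model, X, targets, w = loss_weights(),
                                 adaptive = FALSE, s = NULL) {
  fwd <- model_forward_raw(model, X)
  tn <- variant_term_names(model$variant)
  if (adaptive) {
    if (is.null(s) || length(s) != length(tn))
      stop("config error: adaptive mode needs one s per loss term")
    coef <- stats::setNames(0.5 * exp(-s), tn)
  } else {
    coef <- variant_fixed_coefs(model$variant, w)
  }
  lo <- loss_and_output_grads(model, X, fwd, targets, coef)
  grads <- model_backward(model, X, fwd, lo$dYM, lo$dYO)
  if (adaptive) {
    total <- sum(coef * lo$terms) + 0.5 * sum(s)
    ds <- 0.5 * (1 - exp(-s) * lo$terms)
    breakdown <- loss_breakdown(lo$terms, weights = coef, total = total,
                                s = s)
    list(breakdown = breakdown, grads = grads, ds = as.numeric(ds))
  } else {
    breakdown <- loss_breakdown(lo$terms, weights = coef)
    list(breakdown = breakdown, grads = grads, ds = NULL)
  }
}
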