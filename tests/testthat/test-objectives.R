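unit_field <- function(vecs) {
  # vecs: T x J x 3 of nonzero vectors -> normalized orientation_flow
  n <- sqrt(apply(vecs^2, c(1, 2), sum))
  orientation_flow(vecs / array(n, dim = dim(vecs)),
                   matrix(TRUE, dim(vecs)[1], dim(vecs)[2]))
}

test_that("mse is the mean of squared differences and symmetric", {
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(matrix(1:4, 2), matrix(1:4, 2)), 0)
  a <- matrix(rnorm(6), 2); b <- matrix(rnorm(6), 2)
  expect_equal(mse(a, b), mse(b, a))
  expect_equal(mse(a, b), mean((a - b)^2))
  expect_error(mse(a, c(1, 2)), "shape")
})

test_that("orientation distance hits 0, 1/2, 1 at the canonical fixtures", {
  ex <- array(0, dim = c(2, 2, 3)); ex[, , 1] <- 1     # all +x
  o <- unit_field(ex)
  expect_equal(orientation_distance(o, o), 0)
  anti <- unit_field(-ex)
  expect_equal(orientation_distance(o, anti), 1)
  ey <- array(0, dim = c(2, 2, 3)); ey[, , 2] <- 1     # all +y
  expect_equal(orientation_distance(o, unit_field(ey)), 0.5)
  # bounded in [0, 1] for random unit fields
  set.seed(3)
  for (i in 1:10) {
    a <- unit_field(array(rnorm(12), dim = c(2, 2, 3)))
    b <- unit_field(array(rnorm(12), dim = c(2, 2, 3)))
    d <- orientation_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("orientation distance masks invalid target entries", {
  ex <- array(0, dim = c(1, 2, 3)); ex[, , 1] <- 1
  o <- unit_field(ex)
  o$valid_mask[1, 2] <- FALSE
  o$units[1, 2, ] <- 0
  ohat <- unit_field(-ex)    # antiparallel on the valid entry
  expect_equal(orientation_distance(o, ohat), 1)   # only entry 1 counts
  o$valid_mask[] <- FALSE
  expect_error(orientation_distance(o, ohat), "undefined")
})

test_that("pose/flow losses are zero at truth with closed-form scaling error", {
  s <- random_sequence(6, 4, seed = 5)
  expect_equal(loss_pose(s, s), 0)
  c_ <- 1.7
  scaled <- s; scaled$coords <- c_ * s$coords
  expect_equal(loss_pose(scaled, s), (c_ - 1)^2 * mean(s$coords^2),
               tolerance = 1e-12)
  f <- compute_rpf(s)
  expect_equal(loss_flow(f, f), 0)
  # frame permutation applied to both inputs leaves the value unchanged
  perm <- c(3, 1, 2, 6, 5, 4)
  a <- s$coords; b <- s$coords * 1.1
  expect_equal(mse(a[perm, , ], b[perm, , ]), mse(a, b))
})

test_that("variant losses combine weighted terms as stated", {
  s <- random_sequence(5, 4, seed = 11)
  p <- pdf_of_sequence(s)
  # perfect reconstruction -> all zero
  lb <- loss_explicit(p$magnitude, p$orientation, p$magnitude, p$orientation)
  expect_equal(lb$total, 0)
  # synthetic term values: w1=w2=1, terms 0.4 and 0.2 -> total 0.6
  lb2 <- loss_breakdown(c(magnitude = 0.4, orientation = 0.2),
                        c(magnitude = 1, orientation = 1))
  expect_equal(lb2$total, 0.6)
  # w1 = 0 kills the magnitude term
  mhat <- magnitude_flow(p$magnitude$alpha + 0.3)
  lb3 <- loss_explicit(p$magnitude, p$orientation, mhat, p$orientation,
                       loss_weights(w1 = 0))
  expect_equal(lb3$total, 0)
  expect_gt(lb3$terms[["magnitude"]], 0)

  # implicit: equal decoder outputs zero the constraint
  P1 <- s$coords
  li <- loss_implicit(p$magnitude, p$orientation, p$magnitude, p$orientation,
                      P1, P1)
  expect_equal(li$total, 0)
  # w3 scales only the constraint contribution
  P2 <- P1 + 0.1
  li1 <- loss_implicit(p$magnitude, p$orientation, p$magnitude, p$orientation,
                       P1, P2, loss_weights(w3 = 1))
  li2 <- loss_implicit(p$magnitude, p$orientation, p$magnitude, p$orientation,
                       P1, P2, loss_weights(w3 = 2))
  expect_equal(li2$total, 2 * li1$total, tolerance = 1e-12)

  # generalized: all terms present, total is the weighted sum
  lg <- loss_generalized(p$magnitude, p$orientation, mhat, p$orientation,
                         P1, P2, P1, loss_weights(0.5, 2, 3, 4))
  expect_named(lg$terms, c("magnitude", "orientation", "pose_M", "pose_O"))
  expect_equal(lg$total, sum(lg$weights * lg$terms), tolerance = 1e-12)
  expect_equal(lg$total,
               0.5 * mse(p$magnitude$alpha, mhat$alpha) + 0 + 0 +
                 4 * mse(P2, P1), tolerance = 1e-12)
})

test_that("adaptive combination reproduces the uncertainty-weighted form", {
  # delta1 = delta2 = 1 (s = 0), losses (0.4, 0.2): 0.5*0.4 + 0.5*0.2 = 0.3
  u0 <- uncertainty_params(c(0, 0))
  expect_equal(adaptive_combine(c(0.4, 0.2), u0), 0.3)
  # zero losses leave only the log-variance penalty: sum(s)/2
  u <- uncertainty_params(c(0.8, -0.3))
  expect_equal(adaptive_combine(c(0, 0), u), 0.25)
  # with s frozen at 0 the combination is half the unweighted sum
  L <- c(0.11, 0.77, 0.35)
  expect_equal(adaptive_combine(L, uncertainty_params(c(0, 0, 0))),
               0.5 * sum(L))
  # general equivalence to the delta parameterization
  s <- c(0.4, -1.2)
  delta2 <- exp(s)
  expect_equal(adaptive_combine(c(0.4, 0.2), uncertainty_params(s)),
               0.4 / (2 * delta2[1]) + 0.2 / (2 * delta2[2]) +
                 log(sqrt(delta2[1]) * sqrt(delta2[2])), tolerance = 1e-12)
  # count mismatch is a config error
  expect_error(adaptive_combine(c(1, 2, 3), u0), "config error")
})

test_that("the optimal log-variance matches the stationarity condition", {
  # minimizing 0.5*exp(-s)*L + 0.5*s over s gives exp(s) = L
  for (L in c(0.05, 0.4, 2.3)) {
    f <- function(s) 0.5 * exp(-s) * L + 0.5 * s
    opt <- optimize(f, c(-10, 10))$minimum
    expect_equal(exp(opt), L, tolerance = 1e-4)
  }
})

test_that("analytic loss gradients match finite differences", {
  # per variant, gradient of the total loss w.r.t. the raw decoder outputs
  set.seed(21)
  J <- 2L; TT <- 3L; B <- 2L
  X <- array(rnorm(B * TT * J * 3), dim = c(B, TT, J * 3))
  tg <- skelflow:::variant_targets(X, J, 1e-8)
  for (variant in c("baseline", "pdf_e", "pdf_i", "pdf_g")) {
    m <- build_model(variant, J = J, T_frames = TT, hidden_dim = 4L,
                     seed = 3L)
    fwd <- skelflow:::model_forward_raw(m, X)
    coef <- skelflow:::variant_fixed_coefs(variant, loss_weights())
    lo <- skelflow:::loss_and_output_grads(m, X, fwd, tg, coef)
    total_at <- function(YM, YO) {
      fwd2 <- fwd
      fwd2$dM$Y <- YM; fwd2$dO$Y <- YO
      sum(coef * skelflow:::loss_and_output_grads(m, X, fwd2, tg, coef)$terms)
    }
    numM <- numeric_gradient(function(y) total_at(y, fwd$dO$Y), fwd$dM$Y)
    numO <- numeric_gradient(function(y) total_at(fwd$dM$Y, y), fwd$dO$Y)
    expect_lt(max(abs(numM - lo$dYM)), 1e-4)
    expect_lt(max(abs(numO - lo$dYO)), 1e-4)
  }
})
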