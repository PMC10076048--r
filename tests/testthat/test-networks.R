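# Small hidden sizes keep these structural checks fast; one shape check runs
# at the full default width.

norm_batch <- function(n = 3, seed = 0) {
  d <- small_norm_dataset(n_per_class = 1, seed = seed)
  d$train$sequences[seq_len(n)]
}

test_that("encoding yields the latent code with the configured width", {
  m <- build_model("baseline", J = 25, T_frames = 50, hidden_dim = 256,
                   seed = 0)
  s <- norm_batch(1)[[1]]
  z <- encode(m, s)
  expect_length(z, 256)
  expect_true(all(is.finite(z)))
  # determinism
  expect_identical(z, encode(m, s))
})

test_that("batched encoding equals one-at-a-time encoding", {
  m <- build_model("pdf_g", J = 25, T_frames = 50, hidden_dim = 32, seed = 1)
  seqs <- norm_batch(3)
  Z <- encode(m, seqs)
  expect_identical(dim(Z), c(3L, 32L))
  for (i in 1:3)
    expect_equal(Z[i, ], encode(m, seqs[[i]]), tolerance = 1e-6)
})

test_that("latent tiling repeats the code at every decoder step", {
  z <- matrix(rnorm(2 * 8), 2, 8)
  tiled <- skelflow:::tile_latent(z, 5)            # stacked (B*T) x C layout
  expect_identical(dim(tiled), c(10L, 8L))
  for (t in 1:5)
    expect_identical(tiled[skelflow:::t_rows(t, 2L), ], z)
})

test_that("decoding produces T x output_dim with the documented shapes", {
  m <- build_model("baseline", J = 25, T_frames = 50, hidden_dim = 256,
                   seed = 0)
  z <- rnorm(256)
  Y <- decode(m, z, "M")
  expect_identical(dim(Y), c(50L, 75L))
  expect_error(decode(m, rnorm(10), "M"), "shape")
})

test_that("baseline forward emits two pose reconstructions", {
  m <- build_model("baseline", J = 25, T_frames = 50, hidden_dim = 32,
                   seed = 2)
  s <- norm_batch(1)[[1]]
  out <- forward_baseline(m, s)
  expect_identical(dim(out$P_a), c(50L, 75L))
  expect_identical(dim(out$P_b), c(50L, 75L))
  # identical decoder weights force identical outputs
  m2 <- m
  for (suf in c("W", "U", "b", "fcW", "fcb"))
    m2$params[[paste0("dO_", suf)]] <- m2$params[[paste0("dM_", suf)]]
  out2 <- forward_baseline(m2, s)
  expect_identical(out2$P_a, out2$P_b)
  # variant guard
  expect_error(forward_explicit(m, s), "usage error")
})

test_that("explicit forward emits unit orientations and J-wide magnitudes", {
  m <- build_model("pdf_e", J = 25, T_frames = 50, hidden_dim = 32, seed = 3)
  s <- norm_batch(1)[[1]]
  out <- forward_explicit(m, s)
  expect_identical(dim(out$magnitude$alpha), c(50L, 25L))
  expect_identical(dim(out$orientation$units), c(50L, 25L, 3L))
  expect_true(all(out$orientation$valid_mask))
  norms <- sqrt(apply(out$orientation$units^2, c(1, 2), sum))
  expect_equal(as.numeric(norms), rep(1, length(norms)), tolerance = 1e-6)
})

test_that("implicit forward derives flows from its generated sequences", {
  m <- build_model("pdf_i", J = 25, T_frames = 50, hidden_dim = 32, seed = 4)
  s <- norm_batch(1)[[1]]
  out <- forward_implicit(m, s)
  expect_identical(dim(out$P_M), c(50L, 75L))
  expect_identical(dim(out$P_O), c(50L, 75L))
  # the derived magnitude equals the decoupled reference flow of P_M
  pm_seq <- pose_sequence(array(out$P_M, dim = c(50, 25, 3)))
  expect_equal(out$magnitude$alpha, pdf_of_sequence(pm_seq)$magnitude$alpha,
               tolerance = 1e-12)
  # orientation obeys the decouple convention
  norms <- sqrt(apply(out$orientation$units^2, c(1, 2), sum))
  expect_equal(norms[out$orientation$valid_mask],
               rep(1, sum(out$orientation$valid_mask)), tolerance = 1e-6)
  expect_true(all(norms[!out$orientation$valid_mask] == 0))
  # a temporally constant generated sequence has zero derived magnitude
  mconst <- m
  mconst$params$dM_fcW[] <- 0
  mconst$params$dM_fcb[] <- 0.3
  outc <- forward_implicit(mconst, s)
  expect_lt(max(outc$magnitude$alpha), 1e-12)
  # pdf_g shares the forward pass
  mg <- build_model("pdf_g", J = 25, T_frames = 50, hidden_dim = 32, seed = 4)
  expect_silent(forward_implicit(mg, s))
})

test_that("batched forwards equal per-sequence forwards", {
  seqs <- norm_batch(3)
  X <- array(0, dim = c(3, 50, 75))
  for (i in 1:3) X[i, , ] <- matrix(seqs[[i]]$coords, 50, 75)
  mi <- build_model("pdf_i", J = 25, T_frames = 50, hidden_dim = 16, seed = 5)
  outb <- forward_implicit(mi, X)
  for (i in 1:3) {
    outi <- forward_implicit(mi, seqs[[i]])
    expect_equal(matrix(outb$P_M[i, , ], 50), outi$P_M, tolerance = 1e-6)
    expect_equal(matrix(outb$alpha[i, , ], 50), outi$magnitude$alpha,
                 tolerance = 1e-6)
  }
})

test_that("parameter counts reflect topology, not loss wiring", {
  specs <- list(J = 25, T_frames = 50, hidden_dim = 32, seed = 0)
  n_base1 <- count_parameters(do.call(build_model, c(list("baseline"), specs)))
  n_base2 <- count_parameters(do.call(build_model, c(list("baseline"),
                                                     specs, list())))
  expect_identical(n_base1, n_base2)
  n_i <- count_parameters(do.call(build_model, c(list("pdf_i"), specs)))
  n_g <- count_parameters(do.call(build_model, c(list("pdf_g"), specs)))
  expect_identical(n_i, n_g)          # same topology, different loss
  expect_identical(n_base1, n_i)      # baseline decoders share that topology
  n_e <- count_parameters(do.call(build_model, c(list("pdf_e"), specs)))
  expect_lt(n_e, n_i)                 # narrower magnitude head
  # depth increases the count
  m2 <- build_model("pdf_g", J = 25, T_frames = 50, hidden_dim = 32,
                    num_layers = 2, seed = 0)
  expect_gt(count_parameters(m2), n_g)
})

test_that("full-model gradients match finite differences on a tiny model", {
  set.seed(12)
  J <- 2L; TT <- 3L; B <- 2L
  X <- array(rnorm(B * TT * J * 3), dim = c(B, TT, J * 3))
  tg <- skelflow:::variant_targets(X, J, 1e-8)
  for (variant in c("baseline", "pdf_g")) {
    m <- build_model(variant, J = J, T_frames = TT, hidden_dim = 3L,
                     num_layers = 2L, seed = 7L)
    mlg <- skelflow:::model_loss_and_grads(m, X, tg)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      fwd <- skelflow:::model_forward_raw(m2, X)
      coef <- skelflow:::variant_fixed_coefs(variant, loss_weights())
      sum(coef * skelflow:::loss_and_output_grads(m2, X, fwd, tg, coef)$terms)
    }
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      ks <- if (length(p) > 6) round(seq(1, length(p), length.out = 6)) else
        seq_along(p)
      for (k in ks) {
        h <- 1e-5
        pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + h
        pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - h
        num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
        expect_lt(abs(num - mlg$grads[[nm]][k]) / max(1, abs(num)), 1e-4)
      }
    }
    # encoder gradients are nonzero for generic input
    expect_gt(max(abs(mlg$grads$enc1_W)), 0)
  }
})
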