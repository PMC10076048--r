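# Training mechanics and the 1-NN cosine protocol. Heavier capacity and
# benchmark runs live in test-acceptance.R; here sizes are small.

tiny_train_data <- function(n = 4, seed = 0) {
  d <- small_norm_dataset(n_per_class = 1, seed = seed)
  dataset_handle(d$train$sequences[seq_len(n)],
                 labels = d$train$labels[seq_len(n)])
}

test_that("max_epochs = 0 returns initial weights and empty history", {
  data <- tiny_train_data()
  cfg <- train_config("pdf_e", max_epochs = 0, hidden_dim = 8, seed = 3)
  tr <- train_model(data, cfg)
  ref <- build_model("pdf_e", J = 25, T_frames = 50, hidden_dim = 8, seed = 3)
  expect_identical(tr$model$params, ref$params)
  expect_identical(nrow(tr$history), 0L)
})

test_that("the learning-rate schedule decays by 0.1 every 80 epochs", {
  cfg <- train_config("baseline")
  expect_equal(lr_at_epoch(cfg, 1), 0.001)
  expect_equal(lr_at_epoch(cfg, 80), 0.001)
  expect_equal(lr_at_epoch(cfg, 81), 0.0001)     # 0.001 * 0.1
  expect_equal(lr_at_epoch(cfg, 100), 0.0001)
  expect_equal(lr_at_epoch(cfg, 161), 1e-5)
})

test_that("training is reproducible from the master seed and decreases loss", {
  data <- tiny_train_data()
  cfg <- train_config("pdf_g", max_epochs = 15, batch_size = 2,
                      hidden_dim = 8, seed = 11)
  t1 <- train_model(data, cfg)
  t2 <- train_model(data, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
  expect_lt(t1$history$total[15], t1$history$total[1])
  # history carries the raw terms and their weighted total
  expect_true(all(c("magnitude", "orientation", "pose_M", "pose_O",
                    "total") %in% names(t1$history)))
})

test_that("adaptive training learns per-term uncertainties", {
  data <- tiny_train_data()
  cfg <- train_config("pdf_e", max_epochs = 12, batch_size = 4,
                      hidden_dim = 8, seed = 2, adaptive = TRUE)
  tr <- train_model(data, cfg)
  expect_length(tr$uncertainty, 2)
  expect_true(all(is.finite(tr$uncertainty)))
  expect_false(all(tr$uncertainty == 0))        # the s parameters moved
  expect_true(all(c("s_magnitude", "s_orientation") %in% names(tr$history)))
})

test_that("checkpoints round-trip trained models", {
  data <- tiny_train_data()
  cfg <- train_config("baseline", max_epochs = 2, hidden_dim = 8, seed = 0)
  path <- tempfile(fileext = ".rds")
  tr <- train_model(data, cfg, checkpoint_path = path)
  back <- load_checkpoint(path)
  expect_identical(back$model$params, tr$model$params)
  expect_identical(back$model$variant, "baseline")
  expect_error(load_checkpoint(save_dataset(data, tempfile())),
               "container error")
})

test_that("representations are deterministic and batch-partition independent", {
  data <- tiny_train_data()
  m <- build_model("pdf_g", J = 25, T_frames = 50, hidden_dim = 16, seed = 1)
  r1 <- extract_representations(m, data)
  r2 <- extract_representations(m, data)
  expect_identical(r1$rows, r2$rows)
  expect_identical(dim(r1$rows), c(4L, 16L))
  r3 <- extract_representations(m, data, batch_size = 1)
  expect_equal(r3$rows, r1$rows, tolerance = 1e-6)
  expect_identical(r1$labels, data$labels)
})

test_that("default-width representations are 256-dimensional", {
  data <- tiny_train_data(n = 1)
  m <- build_model("baseline", J = 25, T_frames = 50, seed = 0)
  expect_identical(dim(extract_representations(m, data)$rows), c(1L, 256L))
})

test_that("1-NN cosine classification matches hand and brute-force results", {
  tr <- representation_matrix(rbind(c(1, 0), c(0, 1)), labels = c(10L, 20L))
  # hand fixture: (0.9, 0.1) is closer in angle to (1,0)
  expect_identical(knn1_classify(tr, representation_matrix(rbind(c(0.9, 0.1)),
                                                           labels = 0L)), 10L)
  # identical row and scaled row map to the source label
  expect_identical(knn1_classify(tr, representation_matrix(rbind(c(0, 1)),
                                                           labels = 0L)), 20L)
  expect_identical(knn1_classify(tr, representation_matrix(rbind(c(0, 3)),
                                                           labels = 0L)), 20L)
  # zero-norm rows are rejected
  expect_error(knn1_classify(tr, representation_matrix(rbind(c(0, 0)),
                                                       labels = 0L)),
               "zero-norm")

  # brute-force agreement on random instances
  set.seed(99)
  for (i in 1:30) {
    ntr <- sample(3:12, 1); nte <- sample(1:6, 1); C <- sample(2:5, 1)
    A <- matrix(rnorm(ntr * C), ntr); B <- matrix(rnorm(nte * C), nte)
    la <- sample(1:3, ntr, replace = TRUE)
    pred <- knn1_classify(representation_matrix(A, la),
                          representation_matrix(B, rep(1L, nte)))
    brute <- vapply(seq_len(nte), function(j) {
      sims <- vapply(seq_len(ntr), function(k)
        sum(A[k, ] * B[j, ]) / sqrt(sum(A[k, ]^2) * sum(B[j, ]^2)),
        numeric(1))
      la[which.max(sims)]
    }, integer(1))
    expect_identical(pred, brute)
  }
})

test_that("ties in cosine similarity resolve to the lowest training index", {
  tr <- representation_matrix(rbind(c(2, 0), c(1, 0), c(0, 1)),
                              labels = c(5L, 6L, 7L))
  # rows 1 and 2 are parallel: equal similarity to (1, 0) -> index 1 wins
  expect_identical(knn1_classify(tr, representation_matrix(rbind(c(1, 0)),
                                                           labels = 0L)), 5L)
})

test_that("evaluation accuracy, confusion and recall are consistent", {
  set.seed(5)
  Z <- matrix(rnorm(20 * 4), 20)
  labs <- rep(1:4, each = 5)
  rm_ <- representation_matrix(Z, labs)
  res <- evaluate_knn(rm_, rm_)
  expect_equal(res$accuracy, 1)                 # each point is its own NN
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion), res$accuracy)
  expect_equal(as.numeric(rowSums(res$confusion)), rep(5, 4))
  expect_equal(res$per_class_recall, rep(1, 4), ignore_attr = TRUE)

  # label-permutation invariance of accuracy
  perm <- c(3L, 4L, 1L, 2L)
  rm_p <- representation_matrix(Z, perm[labs])
  te <- representation_matrix(Z + rnorm(80, sd = 0.05), labs)
  te_p <- representation_matrix(te$rows, perm[labs])
  expect_equal(evaluate_knn(rm_p, te_p)$accuracy,
               evaluate_knn(rm_, te)$accuracy)

  # disjoint label sets warn
  expect_warning(evaluate_knn(rm_, representation_matrix(Z, labs + 10L)),
                 "disjoint")
})

test_that("random balanced representations score near chance", {
  set.seed(123)
  K <- 4; n_tr <- 40; n_te <- 400; C <- 16
  tr <- representation_matrix(matrix(rnorm(n_tr * C), n_tr),
                              rep(seq_len(K), each = n_tr / K))
  te <- representation_matrix(matrix(rnorm(n_te * C), n_te),
                              rep(seq_len(K), each = n_te / K))
  acc <- evaluate_knn(tr, te)$accuracy
  # binomial(400, 1/4): sd ~ 0.0217; allow 4 sd
  expect_lt(abs(acc - 1 / K), 4 * sqrt((1 / K) * (1 - 1 / K) / n_te))
})

test_that("the ablation harness tabulates runs and summaries", {
  d <- small_norm_dataset(n_per_class = 2, seed = 1)
  cfg <- train_config(max_epochs = 2, batch_size = 4, hidden_dim = 8)
  res <- run_ablation(d$train, d$test, variants = "baseline", seeds = 0L,
                      cfg = cfg)
  expect_identical(nrow(res$runs), 1L)
  expect_identical(nrow(res$summary), 1L)
  res2 <- run_ablation(d$train, d$test, variants = "pdf_e", seeds = c(0L, 1L),
                       cfg = cfg)
  expect_identical(nrow(res2$runs), 2L)
  expect_false(identical(res2$runs$accuracy[1], NULL))
  expect_equal(res2$summary$mean_accuracy, mean(res2$runs$accuracy))
  csv <- tempfile(fileext = ".csv")
  run_ablation(d$train, d$test, "baseline", 0L, cfg, csv_path = csv)
  expect_true(file.exists(csv))
})
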