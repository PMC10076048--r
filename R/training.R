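# Adam training loop with the staged learning-rate schedule, plus the
# overfit-capacity harness.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam starting at learning rate
#' 0.001, decayed by a factor of 0.1 every 80 epochs, batch size 128, at most
#' 100 epochs. The decay interval is interpreted in epochs by default (one
#' decay within a 100-epoch run); `decay_unit = "step"` applies it per
#' optimizer step instead.
#'
#' @param variant model variant tag (see [build_model()]).
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay factor.
#' @param lr_decay_every decay interval, in `decay_unit`s.
#' @param decay_unit `"epoch"` (default) or `"step"`.
#' @param batch_size minibatch size.
#' @param max_epochs number of passes over the data (0 = no training).
#' @param seed master seed: weight initialization and shuffling derive from
#'   it.
#' @param adaptive if `TRUE`, loss terms are combined by learnable
#'   homoscedastic-uncertainty weights ([adaptive_combine()]) instead of the
#'   fixed `weights`.
#' @param weights a [loss_weights] for non-adaptive mode.
#' @param hidden_dim,num_layers encoder/decoder sizes (see [build_model()]).
#' @param magnitude_activation see [build_model()].
#' @param eps zero-motion threshold.
#' @return An object of class `train_config`.
#' @export
train_config <- function(variant = c("pdf_g", "baseline", "pdf_e", "pdf_i"),
                         learning_rate = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 80L,
                         decay_unit = c("epoch", "step"),
                         batch_size = 128L, max_epochs = 100L, seed = 0L,
                         adaptive = FALSE, weights = loss_weights(),
                         hidden_dim = 256L, num_layers = 1L,
                         magnitude_activation = "identity", eps = 1e-8) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 0L) stop("max_epochs must be >= 0")
  if (lr_decay_every < 1L) stop("lr_decay_every must be >= 1")
  structure(list(variant = match.arg(variant),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 decay_unit = match.arg(decay_unit),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), adaptive = isTRUE(adaptive),
                 weights = weights, hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 magnitude_activation = magnitude_activation, eps = eps),
            class = "train_config")
}

#' Effective learning rate at a given epoch
#'
#' `learning_rate * lr_decay_factor ^ floor((epoch - 1) / lr_decay_every)`;
#' with the defaults, epochs 1-80 run at 0.001 and epochs 81-100 at 0.0001.
#'
#' @param cfg a [train_config].
#' @param epoch 1-based epoch number.
#' @return The learning rate in effect during that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$learning_rate * cfg$lr_decay_factor ^ (as.integer((epoch - 1) %/%
                                                          cfg$lr_decay_every))
}

# stack a normalized dataset into the B x T x 3J tensor the models consume
dataset_tensor <- function(data) {
  if (length(data$sequences) < 1L) stop("empty dataset")
  TT <- n_frames(data$sequences[[1]])
  J <- n_joints(data$sequences[[1]])
  for (s in data$sequences)
    if (n_frames(s) != TT || n_joints(s) != J)
      stop("sequences must share T and J: normalize the dataset first")
  X <- array(0, dim = c(length(data$sequences), TT, J * 3L))
  for (i in seq_along(data$sequences))
    X[i, , ] <- flatten_frames(data$sequences[[i]]$coords)
  X
}

subset_targets <- function(targets, idx) {
  list(P = targets$P[idx, , , drop = FALSE],
       alpha = targets$alpha[idx, , , drop = FALSE],
       units = targets$units[idx, , , , drop = FALSE],
       mask = targets$mask[idx, , , drop = FALSE])
}

#' Train a model on a dataset
#'
#' Runs minibatch Adam on the variant's loss over the normalized dataset.
#' All randomness (weight initialization, shuffling) derives from
#' `cfg$seed`, so a run is exactly reproducible. The learning rate follows
#' [lr_at_epoch()]. In adaptive mode the uncertainty log-variances are
#' optimized jointly with the weights. Training aborts with a diagnostic
#' naming the offending term if any loss term becomes non-finite.
#'
#' @param data a normalized [dataset_handle] (fixed T across sequences).
#' @param cfg a [train_config].
#' @param checkpoint_path optional path: the trained model is saved there via
#'   [save_checkpoint()].
#' @return A list of class `trained_model` with fields `model` (the
#'   [build_model()] object with trained weights), `history` (one row per
#'   epoch: raw loss terms, combined total, and uncertainty parameters when
#'   adaptive), `uncertainty` (final `s`, or `NULL`), and `config`.
#' @export
train_model <- function(data, cfg = train_config(), checkpoint_path = NULL) {
  X <- dataset_tensor(data)
  n <- dim(X)[1]; TT <- dim(X)[2]; J <- dim(X)[3] %/% 3L
  model <- build_model(cfg$variant, J = J, T_frames = TT,
                       hidden_dim = cfg$hidden_dim,
                       num_layers = cfg$num_layers, seed = cfg$seed,
                       eps = cfg$eps,
                       magnitude_activation = cfg$magnitude_activation)
  targets <- variant_targets(X, J, cfg$eps)
  tn <- variant_term_names(cfg$variant)
  s <- if (cfg$adaptive) rep(0, length(tn)) else NULL
  history <- NULL
  if (cfg$max_epochs > 0L) {
    opt <- adam_init(model$params)
    opt_s <- if (cfg$adaptive) list(m = rep(0, length(tn)),
                                    v = rep(0, length(tn)), t = 0L) else NULL
    rows <- vector("list", cfg$max_epochs)
    step <- 0L
    withr_seed(cfg$seed, {
      for (epoch in seq_len(cfg$max_epochs)) {
        idx_all <- sample.int(n)
        n_batches <- ceiling(n / cfg$batch_size)
        acc_terms <- stats::setNames(rep(0, length(tn)), tn)
        acc_total <- 0
        for (bi in seq_len(n_batches)) {
          step <- step + 1L
          lr <- if (cfg$decay_unit == "epoch") lr_at_epoch(cfg, epoch)
          else cfg$learning_rate *
            cfg$lr_decay_factor ^ ((step - 1L) %/% cfg$lr_decay_every)
          idx <- idx_all[((bi - 1L) * cfg$batch_size + 1L):
                           min(bi * cfg$batch_size, n)]
          mlg <- model_loss_and_grads(model, X[idx, , , drop = FALSE],
                                      subset_targets(targets, idx),
                                      w = cfg$weights,
                                      adaptive = cfg$adaptive, s = s)
          bad <- !is.finite(mlg$breakdown$terms)
          if (any(bad))
            stop("non-finite loss term during training: ",
                 paste(names(mlg$breakdown$terms)[bad], collapse = ", "))
          up <- adam_step(model$params, mlg$grads, opt, lr)
          model$params <- up$params; opt <- up$state
          if (cfg$adaptive) {
            opt_s$t <- opt_s$t + 1L
            g <- mlg$ds
            opt_s$m <- 0.9 * opt_s$m + 0.1 * g
            opt_s$v <- 0.999 * opt_s$v + 0.001 * g^2
            s <- s - lr * (opt_s$m / (1 - 0.9^opt_s$t)) /
              (sqrt(opt_s$v / (1 - 0.999^opt_s$t)) + 1e-8)
          }
          acc_terms <- acc_terms + mlg$breakdown$terms
          acc_total <- acc_total + mlg$breakdown$total
        }
        row <- as.list(acc_terms / n_batches)
        row$total <- acc_total / n_batches
        row$epoch <- epoch
        row$lr <- if (cfg$decay_unit == "epoch") lr_at_epoch(cfg, epoch) else NA
        if (cfg$adaptive)
          for (k in seq_along(tn)) row[[paste0("s_", tn[k])]] <- s[k]
        rows[[epoch]] <- row
      }
    })
    history <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    history <- history[, c("epoch", setdiff(names(history), "epoch"))]
  } else {
    history <- data.frame()
  }
  out <- structure(list(model = model, history = history,
                        uncertainty = s, config = cfg),
                   class = "trained_model")
  if (!is.null(checkpoint_path)) save_checkpoint(out, checkpoint_path)
  out
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s: %d epoch(s)%s>\n", x$model$variant,
              nrow(x$history),
              if (nrow(x$history)) sprintf(", final loss %.6g",
                                           x$history$total[nrow(x$history)])
              else ""))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the trained weights, the model specification, the
#' training configuration, the final uncertainty parameters and the loss
#' history in a single serialized file, with a JSON-compatible summary in
#' `$summary`.
#'
#' @param trained a `trained_model` (or bare `pdf_model`).
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored `trained_model`.
#' @export
save_checkpoint <- function(trained, path) {
  if (inherits(trained, "pdf_model"))
    trained <- structure(list(model = trained, history = data.frame(),
                              uncertainty = NULL, config = NULL),
                         class = "trained_model")
  if (!inherits(trained, "trained_model")) stop("not a trained_model")
  payload <- list(format = "skelflow-checkpoint", version = 1L,
                  trained = trained,
                  summary = list(variant = trained$model$variant,
                                 spec = trained$model$spec,
                                 seed = trained$model$seed,
                                 n_parameters = count_parameters(trained$model),
                                 epochs = nrow(trained$history)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "skelflow-checkpoint"))
    stop("container error: not a skelflow checkpoint")
  payload$trained
}

#' Overfit-capacity check
#'
#' Trains a variant on a small fixed set of sequences for a given number of
#' full-batch optimizer steps at a constant learning rate and reports the
#' ratio of final to initial training loss. A healthy implementation drives
#' the loss well below 10% of its starting value on a handful of sequences.
#'
#' @param data a small normalized [dataset_handle] (e.g. 8 sequences).
#' @param variant model variant tag.
#' @param steps optimizer steps (default 500).
#' @param seed master seed.
#' @param hidden_dim latent size.
#' @param learning_rate Adam learning rate (constant throughout).
#' @param adaptive use adaptive uncertainty weighting.
#' @return A list with `initial`, `final`, `ratio`, and the full `history`.
#' @export
overfit_check <- function(data, variant = "pdf_g", steps = 500L, seed = 0L,
                          hidden_dim = 256L, learning_rate = 0.001,
                          adaptive = FALSE) {
  n <- length(data$sequences)
  cfg <- train_config(variant = variant, batch_size = n, max_epochs = steps,
                      seed = seed, hidden_dim = hidden_dim,
                      learning_rate = learning_rate,
                      lr_decay_every = as.integer(steps) + 1L,
                      adaptive = adaptive)
  tr <- train_model(data, cfg)
  list(initial = tr$history$total[1],
       final = tr$history$total[nrow(tr$history)],
       ratio = tr$history$total[nrow(tr$history)] / tr$history$total[1],
       history = tr$history)
}
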