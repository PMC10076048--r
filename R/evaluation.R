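# Unsupervised evaluation: extract latent representations, classify by
# 1-nearest-neighbor under cosine similarity, report accuracy and confusion.

#' Representation matrix
#'
#' Latent codes for a set of sequences, with their labels and ids.
#'
#' @param rows numeric `n x C` matrix of latent codes (finite).
#' @param labels integer labels, length n.
#' @param ids character ids, length n.
#' @return An object of class `representation_matrix`.
#' @export
representation_matrix <- function(rows, labels, ids = NULL) {
  rows <- as.matrix(rows)
  if (!all(is.finite(rows))) stop("representations must be finite")
  labels <- as.integer(labels)
  if (length(labels) != nrow(rows)) stop("one label per row required")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rows)))
  structure(list(rows = rows, labels = labels, ids = as.character(ids)),
            class = "representation_matrix")
}

#' @export
print.representation_matrix <- function(x, ...) {
  cat(sprintf("<representation_matrix: %d x %d, %d classes>\n",
              nrow(x$rows), ncol(x$rows), length(unique(x$labels))))
  invisible(x)
}

#' Extract latent representations for a dataset
#'
#' Encodes every sequence with the trained encoder (inference is
#' deterministic and independent of batch partitioning).
#'
#' @param model a `pdf_model` or `trained_model`.
#' @param data a normalized [dataset_handle].
#' @param batch_size encoding batch size (no effect on values).
#' @return A [representation_matrix] with one row per sequence.
#' @export
extract_representations <- function(model, data, batch_size = 256L) {
  if (inherits(model, "trained_model")) model <- model$model
  X <- dataset_tensor(data)
  n <- dim(X)[1]
  rows <- matrix(0, n, model$spec$hidden_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    rows[idx, ] <- encode(model, X[idx, , , drop = FALSE])
  }
  ids <- vapply(data$sequences, function(s) s$seq_id, character(1))
  representation_matrix(rows, data$labels, ids)
}

#' 1-nearest-neighbor classification under cosine similarity
#'
#' Each test row receives the label of the training row with the highest
#' cosine similarity; ties are broken by the lowest training index, so the
#' prediction is deterministic.
#'
#' @param train,test [representation_matrix] objects with equal code length.
#' @return Integer vector of predicted labels, one per test row.
#' @export
knn1_classify <- function(train, test) {
  A <- train$rows; B <- test$rows
  if (nrow(A) < 1L) stop("empty training representation")
  if (ncol(A) != ncol(B)) stop("shape error: code lengths differ")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0))
    stop("undefined similarity: zero-norm representation row")
  S <- (B / nb) %*% t(A / na)          # test x train cosine similarities
  pred <- apply(S, 1, which.max)       # which.max returns the first maximum
  train$labels[pred]
}

#' Evaluation result
#'
#' @param accuracy fraction of correct predictions.
#' @param confusion `K x K` count matrix, rows = true class, columns =
#'   predicted class.
#' @param per_class_recall per-true-class recall, length K.
#' @return An object of class `eval_result`.
#' @export
eval_result <- function(accuracy, confusion, per_class_recall) {
  structure(list(accuracy = accuracy, confusion = confusion,
                 per_class_recall = per_class_recall),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: accuracy %.4f over %d test sequences, %d classes>\n",
              x$accuracy, sum(x$confusion), nrow(x$confusion)))
  invisible(x)
}

#' Evaluate representations by the 1-NN cosine protocol
#'
#' Classifies every test representation by [knn1_classify()] against the
#' training set and tabulates accuracy, the confusion matrix (rows = true
#' class, columns = predicted class) and per-class recall.
#'
#' @param train,test labeled [representation_matrix] objects.
#' @param confusion_csv optional path: the confusion matrix is written there
#'   as CSV.
#' @return An [eval_result].
#' @export
evaluate_knn <- function(train, test, confusion_csv = NULL) {
  if (length(intersect(train$labels, test$labels)) == 0L)
    warning("train and test label sets are disjoint; accuracy will be 0")
  pred <- knn1_classify(train, test)
  classes <- sort(unique(c(train$labels, test$labels)))
  K <- length(classes)
  confusion <- matrix(0L, K, K, dimnames = list(true = classes,
                                                predicted = classes))
  for (i in seq_along(pred)) {
    r <- match(test$labels[i], classes); c_ <- match(pred[i], classes)
    confusion[r, c_] <- confusion[r, c_] + 1L
  }
  accuracy <- sum(diag(confusion)) / length(pred)
  row_tot <- rowSums(confusion)
  recall <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  if (!is.null(confusion_csv))
    utils::write.csv(as.data.frame(confusion), confusion_csv)
  eval_result(accuracy, confusion, recall)
}

#' Ablation harness over model variants and seeds
#'
#' Trains each variant with each seed on the training split, evaluates on the
#' test split by the 1-NN cosine protocol, and tabulates per-run and
#' per-variant (mean, sd) accuracies.
#'
#' @param train_data,test_data normalized [dataset_handle] splits.
#' @param variants character vector of variant tags.
#' @param seeds integer vector of seeds.
#' @param cfg a [train_config] template; its `variant` and `seed` are
#'   overridden per run.
#' @param csv_path optional path for the per-variant summary CSV.
#' @param verbose print one line per completed run.
#' @return A list of class `ablation_result` with `runs` (variant, seed,
#'   accuracy, final_loss) and `summary` (variant, mean_accuracy,
#'   sd_accuracy).
#' @export
run_ablation <- function(train_data, test_data, variants, seeds,
                         cfg = train_config(), csv_path = NULL,
                         verbose = FALSE) {
  if (length(variants) < 1L || length(seeds) < 1L)
    stop("need at least one variant and one seed")
  runs <- list()
  for (v in variants) {
    for (sd_ in seeds) {
      cfg_run <- cfg
      cfg_run$variant <- v
      cfg_run$seed <- as.integer(sd_)
      tr <- train_model(train_data, cfg_run)
      rep_tr <- extract_representations(tr, train_data)
      rep_te <- extract_representations(tr, test_data)
      res <- evaluate_knn(rep_tr, rep_te)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = v, seed = as.integer(sd_), accuracy = res$accuracy,
        final_loss = if (nrow(tr$history)) tr$history$total[nrow(tr$history)]
        else NA_real_)
      if (verbose)
        message(sprintf("ablation: %s seed %d -> accuracy %.4f", v, sd_,
                        res$accuracy))
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$variant), function(g)
    data.frame(variant = g$variant[1], mean_accuracy = mean(g$accuracy),
               sd_accuracy = if (nrow(g) > 1) stats::sd(g$accuracy) else NA_real_)))
  summary <- summary[match(unique(runs$variant), summary$variant), ]
  rownames(summary) <- NULL
  if (!is.null(csv_path)) utils::write.csv(summary, csv_path,
                                           row.names = FALSE)
  structure(list(runs = runs, summary = summary), class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(x$summary)
  invisible(x)
}
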