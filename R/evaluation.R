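#' Percent accuracy from correct/total counts
#'
#' `100 * correct / total`, rounded half-up to 2 decimals (so 64/88
#' yields 72.73 and 83/88 yields 94.32).
#'
#' @param correct Number of correctly classified instances.
#' @param total Total instances (> 0).
#' @return Percent accuracy to 2 decimals.
#' @export
accuracy_pct <- function(correct, total) {
  if (total <= 0) stop("total must be positive")
  if (correct < 0 || correct > total) stop("correct must lie in [0, total]")
  round_half_up(100 * correct / total, 2L)
}

#' @keywords internal
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Stratified k-fold partition
#'
#' Splits indices into `k` disjoint folds preserving class proportions:
#' within each class, shuffled indices are dealt round-robin, so
#' per-class counts across folds differ by at most 1. Deterministic for
#' a given seed.
#'
#' @param labels Class label per instance.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  n_min <- min(table(labels))
  if (n_min < k) {
    k <- max(2L, as.integer(n_min))
    warning("smallest class has fewer members than k; reduced k to ", k)
  }
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # continue the round-robin deal across classes so the leftover
    # members rotate and fold sizes differ by at most 1 overall
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score from high to low as a classification
#' threshold, yielding ROC points from (0,0) to (1,1); the AUC is the
#' trapezoidal area under that curve, which equals the Mann-Whitney
#' statistic (fraction of positive/negative pairs where the positive
#' outscores the negative, ties counting half).
#'
#' @param scores Numeric classifier scores, higher = more `selected`.
#' @param labels Labels over `selected`/`random` (or a 0/1 vector).
#' @return List with `roc_points` (data frame `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else labels_binary(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative instance")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' @keywords internal
confusion_2x2 <- function(pred, y) {
  # rows: truth (selected, random); cols: predicted (selected, random)
  matrix(c(sum(y == 1L & pred == 1L), sum(y == 1L & pred == 0L),
           sum(y == 0L & pred == 1L), sum(y == 0L & pred == 0L)),
         2L, 2L, byrow = TRUE,
         dimnames = list(truth = c("selected", "random"),
                         predicted = c("selected", "random")))
}

#' @keywords internal
make_eval_report <- function(classifier, scores, y, per_fold = NULL) {
  pred <- as.integer(scores >= 0.5)
  correct <- sum(pred == y)
  total <- length(y)
  roc <- roc_auc(scores, y)
  structure(list(classifier = classifier,
                 correct = correct,
                 total = total,
                 accuracy_pct = accuracy_pct(correct, total),
                 confusion = confusion_2x2(pred, y),
                 roc_points = roc$roc_points,
                 auc = roc$auc,
                 per_fold = per_fold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d correct (%.2f%%), AUC %.3f\n",
              x$classifier, x$correct, x$total, x$accuracy_pct, x$auc))
  invisible(x)
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Out-of-fold scores are pooled over all folds; accuracy (0.5
#' threshold), the confusion matrix, and ROC/AUC are computed on the
#' pooled predictions, matching a single correct/total summary over the
#' whole cohort. All fitting — including the z-scoring of numeric
#' columns for the gradient-trained learners — uses only the training
#' fold. Per-fold accuracies are retained in `per_fold`.
#'
#' @param spec A [classifier_spec()].
#' @param table A `feature_table`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment; fold `f` trains with seed
#'   `spec$seed + f` so stochastic learners re-initialize per fold.
#' @return An `eval_report`.
#' @export
cross_validate <- function(spec, table, k = 10L, seed = 1L) {
  y <- labels_binary(table$labels)
  folds <- stratified_kfold(table$labels, k = k, seed = seed)
  scores <- rep(NA_real_, length(y))
  per_fold <- data.frame(fold = seq_along(folds), n = NA_integer_,
                         accuracy_pct = NA_real_)
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    fold_spec <- classifier_spec(spec$name, spec$hyperparams,
                                 seed = spec$seed + f)
    model <- fit_classifier(fold_spec, ft_rows(table, train_idx))
    sc <- predict_prob(model, ft_rows(table, test_idx))
    scores[test_idx] <- sc
    pred <- as.integer(sc >= 0.5)
    per_fold$n[f] <- length(test_idx)
    per_fold$accuracy_pct[f] <- accuracy_pct(sum(pred == y[test_idx]),
                                             length(test_idx))
  }
  stopifnot(!anyNA(scores))
  make_eval_report(spec$name, scores, y, per_fold)
}

#' Evaluate a trained model on an independent validation table
#'
#' Single-pass holdout evaluation; the validation columns must equal the
#' model's training columns (build the validation table with the frozen
#' training vocabulary and run [exclude_overlap()] first).
#'
#' @param model A trained `mirnadx_model`.
#' @param validation A labeled `feature_table`.
#' @return An `eval_report`.
#' @export
validate_holdout <- function(model, validation) {
  y <- labels_binary(validation$labels)
  scores <- predict_prob(model, validation)
  make_eval_report(model$spec$name, scores, y)
}

#' Serialize an eval report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(classifier = report$classifier,
              correct = report$correct,
              total = report$total,
              accuracy_pct = report$accuracy_pct,
              confusion = as.vector(report$confusion),
              auc = report$auc,
              roc_points = report$roc_points)
  if (!is.null(report$per_fold)) out$per_fold <- report$per_fold
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
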