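test_that("percent accuracy rounds half-up to two decimals", {
  expect_equal(accuracy_pct(0, 10), 0.00)
  expect_equal(accuracy_pct(64, 88), 72.73)
  expect_equal(accuracy_pct(1, 3), 33.33)
  expect_equal(accuracy_pct(2, 3), 66.67)
  expect_error(accuracy_pct(1, 0), "positive")
  expect_error(accuracy_pct(5, 3), "correct")
})

test_that("stratified folds balance classes and partition the indices", {
  labels <- rep(c("selected", "random"), each = 44)
  folds <- stratified_kfold(labels, k = 10, seed = 3)
  expect_length(folds, 10)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(8, 9)))
  for (f in folds) {
    per_class <- table(labels[f])
    expect_true(all(per_class %in% c(4, 5)))
  }
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(labels))
  expect_identical(folds, stratified_kfold(labels, k = 10, seed = 3))
  expect_false(identical(folds, stratified_kfold(labels, k = 10, seed = 4)))
  expect_error(stratified_kfold(labels, k = 1), "k must")
})

test_that("ROC sweep produces a monotone curve with the tie-aware AUC", {
  y <- c(1, 1, 1, 0, 0, 0)
  perfect <- roc_auc(c(.9, .8, .7, .3, .2, .1), y)
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(0.5, 6), y)
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    yy <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 2)  # rounding forces ties
    r <- roc_auc(sc, yy)
    expect_equal(r$auc, oracle_auc(sc, yy), tolerance = 1e-12)
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[1], 0)
    expect_equal(utils::tail(r$roc_points$fpr, 1), 1)
    expect_equal(utils::tail(r$roc_points$tpr, 1), 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    # AUC invariant under strictly monotone score transforms
    expect_equal(roc_auc(exp(3 * sc), yy)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("cross-validation pools out-of-fold predictions over all rows", {
  tab <- random_cfs_table(n = 40, p = 6, n_informative = 3, seed = 13)
  rep_nb <- cross_validate(classifier_spec("naive_bayes", seed = 1), tab,
                           k = 10, seed = 1)
  expect_equal(rep_nb$total, 40)
  expect_equal(sum(rep_nb$confusion), 40)
  expect_equal(sum(diag(rep_nb$confusion)), rep_nb$correct)
  expect_equal(accuracy_pct(rep_nb$correct, rep_nb$total),
               rep_nb$accuracy_pct)
  expect_equal(sum(rep_nb$per_fold$n), 40)
  # informative features: well above chance
  expect_gt(rep_nb$accuracy_pct, 65)
})

test_that("label permutation drives accuracy to chance", {
  cohort <- generate_cohort(synthetic_config(seed = 5))
  tab <- build_table(cohort$records, filter_annotations(cohort$annotations))
  set.seed(1)
  tab$labels <- sample(tab$labels)
  rep_nb <- cross_validate(classifier_spec("naive_bayes", seed = 1), tab,
                           k = 10, seed = 1)
  expect_gte(rep_nb$accuracy_pct, 35)
  expect_lte(rep_nb$accuracy_pct, 65)
})

test_that("holdout evaluation reports the validation size and rejects drift", {
  cohort <- generate_cohort(synthetic_config(seed = 6))
  annf <- filter_annotations(cohort$annotations)
  train <- build_table(cohort$records, annf)
  model <- fit_classifier(classifier_spec("naive_bayes", seed = 1), train)
  val <- generate_validation(synthetic_config(seed = 6),
                             cohort$records$mirna_id, n = 18)
  vtab <- suppressWarnings(
    build_table(val$records, filter_annotations(val$annotations),
                vocab = ft_vocabulary(train)))
  rep_h <- validate_holdout(model, vtab)
  expect_equal(rep_h$total, 18)
  expect_equal(sum(rep_h$confusion), 18)
  # a table with mismatched columns is refused with a named error
  bad <- ft_cols(vtab, seq_len(ncol(vtab$matrix) - 1))
  expect_error(validate_holdout(model, bad), "feature mismatch")
})

test_that("eval reports serialize to JSON and back", {
  y <- rep(c(1, 0), 10)
  r <- roc_auc(runif(20), y)
  rep1 <- cross_validate(classifier_spec("naive_bayes", seed = 1),
                         random_cfs_table(seed = 3), k = 5, seed = 2)
  f <- tempfile(fileext = ".json")
  write_eval_report(rep1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$accuracy_pct, rep1$accuracy_pct)
  expect_equal(back$correct, rep1$correct)
  expect_equal(back$auc, rep1$auc, tolerance = 1e-12)
})
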