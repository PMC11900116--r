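# toy naive Bayes cohort: 3 selected rows (1,1),(1,0),(1,1) and
# 3 random rows (0,0),(0,1),(0,0)
nb_toy <- function() {
  mat <- rbind(c(1, 1), c(1, 0), c(1, 1), c(0, 0), c(0, 1), c(0, 0))
  colnames(mat) <- c("GA", "GB")
  binary_table(mat, c(rep("selected", 3), rep("random", 3)))
}

test_that("naive Bayes posteriors match add-1-smoothing Bayes arithmetic", {
  train <- nb_toy()
  test <- binary_table(rbind(c(1, 1), c(0, 0), c(1, 0)),
                       rep("unlabeled", 3))
  colnames(test$matrix) <- c("GA", "GB")
  post <- nb_fit_predict(train, test)
  # hand: p(GA=1|sel)=4/5, p(GB=1|sel)=3/5, p(GA=1|rand)=1/5, p(GB=1|rand)=2/5
  p11 <- (0.5 * 0.8 * 0.6) / (0.5 * 0.8 * 0.6 + 0.5 * 0.2 * 0.4)
  p00 <- (0.5 * 0.2 * 0.4) / (0.5 * 0.2 * 0.4 + 0.5 * 0.8 * 0.6)
  p10 <- (0.5 * 0.8 * 0.4) / (0.5 * 0.8 * 0.4 + 0.5 * 0.2 * 0.6)
  expect_equal(post, c(p11, p00, p10), tolerance = 1e-12)
})

test_that("naive Bayes is symmetric on class-symmetric data and smooths unseen values", {
  mat <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  colnames(mat) <- c("GA", "GB")
  train <- binary_table(mat, c("selected", "selected", "random", "random"))
  post <- nb_fit_predict(train, train)
  expect_equal(post, rep(0.5, 4), tolerance = 1e-12)
  # feature all-zero in training, 1 at test time: finite nonzero posterior
  mat2 <- cbind(nb_toy()$matrix, GC = 0)
  train2 <- binary_table(mat2, nb_toy()$labels)
  test2 <- binary_table(matrix(c(1, 1, 1), 1, 3,
                               dimnames = list(NULL, c("GA", "GB", "GC"))),
                        "unlabeled")
  post2 <- nb_fit_predict(train2, test2)
  expect_true(is.finite(post2) && post2 > 0 && post2 < 1)
  # single-class training is rejected
  one_class <- binary_table(mat, rep("selected", 4))
  expect_error(fit_classifier(classifier_spec("naive_bayes"), one_class),
               "single class")
})

test_that("the Hoeffding bound follows its closed form and monotonicity", {
  expect_equal(hoeffding_bound(1, 0.05, 1000),
               sqrt(log(1 / 0.05) / 2000), tolerance = 1e-12)
  ns <- c(10, 50, 100, 500, 1000, 5000)
  eps <- vapply(ns, function(n) hoeffding_bound(1, 0.05, n), numeric(1))
  expect_true(all(diff(eps) < 0))
  expect_lt(hoeffding_bound(1, 1 - 1e-12, 100), 1e-6)
  expect_error(hoeffding_bound(0, 0.05, 10), "positive")
  expect_error(hoeffding_bound(1, 1.5, 10), "delta")
  expect_error(hoeffding_bound(1, 0.05, 0), "n must")
})

test_that("Hoeffding tree splits on a strong attribute and predicts it", {
  set.seed(8)
  n <- 200
  y <- rep(c(1L, 0L), n / 2)
  mat <- cbind(s1 = y, s2 = rbinom(n, 1, 0.5), s3 = rbinom(n, 1, 0.5))
  tab <- binary_table(mat, ifelse(y == 1, "selected", "random"))
  model <- fit_classifier(classifier_spec("hoeffding_tree", seed = 1), tab)
  expect_false(model$fit$root$is_leaf)
  expect_equal(model$fit$root$split_attr, 1L)
  pred <- as.integer(predict_prob(model, tab) >= 0.5)
  expect_gte(mean(pred == y), 0.95)
})

test_that("AdaBoost.M1 reweighting follows the beta update", {
  w <- rep(1 / 8, 8)
  correct <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  upd <- adaboost_round(w, correct, 0.25)
  expect_equal(upd$beta, 1 / 3)
  # correct weights shrink by beta pre-normalization, then renormalize
  raw <- w
  raw[correct] <- raw[correct] / 3
  expect_equal(upd$weights, raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
  expect_equal(adaboost_round(w, correct, 0.5)$status, "abort")
  expect_equal(adaboost_round(w, rep(TRUE, 8), 0)$status, "perfect")
})

test_that("random forest with one tree equals the random tree", {
  tab <- random_cfs_table(n = 60, p = 6, n_informative = 3, seed = 77)
  m_rt <- fit_classifier(classifier_spec("random_tree", seed = 9), tab)
  m_rf1 <- fit_classifier(classifier_spec("random_forest",
                                          hyperparams = list(ntree = 1L),
                                          seed = 9), tab)
  expect_equal(predict_prob(m_rt, tab), predict_prob(m_rf1, tab))
})

test_that("sequential forward pass matches a hand matrix-multiply chain", {
  w <- seq_init_weights(2, seed = 5)
  x <- matrix(c(0.3, -1.2), 1, 2)
  a <- x
  for (l in 1:4) {
    a <- pmax(sweep(a %*% w[[paste0("W", l)]], 2, w[[paste0("b", l)]], "+"), 0)
  }
  hand <- 1 / (1 + exp(-(a %*% w$W5 + w$b5)))
  expect_equal(sequential_forward(w, x), as.numeric(hand), tolerance = 1e-12)
  # all-zero weights give sigmoid(0) = 0.5
  w0 <- lapply(w, function(p) p * 0)
  expect_equal(sequential_forward(w0, x), 0.5)
  # output range on random inputs
  set.seed(6)
  xs <- matrix(rnorm(20), 10, 2)
  p <- sequential_forward(w, xs)
  expect_true(all(p > 0 & p < 1))
  # shape mismatch is an error
  expect_error(sequential_forward(w, matrix(0, 1, 3)), "shape mismatch")
})

test_that("sequential training separates a strong-signal table reproducibly", {
  set.seed(12)
  n <- 60
  y <- rep(c(1L, 0L), n / 2)
  mat <- cbind(g1 = ifelse(runif(n) < 0.05, 1L - y, y),
               g2 = ifelse(runif(n) < 0.05, 1L - y, y),
               score = y * 2 + rnorm(n, sd = 0.3))
  tab <- feature_table(mat, ifelse(y == 1, "selected", "random"),
                       c("gene", "gene", "descriptor"),
                       paste0("m", seq_len(n)))
  model <- train_sequential(tab, seed = 4)
  p <- predict_prob(model, tab)
  expect_gte(mean((p >= 0.5) == (y == 1)), 0.95)
  # loss trend decreases on average
  h <- model$fit$loss_history
  expect_lt(mean(utils::tail(h, 20)), mean(utils::head(h, 20)))
  # same seed twice: identical predictions
  model2 <- train_sequential(tab, seed = 4)
  expect_identical(p, predict_prob(model2, tab))
  # non-binary labels rejected
  bad <- tab
  bad$labels[1] <- "unlabeled"
  expect_error(fit_classifier(classifier_spec("sequential_nn"), bad),
               "selected")
})

test_that("every learner predicts deterministically from its fitted state", {
  tab <- random_cfs_table(n = 40, p = 5, n_informative = 3, seed = 55)
  for (nm in c("naive_bayes", "random_tree", "random_forest", "adaboost_m1",
               "hoeffding_tree", "mlp")) {
    model <- fit_classifier(classifier_spec(nm, seed = 2), tab)
    expect_identical(predict_prob(model, tab), predict_prob(model, tab),
                     label = nm)
  }
})
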