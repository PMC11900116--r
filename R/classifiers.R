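CLASSIFIER_NAMES <- c("naive_bayes", "random_tree", "random_forest",
                      "adaboost_m1", "hoeffding_tree", "mlp", "sequential_nn")

#' Specify a classifier
#'
#' @param name One of `naive_bayes`, `random_tree`, `random_forest`,
#'   `adaboost_m1`, `hoeffding_tree`, `mlp`, `sequential_nn`.
#' @param hyperparams Named list of learner hyperparameters.
#' @param seed Integer seed recorded and used for every stochastic step.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparams = list(), seed = 1L) {
  name <- match.arg(name, CLASSIFIER_NAMES)
  structure(list(name = name, hyperparams = hyperparams,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @keywords internal
labels_binary <- function(labels) {
  if (!all(labels %in% c("selected", "random"))) {
    stop("labels must be 'selected' or 'random'")
  }
  as.integer(labels == "selected")
}

#' Fit any classifier in the bank
#'
#' Dispatches on `spec$name` and returns a trained model that carries its
#' spec, the training feature names, and (for the gradient-trained
#' learners) the z-scoring statistics of the numeric columns computed on
#' the training data.
#'
#' @param spec A [classifier_spec()].
#' @param table A `feature_table` with binary labels.
#' @return An object of class `mirnadx_model`.
#' @export
fit_classifier <- function(spec, table) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  y <- labels_binary(table$labels)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  set.seed(spec$seed)
  x <- table$matrix
  scaler <- NULL
  if (spec$name %in% c("mlp", "sequential_nn")) {
    scaler <- fit_scaler(x)
    x <- apply_scaler(scaler, x)
  }
  hp <- spec$hyperparams
  fit <- switch(spec$name,
    naive_bayes = nb_fit(x, y),
    random_tree = rf_fit(x, y, ntree = 1L,
                         mtry = hp$mtry %||% floor(sqrt(ncol(x)))),
    random_forest = rf_fit(x, y, ntree = hp$ntree %||% 100L,
                           mtry = hp$mtry %||% floor(sqrt(ncol(x)))),
    adaboost_m1 = adaboost_fit(x, y, iterations = hp$iterations %||% 10L),
    hoeffding_tree = ht_fit(x, y,
                            delta = hp$delta %||% 1e-7,
                            tie_tau = hp$tie_tau %||% 0.05,
                            grace = hp$grace %||% 10L),
    mlp = mlp_fit(x, y, maxit = hp$maxit %||% 500L,
                  decay = hp$decay %||% 1e-4),
    sequential_nn = train_sequential_core(x, y,
                                          epochs = hp$epochs %||% 200L,
                                          batch_size = hp$batch_size %||% 16L,
                                          lr = hp$lr %||% 1e-3)
  )
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(table$matrix),
                 scaler = scaler),
            class = "mirnadx_model")
}

#' Predict P(selected) for each row of a feature table
#'
#' @param model A trained `mirnadx_model`.
#' @param table A `feature_table` whose columns equal the model's
#'   training columns (same names, same order).
#' @return Numeric vector of probabilities/scores for the `selected`
#'   class, one per row.
#' @export
predict_prob <- function(model, table) {
  stopifnot(inherits(model, "mirnadx_model"), inherits(table, "feature_table"))
  nm <- colnames(table$matrix)
  if (!identical(nm, model$feature_names)) {
    miss <- setdiff(model$feature_names, nm)
    extra <- setdiff(nm, model$feature_names)
    stop("feature mismatch: missing [",
         paste(utils::head(miss, 5), collapse = ", "), "], extra [",
         paste(utils::head(extra, 5), collapse = ", "), "]",
         if (!identical(sort(nm), sort(model$feature_names))) "" else
           " (column order differs)")
  }
  x <- table$matrix
  if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
  switch(model$spec$name,
    naive_bayes = nb_predict(model$fit, x),
    random_tree = rf_predict(model$fit, x),
    random_forest = rf_predict(model$fit, x),
    adaboost_m1 = adaboost_predict(model$fit, x),
    hoeffding_tree = ht_predict(model$fit, x),
    mlp = mlp_predict(model$fit, x),
    sequential_nn = as.numeric(sequential_forward(model$fit$weights, x))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- z-scoring of numeric (non-binary) columns -----------------------------

#' @keywords internal
fit_scaler <- function(x) {
  num <- which(!apply(x, 2L, is_binary_column))
  mu <- colMeans(x[, num, drop = FALSE])
  sd <- apply(x[, num, drop = FALSE], 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  list(num = num, mu = mu, sd = sd)
}

#' @keywords internal
apply_scaler <- function(scaler, x) {
  if (length(scaler$num)) {
    x[, scaler$num] <- sweep(sweep(x[, scaler$num, drop = FALSE], 2L,
                                   scaler$mu, "-"), 2L, scaler$sd, "/")
  }
  x
}

# ---- Naive Bayes (from scratch) --------------------------------------------

#' @keywords internal
nb_fit <- function(x, y) {
  classes <- c(0L, 1L)
  n <- length(y)
  binary <- apply(x, 2L, is_binary_column)
  per_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    nc <- nrow(xc)
    # Bernoulli with add-1 smoothing for binary columns
    p1 <- (colSums(xc[, binary, drop = FALSE] == 1) + 1) / (nc + 2)
    mu <- colMeans(xc[, !binary, drop = FALSE])
    sd <- apply(xc[, !binary, drop = FALSE], 2L, stats::sd)
    sd[is.na(sd) | sd < 1e-6] <- 1e-6
    list(n = nc, prior = nc / n, p1 = p1, mu = mu, sd = sd)
  })
  list(binary = binary, per_class = per_class)
}

#' @keywords internal
nb_predict <- function(fit, x) {
  binary <- fit$binary
  xb <- x[, binary, drop = FALSE]
  xn <- x[, !binary, drop = FALSE]
  loglik <- vapply(fit$per_class, function(cl) {
    ll <- rep(log(cl$prior), nrow(x))
    if (ncol(xb)) {
      lp1 <- matrix(log(cl$p1), nrow(x), ncol(xb), byrow = TRUE)
      lp0 <- matrix(log(1 - cl$p1), nrow(x), ncol(xb), byrow = TRUE)
      ll <- ll + rowSums(ifelse(xb == 1, lp1, lp0))
    }
    if (ncol(xn)) {
      for (j in seq_len(ncol(xn))) {
        ll <- ll + stats::dnorm(xn[, j], cl$mu[j], cl$sd[j], log = TRUE)
      }
    }
    ll
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  mx <- apply(loglik, 1L, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  post[, 2L]  # P(class = selected)
}

#' Naive Bayes posteriors in one call
#'
#' Fits the add-1-smoothed naive Bayes model (Bernoulli likelihoods for
#' binary/one-hot columns, per-class Gaussians for numeric columns) on
#' the training table and returns P(selected) for each test row.
#'
#' @param train A `feature_table` with both classes present.
#' @param test A `feature_table` with the same columns.
#' @return Numeric vector of posterior probabilities of `selected`.
#' @export
nb_fit_predict <- function(train, test) {
  model <- fit_classifier(classifier_spec("naive_bayes"), train)
  predict_prob(model, test)
}

# ---- Hoeffding bound and tree ----------------------------------------------

#' The Hoeffding bound
#'
#' `epsilon = sqrt(R^2 * ln(1/delta) / (2n))`: with probability
#' `1 - delta`, the true mean of a random variable of range `R` is within
#' `epsilon` of its mean over `n` observations. A VFDT splits a node on
#' the best attribute once the observed gap between the top two
#' attribute evaluations exceeds `epsilon`.
#'
#' @param R Range of the split evaluation measure (log2(nclasses) for
#'   information gain).
#' @param delta Allowed probability of choosing a wrong split, in (0, 1).
#' @param n Number of observations at the node.
#' @return The confidence radius `epsilon`.
#' @export
hoeffding_bound <- function(R, delta, n) {
  if (R <= 0) stop("R must be positive")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  sqrt(R^2 * log(1 / delta) / (2 * n))
}

#' @keywords internal
ht_info_gain <- function(counts) {
  # counts: 2 x nvals class-by-value matrix
  n <- sum(counts)
  if (n == 0) return(0)
  h <- function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log2(p))
  }
  h_parent <- h(rowSums(counts))
  nv <- colSums(counts)
  h_children <- sum(vapply(seq_len(ncol(counts)), function(j) {
    if (nv[j] == 0) 0 else nv[j] / n * h(counts[, j])
  }, numeric(1)))
  h_parent - h_children
}

# A VFDT-style Hoeffding tree on discretized attributes: each leaf keeps
# class-by-value counts per attribute, examples are streamed once, and a
# leaf splits when the information-gain gap between the top two
# attributes exceeds the Hoeffding bound (or the bound falls below the
# tie threshold). Leaves predict with naive Bayes over their counts.
#' @keywords internal
ht_fit <- function(x, y, delta = 1e-7, tie_tau = 0.05, grace = 10L,
                   max_depth = 6L, bins = 10L) {
  disc_maps <- lapply(seq_len(ncol(x)), function(j) sort(unique(
    discretize_ef(x[, j], bins))))
  disc <- matrix(0L, nrow(x), ncol(x))
  nvals <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    disc[, j] <- discretize_ef(x[, j], bins)
    nvals[j] <- max(disc[, j])
  }
  new_leaf <- function(depth) {
    env <- new.env(parent = emptyenv())
    env$is_leaf <- TRUE
    env$depth <- depth
    env$counts <- lapply(nvals, function(nv) matrix(0, 2L, nv))
    env$class_n <- c(0, 0)
    env$since_check <- 0L
    env
  }
  root <- new_leaf(0L)
  route <- function(node, row) {
    while (!node$is_leaf) {
      v <- row[node$split_attr]
      child <- node$children[[v]]
      if (is.null(child)) return(node)  # unseen branch: stop at this node
      node <- child
    }
    node
  }
  try_split <- function(node) {
    n <- sum(node$class_n)
    if (n < grace || node$depth >= max_depth) return(invisible(NULL))
    gains <- vapply(node$counts, ht_info_gain, numeric(1))
    ord <- order(gains, decreasing = TRUE)
    g1 <- gains[ord[1]]
    g2 <- if (length(gains) > 1) gains[ord[2]] else 0
    eps <- hoeffding_bound(1, delta, n)
    if (g1 > 0 && (g1 - g2 > eps || eps < tie_tau)) {
      j <- ord[1]
      node$is_leaf <- FALSE
      node$split_attr <- j
      node$children <- vector("list", nvals[j])
      for (v in seq_len(nvals[j])) {
        node$children[[v]] <- new_leaf(node$depth + 1L)
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(nrow(disc))) {
    leaf <- route(root, disc[i, ])
    cl <- y[i] + 1L
    leaf$class_n[cl] <- leaf$class_n[cl] + 1
    for (j in seq_len(ncol(disc))) {
      leaf$counts[[j]][cl, disc[i, j]] <- leaf$counts[[j]][cl, disc[i, j]] + 1
    }
    leaf$since_check <- leaf$since_check + 1L
    if (leaf$is_leaf && leaf$since_check >= grace) {
      leaf$since_check <- 0L
      try_split(leaf)
    }
  }
  # freeze discretization breaks for prediction
  breaks <- lapply(seq_len(ncol(x)), function(j) {
    ux <- unique(x[, j])
    if (length(ux) <= bins) list(kind = "match", levels = sort(ux))
    else list(kind = "cut",
              br = unique(stats::quantile(x[, j],
                                          probs = seq(0, 1, length.out = bins + 1),
                                          type = 7, names = FALSE)))
  })
  list(root = root, breaks = breaks, nvals = nvals)
}

#' @keywords internal
ht_discretize_row <- function(breaks, nvals, row) {
  out <- integer(length(row))
  for (j in seq_along(row)) {
    b <- breaks[[j]]
    v <- if (b$kind == "match") {
      idx <- match(row[j], b$levels)
      if (is.na(idx)) idx <- which.min(abs(b$levels - row[j]))
      idx
    } else {
      br <- b$br
      vv <- findInterval(row[j], br, all.inside = TRUE)
      min(vv, length(br) - 1L)
    }
    out[j] <- min(max(v, 1L), nvals[j])
  }
  out
}

#' @keywords internal
ht_leaf_nb_score <- function(node, row) {
  # naive Bayes over the leaf's per-attribute counts (add-1 smoothing)
  nc <- node$class_n
  if (sum(nc) == 0) return(0.5)
  ll <- log((nc + 1) / (sum(nc) + 2))
  for (j in seq_along(node$counts)) {
    cm <- node$counts[[j]]
    nv <- ncol(cm)
    ll <- ll + log((cm[, row[j]] + 1) / (nc + nv))
  }
  p <- exp(ll - max(ll))
  (p / sum(p))[2L]
}

#' @keywords internal
ht_predict <- function(fit, x) {
  vapply(seq_len(nrow(x)), function(i) {
    row <- ht_discretize_row(fit$breaks, fit$nvals, x[i, ])
    node <- fit$root
    while (!node$is_leaf) {
      child <- node$children[[row[node$split_attr]]]
      if (is.null(child)) break
      if (sum(child$class_n) == 0) break  # empty branch: score at parent
      node <- child
    }
    ht_leaf_nb_score(node, row)
  }, numeric(1))
}

# ---- AdaBoost.M1 -----------------------------------------------------------

#' One AdaBoost.M1 reweighting round
#'
#' Given the current instance weights, which instances the round's weak
#' hypothesis classified correctly, and its weighted error rate
#' `epsilon_t`, computes `beta_t = epsilon_t / (1 - epsilon_t)`,
#' multiplies the weights of correctly classified instances by `beta_t`,
#' and renormalizes all weights to sum 1. An error rate of 0 flags a
#' perfect learner (boosting stops, weights unchanged); an error rate
#' >= 0.5 aborts boosting.
#'
#' @param weights Current instance weights (sum 1).
#' @param correct Logical vector: was each instance classified correctly?
#' @param error_rate The weighted error `epsilon_t` of the hypothesis.
#' @return List with `weights`, `beta`, and `status` in
#'   `c("ok", "perfect", "abort")`.
#' @export
adaboost_round <- function(weights, correct, error_rate) {
  stopifnot(length(weights) == length(correct))
  if (error_rate >= 0.5) {
    return(list(weights = weights, beta = NA_real_, status = "abort"))
  }
  if (error_rate == 0) {
    return(list(weights = weights, beta = 0, status = "perfect"))
  }
  beta <- error_rate / (1 - error_rate)
  w <- weights
  w[correct] <- w[correct] * beta
  w <- w / sum(w)
  list(weights = w, beta = beta, status = "ok")
}

#' @keywords internal
stump_fit <- function(x, y, w) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = c(0L, 1L))
  rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = 1L, minsplit = 2L,
                                              cp = 0, xval = 0))
}

#' @keywords internal
stump_predict <- function(fit, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  as.integer(as.character(stats::predict(fit, df, type = "class")))
}

#' @keywords internal
adaboost_fit <- function(x, y, iterations = 10L) {
  n <- length(y)
  w <- rep(1 / n, n)
  committee <- list()
  alphas <- numeric(0)
  for (t in seq_len(iterations)) {
    stump <- stump_fit(x, y, w)
    pred <- stump_predict(stump, x)
    correct <- pred == y
    eps <- sum(w[!correct])
    if (eps >= 0.5) {
      if (length(committee) == 0L) {
        committee <- list(stump)
        alphas <- 1
      }
      break
    }
    if (eps == 0) {
      committee[[length(committee) + 1L]] <- stump
      alphas <- c(alphas, log(1 / 1e-10))
      break
    }
    upd <- adaboost_round(w, correct, eps)
    committee[[length(committee) + 1L]] <- stump
    alphas <- c(alphas, log(1 / upd$beta))
    w <- upd$weights
  }
  list(committee = committee, alphas = alphas)
}

#' @keywords internal
adaboost_predict <- function(fit, x) {
  votes1 <- numeric(nrow(x))
  total <- sum(fit$alphas)
  for (t in seq_along(fit$committee)) {
    pred <- stump_predict(fit$committee[[t]], x)
    votes1 <- votes1 + fit$alphas[t] * (pred == 1L)
  }
  if (total == 0) return(rep(0.5, nrow(x)))
  votes1 / total
}

# ---- delegated learners: random forest / random tree / MLP -----------------

#' @keywords internal
rf_fit <- function(x, y, ntree, mtry) {
  randomForest::randomForest(x = x, y = factor(y, levels = c(0L, 1L)),
                             ntree = ntree, mtry = max(1L, mtry))
}

#' @keywords internal
rf_predict <- function(fit, x) {
  unname(stats::predict(fit, x, type = "prob")[, "1"])
}

#' @keywords internal
mlp_fit <- function(x, y, maxit = 500L, decay = 1e-4) {
  size <- max(2L, min(20L, floor((ncol(x) + 2) / 2)))
  nnet::nnet(x = x, y = y, size = size, entropy = TRUE, maxit = maxit,
             decay = decay, trace = FALSE, MaxNWts = 100000L)
}

#' @keywords internal
mlp_predict <- function(fit, x) {
  as.numeric(stats::predict(fit, x))
}

# ---- sequential neural network (from scratch) ------------------------------

SEQNN_HIDDEN <- c(100L, 70L, 50L, 30L)

#' Initialize sequential-network weights
#'
#' Glorot-uniform initialization for the fixed architecture
#' input -> 100 -> 70 -> 50 -> 30 -> 1 (ReLU on the dense layers,
#' sigmoid output).
#'
#' @param n_in Number of input features.
#' @param seed Integer seed.
#' @return List of weight matrices `W1..W5` and bias vectors `b1..b5`.
#' @export
seq_init_weights <- function(n_in, seed = 1L) {
  set.seed(seed)
  dims <- c(n_in, SEQNN_HIDDEN, 1L)
  w <- list()
  for (l in seq_len(5L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    w[[paste0("W", l)]] <- matrix(stats::runif(dims[l] * dims[l + 1],
                                               -lim, lim),
                                  dims[l], dims[l + 1])
    w[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  w
}

#' @keywords internal
check_seq_shapes <- function(weights, n_in) {
  dims <- c(n_in, SEQNN_HIDDEN, 1L)
  for (l in seq_len(5L)) {
    W <- weights[[paste0("W", l)]]
    b <- weights[[paste0("b", l)]]
    if (is.null(W) || is.null(b) ||
        nrow(W) != dims[l] || ncol(W) != dims[l + 1] ||
        length(b) != dims[l + 1]) {
      stop("sequential network shape mismatch at layer ", l,
           ": expected ", dims[l], "x", dims[l + 1])
    }
  }
  invisible(TRUE)
}

#' Forward pass of the sequential network
#'
#' Deterministic forward pass through the fixed five-layer architecture:
#' four dense ReLU layers of 100, 70, 50 and 30 neurons, then a single
#' sigmoid output unit. Output is strictly inside (0, 1).
#'
#' @param weights Weight list as produced by [seq_init_weights()].
#' @param x Numeric matrix (rows = instances) or a single row vector.
#' @return Numeric vector of probabilities, one per row.
#' @export
sequential_forward <- function(weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  check_seq_shapes(weights, ncol(x))
  a <- x
  for (l in 1:4) {
    z <- sweep(a %*% weights[[paste0("W", l)]], 2L,
               weights[[paste0("b", l)]], "+")
    a <- pmax(z, 0)
  }
  z5 <- as.numeric(a %*% weights$W5 + weights$b5)
  p <- 1 / (1 + exp(-z5))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @keywords internal
seqnn_forward_full <- function(weights, x) {
  acts <- list(a0 = x)
  a <- x
  for (l in 1:4) {
    z <- sweep(a %*% weights[[paste0("W", l)]], 2L,
               weights[[paste0("b", l)]], "+")
    a <- pmax(z, 0)
    acts[[paste0("a", l)]] <- a
  }
  z5 <- as.numeric(a %*% weights$W5 + weights$b5)
  acts$p <- 1 / (1 + exp(-z5))
  acts
}

#' @keywords internal
train_sequential_core <- function(x, y, epochs = 200L, batch_size = 16L,
                                  lr = 1e-3) {
  # Adam on binary cross-entropy; R's RNG already seeded by the caller.
  n <- nrow(x)
  w <- seq_init_weights_no_seed(ncol(x))
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      acts <- seqnn_forward_full(w, xb)
      p <- pmin(pmax(acts$p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      g <- seqnn_gradients(w, acts, yb)
      t_step <- t_step + 1L
      for (nm in names(w)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^t_step)
        vhat <- v[[nm]] / (1 - b2^t_step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep] <- ep_loss / n
  }
  list(weights = w, loss_history = history)
}

#' @keywords internal
seq_init_weights_no_seed <- function(n_in) {
  dims <- c(n_in, SEQNN_HIDDEN, 1L)
  w <- list()
  for (l in seq_len(5L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    w[[paste0("W", l)]] <- matrix(stats::runif(dims[l] * dims[l + 1],
                                               -lim, lim),
                                  dims[l], dims[l + 1])
    w[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  w
}

#' @keywords internal
seqnn_gradients <- function(w, acts, y) {
  nb <- length(y)
  g <- list()
  delta <- matrix((acts$p - y) / nb, ncol = 1L)        # dL/dz5
  g$W5 <- t(acts$a4) %*% delta
  g$b5 <- colSums(delta)
  back <- delta %*% t(w$W5)
  for (l in 4:1) {
    a_prev <- acts[[paste0("a", l - 1L)]]
    if (l == 1L) a_prev <- acts$a0
    dz <- back * (acts[[paste0("a", l)]] > 0)           # ReLU gate
    g[[paste0("W", l)]] <- t(a_prev) %*% dz
    g[[paste0("b", l)]] <- colSums(dz)
    if (l > 1L) back <- dz %*% t(w[[paste0("W", l)]])
  }
  g
}

#' Train the sequential network on a feature table
#'
#' Convenience wrapper: z-scores numeric columns with training
#' statistics, trains with Adam on binary cross-entropy (learning rate
#' 1e-3, 200 epochs, batch size 16 by default), reproducibly for a given
#' seed.
#'
#' @param train A `feature_table` with binary labels.
#' @param epochs,batch_size,seed Training controls.
#' @return A `mirnadx_model`; its `fit$loss_history` holds the per-epoch
#'   mean training loss.
#' @export
train_sequential <- function(train, epochs = 200L, batch_size = 16L,
                             seed = 1L) {
  fit_classifier(classifier_spec("sequential_nn",
                                 hyperparams = list(epochs = epochs,
                                                    batch_size = batch_size),
                                 seed = seed),
                 train)
}
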