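# Independent oracles and small fixture builders used across tests.
# These deliberately re-derive quantities from first principles (own
# entropy code, pairwise AUC counting, explicit Bayes arithmetic) so
# they stay independent of the package's implementation paths.

# Shannon entropy (bits) of a discrete vector, from scratch
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# symmetric uncertainty from scratch
oracle_su <- function(x, y) {
  hx <- oracle_entropy(x)
  hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  hxy <- oracle_entropy(paste(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

# CFS merit of a subset from a precomputed SU structure
oracle_merit <- function(subset, su_cf, su_ff) {
  k <- length(subset)
  rcf <- mean(su_cf[subset])
  rff <- if (k > 1) {
    pairs <- utils::combn(subset, 2)
    mean(su_ff[cbind(pairs[1, ], pairs[2, ])])
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# AUC by brute-force pairwise comparison (wins + half-ties)
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# a small all-binary feature table with given matrix and labels
binary_table <- function(mat, labels, kinds = NULL) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("G", seq_len(ncol(mat)))
  if (is.null(kinds)) kinds <- rep("gene", ncol(mat))
  feature_table(mat, labels, kinds, paste0("m", seq_len(nrow(mat))))
}

# random binary table with a mix of label-linked and noise features
random_cfs_table <- function(n = 40, p = 8, n_informative = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  mat <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (j <= n_informative) {
      flip <- runif(n) < runif(1, 0.1, 0.4)
      mat[, j] <- ifelse(flip, 1L - y, y)
    } else {
      mat[, j] <- rbinom(n, 1, runif(1, 0.2, 0.8))
    }
  }
  binary_table(mat, ifelse(y == 1, "selected", "random"))
}

motifless <- data.frame(motif = character(0), p_pos = numeric(0),
                        p_neg = numeric(0), stringsAsFactors = FALSE)

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
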