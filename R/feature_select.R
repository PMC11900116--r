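# Correlation-based feature subset selection (CFS): features are scored
# as a set by high feature-class and low feature-feature symmetric
# uncertainty, searched with best-first forward search.

#' Equal-frequency discretization
#'
#' Bins a numeric vector into up to `bins` equal-frequency intervals
#' (quantile cut points, duplicates collapsed). Already-discrete inputs
#' with few unique values pass through as integer codes.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 10).
#' @return Integer codes, one per element.
#' @export
discretize_ef <- function(x, bins = 10) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' @keywords internal
entropy_bits <- function(codes) {
  p <- tabulate(codes)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

#' Symmetric uncertainty between two discrete columns
#'
#' `SU(x, y) = 2 * (H(x) + H(y) - H(x, y)) / (H(x) + H(y))`, the
#' normalized mutual information in \[0, 1\]. Defined as 0 when both
#' marginal entropies are 0 (two constant columns).
#'
#' @param x,y Vectors of equal length; coerced to discrete codes
#'   (numeric input should be discretized first, see [discretize_ef()]).
#' @return A number in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 1L) stop("empty input")
  cx <- match(x, unique(x))
  cy <- match(y, unique(y))
  hx <- entropy_bits(cx)
  hy <- entropy_bits(cy)
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(match(paste(cx, cy), unique(paste(cx, cy))))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

#' @keywords internal
discretized_matrix <- function(table, bins = 10) {
  m <- table$matrix
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) out[, j] <- discretize_ef(m[, j], bins)
  out
}

#' @keywords internal
merit_from_su <- function(rcf_sum, rff_sum, k) {
  # rcf_sum: sum of SU(feature, class); rff_sum: sum over unordered pairs
  rcf <- rcf_sum / k
  rff <- if (k > 1) rff_sum / (k * (k - 1) / 2) else 0
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom == 0) return(0)
  k * rcf / denom
}

#' CFS merit of a feature subset
#'
#' `Merit = k * mean(SU(f, class)) / sqrt(k + k*(k-1) * mean(SU(f, f')))`
#' with k the subset size; the pairwise term is vacuous (0) at k = 1.
#' Numeric columns are discretized by 10-bin equal-frequency binning
#' before the entropy computations.
#'
#' @param subset Integer vector of feature column indices.
#' @param table A `feature_table`.
#' @return The merit, a non-negative number.
#' @export
merit_of <- function(subset, table) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  stopifnot(inherits(table, "feature_table"))
  disc <- discretized_matrix(table)
  y <- match(table$labels, unique(table$labels))
  k <- length(subset)
  rcf_sum <- sum(vapply(subset, function(j)
    symmetric_uncertainty(disc[, j], y), numeric(1)))
  rff_sum <- 0
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        rff_sum <- rff_sum +
          symmetric_uncertainty(disc[, subset[a]], disc[, subset[b]])
      }
    }
  }
  merit_from_su(rcf_sum, rff_sum, k)
}

#' Best-first forward CFS feature selection
#'
#' Greedy best-first search over feature subsets maximizing the CFS
#' merit, starting from the empty set and expanding by single-feature
#' additions. The search stops after `stale_limit` consecutive
#' expansions that fail to improve the best merit. Ties between equally
#' meritorious candidates break toward the lowest feature index, so the
#' result is deterministic given the table.
#'
#' @param table A `feature_table`.
#' @param stale_limit Consecutive non-improving expansions tolerated
#'   (default 5).
#' @param max_features Optional hard cap on the subset size.
#' @return An object of class `selected_subset`: list with
#'   `feature_indices` (in order of addition), `feature_names`, `merit`,
#'   and `search_trace` (data frame of expanded subsets and merits).
#' @export
best_first_select <- function(table, stale_limit = 5, max_features = Inf) {
  stopifnot(inherits(table, "feature_table"), ncol(table$matrix) >= 1)
  disc <- discretized_matrix(table)
  y <- match(table$labels, unique(table$labels))
  p <- ncol(disc)
  su_cf <- vapply(seq_len(p), function(j)
    symmetric_uncertainty(disc[, j], y), numeric(1))
  if (all(su_cf == 0)) {
    warning("all features are uninformative (class SU = 0); empty selection")
    return(structure(list(feature_indices = integer(0),
                          feature_names = character(0),
                          merit = 0,
                          search_trace = data.frame(subset = character(0),
                                                    merit = numeric(0))),
                     class = "selected_subset"))
  }
  su_ff <- matrix(NA_real_, p, p)
  pair_su <- function(a, b) {
    v <- su_ff[a, b]
    if (is.na(v)) {
      v <- symmetric_uncertainty(disc[, a], disc[, b])
      su_ff[a, b] <<- v
      su_ff[b, a] <<- v
    }
    v
  }
  merit_cached <- function(idx) {
    k <- length(idx)
    rff_sum <- 0
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        for (b in seq((a + 1), k)) rff_sum <- rff_sum + pair_su(idx[a], idx[b])
      }
    }
    merit_from_su(sum(su_cf[idx]), rff_sum, k)
  }
  key_of <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  open_sets <- list(integer(0))
  open_merits <- 0
  visited <- new.env(hash = TRUE)
  assign(key_of(integer(0)), TRUE, envir = visited)
  best_idx <- integer(0)
  best_merit <- 0
  stale <- 0L
  trace_subset <- character(0)
  trace_merit <- numeric(0)
  while (length(open_sets) > 0L && stale < stale_limit) {
    i_best <- which.max(open_merits)
    node <- open_sets[[i_best]]
    node_merit <- open_merits[[i_best]]
    open_sets[[i_best]] <- NULL
    open_merits <- open_merits[-i_best]
    trace_subset <- c(trace_subset, key_of(node))
    trace_merit <- c(trace_merit, node_merit)
    improved <- FALSE
    if (length(node) < max_features) {
      for (j in setdiff(seq_len(p), node)) {
        child <- c(node, j)
        key <- key_of(child)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, TRUE, envir = visited)
        m <- merit_cached(child)
        open_sets[[length(open_sets) + 1L]] <- child
        open_merits <- c(open_merits, m)
        if (m > best_merit + 1e-12) {
          best_merit <- m
          best_idx <- child
          improved <- TRUE
        }
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(feature_indices = best_idx,
                 feature_names = colnames(table$matrix)[best_idx],
                 merit = best_merit,
                 search_trace = data.frame(subset = trace_subset,
                                           merit = trace_merit,
                                           stringsAsFactors = FALSE)),
            class = "selected_subset")
}

#' @export
print.selected_subset <- function(x, ...) {
  cat(sprintf("selected_subset: %d features, merit %.4f\n",
              length(x$feature_indices), x$merit))
  if (length(x$feature_names)) {
    cat(paste(strwrap(paste(x$feature_names, collapse = ", "), 70),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
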