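#' Construct a feature table
#'
#' The central design-matrix container: a numeric matrix with named
#' columns, per-row miRNA identifiers, class labels, and a per-column
#' kind tag (`descriptor`, `gene`, or `pathway`).
#'
#' @param matrix Numeric matrix, rows = miRNAs, columns = features.
#' @param labels Character vector over `selected`/`random` (or
#'   `unlabeled`), one per row.
#' @param column_kinds Character vector, one of
#'   `c("descriptor","gene","pathway")` per column.
#' @param row_ids miRNA identifiers, one per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, labels, column_kinds, row_ids) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("feature names must be present and unique")
  }
  if (length(labels) != nrow(matrix)) stop("labels/matrix row mismatch")
  if (length(row_ids) != nrow(matrix)) stop("row_ids/matrix row mismatch")
  if (length(column_kinds) != ncol(matrix)) {
    stop("column_kinds/matrix column mismatch")
  }
  stopifnot(all(column_kinds %in% c("descriptor", "gene", "pathway")))
  onehot <- matrix[, column_kinds != "descriptor", drop = FALSE]
  if (length(onehot) && !all(onehot %in% c(0, 1))) {
    stop("gene and pathway columns must be binary 0/1")
  }
  structure(list(matrix = matrix,
                 labels = as.character(labels),
                 column_kinds = column_kinds,
                 row_ids = as.character(row_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d miRNAs x %d features (%d descriptor, %d gene, %d pathway)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$column_kinds == "descriptor"),
              sum(x$column_kinds == "gene"),
              sum(x$column_kinds == "pathway")))
  lab <- table(x$labels)
  cat("labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Subset the rows of a feature table
#' @param table A `feature_table`.
#' @param i Row index vector.
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(table, i) {
  feature_table(table$matrix[i, , drop = FALSE], table$labels[i],
                table$column_kinds, table$row_ids[i])
}

#' Subset the columns of a feature table
#' @param table A `feature_table`.
#' @param j Column index vector.
#' @return A `feature_table` with the selected columns.
#' @export
ft_cols <- function(table, j) {
  feature_table(table$matrix[, j, drop = FALSE], table$labels,
                table$column_kinds[j], table$row_ids)
}

#' Filter annotations by target score and pathway significance
#'
#' Keeps gene targets with prediction score >= `score_min` (boundary
#' inclusive, mirroring a 97-100% score band) and pathways with
#' enrichment p-value strictly below `p_max` (significance at p < 0.05).
#' Row order is preserved.
#'
#' @param ann An `annotation_set`.
#' @param score_min Minimum target prediction score kept (default 97).
#' @param p_max Pathway p-value threshold, strict (default 0.05).
#' @return A filtered `annotation_set`.
#' @export
filter_annotations <- function(ann, score_min = 97, p_max = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  tg <- ann$targets[ann$targets$score >= score_min, , drop = FALSE]
  pw <- ann$pathways[ann$pathways$p_value < p_max, , drop = FALSE]
  rownames(tg) <- NULL
  rownames(pw) <- NULL
  structure(list(targets = tg, pathways = pw), class = "annotation_set")
}

#' Build the one-hot feature table for a cohort
#'
#' One row per miRNA. Columns are the descriptor block (length,
#' composition, GC, hydrogen bonds, mean mass, 256 tetramer flags)
#' followed by one binary column per gene and per pathway in the
#' vocabulary. With `vocab = NULL` (training mode) the vocabulary is the
#' sorted union of annotated genes/pathways over the cohort, excluding
#' any that attach to zero cohort miRNAs. With a supplied `vocab`
#' (validation mode) the columns match it exactly and unseen
#' genes/pathways are dropped, so train and validation matrices always
#' align by name.
#'
#' @param records Data frame of miRNA records (`mirna_id`, `sequence`,
#'   `label`).
#' @param ann An `annotation_set` (typically already passed through
#'   [filter_annotations()]).
#' @param vocab Optional list with character vectors `genes` and
#'   `pathways` frozen from a training table (see [ft_vocabulary()]).
#' @return A `feature_table`.
#' @export
build_table <- function(records, ann, vocab = NULL) {
  if (is.null(records) || nrow(records) == 0L) stop("cohort is empty")
  stopifnot(inherits(ann, "annotation_set"))
  ids <- records$mirna_id
  if (anyDuplicated(ids)) stop("duplicate miRNA ids in cohort")
  tg <- ann$targets
  pw <- ann$pathways
  stray <- setdiff(unique(c(tg$mirna_id, pw$mirna_id)), ids)
  if (length(stray)) {
    warning(length(stray), " annotation miRNA id(s) not in cohort; ignored")
    tg <- tg[tg$mirna_id %in% ids, , drop = FALSE]
    pw <- pw[pw$mirna_id %in% ids, , drop = FALSE]
  }
  if (is.null(vocab)) {
    vocab <- list(genes = sort(unique(tg$gene)),
                  pathways = sort(unique(pw$pathway_id)))
  } else {
    tg <- tg[tg$gene %in% vocab$genes, , drop = FALSE]
    pw <- pw[pw$pathway_id %in% vocab$pathways, , drop = FALSE]
  }
  desc <- descriptor_matrix(records)
  one_hot_block <- function(df, key, levels) {
    m <- matrix(0, nrow = length(ids), ncol = length(levels),
                dimnames = list(ids, levels))
    if (nrow(df) && length(levels)) {
      m[cbind(match(df$mirna_id, ids), match(df[[key]], levels))] <- 1
    }
    m
  }
  gmat <- one_hot_block(tg, "gene", vocab$genes)
  pmat <- one_hot_block(pw, "pathway_id", vocab$pathways)
  mat <- cbind(desc, gmat, pmat)
  kinds <- c(rep("descriptor", ncol(desc)),
             rep("gene", ncol(gmat)),
             rep("pathway", ncol(pmat)))
  feature_table(mat, records$label, kinds, ids)
}

#' Frozen gene/pathway vocabulary of a feature table
#'
#' @param table A `feature_table` built in training mode.
#' @return List with character vectors `genes` and `pathways`, usable as
#'   the `vocab` argument of [build_table()].
#' @export
ft_vocabulary <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  nm <- colnames(table$matrix)
  list(genes = nm[table$column_kinds == "gene"],
       pathways = nm[table$column_kinds == "pathway"])
}

#' Remove validation miRNAs already seen in training
#'
#' Leakage control for the holdout protocol: any validation record whose
#' id appears among the training ids is dropped, and the number removed
#' is reported via a message.
#'
#' @param validation Data frame of miRNA records.
#' @param training_ids Character vector of training miRNA ids.
#' @return The validation records with overlapping ids removed.
#' @export
exclude_overlap <- function(validation, training_ids) {
  keep <- !(validation$mirna_id %in% training_ids)
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message("exclude_overlap: removed ", n_removed,
            " validation miRNA(s) present in training")
  }
  out <- validation[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
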