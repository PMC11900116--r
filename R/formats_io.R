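#' Read miRNA sequences from a FASTA file
#'
#' Parses a miRBase-style FASTA file into a data frame of miRNA records.
#' The first whitespace-delimited token of each header is taken as the
#' miRNA identifier. Sequences are normalized to the internal RNA alphabet:
#' case-folded to upper case and `T` mapped to `U`. Records come back in
#' file order and are initially unlabeled.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `mirna_id`, `sequence`, `label`
#'   (all `"unlabeled"`), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-test", "acgt"), fa)
#' read_mirna_fasta(fa)  # sequence normalized to "ACGU"
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_seq <- character(0)
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    s <- paste(cur_seq, collapse = "")
    if (!nzchar(s)) {
      stop("FASTA parse error at line ", cur_line,
           ": record '", cur_id, "' has an empty sequence")
    }
    ids[[length(ids) + 1L]] <<- cur_id
    seqs[[length(seqs) + 1L]] <<- s
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>\\s*", "", ln)
      tok <- strsplit(trimws(header), "\\s+")[[1]]
      if (length(tok) == 0L || !nzchar(tok[[1]])) {
        stop("FASTA parse error at line ", i, ": malformed header")
      }
      cur_id <- tok[[1]]
      cur_seq <- character(0)
      cur_line <- i
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) {
        stop("FASTA parse error at line ", i,
             ": sequence data before any header")
      }
      cur_seq[[length(cur_seq) + 1L]] <- trimws(ln)
    }
  }
  flush()
  if (length(ids) == 0L) stop("FASTA parse error: no records in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_rna(seqs, ids)
  data.frame(mirna_id = ids, sequence = seqs,
             label = "unlabeled", stringsAsFactors = FALSE)
}

#' @keywords internal
normalize_rna <- function(seqs, ids) {
  seqs <- chartr("t", "u", toupper(seqs))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("alphabet error: sequence of '", ids[bad][[1]],
         "' contains characters outside A/C/G/U/T")
  }
  seqs
}

#' Write miRNA records to FASTA
#'
#' @param records Data frame with `mirna_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(records, path) {
  stopifnot(nrow(records) >= 1)
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", records$mirna_id)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}

#' Read gene-target and pathway annotation tables
#'
#' Reads the two tab-separated annotation tables that stand in for
#' miRDB-style target predictions and DAVID-style pathway enrichment
#' exports. Both files must have a header row. The targets table needs
#' columns `mirna_id`, `gene`, `score` (score in \[0, 100\]); the pathways
#' table needs `mirna_id`, `pathway_id` (matching `hsa` + 5 digits) and
#' `p_value` (in (0, 1\]). Duplicate (miRNA, gene) rows keep the maximum
#' score; duplicate (miRNA, pathway) rows keep the minimum p-value.
#'
#' @param targets_path Path to the gene-target TSV.
#' @param pathways_path Path to the pathway TSV.
#' @return An `annotation_set`: a list with data frames `targets`
#'   (`mirna_id`, `gene`, `score`) and `pathways` (`mirna_id`,
#'   `pathway_id`, `p_value`).
#' @export
read_annotations <- function(targets_path, pathways_path) {
  tg <- read_tsv_checked(targets_path, c("mirna_id", "gene", "score"))
  pw <- read_tsv_checked(pathways_path, c("mirna_id", "pathway_id", "p_value"))
  tg$score <- parse_num_col(tg$score, targets_path, "score")
  pw$p_value <- parse_num_col(pw$p_value, pathways_path, "p_value")
  annotation_set(tg, pw)
}

#' @keywords internal
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df[required]
}

#' @keywords internal
parse_num_col <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    # +1 for the header row
    stop("row-level error in ", path, " line ", bad[[1]] + 1L,
         ": cannot parse ", col, " value '", x[bad[[1]]], "'")
  }
  v
}

#' Construct an annotation set
#'
#' Validates and deduplicates target/pathway annotation data frames.
#' @param targets Data frame `mirna_id`, `gene`, `score`.
#' @param pathways Data frame `mirna_id`, `pathway_id`, `p_value`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(targets, pathways) {
  stopifnot(all(c("mirna_id", "gene", "score") %in% names(targets)),
            all(c("mirna_id", "pathway_id", "p_value") %in% names(pathways)))
  if (nrow(targets) && any(targets$score < 0 | targets$score > 100)) {
    stop("target score outside [0, 100]")
  }
  if (nrow(pathways)) {
    if (any(!grepl("^hsa[0-9]{5}$", pathways$pathway_id))) {
      stop("pathway_id must match 'hsa' + 5 digits")
    }
    if (any(pathways$p_value <= 0 | pathways$p_value > 1)) {
      stop("pathway p_value outside (0, 1]")
    }
  }
  # duplicate resolution: max score per (mirna, gene), min p per (mirna, pathway)
  if (nrow(targets)) {
    key <- paste(targets$mirna_id, targets$gene, sep = "\r")
    ord <- order(match(key, unique(key)), -targets$score)
    targets <- targets[ord, , drop = FALSE]
    targets <- targets[!duplicated(paste(targets$mirna_id, targets$gene,
                                         sep = "\r")), , drop = FALSE]
    rownames(targets) <- NULL
  }
  if (nrow(pathways)) {
    key <- paste(pathways$mirna_id, pathways$pathway_id, sep = "\r")
    ord <- order(match(key, unique(key)), pathways$p_value)
    pathways <- pathways[ord, , drop = FALSE]
    pathways <- pathways[!duplicated(paste(pathways$mirna_id,
                                           pathways$pathway_id,
                                           sep = "\r")), , drop = FALSE]
    rownames(pathways) <- NULL
  }
  structure(list(targets = targets, pathways = pathways),
            class = "annotation_set")
}

#' Write an annotation set to two TSV files
#'
#' @param ann An `annotation_set`.
#' @param targets_path,pathways_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotations <- function(ann, targets_path, pathways_path) {
  utils::write.table(ann$targets, targets_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$pathways, pathways_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(targets_path, pathways_path))
}

#' Export a feature table as ARFF
#'
#' Writes the design matrix in WEKA's native ARFF format: numeric
#' attributes for numeric descriptors, nominal `{0,1}` attributes for
#' one-hot columns, and a final nominal `{selected,random}` class
#' attribute. Re-reading the file with [read_feature_arff()] reproduces
#' the table exactly.
#'
#' @param table A `feature_table` (see [build_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_arff <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$matrix) < 1 || ncol(table$matrix) < 1) {
    stop("cannot write an empty feature table")
  }
  df <- as.data.frame(table$matrix, check.names = FALSE)
  for (j in seq_len(ncol(df))) {
    if (is_binary_column(table$matrix[, j])) {
      df[[j]] <- factor(as.character(as.integer(table$matrix[, j])),
                        levels = c("0", "1"))
    }
  }
  df$class <- factor(table$labels, levels = c("selected", "random"))
  rownames(df) <- NULL
  foreign::write.arff(df, path)
  invisible(path)
}

#' Read a feature table back from ARFF
#'
#' Inverse of [write_feature_arff()]. Column kinds are recovered from the
#' naming convention: the fixed descriptor names (`len`, `frac_*`, `gc`,
#' `hbonds`, `mean_mass`, `motif_*`) are descriptors, names matching
#' `hsaNNNNN` are pathways, everything else is a gene column.
#'
#' @param path Path to an ARFF file written by [write_feature_arff()].
#' @param row_ids Optional row identifiers (ARFF does not carry them).
#' @return A `feature_table`.
#' @export
read_feature_arff <- function(path, row_ids = NULL) {
  df <- foreign::read.arff(path)
  if (!"class" %in% names(df)) stop("ARFF file lacks a 'class' attribute")
  labels <- as.character(df$class)
  df$class <- NULL
  mat <- vapply(df, function(col) {
    if (is.factor(col)) as.numeric(as.character(col)) else as.numeric(col)
  }, numeric(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(NULL, names(df)))
  if (is.null(row_ids)) row_ids <- paste0("row", seq_len(nrow(df)))
  rownames(mat) <- row_ids
  feature_table(mat, labels, infer_column_kinds(colnames(mat)),
                row_ids = row_ids)
}

#' @keywords internal
infer_column_kinds <- function(nm) {
  kinds <- rep("gene", length(nm))
  desc <- c("len", "frac_A", "frac_C", "frac_G", "frac_U", "gc",
            "hbonds", "mean_mass")
  kinds[nm %in% desc | startsWith(nm, "motif_")] <- "descriptor"
  kinds[grepl("^hsa[0-9]{5}$", nm)] <- "pathway"
  kinds
}

#' Export a feature table as CSV
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(mirna_id = table$row_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$matrix, check.names = FALSE))
  df$class <- table$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
is_binary_column <- function(x) all(x %in% c(0, 1))
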