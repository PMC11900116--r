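# Synthetic labeled miRNA cohorts: sequences plus target/pathway
# annotation tables with class-conditional enrichment of marker genes,
# marker pathways, and sequence motifs, so the full pipeline (filters,
# one-hot building, selection, classification) is exercisable end to end.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the scale of a two-arm biomarker cohort: 44 selected
#' (disease-associated) and 44 random miRNAs of 18-25 nt, 5 marker genes
#' and 2 marker pathways carried with probability 0.9 by selected and
#' 0.1 by random miRNAs, a class-independent background of genes and
#' pathways, and 2 class-biased tetramer motifs. Target scores are drawn
#' uniformly in \[90, 100\] so the score >= 97 filter removes some
#' annotations; marker pathway p-values mostly pass the p < 0.05 filter
#' while background p-values mostly fail it.
#'
#' @param n_selected,n_random Cohort arm sizes.
#' @param seq_len_range Min/max sequence length (nt).
#' @param marker_genes,background_genes,marker_pathways,background_pathways
#'   Vocabulary sizes.
#' @param p_marker_pos,p_marker_neg Carriage probability of each marker
#'   gene/pathway for selected resp. random miRNAs.
#' @param p_background Class-independent carriage probability of
#'   background genes/pathways.
#' @param motif_bias Data frame with columns `motif`, `p_pos`, `p_neg`:
#'   tetramers implanted with class-dependent probability.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_selected = 44L, n_random = 44L,
                             seq_len_range = c(18L, 25L),
                             marker_genes = 5L, background_genes = 40L,
                             marker_pathways = 2L, background_pathways = 10L,
                             p_marker_pos = 0.9, p_marker_neg = 0.1,
                             p_background = 0.3,
                             motif_bias = data.frame(
                               motif = c("AACA", "GUGU"),
                               p_pos = c(0.9, 0.85),
                               p_neg = c(0.1, 0.15),
                               stringsAsFactors = FALSE),
                             seed = 1L) {
  stopifnot(n_selected >= 1L, n_random >= 1L,
            length(seq_len_range) == 2L,
            seq_len_range[1] >= 4L, seq_len_range[1] <= seq_len_range[2])
  probs <- c(p_marker_pos, p_marker_neg, p_background,
             motif_bias$p_pos, motif_bias$p_neg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (nrow(motif_bias) && any(nchar(motif_bias$motif) != 4L)) {
    stop("biased motifs must be tetramers")
  }
  structure(list(n_selected = as.integer(n_selected),
                 n_random = as.integer(n_random),
                 seq_len_range = as.integer(seq_len_range),
                 marker_genes = as.integer(marker_genes),
                 background_genes = as.integer(background_genes),
                 marker_pathways = as.integer(marker_pathways),
                 background_pathways = as.integer(background_pathways),
                 p_marker_pos = p_marker_pos,
                 p_marker_neg = p_marker_neg,
                 p_background = p_background,
                 motif_bias = motif_bias,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @keywords internal
marker_gene_names <- function(k) {
  base <- c("CLIP1", "DSCAM", "MAPK10", "ERCC2", "E2F3",
            "MAP3K9", "TBC1D16", "ASB5")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, sprintf("MRKG%02d", seq_len(k - length(base))))
}

#' @keywords internal
marker_pathway_names <- function(k) {
  base <- c("hsa05161", "hsa05142", "hsa04080", "hsa04724", "hsa04730")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, sprintf("hsa061%02d", seq_len(k - length(base))))
}

#' @keywords internal
random_rna <- function(len) {
  paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' @keywords internal
implant_motif <- function(seq, motif) {
  n <- nchar(seq)
  if (n < 4L) return(seq)
  pos <- sample.int(n - 3L, 1L)
  paste0(substr(seq, 1L, pos - 1L), motif, substr(seq, pos + 4L, n))
}

#' @keywords internal
generate_records <- function(cfg, ids, labels) {
  n <- length(ids)
  pos <- labels == "selected"
  lens <- sample(seq(cfg$seq_len_range[1], cfg$seq_len_range[2]), n,
                 replace = TRUE)
  seqs <- vapply(lens, random_rna, character(1))
  if (nrow(cfg$motif_bias)) {
    for (m in seq_len(nrow(cfg$motif_bias))) {
      p <- ifelse(pos, cfg$motif_bias$p_pos[m], cfg$motif_bias$p_neg[m])
      hit <- stats::runif(n) < p
      for (i in which(hit)) {
        seqs[i] <- implant_motif(seqs[i], cfg$motif_bias$motif[m])
      }
    }
  }
  data.frame(mirna_id = ids, sequence = seqs, label = labels,
             stringsAsFactors = FALSE)
}

#' @keywords internal
generate_annotations <- function(cfg, ids, labels) {
  n <- length(ids)
  pos <- labels == "selected"
  genes_m <- marker_gene_names(cfg$marker_genes)
  genes_b <- if (cfg$background_genes > 0)
    sprintf("BGRN%03d", seq_len(cfg$background_genes)) else character(0)
  paths_m <- marker_pathway_names(cfg$marker_pathways)
  paths_b <- if (cfg$background_pathways > 0)
    sprintf("hsa001%02d", seq_len(cfg$background_pathways)) else character(0)
  tg <- list()
  for (g in genes_m) {
    p <- ifelse(pos, cfg$p_marker_pos, cfg$p_marker_neg)
    hit <- stats::runif(n) < p
    if (any(hit)) {
      tg[[length(tg) + 1L]] <- data.frame(
        mirna_id = ids[hit], gene = g,
        score = stats::runif(sum(hit), 90, 100), stringsAsFactors = FALSE)
    }
  }
  for (g in genes_b) {
    hit <- stats::runif(n) < cfg$p_background
    if (any(hit)) {
      tg[[length(tg) + 1L]] <- data.frame(
        mirna_id = ids[hit], gene = g,
        score = stats::runif(sum(hit), 90, 100), stringsAsFactors = FALSE)
    }
  }
  pw <- list()
  for (pth in paths_m) {
    p <- ifelse(pos, cfg$p_marker_pos, cfg$p_marker_neg)
    hit <- stats::runif(n) < p
    if (any(hit)) {
      pw[[length(pw) + 1L]] <- data.frame(
        mirna_id = ids[hit], pathway_id = pth,
        p_value = stats::runif(sum(hit), 0.001, 0.06),
        stringsAsFactors = FALSE)
    }
  }
  for (pth in paths_b) {
    hit <- stats::runif(n) < cfg$p_background
    if (any(hit)) {
      pw[[length(pw) + 1L]] <- data.frame(
        mirna_id = ids[hit], pathway_id = pth,
        p_value = stats::runif(sum(hit), 0.02, 0.8),
        stringsAsFactors = FALSE)
    }
  }
  tg <- if (length(tg)) do.call(rbind, tg) else
    data.frame(mirna_id = character(0), gene = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  pw <- if (length(pw)) do.call(rbind, pw) else
    data.frame(mirna_id = character(0), pathway_id = character(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  tg$score <- round(tg$score, 1)
  pw$p_value <- signif(pw$p_value, 4)
  annotation_set(tg, pw)
}

#' Generate a labeled synthetic cohort
#'
#' @param cfg A [synthetic_config()].
#' @return List with `records` (miRNA data frame: `mirna_id`,
#'   `sequence`, `label`) and `annotations` (an `annotation_set`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 1))
#' table(cohort$records$label)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_selected + cfg$n_random
  ids <- sprintf("hsa-miR-syn-%03d", seq_len(n))
  labels <- c(rep("selected", cfg$n_selected), rep("random", cfg$n_random))
  records <- generate_records(cfg, ids, labels)
  ann <- generate_annotations(cfg, ids, labels)
  list(records = records, annotations = ann)
}

#' Generate an independent validation cohort
#'
#' Draws `n` new miRNAs (half selected, half random — selected gets the
#' extra one for odd `n`) from the same class-conditional mechanism as
#' the training configuration, with identifiers disjoint from
#' `training_ids`.
#'
#' @param cfg The training [synthetic_config()].
#' @param training_ids Character vector of training miRNA ids.
#' @param n Validation cohort size (default 18).
#' @return List with `records` and `annotations`, as [generate_cohort()].
#' @export
generate_validation <- function(cfg, training_ids, n = 18L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed((cfg$seed + 7919L) %% .Machine$integer.max)
  n_sel <- as.integer(ceiling(n / 2))
  ids <- sprintf("hsa-miR-val-%03d", seq_len(n))
  if (any(ids %in% training_ids)) {
    stop("validation id namespace collides with training ids")
  }
  labels <- c(rep("selected", n_sel), rep("random", n - n_sel))
  records <- generate_records(cfg, ids, labels)
  ann <- generate_annotations(cfg, ids, labels)
  list(records = records, annotations = ann)
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.fa` (FASTA), `targets.tsv`, `pathways.tsv`, and
#' `labels.tsv` under `dir`.
#'
#' @param cohort Output of [generate_cohort()] / [generate_validation()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirna_fasta(cohort$records, file.path(dir, "cohort.fa"))
  write_annotations(cohort$annotations,
                    file.path(dir, "targets.tsv"),
                    file.path(dir, "pathways.tsv"))
  utils::write.table(cohort$records[, c("mirna_id", "label")],
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `cohort.fa`, `targets.tsv`,
#'   `pathways.tsv`, and optionally `labels.tsv`.
#' @return List with `records` and `annotations`.
#' @export
read_cohort <- function(dir) {
  records <- read_mirna_fasta(file.path(dir, "cohort.fa"))
  lab_path <- file.path(dir, "labels.tsv")
  if (file.exists(lab_path)) {
    lab <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    records$label <- lab$label[match(records$mirna_id, lab$mirna_id)]
    records$label[is.na(records$label)] <- "unlabeled"
  }
  ann <- read_annotations(file.path(dir, "targets.tsv"),
                          file.path(dir, "pathways.tsv"))
  list(records = records, annotations = ann)
}
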