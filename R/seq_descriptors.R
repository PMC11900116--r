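# Residue masses: internal (monophosphate) ribonucleotide residues, Da.
RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)

RNA_ALPHABET <- c("A", "C", "G", "U")

#' All 256 tetramers over the RNA alphabet, lexicographically sorted
#'
#' @return Character vector of length 256 (`"AAAA"` ... `"UUUU"`).
#' @export
tetramer_vocabulary <- function() {
  g <- expand.grid(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET,
                   stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste, collapse = ""))
}

#' Tetramer motif presence in a sequence
#'
#' Returns 1 if `motif` occurs as a contiguous substring of `sequence`
#' (overlapping occurrences count), else 0.
#'
#' @param sequence RNA sequence over A/C/G/U.
#' @param motif A 4-mer over A/C/G/U.
#' @return Integer 0 or 1.
#' @export
motif_present <- function(sequence, motif) {
  if (nchar(motif) != 4L) stop("motif must be exactly 4 nt, got '", motif, "'")
  if (grepl("[^ACGU]", motif)) stop("motif contains non-ACGU characters")
  as.integer(grepl(motif, sequence, fixed = TRUE))
}

#' Compute the per-miRNA sequence descriptor vector
#'
#' Descriptors are length (nt), per-base composition fractions, GC
#' fraction, hydrogen-bond count and mean residue mass, plus a binary
#' presence flag for each of the 256 tetramers. The hydrogen-bond count
#' uses each base's Watson-Crick pairing capacity (A/U contribute 2,
#' G/C contribute 3): `2*(nA+nU) + 3*(nG+nC)`. Mean mass is the average
#' internal-residue mass over the sequence, with A = 329.21, C = 305.18,
#' G = 345.21, U = 306.17 Da. Sequences shorter than 4 nt get an all-zero
#' motif block.
#'
#' @param sequence An RNA sequence over A/C/G/U (already normalized).
#' @return A named numeric vector: `len`, `frac_A`, `frac_C`, `frac_G`,
#'   `frac_U`, `gc`, `hbonds`, `mean_mass`, then `motif_AAAA` ...
#'   `motif_UUUU`.
#' @examples
#' d <- compute_descriptors("AAUU")
#' d[["hbonds"]]  # 8
#' @export
compute_descriptors <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGU]", sequence)) {
    stop("sequence contains characters outside A/C/G/U")
  }
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  counts <- vapply(RNA_ALPHABET, function(b) sum(chars == b), integer(1))
  fr <- counts / n
  hb <- 2L * (counts[["A"]] + counts[["U"]]) +
        3L * (counts[["G"]] + counts[["C"]])
  mm <- sum(RNA_RESIDUE_MASS[RNA_ALPHABET] * counts) / n
  vocab <- tetramer_vocabulary()
  if (n >= 4L) {
    starts <- substring(sequence, seq_len(n - 3L), seq(4L, n))
    motifs <- as.numeric(vocab %in% starts)
  } else {
    motifs <- numeric(256L)
  }
  names(motifs) <- paste0("motif_", vocab)
  c(len = n,
    frac_A = fr[["A"]], frac_C = fr[["C"]],
    frac_G = fr[["G"]], frac_U = fr[["U"]],
    gc = fr[["G"]] + fr[["C"]],
    hbonds = hb, mean_mass = mm,
    motifs)
}

#' Descriptor matrix for a cohort
#'
#' @param records Data frame with `mirna_id` and `sequence` columns.
#' @return Numeric matrix, one row per miRNA (rownames = ids), one column
#'   per descriptor.
#' @export
descriptor_matrix <- function(records) {
  stopifnot(nrow(records) >= 1)
  mat <- t(vapply(records$sequence, compute_descriptors, numeric(264L)))
  rownames(mat) <- records$mirna_id
  mat
}
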