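test_that("annotation filters are inclusive at 97 and strict at 0.05", {
  tg <- data.frame(mirna_id = c("m1", "m1", "m1"),
                   gene = c("G1", "G2", "G3"),
                   score = c(96.9, 97.0, 100), stringsAsFactors = FALSE)
  pw <- data.frame(mirna_id = c("m1", "m1"),
                   pathway_id = c("hsa00001", "hsa00002"),
                   p_value = c(0.05, 0.049), stringsAsFactors = FALSE)
  out <- filter_annotations(annotation_set(tg, pw))
  expect_equal(out$targets$score, c(97.0, 100))
  expect_equal(out$pathways$p_value, 0.049)
  empty <- filter_annotations(annotation_set(tg[0, ], pw[0, ]))
  expect_equal(nrow(empty$targets), 0)
  expect_equal(nrow(empty$pathways), 0)
})

test_that("one-hot gene block follows the vocabulary", {
  rec <- data.frame(mirna_id = "m1", sequence = "ACGUACGUACGUACGUAC",
                    label = "selected", stringsAsFactors = FALSE)
  ann <- annotation_set(
    data.frame(mirna_id = "m1", gene = "CLIP1", score = 99,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = character(0), pathway_id = character(0),
               p_value = numeric(0), stringsAsFactors = FALSE))
  tab <- build_table(rec, ann, vocab = list(genes = c("CLIP1", "DSCAM"),
                                            pathways = character(0)))
  expect_equal(unname(tab$matrix[1, c("CLIP1", "DSCAM")]), c(1, 0))
  expect_equal(tab$column_kinds[match(c("CLIP1", "DSCAM"),
                                      colnames(tab$matrix))],
               c("gene", "gene"))
})

test_that("default cohort builds an 88-row balanced table", {
  cohort <- generate_cohort(synthetic_config(seed = 2))
  tab <- build_table(cohort$records, filter_annotations(cohort$annotations))
  expect_equal(nrow(tab$matrix), 88)
  expect_equal(unname(table(tab$labels)["selected"]), 44L, ignore_attr = TRUE)
  expect_equal(unname(table(tab$labels)["random"]), 44L, ignore_attr = TRUE)
  # one-hot row sums equal the miRNA's post-filter in-vocabulary annotations
  annf <- filter_annotations(cohort$annotations)
  vocab <- ft_vocabulary(tab)
  onehot <- tab$matrix[, tab$column_kinds != "descriptor", drop = FALSE]
  for (i in sample(seq_len(88), 10)) {
    id <- tab$row_ids[i]
    n_ann <- sum(annf$targets$mirna_id == id &
                   annf$targets$gene %in% vocab$genes) +
      sum(annf$pathways$mirna_id == id &
            annf$pathways$pathway_id %in% vocab$pathways)
    expect_equal(sum(onehot[i, ]), n_ann)
  }
})

test_that("validation tables align exactly with the training vocabulary", {
  cohort <- generate_cohort(synthetic_config(seed = 3))
  annf <- filter_annotations(cohort$annotations)
  train <- build_table(cohort$records, annf)
  val <- generate_validation(synthetic_config(seed = 3),
                             cohort$records$mirna_id)
  vtab <- suppressWarnings(
    build_table(val$records, filter_annotations(val$annotations),
                vocab = ft_vocabulary(train)))
  expect_identical(colnames(vtab$matrix), colnames(train$matrix))
  expect_identical(vtab$column_kinds, train$column_kinds)
})

test_that("training-overlap exclusion removes exactly the shared ids", {
  val <- data.frame(mirna_id = c("v1", "v2"), sequence = c("ACGU", "ACGU"),
                    label = "selected", stringsAsFactors = FALSE)
  expect_message(out <- exclude_overlap(val, "v2"), "removed 1")
  expect_equal(out$mirna_id, "v1")
  expect_silent(out2 <- exclude_overlap(val, c("x1", "x2")))
  expect_equal(out2$mirna_id, c("v1", "v2"))
})

test_that("degenerate build inputs are rejected", {
  ann <- annotation_set(
    data.frame(mirna_id = character(0), gene = character(0),
               score = numeric(0), stringsAsFactors = FALSE),
    data.frame(mirna_id = character(0), pathway_id = character(0),
               p_value = numeric(0), stringsAsFactors = FALSE))
  expect_error(build_table(NULL, ann), "empty")
  rec0 <- data.frame(mirna_id = character(0), sequence = character(0),
                     label = character(0), stringsAsFactors = FALSE)
  expect_error(build_table(rec0, ann), "empty")
})
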