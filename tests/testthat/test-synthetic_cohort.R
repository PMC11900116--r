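test_that("default cohort matches the study scale and is seed-reproducible", {
  cohort <- generate_cohort(synthetic_config(n_selected = 44, n_random = 44,
                                             seed = 1))
  expect_equal(nrow(cohort$records), 88)
  expect_equal(sum(cohort$records$label == "selected"), 44)
  expect_equal(sum(cohort$records$label == "random"), 44)
  lens <- nchar(cohort$records$sequence)
  expect_true(all(lens >= 18 & lens <= 25))
  expect_true(all(!grepl("[^ACGU]", cohort$records$sequence)))
  # byte-identical artifacts from the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(synthetic_config(seed = 1)), d1)
  write_cohort(generate_cohort(synthetic_config(seed = 1)), d2)
  for (f in c("cohort.fa", "targets.tsv", "pathways.tsv", "labels.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # round trip through the writers/readers
  back <- read_cohort(d1)
  expect_equal(back$records$sequence, cohort$records$sequence)
  expect_equal(back$records$label, cohort$records$label)
})

test_that("score and p-value distributions make the filters bite", {
  cohort <- generate_cohort(synthetic_config(seed = 2))
  ann <- cohort$annotations
  annf <- filter_annotations(ann)
  expect_lt(nrow(annf$targets), nrow(ann$targets))
  expect_gt(nrow(annf$targets), 0)
  expect_lt(nrow(annf$pathways), nrow(ann$pathways))
  expect_gt(nrow(annf$pathways), 0)
})

test_that("a null configuration yields chance-level classification", {
  cfg <- synthetic_config(p_marker_pos = 0.3, p_marker_neg = 0.3,
                          motif_bias = motifless, seed = 9)
  cohort <- generate_cohort(cfg)
  tab <- build_table(cohort$records, filter_annotations(cohort$annotations))
  rep_nb <- cross_validate(classifier_spec("naive_bayes", seed = 9), tab,
                           k = 10, seed = 9)
  expect_gte(rep_nb$accuracy_pct, 35)
  expect_lte(rep_nb$accuracy_pct, 65)
})

test_that("classification accuracy is monotone in the marker effect size", {
  medians <- vapply(list(c(0.5, 0.5), c(0.7, 0.3), c(0.9, 0.1)),
                    function(pp) {
    accs <- vapply(1:5, function(s) {
      cfg <- synthetic_config(p_marker_pos = pp[1], p_marker_neg = pp[2],
                              motif_bias = motifless, seed = s)
      cohort <- generate_cohort(cfg)
      tab <- build_table(cohort$records,
                         filter_annotations(cohort$annotations))
      cross_validate(classifier_spec("naive_bayes", seed = s), tab,
                     k = 10, seed = s)$accuracy_pct
    }, numeric(1))
    stats::median(accs)
  }, numeric(1))
  expect_true(all(diff(medians) >= 0))
})

test_that("feature selection recovers implanted marker genes", {
  markers <- c("CLIP1", "DSCAM", "MAPK10", "ERCC2", "E2F3")
  hits <- vapply(1:5, function(s) {
    cfg <- synthetic_config(marker_pathways = 0L, motif_bias = motifless,
                            seed = s)
    cohort <- generate_cohort(cfg)
    tab <- build_table(cohort$records, cohort$annotations)
    sel <- best_first_select(tab)
    sum(markers %in% sel$feature_names)
  }, numeric(1))
  expect_gte(sum(hits >= 3), 4)
})

test_that("validation cohorts are disjoint from training and well-calibrated", {
  cfg <- synthetic_config(seed = 4)
  cohort <- generate_cohort(cfg)
  val <- generate_validation(cfg, cohort$records$mirna_id, n = 18)
  expect_equal(nrow(val$records), 18)
  expect_length(intersect(val$records$mirna_id, cohort$records$mirna_id), 0)
  expect_silent(out <- exclude_overlap(val$records, cohort$records$mirna_id))
  expect_equal(nrow(out), 18)
  # marker-gene carriage among validation positives within a binomial CI
  # of p_marker_pos (pooled over marker genes and seeds for power)
  markers <- c("CLIP1", "DSCAM", "MAPK10", "ERCC2", "E2F3")
  carried <- 0L; trials <- 0L
  for (s in 1:5) {
    cfgs <- synthetic_config(seed = s)
    co <- generate_cohort(cfgs)
    v <- generate_validation(cfgs, co$records$mirna_id, n = 18)
    pos_ids <- v$records$mirna_id[v$records$label == "selected"]
    for (g in markers) {
      gid <- v$annotations$targets$mirna_id[v$annotations$targets$gene == g]
      carried <- carried + sum(pos_ids %in% gid)
      trials <- trials + length(pos_ids)
    }
  }
  ci <- stats::binom.test(carried, trials)$conf.int
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(p_marker_pos = 1.2), "probabilities")
  expect_error(synthetic_config(n_selected = 0), "n_selected")
  expect_error(synthetic_config(
    motif_bias = data.frame(motif = "AAC", p_pos = .5, p_neg = .5)),
    "tetramer")
})
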