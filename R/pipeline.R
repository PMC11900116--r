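# Pipeline orchestration: simulate/ingest -> descriptors -> filter ->
# build -> select -> cross-validate the classifier bank -> train the two
# best learners on the full training table -> independent holdout.

#' Default run configuration
#'
#' @param seed Master seed for the run; every stochastic stage derives
#'   its seed from it.
#' @param outdir Output directory for artifacts (`NULL` = no files).
#' @param simulate If `TRUE`, generate the default synthetic cohort; if
#'   `FALSE` the `paths` entries must point at FASTA/TSV inputs.
#' @return A named list usable as `config` in [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, outdir = NULL, simulate = TRUE) {
  list(simulate = simulate,
       synthetic = list(),          # overrides for synthetic_config()
       paths = list(fasta = NULL, targets = NULL, pathways = NULL,
                    labels = NULL,
                    validation_fasta = NULL, validation_targets = NULL,
                    validation_pathways = NULL, validation_labels = NULL),
       filter = list(score_min = 97, p_max = 0.05),
       selection = list(stale_limit = 5L, max_features = Inf),
       classifiers = CLASSIFIER_NAMES,
       k = 10L,
       validation_n = 18L,
       seed = as.integer(seed),
       outdir = outdir)
}

#' Read a YAML run configuration
#'
#' Missing entries fall back to [default_run_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (is.null(user$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @keywords internal
stage_error <- function(stage, ...) {
  stop("stage '", stage, "': ", ..., call. = FALSE)
}

#' @keywords internal
ingest_training <- function(config) {
  if (isTRUE(config$simulate)) {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% config$seed
    cfg <- do.call(synthetic_config, syn_args)
    list(cohort = generate_cohort(cfg), syn_cfg = cfg)
  } else {
    p <- config$paths
    for (need in c("fasta", "targets", "pathways", "labels")) {
      if (is.null(p[[need]])) {
        stage_error("ingest", "config is missing paths$", need)
      }
    }
    records <- read_mirna_fasta(p$fasta)
    lab <- utils::read.delim(p$labels, stringsAsFactors = FALSE)
    records$label <- lab$label[match(records$mirna_id, lab$mirna_id)]
    if (anyNA(records$label)) {
      stage_error("ingest", "labels file does not cover every miRNA")
    }
    ann <- read_annotations(p$targets, p$pathways)
    list(cohort = list(records = records, annotations = ann), syn_cfg = NULL)
  }
}

#' @keywords internal
ingest_validation <- function(config, training, syn_cfg) {
  if (isTRUE(config$simulate)) {
    generate_validation(syn_cfg, training$records$mirna_id,
                        n = config$validation_n %||% 18L)
  } else {
    p <- config$paths
    if (is.null(p$validation_fasta)) return(NULL)
    records <- read_mirna_fasta(p$validation_fasta)
    lab <- utils::read.delim(p$validation_labels, stringsAsFactors = FALSE)
    records$label <- lab$label[match(records$mirna_id, lab$mirna_id)]
    ann <- read_annotations(p$validation_targets, p$validation_pathways)
    list(records = records, annotations = ann)
  }
}

#' Run the full classification pipeline
#'
#' Executes: cohort ingest (or synthesis), descriptor computation,
#' annotation filtering, one-hot table construction, CFS feature
#' selection, stratified k-fold cross-validation of the whole classifier
#' bank on the selected features, training of the two best classifiers
#' (highest pooled CV accuracy, ties broken by AUC) on the full training
#' table, and holdout evaluation on an independent validation cohort
#' with training-id overlap excluded. When `config$outdir` is set, the
#' training table (ARFF + CSV), selection report, per-classifier
#' cross-validation reports, holdout reports, and a run manifest are
#' written there.
#'
#' @param config A config list, see [default_run_config()] /
#'   [read_run_config()].
#' @return List with `table` (training `feature_table`), `selection`
#'   (a `selected_subset`), `cv_reports` (named list of `eval_report`),
#'   `holdout_reports` (named list, the two best), `top2` (their names),
#'   and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  ing <- tryCatch(ingest_training(config),
                  error = function(e) stage_error("ingest", conditionMessage(e)))
  cohort <- ing$cohort

  ann_f <- tryCatch(
    filter_annotations(cohort$annotations,
                       score_min = config$filter$score_min %||% 97,
                       p_max = config$filter$p_max %||% 0.05),
    error = function(e) stage_error("filter", conditionMessage(e)))

  full_table <- tryCatch(build_table(cohort$records, ann_f),
                         error = function(e)
                           stage_error("build", conditionMessage(e)))

  selection <- tryCatch(
    best_first_select(full_table,
                      stale_limit = config$selection$stale_limit %||% 5L,
                      max_features = config$selection$max_features %||% Inf),
    error = function(e) stage_error("select", conditionMessage(e)))
  sel_idx <- selection$feature_indices
  work_table <- if (length(sel_idx)) ft_cols(full_table, sel_idx) else full_table

  cls <- config$classifiers %||% CLASSIFIER_NAMES
  cv_reports <- list()
  for (nm in cls) {
    spec <- classifier_spec(nm, seed = config$seed)
    cv_reports[[nm]] <- tryCatch(
      cross_validate(spec, work_table, k = config$k %||% 10L,
                     seed = config$seed),
      error = function(e) stage_error("evaluate", nm, ": ",
                                      conditionMessage(e)))
  }

  acc <- vapply(cv_reports, function(r) r$accuracy_pct, numeric(1))
  auc <- vapply(cv_reports, function(r) r$auc, numeric(1))
  top2 <- names(sort(-(acc + 1e-6 * auc)))[seq_len(min(2L, length(acc)))]

  holdout_reports <- list()
  validation <- tryCatch(ingest_validation(config, cohort, ing$syn_cfg),
                         error = function(e)
                           stage_error("validate", conditionMessage(e)))
  if (!is.null(validation)) {
    vrec <- exclude_overlap(validation$records, cohort$records$mirna_id)
    v_ann <- filter_annotations(validation$annotations,
                                score_min = config$filter$score_min %||% 97,
                                p_max = config$filter$p_max %||% 0.05)
    v_full <- suppressWarnings(
      build_table(vrec, v_ann, vocab = ft_vocabulary(full_table)))
    v_table <- if (length(sel_idx)) ft_cols(v_full, sel_idx) else v_full
    for (nm in top2) {
      model <- fit_classifier(classifier_spec(nm, seed = config$seed),
                              work_table)
      holdout_reports[[nm]] <- tryCatch(
        validate_holdout(model, v_table),
        error = function(e) stage_error("validate", nm, ": ",
                                        conditionMessage(e)))
    }
  }

  manifest <- list(
    package = "mirnadx",
    version = as.character(utils::packageVersion("mirnadx")),
    seed = config$seed,
    k = config$k %||% 10L,
    filter = config$filter,
    simulate = isTRUE(config$simulate),
    synthetic = if (!is.null(ing$syn_cfg))
      ing$syn_cfg[setdiff(names(ing$syn_cfg), "motif_bias")],
    motif_bias = if (!is.null(ing$syn_cfg)) ing$syn_cfg$motif_bias,
    classifiers = cls,
    n_training = nrow(full_table$matrix),
    n_features_full = ncol(full_table$matrix),
    selected_features = selection$feature_names,
    selection_merit = selection$merit,
    top2 = top2)

  result <- list(table = full_table, selection = selection,
                 cv_reports = cv_reports, holdout_reports = holdout_reports,
                 top2 = top2, manifest = manifest)

  if (!is.null(config$outdir)) {
    write_run_artifacts(result, work_table, config$outdir)
  }
  result
}

#' @keywords internal
write_run_artifacts <- function(result, work_table, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "reports"), showWarnings = FALSE)
  write_feature_arff(work_table, file.path(outdir, "training.arff"))
  write_feature_csv(work_table, file.path(outdir, "training.csv"))
  jsonlite::write_json(
    list(feature_names = result$selection$feature_names,
         merit = result$selection$merit,
         trace = result$selection$search_trace),
    file.path(outdir, "selection.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (nm in names(result$cv_reports)) {
    write_eval_report(result$cv_reports[[nm]],
                      file.path(outdir, "reports", paste0("cv_", nm, ".json")))
  }
  for (nm in names(result$holdout_reports)) {
    write_eval_report(result$holdout_reports[[nm]],
                      file.path(outdir, "reports",
                                paste0("holdout_", nm, ".json")))
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
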