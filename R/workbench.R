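#' End-to-end experiment configuration
#'
#' Bundles the simulator, quality-control, panel-selection and classifier
#' settings for [run_end_to_end()]. The default mirrors the reference study
#' design: a balanced simulated training cohort (50 specimens per class over
#' 21 classes) standing in for the external pan-cancer training database, and
#' an independently simulated validation cohort with the published cohort
#' composition plus injected quality-control failures.
#'
#' @param sim A [sim_config()].
#' @param train_per_class Training specimens per class (default 50).
#' @param validation A [cohort_composition()] for the validation cohort
#'   (default [table1_composition()]).
#' @param failures Named QC-failure counts injected into the validation
#'   cohort (default 7 low tumor content, 1 high necrosis, 2 reference-Ct
#'   failures).
#' @param thresholds A [qc_thresholds()].
#' @param k Panel genes kept per class (default 10).
#' @param rfe_cost Margin cost of the RFE inner separator (default 0.01, see
#'   [rfe_rank()]).
#' @param cost,cv_folds Classifier hyperparameters.
#' @param seed Global seed; all stage seeds derive from it.
#' @param panel_file Optional path to a [write_panel_json()] file; when set,
#'   panel selection is skipped and the external panel is used.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              train_per_class = 50,
                              validation = table1_composition(),
                              failures = c(low_tumor_content = 7,
                                           high_necrosis = 1,
                                           reference_ct_high = 2),
                              thresholds = qc_thresholds(),
                              k = 10, rfe_cost = 0.01, cost = 1, cv_folds = 3,
                              seed = 7,
                              panel_file = NULL) {
  if (!inherits(sim, "sim_config")) abort("`sim` must be a sim_config.")
  if (!inherits(validation, "cohort_composition")) {
    abort("`validation` must be a cohort_composition.")
  }
  if (!is.null(panel_file) && !file.exists(panel_file)) {
    abort(sprintf("panel_file '%s' does not exist.", panel_file))
  }
  structure(
    list(sim = sim, train_per_class = train_per_class,
         validation = validation, failures = failures,
         thresholds = thresholds, k = k, rfe_cost = rfe_cost, cost = cost,
         cv_folds = cv_folds,
         seed = as.integer(seed), panel_file = panel_file),
    class = "experiment_config"
  )
}

#' Run the full simulated experiment
#'
#' Simulates independent training and validation cohorts, injects
#' quality-control failures into the validation cohort, runs the two-stage QC
#' with sample accounting, normalizes Ct profiles to delta-Ct, selects the
#' marker panel by per-class SVM-RFE (or loads an external panel), trains the
#' calibrated one-vs-rest classifier on the training cohort, predicts the
#' validation specimens that passed QC, and evaluates concordance, exact
#' binomial CI, subgroup comparisons, micro-averaged AUC and clustering.
#' Deterministic for a fixed config.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with elements `qc`,
#'   `accounting`, `panel`, `classifier`, `predictions`, `concordance`,
#'   `accuracy`, `ci`, `auc`, `comparisons`, `clustering`, `discordant`,
#'   `provenance`.
#' @export
run_end_to_end <- function(config) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must be an experiment_config.")
  }
  sim <- config$sim
  truth <- generate_marker_truth(sim)
  refs <- reference_genes(truth)
  panel_all <- panel_genes(truth)

  train <- simulate_cohort(
    truth, uniform_composition(sim$classes, config$train_per_class),
    seed = config$seed, id_prefix = "T"
  )
  valid <- simulate_cohort(truth, config$validation,
                           seed = config$seed + 1L, id_prefix = "V")
  if (sum(config$failures) > 0) {
    valid <- inject_qc_failures(valid, truth, config$failures,
                                seed = config$seed + 2L)
  }

  qc <- run_qc(valid, refs, config$thresholds)
  accounting <- qc_accounting(qc)
  valid_pass <- qc_passed(qc)

  train_expr <- normalize_expression(train, refs, panel_all, cap = sim$ct_cap)
  valid_expr <- normalize_expression(valid_pass, refs, panel_all,
                                     cap = sim$ct_cap)

  if (!is.null(config$panel_file)) {
    panel <- read_panel_json(config$panel_file)
    panel_source <- list(file = config$panel_file,
                         hash = rlang::hash(readr::read_file(config$panel_file)))
  } else {
    panel <- select_panel(train_expr, train$reference_diagnosis, k = config$k,
                          cost = config$rfe_cost)
    panel_source <- list(file = NULL, hash = NULL)
  }

  clf <- train_origin_classifier(
    dplyr::select(train_expr, "specimen_id", dplyr::all_of(panel$genes)),
    train$reference_diagnosis,
    cost = config$cost, cv_folds = config$cv_folds, classes = sim$classes,
    seed = config$seed + 3L
  )

  predictions <- predict_origin(clf, valid_expr)
  eval_tbl <- dplyr::inner_join(
    predictions[, c("specimen_id", "predicted")],
    valid_pass[, intersect(c("specimen_id", "reference_diagnosis",
                             "specimen_type", "differentiation"),
                           names(valid_pass))],
    by = "specimen_id"
  )
  concordance <- concordance_table(eval_tbl)
  n_total <- nrow(eval_tbl)
  n_correct <- sum(eval_tbl$reference_diagnosis == eval_tbl$predicted)
  ci <- binomial_accuracy_ci(n_correct, n_total)
  auc <- multiclass_auc(predictions, eval_tbl$reference_diagnosis)
  comparisons <- dplyr::bind_rows(
    subgroup_comparison(eval_tbl, "specimen_type", "biopsy", "resection"),
    subgroup_comparison(eval_tbl, "differentiation", "well", "poor")
  )
  discordant <- discordance_report(predictions, valid_pass)

  # clustering restricted to tumor types with more than five specimens
  big <- names(which(table(eval_tbl$reference_diagnosis) > 5))
  clustering <- NULL
  if (length(big) >= 2) {
    rows <- eval_tbl$specimen_id[eval_tbl$reference_diagnosis %in% big]
    clustering <- cluster_expression(
      valid_expr[valid_expr$specimen_id %in% rows, ]
    )
  }

  structure(
    list(
      qc = qc, accounting = accounting, panel = panel, classifier = clf,
      predictions = predictions, concordance = concordance,
      accuracy = n_correct / n_total, ci = ci, auc = auc,
      comparisons = comparisons, clustering = clustering,
      discordant = discordant,
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        panel_source = panel_source,
        package_version = as.character(utils::packageVersion("ctorigin"))
      )
    ),
    class = "experiment_result"
  )
}

subgroup_comparison <- function(eval_tbl, covariate, level1, level2) {
  if (!covariate %in% names(eval_tbl)) return(NULL)
  ok <- eval_tbl$reference_diagnosis == eval_tbl$predicted
  g1 <- eval_tbl[[covariate]] == level1
  g2 <- eval_tbl[[covariate]] == level2
  counts <- matrix(
    c(sum(ok & g1), sum(!ok & g1), sum(ok & g2), sum(!ok & g2)),
    2, 2, byrow = TRUE
  )
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) return(NULL)
  out <- compare_group_accuracy(counts)
  dplyr::mutate(out, covariate = covariate,
                groups = paste(level1, "vs", level2), .before = 1)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %d/%d QC-passing specimens, accuracy %.3f, micro AUC %.3f\n",
    x$accounting$n_pass_rtpcr, x$accounting$n_input, x$accuracy, x$auc$micro_auc))
  invisible(x)
}

#' @export
glance.experiment_result <- function(x, ...) {
  tibble(
    n_input = x$accounting$n_input,
    n_pass = x$accounting$n_pass_rtpcr,
    accuracy = x$accuracy,
    ci_lower = x$ci$lower, ci_upper = x$ci$upper,
    micro_auc = x$auc$micro_auc,
    panel_size = length(x$panel$genes)
  )
}

paper_fixture <- function(name) {
  path <- system.file("extdata", name, package = "ctorigin")
  if (path == "") abort(sprintf("Fixture '%s' not found.", name))
  read_tsv_file(path)
}

#' Recompute the published summary statistics from the printed count tables
#'
#' Loads the shipped count fixtures (cohort composition and characteristics,
#' per-type concordance counts, and the discordant-case listing), recomputes
#' every derived statistic from raw counts — per-type sensitivities, the
#' overall concordance over liver metastases and over all specimens, the
#' exact binomial confidence interval, subgroup accuracies obtained by
#' cross-referencing cohort counts with the discordant cases, and the
#' group-comparison p-values — and compares each against the published value
#' at its printed rounding.
#'
#' @param strict Error if any recomputed value disagrees with the published
#'   one (default `FALSE`).
#' @return Tibble: `quantity`, `value` (recomputed, at printed rounding),
#'   `printed`, `match`.
#' @export
#' @examples
#' reproduce_paper_tables()
reproduce_paper_tables <- function(strict = FALSE) {
  types <- paper_fixture("table1_tumor_types.tsv")
  chars <- paper_fixture("table1_characteristics.tsv")
  conc <- paper_fixture("table2_concordance.tsv")
  disc <- paper_fixture("table3_discordant.tsv")
  printed <- paper_fixture("printed_statistics.tsv")

  char_n <- function(characteristic, level) {
    chars$n[chars$characteristic == characteristic & chars$level == level]
  }
  n_misc <- function(flag) sum(flag)

  lm_n <- sum(conc$n_samples)
  lm_correct <- sum(conc$n_correct)
  n_liver <- types$n[types$tumor_type == "Liver"]
  liver_correct <- n_liver - sum(disc$reference_diagnosis == "Liver")
  overall_n <- sum(types$n)
  overall_correct <- lm_correct + liver_correct

  ci <- binomial_accuracy_ci(lm_correct, lm_n)

  n_well <- char_n("differentiation", "Well")
  n_poor <- char_n("differentiation", "Poorly")
  misc_well <- n_misc(disc$differentiation == "Well")
  misc_poor <- n_misc(disc$differentiation == "Poorly")
  n_biopsy <- char_n("specimen_type", "Biopsy")
  n_resection <- char_n("specimen_type", "Resection")
  misc_biopsy <- n_misc(disc$sample_type == "Biopsy")
  misc_resection <- n_misc(disc$sample_type == "Surgery")
  n_scc <- char_n("histology", "Squamous cell carcinoma")
  misc_scc <- n_misc(disc$histological_subtype == "SCC")

  p_diff <- compare_group_accuracy(matrix(
    c(n_well - misc_well, misc_well, n_poor - misc_poor, misc_poor),
    2, 2, byrow = TRUE))$p_value
  p_type <- compare_group_accuracy(matrix(
    c(n_biopsy - misc_biopsy, misc_biopsy,
      n_resection - misc_resection, misc_resection),
    2, 2, byrow = TRUE))$p_value

  pct <- function(num, den) round_away(100 * num / den, 1)
  headline <- tibble(
    quantity = c(
      "lm_concordance_pct", "overall_concordance_pct",
      "primary_liver_concordance_pct", "ci_lower", "ci_upper",
      "well_differentiated_pct", "poorly_differentiated_pct",
      "biopsy_pct", "resection_pct", "scc_subgroup_pct",
      "p_differentiation", "p_specimen_type"
    ),
    value = c(
      pct(lm_correct, lm_n), pct(overall_correct, overall_n),
      pct(liver_correct, n_liver),
      round_away(ci$lower, 2), round_away(ci$upper, 2),
      pct(n_well - misc_well, n_well), pct(n_poor - misc_poor, n_poor),
      pct(n_biopsy - misc_biopsy, n_biopsy),
      pct(n_resection - misc_resection, n_resection),
      pct(n_scc - misc_scc, n_scc),
      round_away(p_diff, 2), round_away(p_type, 2)
    )
  )
  headline <- dplyr::left_join(headline, printed, by = c(quantity = "statistic"))

  per_type <- tibble(
    quantity = paste0("sensitivity_", gsub("[^A-Za-z0-9]", "_",
                                           tolower(conc$tumor_type))),
    value = round_away(100 * conc$n_correct / conc$n_samples, 1),
    printed = conc$printed_sensitivity
  )

  out <- dplyr::bind_rows(headline, per_type)
  out$match <- abs(out$value - out$printed) < 1e-9
  if (strict && !all(out$match)) {
    bad <- out$quantity[!out$match]
    abort(sprintf("Recomputed value(s) disagree with the printed ones: %s",
                  paste(bad, collapse = ", ")))
  }
  out
}
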