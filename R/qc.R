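#' Quality-control thresholds
#'
#' Defaults follow the assay's enrollment and laboratory gates: at least 60%
#' tumor-cell content, less than 40% necrosis, reference-gene Ct no greater
#' than 38, and an A260/A280 purity ratio between 1.7 and 2.1 (inclusive).
#'
#' @param tumor_content_min Minimum tumor-cell fraction (inclusive).
#' @param necrosis_max Maximum necrotic fraction (inclusive).
#' @param ref_ct_max Maximum reference-gene Ct statistic (inclusive).
#' @param purity_ratio_window Inclusive A260/A280 window.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(tumor_content_min = 0.60,
                          necrosis_max = 0.40,
                          ref_ct_max = 38,
                          purity_ratio_window = c(1.7, 2.1)) {
  if (!all(is.finite(c(tumor_content_min, necrosis_max, ref_ct_max,
                       purity_ratio_window)))) {
    abort("All thresholds must be finite.")
  }
  if (purity_ratio_window[1] >= purity_ratio_window[2]) {
    abort("purity_ratio_window lower bound must be below the upper bound.")
  }
  structure(
    list(tumor_content_min = tumor_content_min, necrosis_max = necrosis_max,
         ref_ct_max = ref_ct_max, purity_ratio_window = purity_ratio_window),
    class = "qc_thresholds"
  )
}

#' Run the two-stage specimen quality-control pipeline
#'
#' Stage 1 (histologic) excludes specimens with tumor content below the
#' minimum or necrosis above the maximum. Stage 2 (RT-PCR) excludes surviving
#' specimens whose reference-gene Ct statistic exceeds the cap or whose
#' A260/A280 ratio falls outside the window. A specimen missing a required
#' attribute is excluded at the stage that needs it with reason
#' `"missing_attribute"`. Row order is preserved.
#'
#' @param cohort Manifest tibble (one row per specimen) including reference
#'   gene Ct columns.
#' @param reference_genes Character vector naming the reference-gene columns.
#' @param thresholds A [qc_thresholds()].
#' @param ref_stat How reference-gene Cts are aggregated for the gate:
#'   `"mean"` (default), `"any"` (fail if any reference Ct exceeds the cap) or
#'   `"all"` (fail only if all do).
#' @return The cohort tibble with added columns `qc_pass` (logical),
#'   `qc_stage` and `qc_reason` (NA for passing specimens). Summaries via
#'   [qc_accounting()], [qc_exclusions()], [qc_passed()].
#' @export
run_qc <- function(cohort, reference_genes,
                   thresholds = qc_thresholds(),
                   ref_stat = c("mean", "any", "all")) {
  ref_stat <- match.arg(ref_stat)
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) {
    cohort$qc_pass <- logical(0)
    cohort$qc_stage <- character(0)
    cohort$qc_reason <- character(0)
    return(cohort)
  }
  missing_ref <- setdiff(reference_genes, names(cohort))
  if (length(missing_ref) > 0) {
    abort(sprintf("Reference gene column(s) not in cohort: %s",
                  paste(missing_ref, collapse = ", ")))
  }
  refmat <- as.matrix(cohort[, reference_genes, drop = FALSE])
  ref_gate <- switch(ref_stat,
    mean = rowMeans(refmat) > thresholds$ref_ct_max,
    any = apply(refmat > thresholds$ref_ct_max, 1, any),
    all = apply(refmat > thresholds$ref_ct_max, 1, all)
  )
  ref_missing <- apply(refmat, 1, function(r) all(is.na(r)))

  stage <- rep(NA_character_, nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))

  hist_missing <- is.na(cohort$tumor_content) | is.na(cohort$necrosis)
  low_tc <- !hist_missing & cohort$tumor_content < thresholds$tumor_content_min
  high_nec <- !hist_missing & !low_tc &
    cohort$necrosis > thresholds$necrosis_max
  stage[hist_missing | low_tc | high_nec] <- "histologic"
  reason[hist_missing] <- "missing_attribute"
  reason[low_tc] <- "low_tumor_content"
  reason[high_nec] <- "high_necrosis"

  surv <- is.na(stage)
  rt_missing <- surv & (is.na(cohort$a260_a280) | ref_missing)
  ref_fail <- surv & !rt_missing & ref_gate
  window <- thresholds$purity_ratio_window
  purity_fail <- surv & !rt_missing & !ref_fail &
    (cohort$a260_a280 < window[1] | cohort$a260_a280 > window[2])
  stage[rt_missing | ref_fail | purity_fail] <- "rtpcr"
  reason[rt_missing] <- "missing_attribute"
  reason[ref_fail] <- "reference_ct_high"
  reason[purity_fail] <- "purity_ratio_out_of_range"

  cohort$qc_pass <- is.na(stage)
  cohort$qc_stage <- stage
  cohort$qc_reason <- reason
  cohort
}

#' Sample-accounting funnel of a QC run
#'
#' @param qc A [run_qc()] result.
#' @return One-row tibble with `n_input`, `n_pass_histologic`,
#'   `n_pass_rtpcr`, `n_excluded`.
#' @export
qc_accounting <- function(qc) {
  n_input <- nrow(qc)
  n_hist <- sum(is.na(qc$qc_stage) | qc$qc_stage != "histologic")
  n_rt <- sum(qc$qc_pass)
  tibble(n_input = n_input, n_pass_histologic = n_hist,
         n_pass_rtpcr = n_rt, n_excluded = n_input - n_rt)
}

#' @rdname qc_accounting
#' @return `qc_exclusions()`: tibble of `specimen_id`, `stage`, `reason` for
#'   every excluded specimen, in input order.
#' @export
qc_exclusions <- function(qc) {
  out <- qc[!qc$qc_pass, c("specimen_id", "qc_stage", "qc_reason")]
  names(out) <- c("specimen_id", "stage", "reason")
  out
}

#' @rdname qc_accounting
#' @return `qc_passed()`: the passing specimens with the QC columns dropped.
#' @export
qc_passed <- function(qc) {
  qc[qc$qc_pass, setdiff(names(qc), c("qc_pass", "qc_stage", "qc_reason"))]
}

#' Normalize raw Ct profiles to multi-reference-gene delta-Ct
#'
#' For every panel gene g, `dCt_g = mean(reference Cts) - Ct_g`, so larger
#' values mean higher expression. Missing target Cts enter at the censoring
#' cap. Reference genes are not part of the output.
#'
#' @param data Manifest/Ct tibble (one row per specimen).
#' @param reference_genes Character vector of reference-gene column names.
#' @param panel_genes Panel gene columns; defaults to every gene column that
#'   is not a reference gene.
#' @param cap Censoring cap substituted for missing target Cts (default 40).
#' @return Tibble: `specimen_id` plus one delta-Ct column per panel gene.
#' @export
#' @examples
#' rec <- tibble::tibble(specimen_id = "S1", G1 = 24, REF_1 = 25, REF_2 = 27)
#' normalize_expression(rec, reference_genes = c("REF_1", "REF_2"))
normalize_expression <- function(data, reference_genes, panel_genes = NULL,
                                 cap = 40) {
  data <- as_tibble(data)
  panel_genes <- panel_genes %||% setdiff(gene_cols(data), reference_genes)
  refmat <- as.matrix(data[, reference_genes, drop = FALSE])
  ref_mean <- rowMeans(refmat, na.rm = TRUE)
  bad <- !is.finite(ref_mean)
  if (any(bad)) {
    ids <- data$specimen_id[bad] %||% which(bad)
    abort(sprintf("No valid reference-gene Ct for specimen(s): %s",
                  paste(ids, collapse = ", ")))
  }
  ct <- as.matrix(data[, panel_genes, drop = FALSE])
  ct[is.na(ct)] <- cap
  dct <- ref_mean - ct
  out <- as_tibble(dct)
  dplyr::bind_cols(
    tibble(specimen_id = data$specimen_id %||% as.character(seq_len(nrow(data)))),
    out
  )
}

#' Stack expression profiles into one matrix-shaped tibble
#'
#' @param profiles A list of single- or multi-row expression tibbles (as
#'   produced by [normalize_expression()]) or a single tibble.
#' @return Tibble with rows in input order and gene columns in the order of
#'   the first profile. Errors if the profiles do not share one gene set,
#'   listing the symmetric difference.
#' @export
assemble_matrix <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  genes <- gene_cols(profiles[[1]])
  for (p in profiles[-1]) {
    g <- gene_cols(p)
    if (!setequal(g, genes)) {
      diff <- c(setdiff(genes, g), setdiff(g, genes))
      abort(sprintf("Profiles have inconsistent gene sets; symmetric difference: %s",
                    paste(diff, collapse = ", ")))
    }
  }
  purrr::map_dfr(profiles, function(p) p[, c("specimen_id", genes)])
}

#' Read and write the package's tab-separated interchange files
#'
#' Plain UTF-8 TSV with a header row and `.` as the decimal mark; missing
#' values are empty cells. Numeric columns round-trip at full double
#' precision.
#'
#' @param data Tibble to write.
#' @param path File path.
#' @return `read_tsv_file()` returns a tibble; the writers return `data`
#'   invisibly.
#' @export
write_tsv_file <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(data)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE, progress = FALSE)
}
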