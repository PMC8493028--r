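#' Canonical tumor-type class list
#'
#' The default 21-entry class list used by the simulator and the classifier.
#' It contains the 16 origins observed in a typical liver-metastasis cohort
#' plus endometrium and four configurable placeholder labels standing in for
#' the remaining assay classes.
#'
#' @param placeholders Character vector of labels used to pad the list to 21
#'   classes.
#' @return Character vector of 21 unique class labels; `"Liver"` is first.
#' @export
#' @examples
#' canonical_classes()
canonical_classes <- function(placeholders = paste0("Other-", 1:4)) {
  base <- c(
    "Liver", "Colorectum", "Ovary", "Breast", "Neuroendocrine", "Pancreas",
    "Gastroesophagus", "Melanoma", "Cervix", "Lung", "Adrenal", "Germ cell",
    "Head&neck", "Sarcoma", "Kidney", "Urinary", "Endometrium"
  )
  out <- c(base, placeholders)
  if (anyDuplicated(out)) abort("Class labels must be unique.")
  out
}

#' Simulation configuration for synthetic RT-PCR panel cohorts
#'
#' Describes the generative model for synthetic panel RT-PCR data: each tumor
#' class over-expresses its own marker genes by `marker_shift` cycles of
#' delta-Ct relative to a flat background, Ct measurements carry Gaussian
#' noise, specimens below full tumor purity are mixed with a normal-liver
#' background profile on the linear (2^delta-Ct) scale, and poorly
#' differentiated specimens retain only a fraction of their marker signal.
#'
#' @param n_classes Number of tumor classes (default 21).
#' @param markers_per_class Marker genes per class before deduplication
#'   (default 10).
#' @param n_reference_genes Number of housekeeping reference genes (default 5).
#' @param baseline_ct Expected Ct of an unexpressed panel gene and of the
#'   reference genes, in cycles (default 30).
#' @param marker_shift Delta-Ct separation of a class's own markers, in cycles
#'   (default 4).
#' @param noise_sd Standard deviation of Gaussian Ct noise, in cycles
#'   (default 1).
#' @param attenuation_range_poor Interval in \[0, 1\] from which the marker
#'   signal retention of poorly differentiated specimens is drawn
#'   (default \[0.3, 0.7\]).
#' @param contamination_class Class whose marker profile acts as the
#'   normal-tissue contamination background (default `"Liver"`).
#' @param classes Character vector of class labels, length `n_classes`.
#' @param overlap Optional tibble/data frame with columns `class_a`, `class_b`,
#'   `n_shared`: for each row, the last `n_shared` marker slots of `class_b`
#'   reuse markers of `class_a`, so the merged panel contains duplicates that
#'   panel selection must remove.
#' @param ct_cap Maximum reportable Ct; reactions beyond it are censored at
#'   this value (default 40, the cycle count of the RT-PCR program).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_classes = 3, classes = c("Liver", "Lung", "Breast"))
sim_config <- function(n_classes = 21,
                       markers_per_class = 10,
                       n_reference_genes = 5,
                       baseline_ct = 30,
                       marker_shift = 4,
                       noise_sd = 1,
                       attenuation_range_poor = c(0.3, 0.7),
                       contamination_class = "Liver",
                       classes = canonical_classes(),
                       overlap = NULL,
                       ct_cap = 40) {
  if (!is.numeric(n_classes) || n_classes < 2) {
    abort("`n_classes` must be at least 2.")
  }
  if (!is.numeric(markers_per_class) || markers_per_class < 1) {
    abort("`markers_per_class` must be at least 1.")
  }
  if (n_reference_genes < 1) abort("`n_reference_genes` must be at least 1.")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  ar <- attenuation_range_poor
  if (length(ar) != 2 || any(ar < 0) || any(ar > 1) || ar[1] > ar[2]) {
    abort("`attenuation_range_poor` must be an interval inside [0, 1].")
  }
  if (length(classes) != n_classes) {
    abort(sprintf("`classes` must have length n_classes = %d.", n_classes))
  }
  if (!contamination_class %in% classes) {
    abort(sprintf("contamination_class '%s' is not among the classes.",
                  contamination_class))
  }
  if (!is.null(overlap)) {
    overlap <- as_tibble(overlap)
    need <- c("class_a", "class_b", "n_shared")
    if (!all(need %in% names(overlap))) {
      abort("`overlap` needs columns class_a, class_b, n_shared.")
    }
    bad <- setdiff(c(overlap$class_a, overlap$class_b), classes)
    if (length(bad) > 0) {
      abort(sprintf("Unknown class in overlap: %s", paste(bad, collapse = ", ")))
    }
    if (any(overlap$n_shared < 0) || any(overlap$n_shared > markers_per_class)) {
      abort("`n_shared` must be between 0 and markers_per_class.")
    }
  }
  structure(
    list(
      n_classes = as.integer(n_classes),
      markers_per_class = as.integer(markers_per_class),
      n_reference_genes = as.integer(n_reference_genes),
      baseline_ct = baseline_ct,
      marker_shift = marker_shift,
      noise_sd = noise_sd,
      attenuation_range_poor = ar,
      contamination_class = contamination_class,
      classes = classes,
      overlap = overlap,
      ct_cap = ct_cap
    ),
    class = "sim_config"
  )
}

gene_prefix <- function(class) {
  toupper(gsub("[^A-Za-z0-9]", "", class))
}

#' Generate the ground-truth marker map for a simulated assay panel
#'
#' Assigns `markers_per_class` marker genes to every class plus a set of
#' reference genes that belong to no class. With an `overlap` specification in
#' the config, designated class pairs share markers so the merged panel
#' contains fewer unique genes than class slots — exercising the redundancy
#' removal step of panel selection.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `marker_truth` with one row per (class, marker
#'   slot) assignment plus one row per reference gene (`class = NA`); columns
#'   `gene_id`, `class`, `slot`. Attributes: `config`, `panel_genes` (unique
#'   marker gene ids, canonical order), `reference_genes`,
#'   `panel_size_after_dedup`.
#' @export
#' @examples
#' truth <- generate_marker_truth(sim_config(n_classes = 3,
#'   classes = c("Liver", "Lung", "Breast")))
#' panel_genes(truth)
generate_marker_truth <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  k <- config$markers_per_class
  rows <- purrr::map_dfr(config$classes, function(cl) {
    tibble(
      gene_id = sprintf("%s_M%02d", gene_prefix(cl), seq_len(k)),
      class = cl,
      slot = seq_len(k)
    )
  })
  if (!is.null(config$overlap)) {
    for (i in seq_len(nrow(config$overlap))) {
      a <- config$overlap$class_a[i]
      b <- config$overlap$class_b[i]
      ns <- config$overlap$n_shared[i]
      if (ns == 0) next
      # the last `ns` slots of class b reuse the first `ns` markers of class a
      idx <- which(rows$class == b & rows$slot > k - ns)
      rows$gene_id[idx] <- sprintf("%s_M%02d", gene_prefix(a), seq_len(ns))
    }
  }
  refs <- tibble(
    gene_id = sprintf("REF_%d", seq_len(config$n_reference_genes)),
    class = NA_character_,
    slot = NA_integer_
  )
  out <- dplyr::bind_rows(rows, refs)
  panel <- unique(rows$gene_id)
  structure(
    out,
    class = c("marker_truth", class(tibble())),
    config = config,
    panel_genes = panel,
    reference_genes = refs$gene_id,
    panel_size_after_dedup = length(panel)
  )
}

#' @rdname generate_marker_truth
#' @param truth A `marker_truth` object.
#' @export
panel_genes <- function(truth) attr(truth, "panel_genes")

#' @rdname generate_marker_truth
#' @export
reference_genes <- function(truth) attr(truth, "reference_genes")

sim_config_of <- function(truth) attr(truth, "config")

# expected noiseless delta-Ct profile over the panel genes for one specimen:
# own markers sit marker_shift * attenuation above background, then the
# profile is mixed with the contamination-class profile on the linear scale
expected_dct <- function(truth, class_label, purity, attenuation) {
  config <- sim_config_of(truth)
  genes <- panel_genes(truth)
  markers <- truth$gene_id[!is.na(truth$class) & truth$class == class_label]
  bg_markers <- truth$gene_id[!is.na(truth$class) &
                                truth$class == config$contamination_class]
  own <- ifelse(genes %in% markers, config$marker_shift * attenuation, 0)
  bg <- ifelse(genes %in% bg_markers, config$marker_shift, 0)
  dct <- log2(purity * 2^own + (1 - purity) * 2^bg)
  setNames(dct, genes)
}

#' Simulate one panel RT-PCR specimen
#'
#' Draws the raw Ct profile of a single specimen of known class: own-class
#' markers sit `marker_shift * attenuation` delta-Ct cycles above baseline,
#' the profile is mixed with the normal-liver background profile on the linear
#' scale with weights `purity` / `1 - purity`, Gaussian Ct noise is added, and
#' Ct values are censored at the cap. Reference genes are drawn around
#' `baseline_ct`.
#'
#' @param truth A [generate_marker_truth()] result.
#' @param class_label Tumor class of the specimen; must be in the truth.
#' @param purity Tumor-cell fraction in \[0, 1\]; the complement is filled with
#'   the contamination-class profile.
#' @param attenuation Fraction of the marker signal retained (1 = fully
#'   differentiated signal).
#' @param noise_sd Ct noise SD; defaults to the config value.
#' @param seed Optional integer seed for a reproducible draw.
#' @param specimen_id,specimen_type,differentiation Manifest metadata for the
#'   record.
#' @return One-row tibble: manifest columns followed by one Ct column per gene
#'   (panel then reference genes).
#' @export
#' @examples
#' truth <- generate_marker_truth(sim_config(n_classes = 3,
#'   classes = c("Liver", "Lung", "Breast")))
#' simulate_specimen(truth, "Lung", purity = 0.8, seed = 1)
simulate_specimen <- function(truth, class_label, purity,
                              attenuation = 1,
                              noise_sd = NULL,
                              seed = NULL,
                              specimen_id = "S001",
                              specimen_type = "resection",
                              differentiation = "well") {
  config <- sim_config_of(truth)
  if (!class_label %in% config$classes) {
    abort(sprintf("Unknown class '%s'.", class_label))
  }
  stopifnot_scalar_prob(purity, "purity")
  stopifnot_scalar_prob(attenuation, "attenuation")
  noise_sd <- noise_sd %||% config$noise_sd
  draw <- function() {
    dct <- expected_dct(truth, class_label, purity, attenuation)
    ct_panel <- config$baseline_ct - dct + rnorm(length(dct), 0, noise_sd)
    ct_ref <- config$baseline_ct + rnorm(config$n_reference_genes, 0, noise_sd)
    ct <- pmin(c(ct_panel, ct_ref), config$ct_cap)
    names(ct) <- c(panel_genes(truth), reference_genes(truth))
    meta <- tibble(
      specimen_id = specimen_id,
      reference_diagnosis = class_label,
      is_primary_liver = class_label == config$contamination_class,
      specimen_type = specimen_type,
      differentiation = differentiation,
      tumor_content = purity,
      necrosis = runif(1, 0, 0.3),
      a260_a280 = runif(1, 1.8, 2.0),
      qc_truth = NA_character_
    )
    dplyr::bind_cols(meta, as_tibble(as.list(ct)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cohort composition for the simulator
#'
#' @param counts Named integer vector or tibble (`class`, `n`) of specimens
#'   per class.
#' @param biopsy_fraction Fraction of specimens that are biopsies (the rest
#'   are resections).
#' @param poor_fraction Fraction of specimens flagged poorly differentiated.
#' @param undefined_fraction Fraction with undefined differentiation.
#' @param purity Length-2 interval from which tumor-cell content is drawn
#'   uniformly (default \[0.6, 1\], matching the enrollment gate).
#' @return A list of class `cohort_composition`.
#' @export
cohort_composition <- function(counts,
                               biopsy_fraction = 36 / 146,
                               poor_fraction = 71 / 146,
                               undefined_fraction = 49 / 146,
                               purity = c(0.6, 1)) {
  if (is.data.frame(counts)) counts <- setNames(counts$n, counts$class)
  if (length(counts) > 0 && any(counts < 0)) {
    abort("Per-class counts must be >= 0.")
  }
  stopifnot_scalar_prob(biopsy_fraction, "biopsy_fraction")
  stopifnot_scalar_prob(poor_fraction, "poor_fraction")
  stopifnot_scalar_prob(undefined_fraction, "undefined_fraction")
  if (poor_fraction + undefined_fraction > 1) {
    abort("poor_fraction + undefined_fraction must be <= 1.")
  }
  if (length(purity) != 2 || any(purity < 0) || any(purity > 1) ||
      purity[1] > purity[2]) {
    abort("`purity` must be an interval inside [0, 1].")
  }
  structure(
    list(counts = counts, biopsy_fraction = biopsy_fraction,
         poor_fraction = poor_fraction,
         undefined_fraction = undefined_fraction, purity = purity),
    class = "cohort_composition"
  )
}

#' Composition of the reference validation cohort
#'
#' The shipped 146-specimen composition: 16 primary liver tumors plus 130
#' liver metastases over 15 origins, with the published biopsy (36/146) and
#' differentiation (71 poorly differentiated, 49 undefined) structure.
#'
#' @inheritParams cohort_composition
#' @return A [cohort_composition()].
#' @export
#' @examples
#' sum(table1_composition()$counts)
table1_composition <- function(purity = c(0.6, 1)) {
  counts <- c(
    Liver = 16, Colorectum = 23, Ovary = 23, Breast = 19,
    Neuroendocrine = 16, Pancreas = 16, Gastroesophagus = 10, Melanoma = 4,
    Cervix = 4, Lung = 3, Adrenal = 3, `Germ cell` = 2, `Head&neck` = 2,
    Sarcoma = 2, Kidney = 2, Urinary = 1
  )
  cohort_composition(counts, purity = purity)
}

#' Uniform composition with `n` specimens in every class
#'
#' Used for simulated training cohorts (the reference assay trains on a large
#' balanced pan-cancer database).
#'
#' @param classes Class labels to include.
#' @param n Specimens per class.
#' @inheritParams cohort_composition
#' @return A [cohort_composition()].
#' @export
uniform_composition <- function(classes, n = 50, purity = c(0.6, 1), ...) {
  cohort_composition(setNames(rep(n, length(classes)), classes),
                     purity = purity, ...)
}

#' Simulate a full specimen cohort
#'
#' Draws one [simulate_specimen()] record per slot of the composition.
#' Biopsy/resection and differentiation flags are assigned to exact rounded
#' counts and shuffled across the cohort; poorly differentiated specimens draw
#' their marker-signal attenuation from `attenuation_range_poor`.
#'
#' @param truth A [generate_marker_truth()] result.
#' @param composition A [cohort_composition()].
#' @param seed Integer seed; the cohort is byte-identical across re-runs with
#'   the same truth, composition and seed.
#' @param id_prefix Prefix for generated specimen ids.
#' @return Tibble with one row per specimen (manifest columns + Ct columns).
#' @export
simulate_cohort <- function(truth, composition, seed, id_prefix = "S") {
  if (!inherits(composition, "cohort_composition")) {
    abort("`composition` must be a cohort_composition.")
  }
  config <- sim_config_of(truth)
  unknown <- setdiff(names(composition$counts), config$classes)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown class in composition: %s",
                  paste(unknown, collapse = ", ")))
  }
  n <- sum(composition$counts)
  if (n == 0) {
    return(simulate_specimen(truth, config$classes[1], 1)[0, ])
  }
  with_seed(seed, {
    labels <- rep(names(composition$counts), composition$counts)
    n_biopsy <- round(n * composition$biopsy_fraction)
    types <- sample(rep(c("biopsy", "resection"), c(n_biopsy, n - n_biopsy)))
    n_poor <- round(n * composition$poor_fraction)
    n_undef <- round(n * composition$undefined_fraction)
    diffn <- sample(rep(c("poor", "undefined", "well"),
                        c(n_poor, n_undef, n - n_poor - n_undef)))
    purity <- runif(n, composition$purity[1], composition$purity[2])
    atten <- ifelse(
      diffn == "poor",
      runif(n, config$attenuation_range_poor[1], config$attenuation_range_poor[2]),
      1
    )
    purrr::map_dfr(seq_len(n), function(i) {
      simulate_specimen(
        truth, labels[i], purity = purity[i], attenuation = atten[i],
        specimen_id = sprintf("%s%03d", id_prefix, i),
        specimen_type = types[i], differentiation = diffn[i]
      )
    })
  })
}

#' Append specimens that violate a single quality-control gate
#'
#' Each injected specimen is a normal draw from the cohort's classes with
#' exactly one attribute pushed past one QC gate: tumor content below 60%,
#' necrosis above 40%, all reference-gene Cts above 38, or an A260/A280 ratio
#' outside \[1.7, 2.1\]. The intended failure mode is recorded in `qc_truth`.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param truth The [generate_marker_truth()] used for the cohort.
#' @param failures Named counts per failure mode; recognized names are
#'   `low_tumor_content`, `high_necrosis`, `reference_ct_high`,
#'   `purity_ratio_out_of_range`.
#' @param seed Integer seed.
#' @return The cohort with the failing specimens appended.
#' @export
#' @examples
#' truth <- generate_marker_truth(sim_config(n_classes = 3,
#'   classes = c("Liver", "Lung", "Breast")))
#' cohort <- simulate_cohort(truth, uniform_composition(c("Lung", "Breast"), 3),
#'                           seed = 1)
#' nrow(inject_qc_failures(cohort, truth,
#'   c(low_tumor_content = 2, high_necrosis = 1), seed = 2))
inject_qc_failures <- function(cohort, truth, failures, seed) {
  modes <- c("low_tumor_content", "high_necrosis", "reference_ct_high",
             "purity_ratio_out_of_range")
  unknown <- setdiff(names(failures), modes)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown failure mode(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(failures < 0)) abort("Failure counts must be >= 0.")
  total <- sum(failures)
  if (total == 0) return(cohort)
  config <- sim_config_of(truth)
  classes <- unique(cohort$reference_diagnosis)
  if (length(classes) == 0) classes <- config$classes
  with_seed(seed, {
    mode_seq <- rep(names(failures), failures)
    cls <- sample(classes, total, replace = TRUE)
    extra <- purrr::map_dfr(seq_len(total), function(i) {
      rec <- simulate_specimen(
        truth, cls[i], purity = runif(1, 0.7, 1),
        specimen_id = sprintf("F%03d", i)
      )
      rec$qc_truth <- mode_seq[i]
      switch(mode_seq[i],
        low_tumor_content = {
          rec$tumor_content <- runif(1, 0.2, 0.55)
        },
        high_necrosis = {
          rec$necrosis <- runif(1, 0.45, 0.8)
        },
        reference_ct_high = {
          refs <- reference_genes(truth)
          rec[refs] <- as.list(pmin(runif(length(refs), 38.3, 39.8),
                                    config$ct_cap))
        },
        purity_ratio_out_of_range = {
          rec$a260_a280 <- sample(c(runif(1, 1.2, 1.6), runif(1, 2.2, 2.6)), 1)
        }
      )
      rec
    })
    dplyr::bind_rows(cohort, extra)
  })
}
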