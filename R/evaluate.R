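#' Per-class concordance table
#'
#' Counts samples and correct predictions per reference class and reports
#' sensitivities as percentages rounded to one decimal (half away from zero),
#' with a `Total` row aggregating all classes.
#'
#' @param data Tibble holding one row per specimen with reference and
#'   predicted class columns.
#' @param truth,estimate Column names (strings) of the reference diagnosis
#'   and the prediction (defaults `"reference_diagnosis"`, `"predicted"`).
#' @return Tibble of class `concordance_table`: `class`, `n`, `n_correct`,
#'   `sensitivity`.
#' @export
concordance_table <- function(data, truth = "reference_diagnosis",
                              estimate = "predicted") {
  data <- as_tibble(data)
  for (col in c(truth, estimate)) {
    if (!col %in% names(data)) abort(sprintf("Column '%s' not found.", col))
  }
  per <- data |>
    dplyr::group_by(class = .data[[truth]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data[[truth]] == .data[[estimate]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$class)
  out <- dplyr::bind_rows(
    per,
    tibble(class = "Total", n = sum(per$n), n_correct = sum(per$n_correct))
  )
  out$sensitivity <- round_away(100 * out$n_correct / out$n, 1)
  structure(out, class = c("concordance_table", class(tibble())))
}

#' Exact binomial confidence interval for an accuracy
#'
#' Clopper-Pearson interval in beta-quantile form (the default), or the
#' Wilson score interval.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return One-row tibble: `successes`, `trials`, `estimate`, `lower`,
#'   `upper`, `level`, `method`.
#' @export
#' @examples
#' binomial_accuracy_ci(121, 130)
binomial_accuracy_ci <- function(successes, trials, level = 0.95,
                                 method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (trials <= 0 || successes < 0 || successes > trials) {
    abort("Need 0 <= successes <= trials and trials > 0.")
  }
  alpha <- 1 - level
  est <- successes / trials
  if (method == "clopper-pearson") {
    lower <- if (successes == 0) 0 else {
      qbeta(alpha / 2, successes, trials - successes + 1)
    }
    upper <- if (successes == trials) 1 else {
      qbeta(1 - alpha / 2, successes + 1, trials - successes)
    }
  } else {
    zc <- stats::qnorm(1 - alpha / 2)
    den <- 1 + zc^2 / trials
    mid <- (est + zc^2 / (2 * trials)) / den
    half <- zc * sqrt(est * (1 - est) / trials + zc^2 / (4 * trials^2)) / den
    lower <- max(0, mid - half)
    upper <- min(1, mid + half)
  }
  tibble(successes = successes, trials = trials, estimate = est,
         lower = lower, upper = upper, level = level, method = method)
}

#' Compare classification accuracy between two specimen groups
#'
#' Tests a 2x2 table of correct/incorrect counts by group with the
#' continuity-corrected (Yates) chi-square test, or Fisher's exact test.
#'
#' @param counts 2x2 matrix (rows = groups, columns = correct / incorrect) or
#'   a tibble with columns `group`, `correct`, `incorrect`.
#' @param test `"chisq"` (default, Yates-corrected) or `"fisher"`.
#' @return One-row tibble: per-group accuracies, `statistic` (NA for Fisher),
#'   `p_value`, `test`.
#' @export
#' @examples
#' compare_group_accuracy(matrix(c(25, 1, 63, 8), 2, byrow = TRUE))
compare_group_accuracy <- function(counts, test = c("chisq", "fisher")) {
  test <- match.arg(test)
  if (is.data.frame(counts)) {
    counts <- as.matrix(counts[, c("correct", "incorrect")])
  }
  if (!all(dim(counts) == c(2, 2))) abort("`counts` must be a 2x2 table.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Both margins of the 2x2 table must be positive.")
  }
  if (test == "chisq") {
    ht <- suppressWarnings(chisq.test(counts, correct = TRUE))
    statistic <- unname(ht$statistic)
  } else {
    ht <- fisher.test(counts)
    statistic <- NA_real_
  }
  tibble(
    accuracy_group1 = counts[1, 1] / sum(counts[1, ]),
    accuracy_group2 = counts[2, 1] / sum(counts[2, ]),
    statistic = statistic,
    p_value = unname(ht$p.value),
    test = if (test == "chisq") "Yates chi-square" else "Fisher exact"
  )
}

# ROC curve from scores: unique thresholds swept high to low; tied scores
# collapse into a single step, so the trapezoid AUC equals the midrank
# Mann-Whitney statistic
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  positive <- positive[ord]
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  last <- !duplicated(score, fromLast = TRUE)
  tibble(
    threshold = c(Inf, score[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg)
  )
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Per-class and micro-averaged multiclass ROC/AUC
#'
#' Builds one-vs-rest ROC curves per class from the similarity scores, and a
#' micro-averaged ROC by pooling every (specimen, class) pair into a single
#' binary problem. AUC is computed by the trapezoid rule with tied scores
#' handled by the midrank convention.
#'
#' @param scores Wide score tibble (`specimen_id` + one column per class,
#'   e.g. from [predict_origin()]) or numeric matrix with class columns.
#' @param truth Reference class per specimen.
#' @return A list of class `auc_result`: `per_class` (tibble `class`, `auc`,
#'   `n_pos`, `n_neg`), `micro_auc`, `roc` (tibble of ROC points per class
#'   plus `"micro"`).
#' @export
multiclass_auc <- function(scores, truth) {
  if (is.data.frame(scores)) {
    cls <- setdiff(names(scores), c("specimen_id", "predicted"))
    smat <- as.matrix(scores[, cls, drop = FALSE])
  } else {
    smat <- scores
    cls <- colnames(smat)
  }
  truth <- as.character(truth)
  if (length(truth) != nrow(smat)) {
    abort("`truth` must have one entry per score row.")
  }
  bad <- setdiff(unique(truth), cls)
  if (length(bad) > 0) {
    abort(sprintf("Truth label(s) outside the class list: %s",
                  paste(bad, collapse = ", ")))
  }
  eval_cls <- intersect(cls, unique(truth))
  per_class <- purrr::map_dfr(eval_cls, function(cl) {
    pos <- truth == cl
    roc <- roc_points(smat[, cl], pos)
    tibble(class = cl, auc = trapezoid_auc(roc),
           n_pos = sum(pos), n_neg = sum(!pos))
  })
  roc_tbl <- purrr::map_dfr(eval_cls, function(cl) {
    dplyr::mutate(roc_points(smat[, cl], truth == cl), class = cl,
                  .before = 1)
  })
  pooled_score <- as.numeric(smat)
  pooled_pos <- as.logical(outer(truth, cls, "=="))
  micro_roc <- roc_points(pooled_score, pooled_pos)
  structure(
    list(
      per_class = per_class,
      micro_auc = trapezoid_auc(micro_roc),
      roc = dplyr::bind_rows(roc_tbl,
                             dplyr::mutate(micro_roc, class = "micro",
                                           .before = 1))
    ),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> micro-averaged AUC %.3f over %d classes\n",
              x$micro_auc, nrow(x$per_class)))
  invisible(x)
}

#' @export
tidy.auc_result <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class,
    tibble(class = "micro", auc = x$micro_auc,
           n_pos = sum(x$per_class$n_pos), n_neg = sum(x$per_class$n_neg))
  )
}

#' @export
glance.auc_result <- function(x, ...) {
  tibble(micro_auc = x$micro_auc, n_classes = nrow(x$per_class))
}

# order subtrees so every internal node lists the branch containing the
# lexicographically smallest specimen label first; makes the leaf order
# invariant to specimen input order (up to the clustering itself)
canonical_leaf_order <- function(hc) {
  n <- nrow(hc$merge) + 1
  labels <- hc$labels %||% as.character(seq_len(n))
  leaves <- function(node) {
    if (node < 0) return(-node)
    row <- hc$merge[node, ]
    a <- leaves(row[1])
    b <- leaves(row[2])
    if (min(labels[a]) <= min(labels[b])) c(a, b) else c(b, a)
  }
  if (n == 1) return(1L)
  leaves(nrow(hc$merge))
}

#' Average-linkage correlation clustering of specimens
#'
#' Clusters specimens with UPGMA (average linkage) on the distance
#' `1 - Pearson correlation` between every pair of specimen expression
#' profiles. Zero-variance genes are dropped with a warning. Heatmap values
#' are centered per gene (expression relative to the gene's mean). The leaf
#' order is canonicalized so it does not depend on specimen input order.
#'
#' @param data Expression tibble or matrix (>= 2 specimens).
#' @return A list of class `expression_clustering`: `hclust` (the tree),
#'   `order` (canonical leaf order, integer indices), `labels`, `centered`
#'   (per-gene centered matrix), `dist` (the distance object).
#' @export
cluster_expression <- function(data) {
  x <- as_expression_matrix(data)
  if (nrow(x) < 2) abort("Need at least 2 specimens to cluster.")
  v <- apply(x, 2, sd)
  drop <- v == 0 | !is.finite(v)
  if (any(drop)) {
    warn(sprintf("Dropping %d zero-variance gene(s) before clustering.",
                 sum(drop)))
    x <- x[, !drop, drop = FALSE]
  }
  if (ncol(x) < 2) abort("Need at least 2 informative genes to correlate.")
  d <- as.dist(1 - cor(t(x)))
  hc <- hclust(d, method = "average")
  ord <- canonical_leaf_order(hc)
  structure(
    list(hclust = hc, order = ord, labels = rownames(x),
         centered = scale(x, center = TRUE, scale = FALSE), dist = d),
    class = "expression_clustering"
  )
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("<expression_clustering> %d specimens, %d genes (UPGMA on 1 - Pearson r)\n",
              length(x$labels), ncol(x$centered)))
  invisible(x)
}

#' @export
tidy.expression_clustering <- function(x, ...) {
  tibble(
    step = seq_len(nrow(x$hclust$merge)),
    height = x$hclust$height,
    member_a = x$hclust$merge[, 1],
    member_b = x$hclust$merge[, 2]
  )
}

#' Report specimens whose prediction disagrees with the reference diagnosis
#'
#' @param predictions Tibble with `specimen_id` and predicted class.
#' @param manifest Manifest tibble carrying `specimen_id`,
#'   `reference_diagnosis` and covariates (specimen type, differentiation,
#'   histology where present).
#' @param estimate Prediction column name (default `"predicted"`).
#' @return Tibble of class `discordance_report`, one row per discordant
#'   specimen with the manifest covariates attached. Summaries via
#'   [discordance_summary()].
#' @export
discordance_report <- function(predictions, manifest,
                               estimate = "predicted") {
  keep <- intersect(
    c("specimen_id", "reference_diagnosis", "specimen_type",
      "differentiation", "histology"),
    names(manifest)
  )
  joined <- dplyr::inner_join(
    predictions[, c("specimen_id", estimate)],
    manifest[, keep], by = "specimen_id"
  )
  if (nrow(joined) != nrow(predictions)) {
    abort("Specimen ids of predictions and manifest do not match.")
  }
  out <- joined[joined$reference_diagnosis != joined[[estimate]], ]
  out <- dplyr::relocate(out, "specimen_id", "reference_diagnosis",
                         dplyr::all_of(estimate))
  structure(as_tibble(out),
            class = c("discordance_report", class(tibble())))
}

#' @rdname discordance_report
#' @param report A `discordance_report`.
#' @return `discordance_summary()`: long tibble of discordance counts by
#'   covariate level.
#' @export
discordance_summary <- function(report) {
  covs <- intersect(c("specimen_type", "differentiation", "histology"),
                    names(report))
  purrr::map_dfr(covs, function(cv) {
    report |>
      dplyr::count(level = .data[[cv]]) |>
      dplyr::mutate(covariate = cv, .before = 1)
  })
}
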