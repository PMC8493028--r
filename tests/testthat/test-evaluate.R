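# expand per-class (n, correct) counts into a prediction tibble
counts_to_predictions <- function(class, n, correct, wrong_label = "Other") {
  purrr::pmap_dfr(list(class, n, correct), function(cl, nn, cc) {
    tibble::tibble(
      reference_diagnosis = rep(cl, nn),
      predicted = c(rep(cl, cc), rep(wrong_label, nn - cc))
    )
  })
}

test_that("the concordance table reproduces the published per-type arithmetic", {
  counts <- read_tsv_file(system.file("extdata", "table2_concordance.tsv",
                                      package = "ctorigin"))
  preds <- counts_to_predictions(counts$tumor_type, counts$n_samples,
                                 counts$n_correct)
  tab <- concordance_table(preds)
  total <- tab[tab$class == "Total", ]
  expect_equal(total$n, 130)
  expect_equal(total$n_correct, 121)
  expect_equal(total$sensitivity, 93.1)
  for (i in seq_len(nrow(counts))) {
    row <- tab[tab$class == counts$tumor_type[i], ]
    expect_equal(row$n, counts$n_samples[i])
    expect_equal(row$sensitivity, counts$printed_sensitivity[i])
  }
})

test_that("per-class sensitivities match a brute-force recount", {
  withr::with_seed(41, {
    classes <- LETTERS[1:6]
    ref <- sample(classes, 300, replace = TRUE)
    pred <- ifelse(runif(300) < 0.8, ref, sample(classes, 300, replace = TRUE))
    tab <- concordance_table(tibble::tibble(reference_diagnosis = ref,
                                            predicted = pred))
    for (cl in classes) {
      expect_equal(tab$n_correct[tab$class == cl],
                   sum(ref == cl & pred == ref))
      expect_equal(tab$n[tab$class == cl], sum(ref == cl))
    }
    # conservation: class counts add to the total row
    expect_equal(sum(tab$n_correct[tab$class != "Total"]),
                 tab$n_correct[tab$class == "Total"])
  })
  all_ok <- tibble::tibble(reference_diagnosis = c("A", "B"),
                           predicted = c("A", "B"))
  expect_true(all(concordance_table(all_ok)$sensitivity == 100))
})

test_that("the exact binomial interval reproduces the published CI and its boundaries", {
  ci <- binomial_accuracy_ci(121, 130)
  expect_equal(round(ci$lower, 2), 0.87)
  expect_equal(round(ci$upper, 2), 0.97)
  expect_equal(ci$estimate, 121 / 130)
  expect_equal(binomial_accuracy_ci(16, 16)$upper, 1)
  zero <- binomial_accuracy_ci(0, 20)
  expect_equal(zero$lower, 0)
  # closed-form oracle at zero successes
  expect_equal(zero$upper, 1 - 0.025^(1 / 20), tolerance = 1e-12)
  expect_error(binomial_accuracy_ci(5, 3), "successes")
})

test_that("the exact interval covers the true proportion at least 95% of the time", {
  withr::with_seed(42, {
    p <- 0.93
    draws <- stats::rbinom(2000, 130, p)
    covered <- vapply(draws, function(s) {
      ci <- binomial_accuracy_ci(s, 130)
      ci$lower <= p && p <= ci$upper
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  })
})

test_that("subgroup comparisons reproduce the published p-values", {
  diffn <- compare_group_accuracy(matrix(c(25, 1, 63, 8), 2, byrow = TRUE))
  expect_equal(round(diffn$p_value, 2), 0.47)
  stype <- compare_group_accuracy(matrix(c(32, 4, 105, 5), 2, byrow = TRUE))
  expect_equal(round(stype$p_value, 2), 0.31)
  expect_equal(diffn$accuracy_group1, 25 / 26)
  # a symmetric table carries no association
  sym <- compare_group_accuracy(matrix(c(10, 3, 10, 3), 2, byrow = TRUE))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  fisher <- compare_group_accuracy(matrix(c(25, 1, 63, 8), 2, byrow = TRUE),
                                   test = "fisher")
  expect_true(fisher$p_value > 0 && fisher$p_value <= 1)
  expect_error(compare_group_accuracy(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("a perfect scorer attains micro-averaged AUC 1", {
  scores <- tibble::tibble(
    specimen_id = paste0("S", 1:6),
    A = c(90, 80, 10, 5, 10, 20),
    B = c(5, 15, 85, 90, 10, 10),
    C = c(5, 5, 5, 5, 80, 70)
  )
  truth <- c("A", "A", "B", "B", "C", "C")
  res <- multiclass_auc(scores, truth)
  expect_equal(res$micro_auc, 1)
  expect_true(all(res$per_class$auc == 1))
  # ROC curves are monotone non-decreasing in both coordinates
  for (cl in unique(res$roc$class)) {
    r <- res$roc[res$roc$class == cl, ]
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
  }
})

test_that("random scores give chance-level micro AUC", {
  withr::with_seed(43, {
    n <- 200
    s <- runif(n)
    scores <- tibble::tibble(specimen_id = paste0("S", 1:n),
                             A = 100 * s, B = 100 * (1 - s))
    truth <- sample(c("A", "B"), n, replace = TRUE)
    res <- multiclass_auc(scores, truth)
    expect_lt(abs(res$micro_auc - 0.5), 0.08)
  })
})

test_that("micro AUC equals brute-force pairwise enumeration, ties at half", {
  withr::with_seed(44, {
    for (i in 1:10) {
      n <- sample(6:16, 1)
      classes <- c("A", "B", "C")
      truth <- sample(classes, n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- c("A", "B")
      # coarse scores force ties
      raw <- matrix(sample(0:5, n * 3, replace = TRUE), n)
      smat <- 100 * raw / pmax(rowSums(raw), 1)
      colnames(smat) <- classes
      res <- multiclass_auc(smat, truth)
      pooled_pos <- as.logical(outer(truth, classes, "=="))
      expect_equal(res$micro_auc, pairwise_auc(as.numeric(smat), pooled_pos),
                   tolerance = 1e-12)
      for (cl in unique(truth)) {
        expect_equal(res$per_class$auc[res$per_class$class == cl],
                     pairwise_auc(smat[, cl], truth == cl), tolerance = 1e-12)
      }
    }
  })
})

test_that("micro AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(45, {
    n <- 40
    truth <- sample(c("A", "B"), n, replace = TRUE)
    s <- rnorm(n) + (truth == "A")
    scores <- cbind(A = s, B = -s)
    res <- multiclass_auc(scores, truth)
    pooled_score <- as.numeric(scores)
    pooled_pos <- as.logical(outer(truth, c("A", "B"), "=="))
    ext <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(pooled_pos), predictor = pooled_score,
      levels = c(0, 1), direction = "<", quiet = TRUE
    )))
    expect_equal(res$micro_auc, ext, tolerance = 1e-12)
  })
})

test_that("duplicated specimens merge first at distance zero", {
  withr::with_seed(46, {
    x <- matrix(rnorm(40), 4, dimnames = list(paste0("S", 1:4)))
    x[2, ] <- x[1, ]
    cl <- cluster_expression(x)
    merges <- tidy(cl)
    expect_equal(sort(c(merges$member_a[1], merges$member_b[1])), c(-2, -1))
    expect_equal(merges$height[1], 0, tolerance = 1e-12)
  })
})

test_that("three-leaf UPGMA merge order and heights match hand computation", {
  withr::with_seed(47, {
    x <- matrix(rnorm(24), 3, dimnames = list(c("S1", "S2", "S3")))
    d <- 1 - cor(t(x))
    cl <- cluster_expression(x)
    merges <- tidy(cl)
    # hand-computed UPGMA: closest pair merges first, then the remaining
    # leaf joins at the mean of its two distances
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    dv <- c(d[1, 2], d[1, 3], d[2, 3])
    first <- pairs[which.min(dv), ]
    rest <- setdiff(1:3, first)
    expect_setequal(c(merges$member_a[1], merges$member_b[1]), -first)
    expect_equal(merges$height[1], min(dv), tolerance = 1e-12)
    expect_equal(merges$height[2],
                 mean(d[rest, first]), tolerance = 1e-12)
  })
})

test_that("clustering separates simulated tumor types and ignores input order", {
  truth <- generate_marker_truth(sim_config())
  types <- c("Liver", "Colorectum", "Ovary", "Breast", "Neuroendocrine",
             "Pancreas", "Gastroesophagus")
  comp <- cohort_composition(
    stats::setNames(c(16, 23, 23, 19, 16, 16, 10), types),
    biopsy_fraction = 0, poor_fraction = 0, undefined_fraction = 0,
    purity = c(0.6, 1)
  )
  cohort <- simulate_cohort(truth, comp, seed = 48)
  expr <- normalize_expression(cohort, reference_genes(truth),
                               panel_genes(truth))
  cl <- cluster_expression(expr)
  cut <- stats::cutree(cl$hclust, k = 7)
  ari <- mclust::adjustedRandIndex(cut, cohort$reference_diagnosis)
  expect_gt(ari, 0.8)
  # specimen order only permutes, never changes, the canonical leaf order
  perm <- withr::with_seed(4, sample(nrow(expr)))
  cl2 <- cluster_expression(expr[perm, ])
  expect_equal(cl2$labels[cl2$order], cl$labels[cl$order])
})

test_that("discordance reports exactly the planted mismatches", {
  truth <- small_truth()
  cohort <- simulate_cohort(truth, clean_composition(five_classes, 4), seed = 49)
  preds <- tibble::tibble(specimen_id = cohort$specimen_id,
                          predicted = cohort$reference_diagnosis)
  expect_equal(nrow(discordance_report(preds, cohort)), 0)
  planted <- c(3, 8, 15)
  preds$predicted[planted] <- "Lung"
  planted <- planted[cohort$reference_diagnosis[planted] != "Lung"]
  rep <- discordance_report(preds, cohort)
  expect_setequal(rep$specimen_id, cohort$specimen_id[planted])
  expect_true(all(rep$reference_diagnosis != rep$predicted))
  # conservation: discordant + concordant = cohort size
  expect_equal(nrow(rep) + sum(preds$predicted == cohort$reference_diagnosis),
               nrow(cohort))
  summ <- discordance_summary(rep)
  expect_equal(sum(summ$n[summ$covariate == "specimen_type"]), nrow(rep))
})
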