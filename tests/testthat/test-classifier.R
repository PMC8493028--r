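test_that("the Platt fit matches the smoothed targets under perfect separation", {
  d <- c(rep(-1, 10), rep(1, 10))
  pos <- d > 0
  ab <- fit_platt_sigmoid(d, pos)
  t_hi <- 11 / 12
  t_lo <- 1 / 12
  p <- function(x) 1 / (1 + exp(ab["A"] * x + ab["B"]))
  expect_equal(unname(p(1)), t_hi, tolerance = 1e-6)
  expect_equal(unname(p(-1)), t_lo, tolerance = 1e-6)
  expect_lt(ab["A"], 0)
})

test_that("the Platt fit attains the brute-force grid MLE on random instances", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(20:60, 1)
      pos <- runif(n) < runif(1, 0.3, 0.7)
      if (!any(pos)) pos[1] <- TRUE
      if (all(pos)) pos[1] <- FALSE
      d <- rnorm(n) + ifelse(pos, runif(1, 0, 3), 0)
      ab <- suppressWarnings(fit_platt_sigmoid(d, pos))
      fit_nll <- platt_nll(unname(ab), d, pos)
      oracle <- platt_grid_mle(d, pos)
      expect_lte(fit_nll, oracle$nll + 1e-6)
    }
  })
})

test_that("uninformative decision values give a flat prevalence-level sigmoid", {
  withr::with_seed(32, {
    d <- rnorm(200)
    pos <- rep(c(TRUE, FALSE), 100)
    ab <- suppressWarnings(fit_platt_sigmoid(d, pos))
    expect_lt(abs(ab["A"]), 0.5)
    p_mid <- 1 / (1 + exp(ab["B"]))
    expect_equal(unname(p_mid), 0.5, tolerance = 0.1)
  })
})

test_that("one-sided labels are rejected", {
  expect_error(fit_platt_sigmoid(1:5, rep(TRUE, 5)), "Both classes")
})

test_that("a separable three-class problem is classified perfectly", {
  withr::with_seed(33, {
    n <- 30
    labels <- rep(c("A", "B", "C"), each = n / 3)
    mu <- matrix(0, 3, 6, dimnames = list(c("A", "B", "C")))
    mu[1, 1:2] <- 6
    mu[2, 3:4] <- 6
    mu[3, 5:6] <- 6
    x <- mu[labels, ] + matrix(rnorm(n * 6, sd = 0.3), n)
    colnames(x) <- paste0("G", 1:6)
    rownames(x) <- paste0("S", 1:n)
    clf <- train_origin_classifier(x, labels, cv_folds = 3)
    pred <- predict_origin(clf, x)
    expect_equal(mean(pred$predicted == labels), 1)
  })
})

test_that("similarity scores stay in [0, 100] and sum to 100 per specimen", {
  truth <- small_truth()
  cohort <- simulate_cohort(truth, clean_composition(five_classes, 8), seed = 34)
  expr <- normalize_expression(cohort, reference_genes(truth),
                               panel_genes(truth))
  clf <- train_origin_classifier(expr, cohort$reference_diagnosis)
  scores <- score_specimens(clf, expr)
  sums <- tapply(scores$score, scores$specimen_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(scores$score >= 0 & scores$score <= 100))
})

test_that("a degenerate classifier scores every class 100 / n and ties break canonically", {
  classes <- canonical_classes()
  genes <- paste0("G", 1:3)
  clf <- structure(list(
    classes = classes, genes = genes,
    center = stats::setNames(rep(0, 3), genes),
    scale = stats::setNames(rep(1, 3), genes),
    W = matrix(1, 21, 3, dimnames = list(classes, genes)),
    b = stats::setNames(rep(0, 21), classes),
    w_norm = stats::setNames(rep(sqrt(3), 21), classes),
    platt_A = stats::setNames(rep(0, 21), classes),
    platt_B = stats::setNames(rep(0, 21), classes),
    cost = 1, cv_folds = 3, calibration = "cv_out_of_fold", n_train = 0,
    version = "1.0"
  ), class = "origin_classifier")
  x <- matrix(rnorm(3), 1, dimnames = list("S1", genes))
  scores <- score_specimens(clf, x)
  expect_equal(scores$score, rep(100 / 21, 21), tolerance = 1e-12)
  pred <- predict_origin(clf, x)
  expect_equal(pred$predicted, classes[1])
})

test_that("scores recompute by hand from the serialized model", {
  truth <- small_truth()
  cohort <- simulate_cohort(truth, clean_composition(five_classes, 8), seed = 35)
  expr <- normalize_expression(cohort, reference_genes(truth),
                               panel_genes(truth))
  clf <- train_origin_classifier(expr, cohort$reference_diagnosis)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(clf, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  xrow <- as.numeric(expr[3, raw$genes])
  z <- (xrow - raw$center) / raw$scale
  W <- if (is.matrix(raw$W)) raw$W else do.call(rbind, raw$W)
  d <- numeric(length(raw$classes))
  p <- numeric(length(raw$classes))
  for (i in seq_along(raw$classes)) {
    w <- W[i, ]
    d[i] <- (sum(w * z) + raw$b[i]) / sqrt(sum(w^2))
    p[i] <- 1 / (1 + exp(raw$platt_A[i] * d[i] + raw$platt_B[i]))
  }
  s <- 100 * p / sum(p)
  got <- score_specimens(clf, expr[3, ])
  expect_equal(got$decision, d, tolerance = 1e-9)
  expect_equal(got$score, s, tolerance = 1e-9)
  # argmax recomputed independently from the score map
  pred <- predict_origin(clf, expr[3, ])
  expect_equal(pred$predicted, raw$classes[which.max(s)])
})

test_that("serialization round-trips to identical predictions", {
  truth <- small_truth()
  cohort <- simulate_cohort(truth, clean_composition(five_classes, 8), seed = 36)
  expr <- normalize_expression(cohort, reference_genes(truth),
                               panel_genes(truth))
  clf <- train_origin_classifier(expr, cohort$reference_diagnosis)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(clf, path)
  back <- read_classifier_json(path)
  expect_identical(predict_origin(back, expr), predict_origin(clf, expr))
})

test_that("similarity scores increase with the class decision value", {
  truth <- small_truth()
  cohort <- simulate_cohort(truth, clean_composition(five_classes, 8), seed = 37)
  expr <- normalize_expression(cohort, reference_genes(truth),
                               panel_genes(truth))
  clf <- train_origin_classifier(expr, cohort$reference_diagnosis)
  expect_true(all(clf$platt_A < 0))
  # hold other classes fixed, sweep d for one class
  cl <- clf$classes[2]
  other_p <- 0.8
  d_grid <- seq(-3, 3, length.out = 25)
  s <- vapply(d_grid, function(d) {
    p <- 1 / (1 + exp(clf$platt_A[cl] * d + clf$platt_B[cl]))
    100 * p / (p + other_p)
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("calibration uses out-of-fold decision values by default", {
  withr::with_seed(38, {
    # noisy, overlapping two-class-ish data so the two calibration routes
    # disagree measurably
    n <- 60
    labels <- rep(c("A", "B", "C"), each = n / 3)
    mu <- matrix(0, 3, 4, dimnames = list(c("A", "B", "C")))
    diag(mu[, 1:3]) <- 1.5
    x <- mu[labels, ] + matrix(rnorm(n * 4), n)
    colnames(x) <- paste0("G", 1:4)
    rownames(x) <- paste0("S", 1:n)
    default <- train_origin_classifier(x, labels, seed = 5)
    cv <- train_origin_classifier(x, labels, calibration = "cv", seed = 5)
    resub <- train_origin_classifier(x, labels, calibration = "train", seed = 5)
    expect_identical(default$platt_A, cv$platt_A)
    expect_identical(default$calibration, "cv_out_of_fold")
    expect_false(isTRUE(all.equal(default$platt_A, resub$platt_A)))
  })
})

test_that("training validates fold counts, class coverage and finiteness", {
  x <- matrix(rnorm(20), 10, dimnames = list(paste0("S", 1:10), c("G1", "G2")))
  labels <- c(rep("A", 8), "B", "B")
  expect_error(train_origin_classifier(x, labels, cv_folds = 3), "cv_folds")
  x2 <- x
  x2[1] <- NA
  expect_error(train_origin_classifier(x2, rep(c("A", "B"), 5)), "finite")
  clf <- suppressWarnings(train_origin_classifier(x, rep(c("A", "B"), 5), cv_folds = 2))
  expect_error(score_specimens(clf, x[, 1, drop = FALSE]), "G2")
})
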