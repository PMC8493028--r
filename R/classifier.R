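#' Fit a Platt calibration sigmoid to decision values
#'
#' Maximizes the regularized sigmoid likelihood `p(d) = 1 / (1 + exp(A d + B))`
#' with the smoothed targets `t+ = (N+ + 1) / (N+ + 2)` for positives and
#' `t- = 1 / (N- + 2)` for negatives, by Newton's method with backtracking line
#' search on the numerically stabilized objective. With larger decision values
#' indicating class membership the fitted slope `A` is negative; a
#' non-negative slope triggers a monotonicity warning.
#'
#' @param decision Numeric decision values.
#' @param positive Logical class membership, same length.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient norm.
#' @return Named numeric vector `c(A, B)`.
#' @export
#' @examples
#' fit_platt_sigmoid(c(-1, -1, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
fit_platt_sigmoid <- function(decision, positive, max_iter = 200,
                              tol = 1e-10) {
  positive <- as.logical(positive)
  if (length(decision) != length(positive)) {
    abort("`decision` and `positive` must have the same length.")
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to fit the calibration sigmoid.")
  }
  t_hi <- (n_pos + 1) / (n_pos + 2)
  t_lo <- 1 / (n_neg + 2)
  t <- ifelse(positive, t_hi, t_lo)

  # stabilized negative log-likelihood of the smoothed targets
  objective <- function(a, b) {
    f <- a * decision + b
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  val <- objective(a, b)
  sigma <- 1e-12 # Hessian ridge
  converged <- FALSE
  g_norm <- NA_real_
  for (iter in seq_len(max_iter)) {
    f <- a * decision + b
    p <- 1 / (1 + exp(f))
    # d/df of objective terms is t - p
    g_a <- sum(decision * (t - p))
    g_b <- sum(t - p)
    g_norm <- max(abs(g_a), abs(g_b))
    if (g_norm < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    h11 <- sum(decision^2 * w) + sigma
    h22 <- sum(w) + sigma
    h12 <- sum(decision * w)
    det <- h11 * h22 - h12^2
    da <- -(h22 * g_a - h12 * g_b) / det
    db <- -(-h12 * g_a + h11 * g_b) / det
    step <- 1
    repeat {
      new_val <- objective(a + step * da, b + step * db)
      if (new_val <= val + 1e-4 * step * (g_a * da + g_b * db)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    a <- a + step * da
    b <- b + step * db
    val <- objective(a, b)
  }
  if (!converged && g_norm >= 1e-6) {
    abort(sprintf(
      "Platt sigmoid fit did not converge in %d iterations (gradient norm %.3g).",
      max_iter, g_norm))
  }
  if (a >= 0) {
    warn(sprintf("Fitted Platt slope A = %.3g is non-negative; decision values do not increase with class membership.", a))
  }
  c(A = a, B = b)
}

platt_probability <- function(decision, A, B) {
  1 / (1 + exp(A * decision + B))
}

make_folds <- function(labels, k) {
  idx <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    idx[members] <- sample(rep_len(seq_len(k), length(members)))
  }
  idx
}

#' Train the one-vs-rest tissue-of-origin classifier
#'
#' Standardizes expression per gene, fits one linear maximum-margin hyperplane
#' per class against the rest, and calibrates each class's signed
#' hyperplane distances with a Platt sigmoid fitted on out-of-fold decision
#' values from stratified cross-validation (never on training-set decision
#' values, which are over-confident).
#'
#' @param data Expression tibble (`specimen_id` + gene columns) or matrix.
#' @param labels Class label per specimen.
#' @param cost Margin-cost parameter of the linear separators (default 1).
#' @param cv_folds Folds used to collect calibration decision values
#'   (default 3).
#' @param classes Canonical class order; defaults to the classes present in
#'   `labels`, in [canonical_classes()] order where applicable.
#' @param calibration `"cv"` (default) fits the sigmoids on out-of-fold
#'   decision values; `"train"` (for comparison only) fits them on
#'   training-set decision values.
#' @param seed Seed for the fold assignment (default 1), making training
#'   deterministic.
#' @return An object of class `origin_classifier`: per-class weights `W`
#'   (classes x genes, on the standardized scale), biases `b`, weight norms,
#'   Platt parameters `A`, `B`, standardization `center`/`scale`, `classes`,
#'   `genes`.
#' @export
train_origin_classifier <- function(data, labels, cost = 1, cv_folds = 3,
                                    classes = NULL,
                                    calibration = c("cv", "train"),
                                    seed = 1) {
  calibration <- match.arg(calibration)
  x <- as_expression_matrix(data)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    abort("`labels` must have one entry per specimen.")
  }
  if (!all(is.finite(x))) abort("Expression values must be finite.")
  present <- unique(labels)
  if (length(present) < 2) abort("Need at least 2 classes to train.")
  classes <- classes %||% {
    canon <- canonical_classes()
    c(intersect(canon, present), sort(setdiff(present, canon)))
  }
  if (anyDuplicated(classes)) abort("`classes` must not contain duplicates.")
  missing_cls <- setdiff(present, classes)
  if (length(missing_cls) > 0) {
    abort(sprintf("Labels outside the class list: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  counts <- table(labels)
  if (calibration == "cv" && any(counts < cv_folds)) {
    abort(sprintf("Every class needs at least cv_folds = %d specimens; too small: %s",
                  cv_folds, paste(names(counts)[counts < cv_folds], collapse = ", ")))
  }
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(x, center = center, scale = scl)

  fit_class <- function(zmat, cl, rows = seq_len(nrow(zmat))) {
    fit_linear_svm(zmat[rows, , drop = FALSE], labels[rows] == cl, cost = cost)
  }

  W <- matrix(0, length(classes), ncol(z),
              dimnames = list(classes, colnames(z)))
  b <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    if (!cl %in% present) {
      abort(sprintf("Class '%s' has no training specimens.", cl))
    }
    fit <- fit_class(z, cl)
    W[cl, ] <- fit$w
    b[cl] <- fit$b
  }
  w_norm <- sqrt(rowSums(W^2))

  # calibration decision values
  decision_for <- function(zmat, w, bias) {
    (as.numeric(zmat %*% w) + bias) / sqrt(sum(w^2))
  }
  if (calibration == "cv") {
    folds <- with_seed(seed, make_folds(labels, cv_folds))
    d_cal <- matrix(NA_real_, nrow(z), length(classes),
                    dimnames = list(NULL, classes))
    for (f in seq_len(cv_folds)) {
      train_rows <- which(folds != f)
      test_rows <- which(folds == f)
      for (cl in classes) {
        fit <- fit_class(z, cl, rows = train_rows)
        d_cal[test_rows, cl] <- decision_for(z[test_rows, , drop = FALSE],
                                             fit$w, fit$b)
      }
    }
  } else {
    d_cal <- vapply(classes, function(cl) decision_for(z, W[cl, ], b[cl]),
                    numeric(nrow(z)))
  }
  AB <- vapply(classes, function(cl) {
    fit_platt_sigmoid(d_cal[, cl], labels == cl)
  }, numeric(2))

  structure(
    list(
      classes = classes, genes = colnames(z),
      center = center, scale = scl,
      W = W, b = b, w_norm = w_norm,
      platt_A = setNames(AB["A", ], classes),
      platt_B = setNames(AB["B", ], classes),
      cost = cost, cv_folds = cv_folds,
      calibration = if (calibration == "cv") "cv_out_of_fold" else "train",
      n_train = nrow(z),
      version = "1.0"
    ),
    class = "origin_classifier"
  )
}

#' @export
print.origin_classifier <- function(x, ...) {
  cat(sprintf("<origin_classifier> %d classes, %d panel genes, cost %.3g, calibration: %s\n",
              length(x$classes), length(x$genes), x$cost, x$calibration))
  invisible(x)
}

#' @export
tidy.origin_classifier <- function(x, ...) {
  tibble(
    class = rep(x$classes, each = length(x$genes)),
    gene = rep(x$genes, length(x$classes)),
    weight = as.numeric(t(x$W))
  )
}

#' @export
glance.origin_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_genes = length(x$genes),
         n_train = x$n_train, cost = x$cost, cv_folds = x$cv_folds,
         calibration = x$calibration)
}

classifier_decisions <- function(clf, data) {
  x <- as_expression_matrix(data, genes = clf$genes)
  z <- scale(x, center = clf$center, scale = clf$scale)
  d <- z %*% t(clf$W)
  sweep(sweep(d, 2, clf$b, "+"), 2, clf$w_norm, "/")
}

#' Similarity scores for specimens
#'
#' For each specimen, the signed geometric distance to each class hyperplane,
#' `d_c = (w_c . z + b_c) / ||w_c||`, is mapped through the class's Platt
#' sigmoid and the resulting probabilities are normalized to similarity scores
#' `s_c = 100 p_c / sum(p)`, which lie in \[0, 100\] and sum to 100.
#'
#' @param clf An [train_origin_classifier()] result.
#' @param data Expression tibble or matrix covering the panel genes (missing
#'   genes are an error).
#' @return Long tibble: `specimen_id`, `class`, `decision`, `probability`,
#'   `score`.
#' @export
score_specimens <- function(clf, data) {
  d <- classifier_decisions(clf, data)
  p <- vapply(clf$classes, function(cl) {
    platt_probability(d[, cl], clf$platt_A[cl], clf$platt_B[cl])
  }, numeric(nrow(d)))
  p <- matrix(p, nrow = nrow(d), dimnames = list(rownames(d), clf$classes))
  s <- 100 * p / rowSums(p)
  tibble(
    specimen_id = rep(rownames(d), times = length(clf$classes)),
    class = rep(clf$classes, each = nrow(d)),
    decision = as.numeric(d),
    probability = as.numeric(p),
    score = as.numeric(s)
  )
}

#' Predict the tissue of origin
#'
#' The predicted class attains the maximum similarity score; exact ties are
#' broken by canonical class-list order.
#'
#' @inheritParams score_specimens
#' @return Wide tibble: `specimen_id`, `predicted`, then one similarity-score
#'   column per class (canonical order).
#' @export
predict_origin <- function(clf, data) {
  scores <- score_specimens(clf, data)
  wide <- tidyr::pivot_wider(scores[, c("specimen_id", "class", "score")],
                             names_from = "class", values_from = "score")
  smat <- as.matrix(wide[, clf$classes, drop = FALSE])
  predicted <- clf$classes[apply(smat, 1, which.max)]
  dplyr::bind_cols(
    tibble(specimen_id = wide$specimen_id, predicted = predicted),
    wide[, clf$classes, drop = FALSE]
  )
}

#' Serialize a trained classifier to versioned JSON
#'
#' Stores the class list, panel gene order, standardization parameters,
#' per-class weights, biases and Platt parameters at full double precision,
#' so a round trip reproduces identical predictions.
#'
#' @param clf An `origin_classifier`.
#' @param path File path.
#' @return `read_classifier_json()` returns the `origin_classifier`.
#' @export
write_classifier_json <- function(clf, path) {
  payload <- list(
    version = clf$version,
    classes = clf$classes, genes = clf$genes,
    center = unname(clf$center), scale = unname(clf$scale),
    W = unname(apply(clf$W, 1, identity, simplify = FALSE)),
    b = unname(clf$b),
    platt_A = unname(clf$platt_A), platt_B = unname(clf$platt_B),
    cost = clf$cost, cv_folds = clf$cv_folds, calibration = clf$calibration,
    n_train = clf$n_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(clf)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(raw$W)) raw$W else do.call(rbind, raw$W)
  dimnames(W) <- list(raw$classes, raw$genes)
  structure(
    list(
      classes = raw$classes, genes = raw$genes,
      center = setNames(raw$center, raw$genes),
      scale = setNames(raw$scale, raw$genes),
      W = W, b = setNames(raw$b, raw$classes),
      w_norm = sqrt(rowSums(W^2)),
      platt_A = setNames(raw$platt_A, raw$classes),
      platt_B = setNames(raw$platt_B, raw$classes),
      cost = raw$cost, cv_folds = raw$cv_folds, calibration = raw$calibration,
      n_train = raw$n_train, version = raw$version
    ),
    class = "origin_classifier"
  )
}
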