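# small shared fixtures; everything is generated in code

five_classes <- c("Liver", "Lung", "Breast", "Ovary", "Pancreas")

small_config <- function(...) {
  sim_config(n_classes = 5, classes = five_classes, ...)
}

small_truth <- function(...) generate_marker_truth(small_config(...))

# balanced clean cohort for classifier tests: no poor specimens, full purity
clean_composition <- function(classes, n) {
  cohort_composition(
    stats::setNames(rep(n, length(classes)), classes),
    biopsy_fraction = 0, poor_fraction = 0, undefined_fraction = 0,
    purity = c(1, 1)
  )
}

# negative log-likelihood of the Platt sigmoid with smoothed targets;
# shared by the grid-search oracle and the fit checks
platt_nll <- function(par, decision, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  t <- ifelse(positive, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  f <- par[1] * decision + par[2]
  sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
}

# brute-force 2-D grid MLE for the Platt sigmoid, iteratively refined until
# the grid step drops below `step`; independent of the Newton fit
platt_grid_mle <- function(decision, positive, step = 1e-4) {
  a_rng <- c(-60, 10)
  b_rng <- c(-30, 30)
  best <- c(0, 0)
  repeat {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = 41)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = 41)
    vals <- outer(a_grid, b_grid, Vectorize(function(a, b) {
      platt_nll(c(a, b), decision, positive)
    }))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(a_grid[idx[1]], b_grid[idx[2]])
    da <- diff(a_rng) / 40
    db <- diff(b_rng) / 40
    if (max(da, db) < step) break
    a_rng <- best[1] + c(-2, 2) * da
    b_rng <- best[2] + c(-2, 2) * db
  }
  list(par = best, nll = platt_nll(best, decision, positive))
}

# brute-force AUC by pair enumeration with ties counted 1/2
pairwise_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
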