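# fit a soft-margin linear separator and return the hyperplane oriented so
# that positive-class specimens have larger decision values
fit_linear_svm <- function(x, positive, cost = 1) {
  y <- factor(ifelse(positive, "pos", "rest"), levels = c("pos", "rest"))
  m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  d <- as.numeric(x %*% w) + b
  if (mean(d[positive]) < mean(d[!positive])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Rank genes by SVM recursive feature elimination
#'
#' Iteratively fits a linear maximum-margin separator on the surviving genes,
#' scores each gene by its squared hyperplane weight, and removes the
#' lowest-scoring genes according to the elimination schedule, recording the
#' full elimination order. The last survivor ranks first. Expression is
#' centered and scaled to unit variance inside the ranking so weights are
#' comparable across genes; constant genes are dropped with a warning and
#' placed at the bottom of the ranking.
#'
#' @param data Expression tibble (`specimen_id` + gene columns) or numeric
#'   matrix.
#' @param positive Logical vector (one class vs rest), one entry per
#'   specimen.
#' @param step_fraction Fraction of surviving genes removed per iteration
#'   (floor one gene; default 0.1).
#' @param fine_threshold Gene count below which elimination switches to
#'   one-by-one (default 20).
#' @param cost Margin-cost parameter of the inner separator (default 0.01).
#'   The inner fit is strongly regularized so gene scores reflect
#'   population-level class contrasts rather than a few borderline specimens,
#'   which keeps elimination stable when markers are mutually redundant.
#' @return A tibble of class `gene_ranking`: `gene`, `rank`, `iteration` (the
#'   elimination iteration; `NA` for genes dropped as constant). Ties in
#'   weight are broken by the input gene order.
#' @export
rfe_rank <- function(data, positive, step_fraction = 0.1,
                     fine_threshold = 20, cost = 0.01) {
  x <- as_expression_matrix(data)
  positive <- as.logical(positive)
  if (length(positive) != nrow(x)) {
    abort("`positive` must have one entry per specimen.")
  }
  if (sum(positive) < 2 || sum(!positive) < 2) {
    abort("Need at least 2 specimens on each side of the binary split.")
  }
  genes <- colnames(x)
  sds <- apply(x, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warn(sprintf("Dropping %d constant gene(s) from the ranking: %s",
                 sum(constant), paste(genes[constant], collapse = ", ")))
  }
  active <- genes[!constant]
  if (length(active) < 1) abort("No non-constant genes to rank.")
  z <- scale(x[, active, drop = FALSE])

  eliminated <- character(0)
  elim_iter <- integer(0)
  surv <- active
  iter <- 0L
  while (length(surv) > 1) {
    iter <- iter + 1L
    fit <- fit_linear_svm(z[, surv, drop = FALSE], positive, cost = cost)
    score <- fit$w^2
    n_rm <- if (length(surv) > fine_threshold) {
      max(1L, floor(length(surv) * step_fraction))
    } else {
      1L
    }
    # remove lowest scores; among ties the gene latest in canonical order goes
    # first, so earlier canonical genes rank higher
    ord <- order(score, -match(surv, genes))
    drop <- surv[ord][seq_len(n_rm)] # worst first
    eliminated <- c(eliminated, drop)
    elim_iter <- c(elim_iter, rep(iter, n_rm))
    surv <- setdiff(surv, drop)
  }
  order_desc <- c(surv, rev(eliminated)) # best first
  ranking <- tibble(
    gene = c(order_desc, genes[constant]),
    rank = seq_len(length(order_desc) + sum(constant)),
    iteration = c(iter + 1L, rev(elim_iter), rep(NA_integer_, sum(constant)))[
      seq_len(length(order_desc) + sum(constant))]
  )
  structure(ranking, class = c("gene_ranking", class(tibble())))
}

#' Build a marker panel by per-class SVM-RFE
#'
#' Runs [rfe_rank()] once per class (one vs rest), keeps the top `k` genes per
#' class, and merges the per-class lists into a deduplicated panel in the
#' canonical gene order of the input. Genes serving more than one class are
#' reported.
#'
#' @param data Expression tibble or matrix.
#' @param labels Class label per specimen.
#' @param k Genes kept per class (default 10).
#' @inheritParams rfe_rank
#' @return A list of class `gene_panel`: `per_class` (tibble `class`, `gene`,
#'   `rank`), `genes` (deduplicated union, canonical order), `shared` (genes
#'   in more than one per-class list), `k`.
#' @export
select_panel <- function(data, labels, k = 10, step_fraction = 0.1,
                         fine_threshold = 2 * k, cost = 0.01) {
  x <- as_expression_matrix(data)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    abort("`labels` must have one entry per specimen.")
  }
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(sprintf("Class(es) with fewer than 2 specimens: %s",
                  paste(small, collapse = ", ")))
  }
  classes <- unique(labels)
  per_class <- purrr::map_dfr(classes, function(cl) {
    r <- rfe_rank(x, labels == cl, step_fraction = step_fraction,
                  fine_threshold = fine_threshold, cost = cost)
    tibble(class = cl, gene = head(r$gene, k), rank = seq_len(min(k, nrow(r))))
  })
  merged <- intersect(colnames(x), unique(per_class$gene))
  dup <- per_class |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1)
  structure(
    list(per_class = per_class, genes = merged, shared = dup$gene, k = k),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d classes x top-%d, %d genes after dedup (%d shared)\n",
              length(unique(x$per_class$class)), x$k, length(x$genes),
              length(x$shared)))
  invisible(x)
}

#' @export
tidy.gene_panel <- function(x, ...) x$per_class

#' @export
glance.gene_panel <- function(x, ...) {
  tibble(n_classes = length(unique(x$per_class$class)), k = x$k,
         n_genes = length(x$genes), n_shared = length(x$shared))
}

#' Write or read a gene panel
#'
#' The JSON schema stores the class list, the per-class top-k lists and the
#' merged gene order, so an externally supplied panel can be loaded in place
#' of a selected one. The TSV form is a flat gene list.
#'
#' @param panel A [select_panel()] result (or a list in the same schema).
#' @param path File path.
#' @return `read_panel_json()` returns a `gene_panel`.
#' @export
write_panel_json <- function(panel, path) {
  per_class <- split(panel$per_class$gene, panel$per_class$class)
  jsonlite::write_json(
    list(k = panel$k, classes = unique(panel$per_class$class),
         per_class = per_class, genes = panel$genes),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(panel)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_class <- purrr::imap_dfr(raw$per_class, function(genes, cl) {
    tibble(class = cl, gene = genes, rank = seq_along(genes))
  })
  dup <- per_class |> dplyr::count(.data$gene) |> dplyr::filter(.data$n > 1)
  structure(
    list(per_class = per_class, genes = raw$genes, shared = dup$gene,
         k = raw$k),
    class = "gene_panel"
  )
}

#' @rdname write_panel_json
#' @export
write_panel_tsv <- function(panel, path) {
  write_tsv_file(tibble(gene = panel$genes), path)
  invisible(panel)
}
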