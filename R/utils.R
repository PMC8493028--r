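# internal helpers shared across modules

# round half away from zero at `digits` decimals (base round() is
# round-half-even; reported percentages follow the away-from-zero convention)
round_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate `code` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1], got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# columns of `data` that are gene measurements: everything numeric that is not
# a known metadata column
manifest_cols <- function() {
  c("specimen_id", "reference_diagnosis", "is_primary_liver", "specimen_type",
    "differentiation", "tumor_content", "necrosis", "a260_a280",
    "qc_truth", "qc_pass", "qc_stage", "qc_reason", "predicted")
}

gene_cols <- function(data) {
  setdiff(names(data), manifest_cols())
}

# expression tibble (specimen_id + gene columns) -> numeric matrix with
# specimen ids as rownames; accepts a matrix unchanged
as_expression_matrix <- function(x, genes = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- as_tibble(x)
    g <- genes %||% gene_cols(x)
    m <- as.matrix(x[, g, drop = FALSE])
    rownames(m) <- x$specimen_id %||% as.character(seq_len(nrow(m)))
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(m))
    if (length(missing) > 0) {
      abort(sprintf("Expression data is missing %d panel gene(s): %s",
                    length(missing), paste(missing, collapse = ", ")))
    }
    m <- m[, genes, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}
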