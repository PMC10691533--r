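#' Filter lowly expressed genes
#'
#' Removes genes whose fraction of missing-or-zero entries exceeds
#' `max_bad_fraction` of samples.  A gene sitting exactly at the boundary is
#' retained (removal requires a strictly greater fraction).
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param max_bad_fraction Maximum tolerated fraction of `NA`-or-zero
#'   entries per gene (default 0.75).
#' @return The matrix restricted to passing genes, row order preserved.
#' @export
filter_genes <- function(mat, max_bad_fraction = 0.75) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  bad <- is.na(mat) | mat == 0
  frac <- rowMeans(bad)
  keep <- frac <= max_bad_fraction
  if (!any(keep)) stop("no genes pass filter")
  mat[keep, , drop = FALSE]
}

#' Log2-transform expression values
#'
#' @param mat Nonnegative numeric matrix.
#' @param offset Pseudo-count added before taking logs (default 1).
#' @return `log2(mat + offset)`.
#' @export
log2_transform <- function(mat, offset = 1) {
  if (any(mat < 0, na.rm = TRUE)) stop("negative values cannot be log2-transformed")
  log2(mat + offset)
}

#' Regress confounding covariates out of an expression matrix
#'
#' Replaces each gene row by the residuals of an ordinary-least-squares fit
#' on an intercept plus the supplied covariates (age, sex, race by default in
#' the pipeline).  Categorical covariates are expanded to indicator
#' contrasts.  Constant covariate columns are dropped with a warning.
#' Genes containing missing values are fitted on their complete cases;
#' missing entries stay missing.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param covariates data.frame with one row per sample (aligned with
#'   `colnames(mat)` when both are named).
#' @return Residual matrix with the same dimensions and dimnames.
#' @export
adjust_covariates <- function(mat, covariates) {
  stopifnot(is.matrix(mat), nrow(covariates) == ncol(mat))
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) && !is.null(colnames(mat)) &&
      !all(rownames(covariates) == colnames(mat))) {
    if (!all(colnames(mat) %in% rownames(covariates)))
      stop("covariate rows do not match matrix samples")
    covariates <- covariates[colnames(mat), , drop = FALSE]
  }
  constant <- vapply(covariates, function(x) length(unique(na.omit(x))) < 2,
                     logical(1))
  if (any(constant)) {
    warning("dropping constant covariate column(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[, !constant, drop = FALSE]
  }
  if (ncol(covariates) == 0) {
    res <- mat - rowMeans(mat, na.rm = TRUE)
    return(res)
  }
  if (is.null(rownames(covariates))) rownames(covariates) <- seq_len(nrow(covariates))
  design <- model.matrix(~ ., data = covariates)
  # rows with NA covariates drop out of model.matrix; mark them
  sample_ok <- rownames(covariates) %in% rownames(design)
  design_full <- matrix(NA_real_, ncol(mat), ncol(design))
  design_full[sample_ok, ] <- design
  res <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  complete_gene <- !apply(is.na(mat), 1, any)
  qr_d <- qr(design)
  if (any(complete_gene) && all(sample_ok)) {
    res[complete_gene, ] <- t(qr.resid(qr_d, t(mat[complete_gene, , drop = FALSE])))
  } else {
    complete_gene[] <- FALSE  # fall through to per-gene fits
  }
  for (g in which(!complete_gene)) {
    obs <- !is.na(mat[g, ]) & sample_ok
    if (sum(obs) <= ncol(design)) next  # leave as NA: unidentifiable
    fit <- lm.fit(design_full[obs, , drop = FALSE], mat[g, obs])
    res[g, obs] <- fit$residuals
  }
  res
}
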