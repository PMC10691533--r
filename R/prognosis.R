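#' Module eigengene (first principal component)
#'
#' PC1 of the standardized gene x sample submatrix.  Gene rows are centered
#' and scaled before the singular value decomposition; the per-sample score
#' is the first right singular vector, sign-oriented so that it correlates
#' non-negatively with the module's mean expression profile.
#'
#' @param module Character vector of module genes.
#' @param expr Expression matrix (genes x samples).
#' @return Object of class `eigengene`: list with `score` (named,
#'   zero-mean), `var_explained`, `flipped` (logical sign flag), `n_genes`.
#' @export
compute_eigengene <- function(module, expr) {
  genes <- intersect(unique(module), rownames(expr))
  if (length(genes) < 2) stop("need at least 2 module genes in the matrix")
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping zero-variance module gene(s)")
    sub <- sub[sds > 0 & !is.na(sds), , drop = FALSE]
    if (nrow(sub) < 2) stop("need at least 2 module genes in the matrix")
  }
  z <- t(scale(t(sub)))
  z[is.na(z)] <- 0
  sv <- svd(z)
  score <- sv$v[, 1]
  score <- score - mean(score)
  profile <- colMeans(sub, na.rm = TRUE)
  flipped <- FALSE
  if (sd(profile) > 0 && cor(score, profile) < 0) {
    score <- -score
    flipped <- TRUE
  }
  names(score) <- colnames(expr)
  structure(list(score = score,
                 var_explained = sv$d[1]^2 / sum(sv$d^2),
                 flipped = flipped, n_genes = nrow(sub)),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("Eigengene over %d genes: %.1f%% variance explained\n",
              x$n_genes, 100 * x$var_explained))
  invisible(x)
}

#' Median stratification of per-sample scores
#'
#' Samples strictly above the median are labeled `high`; samples at or
#' below it (including the median value itself) are labeled `low`.
#'
#' @param scores Numeric vector (named by sample when available).
#' @return Factor with levels `low`, `high`.
#' @export
median_stratify <- function(scores) {
  stopifnot(length(scores) >= 2)
  if (length(unique(scores)) == 1) stop("degenerate stratification: all scores identical")
  med <- median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional-hazards fit for a module score
#'
#' Fits `survival::coxph` with Efron tie handling on a single covariate:
#' either the high/low group indicator from [median_stratify()] (the
#' default analysis) or the continuous standardized score.
#'
#' @param x Either a factor/character vector of `high`/`low` group labels or
#'   a numeric score vector; aligned with `survival$sample` by names when
#'   named, otherwise by position.
#' @param survival data.frame with columns `sample`, `time` (positive),
#'   `event` (1 = event, 0 = censored).
#' @param alpha Significance level for the prognostic flag (default 0.05).
#' @return Object of class `cox_result`: one-row data.frame with `beta`,
#'   `hr`, `p`, `n`, `n_events`, `prognostic`, `direction`, `separation`.
#' @export
cox_fit <- function(x, survival, alpha = 0.05) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival)))
  if (any(survival$time <= 0)) stop("survival times must be positive")
  if (!is.null(names(x))) {
    if (!all(survival$sample %in% names(x)))
      stop("samples missing from the score/group vector")
    x <- x[as.character(survival$sample)]
  } else if (length(x) != nrow(survival)) {
    stop("length of x does not match the survival table")
  }
  if (sum(survival$event) == 0) stop("no events observed")
  if (is.factor(x) || is.character(x)) {
    x <- factor(as.character(x), levels = c("low", "high"))
    if (any(table(x) == 0)) stop("both groups must be non-empty")
    cov <- as.numeric(x == "high")
  } else {
    if (sd(x) == 0) stop("degenerate score: zero variance")
    cov <- as.numeric(scale(x))
  }
  fit <- survival::coxph(survival::Surv(survival$time, survival$event) ~ cov,
                         ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  separation <- FALSE
  if (!is.finite(beta) || abs(beta) > 10) {
    warning("possible complete separation; capping beta at +/-10")
    separation <- TRUE
    beta <- sign(beta) * 10
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  res <- data.frame(beta = beta, hr = exp(beta), p = p,
                    n = nrow(survival), n_events = sum(survival$event),
                    prognostic = p < alpha,
                    direction = ifelse(exp(beta) > 1, "poor", "good"),
                    separation = separation, stringsAsFactors = FALSE)
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator via `survival::survfit`.
#'
#' @param groups Factor/character group labels aligned with
#'   `survival$sample` (by names when named).
#' @param survival data.frame `sample`, `time`, `event`.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   including the `time = 0, surv = 1` anchor per group.
#' @export
kaplan_meier <- function(groups, survival) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival)))
  if (!is.null(names(groups))) groups <- groups[as.character(survival$sample)]
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ groups)
  strata_names <- if (is.null(fit$strata)) levels(groups)[1] else
    sub("^groups=", "", names(fit$strata))
  grp <- if (is.null(fit$strata)) rep(strata_names, length(fit$time)) else
    rep(strata_names, fit$strata)
  out <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE)
  anchors <- data.frame(group = unique(grp), time = 0,
                        n_risk = as.vector(table(groups)[unique(grp)]),
                        n_event = 0, surv = 1, stringsAsFactors = FALSE)
  out <- rbind(anchors, out)
  out <- out[order(out$group, out$time), ]
  rownames(out) <- NULL
  out
}

#' Filter Cox results down to prognostic modules
#'
#' @param results data.frame of stacked [cox_fit()] rows (needs `p` and
#'   `hr` columns).
#' @param alpha Significance level (default 0.05).
#' @return The rows with `p < alpha`, with `direction` (re)annotated from
#'   the hazard ratio.
#' @export
flag_prognostic <- function(results, alpha = 0.05) {
  stopifnot(all(c("p", "hr") %in% names(results)))
  out <- results[results$p < alpha, , drop = FALSE]
  out$direction <- ifelse(out$hr > 1, "poor", "good")
  rownames(out) <- NULL
  out
}
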