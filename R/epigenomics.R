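#' Moderated t-test between tumor and normal groups
#'
#' Per-feature linear model of value on group plus covariates, with
#' empirical-Bayes variance shrinkage (limma's `lmFit`/`eBayes`):
#' the posterior variance is `(d0*s0^2 + dg*sg^2) / (d0 + dg)` and the
#' moderated t uses `d0 + dg` degrees of freedom.
#'
#' @param values Feature x sample matrix (log2 expression or methylation
#'   beta values).
#' @param groups Factor/character with two levels; the effect is the second
#'   level minus the first (pass `factor(..., levels = c("normal",
#'   "tumor"))` for tumor-vs-normal effects).
#' @param covariates Optional data.frame of per-sample covariates (age,
#'   sex, race in the pipeline).
#' @return data.frame of class `diff_result`: `feature`, `effect`, `s2`,
#'   `t`, `p`, `adj_p`, plus attributes `d0` (prior df) and `s0_sq` (prior
#'   variance).
#' @export
moderated_t_test <- function(values, groups, covariates = NULL) {
  stopifnot(is.matrix(values))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  if (is.null(covariates)) {
    design <- model.matrix(~ groups)
  } else {
    stopifnot(nrow(covariates) == ncol(values))
    design <- model.matrix(~ groups + ., data = as.data.frame(covariates))
  }
  if (ncol(values) - qr(design)$rank < 1) stop("zero residual degrees of freedom")
  fit <- limma::lmFit(values, design)
  eb <- limma::eBayes(fit)
  res <- data.frame(feature = rownames(values),
                    effect = fit$coefficients[, 2],
                    s2 = fit$sigma^2,
                    t = eb$t[, 2],
                    p = eb$p.value[, 2],
                    stringsAsFactors = FALSE)
  res$adj_p <- bh_adjust(res$p)
  rownames(res) <- NULL
  attr(res, "d0") <- eb$df.prior
  attr(res, "s0_sq") <- eb$s2.prior
  attr(res, "df_resid") <- fit$df.residual[1]
  attr(res, "s2_post") <- unname(eb$s2.post)
  attr(res, "stdev_unscaled") <- unname(fit$stdev.unscaled[, 2])
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Call differentially expressed genes
#'
#' Labels features `up` when the natural-scale fold change `2^effect`
#' exceeds `fc_threshold` with adjusted p below `alpha`, `down` for the
#' mirror condition, `ns` otherwise.
#'
#' @param results A `diff_result` (log2-scale effects).
#' @param fc_threshold Natural-scale fold-change cutoff (default 2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return `results` with a `direction` column.
#' @export
call_degs <- function(results, fc_threshold = 2, alpha = 0.05) {
  up <- 2^results$effect > fc_threshold & results$adj_p < alpha
  down <- 2^(-results$effect) > fc_threshold & results$adj_p < alpha
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Map methylation probes to gene promoters
#'
#' The promoter of a `+` strand gene with TSS `t` is `[t - up, t + down]`;
#' for a `-` strand gene the window is mirrored to `[t - down, t + up]`.
#' Coordinates are 1-based inclusive; a probe maps to every gene whose
#' promoter window contains its position.
#'
#' @param probes data.frame `probe`, `chrom`, `pos` (and optionally `maf`).
#' @param genes data.frame `gene`, `chrom`, `tss`, `strand` (`+`/`-`;
#'   anything else is treated as `+` with a warning).
#' @param up Bases upstream of the TSS (default 2000).
#' @param down Bases downstream of the TSS (default 200).
#' @return data.frame `probe`, `gene` with one row per mapping.
#' @export
map_promoter_probes <- function(probes, genes, up = 2000, down = 200) {
  stopifnot(all(c("probe", "chrom", "pos") %in% names(probes)),
            all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  strand <- as.character(genes$strand)
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warning(sprintf("%d gene(s) with unknown strand treated as '+'",
                    sum(unknown)))
    strand[unknown] <- "+"
  }
  win_start <- ifelse(strand == "+", genes$tss - up, genes$tss - down)
  win_end <- ifelse(strand == "+", genes$tss + down, genes$tss + up)
  lv <- union(unique(genes$chrom), unique(probes$chrom))
  prom <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = lv),
    ranges = IRanges::IRanges(start = pmax(win_start, 1), end = win_end))
  pr <- GenomicRanges::GRanges(
    seqnames = factor(probes$chrom, levels = lv),
    ranges = IRanges::IRanges(start = probes$pos, width = 1))
  hits <- GenomicRanges::findOverlaps(pr, prom)
  data.frame(probe = probes$probe[S4Vectors::queryHits(hits)],
             gene = genes$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Call differentially methylated CpGs
#'
#' Probes carrying a SNP with minor allele frequency above `maf_cut` are
#' excluded before multiple-testing adjustment; remaining probes are
#' labeled by the sign of the beta-value change when `|delta| >
#' delta_threshold` and the re-adjusted p is below `alpha`.
#'
#' @param results A `diff_result` on beta values (effects in `[-1, 1]`).
#' @param probe_annot data.frame `probe` and `maf` (NA = no known SNP).
#' @param delta_threshold Beta-change cutoff (default 0.2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param maf_cut SNP minor-allele-frequency exclusion cutoff (default 0.05).
#' @return Filtered `results` with recomputed `adj_p` and a `direction`
#'   column.
#' @export
call_dmcs <- function(results, probe_annot, delta_threshold = 0.2,
                      alpha = 0.05, maf_cut = 0.05) {
  stopifnot(all(c("probe", "maf") %in% names(probe_annot)))
  maf <- probe_annot$maf[match(results$feature, probe_annot$probe)]
  keep <- is.na(maf) | maf <= maf_cut
  results <- results[keep, , drop = FALSE]
  results$adj_p <- bh_adjust(results$p)
  sig <- abs(results$effect) > delta_threshold & results$adj_p < alpha
  results$direction <- ifelse(sig & results$effect > 0, "up",
                              ifelse(sig, "down", "ns"))
  rownames(results) <- NULL
  results
}

#' DEG/DMC co-regulation categories per module
#'
#' Runs four Fisher enrichments per eligible module (up/down DEG gene sets
#' and up/down DMC gene sets, DMCs lifted to genes through the promoter
#' mapping) and assembles a combined label such as `dDEG-uDMC` from the
#' significant flags.
#'
#' @param hierarchy A `module_hierarchy`.
#' @param deg_results Output of [call_degs()].
#' @param dmc_results Output of [call_dmcs()].
#' @param probe_map Output of [map_promoter_probes()].
#' @param universe Gene universe for the enrichment test.
#' @param size_bounds,min_overlap,alpha Passed to [fisher_enrichment()].
#' @return data.frame `module`, `uDEG`, `dDEG`, `uDMC`, `dDMC` (logical
#'   flags), `label`.
#' @export
categorize_modules <- function(hierarchy, deg_results, dmc_results,
                               probe_map, universe,
                               size_bounds = c(10, 500), min_overlap = 4,
                               alpha = 0.05) {
  lift <- function(dirn) {
    probes <- dmc_results$feature[dmc_results$direction == dirn]
    unique(probe_map$gene[probe_map$probe %in% probes])
  }
  sets <- list(
    uDEG = deg_results$feature[deg_results$direction == "up"],
    dDEG = deg_results$feature[deg_results$direction == "down"],
    uDMC = lift("up"),
    dDMC = lift("down"))
  ids <- eligible_modules(hierarchy, size_bounds)
  flags <- matrix(FALSE, length(ids), 4,
                  dimnames = list(ids, names(sets)))
  nonempty <- vapply(sets, length, integer(1)) > 0
  coll <- if (any(nonempty)) tryCatch(
    suppressWarnings(gene_set_collection(sets[nonempty], universe,
                                         name = "deg_dmc")),
    error = function(e) NULL) else NULL
  if (!is.null(coll)) {
    for (mid in ids) {
      r <- fisher_enrichment(hierarchy$genes[[mid]], coll,
                             size_bounds = size_bounds,
                             min_overlap = min_overlap, alpha = alpha)
      if (nrow(r)) flags[mid, r$set] <- r$significant
    }
  }
  label <- apply(flags, 1, function(fl) {
    parts <- colnames(flags)[fl]
    if (length(parts) == 0) "none" else paste(parts, collapse = "-")
  })
  data.frame(module = ids, uDEG = flags[, "uDEG"], dDEG = flags[, "dDEG"],
             uDMC = flags[, "uDMC"], dDMC = flags[, "dDMC"],
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}
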