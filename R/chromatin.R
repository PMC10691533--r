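#' Mean accessibility signal per cytoband
#'
#' A cytoband's value is the mean of the normalized peak counts over all
#' (region, sample) cells of the fixed-width regions overlapping the band
#' (any overlap counts; a region spanning a boundary contributes to every
#' band it touches).  Bands without any region get `NA` and are excluded
#' downstream.
#'
#' @param peaks List with `regions` (data.frame `chrom`, `start`, `end`,
#'   1-based inclusive) and `counts` (region x sample matrix of normalized
#'   log2 counts).
#' @param bands data.frame `chrom`, `start`, `end`, `band` (1-based
#'   inclusive; UCSC-style names).
#' @return data.frame `band`, `mean_signal`, `n_regions`, with the global
#'   background mean attached as attribute `background`.
#' @export
cytoband_peak_signal <- function(peaks, bands) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks$regions)),
            all(c("chrom", "start", "end", "band") %in% names(bands)),
            nrow(peaks$regions) == nrow(peaks$counts))
  lv <- union(unique(peaks$regions$chrom), unique(bands$chrom))
  rg <- GenomicRanges::GRanges(
    factor(peaks$regions$chrom, levels = lv),
    IRanges::IRanges(peaks$regions$start, peaks$regions$end))
  bg <- GenomicRanges::GRanges(
    factor(bands$chrom, levels = lv),
    IRanges::IRanges(bands$start, bands$end))
  hits <- GenomicRanges::findOverlaps(rg, bg)
  if (length(hits) == 0) stop("no peak regions overlap any cytoband")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  region_mean <- rowMeans(peaks$counts)
  out <- data.frame(band = bands$band, mean_signal = NA_real_,
                    n_regions = 0L, stringsAsFactors = FALSE)
  agg_n <- tabulate(sh, nbins = nrow(bands))
  agg_sum <- vapply(seq_len(nrow(bands)), function(b)
    sum(region_mean[qh[sh == b]]), numeric(1))
  out$n_regions <- agg_n
  out$mean_signal[agg_n > 0] <- agg_sum[agg_n > 0] / agg_n[agg_n > 0]
  attr(out, "background") <- mean(peaks$counts)
  out
}

#' Fold change of per-band signal over the genome background
#'
#' The background is the mean over all peak values from all samples;
#' `FC(band) = band mean / background`.
#'
#' @param band_signals Output of [cytoband_peak_signal()] (carries the
#'   background as an attribute), or a data.frame with `band` and
#'   `mean_signal` plus a `background` argument.
#' @param background Optional explicit background mean.
#' @return data.frame `band`, `fold_change` (NA bands dropped).
#' @export
fold_change_vs_background <- function(band_signals, background = NULL) {
  if (is.null(background)) background <- attr(band_signals, "background")
  if (is.null(background)) stop("background mean not supplied")
  if (background <= 0) stop("background mean must be positive")
  keep <- !is.na(band_signals$mean_signal)
  data.frame(band = band_signals$band[keep],
             fold_change = band_signals$mean_signal[keep] / background,
             stringsAsFactors = FALSE)
}

#' Compare accessibility fold changes of module-enriched vs depleted bands
#'
#' Two-sided Wilcoxon rank-sum test on the per-band fold changes, exact for
#' small tie-free samples and normal approximation with continuity
#' correction otherwise (the `stats::wilcox.test` rule).
#'
#' @param fold_changes Output of [fold_change_vs_background()].
#' @param enriched_bands Character vector of module-enriched band names;
#'   the remaining bands form the depleted group.
#' @return List `statistic`, `p`, `median_enriched`, `median_depleted`,
#'   `n_enriched`, `n_depleted`.
#' @export
compare_enriched_vs_depleted <- function(fold_changes, enriched_bands) {
  grp <- fold_changes$band %in% enriched_bands
  x <- fold_changes$fold_change[grp]
  y <- fold_changes$fold_change[!grp]
  if (length(x) < 2 || length(y) < 2)
    stop("both band groups need at least 2 members")
  wt <- wilcox.test(x, y, alternative = "two.sided")
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_enriched = median(x), median_depleted = median(y),
       n_enriched = length(x), n_depleted = length(y))
}
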