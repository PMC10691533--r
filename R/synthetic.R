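#' Default planted-module layout
#'
#' Twelve 40-gene modules over three cohorts: four shared by all cohorts,
#' two shared by a cohort pair, six private (two per cohort).  Module M01
#' carries a poor-prognosis hazard (HR 2) and M02 a protective one
#' (HR 0.5); M03 and M04 are methylation-coupled (expression down/up in
#' tumors with promoter methylation moving oppositely); four modules are
#' anchored on cytobands, which double as the open-chromatin bands.
#'
#' @param n_cohorts Number of cohorts the layout spans (default 3).
#' @return data.frame with one row per module: `id`, `size`, `target_r`,
#'   `cohorts` (comma-joined cohort indices), `children`, `cytoband`,
#'   `log_hr`, `meth_coupling`.
#' @export
default_module_spec <- function(n_cohorts = 3) {
  stopifnot(n_cohorts >= 3)
  data.frame(
    id = sprintf("P%02d", 1:12),
    size = 40L,
    target_r = 0.7,
    cohorts = c(rep("1,2,3", 4), "1,2", "2,3",
                "1", "1", "2", "2", "3", "3"),
    children = 1L,
    cytoband = c("1p11", NA, "2p11", "2q11", NA, NA,
                 "3p11", NA, NA, NA, NA, NA),
    log_hr = c(log(2), log(0.5), rep(0, 10)),
    meth_coupling = c(0L, 0L, -1L, 1L, rep(0L, 8)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic multi-cohort,
#' multi-omic generator.  The defaults are the package's reference study
#' conditions: 3 cohorts x 1200 genes x 200 tumor samples (plus 60 normals
#' per cohort), the [default_module_spec()] planted layout, 30% censoring,
#' and mild age/sex/race confounder effects.
#'
#' @param n_cohorts,genes_per_cohort,samples_per_cohort,n_normal Cohort
#'   dimensions.
#' @param modules Module layout data.frame (see [default_module_spec()]);
#'   `NULL` plants no structure.
#' @param censoring_fraction Target fraction of censored samples, in
#'   `[0, 1)`.
#' @param covariate_effects Named vector: `age` (per year), `sex` (added
#'   for males), `race` (spread across race levels).
#' @param de_lfc Log2 fold change planted for methylation-coupled modules
#'   (tumor vs normal; default 2).
#' @param meth_slope Logistic slope linking standardized expression to
#'   promoter beta values (default 2).
#' @param meth_noise_sd Logit-scale methylation noise (default 0.5).
#' @param baseline_hazard Exponential baseline hazard per day
#'   (default 1/1000).
#' @param n_atac_samples Accessibility samples (default 20).
#' @param open_shift Log2 count elevation of open cytobands (default 1.5).
#' @param seed Integer master seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 3, genes_per_cohort = 1200,
                              samples_per_cohort = 200, n_normal = 60,
                              modules = default_module_spec(n_cohorts),
                              censoring_fraction = 0.3,
                              covariate_effects = c(age = 0.02, sex = 0.5,
                                                    race = 0.3),
                              de_lfc = 2, meth_slope = 2,
                              meth_noise_sd = 0.5,
                              baseline_hazard = 1 / 1000,
                              n_atac_samples = 20, open_shift = 1.5,
                              seed = 1) {
  if (is.null(modules))
    modules <- default_module_spec()[0, ]
  if (nrow(modules) > 0) {
    if (any(modules$size < 10 | modules$size > 500))
      stop("module gene counts must lie in [10, 500]")
    if (sum(modules$size) > genes_per_cohort)
      stop("configuration error: module gene counts exceed genes_per_cohort")
    if (anyDuplicated(modules$id)) stop("duplicated module ids")
  }
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must lie in [0, 1)")
  stopifnot(samples_per_cohort >= 4, genes_per_cohort >= 20, n_cohorts >= 1)
  structure(list(n_cohorts = n_cohorts,
                 genes_per_cohort = genes_per_cohort,
                 samples_per_cohort = samples_per_cohort,
                 n_normal = n_normal, modules = modules,
                 censoring_fraction = censoring_fraction,
                 covariate_effects = covariate_effects, de_lfc = de_lfc,
                 meth_slope = meth_slope, meth_noise_sd = meth_noise_sd,
                 baseline_hazard = baseline_hazard,
                 n_atac_samples = n_atac_samples, open_shift = open_shift,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d cohorts x %d genes x %d tumor ",
                     "(+%d normal) samples, %d planted modules, seed %d\n"),
              x$n_cohorts, x$genes_per_cohort, x$samples_per_cohort,
              x$n_normal, nrow(x$modules), x$seed))
  invisible(x)
}

.module_cohorts <- function(modules) {
  lapply(strsplit(modules$cohorts, ","), as.integer)
}

.module_gene_map <- function(config) {
  # deterministic: modules claim leading gene ids in spec order
  genes <- sprintf("g%04d", seq_len(config$genes_per_cohort))
  out <- list()
  pos <- 0
  for (i in seq_len(nrow(config$modules))) {
    out[[config$modules$id[i]]] <- genes[pos + seq_len(config$modules$size[i])]
    pos <- pos + config$modules$size[i]
  }
  list(genes = genes, module_genes = out)
}

#' Generate correlated multi-cohort expression matrices
#'
#' Latent-factor (spiked covariance) model: each planted module draws a
#' parent factor per sample; member genes load on it (plus a child factor
#' when the module declares children) with loadings tuned so the expected
#' within-module Pearson correlation equals the module's `target_r`.
#' Shared modules reuse identical gene sets across cohorts; genes outside
#' any active module are independent noise.  Methylation-coupled modules
#' are shifted by `de_lfc` in tumors relative to normals; age/sex/race
#' effects are added linearly to every gene.  Values are on a log2
#' expression scale (per-gene baselines drawn once for all cohorts).
#'
#' @param config A [simulation_config()].
#' @return List with `cohorts` (per cohort: `cohort` label, `expr` tumor
#'   matrix, `expr_all` tumor+normal matrix, `groups` factor
#'   (`normal`/`tumor`), `covariates` data.frame, `factor_scores` tumor
#'   sample x active-module matrix of true parent factors) and `truth`
#'   (gene-module assignments per cohort, module table, DEG/DMC truth).
#' @export
generate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gm <- .module_gene_map(config)
  genes <- gm$genes
  baseline <- runif(length(genes), 4, 10)
  names(baseline) <- genes
  mod_cohorts <- .module_cohorts(config$modules)
  eff <- config$covariate_effects

  cohorts <- vector("list", config$n_cohorts)
  assignments <- list()
  for (co in seq_len(config$n_cohorts)) {
    n_t <- config$samples_per_cohort
    n_n <- config$n_normal
    n_all <- n_t + n_n
    ids <- c(sprintf("C%d_T%03d", co, seq_len(n_t)),
             sprintf("C%d_N%03d", co, seq_len(max(n_n, 0))))
    groups <- factor(rep(c("tumor", "normal"), c(n_t, n_n)),
                     levels = c("normal", "tumor"))
    covariates <- data.frame(
      age = round(runif(n_all, 40, 80)),
      sex = factor(sample(c("F", "M"), n_all, replace = TRUE)),
      race = factor(sample(c("A", "B", "C"), n_all, replace = TRUE)),
      row.names = ids)
    X <- matrix(rnorm(length(genes) * n_all), length(genes), n_all,
                dimnames = list(genes, ids))
    active <- which(vapply(mod_cohorts, function(cs) co %in% cs, logical(1)))
    fs <- matrix(0, n_t, length(active),
                 dimnames = list(ids[seq_len(n_t)],
                                 config$modules$id[active]))
    for (ai in seq_along(active)) {
      i <- active[ai]
      mg <- gm$module_genes[[config$modules$id[i]]]
      r <- config$modules$target_r[i]
      kids <- max(1L, config$modules$children[i])
      fp <- rnorm(n_all)
      fs[, ai] <- fp[seq_len(n_t)]
      if (kids == 1) {
        lam <- sqrt(r)
        X[mg, ] <- lam * matrix(fp, length(mg), n_all, byrow = TRUE) +
          sqrt(1 - r) * X[mg, ]
      } else {
        lp <- sqrt(r / 2)          # cross-child correlation r/2
        lc <- sqrt(r / 2)          # within-child correlation r
        split_idx <- rep(seq_len(kids), length.out = length(mg))
        for (kk in seq_len(kids)) {
          fc <- rnorm(n_all)
          cg <- mg[split_idx == kk]
          X[cg, ] <- lp * matrix(fp, length(cg), n_all, byrow = TRUE) +
            lc * matrix(fc, length(cg), n_all, byrow = TRUE) +
            sqrt(1 - r) * X[cg, ]
        }
      }
      s <- config$modules$meth_coupling[i]
      if (s != 0 && n_t > 0)
        X[mg, seq_len(n_t)] <- X[mg, seq_len(n_t)] + s * config$de_lfc
    }
    conf <- eff[["age"]] * (covariates$age - 60) +
      eff[["sex"]] * (covariates$sex == "M") +
      eff[["race"]] * (as.integer(covariates$race) - 2)
    X <- X + matrix(conf, length(genes), n_all, byrow = TRUE)
    X <- X + baseline
    if (length(active)) {
      assignments[[co]] <- data.frame(
        cohort = paste0("C", co),
        gene = unlist(gm$module_genes[config$modules$id[active]],
                      use.names = FALSE),
        module = rep(config$modules$id[active],
                     config$modules$size[active]),
        stringsAsFactors = FALSE)
    }
    cohorts[[co]] <- list(cohort = paste0("C", co),
                          expr = X[, seq_len(n_t), drop = FALSE],
                          expr_all = X, groups = groups,
                          covariates = covariates, factor_scores = fs)
  }
  coupled <- config$modules$meth_coupling != 0
  deg_truth <- if (any(coupled)) data.frame(
    gene = unlist(gm$module_genes[config$modules$id[coupled]],
                  use.names = FALSE),
    module = rep(config$modules$id[coupled], config$modules$size[coupled]),
    direction = rep(ifelse(config$modules$meth_coupling[coupled] > 0,
                           "up", "down"), config$modules$size[coupled]),
    stringsAsFactors = FALSE) else
    data.frame(gene = character(0), module = character(0),
               direction = character(0))
  dmc_truth <- deg_truth
  if (nrow(dmc_truth)) {
    dmc_truth$probe <- paste0("cg_", dmc_truth$gene)
    dmc_truth$direction <- ifelse(deg_truth$direction == "up", "down", "up")
  }
  truth <- list(assignments = do.call(rbind, assignments),
                module_genes = gm$module_genes,
                modules = config$modules,
                gene_ids = genes,
                deg_truth = deg_truth, dmc_truth = dmc_truth)
  list(cohorts = cohorts, truth = truth)
}

#' Generate survival outcomes from module activity
#'
#' Event times follow an exponential model whose log hazard is linear in
#' the standardized per-sample module scores:
#' `h(s) = h0 * exp(sum_m log_hr_m * z_m(s))`.  Censoring times are drawn
#' from an independent exponential calibrated to the target censoring
#' fraction.
#'
#' @param scores Sample x module matrix of module activity (column names
#'   must match module ids in the config).
#' @param config A [simulation_config()] (provides the true log hazard
#'   ratios, the baseline hazard and the censoring fraction).
#' @param seed Integer seed (default derived from the config seed).
#' @return data.frame `sample`, `time` (days, positive), `event`
#'   (1 = event), `endpoint` (`"OS"`).
#' @export
generate_survival <- function(scores, config, seed = config$seed + 77L) {
  stopifnot(is.matrix(scores))
  if (nrow(scores) == 0) stop("empty sample set")
  set.seed(seed)
  lp <- rep(0, nrow(scores))
  for (i in seq_len(nrow(config$modules))) {
    b <- config$modules$log_hr[i]
    mid <- config$modules$id[i]
    if (b != 0 && mid %in% colnames(scores))
      lp <- lp + b * as.numeric(scale(scores[, mid]))
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- rexp(length(rate), rate)
  cf <- config$censoring_fraction
  if (cf > 0) {
    # calibrate the censoring rate c so that mean_i c/(rate_i + c) = cf
    c_rate <- stats::uniroot(
      function(cc) mean(cc / (rate + cc)) - cf,
      lower = min(rate) * 1e-6, upper = max(rate) * 1e6, tol = 1e-10)$root
    t_cens <- rexp(length(rate), c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, length(rate))
  }
  data.frame(sample = rownames(scores), time = pmax(time, 1e-3),
             event = event, endpoint = "OS", stringsAsFactors = FALSE)
}

#' Generate a synthetic genome annotation and accessibility peaks
#'
#' Builds a small genome of 4 chromosomes x 6 cytobands (1 Mb each).
#' Genes of cytoband-anchored modules are placed contiguously inside their
#' band; all other genes are placed uniformly.  Fixed-width (500 bp)
#' accessibility regions are tiled every 5 kb; regions inside "open"
#' cytobands (the bands hosting anchored modules, by default) receive
#' counts elevated by `open_shift`.
#'
#' @param config A [simulation_config()].
#' @return List with `bands` (data.frame `chrom`, `start`, `end`, `band`,
#'   `stain`), `genes` (data.frame `gene`, `chrom`, `tss`, `strand`,
#'   `cytoband`), `peaks` (list `regions`, `counts`), `open_bands`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 500L)
  band_len <- 1e6L
  band_names <- c("p13", "p12", "p11", "q11", "q12", "q13")
  bands <- do.call(rbind, lapply(1:4, function(ch) {
    data.frame(chrom = paste0("chr", ch),
               start = (seq_along(band_names) - 1L) * band_len + 1L,
               end = seq_along(band_names) * band_len,
               band = paste0(ch, band_names),
               stain = rep(c("gneg", "gpos50"), 3),
               stringsAsFactors = FALSE)
  }))
  gm <- .module_gene_map(config)
  genes <- gm$genes
  chrom <- character(length(genes))
  tss <- integer(length(genes))
  placed <- rep(FALSE, length(genes))
  names(placed) <- genes
  anchored <- which(!is.na(config$modules$cytoband))
  for (i in anchored) {
    b <- bands[bands$band == config$modules$cytoband[i], ]
    if (nrow(b) == 0) stop("unknown cytoband in module spec: ",
                           config$modules$cytoband[i])
    mg <- gm$module_genes[[config$modules$id[i]]]
    step <- (b$end - b$start) %/% (length(mg) + 1L)
    idx <- match(mg, genes)
    chrom[idx] <- b$chrom
    tss[idx] <- b$start + step * seq_along(mg)
    placed[idx] <- TRUE
  }
  free <- which(!placed)
  chrom[free] <- paste0("chr", sample(1:4, length(free), replace = TRUE))
  tss[free] <- sample.int(6L * band_len - 1000L, length(free),
                          replace = TRUE)
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  band_of <- function(ch, pos) {
    hit <- bands$chrom == ch & bands$start <= pos & bands$end >= pos
    if (any(hit)) bands$band[which(hit)[1]] else NA_character_
  }
  cytoband <- mapply(band_of, chrom, tss, USE.NAMES = FALSE)
  gene_df <- data.frame(gene = genes, chrom = chrom, tss = tss,
                        strand = strand, cytoband = cytoband,
                        stringsAsFactors = FALSE)
  open_bands <- unique(na.omit(config$modules$cytoband))
  # fixed-width regions, 500 bp wide, every 5 kb
  starts <- seq(1L, 6L * band_len - 500L, by = 5000L)
  regions <- do.call(rbind, lapply(1:4, function(ch) {
    data.frame(chrom = paste0("chr", ch), start = starts,
               end = starts + 499L, stringsAsFactors = FALSE)
  }))
  region_band <- mapply(band_of, regions$chrom, regions$start,
                        USE.NAMES = FALSE)
  counts <- matrix(rnorm(nrow(regions) * config$n_atac_samples, 2, 0.4),
                   nrow(regions), config$n_atac_samples)
  open <- region_band %in% open_bands
  counts[open, ] <- counts[open, ] + config$open_shift
  rownames(counts) <- paste0("peak_", seq_len(nrow(regions)))
  colnames(counts) <- sprintf("atac_%02d", seq_len(config$n_atac_samples))
  list(bands = bands, genes = gene_df,
       peaks = list(regions = regions, counts = counts),
       open_bands = open_bands)
}

#' Generate promoter methylation beta values
#'
#' One promoter CpG probe per gene, placed strand-aware inside the
#' `[TSS - 2000, TSS + 200]` promoter window.  For genes of
#' methylation-coupled modules the beta value is a logistic transform of
#' minus the gene's standardized expression plus noise, giving the planted
#' anti-correlation; all other probes get independent logit-normal betas.
#' A handful of background probes carry a common SNP (MAF 0.1) to exercise
#' the SNP mask.
#'
#' @param expr Gene x sample expression matrix (tumor + normal).
#' @param truth Truth list from [generate_multi_cohort()].
#' @param config A [simulation_config()].
#' @param annotation Output of [generate_annotation()].
#' @param seed Integer seed.
#' @return List with `beta` (probe x sample matrix in `[0, 1]`) and
#'   `probes` (data.frame `probe`, `gene`, `chrom`, `pos`, `maf`).
#' @export
generate_methylation <- function(expr, truth, config, annotation,
                                 seed = config$seed + 200L) {
  set.seed(seed)
  genes <- rownames(expr)
  ann <- annotation$genes[match(genes, annotation$genes$gene), ]
  pos <- ifelse(ann$strand == "+", ann$tss - 500L, ann$tss + 500L)
  coupled_modules <- config$modules$id[config$modules$meth_coupling != 0]
  coupled_genes <- unlist(truth$module_genes[coupled_modules],
                          use.names = FALSE)
  beta <- matrix(NA_real_, length(genes), ncol(expr),
                 dimnames = list(paste0("cg_", genes), colnames(expr)))
  is_coupled <- genes %in% coupled_genes
  for (g in which(is_coupled)) {
    z <- as.numeric(scale(expr[g, ]))
    beta[g, ] <- plogis(-config$meth_slope * z +
                          rnorm(ncol(expr), 0, config$meth_noise_sd))
  }
  n_unc <- sum(!is_coupled)
  if (n_unc > 0) {
    b0 <- rnorm(n_unc, 0, 1.5)
    beta[!is_coupled, ] <- plogis(
      b0 + matrix(rnorm(n_unc * ncol(expr), 0, 0.5), n_unc, ncol(expr)))
  }
  maf <- rep(NA_real_, length(genes))
  background <- setdiff(genes, unlist(truth$module_genes, use.names = FALSE))
  snp_genes <- head(background, 5)
  maf[genes %in% snp_genes] <- 0.10
  probes <- data.frame(probe = rownames(beta), gene = genes,
                       chrom = ann$chrom, pos = pos, maf = maf,
                       stringsAsFactors = FALSE)
  list(beta = beta, probes = probes)
}

#' Build the complete default synthetic fixture
#'
#' Runs every generator in sequence under one master seed and assembles
#' the package's reference multi-cohort, multi-omic data set with ground
#' truth: expression (tumor + normal), covariates, survival, promoter
#' methylation, genome annotation and accessibility peaks.
#'
#' @param seed Master seed (default 1).
#' @param config Optional pre-built [simulation_config()].
#' @return List `config`, `truth`, `annotation`, `cohorts`; each cohort
#'   additionally carries `survival`, `beta`, `probes`.
#' @export
make_default_fixture <- function(seed = 1, config = simulation_config(seed = seed)) {
  annotation <- generate_annotation(config)
  mc <- generate_multi_cohort(config)
  for (co in seq_along(mc$cohorts)) {
    ch <- mc$cohorts[[co]]
    ch$survival <- generate_survival(ch$factor_scores, config,
                                     seed = config$seed + 77L + co)
    me <- generate_methylation(ch$expr_all, mc$truth, config, annotation,
                               seed = config$seed + 200L + co)
    ch$beta <- me$beta
    ch$probes <- me$probes
    mc$cohorts[[co]] <- ch
  }
  list(config = config, truth = mc$truth, annotation = annotation,
       cohorts = mc$cohorts)
}
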