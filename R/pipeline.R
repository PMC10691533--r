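#' Pipeline configuration with the analysis defaults
#'
#' Collects every stage threshold in one validated list.  Defaults: 10
#' permutations and FDR 0.05 for the correlation cutoff, module sizes
#' 10-500, enrichment rule overlap above 3 with adjusted p below 0.05,
#' fold change above 2 for DEGs, beta change above 0.2 for DMCs, SNP MAF
#' mask 0.05, promoter window 2000/200 bp, conserved-pair rule J above 0.4
#' with adjusted p below 0.05 (specific below J 0.05), aggregation node
#' weight at least 4, Cox alpha 0.05.
#'
#' @param n_perm,corr_alpha Correlation-threshold permutations and FDR.
#' @param min_module,max_module Module size bounds.
#' @param min_overlap,enrich_alpha Enrichment significance rule.
#' @param fc_threshold,delta_threshold,maf_cut DEG/DMC thresholds.
#' @param promoter_up,promoter_down Promoter window (bases).
#' @param jaccard_conserved,jaccard_specific,preserve_alpha Preservation
#'   thresholds.
#' @param agg_min_weight Aggregated-network node weight cutoff.
#' @param cox_alpha Prognostic significance level.
#' @param n_null Null planar graphs gating each modularity split.
#' @param seed Master seed for the stochastic stages.
#' @param endpoint Survival endpoint label (per-cohort named vector or a
#'   single value recycled).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_perm = 10, corr_alpha = 0.05,
                            min_module = 10, max_module = 500,
                            min_overlap = 4, enrich_alpha = 0.05,
                            fc_threshold = 2, delta_threshold = 0.2,
                            maf_cut = 0.05, promoter_up = 2000,
                            promoter_down = 200, jaccard_conserved = 0.4,
                            jaccard_specific = 0.05, preserve_alpha = 0.05,
                            agg_min_weight = 4, cox_alpha = 0.05,
                            n_null = 30, seed = 7, endpoint = "OS") {
  cfg <- list(n_perm = n_perm, corr_alpha = corr_alpha,
              min_module = min_module, max_module = max_module,
              min_overlap = min_overlap, enrich_alpha = enrich_alpha,
              fc_threshold = fc_threshold,
              delta_threshold = delta_threshold, maf_cut = maf_cut,
              promoter_up = promoter_up, promoter_down = promoter_down,
              jaccard_conserved = jaccard_conserved,
              jaccard_specific = jaccard_specific,
              preserve_alpha = preserve_alpha,
              agg_min_weight = agg_min_weight, cox_alpha = cox_alpha,
              n_null = n_null, seed = as.integer(seed),
              endpoint = endpoint)
  stopifnot(cfg$corr_alpha > 0, cfg$corr_alpha < 1, cfg$n_perm >= 1,
            cfg$min_module >= 2, cfg$max_module >= cfg$min_module,
            cfg$maf_cut >= 0, cfg$fc_threshold >= 1,
            cfg$delta_threshold >= 0, cfg$delta_threshold <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full multi-cohort pipeline on a fixture-format directory
#'
#' Executes, in order: preprocessing (gene filter + covariate
#' adjustment), permutation-FDR correlation thresholding, PMFG
#' construction, multiscale module detection, hub analysis, eigengene
#' prognosis (median-split Cox), cytoband enrichment, tumor-vs-normal DEG
#' and promoter DMC analysis with module co-regulation categories,
#' cytoband accessibility contrast, cross-cohort preservation with module
#' clusters and cohort clustering, and conservation-weighted aggregation.
#' Every stage writes its table under `out_dir`; `manifest.json` records
#' thresholds, seeds and per-stage counts.
#'
#' @param input_dir Directory produced by [write_fixture()] (or files in
#'   the same naming convention).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr_files <- sort(list.files(input_dir, "^expression_.*\\.tsv$"))
  if (length(expr_files) == 0) stop("no expression_<cohort>.tsv files in ", input_dir)
  cohorts <- sub("^expression_(.*)\\.tsv$", "\\1", expr_files)
  sb <- c(config$min_module, config$max_module)
  genes_ann <- read_table_tsv(file.path(input_dir, "genes.tsv"))
  bands <- read_cytoband(file.path(input_dir, "cytoband.tsv"))
  manifest <- list(config = unclass(config), cohorts = cohorts,
                   stages = list())

  resid <- list(); hier <- list(); nets <- list(); universes <- list()
  prognosis <- list(); categories <- list(); cyto_enr <- list()
  hubs <- list()
  for (co in cohorts) {
    message("== cohort ", co, " ==")
    expr_all <- read_expression(file.path(input_dir, paste0("expression_", co, ".tsv")))
    samples <- read_table_tsv(file.path(input_dir, paste0("samples_", co, ".tsv")))
    if (!all(samples$sample == colnames(expr_all)))
      stop("sample table does not match expression columns for ", co)
    surv <- read_table_tsv(file.path(input_dir, paste0("survival_", co, ".tsv")))
    tumor <- samples$sample[samples$group == "tumor"]
    covars <- samples[, c("age", "sex", "race"), drop = FALSE]
    rownames(covars) <- samples$sample

    ## -- preprocess ------------------------------------------------------
    kept <- filter_genes(expr_all[, tumor, drop = FALSE])
    message(sprintf("preprocess: %d/%d genes kept", nrow(kept), nrow(expr_all)))
    adj <- adjust_covariates(kept, covars[tumor, , drop = FALSE])
    resid[[co]] <- adj
    universes[[co]] <- rownames(adj)

    ## -- network ---------------------------------------------------------
    co_seed <- config$seed + match(co, cohorts)
    thr <- permutation_fdr_threshold(adj, n_perm = config$n_perm,
                                     alpha = config$corr_alpha,
                                     seed = co_seed)
    message(sprintf("network: cutoff %.2f, %d significant pairs",
                    thr$cutoff, nrow(thr$pairs)))
    net <- build_pfn(thr$pairs)
    nets[[co]] <- net
    h <- multiscale_cluster(net, min_size = config$min_module,
                            max_size = config$max_module,
                            n_null = config$n_null, seed = co_seed)
    hier[[co]] <- h
    write_table_tsv(data.frame(igraph::as_data_frame(net, "edges")),
                    file.path(out_dir, paste0("edges_", co, ".tsv")))
    mod_tab <- h$modules
    mod_tab$genes <- vapply(h$genes[mod_tab$id], paste, character(1),
                            collapse = ",")
    write_table_tsv(mod_tab, file.path(out_dir, paste0("modules_", co, ".tsv")))
    hb <- detect_hubs(net, seed = co_seed)
    hubs[[co]] <- hb
    write_table_tsv(hb, file.path(out_dir, paste0("hubs_", co, ".tsv")))

    ## -- prognosis -------------------------------------------------------
    surv <- surv[surv$sample %in% tumor, , drop = FALSE]
    elig <- eligible_modules(h, sb)
    prog <- lapply(elig, function(mid) {
      eg <- compute_eigengene(h$genes[[mid]], adj)
      groups <- median_stratify(eg$score)
      res <- cox_fit(groups, surv, alpha = config$cox_alpha)
      cbind(module = mid, res, var_explained = eg$var_explained,
            stringsAsFactors = FALSE)
    })
    prog <- do.call(rbind, prog)
    if (!is.null(prog)) {
      prog$endpoint <- if (length(config$endpoint) > 1)
        config$endpoint[[co]] else config$endpoint
      write_table_tsv(prog, file.path(out_dir, paste0("prognosis_", co, ".tsv")))
    }
    prognosis[[co]] <- prog
    if (!is.null(prog))
      message(sprintf("prognosis: %d/%d modules significant",
                      sum(prog$p < config$cox_alpha), nrow(prog)))

    ## -- cytoband enrichment --------------------------------------------
    ce <- cytoband_enrichment(h, genes_ann, universe = universes[[co]],
                              size_bounds = sb,
                              min_overlap = config$min_overlap,
                              alpha = config$enrich_alpha)
    cyto_enr[[co]] <- ce
    write_table_tsv(ce, file.path(out_dir, paste0("cytoband_enrichment_", co, ".tsv")))

    ## -- epigenomics -----------------------------------------------------
    beta_path <- file.path(input_dir, paste0("beta_", co, ".tsv"))
    if (file.exists(beta_path) && length(tumor) < nrow(samples)) {
      grp <- factor(samples$group, levels = c("normal", "tumor"))
      deg <- call_degs(
        moderated_t_test(expr_all[universes[[co]], , drop = FALSE], grp,
                         covars),
        fc_threshold = config$fc_threshold, alpha = config$enrich_alpha)
      beta <- read_expression(beta_path)
      probes <- read_table_tsv(file.path(input_dir, paste0("probes_", co, ".tsv")))
      dmc <- call_dmcs(moderated_t_test(beta, grp, covars), probes,
                       delta_threshold = config$delta_threshold,
                       alpha = config$enrich_alpha,
                       maf_cut = config$maf_cut)
      pmap <- map_promoter_probes(probes, genes_ann,
                                  up = config$promoter_up,
                                  down = config$promoter_down)
      cat_tab <- categorize_modules(h, deg, dmc, pmap, universes[[co]],
                                    size_bounds = sb,
                                    min_overlap = config$min_overlap,
                                    alpha = config$enrich_alpha)
      categories[[co]] <- cat_tab
      write_table_tsv(deg, file.path(out_dir, paste0("deg_", co, ".tsv")))
      write_table_tsv(dmc, file.path(out_dir, paste0("dmc_", co, ".tsv")))
      write_table_tsv(cat_tab,
                      file.path(out_dir, paste0("module_categories_", co, ".tsv")))
      message(sprintf("epigenomics: %d DEGs, %d DMCs",
                      sum(deg$direction != "ns"), sum(dmc$direction != "ns")))
    }
  }

  ## -- chromatin ---------------------------------------------------------
  peaks <- read_bed_counts(file.path(input_dir, "peaks.bed"),
                           file.path(input_dir, "peak_counts.tsv"))
  sig <- cytoband_peak_signal(peaks, bands)
  fc <- fold_change_vs_background(sig)
  enr_bands <- unique(unlist(lapply(cyto_enr, function(ce)
    ce$set[ce$significant])))
  chromatin <- NULL
  if (length(enr_bands) >= 2 && nrow(fc) - length(enr_bands) >= 2) {
    chromatin <- compare_enriched_vs_depleted(fc, enr_bands)
    message(sprintf("chromatin: enriched vs depleted Wilcoxon p = %.3g",
                    chromatin$p))
  }
  fc$module_enriched <- fc$band %in% enr_bands
  write_table_tsv(fc, file.path(out_dir, "band_fold_change.tsv"))

  ## -- preservation ------------------------------------------------------
  pairs <- pairwise_similarity(hier, universes, size_bounds = sb,
                               jaccard_cut = config$jaccard_conserved,
                               alpha = config$preserve_alpha)
  classes <- classify_modules(pairs,
                              jaccard_conserved = config$jaccard_conserved,
                              jaccard_specific = config$jaccard_specific,
                              alpha = config$preserve_alpha)
  clusters <- greedy_module_clusters(pairs)
  write_table_tsv(pairs, file.path(out_dir, "preservation_pairs.tsv"))
  write_table_tsv(classes, file.path(out_dir, "module_classes.tsv"))
  write_table_tsv(clusters, file.path(out_dir, "module_clusters.tsv"))
  jsonlite::write_json(split(paste(clusters$cohort, clusters$module),
                             clusters$cluster),
                       file.path(out_dir, "module_clusters.json"))
  cohort_cl <- if (length(cohorts) >= 2) cluster_cohorts(pairs, clusters)
    else NULL
  message(sprintf("preservation: %d pairs, %d conserved, %d clusters",
                  nrow(pairs), sum(pairs$conserved),
                  length(unique(clusters$cluster))))

  ## -- aggregation -------------------------------------------------------
  targets <- lapply(cohorts, function(co) {
    pr <- prognosis[[co]]
    if (is.null(pr)) return(character(0))
    sel <- pr$module[pr$p < config$cox_alpha]
    unique(unlist(hier[[co]]$genes[sel], use.names = FALSE))
  })
  names(targets) <- cohorts
  agg <- NULL
  if (any(vapply(targets, length, integer(1)) > 0)) {
    agg <- aggregate_network(targets, nets,
                             min_weight = min(config$agg_min_weight,
                                              length(cohorts)))
    write_table_tsv(agg$edges, file.path(out_dir, "aggregated_edges.tsv"))
    write_table_tsv(agg$nodes, file.path(out_dir, "aggregated_nodes.tsv"))
  }

  manifest$stages <- list(
    preprocess = lapply(resid, function(x) nrow(x)),
    network = lapply(nets, igraph::ecount),
    modules = lapply(hier, function(h) nrow(h$modules)),
    hubs = lapply(hubs, function(h) sum(h$is_hub)),
    prognostic = lapply(prognosis, function(p)
      if (is.null(p)) 0 else sum(p$p < config$cox_alpha)),
    conserved = sum(pairs$conserved),
    clusters = length(unique(clusters$cluster)),
    chromatin_p = if (is.null(chromatin)) NA else chromatin$p)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(residuals = resid, networks = nets, hierarchies = hier,
                 hubs = hubs, prognosis = prognosis,
                 cytoband_enrichment = cyto_enr, categories = categories,
                 band_fold_change = fc, chromatin = chromatin,
                 pairs = pairs, classes = classes, clusters = clusters,
                 cohort_clustering = cohort_cl, aggregated = agg,
                 universes = universes))
}
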