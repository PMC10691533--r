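test_that("moderated t reduces to ordinary t when variances are equal", {
  # features engineered to share the same residual variance
  set.seed(2)
  base <- rnorm(12)
  vals <- rbind(f1 = base, f2 = base * -1 + 5, f3 = base + 2)
  colnames(vals) <- paste0("s", 1:12)
  groups <- factor(rep(c("normal", "tumor"), each = 6),
                   levels = c("normal", "tumor"))
  res <- moderated_t_test(vals, groups)
  expect_equal(max(res$s2) / min(res$s2), 1, tolerance = 1e-10)
  # with equal s2 the posterior variance equals s2 -> t is the OLS t
  fit <- lm(vals[1, ] ~ groups)
  t_ols <- summary(fit)$coefficients[2, "t value"]
  expect_equal(res$t[1], t_ols, tolerance = 1e-8)
})

test_that("moderated t equals the shrinkage formula given the estimated prior", {
  set.seed(23)
  vals <- matrix(rnorm(50 * 10, sd = rep(runif(50, 0.5, 2), 10)), 50, 10)
  rownames(vals) <- paste0("f", 1:50)
  colnames(vals) <- paste0("s", 1:10)
  groups <- factor(rep(c("normal", "tumor"), each = 5),
                   levels = c("normal", "tumor"))
  res <- moderated_t_test(vals, groups)
  d0 <- attr(res, "d0")
  s0 <- attr(res, "s0_sq")
  dg <- attr(res, "df_resid")
  s2_post <- (d0 * s0 + dg * res$s2) / (d0 + dg)
  expect_equal(unname(attr(res, "s2_post")), unname(s2_post),
               tolerance = 1e-9)
  t_manual <- res$effect / (attr(res, "stdev_unscaled") * sqrt(s2_post))
  expect_equal(res$t, unname(t_manual), tolerance = 1e-9)
  # shrinkage bounds: posterior variance lies between s2 and the prior
  expect_true(all(s2_post >= pmin(res$s2, s0) - 1e-12))
  expect_true(all(s2_post <= pmax(res$s2, s0) + 1e-12))
  # p-values from the t distribution with d0 + dg df
  expect_equal(res$p, 2 * pt(-abs(res$t), d0 + dg), tolerance = 1e-9)
})

test_that("moderated t holds its type-I error on null data", {
  set.seed(77)
  vals <- matrix(rnorm(1000 * 20), 1000, 20,
                 dimnames = list(paste0("f", 1:1000), paste0("s", 1:20)))
  groups <- factor(rep(c("normal", "tumor"), each = 10),
                   levels = c("normal", "tumor"))
  res <- moderated_t_test(vals, groups)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("moderated t validates its inputs", {
  vals <- matrix(rnorm(20), 4, 5)
  rownames(vals) <- paste0("f", 1:4)
  expect_error(moderated_t_test(vals, c("a", "a", "a", "a", "b")),
               "at least 2")
  expect_error(moderated_t_test(vals, c("a", "a", "b", "b", "c")),
               "two levels")
})

test_that("DEG calling applies the fold-change and adjusted-p rules", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    effect = c(1.2, 0.8, -1.5, 2.0),
                    adj_p = c(0.01, 0.001, 0.04, 0.2))
  out <- call_degs(res)
  expect_equal(out$direction, c("up", "ns", "down", "ns"))
})

test_that("promoter windows are strand-aware and boundary-exact", {
  genes <- data.frame(gene = c("gp", "gm"), chrom = "chr1",
                      tss = c(10000, 10000), strand = c("+", "-"))
  probes <- data.frame(probe = paste0("p", 1:6), chrom = "chr1",
                       pos = c(9500, 7999, 8000, 11500, 12000, 12001))
  map <- map_promoter_probes(probes, genes)
  plus <- map$probe[map$gene == "gp"]
  minus <- map$probe[map$gene == "gm"]
  expect_true(all(c("p1", "p3") %in% plus))   # 9500, 8000 in [8000, 10200]
  expect_false("p2" %in% plus)                # 7999 just outside
  expect_true(all(c("p4", "p5") %in% minus))  # in [9800, 12000]
  expect_false("p6" %in% minus)               # 12001 just outside
  # window length is up + down + 1 positions on either strand
  expect_equal(10200 - 8000 + 1, 2000 + 200 + 1)
  expect_equal(12000 - 9800 + 1, 2000 + 200 + 1)
  genes$strand <- c("+", "*")
  expect_warning(map_promoter_probes(probes, genes), "unknown strand")
})

test_that("DMC calling masks SNP probes before testing", {
  res <- data.frame(feature = c("p1", "p2", "p3", "p4"),
                    effect = c(0.25, 0.15, -0.30, 0.40),
                    p = c(0.001, 0.0001, 0.002, 0.003),
                    adj_p = NA)
  annot <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                      maf = c(NA, NA, 0.01, 0.10))
  out <- call_dmcs(res, annot)
  expect_false("p4" %in% out$feature)           # MAF 0.10 excluded
  expect_equal(out$direction[out$feature == "p1"], "up")
  expect_equal(out$direction[out$feature == "p2"], "ns")  # delta too small
  expect_equal(out$direction[out$feature == "p3"], "down")
})

test_that("methylation-coupled modules get the inverse DEG-DMC label", {
  cfg <- simulation_config(
    n_cohorts = 1, genes_per_cohort = 300, samples_per_cohort = 80,
    n_normal = 40,
    modules = data.frame(id = c("A", "B", "C"), size = 40, target_r = 0.7,
                         cohorts = "1", children = 1,
                         cytoband = NA_character_,
                         log_hr = 0, meth_coupling = c(-1, 1, 0)),
    seed = 5)
  ann <- generate_annotation(cfg)
  mc <- generate_multi_cohort(cfg)
  ch <- mc$cohorts[[1]]
  me <- generate_methylation(ch$expr_all, mc$truth, cfg, ann)
  deg <- call_degs(moderated_t_test(ch$expr_all, ch$groups, ch$covariates))
  dmc <- call_dmcs(moderated_t_test(me$beta, ch$groups, ch$covariates),
                   me$probes)
  pmap <- map_promoter_probes(me$probes, ann$genes)
  hier <- structure(list(
    modules = data.frame(id = c("M1", "M2", "M3", "M4"),
                         parent = c(NA, "M1", "M1", "M1"),
                         depth = c(0, 1, 1, 1),
                         size = c(300, 40, 40, 40), split_Q = NA_real_),
    genes = list(M1 = rownames(ch$expr),
                 M2 = mc$truth$module_genes$A,
                 M3 = mc$truth$module_genes$B,
                 M4 = mc$truth$module_genes$C)),
    class = "module_hierarchy")
  cats <- categorize_modules(hier, deg, dmc, pmap, rownames(ch$expr))
  expect_equal(cats$label[cats$module == "M2"], "dDEG-uDMC")
  expect_equal(cats$label[cats$module == "M3"], "uDEG-dDMC")
  expect_equal(cats$label[cats$module == "M4"], "none")
})
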