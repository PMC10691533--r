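small_config <- function(...) {
  simulation_config(
    n_cohorts = 1, genes_per_cohort = 200, samples_per_cohort = 100,
    n_normal = 0,
    modules = data.frame(id = "A", size = 50, target_r = 0.6,
                         cohorts = "1", children = 1,
                         cytoband = NA_character_, log_hr = 0,
                         meth_coupling = 0),
    seed = 3, ...)
}

test_that("generators are bitwise deterministic under a seed", {
  cfg <- small_config()
  a <- generate_multi_cohort(cfg)
  b <- generate_multi_cohort(cfg)
  expect_identical(a$cohorts[[1]]$expr, b$cohorts[[1]]$expr)
  f1 <- make_default_fixture(seed = 4)
  f2 <- make_default_fixture(seed = 4)
  expect_identical(f1$cohorts[[2]]$expr, f2$cohorts[[2]]$expr)
  expect_identical(f1$cohorts[[1]]$survival, f2$cohorts[[1]]$survival)
  expect_identical(f1$cohorts[[3]]$beta, f2$cohorts[[3]]$beta)
  expect_identical(f1$annotation$peaks$counts, f2$annotation$peaks$counts)
})

test_that("realized within-module correlation is near the target", {
  cfg <- small_config()
  mc <- generate_multi_cohort(cfg)
  expr <- mc$cohorts[[1]]$expr
  mg <- mc$truth$module_genes$A
  cc <- cor(t(expr[mg, ]))
  mean_r <- mean(abs(cc[upper.tri(cc)]))
  expect_gte(mean_r, 0.5)
  expect_lte(mean_r, 0.7)
})

test_that("a null configuration shows almost no strong correlations", {
  cfg <- simulation_config(n_cohorts = 1, genes_per_cohort = 300,
                           samples_per_cohort = 100, n_normal = 0,
                           modules = NULL, covariate_effects =
                             c(age = 0, sex = 0, race = 0), seed = 8)
  mc <- generate_multi_cohort(cfg)
  cc <- cor(t(mc$cohorts[[1]]$expr))
  frac <- mean(abs(cc[upper.tri(cc)]) > 0.5)
  expect_lt(frac, 0.01)
})

test_that("child-module layouts nest correlations", {
  cfg <- simulation_config(
    n_cohorts = 1, genes_per_cohort = 120, samples_per_cohort = 150,
    n_normal = 0,
    modules = data.frame(id = "A", size = 60, target_r = 0.7,
                         cohorts = "1", children = 2,
                         cytoband = NA_character_, log_hr = 0,
                         meth_coupling = 0),
    seed = 9)
  mc <- generate_multi_cohort(cfg)
  expr <- mc$cohorts[[1]]$expr
  mg <- mc$truth$module_genes$A
  child <- rep(1:2, length.out = length(mg))  # generator's layout rule
  cc <- cor(t(expr[mg, ]))
  within <- mean(cc[child == 1, child == 1][upper.tri(diag(30))])
  cross <- mean(cc[child == 1, child == 2])
  expect_gt(within, cross + 0.15)  # within-child tighter than cross-child
  expect_gt(cross, 0.15)           # children still cohere via the parent
})

test_that("module layout constraints are validated", {
  expect_error(simulation_config(modules = data.frame(
    id = "A", size = 5, target_r = 0.5, cohorts = "1", children = 1,
    cytoband = NA, log_hr = 0, meth_coupling = 0)), "\\[10, 500\\]")
  expect_error(simulation_config(genes_per_cohort = 100,
                                 modules = data.frame(
    id = c("A", "B"), size = 60, target_r = 0.5, cohorts = "1",
    children = 1, cytoband = NA, log_hr = 0, meth_coupling = 0)),
    "exceed")
  expect_error(simulation_config(censoring_fraction = 1), "censoring")
})

test_that("survival generation respects censoring and recovers hazards", {
  cfg <- simulation_config(seed = 6)
  scores <- matrix(rnorm(500 * 2), 500, 2,
                   dimnames = list(sprintf("s%03d", 1:500),
                                   c("P01", "P02")))
  surv <- generate_survival(scores, cfg)
  expect_true(all(surv$time > 0))
  expect_gte(mean(surv$event == 0), 0.25)  # near the 0.3 target
  expect_lte(mean(surv$event == 0), 0.35)
  # continuous Cox on the generating score recovers HR = 2 per SD when
  # the module is the only planted hazard (a univariate fit of one of
  # two planted hazards estimates the attenuated marginal HR instead)
  surv1 <- generate_survival(scores[, "P01", drop = FALSE], cfg)
  fit <- cox_fit(setNames(scores[, "P01"], rownames(scores)), surv1)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.3)
  # no censoring configuration
  cfg0 <- simulation_config(censoring_fraction = 0, seed = 6)
  surv0 <- generate_survival(scores, cfg0)
  expect_true(all(surv0$event == 1))
  # null hazards give HR near 1
  cfgn <- simulation_config(
    modules = transform(default_module_spec(), log_hr = 0), seed = 6)
  survn <- generate_survival(scores, cfgn)
  fitn <- cox_fit(setNames(scores[, "P01"], rownames(scores)), survn)
  expect_gt(fitn$hr, 0.8)
  expect_lt(fitn$hr, 1.25)
  expect_error(generate_survival(scores[0, , drop = FALSE], cfg),
               "empty")
})

test_that("methylation is anti-correlated with expression for coupled genes", {
  fx <- default_fixture_cached()
  ch <- fx$cohorts[[1]]
  coupled <- fx$truth$module_genes$P03
  uncoupled <- fx$truth$module_genes$P05
  cors <- vapply(coupled, function(g)
    cor(ch$beta[paste0("cg_", g), ], ch$expr_all[g, ]), numeric(1))
  expect_lte(mean(cors), -0.3)
  cors0 <- vapply(uncoupled, function(g)
    cor(ch$beta[paste0("cg_", g), ], ch$expr_all[g, ]), numeric(1))
  expect_lt(max(abs(cors0)), 0.35)
  expect_gt(mean(abs(cors0) < 0.2), 0.8)  # typically near zero
  expect_true(all(ch$beta >= 0 & ch$beta <= 1))
})

test_that("probes sit inside their gene's promoter window", {
  fx <- default_fixture_cached()
  ch <- fx$cohorts[[1]]
  map <- map_promoter_probes(ch$probes, fx$annotation$genes)
  own <- map[map$gene == sub("^cg_", "", map$probe), ]
  expect_equal(sort(unique(own$probe)), sort(ch$probes$probe))
})

test_that("annotation places module genes in their band and boosts open bands", {
  fx <- default_fixture_cached()
  ann <- fx$annotation
  expect_gte(nrow(ann$bands), 20)
  for (i in which(!is.na(fx$config$modules$cytoband))) {
    band <- fx$config$modules$cytoband[i]
    mg <- fx$truth$module_genes[[fx$config$modules$id[i]]]
    placed <- ann$genes[match(mg, ann$genes$gene), ]
    expect_true(all(placed$cytoband == band))
    expect_gte(sum(ann$genes$cytoband == band, na.rm = TRUE),
               length(mg))
  }
  sig <- cytoband_peak_signal(ann$peaks, ann$bands)
  fc <- fold_change_vs_background(sig)
  open_fc <- fc$fold_change[fc$band %in% ann$open_bands]
  other_fc <- fc$fold_change[!fc$band %in% ann$open_bands]
  expect_gt(min(open_fc) / mean(other_fc), 1.5)
})
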