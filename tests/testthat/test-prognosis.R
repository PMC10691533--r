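test_that("eigengene of a rank-1 module is the shared profile", {
  base <- rnorm(30)
  m <- rbind(g1 = base, g2 = base, g3 = base)
  colnames(m) <- paste0("s", 1:30)
  eg <- compute_eigengene(c("g1", "g2", "g3"), m)
  expect_equal(eg$var_explained, 1, tolerance = 1e-10)
  expect_equal(abs(cor(eg$score, base)), 1, tolerance = 1e-10)
  expect_gte(cor(eg$score, base), 0)  # orientation convention
  expect_equal(mean(eg$score), 0, tolerance = 1e-12)
})

test_that("two-gene eigengene matches the closed-form 2x2 eigenvector", {
  set.seed(13)
  n <- 200
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  m <- rbind(g1 = z1, g2 = z2)
  colnames(m) <- paste0("s", 1:n)
  eg <- compute_eigengene(c("g1", "g2"), m)
  # for a standardized 2x2 correlation matrix PC1 is (1,1)/sqrt(2)
  manual <- (scale(z1)[, 1] + scale(z2)[, 1]) / sqrt(2)
  expect_equal(abs(cor(eg$score, manual)), 1, tolerance = 1e-10)
  r <- cor(z1, z2)
  expect_equal(eg$var_explained, (1 + r) / 2, tolerance = 1e-10)
})

test_that("eigengene orientation follows mean module expression", {
  set.seed(99)
  for (i in 1:5) {
    m <- block_matrix(c(15), n_samples = 60, r = 0.6, seed = i)
    eg <- compute_eigengene(rownames(m), m)
    expect_gte(cor(eg$score, colMeans(m[rownames(m), ])), 0)
  }
  expect_error(compute_eigengene("g1", matrix(0, 2, 3,
    dimnames = list(c("g1", "g2"), NULL))), "at least 2")
})

test_that("median stratification uses the stated tie rule", {
  expect_equal(as.character(median_stratify(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_stratify(c(1, 2, 3))),
               c("low", "low", "high"))  # the median itself goes low
  expect_error(median_stratify(rep(2, 5)), "degenerate")
  expect_error(median_stratify(1), "length")
})

test_that("Cox beta matches the grid-search partial-likelihood oracle", {
  # alternating groups: interior maximum of the partial likelihood
  surv <- data.frame(sample = paste0("s", 1:6), time = 1:6,
                     event = rep(1, 6))
  x6 <- c(1, 0, 1, 0, 1, 0)
  groups <- setNames(ifelse(x6 == 1, "high", "low"), surv$sample)
  fit <- cox_fit(groups, surv)
  beta_oracle <- oracle_cox_beta(x6, surv$time, surv$event)
  expect_lt(abs(fit$beta - beta_oracle), 1e-4)

  # tied event times exercise the Efron correction
  set.seed(17)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    time <- sample(1:5, n, TRUE)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    surv <- data.frame(sample = paste0("s", 1:n), time = time,
                       event = event)
    groups <- setNames(ifelse(x == 1, "high", "low"), surv$sample)
    fit <- suppressWarnings(cox_fit(groups, surv))
    if (fit$separation || abs(fit$beta) > 3.9) next
    expect_lt(abs(fit$beta - oracle_cox_beta(x, time, event)), 1e-4)
  }
})

test_that("identical survival in both groups gives HR near 1", {
  times <- c(2, 4, 6, 8, 10)
  surv <- data.frame(sample = paste0("s", 1:10), time = rep(times, 2),
                     event = 1)
  groups <- setNames(rep(c("high", "low"), each = 5), surv$sample)
  fit <- cox_fit(groups, surv)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_gt(fit$p, 0.9)
})

test_that("exponential data with true group HR 2 is recovered at n = 500", {
  set.seed(2)
  n <- 500
  x <- rep(c(1, 0), each = n / 2)
  time <- rexp(n, 0.002 * exp(log(2) * x))
  surv <- data.frame(sample = paste0("s", 1:n), time = time, event = 1)
  groups <- setNames(ifelse(x == 1, "high", "low"), surv$sample)
  fit <- cox_fit(groups, surv)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.3)
  expect_true(fit$prognostic)
})

test_that("Cox input validation catches degenerate designs", {
  surv <- data.frame(sample = paste0("s", 1:4), time = 1:4, event = 0)
  groups <- setNames(rep(c("high", "low"), 2), surv$sample)
  expect_error(cox_fit(groups, surv), "no events")
  surv$event <- 1
  expect_error(cox_fit(setNames(rep("high", 4), surv$sample), surv),
               "non-empty")
  surv$time[1] <- -1
  expect_error(cox_fit(groups, surv), "positive")
})

test_that("Kaplan-Meier curves match the product-limit hand computation", {
  surv <- data.frame(sample = paste0("s", 1:3), time = c(1, 2, 3),
                     event = c(1, 0, 1))
  km <- kaplan_meier(setNames(rep("all", 3), surv$sample), surv)
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)
  o <- oracle_km(surv$time, surv$event)
  got <- km[km$time %in% o$time & km$n_event > 0, ]
  expect_equal(got$surv, o$surv, tolerance = 1e-12)
  # curves are nonincreasing within groups and bounded in [0, 1]
  set.seed(31)
  surv2 <- data.frame(sample = paste0("s", 1:40),
                      time = rexp(40, 0.1) + 0.01,
                      event = rbinom(40, 1, 0.7))
  g2 <- setNames(rep(c("high", "low"), 20), surv2$sample)
  km2 <- kaplan_meier(g2, surv2)
  for (grp in c("high", "low")) {
    s <- km2$surv[km2$group == grp]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # all-censored group stays at 1
  surv3 <- data.frame(sample = paste0("s", 1:5), time = 1:5, event = 0)
  km3 <- kaplan_meier(setNames(rep("all", 5), surv3$sample), surv3)
  expect_true(all(km3$surv == 1))
})

test_that("prognostic flagging keeps p < alpha and annotates direction", {
  res <- data.frame(module = c("a", "b", "c"),
                    hr = c(1.4, 0.7, 1.1),
                    p = c(0.04, 0.001, 0.06))
  out <- flag_prognostic(res)
  expect_setequal(out$module, c("a", "b"))
  expect_equal(out$direction[out$module == "a"], "poor")
  expect_equal(out$direction[out$module == "b"], "good")
})
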