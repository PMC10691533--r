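mini_hierarchy <- function(sets, n_total = 200, prefix = "g") {
  genes <- sprintf("%s%03d", prefix, seq_len(n_total))
  mods <- data.frame(id = c("M1", names(sets)),
                     parent = c(NA, rep("M1", length(sets))),
                     depth = c(0, rep(1, length(sets))),
                     size = c(n_total, lengths(sets)),
                     split_Q = NA_real_)
  structure(list(modules = mods, genes = c(list(M1 = genes), sets)),
            class = "module_hierarchy")
}

test_that("Jaccard index follows the set formula", {
  u <- sprintf("g%03d", 1:200)
  h1 <- mini_hierarchy(list(A = u[1:20]))
  h2 <- mini_hierarchy(list(B = u[1:20], C = u[101:120],
                            D = c(u[11:20], u[121:130])))
  pairs <- pairwise_similarity(list(c1 = h1, c2 = h2),
                               list(c1 = u, c2 = u))
  j <- function(mb) pairs$jaccard[pairs$module_a == "A" &
                                    pairs$module_b == mb]
  expect_equal(j("B"), 1)        # identical sets
  expect_equal(j("C"), 0)        # disjoint
  expect_equal(j("D"), 10 / 30)  # 10 shared of 30 in the union
  # {A,B,C} vs {B,C,D} worked example
  h3 <- mini_hierarchy(list(X = c("x1", "x2", "x3")), prefix = "x")
  h4 <- mini_hierarchy(list(Y = c("x2", "x3", "x4")), prefix = "x")
  p2 <- pairwise_similarity(list(a = h3, b = h4),
                            list(a = sprintf("x%03d", 1:200),
                                 b = sprintf("x%03d", 1:200)),
                            size_bounds = c(1, 500))
  expect_equal(p2$jaccard[p2$module_a == "X" & p2$module_b == "Y"], 0.5)
})

test_that("conserved / specific / intermediate rules apply the thresholds", {
  pairs <- data.frame(
    cohort_a = "c1", module_a = c("A", "B", "C"),
    cohort_b = "c2", module_b = c("X", "Y", "Z"),
    jaccard = c(0.45, 0.03, 0.20), overlap = c(9, 1, 5),
    p = c(1e-6, 0.5, 1e-4), afetp = c(1e-5, 0.6, 1e-3))
  pairs$conserved <- pairs$jaccard > 0.4 & pairs$afetp < 0.05
  cls <- classify_modules(pairs)
  get <- function(co, m) cls$class[cls$cohort == co & cls$module == m]
  expect_equal(get("c1", "A"), "conserved")
  expect_equal(get("c2", "X"), "conserved")
  expect_equal(get("c1", "B"), "specific")      # best match J = 0.03
  expect_equal(get("c1", "C"), "intermediate")  # passes neither rule
})

test_that("FET uses the shared universe of the cohort pair", {
  u1 <- sprintf("g%03d", 1:150)
  u2 <- sprintf("g%03d", 51:200)   # shared universe is g051..g150
  shared <- intersect(u1, u2)
  A <- sprintf("g%03d", 41:60)     # 10 genes inside the shared universe
  B <- sprintf("g%03d", 51:70)
  h1 <- mini_hierarchy(list(A = A))
  h2 <- mini_hierarchy(list(B = B))
  pairs <- pairwise_similarity(list(c1 = h1, c2 = h2),
                               list(c1 = u1, c2 = u2))
  pairs <- pairs[pairs$module_a == "A" & pairs$module_b == "B", ]
  k <- length(intersect(intersect(A, shared), intersect(B, shared)))
  expect_equal(pairs$overlap, k)
  expect_equal(pairs$p,
               oracle_hyper_tail(k, length(intersect(B, shared)),
                                 length(shared),
                                 length(intersect(A, shared))),
               tolerance = 1e-12)
})

test_that("greedy clusters equal union-find components on random graphs", {
  set.seed(25)
  for (rep in 1:20) {
    n_mod <- 100
    mods <- sprintf("m%03d", seq_len(n_mod))
    cohort <- sample(paste0("c", 1:6), n_mod, TRUE)
    n_edge <- sample(30:120, 1)
    a <- sample(n_mod, n_edge, TRUE)
    b <- sample(n_mod, n_edge, TRUE)
    ok <- a != b
    pairs <- data.frame(
      cohort_a = cohort[a[ok]], module_a = mods[a[ok]],
      cohort_b = cohort[b[ok]], module_b = mods[b[ok]],
      jaccard = 0.5, overlap = 10, p = 1e-6, afetp = 1e-5,
      conserved = TRUE)
    cl <- greedy_module_clusters(pairs)
    nodes <- paste(cl$cohort, cl$module)
    comp <- oracle_union_find(
      nodes,
      paste(pairs$cohort_a, pairs$module_a),
      paste(pairs$cohort_b, pairs$module_b))
    # same partition: cluster labels must be a bijection of components
    key <- paste(cl$cluster, comp[nodes])
    expect_equal(length(unique(cl$cluster)),
                 length(unique(comp[nodes])))
    expect_equal(length(unique(key)), length(unique(cl$cluster)))
  }
})

test_that("transitive conserved pairs form one cluster, disjoint pairs two", {
  pairs <- data.frame(
    cohort_a = c("c1", "c2", "c1"), module_a = c("A", "B", "D"),
    cohort_b = c("c2", "c3", "c3"), module_b = c("B", "C", "E"),
    jaccard = 0.6, overlap = 12, p = 1e-8, afetp = 1e-7,
    conserved = TRUE)
  cl <- greedy_module_clusters(pairs)
  abc <- cl$cluster[cl$module %in% c("A", "B", "C")]
  de <- cl$cluster[cl$module %in% c("D", "E")]
  expect_equal(length(unique(abc)), 1)
  expect_equal(length(unique(de)), 1)
  expect_false(unique(abc) == unique(de))
  expect_equal(nrow(greedy_module_clusters(pairs[0, ])), 0)
})

test_that("cohort clustering merges cohorts with identical module sets first", {
  u <- sprintf("g%03d", 1:300)
  sets <- list(A = u[1:20], B = u[31:50], C = u[61:80])
  h1 <- mini_hierarchy(sets, 300)
  h2 <- mini_hierarchy(sets, 300)                      # identical to h1
  h3 <- mini_hierarchy(list(A = c(u[1:12], u[101:108]),
                            Z = u[201:220]), 300)      # partly similar
  pairs <- pairwise_similarity(list(x = h1, y = h2, z = h3),
                               list(x = u, y = u, z = u))
  clusters <- greedy_module_clusters(pairs)
  cc <- cluster_cohorts(pairs, clusters)
  expect_equal(cc$distance["x", "y"], 0, tolerance = 1e-12)
  expect_true(isSymmetric(cc$distance))
  expect_true(all(diag(cc$distance) == 0))
  merge1 <- cc$hclust$merge[1, ]
  expect_setequal(cc$hclust$labels[-merge1], c("x", "y"))
})

test_that("aggregated network counts cohort support and filters weak nodes", {
  gsets <- list(c1 = c("a", "b", "c"), c2 = c("a", "b"),
                c3 = c("a", "b", "d"), c4 = c("a", "x"),
                c5 = c("a", "b"))
  mknet <- function(edges, vertices) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vertices)
    igraph::E(g)$weight <- 0.8
    g
  }
  nets <- list(
    c1 = mknet(data.frame(from = c("a", "b"), to = c("b", "c")),
               c("a", "b", "c")),
    c2 = mknet(data.frame(from = "a", to = "b"), c("a", "b")),
    c3 = mknet(data.frame(from = c("a", "a"), to = c("b", "d")),
               c("a", "b", "d")),
    c4 = mknet(data.frame(from = "a", to = "x"), c("a", "x")),
    c5 = mknet(data.frame(from = "a", to = "b"), c("a", "b")))
  agg <- aggregate_network(gsets, nets, min_weight = 4)
  expect_setequal(agg$nodes$gene, c("a", "b"))
  expect_equal(agg$nodes$weight[agg$nodes$gene == "a"], 5)
  expect_equal(agg$nodes$weight[agg$nodes$gene == "b"], 4)
  ab <- agg$edges[agg$edges$gene_a == "a" & agg$edges$gene_b == "b", ]
  expect_equal(ab$weight, 4)      # a-b linked in c1, c2, c3, c5
  expect_false("c" %in% agg$nodes$gene)  # weight 1 < 4 removed
  expect_error(aggregate_network(list(c1 = character(0)), nets), "empty")
})
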