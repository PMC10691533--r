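# Shared fixture builders.  The heavy default-fixture pipeline run is
# computed once per session and reused by the acceptance tests.

# Gene x sample matrix with planted equicorrelated factor blocks.
block_matrix <- function(block_sizes, n_noise = 0, n_samples = 100,
                         r = 0.8, seed = 42) {
  set.seed(seed)
  n <- sum(block_sizes) + n_noise
  X <- matrix(rnorm(n * n_samples), n, n_samples)
  lab <- rep(c(seq_along(block_sizes), 0),
             c(block_sizes, n_noise))
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_samples)
    idx <- which(lab == b)
    X[idx, ] <- sqrt(r) * matrix(f, length(idx), n_samples, byrow = TRUE) +
      sqrt(1 - r) * X[idx, ]
  }
  rownames(X) <- sprintf("g%04d", seq_len(n))
  attr(X, "blocks") <- lab
  X
}

# Small weighted complete graph helpers.
complete_graph <- function(n, weights = NULL) {
  p <- t(combn(n, 2))
  g <- igraph::graph_from_edgelist(p, directed = FALSE)
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

two_cliques_bridge <- function(k) {
  # two k-cliques joined by one bridge edge (1 -- k+1)
  p1 <- t(combn(seq_len(k), 2))
  p2 <- t(combn(k + seq_len(k), 2))
  el <- rbind(p1, p2, c(1, k + 1))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Session-level cache for expensive objects.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

default_fixture_cached <- function() {
  cached("fixture", make_default_fixture(seed = 1))
}

# One full pipeline run on the default fixture (written to a temp dir).
pipeline_run_cached <- function() {
  cached("pipeline", {
    fx <- default_fixture_cached()
    dir <- file.path(tempdir(), "panconet_fixture")
    write_fixture(fx, dir)
    out <- file.path(dir, "out")
    res <- suppressMessages(run_pipeline(dir, out))
    list(fixture = fx, input_dir = dir, out_dir = out, res = res)
  })
}

# Leaf-module ARI against planted truth, restricted to planted genes.
leaf_ari <- function(hierarchy, truth, cohort) {
  tc <- truth$assignments[truth$assignments$cohort == cohort, ]
  det <- rep("none", nrow(tc))
  for (l in leaf_modules(hierarchy)) {
    det[tc$gene %in% hierarchy$genes[[l]]] <- l
  }
  mclust::adjustedRandIndex(tc$module, det)
}
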