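# Independent oracles used across the suite.  Each one recomputes a
# quantity by brute force / closed form / enumeration, deliberately
# avoiding the code path it checks.

# Hypergeometric upper-tail p by direct summation of the density.
oracle_hyper_tail <- function(k, set_size, universe, module) {
  i <- k:min(set_size, module)
  sum(choose(set_size, i) * choose(universe - set_size, module - i)) /
    choose(universe, module)
}

# Step-up Benjamini-Hochberg by its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Efron-tie Cox partial log-likelihood for a single covariate, maximized
# on a fine beta grid.
oracle_cox_beta <- function(x, time, event, grid = seq(-4, 4, by = 1e-4)) {
  logpl <- function(beta) {
    ll <- 0
    for (t in unique(time[event == 1])) {
      D <- which(time == t & event == 1)
      R <- which(time >= t)
      d <- length(D)
      sumD <- sum(exp(x[D] * beta))
      sumR <- sum(exp(x[R] * beta))
      ll <- ll + beta * sum(x[D]) -
        sum(log(sumR - (seq_len(d) - 1) / d * sumD))
    }
    ll
  }
  vals <- vapply(grid, logpl, numeric(1))
  grid[which.max(vals)]
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free data).
oracle_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Union-find connected components over an edge list of character nodes.
oracle_union_find <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

# Exhaustive best 2-partition modularity via igraph's Q implementation
# (independent of the package's modularity-matrix search).
oracle_best_bipartition_q <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 14)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else NULL
  best <- -Inf
  for (mask in seq_len(2^(n - 1) - 1)) {
    mem <- as.integer(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0) + 1L
    q <- igraph::modularity(graph, mem, weights = w)
    if (q > best) best <- q
  }
  best
}

# Planarity oracle: networkx check_planarity through the system python,
# batched over a list of igraph objects (one interpreter call).
oracle_nx_planar <- function(graphs) {
  tmp <- tempfile(fileext = ".txt")
  con <- file(tmp, "w")
  for (g in graphs) {
    el <- igraph::as_edgelist(g, names = FALSE)
    writeLines(sprintf("G %d %d", igraph::vcount(g), nrow(el)), con)
    if (nrow(el)) writeLines(paste(el[, 1] - 1L, el[, 2] - 1L), con)
  }
  close(con)
  script <- c(
    "import sys, networkx as nx",
    sprintf("lines = open(%s).read().split(chr(10))", shQuote(tmp)),
    "res, i = [], 0",
    "while i < len(lines):",
    "    if not lines[i].startswith('G'):",
    "        i += 1; continue",
    "    _, n, m = lines[i].split(); n, m = int(n), int(m)",
    "    G = nx.Graph(); G.add_nodes_from(range(n))",
    "    for j in range(m):",
    "        a, b = lines[i + 1 + j].split(); G.add_edge(int(a), int(b))",
    "    res.append('1' if nx.check_planarity(G)[0] else '0')",
    "    i += 1 + m",
    "print(''.join(res))")
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", py, stdout = TRUE)
  unlink(c(tmp, py))
  strsplit(out[length(out)], "")[[1]] == "1"
}

# Kaplan-Meier product-limit estimator computed directly.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in tt) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
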