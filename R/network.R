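#' Choose a correlation cutoff by permutation FDR
#'
#' Computes all pairwise Pearson correlations of the gene rows, then
#' re-computes them on `n_perm` matrices in which every gene row has been
#' independently permuted across samples.  For each candidate cutoff `c` on
#' a fixed grid, the empirical FDR is the mean permuted count of pairs with
#' `|r| >= c` divided by the observed count (0/0 counts as 0, k/0 as Inf).
#' The chosen cutoff is the smallest candidate with FDR at or below `alpha`.
#'
#' @param mat Expression matrix (genes x samples), typically
#'   covariate-adjusted residuals.
#' @param n_perm Number of row-wise permutations (default 10).
#' @param alpha FDR level (default 0.05).
#' @param seed Optional integer seed for the permutations.
#' @param grid Candidate cutoffs in (0, 1); default `seq(0.01, 0.99, 0.01)`.
#' @param min_obs Minimum shared samples for a pair's correlation to be
#'   defined when values are missing (default 10).
#' @return An object of class `corr_threshold`: list with `grid`,
#'   `observed_counts`, `permuted_counts` (mean over permutations), `fdr`,
#'   `cutoff`, `n_perm`, and `pairs` (data.frame `gene_a`, `gene_b`,
#'   `abs_r`, `signed_r`, sorted by decreasing `|r|`, ties broken by
#'   lexicographic gene pair).
#' @export
permutation_fdr_threshold <- function(mat, n_perm = 10, alpha = 0.05,
                                      seed = NULL,
                                      grid = seq(0.01, 0.99, by = 0.01),
                                      min_obs = 10) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 3, n_perm >= 1)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(grid)

  abs_upper <- function(x) {
    has_na <- anyNA(x)
    r <- if (has_na) cor(t(x), use = "pairwise.complete.obs") else cor(t(x))
    if (has_na && min_obs > 0) {
      obs <- (!is.na(x)) + 0
      shared <- tcrossprod(obs)
      r[shared < min_obs] <- NA
    }
    abs(r[upper.tri(r)])
  }
  count_grid <- function(av) {
    av <- av[!is.na(av)]
    f <- findInterval(av, grid)            # grid points at or below value
    tab <- tabulate(f + 1L, nbins = length(grid) + 1L)
    rev(cumsum(rev(tab)))[-1L]             # counts with |r| >= grid[i]
  }

  av_obs <- abs_upper(mat)
  obs_counts <- count_grid(av_obs)
  perm_counts <- matrix(0, n_perm, length(grid))
  for (p in seq_len(n_perm)) {
    perm <- t(apply(mat, 1, sample))
    perm_counts[p, ] <- count_grid(abs_upper(perm))
  }
  mean_perm <- colMeans(perm_counts)
  fdr <- ifelse(obs_counts == 0, ifelse(mean_perm == 0, 0, Inf),
                mean_perm / obs_counts)
  ok <- which(fdr <= alpha)
  if (length(ok) == 0) stop("no significant correlation structure")
  cutoff <- grid[ok[1]]

  r <- if (anyNA(mat)) cor(t(mat), use = "pairwise.complete.obs") else cor(t(mat))
  if (anyNA(mat) && min_obs > 0) {
    obs <- (!is.na(mat)) + 0
    shared <- tcrossprod(obs)
    r[shared < min_obs] <- NA
  }
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) >= cutoff, arr.ind = TRUE)
  genes <- rownames(mat)
  pairs <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      abs_r = abs(r[idx]), signed_r = r[idx],
                      stringsAsFactors = FALSE)
  swap <- pairs$gene_a > pairs$gene_b
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  pairs <- pairs[order(-pairs$abs_r, pairs$gene_a, pairs$gene_b), ]
  rownames(pairs) <- NULL

  structure(list(grid = grid, observed_counts = obs_counts,
                 permuted_counts = mean_perm, fdr = fdr, cutoff = cutoff,
                 n_perm = n_perm, alpha = alpha, pairs = pairs),
            class = "corr_threshold")
}

#' @export
print.corr_threshold <- function(x, ...) {
  cat("Permutation-FDR correlation threshold\n")
  cat(sprintf("  cutoff |r| >= %.2f (FDR <= %.3g, %d permutations)\n",
              x$cutoff, x$alpha, x$n_perm))
  cat(sprintf("  significant pairs: %d\n", nrow(x$pairs)))
  invisible(x)
}

#' Test a graph for planarity
#'
#' Left-right planarity test (de Fraysseix-Rosenstiehl).
#'
#' @param graph An `igraph` object, or a two-column edge matrix/data.frame.
#' @return `TRUE` if the graph is planar.
#' @export
is_planar <- function(graph) {
  if (inherits(graph, "igraph")) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    n <- igraph::vcount(graph)
  } else {
    el <- as.matrix(graph)
    verts <- unique(c(el[, 1], el[, 2]))
    el <- matrix(match(el, verts), ncol = 2)
    n <- length(verts)
  }
  if (nrow(el) == 0) return(TRUE)
  if (any(el[, 1] == el[, 2])) stop("self-loops are not supported")
  .lr_planar_cpp(n, as.integer(el[, 1]) - 1L, as.integer(el[, 2]) - 1L)
}

#' Build a planar maximally filtered graph (PMFG)
#'
#' Inserts candidate edges in decreasing `|r|` order (ties broken by
#' lexicographic gene pair), keeping an edge iff the growing graph stays
#' planar; insertion stops when the planar bound of `3(n - 2)` edges is
#' reached or the list is exhausted.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `abs_r` and
#'   optionally `signed_r` (as produced by [permutation_fdr_threshold()]).
#' @return An undirected `igraph` with edge attributes `weight` (`|r|`) and
#'   `signed_r`.
#' @export
build_pfn <- function(pairs) {
  stopifnot(all(c("gene_a", "gene_b", "abs_r") %in% names(pairs)))
  if (is.null(pairs$signed_r)) pairs$signed_r <- pairs$abs_r
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (any(pairs$gene_a == pairs$gene_b)) stop("self-loops are not allowed")
  swap <- pairs$gene_a > pairs$gene_b
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    pairs <- pairs[!duplicated(key), ]
  }
  pairs <- pairs[order(-pairs$abs_r, pairs$gene_a, pairs$gene_b), ]
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  n <- length(nodes)
  if (n < 3) {
    keep <- rep(TRUE, nrow(pairs))
  } else {
    keep <- .pmfg_cpp(n, match(pairs$gene_a, nodes) - 1L,
                      match(pairs$gene_b, nodes) - 1L)
  }
  kept <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$gene_a, to = kept$gene_b,
               weight = kept$abs_r, signed_r = kept$signed_r),
    directed = FALSE, vertices = nodes)
  g
}

#' Best modularity bipartition of a weighted graph
#'
#' Finds a 2-way partition maximizing Newman's weighted modularity
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) d(c_i, c_j)`.  For graphs
#' with up to `n_exhaustive` vertices all bipartitions are enumerated
#' (exact optimum); larger graphs use leading-eigenvector spectral
#' bisection of the modularity matrix followed by Kernighan-Lin style
#' single-node refinement.
#'
#' @param graph An `igraph`; edge attribute `weight` is used when present.
#' @param n_exhaustive Exhaustive-search size limit (default 16).
#' @return List with `membership` (integer vector of 1/2) and `Q`; `Q` is
#'   `-Inf` when no 2-way split exists (fewer than 2 vertices or no edges).
#' @export
best_modularity_bipartition <- function(graph, n_exhaustive = 16) {
  n <- igraph::vcount(graph)
  if (n < 2 || igraph::ecount(graph) == 0)
    return(list(membership = NULL, Q = -Inf))
  A <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
    igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
  k <- rowSums(A)
  m2 <- sum(k)
  B <- A - outer(k, k) / m2

  if (n <= n_exhaustive) {
    bits <- 2^(seq_len(n) - 1)
    best_q <- -Inf
    best_x <- NULL
    for (mask in seq_len(2^(n - 1) - 1)) {
      x <- bitwAnd(mask, bits) > 0
      q <- 2 * sum(B[x, x, drop = FALSE]) / m2
      if (q > best_q + 1e-15) {
        best_q <- q
        best_x <- x
      }
    }
    return(list(membership = as.integer(best_x) + 1L, Q = best_q))
  }

  ev <- eigen(B, symmetric = TRUE)
  v <- ev$vectors[, 1]
  s <- ifelse(v >= 0, 1, -1)
  if (all(s == s[1])) s[which.min(v * s[1])] <- -s[1]  # force two groups
  qual <- function(s) as.numeric(t(s) %*% B %*% s) / (2 * m2)
  # Kernighan-Lin style refinement: move every node once per pass in order
  # of best gain, keep the best intermediate state, repeat while improving
  for (pass in 1:10) {
    s_work <- s
    g <- as.vector(B %*% s_work)
    moved <- rep(FALSE, n)
    best_state <- s
    best_gain <- 0
    cur_gain <- 0
    for (step in seq_len(n)) {
      delta <- (-4 * s_work * g + 4 * diag(B)) / (2 * m2)
      delta[moved] <- -Inf
      # keep both groups nonempty
      grp <- s_work > 0
      if (sum(grp) == 1) delta[grp] <- -Inf
      if (sum(!grp) == 1) delta[!grp] <- -Inf
      i <- which.max(delta)
      if (!is.finite(delta[i])) break
      cur_gain <- cur_gain + delta[i]
      g <- g - 2 * s_work[i] * B[, i]
      s_work[i] <- -s_work[i]
      moved[i] <- TRUE
      if (cur_gain > best_gain + 1e-12) {
        best_gain <- cur_gain
        best_state <- s_work
      }
    }
    if (best_gain <= 1e-12) break
    s <- best_state
  }
  list(membership = as.integer(s > 0) + 1L, Q = qual(s))
}

#' Multiscale modularity clustering of a planar filtered network
#'
#' Recursive top-down decomposition.  A disconnected (sub)graph first splits
#' into its connected components; a connected one is split by the best
#' Newman-Q partition (exhaustive 2-way search for parents of up to 16
#' nodes, agglomerative multiway modularity optimization above that), with
#' children below `min_size` merged into the sibling sharing the most edge
#' weight.  Because every PMFG-filtered subgraph is planar and planar
#' graphs always admit positive-Q partitions, a split is accepted only
#' when its `Q` is positive and it beats `n_null` matched random planar
#' null graphs on at least one of two statistics: a higher `Q`, or a
#' sparser cut-weight fraction (splits of modules larger than `max_size`
#' skip the null gate so oversized modules are always broken up).
#' Recursion continues inside every accepted child.
#'
#' @param network `igraph` as returned by [build_pfn()].
#' @param min_size Minimum module size reported (default 10).
#' @param max_size Modules above this size are always split when possible
#'   (default 500).
#' @param n_null Number of random planar null graphs for the split gate
#'   (default 30).
#' @param seed Integer seed for the null graphs (default 1).
#' @return Object of class `module_hierarchy`: list with `modules`
#'   (data.frame `id`, `parent`, `depth`, `size`, `split_Q`) and `genes`
#'   (named list of character vectors).  The root module `M1` holds all
#'   network nodes.
#' @export
multiscale_cluster <- function(network, min_size = 10, max_size = 500,
                               n_null = 30, seed = 1) {
  stopifnot(igraph::vcount(network) > 0)
  set.seed(seed)
  if (is.null(igraph::V(network)$name))
    igraph::V(network)$name <- paste0("n", seq_len(igraph::vcount(network)))
  has_w <- "weight" %in% igraph::edge_attr_names(network)

  modules <- list()
  genes <- list()
  next_id <- 1L
  new_module <- function(gene_set, parent, depth) {
    id <- paste0("M", next_id)
    next_id <<- next_id + 1L
    modules[[id]] <<- data.frame(id = id,
                                 parent = if (is.null(parent)) NA_character_ else parent,
                                 depth = depth, size = length(gene_set),
                                 split_Q = NA_real_, stringsAsFactors = FALSE)
    genes[[id]] <<- gene_set
    id
  }

  # Cut-weight fraction of a partition (weighted when weights exist).
  cut_fraction <- function(g, membership) {
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1, nrow(el))
    crossing <- membership[el[, 1]] != membership[el[, 2]]
    sum(w[crossing]) / sum(w)
  }

  # Merge communities below min_size into the sibling they share the most
  # edge weight with, smallest first; relabel 1..k.
  merge_small <- function(sub, mem) {
    if (is.null(mem)) return(NULL)
    el <- igraph::as_edgelist(sub, names = FALSE)
    w <- if (has_w) igraph::E(sub)$weight else rep(1, nrow(el))
    repeat {
      sizes <- table(mem)
      small <- names(sizes)[sizes < min_size]
      if (length(small) == 0 || length(sizes) <= 1) break
      s <- small[which.min(sizes[small])]
      inside <- mem[el[, 1]] == s | mem[el[, 2]] == s
      other <- ifelse(mem[el[inside, 1]] == s,
                      mem[el[inside, 2]], mem[el[inside, 1]])
      link <- tapply(w[inside][other != s], other[other != s], sum)
      target <- if (length(link)) names(link)[which.max(link)] else
        setdiff(names(sizes), s)[1]
      mem[mem == as.integer(s)] <- as.integer(target)
    }
    mem <- match(mem, sort(unique(mem)))
    if (length(unique(mem)) < 2) return(NULL)
    mem
  }

  part_stats <- function(sub, mem) {
    if (is.null(mem)) return(NULL)
    list(membership = mem,
         Q = igraph::modularity(sub, mem,
                                weights = if (has_w) igraph::E(sub)$weight
                                          else NULL),
         cut = cut_fraction(sub, mem))
  }

  # Two candidate Q-partitions of a connected parent.  The agglomerative
  # multiway optimum resolves parents holding three or more true modules
  # but over-partitions a two-module parent once it is smaller than the
  # modularity resolution limit; the best bipartition is exact for two
  # modules but mixes members when three or more are present.  Each
  # candidate is therefore judged against nulls partitioned by its own
  # procedure.  Small parents use the exhaustive bipartition only (exact).
  candidate_partitions <- function(sub) {
    n <- igraph::vcount(sub)
    out <- list()
    if (n <= 16) {
      out$two <- part_stats(sub,
        merge_small(sub, best_modularity_bipartition(sub)$membership))
      return(out)
    }
    cl <- igraph::cluster_fast_greedy(
      sub, weights = if (has_w) igraph::E(sub)$weight else NULL)
    out$kway <- part_stats(sub,
      merge_small(sub, as.integer(igraph::membership(cl))))
    out$two <- part_stats(sub,
      merge_small(sub, best_modularity_bipartition(sub)$membership))
    out
  }

  # Null model for the split gate: random planar graphs with the same
  # node and edge count (PMFG grown from randomly ordered candidate
  # pairs), carrying a random permutation of the observed edge weights,
  # passed through the identical candidate-partition procedures.  Planar
  # graphs have good separators, so any PMFG-filtered module yields a
  # positive-Q partition with a fairly sparse cut; a candidate split is
  # believed only when its modularity exceeds, or its cut is sparser
  # than, everything planarity alone produces under the same optimizer.
  null_split_stats <- function(sub) {
    n <- igraph::vcount(sub)
    m <- igraph::ecount(sub)
    w <- if (has_w) igraph::E(sub)$weight else rep(1, m)
    n_pairs <- n * (n - 1) / 2
    stats <- list(kway = list(q = rep(-Inf, n_null), cut = rep(1, n_null)),
                  two = list(q = rep(-Inf, n_null), cut = rep(1, n_null)))
    for (i in seq_len(n_null)) {
      n_cand <- min(n_pairs, max(4 * m, 200))
      cand <- sample.int(n_pairs, n_cand)
      # unrank upper-triangle index -> (row, col)
      a <- ceiling((sqrt(8 * cand + 1) - 1) / 2)
      u <- cand - a * (a - 1) / 2
      v <- a + 1L
      ord <- sample.int(n_cand)  # random insertion order = random weights
      keep <- .pmfg_cpp(n, as.integer(u[ord]) - 1L, as.integer(v[ord]) - 1L)
      ki <- which(keep)
      if (length(ki) > m) ki <- ki[seq_len(m)]
      g0 <- igraph::graph_from_edgelist(
        cbind(as.integer(u[ord][ki]), as.integer(v[ord][ki])),
        directed = FALSE)
      if (has_w)
        igraph::E(g0)$weight <- sample(w, length(ki),
                                       replace = length(ki) > length(w))
      comp0 <- igraph::components(g0)
      if (comp0$no > 1) {  # keep the giant component for comparability
        g0 <- igraph::induced_subgraph(
          g0, which(comp0$membership == which.max(comp0$csize)))
      }
      cands0 <- candidate_partitions(g0)
      for (nm in names(cands0)) {
        if (is.null(cands0[[nm]])) next
        stats[[nm]]$q[i] <- cands0[[nm]]$Q
        stats[[nm]]$cut[i] <- cands0[[nm]]$cut
      }
    }
    lapply(stats, function(s) list(max_q = max(s$q), min_cut = min(s$cut)))
  }

  recurse <- function(id, depth) {
    gene_set <- genes[[id]]
    sub <- igraph::induced_subgraph(network, gene_set)
    n <- length(gene_set)
    if (n < 2 * min_size) return(invisible())
    comp <- igraph::components(sub)
    if (comp$no > 1) {
      # components are the first split level, before Q optimization
      for (ci in seq_len(comp$no)) {
        members <- gene_set[comp$membership == ci]
        if (length(members) >= min_size && length(members) < n) {
          cid <- new_module(sort(members), id, depth + 1)
          recurse(cid, depth + 1)
        }
      }
      return(invisible())
    }
    cands <- candidate_partitions(sub)
    cands <- Filter(function(cn) !is.null(cn) && cn$Q > 0, cands)
    if (length(cands) == 0) return(invisible())
    sp <- NULL
    if (n > max_size) {
      # oversized modules are always split: take the highest-Q candidate
      sp <- cands[[which.max(vapply(cands, `[[`, numeric(1), "Q"))]]
    } else {
      ns <- null_split_stats(sub)
      best_ratio <- Inf
      for (nm in names(cands)) {
        cn <- cands[[nm]]
        passed <- cn$Q > ns[[nm]]$max_q || cn$cut < ns[[nm]]$min_cut
        if (!passed) next
        ratio <- cn$cut / max(ns[[nm]]$min_cut, 1e-12)
        if (ratio < best_ratio) {
          best_ratio <- ratio
          sp <- cn
        }
      }
      if (is.null(sp)) return(invisible())
    }
    modules[[id]]$split_Q <<- sp$Q
    for (gi in sort(unique(sp$membership))) {
      members <- sort(gene_set[sp$membership == gi])
      cid <- new_module(members, id, depth + 1)
      recurse(cid, depth + 1)
    }
    invisible()
  }

  root <- new_module(sort(igraph::V(network)$name), NULL, 0)
  recurse(root, 0)
  structure(list(modules = do.call(rbind, c(modules, list(make.row.names = FALSE))),
                 genes = genes, min_size = min_size, max_size = max_size),
            class = "module_hierarchy")
}

#' @export
print.module_hierarchy <- function(x, ...) {
  cat(sprintf("Module hierarchy: %d modules (sizes %d-%d, max depth %d)\n",
              nrow(x$modules), min(x$modules$size), max(x$modules$size),
              max(x$modules$depth)))
  invisible(x)
}

#' Leaf modules of a hierarchy
#'
#' @param hierarchy A `module_hierarchy`.
#' @return Character ids of modules without children.
#' @export
leaf_modules <- function(hierarchy) {
  m <- hierarchy$modules
  setdiff(m$id, m$parent[!is.na(m$parent)])
}

#' Modules eligible for enrichment-style tests
#'
#' @param hierarchy A `module_hierarchy`.
#' @param size_bounds Inclusive size bounds, default `c(10, 500)`.
#' @return Character ids of modules within the bounds.
#' @export
eligible_modules <- function(hierarchy, size_bounds = c(10, 500)) {
  m <- hierarchy$modules
  m$id[m$size >= size_bounds[1] & m$size <= size_bounds[2]]
}

#' Detect hub genes in a planar filtered network
#'
#' The null connectivity of a node is its degree under random relabeling of
#' the network nodes: with continuous correlation weights the PFN grown from
#' a label-permuted pair list is the same graph up to isomorphism, so each
#' permutation assigns every node a draw from the observed degree sequence.
#' Per node, `p = (1 + #{permuted degree >= observed}) / (1 + n_perm)`.
#'
#' @param network `igraph` PFN.
#' @param n_perm Number of permutations (default 100).
#' @param alpha Significance level for the hub flag (default 0.05).
#' @param seed Optional integer seed.
#' @return data.frame `gene`, `degree`, `p`, `is_hub`.
#' @export
detect_hubs <- function(network, n_perm = 100, alpha = 0.05, seed = NULL) {
  if (igraph::ecount(network) < 1) stop("network has no edges")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(igraph::V(network)$name))
    igraph::V(network)$name <- paste0("n", seq_len(igraph::vcount(network)))
  deg <- igraph::degree(network)
  exceed <- integer(length(deg))
  for (i in seq_len(n_perm)) {
    exceed <- exceed + (sample(deg) >= deg)
  }
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(gene = names(deg), degree = as.integer(deg), p = p,
             is_hub = p < alpha, row.names = NULL, stringsAsFactors = FALSE)
}
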