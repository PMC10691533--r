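#' Pairwise cross-cohort module similarity
#'
#' For every unordered cohort pair, compares every eligible module of one
#' cohort with every eligible module of the other: Jaccard index on the raw
#' gene sets, Fisher's exact test on the sets restricted to the shared
#' universe (the intersection of the two cohorts' gene universes, so genes
#' unmeasured in one cohort cannot drive the test), BH adjustment within
#' the cohort-pair family.  A pair is conserved when `J > 0.4` and the
#' adjusted p is below 0.05.
#'
#' @param hierarchies Named list of `module_hierarchy` objects, one per
#'   cohort.
#' @param universes Named list of character vectors: each cohort's filtered
#'   gene universe.
#' @param size_bounds Module-size eligibility bounds (default `c(10, 500)`).
#' @param jaccard_cut Conserved-pair Jaccard threshold (default 0.4).
#' @param alpha Conserved-pair adjusted-p threshold (default 0.05).
#' @return data.frame `cohort_a`, `module_a`, `cohort_b`, `module_b`,
#'   `jaccard`, `overlap`, `p`, `afetp`, `conserved`.
#' @export
pairwise_similarity <- function(hierarchies, universes,
                                size_bounds = c(10, 500),
                                jaccard_cut = 0.4, alpha = 0.05) {
  stopifnot(length(hierarchies) >= 2, !is.null(names(hierarchies)),
            all(names(hierarchies) %in% names(universes)))
  cohorts <- names(hierarchies)
  rows <- list()
  for (i in seq_along(cohorts)[-length(cohorts)]) {
    for (j in seq((i + 1), length(cohorts))) {
      ca <- cohorts[i]; cb <- cohorts[j]
      shared <- intersect(universes[[ca]], universes[[cb]])
      N <- length(shared)
      ids_a <- eligible_modules(hierarchies[[ca]], size_bounds)
      ids_b <- eligible_modules(hierarchies[[cb]], size_bounds)
      if (length(ids_a) == 0 || length(ids_b) == 0 || N == 0) next
      block <- expand.grid(module_a = ids_a, module_b = ids_b,
                           stringsAsFactors = FALSE)
      stats <- mapply(function(ma, mb) {
        A <- hierarchies[[ca]]$genes[[ma]]
        B <- hierarchies[[cb]]$genes[[mb]]
        inter <- length(intersect(A, B))
        J <- inter / length(union(A, B))
        Au <- intersect(A, shared); Bu <- intersect(B, shared)
        k <- length(intersect(Au, Bu))
        p <- phyper(k - 1, length(Bu), N - length(Bu), length(Au),
                    lower.tail = FALSE)
        c(J, k, p)
      }, block$module_a, block$module_b)
      block$cohort_a <- ca
      block$cohort_b <- cb
      block$jaccard <- stats[1, ]
      block$overlap <- as.integer(stats[2, ])
      block$p <- stats[3, ]
      block$afetp <- bh_adjust(block$p)
      rows[[length(rows) + 1]] <- block
    }
  }
  if (length(rows) == 0) stop("no eligible module pairs across cohorts")
  out <- do.call(rbind, rows)
  out$conserved <- out$jaccard > jaccard_cut & out$afetp < alpha
  out <- out[, c("cohort_a", "module_a", "cohort_b", "module_b", "jaccard",
                 "overlap", "p", "afetp", "conserved")]
  rownames(out) <- NULL
  out
}

#' Classify modules as conserved, specific, or intermediate
#'
#' A module is conserved when at least one cross-cohort pair passes the
#' conserved rule (`J > 0.4`, adjusted p < 0.05).  It is specific when in
#' every other cohort its best-matching counterpart (highest Jaccard, ties
#' broken by smaller adjusted p) has `J < 0.05` or adjusted p > 0.05
#' (cohorts offering no counterpart count as no overlap).  Everything else
#' is intermediate.
#'
#' @param pairs Output of [pairwise_similarity()].
#' @param jaccard_conserved,jaccard_specific,alpha The thresholds
#'   (defaults 0.4, 0.05, 0.05).
#' @return data.frame `cohort`, `module`, `class`, `best_jaccard`,
#'   `n_conserved_pairs`.
#' @export
classify_modules <- function(pairs, jaccard_conserved = 0.4,
                             jaccard_specific = 0.05, alpha = 0.05) {
  long <- rbind(
    data.frame(cohort = pairs$cohort_a, module = pairs$module_a,
               other = pairs$cohort_b, jaccard = pairs$jaccard,
               afetp = pairs$afetp, conserved = pairs$conserved,
               stringsAsFactors = FALSE),
    data.frame(cohort = pairs$cohort_b, module = pairs$module_b,
               other = pairs$cohort_a, jaccard = pairs$jaccard,
               afetp = pairs$afetp, conserved = pairs$conserved,
               stringsAsFactors = FALSE))
  key <- paste(long$cohort, long$module, sep = "\r")
  cohorts <- unique(c(pairs$cohort_a, pairs$cohort_b))
  out <- lapply(split(long, key), function(d) {
    spec <- TRUE
    for (oc in setdiff(cohorts, d$cohort[1])) {
      dd <- d[d$other == oc, , drop = FALSE]
      if (nrow(dd) == 0) next  # no counterpart at all: no overlap
      best <- dd[order(-dd$jaccard, dd$afetp), ][1, ]
      if (!(best$jaccard < jaccard_specific || best$afetp > alpha))
        spec <- FALSE
    }
    cls <- if (any(d$conserved)) "conserved" else
      if (spec) "specific" else "intermediate"
    data.frame(cohort = d$cohort[1], module = d$module[1], class = cls,
               best_jaccard = max(d$jaccard),
               n_conserved_pairs = sum(d$conserved),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cohort, out$module), ]
  rownames(out) <- NULL
  out
}

#' Greedy module clusters from conserved pairs
#'
#' Starting from an unassigned conserved module, repeatedly pools the
#' conserved counterparts of the current set until closure, emits the
#' group as one module cluster, and removes it from the search list.  The
#' result partitions the conserved modules and does not depend on the
#' starting order (it equals the connected components of the conserved-pair
#' graph).
#'
#' @param pairs Output of [pairwise_similarity()] (only rows with
#'   `conserved = TRUE` are used).
#' @return data.frame `cohort`, `module`, `cluster` (ids `c1`, `c2`, ...,
#'   numbered by decreasing cluster size, ties by first member).
#' @export
greedy_module_clusters <- function(pairs) {
  cp <- pairs[pairs$conserved, , drop = FALSE]
  if (nrow(cp) == 0)
    return(data.frame(cohort = character(0), module = character(0),
                      cluster = character(0)))
  node_a <- paste(cp$cohort_a, cp$module_a, sep = "\r")
  node_b <- paste(cp$cohort_b, cp$module_b, sep = "\r")
  nodes <- sort(unique(c(node_a, node_b)))
  adj <- split(c(node_b, node_a), c(node_a, node_b))
  assigned <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cluster_members <- list()
  for (start in nodes) {
    if (!is.na(assigned[start])) next
    frontier <- start
    members <- character(0)
    while (length(frontier) > 0) {      # pool counterparts until closure
      members <- union(members, frontier)
      counterparts <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- setdiff(counterparts, members)
    }
    cid <- length(cluster_members) + 1L
    cluster_members[[cid]] <- sort(members)
    assigned[members] <- cid
  }
  sizes <- vapply(cluster_members, length, integer(1))
  rank <- order(-sizes, vapply(cluster_members, `[`, character(1), 1))
  relabel <- integer(length(cluster_members))
  relabel[rank] <- seq_along(rank)
  parts <- strsplit(nodes, "\r", fixed = TRUE)
  out <- data.frame(cohort = vapply(parts, `[`, character(1), 1),
                    module = vapply(parts, `[`, character(1), 2),
                    cluster = paste0("c", relabel[assigned[nodes]]),
                    stringsAsFactors = FALSE)
  out[order(out$cluster, out$cohort, out$module), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster cohorts by conserved-module similarity
#'
#' Builds a cohort x module-cluster profile (entry = the cohort's best
#' conserved-pair Jaccard within the cluster, 0 when the cohort has no
#' module there), takes `1 - Pearson correlation` of the profiles as the
#' distance, and applies average-linkage hierarchical clustering.
#'
#' @param pairs Output of [pairwise_similarity()].
#' @param clusters Output of [greedy_module_clusters()].
#' @param linkage `hclust` method (default "average").
#' @return List with `hclust` (the tree), `distance` (the distance
#'   matrix), and `profiles`.
#' @export
cluster_cohorts <- function(pairs, clusters, linkage = "average") {
  cohorts <- sort(unique(c(pairs$cohort_a, pairs$cohort_b)))
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  cl_ids <- sort(unique(clusters$cluster))
  prof <- matrix(0, length(cohorts), max(1, length(cl_ids)),
                 dimnames = list(cohorts, if (length(cl_ids)) cl_ids else "c0"))
  if (length(cl_ids)) {
    ckey <- setNames(clusters$cluster,
                     paste(clusters$cohort, clusters$module, sep = "\r"))
    cp <- pairs[pairs$conserved, , drop = FALSE]
    for (r in seq_len(nrow(cp))) {
      ka <- paste(cp$cohort_a[r], cp$module_a[r], sep = "\r")
      cl <- ckey[[ka]]
      prof[cp$cohort_a[r], cl] <- max(prof[cp$cohort_a[r], cl], cp$jaccard[r])
      prof[cp$cohort_b[r], cl] <- max(prof[cp$cohort_b[r], cl], cp$jaccard[r])
    }
  }
  D <- matrix(1, length(cohorts), length(cohorts),
              dimnames = list(cohorts, cohorts))
  diag(D) <- 0
  for (i in seq_along(cohorts)) {
    for (j in seq_along(cohorts)) {
      if (i >= j) next
      a <- prof[i, ]; b <- prof[j, ]
      d <- if (sd(a) == 0 || sd(b) == 0) {
        if (all(a == b)) 0 else 1
      } else {
        1 - cor(a, b)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  hc <- hclust(as.dist(D), method = linkage)
  list(hclust = hc, distance = D, profiles = prof)
}

#' Conservation-weighted aggregated network
#'
#' Merges the target-module genes and their PFN coexpression links across
#' cohorts.  A gene's conservation weight is the number of cohorts whose
#' target modules contain it; an edge's weight is the number of cohorts
#' whose network links the pair within the target genes.  Nodes with weight
#' below `min_weight` are removed together with their incident edges.
#'
#' @param target_modules Named list (per cohort) of character vectors: the
#'   union of the cohort's target-module genes.
#' @param networks Named list of `igraph` PFNs, same cohorts.
#' @param min_weight Minimum node conservation weight kept (default 4,
#'   i.e. conserved in more than three cohorts).
#' @return Object of class `aggregated_network`: list with `nodes`
#'   (data.frame `gene`, `weight`) and `edges` (data.frame `gene_a`,
#'   `gene_b`, `weight`).
#' @export
aggregate_network <- function(target_modules, networks, min_weight = 4) {
  stopifnot(!is.null(names(target_modules)),
            all(names(target_modules) %in% names(networks)))
  if (all(vapply(target_modules, length, integer(1)) == 0))
    stop("empty target module sets")
  node_tab <- table(unlist(lapply(target_modules, unique)))
  nodes <- data.frame(gene = names(node_tab),
                      weight = as.integer(node_tab),
                      stringsAsFactors = FALSE)
  edge_keys <- unlist(lapply(names(target_modules), function(co) {
    g <- networks[[co]]
    tg <- intersect(target_modules[[co]], igraph::V(g)$name)
    if (length(tg) < 2) return(character(0))
    el <- igraph::as_edgelist(igraph::induced_subgraph(g, tg))
    if (nrow(el) == 0) return(character(0))
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  }), use.names = FALSE)
  keep_genes <- nodes$gene[nodes$weight >= min_weight]
  nodes <- nodes[nodes$gene %in% keep_genes, , drop = FALSE]
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (length(edge_keys) > 0) {
    et <- table(edge_keys)
    parts <- strsplit(names(et), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(parts, `[`, character(1), 1),
                        gene_b = vapply(parts, `[`, character(1), 2),
                        weight = as.integer(et), stringsAsFactors = FALSE)
    edges <- edges[edges$gene_a %in% keep_genes &
                   edges$gene_b %in% keep_genes, , drop = FALSE]
    edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes[order(-nodes$weight, nodes$gene), ],
                 edges = edges, min_weight = min_weight),
            class = "aggregated_network")
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat(sprintf("Aggregated network: %d nodes, %d edges (node weight >= %d)\n",
              nrow(x$nodes), nrow(x$edges), x$min_weight))
  invisible(x)
}
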