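#' Assemble a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> genes).
#' @param universe Character vector of genes forming the test universe.
#' @param name Collection label.
#' @return Object of class `gene_set_collection`.  Genes outside the
#'   universe are dropped with a warning; sets left empty are removed.
#' @export
gene_set_collection <- function(sets, universe, name = "collection") {
  stopifnot(is.list(sets), length(sets) > 0, length(universe) > 0)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  outside <- sum(vapply(sets, function(s) sum(!s %in% universe), numeric(1)))
  if (outside > 0) {
    warning(sprintf("%d set gene(s) outside the universe dropped", outside))
    sets <- lapply(sets, function(s) s[s %in% universe])
  }
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("dropping empty set(s): ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no non-empty sets remain")
  structure(list(name = name, sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, universe %d genes\n",
              x$name, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH via [stats::p.adjust()], with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's exact test enrichment of one module against a collection
#'
#' One-sided hypergeometric upper-tail p per set; BH adjustment within the
#' module x collection family.  A result is flagged significant when the
#' overlap exceeds three genes (`k >= min_overlap`) and the adjusted p is
#' below `alpha`.
#'
#' @param module Character vector of module genes.
#' @param collection A [gene_set_collection()].
#' @param size_bounds Module-size eligibility bounds after intersecting with
#'   the universe (default `c(10, 500)`); ineligible modules return a
#'   zero-row result with a message.
#' @param min_overlap Minimum overlap for significance (default 4, i.e.
#'   strictly more than three shared genes).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return data.frame `set`, `overlap`, `module_size`, `set_size`,
#'   `universe_size`, `p`, `afetp`, `significant`.
#' @export
fisher_enrichment <- function(module, collection, size_bounds = c(10, 500),
                              min_overlap = 4, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  module <- unique(as.character(module))
  module <- module[module %in% collection$universe]
  m <- length(module)
  if (m == 0) stop("module has no genes in the universe")
  empty <- data.frame(set = character(0), overlap = integer(0),
                      module_size = integer(0), set_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      afetp = numeric(0), significant = logical(0))
  if (m < size_bounds[1] || m > size_bounds[2]) {
    message(sprintf("module size %d outside [%d, %d]: skipped", m,
                    size_bounds[1], size_bounds[2]))
    return(empty)
  }
  N <- length(collection$universe)
  res <- lapply(names(collection$sets), function(sid) {
    s <- collection$sets[[sid]]
    k <- length(intersect(module, s))
    p <- phyper(k - 1, length(s), N - length(s), m, lower.tail = FALSE)
    data.frame(set = sid, overlap = k, module_size = m,
               set_size = length(s), universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$afetp <- bh_adjust(res$p)
  res$significant <- res$overlap >= min_overlap & res$afetp < alpha
  rownames(res) <- NULL
  res
}

#' Cytoband enrichment of every eligible module
#'
#' Treats each cytoband's gene set as one entry of a gene-set collection and
#' runs [fisher_enrichment()] per eligible module, using the same
#' significance rule (overlap > 3 and adjusted p < 0.05).
#'
#' @param hierarchy A `module_hierarchy`.
#' @param annotation Gene annotation data.frame with columns `gene` and
#'   `cytoband` (as produced by the synthetic generator or a cytoband
#'   reader).
#' @param universe Optional universe; defaults to the annotated genes.
#' @param size_bounds,min_overlap,alpha Passed to [fisher_enrichment()].
#' @return data.frame with a `module` column prepended to the
#'   [fisher_enrichment()] output (`set` holds the cytoband).
#' @export
cytoband_enrichment <- function(hierarchy, annotation, universe = NULL,
                                size_bounds = c(10, 500), min_overlap = 4,
                                alpha = 0.05) {
  stopifnot(all(c("gene", "cytoband") %in% names(annotation)))
  annotation <- annotation[!is.na(annotation$cytoband), ]
  if (nrow(annotation) == 0) stop("no annotated genes")
  if (is.null(universe)) universe <- annotation$gene
  annotation <- annotation[annotation$gene %in% universe, ]
  if (nrow(annotation) == 0) stop("no annotated genes in the universe")
  coll <- gene_set_collection(split(annotation$gene, annotation$cytoband),
                              universe, name = "cytobands")
  out <- lapply(eligible_modules(hierarchy, size_bounds), function(mid) {
    r <- fisher_enrichment(hierarchy$genes[[mid]], coll,
                           size_bounds = size_bounds,
                           min_overlap = min_overlap, alpha = alpha)
    if (nrow(r)) cbind(module = mid, r, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(module = character(0), set = character(0),
                      overlap = integer(0), module_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      p = numeric(0), afetp = numeric(0),
                      significant = logical(0))
  }
  rownames(out) <- NULL
  out
}
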