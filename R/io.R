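#' Read an expression matrix from TSV
#'
#' First column gene ids, header = sample ids, tab-separated.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty expression table: ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  rownames(mat) <- ids
  dups <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dups))
    stop("duplicated sample id(s): ", paste(unique(dups), collapse = ", "))
  mat
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: set name, description, then tab-separated genes.
#' Duplicate genes within a set are dropped; empty sets warn.
#'
#' @param path File path.
#' @param universe Optional universe; defaults to the union of all genes.
#' @param name Collection label (default: file base name).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL,
                     name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("line %d of %s: fewer than 3 tab-separated fields",
                   i, path))
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  gene_set_collection(sets, universe, name = name)
}

#' Write a gene-set collection (or named list of sets) to GMT
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cytoband table (UCSC cytoBand dialect)
#'
#' Columns chrom, start, end, band name, stain; no header; BED-style
#' 0-based half-open coordinates, converted to 1-based inclusive.
#'
#' @param path File path.
#' @return data.frame `chrom`, `start`, `end`, `band` (chrom number +
#'   name, e.g. `1p11`), `stain`.
#' @export
read_cytoband <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("cytoband table needs >= 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  df$stain <- if (ncol(df) >= 5) df[[5]] else NA_character_
  data.frame(chrom = df$chrom, start = df$start + 1L, end = df$end,
             band = paste0(sub("^chr", "", df$chrom), df$name),
             stain = df$stain, stringsAsFactors = FALSE)
}

#' Write a cytoband table in UCSC dialect (0-based half-open)
#' @param bands data.frame `chrom`, `start`, `end`, `band`, `stain`
#'   (1-based inclusive, band = chrom number + name).
#' @param path Output path.
#' @export
write_cytoband <- function(bands, path) {
  name <- sub("^[0-9XY]+", "", bands$band)
  out <- data.frame(bands$chrom, bands$start - 1L, bands$end, name,
                    bands$stain)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read fixed-width peak regions (BED) plus a counts matrix (TSV)
#'
#' BED coordinates are 0-based half-open and converted to 1-based
#' inclusive; the counts table is region x sample with a `region` id
#' column matching BED line order (`peak_<i>`).
#'
#' @param bed_path BED file of regions.
#' @param counts_path TSV of normalized log2 counts.
#' @return List `regions`, `counts` as consumed by
#'   [cytoband_peak_signal()].
#' @export
read_bed_counts <- function(bed_path, counts_path) {
  bed <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs >= 3 columns: ", bed_path)
  regions <- data.frame(chrom = bed[[1]], start = bed[[2]] + 1L,
                        end = bed[[3]], stringsAsFactors = FALSE)
  counts <- read_expression(counts_path)
  if (nrow(counts) != nrow(regions))
    stop("counts rows do not match BED regions")
  widths <- regions$end - regions$start + 1L
  if (length(unique(widths)) != 1)
    stop("peak regions must share a fixed width")
  list(regions = regions, counts = counts)
}

#' Write peak regions and counts
#' @param peaks List `regions`, `counts`.
#' @param bed_path,counts_path Output paths.
#' @export
write_bed_counts <- function(peaks, bed_path, counts_path) {
  out <- data.frame(peaks$regions$chrom, peaks$regions$start - 1L,
                    peaks$regions$end)
  write.table(out, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  cm <- peaks$counts
  if (is.null(rownames(cm))) rownames(cm) <- paste0("peak_", seq_len(nrow(cm)))
  df <- data.frame(region = rownames(cm), cm, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}

#' Read a simple keyed TSV table
#' @param path File path.
#' @return data.frame with check.names disabled.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a synthetic fixture to a directory of pipeline input files
#'
#' Writes, per cohort, `expression_<C>.tsv` (tumor + normal, log2 scale),
#' `samples_<C>.tsv` (group + covariates), `survival_<C>.tsv`,
#' `beta_<C>.tsv`, `probes_<C>.tsv`; plus genome-level `genes.tsv`,
#' `cytoband.tsv` (UCSC dialect), `peaks.bed` + `peak_counts.tsv`,
#' `modules.gmt` (planted module gene sets) and `truth.json`.
#'
#' @param fixture Output of [make_default_fixture()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in fixture$cohorts) {
    co <- ch$cohort
    write_expression(ch$expr_all, file.path(dir, paste0("expression_", co, ".tsv")))
    samples <- data.frame(sample = colnames(ch$expr_all),
                          group = as.character(ch$groups),
                          ch$covariates, stringsAsFactors = FALSE)
    write_table_tsv(samples, file.path(dir, paste0("samples_", co, ".tsv")))
    write_table_tsv(ch$survival, file.path(dir, paste0("survival_", co, ".tsv")))
    write_expression(ch$beta, file.path(dir, paste0("beta_", co, ".tsv")))
    write_table_tsv(ch$probes, file.path(dir, paste0("probes_", co, ".tsv")))
  }
  write_table_tsv(fixture$annotation$genes, file.path(dir, "genes.tsv"))
  write_cytoband(fixture$annotation$bands, file.path(dir, "cytoband.tsv"))
  write_bed_counts(fixture$annotation$peaks, file.path(dir, "peaks.bed"),
                   file.path(dir, "peak_counts.tsv"))
  write_gmt(fixture$truth$module_genes, file.path(dir, "modules.gmt"))
  truth <- fixture$truth
  truth_json <- list(
    assignments = truth$assignments,
    modules = truth$modules,
    deg_truth = truth$deg_truth,
    dmc_truth = truth$dmc_truth,
    open_bands = fixture$annotation$open_bands)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
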