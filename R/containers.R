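# Core data containers: sparse cell x feature matrices plus tabular metadata.
# Result tables elsewhere in the package are plain tibbles; these containers
# exist because cell x gene and cell x site count matrices are not naturally
# tabular and are held sparse.

#' Expression matrix container
#'
#' Bundles a sparse cells-by-transcripts UMI count matrix with per-feature
#' genomic coordinates and per-cell metadata. Total UMIs per cell are always
#' recomputed from the counts so the invariant `total_umis == rowSums(counts)`
#' holds by construction.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells in rows,
#'   transcripts in columns; dimnames give barcodes and feature ids.
#' @param features data frame with columns `feature`, `chrom`, `pos` (1-based
#'   representative position, e.g. transcript midpoint), one row per column of
#'   `counts`.
#' @param cell_meta optional data frame with column `barcode` plus any of
#'   `batch`, `stage`, `segregant`, `doublet`. Missing `batch` defaults to a
#'   single batch.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, features, cell_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0) || any(counts@x != floor(counts@x))) {
    stop_format("expression counts must be non-negative integers")
  }
  features <- as_tibble(features)
  if (!all(c("feature", "chrom", "pos") %in% names(features))) {
    stop_format("`features` needs columns feature, chrom, pos")
  }
  if (nrow(features) != ncol(counts)) {
    stop_format("features table and count matrix disagree on transcript count")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%06d", seq_len(nrow(counts)))
  }
  colnames(counts) <- features$feature
  if (is.null(cell_meta)) {
    cell_meta <- tibble(barcode = rownames(counts))
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"barcode" %in% names(cell_meta)) stop_format("cell_meta needs `barcode`")
    if (!identical(cell_meta$barcode, rownames(counts))) {
      stop_format("cell_meta barcodes must match count matrix rows in order")
    }
  }
  if (!"batch" %in% names(cell_meta)) cell_meta$batch <- "batch1"
  cell_meta$total_umis <- Matrix::rowSums(counts)
  structure(
    list(counts = counts, features = features, cell_meta = cell_meta),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d cells x %d transcripts (%d batches)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$cell_meta$batch))
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Allele count matrix container
#'
#' Per-cell, per-site UMI counts supporting each parental allele, as produced
#' by allele-aware counting of scRNA-seq reads at sites where the two cross
#' parents differ. `countsA` holds reads supporting the parent-A allele,
#' `countsB` the parent-B allele; total depth D is their sum.
#'
#' @param countsA,countsB sparse non-negative integer matrices (cells x sites)
#'   with identical dimensions and cell ordering.
#' @param sites data frame with columns `chrom`, `pos` (1-based), `alleleA`,
#'   `alleleB`; must be sorted by (chrom, pos) and unique.
#' @param mask optional logical vector, `TRUE` for usable sites. Defaults to
#'   all usable.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(countsA, countsB, sites, mask = NULL) {
  countsA <- as(as(countsA, "CsparseMatrix"), "generalMatrix")
  countsB <- as(as(countsB, "CsparseMatrix"), "generalMatrix")
  if (!identical(dim(countsA), dim(countsB))) {
    stop_format("countsA and countsB must share dimensions")
  }
  if (any(countsA@x < 0) || any(countsB@x < 0)) {
    stop_format("allele counts must be non-negative")
  }
  sites <- as_tibble(sites)
  req <- c("chrom", "pos")
  if (!all(req %in% names(sites))) stop_format("`sites` needs chrom and pos")
  if (!"alleleA" %in% names(sites)) sites$alleleA <- "A"
  if (!"alleleB" %in% names(sites)) sites$alleleB <- "B"
  if (nrow(sites) != ncol(countsA)) {
    stop_format("sites table and count matrices disagree on site count")
  }
  o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    warn("sites were not sorted by (chrom, pos); sorting")
    sites <- sites[o, ]
    countsA <- countsA[, o, drop = FALSE]
    countsB <- countsB[, o, drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stop_format("duplicate (chrom, pos) in sites")
  }
  if (is.null(rownames(countsA))) {
    rownames(countsA) <- sprintf("cell%06d", seq_len(nrow(countsA)))
  }
  rownames(countsB) <- rownames(countsA)
  if (is.null(mask)) mask <- rep(TRUE, nrow(sites))
  structure(
    list(countsA = countsA, countsB = countsB, sites = sites,
         mask = as.logical(mask)),
    class = "allele_counts"
  )
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf(
    "<allele_counts> %d cells x %d sites (%d masked)\n",
    nrow(x$countsA), ncol(x$countsA), sum(!x$mask)
  ))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$countsA)

#' Genetic map container
#'
#' Ordered marker table with genomic (bp) and genetic (cM) coordinates,
#' used both to simulate recombinant genomes and to supply transition
#' probabilities for genotype inference.
#'
#' @param markers data frame with columns `chrom`, `pos` (bp, 1-based), `cM`.
#' @return A tibble of class `genetic_map`.
#' @export
genetic_map <- function(markers) {
  m <- as_tibble(markers)
  if (!all(c("chrom", "pos", "cM") %in% names(m))) {
    stop_format("genetic map needs columns chrom, pos, cM")
  }
  # chromosomes keep their order of first appearance (e.g. chrI..chrXVI),
  # positions sort within chromosome
  o <- order(match(m$chrom, unique(m$chrom)), m$pos)
  if (!identical(o, seq_len(nrow(m)))) {
    warn("genetic map rows were not sorted by (chrom, pos); sorting")
    m <- m[o, ]
  }
  if (anyDuplicated(m[c("chrom", "pos")])) {
    stop_format("duplicate (chrom, pos) in genetic map")
  }
  for (ch in unique(m$chrom)) {
    cm <- m$cM[m$chrom == ch]
    if (any(diff(cm) < 0)) {
      stop_format("cM must be non-decreasing within chromosome ", ch)
    }
  }
  class(m) <- c("genetic_map", class(m))
  m
}

#' Genotype posterior container
#'
#' @param p_a numeric matrix of posterior probabilities of the parent-A allele,
#'   cells in rows, markers in columns.
#' @param markers tibble describing the marker columns (chrom, pos, cM, ...).
#' @return An object of class `genotype_posterior`.
#' @export
genotype_posterior <- function(p_a, markers) {
  if (any(p_a < -1e-9 | p_a > 1 + 1e-9)) {
    stop_format("posterior probabilities must lie in [0, 1]")
  }
  p_a <- pmin(pmax(p_a, 0), 1)
  markers <- as_tibble(markers)
  if (nrow(markers) != ncol(p_a)) {
    stop_format("marker table and posterior matrix disagree on marker count")
  }
  structure(list(p_a = p_a, markers = markers), class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat(sprintf(
    "<genotype_posterior> %d cells x %d markers; mean max-posterior %.3f\n",
    nrow(x$p_a), ncol(x$p_a), mean(pmax(x$p_a, 1 - x$p_a))
  ))
  invisible(x)
}

#' @export
dim.genotype_posterior <- function(x) dim(x$p_a)
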