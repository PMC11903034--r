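# On-disk formats: MatrixMarket triplets for counts, TSV for sites / maps /
# results, VCF for parental variants. Readers validate rather than coerce;
# every writer's output round-trips through its paired reader.

read_tsv_strict <- function(path, required, what = path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  as_tibble(df)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_mm_strict <- function(path) {
  if (!file.exists(path)) stop_format("matrix file not found: ", path)
  # readMM only warns on truncated entry lists; treat that as malformed too
  m <- tryCatch(
    withCallingHandlers(
      Matrix::readMM(path),
      warning = function(w) stop_format("malformed MatrixMarket file ",
                                        path, ": ", conditionMessage(w))
    ),
    onepot_format_error = function(e) stop(e),
    error = function(e) stop_format("malformed MatrixMarket file ",
                                    path, ": ", conditionMessage(e)))
  if (methods::is(m, "nMatrix")) m <- as(m, "dMatrix")
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  if (any(m@x != floor(m@x)) || any(m@x < 0)) {
    stop_format("non-negative integer entries required in ", path)
  }
  m
}

#' Read a CellRanger-style UMI count triplet
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate integer, 1-based, cells in
#' rows and transcripts in columns), `barcodes.tsv` (one barcode per line) and
#' `features.tsv` (feature, chrom, pos).
#'
#' @param dir directory containing the triplet.
#' @return An [expression_matrix()].
#' @export
read_umi_matrix <- function(dir) {
  counts <- read_mm_strict(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- read_tsv_strict(file.path(dir, "features.tsv"),
                              c("feature", "chrom", "pos"))
  if (length(barcodes) != nrow(counts)) {
    stop_format("barcodes.tsv has ", length(barcodes),
                " entries but matrix.mtx has ", nrow(counts), " rows")
  }
  if (nrow(features) != ncol(counts)) {
    stop_format("features.tsv has ", nrow(features),
                " entries but matrix.mtx has ", ncol(counts), " columns")
  }
  rownames(counts) <- barcodes
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    read_tsv_strict(meta_path, "barcode")
  } else NULL
  expression_matrix(counts, features, meta)
}

#' Write a UMI count triplet
#'
#' @param expr an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_umi_matrix <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(expr$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr$counts), file.path(dir, "barcodes.tsv"))
  write_tsv_plain(expr$features, file.path(dir, "features.tsv"))
  meta <- expr$cell_meta
  write_tsv_plain(meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read Vartrix-style allele count matrices
#'
#' @param pathA,pathB MatrixMarket files of parent-A and parent-B supporting
#'   UMI counts (cells x sites, identical shapes and cell order).
#' @param sites_path TSV with columns chrom, pos, alleleA, alleleB.
#' @param barcodes_path optional file of cell barcodes (one per line).
#' @return An [allele_counts()] object.
#' @export
read_allele_counts <- function(pathA, pathB, sites_path, barcodes_path = NULL) {
  a <- read_mm_strict(pathA)
  b <- read_mm_strict(pathB)
  if (!identical(dim(a), dim(b))) {
    stop_format("allele matrices differ in shape: ",
                paste(dim(a), collapse = "x"), " vs ",
                paste(dim(b), collapse = "x"))
  }
  sites <- read_tsv_strict(sites_path, c("chrom", "pos"))
  if (!is.null(barcodes_path)) {
    bc <- readLines(barcodes_path)
    if (length(bc) != nrow(a)) stop_format("barcode count mismatch")
    rownames(a) <- bc
  }
  allele_counts(a, b, sites)
}

#' Write allele count matrices
#'
#' @param ac an [allele_counts()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_allele_counts <- function(ac, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ac$countsA, file.path(dir, "parentA.mtx"))
  Matrix::writeMM(ac$countsB, file.path(dir, "parentB.mtx"))
  write_tsv_plain(ac$sites, file.path(dir, "sites.tsv"))
  writeLines(rownames(ac$countsA), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Extract cross-informative biallelic SNPs from a VCF
#'
#' Retains sites where the two named parents are homozygous for different
#' alleles — the only sites informative for genotyping haploid progeny.
#' Multi-allelic records and records where either parent is heterozygous or
#' missing are dropped (a count is reported).
#'
#' @param path VCF file (uncompressed or gzip) with genotype columns for both
#'   parents.
#' @param parents character vector of the two parent sample names; defaults to
#'   the first two genotype columns.
#' @return tibble with columns chrom, pos, alleleA, alleleB.
#' @export
read_vcf_sites <- function(path, parents = NULL) {
  if (!file.exists(path)) stop_format("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_format("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  if (length(cols) < 11) stop_format("VCF must carry two genotype columns")
  samples <- cols[-(1:9)]
  if (is.null(parents)) parents <- samples[1:2]
  if (!all(parents %in% samples)) {
    stop_format("parents not found in VCF: ",
                paste(setdiff(parents, samples), collapse = ", "))
  }
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  n_multi <- 0L
  n_uninform <- 0L
  out <- vector("list", length(body))
  idx <- match(parents, samples) + 9L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) < max(idx)) stop_format("malformed VCF record at data line ", i)
    if (grepl(",", f[5], fixed = TRUE)) { n_multi <- n_multi + 1L; next }
    gt <- sub(":.*", "", f[idx])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    hom <- function(g) g %in% c("0/0", "1/1", "0", "1")
    if (!all(hom(gt))) { n_uninform <- n_uninform + 1L; next }
    a1 <- substr(gt[1], 1, 1); a2 <- substr(gt[2], 1, 1)
    if (a1 == a2) { n_uninform <- n_uninform + 1L; next }
    alleles <- c(`0` = f[4], `1` = f[5])
    out[[i]] <- tibble(chrom = f[1], pos = as.integer(f[2]),
                       alleleA = unname(alleles[a1]),
                       alleleB = unname(alleles[a2]))
  }
  if (n_multi + n_uninform > 0) {
    inform(sprintf("read_vcf_sites: dropped %d multi-allelic and %d non-informative records",
                   n_multi, n_uninform))
  }
  res <- bind_rows(out)
  if (!nrow(res)) stop_format("no informative biallelic SNPs found in ", path)
  arrange(res, .data$chrom, .data$pos)
}

#' Read a genetic map TSV
#'
#' @param path TSV with header columns chrom, pos, cM.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "pos", "cM"))
  genetic_map(df)
}

#' Write a genetic map TSV
#'
#' @param map a [genetic_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  write_tsv_plain(as_tibble(map)[c("chrom", "pos", "cM")], path)
  invisible(path)
}
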