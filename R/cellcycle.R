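# Cell-cycle stage assignment from marker-gene expression and the per-gene
# stage-variation likelihood-ratio test. The classifier is a deterministic
# marker-score rule: normalize, z-score the markers, average per stage,
# argmax. Externally produced stage labels can be supplied to all downstream
# steps instead.

stage_order_haploid <- c("M/G1", "G1", "G1/S", "S", "G2/M")
stage_order_diploid <- c("M/G1", "G1/S", "S", "G2/M")

#' Cell-cycle marker panel
#'
#' Canonical stage marker genes for budding yeast. The diploid panel drops
#' MFA1 (not expressed in diploids) and with it the discrete G1 stage.
#'
#' @param ploidy `"haploid"` (5 stages) or `"diploid"` (4 stages).
#' @return named list, stage -> character vector of gene names.
#' @export
marker_panel <- function(ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  panel <- list(
    "M/G1" = c("PIR1", "EGT2", "ASH1", "DSE1", "DSE2", "CTS1"),
    "G1"   = "MFA1",
    "G1/S" = c("CSI1", "TOS4", "POL30", "PRY2", "AXL2", "CLN2"),
    "S"    = c("HTB1", "HHF2"),
    "G2/M" = c("HOF1", "PHO3", "MMR1", "CLB2", "WSC4", "CDC5", "CHS2")
  )
  if (ploidy == "diploid") panel[["G1"]] <- NULL
  panel
}

#' Assign cells to cell-cycle stages from marker expression
#'
#' Counts are normalized to log1p counts-per-10k, each marker gene is
#' z-scored across cells (population SD), and each stage's score is the mean
#' z of its markers. The cell's label is the argmax score; exact ties go to
#' the earlier stage in cycle order (M/G1 first). Cells with zero total
#' counts get a missing label.
#'
#' @param expr an [expression_matrix()].
#' @param panel stage -> gene list, see [marker_panel()].
#' @return tibble: barcode, stage, plus one `score_*` column per stage.
#' @export
assign_stage <- function(expr, panel = marker_panel("haploid")) {
  stages <- names(panel)
  genes <- unlist(panel, use.names = FALSE)
  present <- genes %in% expr$features$feature
  if (!all(present)) {
    warn(paste("markers absent from expression matrix:",
               paste(genes[!present], collapse = ", ")))
  }
  panel <- lapply(panel, intersect, y = expr$features$feature)
  if (any(!lengths(panel))) {
    stop_arg("a stage lost all its marker genes: ",
             paste(stages[!lengths(panel)], collapse = ", "))
  }
  tot <- expr$cell_meta$total_umis
  ok <- tot > 0
  markers <- unique(unlist(panel))
  m <- as.matrix(expr$counts[, markers, drop = FALSE])
  norm <- log1p(m / pmax(tot, 1) * 1e4)
  norm[!ok, ] <- NA
  mu <- colMeans(norm, na.rm = TRUE)
  sdv <- apply(norm, 2, function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))       # population SD
  })
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(norm, 2, mu), 2, sdv, "/")
  scores <- vapply(stages, function(s) {
    rowMeans(z[, panel[[s]], drop = FALSE])
  }, numeric(nrow(z)))
  filled <- scores
  filled[!ok, ] <- 0
  lab <- stages[max.col(filled, ties.method = "first")]  # first max = tie rule
  lab[!ok] <- NA_character_
  out <- tibble(barcode = expr$cell_meta$barcode, stage = lab)
  colnames(scores) <- paste0("score_", gsub("/", "", stages))
  dplyr::bind_cols(out, as_tibble(scores))
}

#' Test genes for expression variation across cell-cycle stages
#'
#' Per gene, an NB GLM with stage indicators plus ln(total UMIs) and batch is
#' compared to the same model without the stage terms by a likelihood-ratio
#' test (df = number of stages - 1; theta estimated on the full model and
#' held fixed for the null). P-values are Benjamini-Hochberg adjusted across
#' genes.
#'
#' @param expr an [expression_matrix()].
#' @param stages per-cell stage labels (NA cells are dropped).
#' @param genes genes to test; defaults to [filter_transcripts()] output.
#' @param min_cells detection filter used for the default gene set.
#' @return tibble: gene, lr, df, p, q.
#' @export
stage_variation_test <- function(expr, stages, genes = NULL,
                                 min_cells = 128) {
  keep_cells <- which(!is.na(stages))
  st <- factor(stages[keep_cells])
  if (nlevels(st) < 2) stop_arg("need at least two stages present")
  if (is.null(genes)) genes <- filter_transcripts(expr, min_cells)
  X0 <- base_design(expr, keep_cells)
  Xs <- stats::model.matrix(~st)[, -1, drop = FALSE]
  df <- ncol(Xs)
  purrr::map_dfr(genes, function(g) {
    y <- expr$counts[keep_cells, g]
    if (all(y == 0)) {
      inform(paste("stage_variation_test: skipping all-zero gene", g))
      return(NULL)
    }
    full <- fit_nb_glm(y, cbind(X0, Xs))
    null <- cpp_nb_fit(y, X0, full$theta)
    lr <- max(2 * (full$loglik - null$loglik), 0)
    tibble(gene = g, lr = lr, df = df,
           p = pchisq(lr, df, lower.tail = FALSE))
  }) |>
    mutate(q = p.adjust(.data$p, "BH"))
}
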