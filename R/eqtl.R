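# Local and genome-wide eQTL scans: standardized genotype posteriors,
# LD pruning, transcript filtering, LOD scores, 1.5-LOD-drop intervals and
# permutation-based FDR.

#' Standardize genotype posteriors
#'
#' Scales each marker's posterior column to mean 0 and SD 1 across cells.
#' Constant columns become all-zero.
#'
#' @param gp a [genotype_posterior()].
#' @param markers optional integer subset of marker columns.
#' @return numeric matrix, cells x markers.
#' @export
standardize_genotypes <- function(gp, markers = NULL) {
  X <- gp$p_a
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Prune markers in very high linkage disequilibrium
#'
#' Greedy left-to-right scan per chromosome: a marker is dropped when its
#' posterior correlation with the last retained marker exceeds `r_max`; the
#' first marker of each chromosome is always kept.
#'
#' @param gp a [genotype_posterior()].
#' @param r_max correlation threshold (default 0.999).
#' @return integer vector of retained marker indices.
#' @export
prune_markers <- function(gp, r_max = 0.999) {
  if (ncol(gp$p_a) < 2) stop_arg("need at least two markers to prune")
  keep <- integer(0)
  for (ch in unique(gp$markers$chrom)) {
    idx <- which(gp$markers$chrom == ch)
    last <- idx[1]
    keep <- c(keep, last)
    for (j in idx[-1]) {
      r <- suppressWarnings(cor(gp$p_a[, last], gp$p_a[, j]))
      if (is.na(r) || r <= r_max) {
        keep <- c(keep, j)
        last <- j
      }
    }
  }
  keep
}

#' Filter transcripts by detection
#'
#' Keeps transcripts detected (count >= 1) in at least `min_cells` cells.
#'
#' @param expr an [expression_matrix()].
#' @param min_cells detection threshold (default 128).
#' @return character vector of retained transcript ids.
#' @export
filter_transcripts <- function(expr, min_cells = 128) {
  ncells <- Matrix::colSums(expr$counts > 0)
  keep <- expr$features$feature[ncells >= min_cells]
  if (!length(keep)) stop_format("no transcripts pass the detection filter")
  keep
}

base_design <- function(expr, cells = NULL) {
  meta <- expr$cell_meta
  if (!is.null(cells)) meta <- meta[cells, , drop = FALSE]
  ln_umis <- log(pmax(meta$total_umis, 1))
  b <- factor(meta$batch)
  X <- cbind(`(Intercept)` = 1, ln_umis = ln_umis)
  if (nlevels(b) > 1) {
    Xb <- stats::model.matrix(~b)[, -1, drop = FALSE]
    colnames(Xb) <- paste0("batch_", levels(b)[-1])
    X <- cbind(X, Xb)
  }
  X
}

closest_marker <- function(chrom, pos, markers, retained) {
  vapply(seq_along(chrom), function(i) {
    cand <- retained[markers$chrom[retained] == chrom[i]]
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(markers$pos[cand] - pos[i]))]
  }, integer(1))
}

#' Permute genotype assignment within batches
#'
#' Returns a cell-index permutation in which genotype rows are shuffled
#' against cells within each batch, with all cells of one segregant moving
#' together when `segregant` ids are supplied.
#'
#' @param batch per-cell batch labels.
#' @param segregant optional per-cell segregant ids.
#' @return integer vector `perm` such that permuted genotypes are
#'   `G[perm, ]`.
#' @export
permute_within_batch <- function(batch, segregant = NULL) {
  n <- length(batch)
  if (is.null(segregant)) segregant <- seq_len(n)
  perm <- seq_len(n)
  for (b in unique(batch)) {
    cells_b <- which(batch == b)
    segs <- unique(segregant[cells_b])
    new_seg <- setNames(sample(segs), segs)
    donor_cells <- split(cells_b, segregant[cells_b])
    for (s in segs) {
      mine <- which(segregant[cells_b] == s)
      donors <- donor_cells[[as.character(new_seg[[as.character(s)]])]]
      perm[cells_b[mine]] <- donors[((seq_along(mine) - 1) %% length(donors)) + 1]
    }
  }
  perm
}

#' Local eQTL scan
#'
#' For every transcript passing the detection filter, fits the full NB model
#' (intercept + ln UMIs + batch + standardized posterior at the closest
#' pruned marker) with theta estimated, then the null model without the
#' marker term at that fixed theta. The likelihood-ratio statistic becomes a
#' LOD score; significance is assessed by a permutation FDR in which
#' segregant identity is shuffled against genotype within batch.
#'
#' @param expr an [expression_matrix()].
#' @param gp a [genotype_posterior()] over the same cells.
#' @param pruned integer indices of pruned markers (see [prune_markers()]);
#'   `NULL` prunes internally.
#' @param min_cells transcript detection filter (default 128).
#' @param n_perm number of permutations (default 5).
#' @param segregant optional per-cell segregant ids for the permutation unit.
#' @param seed integer seed for the permutations.
#' @return object of class `local_scan` with elements `table` (tibble:
#'   transcript, marker, chrom, pos, beta, se, theta, lod, fdr), `fdr_map`,
#'   `perm_lod` and `n_perm`.
#' @export
local_scan <- function(expr, gp, pruned = NULL, min_cells = 128, n_perm = 5,
                       segregant = NULL, seed = 1L) {
  if (is.null(pruned)) pruned <- prune_markers(gp)
  keep <- filter_transcripts(expr, min_cells)
  feats <- expr$features[match(keep, expr$features$feature), ]
  G <- standardize_genotypes(gp)
  X0 <- base_design(expr)
  batch <- expr$cell_meta$batch
  cm <- closest_marker(feats$chrom, feats$pos, gp$markers, pruned)
  ok <- !is.na(cm)
  if (any(!ok)) {
    inform(sprintf("local_scan: %d transcript(s) on chromosomes without markers skipped",
                   sum(!ok)))
  }
  feats <- feats[ok, ]; cm <- cm[ok]

  res <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    y <- expr$counts[, feats$feature[i]]
    Xc <- G[, cm[i]]
    full <- fit_nb_glm(y, cbind(X0, marker = Xc))
    null <- cpp_nb_fit(y, X0, full$theta)
    lr <- max(2 * (full$loglik - null$loglik), 0)
    tibble(transcript = feats$feature[i], marker = cm[i],
           chrom = gp$markers$chrom[cm[i]], pos = gp$markers$pos[cm[i]],
           beta = unname(full$coefficients["marker"]),
           se = unname(full$se["marker"]), theta = full$theta,
           lod = lod_from_lr(lr), converged = full$converged)
  })

  set.seed(seed)
  perm_lod <- matrix(0, n_perm, nrow(res))
  for (p in seq_len(n_perm)) {
    perm <- permute_within_batch(batch, segregant)
    for (i in seq_len(nrow(res))) {
      y <- expr$counts[, res$transcript[i]]
      Xc <- G[perm, res$marker[i]]
      fit <- cpp_nb_fit(y, cbind(X0, Xc), res$theta[i])
      null <- cpp_nb_fit(y, X0, res$theta[i])
      perm_lod[p, i] <- lod_from_lr(max(2 * (fit$loglik - null$loglik), 0))
    }
  }
  fdr <- permutation_fdr(res$lod, perm_lod)
  res$fdr <- fdr$adjusted
  structure(list(table = res, fdr_map = fdr$map, perm_lod = perm_lod,
                 n_perm = n_perm),
            class = "local_scan")
}

#' @export
print.local_scan <- function(x, ...) {
  cat(sprintf("<local_scan> %d transcripts, %d at FDR<0.05 (%d permutations)\n",
              nrow(x$table), sum(x$table$fdr < 0.05), x$n_perm))
  invisible(x)
}

#' Genome-wide eQTL scan
#'
#' Scans every pruned marker for every transcript, one marker at a time, in
#' an NB GLM at the transcript's fixed theta; returns a transcripts x markers
#' LOD matrix plus marker effects.
#'
#' @param expr an [expression_matrix()].
#' @param gp a [genotype_posterior()].
#' @param pruned integer indices of scanned markers.
#' @param thetas named vector of per-transcript NB sizes (from
#'   [estimate_theta()] / [local_scan()]); transcripts absent from it are
#'   skipped.
#' @param cells optional logical/integer subset of cells (e.g. one cell-cycle
#'   stage); fewer than `min_cells_stage` cells aborts with a message.
#' @param min_cells_stage minimum cells for a stage-restricted scan
#'   (default 100).
#' @param perm optional cell-index permutation (see
#'   [permute_within_batch()]) applied to the genotype rows.
#' @return object of class `genome_scan`: `lod`, `beta`, `se` matrices
#'   (transcripts x markers), `markers` tibble, `transcripts`.
#' @export
genome_scan <- function(expr, gp, pruned, thetas, cells = NULL,
                        min_cells_stage = 100, perm = NULL) {
  keep <- intersect(names(thetas), expr$features$feature)
  if (!length(keep)) stop_arg("no transcripts with theta estimates")
  G <- standardize_genotypes(gp)[, pruned, drop = FALSE]
  if (!is.null(perm)) G <- G[perm, , drop = FALSE]
  if (!is.null(cells)) {
    idx <- if (is.logical(cells)) which(cells) else cells
    if (length(idx) < min_cells_stage) {
      inform(sprintf("genome_scan: only %d cells in subset; skipping",
                     length(idx)))
      return(NULL)
    }
    G <- G[idx, , drop = FALSE]
    X0 <- base_design(expr, idx)
    counts <- expr$counts[idx, keep, drop = FALSE]
  } else {
    X0 <- base_design(expr)
    counts <- expr$counts[, keep, drop = FALSE]
  }
  # restandardize within the cell subset so effects stay per-SD
  G <- scale(G)
  G[, attr(G, "scaled:scale") == 0] <- 0
  m <- length(pruned)
  lod <- beta <- se <- matrix(NA_real_, length(keep), m,
                              dimnames = list(keep, NULL))
  for (i in seq_along(keep)) {
    y <- counts[, i]
    sc <- cpp_nb_scan(y, X0, G, thetas[[keep[i]]])
    lod[i, ] <- sc$lod
    beta[i, ] <- sc$beta
    se[i, ] <- sc$se
  }
  structure(list(lod = lod, beta = beta, se = se,
                 markers = gp$markers[pruned, ], marker_index = pruned,
                 transcripts = keep),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat(sprintf("<genome_scan> %d transcripts x %d markers, max LOD %.2f\n",
              nrow(x$lod), ncol(x$lod), max(x$lod, na.rm = TRUE)))
  invisible(x)
}

#' Call QTL peaks with 1.5-LOD-drop intervals
#'
#' For each transcript and each scanned chromosome, the peak is the marker
#' with the highest LOD (leftmost on ties) and the confidence interval is the
#' contiguous marker run around the peak with LOD >= peak - `drop`, clipped
#' at the chromosome ends.
#'
#' @param scan a `genome_scan` (or a list with `lod` and `markers`).
#' @param drop LOD drop defining the interval (default 1.5).
#' @return tibble: transcript, chrom, peak_index (column in the scan),
#'   marker (index in the original map), pos, lod, beta, se, ci_left,
#'   ci_right (bp).
#' @export
find_peaks <- function(scan, drop = 1.5) {
  mk <- scan$markers
  purrr::map_dfr(seq_len(nrow(scan$lod)), function(i) {
    purrr::map_dfr(unique(mk$chrom), function(ch) {
      idx <- which(mk$chrom == ch)
      l <- scan$lod[i, idx]
      p <- which.max(l)                      # leftmost tie by which.max
      thr <- l[p] - drop
      left <- p
      while (left > 1 && l[left - 1] >= thr) left <- left - 1
      right <- p
      while (right < length(idx) && l[right + 1] >= thr) right <- right + 1
      tibble(
        transcript = scan$transcripts[i], chrom = ch,
        peak_index = idx[p],
        marker = if (!is.null(scan$marker_index)) scan$marker_index[idx[p]]
                 else idx[p],
        pos = mk$pos[idx[p]], lod = l[p],
        beta = if (!is.null(scan$beta)) scan$beta[i, idx[p]] else NA_real_,
        se = if (!is.null(scan$se)) scan$se[i, idx[p]] else NA_real_,
        ci_left = mk$pos[idx[left]], ci_right = mk$pos[idx[right]]
      )
    })
  })
}

#' Permutation-based FDR for LOD scores
#'
#' For a grid of LOD thresholds t (0.1 to 0.1 + max observed LOD in steps of
#' 0.01), FDR(t) is the average number of permutation statistics exceeding t
#' divided by the number of observed statistics exceeding t, capped at 1 and
#' made monotone non-increasing in t by a running minimum. Observed values
#' are assigned adjusted p-values by linear interpolation of the map.
#'
#' @param observed vector of observed per-transcript (max) LOD scores.
#' @param permuted matrix of permutation LODs, `n_perm` rows x transcripts.
#' @param thresholds optional explicit threshold grid.
#' @return list with `map` (tibble threshold, fdr) and `adjusted` (per
#'   observed value).
#' @export
permutation_fdr <- function(observed, permuted, thresholds = NULL) {
  if (is.null(dim(permuted))) permuted <- matrix(permuted, nrow = 1)
  if (is.null(thresholds)) {
    thresholds <- seq(0.1, 0.1 + max(observed, 0), by = 0.01)
  }
  n_perm <- nrow(permuted)
  raw <- vapply(thresholds, function(t) {
    expected <- mean(vapply(seq_len(n_perm),
                            function(p) sum(permuted[p, ] > t), numeric(1)))
    obs <- sum(observed > t)
    if (obs == 0) 1 else min(expected / obs, 1)
  }, numeric(1))
  fdr <- cummin(raw)                # monotone non-increasing in threshold
  f <- approxfun(thresholds, fdr, rule = 2)
  list(map = tibble(threshold = thresholds, fdr = fdr),
       adjusted = f(observed))
}

#' Sum-LOD combined scan across cell-cycle stages
#'
#' Sums stage-wise LOD matrices (observed and permuted) elementwise, calls
#' peaks on the summed scan and computes the permutation FDR on summed
#' maxima. With a single stage this reduces exactly to the input scan.
#'
#' @param scans named list of `genome_scan` objects on one marker grid.
#' @param perm_scans list (over permutations) of lists of `genome_scan`s with
#'   the same stage names.
#' @return list: `scan` (summed `genome_scan`), `peaks` (tibble with `fdr`),
#'   `fdr_map`.
#' @export
combined_stage_scan <- function(scans, perm_scans) {
  scans <- scans[!vapply(scans, is.null, logical(1))]
  if (!length(scans)) stop_arg("no stage scans supplied")
  ref <- scans[[1]]
  for (s in scans[-1]) {
    if (!identical(s$marker_index, ref$marker_index) ||
        !identical(s$transcripts, ref$transcripts)) {
      stop_arg("stage scans must share the marker grid and transcript set")
    }
  }
  sum_lod <- Reduce(`+`, lapply(scans, `[[`, "lod"))
  combined <- structure(
    list(lod = sum_lod, beta = NULL, se = NULL, markers = ref$markers,
         marker_index = ref$marker_index, transcripts = ref$transcripts),
    class = "genome_scan")
  peaks <- find_peaks(combined)
  obs_max <- vapply(split(peaks$lod, peaks$transcript), max, numeric(1))
  obs_max <- obs_max[combined$transcripts]
  perm_max <- t(vapply(perm_scans, function(ps) {
    ps <- ps[!vapply(ps, is.null, logical(1))]
    s <- Reduce(`+`, lapply(ps, `[[`, "lod"))
    apply(s, 1, max)
  }, numeric(length(combined$transcripts))))
  fdr <- permutation_fdr(obs_max, perm_max)
  peaks$fdr <- fdr$adjusted[match(peaks$transcript, combined$transcripts)]
  list(scan = combined, peaks = peaks, fdr_map = fdr$map)
}

#' Contrast eQTL effects between two cell-cycle stages
#'
#' Z = (beta_i - beta_j) / sqrt(se_i^2 + se_j^2), two-sided normal p, and
#' Benjamini-Hochberg adjustment across all rows (the test family).
#'
#' @param contrasts data frame with columns beta_i, se_i, beta_j, se_j (plus
#'   any identifier columns, carried through).
#' @return the input tibble with z, p and q columns appended.
#' @export
interaction_test <- function(contrasts) {
  contrasts <- as_tibble(contrasts)
  req <- c("beta_i", "se_i", "beta_j", "se_j")
  if (!all(req %in% names(contrasts))) {
    stop_arg("need columns ", paste(req, collapse = ", "))
  }
  if (any(contrasts$se_i <= 0 | contrasts$se_j <= 0)) {
    stop_arg("standard errors must be positive")
  }
  contrasts |>
    mutate(z = (.data$beta_i - .data$beta_j) /
             sqrt(.data$se_i^2 + .data$se_j^2),
           p = 2 * pnorm(-abs(.data$z)),
           q = p.adjust(.data$p, "BH"))
}
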