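# Cell-cycle occupancy QTL mapping: each stage assignment is a binary trait
# mapped by logistic regression with ln(UMIs) as covariate; significance by
# a permutation family-wise error rate threshold on the genome-wide max LOD.
# Chromosome III is excluded because its markers are linked to the mating
# locus, whose allele frequency is strongly distorted in MATa pools.

firth_logistic <- function(y, X, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  beta[1] <- qnorm(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    cov <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
    h <- rowSums((X %*% cov) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(cov %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  info <- crossprod(X, X * w)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(beta = beta, loglik = as.numeric(ll))
}

#' Map cell-cycle occupancy QTLs
#'
#' Treats membership in each cell-cycle stage as a binary trait and scans
#' every pruned marker with a logistic regression of the stage indicator on
#' the standardized genotype posterior plus ln(total UMIs). The LOD is the
#' log10 likelihood ratio against the model without the marker. Markers on
#' the excluded chromosome are never scanned. Quasi-separated markers are
#' refit with Firth-penalized logistic regression and flagged.
#'
#' @param stages per-cell stage labels.
#' @param gp a [genotype_posterior()] over the same cells.
#' @param ln_umis per-cell log total UMIs.
#' @param pruned integer marker indices to scan; `NULL` prunes internally.
#' @param exclude_chrom chromosome name(s) excluded from the scan
#'   (default `"chrIII"`).
#' @return object of class `occupancy_scan`: tibble `table` (stage, marker,
#'   chrom, pos, lod, beta, separated) plus the scanned marker set.
#' @export
occupancy_scan <- function(stages, gp, ln_umis, pruned = NULL,
                           exclude_chrom = "chrIII") {
  if (!all(is.finite(ln_umis))) {
    stop_arg("ln_umis must be finite for every cell")
  }
  if (is.null(pruned)) pruned <- prune_markers(gp)
  scan_idx <- pruned[!gp$markers$chrom[pruned] %in% exclude_chrom]
  if (!length(scan_idx)) stop_arg("no markers left after chromosome exclusion")
  keep_cells <- which(!is.na(stages))
  st <- factor(stages[keep_cells])
  if (nlevels(st) < 2) stop_arg("need at least two stages present")
  G <- standardize_genotypes(gp)[keep_cells, scan_idx, drop = FALSE]
  G <- scale(G); G[, attr(G, "scaled:scale") == 0] <- 0
  X0 <- cbind(1, ln_umis[keep_cells])
  tab <- purrr::map_dfr(levels(st), function(s) {
    y <- as.numeric(st == s)
    sc <- cpp_logistic_scan(y, X0, G)
    lod <- sc$lod; beta <- sc$beta
    sep <- which(sc$separated)
    for (j in sep) {
      f1 <- firth_logistic(y, cbind(X0, G[, j]))
      f0 <- firth_logistic(y, X0)
      lod[j] <- max((f1$loglik - f0$loglik) / log(10), 0)
      beta[j] <- f1$beta[length(f1$beta)]
    }
    tibble(stage = s, marker = scan_idx,
           chrom = gp$markers$chrom[scan_idx],
           pos = gp$markers$pos[scan_idx],
           lod = lod, beta = beta,
           separated = as.logical(sc$separated))
  })
  structure(list(table = tab, markers = scan_idx), class = "occupancy_scan")
}

#' @export
print.occupancy_scan <- function(x, ...) {
  top <- x$table |> group_by(.data$stage) |>
    summarise(max_lod = max(.data$lod), .groups = "drop")
  cat(sprintf("<occupancy_scan> %d markers x %d stages; max LOD per stage:\n",
              length(x$markers), nrow(top)))
  print(as.data.frame(top))
  invisible(x)
}

#' Permutation FWER threshold for the occupancy scan
#'
#' Permutes segregant identity against genotype (cells of one segregant move
#' together), reruns the genome-wide scan per stage, and returns the
#' (1 - alpha) quantile of the genome-wide maximum LOD per stage.
#'
#' @inheritParams occupancy_scan
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha family-wise error rate (default 0.05).
#' @param batch optional per-cell batch labels for permutation strata.
#' @param segregant optional per-cell segregant ids.
#' @param seed integer seed.
#' @return list: `thresholds` (tibble stage, threshold), `max_lods`
#'   (n_perm x stages matrix of permutation maxima).
#' @export
fwer_threshold <- function(stages, gp, ln_umis, pruned = NULL,
                           exclude_chrom = "chrIII", n_perm = 1000,
                           alpha = 0.05, batch = NULL, segregant = NULL,
                           seed = 1L) {
  if (n_perm < 100) stop_arg("n_perm must be at least 100")
  if (!all(is.finite(ln_umis))) {
    stop_arg("ln_umis must be finite for every cell")
  }
  if (is.null(pruned)) pruned <- prune_markers(gp)
  scan_idx <- pruned[!gp$markers$chrom[pruned] %in% exclude_chrom]
  keep_cells <- which(!is.na(stages))
  st <- factor(stages[keep_cells])
  if (is.null(batch)) batch <- rep("batch1", nrow(gp$p_a))
  Gall <- standardize_genotypes(gp)[, scan_idx, drop = FALSE]
  X0 <- cbind(1, ln_umis[keep_cells])
  Y <- vapply(levels(st), function(s) as.numeric(st == s),
              numeric(length(keep_cells)))
  set.seed(seed)
  mx <- matrix(NA_real_, n_perm, nlevels(st),
               dimnames = list(NULL, levels(st)))
  for (p in seq_len(n_perm)) {
    perm <- permute_within_batch(batch, segregant)
    G <- Gall[perm, , drop = FALSE][keep_cells, , drop = FALSE]
    G <- scale(G); G[, attr(G, "scaled:scale") == 0] <- 0
    for (k in seq_len(ncol(Y))) {
      mx[p, k] <- max(cpp_logistic_scan(Y[, k], X0, G)$lod)
    }
  }
  thr <- apply(mx, 2, quantile, probs = 1 - alpha)
  list(thresholds = tibble(stage = levels(st), threshold = unname(thr)),
       max_lods = mx)
}
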