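# Synthetic-data generator: recombinant genotypes from a genetic map,
# NB-distributed UMI counts with planted eQTL / cell-cycle / batch structure,
# allelic reads with sequencing error, doublets, and F1-hybrid allelic counts.
# Every downstream stage of the pipeline is testable against the recorded truth.

#' Map-function recombination fraction
#'
#' Converts a genetic distance in centimorgans to a recombination fraction.
#' Haldane: r = 0.5 (1 - exp(-2 d / 100)); Kosambi: r = 0.5 tanh(2 d / 100).
#'
#' @param d genetic distance(s) in cM, non-negative.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return recombination fraction(s) in \[0, 0.5).
#' @export
recomb_fraction <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop_arg("genetic distances must be non-negative")
  switch(map_function,
    haldane = 0.5 * (1 - exp(-2 * d / 100)),
    kosambi = 0.5 * tanh(2 * d / 100)
  )
}

#' Simulate a uniform genetic map
#'
#' Builds a map with evenly spaced markers per chromosome; genetic positions
#' span \[0, `chrom_length_cM`\] and physical positions span
#' \[1, `chrom_length_bp`\].
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome (>= 2 recommended).
#' @param chrom_length_cM genetic length per chromosome.
#' @param chrom_length_bp physical length per chromosome.
#' @return A [genetic_map()].
#' @export
simulate_map <- function(n_chrom, markers_per_chrom, chrom_length_cM,
                         chrom_length_bp) {
  n_chrom <- check_pos_int(n_chrom, "n_chrom")
  markers_per_chrom <- check_pos_int(markers_per_chrom, "markers_per_chrom")
  if (chrom_length_cM <= 0 || chrom_length_bp <= 0) {
    stop_arg("chromosome lengths must be positive")
  }
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(n_chrom))))
  per <- lapply(chroms, function(ch) {
    m <- markers_per_chrom
    pos <- if (m == 1) round(chrom_length_bp / 2) else
      round(seq(1, chrom_length_bp, length.out = m))
    cm <- if (m == 1) 0 else seq(0, chrom_length_cM, length.out = m)
    tibble(chrom = ch, pos = as.integer(pos), cM = cm)
  })
  genetic_map(bind_rows(per))
}

#' Simulate recombinant haploid segregants
#'
#' Draws genome-wide parental genotypes for haploid progeny of a biparental
#' cross. The first marker of each chromosome is Bernoulli(0.5); adjacent
#' markers switch parent with the map-function recombination fraction of
#' their cM gap; chromosomes are independent.
#'
#' @param map a [genetic_map()].
#' @param n number of segregants.
#' @param seed integer seed.
#' @param map_function see [recomb_fraction()].
#' @return integer matrix (n x markers), 1 = parent-A allele, 0 = parent-B.
#' @export
simulate_segregants <- function(map, n, seed = 1L,
                                map_function = "haldane") {
  n <- check_pos_int(n, "n")
  if (!nrow(map)) stop_arg("empty genetic map")
  set.seed(seed)
  G <- matrix(0L, n, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    g <- matrix(0L, n, m)
    g[, 1] <- rbinom(n, 1L, 0.5)
    if (m > 1) {
      r <- recomb_fraction(diff(map$cM[idx]), map_function)
      for (j in 2:m) {
        sw <- rbinom(n, 1L, r[j - 1])
        g[, j] <- bitwXor(g[, j - 1], sw)
      }
    }
    G[, idx] <- g
  }
  colnames(G) <- paste0(map$chrom, ":", map$pos)
  G
}

default_stage_probs <- function(ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (ploidy == "haploid") {
    c("M/G1" = 0.25, "G1" = 0.15, "G1/S" = 0.20, "S" = 0.15, "G2/M" = 0.25)
  } else {
    c("M/G1" = 0.30, "G1/S" = 0.25, "S" = 0.15, "G2/M" = 0.30)
  }
}

#' Transcript generative models
#'
#' Convenience constructor for the per-transcript models used by
#' [sim_design()]: transcripts are placed at random map positions with
#' log-normal-ish baseline expression and a shared NB size.
#'
#' @param map a [genetic_map()].
#' @param n_transcripts number of transcripts.
#' @param baseline_log_mean mean of the per-transcript baseline
#'   log-expression (log fraction of cell depth); default `log(5e-4)` gives
#'   ~0.75 UMIs per transcript in a 1500-UMI cell.
#' @param baseline_sd SD of baselines across transcripts.
#' @param theta NB size parameter (noise is 1/theta); recycled.
#' @param seed integer seed.
#' @return tibble with columns transcript, chrom, pos, baseline_log_mean,
#'   theta, and empty effect list-columns (stage_effects, batch_effects,
#'   eqtl_effects) to be filled by the caller or by plant helpers.
#' @export
sim_transcripts <- function(map, n_transcripts, baseline_log_mean = log(5e-4),
                            baseline_sd = 0.5, theta = 2, seed = 1L) {
  n_transcripts <- check_pos_int(n_transcripts, "n_transcripts")
  set.seed(seed)
  idx <- sample.int(nrow(map), n_transcripts, replace = TRUE)
  tibble(
    transcript = sprintf("gene%04d", seq_len(n_transcripts)),
    chrom = map$chrom[idx],
    pos = map$pos[idx],
    baseline_log_mean = stats::rnorm(n_transcripts, baseline_log_mean,
                                     baseline_sd),
    theta = rep_len(theta, n_transcripts),
    stage_effects = vector("list", n_transcripts),
    batch_effects = vector("list", n_transcripts),
    eqtl_effects = vector("list", n_transcripts)
  )
}

#' Plant local eQTL effects
#'
#' Assigns a local eQTL (the map marker nearest the transcript) with the given
#' log fold change per parent-A allele to a subset of transcripts.
#'
#' @param transcripts output of [sim_transcripts()].
#' @param map a [genetic_map()].
#' @param which integer indices of transcripts to receive an effect.
#' @param beta log fold change(s), recycled over `which`.
#' @return `transcripts` with filled `eqtl_effects`.
#' @export
plant_local_eqtl <- function(transcripts, map, which, beta) {
  beta <- rep_len(beta, length(which))
  for (k in seq_along(which)) {
    i <- which[k]
    on_chr <- map$chrom == transcripts$chrom[i]
    if (!any(on_chr)) stop_arg("transcript chromosome absent from map")
    j <- base::which(on_chr)[which.min(abs(map$pos[on_chr] - transcripts$pos[i]))]
    transcripts$eqtl_effects[[i]] <- tibble(marker = j, beta = beta[k])
  }
  transcripts
}

#' Plant a trans-eQTL hotspot
#'
#' Gives each of the selected transcripts an eQTL at one shared marker,
#' regardless of the transcript's own location.
#'
#' @inheritParams plant_local_eqtl
#' @param marker integer index into the map of the hotspot marker.
#' @return `transcripts` with appended `eqtl_effects`.
#' @export
plant_hotspot <- function(transcripts, map, which, marker, beta) {
  if (marker < 1 || marker > nrow(map)) stop_arg("hotspot marker outside map")
  beta <- rep_len(beta, length(which))
  for (k in seq_along(which)) {
    i <- which[k]
    eff <- tibble(marker = as.integer(marker), beta = beta[k])
    transcripts$eqtl_effects[[i]] <-
      bind_rows(transcripts$eqtl_effects[[i]], eff)
  }
  transcripts
}

#' Simulation design for a one-pot single-cell eQTL experiment
#'
#' @param genetic_map a [genetic_map()].
#' @param n_segregants number of distinct recombinant segregants in the pool.
#' @param n_cells number of cells captured.
#' @param transcripts transcript models, see [sim_transcripts()].
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-cell total
#'   UMI depth; defaults give a median of ~1500 UMIs per cell.
#' @param batches named numeric vector of batch fractions (must sum to 1).
#' @param stage_probs named baseline stage probabilities (sum to 1).
#' @param occupancy_qtl optional list(marker = integer index, effects = named
#'   per-stage log-odds shifts per parent-A allele).
#' @param site_rates per-site expected reads as a fraction of cell depth;
#'   a scalar is recycled over all map markers. The default spreads 2/3 of
#'   cell depth over the marker set, giving on the order of 1000 informative
#'   UMIs for a 1500-UMI cell.
#' @param error_rate per-read sequencing error probability (default 0.005).
#' @param doublet_rate fraction of barcodes that are doublets (default 0.05).
#' @param seed single integer seed; all sub-streams derive from it.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(genetic_map, n_segregants, n_cells, transcripts,
                       depth_meanlog = log(1500), depth_sdlog = 0.35,
                       batches = c(batch1 = 1), stage_probs = NULL,
                       occupancy_qtl = NULL, site_rates = NULL,
                       error_rate = 0.005, doublet_rate = 0.05, seed = 1L) {
  check_prob(error_rate, "error_rate")
  check_prob(doublet_rate, "doublet_rate")
  n_segregants <- check_pos_int(n_segregants, "n_segregants")
  n_cells <- check_pos_int(n_cells, "n_cells")
  if (is.null(stage_probs)) stage_probs <- default_stage_probs("haploid")
  if (abs(sum(stage_probs) - 1) > 1e-12) {
    stop_arg("stage probabilities must sum to 1")
  }
  if (abs(sum(batches) - 1) > 1e-12) stop_arg("batch fractions must sum to 1")
  if (is.null(site_rates)) site_rates <- (2 / 3) / nrow(genetic_map)
  site_rates <- rep_len(site_rates, nrow(genetic_map))
  if (any(site_rates < 0)) stop_arg("site rates must be non-negative")
  if (any(transcripts$theta <= 0)) stop_arg("theta must be positive")
  for (eff in transcripts$eqtl_effects) {
    if (!is.null(eff) && nrow(eff) &&
        any(eff$marker < 1 | eff$marker > nrow(genetic_map))) {
      stop_arg("eQTL effect marker index outside the genetic map")
    }
  }
  if (!is.null(occupancy_qtl)) {
    if (occupancy_qtl$marker < 1 || occupancy_qtl$marker > nrow(genetic_map)) {
      stop_arg("occupancy QTL marker outside the genetic map")
    }
    occupancy_qtl$effects <-
      occupancy_qtl$effects[names(stage_probs)] |>
      (\(x) { x[is.na(x)] <- 0; names(x) <- names(stage_probs); x })()
  }
  structure(
    list(genetic_map = genetic_map, n_segregants = n_segregants,
         n_cells = n_cells, transcripts = transcripts,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         batches = batches, stage_probs = stage_probs,
         occupancy_qtl = occupancy_qtl, site_rates = site_rates,
         error_rate = error_rate, doublet_rate = doublet_rate,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

effect_of <- function(lst, level) {
  if (is.null(lst) || is.null(names(lst))) return(0)
  i <- match(level, names(lst))
  if (is.na(i)) return(0)
  v <- lst[[i]]
  if (is.null(v) || is.na(v)) 0 else v
}

#' Simulate a one-pot single-cell eQTL experiment
#'
#' Draws a pool of recombinant segregants, captures cells from it, and
#' generates UMI counts (negative binomial, with planted eQTL, batch and
#' cell-cycle-stage effects, depth offsets) and per-site allelic reads
#' (Poisson site depth, binomial allele sampling with sequencing error).
#' A fraction of barcodes are doublets formed by summing two cells' counts.
#' All ground truth is recorded.
#'
#' @param design a [sim_design()].
#' @return list of class `onepot_sim` with elements `expr`
#'   ([expression_matrix()]), `allele` ([allele_counts()]), `genotypes`
#'   (segregant x marker 0/1), `cells` (truth tibble), `transcripts`,
#'   `map`, `design`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  map <- design$genetic_map
  M <- nrow(map)
  set.seed(design$seed)
  G <- simulate_segregants(map, design$n_segregants,
                           seed = design$seed + 1L)
  n <- design$n_cells
  seg <- sample.int(design$n_segregants, n, replace = TRUE)
  batch <- sample(names(design$batches), n, replace = TRUE,
                  prob = design$batches)
  depth <- rlnorm(n, design$depth_meanlog, design$depth_sdlog)

  stage_names <- names(design$stage_probs)
  if (is.null(design$occupancy_qtl)) {
    stage <- sample(stage_names, n, replace = TRUE, prob = design$stage_probs)
  } else {
    g_occ <- G[seg, design$occupancy_qtl$marker]
    logit <- log(design$stage_probs)
    stage <- character(n)
    for (gv in c(0, 1)) {
      idx <- which(g_occ == gv)
      p <- exp(logit + gv * design$occupancy_qtl$effects)
      p <- p / sum(p)
      stage[idx] <- sample(stage_names, length(idx), replace = TRUE, prob = p)
    }
  }

  tr <- design$transcripts
  Tn <- nrow(tr)
  log_mu <- matrix(rep(tr$baseline_log_mean, each = n), n, Tn)
  log_mu <- log_mu + log(depth)
  for (t in seq_len(Tn)) {
    se <- tr$stage_effects[[t]]
    if (!is.null(se)) {
      log_mu[, t] <- log_mu[, t] +
        vapply(stage, function(s) effect_of(se, s), numeric(1))
    }
    be <- tr$batch_effects[[t]]
    if (!is.null(be)) {
      log_mu[, t] <- log_mu[, t] +
        vapply(batch, function(b) effect_of(be, b), numeric(1))
    }
    qe <- tr$eqtl_effects[[t]]
    if (!is.null(qe) && nrow(qe)) {
      for (k in seq_len(nrow(qe))) {
        log_mu[, t] <- log_mu[, t] + qe$beta[k] * G[seg, qe$marker[k]]
      }
    }
  }
  counts <- matrix(0L, n, Tn)
  for (t in seq_len(Tn)) {
    counts[, t] <- rnbinom(n, size = tr$theta[t], mu = exp(log_mu[, t]))
  }

  # allelic reads at map markers
  rate <- outer(depth, design$site_rates)
  D <- matrix(rpois(n * M, rate), n, M)
  gcell <- G[seg, , drop = FALSE]
  pA <- ifelse(gcell == 1L, 1 - design$error_rate, design$error_rate)
  rA <- matrix(rbinom(n * M, D, pA), n, M)
  rB <- D - rA

  doublet <- rbinom(n, 1L, design$doublet_rate) == 1L
  partner <- rep(NA_integer_, n)
  if (any(doublet)) {
    partner[doublet] <- vapply(which(doublet), function(i) {
      sample(setdiff(seq_len(n), i), 1L)
    }, integer(1))
    pd <- partner[doublet]
    counts[doublet, ] <- counts[doublet, , drop = FALSE] +
      counts[pd, , drop = FALSE]
    rA[doublet, ] <- rA[doublet, , drop = FALSE] + rA[pd, , drop = FALSE]
    rB[doublet, ] <- rB[doublet, , drop = FALSE] + rB[pd, , drop = FALSE]
    depth[doublet] <- depth[doublet] + depth[pd]
  }

  barcodes <- sprintf("cell%06d", seq_len(n))
  rownames(counts) <- barcodes
  rownames(rA) <- rownames(rB) <- barcodes
  features <- tr[c("transcript", "chrom", "pos")]
  names(features)[1] <- "feature"
  cells <- tibble(barcode = barcodes, segregant = seg, batch = batch,
                  stage = stage, depth = depth, doublet = doublet,
                  partner_segregant = ifelse(is.na(partner), NA_integer_,
                                             seg[partner]))
  expr <- expression_matrix(
    Matrix::Matrix(counts, sparse = TRUE), features,
    tibble(barcode = barcodes, batch = batch)
  )
  sites <- tibble(chrom = map$chrom, pos = map$pos,
                  alleleA = "A", alleleB = "B")
  allele <- allele_counts(Matrix::Matrix(rA, sparse = TRUE),
                          Matrix::Matrix(rB, sparse = TRUE), sites)
  structure(
    list(expr = expr, allele = allele, genotypes = G, cells = cells,
         transcripts = tr, map = map, design = design),
    class = "onepot_sim"
  )
}

#' Write a simulated experiment to disk
#'
#' Emits the CellRanger-style UMI triplet, Vartrix-style allele matrices,
#' the genetic map, and truth tables.
#'
#' @param sim an `onepot_sim` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  write_umi_matrix(sim$expr, dir)
  write_allele_counts(sim$allele, dir)
  write_genetic_map(sim$map, file.path(dir, "map.tsv"))
  write_tsv_plain(sim$cells, file.path(dir, "truth", "cells.tsv"))
  gt <- as.data.frame(sim$genotypes)
  gt <- cbind(segregant = seq_len(nrow(gt)), gt)
  write_tsv_plain(gt, file.path(dir, "truth", "genotypes.tsv"))
  eff <- purrr::map_dfr(seq_len(nrow(sim$transcripts)), function(i) {
    qe <- sim$transcripts$eqtl_effects[[i]]
    if (is.null(qe) || !nrow(qe)) return(NULL)
    mutate(qe, transcript = sim$transcripts$transcript[i], .before = 1)
  })
  write_tsv_plain(eff, file.path(dir, "truth", "eqtl_effects.tsv"))
  invisible(dir)
}

# F1 hybrid allele-specific simulation ---------------------------------

#' Design for F1-hybrid allele-specific count simulation
#'
#' Generates per-gene allelic counts for a diploid F1 hybrid with
#' allele-specific means and allele-specific NB overdispersion, for studying
#' estimation bias and test calibration.
#'
#' @param n_cells cells per instantiation (default 5000).
#' @param fc_log2 grid of allelic log2 fold changes (alt / ref mean).
#' @param dispersion_fc_log2 grid of log2 fold changes of dispersion
#'   (1/theta, alt / ref).
#' @param expression_level `"median"` (~1 total allelic UMI per cell) or
#'   `"top5"` (~20 per cell), or a numeric total expected allelic count per
#'   cell.
#' @param theta_ref reference-allele NB size (default 2).
#' @param n_reps instantiations per grid point (default 250).
#' @param seed integer seed.
#' @return An object of class `ase_sim_design`.
#' @export
ase_sim_design <- function(n_cells = 5000, fc_log2 = 0,
                           dispersion_fc_log2 = 0,
                           expression_level = "median", theta_ref = 2,
                           n_reps = 250, seed = 1L) {
  n_cells <- check_pos_int(n_cells, "n_cells")
  n_reps <- check_pos_int(n_reps, "n_reps")
  if (!length(fc_log2) || !length(dispersion_fc_log2)) {
    stop_arg("effect grids must be non-empty")
  }
  total <- if (is.character(expression_level)) {
    switch(match.arg(expression_level, c("median", "top5")),
           median = 1, top5 = 20)
  } else as.numeric(expression_level)
  if (total <= 0) stop_arg("expression level must be positive")
  structure(
    list(n_cells = n_cells, fc_log2 = fc_log2,
         dispersion_fc_log2 = dispersion_fc_log2, total = total,
         theta_ref = theta_ref, n_reps = n_reps, seed = as.integer(seed)),
    class = "ase_sim_design"
  )
}

#' Simulate F1-hybrid allelic counts
#'
#' For every grid point (allelic fold change x dispersion fold change) and
#' every instantiation, draws per-cell counts for both alleles from negative
#' binomials with allele-specific mean and allele-specific size. Dispersion is
#' 1/theta, so a dispersion fold change f means theta_alt = theta_ref / f.
#'
#' @param design an [ase_sim_design()].
#' @return tibble with one row per (grid point, rep): columns fc_log2,
#'   dfc_log2, rep, and a `data` list-column of tibbles (cell, count_ref,
#'   count_alt).
#' @export
simulate_f1_hybrid <- function(design) {
  stopifnot(inherits(design, "ase_sim_design"))
  grid <- tidyr::expand_grid(fc_log2 = design$fc_log2,
                             dfc_log2 = design$dispersion_fc_log2)
  set.seed(design$seed)
  out <- purrr::pmap_dfr(grid, function(fc_log2, dfc_log2) {
    fc <- 2^fc_log2
    mu_ref <- design$total / (1 + fc)
    mu_alt <- design$total - mu_ref
    th_ref <- design$theta_ref
    th_alt <- design$theta_ref / (2^dfc_log2)
    purrr::map_dfr(seq_len(design$n_reps), function(r) {
      tibble(
        fc_log2 = fc_log2, dfc_log2 = dfc_log2, rep = r,
        data = list(tibble(
          cell = seq_len(design$n_cells),
          count_ref = rnbinom(design$n_cells, size = th_ref, mu = mu_ref),
          count_alt = rnbinom(design$n_cells, size = th_alt, mu = mu_alt)
        ))
      )
    })
  })
  out
}
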