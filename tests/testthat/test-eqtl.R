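small_scan_sim <- function(n_cells = 800, n_tr = 12, beta = 0.5, seed = 41) {
  map <- simulate_map(3, 8, 80, 6e5)
  tr <- sim_transcripts(map, n_tr, baseline_log_mean = log(2e-3),
                        theta = 2, seed = seed)
  tr <- plant_local_eqtl(tr, map, which = 1:3, beta = beta)
  des <- sim_design(map, n_segregants = 150, n_cells = n_cells,
                    transcripts = tr, doublet_rate = 0, seed = seed + 1)
  sim <- simulate_experiment(des)
  gp <- genotype_posterior(sim$genotypes[sim$cells$segregant, ] + 0, map)
  list(sim = sim, gp = gp, map = map, tr = tr)
}

test_that("prune_markers drops only near-duplicate columns", {
  map <- simulate_map(1, 4, 90, 4e5)
  set.seed(1)
  base <- matrix(runif(50 * 4), 50, 4)
  base[, 2] <- base[, 1]                      # identical pair
  gp <- genotype_posterior(base, map)
  expect_equal(prune_markers(gp), c(1L, 3L, 4L))
  # independent columns all kept
  gp2 <- genotype_posterior(matrix(runif(50 * 4), 50, 4), map)
  expect_equal(prune_markers(gp2), 1:4)
})

test_that("pruning a dense HMM-posterior grid thins the marker spacing", {
  # 0.5-cM grid genotyped from sparse reads: adjacent posteriors are nearly
  # identical, so pruning must coarsen the grid substantially.
  map <- simulate_map(1, 201, 100, 1e6)
  G <- simulate_segregants(map, 120, seed = 2)
  set.seed(3)
  D <- matrix(rpois(120 * 201, 0.12), 120, 201)
  rA <- matrix(rbinom(120 * 201, D, ifelse(G == 1, 0.995, 0.005)), 120, 201)
  ac <- make_ac(rA, D - rA, map)
  gp <- infer_genotypes(ac, map)
  kept <- prune_markers(gp)
  spacing <- diff(gp$markers$cM[kept])
  expect_gt(median(spacing), 0.5)            # strictly coarser than the grid
  expect_lt(median(spacing), 25)             # but still a usable scan grid
})

test_that("filter_transcripts applies the 128-cell detection boundary", {
  counts <- matrix(0, 200, 3)
  counts[1:127, 1] <- 1
  counts[1:128, 2] <- 1
  expr <- make_expr(counts)
  expect_equal(filter_transcripts(expr, 128), "g002")
  expect_error(filter_transcripts(expr, 300), class = "onepot_format_error")
})

test_that("find_peaks applies the 1.5-LOD-drop rule", {
  mk <- tibble::tibble(chrom = "chrI", pos = 1:5 * 100L, cM = 0:4 * 10)
  scan <- structure(list(lod = matrix(c(0, 1, 3, 1, 0), 1),
                         markers = mk, transcripts = "t1"),
                    class = "genome_scan")
  pk <- find_peaks(scan)
  expect_equal(pk$peak_index, 3L)
  expect_equal(pk$ci_left, 300)
  expect_equal(pk$ci_right, 300)

  flat <- structure(list(lod = matrix(rep(2, 5), 1), markers = mk,
                         transcripts = "t1"), class = "genome_scan")
  pf <- find_peaks(flat)
  expect_equal(pf$peak_index, 1L)
  expect_equal(c(pf$ci_left, pf$ci_right), c(100, 500))

  inc <- structure(list(lod = matrix(c(1, 2, 3, 4, 5), 1), markers = mk,
                        transcripts = "t1"), class = "genome_scan")
  pi_ <- find_peaks(inc)
  expect_equal(pi_$peak_index, 5L)
  expect_equal(pi_$ci_right, 500)
  expect_equal(pi_$ci_left, 400)             # 4 >= 5 - 1.5 fails at 3.5? no: 4 >= 3.5
})

test_that("permutation FDR matches the hand-evaluated toy example", {
  fdr <- permutation_fdr(c(1, 2, 3, 4), matrix(c(1, 1, 1, 1), 1))
  m <- fdr$map
  expect_equal(m$fdr[m$threshold == 0.5], 1)
  expect_equal(m$fdr[abs(m$threshold - 2.5) < 1e-9], 0)
  # monotone non-increasing in the threshold
  expect_true(all(diff(m$fdr) <= 1e-12))
  # observed == permuted distribution: FDR ~ 1 at low thresholds
  same <- permutation_fdr(c(1, 2, 3), matrix(c(1, 2, 3), 1))
  expect_equal(same$map$fdr[1], 1)
  # observed far above permuted: adjusted values reach 0
  far <- permutation_fdr(c(10, 12), matrix(c(0.2, 0.3), 1))
  expect_equal(far$adjusted, c(0, 0))
})

test_that("interaction_test computes the stage-contrast Z statistic", {
  out <- interaction_test(tibble::tibble(beta_i = c(1, 1),
                                         beta_j = c(0, 1),
                                         se_i = 0.5, se_j = 0.5))
  expect_equal(out$z[1], 1 / sqrt(0.5), tolerance = 1e-6)
  expect_equal(out$z[2], 0)
  expect_equal(out$p[2], 1)
  z196 <- interaction_test(tibble::tibble(beta_i = 1.96, beta_j = 0,
                                          se_i = sqrt(0.5),
                                          se_j = sqrt(0.5)))
  expect_equal(z196$p, 0.05, tolerance = 1e-3)
  expect_error(interaction_test(tibble::tibble(beta_i = 1, beta_j = 0,
                                               se_i = 0, se_j = 1)),
               class = "onepot_argument_error")
})

test_that("permute_within_batch keeps batches and segregant groups intact", {
  set.seed(4)
  batch <- rep(c("b1", "b2"), each = 50)
  segregant <- sample(1:10, 100, replace = TRUE)
  perm <- permute_within_batch(batch, segregant)
  expect_equal(batch[perm], batch)
  # all cells of one segregant receive cells of a single donor segregant
  donor <- tapply(segregant[perm], paste(batch, segregant),
                  function(x) length(unique(x)))
  expect_true(all(donor == 1))
})

test_that("local_scan finds planted local eQTLs and matches genome_scan", {
  x <- small_scan_sim()
  ls <- local_scan(x$sim$expr, x$gp, n_perm = 2,
                   segregant = x$sim$cells$segregant, seed = 7)
  tab <- ls$table
  planted <- x$tr$transcript[1:3]
  expect_true(all(tab$fdr[tab$transcript %in% planted] < 0.05))
  expect_true(all(tab$beta[tab$transcript %in% planted] > 0))

  # genome_scan at the same marker and theta reproduces the LOD exactly
  thetas <- setNames(tab$theta, tab$transcript)
  pruned <- prune_markers(x$gp)
  gs <- genome_scan(x$sim$expr, x$gp, pruned, thetas)
  for (i in seq_len(nrow(tab))) {
    j <- match(tab$marker[i], pruned)
    expect_lt(abs(unname(gs$lod[tab$transcript[i], j]) - tab$lod[i]), 1e-9)
  }
})

test_that("stage-restricted scans skip undersized subsets", {
  x <- small_scan_sim(n_cells = 300, n_tr = 4)
  thetas <- c(gene0001 = 2)
  expect_message(
    out <- genome_scan(x$sim$expr, x$gp, prune_markers(x$gp), thetas,
                       cells = 1:50, min_cells_stage = 100),
    "skipping")
  expect_null(out)
})

test_that("combined_stage_scan with one stage reduces to the input scan", {
  x <- small_scan_sim(n_cells = 500, n_tr = 6)
  pruned <- prune_markers(x$gp)
  thetas <- setNames(rep(2, 6), x$tr$transcript)
  gs <- genome_scan(x$sim$expr, x$gp, pruned, thetas)
  perm <- permute_within_batch(x$sim$cells$batch, x$sim$cells$segregant)
  ps <- genome_scan(x$sim$expr, x$gp, pruned, thetas, perm = perm)
  comb <- combined_stage_scan(list(all = gs), list(list(all = ps)))
  expect_equal(comb$scan$lod, gs$lod)
  keep <- c("transcript", "chrom", "peak_index", "marker", "pos", "lod",
            "ci_left", "ci_right")
  expect_equal(comb$peaks[keep], find_peaks(gs)[keep], ignore_attr = TRUE)
  # summed LOD dominates each component when two stages are combined
  comb2 <- combined_stage_scan(list(a = gs, b = gs),
                               list(list(a = ps, b = ps)))
  expect_equal(comb2$scan$lod, 2 * gs$lod)
  expect_error(
    combined_stage_scan(list(), list()),
    class = "onepot_argument_error")
})
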