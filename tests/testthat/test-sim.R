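test_that("simulate_map builds uniform grids with the requested shape", {
  m <- simulate_map(1, 2, 100, 1e6)
  expect_equal(nrow(m), 2L)
  expect_equal(m$cM, c(0, 100))
  m2 <- simulate_map(16, 10, 80, 1e6)
  expect_equal(nrow(m2), 160L)
  expect_equal(length(unique(m2$chrom)), 16L)
})

test_that("recomb_fraction evaluates the map functions", {
  expect_equal(recomb_fraction(0), 0)
  expect_equal(recomb_fraction(1), 0.5 * (1 - exp(-0.02)))
  expect_equal(recomb_fraction(1), 0.009901, tolerance = 1e-4)
  expect_lt(abs(recomb_fraction(1e6) - 0.5), 1e-12)
  expect_equal(recomb_fraction(10, "kosambi"), 0.5 * tanh(0.2))
  expect_error(recomb_fraction(-1), class = "onepot_argument_error")
})

test_that("segregant switch frequencies follow the Haldane map function", {
  map <- genetic_map(tibble::tibble(chrom = "chrI", pos = c(1L, 2L, 3L),
                                    cM = c(0, 0, 10)))
  G <- simulate_segregants(map, 20000, seed = 42)
  # zero-cM gap: never switches
  expect_equal(sum(G[, 1] != G[, 2]), 0L)
  # 10-cM gap: switch fraction = 0.5(1 - e^-0.2) = 0.0906 within 3 SE
  r <- 0.5 * (1 - exp(-0.2))
  frac <- mean(G[, 2] != G[, 3])
  expect_lt(abs(frac - r), 3 * sqrt(r * (1 - r) / 20000))
  # allele frequency 0.5 within 3 SE at each marker
  f <- colMeans(G)
  expect_true(all(abs(f - 0.5) < 3 * sqrt(0.25 / 20000)))
})

test_that("unlinked markers switch half the time", {
  map <- genetic_map(tibble::tibble(chrom = "chrI", pos = c(1L, 2L),
                                    cM = c(0, 1e6)))
  G <- simulate_segregants(map, 10000, seed = 7)
  frac <- mean(G[, 1] != G[, 2])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("simulated counts reach the Poisson limit as theta grows", {
  map <- simulate_map(1, 2, 50, 1e5)
  tr <- sim_transcripts(map, 1, baseline_log_mean = log(2e-3),
                        baseline_sd = 0, theta = 1e9, seed = 3)
  des <- sim_design(map, n_segregants = 50, n_cells = 5000, transcripts = tr,
                    depth_sdlog = 0, doublet_rate = 0, seed = 5)
  sim <- simulate_experiment(des)
  y <- as.numeric(sim$expr$counts[, 1])
  expect_lt(abs(var(y) / mean(y) - 1), 0.1)
})

test_that("error-free allelic reads never contradict the genotype", {
  map <- simulate_map(2, 5, 80, 5e5)
  tr <- sim_transcripts(map, 2, seed = 1)
  des <- sim_design(map, n_segregants = 30, n_cells = 300, transcripts = tr,
                    error_rate = 0, doublet_rate = 0, seed = 9)
  sim <- simulate_experiment(des)
  gcell <- sim$genotypes[sim$cells$segregant, ]
  rB <- as.matrix(sim$allele$countsB)
  rA <- as.matrix(sim$allele$countsA)
  expect_equal(sum(rB[gcell == 1L]), 0)
  expect_equal(sum(rA[gcell == 0L]), 0)
})

test_that("a planted local eQTL shifts the empirical means by its log-FC", {
  map <- simulate_map(2, 10, 80, 8e5)
  tr <- sim_transcripts(map, 3, baseline_log_mean = log(3e-3),
                        baseline_sd = 0, theta = 2, seed = 2)
  tr <- plant_local_eqtl(tr, map, which = 1, beta = 0.3)
  des <- sim_design(map, n_segregants = 100, n_cells = 5000,
                    transcripts = tr, doublet_rate = 0, seed = 11)
  sim <- simulate_experiment(des)
  marker <- tr$eqtl_effects[[1]]$marker
  g <- sim$genotypes[sim$cells$segregant, marker]
  y <- as.numeric(sim$expr$counts[, 1])
  # normalize by depth before comparing genotype-class means
  yn <- y / sim$cells$depth
  est <- log(mean(yn[g == 1]) / mean(yn[g == 0]))
  se <- sqrt(var(yn[g == 1]) / mean(yn[g == 1])^2 / sum(g == 1) +
               var(yn[g == 0]) / mean(yn[g == 0])^2 / sum(g == 0))
  expect_lt(abs(est - 0.3), 3 * se)
})

test_that("doublets sum the counts of their two member cells", {
  map <- simulate_map(1, 6, 80, 5e5)
  tr <- sim_transcripts(map, 2, seed = 1)
  des <- sim_design(map, n_segregants = 20, n_cells = 400, transcripts = tr,
                    doublet_rate = 0.2, seed = 13)
  sim <- simulate_experiment(des)
  expect_gt(sum(sim$cells$doublet), 0)
  expect_true(all(!is.na(sim$cells$partner_segregant[sim$cells$doublet])))
  expect_true(all(is.na(sim$cells$partner_segregant[!sim$cells$doublet])))
})

test_that("the experiment simulator is deterministic in its seed", {
  map <- simulate_map(1, 5, 60, 4e5)
  tr <- sim_transcripts(map, 3, seed = 4)
  des <- sim_design(map, n_segregants = 10, n_cells = 50, transcripts = tr,
                    seed = 21)
  s1 <- simulate_experiment(des)
  s2 <- simulate_experiment(des)
  expect_identical(as.matrix(s1$expr$counts), as.matrix(s2$expr$counts))
  expect_identical(as.matrix(s1$allele$countsA), as.matrix(s2$allele$countsA))
  expect_identical(s1$cells, s2$cells)
})

test_that("design validation rejects inconsistent inputs", {
  map <- simulate_map(1, 5, 60, 4e5)
  tr <- sim_transcripts(map, 2, seed = 1)
  expect_error(sim_design(map, 10, 50, tr, error_rate = 1.5),
               class = "onepot_argument_error")
  expect_error(sim_design(map, 10, 50, tr,
                          batches = c(a = 0.6, b = 0.6)),
               class = "onepot_argument_error")
  expect_error(sim_design(map, 10, 50, tr,
                          stage_probs = c("M/G1" = 0.7, "G1" = 0.7)),
               class = "onepot_argument_error")
  bad <- tr
  bad$eqtl_effects[[1]] <- tibble::tibble(marker = 99L, beta = 1)
  expect_error(sim_design(map, 10, 50, bad),
               class = "onepot_argument_error")
})

test_that("F1 hybrid generator matches its allele-level parameters", {
  des <- ase_sim_design(n_cells = 5000, fc_log2 = 0, dispersion_fc_log2 = 0,
                        expression_level = "top5", n_reps = 1, seed = 31)
  d <- simulate_f1_hybrid(des)$data[[1]]
  se <- sqrt(var(d$count_ref) / 5000 + var(d$count_alt) / 5000)
  expect_lt(abs(mean(d$count_ref) - mean(d$count_alt)), 3 * se)

  # dispersion FC 4 at fixed mean: alt-allele variance exceeds ref variance
  des2 <- ase_sim_design(n_cells = 5000, fc_log2 = 0, dispersion_fc_log2 = 2,
                         expression_level = "top5", n_reps = 1, seed = 32)
  d2 <- simulate_f1_hybrid(des2)$data[[1]]
  expect_gt(var(d2$count_alt) / var(d2$count_ref), 1)

  # seeded determinism
  expect_identical(simulate_f1_hybrid(des), simulate_f1_hybrid(des))
})
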