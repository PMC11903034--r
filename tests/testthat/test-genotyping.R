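test_that("filter_sites masks on strict pooled minor-allele fraction", {
  map <- simulate_map(1, 3, 20, 3e4)
  # pooled fractions: 0.02 (masked), 0.50 (kept), exactly 0.05 (kept)
  rA <- rbind(c(2, 50, 5), c(0, 0, 0))
  rB <- rbind(c(98, 50, 95), c(0, 0, 0))
  ac <- make_ac(rA, rB, map)
  out <- filter_sites(ac, 0.05)
  expect_equal(out$mask, c(FALSE, TRUE, TRUE))
  # a coverage-free site is masked too
  ac2 <- make_ac(cbind(rA, c(0, 0)),
                 cbind(rB, c(0, 0)),
                 simulate_map(1, 4, 20, 4e4))
  expect_equal(filter_sites(ac2)$mask, c(FALSE, TRUE, TRUE, FALSE))
  # everything masked is an error, not an empty object
  ac3 <- make_ac(matrix(0, 2, 3), matrix(0, 2, 3), map)
  expect_error(filter_sites(ac3), class = "onepot_format_error")
})

test_that("detect_doublets flags cross-parental allele co-observation", {
  map <- simulate_map(1, 40, 100, 4e5)
  G <- simulate_segregants(map, 200, seed = 5)
  set.seed(6)
  n <- 1000
  half <- n / 2
  seg1 <- sample.int(200, n, replace = TRUE)
  D <- matrix(rpois(n * 40, 4), n, 40)
  gA <- G[seg1, ]
  # first half: pure haploid cells with e = 0 -> all reads match genotype
  rA <- D * gA
  # second half: doublets whose partner differs at 50% of the markers,
  # reads drawn evenly from the two genomes
  gB <- gA
  for (i in (half + 1):n) {
    flip <- sample.int(40, 20)
    gB[i, flip] <- 1L - gB[i, flip]
  }
  mix <- matrix(rbinom(half * 40, D[(half + 1):n, ], 0.5), half, 40)
  rA[(half + 1):n, ] <- mix * gA[(half + 1):n, ] +
    (D[(half + 1):n, ] - mix) * gB[(half + 1):n, ]
  ac <- make_ac(rA, D - rA, map)
  out <- detect_doublets(ac, tau = 0.1)
  expect_equal(sum(out$doublet[1:half]), 0L)       # e=0 singlets never flagged
  expect_gte(mean(out$doublet[(half + 1):n]), 0.99)
  # vacuous threshold
  expect_equal(sum(detect_doublets(ac, tau = 1)$doublet), 0L)
})

test_that("emission probabilities match the error model", {
  e1 <- emission_probs(1, 1, 0.005)
  expect_equal(e1$pA, 0.995)
  expect_equal(e1$pB, 0.005)
  e2 <- emission_probs(1, 2, 0.005)
  expect_equal(e2$pA, e2$pB)
  expect_equal(e2$pA, 2 * 0.005 * 0.995)
  e3 <- emission_probs(10, 10, 0.005)
  expect_equal(e3$pA, 0.995^10)
  expect_error(emission_probs(3, 2), class = "onepot_argument_error")
})

test_that("transition matrices follow the map function", {
  expect_equal(transition_matrix(0), diag(2),
               ignore_attr = TRUE)
  expect_equal(unname(transition_matrix(1e9)),
               matrix(0.5, 2, 2))
  t1 <- transition_matrix(1)
  expect_equal(t1["A", "B"], 0.009901, tolerance = 1e-4)
  expect_equal(rowSums(t1), c(A = 1, B = 1))
})

test_that("single-site posteriors reduce to Bayes' rule", {
  map <- genetic_map(tibble::tibble(chrom = "chrI", pos = 5000L, cM = 0))
  ac <- make_ac(matrix(1, 1, 1), matrix(0, 1, 1), map)
  gp <- infer_genotypes(ac, map)
  expect_equal(unname(gp$p_a[1, 1]), 0.995)
})

test_that("perfectly linked contradictory sites give posterior 1/2", {
  map <- genetic_map(tibble::tibble(chrom = "chrI", pos = c(100L, 200L),
                                    cM = c(0, 0)))
  ac <- make_ac(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2), map)
  gp <- infer_genotypes(ac, map)
  expect_equal(unname(gp$p_a[1, ]), c(0.5, 0.5))
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(8)
  for (case in 1:3) {
    n_mark <- c(8, 12, 10)[case]
    n_chrom <- c(1, 1, 2)[case]
    per <- n_mark / n_chrom
    map <- simulate_map(n_chrom, per, 40, 2e5)
    n_cells <- 4
    D <- matrix(rpois(n_cells * n_mark, 1.2), n_cells, n_mark)
    rA <- matrix(rbinom(n_cells * n_mark, D, 0.6), n_cells, n_mark)
    ac <- make_ac(rA, D - rA, map)
    if (case == 2) ac$mask[c(3, 7)] <- FALSE  # exercise imputation
    gp <- infer_genotypes(ac, map, error_rate = 0.01)
    cm <- onepot:::interp_cM(ac$sites, map)
    for (i in seq_len(n_cells)) {
      oracle <- hmm_oracle_cell(rA[i, ], D[i, ], ac$sites, cm, !ac$mask,
                                e = 0.01)
      expect_lt(max(abs(gp$p_a[i, ] - oracle)), 1e-10)
    }
  }
})

test_that("posteriors are valid probabilities and runs are deterministic", {
  map <- simulate_map(2, 10, 60, 3e5)
  set.seed(9)
  D <- matrix(rpois(60 * 20, 0.8), 60, 20)
  rA <- matrix(rbinom(60 * 20, D, 0.5), 60, 20)
  ac <- make_ac(rA, D - rA, map)
  gp1 <- infer_genotypes(ac, map)
  gp2 <- infer_genotypes(ac, map)
  expect_identical(gp1$p_a, gp2$p_a)
  expect_true(all(gp1$p_a >= 0 & gp1$p_a <= 1))
})

test_that("binarize uses a strict > 0.5 rule", {
  gp <- genotype_posterior(matrix(c(0.6, 0.4, 0.5), 1, 3),
                           tibble::tibble(chrom = "chrI",
                                          pos = c(1L, 2L, 3L),
                                          cM = c(0, 1, 2)))
  expect_equal(unname(binarize(gp)[1, ]), c(1L, 0L, 0L))
})

test_that("match_segregant ranks references by correlation", {
  map <- simulate_map(1, 8, 80, 2e5)
  ref <- rbind(c(1, 1, 0, 0, 1, 0, 1, 0),
               c(0, 1, 1, 0, 0, 1, 0, 1),
               c(1, 0, 1, 1, 0, 0, 1, 1))
  gp <- genotype_posterior(ref[c(1, 3), ] * 0.98 + 0.01, map)
  out <- match_segregant(gp, ref)
  expect_equal(out$match, c(1L, 3L))
  expect_true(all(out$correlation > 0.9))
  # the complement of row 1 correlates at -1 with row 1
  comp <- genotype_posterior(matrix(1 - ref[1, ], 1), map)
  cc <- match_segregant(comp, ref[1, , drop = FALSE])
  expect_equal(unname(cc$correlation), -1)
  # constant posteriors yield no match
  flatgp <- genotype_posterior(matrix(0.5, 1, 8), map)
  expect_message(fm <- match_segregant(flatgp, ref), "constant")
  expect_true(is.na(fm$match))
})

test_that("uniqueness_filter keeps the deepest cell of each duplicate group", {
  # distinct genotype vectors by construction: binary encodings of 1..k
  enc <- function(k, bits) t(vapply(k, function(x) {
    as.integer(intToBits(x))[seq_len(bits)]
  }, integer(bits)))
  G <- enc(1:4, 12)
  hard <- G[c(1, 1, 2, 3), ]
  umis <- c(1000, 500, 800, 700)
  out <- uniqueness_filter(hard, umis)       # 50% duplicated > 10% trigger
  expect_equal(out$retained, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$duplicate, c(TRUE, TRUE, FALSE, FALSE))

  # all distinct: nothing filtered
  out2 <- uniqueness_filter(G, c(4, 3, 2, 1))
  expect_true(all(out2$retained))

  # duplicate fraction at/below the trigger: filtering stays off
  G40 <- enc(1:40, 30)
  hard3 <- rbind(G40, G40[1, , drop = FALSE]) # 2 of 41 cells ~ 4.9%
  out3 <- uniqueness_filter(hard3, seq_len(41))
  expect_true(all(out3$retained))
  expect_equal(sum(out3$duplicate), 2L)
})
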