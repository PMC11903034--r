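test_that("bin_genome tiles chromosomes with half-open bins", {
  bins <- bin_genome(c(chrA = 120000))
  expect_equal(bins$start, c(0, 50000, 100000))
  expect_equal(bins$end, c(50000, 100000, 120000))
  # no overlap, full coverage
  expect_true(all(bins$end[-3] == bins$start[-1]))
  expect_equal(sum(bins$end - bins$start), 120000)
  expect_error(bin_genome(c(chrA = -5)), class = "onepot_argument_error")
})

test_that("count_distant applies the cross-chromosome and boundary rules", {
  bins <- bin_genome(c(chrIV = 200000, chrII = 200000))
  peaks <- tibble::tibble(
    transcript = c("t1", "t2", "t3"),
    chrom = c("chrIV", "chrIV", "chrIV"),
    pos = c(10000, 10000, 50000),
    lod = c(5, 5, 5), ci_left = 0, ci_right = 60000)
  tc <- c(t1 = "chrII", t2 = "chrIV", t3 = "chrII")
  out <- count_distant(peaks, bins, tc)
  cnt <- out$bins
  # t1: distant, first chrIV bin; t2: same chromosome, not counted;
  # t3: exactly 50,000 -> second bin by the half-open convention
  expect_equal(cnt$count[cnt$chrom == "chrIV" & cnt$bin == 0], 1)
  expect_equal(cnt$count[cnt$chrom == "chrIV" & cnt$bin == 1], 1)
  expect_equal(sum(cnt$count), 2)
  expect_equal(sort(out$members$transcript), c("t1", "t3"))

  bad <- peaks; bad$pos[1] <- 999999
  expect_error(count_distant(bad, bins, tc), class = "onepot_format_error")
  expect_error(count_distant(peaks, bins, tc[1:2]),
               class = "onepot_argument_error")
})

test_that("per-bin counts conserve the number of distant eQTLs", {
  set.seed(1)
  bins <- bin_genome(c(chrI = 3e5, chrII = 3e5, chrIII = 3e5))
  n <- 60
  peaks <- tibble::tibble(
    transcript = sprintf("t%02d", 1:n),
    chrom = sample(c("chrI", "chrII", "chrIII"), n, replace = TRUE),
    pos = runif(n, 0, 3e5 - 1),
    lod = runif(n, 3, 10), ci_left = 0, ci_right = 1)
  tc <- setNames(sample(c("chrI", "chrII", "chrIII"), n, replace = TRUE),
                 peaks$transcript)
  out <- count_distant(peaks, bins, tc)
  expect_equal(sum(out$bins$count), sum(tc[peaks$transcript] != peaks$chrom))
  expect_equal(sum(out$bins$count), nrow(out$members))
})

test_that("the Poisson bin test matches the tail oracle and merges regions", {
  bins <- bin_genome(c(chrI = 50000 * 20))
  counts <- rep(2L, 20)
  counts[8:10] <- c(10L, 12L, 10L)           # three adjacent hot bins
  counts[15] <- 0L
  binned <- dplyr::mutate(bins, count = counts)
  out <- poisson_hotspot_test(binned)
  lambda <- sum(counts) / 20
  expect_equal(out$p, ppois(counts - 1, lambda, lower.tail = FALSE))
  expect_equal(out$p_adj, pmin(1, out$p * 20))
  expect_true(all(out$p_adj >= out$p))
  expect_equal(out$p[counts == 0], 1)
  # one merged region spanning the three adjacent significant bins
  expect_equal(unique(na.omit(out$region)), 1L)
  expect_equal(which(!is.na(out$region)), 8:10)

  # the quoted oracle example: lambda = 2, observed 10
  expect_equal(ppois(9, 2, lower.tail = FALSE), 4.649808e-05,
               tolerance = 1e-6)

  empty <- dplyr::mutate(bins, count = 0L)
  expect_message(res <- poisson_hotspot_test(empty), "no distant")
  expect_false(any(res$significant))
})

test_that("hotspot confidence intervals follow the percentile-plus-2 rule", {
  markers <- tibble::tibble(chrom = "chrI", pos = seq(0, 1e6, by = 2e4))
  # 20 identical member CIs [a, b]
  mem <- tibble::tibble(lod = 21:40, ci_left = 300000, ci_right = 400000)
  ci <- hotspot_ci(mem, markers)
  expect_equal(unname(ci[1]), 260000)  # two markers left of 300,000
  expect_equal(unname(ci[2]), 440000)  # two markers right of 400,000

  # a single member behaves the same way
  ci1 <- hotspot_ci(mem[1, ], markers)
  expect_equal(unname(ci1), unname(ci))

  # staggered members: percentile bounds match quantile(type = 7), and only
  # the 20 highest-LOD members count
  set.seed(2)
  mem2 <- tibble::tibble(lod = 1:30,
                         ci_left = seq(100000, 390000, by = 10000),
                         ci_right = seq(400000, 690000, by = 10000))
  top <- mem2[order(-mem2$lod)[1:20], ]
  ci2 <- hotspot_ci(mem2, markers)
  ql <- quantile(top$ci_left, 0.1, type = 7, names = FALSE)
  qr <- quantile(top$ci_right, 0.9, type = 7, names = FALSE)
  expect_lte(ci2[1], ql)
  expect_gte(ci2[2], qr)
  mpos <- markers$pos
  expect_equal(unname(ci2[1]), rev(mpos[mpos < ql])[2])
  expect_equal(unname(ci2[2]), mpos[mpos > qr][2])

  # clipping at the chromosome ends
  edge <- tibble::tibble(lod = 1, ci_left = 10000, ci_right = 995000)
  cie <- hotspot_ci(edge, markers)
  expect_equal(unname(cie), c(0, 1e6))
  expect_error(hotspot_ci(mem[0, ], markers),
               class = "onepot_argument_error")
})

test_that("detect_hotspots is invariant to peak ordering", {
  set.seed(3)
  chrlen <- c(chrI = 5e5, chrII = 5e5)
  markers <- tibble::tibble(chrom = rep(c("chrI", "chrII"), each = 26),
                            pos = rep(seq(0, 5e5, by = 2e4), 2))
  n <- 45
  peaks <- tibble::tibble(
    transcript = sprintf("t%02d", 1:n),
    chrom = "chrI",
    pos = c(runif(35, 120000, 140000), runif(10, 0, 5e5)),
    lod = runif(n, 3, 15))
  peaks$ci_left <- pmax(peaks$pos - 30000, 0)
  peaks$ci_right <- pmin(peaks$pos + 30000, 5e5)
  tc <- setNames(rep("chrII", n), peaks$transcript)
  h1 <- detect_hotspots(peaks, chrlen, tc, markers)
  h2 <- detect_hotspots(peaks[sample.int(n), ], chrlen, tc, markers)
  expect_equal(h1$hotspots, h2$hotspots)
  expect_gte(nrow(h1$hotspots), 1L)
  main <- h1$hotspots[which.max(h1$hotspots$count), ]
  expect_true(main$start <= 140000 && main$end >= 120000)
  expect_true(main$ci_left <= 120000 && main$ci_right >= 140000)
})
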