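# Trans-eQTL hotspot detection: 50-kb genomic bins, Poisson test on the
# distant-eQTL count per bin with Bonferroni correction, merging of adjacent
# significant bins, and percentile-based hotspot confidence intervals.

#' Tile the genome into fixed-size bins
#'
#' Half-open bins `[start, end)` per chromosome; the last bin of each
#' chromosome is truncated to the chromosome length.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 50000).
#' @return tibble: chrom, bin (0-based index within chromosome), start, end.
#' @export
bin_genome <- function(chrom_lengths, bin_size = 50000) {
  if (any(chrom_lengths <= 0)) stop_arg("chromosome lengths must be positive")
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- bin_size * (seq_len(ceiling(len / bin_size)) - 1)
    tibble(chrom = ch, bin = seq_along(starts) - 1L, start = starts,
           end = pmin(starts + bin_size, len))
  })
}

#' Count distant eQTLs per genomic bin
#'
#' A peak is assigned to the bin containing its peak-marker coordinate and is
#' counted iff its transcript lies on a different chromosome than the bin.
#'
#' @param peaks tibble of significant eQTL peaks with columns transcript,
#'   chrom (scanned chromosome), pos (peak marker bp) and, optionally, lod,
#'   ci_left, ci_right (used later for hotspot CIs).
#' @param bins output of [bin_genome()].
#' @param transcript_chrom named vector mapping transcript id to its
#'   chromosome.
#' @return list: `bins` (the bin tibble with a `count` column), `members`
#'   (peaks annotated with their bin).
#' @export
count_distant <- function(peaks, bins, transcript_chrom) {
  bin_size <- max(bins$end - bins$start)
  tc <- transcript_chrom[peaks$transcript]
  if (any(is.na(tc))) stop_arg("transcript chromosome missing for some peaks")
  b <- floor(peaks$pos / bin_size)
  # a peak at exactly the chromosome end (1-based inclusive coordinates)
  # belongs to the last half-open bin
  last_bin <- tapply(bins$bin, bins$chrom, max)
  chrom_end <- tapply(bins$end, bins$chrom, max)
  known <- peaks$chrom %in% bins$chrom
  clamp <- known & peaks$pos <= chrom_end[peaks$chrom] &
    b > last_bin[peaks$chrom]
  b[clamp] <- last_bin[peaks$chrom[clamp]]
  key <- paste(peaks$chrom, b)
  bin_key <- paste(bins$chrom, bins$bin)
  idx <- match(key, bin_key)
  if (any(is.na(idx))) {
    stop_format("eQTL peak outside all genomic bins (coordinate mismatch)")
  }
  distant <- tc != peaks$chrom
  members <- peaks |>
    mutate(transcript_chrom = unname(tc), bin_row = idx, distant = distant) |>
    filter(distant)
  counts <- tabulate(members$bin_row, nbins = nrow(bins))
  list(bins = mutate(bins, count = counts), members = members)
}

#' Poisson test for hotspot bins
#'
#' Under the null every bin receives on average lambda = (total distant
#' eQTLs) / (number of bins) linking transcripts. Per bin,
#' p = P(Poisson(lambda) >= count), Bonferroni-adjusted by the number of
#' bins; adjacent significant bins on one chromosome merge into a hotspot
#' region.
#'
#' @param binned output of [count_distant()] (or a bin tibble with `count`).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return tibble of bins with p, p_adj, significant, and `region` id
#'   (NA for non-significant bins).
#' @export
poisson_hotspot_test <- function(binned, alpha = 0.05) {
  bins <- if (is.list(binned) && !is.data.frame(binned)) binned$bins else binned
  if (sum(bins$count) == 0) {
    inform("poisson_hotspot_test: no distant eQTLs; empty result")
    return(mutate(bins, p = 1, p_adj = 1, significant = FALSE,
                  region = NA_integer_))
  }
  n_bins <- nrow(bins)
  lambda <- sum(bins$count) / n_bins
  p <- ppois(bins$count - 1, lambda, lower.tail = FALSE)
  p_adj <- pmin(1, p * n_bins)
  sig <- p_adj < alpha
  region <- rep(NA_integer_, n_bins)
  rid <- 0L
  for (i in seq_len(n_bins)) {
    if (!sig[i]) next
    if (i > 1 && sig[i - 1] && bins$chrom[i] == bins$chrom[i - 1] &&
        bins$bin[i] == bins$bin[i - 1] + 1L) {
      region[i] <- region[i - 1]
    } else {
      rid <- rid + 1L
      region[i] <- rid
    }
  }
  mutate(bins, p = p, p_adj = p_adj, significant = sig, region = region)
}

#' Hotspot confidence interval from member eQTLs
#'
#' Takes the up-to-20 highest-LOD member peaks of a hotspot, uses the 10th
#' percentile of their left CI bounds and the 90th percentile of their right
#' CI bounds (linear-interpolation percentiles), and conservatively extends
#' the interval by two markers on either side of the pruned grid, clipped to
#' the chromosome's marker range.
#'
#' @param members tibble of member peaks with columns lod, ci_left, ci_right
#'   (bp) on one chromosome.
#' @param markers tibble of the pruned marker grid (chrom, pos) for that
#'   chromosome.
#' @return numeric `c(left, right)` in bp.
#' @export
hotspot_ci <- function(members, markers) {
  if (!nrow(members)) stop_arg("no member peaks")
  top <- members |> arrange(dplyr::desc(.data$lod)) |> utils::head(20)
  left <- quantile(top$ci_left, 0.10, type = 7, names = FALSE)
  right <- quantile(top$ci_right, 0.90, type = 7, names = FALSE)
  mpos <- sort(markers$pos)
  below <- mpos[mpos < left]
  above <- mpos[mpos > right]
  left2 <- if (length(below) >= 2) below[length(below) - 1] else mpos[1]
  right2 <- if (length(above) >= 2) above[2] else mpos[length(mpos)]
  c(left = min(left, left2), right = max(right, right2))
}

#' Detect trans-eQTL hotspots
#'
#' Convenience wrapper: bins the genome, counts distant eQTLs, runs the
#' Poisson/Bonferroni test, merges adjacent significant bins and computes a
#' confidence interval per merged hotspot.
#'
#' @param peaks significant eQTL peaks (see [count_distant()]).
#' @param chrom_lengths named chromosome lengths.
#' @param transcript_chrom named transcript -> chromosome map.
#' @param markers pruned marker grid tibble (chrom, pos) for CI extension.
#' @param bin_size bin width (default 50000).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @return list: `bins` (tested bins), `hotspots` (one row per merged
#'   region: chrom, start, end, count, ci_left, ci_right, n_transcripts),
#'   `members` (distant peaks with bin and region).
#' @export
detect_hotspots <- function(peaks, chrom_lengths, transcript_chrom, markers,
                            bin_size = 50000, alpha = 0.05) {
  bins <- bin_genome(chrom_lengths, bin_size)
  cd <- count_distant(peaks, bins, transcript_chrom)
  tested <- poisson_hotspot_test(cd, alpha)
  members <- mutate(cd$members, region = tested$region[.data$bin_row])
  if (all(is.na(tested$region))) {
    hs <- tibble(region = integer(), chrom = character(),
                 start = numeric(), end = numeric(), count = integer(),
                 ci_left = numeric(), ci_right = numeric(),
                 n_transcripts = integer())
    return(list(bins = tested, hotspots = hs, members = members))
  }
  hs <- tested |>
    filter(!is.na(.data$region)) |>
    group_by(.data$region, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              count = sum(.data$count), .groups = "drop")
  if (nrow(hs)) {
    cis <- purrr::map(hs$region, function(r) {
      mem <- filter(members, .data$region == r)
      hotspot_ci(mem, filter(markers, .data$chrom == hs$chrom[hs$region == r]))
    })
    hs$ci_left <- vapply(cis, `[[`, numeric(1), 1)
    hs$ci_right <- vapply(cis, `[[`, numeric(1), 2)
    hs$n_transcripts <- vapply(hs$region, function(r) {
      length(unique(members$transcript[members$region == r & !is.na(members$region)]))
    }, integer(1))
  }
  list(bins = tested, hotspots = hs, members = members)
}
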