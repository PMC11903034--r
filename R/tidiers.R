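# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# scan results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.nb_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$coefficients / x$se),
         p.value = 2 * pnorm(-abs(unname(x$coefficients / x$se))))
}

#' @export
glance.nb_fit <- function(x, ...) {
  tibble(logLik = x$loglik, theta = x$theta, theta_fixed = x$theta_fixed,
         nobs = x$n, df = x$df, converged = x$converged)
}

#' @export
tidy.ase_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$coefficients / x$se),
         p.value = 2 * pnorm(-abs(unname(x$coefficients / x$se))))
}

#' @export
glance.ase_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = 2 * x$n_cells,
         allele_lfc = x$allele_lfc, noise_fc = x$noise_fc,
         converged = x$converged)
}

#' @export
tidy.local_scan <- function(x, ...) x$table

#' @export
glance.local_scan <- function(x, ...) {
  tibble(n_transcripts = nrow(x$table),
         n_fdr05 = sum(x$table$fdr < 0.05),
         n_perm = x$n_perm)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline facet_grid labs theme_bw vars
#' @export
ggplot2::autoplot

#' Plot LOD curves from a genome scan
#'
#' @param object a `genome_scan`.
#' @param transcripts transcripts to draw (default: the 5 with highest LOD).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.genome_scan <- function(object, transcripts = NULL, ...) {
  if (is.null(transcripts)) {
    mx <- apply(object$lod, 1, max)
    transcripts <- object$transcripts[order(-mx)[seq_len(min(5, length(mx)))]]
  }
  df <- purrr::map_dfr(transcripts, function(tr) {
    i <- match(tr, object$transcripts)
    mutate(object$markers, transcript = tr, lod = object$lod[i, ])
  })
  ggplot(df, aes(x = .data$pos / 1e3, y = .data$lod,
                 colour = .data$transcript)) +
    geom_line() +
    facet_grid(cols = vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (kb)", y = "LOD") +
    theme_bw()
}

#' eQTL map: peak position against transcript position
#'
#' The classic two-dimensional eQTL plot; local eQTLs fall on the diagonal,
#' trans hotspots appear as vertical bands.
#'
#' @param peaks significant peak tibble (transcript, chrom, pos, lod).
#' @param features tibble mapping transcripts to chrom/pos.
#' @return a ggplot.
#' @export
plot_eqtl_map <- function(peaks, features) {
  f <- features[match(peaks$transcript, features$feature), ]
  df <- mutate(peaks, t_chrom = f$chrom, t_pos = f$pos)
  ggplot(df, aes(x = .data$pos / 1e3, y = .data$t_pos / 1e3)) +
    geom_point(alpha = 0.6, size = 0.8) +
    facet_grid(rows = vars(.data$t_chrom), cols = vars(.data$chrom),
               scales = "free", space = "free") +
    labs(x = "eQTL peak position (kb)", y = "transcript position (kb)") +
    theme_bw()
}

#' Plot distant-eQTL counts per genomic bin
#'
#' @param bins output of [poisson_hotspot_test()].
#' @param alpha significance level used to draw the detection threshold.
#' @return a ggplot.
#' @export
plot_hotspot_bins <- function(bins, alpha = 0.05) {
  lambda <- sum(bins$count) / nrow(bins)
  thr <- stats::qpois(1 - alpha / nrow(bins), lambda) + 1
  ggplot(bins, aes(x = (.data$start + .data$end) / 2e3, y = .data$count,
                   fill = .data$significant)) +
    geom_col(width = max(bins$end - bins$start) / 1e3) +
    geom_hline(yintercept = thr, colour = "red", linetype = 2) +
    facet_grid(cols = vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (kb)", y = "distant eQTLs per bin") +
    theme_bw()
}
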