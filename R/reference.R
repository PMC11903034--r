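# Worked-example arithmetic on headline counts from published one-pot yeast
# cross experiments. These small reference tables let the contingency and
# percentage computations be rerun without any sequencing data.

#' Headline eQTL counts from the published one-pot yeast experiments
#'
#' Counts of mapped eQTLs and hotspots across the three yeast crosses used
#' as worked-example inputs: local eQTLs with significant cell-cycle
#' interactions (116 of 2945), distant eQTLs with interactions (790 of
#' 3238), bulk-experiment support of one-pot local eQTLs in the lab x wine
#' cross (717 significant and 825 direction-consistent of 1031), and
#' cross-specificity of hotspots (14 of 25 unique to one cross).
#'
#' @return a named list of integer counts.
#' @export
reference_eqtl_counts <- function() {
  list(
    local_interacting = 116L, local_total = 2945L,
    distant_interacting = 790L, distant_total = 3238L,
    local_onepot = 1031L, local_bulk_significant = 717L,
    local_bulk_supported = 825L,
    hotspots_total = 25L, hotspots_unique = 14L
  )
}

#' Cell-cycle interaction enrichment of distant vs local eQTLs
#'
#' Builds the 2x2 table of (interacting / non-interacting) x (distant /
#' local) eQTLs and runs Fisher's exact test; the odds ratio measures how
#' much more often distant eQTL effects depend on cell-cycle stage.
#'
#' @param local_sig,local_total interacting and total local eQTLs.
#' @param distant_sig,distant_total interacting and total distant eQTLs.
#' @return tibble: odds_ratio (conditional MLE), sample_odds_ratio,
#'   p.value, conf.low, conf.high.
#' @export
cc_interaction_enrichment <- function(local_sig = 116, local_total = 2945,
                                      distant_sig = 790,
                                      distant_total = 3238) {
  tab <- matrix(c(distant_sig, distant_total - distant_sig,
                  local_sig, local_total - local_sig), 2, 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  tibble(
    odds_ratio = unname(ft$estimate),
    sample_odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
    p.value = ft$p.value,
    conf.low = ft$conf.int[1], conf.high = ft$conf.int[2]
  )
}
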