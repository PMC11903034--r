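# Genome-wide genotyping of single cells from sparse allelic UMI counts with
# a two-state HMM (parent A vs parent B), plus the surrounding QC: MAF site
# masking, doublet flagging, segregant matching and uniqueness filtering.

#' Mask sites with distorted pooled allele frequency
#'
#' Sites whose pooled minor-allele read fraction falls below `maf_threshold`
#' are treated as missing for genotype inference (their positions are kept so
#' genotypes there are imputed through the HMM transitions). Sites with no
#' reads at all are likewise masked.
#'
#' @param ac an [allele_counts()] object.
#' @param maf_threshold minor allele frequency cutoff; strictly-below is
#'   masked (default 0.05).
#' @return `ac` with an updated `mask`.
#' @export
filter_sites <- function(ac, maf_threshold = 0.05) {
  check_prob(maf_threshold, "maf_threshold")
  a <- Matrix::colSums(ac$countsA)
  b <- Matrix::colSums(ac$countsB)
  tot <- a + b
  f <- ifelse(tot > 0, pmin(a, b) / tot, NA_real_)
  mask <- !is.na(f) & f >= maf_threshold
  if (!any(mask)) {
    stop_format("all sites masked by the MAF filter; inspect allele counts")
  }
  ac$mask <- mask
  ac
}

#' Flag doublet cells from cross-parental allele co-observation
#'
#' For each cell, among sites with total depth >= 2, computes the fraction at
#' which both parental alleles were observed; cells exceeding `tau` are
#' flagged as doublets. Haploid cells should essentially never show both
#' alleles at one site except through sequencing error.
#'
#' @param ac an [allele_counts()] object.
#' @param tau flag threshold on the het-site fraction (default 0.1).
#' @return tibble with columns barcode, n_sites (depth >= 2), het_fraction,
#'   doublet.
#' @export
detect_doublets <- function(ac, tau = 0.1) {
  check_prob(tau, "tau")
  D <- ac$countsA + ac$countsB
  informative <- D >= 2
  het <- informative & (ac$countsA > 0) & (ac$countsB > 0)
  n_inf <- Matrix::rowSums(informative)
  n_het <- Matrix::rowSums(het)
  frac <- ifelse(n_inf > 0, n_het / n_inf, 0)
  if (any(n_inf == 0)) {
    inform(sprintf("detect_doublets: %d cell(s) had no depth>=2 sites; left unflagged",
                   sum(n_inf == 0)))
  }
  tibble(barcode = rownames(ac$countsA), n_sites = as.integer(n_inf),
         het_fraction = frac, doublet = n_inf > 0 & frac > tau)
}

#' Emission probabilities for allelic read counts
#'
#' Probability of observing `r` parent-A reads out of `D` total reads at an
#' informative site, under binomial sampling with per-read error `e`:
#' P(Y | g = A) = C(D, r) (1-e)^r e^(D-r) and
#' P(Y | g = B) = C(D, r) e^r (1-e)^(D-r).
#'
#' @param r parent-A read count(s).
#' @param D total read count(s), `r <= D`.
#' @param e per-read error probability.
#' @return tibble with columns pA, pB.
#' @export
emission_probs <- function(r, D, e = 0.005) {
  if (any(r < 0) || any(D < 0) || any(r > D)) {
    stop_arg("need 0 <= r <= D")
  }
  check_prob(e, "e")
  tibble(pA = dbinom(r, D, 1 - e), pB = dbinom(r, D, e))
}

#' Transition matrix between parental genotypes
#'
#' 2x2 stochastic matrix for a cM gap `d`; the off-diagonal entry is the
#' map-function recombination fraction.
#'
#' @param d genetic distance in cM (scalar, >= 0).
#' @param map_function see [recomb_fraction()].
#' @return 2x2 matrix with rows/cols (A, B).
#' @export
transition_matrix <- function(d, map_function = "haldane") {
  if (length(d) != 1 || d < 0) stop_arg("d must be a single non-negative distance")
  r <- recomb_fraction(d, map_function)
  matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE,
         dimnames = list(c("A", "B"), c("A", "B")))
}

interp_cM <- function(sites, map) {
  cm <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    j <- map$chrom == ch
    if (!any(j)) stop_arg("chromosome absent from genetic map: ", ch)
    if (sum(j) == 1) {
      cm[i] <- map$cM[j]
    } else {
      f <- approxfun(map$pos[j], map$cM[j], rule = 2)
      cm[i] <- f(sites$pos[i])
    }
  }
  cm
}

#' Infer per-cell genotypes with a two-state HMM
#'
#' Runs forward-backward per chromosome, independently per cell, over the
#' allele-informative sites. Priors are `prior` for parent A at the first
#' site; emissions follow [emission_probs()]; transitions use the
#' map-function recombination fraction of the cM gap between adjacent sites
#' (cM positions linearly interpolated from the genetic map). Masked sites
#' and sites with zero depth contribute flat emissions, so their genotypes
#' are imputed through the transitions. The recursion is scaled per step for
#' numerical stability.
#'
#' @param ac an [allele_counts()] object (typically after [filter_sites()]).
#' @param map a [genetic_map()].
#' @param error_rate per-read error probability (default 0.005).
#' @param prior prior probability of the parent-A genotype (default 0.5).
#' @param map_function see [recomb_fraction()].
#' @return A [genotype_posterior()] whose markers are the sites of `ac`.
#' @export
infer_genotypes <- function(ac, map, error_rate = 0.005, prior = 0.5,
                            map_function = "haldane") {
  check_prob(error_rate, "error_rate")
  check_prob(prior, "prior")
  e <- error_rate
  sites <- ac$sites
  cm <- interp_cM(sites, map)
  n <- nrow(ac$countsA)
  M <- nrow(sites)
  rA <- as.matrix(ac$countsA)
  D <- rA + as.matrix(ac$countsB)
  # log emissions (binomial coefficient cancels under per-step normalization)
  la <- rA * log(1 - e) + (D - rA) * log(e)
  lb <- rA * log(e) + (D - rA) * log(1 - e)
  flat <- matrix(rep(!ac$mask, each = n), n, M) | D == 0
  la[flat] <- 0
  lb[flat] <- 0
  mx <- pmax(la, lb)
  EA <- exp(la - mx)
  EB <- exp(lb - mx)

  P <- matrix(NA_real_, n, M)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    m <- length(idx)
    r <- if (m > 1) recomb_fraction(diff(cm[idx]), map_function) else numeric(0)
    fA <- matrix(0, n, m); fB <- matrix(0, n, m)
    a <- prior * EA[, idx[1]]; b <- (1 - prior) * EB[, idx[1]]
    s <- a + b
    fA[, 1] <- a / s; fB[, 1] <- b / s
    if (m > 1) {
      for (j in 2:m) {
        a <- (fA[, j - 1] * (1 - r[j - 1]) + fB[, j - 1] * r[j - 1]) *
          EA[, idx[j]]
        b <- (fB[, j - 1] * (1 - r[j - 1]) + fA[, j - 1] * r[j - 1]) *
          EB[, idx[j]]
        s <- a + b
        fA[, j] <- a / s; fB[, j] <- b / s
      }
    }
    bA <- rep(1, n); bB <- rep(1, n)
    post <- matrix(0, n, m)
    post[, m] <- fA[, m] / (fA[, m] + fB[, m])
    if (m > 1) {
      for (j in (m - 1):1) {
        ea <- EA[, idx[j + 1]] * bA
        eb <- EB[, idx[j + 1]] * bB
        bA <- (1 - r[j]) * ea + r[j] * eb
        bB <- r[j] * ea + (1 - r[j]) * eb
        s <- bA + bB
        bA <- bA / s; bB <- bB / s
        num <- fA[, j] * bA
        post[, j] <- num / (num + fB[, j] * bB)
      }
    }
    P[, idx] <- post
  }
  rownames(P) <- rownames(ac$countsA)
  colnames(P) <- paste0(sites$chrom, ":", sites$pos)
  genotype_posterior(P, mutate(sites, cM = cm, masked = !ac$mask))
}

#' Binarize genotype posteriors
#'
#' Calls the parent-A allele where P(A) > 0.5 and parent B otherwise
#' (a posterior of exactly 0.5 is called B).
#'
#' @param gp a [genotype_posterior()].
#' @return integer matrix of hard calls, 1 = parent A, 0 = parent B.
#' @export
binarize <- function(gp) {
  h <- (gp$p_a > 0.5) * 1L
  dimnames(h) <- dimnames(gp$p_a)
  h
}

#' Match cells to reference segregant genotypes
#'
#' Pearson-correlates each cell's posterior vector against every reference
#' genotype row over the shared markers and reports the best match. Ties go
#' to the lowest reference index; constant posterior vectors yield no match.
#'
#' @param gp a [genotype_posterior()].
#' @param reference 0/1 matrix, reference segregants x markers (markers must
#'   align with `gp`'s columns).
#' @return tibble with columns barcode, match (reference row index, NA for
#'   no-match), correlation.
#' @export
match_segregant <- function(gp, reference) {
  if (ncol(reference) != ncol(gp$p_a)) {
    stop_arg("reference and posterior must share the marker set")
  }
  X <- gp$p_a
  sx <- apply(X, 1, sd)
  Xs <- X - rowMeans(X)
  R <- reference - rowMeans(reference)
  sr <- sqrt(rowSums(R^2))
  if (any(sr == 0)) stop_arg("constant reference genotype row")
  num <- Xs %*% t(R)
  den <- outer(sqrt(rowSums(Xs^2)), sr)
  C <- num / den
  best <- apply(C, 1, which.max)
  bestr <- C[cbind(seq_len(nrow(C)), best)]
  nomatch <- sx == 0
  if (any(nomatch)) {
    inform(sprintf("match_segregant: %d cell(s) had constant posteriors; no match",
                   sum(nomatch)))
  }
  tibble(barcode = rownames(X),
         match = ifelse(nomatch, NA_integer_, as.integer(best)),
         correlation = ifelse(nomatch, NA_real_, bestr))
}

#' Retain unique segregants among duplicated cell genotypes
#'
#' Computes the fraction of cells whose hard-call genotype vector duplicates
#' another cell's (Hamming distance <= `dup_tolerance`). If that fraction
#' exceeds `trigger`, only the highest-UMI cell of each duplicate group is
#' retained; otherwise all cells are kept.
#'
#' @param hard_calls 0/1 matrix of hard calls, cells x markers.
#' @param total_umis per-cell total UMI counts.
#' @param dup_tolerance allowed mismatches for two cells to count as
#'   duplicates (default 0, exact equality).
#' @param trigger duplicate fraction above which filtering activates
#'   (default 0.10).
#' @return tibble with columns barcode, group, duplicate, retained.
#' @export
uniqueness_filter <- function(hard_calls, total_umis, dup_tolerance = 0,
                              trigger = 0.10) {
  n <- nrow(hard_calls)
  if (length(total_umis) != n) stop_arg("total_umis length mismatch")
  if (dup_tolerance == 0) {
    key <- apply(hard_calls, 1, paste, collapse = "")
    group <- match(key, unique(key))
  } else {
    # O(n^2) fallback for tolerant matching; fine at QC scales
    group <- seq_len(n)
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (sum(hard_calls[i, ] != hard_calls[j, ]) <= dup_tolerance) {
          group[i] <- group[j]
          break
        }
      }
    }
    group <- match(group, unique(group))
  }
  dup <- duplicated(group) | duplicated(group, fromLast = TRUE)
  frac <- mean(dup)
  retained <- rep(TRUE, n)
  if (frac > trigger) {
    for (g in unique(group[dup])) {
      members <- which(group == g)
      keep <- members[which.max(total_umis[members])]
      retained[setdiff(members, keep)] <- FALSE
    }
  }
  bc <- rownames(hard_calls)
  if (is.null(bc)) bc <- sprintf("cell%06d", seq_len(n))
  tibble(barcode = bc, group = group, duplicate = dup, retained = retained)
}
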