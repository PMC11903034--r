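# Shared test utilities: an exhaustive-path HMM oracle and small builders
# for synthetic containers.

# Posterior P(genotype = A) by brute-force enumeration over all 2^m genotype
# paths of one cell, chromosome by chromosome. Deliberately independent of
# the forward-backward implementation: it computes the joint probability of
# every path explicitly and sums. Masked and zero-depth sites contribute a
# constant emission (their likelihood terms cancel in the posterior).
hmm_oracle_cell <- function(rA, D, sites, cm, mask, e = 0.005, prior = 0.5,
                            map_function = "haldane") {
  post <- numeric(length(rA))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    m <- length(idx)
    stopifnot(m <= 14) # 2^m paths
    r <- if (m > 1) recomb_fraction(diff(cm[idx]), map_function) else numeric(0)
    paths <- as.matrix(expand.grid(rep(list(c(1L, 0L)), m)))
    logp <- numeric(nrow(paths))
    for (k in seq_len(nrow(paths))) {
      g <- paths[k, ]
      lp <- log(ifelse(g[1] == 1L, prior, 1 - prior))
      if (m > 1) {
        sw <- abs(diff(g))
        lp <- lp + sum(log(ifelse(sw == 1, r, 1 - r)))
      }
      for (j in seq_len(m)) {
        i <- idx[j]
        if (mask[i] || D[i] == 0) next
        p <- if (g[j] == 1L) 1 - e else e
        lp <- lp + dbinom(rA[i], D[i], p, log = TRUE)
      }
      logp[k] <- lp
    }
    w <- exp(logp - max(logp))
    w <- w / sum(w)
    for (j in seq_len(m)) {
      post[idx[j]] <- sum(w[paths[, j] == 1L])
    }
  }
  post
}

# allele_counts from dense matrices with map-marker sites.
make_ac <- function(rA, rB, map) {
  allele_counts(
    Matrix::Matrix(rA, sparse = TRUE),
    Matrix::Matrix(rB, sparse = TRUE),
    tibble::tibble(chrom = map$chrom, pos = map$pos,
                   alleleA = "A", alleleB = "B")
  )
}

# Minimal expression_matrix from a dense count matrix; features placed on
# chrI at arbitrary increasing positions unless supplied.
make_expr <- function(counts, features = NULL, cell_meta = NULL) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  if (is.null(features)) {
    features <- tibble::tibble(feature = colnames(counts), chrom = "chrI",
                               pos = seq_len(ncol(counts)) * 1000L)
  }
  expression_matrix(Matrix::Matrix(counts, sparse = TRUE), features,
                    cell_meta)
}
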