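# Allele-specific expression in F1 hybrids: joint NB model with
# allele-specific mean and allele-specific overdispersion (noise = 1/theta),
# estimation-bias simulation, and the global noise-vs-expression trend check.

#' Classify F1 cells among candidate diploids
#'
#' When several F1 hybrid diploids are pooled in one experiment, each cell is
#' assigned to the candidate whose site genotypes best explain the cell's
#' allelic reads. The per-cell log-likelihood of a candidate is the sum over
#' covered sites of the binomial log-probability of the parent-A read count,
#' with allele-A read probability 1-e, 0.5 or e for genotypes AA, AB, BB.
#' Cells whose best-vs-second log-likelihood margin falls below `margin` are
#' left unassigned, as are cells with no reads.
#'
#' @param ac an [allele_counts()] object.
#' @param diploids named list; each element an integer vector over sites with
#'   values 2 (homozygous allele A), 1 (heterozygous), 0 (homozygous B).
#' @param error_rate per-read error probability (default 0.005).
#' @param margin assignment margin in log-likelihood units (default 2).
#' @return tibble: barcode, diploid (NA if unassigned), loglik, margin.
#' @export
classify_f1_cells <- function(ac, diploids, error_rate = 0.005, margin = 2) {
  if (length(diploids) < 2) stop_arg("need at least two candidate diploids")
  gmat <- do.call(cbind, diploids)
  if (nrow(gmat) != nrow(ac$sites)) stop_arg("diploid genotypes must cover all sites")
  if (any(duplicated(t(gmat)))) stop_arg("two candidate diploids are identical")
  e <- error_rate
  pa <- matrix(c(e, 0.5, 1 - e)[gmat + 1L], nrow(gmat), ncol(gmat))
  rA <- as.matrix(ac$countsA)
  D <- rA + as.matrix(ac$countsB)
  ll <- vapply(seq_along(diploids), function(k) {
    P <- matrix(pa[, k], nrow(rA), ncol(rA), byrow = TRUE)
    rowSums(dbinom(rA, D, P, log = TRUE) * (D > 0))
  }, numeric(nrow(rA)))
  colnames(ll) <- names(diploids)
  best <- apply(ll, 1, which.max)
  ord <- t(apply(ll, 1, sort, decreasing = TRUE))
  marg <- ord[, 1] - ord[, 2]
  covered <- rowSums(D) > 0
  assigned <- covered & marg >= margin
  tibble(barcode = rownames(rA),
         diploid = ifelse(assigned, names(diploids)[best], NA_character_),
         loglik = ord[, 1], margin = ifelse(covered, marg, NA_real_))
}

#' Filter cells and genes for allele-specific analysis
#'
#' Drops cells with total UMIs at or above `max_umis` (suspected multiplets)
#' and keeps genes with an allelic count observed in at least `min_cells` of
#' the remaining cells.
#'
#' @param countA,countB cells x genes matrices of allelic UMI counts.
#' @param total_umis per-cell total UMIs.
#' @param max_umis strict upper bound on cell total UMIs (default 20000).
#' @param min_cells gene detection threshold on allelic counts (default 64).
#' @return list with `cells` (integer indices) and `genes` (indices).
#' @export
filter_ase <- function(countA, countB, total_umis, max_umis = 20000,
                       min_cells = 64) {
  cells <- which(total_umis < max_umis)
  det <- Matrix::colSums((countA[cells, , drop = FALSE] +
                            countB[cells, , drop = FALSE]) > 0)
  list(cells = cells, genes = which(det >= min_cells))
}

ase_negll <- function(par, y, X, xk, Tmat) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  tau <- par[p + 1:2]
  mu <- exp(pmin(pmax(drop(X %*% beta), -30), 30))
  theta <- exp(pmin(pmax(drop(Tmat %*% tau), -20), 20))
  -sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
         theta * log(theta) + ifelse(y > 0, y * log(mu), 0) -
         (y + theta) * log(mu + theta))
}

ase_neggrad <- function(par, y, X, xk, Tmat) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  tau <- par[p + 1:2]
  mu <- exp(pmin(pmax(drop(X %*% beta), -30), 30))
  theta <- exp(pmin(pmax(drop(Tmat %*% tau), -20), 20))
  dldeta <- y - (y + theta) * mu / (mu + theta)
  dldth <- digamma(y + theta) - digamma(theta) + log(theta) + 1 -
    log(mu + theta) - (y + theta) / (mu + theta)
  -c(drop(crossprod(X, dldeta)), drop(crossprod(Tmat, theta * dldth)))
}

#' Fit the allele-specific expression and noise model for one gene
#'
#' Stacks each cell's two allelic counts and fits a negative-binomial model
#' in which the mean includes an allele effect (plus optional ln-UMI, batch,
#' stage and allele-by-stage terms shared per cell) and the overdispersion is
#' allele-specific through a log-linear model for theta:
#' `ln theta = tau0 + tau1 * allele`. Reported "noise" is 1/theta, so the
#' noise fold change (alt vs ref) is `exp(-tau1)`. Estimation is joint
#' maximum likelihood (BFGS with analytic gradients, IRLS warm start);
#' standard errors come from the numerically evaluated observed information.
#'
#' @param count_ref,count_alt per-cell allelic UMI counts for the reference
#'   and alternate parental allele.
#' @param ln_umis optional per-cell log total UMIs (compositional covariate).
#' @param batch optional per-cell batch labels.
#' @param stage optional per-cell cell-cycle stage labels; adds stage and
#'   allele-by-stage terms. Empty levels are dropped with a warning.
#' @return object of class `ase_fit`: `coefficients`, `se`, `loglik`,
#'   `converged`, `n_cells`, and the headline quantities `allele_lfc`
#'   (natural-log mean fold change alt/ref), `tau1` (log theta difference),
#'   `noise_fc` (= exp(-tau1)) and their standard errors.
#' @export
fit_ase_model <- function(count_ref, count_alt, ln_umis = NULL, batch = NULL,
                          stage = NULL) {
  n <- length(count_ref)
  if (length(count_alt) != n) stop_arg("allelic count vectors differ in length")
  if (all(count_ref == 0) || all(count_alt == 0)) {
    stop_arg("both alleles must be observed")
  }
  y <- c(count_ref, count_alt)
  xk <- rep(c(0, 1), each = n)
  X <- matrix(1, 2 * n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(ln_umis)) X <- cbind(X, ln_umis = rep(ln_umis, 2))
  if (!is.null(batch)) {
    b <- factor(rep(batch, 2))
    if (nlevels(b) > 1) {
      Xb <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(Xb) <- paste0("batch_", levels(b)[-1])
      X <- cbind(X, Xb)
    }
  }
  X <- cbind(X, allele = xk)
  if (!is.null(stage)) {
    s <- factor(rep(stage, 2))
    s <- droplevels(s)
    if (nlevels(s) > 1) {
      Xs <- stats::model.matrix(~s)[, -1, drop = FALSE]
      colnames(Xs) <- paste0("stage_", levels(s)[-1])
      Xi <- Xs * xk
      colnames(Xi) <- paste0("allele_x_", colnames(Xs))
      X <- cbind(X, Xs, Xi)
    } else {
      warn("only one stage present; stage terms dropped")
    }
  }
  Tmat <- cbind(tau0 = 1, tau1 = xk)
  warm <- fit_nb_glm(y, X)
  par0 <- c(warm$coefficients, log(warm$theta), 0)
  opt <- optim(par0, ase_negll, ase_neggrad, y = y, X = X, xk = xk,
               Tmat = Tmat, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  H <- optim(opt$par, ase_negll, ase_neggrad, y = y, X = X, xk = xk,
             Tmat = Tmat, method = "BFGS",
             control = list(maxit = 0), hessian = TRUE)$hessian
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(par0),
                                                       length(par0)))
  se <- sqrt(pmax(diag(cov), 0))
  nm <- c(colnames(X), "tau0", "tau1")
  co <- setNames(opt$par, nm)
  se <- setNames(se, nm)
  structure(
    list(coefficients = co, se = se, loglik = -opt$value,
         converged = opt$convergence == 0, n_cells = n,
         allele_lfc = unname(co["allele"]), allele_se = unname(se["allele"]),
         tau1 = unname(co["tau1"]), tau1_se = unname(se["tau1"]),
         noise_fc = exp(-unname(co["tau1"]))),
    class = "ase_fit"
  )
}

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf(
    "<ase_fit> n=%d cells; allele logFC %.3f (SE %.3f); noise FC %.3f (tau1 %.3f, SE %.3f)%s\n",
    x$n_cells, x$allele_lfc, x$allele_se, x$noise_fc, x$tau1, x$tau1_se,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Allele-specific scan over genes
#'
#' Fits [fit_ase_model()] per gene and collects mean and noise tests; the
#' two families are Benjamini-Hochberg adjusted separately.
#'
#' @param countA,countB cells x genes allelic count matrices (already
#'   filtered, see [filter_ase()]).
#' @param ln_umis,batch,stage optional per-cell covariates.
#' @return tibble: gene, allele_lfc, allele_se, z_mean, p_mean, q_mean,
#'   tau1, tau1_se, t_noise, p_noise, q_noise, noise_fc, converged.
#' @export
ase_scan <- function(countA, countB, ln_umis = NULL, batch = NULL,
                     stage = NULL) {
  genes <- colnames(countA)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(ncol(countA)))
  res <- purrr::map_dfr(seq_len(ncol(countA)), function(j) {
    fit <- tryCatch(
      fit_ase_model(countA[, j], countB[, j], ln_umis, batch, stage),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(gene = genes[j], allele_lfc = NA_real_,
                    allele_se = NA_real_, tau1 = NA_real_,
                    tau1_se = NA_real_, noise_fc = NA_real_,
                    converged = FALSE))
    }
    tibble(gene = genes[j], allele_lfc = fit$allele_lfc,
           allele_se = fit$allele_se, tau1 = fit$tau1,
           tau1_se = fit$tau1_se, noise_fc = fit$noise_fc,
           converged = fit$converged)
  })
  res |>
    mutate(z_mean = .data$allele_lfc / .data$allele_se,
           p_mean = 2 * pnorm(-abs(.data$z_mean)),
           q_mean = p.adjust(.data$p_mean, "BH"),
           t_noise = .data$tau1 / .data$tau1_se,
           p_noise = 2 * pnorm(-abs(.data$t_noise)),
           q_noise = p.adjust(.data$p_noise, "BH"))
}

#' Bias and calibration simulation for the allele-specific noise test
#'
#' For each grid point of the design, simulates allelic counts and refits the
#' intercept + allele model, recording the estimated allelic fold change,
#' the estimated dispersion fold change and the noise-test p-value.
#'
#' @param design an [ase_sim_design()].
#' @param alpha rejection level for the summary (default 0.05).
#' @return list with `fits` (one row per rep; `boundary` flags fits whose
#'   estimated dispersion hit the effective boundary, i.e. an allele's
#'   estimated theta left (1e-4, 1e4) -- at very low counts the theta MLE
#'   has positive probability of diverging, and the dispersion fold change
#'   is then meaningless) and `summary` (one row per grid point: mean
#'   estimates, bias, rejection rate).
#' @export
bias_simulation <- function(design, alpha = 0.05) {
  sims <- simulate_f1_hybrid(design)
  fits <- purrr::map_dfr(seq_len(nrow(sims)), function(i) {
    d <- sims$data[[i]]
    fit <- tryCatch(fit_ase_model(d$count_ref, d$count_alt),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ln_th <- c(fit$coefficients["tau0"],
               fit$coefficients["tau0"] + fit$coefficients["tau1"])
    tibble(fc_log2 = sims$fc_log2[i], dfc_log2 = sims$dfc_log2[i],
           rep = sims$rep[i],
           est_fc_log2 = fit$allele_lfc / log(2),
           est_dfc_log2 = -fit$tau1 / log(2),
           p_noise = 2 * pnorm(-abs(fit$tau1 / fit$tau1_se)),
           converged = fit$converged,
           boundary = max(abs(ln_th)) > log(1e4))
  })
  summary <- fits |>
    group_by(.data$fc_log2, .data$dfc_log2) |>
    summarise(n = n(),
              mean_est_fc_log2 = mean(.data$est_fc_log2),
              mean_est_dfc_log2 = mean(.data$est_dfc_log2),
              bias_dfc_log2 = mean(.data$est_dfc_log2 - .data$dfc_log2),
              rejection_rate = mean(.data$p_noise < alpha),
              .groups = "drop")
  list(fits = fits, summary = summary)
}

#' Flag noise effects violating the global noise-expression trend
#'
#' Across genes with a significant allele-specific mean and/or noise effect,
#' noise log fold change tends to fall with expression log fold change. A
#' robust (Huber M-estimation) linear regression of noise change on
#' expression change captures the trend; a gene is flagged when the 95% CI
#' of its noise effect is disjoint from the pointwise 95% CI of the trend
#' line at the gene's expression change.
#'
#' @param results an [ase_scan()]-style tibble with columns allele_lfc,
#'   tau1, tau1_se, q_mean, q_noise. Noise change is taken as
#'   `-tau1` (log noise fold change).
#' @param q_threshold significance filter for inclusion (default 0.05).
#' @return list: `fit` (the rlm object), `table` (gene rows with trend
#'   predictions, CIs and `violates` flag).
#' @export
noise_trend <- function(results, q_threshold = 0.05) {
  sig <- filter(results, .data$q_mean < q_threshold |
                  .data$q_noise < q_threshold)
  if (nrow(sig) < 10) stop_arg("need at least 10 significant genes for the trend")
  if (sd(sig$allele_lfc) == 0) stop_arg("expression changes are constant")
  df <- tibble(x = sig$allele_lfc, y = -sig$tau1)
  fit <- MASS::rlm(y ~ x, data = df, psi = MASS::psi.huber, maxit = 100)
  pred <- predict(fit, newdata = df, se.fit = TRUE)
  tab <- sig |>
    mutate(noise_lfc = -.data$tau1,
           noise_lo = .data$noise_lfc - 1.96 * .data$tau1_se,
           noise_hi = .data$noise_lfc + 1.96 * .data$tau1_se,
           trend = pred$fit,
           trend_lo = pred$fit - 1.96 * pred$se.fit,
           trend_hi = pred$fit + 1.96 * pred$se.fit,
           violates = .data$noise_hi < .data$trend_lo |
             .data$noise_lo > .data$trend_hi)
  list(fit = fit, table = tab)
}
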