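# Negative-binomial GLM fitting: IRLS for the coefficients at fixed
# overdispersion, profile maximization for theta, observed-information SEs.

nb_profile_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) + ifelse(y > 0, y * log(mu), 0) -
        (y + theta) * log(mu + theta))
}

#' Fit a negative-binomial GLM with log link
#'
#' Coefficients are estimated by iteratively reweighted least squares at
#' fixed overdispersion; when `theta` is not supplied it is estimated by
#' alternating IRLS for the coefficients with one-dimensional profile
#' likelihood maximization for theta (bounded to \[1e-3, 1e5\]). Standard
#' errors come from the observed information. The model is
#' E(Y) = mu, Var(Y) = mu + mu^2 / theta, log mu = X beta.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (n x p), full rank, including the intercept.
#' @param theta optional fixed NB size; `NULL` to estimate.
#' @param max_outer maximum alternations when estimating theta.
#' @return object of class `nb_fit` with elements `coefficients`, `se`,
#'   `loglik`, `theta`, `theta_fixed`, `converged`, `fitted`, `n`, `df`.
#' @export
fit_nb_glm <- function(y, X, theta = NULL, max_outer = 50) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_arg("y and X disagree on n")
  if (nrow(X) <= ncol(X)) stop_arg("need more observations than coefficients")
  theta_fixed <- !is.null(theta)
  if (theta_fixed) {
    fit <- cpp_nb_fit(y, X, theta)
  } else {
    theta <- 1
    fit <- cpp_nb_fit(y, X, theta)
    ll_old <- -Inf
    for (it in seq_len(max_outer)) {
      mu <- exp(pmin(pmax(drop(X %*% fit$beta), -30), 30))
      opt <- optimize(function(lt) nb_profile_loglik(y, mu, exp(lt)),
                      lower = log(1e-3), upper = log(1e5), maximum = TRUE,
                      tol = 1e-8)
      theta <- exp(opt$maximum)
      fit <- cpp_nb_fit(y, X, theta, beta_init = fit$beta)
      if (abs(fit$loglik - ll_old) < 1e-8) break
      ll_old <- fit$loglik
    }
    if (theta <= 1e-3 * 1.01 || theta >= 1e5 * 0.99) {
      warn(sprintf("theta estimate at search bound: %.4g", theta))
    }
  }
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(ncol(X)) - 1L)
  structure(
    list(coefficients = setNames(drop(fit$beta), cn),
         se = setNames(drop(fit$se), cn),
         loglik = fit$loglik, theta = theta, theta_fixed = theta_fixed,
         converged = isTRUE(fit$converged),
         fitted = exp(pmin(pmax(drop(X %*% fit$beta), -30), 30)),
         n = length(y), df = ncol(X)),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> n=%d, theta=%.4g%s, logLik=%.3f%s\n", x$n, x$theta,
              if (x$theta_fixed) " (fixed)" else "", x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Estimate the per-transcript overdispersion
#'
#' Fits the full local-marker model once and returns the NB size; the
#' estimate is then held fixed for all genome scans of that transcript.
#'
#' @inheritParams fit_nb_glm
#' @return the estimated theta (scalar).
#' @export
estimate_theta <- function(y, X) {
  fit_nb_glm(y, X)$theta
}

#' LOD score from a likelihood-ratio statistic
#'
#' LOD = LR / (2 ln 10). Negative inputs (numerical noise from boundary
#' fits) are clamped to zero with a warning.
#'
#' @param lr likelihood-ratio statistic(s).
#' @return LOD score(s).
#' @export
lod_from_lr <- function(lr) {
  if (any(lr < 0)) {
    warn("negative likelihood-ratio statistic clamped to 0")
    lr <- pmax(lr, 0)
  }
  lr / (2 * log(10))
}
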