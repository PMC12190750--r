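# Empirical-Bayes adaptive shrinkage of meta-analyzed effect sizes under a
# zero-centered normal mixture prior (point mass at zero plus a geometric
# grid of normal components), fit by a penalized EM algorithm.

#' Build the mixture standard-deviation grid
#'
#' The prior is a mixture of zero-centered normals whose standard deviations
#' lie on `{0} U {sigma_min * sqrt(2)^i}`, a geometric grid with ratio
#' `sqrt(2)` from `sigma_min = min(se)/10` up to
#' `sigma_max = 2 * sqrt(max(betahat^2 - se^2, 0))`. When every observation
#' is consistent with pure noise (`betahat^2 <= se^2` throughout),
#' `sigma_max = 8 * sigma_min`.
#'
#' @param betahat Observed effect estimates.
#' @param se Their standard errors (all `> 0`).
#' @return Increasing numeric vector of component standard deviations,
#'   starting with 0 (the null point mass).
#' @export
build_ash_grid <- function(betahat, se) {
  if (length(betahat) == 0L) stop("no observations")
  stopifnot(length(betahat) == length(se), all(se > 0))
  sigma_min <- min(se) / 10
  sigma_max <- 2 * sqrt(max(c(betahat^2 - se^2, 0)))
  if (sigma_max <= 0) sigma_max <- 8 * sigma_min
  m <- floor(log(sigma_max / sigma_min) / log(sqrt(2)) + 1e-10)
  c(0, sigma_min * sqrt(2)^(0:max(m, 0)))
}

#' Fit the normal-mixture adaptive-shrinkage model
#'
#' Maximizes the penalized marginal log-likelihood
#' `sum_j log sum_k pi_k N(betahat_j; 0, se_j^2 + sigma_k^2)
#'  + (penalty_null - 1) * log pi_0`
#' over the mixture weights by EM (the M-step is the usual responsibility
#' average with `penalty_null - 1` pseudo-counts on the null component).
#' The null penalty biases the fit toward the zero point mass, the standard
#' conservative default for effect-size shrinkage. Posterior mean effects are
#' `PM_j = sum_k gamma_jk * betahat_j * sigma_k^2 / (sigma_k^2 + se_j^2)`,
#' so every component shrinks multiplicatively toward zero and
#' `|PM_j| <= |betahat_j|` always.
#'
#' @param betahat,se Effect estimates and standard errors.
#' @param grid Mixture component standard deviations; defaults to
#'   [build_ash_grid()].
#' @param penalty_null Dirichlet-style pseudo-count on the null weight
#'   (default 10; 1 disables the penalty).
#' @param tol EM stops when the penalized log-likelihood increases by less
#'   than `tol` (default 1e-7).
#' @param max_iter Iteration cap (default 5000).
#' @return Object of class `ash_normal`: list with `grid`, `pi` (weights),
#'   `loglik` (penalized), `n_iter`, `converged` and `posterior_mean`.
#' @export
fit_ash_normal <- function(betahat, se, grid = build_ash_grid(betahat, se),
                           penalty_null = 10, tol = 1e-7, max_iter = 5000) {
  stopifnot(length(betahat) == length(se), all(se > 0), penalty_null >= 1)
  if (grid[1L] != 0) stop("grid must start with the null component sigma = 0")
  n <- length(betahat)
  K <- length(grid)
  # n x K matrix of component likelihoods N(betahat; 0, se^2 + sigma_k^2)
  sd_jk <- sqrt(outer(se^2, grid^2, `+`))
  L <- stats::dnorm(matrix(betahat, n, K), mean = 0, sd = sd_jk)
  L[L < .Machine$double.xmin] <- .Machine$double.xmin
  pi_k <- rep(1 / K, K)
  pen <- penalty_null - 1
  pen_ll <- function(pi_k) {
    sum(log(L %*% pi_k)) + pen * log(pi_k[1L])
  }
  ll_old <- pen_ll(pi_k)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    num <- sweep(L, 2L, pi_k, `*`)
    gamma <- num / rowSums(num)
    nk <- colSums(gamma)
    nk[1L] <- nk[1L] + pen
    pi_k <- nk / (n + pen)
    ll <- pen_ll(pi_k)
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
      stop("penalized log-likelihood decreased during EM; this is a bug")
    }
    if (ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  num <- sweep(L, 2L, pi_k, `*`)
  gamma <- num / rowSums(num)
  shrink <- outer(1 / se^2, grid^2) / (1 + outer(1 / se^2, grid^2))  # sigma^2/(sigma^2+se^2)
  pm <- rowSums(gamma * shrink) * betahat
  structure(list(grid = grid, pi = as.numeric(pi_k), loglik = ll_old,
                 n_iter = iter, converged = converged,
                 posterior_mean = as.numeric(pm)),
            class = "ash_normal")
}

#' @export
print.ash_normal <- function(x, ...) {
  cat("ash_normal: ", length(x$grid), " components, pi0 = ",
      format(x$pi[1L], digits = 4), ", penalized loglik = ",
      format(x$loglik, digits = 8), " (", x$n_iter, " EM iterations)\n",
      sep = "")
  invisible(x)
}

#' Add shrunken effect sizes to a DMS table
#'
#' Fits the adaptive-shrinkage model separately within each modification code
#' on the meta-analysis `(beta_meta, se_meta)` pairs and stores the posterior
#' means in `shrunken_beta`.
#'
#' @param dms A `dms_table` from [call_dms()].
#' @param penalty_null,tol,max_iter Passed to [fit_ash_normal()].
#' @return The table with `shrunken_beta` filled in.
#' @export
add_shrunken_effects <- function(dms, penalty_null = 10, tol = 1e-7,
                                 max_iter = 5000) {
  for (mc in unique(dms$mod_code)) {
    i <- which(dms$mod_code == mc & is.finite(dms$beta_meta) &
                 is.finite(dms$se_meta))
    if (length(i) == 0L) next
    fit <- fit_ash_normal(dms$beta_meta[i], dms$se_meta[i],
                          penalty_null = penalty_null, tol = tol,
                          max_iter = max_iter)
    dms$shrunken_beta[i] <- fit$posterior_mean
  }
  dms
}
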