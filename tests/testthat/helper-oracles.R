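# Independent oracles used across the suite. Each re-derives the quantity it
# checks from first principles, separately from the package implementation.

# Closed-form MLE of the two-group binomial logit model: the pooled log-odds
# ratio and its delta-method standard error.
oracle_pooled_logodds <- function(n_mod, n_canonical, condition) {
  M1 <- sum(n_mod[condition == "high"]); C1 <- sum(n_canonical[condition == "high"])
  M0 <- sum(n_mod[condition == "low"]); C0 <- sum(n_canonical[condition == "low"])
  list(beta0 = log(M0 / C0),
       beta1 = log((M1 / C1) / (M0 / C0)),
       se1 = sqrt(1 / M1 + 1 / C1 + 1 / M0 + 1 / C0))
}

# Cook's distance recomputed from the weighted hat matrix and Pearson
# residuals at the converged fit (no call into stats influence helpers).
oracle_cooks <- function(n_mod, n_canonical, condition) {
  tot <- n_mod + n_canonical
  y <- n_mod / tot
  x <- as.integer(condition == "high")
  X <- cbind(1, x)
  fit <- glm(cbind(n_mod, n_canonical) ~ x, family = binomial(),
             control = glm.control(epsilon = 1e-12, maxit = 200))
  mu <- fitted(fit)
  w <- tot * mu * (1 - mu)
  WX <- sqrt(w) * X
  H <- WX %*% solve(crossprod(WX), t(WX))
  h <- diag(H)
  r <- (y - mu) * sqrt(tot / (mu * (1 - mu)))
  D <- r^2 * h / (2 * (1 - h)^2)
  list(h = h, r = r, D = as.numeric(D))
}

# Brute-force penalized EM for the zero-centered normal mixture, written
# independently, with random restarts (the penalized likelihood is concave in
# the weights, so all starts reach the same optimum).
oracle_ash_em <- function(betahat, se, grid, penalty = 10, n_restart = 10,
                          max_iter = 50000, tol = 1e-13) {
  K <- length(grid)
  n <- length(betahat)
  L <- sapply(grid, function(s) dnorm(betahat, 0, sqrt(se^2 + s^2)))
  L <- matrix(pmax(L, 1e-300), n, K)
  best <- NULL
  for (r in seq_len(n_restart)) {
    pi_k <- if (r == 1) rep(1 / K, K) else {
      x <- rgamma(K, 1); x / sum(x)
    }
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      post <- sweep(L, 2, pi_k, `*`)
      rs <- rowSums(post)
      ll <- sum(log(rs)) + (penalty - 1) * log(pi_k[1])
      if (it > 1 && ll - ll_old < tol) break
      ll_old <- ll
      g <- post / rs
      nk <- colSums(g)
      nk[1] <- nk[1] + penalty - 1
      pi_k <- nk / sum(nk)
    }
    if (is.null(best) || ll > best$ll) best <- list(pi = pi_k, ll = ll)
  }
  pi_k <- best$pi
  post <- sweep(L, 2, pi_k, `*`)
  g <- post / rowSums(post)
  shrink <- outer(se^2, grid^2, function(a, b) b / (a + b))
  list(pi = pi_k, loglik = best$ll,
       posterior_mean = rowSums(g * shrink) * betahat)
}

# Exhaustive upper-tail hypergeometric probability by direct enumeration of
# binomial coefficients (exact for small universes).
oracle_hyper_upper <- function(k, K_set, n_draw, N) {
  js <- k:min(n_draw, K_set)
  if (length(js) == 0 || k > min(n_draw, K_set)) return(0)
  sum(choose(K_set, js) * choose(N - K_set, n_draw - js)) / choose(N, n_draw)
}

# Fieller limits as the roots of the defining quadratic in the ratio rho:
# (xH - rho*xL)^2 = t^2 (vH + rho^2 vL), solved with polyroot.
oracle_fieller_roots <- function(high, low, conf = 0.95) {
  nH <- length(high); nL <- length(low)
  xH <- mean(high); xL <- mean(low)
  vH <- var(high) / nH; vL <- var(low) / nL
  tc <- qt(1 - (1 - conf) / 2, nH + nL - 2)
  # (xL^2 - t^2 vL) rho^2 - 2 xH xL rho + (xH^2 - t^2 vH) = 0
  roots <- sort(Re(polyroot(c(xH^2 - tc^2 * vH, -2 * xH * xL, xL^2 - tc^2 * vL))))
  roots
}

# Random bedMethyl record frames for round-trip tests.
random_records <- function(n, mod_codes = dms_mod_codes()) {
  nv <- rpois(n, 40)
  nm <- rbinom(n, nv, runif(n))
  noth <- rbinom(n, nv - nm, 0.05)
  start <- sample.int(1e6, n)
  data.frame(
    reference = sprintf("tx%03d", sample.int(50, n, replace = TRUE)),
    start = start, end = start + 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mod_code = sample(mod_codes, n, replace = TRUE),
    n_valid = nv, n_mod = nm, n_canonical = nv - nm - noth, n_other = noth,
    percent_modified = ifelse(nv > 0, nm / nv, 0),
    stringsAsFactors = FALSE
  )
}

# Build a one-mod count table directly from per-replicate count pairs.
table_from_counts <- function(n_mod, n_canonical, conditions = NULL,
                              cell_line = "A", material = "native") {
  stopifnot(is.matrix(n_mod), all(dim(n_mod) == dim(n_canonical)))
  ns <- ncol(n_mod)
  if (is.null(conditions)) conditions <- rep("low", ns)
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(ns)), cell_line = cell_line,
    condition = conditions, material = material,
    replicate = seq_len(ns), path = NA_character_,
    stringsAsFactors = FALSE)
  sites <- data.frame(reference = sprintf("tx%d", seq_len(nrow(n_mod))),
                      start = seq_len(nrow(n_mod)),
                      end = seq_len(nrow(n_mod)) + 1L,
                      strand = "+", mod_code = "a", stringsAsFactors = FALSE)
  ids <- dmscall:::site_id(sites$reference, sites$start, sites$strand,
                           sites$mod_code)
  dimnames(n_mod) <- dimnames(n_canonical) <- list(ids, samples$sample_id)
  structure(list(mod_code = "a", sites = sites, site_ids = ids,
                 samples = samples, n_mod = n_mod, n_canonical = n_canonical),
            class = "site_count_table")
}

# Small two-line experiment fitted end-to-end; shared by several tests.
fit_sim <- function(sim, ...) {
  dms_call(sim$sheet, tables = dmscall:::sim_count_tables(sim), ...)
}
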