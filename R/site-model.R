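# Per-site, per-cell-line binomial regression of modification counts on
# condition, with Cook's-distance influence diagnostics.

#' Fit the per-site binomial GLM
#'
#' Maximum-likelihood logistic-binomial regression of the modification ratio
#' on the condition indicator (`high` = 1):
#' `cbind(n_mod, n_canonical) ~ condition`, fit by iteratively reweighted
#' least squares. The slope is the log-odds difference in modification
#' between conditions (positive = more modified under `high`); its Wald
#' two-sided P-value uses the normal reference distribution. For this
#' two-group design the MLE has the closed form
#' `beta1 = log((M1/C1)/(M0/C0))`, `se1 = sqrt(1/M1 + 1/C1 + 1/M0 + 1/C0)`
#' with pooled per-condition modified / canonical counts.
#'
#' Quasi-complete separation (a pooled modified or canonical count of zero in
#' either condition) yields no finite MLE; such fits are returned with
#' `converged = FALSE` and NA estimates.
#'
#' @param n_mod,n_canonical Integer vectors of per-sample modified and
#'   canonical read counts.
#' @param condition Character/factor vector in `{"low", "high"}`, one per
#'   sample.
#' @return An object of class `site_glm`: list with `beta0`, `beta1`, `se1`,
#'   `wald_z`, `p`, `converged`, `n_samples`, `leverages`, `cooks_d`,
#'   `cooks_p` and the underlying `glm` fit (`NULL` when not estimable).
#' @export
fit_site_glm <- function(n_mod, n_canonical, condition) {
  stopifnot(length(n_mod) == length(n_canonical),
            length(n_mod) == length(condition))
  condition <- as.character(condition)
  if (!all(condition %in% c("low", "high")))
    stop("condition labels must be 'low' or 'high'")
  tot <- n_mod + n_canonical
  keep <- tot > 0
  n_mod <- n_mod[keep]; n_canonical <- n_canonical[keep]
  condition <- condition[keep]
  res <- list(beta0 = NA_real_, beta1 = NA_real_, se1 = NA_real_,
              wald_z = NA_real_, p = NA_real_, converged = FALSE,
              n_samples = length(n_mod), leverages = NULL,
              cooks_d = NULL, cooks_p = NULL, glm = NULL)
  class(res) <- "site_glm"
  if (!any(condition == "low") || !any(condition == "high")) {
    res$testable <- FALSE
    return(res)
  }
  res$testable <- TRUE
  M1 <- sum(n_mod[condition == "high"]); C1 <- sum(n_canonical[condition == "high"])
  M0 <- sum(n_mod[condition == "low"]); C0 <- sum(n_canonical[condition == "low"])
  if (min(M0, C0, M1, C1) == 0) {
    # quasi-complete separation: no finite MLE
    return(res)
  }
  x <- as.integer(condition == "high")
  fit <- stats::glm(cbind(n_mod, n_canonical) ~ x, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  cf <- stats::coef(fit)
  # Wald covariance from the Fisher information evaluated at the converged
  # coefficients (glm's vcov uses the weights of the previous IRLS half-step)
  X <- cbind(1, x)
  w <- (n_mod + n_canonical) * stats::fitted(fit) * (1 - stats::fitted(fit))
  V <- solve(crossprod(X, w * X))
  res$beta0 <- unname(cf[1L]); res$beta1 <- unname(cf[2L])
  res$se1 <- sqrt(V[2L, 2L])
  res$wald_z <- res$beta1 / res$se1
  res$p <- 2 * stats::pnorm(-abs(res$wald_z))
  res$converged <- fit$converged
  res$glm <- fit
  cd <- glm_cooks(fit)
  res$leverages <- cd$leverage
  res$cooks_d <- cd$cooks_d
  res$cooks_p <- cd$cooks_p
  res
}

#' Cook's distances and influence P-values for a binomial GLM
#'
#' Per-sample Cook's distance from the weighted hat matrix at convergence:
#' `D_i = r_i^2 h_i / (phi * p * (1 - h_i)^2)` with `r_i` the Pearson
#' residual, `h_i` the leverage, dispersion `phi = 1` (binomial) and `p = 2`
#' coefficients. Each distance is referred to the F distribution with
#' `(p, n - p)` degrees of freedom; `cooks_p = 1 - F(D_i)`, so small values
#' flag influential samples.
#'
#' @param fit A converged `glm` fit with two coefficients.
#' @return Data frame with per-sample `leverage`, `cooks_d` and `cooks_p`
#'   (`cooks_p` is NA when `n <= p`, leaving the site un-prunable).
#' @export
glm_cooks <- function(fit) {
  h <- stats::hatvalues(fit)
  d <- stats::cooks.distance(fit)
  n <- length(h)
  p <- length(stats::coef(fit))
  cp <- if (n > p) stats::pf(d, p, n - p, lower.tail = FALSE) else rep(NA_real_, n)
  data.frame(leverage = as.numeric(h), cooks_d = as.numeric(d),
             cooks_p = as.numeric(cp), row.names = NULL)
}

#' @export
print.site_glm <- function(x, ...) {
  cat("site_glm: beta1 =", format(x$beta1, digits = 5),
      "se =", format(x$se1, digits = 5),
      "p =", format(x$p, digits = 3),
      if (!x$converged) "(not estimable)" else "", "\n")
  invisible(x)
}

#' Test every eligible site of one cell line
#'
#' Restricts the count table to the native samples of `line`, applies the
#' per-line eligibility rules (mean total reads >= `min_mean_reads` and
#' modification proportion >= `min_native_prop`, both re-applied within the
#' line), fits the binomial GLM at each eligible site and computes
#' Cook's-distance influence diagnostics. A site whose minimum Cook's
#' P-value falls below `alpha_influence` is flagged `pruned` (excluded from
#' meta-analysis downstream, but kept in the record).
#'
#' @param table A native-material `site_count_table`.
#' @param line Cell line to test.
#' @param cfg A [filter_config()] supplying the per-line eligibility
#'   thresholds.
#' @param alpha_influence Cook's P-value threshold for pruning; default 0.05.
#' @param eligible_sites Optional character vector of site ids (e.g. the
#'   IVT-filtered set); sites outside it are not tested.
#' @return Data frame (class `site_fits`) with one row per site in the table:
#'   site key columns, `cell_line`, `tested`, `converged`, `beta1`, `se1`,
#'   `wald_z`, `p`, `min_cooks_p`, `max_cooks_d`, `outlier_sample` (sample id
#'   with the largest Cook's distance) and `pruned`.
#' @export
test_sites_per_line <- function(table, line, cfg = filter_config(),
                                alpha_influence = 0.05,
                                eligible_sites = NULL) {
  samples <- table$samples
  keep <- samples$cell_line == line & samples$material == "native"
  if (!any(keep)) stop("no native samples for cell line ", line)
  tab <- subset_table_samples(table, samples$sample_id[keep])
  smp <- tab$samples
  summ <- summarize_sites(tab)
  prop <- if (cfg$prop_mode == "pooled") summ$pooled_prop else summ$mean_prop
  eligible <- summ$mean_total_reads >= cfg$min_mean_reads &
    prop >= cfg$min_native_prop
  if (!is.null(eligible_sites)) eligible <- eligible & tab$site_ids %in% eligible_sites

  n <- length(tab$site_ids)
  out <- data.frame(
    site_id = tab$site_ids, tab$sites, cell_line = line,
    tested = eligible, converged = FALSE,
    beta1 = NA_real_, se1 = NA_real_, wald_z = NA_real_, p = NA_real_,
    min_cooks_p = NA_real_, max_cooks_d = NA_real_,
    outlier_sample = NA_character_, pruned = FALSE,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in which(eligible)) {
    f <- fit_site_glm(tab$n_mod[i, ], tab$n_canonical[i, ], smp$condition)
    if (!isTRUE(f$testable)) {
      out$tested[i] <- FALSE
      next
    }
    out$converged[i] <- f$converged
    if (!f$converged) next
    out$beta1[i] <- f$beta1; out$se1[i] <- f$se1
    out$wald_z[i] <- f$wald_z; out$p[i] <- f$p
    if (!is.null(f$cooks_p) && !all(is.na(f$cooks_p))) {
      out$min_cooks_p[i] <- min(f$cooks_p, na.rm = TRUE)
      j <- which.max(f$cooks_d)
      out$max_cooks_d[i] <- f$cooks_d[j]
      covered <- smp$sample_id[tab$n_mod[i, ] + tab$n_canonical[i, ] > 0]
      out$outlier_sample[i] <- covered[j]
      out$pruned[i] <- out$min_cooks_p[i] < alpha_influence
    }
  }
  class(out) <- c("site_fits", "data.frame")
  out
}
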