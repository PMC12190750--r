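# Inverse-variance fixed-effects meta-analysis across cell lines, Cochran's Q
# heterogeneity filtering, and Benjamini-Hochberg FDR control.

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study effect estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b)/sum(w)`, `se_meta = 1/sqrt(sum(w))`, two-sided
#' normal P-value on `z = beta_meta/se_meta`, and Cochran's heterogeneity
#' statistic `Q = sum(w (b - beta_meta)^2)` referred to the chi-square
#' distribution with `k - 1` degrees of freedom (for a single study
#' `Q = 0`, `p_Q = 1`).
#'
#' @param beta Numeric vector of per-study effect estimates.
#' @param se Numeric vector of their standard errors (all `> 0`).
#' @return List with `beta_meta`, `se_meta`, `z`, `p`, `Q`, `p_Q` and `k`.
#' @export
fixed_effects_meta <- function(beta, se) {
  if (length(beta) == 0L) stop("no estimates to meta-analyze")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be finite and > 0")
  if (any(!is.finite(beta))) stop("all estimates must be finite")
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  k <- length(beta)
  Q <- sum(w * (beta - beta_meta)^2)
  p_Q <- if (k > 1) stats::pchisq(Q, df = k - 1, lower.tail = FALSE) else 1
  list(beta_meta = beta_meta, se_meta = se_meta, z = z,
       p = 2 * stats::pnorm(-abs(z)), Q = Q, p_Q = p_Q, k = k)
}

# Vectorized two-study special case used by call_dms: rows with an NA in
# either column are treated as single-study records.
meta_two_lines <- function(b1, s1, b2, s2) {
  w1 <- ifelse(is.na(s1), 0, 1 / s1^2)
  w2 <- ifelse(is.na(s2), 0, 1 / s2^2)
  b1z <- ifelse(is.na(b1), 0, b1)
  b2z <- ifelse(is.na(b2), 0, b2)
  sw <- w1 + w2
  beta <- (w1 * b1z + w2 * b2z) / sw
  se <- 1 / sqrt(sw)
  k <- (w1 > 0) + (w2 > 0)
  Q <- w1 * (b1z - beta)^2 + w2 * (b2z - beta)^2
  Q[k < 2] <- 0
  p_Q <- ifelse(k > 1, stats::pchisq(Q, df = pmax(k - 1, 1), lower.tail = FALSE), 1)
  z <- beta / se
  data.frame(beta_meta = beta, se_meta = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), Q = Q, p_Q = p_Q, k = k)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotonicity enforcement. Missing (NA/NaN)
#' P-values are propagated as NA and excluded from the ranking (they do not
#' count toward the number of tests).
#'
#' @param p Numeric vector of P-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("P-values must lie in [0, 1]")
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Meta-analyze per-line site fits and call differentially modified sites
#'
#' Joins the per-cell-line fit tables on site, combines sites that are
#' tested, converged and not influence-pruned in at least one line with the
#' inverse-variance fixed-effects model, flags heterogeneous sites
#' (Cochran's Q P-value below `alpha_het`; only possible when both lines
#' contribute), removes them from the multiple-testing pool, applies
#' Benjamini-Hochberg within the modification code, and calls a site
#' differentially modified at `q < q_threshold`.
#'
#' @param fits_by_line List of `site_fits` data frames, one per cell line
#'   (see [test_sites_per_line()]).
#' @param alpha_het Heterogeneity threshold on the Q P-value; default 0.05.
#' @param q_threshold FDR threshold for the DMS call; default 0.05.
#' @param both_lines_only If `TRUE`, only sites testable in every supplied
#'   line enter the meta-analysis (the strict two-line policy); default
#'   `FALSE` carries single-line sites through as one-study meta-analyses.
#' @return Data frame (class `dms_table`) with one row per meta-analyzed
#'   site: site key columns, per-line estimates, `beta_meta`, `se_meta`,
#'   `z`, `p`, `Q`, `p_Q`, `k`, `heterogeneous`, `q_value`, `is_dms` and a
#'   `shrunken_beta` placeholder (filled by [add_shrunken_effects()]).
#' @export
call_dms <- function(fits_by_line, alpha_het = 0.05, q_threshold = 0.05,
                     both_lines_only = FALSE) {
  stopifnot(length(fits_by_line) >= 1L)
  usable <- lapply(fits_by_line, function(f) {
    f[f$tested & f$converged & !f$pruned & is.finite(f$beta1) & is.finite(f$se1), ,
      drop = FALSE]
  })
  ids <- unique(unlist(lapply(usable, `[[`, "site_id")))
  if (length(ids) == 0L) return(empty_dms_table())
  key_cols <- c("site_id", "reference", "start", "end", "strand", "mod_code")
  keys <- do.call(rbind, lapply(usable, function(f) f[, key_cols, drop = FALSE]))
  keys <- keys[match(ids, keys$site_id), , drop = FALSE]

  k_lines <- length(usable)
  B <- S <- matrix(NA_real_, nrow = length(ids), ncol = k_lines)
  for (j in seq_len(k_lines)) {
    idx <- match(usable[[j]]$site_id, ids)
    B[idx, j] <- usable[[j]]$beta1
    S[idx, j] <- usable[[j]]$se1
  }
  if (both_lines_only) {
    keep <- rowSums(!is.na(S)) == k_lines
    B <- B[keep, , drop = FALSE]; S <- S[keep, , drop = FALSE]
    keys <- keys[keep, , drop = FALSE]
    if (nrow(keys) == 0L) return(empty_dms_table())
  }
  if (k_lines == 1L) {
    meta <- data.frame(beta_meta = B[, 1L], se_meta = S[, 1L],
                       z = B[, 1L] / S[, 1L], Q = 0, p_Q = 1, k = 1L)
    meta$p <- 2 * stats::pnorm(-abs(meta$z))
  } else if (k_lines == 2L) {
    meta <- meta_two_lines(B[, 1L], S[, 1L], B[, 2L], S[, 2L])
  } else {
    meta <- do.call(rbind, lapply(seq_len(nrow(B)), function(i) {
      ok <- !is.na(S[i, ])
      as.data.frame(fixed_effects_meta(B[i, ok], S[i, ok]))
    }))
  }
  out <- cbind(keys, meta)
  ln <- names(fits_by_line)
  if (is.null(ln)) ln <- paste0("line", seq_len(k_lines))
  for (j in seq_len(k_lines)) {
    out[[paste0("beta_", ln[j])]] <- B[, j]
    out[[paste0("se_", ln[j])]] <- S[, j]
  }
  out$heterogeneous <- out$p_Q < alpha_het & out$k >= 2
  # heterogeneous sites leave the pool before BH: they are not counted in m
  out$q_value <- NA_real_
  for (mc in unique(out$mod_code)) {
    pool <- out$mod_code == mc & !out$heterogeneous
    out$q_value[pool] <- bh_adjust(out$p[pool])
  }
  out$is_dms <- !is.na(out$q_value) & out$q_value < q_threshold
  out$shrunken_beta <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("dms_table", "data.frame")
  out
}

empty_dms_table <- function() {
  out <- data.frame(site_id = character(), reference = character(),
                    start = integer(), end = integer(), strand = character(),
                    mod_code = character(), beta_meta = numeric(),
                    se_meta = numeric(), z = numeric(), p = numeric(),
                    Q = numeric(), p_Q = numeric(), k = integer(),
                    heterogeneous = logical(), q_value = numeric(),
                    is_dms = logical(), shrunken_beta = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("dms_table", "data.frame")
  out
}
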