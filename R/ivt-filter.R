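# Removal of likely false-positive modification calls using the
# in-vitro-transcribed (modification-free) control and coverage thresholds.

#' Filter configuration
#'
#' Thresholds for the artifact/coverage screen applied before testing:
#' a site is kept when its native mean total reads are at least
#' `min_mean_reads`, its native modification proportion is at least
#' `min_native_prop`, and its IVT proportion is strictly below
#' `max_ivt_prop` (sites never observed in any IVT sample pass the IVT rule).
#'
#' @param min_mean_reads Minimum mean total (modified + canonical) reads
#'   across native replicates; default 20.
#' @param min_native_prop Minimum native modification proportion; default 0.05.
#' @param max_ivt_prop Maximum (exclusive) IVT modification proportion;
#'   default 0.05.
#' @param prop_mode How the proportion is computed: `"pooled"` (summed counts,
#'   depth-weighted; default) or `"mean"` (mean of per-replicate proportions
#'   over covered replicates).
#' @param require_ivt_coverage Optional minimum IVT mean coverage a site must
#'   have before the IVT rule can pass it; default 0 (off), i.e. unobserved
#'   sites are not penalised.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mean_reads = 20, min_native_prop = 0.05,
                          max_ivt_prop = 0.05,
                          prop_mode = c("pooled", "mean"),
                          require_ivt_coverage = 0) {
  prop_mode <- match.arg(prop_mode)
  stopifnot(min_native_prop >= 0, min_native_prop <= 1,
            max_ivt_prop >= 0, max_ivt_prop <= 1, min_mean_reads >= 0)
  structure(list(min_mean_reads = min_mean_reads,
                 min_native_prop = min_native_prop,
                 max_ivt_prop = max_ivt_prop,
                 prop_mode = prop_mode,
                 require_ivt_coverage = require_ivt_coverage),
            class = "filter_config")
}

#' Summarize per-site coverage and modification proportion
#'
#' For each site of a count table, computes the mean total reads across the
#' designated replicate set (replicates without coverage contribute 0 to the
#' mean), the pooled modification proportion (summed modified counts over
#' summed totals) and the mean of per-replicate proportions over replicates
#' with coverage.
#'
#' @param table A `site_count_table`.
#' @param sample_ids Replicate set to summarize over; defaults to all samples
#'   in the table.
#' @return Data frame with columns `site_id`, `mean_total_reads`,
#'   `pooled_prop`, `mean_prop` and `covered` (any replicate with coverage;
#'   sites with no coverage report proportion 0 and `covered = FALSE`).
#' @export
summarize_sites <- function(table, sample_ids = table$samples$sample_id) {
  if (length(sample_ids) == 0L) stop("replicate set is empty")
  tab <- subset_table_samples(table, sample_ids)
  tot <- tab$n_mod + tab$n_canonical
  mean_total <- rowMeans(tot)
  sum_mod <- rowSums(tab$n_mod)
  sum_tot <- rowSums(tot)
  pooled <- ifelse(sum_tot > 0, sum_mod / sum_tot, 0)
  prop <- ifelse(tot > 0, tab$n_mod / tot, NA_real_)
  mean_prop <- rowMeans(prop, na.rm = TRUE)
  mean_prop[is.nan(mean_prop)] <- 0
  data.frame(site_id = tab$site_ids,
             mean_total_reads = as.numeric(mean_total),
             pooled_prop = as.numeric(pooled),
             mean_prop = as.numeric(mean_prop),
             covered = sum_tot > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the IVT false-positive filter
#'
#' Retains a site iff (1) native mean total reads >= `min_mean_reads`,
#' (2) native proportion >= `min_native_prop`, and (3) the site is absent
#' from the IVT summary or its IVT proportion is strictly below
#' `max_ivt_prop`. Rules are checked in that order and a failing site is
#' counted against the first rule it fails.
#'
#' @param native_summary Summary of the native replicate group
#'   (see [summarize_sites()]).
#' @param ivt_summary Summary of the IVT group, or `NULL` when the experiment
#'   has no IVT samples (the IVT rule is then skipped).
#' @param cfg A [filter_config()].
#' @return List with `retained` (character vector of site ids) and `report`
#'   (one-row data frame of input / pass / per-rule failure counts).
#' @export
apply_ivt_filter <- function(native_summary, ivt_summary = NULL,
                             cfg = filter_config()) {
  prop <- if (cfg$prop_mode == "pooled") native_summary$pooled_prop else native_summary$mean_prop
  ok_cov <- native_summary$mean_total_reads >= cfg$min_mean_reads
  ok_nat <- prop >= cfg$min_native_prop
  if (is.null(ivt_summary) || nrow(ivt_summary) == 0L) {
    ivt_prop <- rep(NA_real_, nrow(native_summary))
    ivt_cov <- rep(0, nrow(native_summary))
  } else {
    idx <- match(native_summary$site_id, ivt_summary$site_id)
    ip <- if (cfg$prop_mode == "pooled") ivt_summary$pooled_prop else ivt_summary$mean_prop
    ivt_prop <- ifelse(is.na(idx) | !ivt_summary$covered[pmax(idx, 1L)], NA_real_, ip[pmax(idx, 1L)])
    ivt_cov <- ifelse(is.na(idx), 0, ivt_summary$mean_total_reads[pmax(idx, 1L)])
  }
  # unobserved-in-IVT sites pass unless a strict coverage floor is requested
  ok_ivt <- ifelse(is.na(ivt_prop),
                   ivt_cov >= cfg$require_ivt_coverage | cfg$require_ivt_coverage == 0,
                   ivt_prop < cfg$max_ivt_prop)
  keep <- ok_cov & ok_nat & ok_ivt
  report <- data.frame(
    n_input_sites = nrow(native_summary),
    n_pass = sum(keep),
    n_fail_coverage = sum(!ok_cov),
    n_fail_native_prop = sum(ok_cov & !ok_nat),
    n_fail_ivt_prop = sum(ok_cov & ok_nat & !ok_ivt)
  )
  list(retained = native_summary$site_id[keep], report = report)
}

#' Fraction of qualifying sites removed by the IVT rule
#'
#' Among sites that passed the coverage and native-proportion rules, the
#' fraction removed because of nonzero IVT signal — the artifact rate of the
#' modification caller as estimated by the modification-free control.
#'
#' @param report Filter report from [apply_ivt_filter()].
#' @return Fraction in \[0, 1\] (0 when no site qualified).
#' @export
artifact_rate <- function(report) {
  qualifying <- report$n_pass + report$n_fail_ivt_prop
  if (qualifying == 0) return(0)
  report$n_fail_ivt_prop / qualifying
}
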