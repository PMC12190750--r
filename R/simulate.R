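# Synthetic bedMethyl experiment generator with ground truth. Emulates the
# statistical structure the caller assumes: per-site binomial modification
# counts over negative-binomial coverage, replicate structure across two cell
# lines and two glucose conditions, an IVT artifact process, condition
# effects on the log-odds scale, line-specific (heterogeneous) effects, and
# injectable outlier replicates.

#' Simulation configuration
#'
#' Defaults mirror the study design the caller targets: two cell lines with
#' 3 and 4 biological replicates, each cultured under a low and a high
#' glucose condition, one IVT (modification-free) sample per line and
#' condition, negative-binomial per-site coverage, baseline modification
#' proportions from a Beta(2, 8) truncated to >= 0.05, a ~1% basecall error
#' floor (Beta(1, 99)) at unmodified positions, and IVT artifact sites whose
#' spurious proportion is drawn from Beta(2, 8).
#'
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @param n_sites Sites per modification code.
#' @param mod_codes Modification codes to simulate.
#' @param replicates Named integer vector: biological replicates per cell
#'   line (each replicate yields one low- and one high-condition sample).
#' @param ivt_replicates IVT samples per line and condition.
#' @param depth_mean,depth_dispersion Negative-binomial coverage mean and
#'   size for native samples.
#' @param ivt_depth_mean Coverage mean for IVT samples (defaults to the
#'   native depth).
#' @param baseline_shape Beta shape parameters of the baseline modification
#'   proportion at genuinely modified sites (truncated to
#'   `>= baseline_floor`).
#' @param baseline_floor Truncation floor of the baseline proportion.
#' @param error_floor_shape Beta shape parameters of the basecall error floor
#'   at unmodified positions.
#' @param artifact_shape Beta shape parameters of the spurious proportion at
#'   IVT artifact sites.
#' @param frac_dms Fraction of (non-artifact) sites with a shared condition
#'   effect.
#' @param frac_heterogeneous Fraction of sites with line-specific effects
#'   (each line draws an independent effect and sign).
#' @param frac_ivt_artifact Fraction of sites that are caller artifacts
#'   (spurious signal in native and IVT alike, no condition effect).
#' @param effect_dist `"fixed"` (|delta logit| = `effect_size`, random sign)
#'   or `"normal"` (delta ~ N(0, `effect_tau`^2)).
#' @param effect_size,effect_tau Effect magnitude parameters.
#' @param outlier_rate Fraction of effect-bearing sites receiving one
#'   swapped-condition outlier replicate.
#' @param sites_per_transcript,transcripts_per_gene Layout of sites on the
#'   synthetic transcriptome (drives the bundled gene map).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 1000L,
                       mod_codes = "a",
                       replicates = c(lineA = 3L, lineB = 4L),
                       ivt_replicates = 1L,
                       depth_mean = 60,
                       depth_dispersion = 5,
                       ivt_depth_mean = depth_mean,
                       baseline_shape = c(2, 8),
                       baseline_floor = 0.05,
                       error_floor_shape = c(1, 99),
                       artifact_shape = c(2, 8),
                       frac_dms = 0.1,
                       frac_heterogeneous = 0.02,
                       frac_ivt_artifact = 0.05,
                       effect_dist = c("fixed", "normal"),
                       effect_size = 1.5,
                       effect_tau = 1,
                       outlier_rate = 0,
                       sites_per_transcript = 5L,
                       transcripts_per_gene = 2L) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(frac_dms >= 0, frac_dms <= 1, frac_heterogeneous >= 0,
            frac_ivt_artifact >= 0, frac_dms + frac_heterogeneous + frac_ivt_artifact <= 1,
            all(replicates >= 2), n_sites >= 1, outlier_rate >= 0, outlier_rate <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rbeta_floor <- function(n, shape, floor) {
  # inverse-CDF draw from Beta truncated to [floor, 1]
  lo <- stats::pbeta(floor, shape[1], shape[2])
  stats::qbeta(lo + stats::runif(n) * (1 - lo), shape[1], shape[2])
}

#' Simulate a native + IVT bedMethyl experiment with known truth
#'
#' Draws per-site truth (baseline proportion, per-line condition effects on
#' the log-odds scale, artifact status), then per-sample counts: coverage
#' `n ~ NegBin(depth_mean, depth_dispersion)` and modified reads
#' `~ Binomial(n, p)` with `logit(p) = logit(baseline) + delta_line * 1[high]`.
#' Artifact sites show their spurious proportion in native and IVT samples
#' alike; other sites show the basecall error floor in IVT. Outlier
#' replicates have the two conditions' proportions swapped. When `dir` is
#' given, writes one bedMethyl file per sample plus `samples.tsv`,
#' `truth.tsv` and `gene_map.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed), or `NULL` to keep the
#'   experiment in memory only.
#' @return List of class `sim_experiment` with `sheet` (sample sheet,
#'   including paths when written), `truth` (ground-truth data frame),
#'   `gene_map`, `records` (per-sample list of bedMethyl record frames) and
#'   `cfg`.
#' @export
simulate_experiment <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  lines <- names(cfg$replicates)

  truth_list <- list()
  for (mc in cfg$mod_codes) {
    n <- cfg$n_sites
    ntx <- ceiling(n / cfg$sites_per_transcript)
    tx <- sprintf("%s_tx%05d", mc, rep(seq_len(ntx), each = cfg$sites_per_transcript))[seq_len(n)]
    pos <- 50L * stats::ave(seq_len(n), tx, FUN = seq_along)
    cat_draw <- stats::runif(n)
    is_artifact <- cat_draw < cfg$frac_ivt_artifact
    is_het <- !is_artifact & cat_draw < cfg$frac_ivt_artifact + cfg$frac_heterogeneous
    is_dms_cat <- !is_artifact & !is_het &
      cat_draw < cfg$frac_ivt_artifact + cfg$frac_heterogeneous + cfg$frac_dms

    baseline <- rbeta_floor(n, cfg$baseline_shape, cfg$baseline_floor)
    artifact_prop <- stats::rbeta(n, cfg$artifact_shape[1], cfg$artifact_shape[2])
    error_floor <- stats::rbeta(n, cfg$error_floor_shape[1], cfg$error_floor_shape[2])

    draw_effect <- function(m) {
      if (cfg$effect_dist == "fixed") {
        cfg$effect_size * sample(c(-1, 1), m, replace = TRUE)
      } else {
        stats::rnorm(m, 0, cfg$effect_tau)
      }
    }
    delta <- matrix(0, n, length(lines), dimnames = list(NULL, lines))
    shared <- draw_effect(n)
    for (L in lines) delta[is_dms_cat, L] <- shared[is_dms_cat]
    for (L in lines) delta[is_het, L] <- draw_effect(sum(is_het))

    truth_list[[mc]] <- data.frame(
      reference = tx, start = pos, end = pos + 1L, strand = "+", mod_code = mc,
      baseline = baseline, artifact_prop = artifact_prop,
      error_floor = error_floor,
      is_dms = is_dms_cat | is_het, is_artifact = is_artifact,
      is_heterogeneous = is_het,
      outlier_line = NA_character_, outlier_replicate = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (L in lines) truth_list[[mc]][[paste0("delta_", L)]] <- delta[, L]

    # one swapped-condition outlier replicate for a fraction of
    # effect-bearing sites, in a randomly chosen line
    can_outlie <- which(is_dms_cat | is_het)
    n_out <- round(cfg$outlier_rate * length(can_outlie))
    if (n_out > 0) {
      sel <- sample(can_outlie, n_out)
      ol <- sample(lines, n_out, replace = TRUE)
      truth_list[[mc]]$outlier_line[sel] <- ol
      truth_list[[mc]]$outlier_replicate[sel] <-
        vapply(ol, function(L) sample.int(cfg$replicates[[L]], 1L), 1L)
    }
  }
  truth <- do.call(rbind, truth_list)
  truth$site_id <- site_id(truth$reference, truth$start, truth$strand, truth$mod_code)
  rownames(truth) <- NULL

  # sample sheet
  rows <- list()
  for (L in lines) {
    for (r in seq_len(cfg$replicates[[L]])) {
      for (cond in c("low", "high")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_rep%d", L, cond, r), cell_line = L,
          condition = cond, material = "native", replicate = r,
          stringsAsFactors = FALSE)
      }
    }
    for (r in seq_len(cfg$ivt_replicates)) {
      for (cond in c("low", "high")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_ivt%d", L, cond, r), cell_line = L,
          condition = cond, material = "IVT", replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)

  # per-site success probability for each sample
  p_for_sample <- function(smp) {
    p <- numeric(nrow(truth))
    L <- smp$cell_line
    if (smp$material == "IVT") {
      p <- ifelse(truth$is_artifact, truth$artifact_prop, truth$error_floor)
    } else {
      cond_eff <- smp$condition == "high"
      swap <- !is.na(truth$outlier_line) & truth$outlier_line == L &
        truth$outlier_replicate == smp$replicate
      eff_high <- xor(cond_eff, swap)  # swapped replicates see the other condition's p
      d <- truth[[paste0("delta_", L)]]
      p <- stats::plogis(stats::qlogis(truth$baseline) + d * eff_high)
      p[truth$is_artifact] <- truth$artifact_prop[truth$is_artifact]
    }
    p
  }

  records <- vector("list", nrow(sheet))
  names(records) <- sheet$sample_id
  for (i in seq_len(nrow(sheet))) {
    smp <- sheet[i, ]
    mu <- if (smp$material == "IVT") cfg$ivt_depth_mean else cfg$depth_mean
    nv <- stats::rnbinom(nrow(truth), mu = mu, size = cfg$depth_dispersion)
    m <- stats::rbinom(nrow(truth), nv, p_for_sample(smp))
    keep <- nv > 0
    records[[i]] <- data.frame(
      reference = truth$reference[keep], start = truth$start[keep],
      end = truth$end[keep], strand = truth$strand[keep],
      mod_code = truth$mod_code[keep],
      n_valid = nv[keep], n_mod = m[keep],
      n_canonical = nv[keep] - m[keep], n_other = 0L,
      percent_modified = ifelse(nv[keep] > 0, m[keep] / nv[keep], 0),
      stringsAsFactors = FALSE
    )
  }

  gene_map <- local({
    tx <- unique(truth$reference)
    gi <- ceiling(seq_along(tx) / cfg$transcripts_per_gene)
    data.frame(transcript_id = tx,
               gene_id = sprintf("gene%05d", gi),
               gene_name = sprintf("GENE%05d", gi),
               stringsAsFactors = FALSE)
  })

  sheet$path <- NA_character_
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(sheet))) {
      sheet$path[i] <- file.path(dir, paste0(sheet$sample_id[i], ".bedmethyl"))
      write_bedmethyl(records[[i]], sheet$path[i])
    }
    sheet_out <- sheet
    sheet_out$path <- basename(sheet_out$path)  # portable, resolved on read
    utils::write.table(sheet_out, file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(gene_map, file.path(dir, "gene_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(list(sheet = sheet, truth = truth, gene_map = gene_map,
                 records = records, cfg = cfg, dir = dir),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", nrow(x$truth), "sites x", nrow(x$sheet), "samples;",
      sum(x$truth$is_dms), "true DMS,", sum(x$truth$is_artifact),
      "IVT artifacts (seed", x$cfg$seed, ")\n")
  invisible(x)
}

# Count tables straight from an in-memory simulated experiment (no file IO).
sim_count_tables <- function(sim) {
  recs <- mapply(function(r, id) {
    if (nrow(r)) r$sample_id <- id
    r
  }, sim$records, sim$sheet$sample_id, SIMPLIFY = FALSE)
  all_rec <- do.call(rbind, recs)
  out <- list()
  for (mc in sim$cfg$mod_codes) {
    sub <- all_rec[all_rec$mod_code == mc, , drop = FALSE]
    out[[mc]] <- list(
      native = make_count_table(sub, sim$sheet[sim$sheet$material == "native", , drop = FALSE], mc),
      ivt = make_count_table(sub, sim$sheet[sim$sheet$material == "IVT", , drop = FALSE], mc)
    )
  }
  out
}

#' Evaluate a DMS call set against simulation truth
#'
#' @param dms A `dms_table` from [call_dms()].
#' @param truth Truth table from [simulate_experiment()].
#' @param retained Optional character vector of site ids that survived the
#'   IVT filter, enabling the artifact-removal metric.
#' @param min_depth Mean native depth above which the effect-recovery metrics
#'   are computed (deeply covered sites); default 0 (all).
#' @param depth Optional named vector of per-site mean native depths
#'   (required when `min_depth > 0`).
#' @return List of metrics: `n_called`, `fdp` (realized false-discovery
#'   proportion among called DMS), `power` (true shared-effect DMS recovered
#'   among those that entered testing), `effect_cor` / `shrunken_cor`
#'   (Pearson correlation of estimated and true effects on true-DMS sites),
#'   `rmse_raw` / `rmse_shrunken`, and `artifact_removal_rate` when
#'   `retained` is supplied.
#' @export
truth_eval <- function(dms, truth, retained = NULL, min_depth = 0,
                       depth = NULL) {
  idx <- match(dms$site_id, truth$site_id)
  if (nrow(dms) > 0 && all(is.na(idx))) stop("DMS table and truth share no sites")
  tr <- truth[idx, , drop = FALSE]
  delta_cols <- grep("^delta_", names(truth), value = TRUE)
  true_eff <- rowMeans(as.matrix(tr[, delta_cols, drop = FALSE]))
  is_null <- !tr$is_dms

  called <- which(dms$is_dms)
  fdp <- if (length(called)) mean(is_null[called]) else 0

  # power over true shared-effect sites that entered testing
  shared_true <- which(tr$is_dms & !tr$is_heterogeneous)
  power <- if (length(shared_true)) mean(dms$is_dms[shared_true]) else NA_real_

  sel <- shared_true
  if (min_depth > 0) {
    if (is.null(depth)) stop("depth vector required when min_depth > 0")
    sel <- sel[depth[dms$site_id[sel]] >= min_depth]
  }
  eff_cor <- shr_cor <- rmse_raw <- rmse_shr <- NA_real_
  if (length(sel) >= 3) {
    eff_cor <- stats::cor(dms$beta_meta[sel], true_eff[sel])
    rmse_raw <- sqrt(mean((dms$beta_meta[sel] - true_eff[sel])^2))
    if (any(is.finite(dms$shrunken_beta[sel]))) {
      shr_cor <- stats::cor(dms$shrunken_beta[sel], true_eff[sel])
      rmse_shr <- sqrt(mean((dms$shrunken_beta[sel] - true_eff[sel])^2))
    }
  }
  out <- list(n_called = length(called), fdp = fdp, power = power,
              power_deep = if (length(sel)) mean(dms$is_dms[sel]) else NA_real_,
              effect_cor = eff_cor, shrunken_cor = shr_cor,
              rmse_raw = rmse_raw, rmse_shrunken = rmse_shr)
  if (!is.null(retained)) {
    art <- truth$site_id[truth$is_artifact]
    out$artifact_removal_rate <- if (length(art)) mean(!(art %in% retained)) else NA_real_
  }
  out
}
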