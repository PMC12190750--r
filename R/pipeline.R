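# End-to-end differential modification calling: IVT/coverage filter ->
# per-line binomial GLM fits -> fixed-effects meta-analysis -> BH FDR ->
# adaptive shrinkage -> optional gene-set enrichment.

#' Call differentially modified sites from a sample sheet
#'
#' The central fitter. For each requested modification code it (1) assembles
#' native and IVT count tables, (2) removes sites failing the coverage /
#' native-proportion / IVT false-positive screen, (3) fits the per-site
#' binomial GLM within each cell line with Cook's-distance influence
#' pruning, (4) meta-analyzes lines with the inverse-variance fixed-effects
#' model, drops heterogeneous sites (Cochran's Q), adjusts by
#' Benjamini-Hochberg and calls sites at FDR below `q_threshold`, and
#' (5) attaches adaptive-shrinkage posterior-mean effects. When a gene map
#' and gene sets are supplied, hypergeometric enrichment of DMS-bearing
#' genes is computed as well.
#'
#' @param sheet Sample sheet data frame (see [read_sample_sheet()]) or path
#'   to a sample sheet TSV.
#' @param mod_codes Modification codes to analyze.
#' @param filter A [filter_config()] holding the screening thresholds.
#' @param alpha_influence Cook's P-value pruning threshold; default 0.05.
#' @param alpha_het Cochran's Q heterogeneity threshold; default 0.05.
#' @param q_threshold FDR threshold for the DMS call; default 0.05.
#' @param both_lines_only Restrict the meta-analysis to sites testable in
#'   every line; default `FALSE`.
#' @param bh_scope `"per_mod"` (default) adjusts within each modification
#'   code; `"global"` adjusts across all codes jointly.
#' @param ivt_per_line Match IVT controls to their own cell line instead of
#'   pooling IVT samples across lines; default `FALSE`.
#' @param gene_map,gene_sets Optional transcript-to-gene map and gene sets
#'   for enrichment (see [read_gene_map()], [read_gene_sets()]).
#' @param tables Optional precomputed output of [build_count_tables()]
#'   (skips file reading).
#' @return Object of class `dms_fit` with components `dms` (the combined
#'   `dms_table`), `fits` (per mod code, per line `site_fits`), `retained`,
#'   `filter_report`, `enrichment` (or `NULL`) and `config`. Methods:
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 7, n_sites = 150))
#' fit <- dms_call(sim$sheet, tables = dmscall:::sim_count_tables(sim))
#' fit
#' head(coef(fit))
#' @export
dms_call <- function(sheet, mod_codes = NULL,
                     filter = filter_config(),
                     alpha_influence = 0.05, alpha_het = 0.05,
                     q_threshold = 0.05, both_lines_only = FALSE,
                     bh_scope = c("per_mod", "global"),
                     ivt_per_line = FALSE,
                     gene_map = NULL, gene_sets = NULL,
                     tables = NULL) {
  bh_scope <- match.arg(bh_scope)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  validate_sample_sheet(sheet)
  if (is.null(mod_codes)) {
    mod_codes <- if (is.null(tables)) dms_mod_codes() else names(tables)
  }
  if (!all(mod_codes %in% dms_mod_codes()))
    stop("unknown modification code(s): ",
         paste(setdiff(mod_codes, dms_mod_codes()), collapse = ", "))
  if (is.null(tables)) tables <- build_count_tables(sheet, mod_codes)

  lines <- unique(sheet$cell_line[sheet$material == "native"])
  no_ivt <- !any(sheet$material == "IVT")
  if (no_ivt) {
    warning("no IVT samples in the sheet; filtering on coverage and native ",
            "proportion only")
  }

  fits <- retained <- list()
  reports <- list()
  dms_parts <- list()
  for (mc in mod_codes) {
    nat <- tables[[mc]]$native
    ivt <- tables[[mc]]$ivt
    if (is.null(nat) || length(nat$site_ids) == 0L) next
    nat_summary <- summarize_sites(nat)
    ivt_summary <- if (is.null(ivt)) NULL else summarize_sites(ivt)
    flt <- apply_ivt_filter(nat_summary, ivt_summary, filter)
    reports[[mc]] <- cbind(mod_code = mc, flt$report)
    retained[[mc]] <- flt$retained

    fits[[mc]] <- list()
    for (L in lines) {
      elig <- flt$retained
      if (ivt_per_line && !is.null(ivt)) {
        ivt_line <- ivt$samples$sample_id[ivt$samples$cell_line == L]
        if (length(ivt_line)) {
          flt_line <- apply_ivt_filter(nat_summary,
                                       summarize_sites(ivt, ivt_line), filter)
          elig <- flt_line$retained
        }
      }
      fits[[mc]][[L]] <- test_sites_per_line(nat, L, cfg = filter,
                                             alpha_influence = alpha_influence,
                                             eligible_sites = elig)
    }
    dms_parts[[mc]] <- call_dms(fits[[mc]], alpha_het = alpha_het,
                                q_threshold = q_threshold,
                                both_lines_only = both_lines_only)
  }
  dms <- if (length(dms_parts)) do.call(rbind, dms_parts) else empty_dms_table()
  rownames(dms) <- NULL
  class(dms) <- c("dms_table", "data.frame")
  if (bh_scope == "global" && nrow(dms)) {
    pool <- !dms$heterogeneous
    dms$q_value <- NA_real_
    dms$q_value[pool] <- bh_adjust(dms$p[pool])
    dms$is_dms <- !is.na(dms$q_value) & dms$q_value < q_threshold
  }
  if (nrow(dms)) dms <- add_shrunken_effects(dms)

  enr <- NULL
  if (!is.null(gene_map) && !is.null(gene_sets) && nrow(dms)) {
    enr <- enrich_gene_sets(dms, gene_map, gene_sets)
  }
  structure(list(
    dms = dms, fits = fits, retained = retained,
    filter_report = if (length(reports)) do.call(rbind, reports) else NULL,
    enrichment = enr,
    config = list(filter = filter, alpha_influence = alpha_influence,
                  alpha_het = alpha_het, q_threshold = q_threshold,
                  both_lines_only = both_lines_only, bh_scope = bh_scope,
                  ivt_per_line = ivt_per_line, lines = lines, no_ivt = no_ivt)
  ), class = "dms_fit")
}

#' @export
print.dms_fit <- function(x, ...) {
  cat("Differential RNA modification fit\n")
  cat("  cell lines:", paste(x$config$lines, collapse = ", "), "\n")
  if (!is.null(x$filter_report)) {
    for (i in seq_len(nrow(x$filter_report))) {
      r <- x$filter_report[i, ]
      cat(sprintf("  [%s] %d sites in, %d passed filter", r$mod_code,
                  r$n_input_sites, r$n_pass))
      d <- x$dms[x$dms$mod_code == r$mod_code, ]
      cat(sprintf(", %d meta-analyzed, %d DMS at FDR < %g\n",
                  nrow(d), sum(d$is_dms), x$config$q_threshold))
    }
  }
  invisible(x)
}

#' @export
summary.dms_fit <- function(object, ...) {
  d <- object$dms
  per_mod <- do.call(rbind, lapply(split(d, d$mod_code), function(s) {
    data.frame(mod_code = s$mod_code[1], n_tested = nrow(s),
               n_heterogeneous = sum(s$heterogeneous),
               n_dms = sum(s$is_dms),
               median_abs_effect = stats::median(abs(s$beta_meta)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_mod) <- NULL
  out <- list(per_mod = per_mod, config = object$config,
              enrichment = object$enrichment)
  class(out) <- "summary.dms_fit"
  out
}

#' @export
print.summary.dms_fit <- function(x, ...) {
  cat("DMS call summary (FDR <", x$config$q_threshold, ")\n")
  print(x$per_mod, row.names = FALSE)
  if (!is.null(x$enrichment)) {
    cat("\nGene-set enrichment:\n")
    print(x$enrichment, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dms_fit <- function(object, shrunken = FALSE, ...) {
  v <- if (shrunken) object$dms$shrunken_beta else object$dms$beta_meta
  stats::setNames(v, object$dms$site_id)
}

#' Volcano plot of a DMS fit
#'
#' Meta-analysis effect size (log-odds difference, high vs low) against
#' -log10 P, one panel per modification code; called sites are highlighted.
#'
#' @param x A `dms_fit`.
#' @param shrunken Plot shrunken instead of raw effects; default `FALSE`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dms_fit <- function(x, shrunken = FALSE, ...) {
  d <- x$dms
  if (nrow(d) == 0L) stop("nothing to plot: empty DMS table")
  mods <- unique(d$mod_code)
  op <- graphics::par(mfrow = c(1, length(mods)))
  on.exit(graphics::par(op))
  for (mc in mods) {
    s <- d[d$mod_code == mc, ]
    b <- if (shrunken) s$shrunken_beta else s$beta_meta
    graphics::plot(b, -log10(pmax(s$p, 1e-300)),
                   col = ifelse(s$is_dms, "dodgerblue3", "grey60"),
                   pch = 16, cex = 0.6,
                   xlab = "log-odds effect (high vs low)",
                   ylab = expression(-log[10] ~ P), main = mc, ...)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' Run the pipeline on files and write stage outputs
#'
#' File-level wrapper around [dms_call()]: reads the sample sheet (and
#' optional gene map / gene sets), runs the full calling pipeline and writes
#' `filter_report.tsv`, per-line `fits_<mod>_<line>.tsv`, `dms_table.tsv`,
#' `retained_sites.bed`, optional `enrichment.tsv` and a `manifest.txt`
#' recording package version and every threshold, so a run can be reproduced
#' exactly.
#'
#' @param sheet_path Path to the sample sheet TSV.
#' @param out_dir Output directory (created if needed).
#' @param gene_map_path,gene_sets_path Optional TSV inputs for enrichment.
#' @param ... Passed to [dms_call()].
#' @return The `dms_fit`, invisibly.
#' @export
run_dms_pipeline <- function(sheet_path, out_dir,
                             gene_map_path = NULL, gene_sets_path = NULL,
                             ...) {
  sheet <- read_sample_sheet(sheet_path)
  gene_map <- if (!is.null(gene_map_path)) read_gene_map(gene_map_path)
  gene_sets <- if (!is.null(gene_sets_path)) read_gene_sets(gene_sets_path)
  fit <- dms_call(sheet, gene_map = gene_map, gene_sets = gene_sets, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  if (!is.null(fit$filter_report)) wt(fit$filter_report, "filter_report.tsv")
  for (mc in names(fit$fits)) {
    for (L in names(fit$fits[[mc]])) {
      wt(fit$fits[[mc]][[L]], sprintf("fits_%s_%s.tsv", mc, L))
    }
  }
  wt(fit$dms, "dms_table.tsv")
  bed <- fit$dms[fit$dms$is_dms,
                 c("reference", "start", "end", "site_id", "q_value", "strand")]
  wt(bed, "dms_sites.bed")
  if (!is.null(fit$enrichment)) wt(fit$enrichment, "enrichment.tsv")
  cfg <- fit$config
  writeLines(c(
    paste0("dmscall version: ", as.character(utils::packageVersion("dmscall"))),
    paste0("sample_sheet: ", sheet_path),
    paste0("min_mean_reads: ", cfg$filter$min_mean_reads),
    paste0("min_native_prop: ", cfg$filter$min_native_prop),
    paste0("max_ivt_prop: ", cfg$filter$max_ivt_prop),
    paste0("prop_mode: ", cfg$filter$prop_mode),
    paste0("alpha_influence: ", cfg$alpha_influence),
    paste0("alpha_het: ", cfg$alpha_het),
    paste0("q_threshold: ", cfg$q_threshold),
    paste0("both_lines_only: ", cfg$both_lines_only),
    paste0("bh_scope: ", cfg$bh_scope),
    paste0("n_dms: ", sum(fit$dms$is_dms))
  ), file.path(out_dir, "manifest.txt"))
  invisible(fit)
}
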