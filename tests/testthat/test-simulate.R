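# Synthetic experiment generator: determinism, validity of outputs, truth
# bookkeeping and evaluation metrics.

test_that("the experiment is byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 123, n_sites = 80, outlier_rate = 0.2)
  simulate_experiment(cfg, dir = d1)
  simulate_experiment(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  simulate_experiment(sim_config(seed = 124, n_sites = 80), dir = d2)
  expect_false(identical(readLines(file.path(d1, "lineA_low_rep1.bedmethyl")),
                         readLines(file.path(d2, "lineA_low_rep1.bedmethyl"))))
})

test_that("generated files are valid bedMethyl inputs with zero parse warnings", {
  d <- withr::local_tempdir()
  sim <- simulate_experiment(sim_config(seed = 5, n_sites = 60,
                                        mod_codes = c("a", "17802")), dir = d)
  sheet <- read_sample_sheet(file.path(d, "samples.tsv"))
  expect_equal(nrow(sheet), nrow(sim$sheet))
  for (p in sheet$path) {
    expect_no_warning(rec <- read_bedmethyl(p))
    expect_true(all(rec$n_mod + rec$n_canonical + rec$n_other == rec$n_valid))
    expect_true(all(rec$end == rec$start + 1L))
  }
  tabs <- build_count_tables(sheet, mod_codes = c("a", "17802"))
  expect_equal(length(tabs[["a"]]$native$site_ids), 60L)
  expect_equal(ncol(tabs[["a"]]$native$n_mod), 14L)  # (3+4) replicates x 2 conditions
  expect_equal(ncol(tabs[["a"]]$ivt$n_mod), 4L)      # 1 IVT per line and condition
})

test_that("truth fractions and site categories respect the configuration", {
  sim <- simulate_experiment(sim_config(seed = 8, n_sites = 4000,
                                        frac_dms = 0.1,
                                        frac_ivt_artifact = 0.05,
                                        frac_heterogeneous = 0.02))
  tr <- sim$truth
  expect_equal(mean(tr$is_artifact), 0.05, tolerance = 0.35)
  expect_equal(mean(tr$is_heterogeneous), 0.02, tolerance = 0.5)
  # categories are mutually exclusive
  expect_false(any(tr$is_artifact & tr$is_dms))
  # every flagged DMS carries a nonzero effect in at least one line
  d <- abs(tr$delta_lineA) + abs(tr$delta_lineB)
  expect_true(all(d[tr$is_dms] > 0))
  expect_true(all(d[!tr$is_dms] == 0))
  # artifact proportions clear the 5% screen about as often as the
  # Beta(2, 8) upper tail says
  expect_equal(mean(tr$artifact_prop[tr$is_artifact] >= 0.05),
               pbeta(0.05, 2, 8, lower.tail = FALSE), tolerance = 0.05)
})

test_that("swapped-condition outliers land where the truth says", {
  sim <- simulate_experiment(sim_config(seed = 17, n_sites = 200,
                                        frac_dms = 1, frac_ivt_artifact = 0,
                                        frac_heterogeneous = 0,
                                        depth_mean = 400, effect_size = 3,
                                        outlier_rate = 1))
  tr <- sim$truth
  expect_true(all(!is.na(tr$outlier_line)))
  tabs <- dmscall:::sim_count_tables(sim)
  tab <- tabs[["a"]]$native
  # at a deep site with a huge effect, the swapped replicate's low sample
  # should look like the high condition
  i <- 1L
  L <- tr$outlier_line[i]; r <- tr$outlier_replicate[i]
  smp <- tab$samples
  swapped_low <- smp$sample_id == sprintf("%s_low_rep%d", L, r)
  normal_low <- smp$cell_line == L & smp$condition == "low" & !swapped_low
  prop <- tab$n_mod[i, ] / (tab$n_mod[i, ] + tab$n_canonical[i, ])
  p_low <- plogis(qlogis(tr$baseline[i]))
  p_high <- plogis(qlogis(tr$baseline[i]) + tr[[paste0("delta_", L)]][i])
  expect_lt(abs(prop[swapped_low] - p_high), abs(prop[swapped_low] - p_low))
  expect_true(all(abs(prop[normal_low] - p_low) < abs(prop[normal_low] - p_high)))
})

test_that("truth evaluation scores a perfect and an empty caller correctly", {
  sim <- simulate_experiment(sim_config(seed = 9, n_sites = 50,
                                        frac_ivt_artifact = 0))
  tr <- sim$truth
  dms <- data.frame(site_id = tr$site_id, reference = tr$reference,
                    start = tr$start, end = tr$end, strand = tr$strand,
                    mod_code = tr$mod_code,
                    beta_meta = rowMeans(cbind(tr$delta_lineA, tr$delta_lineB)),
                    se_meta = 0.1, z = 0, p = 1, Q = 0, p_Q = 1, k = 2L,
                    heterogeneous = FALSE,
                    q_value = ifelse(tr$is_dms, 0.001, 0.9),
                    is_dms = tr$is_dms,
                    shrunken_beta = NA_real_, stringsAsFactors = FALSE)
  ev <- truth_eval(dms, tr)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$power, 1)
  expect_equal(ev$effect_cor, 1, tolerance = 1e-12)
  dms$is_dms <- FALSE
  ev0 <- truth_eval(dms, tr)
  expect_equal(ev0$n_called, 0L)
  expect_equal(ev0$power, 0)
  dms$site_id <- paste0("nope", seq_len(nrow(dms)))
  expect_error(truth_eval(dms, tr), "share no sites")
})
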