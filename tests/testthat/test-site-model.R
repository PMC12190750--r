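# Per-site binomial GLM: closed-form agreement, Wald symmetry, influence
# diagnostics.

test_that("the IRLS fit equals the pooled log-odds closed form on the worked case", {
  # pooled low (M0=10, C0=90), high (M1=30, C1=70) split over replicates
  m <- c(5, 5, 15, 15); cc <- c(45, 45, 35, 35)
  cond <- c("low", "low", "high", "high")
  f <- fit_site_glm(m, cc, cond)
  expect_true(f$converged)
  expect_equal(f$beta1, log(27 / 7), tolerance = 1e-10)
  expect_equal(f$se1, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90), tolerance = 1e-10)
})

test_that("identical pooled counts give a zero effect with P = 1", {
  f <- fit_site_glm(c(10, 10), c(40, 40), c("low", "high"))
  expect_equal(f$beta1, 0, tolerance = 1e-12)
  expect_equal(f$p, 1, tolerance = 1e-12)
})

test_that("swapping condition labels negates the effect and keeps se and P", {
  set.seed(3)
  m <- rbinom(7, 80, 0.3); cc <- 80 - m
  cond <- c(rep("low", 3), rep("high", 4))
  f1 <- fit_site_glm(m, cc, cond)
  f2 <- fit_site_glm(m, cc, ifelse(cond == "low", "high", "low"))
  expect_equal(f2$beta1, -f1$beta1, tolerance = 1e-9)
  expect_equal(f2$se1, f1$se1, tolerance = 1e-9)
  expect_equal(f2$p, f1$p, tolerance = 1e-9)
})

test_that("IRLS agrees with the closed-form oracle on random tables", {
  set.seed(101)
  for (i in 1:200) {
    ns <- sample(4:8, 1)
    cond <- sample(rep(c("low", "high"), length.out = ns))
    tot <- rnbinom(ns, mu = 60, size = 5) + 5
    p0 <- runif(1, 0.05, 0.8)
    d <- runif(1, -1.5, 1.5)
    p <- plogis(qlogis(p0) + d * (cond == "high"))
    m <- rbinom(ns, tot, p)
    if (min(tapply(m, cond, sum)) == 0 || min(tapply(tot - m, cond, sum)) == 0) next
    f <- fit_site_glm(m, tot - m, cond)
    o <- oracle_pooled_logodds(m, tot - m, cond)
    expect_equal(f$beta1, o$beta1, tolerance = 1e-8)
    expect_equal(f$se1, o$se1, tolerance = 1e-8)
    expect_equal(f$beta0, o$beta0, tolerance = 1e-8)
  }
})

test_that("quasi-complete separation is flagged non-estimable", {
  f <- fit_site_glm(c(0, 0, 5, 6), c(50, 50, 45, 44),
                    c("low", "low", "high", "high"))
  expect_false(f$converged)
  expect_true(is.na(f$beta1))
})

test_that("scaling depth shrinks the standard error monotonically", {
  se <- vapply(c(1, 2, 4, 8), function(k) {
    fit_site_glm(k * c(10, 12, 30, 28), k * c(90, 88, 70, 72),
                 c("low", "low", "high", "high"))$se1
  }, 0)
  expect_true(all(diff(se) < 0))
})

test_that("Cook's distances match the hat-matrix recomputation and leverages sum to 2", {
  set.seed(7)
  for (i in 1:25) {
    ns <- 7
    cond <- c(rep("low", 3), rep("high", 4))
    tot <- rnbinom(ns, mu = 100, size = 5) + 10
    m <- rbinom(ns, tot, plogis(rnorm(1, -1, 0.5) + 0.8 * (cond == "high")))
    if (min(tapply(m, cond, sum)) == 0 || min(tapply(tot - m, cond, sum)) == 0) next
    f <- fit_site_glm(m, tot - m, cond)
    o <- oracle_cooks(m, tot - m, cond)
    expect_equal(f$cooks_d, o$D, tolerance = 1e-8)
    expect_equal(sum(f$leverages), 2, tolerance = 1e-8)
    expect_equal(f$cooks_p, pf(o$D, 2, ns - 2, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("a zero residual gives Cook's P of one; symmetric designs share D within condition", {
  # identical counts within each condition: residuals vanish
  f <- fit_site_glm(c(10, 10, 25, 25), c(90, 90, 75, 75),
                    c("low", "low", "high", "high"))
  expect_equal(f$cooks_d, rep(0, 4), tolerance = 1e-12)
  expect_equal(f$cooks_p, rep(1, 4))
  # equal counts within condition but nonzero residual structure
  f2 <- fit_site_glm(c(10, 14, 25, 29), c(90, 86, 75, 71),
                     c("low", "low", "high", "high"))
  expect_equal(f2$cooks_d[1], f2$cooks_d[2], tolerance = 1e-10)
  expect_equal(f2$cooks_d[3], f2$cooks_d[4], tolerance = 1e-10)
})

test_that("per-line testing applies eligibility, flags separation and prunes outliers", {
  sim <- simulate_experiment(sim_config(seed = 21, n_sites = 120,
                                        frac_dms = 0.5, frac_ivt_artifact = 0,
                                        frac_heterogeneous = 0,
                                        depth_mean = 100, outlier_rate = 0.3))
  tabs <- dmscall:::sim_count_tables(sim)
  fits <- test_sites_per_line(tabs[["a"]]$native, "lineA")
  expect_s3_class(fits, "site_fits")
  expect_equal(nrow(fits), length(tabs[["a"]]$native$site_ids))
  # pruning only ever removes tested, converged sites
  expect_true(all(fits$tested[fits$pruned]))
  expect_true(all(fits$converged[fits$pruned]))
  # outlier replicates in this line should drive pruning far above baseline
  tr <- sim$truth[match(fits$site_id, sim$truth$site_id), ]
  has_out <- !is.na(tr$outlier_line) & tr$outlier_line == "lineA"
  expect_gt(mean(fits$pruned[has_out & fits$tested]),
            mean(fits$pruned[!has_out & fits$tested]))
})

test_that("sites below the per-line coverage floor are not tested", {
  tab <- table_from_counts(matrix(c(3, 2, 4, 3), 1), matrix(c(5, 4, 3, 4), 1),
                           conditions = c("low", "low", "high", "high"))
  fits <- test_sites_per_line(tab, "A")
  expect_false(fits$tested)
})
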