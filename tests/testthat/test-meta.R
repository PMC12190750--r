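# Inverse-variance fixed-effects meta-analysis, heterogeneity flagging and
# Benjamini-Hochberg adjustment.

test_that("the worked two-study example matches the closed form to 1e-12", {
  m <- fixed_effects_meta(c(1.0, 0.2), c(0.5, 0.25))
  expect_equal(m$beta_meta, 0.36, tolerance = 1e-12)
  expect_equal(m$se_meta, 1 / sqrt(20), tolerance = 1e-12)
  expect_equal(m$Q, 2.048, tolerance = 1e-12)
  expect_equal(m$p_Q, pchisq(2.048, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identical studies halve the variance and show no heterogeneity", {
  m <- fixed_effects_meta(c(1.0, 1.0), c(0.4, 0.4))
  expect_equal(m$beta_meta, 1.0, tolerance = 1e-12)
  expect_equal(m$se_meta, 0.4 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$Q, 0, tolerance = 1e-12)
  expect_equal(m$p_Q, 1)
})

test_that("a single study passes through unchanged with p_Q = 1", {
  m <- fixed_effects_meta(0.7, 0.2)
  expect_equal(m$beta_meta, 0.7)
  expect_equal(m$se_meta, 0.2)
  expect_equal(m$k, 1L)
  expect_equal(m$Q, 0)
  expect_equal(m$p_Q, 1)
})

test_that("invalid inputs are rejected", {
  expect_error(fixed_effects_meta(numeric(), numeric()), "no estimates")
  expect_error(fixed_effects_meta(1, 0), "standard errors")
  expect_error(fixed_effects_meta(1, Inf), "standard errors")
})

test_that("meta-analysis invariants hold on random instances", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    b <- rnorm(k); s <- runif(k, 0.05, 1)
    m <- fixed_effects_meta(b, s)
    expect_lt(m$se_meta, min(s))
    # Q is invariant under a common shift of all estimates
    m2 <- fixed_effects_meta(b + 3.7, s)
    expect_equal(m2$Q, m$Q, tolerance = 1e-9)
    # an (almost) uninformative study changes nothing
    m3 <- fixed_effects_meta(c(b, 100), c(s, 1e8))
    expect_equal(m3$beta_meta, m$beta_meta, tolerance = 1e-6)
    expect_equal(m3$se_meta, m$se_meta, tolerance = 1e-6)
  }
})

test_that("estimates agree with metafor's fixed-effects fit", {
  skip_if_not_installed("metafor")
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    b <- rnorm(k); s <- runif(k, 0.1, 0.8)
    m <- fixed_effects_meta(b, s)
    r <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(m$beta_meta, as.numeric(r$beta), tolerance = 1e-8)
    expect_equal(m$se_meta, as.numeric(r$se), tolerance = 1e-8)
    expect_equal(m$Q, as.numeric(r$QE), tolerance = 1e-8)
    expect_equal(m$p_Q, as.numeric(r$QEp), tolerance = 1e-8)
  }
})

test_that("BH adjustment reproduces the step-up arithmetic and handles NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  # NA values do not count toward the number of tests
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(order(q[order(p)]), 1:50)  # order-preserving
})

test_that("heterogeneous sites are flagged and leave the BH pool; k=1 never flagged", {
  fits <- function(line, ids, b, se) {
    n <- length(ids)
    data.frame(site_id = ids, reference = ids, start = 1L, end = 2L,
               strand = "+", mod_code = "a", cell_line = line,
               tested = TRUE, converged = TRUE, beta1 = b, se1 = se,
               wald_z = b / se, p = 2 * pnorm(-abs(b / se)),
               min_cooks_p = 1, max_cooks_d = 0,
               outlier_sample = NA_character_, pruned = FALSE,
               stringsAsFactors = FALSE)
  }
  ids <- c("s1", "s2", "s3")
  a <- fits("A", ids, b = c(2, 0.5, 1), se = c(0.1, 0.2, 0.2))
  b <- fits("B", ids, b = c(-2, 0.5, 1), se = c(0.1, 0.2, 0.2))
  # prune s3 in line B: it should enter the meta with k = 1
  b$pruned[3] <- TRUE
  d <- call_dms(list(A = a, B = b))
  expect_equal(d$k[match(c("s1", "s2", "s3"), d$site_id)], c(2L, 2L, 1L))
  s1 <- d[d$site_id == "s1", ]
  expect_equal(s1$Q, 800, tolerance = 1e-9)  # w (b - mean)^2 summed: 2*100*4
  expect_true(s1$heterogeneous)
  expect_true(is.na(s1$q_value))
  expect_false(s1$is_dms)
  expect_false(d$heterogeneous[d$site_id == "s3"])
  # strict policy drops the k=1 site entirely
  d2 <- call_dms(list(A = a, B = b), both_lines_only = TRUE)
  expect_false("s3" %in% d2$site_id)
})
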