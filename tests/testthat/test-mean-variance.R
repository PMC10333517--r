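test_that("per-condition moments use the unbiased variance", {
  counts <- matrix(c(0, 0, 3, 5, 5, 5), nrow = 1)
  meta <- data.frame(cell_id = paste0("c", 1:6), species = "mouse",
                     treatment = "LPS", time_h = rep(c(2, 4), each = 3),
                     replicate = 1L)
  mom <- compute_moments(identity_scale(count_dataset(counts, meta)))
  m2 <- mom[mom$condition == "LPS_2_1", ]
  expect_equal(m2$mu, 1)
  expect_equal(m2$var, 3) # unbiased (n-1) estimator by hand
  m4 <- mom[mom$condition == "LPS_4_1", ]
  expect_equal(m4$var, 0) # constant vector
  expect_equal(m4$var_of_var, 0)
})

test_that("Poisson draws give a variance-to-mean ratio near one", {
  set.seed(21)
  counts <- matrix(rpois(1e5, 5), nrow = 1)
  meta <- data.frame(cell_id = paste0("c", 1:1e5), species = "mouse",
                     treatment = "LPS", time_h = 2, replicate = 1L)
  mom <- compute_moments(identity_scale(count_dataset(counts, meta)))
  expect_gt(mom$var / mom$mu, 0.97)
  expect_lt(mom$var / mom$mu, 1.03)
})

test_that("the robust line recovers noiseless and contaminated data", {
  mu <- c(5, 10, 20, 40, 60, 80, 100, 150)
  pts <- data.frame(mu = mu, var = 20 * mu + 100)
  f <- fit_huber_line(pts)
  expect_equal(f$alpha, 20, tolerance = 1e-8)
  expect_equal(f$alpha0, 100, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-8)

  # one gross outlier (variance x10 at one condition): slope within 10%
  pts_out <- pts
  pts_out$var[4] <- pts_out$var[4] * 10
  f_out <- fit_huber_line(pts_out)
  expect_lt(abs(f_out$alpha - 20) / 20, 0.10)

  # degenerate mean spread fails cleanly
  f_deg <- fit_huber_line(data.frame(mu = c(5, 5, 5), var = c(1, 2, 3)))
  expect_true(f_deg$failed)
  # too few conditions fails cleanly
  expect_true(fit_huber_line(pts[1:2, ])$failed)
})

test_that("Huber equals OLS on well-behaved data and slope is scale-equivariant", {
  # residuals of equal magnitude: every |r| is below 1.345 robust-scale
  # units (scale = MAD/0.6745 = 0.74), so no point is downweighted
  mu <- c(5, 10, 20, 40, 60, 80, 100, 150)
  pts <- data.frame(mu = mu, var = 3 * mu + 0.5 * c(1, -1, 1, -1, 1, -1, 1, -1))
  f <- fit_huber_line(pts)
  ols <- lm(var ~ mu, data = pts)
  expect_equal(f$alpha, unname(coef(ols)[2]), tolerance = 1e-7)
  expect_equal(f$alpha0, unname(coef(ols)[1]), tolerance = 1e-7)
  # scaling (mu, var) by c leaves alpha unchanged and scales alpha0 by c
  fc <- fit_huber_line(data.frame(mu = 7 * pts$mu, var = 7 * pts$var))
  expect_equal(fc$alpha, f$alpha, tolerance = 1e-6)
  expect_equal(fc$alpha0, 7 * f$alpha0, tolerance = 1e-4)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  out <- bh_fdr(c(0.01, NaN, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("confidence classes follow the FDR and R2 rule", {
  fits <- data.frame(q_alpha = c(0.01, 0.01, 0.2, NA),
                     r2 = c(0.9, 0.5, 0.9, 0.9))
  expect_equal(call_confidence(fits),
               c("high_confidence", "significant_only", "failed", "failed"))
})

test_that("slope recovery and confidence interval coverage on synthetic panels", {
  # fast recovery check at desk scale (the 100-seed study is in acceptance)
  mus <- mu_grid8()
  ok <- vapply(1:5, function(s) {
    ds <- generate_linear_family(3, 0, mus, n_cells = 5000, seed = 100 + s)
    f <- fit_huber_line(compute_moments(identity_scale(ds)))
    abs(f$alpha - 3) / 3 < 0.1
  }, logical(1))
  expect_true(all(ok))

  # 95% CI from the moment-propagated SE covers the true slope at the
  # nominal rate (within [90%, 99%]) over 200 seeds
  cover <- vapply(1:200, function(s) {
    ds <- generate_linear_family(3, 0, mus, n_cells = 2000, seed = 2000 + s)
    f <- fit_huber_line(compute_moments(identity_scale(ds)))
    ci <- f$alpha + c(-1, 1) * qt(0.975, f$n_conditions - 2) * f$se_alpha_moment
    ci[1] <= 3 && 3 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("fit_mean_variance assembles per-gene fits with FDR and classes", {
  ds <- generate_linear_family(c(3, 8), alpha0 = 20, mus = mu_grid8(),
                               n_cells = 2000, seed = 31)
  fits <- fit_mean_variance(compute_moments(identity_scale(ds)))
  expect_equal(nrow(fits), 2)
  expect_true(all(fits$q_alpha >= fits$p_alpha))
  expect_true(all(fits$confidence_class == "high_confidence"))
  expect_equal(fits$alpha, c(3, 8), tolerance = 0.15)
})
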