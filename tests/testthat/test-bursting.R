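test_that("moment estimators satisfy their defining identities", {
  expect_equal(moment_burst(10, 10), data.frame(bs = 1, bf = 10))
  expect_equal(moment_burst(10, 30), data.frame(bs = 3, bf = 10 / 3))
  # undefined cases are flagged as NA
  expect_true(all(is.na(moment_burst(c(0, 5), c(5, 0)))))
  # product identity on a random sweep
  set.seed(14)
  mu <- runif(1000, 0.1, 200)
  v <- runif(1000, 0.1, 500)
  mb <- moment_burst(mu, v)
  expect_equal(mb$bs * mb$bf, mu)
})

test_that("theoretical modulation curves match the analytical forms", {
  th <- theoretical_curves(20, 100, 10)
  expect_equal(th$bs, 30)
  expect_equal(th$bf, 1 / 3)
  # zero intercept: constant burst size, frequency linear in mu
  th0 <- theoretical_curves(20, 0, c(1, 5, 50))
  expect_equal(th0$bs, rep(20, 3))
  expect_equal(th0$bf, c(1, 5, 50) / 20)
  # out-of-domain points flagged, not evaluated
  thn <- theoretical_curves(20, -100, c(3, 10))
  expect_false(thn$in_domain[1]) # below |alpha0|/alpha = 5
  expect_true(is.na(thn$bs[1]))

  # monotonicity: sign of db_s/dmu = sign(-alpha0) over the domain
  for (a0 in c(100, -100)) {
    grid <- modulation_grid(20, a0, mu_obs = c(6, 200), length_out = 300)
    bs <- theoretical_curves(20, a0, grid)$bs
    expect_true(all(sign(diff(bs)) == sign(-a0)))
  }
})

test_that("burst frequency minimum sits at 2|alpha0|/alpha with value 4|alpha0|/alpha^2", {
  grid <- seq(5.05, 100, length.out = 20000)
  bf <- theoretical_curves(20, -100, grid)$bf
  expect_equal(grid[which.min(bf)], 10, tolerance = 1e-3)  # 2|a0|/a
  expect_equal(min(bf), 1, tolerance = 1e-6)               # 4|a0|/a^2
  # the derivative vanishes nowhere else: bf strictly decreases then increases
  expect_true(all(diff(bf[grid < 10]) < 0))
  expect_true(all(diff(bf[grid > 10]) > 0))
})

test_that("exact coincidence of moment estimators and curves on the fitted line", {
  mu <- c(6, 9, 15, 40, 120)
  for (a0 in c(100, -100)) {
    v <- 20 * mu + a0
    mb <- moment_burst(mu, v)
    th <- theoretical_curves(20, a0, mu)
    expect_equal(mb$bs, th$bs, tolerance = 1e-12)
    expect_equal(mb$bf, th$bf, tolerance = 1e-12)
  }
})

test_that("the size-frequency relation has the printed values, minimum and asymptote", {
  expect_equal(bs_bf_relation(20, 100, 25)$bf, 0.8) # 100/(25 * 5)
  # alpha0 < 0: minimum over the (0, alpha) interval at alpha/2
  grid <- seq(0.05, 19.95, length.out = 20000)
  rel <- bs_bf_relation(20, -100, grid)
  expect_equal(grid[which.min(rel$bf)], 10, tolerance = 1e-2)
  # alpha0 > 0: defined only above alpha, decreasing to zero
  grid_hi <- seq(20.5, 2000, length.out = 5000)
  rel_hi <- bs_bf_relation(20, 100, grid_hi)
  expect_true(all(diff(rel_hi$bf) < 0))
  expect_lt(rel_hi$bf[5000], 0.01)
  expect_false(bs_bf_relation(20, 100, 20)$in_domain) # pole excluded
  expect_error(bs_bf_relation(20, 0, 5), "alpha0 = 0")
})

test_that("RRMSE matches hand arithmetic and is scale invariant", {
  expect_equal(rrmse(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(rrmse(10, 11), 10) # sqrt(1/1)/sqrt(100) in percent
  m <- c(2, 5, 9); d <- c(2.2, 4.4, 9.9)
  expect_equal(rrmse(7 * m, 7 * d), rrmse(m, d))
  expect_error(rrmse(c(0, 0), c(1, 2)), "all model values are zero")
})

test_that("fold-change modulation and dominance labels follow the 2x rule", {
  fc <- modulation_fold_changes(bs = c(2, 2, 2), bf = c(1, 3, 5))
  expect_equal(fc$delta_bs, 0)
  expect_equal(fc$modulation_ratio, Inf)
  expect_equal(fc$dominance, "frequency")

  fc2 <- modulation_fold_changes(bs = c(2, 4), bf = c(3, 6))
  expect_equal(fc2$delta_bs, 1)
  expect_equal(fc2$delta_bf, 1)
  expect_equal(fc2$modulation_ratio, 1)
  expect_equal(fc2$dominance, "comparable")

  expect_error(modulation_fold_changes(c(2, NA), c(1, NA)), ">= 2 conditions")
})

test_that("modulation modes follow the intercept sign and the straddle rule", {
  expect_equal(classify_mode(20, 100, bs_obs = c(25, 40)), "inverse")
  expect_equal(classify_mode(20, -100, bs_obs = c(5, 15)), "U_shape")
  expect_equal(classify_mode(20, -100, bs_obs = c(12, 18)), "concurrent")
  expect_equal(classify_mode(20, -100, bs_obs = c(3, 8)), "inverse")
  expect_equal(classify_mode(20, 0, bs_obs = c(19, 21)), "frequency_only")
  expect_equal(classify_mode(20, -100, bs_obs = c(5, 15), q_alpha0 = 0.4,
                             zero_if_ns_intercept = TRUE), "frequency_only")
})

test_that("a zero-intercept synthetic gene is frequency-dominant with low RRMSE", {
  ds <- generate_linear_family(20, 0, mus = c(10, 20, 40, 80, 120, 160, 200, 300),
                               n_cells = 20000, seed = 77)
  mom <- compute_moments(identity_scale(ds))
  fits <- fit_mean_variance(mom)
  bm <- burst_modulation(mom, fits)
  expect_equal(bm$per_gene$dominance, "frequency")
  # self-consistent data: theoretical curves track the moment estimates
  expect_lt(bm$per_gene$rrmse_meanvar, 2)
  expect_lt(bm$per_gene$rrmse_bs, 2)
  expect_lt(bm$per_gene$rrmse_bf, 2)
})
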