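test_that("empirical CDF steps through the observed unique counts", {
  ec <- empirical_cdf(c(0, 0, 1))
  expect_equal(ec$x, c(0, 1))
  expect_equal(ec$F, c(2 / 3, 1))
  ec_const <- empirical_cdf(rep(4, 10))
  expect_equal(ec_const$F, 1)
  set.seed(3)
  for (i in 1:5) {
    ec_r <- empirical_cdf(rpois(200, 8))
    expect_true(all(diff(ec_r$F) > 0))
    expect_equal(ec_r$F[nrow(ec_r)], 1)
  }
})

test_that("the CDF objective separates generating from perturbed parameters", {
  kd <- half_life_to_rate(30)
  truth <- c(0.05, 0.5, 2)
  wins <- 0
  for (s in 1:10) {
    cnt <- sample_from_cme(telegraph2(truth[1], truth[2], truth[3], kd),
                           t = 120, n_cells = 5000, seed = 40 + s)
    o_true <- cdf_objective(truth, "two_state", cnt, 120, kd)
    o_pert <- cdf_objective(truth * c(1, 1, 2), "two_state", cnt, 120, kd)
    wins <- wins + (o_true < o_pert)
  }
  expect_gte(wins, 9)
  # invariant to permuting cells within the condition
  cnt <- sample_from_cme(params_bursty(), t = 120, n_cells = 1000, seed = 2)
  expect_equal(cdf_objective(c(0.02, 0.74, 1.2), "two_state", cnt, 120, kd),
               cdf_objective(c(0.02, 0.74, 1.2), "two_state",
                             sample(cnt), 120, kd))
  expect_error(cdf_objective(truth, "two_state", rep(3, 10), 120, kd),
               "unique count")
})

test_that("multinomial likelihood and AIC match hand computations", {
  # counts {0: 2, 1: 1} under P(0) = P(1) = 0.5: L = 3 * 0.125 = 0.375
  ll <- multinomial_loglik(c(0.5, 0.5), c(0, 0, 1))
  expect_equal(ll, log(0.375))
  expect_equal(multinomial_loglik(c(0, 1), 1), 0) # single cell, P(x) = 1
  expect_identical(multinomial_loglik(c(1, 0), c(0, 1)), -Inf)
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(0, 7), 14)
  expect_equal(aic(ll, 3), 6 - 2 * log(0.375))
  # Bernoulli check: logL is maximized at the empirical frequency
  cnt <- c(rep(0, 7), rep(1, 3))
  lls <- sapply(seq(0.05, 0.95, by = 0.01),
                function(q) multinomial_loglik(c(1 - q, q), cnt))
  expect_equal(seq(0.05, 0.95, by = 0.01)[which.max(lls)], 0.3)
})

test_that("AIC outlier filtering uses interpolated quartiles and is idempotent", {
  aics <- c(10, 12, 14, 16, 100)
  keep <- filter_aic_outliers(aics)
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE)) # threshold 22
  expect_true(all(filter_aic_outliers(rep(5, 6))))
  kept <- aics[keep]
  expect_true(all(filter_aic_outliers(kept))) # second pass drops nothing
  expect_error(filter_aic_outliers(c(1, 2, 3)), "length")
})

test_that("model selection rules rank AIC pairs correctly", {
  for (rule in c("absolute", "half", "twofold")) {
    expect_equal(select_model(100, 40, rule), "three_state")
    expect_equal(select_model(70, 70, rule), "tie")
  }
  expect_equal(select_model(100, 60, "absolute"), "three_state")
  expect_equal(select_model(100, 60, "half"), "tie")
  expect_equal(select_model(NA, 60, "half"), "three_state") # by presence
  expect_equal(select_model(60, NA, "absolute"), "two_state")
  # nesting of winners: twofold subset of half subset of absolute
  set.seed(9)
  a2 <- runif(50, 10, 200); a3 <- runif(50, 10, 200)
  abs_w <- select_model(a2, a3, "absolute") == "three_state"
  half_w <- select_model(a2, a3, "half") == "three_state"
  expect_true(all(half_w <= abs_w))
})

test_that("the three-state fraction counts absolute-rule wins", {
  sel <- c(rep("three_state", 3), rep("two_state", 15), rep("tie", 2))
  expect_equal(fraction_three_state(sel), 0.15)
  expect_equal(fraction_three_state(rep("three_state", 4)), 1)
})

test_that("a GA fit honors bounds, the argmin contract and seed determinism", {
  kd <- half_life_to_rate(30)
  cnt <- sample_from_cme(params_bursty(), t = 120, n_cells = 2000, seed = 13)
  ga <- ga_config(population = 20, generations = 8, runs = 2)
  f <- fit_condition(cnt, 120, kd, "two_state", ga = ga, seed = 5)
  expect_lte(f$par[["k_t"]], 50)
  expect_lte(f$par[["k_on"]], 1)
  expect_lte(f$objective, min(f$runs)) # best of all runs (refinement can improve)
  expect_equal(f$aic, 2 * 3 - 2 * f$logL)
  f2 <- fit_condition(cnt, 120, kd, "two_state", ga = ga, seed = 5)
  expect_identical(f$par, f2$par)
  # best-of-n monotone: more runs never worsen the chosen objective
  ga3 <- ga_config(population = 20, generations = 8, runs = 3)
  f3 <- fit_condition(cnt, 120, kd, "two_state", ga = ga3, seed = 5)
  expect_lte(min(f3$runs), min(f$runs))
  expect_error(fit_condition(rep(2, 50), 120, kd, "two_state", ga = ga),
               "unique count")
})

test_that("the pipeline wrapper fits integer-view conditions end to end", {
  ds <- generate_linear_family(3, 0, mus = c(3, 8), n_cells = 300, seed = 6)
  nds <- identity_scale(ds)
  hl <- data.frame(gene_id = "gene1", half_life_min = 30,
                   k_d = half_life_to_rate(30))
  res <- fit_dynamic_models(nds, hl, "gene1", models = "two_state",
                            ga = ga_config(population = 10, generations = 4,
                                           runs = 1), seed = 2)
  expect_equal(nrow(res), 2)
  expect_true(all(res$model == "two_state"))
  expect_true(all(is.finite(res$aic)))
  # the t = 0 condition is fitted from a steady-state initial distribution
  expect_true(res$steady_init[grepl("_0_", res$condition)])
})
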