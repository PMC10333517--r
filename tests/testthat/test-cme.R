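test_that("the generator is a proper rate matrix", {
  p <- params_symmetric()
  for (alleles in 1:2) {
    Q <- build_generator(p, N = 15, alleles = alleles)
    expect_true(all(abs(Matrix::colSums(Q)) < 1e-12)) # probability conserved
    off <- Q; Matrix::diag(off) <- 0
    expect_true(all(off@x >= 0)) # off-diagonal rates non-negative
  }
  # no transcription flux when k_t = 0: nothing leaves the m = 0 block upward
  Q0 <- build_generator(telegraph2(1, 1, 0, 1), N = 5, alleles = 1)
  expect_true(all(Q0[3:4, 1:2] == 0)) # (s, m=1) <- (s, m=0) entries absent
})

test_that("the 3-state generator nests the 2-state generator under relabeling", {
  # off <-> I only, transcription k_ti in I: identical to a 2-state chain
  # with rates (t_on, t_off) and transcription lambda
  N <- 8
  Q3 <- build_generator(
    telegraph3(t_on = 0.3, t_off = 0.9, k_on = 0, k_off = 0, k_c = 0,
               k_ti = 4, k_t = 0, k_d = 0.5), N = N, alleles = 1)
  Q2 <- build_generator(telegraph2(0.3, 0.9, 4, 0.5), N = N, alleles = 1)
  keep <- as.vector(outer(1:2, 3 * (0:N), `+`)) # states (off, I) x m
  expect_equal(as.matrix(Q3[keep, keep]), as.matrix(Q2),
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("propagation conserves probability and satisfies the semigroup law", {
  p <- params_symmetric()
  Q <- build_generator(p, N = 40, alleles = 1)
  # t = 0: point mass at the initial state
  expect_equal(propagate(Q, 0)[1], 1)
  set.seed(8)
  for (i in 1:3) {
    pr <- telegraph2(runif(1), runif(1), runif(1, 0, 8), runif(1, 0.5, 2))
    Qi <- build_generator(pr, N = 40, alleles = 1)
    pi_t <- propagate(Qi, 3)
    expect_true(all(pi_t >= -1e-12))
    expect_lt(abs(sum(pi_t) - 1), 1e-8)
  }
  # semigroup: propagate(t1 + t2) == propagate(t2) from the t1 state
  p_a <- propagate(Q, 4)
  p_b <- propagate(Q, 1.5, p0 = propagate(Q, 2.5))
  expect_lt(0.5 * sum(abs(p_a - p_b)), 1e-10)
  # uniformization agrees with the dense matrix exponential
  expect_lt(max(abs(propagate(Q, 4) - propagate(Q, 4, method = "expm"))),
            1e-10)
})

test_that("the compiled solver agrees with the dense matrix exponential", {
  for (pars in list(params_symmetric(), params_bursty(),
                    params_three_state())) {
    N <- 30
    kin <- burstlin:::allele_kinetics(pars)
    Q <- build_generator(pars, N = N, alleles = 1)
    pe <- propagate(Q, 7, method = "expm")
    d <- cme_distribution(pars, t = 7, n_alleles = 1, N = N,
                          tail_tol = Inf, max_doublings = 0)
    expect_lt(max(abs(colSums(matrix(pe, nrow = nrow(kin$sw))) - d$p)), 1e-12)
  }
})

test_that("two-allele convolution equals the joint two-allele chain", {
  # convolution identities
  expect_equal(two_allele_convolution(c(1, 0, 0)), c(1, 0, 0, 0, 0))
  lam <- 3
  pois <- dpois(0:60, lam)
  expect_lt(tv_distance(two_allele_convolution(pois), dpois(0:120, 2 * lam)),
            1e-10)
  # joint-chain oracle on a parameter grid
  grid <- list(telegraph2(1, 1, 10, 1),        # symmetric
               telegraph2(0.1, 1, 12, 0.5),    # bursty
               telegraph2(2, 0.1, 6, 1))       # mostly on
  for (pars in grid) {
    N <- 80
    Qj <- build_generator(pars, N = N, alleles = 2)
    marg <- colSums(matrix(propagate(Qj, 5, method = "expm"), nrow = 4))
    d1 <- cme_distribution(pars, t = 5, n_alleles = 1, N = N,
                           tail_tol = Inf, max_doublings = 0)
    expect_lt(tv_distance(marg, two_allele_convolution(d1$p)), 1e-8)
  }
})

test_that("long-time CME matches the closed-form stationary moments", {
  p <- params_symmetric()
  mom <- stationary_moments_2state(p)
  expect_equal(unname(mom), c(5, 8 / 3))
  expect_equal(unname(stationary_moments_2state(telegraph2(1, 0, 10, 1))["fano"]), 1)
  # 20 half-lives out, the CME moments sit within 0.1% of the closed form
  d <- cme_distribution(p, t = 20 * log(2) / p$k_d, n_alleles = 1)
  m <- sum(d$counts * d$p)
  fano <- sum((d$counts - m)^2 * d$p) / m
  expect_lt(abs(m - mom["mean"]) / mom["mean"], 1e-3)
  expect_lt(abs(fano - mom["fano"]) / mom["fano"], 1e-3)
})

test_that("the constitutive limit is Poisson with rate 2 k_t / k_d", {
  p <- telegraph2(k_on = 100, k_off = 0, k_t = 10, k_d = 1)
  d <- cme_distribution(p, t = 30, n_alleles = 2)
  expect_lt(tv_distance(d$p, dpois(0:(length(d$p) - 1), 20)), 0.01)
})

test_that("truncation auto-doubles on tail-mass failure and errors at the cap", {
  p <- params_symmetric() # two-allele stationary mean 10
  d <- cme_distribution(p, t = 30, n_alleles = 1, N = 12)
  expect_gt(d$N, 12) # had to enlarge
  expect_lt(d$p[d$N + 1], 1e-8)
  expect_error(
    cme_distribution(p, t = 30, n_alleles = 1, N = 4, max_doublings = 0),
    "truncation insufficient")
  # steady-state initial condition reproduces the stationary moments at t = 0
  ds <- cme_distribution(p, t = 0, n_alleles = 1, init = "steady", N = 60)
  expect_equal(sum(ds$counts * ds$p),
               unname(stationary_moments_2state(p)["mean"]), tolerance = 1e-6)
})
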