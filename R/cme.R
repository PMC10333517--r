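#' Build the chemical master equation generator
#'
#' Constructs the transition-rate matrix of the chemical master equation (CME)
#' on the truncated state space (allele-state combination) x (mRNA count
#' 0..N). A state gains probability through allele switching, transcription
#' from the state one transcript below, and degradation from the state one
#' transcript above; transcription out of the truncation boundary m = N is
#' suppressed so the generator conserves probability (truncation adequacy is
#' checked downstream through the mass at N). Column convention: dP/dt = Q P,
#' so every column sums to zero.
#'
#' With `alleles = 2` the joint chain over ordered allele-state pairs is
#' built, with additive transcription and shared first-order degradation of
#' the pooled transcript count. The joint chain is mainly an oracle: because
#' degradation is linear in total mRNA the two alleles evolve independently,
#' and [two_allele_convolution()] on the single-allele solution is the fast
#' equivalent path.
#'
#' @param params A [telegraph2()] or [telegraph3()] parameter set.
#' @param N Truncation: maximum mRNA count represented.
#' @param alleles 1 or 2.
#' @return A sparse `dgCMatrix` of dimension S(N+1), with attributes
#'   `n_allele_states` (S) and `N`. State (s, m) maps to column s + S*m + 1.
#' @export
build_generator <- function(params, N, alleles = 1) {
  stopifnot(N >= 1, alleles %in% c(1, 2))
  kin <- allele_kinetics(params)
  if (alleles == 2) kin <- joint_allele_kinetics(kin)
  S <- nrow(kin$sw)
  n <- S * (N + 1)

  idx <- function(s, m) s + S * m + 1 # s 0-based, m 0-based
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(to, from, rate) {
    if (rate > 0) {
      ii <<- c(ii, to); jj <<- c(jj, from); xx <<- c(xx, rate)
    }
  }
  for (m in 0:N) {
    for (s in 0:(S - 1)) {
      from <- idx(s, m)
      for (s2 in 0:(S - 1)) {
        if (s2 != s) add(idx(s2, m), from, kin$sw[s + 1, s2 + 1])
      }
      if (m < N) add(idx(s, m + 1), from, kin$ktr[s + 1])
      if (m > 0) add(idx(s, m - 1), from, m * params$k_d)
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- -Matrix::colSums(Q)
  attr(Q, "n_allele_states") <- S
  attr(Q, "N") <- N
  Q
}

# Joint kinetics of two independent alleles: ordered pairs (s1, s2) with
# component-wise switching and additive transcription.
joint_allele_kinetics <- function(kin) {
  S <- nrow(kin$sw)
  S2 <- S * S
  sw2 <- matrix(0, S2, S2)
  ktr2 <- numeric(S2)
  id <- function(s1, s2) (s1 - 1) + S * (s2 - 1) + 1
  for (s1 in 1:S) for (s2 in 1:S) {
    ktr2[id(s1, s2)] <- kin$ktr[s1] + kin$ktr[s2]
    for (s1b in 1:S) if (s1b != s1) sw2[id(s1, s2), id(s1b, s2)] <- kin$sw[s1, s1b]
    for (s2b in 1:S) if (s2b != s2) sw2[id(s1, s2), id(s1, s2b)] <- kin$sw[s2, s2b]
  }
  list(sw = sw2, ktr = ktr2, states = as.vector(outer(kin$states, kin$states, paste, sep = "/")))
}

#' Propagate an initial distribution under a CME generator
#'
#' Computes exp(Q t) p0 for a generator from [build_generator()]. The default
#' method is uniformization (Poisson-weighted powers of the uniformized
#' transition matrix, using sparse matrix-vector products); `method = "expm"`
#' forms the dense matrix exponential via [Matrix::expm()] and serves as an
#' independent cross-check on small instances.
#'
#' @param Q Generator from [build_generator()].
#' @param t Time in minutes (>= 0).
#' @param p0 Initial probability vector over the joint states; default is all
#'   probability on (all alleles 'off', 0 mRNA).
#' @param method "uniformization" or "expm".
#' @return Probability vector over the joint states at time t.
#' @export
propagate <- function(Q, t, p0 = NULL,
                      method = c("uniformization", "expm")) {
  method <- match.arg(method)
  n <- nrow(Q)
  if (is.null(p0)) {
    p0 <- numeric(n)
    p0[1] <- 1 # state (all off, m = 0) is the first column
  }
  stopifnot(length(p0) == n, t >= 0)
  if (t == 0) return(p0)
  if (method == "expm") {
    E <- Matrix::expm(Q * t)
    return(as.numeric(E %*% p0))
  }
  lam <- max(-Matrix::diag(Q))
  if (lam <= 0) return(p0)
  P <- Q / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1
  chunk <- ceiling(lam * t / 300)
  dt <- t / chunk
  a <- lam * dt
  p <- p0
  for (ch in seq_len(chunk)) {
    v <- p
    w <- exp(-a)
    res <- w * v
    wsum <- w
    kmax <- ceiling(a + 12 * sqrt(a) + 40)
    for (k in seq_len(kmax)) {
      v <- as.numeric(P %*% v)
      w <- w * a / k
      res <- res + w * v
      wsum <- wsum + w
      if (k > a && 1 - wsum < 1e-14) break
    }
    p <- res / wsum
  }
  p
}

# Marginal mRNA distribution from a joint state vector.
mrna_marginal <- function(p, S) {
  colSums(matrix(p, nrow = S))
}

#' Time-dependent mRNA count distribution of a telegraph model
#'
#' Solves the CME for the single-allele chain with the compiled
#' uniformization solver, automatically enlarging the truncation until the
#' boundary mass P(N) falls below `tail_tol`, and returns the mRNA count
#' marginal. For two alleles the single-allele marginal is self-convolved
#' (valid because the alleles are independent); the joint two-allele chain is
#' available through [build_generator()] as an oracle.
#'
#' @param params Telegraph parameter set.
#' @param t Time in minutes.
#' @param n_alleles 1 or 2 (default 2: a diploid gene).
#' @param init `"off"` starts with no mRNA and all alleles 'off' (the
#'   stimulation-onset condition); `"steady"` starts from the stationary
#'   distribution at the same parameters (for unstimulated 0 h data).
#' @param N Optional starting truncation; default ceiling(4 x stationary
#'   mean per allele + 30).
#' @param tail_tol Maximum tolerated boundary mass (default 1e-8).
#' @param max_doublings Truncation doublings allowed before a hard error.
#' @return Object of class `cme_distribution`: list with `p` (probabilities
#'   over counts 0..length(p)-1), `counts`, `t`, `N`, `n_alleles`, `init`.
#' @export
cme_distribution <- function(params, t, n_alleles = 2,
                             init = c("off", "steady"), N = NULL,
                             tail_tol = 1e-8, max_doublings = 4) {
  init <- match.arg(init)
  stopifnot(t >= 0, n_alleles %in% c(1, 2))
  kin <- allele_kinetics(params)
  S <- nrow(kin$sw)
  if (is.null(N)) {
    N <- max(10L, as.integer(ceiling(4 * stationary_mean_per_allele(params) + 30)))
  }
  for (attempt in 0:max_doublings) {
    if (init == "off") {
      p0 <- numeric(S * (N + 1))
      p0[1] <- 1
      p_joint <- .cme_propagate_cpp(kin$sw, kin$ktr, params$k_d, t, N, p0)
    } else {
      p0 <- stationary_cme(params, N)
      p_joint <- if (t > 0) {
        .cme_propagate_cpp(kin$sw, kin$ktr, params$k_d, t, N, p0)
      } else {
        p0
      }
    }
    marg <- mrna_marginal(p_joint, S)
    if (marg[N + 1] < tail_tol) break
    if (attempt == max_doublings) {
      stop("CME truncation insufficient after ", max_doublings,
           " doublings (boundary mass ", signif(marg[N + 1], 3), ")")
    }
    N <- N * 2L
  }
  p <- marg
  if (n_alleles == 2) p <- two_allele_convolution(p)
  structure(list(p = p, counts = seq_along(p) - 1L, t = t, N = N,
                 n_alleles = n_alleles, init = init, params = params),
            class = "cme_distribution")
}

#' Two-allele distribution by self-convolution
#'
#' Discrete self-convolution of a single-allele mRNA distribution. Because
#' degradation is first order in the pooled transcript count, the two alleles
#' of a gene are independent and the total-count distribution is the
#' convolution of the per-allele marginals.
#'
#' @param p Probability vector over counts 0..N.
#' @return Probability vector over counts 0..2N.
#' @export
two_allele_convolution <- function(p) {
  out <- stats::convolve(p, rev(p), type = "open")
  out <- pmax(out, 0) # FFT round-off can leave ~1e-17 negatives
  out / sum(out)
}

#' Stationary CME distribution on a truncated state space
#'
#' Solves Q p = 0, sum(p) = 1 on the truncation 0..N by sparse LU, returning
#' the joint (allele state x mRNA count) stationary vector of the
#' single-allele chain.
#'
#' @inheritParams cme_distribution
#' @param N Truncation.
#' @return Probability vector over the joint states.
#' @export
stationary_cme <- function(params, N) {
  Q <- build_generator(params, N, alleles = 1)
  n <- nrow(Q)
  A <- Q
  A[n, ] <- 1 # replace one balance equation by normalization
  b <- c(rep(0, n - 1), 1)
  p <- as.numeric(Matrix::solve(A, b))
  pmax(p, 0) / sum(pmax(p, 0))
}

# Mean and variance of a probability vector over counts 0..len-1.
dist_moments <- function(p) {
  x <- seq_along(p) - 1
  m <- sum(x * p)
  v <- sum((x - m)^2 * p)
  c(mean = m, var = v)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q Probability vectors over counts starting at 0 (padded to a
#'   common length with zeros).
#' @return 0.5 * sum |p - q|.
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}
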