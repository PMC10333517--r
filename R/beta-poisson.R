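#' Beta-Poisson probability mass function
#'
#' Stationary distribution of the 2-state telegraph model: a Poisson whose
#' intensity k_t * u is mixed over the Beta(k_on, k_off)-distributed fraction
#' of time the promoter spends 'on'. Rates are dimensionless (expressed in
#' units of the degradation rate). The mixture integral has the closed form
#' P(k) = k_t^k / k! * B(k_on + k, k_off) / B(k_on, k_off) *
#' e^(-k_t) * 1F1(k_off; k_on + k_off + k; k_t), evaluated per allele through
#' the Kummer-transformed confluent hypergeometric series, whose terms are
#' all positive (no cancellation, valid for any k_off < 1 endpoint
#' singularity of the Beta density). The two-allele version is the discrete
#' self-convolution.
#'
#' @param k Count(s) at which to evaluate (>= 0).
#' @param k_on,k_off,k_t Beta-Poisson parameters (positive, in units of k_d).
#' @param n_alleles 1 (default, one allele) or 2.
#' @return Probability/ies.
#' @export
bp_pmf <- function(k, k_on, k_off, k_t, n_alleles = 1) {
  stopifnot(all(k >= 0), k_on > 0, k_off > 0, k_t > 0,
            n_alleles %in% c(1, 2))
  if (n_alleles == 2) {
    kmax <- max(k)
    # support the convolution far enough that the tail is negligible
    K <- bp_support(k_on, k_off, k_t)
    K <- max(K, kmax)
    p1 <- bp_pmf_vec(0:K, k_on, k_off, k_t)
    p2 <- two_allele_convolution(p1)
    return(ifelse(k + 1 <= length(p2), p2[pmin(k + 1, length(p2))], 0))
  }
  bp_pmf_vec(k, k_on, k_off, k_t)
}

bp_support <- function(k_on, k_off, k_t) {
  m <- k_t * k_on / (k_on + k_off)
  as.integer(ceiling(min(k_t, m + 10 * sqrt(m * (1 + k_t)) + 30)))
}

bp_pmf_vec <- function(k, k_on, k_off, k_t) {
  lf1 <- log_kummer_series(k_off, k_on + k_off + k, k_t)
  exp(k * log(k_t) - lgamma(k + 1) +
        lbeta(k_on + k, k_off) - lbeta(k_on, k_off) - k_t + lf1)
}

# log 1F1(b; c; x) for b, c, x > 0 by direct summation of the (all-positive)
# series in log space, vectorized over c; terms peak near n ~ x and the sum
# converges for every x.
log_kummer_series <- function(b, c, x, max_terms = 1e6) {
  if (x == 0) return(rep(0, length(c)))
  lt <- rep(0, length(c)) # log of current term (n = 0)
  ls <- rep(0, length(c)) # log of running sum
  lx <- log(x)
  n <- 0
  repeat {
    lt <- lt + log(b + n) - log(c + n) + lx - log(n + 1)
    hi <- pmax(ls, lt)
    ls <- hi + log1p(exp(pmin(ls, lt) - hi))
    n <- n + 1
    if (n > x && all(lt < ls - 40)) return(ls)
    if (n >= max_terms) {
      stop(sprintf(
        "Beta-Poisson series did not converge (b = %g, x = %g)", b, x))
    }
  }
}

bp_negloglik <- function(logpar, tab_x, tab_y, n_alleles) {
  par <- exp(logpar)
  p <- tryCatch(bp_pmf(tab_x, par[1], par[2], par[3], n_alleles = n_alleles),
                error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p))) return(1e10)
  p <- pmax(p, 1e-300)
  -sum(tab_y * log(p))
}

#' Maximum-likelihood Beta-Poisson fit
#'
#' Fits (k_on, k_off, k_t) by bounded maximum likelihood over
#' log-parameters, starting from a moment-matched initialization plus a
#' small grid of fallback starts. The `converged` flag plays the role of a
#' keep/discard call for downstream coverage selection: it is FALSE when the
#' sample is below `min_cells`, the data are degenerate (all zero, or mean
#' below 0.1), the optimizer lands on a box bound, or the Hessian at the
#' optimum is singular (non-identifiable).
#'
#' @param counts Observed integer counts.
#' @param n_alleles 1 (default) or 2.
#' @param min_cells Minimum number of cells (default 50).
#' @return List with `par` (named k_on, k_off, k_t, in units of k_d),
#'   `logL`, `converged`, and `reason` (why not converged, else NA).
#' @export
fit_bp_ml <- function(counts, n_alleles = 1, min_cells = 50) {
  notconv <- function(reason) {
    list(par = c(k_on = NA_real_, k_off = NA_real_, k_t = NA_real_),
         logL = NA_real_, converged = FALSE, reason = reason)
  }
  if (length(counts) < min_cells) return(notconv("too few cells"))
  m <- mean(counts)
  if (m < 0.1) return(notconv("mean below 0.1"))
  v <- stats::var(counts)
  tab <- table(counts)
  tab_x <- as.integer(names(tab))
  tab_y <- as.integer(tab)

  m1 <- m / n_alleles # per-allele mean
  fano <- max(v / m, 1.01)
  kt0 <- max(max(counts) / n_alleles * 1.2, m1 * 2, 1)
  b0 <- max(fano - 1, 0.05) # burst-size proxy kt/koff
  koff0 <- kt0 / b0
  frac <- min(max(m1 / kt0, 1e-3), 0.999)
  kon0 <- koff0 * frac / (1 - frac)
  starts <- list(c(kon0, koff0, kt0),
                 c(1, 1, max(2 * m1, 1)),
                 c(0.3, 3, max(10 * m1, 5)),
                 c(10, 10, max(2 * m1, 1)))

  lower <- log(c(1e-3, 1e-3, 1e-2))
  upper <- log(c(1e3, 1e3, 1e4))
  best <- NULL
  for (s in starts) {
    logpar <- pmin(pmax(log(s), lower), upper)
    opt <- tryCatch(
      stats::optim(logpar, bp_negloglik, tab_x = tab_x, tab_y = tab_y,
                   n_alleles = n_alleles, method = "L-BFGS-B",
                   lower = lower, upper = upper, hessian = TRUE,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) return(notconv("optimizer failure"))

  par <- exp(best$par)
  at_bound <- any(abs(best$par - lower) < 1e-6 | abs(best$par - upper) < 1e-6)
  ev <- tryCatch(eigen(best$hessian, symmetric = TRUE,
                       only.values = TRUE)$values,
                 error = function(e) NA)
  singular <- any(!is.finite(ev)) || min(ev) < 1e-8 * max(abs(ev))
  conv <- !at_bound && !singular
  list(par = c(k_on = par[1], k_off = par[2], k_t = par[3]),
       logL = -best$value, converged = conv,
       reason = if (conv) NA_character_
                else if (at_bound) "parameter at bound" else "singular Hessian")
}

#' Select high-coverage genes from per-condition convergence flags
#'
#' A gene is high-coverage in a species when at least the species' threshold
#' of its conditions produced a converged (kept) Beta-Poisson fit. Default
#' thresholds: 10 conditions for mouse and rat, 6 for pig and rabbit.
#'
#' @param flags Data frame with columns `gene_id`, `species`, `converged`
#'   (one row per gene x condition).
#' @param thresholds Named vector of minimum converged-condition counts per
#'   species.
#' @return Data frame: `gene_id`, `species`, `n_converged`, `selected`.
#' @export
coverage_select <- function(flags,
                            thresholds = c(mouse = 10, rat = 10,
                                           pig = 6, rabbit = 6)) {
  agg <- stats::aggregate(converged ~ gene_id + species, data = flags, FUN = sum)
  names(agg)[3] <- "n_converged"
  thr <- thresholds[as.character(agg$species)]
  if (any(is.na(thr))) {
    stop("no threshold for species: ",
         paste(unique(agg$species[is.na(thr)]), collapse = ", "))
  }
  agg$selected <- agg$n_converged >= thr
  agg
}
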