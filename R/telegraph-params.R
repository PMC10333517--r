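#' Telegraph-model parameter sets
#'
#' Constructors for the kinetic parameters of the stochastic models of
#' promoter switching used throughout the package. All rates are per minute;
#' transcription rates are mRNA per minute per allele.
#'
#' `telegraph2()` describes the 2-state telegraph model: each allele switches
#' between an 'off' and an 'on' state (rates `k_on`, `k_off`), transcribes at
#' rate `k_t` while 'on', and transcripts degrade at rate `k_d` (first order
#' in the pooled mRNA count).
#'
#' `telegraph3()` adds a sequential intermediate state 'I' between 'off' and
#' 'on': reversible off/I switching (`t_on`, `t_off`), reversible I/on
#' switching (`k_on`, `k_off`), a direct on-to-off transition (`k_c`), and
#' transcription in both the intermediate (`k_ti`) and active (`k_t`) states.
#'
#' @param k_on,k_off Switching rates (min^-1).
#' @param k_t Transcription rate in the 'on' state (mRNA min^-1 per allele).
#' @param k_d Degradation rate (min^-1); must be positive.
#' @param t_on,t_off Off/intermediate switching rates (min^-1).
#' @param k_c Direct on-to-off rate (min^-1).
#' @param k_ti Transcription rate in the intermediate state.
#'
#' @return An object of class `telegraph2` or `telegraph3` (and common parent
#'   class `telegraph_params`): a named list of rates.
#'
#' @examples
#' p <- telegraph2(k_on = 1, k_off = 1, k_t = 10, k_d = 1)
#' stationary_moments_2state(p)
#' @export
telegraph2 <- function(k_on, k_off, k_t, k_d) {
  rates <- c(k_on = k_on, k_off = k_off, k_t = k_t, k_d = k_d)
  stopifnot(all(is.finite(rates)), all(rates >= 0), k_d > 0)
  structure(as.list(rates), class = c("telegraph2", "telegraph_params"))
}

#' @rdname telegraph2
#' @export
telegraph3 <- function(t_on, t_off, k_on, k_off, k_c, k_ti, k_t, k_d) {
  rates <- c(t_on = t_on, t_off = t_off, k_on = k_on, k_off = k_off,
             k_c = k_c, k_ti = k_ti, k_t = k_t, k_d = k_d)
  stopifnot(all(is.finite(rates)), all(rates >= 0), k_d > 0)
  structure(as.list(rates), class = c("telegraph3", "telegraph_params"))
}

#' @export
print.telegraph_params <- function(x, ...) {
  tag <- if (inherits(x, "telegraph2")) "2-state" else "3-state"
  cat(sprintf("<%s telegraph model> rates (min^-1):\n", tag))
  print(unlist(x))
  invisible(x)
}

# Allele-state switching matrix (row = from, col = to) and per-state
# transcription rates. State order: 2-state (off, on); 3-state (off, I, on).
allele_kinetics <- function(params) {
  if (inherits(params, "telegraph2")) {
    sw <- matrix(0, 2, 2)
    sw[1, 2] <- params$k_on
    sw[2, 1] <- params$k_off
    ktr <- c(0, params$k_t)
    states <- c("off", "on")
  } else if (inherits(params, "telegraph3")) {
    sw <- matrix(0, 3, 3)
    sw[1, 2] <- params$t_on
    sw[2, 1] <- params$t_off
    sw[2, 3] <- params$k_on
    sw[3, 2] <- params$k_off
    sw[3, 1] <- params$k_c
    ktr <- c(0, params$k_ti, params$k_t)
    states <- c("off", "I", "on")
  } else {
    stop("params must be a telegraph2 or telegraph3 object")
  }
  list(sw = sw, ktr = ktr, states = states)
}

# Stationary distribution of the allele-state chain alone (no mRNA),
# started from 'off' (state 1). Degenerate rate sets can leave states
# unreachable (zero rows/columns), so the solve is restricted to the states
# reachable from 'off'; there the limiting distribution is well defined.
allele_stationary <- function(sw) {
  S <- nrow(sw)
  reach <- logical(S)
  reach[1] <- TRUE
  repeat {
    new <- reach | apply(sw[reach, , drop = FALSE] > 0, 2, any)
    if (all(new == reach)) break
    reach <- new
  }
  idx <- which(reach)
  Qa <- sw[idx, idx, drop = FALSE]
  diag(Qa) <- -rowSums(Qa)
  A <- rbind(t(Qa), rep(1, length(idx))) # pi Qa = 0, sum pi = 1
  pi_r <- tryCatch(qr.solve(A, c(rep(0, length(idx)), 1)),
                   error = function(e) {
                     as.numeric(MASS::ginv(A) %*% c(rep(0, length(idx)), 1))
                   })
  out <- numeric(S)
  out[idx] <- pmax(as.numeric(pi_r), 0)
  out / sum(out)
}

# Stationary mean mRNA per allele: sum_s pi_s ktr_s / k_d.
stationary_mean_per_allele <- function(params) {
  kin <- allele_kinetics(params)
  pi_s <- allele_stationary(kin$sw)
  sum(pi_s * kin$ktr) / params$k_d
}

#' Closed-form stationary moments of the 2-state telegraph model
#'
#' Per-allele stationary mean and Fano factor of the mRNA count:
#' mean = k_t k_on / (k_d (k_on + k_off)) and
#' Fano = 1 + k_t k_off / ((k_on + k_off)(k_on + k_off + k_d)).
#' Used as an independent oracle for the master-equation solver.
#'
#' @param params A [telegraph2()] parameter set.
#' @return Named numeric vector with elements `mean` and `fano`.
#' @export
stationary_moments_2state <- function(params) {
  stopifnot(inherits(params, "telegraph2"))
  ksum <- params$k_on + params$k_off
  m <- params$k_t * params$k_on / (params$k_d * ksum)
  fano <- 1 + params$k_t * params$k_off / (ksum * (ksum + params$k_d))
  c(mean = m, fano = fano)
}

#' Convert between mRNA half-life and degradation rate
#'
#' Half-life and first-order degradation rate are related by
#' t_1/2 = log(2) / k_d. Times in minutes, rates in min^-1.
#'
#' @param half_life_min Half-life in minutes (positive).
#' @param k_d Degradation (or switching) rate in min^-1 (positive).
#' @return The implied rate (resp. half-life).
#' @examples
#' half_life_to_rate(30)         # k_d for a 30-minute half-life
#' rate_to_half_life(0.0231)     # ~30 min
#' @export
half_life_to_rate <- function(half_life_min) {
  stopifnot(all(half_life_min > 0))
  log(2) / half_life_min
}

#' @rdname half_life_to_rate
#' @export
rate_to_half_life <- function(k_d) {
  stopifnot(all(k_d > 0))
  log(2) / k_d
}
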