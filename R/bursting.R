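#' Moment estimators of burst size and frequency
#'
#' Burst size is estimated by the Fano factor b_s = sigma^2 / mu and burst
#' frequency by b_f = mu / b_s = mu^2 / sigma^2, so that b_s * b_f = mu
#' exactly. Poisson-like genes have b_s = 1. Undefined when mu or sigma^2 is
#' zero; such conditions are returned as NA and should be excluded from
#' modulation statistics.
#'
#' @param mu Sample mean(s).
#' @param var Sample variance(s).
#' @return Data frame with columns `bs` and `bf`.
#' @export
moment_burst <- function(mu, var) {
  stopifnot(length(mu) == length(var))
  bs <- ifelse(mu > 0 & var > 0, var / mu, NA_real_)
  bf <- ifelse(mu > 0 & var > 0, mu^2 / var, NA_real_)
  data.frame(bs = bs, bf = bf)
}

#' Theoretical bursting modulation curves from a mean-variance fit
#'
#' Under the linear constraint sigma^2 = alpha * mu + alpha0 the moment
#' estimators become analytical functions of the mean:
#' b_s(mu) = alpha0 / mu + alpha and b_f(mu) = mu^2 / (alpha0 + alpha * mu).
#' For alpha0 > 0, b_s decreases monotonically to alpha as mu grows; for
#' alpha0 < 0 the curves are defined only for mu > |alpha0| / alpha, b_s
#' increases to alpha, and b_f has a local minimum at mu* = 2 |alpha0| /
#' alpha with value 4 |alpha0| / alpha^2. For alpha0 = 0, b_s is constant at
#' alpha and b_f = mu / alpha. Grid points outside the domain are returned
#' with NA values and `in_domain = FALSE`.
#'
#' @param alpha,alpha0 Fitted slope and intercept.
#' @param mu Mean-expression grid.
#' @return Data frame with columns `mu`, `bs`, `bf`, `in_domain`.
#' @export
theoretical_curves <- function(alpha, alpha0, mu) {
  lower <- if (alpha0 < 0) abs(alpha0) / alpha else 0
  ok <- mu > lower
  bs <- ifelse(ok, alpha0 / mu + alpha, NA_real_)
  bf <- ifelse(ok, mu^2 / (alpha0 + alpha * mu), NA_real_)
  data.frame(mu = mu, bs = bs, bf = bf, in_domain = ok)
}

#' Default mean grid for modulation curves
#'
#' Spans from just above the domain's lower bound (or the smallest observed
#' mean if larger) to the largest observed mean, with 200 points.
#'
#' @param alpha,alpha0 Fitted line.
#' @param mu_obs Observed condition means.
#' @param length_out Number of grid points.
#' @return Numeric grid.
#' @export
modulation_grid <- function(alpha, alpha0, mu_obs, length_out = 200) {
  lower <- if (alpha0 < 0) abs(alpha0) / alpha * 1.01 else 0
  lo <- max(lower, min(mu_obs))
  hi <- max(mu_obs)
  if (hi <= lo) hi <- lo * 1.5 + 1e-9
  seq(lo, hi, length.out = length_out)
}

#' Burst frequency as a function of burst size
#'
#' Eliminating the mean from the modulation curves gives
#' b_f = alpha0 / (b_s (b_s - alpha)). For alpha0 > 0 the relation is
#' defined for b_s > alpha and decreases to zero as b_s grows; for
#' alpha0 < 0 it lives on 0 < b_s < alpha with a local minimum at
#' b_s* = alpha / 2 (frequency diverging at both ends). The pole b_s = alpha
#' is excluded.
#'
#' @param alpha,alpha0 Fitted line (alpha0 must be non-zero).
#' @param bs Burst-size grid.
#' @return Data frame with columns `bs`, `bf`, `in_domain`.
#' @export
bs_bf_relation <- function(alpha, alpha0, bs) {
  if (alpha0 == 0) stop("relation undefined for alpha0 = 0 (constant burst size)")
  ok <- if (alpha0 > 0) bs > alpha else bs > 0 & bs < alpha
  bf <- ifelse(ok, alpha0 / (bs * (bs - alpha)), NA_real_)
  data.frame(bs = bs, bf = bf, in_domain = ok)
}

#' Relative root mean square error
#'
#' RRMSE = sqrt(sum((data - model)^2) / N) / sqrt(sum(model^2)), reported as
#' a percentage. Scale-invariant: multiplying both vectors by a constant
#' leaves it unchanged.
#'
#' @param model Model values (not all zero).
#' @param data Observed values, same length.
#' @return RRMSE in percent.
#' @export
rrmse <- function(model, data) {
  stopifnot(length(model) == length(data), length(model) >= 1)
  denom <- sqrt(sum(model^2))
  if (denom == 0) stop("RRMSE undefined: all model values are zero")
  100 * sqrt(mean((data - model)^2)) / denom
}

#' Fold-change modulation of burst statistics
#'
#' Relative fold change of a statistic across a gene's conditions,
#' Delta x = (max x - min x) / min x, computed for burst size and burst
#' frequency, together with the modulation ratio Delta b_f / Delta b_s and a
#' dominance label: `frequency` when the ratio exceeds 2, `size` when it is
#' below 1/2, `comparable` otherwise. The absolute difference
#' Delta b_f - Delta b_s is reported alongside; the 2-fold ratio rule drives
#' the label. Conditions with undefined estimates (mu or sigma^2 zero) must
#' be excluded beforehand; a minimum of 0 makes the fold change undefined.
#'
#' @param bs,bf Per-condition burst size and frequency (NA allowed; dropped).
#' @return One-row data frame: `delta_bs`, `delta_bf`, `modulation_ratio`,
#'   `abs_difference`, `dominance`, `n_used`, `n_excluded`.
#' @export
modulation_fold_changes <- function(bs, bf) {
  keep <- is.finite(bs) & is.finite(bf)
  n_exc <- sum(!keep)
  bs <- bs[keep]
  bf <- bf[keep]
  if (length(bs) < 2) stop("need >= 2 conditions with defined burst estimates")
  if (min(bs) <= 0 || min(bf) <= 0) stop("fold change undefined: minimum <= 0")
  dbs <- (max(bs) - min(bs)) / min(bs)
  dbf <- (max(bf) - min(bf)) / min(bf)
  ratio <- if (dbs == 0) Inf else dbf / dbs
  dom <- if (ratio > 2) "frequency" else if (ratio < 0.5) "size" else "comparable"
  data.frame(delta_bs = dbs, delta_bf = dbf, modulation_ratio = ratio,
             abs_difference = dbf - dbs, dominance = dom,
             n_used = length(bs), n_excluded = n_exc)
}

#' Classify the bursting modulation mode of a gene
#'
#' A positive intercept implies an inverse burst size / frequency relation.
#' For a negative intercept the relation is non-monotonic with a minimum at
#' b_s* = alpha / 2, and the observed burst sizes decide the label: `U_shape`
#' when they straddle alpha / 2 (max above, min below), `inverse` when all
#' sit below alpha / 2, `concurrent` otherwise. A zero intercept (or one
#' treated as zero because it is not significant, when
#' `zero_if_ns_intercept` is set and `q_alpha0 >= 0.05`) gives constant burst
#' size and the label `frequency_only`.
#'
#' @param alpha,alpha0 Fitted line.
#' @param bs_obs Observed per-condition burst sizes.
#' @param q_alpha0 Optional FDR-adjusted intercept p-value.
#' @param zero_if_ns_intercept Treat a non-significant intercept as zero.
#' @return Mode label (character scalar).
#' @export
classify_mode <- function(alpha, alpha0, bs_obs, q_alpha0 = NA,
                          zero_if_ns_intercept = FALSE) {
  if (alpha0 == 0 ||
      (zero_if_ns_intercept && !is.na(q_alpha0) && q_alpha0 >= 0.05)) {
    return("frequency_only")
  }
  if (alpha0 > 0) return("inverse")
  bs_obs <- bs_obs[is.finite(bs_obs)]
  if (length(bs_obs) < 2) return(NA_character_)
  bs_star <- alpha / 2
  if (max(bs_obs) > bs_star && min(bs_obs) < bs_star) return("U_shape")
  if (all(bs_obs < bs_star)) return("inverse")
  "concurrent"
}

#' Per-gene bursting modulation summary
#'
#' For each gene with a usable mean-variance fit, computes per-condition
#' moment burst estimates, the fold-change modulation statistics, the
#' modulation-mode label, and the RRMSE of the fitted line and of the
#' theoretical burst-size and burst-frequency curves against the data at the
#' observed means.
#'
#' @param moments Output of [compute_moments()].
#' @param fits Output of [fit_mean_variance()].
#' @return List with `per_gene` (one row per gene: alpha, alpha0, mode,
#'   dominance, fold changes, RRMSEs) and `per_condition` (gene, condition,
#'   mu, var, bs, bf).
#' @export
burst_modulation <- function(moments, fits) {
  est <- cbind(moments, moment_burst(moments$mu, moments$var))
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    f <- fits[i, ]
    if (isTRUE(f$failed) || is.na(f$alpha)) return(NULL)
    m <- est[est$gene_id == f$gene_id, , drop = FALSE]
    dom_ok <- m$mu > (if (f$alpha0 < 0) abs(f$alpha0) / f$alpha else 0)
    md <- m[dom_ok & is.finite(m$bs) & is.finite(m$bf), , drop = FALSE]
    if (nrow(md) < 2) return(NULL)
    fc <- modulation_fold_changes(md$bs, md$bf)
    mode <- classify_mode(f$alpha, f$alpha0, md$bs, q_alpha0 = f$q_alpha0)
    th <- theoretical_curves(f$alpha, f$alpha0, md$mu)
    data.frame(gene_id = f$gene_id, alpha = f$alpha, alpha0 = f$alpha0,
               mode = mode, fc,
               rrmse_meanvar = rrmse(f$alpha * md$mu + f$alpha0, md$var),
               rrmse_bs = rrmse(th$bs, md$bs),
               rrmse_bf = rrmse(th$bf, md$bf),
               stringsAsFactors = FALSE)
  })
  list(per_gene = do.call(rbind, rows), per_condition = est)
}
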