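#' Per-condition sample moments
#'
#' Computes the sample mean and unbiased (n - 1) variance of the
#' median-scaled counts of every gene in every condition. Conditions with
#' fewer than 2 cells are excluded with a warning (their variance is
#' undefined).
#'
#' Alongside the moments, the sampling variance of the sample variance is
#' estimated from the fourth central moment,
#' Var(s^2) = (m4 - s^4 (n-3)/(n-1)) / n, and returned as `var_of_var`; it
#' feeds the moment-propagated slope standard error of [fit_huber_line()].
#'
#' @param nds A [median_scale()] result.
#' @param view Which matrix to summarize ("scaled", the default used for
#'   mean-variance fitting, or "integer").
#' @return Data frame with columns `gene_id`, `condition`, `mu`, `var`,
#'   `var_of_var`, `n`.
#' @export
compute_moments <- function(nds, view = c("scaled", "integer")) {
  view <- match.arg(view)
  stopifnot(inherits(nds, "normalized_dataset"))
  mat <- if (view == "scaled") nds$scaled else nds$integer_view
  conds <- levels(nds$condition)
  sizes <- table(nds$condition)
  small <- conds[sizes < 2]
  if (length(small) > 0) {
    warning("condition(s) with < 2 cells excluded: ",
            paste(small, collapse = ", "))
    conds <- setdiff(conds, small)
  }
  res <- lapply(conds, function(cc) {
    sub <- mat[, nds$condition == cc, drop = FALSE]
    n <- ncol(sub)
    mu <- rowMeans(sub)
    dev <- sub - mu
    s2 <- rowSums(dev^2) / (n - 1)
    m4 <- rowMeans(dev^4)
    data.frame(gene_id = nds$gene_ids,
               condition = cc,
               mu = mu,
               var = s2,
               var_of_var = pmax((m4 - (n - 3) / (n - 1) * s2^2) / n, 0),
               n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id, out$condition), ]
}

#' Robust linear fit of variance on mean for one gene
#'
#' Fits sigma^2 = alpha * mu + alpha0 across conditions by iteratively
#' reweighted robust regression (Huber M-estimator, tuning constant 1.345,
#' MAD residual scale), via [MASS::rlm()]. Standard errors come from the
#' robust coefficient covariance; two-sided p-values use a t reference with
#' n - 2 degrees of freedom. R^2 is computed unweighted from the robust
#' line's predictions over all points, including any that were downweighted.
#' On data whose residuals never exceed 1.345 robust-scale units the Huber
#' fit coincides with ordinary least squares; exactly collinear (noiseless)
#' points are detected and fitted by least squares directly, since the MAD
#' scale degenerates to zero there.
#'
#' When `points` carries a `var_of_var` column (see [compute_moments()]),
#' the sampling noise of each condition's variance estimate is known, and a
#' second, moment-propagated standard error is computed by treating the
#' converged IRLS estimate as a fixed linear combination of the per-condition
#' variances: Var(alpha) = sum(c_i^2 var_of_var_i). The count sampling noise
#' of s^2 scales with mu, so the homoscedastic plug-in standard error is
#' anti-conservative for cross-fit slope comparisons; the propagated version
#' is calibrated under that noise and is preferred by [slope_ttest()]. Both
#' are reported.
#'
#' @param points Data frame with columns `mu` and `var` (one row per
#'   condition), e.g. one gene's rows of [compute_moments()]; an optional
#'   `var_of_var` column enables the moment-propagated standard errors.
#' @param min_conditions Minimum number of conditions (default 3).
#' @return One-row data frame: `alpha`, `alpha0`, `se_alpha`, `se_alpha0`,
#'   `se_alpha_moment`, `se_alpha0_moment`, `p_alpha`, `p_alpha0`, `r2`,
#'   `n_conditions`, `failed` (logical).
#' @export
fit_huber_line <- function(points, min_conditions = 3) {
  n <- nrow(points)
  failed <- function() {
    data.frame(alpha = NA_real_, alpha0 = NA_real_, se_alpha = NA_real_,
               se_alpha0 = NA_real_, se_alpha_moment = NA_real_,
               se_alpha0_moment = NA_real_,
               p_alpha = NA_real_, p_alpha0 = NA_real_,
               r2 = NA_real_, n_conditions = n, failed = TRUE)
  }
  if (n < min_conditions) return(failed())
  mu <- points$mu
  y <- points$var
  if (length(unique(mu)) < 2) return(failed()) # degenerate mean spread

  ols <- stats::lm(y ~ mu)
  res_scale <- sqrt(mean(stats::residuals(ols)^2))
  fit <- if (res_scale <= 1e-10 * (stats::sd(y) + 1)) {
    ols # noiseless line: MAD scale is 0, Huber IRLS is undefined
  } else {
    tryCatch(
      MASS::rlm(y ~ mu, psi = MASS::psi.huber, k = 1.345,
                scale.est = "MAD", maxit = 200, acc = 1e-8),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(failed())

  cf <- summary(fit)$coefficients # lm: "Estimate"; rlm: "Value" (1st col)
  est <- stats::setNames(cf[, 1], rownames(cf))
  se <- stats::setNames(cf[, 2], rownames(cf))
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  pred <- as.numeric(stats::fitted(fit))
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  se_a_m <- se_a0_m <- NA_real_
  if (!is.null(points$var_of_var) && all(is.finite(points$var_of_var))) {
    w <- if (inherits(fit, "rlm")) fit$w else rep(1, n)
    xbw <- sum(w * mu) / sum(w)
    sxx <- sum(w * (mu - xbw)^2)
    c_slope <- w * (mu - xbw) / sxx
    c_int <- w / sum(w) - xbw * c_slope
    se_a_m <- sqrt(sum(c_slope^2 * points$var_of_var))
    se_a0_m <- sqrt(sum(c_int^2 * points$var_of_var))
  }

  data.frame(alpha = unname(est["mu"]), alpha0 = unname(est["(Intercept)"]),
             se_alpha = unname(se["mu"]), se_alpha0 = unname(se["(Intercept)"]),
             se_alpha_moment = se_a_m, se_alpha0_moment = se_a0_m,
             p_alpha = unname(pval["mu"]), p_alpha0 = unname(pval["(Intercept)"]),
             r2 = r2, n_conditions = n, failed = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Non-finite p-values are excluded from the ranking
#' (the family size is the number of finite p-values) and propagate as NA.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  ok <- is.finite(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Fit mean-variance lines for all genes
#'
#' Applies [fit_huber_line()] per gene, adjusts slope and intercept p-values
#' by Benjamini-Hochberg across the gene set (the FDR family is all genes in
#' the run), and assigns a confidence class.
#'
#' @param moments Output of [compute_moments()].
#' @param min_conditions Passed to [fit_huber_line()].
#' @return Data frame, one row per gene: fit columns plus `q_alpha`,
#'   `q_alpha0`, `confidence_class`.
#' @export
fit_mean_variance <- function(moments, min_conditions = 3) {
  genes <- unique(moments$gene_id)
  fits <- do.call(rbind, lapply(genes, function(g) {
    f <- fit_huber_line(moments[moments$gene_id == g, , drop = FALSE],
                        min_conditions = min_conditions)
    cbind(gene_id = g, f)
  }))
  fits$q_alpha <- bh_fdr(fits$p_alpha)
  fits$q_alpha0 <- bh_fdr(fits$p_alpha0)
  fits$confidence_class <- call_confidence(fits)
  rownames(fits) <- NULL
  fits
}

#' Confidence classification of mean-variance fits
#'
#' A gene is `high_confidence` when its FDR-adjusted slope p-value is below
#' 0.05 and the unweighted R^2 exceeds 0.6; `significant_only` when only the
#' slope criterion holds; `failed` otherwise.
#'
#' @param fits Data frame with columns `q_alpha` and `r2` (and optionally
#'   `failed`).
#' @param q_threshold,r2_threshold Cut-offs (defaults 0.05 and 0.6).
#' @return Character vector of class labels.
#' @export
call_confidence <- function(fits, q_threshold = 0.05, r2_threshold = 0.6) {
  q <- fits$q_alpha
  r2 <- fits$r2
  out <- rep("failed", nrow(fits))
  sig <- !is.na(q) & q < q_threshold
  out[sig & !is.na(r2) & r2 > r2_threshold] <- "high_confidence"
  out[sig & (is.na(r2) | r2 <= r2_threshold)] <- "significant_only"
  if (!is.null(fits$failed)) out[fits$failed] <- "failed"
  out
}
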