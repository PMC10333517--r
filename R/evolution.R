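#' t-test comparing mean-variance slopes between two species
#'
#' t = (alpha1 - alpha2) / sqrt(SE1^2 + SE2^2) with n1 + n2 - 4 degrees of
#' freedom (two regression lines, two parameters each); two-sided p-value
#' from the Student-t distribution. The slope ratio
#' k = max(alpha1, alpha2) / min(alpha1, alpha2) summarizes the magnitude of
#' divergence symmetrically.
#'
#' When both fits carry a finite `se_alpha_moment` (see [fit_huber_line()])
#' that calibrated standard error is used; otherwise the plug-in robust
#' `se_alpha` is taken.
#'
#' @param fit1,fit2 One-row mean-variance fits (from [fit_mean_variance()]
#'   or [fit_huber_line()]) with `alpha`, `se_alpha` (optionally
#'   `se_alpha_moment`), `n_conditions`.
#' @return One-row data frame: `t`, `dof`, `p`, `k`.
#' @export
slope_ttest <- function(fit1, fit2) {
  se1 <- pick_se(fit1)
  se2 <- pick_se(fit2)
  stopifnot(se1 > 0, se2 > 0)
  dof <- fit1$n_conditions + fit2$n_conditions - 4
  if (dof <= 0) stop("n1 + n2 must exceed 4")
  tval <- (fit1$alpha - fit2$alpha) / sqrt(se1^2 + se2^2)
  p <- 2 * stats::pt(-abs(tval), df = dof)
  k <- max(fit1$alpha, fit2$alpha) / min(fit1$alpha, fit2$alpha)
  data.frame(t = tval, dof = dof, p = p, k = k)
}

pick_se <- function(fit) {
  if (!is.null(fit$se_alpha_moment) && is.finite(fit$se_alpha_moment) &&
      fit$se_alpha_moment > 0) {
    fit$se_alpha_moment
  } else {
    fit$se_alpha
  }
}

#' All pairwise slope comparisons across species
#'
#' Runs [slope_ttest()] for every species pair of every gene (six pairs for
#' four species), applies Benjamini-Hochberg correction across all
#' comparisons in the run (switchable to per-gene families), and counts the
#' significant pairs per gene at FDR < 0.05.
#'
#' @param fits_by_species Named list (by species) of [fit_mean_variance()]
#'   tables sharing gene ids.
#' @param fdr_scope "global" (default: one family across all genes x pairs)
#'   or "per_gene" (six-test families).
#' @return List with `comparisons` (gene, species pair, t, dof, p, q, k,
#'   divergent flag at 2-fold) and `per_gene` (gene, n_significant_pairs).
#' @export
pairwise_species <- function(fits_by_species, fdr_scope = c("global", "per_gene")) {
  fdr_scope <- match.arg(fdr_scope)
  species <- names(fits_by_species)
  stopifnot(length(species) >= 2)
  genes <- Reduce(intersect, lapply(fits_by_species, `[[`, "gene_id"))
  pairs <- utils::combn(species, 2, simplify = FALSE)
  rows <- list()
  for (g in genes) {
    for (pr in pairs) {
      f1 <- fits_by_species[[pr[1]]]
      f2 <- fits_by_species[[pr[2]]]
      f1 <- f1[f1$gene_id == g, ]
      f2 <- f2[f2$gene_id == g, ]
      if (isTRUE(f1$failed) || isTRUE(f2$failed) ||
          is.na(f1$alpha) || is.na(f2$alpha)) next
      tt <- slope_ttest(f1, f2)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(gene_id = g, species_a = pr[1], species_b = pr[2],
                   stringsAsFactors = FALSE), tt)
    }
  }
  comp <- do.call(rbind, rows)
  if (is.null(comp)) stop("no valid fit pairs to compare")
  if (fdr_scope == "global") {
    comp$q <- bh_fdr(comp$p)
  } else {
    comp$q <- stats::ave(comp$p, comp$gene_id, FUN = bh_fdr)
  }
  comp$divergent <- comp$k > 2
  sig <- stats::aggregate(q ~ gene_id, data = comp,
                          FUN = function(x) sum(x < 0.05))
  names(sig)[2] <- "n_significant_pairs"
  list(comparisons = comp, per_gene = sig)
}

#' Stratify genes by slope divergence between two species
#'
#' Divergence threshold is a 2-fold change in the mean-variance slope:
#' `divergent_A` when alpha_A > fold * alpha_B, `divergent_B` when
#' alpha_B > fold * alpha_A, `non_divergent` otherwise.
#'
#' @param alpha_a,alpha_b Slopes in species A and B (vectors).
#' @param fold Fold threshold (default 2).
#' @return Character vector of strata.
#' @export
stratify_divergence <- function(alpha_a, alpha_b, fold = 2) {
  stopifnot(length(alpha_a) == length(alpha_b))
  ifelse(alpha_a > fold * alpha_b, "divergent_A",
         ifelse(alpha_b > fold * alpha_a, "divergent_B", "non_divergent"))
}

#' Response-divergence score of a gene
#'
#' `log[(1/3) sum_j (log FC_pig - log FC_glire_j)^2]` over the three glires
#' (mouse, rat, rabbit), where FC is the per-gene fold change in response to
#' stimulation. Natural logarithms; the score is only used for ranking, so
#' the base is immaterial. Invariant to multiplying all fold changes by a
#' constant. Undefined (NA) when any FC is non-positive or all logs
#' coincide.
#'
#' @param fc_pig Fold change in pig (scalar).
#' @param fc_glires Fold changes in the three glires (length-3 vector).
#' @return Score, or NA when undefined.
#' @export
response_divergence <- function(fc_pig, fc_glires) {
  stopifnot(length(fc_glires) == 3)
  if (fc_pig <= 0 || any(fc_glires <= 0)) return(NA_real_)
  inner <- mean((log(fc_pig) - log(fc_glires))^2)
  if (inner == 0) return(NA_real_)
  log(inner)
}

#' Correlation between slope divergence and regulatory complexity
#'
#' Spearman rank correlation between the per-gene slope ratio
#' alpha_A / alpha_B of a species pair and the corresponding ratio of
#' 3-state model wins (conditions where the 3-state fit beats the 2-state
#' fit by AIC), with a one-sided p-value for positive association. Ties get
#' average ranks.
#'
#' @param slope_ratio Per gene-pair slope ratios.
#' @param fraction_ratio Per gene-pair ratios of 3-state win counts.
#' @return List with `r` (Spearman rho) and `p` (one-sided, r > 0).
#' @export
complexity_slope_correlation <- function(slope_ratio, fraction_ratio) {
  ok <- is.finite(slope_ratio) & is.finite(fraction_ratio)
  stopifnot(sum(ok) >= 5)
  ct <- suppressWarnings(
    stats::cor.test(slope_ratio[ok], fraction_ratio[ok],
                    method = "spearman", alternative = "greater",
                    exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Mean-normalized burst frequency
#'
#' Burst frequency divided by mean expression, b_f / mu = mu / sigma^2 (the
#' reciprocal Fano factor), the per-condition statistic used when comparing
#' burst frequency between species at different expression scales.
#'
#' @param mu,var Per-condition mean and variance.
#' @return Numeric vector.
#' @export
normalized_burst_frequency <- function(mu, var) {
  ifelse(mu > 0 & var > 0, mu / var, NA_real_)
}
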