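#' Genetic-algorithm configuration
#'
#' Settings of the real-coded genetic algorithm used to fit dynamical
#' telegraph models: population size 100, elite count 2, crossover fraction
#' 0.6, 20 generations, tournament selection, and 10 independent runs of
#' which the best is kept. Tests and exploratory fits may scale these down;
#' the defaults are the full fitting budget.
#'
#' @param population Population size.
#' @param elite Number of elite individuals copied unchanged each generation.
#' @param crossover Fraction of non-elite children produced by crossover
#'   (the remainder are Gaussian mutations).
#' @param generations Number of generations.
#' @param runs Independent GA restarts; the best final objective wins.
#' @param tournament_size Tournament size for parent selection.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 100, elite = 2, crossover = 0.6,
                      generations = 20, runs = 10, tournament_size = 2) {
  stopifnot(population >= 2, elite >= 0, elite < population,
            crossover >= 0, crossover <= 1, generations >= 1, runs >= 1,
            tournament_size >= 1)
  structure(list(population = as.integer(population),
                 elite = as.integer(elite), crossover = crossover,
                 generations = as.integer(generations),
                 runs = as.integer(runs),
                 tournament_size = as.integer(tournament_size)),
            class = "ga_config")
}

#' Empirical CDF over observed unique counts
#'
#' Right-continuous empirical cumulative distribution function evaluated at
#' each unique observed count.
#'
#' @param counts Integer vector of observed counts (>= 1 observation).
#' @return Data frame with columns `x` (sorted unique counts) and `F`.
#' @export
empirical_cdf <- function(counts) {
  stopifnot(length(counts) >= 1)
  x <- sort(unique(counts))
  data.frame(x = x, F = stats::ecdf(counts)(x))
}

# Parameter bounds per model: switching rates in [0, 1] min^-1,
# transcription rates in [0, 50] mRNA min^-1 per allele.
model_bounds <- function(model) {
  switch(model,
    two_state = list(lower = c(k_on = 0, k_off = 0, k_t = 0),
                     upper = c(k_on = 1, k_off = 1, k_t = 50)),
    three_state = list(
      lower = c(t_on = 0, t_off = 0, k_on = 0, k_off = 0, k_c = 0,
                k_ti = 0, k_t = 0),
      upper = c(t_on = 1, t_off = 1, k_on = 1, k_off = 1, k_c = 1,
                k_ti = 50, k_t = 50)),
    stop("unknown model: ", model))
}

make_params <- function(model, par, k_d) {
  if (model == "two_state") {
    telegraph2(par[1], par[2], par[3], k_d)
  } else {
    telegraph3(par[1], par[2], par[3], par[4], par[5], par[6], par[7], k_d)
  }
}

n_free_params <- function(model) {
  if (model == "two_state") 3L else 7L # k_d is fixed, not counted
}

#' CDF-distance objective for dynamical model fitting
#'
#' Mean absolute distance between the model (CME) and empirical cumulative
#' distribution functions over the unique observed counts:
#' (1/n) sum_i |CME-CDF(x_i) - ECDF(x_i)|. Only conditions with more than
#' one unique count are fittable. During optimization the CME is solved on a
#' fixed truncation slightly beyond the observed range (candidates whose
#' probability mass escapes the data range score poorly regardless, so the
#' cap does not distort the search); the returned best fit is re-solved with
#' the tail-controlled truncation.
#'
#' @param par Parameter vector (model order; see `model_bounds()`).
#' @param model "two_state" or "three_state".
#' @param counts Observed integer counts of the condition.
#' @param t Time since stimulation, minutes. `t = 0` uses a steady-state
#'   initial distribution (see [fit_condition()]).
#' @param k_d Fixed degradation rate (min^-1).
#' @param n_alleles Alleles per gene (default 2).
#' @param N Truncation for the single-allele solve (default from the data).
#' @return Objective value (>= 0).
#' @export
cdf_objective <- function(par, model, counts, t, k_d, n_alleles = 2, N = NULL) {
  ec <- empirical_cdf(counts)
  if (nrow(ec) <= 1) stop("condition has <= 1 unique count; not fittable")
  if (is.null(N)) N <- objective_truncation(counts, n_alleles)
  params <- make_params(model, par, k_d)
  init <- if (t > 0) "off" else "steady"
  d <- tryCatch(
    cme_distribution(params, t, n_alleles = n_alleles, init = init,
                     N = N, tail_tol = Inf, max_doublings = 0),
    error = function(e) NULL)
  if (is.null(d)) return(Inf)
  cdf <- cumsum(d$p)
  mx <- pmin(ec$x + 1, length(cdf))
  mean(abs(cdf[mx] - ec$F))
}

# Search-time truncation: generous around the bulk of the data, but capped
# so that a handful of extreme outlier counts cannot inflate the state
# space (1.5x the 99.5% quantile); the returned best fit is re-solved with
# the tail-controlled truncation before likelihoods are computed.
objective_truncation <- function(counts, n_alleles) {
  top <- min(max(counts),
             ceiling(1.5 * stats::quantile(counts, 0.995, names = FALSE)))
  max(30L, as.integer(ceiling(top / n_alleles)) + 20L)
}

# One GA run: real-coded, tournament selection, intermediate crossover,
# Gaussian mutation with annealed step size, elitism.
ga_run <- function(fn, lower, upper, config) {
  d <- length(lower)
  np <- config$population
  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  fit <- apply(pop, 1, fn)
  best_par <- pop[which.min(fit), ]
  best_val <- min(fit)

  tournament <- function() {
    cand <- sample.int(np, config$tournament_size, replace = TRUE)
    cand[which.min(fit[cand])]
  }
  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    n_child <- np - config$elite
    n_cross <- round(config$crossover * n_child)
    children <- matrix(0, nrow = n_child, ncol = d)
    for (i in seq_len(n_child)) {
      if (i <= n_cross) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        u <- stats::runif(d)
        children[i, ] <- u * p1 + (1 - u) * p2
      } else {
        p1 <- pop[tournament(), ]
        sdev <- 0.15 * (1 - 0.5 * gen / config$generations) * (upper - lower)
        children[i, ] <- p1 + stats::rnorm(d, 0, sdev)
      }
    }
    children <- pmin(pmax(children, rep(lower, each = n_child)),
                     rep(upper, each = n_child))
    elite_idx <- ord[seq_len(config$elite)]
    pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    fit <- c(fit[elite_idx], apply(children, 1, fn))
    if (min(fit) < best_val) {
      best_val <- min(fit)
      best_par <- pop[which.min(fit), ]
    }
  }
  list(par = best_par, value = best_val)
}

#' Fit a dynamical telegraph model to one condition
#'
#' Minimizes the CDF distance of [cdf_objective()] by a genetic algorithm
#' (best of `ga$runs` independent runs, each seed-deterministic), optionally
#' followed by a bounded Nelder-Mead refinement (flagged in the result). The
#' degradation rate is fixed from the gene's half-life and not estimated.
#' Untreated (t = 0) conditions cannot start from the all-off, zero-mRNA
#' initial condition (it would predict all-zero counts); they are fitted
#' with a steady-state initial distribution at the candidate parameters and
#' flagged `steady_init`. The returned fit carries the multinomial
#' log-likelihood and AIC evaluated on a tail-controlled re-solve of the CME
#' at the fitted parameters.
#'
#' @param counts Integer counts of the condition (> 1 unique value).
#' @param t Time in minutes (>= 0).
#' @param k_d Degradation rate (min^-1), from the half-life table.
#' @param model "two_state" or "three_state".
#' @param ga A [ga_config()].
#' @param seed Master seed; run r uses seed + r - 1.
#' @param refine Apply Nelder-Mead refinement after the GA.
#' @param n_alleles Alleles per gene.
#' @return Object of class `dynamic_fit`: list with `model`, `par`,
#'   `objective`, `logL`, `aic`, `n_params`, `runs` (per-run objectives),
#'   `best_run`, `refined`, `steady_init`, `seed`.
#' @export
fit_condition <- function(counts, t, k_d, model = c("two_state", "three_state"),
                          ga = ga_config(), seed = 1, refine = TRUE,
                          n_alleles = 2) {
  model <- match.arg(model)
  stopifnot(all(counts >= 0), all(counts == floor(counts)), t >= 0, k_d > 0)
  if (length(unique(counts)) <= 1) {
    stop("condition has <= 1 unique count; not fittable")
  }
  b <- model_bounds(model)
  N <- objective_truncation(counts, n_alleles)
  # closure with the empirical CDF and initial vector precomputed once
  ec <- empirical_cdf(counts)
  init <- if (t > 0) "off" else "steady"
  fn <- function(par) {
    params <- make_params(model, par, k_d)
    d <- tryCatch(
      cme_distribution(params, t, n_alleles = n_alleles, init = init,
                       N = N, tail_tol = Inf, max_doublings = 0),
      error = function(e) NULL)
    if (is.null(d)) return(Inf)
    cdf <- cumsum(d$p)
    mean(abs(cdf[pmin(ec$x + 1, length(cdf))] - ec$F))
  }
  run_res <- vector("list", ga$runs)
  for (r in seq_len(ga$runs)) {
    set.seed(seed + r - 1)
    run_res[[r]] <- ga_run(fn, b$lower, b$upper, ga)
  }
  vals <- vapply(run_res, `[[`, numeric(1), "value")
  best_run <- which.min(vals)
  best <- run_res[[best_run]]

  refined <- FALSE
  if (refine) {
    pen_fn <- function(par) {
      viol <- sum(pmax(b$lower - par, 0) + pmax(par - b$upper, 0))
      if (viol > 0) return(best$value + 1 + 100 * viol)
      fn(par)
    }
    opt <- stats::optim(best$par, pen_fn, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
    if (opt$value < best$value) {
      best <- list(par = pmin(pmax(opt$par, b$lower), b$upper),
                   value = opt$value)
      refined <- TRUE
    }
  }

  params <- make_params(model, best$par, k_d)
  init <- if (t > 0) "off" else "steady"
  N_final <- max(as.integer(ceiling(max(counts) / n_alleles)) + 10L,
                 as.integer(ceiling(4 * stationary_mean_per_allele(params) + 30)))
  dist <- cme_distribution(params, t, n_alleles = n_alleles, init = init,
                           N = N_final, tail_tol = 1e-8)
  ll <- multinomial_loglik(dist$p, counts)
  p_free <- n_free_params(model)
  structure(list(model = model, par = stats::setNames(best$par, names(b$lower)),
                 objective = best$value, logL = ll,
                 aic = aic(ll, p_free), n_params = p_free,
                 runs = vals, best_run = best_run, refined = refined,
                 steady_init = (t == 0), seed = seed, t = t, k_d = k_d,
                 n_alleles = n_alleles),
            class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("<dynamic_fit> %s model, objective %.4g, logL %.2f, AIC %.2f\n",
              x$model, x$objective, x$logL, x$aic))
  print(signif(x$par, 4))
  invisible(x)
}

#' Multinomial log-likelihood of a count distribution
#'
#' Log-likelihood of observed counts under a discrete model distribution,
#' including the multinomial coefficient:
#' logL = log(N! / prod_k Y_k!) + sum_k Y_k log P(x_k), where Y_k is the
#' number of cells displaying the k-th observed count. Log-factorials use
#' the log-gamma function. If a count with P = 0 is observed, logL = -Inf.
#'
#' @param p Probability vector over counts 0..length(p)-1 (e.g. the `p`
#'   field of a [cme_distribution()]).
#' @param counts Observed integer counts.
#' @return Log-likelihood (scalar; -Inf if the model excludes an observation).
#' @export
multinomial_loglik <- function(p, counts) {
  tab <- table(counts)
  x <- as.integer(names(tab))
  y <- as.integer(tab)
  px <- ifelse(x + 1 <= length(p), p[pmin(x + 1, length(p))], 0)
  if (any(px == 0 & y > 0)) return(-Inf)
  lgamma(sum(y) + 1) - sum(lgamma(y + 1)) + sum(y * log(px))
}

#' Akaike information criterion
#'
#' AIC = 2p - 2 logL, penalizing model complexity; p counts only the free
#' kinetic rates (3 for the 2-state model, 7 for the 3-state model; the
#' degradation rate is fixed externally).
#'
#' @param logL Log-likelihood (finite).
#' @param n_params Number of free parameters.
#' @return AIC value.
#' @export
aic <- function(logL, n_params) {
  2 * n_params - 2 * logL
}

#' Filter unsatisfactory fits by AIC outliers
#'
#' Within one model family, fits with AIC above Q3 + 1.5 IQR (quartiles by
#' linear interpolation, the default quantile convention) are flagged as
#' unsatisfactory optimizer outcomes and removed from downstream selection.
#' The filter is idempotent on its retained set.
#'
#' @param aics Numeric AIC values for one model family across genes and
#'   conditions (>= 4 values).
#' @return Logical vector: TRUE where the fit is retained.
#' @export
filter_aic_outliers <- function(aics) {
  stopifnot(length(aics) >= 4)
  q <- stats::quantile(aics, c(0.25, 0.75), na.rm = TRUE, type = 7)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  is.finite(aics) & aics <= thr
}

#' AIC model selection between the 2-state and 3-state fits
#'
#' `absolute`: the lower AIC wins. `half` (equivalently `twofold`, the
#' stricter criterion phrased as a two-fold AIC change): the better model
#' wins only if its AIC is below half the other's, otherwise a tie. If one
#' AIC is missing the present model wins by default.
#'
#' @param aic2,aic3 AIC of the 2-state and 3-state fits (vectors; NA for
#'   missing).
#' @param rule "absolute", "half", or "twofold".
#' @return Character vector: "two_state", "three_state", or "tie".
#' @export
select_model <- function(aic2, aic3, rule = c("absolute", "half", "twofold")) {
  rule <- match.arg(rule)
  n <- max(length(aic2), length(aic3))
  aic2 <- rep_len(aic2, n)
  aic3 <- rep_len(aic3, n)
  out <- character(n)
  for (i in seq_len(n)) {
    a2 <- aic2[i]; a3 <- aic3[i]
    if (is.na(a2) && is.na(a3)) { out[i] <- NA_character_; next }
    if (is.na(a3)) { out[i] <- "two_state"; next }
    if (is.na(a2)) { out[i] <- "three_state"; next }
    if (rule == "absolute") {
      out[i] <- if (a3 < a2) "three_state" else if (a2 < a3) "two_state" else "tie"
    } else {
      out[i] <- if (a3 < 0.5 * a2) "three_state"
                else if (a2 < 0.5 * a3) "two_state"
                else "tie"
    }
  }
  out
}

#' Fraction of conditions won by the 3-state model
#'
#' Per gene, the number of conditions whose 3-state fit has lower AIC than
#' the 2-state fit (the absolute rule), over all selectable conditions.
#' Conditions whose fits failed or were outlier-filtered should be excluded
#' before calling.
#'
#' @param selections Character vector of [select_model()] results (absolute
#'   rule) for one gene's conditions.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_three_state <- function(selections) {
  selections <- selections[!is.na(selections)]
  stopifnot(length(selections) >= 1)
  mean(selections == "three_state")
}

#' Fit dynamical models across the conditions of selected genes
#'
#' Pipeline wrapper: for each requested gene and each condition with more
#' than one unique integer count, fits the requested models with
#' [fit_condition()] on the rounded-integer view, using the gene's half-life
#' for the fixed degradation rate and `time_h * 60` minutes as the
#' propagation time.
#'
#' @param nds A [median_scale()] result.
#' @param half_lives Data frame from [read_half_lives()].
#' @param genes Gene ids to fit (must appear in the half-life table).
#' @param models Models to fit.
#' @param ga A [ga_config()].
#' @param seed Master seed; offsets are derived per gene x condition x model.
#' @param ... Passed to [fit_condition()].
#' @return Data frame: gene, condition, model, fitted rates, objective,
#'   logL, AIC, refined and steady-init flags.
#' @export
fit_dynamic_models <- function(nds, half_lives, genes,
                               models = c("two_state", "three_state"),
                               ga = ga_config(), seed = 1, ...) {
  rows <- list()
  offset <- 0L
  for (g in genes) {
    hl <- half_lives$k_d[match(g, half_lives$gene_id)]
    if (is.na(hl)) stop("no half-life for gene ", g)
    for (cc in levels(nds$condition)) {
      cnt <- condition_counts(nds, g, cc, view = "integer")
      meta_row <- nds$cell_meta[match(TRUE, nds$condition == cc), ]
      t_min <- meta_row$time_h * 60
      if (length(unique(cnt)) <= 1) next
      for (mdl in models) {
        f <- fit_condition(cnt, t_min, hl, model = mdl, ga = ga,
                           seed = seed + offset, ...)
        offset <- offset + ga$runs
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = g, condition = cc, model = mdl,
          t(f$par), objective = f$objective, logL = f$logL, aic = f$aic,
          refined = f$refined, steady_init = f$steady_init,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(names(model_bounds("three_state")$lower), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
}
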