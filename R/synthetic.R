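#' Exact stochastic simulation of telegraph-model transcription
#'
#' Gillespie simulation of the same jump process the master equation
#' describes: each allele switches between promoter states, transcribes in
#' permissive states, and transcripts degrade at first order in the pooled
#' mRNA count. Every cell starts with no mRNA and all alleles 'off'. Cells
#' are simulated on independent counter-based random streams derived from the
#' master seed, so results are reproducible and independent of batching.
#'
#' @param params Telegraph parameter set ([telegraph2()]/[telegraph3()]).
#' @param t Simulated time in minutes (>= 0).
#' @param n_cells Number of independent cells.
#' @param seed Master seed (non-negative integer).
#' @param n_alleles Alleles per gene (default 2).
#' @return Integer vector of mRNA totals, one per cell.
#' @export
simulate_ssa <- function(params, t, n_cells, seed, n_alleles = 2) {
  stopifnot(t >= 0, n_cells >= 1, n_alleles >= 1)
  kin <- allele_kinetics(params)
  .ssa_telegraph_cpp(kin$sw, kin$ktr, params$k_d, t, as.integer(n_cells),
                     as.integer(n_alleles), as.double(seed))
}

#' Sample mRNA counts from the CME distribution
#'
#' Draws i.i.d. counts from the time-dependent distribution P(X, t) computed
#' by [cme_distribution()] (auto-truncated until the tail mass is below
#' `tail_tol`).
#'
#' @inheritParams simulate_ssa
#' @param init Initial condition, as in [cme_distribution()].
#' @param tail_tol Tolerated truncation tail mass (default 1e-6).
#' @return Integer vector of counts, one per cell.
#' @export
sample_from_cme <- function(params, t, n_cells, seed, n_alleles = 2,
                            init = "off", tail_tol = 1e-6) {
  d <- cme_distribution(params, t, n_alleles = n_alleles, init = init,
                        tail_tol = tail_tol)
  set.seed(seed)
  sample(d$counts, size = n_cells, replace = TRUE, prob = d$p)
}

#' Generate a count dataset obeying a linear mean-variance constraint
#'
#' For each requested condition mean mu, draws negative-binomial counts with
#' mean mu and variance alpha * mu + alpha0, so that the condition-level
#' sample moments converge to the target line sigma^2 = alpha * mu + alpha0.
#' When the target variance equals the mean the draws are Poisson (the
#' negative-binomial limit). Conditions are labelled with a treatment time
#' course cycling through 0/2/4/6 h replicates, emulating the structure of a
#' stimulation experiment.
#'
#' @param alpha Slope(s) of the mean-variance line; a vector generates one
#'   gene per element (same mu grid, independent draws).
#' @param alpha0 Intercept (shared across genes).
#' @param mus Condition means; each must satisfy alpha * mu + alpha0 >= mu.
#' @param n_cells Cells per condition.
#' @param seed Seed for the draws.
#' @param species Species label for the metadata.
#' @param treatment Treatment label.
#' @return A [count_dataset()] with `length(alpha)` genes and
#'   `length(mus)` conditions.
#' @export
generate_linear_family <- function(alpha, alpha0, mus, n_cells, seed,
                                   species = "synthetic", treatment = "LPS") {
  stopifnot(length(mus) >= 1, n_cells >= 1, all(mus > 0))
  for (a in alpha) {
    v <- a * mus + alpha0
    bad <- which(v < mus)
    if (length(bad) > 0) {
      stop(sprintf(
        "infeasible condition: mu = %g needs variance %g < mean (alpha = %g, alpha0 = %g)",
        mus[bad[1]], v[bad[1]], a, alpha0))
    }
  }
  set.seed(seed)
  n_cond <- length(mus)
  n_genes <- length(alpha)
  times <- rep(c(0, 2, 4, 6), length.out = n_cond)
  reps <- rep(seq_len(ceiling(n_cond / 4)), each = 4)[seq_len(n_cond)]

  counts <- matrix(0L, nrow = n_genes, ncol = n_cond * n_cells)
  for (g in seq_len(n_genes)) {
    for (j in seq_len(n_cond)) {
      mu <- mus[j]
      v <- alpha[g] * mu + alpha0
      cols <- ((j - 1) * n_cells + 1):(j * n_cells)
      counts[g, cols] <- if (v > mu) {
        stats::rnbinom(n_cells, mu = mu, size = mu^2 / (v - mu))
      } else {
        stats::rpois(n_cells, mu)
      }
    }
  }
  meta <- data.frame(
    cell_id = paste0("cell", seq_len(n_cond * n_cells)),
    species = species,
    treatment = treatment,
    time_h = rep(times, each = n_cells),
    replicate = rep(reps, each = n_cells),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- paste0("gene", seq_len(n_genes))
  count_dataset(counts, meta)
}

#' Generate a multi-species panel with species-specific slopes
#'
#' One dataset per species on a shared mean grid, each obeying its own
#' mean-variance line sigma^2 = alpha_s * mu + alpha0. Used to emulate
#' cross-species divergence of response variability, where the slope ratio
#' between two species indexes the evolutionary change in variability.
#'
#' @param slopes Named numeric vector (one gene) or named list of numeric
#'   vectors (several genes), one element per species.
#' @param alpha0 Shared intercept.
#' @param mus Shared condition-mean grid, or a named list of per-species
#'   grids (so species may differ in condition count).
#' @param n_cells Cells per condition.
#' @param seed Master seed; species s uses seed + s - 1.
#' @return Named list of [count_dataset()]s, one per species.
#' @export
generate_species_panel <- function(slopes, alpha0, mus, n_cells, seed) {
  species <- names(slopes)
  if (is.null(species)) stop("slopes must be named by species")
  out <- vector("list", length(species))
  names(out) <- species
  for (s in seq_along(species)) {
    mu_s <- if (is.list(mus)) mus[[species[s]]] else mus
    a_s <- if (is.list(slopes)) slopes[[s]] else slopes[s]
    out[[s]] <- generate_linear_family(a_s, alpha0, mu_s, n_cells,
                                       seed = seed + s - 1,
                                       species = species[s])
  }
  out
}
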