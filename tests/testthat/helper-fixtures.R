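# Shared fixtures built in code.

# Tiny 3-gene x 4-cell dataset with 2 conditions.
tiny_dataset <- function() {
  counts <- matrix(c(0, 1, 2, 3,
                     4, 0, 1, 0,
                     2, 2, 0, 5), nrow = 3, byrow = TRUE)
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     species = "mouse",
                     treatment = "LPS",
                     time_h = c(2, 2, 4, 4),
                     replicate = 1L,
                     stringsAsFactors = FALSE)
  count_dataset(counts, meta, gene_ids = c("g1", "g2", "g3"))
}

# Reference kinetic parameter sets: a symmetric non-bursty gene and the
# bursty regime characteristic of fitted stimulation-response kinetics
# (slow on, fast off, half-life 30 min).
params_symmetric <- function() telegraph2(1, 1, 10, 1)
params_bursty <- function() telegraph2(0.02, 0.74, 1.2, half_life_to_rate(30))
params_three_state <- function() {
  telegraph3(t_on = 0.036, t_off = 0.74, k_on = 0.33, k_off = 0.44,
             k_c = 0.50, k_ti = 2, k_t = 30, k_d = half_life_to_rate(30))
}

# Condition-mean grid used for linear-family generators (8 conditions
# spanning the induction range of a stimulated gene).
mu_grid8 <- function() c(5, 10, 20, 40, 60, 80, 100, 150)

# Reduced GA budget for tests (the package default is the full budget).
ga_small <- function() ga_config(population = 40, generations = 15, runs = 3)

# Moments of an integer sample as a probability vector comparison helper.
empirical_pmf <- function(x, len) tabulate(x + 1, nbins = len) / length(x)
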