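# burstlin

Transcriptional bursting inference from linear mean-variance constraints in
single-cell UMI count data.

## What this package is for

Stimulating innate-immune cells (LPS through TLR4, dsRNA mimics through
TLR3) produces mRNA responses that differ widely between otherwise
identical cells. For many response genes, the per-condition sample mean μ
and variance σ² of a gene's counts — one point per (treatment, time,
replicate) condition — fall on a line

    σ² = α μ + α₀

whose slope α indexes the gene's response heterogeneity. `burstlin` is for
analysts who want to exploit that constraint quantitatively:

* **Mean-variance fitting** — per-gene robust (Huber M-estimator, tuning
  constant 1.345) regression of σ² on μ across conditions, with
  Benjamini–Hochberg FDR on slopes and intercepts and a high-confidence
  call (FDR < 0.05 and unweighted R² > 0.6).
* **Bursting modulation schemes** — under the linear constraint the moment
  estimators of burst size (Fano factor, b_s = σ²/μ) and burst frequency
  (b_f = μ²/σ²) become analytical functions of the mean:
  b_s(μ) = α₀/μ + α, b_f(μ) = μ²/(α₀ + αμ), and
  b_f = α₀/(b_s(b_s − α)). The sign of α₀ decides the modulation mode
  (inverse, U-shape with minimum at b_s = α/2, concurrent, or pure
  frequency modulation at α₀ = 0), validated against the data by relative
  RMS error and fold-change modulation ratios.
* **Dynamical telegraph models** — exact time-dependent mRNA count
  distributions of 2-state (off/on) and 3-state (off/intermediate/on)
  promoter-switching models with two independent alleles, solved from the
  chemical master equation by uniformization (compiled), fitted per
  condition by a genetic algorithm on a CDF distance, and compared by AIC
  with a multinomial likelihood — a readout of regulatory complexity.
* **Beta-Poisson steady state** — maximum-likelihood fitting of the
  stationary 2-state model (closed-form confluent-hypergeometric pmf), with
  convergence flags and high-coverage gene selection.
* **Cross-species divergence** — pairwise slope t-tests between species,
  slope ratios k = max(α₁,α₂)/min(α₁,α₂), 2-fold divergence
  stratification, response-divergence scores, and the Spearman association
  between slope ratios and 3-state model prevalence.
* **Synthetic data with ground truth** — exact Gillespie simulation of the
  telegraph process, sampling from the CME solution, and negative-binomial
  "linear family" generators (per-condition mean μ, variance αμ + α₀), so
  every stage has parameter-recovery tests without downloading anything.

## Worked example

One synthetic gene obeying σ² = 20 μ + 100 across 8 stimulation conditions
(5,000 cells each), fitted and classified:

```r
library(burstlin)
ds   <- generate_linear_family(alpha = 20, alpha0 = 100,
                               mus = c(5, 10, 20, 40, 60, 80, 100, 150),
                               n_cells = 5000, seed = 42)
nds  <- identity_scale(ds)        # synthetic counts are already on one scale
mom  <- compute_moments(nds)
fits <- fit_mean_variance(mom)
fits[, c("gene_id", "alpha", "alpha0", "q_alpha", "r2", "confidence_class")]
#>   gene_id alpha alpha0   q_alpha     r2 confidence_class
#> 1   gene1 20.52  91.78 1.589e-12 0.9992  high_confidence

bm <- burst_modulation(mom, fits)
bm$per_gene[, c("mode", "dominance", "delta_bs", "delta_bf",
                "modulation_ratio", "rrmse_meanvar")]
#>      mode dominance delta_bs delta_bf modulation_ratio rrmse_meanvar
#> 1 inverse frequency    0.816     53.1             65.1         0.587
```

The generating line is recovered (α̂ = 20.5, α̂₀ = 91.8, R² = 0.999) and the
positive intercept correctly implies an inverse burst size/frequency
relationship dominated by frequency modulation: across the fitted mean
range, burst frequency changes 53-fold relative to its minimum while burst
size changes 0.8-fold, and the theoretical curves track the per-condition
moment estimates to a relative RMS error below 1%. At μ = 10 the curves
evaluate to b_s = 30 and b_f = 1/3, as the closed forms require.

Dynamical fitting of a single condition works the same way from raw counts:

```r
kd  <- half_life_to_rate(30)                   # 30-min mRNA half-life
cnt <- sample_from_cme(telegraph2(0.02, 0.74, 1.2, kd),
                       t = 120, n_cells = 5000, seed = 1)
fit <- fit_condition(cnt, t = 120, k_d = kd, model = "two_state",
                     ga = ga_config(population = 40, generations = 15,
                                    runs = 3), seed = 1)
```

which recovers the burst throughput k_t·k_on/(k_on+k_off) of the generating
kinetics within a few percent (see the test suite for the full recovery
studies and their acceptance thresholds).

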