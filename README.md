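# cryptdrift

Stochastic stem-cell competition and clonal drift in intestinal crypts.

Intestinal crypts are maintained by a handful of equipotent Lgr5+ stem
cells that stochastically replace one another ("neutral drift"): a
labelled clone performs a random walk in size until it is lost from the
niche or takes over the whole crypt (monoclonal conversion, *fixation*).
Reducing secreted Wnt ligands — e.g. with a Porcupine inhibitor — shrinks
the competing pool by removing stem-cell activity at the *border* of the
niche while leaving *centre* cells intact, which accelerates fixation; if
the winning clone carries an *Apc* mutation, that acceleration becomes
faster adenoma initiation.  cryptdrift is a simulator + inference package
for exactly this setting, aimed at quantitative stem-cell and
tumour-initiation modellers.

At its core:

* **Ring Moran model** — `N` niche positions on a ring, replacement at
  rate λ per cell per day (each clone boundary resolves at rate λ), with
  biased displacement at mutant/wild-type boundaries: the mutant wins
  with probability *b*, giving the gambler's-ruin fixation probability

  P(fix | n₀) = (1 − ρ^n₀) / (1 − ρ^N),  ρ = (1 − b)/b,

  and n₀/N in the neutral limit b = ½.
* **Exact birth–death oracle** — the contiguous-clone size chain on 0..N
  (absorbing at 0 and N, total stepping rate 2λ), evaluated by matrix
  exponential; every simulator claim is tested against it.
* **Niche compartments** — centre/border split with Wnt inhibition as
  border-pool removal or stochastic border expulsion; intravital-imaging
  style per-day clone persistence curves.
* **Clonal readouts** — clone size in eighths (0–8), fixation fractions,
  clones per field, partial/full crypt genotype scoring.
* **Three-allele Cre-lox model** — reporter + two *Apc* alleles with
  region-specific efficiencies, quantifying reporter/genotype
  discordance (a tdTom+ cell is Apc-null only with probability q²).
* **Synthetic cohorts** — fixed-tissue clonal-fate, daily-imaging and
  *Apc* tumour-initiation experiments with per-mouse sampling, seeded
  and byte-reproducible.
* **Inference** — profile maximum likelihood for (N, λ) from
  eighths-binned cross-sectional records, with likelihood-ratio support
  sets, profile CIs, and cluster-bootstrap arm contrasts.

## Worked example

Simulate the two-arm clonal-fate experiment at the documented defaults
(vehicle vs Porcupine-inhibitor arm; treatment from day 1; ~1.2 induced
cells per labelled crypt) and summarise day 21:

```r
library(cryptdrift)

design <- default_fixation_design(timepoints = c(4, 21),
                                  mice_per_arm = 3, crypts_per_mouse = 200)
ds <- run_neutral_cohort(design, seed = 1)

summarize_timepoint(ds[ds$arm == "vehicle" & ds$day == 21, ])
#> # A tibble: 1 x 6
#>     day n_clones n_surviving mean_clone_size_eighths fraction_fixed clones_per_field
#>   <dbl>    <int>       <int>                   <dbl>          <dbl>            <dbl>
#> 1    21      600         147                    2.76        0.00680             12.2

summarize_timepoint(ds[ds$arm == "inhibitor" & ds$day == 21, ])
#> # A tibble: 1 x 6
#>     day n_clones n_surviving mean_clone_size_eighths fraction_fixed clones_per_field
#>   <dbl>    <int>       <int>                   <dbl>          <dbl>            <dbl>
#> 1    21      600          53                    8              1                4.42
```

By day 21 every surviving inhibitor-arm clone has fixed (fraction_fixed
= 1, mean size 8/8 eighths) while fewer than 1% of surviving
vehicle-arm clones have; the inhibitor arm has also lost more clones
entirely (53 vs 147 survivors of 600), because a smaller pool resolves
competition — in either direction — much faster.

Fit the drift parameters back from a synthetic cohort:

```r
truth <- cohort_design(
  arms = list(truth = cohort_arm(drift_params(16, 0.1), make_niche(16, 0))),
  timepoints = c(4, 7, 10, 14, 21), mice_per_arm = 2, crypts_per_mouse = 200)
fit <- fit_drift(run_neutral_cohort(truth, seed = 1))
fit
#> Drift-parameter fit (profile maximum likelihood)
#>   N hat:      16 (95% support set: 16-16)
#>   lambda hat: 0.09524 /cell/day (95% CI 0.08748-0.1036)
#>   log-likelihood -2398.31 over 2000 records
```

The point estimates recover the generating values (N = 16, λ = 0.1) and
the 95% profile CI covers the true rate.

## Documentation

The methods vignette (`vignettes/crypt-drift-model.Rmd`) documents the
model and its assumptions, the rate convention, the eighths binning, the
recombination model, the likelihood (initial-condition and survival
conventions), the calibrated defaults, and known limitations.
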