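# pftc — quantitative time-course analysis of parallel-factor ChIP-seq

Chromatin immunoprecipitation sequencing (ChIP-seq) of a stimulated
transcription factor over a time course is hard to interpret quantitatively:
each library carries its own immunoprecipitation efficiency and sequencing
depth, so raw per-peak read counts are not comparable between samples.
Parallel-factor ChIP-seq (pfChIP-seq) solves this by immunoprecipitating a
constitutively bound control factor (CTCF) in the same reaction as the
dynamic target (the estrogen receptor, ER, after estra-2-diol stimulation in
the motivating application), so every library contains its own internal
normalization reference.

`pftc` implements the quantitative analysis layer of such an experiment for
researchers in regulatory genomics:

- **Internal-control normalization.** For sample *i* with control-site counts
  *x<sub>ij</sub>* and cross-sample mean control profile
  *m<sub>j</sub> = mean<sub>i</sub>(x<sub>ij</sub>)*, the factor is the
  zero-intercept least-squares slope
  *f<sub>i</sub> = Σ<sub>j</sub> x<sub>ij</sub> m<sub>j</sub> / Σ<sub>j</sub> x<sub>ij</sub>²*,
  re-centered to geometric mean 1; normalized occupancy is
  *count × f<sub>i</sub>*. A median-of-ratios alternative and a log-scale fit
  are available. Consensus peak sets ("found in over 50% of samples") are
  built with `consensus_sites()`.
- **Temporal statistics.** Per-site pairwise Welch t-tests and two-sided
  variance-ratio F-tests over all time-point pairs with Benjamini–Hochberg
  FDR control; and the signal-versus-control variance attribution: pooling
  post-stimulation samples, removing per-time-point means, and testing
  *F = s²<sub>signal</sub> / s²<sub>control</sub>* on df (N−T, N−T) —
  because the control site carries technical noise only, excess signal
  variance is biological.
- **Trajectory classification.** Deterministic thresholds on (response FDR,
  amplitude, baseline) assign classes A (strong ligand-responsive),
  C (weak responsive), B (ligand-independent constitutive) or unassigned;
  t-SNE embeddings with perplexity sweeps visualize the two trajectories and
  quantify their separation.
- **Sustained vs cyclical kinetics.** Nested least-squares comparison of
  *baseline + amp·(1 − e^(−t/τ))* against the same model plus a fitted
  sinusoid (period profiled over a grid), accepted only on a significant
  F-ratio **and** an oscillation amplitude of at least 20% of the plateau.
- **Synthetic data with ground truth.** A seeded generator emulating the
  study design — 10 time points spanning 0–90 min × 6 replicates, one
  library containing both factors' sites, per-sample efficiency × depth
  confounders, negative-binomial counts, per-replicate biological noise on
  signal sites — so the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(pftc)

ds <- simulate_timecourse(study_design(seed = 1))
ds
#> <pftc_counts> 4500 sites (2500 signal, 2000 control) x 60 samples
#>   ground truth classes: A=400, B=400, C=1200, control=2000, null=500; seed 1

f <- derive_factors(ds)           # per-sample normalization factors
f
#> <pftc_factors> 60 samples, method 'control-regression', range [0.6637, 1.97]

b  <- apply_factors(ds, f)        # normalized binding matrix
cl <- classify_sites(b)           # trajectory classes
cl
#> <site_classification> 2500 sites: A=398, B=400, C=1193, unassigned=509 (amplitude split 49.2)

site_profile(b, "signal_0001")[1:3, ]
#>   time_min      mean       sd
#> 1        0  35.90002 11.23785
#> 2       10 107.15744 31.06908
#> 3       20 105.59311 37.03789

variance_attribution(seed = 1)    # signal vs control replicate variance
#> <variance_comparison> signal_0366 vs control_1715 (t >= 10 min)
#>   F = 21.28 on df (45, 45), two-sided p = 7.595e-19
#>   residual CV: signal 0.249, control 0.054

assess_kinetics(b, "signal_0001")
#> <kinetics_assessment> signal_0001: preferred sustained (F = 0.133, p = 0.94, osc/plateau = 0.0404)
#>   sustained SSE 5.587e+04; cyclical SSE 5.546e+04 (period 90 min)
```

Reading the output: the factor range (0.66–1.97) is the per-sample
efficiency × depth confounder the normalization removes; the classification
recovers the generating site classes (398/400 strong responders, 400/400
constitutive sites); the per-site profile shows the rapid (< 10 min)
saturating rise of a strong responder; the variance comparison attributes the
signal site's ~25% replicate CV to biology against a 5% technical control;
and the kinetic assessment prefers the sustained model — the fitted
oscillation would be 4% of plateau, far below the 20% acceptance guard.

The pipeline end to end, with stage outputs and a run record:

```r
run <- run_pipeline(default_config(seed = 1, out_dir = "pftc_run"))
validate_against_truth(run)
```

or from a shell via the thin wrapper `inst/cli/pftc.R`:

```sh
Rscript inst/cli/pftc.R run --simulate --seed 42 --out pftc_run
```

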