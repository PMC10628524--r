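# plisw

Phase-lag-index connectivity and small-world network analysis for
source-space MEG.

## The problem

Resting-state MEG studies of Alzheimer's disease increasingly describe the
brain as a graph: 68 cortical regions (Desikan–Killiany parcellation) as
nodes, band-specific phase synchrony between their source time series as
edges. `plisw` implements that analysis end to end for users who want a
tested, scriptable version of the standard recipe:

1. **Connectivity.** Each recording is cut into 5-s epochs; each epoch is
   zero-phase band-pass filtered into the canonical bands (delta 2–4,
   theta 4–8, alpha 8–13, beta 13–30, gamma 30–60 Hz); instantaneous
   phases come from the analytic signal, and pairwise synchrony is the
   **phase lag index**

   $$\mathrm{PLI} = \Bigl|\tfrac{1}{N}\sum_{k=1}^{N}
     \mathrm{sign}\,\Delta\phi(t_k)\Bigr| \in [0,1],$$

   which ignores zero-lag synchrony and is therefore insensitive to field
   spread between nearby reconstructed sources.
2. **Graphs.** Per-subject epoch-averaged PLI matrices are binarized with
   a proportional threshold (default κ = 0.2, i.e. the strongest 20 % of
   all 2278 possible connections → exactly 455 edges on 68 nodes). From
   the binary graph: mean clustering coefficient *C*, characteristic path
   length *L* over connected node pairs only, and **small-worldness**

   $$SW = \frac{C/C_{rand}}{L/L_{rand}},$$

   with null values averaged over 1000 degree-preserving
   (Maslov–Sneppen) rewired graphs. Eyes-state **reactivity** is
   `(SW_EO − SW_EC) / (SW_EO + SW_EC)`.
3. **Inference.** Per band: linear mixed models predicting SW from
   disease status, eyes condition, and age with subject random intercepts
   and cluster-robust (sandwich) standard errors (α = 0.05); per
   group × condition OLS of SW on delayed recall (WMS-R) and age with
   HC1 robust errors (α = 0.025); the same regression for reactivity; and
   demographic group tests (pooled t, Pearson χ²) from summary
   statistics.

A synthetic-data module generates coupled band-limited oscillators with
known pairwise phase-lag structure, benchmark graphs with known metrics,
and subject tables with known regression coefficients, so every stage is
testable without MEG recordings (none are distributed with the package).

## Worked example

```r
library(plisw)
library(dplyr)

# demographic statistics recomputed from printed group summaries
demographics_from_summary(example_cohort_summaries())
#>                  variable statistic_type statistic df  p_value
#> 1                     age              t  -1.64927 40 1.07e-01
#> 3                    mmse              t   8.92283 40 4.64e-11
#> 8          delayed_recall              t  10.64484 40 3.09e-13
#> 9                     sex           chi2   0.00841  1 9.27e-01
#> ... (education and the remaining WMS-R indices omitted here)

# a small synthetic study, end to end
cfg <- pipeline_config(n_null = 100, master_seed = 42)
sim <- simulate_study(cfg, n_per_group = c(control = 3, AD = 3),
                      duration_s = 20)
metrics <- compute_connectivity(sim$signals, cfg)
head(select(metrics, subject_id, condition, band, C, L, sw, reactivity))
#>   subject_id condition band      C     L    sw reactivity
#> 1 s001       EO        delta 0.413  2.22 1.46       0.149
#> 2 s001       EC        delta 0.391  2.49 1.08       0.149
#> 5 s001       EO        alpha 0.494  2.06 1.95      -0.206
#> 6 s001       EC        alpha 0.822  2.73 2.96      -0.206

fit <- fit_sw_mixed_model(inner_join(metrics, sim$subjects,
                                     by = "subject_id"), "alpha")
tidy(fit)
#>   term        estimate robust_se statistic
#> 1 (Intercept)   8.49      4.24        2.00
#> 2 disease       2.10      0.580       3.62
#> 3 condition    -2.71      0.973      -2.78
#> 4 age          -0.0783    0.0612     -1.28
```

The t of 10.64 for delayed recall says the two groups are separated by
about ten pooled standard errors on that memory index; the sex χ² of 0.008
says the sex split is essentially identical. In the synthetic study the
negative `condition` coefficient reflects the generator's stronger
eyes-closed alpha coupling (higher EC small-worldness), and per-subject
`reactivity` carries the same contrast. Six subjects is a smoke-test
scale: the coefficients are noisy, which is also why this toy fit flags a
spurious disease effect.

Model fits are `plisw_fit` objects with `tidy()`/`glance()` methods;
`autoplot()` draws connectivity heatmaps and coefficient plots, and
`plot_small_worldness()` summarizes a metrics table.

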