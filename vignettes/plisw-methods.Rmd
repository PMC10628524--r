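---
title: "Methods: PLI connectivity, small-world metrics, and the inference layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity, small-world metrics, and the inference layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plisw)
```

This vignette is the package's account of its own methods: the models it
fits, the numerical choices it makes, what the synthetic-data generator
does and does not emulate, and the known limitations of each stage.

## Signal stage

**Preprocessing.** `preprocess()` mirrors the common MEG chain:
polyphase resampling to a target rate (default 500 Hz), second-order
Butterworth band-stop notches at the power-line frequency and harmonics
(default 60/120/180 Hz, half-width 1 Hz), and a broadband Butterworth
band-pass (default 0.5–200 Hz). All filters are applied
forward-and-backward (`signal::filtfilt`), so the net phase response is
zero — essential, since everything downstream is a phase statistic.
Synthetic inputs are clean by construction, so no artifact rejection
(ICA, segment editing) is provided; with real data those steps belong
upstream of this package.

**Epoching and band filtering.** Recordings are segmented into
non-overlapping 5-s epochs (trailing remainder discarded) *before*
band-pass filtering, and each epoch is filtered per band with an order-4
zero-phase Butterworth design. The filter family and order are choices of
this implementation (the recipe this package follows names no design);
order 4 is the highest that remains numerically stable for the narrow
delta band (2–4 Hz) at 500 Hz under forward-backward application, and the
test suite verifies <5 % pass-band droop and <5 % stop-band leakage for
tones inside/outside each band.

**Phase and PLI.** Instantaneous phase is the argument of the analytic
signal, computed per channel by the frequency-domain Hilbert construction
(one-sided spectrum). The phase lag index of a channel pair over an epoch
is $|N^{-1}\sum_k \mathrm{sign}\,\Delta\phi(t_k)|$. Three conventions are
deliberate:

* **Absolute value.** The source formula for the PLI is sometimes printed
  without the $|\cdot|$, but its stated range $[0,1]$ requires it; the
  implementation applies it (Stam's definition).
* **Ties.** $\mathrm{sign}(0) = 0$: exact zero phase differences
  contribute nothing. For continuous phases this is a measure-zero event,
  but it makes the worked examples exact and deterministic.
* **Edge trimming.** The analytic signal distorts phases near the epoch
  boundary, so by default the outermost 5 % of samples at each end are
  excluded from the PLI sum (`edge_trim`, configurable; 0 gives the bare
  formula, used by the exact worked examples). The underlying recipe does
  not state whether transient samples were excluded; this default is this
  package's choice.

The sign is evaluated as $\mathrm{sign}(\sin\Delta\phi)$, which equals
the sign of the difference wrapped to $(-\pi, \pi]$ without an explicit
wrap, and makes the PLI exactly invariant to channel-wise amplitude
scaling (phases do not see amplitudes).

## Graph stage

**Binarization.** `binarize_proportional()` keeps the
$\lfloor \kappa\, n(n-1)/2 \rfloor$ strongest connections (default
$\kappa = 0.2$; on 68 nodes, exactly 455 edges of 2278 pairs). Flooring
means the retained proportion never exceeds the nominal κ. Ties at the
threshold weight are broken by weight (descending) then node-index pair
(ascending) — relevant in practice because short synthetic epochs produce
tied PLI values — and zero-weight pairs are never promoted, so κ = 1
yields the complete graph on nonzero-weight pairs.

**Metrics.** $C$ is the mean over nodes of the local clustering
coefficient, with $C_i = 0$ for nodes of degree < 2. $L$ averages
shortest-path lengths over all ordered pairs at finite distance;
disconnected pairs are excluded from numerator and denominator (for
symmetric graphs, ordered and unordered averaging coincide). Both are
validated against brute-force enumeration (explicit triple counting;
Floyd–Warshall) on a battery of small graphs, including disconnected
ones, to 1e-12.

**Null model.** Small-worldness normalizes $C$ and $L$ by ensemble means
over degree-preserving rewired graphs (Maslov–Sneppen double-edge swaps,
rejecting self-loops and duplicate edges). "1000 rewiring iterations" is
ambiguous across the literature — total swaps, or swaps per edge — so both
accountings exist: the default `per_edge` mode attempts
`iter_per_edge × m` swaps (default 10 per edge, so attempted swaps are at
least ten times the edge count), and a `total` compatibility mode accepts
exactly a fixed number of swaps (default 1000). The mode is recorded in
the ensemble's output. Null seeds are derived from the master seed and a
subject/band key — *not* the condition — so the EO and EC matrices of a
subject are normalized against identically-seeded ensembles and identical
inputs give exactly zero reactivity.

Calibration: on degree-matched Erdős–Rényi graphs (n = 68, density 0.2)
the ensemble-mean small-worldness is 1 within Monte-Carlo error
(acceptance tests use 20 seeds × 200 nulls); Watts–Strogatz graphs in the
small-world regime (n = 68, k ≈ 13, p = 0.1; odd k rounds down to an even
ring-lattice neighbourhood) score well above 1.

## Inference stage

**Mixed model.** `fit_sw_mixed_model()` fits, per band,
`sw ~ disease + condition + age + (1 | subject)` by maximum likelihood
(REML available as a switch; ML is the default so fixed-effect
comparisons are likelihood-based). Coding is control = 0/AD = 1 and
EC = 0/EO = 1, chosen so coefficient signs read in the clinical
direction. Standard errors are cluster-robust by subject: the sandwich is
assembled from the fitted marginal covariance
$\sigma^2 I + \tau^2 J$ per cluster (Sherman–Morrison inverse) with a
$G/(G-1)$ small-sample factor, and referenced against the normal
distribution (z statistics), matching the convention of the software this
layer emulates. No installed R package provides this estimator for
`lmer` fits, so it is implemented here and verified against model-based
SEs (agreement within 15 % for homoscedastic data at n ≥ 200) and against
pooled OLS when the random-intercept variance is zero. Singular fits
(zero between-subject variance) are not an error; they are flagged in the
result.

A caveat the package inherits from its method rather than its code:
cluster-robust z tests over-reject in small cluster counts. The null
calibration in the test suite runs at 200 subjects, where the measured
type-I error is at nominal level; at 100 subjects it measurably exceeds
0.07. At the 42-subject scale of a typical study the z-based robust test
should be read as approximate.

**Regressions.** `fit_recall_regression()` fits OLS of an outcome
(default `sw`) on delayed recall and age within one
group × condition × band slice; `fit_reactivity_regression()` does the
same for the per-subject reactivity. Robust (HC1) standard errors are the
default policy; `se = "auto"` switches to robust only when a
Breusch–Pagan test rejects homoscedasticity at 0.05 — an automated stand-in
for residual-plot inspection — and `se = "model"` gives classical errors.
Statistics are t with $n - 3$ degrees of freedom. Slices need more than 3
subjects; an all-constant outcome is flagged degenerate with zero slopes
rather than an error.

**Effect sizes.** The mixed family reports standardized coefficients
($\hat\beta \cdot sd(x)/sd(y)$); the regression families report partial
$\eta^2 = t^2/(t^2 + \mathrm{df})$. Both are labelled descriptive: the
reference analyses print effect-size columns without defining them, so no
equivalence is claimed and those columns are not reproduction targets.

**Significance policy.** Two tiers, applied strictly ($p < \alpha$):
0.05 for the mixed family, 0.025 for the regression and reactivity
families. The stricter level reflects correcting across the two disease
groups only; no correction is applied across frequency bands, on the
argument that band-wise small-worldness values are not independent.
Boundary values (p = 0.025 exactly) are not significant.

**Summary-statistic tests.** `two_sample_t_from_summary()` is the
pooled-variance Student t from printed means/SDs/sizes
(df = $n_1+n_2-2$); `chi_square_2x2()` is Pearson's χ² without continuity
correction. These reproduce demographic tables exactly from their printed
inputs; `example_cohort_summaries()` ships the summary table of the
motivating 42-participant cohort for the worked example. One printed
p value in that table (attention/concentration, p = 0.002 alongside
t = 4.03 at df = 40) is inconsistent with its own statistic; the package
reproduces the statistic and lets the p value follow from it.

## The synthetic-data generator

**Oscillators.** `generate_coupled_oscillators()` implements a
deliberately simple phase model rather than neural dynamics: channels are
grouped into coupling clusters (connected components of the coupling
matrix); each cluster shares a common band-limited phase process (random
centre frequency within the band, random-walk phase jitter, default
0.01 rad/sample); channel $i$ is
$w_i \cos(\phi_c(t) + o_i) + (1-w_i)\cos(\phi_i(t)) + \varepsilon$, with
$w_i$ the coupling strength, $o_i$ the deterministic per-channel offset
taken from the antisymmetric lag matrix, $\phi_i$ an independent
same-band process, and $\varepsilon$ white noise. This gives monotone,
controllable PLI: coupling 1 with a fixed nonzero lag yields PLI = 1;
coupling 0 yields chance-level PLI (empirically ≈ 0.01 at 5-s epochs in
the alpha band, far below the 0.15 bound the tests assert); zero lag with
full coupling yields PLI ≈ 0 — the field-spread-suppression property the
index is chosen for. Phase noise enters through the shared process,
before the deterministic lag, so the *sign* of each pairwise lag — the
quantity the PLI integrates — is preserved at any noise level.

What the generator does **not** emulate: 1/f background spectra, sensor
physics, volume conduction/leakage (beyond the zero-lag case),
non-stationarity, artifacts. Passing tests therefore demonstrate that the
pipeline measures what it claims on signals with known phase structure,
not that it is robust to everything real MEG contains.

**Study simulator.** `simulate_study()` composes per-band oscillator
sets into broadband recordings for a default cohort of 24 controls and 18
patients, two 120-s recordings (EO/EC) each at 500 Hz over 68 channels —
the scale of the motivating design. Band-wise coupling levels carry two
plausible contrasts: stronger alpha coupling with eyes closed (classic
alpha reactivity) and weaker gamma coupling in patients. These are
round-number emulation choices, not fitted to any dataset. Smoke tests
use 4 subjects × 10 s × 50 nulls, which exercises every code path in
about a minute.

**Subject tables.** `generate_subject_table()` draws covariates and
small-worldness values from an explicit linear model (group-specific age
and recall distributions; per-band disease, condition, age, and recall
effects; subject random intercepts; optionally heteroscedastic residuals
tied to the recall covariate, to exercise the robust-error path).
Covariates are centred at their population means, so the intercept is the
typical small-worldness scale (default 1.05). Default effect magnitudes
are typical published values for this literature: disease effects growing
negative with frequency (to −0.132 in gamma), age slopes near +0.01/year,
recall slopes near −0.01/point. One printed delta-band recall coefficient
in the reference table (−0.129) is inconsistent with its own standard
error and t statistic, which imply a value ten times smaller; the default
uses −0.013, on the scale of the other bands. Reactivity is derived from
the generated EO/EC values by default, or drawn from its own linear model
(`reactivity_model`) when a known reactivity slope is needed.

Because the default table includes nonzero recall slopes while the mixed
model (like the analysis it mirrors) omits recall, and recall is strongly
group-separated, the disease coefficient in a default table is confounded
by construction. Calibration and recovery simulations therefore set their
simulation truths explicitly (e.g. `beta_recall = 0` when the mixed model
is the estimand); this is a property of the models, not a bug in either.

## Problem sizes and reproducibility

Simulation scales used by the tests and the acceptance script, chosen as
the smallest sizes at which the checked properties are in their intended
regime: type-I calibration at 200 subjects (mixed) and 200-subject slices
(OLS) with 1000 replicates; coefficient recovery at 500 subjects with
100–200 replicates; null-model calibration with 200-null ensembles over
20 random graphs; end-to-end smoke at 4 subjects × 10 s × 50 nulls.

Every generator is a pure function of its spec's seed; pipeline stages
draw per-item seeds from the master seed via a documented rolling hash
(`stage_seed()`), so any stage can be re-run in isolation bit-identically.
Each output directory carries a JSON manifest (config snapshot, record
counts, package version).

## Known limitations

* Binary graphs at a single κ only — no weighted metrics, minimum
  spanning trees, efficiency measures, or per-node maps, and no κ sweep
  (run the pipeline at several κ values if needed).
* The pipeline begins at parcellated source time series; sensor-space
  processing, source reconstruction, and atlas mapping are out of scope.
* The robust z-based mixed-model test is approximate at small cluster
  counts (above).
* η² and standardized-coefficient columns are descriptive
  approximations, not reproductions of any published effect-size column.
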