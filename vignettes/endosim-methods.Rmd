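---
title: "Methods: models, simulator and synthetic data in endosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator and synthetic data in endosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosim)
```

# The model and its assumptions

`endosim` is built around a discrete-generation model of vertical
endosymbiont transmission through fungal spores. One propagation round
consists of plating spores, germination, mycelial growth, sporulation
and spore collection. Three probabilities parameterise a round:

| parameter | meaning | unit | default |
|-----------|---------|------|---------|
| `g`  | germination probability of a bacteria-positive spore | fraction | — |
| `e`  | germination probability of a bacteria-negative spore | fraction | 0.69 |
| `p0` | transmission fidelity: fraction of a positive germling's spores that are positive | fraction | — |

The default `e = 0.69` is the long-term average germination of negative
spores across the selection experiment this package models; `g` and
`p0` have no defaults because they are precisely the quantities that
change as the symbiosis adapts. Two operational thresholds complete the
parameter set: the wash-out threshold `t_prop = 1e-5` (with 100,000
spores plated per round, a positive fraction below 1/100,000 means no
positive spore is expected on the next plate) and the detection limit
`t_det = 1e-6` (one positive among the 1,000,000 spores analysed per
flow-cytometry measurement). Threshold comparisons are strict (`<`):
a fraction exactly at a threshold counts as not yet below it.

Under no selection, the positive fraction follows

$$p_x = \frac{p_{x-1}\,g\,p_0}{p_{x-1}\,g + (1-p_{x-1})\,e}.$$

The denominator is the germinating fraction of plated spores; the
numerator the germinating, transmitting fraction. The model assumes
(i) equal spore yield per germling regardless of colonization status —
the documented cost of carrying bacteria is in germination, not in
sporulation yield; (ii) a constant `p0` per round; and (iii) a
well-mixed population with no spatial structure.

Two analytic consequences are exposed because they answer the
experimental questions directly. The map is a Möbius transformation,
so trajectories are monotone and converge to a fixed point. Besides the
absorbing origin, an interior fixed point
$p^* = (g p_0 - e)/(g - e)$ exists in $(0,1]$ exactly when the
rare-symbiont decline factor $\lambda = g p_0 / e$ exceeds 1
(`decline_factor()`, `fixed_points()`). `washout_round()` exploits this:
it decides "persists" by comparing the trajectory's limit with the
threshold rather than by an arbitrary iteration cap, so it terminates
for every valid input. Degenerate corners are handled explicitly: a
zero denominator means no spore germinated at all — `transmission_step`
returns 0 with an `extinct` flag instead of raising, because
biologically there is no next generation; and `g = e` with `p0 = 1`
makes every fraction a fixed point (reported as a degenerate indicator),
except when `g = e = 0`, which is extinction.

One deliberate conflation is inherited from how such experiments are
analysed: the positive fraction measured at round 0 is used both as the
initial condition and as the transmission fidelity `p0`. The package
keeps `p_init` and `p0` as separate arguments that the caller may set
equal, so the conflation is explicit and overridable.

# The stochastic simulator

`run_passage_experiment()` is the finite-population counterpart:
binomial germination per spore class, per-spore Bernoulli transmission
at sporulation (collapsed to one binomial draw per round), and
hypergeometric sampling for FACS measurement and plating. Its
large-population expectation is exactly one application of the
recursion per round, which the test suite verifies empirically
(replicate means against `iterate_trajectory` within 5% wherever
$p \ge 10^{-3}$).

Numerical choices worth knowing:

* Pools reach $10^9$–$10^{10}$ spores (100,000 germlings at the default
  yield of 10,000 spores each), beyond R's integer range. Binomial
  draws above `.Machine$integer.max` use a Poisson approximation when
  the rare side's mean is below $10^4$ and a rounded-normal
  approximation otherwise, clamped to the valid range. At these sizes
  the approximation error is far below sampling noise.
* FACS sampling is hypergeometric, with a binomial shortcut when the
  pool is at least 100× the sample — the depletion correction is then
  below 1% of the sampling standard deviation.
* Sorting is perfectly pure by default (`sort_purity = 1`); gates in
  the modelled experiment were validated microscopically and no error
  rate is reported. Impure sorting is exposed for sensitivity analysis.
* The spore yield per germling `S = 10,000` is not reported in the
  experiment; it sets population sizes (hence drift), not expectations.
* Host adaptation (the observed rise of `g` and `p0` across rounds) has
  no mechanistic model in the source experiments; the simulator accepts
  a per-round parameter schedule instead of inventing one.
* An optional `load_effect` function makes positive-spore germination
  depend on per-spore bacterial load (lognormal per-spore loads); it is
  off by default because the deterministic model deliberately omits
  this mechanism.

R has one global random stream, so "explicit seeding" is realised the R
way: every top-level stochastic entry point (`run_passage_experiment`,
`generate_experiment`, `generate_spore_stack`, ...) takes a seed
argument and seeds once on entry; low-level operations consume the
current stream. Identical seed and configuration give byte-identical
outputs, which the tests assert.

# Inference

`estimate_proportion()` implements Wilson (default) and Clopper–Pearson
intervals from their closed forms; Wilson is the default because it has
near-nominal coverage at the extreme fractions this system produces
(down to $10^{-5}$). `estimate_transmission_params()` maps a round-0
measurement row onto the model: `g` from the positive germination arm,
`e` from the negative arm (falling back to the long-term average 0.69,
flagged, when that arm is absent), `p0` from the FACS positive
fraction. The germination denominator is spores sorted (one per well);
wells that received no spore are not modelled.

The coverage criterion for parameter recovery ("`(g, e, p0)` inside 95%
intervals in ≥ 90% of replicates") is read per parameter: three jointly
independent 95% intervals cover simultaneously only ~86% of the time,
so a joint reading would contradict the nominal level it invokes; each
parameter's own interval covers its truth in ≥ 90% of replicates.

`model_fit_error()` compares observed and predicted trajectories as an
RMSE of $\log_{10} p$, excluding censored rounds (zero positives
detected, reported as "< 1/n"). The significance tests are implemented
from their formulas — Welch's t with Welch–Satterthwaite degrees of
freedom, and the matched-pairs signed-rank test with an exact null
distribution up to n = 25 built by convolution over (doubled, to
handle mid-rank ties) ranks; zero differences are dropped, the standard
convention. R's `t.test`/`wilcox.test` and a literal $2^n$ enumeration
serve as independent oracles in the tests, never as the implementation.
The sweep filter keeps mutations absent from the ancestor whose
frequency reaches at least 50% (inclusive); no multiple-testing
correction is applied, matching how such experiments report p-values.

# Load imaging

Bacterial load is quantified as above-threshold voxel volume in a 3D
stack, `volume = n_voxels * prod(voxel_dims)`, with 26-connected
component labelling for the particle-size sanity check. The original
analysis chose its intensity threshold by visual inspection of the 3D
rendering; `otsu_threshold()` substitutes a reproducible default (the
caller can always override with an explicit threshold). Comparison is
strictly greater-than: a voxel at the threshold is background.
Anisotropic voxels are not resampled — the volume formula already
accounts for them. FACS-style gates are emulated as intensity terciles
(`classify_intensity_bins`), a deterministic stand-in for gates that
were drawn qualitatively; ties are broken by input order so the
assignment is stable.

Because this package's dependency set includes no TIFF reader, stacks
are serialised in a small plain-text format
(`write_voxel_stack`/`read_voxel_stack`: header plus one matrix block
per z-slice). Everything else about the voxel-stack contract is
format-independent.

# The synthetic-data generator as a stated world

`generate_experiment()` emulates the full selection-experiment design:
one injected germling's spore collection (true positive fraction `p0`,
default collection size $10^8$) measured by flow cytometry and split
into 10 lines of 300 sorted positive spores; per round and line, a FACS
measurement (up to 1,000,000 spores), germination plates (3 positive +
1 negative plate of 96 wells; 5 positive plates in round 1), positive
sorting, plating of 100,000 spores, germination and sporulation; after
round 7 the 7 weakest lines (by fitness index) are pooled into line
"LP" by equal numbers of positive spores. The truth manifest (seed and
parameters) is written separately from the data so analyses can run
blind.

Fixed choices, made once:

* **Delayed germination** (first seen on day 2): 0.20 for positive,
  0.05 for negative spores — positives germinate late several-fold more
  often, the qualitative pattern the germination assays show.
* **Per-spore load** is lognormal (median 2 µm³, σ = 0.6): a
  right-skewed positive quantity with no reported distribution;
  intensity is affine in load (baseline 100, 1000 units/µm³), which
  makes tercile gates monotone in true load.
* **Sweeps** are logistic in round number — the minimal standard form
  for a selective sweep — with a built-in example set of 9 sweeping and
  3 non-sweeping mutations observed at read depth 200.
* **Spore aging** enters only as an optional exponential decay of `g`
  (rate 0.09/day), calibrated so a month of storage takes germination
  from above 50% to below 5%; off by default.

What the generator does *not* emulate: flow-cytometer event-level data,
autofluorescence artefacts, sequencing reads, within-mycelium spatial
structure, or any mechanistic model of adaptation. A green end-to-end
test therefore establishes that the pipeline's statistics recover the
stated world's parameters — not that the stated world captures every
feature of real data.

A genuinely ancestral-like truth (g = 0.063, transmission near
$10^{-4}$) makes a 300-spore line infeasible: lines frequently go
extinct under sorting, which mirrors the real system's marginal
viability. The generator reports this as an explicit error rather than
silently resampling; tests of regime contrasts use feasible
parameterisations (g = 0.063/p0 = 0.05 vs g = 0.75/p0 = 0.5).

# Interface conventions

All fractions are stored in $[0,1]$; percent exists only at I/O, where
columns suffixed `_pct` are divided by 100 exactly once on read (a
column pair like `frequency` + `frequency_pct` is rejected as
ambiguous). Configurations are JSON (YAML accepted when available),
validated against per-command schemas that reject unknown keys — the
design constants (100,000; 1,000,000; $10^{-5}$; $10^{-6}$) are too
easy to transpose to tolerate silent typos. Every stochastic command
requires an explicit seed, and run manifests embed the seed, a SHA-256
config hash and the package version, so a run can be reproduced
byte-identically from its manifest.

# Known limitations

* The deterministic model cannot reproduce declines faster than
  $\lambda$ per round; the one mechanism that could (load-dependent
  germination) lives only in the simulator as an option, so
  faster-than-predicted wash-out remains outside the deterministic
  model by design.
* `washout_round`'s analytic termination relies on monotone
  convergence; within double precision, trajectories hovering at a
  fixed point numerically equal to the threshold resolve as "persists"
  (equality is "not below").
* The exact signed-rank path is $O(n \cdot \sum r)$ via convolution;
  beyond n = 25 the normal approximation with tie and continuity
  correction is used, as standard.
* Voxel quantification assumes the point-spread function does not merge
  distinct bacteria into one component; heavily blurred stacks
  undercount components (never volume, which is threshold-based).
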