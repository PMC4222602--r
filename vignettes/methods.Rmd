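---
title: "Models and methods behind hairwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hairwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hairwave` analyses periodic gene expression in hair-cycle time courses:
it detects periodic transcripts on a non-uniform, two-cycle time grid,
describes them as phase oscillators, fits a two-group coupled-oscillator
model to their collective dynamics, deconvolves the expression matrix into
an expanding and a static cell population, and screens for candidate
negative-feedback signals. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
design was genuinely open. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The data model and the merged time axis

The input is a probe-by-sample expression matrix with per-sample metadata:
a cycle label (`natural` or `induced`) and a collection day. Mouse dorsal
skin can be sampled through the second natural hair cycle, or through a
cycle induced by depilation; the two run through the same morphological
stages on different clocks. Following the morphology-based correspondence,
induced days 3, 5, 8, 12 and 17 are mapped onto natural postnatal days
24, 25, 27, 29 and 37 (`hair_time_map()`), and both cycles are pooled onto
one merged axis by `merge_cycles()`. After merging, samples are sorted by
merged day with natural before induced on ties, so downstream design
matrices are reproducible. Periodicity detection operates on log2 values;
the two-population mixture requires the linear scale and refuses log2
input rather than converting silently (`convert_scale()` is the only
conversion path).

## Periodic identification

**Model.** Each probe's log2 signal is represented by a truncated Fourier
series over pre-selected frequencies,
`x(t) = a0 + Σ_l [a_l cos(2π f_l t) + b_l sin(2π f_l t)]`,
fitted by iteratively reweighted least squares with Tukey's biweight
(tuning constant 4.685, scale 1.4826 × median absolute residual,
re-estimated each iteration; tolerance 1e-8, at most 100 iterations).
Robust fitting matters because single corrupted arrays should not fake or
destroy periodicity. When every weight is 1 the fit is ordinary least
squares; when the bulk of the data is fitted exactly, the residual scale
collapses and the current weights are kept (so genuine outliers stay
rejected).

**Frequency grid.** On a non-uniform grid the frequency choice is not
canonical. `build_frequency_grid()` takes harmonics `l/T` of a fundamental
`T = span × fundamental_factor` (default 1.05, placing the fundamental of
the bundled 30-day design at 31.5 days, about one hair cycle), drops
periods shorter than `max_freq_factor` (3) times the median sampling
interval — short periods near the sampling rate mask other frequencies in
the g-statistic — and caps the harmonic count at `(N − 2)/2` so the
regression stays overdetermined. With the default synthetic design this
gives L = 5 harmonics (31.5 to 6.3 days) for 19 samples.

**Scoring.** The power spectrum is `S(f_l) = (N/4)(a_l² + b_l²)`; the
constant is the classical periodogram normalization and cancels in
Fisher's g-statistic `g = max S / Σ S`, which is invariant to any positive
rescaling of the spectrum. Significance comes from permutations of the
signal across time points: with at least 10 null exceedances the estimator
is `(b + 1)/(n + 1)` (never exactly zero); otherwise permutations escalate
(doubling, up to `n_max`), and if exceedances remain scarce a generalized
Pareto distribution is fitted by maximum likelihood to the largest null
statistics (threshold placed to keep at least 100 exceedances) and the
GPD tail probability is returned. If the GPD fit fails, the empirical
estimator is used and flagged. Benjamini–Hochberg adjustment across all
probes at FDR 0.10 yields the periodic calls. Probes whose principal
periodic component (the dominant harmonic; ties resolve to the lowest
frequency) sits at the longest grid period are the low-frequency
oscillators (LFOs).

Two numerical choices deserve a note. First, the statistic used inside the
permutation loop caps the IRLS at 10 iterations with tolerance 1e-4 — a
permutation test is exact for *any* fixed statistic as long as observed
and null signals are treated identically, and this makes runs of a
thousand probes times hundreds of permutations affordable; the
coefficients users see always come from the fully converged fit. Second,
per-probe permutation streams are derived from the master seed and the
probe index, so results are independent of probe order and of any other
RNG activity.

**Power.** With 19 samples and an 11-column robust design, permuted
signals can concentrate spectral power by chance, so the null g
distribution is heavy and per-probe power is moderate; probes carrying
strong intracellular transients lose additional power because their heavy
marginal values inflate the permutation null. FDR control is unaffected
(it follows from exchangeability), and the realized false-discovery
proportion on labeled data is one of the package's acceptance checks.

## Phases, order parameters and the two clusters

For a Fourier series the Hilbert transform is closed-form (cosines map to
sines, sines to negative cosines), so the analytic signal
`z(t) = x(t) − a0 + i x_H(t)` and the instantaneous phase
`ψ = atan2(x_H, x − a0)` are available on any dense grid (default
0.25-day steps). The instantaneous frequency is computed from the exact
derivatives, `ω = (x ẋ_H − x_H ẋ)/(x² + x_H²)`, avoiding both finite
differencing and 2π-unwrapping. Either the full series (`"fsd"`) or the
principal component (`"ppc"`, the default) can serve as the phase source.

Complex order parameters `Z_m = ⟨e^{imψ}⟩` summarize the ensemble: `|Z_1|`
measures overall synchronization, `|Z_2|` detects two opposed clusters
that cancel in `Z_1`; per-cluster order parameters `z_c` satisfy the exact
identity `Z_1 = Σ_c (N_c/N) z_c`. Uniform random phase offsets
(`randomize_phases()`) provide the negative control, dropping both
magnitudes to the `1/√N` floor.

The LFO phase histogram is strongly bimodal, so clustering is done by the
deterministic largest-gaps rule: phase shifts are mapped to the circle and
cut at the two largest gaps of the circular ordering; no seed, no
iteration. Cluster 1 is the group whose mean maximum falls earlier on the
merged axis (the anagen-peaking group). A split is flagged ambiguous when
the second gap collapses relative to the first (below a fifth of it) or
the circular silhouette falls below 0.2 — for a unimodal cloud the empty
arc always dominates the gap ranking, so the second gap, not the first,
carries the bimodality evidence.

## The two-group coupled oscillator model

**Model.** The LFOs are treated as mean-field-coupled phase oscillators,
`dθ_j/dt = ω_j + K_{σ(j)} R sin(Θ − θ_j)`, where `R e^{iΘ}` is the
ensemble order parameter, `σ(j)` assigns each oscillator to the positively
(`K₊ > 0`, attracted to the mean field) or negatively (`K₋ < 0`, repelled)
coupled group, and the intrinsic frequencies `ω_j` are Lorentzian with
location `ω0` and half-width `γ`. For Lorentzian spread the Ott–Antonsen
ansatz reduces the dynamics exactly to the two group order parameters; in
the frame rotating at `ω0`,
`dz_σ/dt = −γ z_σ + (K_σ/2)(W − W̄ z_σ²)`, `W = p z₊ + (1 − p) z₋`,
with `p` the positively coupled fraction. `ω0` is set to `2π` over the
longest grid period.

**Parameter solving.** At the observed quasi-steady, out-of-phase state
the group order parameters can be placed on the real axis
(`z₊ = r₊`, `z₋ = −r₋`) and the time derivatives set to zero, giving two
real equations: `γ r₊ = (K₊/2) W (1 − r₊²)` and
`γ r₋ = (|K₋|/2) W (1 − r₋²)` with `W = p r₊ − (1 − p) r₋`. The package
treats the two coupling strengths as independent: the fixed point is
invariant to a joint rescaling of `(K₊, K₋, γ)`, so only relative
strengths are identifiable and `K₊ = 1` rad/day is adopted as the scale
convention; then the first equation gives `γ` exactly and the second gives
`K₋` exactly, for any observed radii. This choice was made after
establishing numerically that with the magnitudes forced equal
(`K₋ = −K₊`) the reduced system has no traveling-wave attractor at any
`p`, which would erase one of the three states the bifurcation analysis
is meant to exhibit; with independent magnitudes the traveling wave
appears precisely when the negatively coupled group is the less
synchronized one (`r₋ < r₊`).

A configuration is *realizable* iff the implied `γ` is positive. Assigning
the smaller cluster to positive coupling makes the mean field `W`
negative and hence `γ < 0` — which is how that configuration is rejected
on sign grounds alone. The surviving configuration is additionally checked
dynamically: the reduced model is integrated from a slightly perturbed
fixed point (perturbation 1e-3) and declared stable if radii and the 180°
separation return within tolerance; the check window scales with `12/γ`
because the relaxation time diverges as `γ → 0`.

**Bifurcation scan.** Holding `(K₊, K₋, γ)` fixed and varying `p`,
`bifurcation_diagram()` integrates from a small deterministic start and
classifies the long-time attractor on the final quarter of the window:
*incoherent* if both radii stay below 0.01; *π-state* if both groups are
synchronized (radii above 0.1), locked 180° ± 0.1 rad apart, and the mean
field is stationary in the rotating frame (drift below 1e-3 rad/day);
*traveling wave* if the pattern drifts persistently — the system period
`2π/(ω0 + Ω)` then shortens below the intrinsic `2π/ω0`. Non-stationary
radii are labeled `unresolved`, never silently binned. The default horizon
is 400 days (classification always uses the final quarter) and should
be raised to a few thousand days for scans near state boundaries, where
transients are slow; incoherence classification uses the group radii
rather than `|Z_1|` because a symmetric π-state at `p = 1/2` also has
`|Z_1| = 0`.

The full `N`-oscillator system (`simulate_full()`, default `N = 1000`,
adaptive Runge–Kutta 4/5 like the reduced model but with tolerances 1e-6
/1e-8 — attractor structure, not 8-digit trajectories, is the target at
this dimension) validates the reduction: its steady `|Z_1|` fluctuates
around the reduced value within finite-size scatter, which the acceptance
suite quantifies with a 100-seed one-standard-deviation envelope.

## Two-population deconvolution

**Model.** On the linear scale, each mixed sample is
`x_ij = f_i y1_j + (1 − f_i) y2_j`: an expanding population (fraction
`f_i`, static intracellular expression `y1_j`) against a static background
(`y2_j`). Fitting alternates two exact least-squares solves: per gene, a
two-parameter regression on `[f, 1 − f]` given `f`; per sample, the scalar
closed form `f = Σ_j (y1−y2)(x−y2)/Σ_j (y1−y2)²` clipped to `[0, 1]`
(the constrained scalar problem is convex, so clipping is exact). The
total squared error is therefore non-increasing. Initial `f` is a linear
ramp from 0 to 1 over samples in merged-day order; convergence is
`max|Δf| < 1e-6` (at most 500 iterations; non-convergence is reported,
not fatal). No nonnegativity is imposed on the `y`'s; negative estimates
are flagged in the output.

**Identifiability.** The mixture determines `f` only up to an affine
reparameterization — `(f, y1, y2) → ((f−m)/(M−m), M y1 + (1−M) y2,
m y1 + (1−m) y2)` leaves every fitted value unchanged. The `[0, 1]`
constraint pins this gauge only through a nearly flat objective valley, so
after convergence the estimate is normalized explicitly to the canonical
gauge in which `f` spans `[0, 1]`. The synthetic generator reports its
ground truth in the same gauge, which is what makes parameter-recovery
statements well-posed. Population 1 (expanding) is identified after
convergence as the orientation whose trajectory ends low — the expanding
population empties in catagen and telogen.

**Inference.** Standard errors come from the unbiased residual variance
and the design's inverse Gram matrix; `t = (y1 − y2)/se_diff` with
`n − 2` degrees of freedom tests differential expression between the
populations, with BH q-values across genes. LFO probes passing FDR 0.10
are assigned to the population where they are higher expressed. A
per-gene coefficient of determination (COD) measures how much of the
expression variance the static model explains. The negative control
shuffles each probe's time course within each cycle (cycles are never
intermixed) and refits identically; on shuffled data the fraction
trajectory loses its anagen/catagen structure and LFOs lose their COD
advantage.

## The negative-feedback screen

If the background population is static in size, inhibitory signaling from
it toward the expanding population should appear as *intracellular*
changes: genes in the background-associated LFO cluster whose expression
rises above the static-model prediction near catagen onset. The screen
selects probes that (a) belong to LFO cluster 2, (b) have COD below
`cod_max`, and (c) exceed the model prediction (observed/fitted ratio
above `ratio_min`, default 1) at every sample falling 14–16 days after
cycle initiation (natural cycle: merged day minus 23; induced cycle: days
after depilation). "Poorly described" is necessarily relative to the
noise level of the data: on the bundled low-noise synthetic conditions
static probes reach COD ≈ 0.95, so the default ceiling is 0.8 — between
the static population and probes carrying a genuine intracellular
signature; on noisier data a ceiling near 0.5 is the natural choice. Both
thresholds and the window are exposed.

## Enrichment utilities

Set enrichment is the exact hypergeometric upper tail
`P(X ≥ k)` for the overlap `k` of a target with a signature inside a
declared background (default in the pipeline: all probes on the matrix;
the choice of background materially affects p-values and is always
echoed). The Normalized Google Distance is computed from supplied
occurrence tables — no live querying — as
`NGD = (max(log f_x, log f_y) − log f_xy)/(log N − min(log f_x, log f_y))`;
the formula is a ratio of log differences and hence independent of the
logarithm base. If two terms are independent, `f_xy = f_x f_y / N` in
expectation and NGD = 1 exactly, which is why 1.0 is the screening
threshold (strict); terms that never co-occur get NGD = ∞.

## The synthetic generator: what it emulates and what it does not

`simulate_dataset()` generates the structure the analysis assumes: the
merged two-cycle design (natural days 23–53, induced days 3–17 mapped via
the published correspondence); an expanding-population trajectory that
rises logistically from day 23, plateaus through anagen, and collapses to
exactly zero over the last three days before day 42 (sharp, complete
catagen depletion), with peak fraction 0.85; cluster-1 probes high in the
expanding population and cluster-2 probes high in the background
(12-fold separation, log-normal levels around log2 = 8), so both observed
profiles are reciprocal consequences of the same population wave;
non-periodic probes equal in both populations; multiplicative log-normal
noise (0.15 log2 units, a typical replicate-level microarray scatter);
per-probe phase jitter of 0.5 days implemented as a time shift of the
trajectory; and feedback probes — background-type genes at modest
abundance whose background expression rises three-fold in a sigmoid step
centered 15 days after initiation and stays elevated, deliberately
violating the static-expression assumption. The cluster-size asymmetry
(120 vs 200) keeps the smaller cluster the anagen-peaking one.

Deliberate idealizations: no probe-level microarray physics (PM/MM,
saturation), no batch effects between the two cycles, no circadian or
other fast oscillators, Gaussian log-scale noise rather than heavy-tailed
contamination, and a single shared population trajectory for both cycles.
Passing tests on these conditions therefore demonstrates the pipeline's
internal correctness and calibration, not its robustness to artifacts
real microarray data may contain. The natural-day grid is a synthetic
default, not the design of any particular public dataset; it spans a full
cycle (through telogen) because a window covering only two-thirds of a
period genuinely shifts the dominant Fourier component of a mid-window
pulse to the second harmonic, which would misrepresent what the analysis
sees on a full cycle.

Problem sizes used by the tests and the acceptance script — 482-probe
simulations, 1000-probe labeled benchmarks with 500 permutations over 3
seeds, 100-seed full-model envelopes at N = 1000, 20-seed recovery runs —
were chosen as the smallest designs at which the Monte-Carlo error of each
checked quantity is comfortably below its tolerance.

## Known limitations

* Per-probe detection power is modest at 19 samples with an 11-column
  robust design, and heavy intracellular transients reduce it further by
  inflating the permutation null; the package controls the FDR, it does
  not maximize sensitivity.
* The GPD tail can return extremely small p-values when the fitted shape
  implies a bounded null support; these are floored at the smallest
  positive double and are only meaningful as "far beyond the permutation
  resolution".
* The coupled model is phenomenological: couplings are mean-field
  averages, oscillators are probes (not genes or cells), and only
  relative coupling strengths are identifiable (the `K₊ = 1` convention).
* The mixture model assumes exactly two populations with static
  intracellular expression; everything else lands in residuals and COD.
  Its fraction trajectory is identifiable only up to an affine map, and is
  reported in the canonical `[0, 1]` gauge.
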