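# hairwave

Periodic expression, coupled oscillators and two-population deconvolution
for the mouse hair cycle.

Mouse dorsal hair follicles cycle through growth (anagen), regression
(catagen) and rest (telogen) on a roughly monthly clock, and whole-skin
expression time courses carry that rhythm in thousands of transcripts.
`hairwave` is an R package for analysing such time courses end to end:

1. **Periodic identification.** Each probe's signal on the merged,
   non-uniform two-cycle time grid is fitted with a robust Fourier series
   (Tukey-biweight M-estimation over pre-selected frequencies
   `x(t) = a0 + Σ_l a_l cos(2π f_l t) + b_l sin(2π f_l t)`), scored with
   Fisher's g-statistic `g = max_l S(f_l) / Σ_l S(f_l)`, and assigned a
   permutation p-value whose far tail is refined with a generalized Pareto
   fit. Benjamini–Hochberg control at FDR 0.10 yields the periodic calls;
   probes whose principal periodic component (PPC) sits at the longest
   admissible period (~31 days) are the low-frequency oscillators (LFOs).
2. **Oscillator characterization.** The analytic signal of each fit (the
   Fourier series' closed-form Hilbert pair) gives instantaneous phases;
   complex order parameters `Z_m = ⟨e^{i m ψ}⟩` quantify synchronization
   (`|Z_1|`) and two-cluster structure (`|Z_2|`). Phase shifts split the
   LFOs into two clusters almost exactly 180° apart: an anagen-peaking and
   a telogen-peaking group.
3. **Coupled oscillator model.** The two clusters are modeled as
   positively and negatively coupled groups of a mean-field Kuramoto
   system, `dθ_j/dt = ω_j + K_{σ(j)} R sin(Θ − θ_j)`, with
   Lorentzian-spread intrinsic frequencies. Its exact Ott–Antonsen
   reduction is used to solve the quasi-steady state for the coupling
   parameters, test which cluster-to-sign assignment is physically
   realizable and dynamically stable, and scan the bifurcation structure
   over the positively coupled fraction `p` (incoherent state, traveling
   wave, π-state).
4. **In-silico microdissection.** The linear-scale expression matrix is
   deconvolved under `x_ij = f_i y1_j + (1 − f_i) y2_j` into a transiently
   expanding population (fraction `f_i` per sample) and a static
   background, by alternating exact least squares with `f` constrained to
   `[0, 1]`. Per-gene t-statistics assign LFOs to the population where
   they are higher expressed; a coefficient of determination flags genes
   the static model cannot describe.
5. **Negative-feedback screen.** Candidate inhibitory signals are
   background-cluster LFOs that are poorly described by the static model
   and rise above its prediction 14–16 days after cycle initiation, near
   catagen onset.
6. **Enrichment utilities.** Exact hypergeometric set enrichment, and the
   Normalized Google Distance
   `NGD = (max(log f_x, log f_y) − log f_xy) / (log N − min(log f_x, log f_y))`
   computed from supplied occurrence tables (NGD = 1 marks statistically
   independent terms).

A seeded synthetic-data generator (`simulate_dataset()`) reproduces the
statistical structure all of this assumes — the merged natural/induced
time grid, two out-of-phase mixture-driven clusters, noise probes and
feedback probes — so the whole pipeline is testable without any downloads.

## Worked example

```r
library(hairwave)

sim  <- simulate_dataset(sim_config(seed = 4))
ds   <- merge_cycles(sim$dataset)
scan <- periodic_scan(ds, n_perm = 300, n_max = 300, seed = 11)
scan
#> <periodic_scan> 482 probes, FDR 0.1: 339 periodic, 330 LFO (period 31.5 d)

ens <- oscillator_ensemble(scan)
cl  <- cluster_by_phase(ens$shift_days, ens$period, t_ref = ens$t_ref)
cl
#> <phase_clusters> sizes 120/210, mean maxima at days 32.7 / 49.1,
#>   separation 15.1 d (173 deg)

radii <- sapply(1:2, function(k)
  mean(Mod(order_parameter(ens$phase[cl$labels == k, , drop = FALSE]))))
model <- fit_coupled_model(radii[1], radii[2],
                           n_cluster1 = sum(cl$labels == 1),
                           n_cluster2 = sum(cl$labels == 2),
                           omega0 = 2 * pi / ens$period)
model
#> <coupled_fit> two-group mean-field oscillator model
#>   config1 (cluster2 positively coupled, p = 0.636): K+ = 1, K- = -1.05,
#>     gamma = 0.001579  [realizable, stable]
#>   config2 (cluster1 positively coupled, p = 0.364): K+ = 1, K- = -0.95,
#>     gamma = -0.0015  [unrealizable (gamma < 0)]
#>   verdict: config1 stable (cluster 1, the smaller group, negatively coupled)

mix <- fit_mixture(ds)
mix
#> <mixture_fit> 482 genes x 19 samples: converged after 64 iterations
#>   expanding fraction: range 0.000-1.000, final 0.000
#>   median COD 0.935; 0 genes with negative y flagged
```

Reading the output: about 70% of the probes are called periodic at the
31.5-day grid period; their phases fall into two clusters whose maxima sit
half a cycle apart (anagen ~day 33 vs telogen ~day 49). Fitting the
two-group oscillator model to the observed cluster order parameters shows
that only one coupling assignment is physically possible — the smaller,
anagen-peaking cluster must be the negatively coupled (repelled) group;
the reverse assignment implies a negative frequency spread. The mixture
fit recovers an expanding-population trajectory that rises through anagen
and collapses to zero in catagen, and explains most LFO variance
(median COD 0.93) while leaving the implanted feedback probes poorly
described — those are picked up by `feedback_candidates()`.

The one-call orchestration of all stages is `run_pipeline()`, which also
writes per-stage TSVs and a JSON run report.

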