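---
title: "Modeling the fitness cost of platinum resistance: methods and design choices"
author: "costar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the fitness cost of platinum resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costar)
```

# Scope

`costar` implements the quantitative core of an adaptive-therapy study in
high-grade serous ovarian cancer (HGSC) model systems: platinum-resistant
cells carry a proliferative fitness cost under resource limitation, drug
holidays let the fitter sensitive population competitively suppress the
resistant one, and the expansion of a resistant subclone can be tracked in
longitudinal copy-number profiles. The package provides four connected
analysis layers — competition growth modeling, fitness-gap estimation,
an in-silico dosing trial, and subclonal copy-number deconvolution — plus
a synthetic-data layer that generates every input shape with known ground
truth, so that each estimator can be validated end to end without any
external download.

# Growth and competition model

Monoculture growth is logistic. We parameterise the intrinsic rate in
**doublings/day** (`g`), the unit in which fitness differences are
reported, so the exponential rate is `ln(2)·g`:

$$N(t) = \frac{K}{1 + \left(\frac{K - N_0}{N_0}\right)e^{-\ln 2\, g t}}.$$

Cocultures of sensitive (S) and resistant (R) cells use the standard
two-species Lotka–Volterra competition form,

$$\frac{dS}{dt} = \ln 2\, g_s S\!\left(1 - \frac{S + \alpha_{sr}R}{K_s}\right),
\qquad
\frac{dR}{dt} = \ln 2\, g_r R\!\left(1 - \frac{R + \alpha_{rs}S}{K_r}\right),$$

the minimal model consistent with two populations competing for a shared
resource under a carrying capacity. The source experiments name no
explicit competition equations, so this choice is ours; the simulation
presets default to the fully shared-resource regime `α = 1`, and both
coefficients are free parameters of `competition_model()`. Whether a
coculture behaves as one shared capacity or two partially separate ones is
expressible through `(α, K_s, K_r)` and is recorded per run in the model
object. `simulate_competition()` integrates the system with `deSolve`'s
`lsoda` (`rtol 1e-10`); with `α = 0` it agrees with the closed form to
better than `1e-6` relative error over 60 days, which the test suite
asserts.

`fit_monoculture()` estimates `(g, K, N_0)` by nonlinear least squares on
**log counts** (count noise is multiplicative, see below), with parameters
on the log scale to enforce positivity and delta-method standard errors.
Starting values come from the early log2-slope and the maximum count; if
the optimiser fails, five Latin-hypercube restarts around those heuristics
are tried before giving up. Constant series are flagged
`growth_rate unidentifiable` rather than fitted; series that never
approach a plateau keep their rate estimate but flag
`carrying_capacity unidentifiable`.

# Fitness-gap estimation

During exponential coexistence,
$$\log_2 \frac{S(t)}{R(t)} = \log_2\frac{S_0}{R_0} + (g_s - g_r)\,t,$$
so the slope of the log2 ratio series is directly the fitness gap
`g = gs − gr` in doublings/day. This identity is why the package works in
log base 2: a slope of 0.08 means the sensitive population gains 0.08
doublings per day on the resistant one. Natural-log input can be converted
by the user; the convention is stated in the fit object.

`fit_reference_slope()` fits the series from the *lowest sensitive seeding
ratio* by OLS, replicates entering as independent points (a
replicate-cluster bootstrap SE is reported alongside the OLS SE).
`align_and_pool()` then shifts every other seeding ratio in time so that
its first observed point falls exactly on the reference line —
`offset = (y₁ − b)/g − t₁` — and refits one pooled line. The first-point
rule is deliberate (a least-squares time shift is available only as a
diagnostic): under exponential growth the slope is seeding-invariant, so
the offsets simply recover the staggering of compositions, and pooled and
per-ratio slopes agree within statistical error. A zero reference slope
makes the offset undefined; the function falls back to intercept-only
alignment with a warning.

Two caveats are built into the design. Zero counts are dropped with a
warning rather than pseudocounted (a `pseudocount` argument exists for
users who prefer otherwise). And the slope equals `gs − gr` only while
both populations grow exponentially: once the total approaches capacity
the ratio dynamics reflect the capacity difference instead, so the demo
pipeline clips the ratio fit to a pre-saturation window
(`ratio_fit_max_day`, default 12 days under the default growth settings).

# Drug effect and the in-silico trial

A dose `D` administered at time `t₀` applies to sensitive cells the kill
rate

$$k(D, \tau) = k_{\max}\,\frac{D}{D + EC_{50}}\;K(\tau),$$

where `τ` is time since the dose and `K` is a gamma-density kernel
(shape `lag_shape`, mean `lag_mean_eff`) normalised to peak at 1 and
truncated at `effect_duration`. Peak-normalisation keeps the Emax
interpretation exact: at `D = EC₅₀` the peak kill rate is `k_max/2`.
Resistant cells receive the same rate multiplied by
`resistance_factor ∈ [0, 1]`. The delayed kernel encodes the observed
behaviour that the sensitive proportion of a treated coculture declines
only several days after exposure; the effective delay mean contracts with
dose, `lag_mean_eff = lag_mean·(1 − s·D/(D+EC₅₀))` with `s =
lag_dose_shift`, so that higher doses act earlier as well as harder. With
the in-vitro defaults (`k_max = 1.2`/day, `EC₅₀ = 0.2` µmol/L, `lag_mean =
7` d, shape 6, duration 13 d, shift 0.5) the simulated
sensitive-fraction nadir falls 8–10 days after a day-6 pulse across doses
0.1–1.0 µmol/L, inside the experimentally reported 5–12-day window,
arriving earlier and deeper as dose increases.

The trial engine compares three protocols on two-flank tumors measured in
mm³ (`volume = π·short²·long/6` for caliper data; simulated volumes map to
cells at `1e4 cells/mm³`, a constant that only sets the scale):

* **vehicle** — saline every 4 days × 3;
* **ST** — 60 mg/kg carboplatin every 4 days × 3 (cumulative dose is
  therefore exactly 180 mg/kg by construction);
* **AT** — 60 mg/kg once, then weekly dose modulation by the fractional
  change of the **target** tumor volume since the last administered dose,
  through an ordered band table. The published band table exists only as a
  figure image, so the default here is an explicit reconstruction
  constrained by the printed facts (initial 60 mg/kg, weekly interval,
  doses reaching < 3 mg/kg or omission): growth ≥ +10% → ×1.5 capped at
  60 mg/kg; change within ±10% → ×1; shrinkage ≥ 10% → ×0.5; nominal doses
  below 1 mg/kg are omitted while remaining on the books, so dosing can
  resume if the tumor regrows. Nontarget volumes are never consulted — a
  property asserted by a construction test with discordant flanks.

Mice enroll when the target flank reaches 300 mm³ and exit when either
flank reaches the humane endpoint, read as **1440 mm³** (the published
"1.44 cm²" is dimensionally inconsistent with a volume formula; the
cross-sectional-area reading is available via `endpoint_area = TRUE`), or
at 20 weeks. In-vivo stochasticity enters only through lognormal
initial-size jitter per flank and a lognormal growth-rate multiplier per
mouse. Within one injected-ratio cohort the same simulated mice are reused
across protocol arms — matched comparisons reduce variance at these small
group sizes and make the no-drug-effect null (`resistance_factor → 0` on a
fully resistant tumor) coincide with vehicle exactly. Survival summaries
use the product-limit estimator and the Mantel–Cox log-rank test from the
`survival` package behind `kaplan_meier_logrank()`; the test suite checks
the statistic against an independent risk-table computation. Medians are
reported as undefined when the survival curve never crosses 0.5, as
happens in durably controlled AT arms. The survival clock can start at
injection or at treatment initiation.

# Subclone tracking from segment-level copy number

Inputs are BED-like segment tables (0-based half-open) per sample plus a
manifest (`sample_id`, `day`, `purity`, `marker_value`). Purity `ρ` is
accepted as given — upstream tools estimate it — and observed copy number
is corrected by inverting the diploid-contamination model
`CN_obs = ρ·CN_tumor + 2(1−ρ)`.

With an emergent subclone at frequency `r_t` carrying private integer
alterations `Δ_seg`, the purity-corrected shift from the diagnostic
(earliest) sample obeys `shift[t, seg] = r_t · Δ_seg`.
`call_resistance_segments()` selects segments whose final shift is large
and whose trajectory is monotone toward it; clonally shared segments
(no shift) and transient "other CNA" decoys fail these filters. The
configured thresholds (0.1 CN and 0.05 CN) act as floors: the working
values adapt to the data's noise scale (3× and 2× robust MAD of the
null-dominated shift columns), because fixed thresholds break down at low
purity where corrected noise is inflated by `1/ρ`.

`estimate_subclone_ratio()` solves the bilinear integer problem by
alternating least squares: given `r`, each `Δ_seg` is the nonzero rounded
regression coefficient (clamped to ±3 — larger subclonal shifts are not
biologically plausible at these frequencies); given `Δ`, each `r_t` is the
least-squares ratio clipped to `[0, 1]`. Several design choices deserve
explanation:

* **Multi-start.** The sign-of-final-shift initialisation can be a local
  fixed point (true `Δ = (+1, −2)` is unreachable from `(+1, −1)`), so the
  solver also starts from integer scalings of the final-shift vector.
* **Scale selection by parsimony band.** The model is scale-degenerate
  (`2Δ, r/2` fits identically), and with noise the *finer* scalings are
  systematically favoured by raw SSE because a denser integer lattice can
  chase noise. Among converged candidates whose SSE is within 50% of the
  best, the solver therefore prefers minimal `Σ|Δ|`, excluding candidates
  that clip `r` at 1 (a scale artefact). Exact degeneracies are reduced by
  gcd. On noiseless instances with ≤ 3 segments this reproduces the global
  optimum of an exhaustive search over `Δ ∈ {−3..3}^S`, which the test
  suite verifies.
* **Expand-and-refit.** Calling on the final shift alone misses
  low-amplitude (`|Δ| = 1`) resistance segments at low purity, biasing the
  ratio. After the initial fit, segments anywhere in the genome whose full
  trajectory is consistent with an integer multiple of the fitted `r` are
  re-admitted and the model refit once.
* **Two-sample warning.** With only one shift per segment, subclonal
  expansion cannot be distinguished from pervasive copy-number
  instability; the estimate is returned with an explicit reliability
  warning and no correction is attempted.

Confidence intervals repeat the estimation 150 times on random segment
subsamples of 75% of the called set and take 2.5–97.5 percentiles. The
subsamples are drawn **with replacement** (an m-out-of-n bootstrap):
drawing without replacement shrinks the replicate spread to roughly
`(1 − 0.75)` of the estimator's sampling variance and produced ~70%
empirical coverage in calibration runs, versus ~92–94% with replacement.
Replicates keep the full fit's `Δ` scale fixed, so the interval is
conditional on the called model; on noiseless data it collapses to zero
width. Fewer than four called segments raise an `unstable_ci` flag.

`subclone_growth_rate()` reports `(r_{t₂} − r_{t₁})/(t₂ − t₁)` per
consecutive pair of samples by default; comparison against the diagnostic
sample is available via `method = "baseline"` because the two definitions
are both used in the source material and they disagree for ≥ 3 samples.
`correlate_burden()` pools per-interval rates across patients against the
burden marker (CA125-like) at the later end of each interval and reports
Pearson R, R², and the two-sided p.

# The synthetic-data layer

Generators emulate the study designs, not the instruments:

* **Counts** carry multiplicative lognormal noise with median 1 and a
  configurable CV (default 0.05). Cell-count error is scale-proportional,
  and median-1 (rather than mean-1) noise keeps log-scale fits unbiased.
  The source experiments report no noise magnitudes; these defaults were
  chosen once as realistic for automated counting and are surfaced in
  `sim_config()`.
* **Copy-number segments** start from an HGSC-like clonal distribution
  over 1–6 (modal 2–3), with resistant segments given nonzero integer
  deltas in {−2, −1, 1, 2} and a configurable fraction of decoy segments
  given non-monotone perturbations. Observed values follow the
  purity-mixture equation plus Gaussian noise (`cn_noise_sd`, default
  0.05). The default segment count (500) stands in for bin-level
  resolution; segments are the atomic unit throughout.
* **Mouse cohorts** apply lognormal initial-volume jitter (CV 0.3) and
  per-mouse growth-rate heterogeneity (CV 0.2); enrollment day is the
  first day the target flank exceeds 300 mm³ under untreated growth.
* All randomness flows from a single `sim_config()` seed through derived
  sub-seeds recorded in each dataset's `ground_truth` attribute; identical
  configurations give byte-identical outputs.

What the generators deliberately do *not* model: sequencing reads,
flow-cytometry event files, images, pharmacokinetics, toxicity, spatial
structure, or frequency-dependent (game-theoretic) fitness. Passing tests
therefore demonstrate that the estimators invert the stated generative
models at realistic noise, purity and sample sizes — not that those models
capture every feature of real tumors. In particular, real cfDNA series
have sample-specific segmentation error and purity misestimation that the
harmonised-segmentation, known-purity setting here does not probe.

# Numerical choices and problem sizes

Integration uses `lsoda` at `rtol 1e-10` for analysis-grade runs and
`1e-7` inside the trial engine, where daily endpoint checks dominate the
error budget. The logistic fit caps Levenberg–Marquardt at 200 iterations
per start. The ALS mixture solver caps alternation at 100 iterations per
start and treats SSE ties within `1e-12` as exact. Validation suites run
at deliberately moderate sizes chosen to keep the full check fast on one
CPU — e.g. 200 seeded replicates for growth-parameter recovery, 30 for
subclone recovery, 200 outer replicates for bootstrap coverage, 10 seeded
trials for the AT-vs-ST ordering — with thresholds stated in the tests
themselves.

# Known limitations

* The AT band table is a reconstruction; conclusions about exact dose
  sequences depend on it, though the qualitative de-escalation behaviour
  (doses < 3 mg/kg, omissions, durable control) is robust across sensible
  bands.
* The fitness-gap estimator assumes a constant gap (linear log-ratio);
  frequency-dependent fitness is out of scope.
* The subclone model assumes one emergent subclone with fixed integer
  deltas and harmonised segmentation; multiple contemporaneous subclones
  alias into one effective trajectory.
* At purities near 0.3 with 20 informative segments, the ±0.05 absolute
  recovery target sits close to the information-theoretic noise floor;
  estimates there should lean on the bootstrap interval, not the point
  value.
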