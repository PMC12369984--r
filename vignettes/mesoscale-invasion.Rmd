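---
title: "Models and methods: mesoscale dynamics of spheroid invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mesoscale dynamics of spheroid invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoinvasion)
```

This vignette documents the models implemented in `mesoinvasion`, the
assumptions behind them, the tunable parameters and their defaults, and the
numerical and design choices made where more than one reasonable option
existed. Time is in hours and distance in micrometers everywhere in the API;
unit conversions happen only at I/O boundaries (the run config stores the
frame interval in minutes, as imaging protocols quote it).

## The switching model

Disseminated cells carry one of four migration phenotypes — blebbing (BB),
actin-enriched pseudopodial (AE), lamellipodial (LA), filopodial (FP) — and
switch between them as a continuous-time Markov chain with rate matrix
$r_{X \to Y}$ (h$^{-1}$). The generator $Q$ has off-diagonal entries
$r_{X \to Y}$ and diagonal $-\sum_Y r_{X \to Y}$; the stationary composition
solves $\pi Q = 0$, $\sum \pi = 1$ (`stationary_distribution()`, a direct
linear solve with an explicit irreducibility check that names unreachable
states).

Tracking studies of this system report population facts rather than a full
matrix: BB holds about 1/3 of the population, AE about 1/6, and cells switch
about once every 2 h. `calibrate_default_rates()` builds the simplest matrix
consistent with those facts: $r_{X \to Y} = k\,\pi_Y$, with
$k = (1/\tau)\,/\,(1 - \sum_X \pi_X^2)$ so that the population-averaged total
transition rate $\sum_X \pi_X \sum_{Y \ne X} r_{X \to Y}$ equals $1/\tau$.
The LA/FP split of the remaining third is not pinned down by the stated
facts; the default splits it evenly (1/4 each) and the composition is a
config parameter, so a measured matrix can be substituted via the 4×4
interchange format whenever one is available.

An "INTERMEDIATE" label may appear in observation tables (about 6% of frames
in practice, when a cell's morphology cannot be assigned). It is treated
purely as an observation label: the chain has exactly four states, and all
estimators drop INTERMEDIATE frames (and the frame pairs touching them).

## Boundary suppression of the filopodial state

The nonequilibrium ingredient is a space–time rule (`modulation_schedule()`):
for cells within 50 µm of the spheroid boundary, every rate *into* FP is
multiplied by a ramp that is 1 up to $t_\mathrm{start} = 8$ h and then falls
as $(24 - t)/18$, clipped at 0 — so the FP in-rates vanish from $t = 24$ h
onward in the zone. Two deliberate conventions:

* **The printed ramp is the default.** $(24 - t)/18$ is discontinuous at
  $t = 8$ h (it jumps to 16/18). We keep it because it is the stated form;
  `continuous_ramp = TRUE` substitutes $(t_{end} - t)/(t_{end} - t_{start})$,
  which starts at exactly 1.
* **Zone membership is strict** (`depth < zone_width`), half-open at the
  outer edge, matching the half-open annuli used by all spatial statistics.

A variant in which rates *out of* FP are suppressed instead (an alternative
reading of which transitions are reduced) is available as
`direction = "out_of"`; the equations-as-written modulate transitions into
FP, and that is the default.

The *enrichment factor* of a phenotype is the ratio of total in-rate to
total out-rate; under the schedule the FP factor decays to 0 in the zone as
$t \to 24$ h, which is the mechanism read out by the time-resolved
statistics below.

## The agent-based generator

`simulate_tracks()` emulates the statistical structure of the tracking data:

* cells appear at the spheroid boundary ($r_s = 200$ µm, uniform angle) at
  Poisson times with rate `release_flux`, plus `n_initial_cells` at $t = 0$;
  runs last 24 h at 15-min frames by default. The observations constrain
  only "several hundred cells over 24 h"; the default flux of 15 cells/h
  (~360 cells) sits in that range and is a config parameter.
* each cell's phenotype evolves as an exact-event chain, simulated by
  thinning against the maximal base exit rate — valid because modulation
  only ever reduces rates. Between frames the cell's depth is constant, so
  the time-varying acceptance probability is exact. Exact switch times go to
  the event log.
* at each frame boundary the radial position advances by one Gaussian draw
  with the mean/SD of the phenotype held at the *start* of the frame
  (steps are attributed to the initial phenotype, as in the measurements);
  positions reflect at $r_s$ (cells never re-enter the spheroid). The
  spheroid radius is constant (observed expansion is <10% over 24 h).
* the step model is Gaussian because only means and SDs per phenotype are
  reported (BB 1.7 ± 4.2, AE 2.8 ± 3.5, LA 1.8 ± 5.2, FP 4.5 ± 5.9 µm per
  15-min frame); motion is purely radial by default since every statistic
  in the pipeline is radial. An optional independent zero-mean tangential
  step makes the $(x, y)$ output look more realistic without touching the
  radial statistics. INTERMEDIATE labels are added, if requested, as pure
  output noise at a configurable rate.

What the generator does *not* emulate: cell–cell interactions, division and
death, ECM fiber mechanics, persistence of direction, or measurement noise
in positions. Passing tests on synthetic data therefore validates the
estimators and the model mechanisms, not the biology of any particular
dataset.

Two statistical subtleties the generator exposed, documented here because
the tests rely on them:

* **Waiting-time censoring.** The mean of *completed* gaps between events in
  a finite window is biased short (long waits are preferentially cut off);
  with a 24 h window and 2 h mean the bias is ~10%. The package therefore
  estimates the mean inter-transition time as total observed cell-time over
  number of events (`mean_transition_interval_observed()`), the
  censoring-consistent renewal estimator; `transition_gaps()` retains the
  raw gaps with the caveat in its documentation.
* **Mixture autocorrelation.** Pooled raw steps have a small positive
  autocorrelation (~0.05) even though each draw is independent: phenotypes
  persist for ~8 frames and differ in mean step, and reflection at the
  boundary adds mean-reversion. The memoryless property holds conditional
  on the label sequence, and the property test checks exactly that
  (phenotype-mean-adjusted steps away from the boundary).

## Estimators

`fit_phenotype_kinetics()` counts every ordered pair of labels on
consecutive frames within a cell — dwell pairs included — and converts them
to rates as $\hat r_{X \to Y} = n_{XY} / (\mathrm{frames}_X\,\Delta t)$.
This discrete-frame MLE is the right estimator for data that exist only on
a frame grid; its leading bias is $O(r\,\Delta t)$ (about $-k\Delta t/2$
relative for the calibrated matrix, ~8.5% at 15-min frames) and is checked
in tests against the exact discrete-time truth $e^{Q\Delta t}/\Delta t$.
Phenotypes never observed are reported as undefined-with-flag, not zero.

Spatial statistics use half-open 50-µm annuli anchored at the spheroid
boundary, with invasion depth $d = r - r_s$:

* density profiles $\rho_i = N_i / \pi(r_{i+1}^2 - r_i^2)$ (counts are
  conserved exactly by construction);
* the enrichment field $(P(r,t) - P)/P$ with $P$ the global fraction over
  all cells and frames; empty annuli are flagged, not zeroed. Annuli are
  disjoint by default (a sliding mode exists) — the readout is qualitative
  and disjoint bins keep the cells independent across bins;
* the depletion statistic $P_\mathrm{FP,full} - P_\mathrm{FP,near}$ pools
  the final 4 h of a run by default (the accumulation window is not pinned
  down by the source material; it is a parameter), and
  `fit_depletion()` regresses it on cohort mean invasion depth by OLS;
* time-resolved enrichment factors re-estimate rates inside the zone per
  time window, using only frame pairs whose earlier frame lies in the zone.

Monte-Carlo tests compare frame-level proportions using cluster (per-cell)
standard errors rather than naive binomial ones, because frame labels are
autocorrelated within cells.

## The continuum model

Four densities $[X](r, t)$ on a ray $[r_s, r_{max}]$ obey

$$\frac{d[X]}{dt} = \sum_{Y \neq X} r_{Y \to X}[Y]
  - \Big(\sum_{Y \neq X} r_{X \to Y}\Big)[X]
  - H(-\nabla[X])\, v_X \nabla[X],$$

with rates passed through the modulation schedule at each node's depth, a
constant influx $F$ per phenotype at the boundary, and an absorbing outer
edge. Speeds default to mean step over frame interval (FP: 4.5/0.25 = 18
µm/h); optional diffusion uses $D_X = \mathrm{sd}_X^2 / (2\,\Delta t_f)$
(FP ≈ 69.6 µm²/h), the standard variance-to-diffusivity mapping.

**Discretization.** Explicit first-order updates on cell centers with
$\Delta r = 5$ µm and $\Delta t$ from the CFL condition with safety 0.5
(capped at 0.05 h so reactions stay resolved; a separate bound
$D\Delta t/\Delta r^2 \le 1/2$ applies when diffusion is on). The reaction
update is written pairwise (each flow enters once positively, once
negatively), so it conserves total density identically, which the tests
assert symbolically.

**The advection term and the Heaviside gate.** The gate's stated purpose is
that cells always move away from the spheroid. Three discretizations were
evaluated:

1. *Flux-form upwind with a hard per-interface gate* conserves mass but is
   unstable: the gate dams mass behind any uphill wiggle, the dam bursts,
   and the stop-go cycle makes results grid-dependent (mean depths kept
   falling as the grid was refined, with no limit in sight).
2. *The pointwise gated term* $-H(-\nabla\rho)v\nabla\rho$ with backward
   differences converges, but is non-conservative wherever the profile
   locally increases; a persistent inverted boundary layer at the inlet
   (fast phenotypes have $F/v$ below their reaction-equilibrium plateau)
   creates tens of percent of spurious mass over 24 h.
3. *Pure conservative upwind* (interface flux $v\rho_i$, always outward)
   conserves cell number to machine precision, converges at first order
   (<1% change on grid halving), and satisfies the gate's purpose by
   construction — an outward-only flux can never move mass toward the
   spheroid.

The default is (3); the literal gated form (2) is available as
`advection = "gated"` for comparison, with its mass caveat documented. The
two coincide wherever profiles decrease outward, which is everywhere except
thin layers in practice.

**Behavior.** With constant rates, each phenotype's mean invasion depth
$\bar d_X(t) = \sum (r - r_s)[X] / \sum [X]$ carries a persistent offset of
roughly one mixing length $(v_X - \bar v)/k$ (~15 µm for FP): the curves
coincide *relative to the advancing front*, with the maximum relative gap
falling below 2% around $t \approx 100$ h in our parameterization — "the
same invasion depth" is an asymptotic statement, and the acceptance check
evaluates it on a 168 h run. Switching the boundary suppression on breaks
the symmetry immediately: FP leads all other phenotypes by ~40 µm at 24 h,
and adding diffusion does not change the ordering.

## Pore-size estimation

`pore_sizes()` binarizes a grayscale matrix image (Otsu's global threshold
by default — the original binarization rule is not specified — or a numeric
cutoff), takes the pore phase, computes the Euclidean distance transform to
the nearest fiber pixel, and reports one diameter per connected pore region:
twice the maximum distance in the region, i.e. the maximal inscribed disk.
One diameter per region (not per local maximum) avoids double-counting
within a pore; regions under 4 px are dropped as binarization speckle.
Degenerate binarizations (all fiber or all pore) are errors by design — a
"pore" with no fiber boundary has no inscribed-disk diameter without
inventing a frame convention. Analysis is 2D per slice. EBImage provides
the thresholding, labeling and distance transform; `generate_fiber_image()`
renders seeded random fiber chords so the module is testable without
microscopy data. The stripe-pattern oracle (known gap, diameter within 1 px)
and density monotonicity (more fibers, smaller median pore) are the
correctness checks.

## Reproducibility and problem sizes

A single integer seed governs every stochastic stage; the CLI derives
per-stage seeds by fixed offsets (report cohorts `seed + 100 + i`, synthetic
images `seed + 200`) so stages are individually reproducible, and identical
seed + config yields byte-identical tables. The test suite uses cohorts of a
few hundred cells and ~10⁵ frame pairs for parameter-recovery checks, 20
cohorts for the nonequilibrium statistics, and a 168 h continuum run for the
asymptotic coincidence check — sizes chosen so Monte-Carlo error is well
below the effects under test while the full suite stays in the low minutes.

## Known limitations

* The default rate matrix is a calibration to stated population facts, not
  a measured matrix; any measured 4×4 matrix can be supplied via config.
* The discrete-frame rate estimator inherits an $O(r\Delta t)$ bias;
  debias externally if frames are coarse relative to dwell times.
* The continuum model is one-dimensional along a ray; no 2D/3D geometry.
* No bootstrap confidence intervals beyond plug-in/cluster SEs.
* The pore-size module measures 2D slices; anisotropic 3D pores are out of
  scope.
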