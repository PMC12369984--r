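# mesoinvasion

Mesoscale dynamics of tumor-spheroid invasion: migration-phenotype switching
coupled to phenotype-dependent motility.

## The problem

When a breast-cancer spheroid (MDA-MB-231, radius ≈ 200 µm) is embedded in a
3D type-I collagen matrix, hundreds of cells disseminate into the matrix over
24 h. Each cell expresses one of four migration phenotypes — blebbing (BB),
actin-enriched pseudopodial (AE), lamellipodial (LA), filopodial (FP) — and
switches between them every couple of hours, while its motility depends on
the phenotype it currently holds. Filopodial cells take the largest outward
steps and end up leading the invasion front; near the spheroid boundary the
FP state is progressively suppressed as the matrix is remodeled.

`mesoinvasion` provides, for users analyzing cell-tracking tables or
exploring this class of models:

* **Kinetics** — the continuous-time Markov chain on {BB, AE, LA, FP}:
  rate matrices r_{X→Y} (h⁻¹), stationary compositions π solving πQ = 0,
  calibration of a default matrix to stated population facts, the space–time
  rule that ramps transitions *into* FP down to zero near the boundary
  (factor (24 − t)/18 for t > 8 h within 50 µm of the spheroid), and
  enrichment factors (Σ in-rates / Σ out-rates).
* **Agent-based simulator** — exact-event switching plus per-frame Gaussian
  radial steps (BB 1.7 ± 4.2, AE 2.8 ± 3.5, LA 1.8 ± 5.2, FP 4.5 ± 5.9 µm
  per 15-min frame), cells released from the boundary as a Poisson stream,
  reflecting at r_s; emits tracking tables and exact event logs.
* **Track statistics** — transition-count → rate-matrix estimation
  (`fit_phenotype_kinetics`, a classed model object with `coef`, `summary`,
  `simulate`), step statistics and autocorrelation, mean radial position per
  phenotype, annular density profiles ρ_i = N_i / π(r²_{i+1} − r²_i),
  the enrichment field ΔP/P = (P(r,t) − P)/P, the depletion statistic
  P_FP,full − P_FP,near and its OLS regression on invasion depth, and
  time-resolved in-zone enrichment factors.
* **Continuum model** — the four coupled advection–reaction equations
  d[X]/dt = Σ_Y r_{Y→X}[Y] − (Σ_Y r_{X→Y})[X] − H(−∇[X]) v_X ∇[X]
  on a ray from the spheroid, with constant boundary flux, explicit upwind
  integration, optional diffusion, and mean invasion depth d̄_X(t) per
  phenotype.
* **Matrix imaging** — pore sizes of binarized fiber images as diameters of
  maximal inscribed disks (Euclidean distance transform per pore region),
  plus a seeded synthetic fiber-image generator.
* **Interface** — YAML run configs, tab-delimited interchange formats, and a
  CLI (`inst/scripts/mesoinvasion`) with subcommands `simulate-tracks`,
  `analyze-tracks`, `run-continuum`, `pore-size`, `report`.

## Worked example

```r
library(mesoinvasion)

# one spheroid, 24 h, 15-min frames, boundary suppression of FP switched on
sim <- simulate_tracks(simulation_config(release_flux = 15,
                                         schedule = modulation_schedule(),
                                         seed = 11))
fit <- fit_phenotype_kinetics(sim$tracks)
summary(fit)
#> Phenotype-switching kinetics fit (17147 frame pairs)
#> Transition rates (h^-1):
#>        BB     AE     LA     FP
#> BB 0.0000 0.1026 0.1422 0.1288
#> AE 0.1775 0.0000 0.1279 0.1268
#> LA 0.1979 0.1048 0.0000 0.1218
#> FP 0.2027 0.1136 0.1849 0.0000
#> Observed fractions:
#>     BB     AE     LA     FP
#> 0.3410 0.1984 0.2553 0.2053
#> ...
#> Population mean time between transitions: 2.357 h

fp_depletion(sim$tracks)
#> FP depletion near the boundary: P_full - P_near = 0.1331 (P_full = 0.1911, P_near = 0.0580)
#> Mean invasion depth 116.8 um over 5249 frame rows (1207 in zone)

run_continuum(continuum_params(schedule = modulation_schedule()))
#> Continuum run to t = 24 h (200 nodes, dr = 5 um, dt = 0.05 h)
#> Mean invasion depth at end (um):
#>     BB     AE     LA     FP
#> 116.25 117.75 115.02 156.44
#> Total cells in domain: 384.00 (injected: 384.00)
```

The fitted rates recover the calibrated tempo (≈ one transition per 2 h; the
in-sample figure above is the biased discrete-frame estimate, see the
vignette), the depletion statistic is strongly positive because transitions
into FP are suppressed near the boundary, and the continuum model shows FP
leading the invasion by ~40 µm at 24 h — with the schedule off, the four
curves coincide instead.

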