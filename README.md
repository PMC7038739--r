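# dbimtwist

Quantitative microwave tomography for brain stroke detection and
classification, as a self-contained R package.

Microwave tomography (MWT) surrounds the head with an antenna array in a
lossy matching liquid, measures the multistatic scattering matrix over a
wide band, and reconstructs a map of complex permittivity
ε(ω) = ε′ − jε″ inside the head. Because blood raises the dielectric
constant relative to average brain tissue while ischaemic tissue lowers it
(by 10–25%, clinically), a quantitative reconstruction can both locate a
stroke and tell a haemorrhage from an ischaemia — the triage decision that
currently requires CT or MRI.

The package implements the full pipeline around the **DBIM–TwIST**
algorithm:

* **Materials** — single-pole Debye dispersion
  ε(ω) = ε∞ + Δε/(1 + jωτ) + σs/(jωε0), with the curve-fit parameters of
  the 90% glycerol–water matching medium and the average-brain gel built
  in, contrast-scaled ischaemia presets (−25%, −50% at 1 GHz), and
  bound-constrained Debye fitting of measured permittivity samples.
* **Phantoms** — 2D gridded head phantoms: 300 mm tank, 153 × 112 mm brain
  ellipse, optional 5 mm CSF shell, 30 mm off-centre stroke target, plus a
  gel-ageing drift perturbation.
* **Forward solver** — 2D TMz FDTD in dispersive Debye media (C++ core):
  auxiliary-differential-equation Debye update, CPML absorbing boundaries,
  line-current sources, per-unit-excitation frequency-domain transfer
  functions via a running DFT. Validated against the analytic cylindrical
  wave −(ωμ0/4)·H0⁽²⁾(kρ).
* **Acquisition** — 8-antenna elliptical array, the array-sizing rule
  M = 2βα, full 8×8 multistatic scans, calibrated Gaussian noise injection,
  and measurement I/O (native JSON and Touchstone .sNp import/export).
* **Calibration** — reference calibration of target/no-target measurement
  pairs against a simulated baseline:
  Es_cal = (S_t − S_nt) · E_sim,nt / S_nt.
* **Inversion** — the distorted Born iterative method with a TwIST
  (two-step iterative shrinkage/thresholding) inner solver: Jacobian
  assembly in Debye-parameter space (unknowns Δε and σs per 2 mm cell),
  15 iterations per frequency, ascending frequency hopping, physical-bound
  clamping. `dbim_reconstruct()` is the fitting function; the returned
  `"dbim"` object has `print`, `summary`, `plot`, `coef`, `fitted`,
  `residuals` and `predict` methods.
* **Reporting** — connected-component target detection on the ε′ map and
  haemorrhagic/ischaemic classification by signed relative contrast.

## Worked example

A reduced-size virtual experiment (laboratory geometry scaled to a 150 mm
tank; data simulated on a 1 mm grid, inverted on the 2 mm grid so no
inverse crime is committed):

```r
library(dbimtwist)

# haemorrhagic-stroke scenario: blood target in the average-brain phantom
sc <- stroke_scenario("h", scale = 0.5)
st <- run_stroke_study(sc, freqs = 1.0e9, iterations = 15)

print(st$result)
#> DBIM-TwIST reconstruction
#>   schedule: 1.00 GHz, 15 iterations/stage
#>   stage 1 (1.00 GHz): residual 273 -> 0.0266

print(st$report)
#> Target detected: haemorrhagic stroke
#>   centroid: (11.7, 11.9) mm; 55 cells
#>   peak eps' = 62.91 vs background 39.80 (contrast +58%)

plot(st$result)   # reconstructed dielectric-constant map
```

The residual drops four orders of magnitude over the 15 DBIM iterations;
the detected centroid sits within a millimetre of the true target centre at
(11.3, 11.3) mm, and the +58% peak contrast against the 39.8 brain
background classifies the target as haemorrhagic (blood's true ε′ at 1 GHz
is 55.7). Swapping `"h"` for `"i25"` or `"i50"` produces the ischaemic
presets, which reconstruct with negative contrast; `drift = 0.15` ages the
background gel between the no-target and target measurements, and
`csf_thickness = 0.005` adds a CSF shell unknown to the inversion.

The array-sizing rule at the first working frequency reproduces the design
figure for the laboratory system:

```r
antenna_count(0.15, 0.5e9, tissue_library()$glycerol90)
#> [1] 15
```

## Layout

```
R/               materials, phantom, forward, acquisition, calibration,
                 twist, dbim, report, scenarios, io
src/fdtd.cpp     FDTD kernel (Debye ADE + CPML) and component labelling
tests/testthat/  unit, property and end-to-end acceptance tests
scripts/         acceptance.R
vignettes/       methods vignette (models, solvers, design choices)
inst/exec/       dbimtwist CLI (scan / calibrate / reconstruct / classify)
```
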