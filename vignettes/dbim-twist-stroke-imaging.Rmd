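---
title: "Microwave tomography for brain stroke imaging: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave tomography for brain stroke imaging: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbimtwist)
```

## The imaging problem

Haemorrhagic and ischaemic strokes move brain-tissue permittivity in opposite
directions: blood has a higher dielectric constant than average brain tissue,
while ischaemic tissue is 10--25% lower (with -50% used here as an extreme
case). A tomographic microwave scanner -- an antenna array surrounding the
head in a lossy matching liquid -- can in principle recover a quantitative
map of complex permittivity and thus both *detect* a stroke and *classify*
its type without ionizing radiation. The physical experiment this package
virtualizes is a 300 mm tank of 90% glycerol--water holding an elliptical
average-brain phantom (153 x 112 mm axes, optionally wrapped in a 5 mm
CSF-mimicking shell) with a 30 mm cylindrical stroke target, interrogated by
an 8-antenna elliptical array over 0.5--2.5 GHz.

Recovering permittivity from multistatic scattering data is a nonlinear,
ill-posed inverse problem. The package solves it with the distorted Born
iterative method (DBIM): repeatedly linearize the scattering integral about
the current background medium, solve the linear subproblem with an
l1-regularized TwIST solver, and add the solution back into the background.

## Dispersion model

All media are single-pole Debye:

$$\epsilon(\omega) = \epsilon_\infty + \frac{\Delta\epsilon}{1 + j\omega\tau}
  + \frac{\sigma_s}{j\omega\epsilon_0},$$

under the $e^{+j\omega t}$ time convention, so physical loss is a *negative*
imaginary part; the forward solver's DFT kernels use $e^{-j\omega t}$ to
match. The curve-fit parameters for the matching medium
($\Delta\epsilon = 6.56$, $\epsilon_\infty = 16.86$,
$\sigma_s = 0.3232$ S/m) and the average-brain gel
($\Delta\epsilon = 30$, $\epsilon_\infty = 10$, $\sigma_s = 0.147$ S/m)
are built in:

```{r}
tissue_library()
```

Two parameter sets deserve comment:

* **Relaxation times.** The published curve fits do not include $\tau$. The
  defaults (13 ps for tissue-like gels, 400 ps for the glycerol mixture) are
  implementation choices giving smooth, numerically benign dispersion over
  0.5--2.5 GHz. They are configuration, not measured ground truth, and every
  quantitative check that could depend on $\tau$ is formulated through
  static or real-part quantities that do not.
* **Blood/CSF.** No printed Debye fit exists for the blood/CSF gel; the
  library models it as the brain model contrast-scaled by +40% at 1 GHz,
  which puts blood's dielectric constant above brain's throughout 1--2 GHz,
  consistent with the reconstructed ordering in the experiments. Both
  entries are tagged `implementer_default` and are overridable.

`scale_contrast()` implements the ischaemia presets: it multiplies
$\Delta\epsilon$, $(\epsilon_\infty - 1)$ and $\sigma_s$ by a common factor
chosen so the real permittivity at the 1 GHz reference changes by exactly
the requested fraction. Scaling $(\epsilon_\infty - 1)$ rather than
$\epsilon_\infty$ keeps scaled models physical ($\epsilon_\infty \ge 1$)
and makes successive scalings compose exactly.

## Forward solver

The forward model is a 2D transverse-magnetic (TMz) FDTD solver written in
C++: antennas become line currents (matching the monopole excitation of the
hardware), the Debye polarization is advanced with a semi-implicit
auxiliary-differential-equation update that is exact for single-pole media,
and the open boundary is a 10-cell convolutional perfectly-matched layer --
the numerical counterpart of the physical absorber around the tank.
Frequency-domain fields at all analysis frequencies are accumulated by a
running DFT during one wideband run and normalized by the DFT of the source
current, giving per-unit-current transfer functions.

Numerical choices, all exposed through `fdtd_options()`:

* time step at 0.99 of the 2D Courant limit of the fastest medium (the
  medium's $\epsilon_\infty$ governs the instantaneous wave speed);
* modulated-Gaussian excitation centred at 1.25 GHz whose envelope keeps at
  least 2% of peak spectral amplitude across 0.5--2.5 GHz (the solver
  refuses analysis frequencies below 1% of peak, where normalization would
  be ill-conditioned);
* time stepping ends when field energy falls below `decay_tol` (default
  1e-9) of its peak, which truncates transfer values at roughly the 3e-5
  relative level -- ample for imaging. Solver-accuracy studies (e.g. the
  reciprocity check at 1e-6) tighten this to 1e-12;
* antenna positions are snapped to grid nodes, which makes discrete
  reciprocity exact up to ring-down truncation;
* denormal floating-point operands are flushed to zero inside the kernel;
  the decaying field tails otherwise dominate run time on x86.

Validation is against the analytic 2D line-source (cylindrical-wave)
solution $E = -(\omega\mu_0/4)\,H_0^{(2)}(k\rho)$ in a homogeneous medium:
amplitude decay between radii agrees to well under 1%, and the complex
ratio of FDTD to analytic fields (the *discrete source constant* $c_0$,
about $1.00 \angle{-0.1^\circ}$ on the 2 mm grid) is measured once per
grid/frequency by `source_constant()` and used to put Born predictions on
the solver's absolute scale.

## Linearization and inversion

Under the distorted Born approximation, the scattered field for a
transmitter--receiver pair is linear in the contrast between the unknown
and the current background,

$$E_s(r_n, r_m) \approx j\omega\epsilon_0
  \int_V E_b(r, r_m)\, E_b(r, r_n)\, O(r)\, dr,$$

with both background fields taken from line-source runs on the current
background (reciprocity supplies the receiver Green's function). The
unknowns are per-cell perturbations of $\Delta\epsilon$ and $\sigma_s$ with
$\epsilon_\infty$ and $\tau$ frozen at their background values -- the
minimal parameterization that lets the updated Debye maps be re-evaluated
at any frequency. Each cell therefore contributes two columns, with complex
sensitivities $1/(1+j\omega\tau)$ and $1/(j\omega\epsilon_0)$; complex rows
are split into real and imaginary parts so the l1 threshold acts on real
unknowns. The reconstruction domain is restricted to the brain ellipse.
With 8 antennas and all 64 transmit--receive pairs retained (monostatic
entries included, excludable by a flag) each frequency contributes 128 real
rows.

Measured data enter through the reference calibration
$E_{s,\mathrm{cal}} = (S_t - S_{nt})\, E_{\mathrm{sim},nt} / S_{nt}$:
the target/no-target difference rescaled, per pair and frequency, by the
ratio of the simulated to the measured baseline. Any channel factor common
to both measurements cancels, and on fully simulated data the formula
reduces exactly to scattered-field differencing. Baseline entries below a
configurable magnitude floor (default 1e-12 of the per-frequency maximum)
are masked. A plain-difference mode is selectable for comparison.

The TwIST inner solver minimizes
$\tfrac12\|y - Ax\|^2 + \lambda\|x\|_1$ with the two-step recursion
$x_{t+1} = (1-\alpha)x_{t-1} + (\alpha-\beta)x_t + \beta\,\Psi_\lambda(x_t +
A^T(y - Ax_t))$, starting with a plain IST step. The system is
column-normalized and scaled to unit spectral norm, so $\lambda$ is
relative to $\|A^Ty\|_\infty$ (default 1e-3); $\alpha,\beta$ derive from
the assumed spectral bounds $(\xi_1, \xi_m) = (10^{-4}, 1)$. A monotone
safeguard falls back to the IST step whenever the two-step iterate would
increase the objective. Two properties worth knowing:

* with column normalization, the $\lambda \to 0$ limit on underdetermined
  systems is the minimum-$\|Dx\|$ rather than the minimum-$\|x\|$ solution;
  `normalize = FALSE` recovers the pseudo-inverse limit exactly;
* with tiny $\lambda$ the iterates first converge to a least-squares
  solution and then drift slowly toward the minimum-l1 solution, so
  validation against a pseudo-inverse oracle uses a converged-but-bounded
  iteration budget.

The DBIM outer loop re-runs the forward solver on the current background at
every iteration (true distorted-Born updating), forms the residual
*y* = calibrated data − (current simulated scattered data relative to the
initial baseline), solves, and updates with clamping to physical bounds
($\Delta\epsilon \ge 0$, $\sigma_s \ge 0$). Frequencies are processed in
ascending order with the final background of one stage seeding the next
("frequency hopping"), 15 iterations per stage throughout, matching the
laboratory protocol. A divergence guard aborts if the residual exceeds 10x
its stage-initial value.

## Detection and classification

`detect_target()` thresholds the relative contrast of the reconstructed
dielectric-constant map at 10% against a background reference (median over
the reconstruction domain, excluding the detected component, estimated in
two passes), labels 4-connected components, and keeps the one with the
largest summed contrast; ties break deterministically by lowest cell index.
Positive contrast at or above threshold classifies as haemorrhagic,
negative as ischaemic. The 10% default sits well below the smallest
fabricated contrast class (25%) and above typical reconstruction artefacts;
it is configuration, as no numeric decision rule exists in the source
experiments.

For quantitative readouts the package's tests use the *mean reconstructed
dielectric constant over the true target disc*. Single-cell values sit in
the over/undershoot ripples characteristic of l1-regularized Born
iterations (the -50% target, a strong scatterer well outside the Born
regime, reconstructs with a centre dip clamped at the
$\Delta\epsilon \ge 0$ floor), whereas the disc mean is stable across all
contrast classes.

## What the synthetic studies do and do not show

The virtual experiment generates ground-truth data on a 1 mm grid and
inverts on the 2 mm reconstruction grid, with an initial guess that never
contains the target, the CSF shell, or the background drift -- so the
inverse crime is avoided in the discretization sense, and model error is
always present in the CSF/drift scenarios. The reduced-size test study
scales the laboratory geometry by 0.5 (150 mm tank, 15 mm target) while
keeping the protocol's grids, array and iteration counts; the full-size
geometry is the package default. Reported test quantities -- localization
within a few millimetres, noiseless quantitative errors within 30%, the
ordering (50% i-stroke) < (25% i-stroke) < background < (h-stroke) after
hopping over 0.7/1.1/1.5 GHz, and detection/classification surviving a +15%
gel-ageing drift between the no-target and target measurements (inverted
with 1.1--2.0 GHz hopping, as in the laboratory drift experiment) -- are
computed by `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`
at exactly these conditions.

What the synthetic studies deliberately do not emulate: antenna feed and
de-embedding effects (line sources have no pattern or mismatch), 3D
propagation and out-of-plane scattering, cable/switch drift, probe
measurement uncertainty in the material models, and anatomical complexity
(skull, skin, ventricles). Success here validates the algorithmic chain,
not clinical performance.

## Worked example

```{r example, eval = FALSE}
# reduced-size noiseless h-stroke study, single frequency
sc <- stroke_scenario("h", scale = 0.5)
st <- run_stroke_study(sc, freqs = 1.0e9, iterations = 15)
print(st$result)
print(st$report)
plot(st$result)   # reconstructed dielectric-constant map
```

Running the above prints per-stage residual decay (about four orders of
magnitude for this scenario) and a detection report locating the 15 mm
target to within about 1 mm with a positive (haemorrhagic) contrast.

## Known limitations

* 2D TMz physics only; quantitative values inherit the usual 2D bias
  relative to a 3D experiment.
* $\epsilon_\infty$ and $\tau$ are not updated by the inversion; media
  whose true $\epsilon_\infty$ differs strongly from the initial guess
  (the -50% preset) reconstruct with compensating $\Delta\epsilon$ and
  $\sigma_s$ and can clamp at the physical bounds.
* The solver parameters ($\lambda$, inner iteration budget, spectral-bound
  pair) are tunable configuration; the defaults are sensible for the
  scenarios shipped here but, as with any regularized nonlinear inversion,
  other hardware or phantoms may need re-tuning.
* Touchstone import covers version 1 files with one network parameter set;
  noise descriptors and antenna positions travel only in the native JSON
  container.
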