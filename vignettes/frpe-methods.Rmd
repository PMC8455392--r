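---
title: "Fibril-reinforced poroelastic analysis of cartilage indentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibril-reinforced poroelastic analysis of cartilage indentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frpe)
```

## The problem

Articular cartilage is a fluid-saturated fibre-reinforced tissue. Its
response to indentation mixes three constituent-level mechanisms: tensile
stiffness of the collagen fibril network, compressive stiffness of the
proteoglycan (non-fibrillar) matrix, and drag from pressurized interstitial
fluid seeping through the matrix. Osteoarthritis degrades these constituents
in characteristic ways, so constituent-level parameters are more informative
than bulk moduli. Because the constituents cannot be probed directly,
they are identified by fitting a fibril-reinforced poroelastic (FRPE)
finite-element model of the indentation experiment to the measured
force history.

This package implements that entire workflow on synthetic data: a forward
axisymmetric biphasic FE solver, extraction of standard elastic and dynamic
viscoelastic indentation properties, inverse identification of the FRPE
parameters, a synthetic cohort generator, and group-level statistics.

## Constitutive model

The total Cauchy stress is decomposed as

$$\sigma_t = \sigma_{nf} + \sigma_f - p\,\mathbf I,$$

where $p$ is the pore fluid pressure.

* **Fibril network** (`Ef0`, `EfEps`, MPa). Each fibril family carries the
  one-dimensional, tension-only stress
  $\sigma_f = (E_f^0 + E_f^\varepsilon\,\varepsilon_f)\,\varepsilon_f$ for
  $\varepsilon_f > 0$ and zero in compression. $E_f^0$ measures fibril
  pre-tension, $E_f^\varepsilon$ strain-stiffening. Two families are
  modelled, oriented parallel to the articular surface (radial and
  circumferential in the axisymmetric frame), homogeneous through depth.
  Depth-dependent fibril arcades are not identifiable from a single
  indentation record, which is why the surface-parallel architecture is the
  default (an `orientation` option exposes the choice at the material level).
* **Non-fibrillar matrix** (`Enf`, MPa; Poisson ratio `nu_nf`). A
  compressible neo-Hookean solid,
  $\sigma_{nf} = \mu/J\,(B - \mathbf I) + \lambda \ln J/J\,\mathbf I$,
  whose small-strain tangent is isotropic linear elasticity with modulus
  `Enf` and ratio `nu_nf`. Default `nu_nf = 0.42`, the conventional value
  for the cartilage matrix; configurable.
* **Permeability** (`k0` in $10^{-15}\,\mathrm{m^4 N^{-1} s^{-1}}$;
  exponent `M`). Void-ratio power law
  $k = k_0\,[(1+e)/(1+e_0)]^M$; with incompressible constituents
  $(1+e)/(1+e_0) = J$, so compaction reduces permeability when $M > 0$.
  The initial void ratio default `e0 = 4` corresponds to a fluid fraction
  of 0.8, typical for cartilage.

Internally the solver works in mm, MPa, N and s; permeability is converted
from its user-facing unit at the interface
($10^{-15}\,\mathrm{m^4 N^{-1} s^{-1}} = 10^{-3}\,\mathrm{mm^2 MPa^{-1} s^{-1}}$),
which keeps assembled matrices well scaled.

## Finite-element solver

The specimen is an axisymmetric disc (thickness $h$, radius $R$) indented by
a plane-ended cylindrical indenter of radius $a$ (defaults
$h = R = 2$ mm, $a = 0.35$ mm, typical of human condyle testing and
configurable). The biphasic displacement--pressure problem is discretized
with 9-node biquadratic displacement / 4-node bilinear pressure
(Taylor--Hood) quadrilaterals, which satisfy the inf-sup condition without
stabilization, on a structured mesh graded geometrically toward the indenter
edge (where the contact pressure is singular) and the articular surface.
Kinematics are finite-strain by default — four 5% steps plus pre-strain
exceed the small-strain regime — with a small-strain mode used for the
linear verification problems.

The fluid mass balance $\dot J/J + \nabla\!\cdot\!(-k\nabla p) = 0$ is
integrated with backward Euler; hold segments use geometrically growing time
increments (defaults: 3 increments per ramp, initial hold increment 1 s,
growth factor 2), which makes 900-s holds inexpensive while resolving the
early transient. Each increment is solved by Newton iteration with
element-level finite-difference tangents (22 dofs per element, exact
residuals), and the time step is bisected on non-convergence. Reaction force
is the sum of internal nodal forces on the driven contact nodes.

Boundary conditions for indentation: free draining ($p = 0$) on the surface
outside the indenter and at the outer radius; impermeable under the indenter,
at the bone interface (bottom, fully fixed) and on the symmetry axis. The
indenter is displacement-driven on the contact node set; contact is bonded by
default (`friction = "frictionless"` releases the radial constraint, and is
used when comparing against the frictionless-punch analytical solution).
Confined compression (used for verification) fixes radial displacement
everywhere and drains through the loaded top platen only.

The stress-targeted pre-stress of 12.5 kPa is seated by a secant iteration on
the *drained* equilibrium force: holding the pre-stress to equilibrium drains
the tissue, so the drained static solution is the correct initial state for
the subsequent relaxation steps.

**Verification.** Two independent oracles validate the solver in the test
suite: (i) linear-limit confined compression against the closed-form
eigenfunction series for ramp--hold consolidation (relative $L_2$ error
below 1% at a 24-element column with 80 ramp increments), and (ii) drained
equilibrium indentation against the bonded-layer flat-punch (Hayes) solution
within 5% at $a/h \in \{0.1, 0.5, 1.0\}$. Mesh convergence is asserted at
the reference resolution (end-of-step-2 force changes below 2% when element
counts double).

## Indentation analysis

The protocol is the standard one for cartilage characterization: pre-stress
12.5 kPa, four stress-relaxation steps of 5% strain with 15-min holds, then
sinusoidal sweeps of 2% strain amplitude at 0.005--1 Hz. The default ramp
duration is 0.5 s per step; the instantaneous modulus is operationally
defined by the protocol's own ramp speed, so the same value is used in
generation and analysis.

All moduli use the Hayes correction $\kappa(a/h, \nu)$ for a flat punch on a
bonded finite-thickness layer, computed by solving the dual integral
equations of the punch problem: the layer response in Hankel space
(derived from the Love strain-function solution with bonded base and
frictionless surface) reduces the mixed boundary-value problem to a Fredholm
equation of the second kind, solved by Gauss--Legendre Nystrom quadrature
with a spline-cached kernel; values are cached per $(a/h, \nu)$. The force
relation is $P = 2 E a w \kappa / (1 - \nu^2)$.

* **Equilibrium modulus** `E_eq`: slope of the least-squares line through the
  four Hayes-corrected end-of-hold stress--strain points, with $\nu = 0.42$
  (drained). A plateau diagnostic flags holds whose final-minute force slope
  exceeds 0.5% of the step force change per minute.
* **Instantaneous moduli** `E_inst0`, `E_instEps`: per-step Hayes-corrected
  peak stress increment over strain increment ($\nu = 0.5$, short-time
  incompressible), fitted linearly against strain at step onset; intercept
  and slope. The peak is taken from the ramp window of the record rather
  than a fitted initial slope, which is robust to sampling rate.
* **Dynamic properties** per frequency: complex amplitudes of force and
  displacement from the discrete Fourier component at the drive frequency,
  over the largest whole number of cycles counted from the end of the block.
  The quadrature components are estimated jointly with an intercept and a
  linear trend (the residual relaxation drift); fitting them together rather
  than detrending first avoids the phase bias that arises because a linear
  trend is not exactly orthogonal to the sinusoid on a finite window.
  `E_dynamic` is the Hayes-corrected stress/strain amplitude ratio;
  `theta_dynamic` is the force-minus-displacement phase in degrees. Negative
  raw phase differences are reported unwrapped but flagged as artifacts
  rather than silently wrapped into $[0°, 90°)$.

## Inverse identification

The five FRPE parameters are fitted by minimizing the discrepancy between
simulated and measured force over the **2nd and 3rd stress-relaxation steps**
(ramps and holds). Steps 1 and 4 are deliberately excluded, giving a built-in
out-of-window check. The objective is the mean squared force difference
normalized by the squared measured force range over the window. Every record
sample in the window enters the residual: the forward simulation dominates
the cost, so there is no reason to decimate, and dense sampling averages
measurement noise out of the estimator (with decimated residuals the
estimator spread roughly doubles).

Optimization uses bounded Levenberg--Marquardt (`minpack.lm`) on
$(E_f^0, E_f^\varepsilon, E_{nf}, \log_{10} k_0, M)$ — permeability spans
orders of magnitude across OA states, hence the log parameterization.
Multistart: seeded multiplicative perturbations around the initial guess,
screening of every start by its initial objective, full local optimization
from the best `n_refine` (default 2). Failed forward solves return a large
finite penalty so the optimizer survives excursions. Default bounds envelope
human cartilage values across OA states
($E_f^0 \in [10^{-6}, 50]$, $E_f^\varepsilon \in [0, 500]$,
$E_{nf} \in [0.01, 5]$ MPa, $k_0 \in [10^{-2}, 10^3]$, $M \in [0, 25]$).

During optimization the forward model runs at the `"coarse"` mesh resolution
and the default adaptive time grid; recovery studies generate data at the
same discretization, so discretization error cancels and the optimizer's
statistical properties are tested in isolation. On noiseless data all five
parameters are recovered exactly (normalized objective $<10^{-6}$) from
$\pm 50\%$ perturbed starts; with 1% multiplicative force noise the moduli
are recovered within a few percent. With only equilibrium data the objective
is flat in $k_0$ — the transient window is what identifies permeability —
and a flat force record yields a non-convergence flag rather than an error.

## Synthetic cohorts

The generator emulates a 35-specimen osteoarthritis grading study: 17
normal (OARSI 0--1, mostly 1), 15 moderate (OARSI 2--3, mostly 2), 3 severe
(OARSI 4). Ground-truth parameters are log-normal per group; the severe-OA
defaults encode near-total loss of fibril pre-tension, reduced matrix
modulus and `M`, and an order-of-magnitude larger permeability, while
normal and moderate groups are nearly identical — the qualitative pattern
reported for human femoral condyle cartilage. The numeric medians are
package conventions chosen at typical human-knee magnitudes, not published
measurements. Within-knee similarity is modelled by a shared knee-level
random effect on the log scale (variance fraction `knee_rho`, default 0.6);
knees contribute one or two compartments and may straddle groups.
Records are resampled at 10 Hz (relaxation) and 50 samples per cycle
(dynamic blocks), then multiplicative Gaussian force noise (default 1%) and
optional displacement jitter are applied.

What the generator does *not* emulate: device compliance, contact seating
artifacts, thickness measurement error, depth-dependent composition, or
osmotic swelling. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the pipeline under its own model
class, not robustness to model misspecification of real instruments.

## Cohort statistics

Groups are compared descriptively (n, mean, SD, median, IQR per group and
compartment) and by normal-vs-moderate mean differences with percentile
bootstrap 95% confidence intervals that resample *knees*, not samples,
respecting the clustering. The severe group is summarized but excluded from
testing below a configurable size (default 5), mirroring practice with
3-specimen groups. An age/BMI-adjusted mixed-effects regression is a routine
off-the-shelf analysis and is deliberately out of scope; the knee-clustered
bootstrap is the package's substitute. Interval calibration is verified by
simulation: coverage of a known 30% group effect on `Enf` is 95% ± 3% over
500 seeded replicates at the default cohort design.

## Numerical choices and problem sizes

* Mesh presets: `"coarse"` (2+3 x 3 elements, grading 4) for optimization
  and recovery studies; `"medium"` (4+5 x 5, grading 8) as reference;
  `"fine"` (8+10 x 10) for convergence checks. These sizes keep a full
  multistart fit in tens of seconds and the complete recovery studies in
  minutes on a single core while the verification oracles hold to within
  their stated tolerances.
* Newton tolerance $10^{-9}$ (relative increment), maximum 25 iterations,
  8 bisection levels. Finite-difference element tangents use a forward step
  of $10^{-7}(1 + |d_j|)$.
* The Hayes kernel integrals use adaptive quadrature to an upper limit of
  $\max(8, 10\,a/h)$ (the integrand decays like $e^{-2xh/a}$), a 121-point
  kernel spline on $[0, 2]$ and a 48-point Nystrom grid.
* Ties and degenerate inputs: tension-only fibril stress is exactly zero at
  $\varepsilon_f = 0$; `J <= 0` raises a degenerate-deformation error;
  zero-variance force records raise an explicit undefined-R² error.

## Known limitations

* The fibril network law and its surface-parallel architecture are the
  standard FRPE conventions; other variants (viscoelastic fibrils, arcade
  architectures, Donnan swelling) are out of scope.
* Backward Euler introduces $O(\Delta t)$ numerical damping; at the default
  48 increments per cycle the extracted phase angles carry a small
  discretization bias, which cancels in the signal-analysis tests (pure
  synthetic sinusoids) but not in FE-generated dynamic blocks.
* Bonded contact with prescribed axial displacement is an approximation to
  a true contact solver; it is standard for plane-ended indentation at these
  strains, and the frictionless option brackets the contact condition.
* The percentile bootstrap is first-order accurate; its small-sample
  coverage at the default design is verified empirically rather than
  guaranteed.
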