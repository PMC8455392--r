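# frpe: fibril-reinforced poroelastic modeling of cartilage indentation

Articular cartilage owes its mechanical function to three constituents: a
tension-only collagen fibril network, a porous proteoglycan matrix, and
pressurized interstitial fluid. Indentation testing probes all three at
once; separating them requires fitting a constituent-level material model to
the measured force history. `frpe` implements the complete
characterization pipeline used in human cartilage osteoarthritis studies,
end-to-end and testable on synthetic data:

* a **fibril-reinforced poroelastic (FRPE) material model** with total
  stress `sigma_t = sigma_nf + sigma_f - p I`: tension-only strain-stiffening
  fibrils (`sigma_f = (Ef0 + EfEps*eps) * eps`), a compressible neo-Hookean
  non-fibrillar matrix (`Enf`, `nu_nf`), and strain-dependent permeability
  (`k = k0 * ((1+e)/(1+e0))^M`);
* an **axisymmetric biphasic (u-p) finite-element solver** (Taylor-Hood
  Q9/Q4 elements, finite strain, backward Euler, Newton with time-step
  bisection) for plane-ended indentation and confined compression, including
  the stress-targeted 12.5 kPa pre-stress seating;
* **indentation analysis**: equilibrium modulus `E_eq`, instantaneous moduli
  `E_inst0`/`E_instEps`, and per-frequency dynamic modulus and phase
  difference, all with the Hayes finite-thickness correction
  `kappa(a/h, nu)` computed from the bonded-layer punch problem;
* **inverse identification** of the five FRPE parameters
  (`Ef0`, `EfEps`, `Enf`, `k0`, `M`) from the 2nd and 3rd stress-relaxation
  steps by bounded multistart Levenberg-Marquardt (`k0` in log space);
* a **synthetic cohort generator** (35 specimens in normal / moderate OA /
  severe OA groups of 17/15/3, knee-level random effects, OARSI grades,
  measurement noise) and **knee-clustered bootstrap group statistics**.

## Worked example

Simulate one specimen through the full protocol (pre-stress, four 5% strain
steps with 15-min holds, eight-frequency dynamic sweep), extract its
properties, then recover the generating parameters from the relaxation data:

```r
library(frpe)

truth <- frpe_parameters(Ef0 = 0.9, EfEps = 40, Enf = 0.7, k0 = 2, M = 10)
geom  <- sample_geometry(h = 2, R = 2, a = 0.35)

exp1 <- generate_experiment(truth, geom, indentation_protocol(),
                            noise_model(force_noise = 0), resolution = "coarse")
analyze_experiment(exp1)
#> E_eq = 1.387 MPa, E_inst0 = 1.324 MPa, E_instEps = 12.80 MPa
#> dynamic properties:
#>   freq E_dynamic theta_dynamic artifact
#>  0.005  2.572662    14.3140241    FALSE
#>  0.050  3.318979     3.9234362    FALSE
#>  ...
#>  1.000  3.357194     0.2292727    FALSE

fit <- fit_frpe(exp1, optimization_config(n_starts = 5, seed = 1),
                init = frpe_parameters(Ef0 = 1.3, EfEps = 25, Enf = 0.5,
                                       k0 = 4, M = 6))
fit
#> FRPE fit: objective 3.53e-31, R^2 = 1.0000, converged
#> FRPE parameters:
#>   Ef0   = 0.9 MPa (initial fibril network modulus)
#>   EfEps = 40 MPa (strain-dependent fibril network modulus)
#>   Enf   = 0.7 MPa (non-fibrillar matrix modulus)
#>   k0    = 2 e-15 m^4/(N s) (initial permeability)
#>   M     = 10 (permeability strain-dependency)
```

Reading the output: `E_eq` is the drained stiffness of the solid skeleton
(slope of the relaxed stress-strain points); the dynamic modulus rises and
the phase lag falls with frequency as interstitial fluid becomes trapped —
at 1 Hz the tissue responds almost elastically. On noiseless synthetic data
the optimizer returns the generating parameters to machine precision
(objective ~1e-31); with 1% force noise the moduli are typically recovered
within a few percent.

Cohort-level use:

```r
coh <- generate_cohort(cohort_spec(), seed = 1)           # 35 specimens, 17/15/3
summarize_cohort(coh$samples, c("Ef0", "Enf", "k0"))      # knee-clustered bootstrap
```

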