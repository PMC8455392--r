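# Property extraction on records constructed from closed-form ground truth.

# build a relaxation record directly from the Hayes force relation for a
# linear-elastic layer of modulus E: equilibrium force at strain eps is
# F = 2 E a (eps h) kappa / (1 - nu^2), with an exponential transient on top
hayes_relaxation_record <- function(E, geometry, nu = 0.42, n_steps = 4,
                                    step_strain = 0.05, hold_s = 120,
                                    ramp_s = 0.5, peak_factor = 2, tau = 10) {
  kap <- hayes_kappa(geometry$a / geometry$h, nu)
  stiff <- 2 * E * geometry$a * geometry$h * kap / (1 - nu^2)  # F per strain
  tt <- seq(0, n_steps * (ramp_s + hold_s), 0.1)
  eps <- numeric(length(tt)); F <- numeric(length(tt))
  steps <- data.frame(step = seq_len(n_steps),
                      t_start = (seq_len(n_steps) - 1) * (ramp_s + hold_s),
                      t_peak = NA, t_end = NA,
                      strain = seq_len(n_steps) * step_strain,
                      strain_pre = (seq_len(n_steps) - 1) * step_strain)
  steps$t_peak <- steps$t_start + ramp_s
  steps$t_end <- steps$t_start + ramp_s + hold_s
  for (i in seq_len(n_steps)) {
    ramp <- tt >= steps$t_start[i] & tt < steps$t_peak[i]
    eps[ramp] <- steps$strain_pre[i] +
      step_strain * (tt[ramp] - steps$t_start[i]) / ramp_s
    hold <- tt >= steps$t_peak[i] & tt <= steps$t_end[i] + 1e-9
    eps[hold] <- steps$strain[i]
    F_eq_pre <- stiff * steps$strain_pre[i]
    F_eq <- stiff * steps$strain[i]
    dF <- F_eq - F_eq_pre
    F[ramp] <- F_eq_pre + peak_factor * dF *
      (tt[ramp] - steps$t_start[i]) / ramp_s
    F[hold] <- F_eq + (peak_factor - 1) * dF *
      exp(-(tt[hold] - steps$t_peak[i]) / tau)
  }
  rel <- data.frame(time_s = tt, displacement_mm = eps * geometry$h,
                    force_N = F)
  indentation_experiment(rel, steps, geometry, nu_eq = nu, nu_inst = nu)
}

test_that("equilibrium modulus recovers the generating modulus within 1%", {
  g <- sample_geometry()
  exp1 <- hayes_relaxation_record(E = 1.2, g, tau = 5)
  eq <- equilibrium_modulus(exp1)
  expect_equal(eq$E_eq, 1.2, tolerance = 0.01)
  expect_equal(eq$r_squared, 1, tolerance = 1e-6)  # collinear points
  expect_lt(max(abs(eq$residuals)), 1e-4)
})

test_that("non-equilibrated holds are flagged", {
  g <- sample_geometry()
  # relaxation much slower than the hold: plateau criterion must fail
  exp_slow <- hayes_relaxation_record(E = 1.2, g, hold_s = 60, tau = 500)
  expect_warning(equilibrium_modulus(exp_slow), "non-equilibrated")
})

test_that("instantaneous moduli fit recovers intercept and slope", {
  g <- sample_geometry()
  # peak_factor constant => per-step modulus independent of strain
  exp1 <- hayes_relaxation_record(E = 1.0, g, peak_factor = 2, tau = 5)
  inst <- instantaneous_moduli(exp1)
  kap_ratio <- (1 - exp1$nu_inst^2) / (1 - exp1$nu_eq^2) *
    hayes_kappa(g$a / g$h, exp1$nu_eq) / hayes_kappa(g$a / g$h, exp1$nu_inst)
  m_expected <- 2 * 1.0 * kap_ratio   # peak increment is twice the elastic one
  expect_equal(inst$E_inst0, m_expected, tolerance = 1e-6)
  expect_equal(inst$E_instEps, 0, tolerance = 1e-6)
  # per-step moduli are constant to machine precision in this construction
  expect_lt(sd(inst$points$modulus), 1e-8 * mean(inst$points$modulus))
})

test_that("strain stiffening surfaces as a positive instantaneous-modulus slope", {
  exp0 <- noiseless_experiment()   # forward FRPE simulation with EfEps > 0
  inst <- instantaneous_moduli(exp0)
  expect_gt(inst$E_instEps, 0)
})

test_that("sinusoid analysis recovers imposed amplitude ratio and lag", {
  g <- sample_geometry()
  exp_sin <- make_sin_experiment(freqs = c(0.05, 1), lag_deg = 10,
                                 amp_ratio = 5)
  for (f in c(0.05, 1)) {
    d <- dynamic_properties(exp_sin, f)
    expect_equal(d$theta_dynamic, 10, tolerance = 0.1)
    # amplitude ratio 5 N/mm converted through the Hayes relation
    E_exp <- hayes_modulus(5 * g$h / (pi * g$a^2), g, exp_sin$nu_inst)
    expect_equal(d$E_dynamic, E_exp, tolerance = 1e-3)
    expect_false(d$artifact)
  }
  # zero lag: exactly in phase
  exp0 <- make_sin_experiment(freqs = 0.1, lag_deg = 0)
  expect_equal(dynamic_properties(exp0, 0.1)$theta_dynamic, 0,
               tolerance = 0.01)
  # negative lag is reported but flagged as an artifact
  expn <- make_sin_experiment(freqs = 0.1, lag_deg = -5)
  dn <- dynamic_properties(expn, 0.1)
  expect_true(dn$artifact)
  expect_error(dynamic_properties(exp0, 0.7), "no dynamic block")
})

test_that("too-short dynamic records raise a signal-quality error", {
  exp1 <- make_sin_experiment(freqs = 0.1, lag_deg = 5, n_cycles = 1)
  expect_error(dynamic_properties(exp1, 0.1, min_cycles = 4), "signal-quality")
})

test_that("property extraction from a forward simulation is deterministic", {
  exp0 <- noiseless_experiment()
  p1 <- analyze_experiment(exp0)
  p2 <- analyze_experiment(exp0)
  expect_identical(p1$elastic$E_eq, p2$elastic$E_eq)
  expect_identical(p1$elastic$E_inst0, p2$elastic$E_inst0)
})
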