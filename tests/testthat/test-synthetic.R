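test_that("parameter draws are seeded and respect degenerate scales", {
  model <- group_parameter_model()
  set.seed(3); p1 <- draw_parameters("normal", model)
  set.seed(3); p2 <- draw_parameters("normal", model)
  expect_identical(unlist(p1), unlist(p2))
  # zero scale returns the group location exactly
  m0 <- group_parameter_model(sigmas = list(
    normal = c(Ef0 = 0, EfEps = 0, Enf = 0, k0 = 0, M = 0),
    moderate = c(Ef0 = 0, EfEps = 0, Enf = 0, k0 = 0, M = 0),
    severe = c(Ef0 = 0, EfEps = 0, Enf = 0, k0 = 0, M = 0)))
  set.seed(1)
  pd <- draw_parameters("severe", m0)
  expect_equal(unlist(pd), m0$medians$severe)
})

test_that("group medians preserve the configured OA ordering over many draws", {
  model <- group_parameter_model()
  set.seed(10)
  k0n <- replicate(1e4, draw_log_params_test("normal", model)["k0"])
  k0s <- replicate(1e4, draw_log_params_test("severe", model)["k0"])
  ef0n <- replicate(1e4, draw_log_params_test("normal", model)["Ef0"])
  ef0s <- replicate(1e4, draw_log_params_test("severe", model)["Ef0"])
  expect_gt(median(k0s), median(k0n))
  expect_lt(median(ef0s), median(ef0n))
})

test_that("cohort generation matches the requested design", {
  coh <- generate_cohort(cohort_spec(), seed = 2)
  expect_equal(nrow(coh$samples), 35)
  expect_equal(sum(coh$samples$group == "normal"), 17)
  expect_equal(sum(coh$samples$group == "moderate"), 15)
  expect_equal(sum(coh$samples$group == "severe"), 3)
  # grades consistent with groups
  expect_true(all(coh$samples$oarsi[coh$samples$group == "normal"] %in% 0:1))
  expect_true(all(coh$samples$oarsi[coh$samples$group == "moderate"] %in% 2:3))
  expect_true(all(coh$samples$oarsi[coh$samples$group == "severe"] == 4))
  # knees hold 1 or 2 samples
  expect_true(all(table(coh$samples$knee_id) %in% 1:2))
  # single-sample severe cohort
  tiny <- generate_cohort(cohort_spec(0, 0, 1), seed = 1)
  expect_equal(nrow(tiny$samples), 1)
  expect_equal(tiny$samples$group, "severe")
  # bit-reproducible under the same seed
  coh2 <- generate_cohort(cohort_spec(), seed = 2)
  expect_identical(coh$samples, coh2$samples)
})

test_that("the knee random effect induces within-knee correlation", {
  icc <- function(rho) {
    model <- group_parameter_model(knee_rho = rho)
    coh <- generate_cohort(cohort_spec(n_normal = 120, n_moderate = 0,
                                       n_severe = 0, model = model,
                                       pair_prob = 1), seed = 8)
    d <- coh$samples
    x <- log(d$Enf)
    km <- tapply(x, d$knee_id, mean)
    n_per <- 2
    msb <- n_per * var(km)
    msw <- mean(tapply(x, d$knee_id, var))
    (msb - msw) / (msb + (n_per - 1) * msw)
  }
  expect_gt(icc(0.9), icc(0) + 0.3)
})

test_that("a zero-noise experiment is a faithful resampling of the simulation", {
  exp0 <- noiseless_experiment()
  expect_equal(nrow(exp0$steps), 4)
  # analysis on the resampled record agrees with analysis on the raw
  # simulation grid to < 1%
  truth <- truth_params()
  geom <- sample_geometry()
  mesh <- build_mesh(geom, "coarse")
  cc <- constitutive_constants()
  prot <- indentation_protocol(freqs = NULL)
  ps <- frpe:::prestress_seek(mesh, truth, cc, solver_settings())
  sim <- simulate(mesh, truth, cc, prot, solver_settings(),
                  prestrain = -ps$w / geom$h, state0 = ps$state)
  raw <- indentation_experiment(
    data.frame(time_s = sim$time_s, displacement_mm = sim$displacement_mm,
               force_N = sim$force_N),
    exp0$steps, geom, prestrain = -ps$w / geom$h)
  # plateau diagnostic is conservative on the sparse adaptive grid: silence it
  E_raw <- suppressWarnings(equilibrium_modulus(raw))$E_eq
  E_res <- equilibrium_modulus(exp0)$E_eq
  expect_equal(E_res, E_raw, tolerance = 0.01)
})

test_that("generated dynamic blocks carry the eight protocol frequency tags", {
  freqs <- c(0.005, 0.05, 0.1, 0.25, 0.5, 0.625, 0.833, 1)
  # cheap surrogate: the resampling/annotation layer with a tiny protocol
  prot <- indentation_protocol(n_steps = 2, hold_s = 30, freqs = c(0.5, 1),
                               n_cycles = 2)
  exp1 <- generate_experiment(truth_params(), sample_geometry(), prot,
                              noise_model(force_noise = 0),
                              resolution = "coarse")
  expect_equal(sort(unique(exp1$dynamic$freq)), c(0.5, 1))
  expect_equal(nrow(exp1$steps), 2)
  # the full protocol advertises all eight frequencies
  expect_equal(sort(unique(indentation_protocol()$freq[
    indentation_protocol()$type == "sin"])), freqs)
})

test_that("seeded noise is reproducible and scales as configured", {
  truth <- truth_params()
  prot <- indentation_protocol(n_steps = 2, hold_s = 20, freqs = NULL)
  set.seed(5)
  e1 <- generate_experiment(truth, sample_geometry(), prot,
                            noise_model(force_noise = 0.01),
                            resolution = "coarse")
  set.seed(5)
  e2 <- generate_experiment(truth, sample_geometry(), prot,
                            noise_model(force_noise = 0.01),
                            resolution = "coarse")
  expect_identical(e1$relaxation$force_N, e2$relaxation$force_N)
  set.seed(5)
  e0 <- generate_experiment(truth, sample_geometry(), prot,
                            noise_model(force_noise = 0),
                            resolution = "coarse")
  rel_dev <- (e1$relaxation$force_N - e0$relaxation$force_N) /
    pmax(e0$relaxation$force_N, 1e-9)
  expect_equal(sd(rel_dev[e0$relaxation$force_N > 0.01]), 0.01,
               tolerance = 0.15)
})
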