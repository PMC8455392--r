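test_that("an undeformed body produces zero reaction force", {
  mesh <- build_mesh(sample_geometry(), "coarse")
  prot <- loading_protocol(data.frame(type = "hold", target = 0,
                                      amplitude = 0, freq = NA, duration = 5))
  res <- simulate(mesh, frpe_parameters(), constitutive_constants(), prot,
                  solver_settings(dt_hold0 = 1))
  expect_true(all(res$force_N == 0))
})

test_that("reaction force relaxes monotonically during every hold", {
  exp0 <- noiseless_experiment()
  rel <- exp0$relaxation
  for (i in seq_len(nrow(exp0$steps))) {
    st <- exp0$steps[i, ]
    hold <- rel$force_N[rel$time_s > st$t_peak + 0.5 & rel$time_s <= st$t_end]
    expect_true(all(diff(hold) <= 1e-10))
  }
})

test_that("the multi-step protocol composes the prescribed phases", {
  prot <- indentation_protocol()
  holds <- prot[prot$type == "hold", ]
  expect_equal(nrow(holds), 4)
  expect_true(all(holds$duration == 900))
  expect_equal(holds$target, c(0.05, 0.10, 0.15, 0.20))
  sins <- prot[prot$type == "sin", ]
  expect_equal(nrow(sins), 8)
  expect_equal(sins$freq, c(0.005, 0.05, 0.1, 0.25, 0.5, 0.625, 0.833, 1))
  expect_true(all(sins$amplitude == 0.02))
})

test_that("a stiffer matrix needs less displacement to reach the pre-stress", {
  geom <- sample_geometry()
  mesh <- build_mesh(geom, "coarse")
  cc <- constitutive_constants()
  st <- solver_settings()
  soft <- frpe:::prestress_seek(mesh, frpe_parameters(Enf = 0.3), cc, st)
  stiff <- frpe:::prestress_seek(mesh, frpe_parameters(Enf = 1.2), cc, st)
  expect_lt(abs(stiff$w), abs(soft$w))
  # both hit the 12.5 kPa target force
  f_target <- 0.0125 * pi * geom$a^2
  expect_equal(soft$force, f_target, tolerance = 1e-4)
  expect_equal(stiff$force, f_target, tolerance = 1e-4)
})

test_that("protocol strains outside the admissible range are rejected", {
  expect_error(loading_protocol(data.frame(type = "ramp", target = 0.3,
                                           amplitude = 0, freq = NA,
                                           duration = 1)), "within")
  expect_error(loading_protocol(data.frame(type = "hold", target = 0.1,
                                           amplitude = 0, freq = NA,
                                           duration = -5)), "positive")
})

test_that("the indentation force is mesh-converged at the reference resolution", {
  geom <- sample_geometry()
  cc <- constitutive_constants()
  prot2 <- indentation_protocol(n_steps = 2, freqs = NULL)
  run2 <- function(res) {
    m <- build_mesh(geom, res)
    simulate_indentation_protocol(frpe_parameters(), geom, cc, prot2,
                                  solver_settings(), mesh = m)
  }
  rA <- run2(mesh_resolution(4, 5, 5, 8))    # reference ("medium")
  rB <- run2(mesh_resolution(8, 10, 10, 8))  # doubled
  fA <- rA$force_N[nrow(rA)]
  fB <- rB$force_N[nrow(rB)]
  expect_lt(abs(fA - fB) / fB, 0.02)         # end-of-step-2 force
})

test_that("simulation results are bit-reproducible", {
  mesh <- build_mesh(sample_geometry(), "coarse")
  prot <- loading_protocol(data.frame(type = c("ramp", "hold"), target = 0.05,
                                      amplitude = 0, freq = NA,
                                      duration = c(0.5, 30)))
  r1 <- simulate(mesh, frpe_parameters(), constitutive_constants(), prot,
                 solver_settings())
  r2 <- simulate(mesh, frpe_parameters(), constitutive_constants(), prot,
                 solver_settings())
  expect_identical(r1$force_N, r2$force_N)
})
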