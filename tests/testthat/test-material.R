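test_that("fibril stress is tension-only and follows the strain-stiffening law", {
  # no compression transmitted by the fibril network, on a grid of strains
  eps <- seq(-0.3, 0, by = 0.01)
  expect_true(all(fibril_stress(5, 100, eps) == 0))
  # linear Hookean limit when the strain-dependent modulus vanishes
  expect_equal(fibril_stress(1, 0, 0.1), 0.1)
  # hand evaluation of sigma_f = (Ef0 + EfEps * eps) * eps
  expect_equal(fibril_stress(1, 10, 0.1), (1 + 10 * 0.1) * 0.1)
  expect_equal(fibril_stress(0.9, 40, 0.05), (0.9 + 40 * 0.05) * 0.05)
  # strictly increasing and convex in tension for EfEps > 0
  s <- fibril_stress(1, 10, seq(0.01, 0.5, 0.01))
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) > 0))
  expect_error(fibril_stress(1, 10, NaN), "non-finite")
})

test_that("non-fibrillar stress matches linear elasticity at small strain", {
  Enf <- 0.7; nu <- 0.42
  e <- 1e-6
  # uniaxial strain state (zero lateral strain): closed-form linear elasticity
  st <- strain_state(matrix(c(1 + e, 0, 0, 1), 2, 2), 1)
  s <- nonfibrillar_stress(Enf, nu, st)
  lam <- Enf * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- Enf / (2 * (1 + nu))
  expect_equal(s[["rr"]], (lam + 2 * mu) * e, tolerance = 1e-3)
  expect_equal(s[["zz"]], lam * e, tolerance = 1e-3)
  expect_equal(s[["tt"]], lam * e, tolerance = 1e-3)
  # zero stress in the reference configuration
  expect_equal(unname(nonfibrillar_stress(Enf, nu, strain_state())),
               rep(0, 4))
})

test_that("small-strain tangent equals isotropic elasticity to 1e-4", {
  Enf <- 1.3; nu <- 0.3
  lam <- Enf * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- Enf / (2 * (1 + nu))
  h <- 1e-7
  # finite-difference tangent around identity in the (rr, zz, tt) subspace
  D_fd <- matrix(0, 3, 3)
  for (j in 1:3) {
    Fm <- diag(2); Fth <- 1
    if (j == 1) Fm[1, 1] <- 1 + h
    if (j == 2) Fm[2, 2] <- 1 + h
    if (j == 3) Fth <- 1 + h
    s <- nonfibrillar_stress(Enf, nu, strain_state(Fm, Fth))
    D_fd[, j] <- s[c("rr", "zz", "tt")] / h
  }
  D_lin <- matrix(lam, 3, 3) + diag(2 * mu, 3)
  expect_lt(max(abs(D_fd - D_lin)) / max(abs(D_lin)), 1e-4)
})

test_that("neo-Hookean volumetric response matches the strain-energy derivative", {
  # pure volumetric compression to J = 0.9; oracle: central finite difference
  # of W(J) = mu/2 (I1 - 3) - mu ln J + lam/2 (ln J)^2 under F = J^(1/3) I,
  # via sigma = (1/ (3 J^(2/3))) dW/dlambda ... expressed as dW/dJ * J:
  # for hydrostatic states sigma_m = dW/dJ.
  Enf <- 0.7; nu <- 0.42
  lam <- Enf * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- Enf / (2 * (1 + nu))
  W <- function(J) {
    l <- J^(1 / 3)
    mu / 2 * (3 * l^2 - 3) - mu * log(J) + lam / 2 * log(J)^2
  }
  J0 <- 0.9; h <- 1e-6
  sigma_m_fd <- (W(J0 + h) - W(J0 - h)) / (2 * h)
  l0 <- J0^(1 / 3)
  st <- strain_state(diag(c(l0, l0)), l0)
  s <- nonfibrillar_stress(Enf, nu, st)
  expect_equal(s[["rr"]], s[["zz"]])
  expect_equal(s[["rr"]], s[["tt"]])
  expect_equal(s[["rr"]], sigma_m_fd, tolerance = 1e-5)
})

test_that("permeability follows the void-ratio power law", {
  expect_equal(permeability(3, 7, 4, 4), 3)        # identity at reference
  expect_equal(permeability(3, 0, 1.7, 4), 3)      # strain-independent at M=0
  expect_equal(permeability(2, 5, 3, 4), 2 * (4 / 5)^5)  # hand evaluation
  # log-linear in (1+e)/(1+e0): exact slope M on the log-log scale
  e <- seq(1, 6, 0.5)
  lk <- log(permeability(2, 5, e, 4))
  lr <- log((1 + e) / 5)
  expect_equal(diff(lk) / diff(lr), rep(5, length(e) - 1))
  # monotone decreasing in compaction
  expect_true(all(diff(permeability(2, 5, seq(4, 1, -0.5), 4)) < 0))
  expect_error(permeability(2, 5, -1.5, 4), "void ratio")
})

test_that("total stress decomposition reproduces the mixture relation exactly", {
  expect_equal(unname(total_stress(rep(0, 4), rep(0, 4), 0)), rep(0, 4))
  snf <- c(rr = 1, zz = 2, tt = 3, rz = 0.5)
  expect_equal(total_stress(snf, snf * 0, 0), snf)   # drained limit
  sf <- c(rr = 0.1, zz = 0, tt = 0.4, rz = -0.2)
  p <- 0.7
  expect_equal(unname(total_stress(snf, sf, p)),
               unname(snf + sf) - c(p, p, p, 0))
  expect_error(total_stress(snf, sf[1:3], p), "conformable")
})

test_that("stress decomposition satisfies sigma_t = sigma_nf + sigma_f - p I", {
  params <- frpe_parameters(Ef0 = 1, EfEps = 10, Enf = 0.5, k0 = 2, M = 5)
  cc <- constitutive_constants()
  set.seed(11)
  for (i in 1:20) {
    Fm <- diag(2) + matrix(runif(4, -0.1, 0.1), 2, 2)
    Fth <- 1 + runif(1, -0.1, 0.1)
    p <- runif(1, 0, 0.3)
    sd <- stress_decomposition(params, cc, strain_state(Fm, Fth, cc$e0), p)
    recon <- sd$sigma_nf + sd$sigma_f - c(p, p, p, 0)
    expect_equal(unname(sd$sigma_t), unname(recon))
  }
})

test_that("R and compiled constitutive evaluations agree", {
  params <- frpe_parameters(Ef0 = 1, EfEps = 10, Enf = 0.5, k0 = 2, M = 5)
  cc <- constitutive_constants()
  ml <- frpe:::material_list(params, cc, solver_settings())
  set.seed(4)
  for (i in 1:10) {
    Fm <- diag(2) + matrix(runif(4, -0.08, 0.08), 2, 2)
    Fth <- 1 + runif(1, -0.08, 0.08)
    p <- runif(1, 0, 0.2)
    sd <- stress_decomposition(params, cc, strain_state(Fm, Fth, cc$e0), p)
    sc <- as.numeric(frpe:::cpp_point_stress(Fm, Fth, p, ml))
    expect_equal(unname(sd$sigma_t), sc, tolerance = 1e-12)
  }
})

test_that("parameter and constant constructors enforce their invariants", {
  expect_error(frpe_parameters(Enf = 0), "positive")
  expect_error(frpe_parameters(Ef0 = -1), "non-negative")
  expect_error(frpe_parameters(k0 = Inf), "finite")
  expect_error(constitutive_constants(nu_nf = 0.5), "0.5")
  expect_error(strain_state(matrix(c(0, 0, 0, 0), 2, 2), 1), "degenerate")
  # void ratio derived from the Jacobian: e = J (1 + e0) - 1
  st <- strain_state(diag(c(0.95, 0.95)), 0.95, e0 = 4)
  expect_equal(st$e, 0.95^3 * 5 - 1)
})
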