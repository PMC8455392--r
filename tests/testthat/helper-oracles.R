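# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written without reusing the package's own implementation
# paths, so that agreement is evidence, not tautology.

# Closed-form series solution for ramp-hold confined compression of a
# biphasic layer (drained at the loaded surface, sealed at the base):
# surface total stress under a displacement ramp of rate V0 over [0, t0].
# Derived by eigenfunction expansion of the solid-displacement diffusion
# equation u_t = c u_zz with prescribed boundary displacement.
terzaghi_ramphold <- function(t, h, HA, k, V0, t0, nterms = 500) {
  c_v <- HA * k
  n <- seq_len(nterms)
  lam <- (n * pi / h)^2 * c_v
  coef <- 2 / (n^2 * pi^2)
  vapply(t, function(tt) {
    if (tt <= t0) {
      HA * V0 * tt / h + (V0 * h / k) * sum(coef * (1 - exp(-lam * tt)))
    } else {
      HA * V0 * t0 / h + (V0 * h / k) *
        sum(coef * (1 - exp(-lam * t0)) * exp(-lam * (tt - t0)))
    }
  }, numeric(1))
}

# Independent Nystrom solution of the bonded-layer flat-punch problem:
# trapezoid quadrature (instead of Gauss-Legendre) and direct numerical
# kernel integration (instead of the package's spline cache).
hayes_kappa_independent <- function(chi, nu, n = 61) {
  k1 <- 3 - 4 * nu
  Wfun <- function(x) {
    num <- k1 * (1 - exp(-4 * x)) - 4 * x * exp(-2 * x)
    den <- k1 * (1 + exp(-4 * x)) + (k1^2 + 1 + 4 * x^2) * exp(-2 * x)
    ifelse(x == 0, 0, num / den)
  }
  kern <- function(u) {
    vapply(u, function(ui)
      integrate(function(x) (Wfun(x / chi) - 1) * cos(x * ui), 0,
                max(12, 12 * chi), rel.tol = 1e-10, subdivisions = 600L)$value,
      numeric(1))
  }
  t <- seq(0, 1, length.out = n)
  w <- rep(1 / (n - 1), n); w[c(1, n)] <- w[c(1, n)] / 2
  Km <- matrix(kern(as.vector(abs(outer(t, t, "-")))), n, n) +
    matrix(kern(as.vector(outer(t, t, "+"))), n, n)
  A <- diag(n) + (1 / pi) * sweep(Km, 2, w, "*")
  H <- solve(A, rep(1, n))
  sum(w * H)
}

draw_log_params_test <- function(group, model)
  frpe:::draw_log_params(group, model)

perturb_and_seed <- function(p, seed, frac = 0.5) {
  set.seed(seed)
  perturb_params(p, frac)
}

# multiplicative +/- `frac` perturbation of an FRPE parameter set
perturb_params <- function(p, frac = 0.5) {
  fac <- runif(5, 1 - frac, 1 + frac)
  frpe_parameters(Ef0 = p$Ef0 * fac[1], EfEps = p$EfEps * fac[2],
                  Enf = p$Enf * fac[3], k0 = p$k0 * fac[4], M = p$M * fac[5])
}

# reference ground-truth parameter set used across recovery tests
truth_params <- function() frpe_parameters(Ef0 = 0.9, EfEps = 40, Enf = 0.7,
                                           k0 = 2, M = 10)

# lazily-built shared fixtures (forward simulations are the expensive part)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# noiseless coarse relaxation-only synthetic experiment at truth_params()
noiseless_experiment <- function() {
  fixture("noiseless_exp", function() {
    generate_experiment(truth_params(), sample_geometry(),
                        indentation_protocol(freqs = NULL),
                        noise_model(force_noise = 0), resolution = "coarse")
  })
}

# synthetic sinusoidal "experiment" with exact known amplitudes and lag;
# returns the experiment plus the constructed ground truth
make_sin_experiment <- function(freqs, lag_deg, amp_ratio = 5,
                                samples_per_cycle = 50, n_cycles = 4,
                                geometry = sample_geometry()) {
  mean_disp <- 0.2 * geometry$h
  amp_disp <- 0.02 * geometry$h
  t_off <- 0
  dyn <- do.call(rbind, lapply(freqs, function(f) {
    tt <- t_off + seq(0, n_cycles / f, by = 1 / (samples_per_cycle * f))
    ph <- 2 * pi * f * (tt - t_off)
    d <- data.frame(
      time_s = tt,
      displacement_mm = mean_disp + amp_disp * sin(ph),
      force_N = 0.1 + amp_ratio * amp_disp * sin(ph + lag_deg * pi / 180),
      freq = f)
    t_off <<- tt[length(tt)] + 1
    d
  }))
  steps <- data.frame(step = 1:4, t_start = 0:3, t_peak = 0:3 + 0.1,
                      t_end = 1:4, strain = (1:4) * 0.05,
                      strain_pre = (0:3) * 0.05)
  rel <- data.frame(time_s = seq(0, 4, 0.1), displacement_mm = 0, force_N = 0)
  indentation_experiment(rel, steps, geometry, dynamic = dyn)
}
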