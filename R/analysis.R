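# Extraction of elastic (equilibrium, instantaneous) and dynamic viscoelastic
# (dynamic modulus, phase difference) properties from indentation records.

#' Indentation experiment record
#'
#' Time-stamped force/displacement records of a multi-step stress-relaxation
#' indentation test with an optional sinusoidal (dynamic) phase, plus the
#' specimen geometry and the step/frequency annotations needed for analysis.
#'
#' @param relaxation data frame with columns `time_s`, `displacement_mm`
#'   (total indenter displacement, positive in compression), `force_N`.
#' @param steps data frame annotating the stress-relaxation steps: columns
#'   `step`, `t_start` (ramp onset), `t_peak` (ramp end), `t_end` (hold end),
#'   `strain` (nominal strain after the step, relative to the pre-stress
#'   point), `strain_pre` (strain before the step).
#' @param geometry a [sample_geometry()].
#' @param dynamic optional data frame with columns `time_s`,
#'   `displacement_mm`, `force_N`, `freq` (Hz block tag).
#' @param prestrain nominal strain at the pre-stress seating point.
#' @param nu_eq assumed Poisson's ratio for the (drained) equilibrium
#'   response.
#' @param nu_inst assumed Poisson's ratio for the instantaneous and dynamic
#'   (short-time, incompressible) response.
#' @return Object of class `indentation_experiment`.
#' @export
indentation_experiment <- function(relaxation, steps, geometry,
                                   dynamic = NULL, prestrain = 0,
                                   nu_eq = 0.42, nu_inst = 0.5) {
  stopifnot(inherits(geometry, "sample_geometry"))
  req <- c("time_s", "displacement_mm", "force_N")
  stopifnot(all(req %in% names(relaxation)))
  if (is.unsorted(relaxation$time_s))
    stop("relaxation series must be time-sorted", call. = FALSE)
  sreq <- c("step", "t_start", "t_peak", "t_end", "strain", "strain_pre")
  stopifnot(all(sreq %in% names(steps)))
  if (!is.null(dynamic)) {
    stopifnot(all(c(req, "freq") %in% names(dynamic)))
    if (any(!is.finite(dynamic$freq)) || any(dynamic$freq <= 0))
      stop("dynamic blocks must carry positive frequency tags", call. = FALSE)
  }
  structure(list(relaxation = relaxation, steps = steps, dynamic = dynamic,
                 geometry = geometry, prestrain = prestrain,
                 nu_eq = nu_eq, nu_inst = nu_inst),
            class = "indentation_experiment")
}

#' @export
print.indentation_experiment <- function(x, ...) {
  cat(sprintf("indentation experiment: %d relaxation steps, %s dynamic blocks, prestrain %.3f\n",
              nrow(x$steps),
              if (is.null(x$dynamic)) "no" else length(unique(x$dynamic$freq)),
              x$prestrain))
  invisible(x)
}

nominal_stress <- function(force, geometry) force / (pi * geometry$a^2)

# end-of-hold force and plateau diagnostic for one step
step_equilibrium <- function(rel, st, window = 60, plateau_frac = 0.005) {
  hold <- rel[rel$time_s >= st$t_peak & rel$time_s <= st$t_end, ]
  f_end <- mean(hold$force_N[hold$time_s >= st$t_end - min(10, diff(range(hold$time_s)) / 4)])
  tail_w <- hold[hold$time_s >= st$t_end - window, ]
  if (nrow(tail_w) < 3)  # sparse (adaptive) grids: use the last few samples
    tail_w <- hold[max(1, nrow(hold) - 3):nrow(hold), ]
  pre <- rel$force_N[rel$time_s <= st$t_start]
  f_pre <- if (length(pre)) pre[length(pre)] else 0
  slope <- if (nrow(tail_w) >= 3) unname(coef(lm(force_N ~ time_s, tail_w))[2]) else NA
  dstep <- abs(max(hold$force_N) - f_end)
  plateau_ok <- is.finite(slope) && abs(slope) * 60 < plateau_frac * max(dstep, 1e-12)
  list(f_end = f_end, f_pre = f_pre, plateau_ok = plateau_ok, slope = slope)
}

#' Equilibrium modulus from a multi-step stress-relaxation record
#'
#' Converts the end-of-hold (relaxed) force of each step to nominal stress,
#' applies the Hayes thickness correction, and fits a least-squares line
#' through the corrected stress-strain points; the slope is the equilibrium
#' modulus `E_eq`.
#'
#' @param exp an [indentation_experiment()].
#' @return Object of class `elastic_fit` with `E_eq` (MPa), the per-step
#'   points, fit `r_squared`, residuals, and plateau diagnostics (a step that
#'   has not relaxed to the plateau criterion is flagged, not dropped).
#' @export
equilibrium_modulus <- function(exp) {
  stopifnot(inherits(exp, "indentation_experiment"))
  g <- exp$geometry
  eqs <- lapply(seq_len(nrow(exp$steps)), function(i)
    step_equilibrium(exp$relaxation, exp$steps[i, ]))
  strain <- exp$prestrain + exp$steps$strain
  stress <- nominal_stress(vapply(eqs, `[[`, 0, "f_end"), g)
  kap <- hayes_kappa(g$a / g$h, exp$nu_eq)
  corrected <- stress * pi * g$a * (1 - exp$nu_eq^2) / (2 * g$h * kap)
  fit <- lm(corrected ~ strain)
  plateau <- vapply(eqs, `[[`, TRUE, "plateau_ok")
  if (!all(plateau))
    warning("non-equilibrated hold(s): ", paste(which(!plateau), collapse = ", "),
            call. = FALSE)
  structure(list(E_eq = unname(coef(fit)[2]),
                 points = data.frame(strain = strain, stress = stress,
                                     corrected = corrected,
                                     plateau_ok = plateau),
                 r_squared = summary(fit)$r.squared,
                 residuals = unname(stats::residuals(fit))),
            class = "elastic_fit")
}

#' Instantaneous moduli from a multi-step stress-relaxation record
#'
#' The instantaneous modulus of each step is the Hayes-corrected ratio of the
#' peak stress increment (force at the end of the ramp minus pre-step force)
#' to the strain increment. A least-squares line of these per-step moduli
#' against the strain at step onset gives the initial instantaneous modulus
#' `E_inst0` (intercept) and the strain-dependent instantaneous modulus
#' `E_instEps` (slope).
#'
#' @param exp an [indentation_experiment()].
#' @return List of class `instantaneous_fit` with `E_inst0` (MPa),
#'   `E_instEps` (MPa per unit strain), per-step moduli and fit diagnostics.
#' @export
instantaneous_moduli <- function(exp) {
  stopifnot(inherits(exp, "indentation_experiment"))
  g <- exp$geometry
  rel <- exp$relaxation
  kap <- hayes_kappa(g$a / g$h, exp$nu_inst)
  n <- nrow(exp$steps)
  m <- numeric(n)
  for (i in seq_len(n)) {
    st <- exp$steps[i, ]
    ramp <- rel[rel$time_s >= st$t_start & rel$time_s <= st$t_peak + 1e-9, ]
    if (!nrow(ramp)) stop("step detection: no samples in ramp window", call. = FALSE)
    f_peak <- max(ramp$force_N)
    pre <- rel$force_N[rel$time_s < st$t_start]
    f_pre <- if (length(pre)) pre[length(pre)] else 0
    dsig <- nominal_stress(f_peak - f_pre, g)
    deps <- st$strain - st$strain_pre
    m[i] <- (dsig / deps) * pi * g$a * (1 - exp$nu_inst^2) / (2 * g$h * kap)
  }
  strain_on <- exp$prestrain + exp$steps$strain_pre
  fit <- lm(m ~ strain_on)
  structure(list(E_inst0 = unname(coef(fit)[1]),
                 E_instEps = unname(coef(fit)[2]),
                 points = data.frame(strain_onset = strain_on, modulus = m),
                 r_squared = summary(fit)$r.squared),
            class = "instantaneous_fit")
}

# complex amplitude of x(t) at frequency f over the largest whole number of
# cycles counted from the end of the record. The drive component is estimated
# jointly with an intercept and a linear trend (the residual relaxation
# drift): fitting them together keeps the trend removal from biasing the
# phase, which a detrend-then-project scheme does whenever the trend basis is
# not exactly orthogonal to the sinusoid on the sampled window.
phasor_at <- function(t, x, f, min_cycles = 1) {
  span <- t[length(t)] - t[1]
  ncyc <- floor(span * f + 1e-9)
  if (ncyc < min_cycles)
    stop("signal-quality error: fewer than ", min_cycles,
         " full cycles at ", f, " Hz", call. = FALSE)
  t1 <- t[length(t)] - ncyc / f
  keep <- t >= t1 - 1e-9
  tt <- t[keep]; xx <- x[keep]
  # drop the duplicated endpoint sample (exactly one period apart)
  if (abs((tt[length(tt)] - tt[1]) * f - ncyc) < 1e-6) {
    tt <- tt[-length(tt)]; xx <- xx[-length(xx)]
  }
  tc <- tt - mean(tt)                   # centred time for conditioning
  X <- cbind(1, tc, cos(2 * pi * f * tt), sin(2 * pi * f * tt))
  b <- qr.coef(qr(X), xx)
  # x ~ M sin(2 pi f t + phi):  M = |(bs, bc)|, phi = atan2(bc, bs)
  complex(modulus = sqrt(b[3]^2 + b[4]^2), argument = atan2(b[3], b[4]))
}

#' Dynamic modulus and phase difference at one drive frequency
#'
#' Extracts force and displacement amplitude and phase from the discrete
#' Fourier component at the drive frequency (whole cycles, linear detrend),
#' then forms the Hayes-corrected dynamic modulus from the stress/strain
#' amplitude ratio and the phase difference `phase(force) -
#' phase(displacement)` in degrees.
#'
#' @param exp an [indentation_experiment()] with a dynamic phase.
#' @param frequency drive frequency (Hz); must tag a block in the record.
#' @param min_cycles minimum whole cycles required in the record.
#' @return List of class `dynamic_point`: `frequency`, `E_dynamic` (MPa),
#'   `theta_dynamic` (degrees), amplitudes, and an `artifact` flag set when
#'   the raw phase difference is negative (reported unwrapped).
#' @export
dynamic_properties <- function(exp, frequency, min_cycles = 2) {
  stopifnot(inherits(exp, "indentation_experiment"))
  if (is.null(exp$dynamic)) stop("experiment has no dynamic phase", call. = FALSE)
  blk <- exp$dynamic[abs(exp$dynamic$freq - frequency) < 1e-9 * max(1, frequency), ]
  if (!nrow(blk))
    stop("no dynamic block at frequency ", frequency, " Hz", call. = FALSE)
  g <- exp$geometry
  zf <- phasor_at(blk$time_s, blk$force_N, frequency, min_cycles)
  zd <- phasor_at(blk$time_s, blk$displacement_mm, frequency, min_cycles)
  amp_ratio <- Mod(zf) / Mod(zd)         # N per mm
  stress_over_strain <- amp_ratio * g$h / (pi * g$a^2)
  E_dyn <- hayes_modulus(stress_over_strain, g, exp$nu_inst)
  theta <- (Arg(zf) - Arg(zd)) * 180 / pi
  theta <- ((theta + 180) %% 360) - 180
  artifact <- theta < 0 || theta >= 90
  structure(list(frequency = frequency, E_dynamic = E_dyn,
                 theta_dynamic = theta, artifact = artifact,
                 force_amp_N = Mod(zf), disp_amp_mm = Mod(zd)),
            class = "dynamic_point")
}

#' Full property extraction from an indentation experiment
#'
#' Runs [equilibrium_modulus()], [instantaneous_moduli()] and, when a dynamic
#' phase is present, [dynamic_properties()] at every tagged frequency.
#'
#' @param exp an [indentation_experiment()].
#' @return List of class `indentation_properties` with elements `elastic`
#'   (E_eq, E_inst0, E_instEps and diagnostics) and `dynamic` (data frame of
#'   E_dynamic / theta_dynamic per frequency).
#' @export
analyze_experiment <- function(exp) {
  eq <- equilibrium_modulus(exp)
  inst <- instantaneous_moduli(exp)
  dyn <- NULL
  if (!is.null(exp$dynamic)) {
    fr <- sort(unique(exp$dynamic$freq))
    dyn <- do.call(rbind, lapply(fr, function(f) {
      d <- dynamic_properties(exp, f)
      data.frame(freq = f, E_dynamic = d$E_dynamic,
                 theta_dynamic = d$theta_dynamic, artifact = d$artifact)
    }))
  }
  structure(list(elastic = list(E_eq = eq$E_eq, E_inst0 = inst$E_inst0,
                                E_instEps = inst$E_instEps,
                                eq_fit = eq, inst_fit = inst),
                 dynamic = dyn),
            class = "indentation_properties")
}

#' @export
print.indentation_properties <- function(x, ...) {
  cat(sprintf("E_eq = %.3f MPa, E_inst0 = %.3f MPa, E_instEps = %.2f MPa\n",
              x$elastic$E_eq, x$elastic$E_inst0, x$elastic$E_instEps))
  if (!is.null(x$dynamic)) {
    cat("dynamic properties:\n")
    print(x$dynamic, row.names = FALSE)
  }
  invisible(x)
}
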