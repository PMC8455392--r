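#' Loading protocol for indentation simulation
#'
#' An ordered sequence of displacement-controlled segments. Strains are
#' nominal (indenter displacement as a fraction of thickness), positive in
#' compression.
#'
#' @param segments data frame with columns `type` (`"ramp"`, `"hold"` or
#'   `"sin"`), `target` (end strain for ramps; centre strain for sinusoids),
#'   `amplitude` (sinusoid strain amplitude, 0 otherwise), `freq` (Hz,
#'   sinusoids), `duration` (s).
#' @return Object of class `loading_protocol`.
#' @export
loading_protocol <- function(segments) {
  req <- c("type", "target", "amplitude", "freq", "duration")
  stopifnot(is.data.frame(segments), all(req %in% names(segments)))
  if (!all(segments$type %in% c("ramp", "hold", "sin")))
    stop("segment type must be ramp, hold or sin", call. = FALSE)
  if (any(segments$duration <= 0))
    stop("segment durations must be positive", call. = FALSE)
  peak <- segments$target + segments$amplitude
  if (any(peak < 0) || any(peak > 0.25))
    stop("protocol strains must stay within [0, 0.25]", call. = FALSE)
  structure(segments, class = c("loading_protocol", "data.frame"))
}

#' Multi-step stress-relaxation + dynamic sinusoidal indentation protocol
#'
#' The standard cartilage characterization protocol: a contact-seating
#' pre-stress, four stress-relaxation steps of 5\% strain each with 15-minute
#' holds, and a sinusoidal sweep of 2\% strain amplitude at eight frequencies
#' from 0.005 to 1 Hz.
#'
#' The pre-stress phase is handled separately by the solver (it is
#' stress-targeted, see [simulate_indentation_protocol()]); the segments
#' returned here are the strains applied on top of the pre-strain.
#'
#' @param n_steps number of stress-relaxation steps.
#' @param step_strain strain increment per step.
#' @param hold_s relaxation hold per step (s).
#' @param ramp_s ramp duration per step (s).
#' @param freqs sinusoid frequencies (Hz); `NULL` for no dynamic phase.
#' @param amplitude sinusoid strain amplitude.
#' @param n_cycles cycles per frequency block.
#' @return A [loading_protocol()].
#' @export
indentation_protocol <- function(n_steps = 4, step_strain = 0.05,
                                 hold_s = 900, ramp_s = 0.5,
                                 freqs = c(0.005, 0.05, 0.1, 0.25, 0.5,
                                           0.625, 0.833, 1),
                                 amplitude = 0.02, n_cycles = 4) {
  seg <- list()
  for (i in seq_len(n_steps)) {
    eps <- i * step_strain
    seg[[length(seg) + 1L]] <- data.frame(type = "ramp", target = eps,
                                          amplitude = 0, freq = NA_real_,
                                          duration = ramp_s)
    seg[[length(seg) + 1L]] <- data.frame(type = "hold", target = eps,
                                          amplitude = 0, freq = NA_real_,
                                          duration = hold_s)
  }
  eps_end <- n_steps * step_strain
  for (f in freqs) {
    seg[[length(seg) + 1L]] <- data.frame(type = "sin", target = eps_end,
                                          amplitude = amplitude, freq = f,
                                          duration = n_cycles / f)
  }
  loading_protocol(do.call(rbind, seg))
}

#' Solver settings for the biphasic finite-element solver
#'
#' @param n_ramp time increments per ramp segment.
#' @param dt_hold0 initial time increment in a hold (s).
#' @param hold_growth geometric growth factor of hold increments.
#' @param steps_per_cycle time increments per sinusoid cycle.
#' @param newton_tol relative Newton increment tolerance.
#' @param max_iter maximum Newton iterations per increment.
#' @param max_bisect maximum time-step bisection depth on non-convergence.
#' @param kinematics `"finite"` (default) or `"small"` strain kinematics.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(n_ramp = 3, dt_hold0 = 1, hold_growth = 2,
                            steps_per_cycle = 48, newton_tol = 1e-9,
                            max_iter = 25, max_bisect = 8,
                            kinematics = c("finite", "small")) {
  kinematics <- match.arg(kinematics)
  stopifnot(n_ramp >= 1, dt_hold0 > 0, hold_growth > 1, steps_per_cycle >= 8,
            newton_tol > 0, max_iter >= 1)
  structure(list(n_ramp = n_ramp, dt_hold0 = dt_hold0,
                 hold_growth = hold_growth, steps_per_cycle = steps_per_cycle,
                 newton_tol = newton_tol, max_iter = max_iter,
                 max_bisect = max_bisect, kinematics = kinematics),
            class = "solver_settings")
}

# expand one protocol segment into (time, strain) samples, excluding t0
segment_grid <- function(seg, t0, eps0, settings) {
  if (seg$type == "ramp") {
    tt <- t0 + seq_len(settings$n_ramp) / settings$n_ramp * seg$duration
    ee <- eps0 + (seg$target - eps0) * (tt - t0) / seg$duration
  } else if (seg$type == "hold") {
    dts <- settings$dt_hold0 * settings$hold_growth^(0:200)
    ct <- cumsum(dts)
    ct <- c(ct[ct < seg$duration], seg$duration)
    tt <- t0 + ct
    ee <- rep(seg$target, length(tt))
  } else { # sin
    n_cyc <- seg$duration * seg$freq
    nt <- max(2L, round(settings$steps_per_cycle * n_cyc))
    tt <- t0 + seq_len(nt) / nt * seg$duration
    ee <- seg$target + seg$amplitude * sin(2 * pi * seg$freq * (tt - t0))
  }
  list(t = tt, eps = ee)
}

# full (time, strain) path for a protocol, starting from (0, eps0)
protocol_grid <- function(protocol, settings, eps0 = 0) {
  t <- 0; eps <- eps0
  t0 <- 0; e0 <- eps0
  seg_id <- 0L
  seg_of <- integer(1)
  for (i in seq_len(nrow(protocol))) {
    g <- segment_grid(protocol[i, ], t0, e0, settings)
    t <- c(t, g$t); eps <- c(eps, g$eps)
    seg_of <- c(seg_of, rep(i, length(g$t)))
    t0 <- g$t[length(g$t)]; e0 <- g$eps[length(g$eps)]
  }
  list(time = t, strain = eps, segment = seg_of)
}
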