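# Inverse identification of the five FRPE parameters from the 2nd and 3rd
# stress-relaxation steps of an indentation experiment.

#' Coefficient of determination between simulated and measured series
#'
#' @param simulated,measured equal-length aligned numeric vectors.
#' @return `R^2 = 1 - SS_res / SS_tot`.
#' @export
goodness_of_fit <- function(simulated, measured) {
  if (length(simulated) != length(measured))
    stop("series must be equal-length and aligned", call. = FALSE)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0)
    stop("undefined R^2: measured series has zero variance", call. = FALSE)
  1 - sum((measured - simulated)^2) / ss_tot
}

#' Configuration of the FRPE parameter optimization
#'
#' @param lower,upper named bounds for `Ef0`, `EfEps`, `Enf` (MPa), `k0`
#'   (1e-15 m^4/(N s)) and `M`. The defaults envelope values reported for
#'   human cartilage across osteoarthritis states.
#' @param n_starts number of multistart initial points.
#' @param n_refine number of best-scoring starts carried into full local
#'   optimization (the rest are screened by their initial objective only).
#' @param perturb multiplicative half-width of the multistart perturbation
#'   around the initial guess (0.5 = +/- 50\%).
#' @param seed integer seed for the multistart draws.
#' @param weighting `"uniform"` or `"peak"` (ramp samples weighted 5x).
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol LM convergence tolerances.
#' @return Object of class `optimization_config`.
#' @export
optimization_config <- function(lower = c(Ef0 = 1e-6, EfEps = 0, Enf = 0.01,
                                          k0 = 1e-2, M = 0),
                                upper = c(Ef0 = 50, EfEps = 500, Enf = 5,
                                          k0 = 1e3, M = 25),
                                n_starts = 5, n_refine = 2, perturb = 0.5,
                                seed = 1L, weighting = c("uniform", "peak"),
                                max_iter = 20, ftol = 1e-10, ptol = 1e-8) {
  weighting <- match.arg(weighting)
  nm <- c("Ef0", "EfEps", "Enf", "k0", "M")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)),
            n_starts >= 1, n_refine >= 1, perturb >= 0)
  if (any(upper[nm] <= lower[nm]) || !all(is.finite(c(lower, upper))))
    stop("bounds must be finite with upper > lower", call. = FALSE)
  structure(list(lower = lower[nm], upper = upper[nm],
                 n_starts = as.integer(n_starts),
                 n_refine = as.integer(min(n_refine, n_starts)),
                 perturb = perturb, seed = as.integer(seed),
                 weighting = weighting, max_iter = as.integer(max_iter),
                 ftol = ftol, ptol = ptol),
            class = "optimization_config")
}

# parameter vector <-> optimizer coordinates (k0 in log10 space)
par_to_theta <- function(p) c(p$Ef0, p$EfEps, p$Enf, log10(p$k0), p$M)
theta_to_par <- function(th) frpe_parameters(Ef0 = th[1], EfEps = th[2],
                                             Enf = th[3], k0 = 10^th[4],
                                             M = th[5])

# fitting-window sample selection: by default every record sample of steps
# `use_steps` (ramps and holds) enters the residual -- the forward simulation,
# not the residual length, dominates the cost, and dense sampling averages
# measurement noise out of the estimator. A finite `holds_per_step` decimates
# holds to log-spaced times instead.
fit_window_index <- function(exp, use_steps = c(2, 3), holds_per_step = Inf) {
  rel <- exp$relaxation
  idx <- integer(0)
  for (i in use_steps) {
    st <- exp$steps[exp$steps$step == i, ]
    if (!nrow(st)) stop("fitting window: step ", i, " absent", call. = FALSE)
    ramp <- which(rel$time_s >= st$t_start & rel$time_s <= st$t_peak + 1e-9)
    hold <- which(rel$time_s > st$t_peak & rel$time_s <= st$t_end)
    if (length(hold) > holds_per_step) {
      # log-spaced target times: the relaxation decay carries its information
      # roughly uniformly in log time
      dur <- st$t_end - st$t_peak
      tq <- st$t_peak + dur * exp(seq(log(1e-3), 0, length.out = holds_per_step))
      th <- rel$time_s[hold]
      hold <- hold[unique(vapply(tq, function(x) which.min(abs(th - x)), 1L))]
    }
    idx <- c(idx, ramp, hold)
  }
  sort(unique(idx))
}

# forward simulation replaying the experiment's relaxation protocol through
# `max_step` steps, on a given mesh; returns a function of theta evaluating
# force at the requested record times (linear interpolation in time)
make_forward_force <- function(exp, mesh, constants, settings, max_step = 3) {
  steps <- exp$steps[exp$steps$step <= max_step, ]
  segs <- do.call(rbind, lapply(seq_len(nrow(steps)), function(i) {
    st <- steps[i, ]
    data.frame(type = c("ramp", "hold"), target = st$strain, amplitude = 0,
               freq = NA_real_,
               duration = c(st$t_peak - st$t_start, st$t_end - st$t_peak))
  }))
  protocol <- loading_protocol(segs)
  t_off <- steps$t_start[1]
  w0 <- -exp$prestrain * mesh$geometry$h
  function(theta, times) {
    p <- theta_to_par(theta)
    ps <- static_drained_solve(mesh, p, constants, w0, settings)
    sim <- simulate(mesh, p, constants, protocol, settings,
                    prestrain = exp$prestrain, state0 = ps$state)
    approx(sim$time_s + t_off, sim$force_N, xout = times, rule = 2)$y
  }
}

#' Discrepancy between simulation and experiment over steps 2-3
#'
#' Mean squared difference between simulated and measured indenter force over
#' the 2nd and 3rd stress-relaxation steps (ramps and holds), normalized by
#' the squared measured force range over that window.
#'
#' @param params [frpe_parameters()] to evaluate.
#' @param exp an [indentation_experiment()].
#' @param constants [constitutive_constants()].
#' @param settings [solver_settings()] for the forward model.
#' @param resolution mesh resolution for the forward model (`"coarse"`
#'   recommended during optimization).
#' @param mesh optional prebuilt mesh (overrides `resolution`).
#' @param window `"steps23"` (default) or `"equilibrium"` (end-of-hold
#'   plateaus of all steps only; exposes the loss of permeability
#'   identifiability without the transient).
#' @return Scalar normalized MSE (dimensionless).
#' @export
frpe_objective <- function(params, exp, constants = constitutive_constants(),
                           settings = solver_settings(),
                           resolution = "coarse", mesh = NULL,
                           window = c("steps23", "equilibrium")) {
  window <- match.arg(window)
  if (is.null(mesh)) mesh <- build_mesh(exp$geometry, resolution)
  rel <- exp$relaxation
  if (window == "steps23") {
    idx <- fit_window_index(exp, c(2, 3))
    max_step <- 3
  } else {
    idx <- integer(0)
    for (i in exp$steps$step) {
      st <- exp$steps[exp$steps$step == i, ]
      idx <- c(idx, which(rel$time_s >= st$t_end - 10 & rel$time_s <= st$t_end))
    }
    max_step <- max(exp$steps$step)
  }
  fwd <- make_forward_force(exp, mesh, constants, settings, max_step)
  meas <- rel$force_N[idx]
  rng <- diff(range(meas))
  if (rng <= 0) return(Inf)
  sim <- tryCatch(fwd(par_to_theta(params), rel$time_s[idx]),
                  error = function(e) NULL)
  if (is.null(sim)) return(1e6)
  mean((sim - meas)^2) / rng^2
}

#' Fit the five FRPE parameters to a stress-relaxation experiment
#'
#' Bounded multistart Levenberg-Marquardt minimization of the normalized
#' force discrepancy over the 2nd and 3rd stress-relaxation steps. `k0` is
#' optimized in log10 space. Starts are drawn around `init` with
#' multiplicative perturbations; all starts are screened by their initial
#' objective and the best `n_refine` are locally optimized.
#'
#' @param exp an [indentation_experiment()].
#' @param config an [optimization_config()].
#' @param init initial-guess [frpe_parameters()]; by default the geometric
#'   mid-point of the bounds.
#' @param constants,settings,resolution,mesh forward-model options, see
#'   [frpe_objective()].
#' @return Object of class `fit_result`: fitted `params`, `r_squared` over
#'   the fitting window, final `objective`, `converged` flag, number of
#'   forward evaluations, and the per-start screening table.
#' @export
fit_frpe <- function(exp, config = optimization_config(), init = NULL,
                     constants = constitutive_constants(),
                     settings = solver_settings(),
                     resolution = "coarse", mesh = NULL) {
  stopifnot(inherits(exp, "indentation_experiment"))
  if (is.null(mesh)) mesh <- build_mesh(exp$geometry, resolution)
  if (is.null(init)) {
    lo <- config$lower; up <- config$upper
    gm <- sqrt(pmax(lo, 1e-8) * up)
    init <- frpe_parameters(Ef0 = gm["Ef0"], EfEps = gm["EfEps"],
                            Enf = gm["Enf"], k0 = gm["k0"],
                            M = (lo["M"] + up["M"]) / 2)
  }
  rel <- exp$relaxation
  idx <- fit_window_index(exp, c(2, 3))
  meas <- rel$force_N[idx]
  tms <- rel$time_s[idx]
  rng <- diff(range(meas))
  n_eval <- 0L
  if (rng <= 0) {
    return(structure(list(params = init, r_squared = NA_real_,
                          objective = Inf, converged = FALSE,
                          n_eval = 0L, starts = NULL,
                          message = "unidentifiable: flat force record"),
                     class = "fit_result"))
  }
  wts <- rep(1, length(idx))
  if (config$weighting == "peak") {
    for (i in c(2, 3)) {
      st <- exp$steps[exp$steps$step == i, ]
      wts[tms >= st$t_start & tms <= st$t_peak + 1e-9] <- 5
    }
  }
  swts <- sqrt(wts / mean(wts))
  fwd <- make_forward_force(exp, mesh, constants, settings, 3)
  resid_fn <- function(theta) {
    n_eval <<- n_eval + 1L
    sim <- tryCatch(fwd(theta, tms), error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim))) return(rep(1e3, length(meas)))
    (sim - meas) / rng * swts
  }

  lo_th <- c(config$lower[c("Ef0", "EfEps", "Enf")],
             log10(config$lower["k0"]), config$lower["M"])
  up_th <- c(config$upper[c("Ef0", "EfEps", "Enf")],
             log10(config$upper["k0"]), config$upper["M"])
  th0 <- pmin(pmax(par_to_theta(init), lo_th), up_th)

  # seeded multistart draws (restore the caller's RNG state afterwards)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  starts <- matrix(rep(th0, config$n_starts), nrow = config$n_starts, byrow = TRUE)
  if (config$n_starts > 1) {
    for (s in 2:config$n_starts) {
      fac <- runif(5, 1 - config$perturb, 1 + config$perturb)
      th <- th0
      th[c(1, 2, 3, 5)] <- th0[c(1, 2, 3, 5)] * fac[c(1, 2, 3, 5)]
      th[4] <- th0[4] + log10(fac[4])  # multiplicative in k0
      starts[s, ] <- pmin(pmax(th, lo_th), up_th)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  score <- apply(starts, 1, function(th) {
    r <- resid_fn(th)
    mean((r / swts)^2)
  })
  ord <- order(score)
  best <- NULL
  for (s in ord[seq_len(config$n_refine)]) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[s, ], lower = lo_th, upper = up_th,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = config$max_iter, ftol = config$ftol,
                             ptol = config$ptol))),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- mean((stats::residuals(fit) / swts)^2)
    if (is.null(best) || obj < best$obj)
      best <- list(theta = coef(fit), obj = obj, info = fit$info)
  }
  if (is.null(best)) {
    s0 <- ord[1]
    best <- list(theta = starts[s0, ], obj = score[s0], info = 0L)
  }
  sim_best <- fwd(best$theta, tms)
  r2 <- goodness_of_fit(sim_best, meas)
  converged <- best$info %in% 1:4 && is.finite(best$obj)
  structure(list(params = theta_to_par(best$theta), r_squared = r2,
                 objective = best$obj, converged = converged,
                 n_eval = n_eval,
                 starts = data.frame(start = seq_len(config$n_starts),
                                     objective = score),
                 message = sprintf("LM info %d after %d forward evaluations",
                                   best$info, n_eval)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("FRPE fit: objective %.3g, R^2 = %.4f, %s\n", x$objective,
              x$r_squared, if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Write a fit result to JSON
#'
#' @param fit a `fit_result` from [fit_frpe()].
#' @param path output file.
#' @export
write_fit_result <- function(fit, path) {
  obj <- list(params = unclass(fit$params), r_squared = fit$r_squared,
              objective = fit$objective, converged = fit$converged,
              n_eval = fit$n_eval, message = fit$message)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
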