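# Synthetic specimens, indentation experiments and cohorts with the
# statistical structure the analysis pipeline assumes: log-normal FRPE
# parameters per osteoarthritis (OA) severity group, a shared knee-level
# random effect, and measurement noise on the recorded signals.

#' Measurement noise model for synthetic indentation records
#'
#' @param force_noise multiplicative Gaussian force noise (fraction of the
#'   instantaneous force).
#' @param disp_jitter additive displacement jitter (mm).
#' @param rate_relax sampling rate of the relaxation record (Hz).
#' @param samples_per_cycle sampling density of the dynamic blocks.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(force_noise = 0.01, disp_jitter = 0,
                        rate_relax = 10, samples_per_cycle = 50) {
  stopifnot(force_noise >= 0, disp_jitter >= 0, rate_relax > 0,
            samples_per_cycle >= 8)
  structure(list(force_noise = force_noise, disp_jitter = disp_jitter,
                 rate_relax = rate_relax,
                 samples_per_cycle = samples_per_cycle),
            class = "noise_model")
}

#' Group-level distribution model of the FRPE parameters
#'
#' Log-normal location/scale per OA progression group for each of the five
#' FRPE parameters, plus a within-knee correlation implemented as a shared
#' knee-level random effect on the log scale. The default group medians
#' encode the qualitative severe-OA pattern reported for human knee
#' cartilage: a near-total loss of fibril pre-tension (tiny `Ef0`), reduced
#' `Enf` and `M`, and strongly increased permeability `k0` relative to
#' normal tissue, with normal and moderate OA largely similar. The numeric
#' values are package conventions for typical human femoral condyle
#' magnitudes, not measurements.
#'
#' @param medians named list of per-group median parameter vectors.
#' @param sigmas named list of per-group log-scale SD vectors.
#' @param knee_rho within-knee correlation of log-parameters, in `[0, 1)`.
#' @return Object of class `group_parameter_model`.
#' @export
group_parameter_model <- function(
    medians = list(
      normal   = c(Ef0 = 0.9,   EfEps = 40, Enf = 0.7,  k0 = 2,   M = 10),
      moderate = c(Ef0 = 0.95,  EfEps = 35, Enf = 0.65, k0 = 2.4, M = 9),
      severe   = c(Ef0 = 1e-5,  EfEps = 8,  Enf = 0.25, k0 = 12,  M = 2)),
    sigmas = list(
      normal   = c(Ef0 = 0.35, EfEps = 0.35, Enf = 0.35, k0 = 0.35, M = 0.3),
      moderate = c(Ef0 = 0.35, EfEps = 0.35, Enf = 0.35, k0 = 0.35, M = 0.3),
      severe   = c(Ef0 = 1.0,  EfEps = 0.5,  Enf = 0.5,  k0 = 0.5,  M = 0.4)),
    knee_rho = 0.6) {
  groups <- c("normal", "moderate", "severe")
  nm <- c("Ef0", "EfEps", "Enf", "k0", "M")
  stopifnot(all(groups %in% names(medians)), all(groups %in% names(sigmas)),
            knee_rho >= 0, knee_rho < 1)
  for (g in groups) {
    stopifnot(all(nm %in% names(medians[[g]])), all(nm %in% names(sigmas[[g]])))
    if (any(sigmas[[g]][nm] < 0) || any(medians[[g]][nm] <= 0))
      stop("medians must be positive and scales non-negative", call. = FALSE)
  }
  structure(list(medians = lapply(medians, function(x) x[nm]),
                 sigmas = lapply(sigmas, function(x) x[nm]),
                 knee_rho = knee_rho),
            class = "group_parameter_model")
}

# log-normal draw with optional shared knee-level standard-normal vector
draw_log_params <- function(group, model, z_knee = NULL) {
  mu <- log(model$medians[[group]])
  sg <- model$sigmas[[group]]
  z_i <- rnorm(5)
  z <- if (is.null(z_knee)) z_i else
    sqrt(model$knee_rho) * z_knee + sqrt(1 - model$knee_rho) * z_i
  exp(mu + sg * z)
}

#' Draw one FRPE parameter set from a group distribution
#'
#' @param group `"normal"`, `"moderate"` or `"severe"`.
#' @param model a [group_parameter_model()].
#' @return [frpe_parameters()] drawn from the group's log-normal
#'   distributions (uses the current RNG state; seed with [set.seed()]).
#' @export
draw_parameters <- function(group = c("normal", "moderate", "severe"),
                            model = group_parameter_model()) {
  group <- match.arg(group)
  v <- draw_log_params(group, model)
  frpe_parameters(Ef0 = v[["Ef0"]], EfEps = v[["EfEps"]], Enf = v[["Enf"]],
                  k0 = v[["k0"]], M = v[["M"]])
}

# step annotation table for a relaxation protocol (ramp/hold pairs)
protocol_step_table <- function(protocol) {
  ramps <- which(protocol$type == "ramp")
  t0 <- c(0, cumsum(protocol$duration))
  steps <- data.frame(step = seq_along(ramps),
                      t_start = t0[ramps],
                      t_peak = t0[ramps] + protocol$duration[ramps],
                      t_end = NA_real_, strain = protocol$target[ramps],
                      strain_pre = c(0, protocol$target[ramps[-length(ramps)]]))
  for (i in seq_along(ramps)) {
    nxt <- ramps[i] + 1L
    steps$t_end[i] <- if (nxt <= nrow(protocol) && protocol$type[nxt] == "hold")
      t0[nxt] + protocol$duration[nxt] else steps$t_peak[i]
  }
  steps
}

#' Generate a synthetic indentation experiment
#'
#' Runs the forward FRPE model through the full indentation protocol
#' (pre-stress seek, stress-relaxation steps, dynamic sweep), resamples the
#' record at the noise model's rates, applies measurement noise, and
#' annotates steps and frequency blocks. The generating parameters are kept
#' in the `truth` attribute for recovery scoring.
#'
#' @param params ground-truth [frpe_parameters()].
#' @param geometry [sample_geometry()].
#' @param protocol an [indentation_protocol()].
#' @param noise a [noise_model()].
#' @param constants,settings,resolution forward-model options.
#' @return An [indentation_experiment()] (uses the current RNG state for the
#'   noise; seed with [set.seed()]).
#' @export
generate_experiment <- function(params, geometry = sample_geometry(),
                                protocol = indentation_protocol(),
                                noise = noise_model(),
                                constants = constitutive_constants(),
                                settings = solver_settings(),
                                resolution = "coarse") {
  mesh <- build_mesh(geometry, resolution)
  sim <- simulate_indentation_protocol(params, geometry, constants, protocol,
                                       settings, mesh = mesh)
  prestrain <- attr(sim, "prestrain")
  t0 <- c(0, cumsum(protocol$duration))
  relax_idx <- which(protocol$type != "sin")
  t_relax_end <- if (length(relax_idx)) max(t0[relax_idx + 1L]) else 0

  # relaxation phase: uniform resampling
  tr <- seq(0, t_relax_end, by = 1 / noise$rate_relax)
  rel <- data.frame(
    time_s = tr,
    displacement_mm = approx(sim$time_s, sim$displacement_mm, tr, rule = 2)$y,
    force_N = approx(sim$time_s, sim$force_N, tr, rule = 2)$y)
  if (noise$force_noise > 0)
    rel$force_N <- rel$force_N * (1 + noise$force_noise * rnorm(nrow(rel)))
  if (noise$disp_jitter > 0)
    rel$displacement_mm <- rel$displacement_mm + noise$disp_jitter * rnorm(nrow(rel))

  # dynamic phase: per-block resampling at fixed samples per cycle
  dyn <- NULL
  sin_idx <- which(protocol$type == "sin")
  if (length(sin_idx)) {
    dyn <- do.call(rbind, lapply(sin_idx, function(i) {
      f <- protocol$freq[i]
      tt <- seq(t0[i], t0[i + 1L], by = 1 / (noise$samples_per_cycle * f))
      d <- data.frame(
        time_s = tt,
        displacement_mm = approx(sim$time_s, sim$displacement_mm, tt, rule = 2)$y,
        force_N = approx(sim$time_s, sim$force_N, tt, rule = 2)$y,
        freq = f)
      if (noise$force_noise > 0)
        d$force_N <- d$force_N * (1 + noise$force_noise * rnorm(nrow(d)))
      if (noise$disp_jitter > 0)
        d$displacement_mm <- d$displacement_mm + noise$disp_jitter * rnorm(nrow(d))
      d
    }))
  }
  steps <- protocol_step_table(protocol)
  out <- indentation_experiment(rel, steps, geometry, dynamic = dyn,
                                prestrain = prestrain)
  attr(out, "truth") <- params
  out
}

#' Cohort specification
#'
#' @param n_normal,n_moderate,n_severe group sizes; the defaults mirror a
#'   35-specimen human femoral condyle cohort (17 normal, 15 moderate OA,
#'   3 severe OA).
#' @param model a [group_parameter_model()].
#' @param geometry [sample_geometry()] shared by all specimens.
#' @param pair_prob probability that a knee contributes two samples (medial
#'   and lateral compartments).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 17, n_moderate = 15, n_severe = 3,
                        model = group_parameter_model(),
                        geometry = sample_geometry(), pair_prob = 0.6) {
  stopifnot(n_normal >= 0, n_moderate >= 0, n_severe >= 0,
            pair_prob >= 0, pair_prob <= 1)
  structure(list(n_normal = n_normal, n_moderate = n_moderate,
                 n_severe = n_severe, model = model, geometry = geometry,
                 pair_prob = pair_prob),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws ground-truth FRPE parameters for every specimen (grouped by OA
#' severity, with a shared knee-level random effect), assigns knees, OARSI
#' grades and compartments, and optionally generates the full indentation
#' experiment for each specimen.
#'
#' OARSI grades are drawn within each group's defining range (normal: grades
#' 0-1, mostly 1; moderate: grades 2-3, mostly 2; severe: grade 4). Knees may
#' straddle groups, as in real cohorts where the two compartments of one knee
#' can be graded differently.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param experiments logical; generate indentation records (`FALSE` returns
#'   ground truth and design only, which is much faster).
#' @param ... passed to [generate_experiment()] (protocol, noise, settings,
#'   resolution).
#' @return Object of class `synthetic_cohort`: `samples` data frame
#'   (sample/knee/compartment/OARSI/group and ground-truth parameters as
#'   columns `Ef0 ... M`), and `experiments` (list, possibly `NULL`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            experiments = FALSE, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  groups <- rep(c("normal", "moderate", "severe"),
                c(spec$n_normal, spec$n_moderate, spec$n_severe))
  n <- length(groups)
  if (n == 0) stop("empty cohort", call. = FALSE)
  ord <- sample.int(n)   # shuffle so knees can straddle groups
  groups <- groups[ord]
  knee <- integer(n)
  comp <- character(n)
  kid <- 0L
  i <- 1L
  while (i <= n) {
    kid <- kid + 1L
    if (i < n && runif(1) < spec$pair_prob) {
      knee[i] <- kid; knee[i + 1L] <- kid
      comp[i] <- "medial"; comp[i + 1L] <- "lateral"
      i <- i + 2L
    } else {
      knee[i] <- kid
      comp[i] <- sample(c("medial", "lateral"), 1)
      i <- i + 1L
    }
  }
  oarsi <- vapply(groups, function(g) switch(g,
    normal = sample(0:1, 1, prob = c(0.3, 0.7)),
    moderate = sample(2:3, 1, prob = c(0.8, 0.2)),
    severe = 4L), 0L)
  z_knee <- lapply(seq_len(kid), function(k) rnorm(5))
  pars <- t(vapply(seq_len(n), function(i)
    draw_log_params(groups[i], spec$model, z_knee[[knee[i]]]), numeric(5)))
  colnames(pars) <- c("Ef0", "EfEps", "Enf", "k0", "M")
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        knee_id = sprintf("K%02d", knee),
                        compartment = comp, oarsi = oarsi, group = groups,
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(pars))
  exps <- NULL
  if (experiments) {
    exps <- lapply(seq_len(n), function(i) {
      p <- frpe_parameters(Ef0 = pars[i, 1], EfEps = pars[i, 2],
                           Enf = pars[i, 3], k0 = pars[i, 4], M = pars[i, 5])
      generate_experiment(p, spec$geometry, ...)
    })
    names(exps) <- samples$sample_id
  }
  structure(list(samples = samples, experiments = exps, spec = spec,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tb <- table(x$samples$group)
  cat(sprintf("synthetic cohort: %d samples (%s), %d knees, experiments: %s\n",
              nrow(x$samples),
              paste(names(tb), tb, sep = "=", collapse = ", "),
              length(unique(x$samples$knee_id)),
              if (is.null(x$experiments)) "no" else "yes"))
  invisible(x)
}
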