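# Plain-text I/O: time-series records as CSV, parameters and metadata as
# YAML (units documented in the written files).

#' Write an indentation experiment to CSV + YAML
#'
#' Writes `<prefix>_relaxation.csv`, `<prefix>_dynamic.csv` (if present) and
#' `<prefix>_meta.yml` (geometry, step annotations, frequency tags, assumed
#' Poisson's ratios).
#'
#' @param exp an [indentation_experiment()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_experiment <- function(exp, prefix) {
  stopifnot(inherits(exp, "indentation_experiment"))
  write.csv(exp$relaxation, paste0(prefix, "_relaxation.csv"),
            row.names = FALSE)
  if (!is.null(exp$dynamic))
    write.csv(exp$dynamic, paste0(prefix, "_dynamic.csv"), row.names = FALSE)
  meta <- list(
    units = list(time = "s", displacement = "mm", force = "N",
                 geometry = "mm"),
    geometry = unclass(exp$geometry),
    prestrain = exp$prestrain,
    nu_eq = exp$nu_eq, nu_inst = exp$nu_inst,
    steps = lapply(seq_len(nrow(exp$steps)), function(i) as.list(exp$steps[i, ])),
    frequencies_hz = if (is.null(exp$dynamic)) NULL else
      sort(unique(exp$dynamic$freq)))
  yaml::write_yaml(meta, paste0(prefix, "_meta.yml"))
  invisible(prefix)
}

#' Read an indentation experiment written by [write_experiment()]
#'
#' @param prefix path prefix used when writing.
#' @return An [indentation_experiment()].
#' @export
read_experiment <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yml"))
  rel <- read.csv(paste0(prefix, "_relaxation.csv"))
  dyn_path <- paste0(prefix, "_dynamic.csv")
  dyn <- if (file.exists(dyn_path)) read.csv(dyn_path) else NULL
  steps <- do.call(rbind, lapply(meta$steps, as.data.frame))
  geom <- sample_geometry(h = meta$geometry$h, R = meta$geometry$R,
                          a = meta$geometry$a)
  indentation_experiment(rel, steps, geom, dynamic = dyn,
                         prestrain = meta$prestrain,
                         nu_eq = meta$nu_eq, nu_inst = meta$nu_inst)
}

#' Write FRPE parameters (and constants) as YAML
#'
#' One parameter per key with a units block, so files are self-describing.
#'
#' @param params [frpe_parameters()].
#' @param path output file.
#' @param constants optional [constitutive_constants()].
#' @export
write_parameters <- function(params, path, constants = NULL) {
  obj <- list(
    frpe = unclass(params),
    units = list(Ef0 = "MPa", EfEps = "MPa", Enf = "MPa",
                 k0 = "1e-15 m^4/(N s)", M = "dimensionless"))
  if (!is.null(constants)) obj$constants <- unclass(constants)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read FRPE parameters written by [write_parameters()]
#'
#' @param path YAML file.
#' @return List with `params` ([frpe_parameters()]) and `constants`
#'   ([constitutive_constants()] or `NULL`).
#' @export
read_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- obj$frpe
  params <- frpe_parameters(Ef0 = p$Ef0, EfEps = p$EfEps, Enf = p$Enf,
                            k0 = p$k0, M = p$M)
  constants <- if (!is.null(obj$constants))
    constitutive_constants(nu_nf = obj$constants$nu_nf, e0 = obj$constants$e0)
  list(params = params, constants = constants)
}

#' Write a simulation result as CSV
#'
#' @param sim a `simulation_result` from [simulate()].
#' @param path output file (columns `time_s`, `displacement_mm`, `force_N`).
#' @export
write_simulation <- function(sim, path) {
  write.csv(as.data.frame(sim)[c("time_s", "displacement_mm", "force_N")],
            path, row.names = FALSE)
  invisible(path)
}
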