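# Simulation driver: translates meshes, material parameters and loading
# protocols into calls to the compiled axisymmetric u-p solver.

material_list <- function(params, constants, settings, fibrils = TRUE) {
  list(Ef0 = params$Ef0, EfEps = params$EfEps, Enf = params$Enf,
       nu_nf = constants$nu_nf, k0_int = params$k0 * K0_UNIT, M = params$M,
       fibrils = fibrils,
       finite_strain = identical(settings$kinematics, "finite"))
}

# 0-based constrained/driven dof lists for a mesh and boundary configuration.
# Drainage: indentation = free draining on the surface outside the indenter
# and on the outer radius; sealed under the indenter, at the bone interface
# and on the axis. Confined compression = free draining through the (porous)
# top platen only, laterally confined.
bc_dofs <- function(mesh, mode = c("indentation", "confined"),
                    friction = c("bonded", "frictionless")) {
  mode <- match.arg(mode)
  friction <- match.arg(friction)
  nn <- nrow(mesh$nodes)
  rdof <- function(n) 2L * (n - 1L)
  zdof <- function(n) 2L * (n - 1L) + 1L
  pdof <- function(q) 2L * nn + (q - 1L)
  s <- mesh$sets
  if (mode == "indentation") {
    fix <- c(rdof(s$bottom), zdof(s$bottom), rdof(s$axis))
    if (friction == "bonded")
      fix <- c(fix, rdof(setdiff(s$contact, c(s$axis))))
    drive <- zdof(s$contact)
    fixp <- pdof(union(mesh$psets$top_free, mesh$psets$outer))
  } else {
    all_nodes <- seq_len(nn)
    fix <- c(rdof(all_nodes), zdof(s$bottom))
    drive <- zdof(setdiff(s$top, integer(0)))
    fixp <- pdof(mesh$psets$top)
  }
  list(fix = sort(unique(c(fix, fixp))), drive = sort(unique(drive)))
}

new_simulation_result <- function(time, displacement, force, segment = NULL,
                                  state = NULL, prestrain = 0, mesh = NULL) {
  out <- data.frame(time_s = time, displacement_mm = displacement,
                    force_N = force)
  if (!is.null(segment)) out$segment <- segment
  structure(out, class = c("simulation_result", "data.frame"),
            state = state, prestrain = prestrain, mesh_info = mesh)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("FRPE simulation: %d time points, t in [%g, %g] s, peak force %.4g N\n",
              nrow(x), min(x$time_s), max(x$time_s), max(x$force_N)))
  invisible(x)
}

# one transient path through the compiled solver
run_path <- function(mesh, params, constants, settings, bc, times, wvals, d0,
                     transient = TRUE, fibrils = TRUE) {
  ml <- material_list(params, constants, settings, fibrils)
  cpp_simulate_path(mesh$nodes, mesh$elems - 1L, mesh$pelems - 1L, mesh$np,
                    as.integer(bc$fix), as.integer(bc$drive), ml,
                    times, wvals, d0, transient,
                    settings$newton_tol, as.integer(settings$max_iter),
                    as.integer(settings$max_bisect))
}

# drained elastic equilibrium: pore pressure fixed to zero everywhere
static_drained_solve <- function(mesh, params, constants, w, settings,
                                 friction = "bonded", n_incr = 2,
                                 d0 = NULL, fibrils = TRUE,
                                 mode = "indentation") {
  bc <- bc_dofs(mesh, mode, friction)
  nn <- nrow(mesh$nodes)
  allp <- 2L * nn + seq_len(mesh$np) - 1L
  bc$fix <- sort(unique(c(bc$fix, allp)))
  if (is.null(d0)) d0 <- numeric(2L * nn + mesh$np)
  times <- seq(0, 1, length.out = n_incr + 1L)
  w0 <- if (length(bc$drive)) d0[bc$drive[1] + 1L] else 0
  wv <- seq(w0, w, length.out = n_incr + 1L)
  out <- run_path(mesh, params, constants, settings, bc, times, wv, d0,
                  transient = FALSE, fibrils = fibrils)
  list(force = out$force[length(out$force)], state = out$state)
}

# displacement-controlled seek of the contact pre-stress target: secant
# iteration on the drained equilibrium force (holding the pre-stress to
# equilibrium drains the tissue, so the drained solution is the steady state).
prestress_seek <- function(mesh, params, constants, settings,
                           prestress_MPa = 0.0125, friction = "bonded",
                           tol = 1e-5, max_iter = 40) {
  geom <- mesh$geometry
  f_target <- prestress_MPa * pi * geom$a^2
  E_guess <- params$Enf + params$Ef0
  kap <- hayes_kappa(geom$a / geom$h, constants$nu_nf)
  w1 <- -f_target * (1 - constants$nu_nf^2) / (2 * E_guess * geom$a * kap)
  w1 <- max(w1, -0.2 * geom$h)
  s1 <- static_drained_solve(mesh, params, constants, w1, settings, friction)
  f1 <- s1$force
  w2 <- w1 * f_target / max(f1, 1e-12)
  w2 <- max(min(w2, -1e-6 * geom$h), -0.22 * geom$h)
  for (i in seq_len(max_iter)) {
    s2 <- static_drained_solve(mesh, params, constants, w2, settings, friction,
                               d0 = s1$state)
    f2 <- s2$force
    if (abs(f2 - f_target) < tol * f_target)
      return(list(w = w2, state = s2$state, force = f2))
    dw <- if (abs(f2 - f1) > 1e-14) (f_target - f2) * (w2 - w1) / (f2 - f1) else 0
    dw <- sign(dw) * min(abs(dw), 0.05 * geom$h)
    w1 <- w2; f1 <- f2; s1 <- s2
    w2 <- max(min(w2 + dw, -1e-6 * geom$h), -0.24 * geom$h)
  }
  stop("protocol error: pre-stress target not reachable within geometric limits",
       call. = FALSE)
}

#' Simulate an indentation (or confined-compression) loading protocol
#'
#' Runs the axisymmetric biphasic FRPE finite-element model under a
#' displacement-controlled [loading_protocol()] and returns the reaction-force
#' history on the indenter.
#'
#' @param mesh a [build_mesh()] result.
#' @param params [frpe_parameters()].
#' @param constants [constitutive_constants()].
#' @param protocol a [loading_protocol()].
#' @param settings a [solver_settings()].
#' @param mode `"indentation"` (plane-ended indenter, free draining outside
#'   the contact and at the outer radius) or `"confined"` (laterally confined,
#'   draining through the porous top platen).
#' @param friction contact condition under the indenter: `"bonded"` or
#'   `"frictionless"`.
#' @param prestrain initial nominal strain already applied (with its drained
#'   equilibrium state) before the protocol starts; use
#'   [simulate_indentation_protocol()] for the stress-targeted seating phase.
#' @param state0 optional initial solver state (from a previous segment).
#' @param fibrils logical; set `FALSE` to disable the fibril network.
#' @return A `simulation_result` data frame with columns `time_s`,
#'   `displacement_mm` (total indenter displacement, positive in
#'   compression), `force_N` and `segment`.
#' @export
simulate <- function(mesh, params, constants = constitutive_constants(),
                     protocol, settings = solver_settings(),
                     mode = c("indentation", "confined"),
                     friction = c("bonded", "frictionless"),
                     prestrain = 0, state0 = NULL, fibrils = TRUE) {
  mode <- match.arg(mode)
  friction <- match.arg(friction)
  stopifnot(inherits(mesh, "frpe_mesh"), inherits(protocol, "loading_protocol"))
  if (inherits(params, "fit_result")) params <- params$params
  bc <- bc_dofs(mesh, mode, friction)
  nn <- nrow(mesh$nodes)
  if (is.null(state0)) state0 <- numeric(2L * nn + mesh$np)
  h <- mesh$geometry$h
  grid <- protocol_grid(protocol, settings, eps0 = 0)
  wv <- -(prestrain + grid$strain) * h
  out <- run_path(mesh, params, constants, settings, bc,
                  grid$time, wv, state0, transient = TRUE, fibrils = fibrils)
  new_simulation_result(grid$time, -wv, out$force, grid$segment,
                        state = out$state, prestrain = prestrain,
                        mesh = list(ne = nrow(mesh$elems)))
}

#' Simulate the full multi-step stress-relaxation + dynamic protocol
#'
#' Composes the standard experiment: a displacement-controlled seek of the
#' 12.5 kPa contact pre-stress (held to drained equilibrium), the multi-step
#' stress-relaxation phase, and the sinusoidal frequency sweep, as described
#' by [indentation_protocol()].
#'
#' @inheritParams simulate
#' @param geometry a [sample_geometry()]; a mesh is built at `resolution`.
#' @param resolution mesh resolution passed to [build_mesh()] (ignored when
#'   `mesh` is given).
#' @param mesh optional prebuilt mesh.
#' @param prestress_MPa contact pre-stress target (MPa); default 12.5 kPa.
#' @return A `simulation_result`; attribute `prestrain` holds the seated
#'   nominal strain at the pre-stress target.
#' @export
simulate_indentation_protocol <- function(params, geometry = sample_geometry(),
                                          constants = constitutive_constants(),
                                          protocol = indentation_protocol(),
                                          settings = solver_settings(),
                                          resolution = "medium",
                                          mesh = NULL,
                                          friction = c("bonded", "frictionless"),
                                          prestress_MPa = 0.0125) {
  friction <- match.arg(friction)
  if (is.null(mesh)) mesh <- build_mesh(geometry, resolution)
  ps <- prestress_seek(mesh, params, constants, settings, prestress_MPa,
                       friction)
  prestrain <- -ps$w / mesh$geometry$h
  simulate(mesh, params, constants, protocol, settings,
           mode = "indentation", friction = friction,
           prestrain = prestrain, state0 = ps$state)
}
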