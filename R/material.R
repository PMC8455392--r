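#' FRPE constituent parameter set
#'
#' Bundles the five fitted parameters of the fibril-reinforced poroelastic
#' (FRPE) cartilage model: a tension-only strain-stiffening collagen fibril
#' network, a porous hyperelastic (neo-Hookean) proteoglycan matrix, and
#' strain-dependent Darcy permeability of the interstitial fluid.
#'
#' @param Ef0 initial fibril network modulus (MPa); stiffness of the collagen
#'   network at vanishing fibril strain (pre-tension).
#' @param EfEps strain-dependent fibril network modulus (MPa); controls the
#'   strain-stiffening of the fibril network.
#' @param Enf non-fibrillar matrix modulus (MPa); Young's modulus of the
#'   proteoglycan matrix in the small-strain limit.
#' @param k0 initial permeability, in units of 1e-15 m^4 N^-1 s^-1.
#' @param M dimensionless permeability strain-dependency coefficient; the
#'   exponent of the void-ratio power law.
#' @return An object of class `frpe_parameters`.
#' @export
frpe_parameters <- function(Ef0 = 0.9, EfEps = 40, Enf = 0.7, k0 = 2, M = 10) {
  vals <- c(Ef0 = Ef0, EfEps = EfEps, Enf = Enf, k0 = k0, M = M)
  if (!all(is.finite(vals)))
    stop("all FRPE parameters must be finite", call. = FALSE)
  if (Ef0 < 0 || EfEps < 0 || M < 0)
    stop("Ef0, EfEps and M must be non-negative", call. = FALSE)
  if (Enf <= 0 || k0 <= 0)
    stop("Enf and k0 must be positive", call. = FALSE)
  structure(as.list(vals), class = "frpe_parameters")
}

#' @export
print.frpe_parameters <- function(x, ...) {
  cat("FRPE parameters:\n")
  cat(sprintf("  Ef0   = %g MPa (initial fibril network modulus)\n", x$Ef0))
  cat(sprintf("  EfEps = %g MPa (strain-dependent fibril network modulus)\n", x$EfEps))
  cat(sprintf("  Enf   = %g MPa (non-fibrillar matrix modulus)\n", x$Enf))
  cat(sprintf("  k0    = %g e-15 m^4/(N s) (initial permeability)\n", x$k0))
  cat(sprintf("  M     = %g (permeability strain-dependency)\n", x$M))
  invisible(x)
}

#' @export
as.data.frame.frpe_parameters <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Fixed constitutive constants of the FRPE model
#'
#' Constants held fixed during fitting: the Poisson's ratio of the
#' non-fibrillar matrix and the initial void ratio (fluid-to-solid volume
#' ratio) of the tissue. The defaults (`nu_nf = 0.42`, `e0 = 4`, i.e. a fluid
#' fraction of 0.8) are conventional for articular cartilage.
#'
#' @param nu_nf Poisson's ratio of the non-fibrillar matrix, in `[0, 0.5)`.
#' @param e0 initial void ratio, positive.
#' @return An object of class `constitutive_constants`.
#' @export
constitutive_constants <- function(nu_nf = 0.42, e0 = 4) {
  if (!is.finite(nu_nf) || nu_nf < 0 || nu_nf >= 0.5)
    stop("nu_nf must lie in [0, 0.5)", call. = FALSE)
  if (!is.finite(e0) || e0 <= 0)
    stop("e0 must be positive", call. = FALSE)
  structure(list(nu_nf = nu_nf, e0 = e0), class = "constitutive_constants")
}

# conversion: permeability user units (1e-15 m^4 N^-1 s^-1 = 1e-15 m^2/(Pa s))
# to internal mm^2/(MPa s): 1e-15 m^2/(Pa s) = 1e-3 mm^2/(MPa s)
K0_UNIT <- 1e-3

#' Tension-only fibril network stress
#'
#' One-dimensional constitutive law of the collagen fibril network,
#' `sigma_f = (Ef0 + EfEps * eps_f) * eps_f` for tensile fibril strain
#' `eps_f > 0` and zero otherwise: collagen fibrils carry no compression.
#'
#' @param Ef0,EfEps fibril network moduli (MPa).
#' @param eps_f fibril-direction strain (may be a vector).
#' @return Fibril stress (MPa), same length as `eps_f`.
#' @export
fibril_stress <- function(Ef0, EfEps, eps_f) {
  if (!all(is.finite(c(Ef0, EfEps, eps_f))))
    stop("fibril_stress: non-finite input", call. = FALSE)
  ifelse(eps_f > 0, (Ef0 + EfEps * eps_f) * eps_f, 0)
}

#' Strain state at an integration point
#'
#' Axisymmetric deformation measure: the in-plane (r, z) deformation gradient
#' block and the hoop stretch, with the derived volumetric Jacobian and void
#' ratio.
#'
#' @param F_rz 2x2 in-plane deformation gradient `[dr/dR]`.
#' @param F_theta hoop stretch `r/R`.
#' @param e0 reference void ratio.
#' @return Object of class `strain_state` with fields `F_rz`, `F_theta`, `J`
#'   and void ratio `e` (from `1 + e = J (1 + e0)`).
#' @export
strain_state <- function(F_rz = diag(2), F_theta = 1, e0 = 4) {
  F_rz <- matrix(as.numeric(F_rz), 2, 2)
  J <- F_theta * (F_rz[1, 1] * F_rz[2, 2] - F_rz[1, 2] * F_rz[2, 1])
  if (!is.finite(J) || J <= 0)
    stop("degenerate deformation: volumetric Jacobian must be positive",
         call. = FALSE)
  e <- J * (1 + e0) - 1
  structure(list(F_rz = F_rz, F_theta = F_theta, J = J, e = e),
            class = "strain_state")
}

#' Non-fibrillar (proteoglycan) matrix stress
#'
#' Compressible neo-Hookean Cauchy stress of the porous non-fibrillar matrix,
#' `sigma = mu/J (B - I) + lambda ln(J)/J I`, with Lame constants derived from
#' `(Enf, nu_nf)`. Reduces to isotropic linear elasticity in the
#' infinitesimal-strain limit.
#'
#' @param Enf non-fibrillar matrix modulus (MPa).
#' @param nu_nf Poisson's ratio of the matrix.
#' @param strain a [strain_state()].
#' @return Cauchy stress in Voigt-like axisymmetric order
#'   `c(rr, zz, tt, rz)` (MPa).
#' @export
nonfibrillar_stress <- function(Enf, nu_nf, strain) {
  stopifnot(inherits(strain, "strain_state"))
  mu <- Enf / (2 * (1 + nu_nf))
  lam <- Enf * nu_nf / ((1 + nu_nf) * (1 - 2 * nu_nf))
  Fm <- strain$F_rz
  J <- strain$J
  B <- Fm %*% t(Fm)
  Btt <- strain$F_theta^2
  c(rr = mu / J * (B[1, 1] - 1) + lam * log(J) / J,
    zz = mu / J * (B[2, 2] - 1) + lam * log(J) / J,
    tt = mu / J * (Btt - 1) + lam * log(J) / J,
    rz = mu / J * B[1, 2])
}

#' Strain-dependent permeability
#'
#' Void-ratio power law `k = k0 * ((1 + e) / (1 + e0))^M`. Compaction
#' (decreasing void ratio) reduces permeability when `M > 0`.
#'
#' @param k0 initial permeability (1e-15 m^4 N^-1 s^-1).
#' @param M strain-dependency exponent.
#' @param e current void ratio (> -1).
#' @param e0 reference void ratio (> -1).
#' @return Permeability in the same units as `k0`.
#' @export
permeability <- function(k0, M, e, e0) {
  if (any(e <= -1) || e0 <= -1)
    stop("void ratios must exceed -1", call. = FALSE)
  k0 * ((1 + e) / (1 + e0))^M
}

#' Total stress of the biphasic mixture
#'
#' Total Cauchy stress `sigma_t = sigma_nf + sigma_f - p I`: solid matrix
#' stresses minus pore fluid pressure acting on the normal components.
#'
#' @param sigma_nf,sigma_f stress tensors in axisymmetric Voigt order
#'   `c(rr, zz, tt, rz)` (MPa), or conformable arrays.
#' @param p pore fluid pressure (MPa), scalar.
#' @return Total stress, same shape as inputs.
#' @export
total_stress <- function(sigma_nf, sigma_f, p) {
  if (length(sigma_nf) != length(sigma_f))
    stop("sigma_nf and sigma_f must be conformable", call. = FALSE)
  pI <- rep(0, length(sigma_nf))
  nrm <- names(sigma_nf)
  if (!is.null(nrm)) {
    pI[nrm %in% c("rr", "zz", "tt")] <- p
  } else if (length(sigma_nf) == 4L) {
    pI[1:3] <- p  # rr, zz, tt, rz convention
  } else {
    pI[] <- p
  }
  sigma_nf + sigma_f - pI
}

#' Full stress decomposition at an integration point
#'
#' Evaluates non-fibrillar, fibrillar and total stress for a given strain
#' state, with fibrils oriented parallel to the articular surface (one family
#' along the radial direction, one along the hoop direction).
#'
#' @param params [frpe_parameters()].
#' @param constants [constitutive_constants()].
#' @param strain [strain_state()].
#' @param p pore pressure (MPa).
#' @param orientation fibril orientation: `"surface-parallel"` (default) or
#'   `"none"` (fibrils disabled).
#' @return List with `sigma_nf`, `sigma_f`, `p`, `sigma_t` (each in
#'   `c(rr, zz, tt, rz)` order) — class `stress_decomposition`.
#' @export
stress_decomposition <- function(params, constants, strain, p = 0,
                                 orientation = c("surface-parallel", "none")) {
  orientation <- match.arg(orientation)
  s_nf <- nonfibrillar_stress(params$Enf, constants$nu_nf, strain)
  s_f <- c(rr = 0, zz = 0, tt = 0, rz = 0)
  if (orientation == "surface-parallel") {
    Fm <- strain$F_rz
    # radial family: reference direction e_R, deformed to F e_R
    col1 <- Fm[, 1]
    lam_r <- sqrt(sum(col1^2))
    sf_r <- fibril_stress(params$Ef0, params$EfEps, lam_r - 1)
    a <- col1 / lam_r
    s_f["rr"] <- s_f["rr"] + sf_r * a[1]^2
    s_f["zz"] <- s_f["zz"] + sf_r * a[2]^2
    s_f["rz"] <- s_f["rz"] + sf_r * a[1] * a[2]
    # hoop family: stretch is F_theta
    s_f["tt"] <- s_f["tt"] +
      fibril_stress(params$Ef0, params$EfEps, strain$F_theta - 1)
  }
  structure(list(sigma_nf = s_nf, sigma_f = s_f, p = p,
                 sigma_t = total_stress(s_nf, s_f, p)),
            class = "stress_decomposition")
}
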