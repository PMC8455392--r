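# Hayes flat-punch correction for indentation of a thin elastic layer bonded
# to a rigid substrate. The layer response enters through the Hankel-space
# compliance ratio W(x, nu) (W -> 1 recovers the elastic half-space); the
# punch problem reduces, via the standard Abel/cosine-transform substitution,
# to a Fredholm equation of the second kind which is solved by Nystrom
# quadrature.

# Layer compliance ratio for a layer bonded at its base and loaded on a
# frictionless free surface; x = xi * h (Hankel variable times thickness).
# Derived from the Love strain-function solution of the transformed
# elasticity equations with u = 0 at the base and sigma_rz = 0 at the surface.
hayes_layer_response <- function(x, nu) {
  k1 <- 3 - 4 * nu
  # (2 k1 sinh 2x - 4x) / (2 k1 cosh 2x + k1^2 + 1 + 4 x^2), overflow-safe
  num <- k1 * (1 - exp(-4 * x)) - 4 * x * exp(-2 * x)
  den <- k1 * (1 + exp(-4 * x)) + (k1^2 + 1 + 4 * x^2) * exp(-2 * x)
  out <- num / den
  out[x == 0] <- 0
  out
}

# Fredholm kernel K(u) = int_0^inf (W(x / chi, nu) - 1) cos(x u) dx,
# chi = a / h. The integrand decays like exp(-2 x / chi).
hayes_kernel <- function(u, chi, nu) {
  upper <- max(8, 10 * chi)  # e-folding length is chi / 2
  vapply(u, function(ui) {
    stats::integrate(function(x) (hayes_layer_response(x / chi, nu) - 1) * cos(x * ui),
                     0, upper, rel.tol = 1e-9, abs.tol = 1e-11,
                     subdivisions = 400L)$value
  }, numeric(1))
}

# Gauss-Legendre nodes/weights on [0, 1]
gauss_legendre01 <- function(n) {
  # Golub-Welsch on [-1, 1], then affine map
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1)] <- b
  Jm[cbind(i + 1, i)] <- b
  eig <- eigen(Jm, symmetric = TRUE)
  xs <- eig$values
  ws <- 2 * eig$vectors[1, ]^2
  ord <- order(xs)
  list(x = (xs[ord] + 1) / 2, w = ws[ord] / 2)
}

hayes_kappa_one <- function(chi, nu, n = 48) {
  gl <- gauss_legendre01(n)
  t <- gl$x
  # kernel needed at |t_i - t_j| in [0,1] and t_i + t_j in (0,2): spline cache
  ug <- seq(0, 2, length.out = 121)
  Kg <- hayes_kernel(ug, chi, nu)
  Kf <- stats::splinefun(ug, Kg, method = "natural")
  Kmat <- matrix(Kf(abs(outer(t, t, "-"))) + Kf(outer(t, t, "+")), n, n)
  A <- diag(n) + (1 / pi) * sweep(Kmat, 2, gl$w, "*")
  H <- solve(A, rep(1, n))
  sum(gl$w * H)
}

.hayes_cache <- new.env(parent = emptyenv())

#' Hayes correction factor for flat-punch indentation
#'
#' Stiffening factor `kappa(a/h, nu)` of a plane-ended cylindrical indenter on
#' an elastic layer of finite thickness bonded to a rigid substrate, relative
#' to the elastic half-space: the indenter force is
#' `P = 2 E a w kappa / (1 - nu^2)`. Computed by numerically solving the dual
#' integral equations of the bonded-layer punch problem (reduced to a Fredholm
#' equation solved by Nystrom quadrature); results are cached.
#'
#' @param aspect ratio of indenter radius to cartilage thickness, `a/h` (> 0).
#' @param nu Poisson's ratio of the layer, in `[0, 0.5]`.
#' @return Correction factor `kappa >= 1`; `kappa -> 1` as `a/h -> 0`.
#' @export
hayes_kappa <- function(aspect, nu) {
  if (!all(is.finite(aspect)) || any(aspect <= 0))
    stop("aspect ratio a/h must be positive and finite", call. = FALSE)
  if (!is.finite(nu) || nu < 0 || nu > 0.5)
    stop("nu must lie in [0, 0.5]", call. = FALSE)
  if (any(aspect > 10))
    stop("aspect ratio a/h > 10 outside supported range", call. = FALSE)
  vapply(aspect, function(chi) {
    key <- sprintf("%.10g_%.10g", chi, nu)
    if (!is.null(.hayes_cache[[key]])) return(.hayes_cache[[key]])
    val <- hayes_kappa_one(chi, nu)
    .hayes_cache[[key]] <- val
    val
  }, numeric(1))
}

#' Hayes-corrected indentation modulus
#'
#' Converts an indentation "stress over strain" ratio (nominal stress
#' `F / (pi a^2)` over nominal strain `w / h`) into a Young's modulus using
#' the Hayes correction:
#' `E = (sigma / eps) * pi * a * (1 - nu^2) / (2 * h * kappa(a/h, nu))`.
#'
#' @param stress_over_strain ratio of nominal stress (MPa) to nominal strain.
#' @param geometry a [sample_geometry()].
#' @param nu assumed Poisson's ratio.
#' @return Modulus in MPa.
#' @export
hayes_modulus <- function(stress_over_strain, geometry, nu) {
  chi <- geometry$a / geometry$h
  kap <- hayes_kappa(chi, nu)
  stress_over_strain * pi * geometry$a * (1 - nu^2) / (2 * geometry$h * kap)
}
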