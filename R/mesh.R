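#' Specimen and indenter geometry
#'
#' @param h cartilage thickness (mm).
#' @param R sample radius (mm).
#' @param a indenter radius (mm); a plane-ended cylindrical indenter is
#'   assumed. Must satisfy `0 < a < R` (or `a == R` for confined compression).
#' @return Object of class `sample_geometry`.
#' @export
sample_geometry <- function(h = 2.0, R = 2.0, a = 0.35) {
  if (!all(is.finite(c(h, R, a))) || h <= 0 || R <= 0 || a <= 0)
    stop("geometry values must be positive and finite", call. = FALSE)
  if (a > R)
    stop("indenter radius a must not exceed sample radius R", call. = FALSE)
  structure(list(h = h, R = R, a = a), class = "sample_geometry")
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat(sprintf("sample geometry: h = %g mm, R = %g mm, indenter a = %g mm\n",
              x$h, x$R, x$a))
  invisible(x)
}

# geometric grading: n interval breakpoints from `from` to `to`, cell sizes in
# geometric progression with total ratio `bias` (last/first); bias > 1 packs
# cells toward `from`.
graded_breaks <- function(from, to, n, bias = 1) {
  if (n < 1) return(c(from, to)[c(1, 2)][seq_len(0)])
  r <- bias^(1 / max(1, n - 1))
  w <- r^(0:(n - 1))
  from + (to - from) * c(0, cumsum(w)) / sum(w)
}

#' Mesh resolution descriptor
#'
#' @param nra elements along r inside the contact radius.
#' @param nrb elements along r outside the contact radius.
#' @param nz elements through the thickness.
#' @param bias geometric grading ratio toward the indenter edge and the
#'   articular surface (>= 1; 1 = uniform).
#' @return Object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(nra = 3, nrb = 4, nz = 4, bias = 3) {
  stopifnot(nra >= 1, nz >= 1, nrb >= 0, bias >= 1)
  structure(list(nra = nra, nrb = nrb, nz = nz, bias = bias),
            class = "mesh_resolution")
}

#' Build an axisymmetric finite-element mesh of the cartilage disc
#'
#' Structured mesh of 9-node (biquadratic displacement) / 4-node (bilinear
#' pressure) Taylor-Hood quadrilaterals on the half-section `[0, R] x [0, h]`,
#' graded toward the indenter edge `r = a` and the articular surface `z = h`.
#'
#' @param geometry a [sample_geometry()].
#' @param resolution a [mesh_resolution()], or one of `"coarse"`, `"medium"`,
#'   `"fine"`.
#' @return Object of class `frpe_mesh` with displacement nodes, element
#'   connectivity, pressure-node numbering and named boundary node sets
#'   (contact set = surface nodes with `r <= a`).
#' @export
build_mesh <- function(geometry, resolution = "medium") {
  stopifnot(inherits(geometry, "sample_geometry"))
  if (is.character(resolution)) {
    resolution <- switch(match.arg(resolution, c("coarse", "medium", "fine")),
      coarse = mesh_resolution(2, 3, 3, 4),
      medium = mesh_resolution(4, 5, 5, 8),
      fine   = mesh_resolution(8, 10, 10, 8))
  }
  stopifnot(inherits(resolution, "mesh_resolution"))
  confined <- abs(geometry$a - geometry$R) < 1e-12
  if (!confined && geometry$a >= geometry$R)
    stop("mesh error: indenter radius must be smaller than sample radius",
         call. = FALSE)
  rb_in <- graded_breaks(0, geometry$a, resolution$nra, 1 / resolution$bias)
  r_breaks <- if (confined) rb_in else {
    rb_out <- graded_breaks(geometry$a, geometry$R, resolution$nrb,
                            resolution$bias)
    c(rb_in, rb_out[-1])
  }
  z_breaks <- graded_breaks(0, geometry$h, resolution$nz, 1 / resolution$bias)
  nr <- length(r_breaks) - 1L
  nz <- length(z_breaks) - 1L
  if (sum(r_breaks <= geometry$a + 1e-12) < 2)
    stop("mesh error: fewer than 2 radial nodes under the indenter",
         call. = FALSE)

  refine <- function(b) {
    mids <- (b[-1] + b[-length(b)]) / 2
    v <- numeric(2 * length(b) - 1)
    v[seq(1, length(v), by = 2)] <- b
    v[seq(2, length(v), by = 2)] <- mids
    v
  }
  ru <- refine(r_breaks)  # 2*nr + 1 displacement grid lines
  zu <- refine(z_breaks)
  nru <- length(ru)
  nzu <- length(zu)
  nodes <- cbind(r = rep(ru, times = nzu), z = rep(zu, each = nru))
  nid <- function(i, j) (j - 1L) * nru + i

  ne <- nr * nz
  elems <- matrix(0L, ne, 9L)
  pelems <- matrix(0L, ne, 4L)
  npr <- nr + 1L
  pid <- function(ir, jz) (jz - 1L) * npr + ir
  k <- 0L
  for (ez in seq_len(nz)) {
    for (er in seq_len(nr)) {
      k <- k + 1L
      i0 <- 2L * (er - 1L) + 1L
      j0 <- 2L * (ez - 1L) + 1L
      loc <- integer(9)
      for (jj in 0:2) for (ii in 0:2)
        loc[jj * 3L + ii + 1L] <- nid(i0 + ii, j0 + jj)
      elems[k, ] <- loc
      ploc <- integer(4)
      for (jj in 0:1) for (ii in 0:1)
        ploc[jj * 2L + ii + 1L] <- pid(er + ii, ez + jj)
      pelems[k, ] <- ploc
    }
  }
  np <- npr * (nz + 1L)
  # pressure node coordinates (corner grid)
  pnodes <- cbind(r = rep(r_breaks, times = nz + 1L),
                  z = rep(z_breaks, each = npr))

  tol <- 1e-9 * max(geometry$h, geometry$R)
  top <- which(abs(nodes[, 2] - geometry$h) < tol)
  sets <- list(
    bottom  = which(abs(nodes[, 2]) < tol),
    axis    = which(abs(nodes[, 1]) < tol),
    outer   = which(abs(nodes[, 1] - geometry$R) < tol),
    top     = top,
    contact = top[nodes[top, 1] <= geometry$a + tol]
  )
  ptop <- which(abs(pnodes[, 2] - geometry$h) < tol)
  psets <- list(
    top          = ptop,
    top_free     = ptop[pnodes[ptop, 1] > geometry$a + tol],
    outer        = which(abs(pnodes[, 1] - geometry$R) < tol)
  )
  structure(list(geometry = geometry, resolution = resolution,
                 nodes = nodes, elems = elems, pelems = pelems,
                 pnodes = pnodes, np = np, sets = sets, psets = psets,
                 confined = confined),
            class = "frpe_mesh")
}

#' @export
print.frpe_mesh <- function(x, ...) {
  cat(sprintf("axisymmetric Q9/Q4 mesh: %d elements, %d displacement nodes, %d pressure nodes\n",
              nrow(x$elems), nrow(x$nodes), x$np))
  cat(sprintf("  contact set: %d surface nodes with r <= a = %g mm\n",
              length(x$sets$contact), x$geometry$a))
  invisible(x)
}
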