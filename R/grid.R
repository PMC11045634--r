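#' Uniform Cartesian grid
#'
#' Builds a cell-centred uniform grid over a rectangular domain in 2 or 3
#' dimensions. All positions are physical (cm); cell centres sit at
#' \code{lo + (i - 1/2) * h} for \code{i = 1, ..., n} along each axis.
#'
#' @param extent list of per-axis closed intervals \code{c(lo, hi)} in cm, or a
#'   single interval recycled to \code{length(shape)} axes.
#' @param shape integer vector of per-axis cell counts (all >= 4).
#' @return an object of class \code{"msim_grid"} with elements \code{extent}
#'   (matrix 2 x dim), \code{shape}, \code{spacing} (per-axis cell width, cm),
#'   \code{dim}, and \code{cell_volume} (cm^dim).
#' @examples
#' g <- make_grid(c(-0.05, 0.05), shape = c(16, 16, 16))
#' g$spacing
#' @export
make_grid <- function(extent = c(-0.05, 0.05), shape = c(64, 64, 64)) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (!d %in% c(2L, 3L) && d != 1L)
    stop("grid must be 1-, 2- or 3-dimensional, got dim = ", d)
  if (any(shape < 4L))
    stop("all axis cell counts must be >= 4, got ", paste(shape, collapse = "x"))
  if (!is.list(extent)) extent <- rep(list(extent), d)
  if (length(extent) == 1L) extent <- rep(extent, d)
  if (length(extent) != d)
    stop("extent must give one interval per axis")
  ext <- vapply(extent, function(e) {
    e <- as.numeric(e)
    if (length(e) != 2L || !all(is.finite(e)) || e[2] <= e[1])
      stop("each extent must be a finite non-degenerate interval c(lo, hi)")
    e
  }, numeric(2))
  spacing <- (ext[2, ] - ext[1, ]) / shape
  structure(list(
    extent = ext, shape = shape, spacing = spacing, dim = d,
    cell_volume = prod(spacing)
  ), class = "msim_grid")
}

#' @export
print.msim_grid <- function(x, ...) {
  cat("<msim_grid> ", paste(x$shape, collapse = " x "),
      " cells, extent ",
      paste(sprintf("[%g, %g]", x$extent[1, ], x$extent[2, ]), collapse = " x "),
      " cm, h = (", paste(signif(x$spacing, 6), collapse = ", "), ") cm\n",
      sep = "")
  invisible(x)
}

#' Cell-centre coordinates along one axis
#'
#' @param grid an \code{msim_grid}.
#' @param axis axis index (1-based).
#' @return numeric vector of the \code{shape[axis]} cell-centre coordinates.
#' @export
cell_centres <- function(grid, axis) {
  grid$extent[1, axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

#' Field of a coordinate function evaluated at cell centres
#'
#' Convenience for building scalar fields such as the directional matrix
#' profile \code{x + y + z}: evaluates \code{f(x, y[, z])} at every cell
#' centre.
#'
#' @param grid an \code{msim_grid}.
#' @param f function of \code{dim} coordinate vectors, vectorised.
#' @return array with \code{dim = grid$shape}.
#' @export
coord_field <- function(grid, f) {
  axes <- lapply(seq_len(grid$dim), function(a) cell_centres(grid, a))
  pts <- do.call(expand.grid, axes)
  vals <- do.call(f, unname(as.list(pts)))
  array(vals, dim = grid$shape)
}

new_field <- function(grid, value = 0) array(value, dim = grid$shape)

check_field <- function(f, grid, name = "field") {
  if (!identical(as.integer(dim(f)), grid$shape))
    stop(name, " shape ", paste(dim(f), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  invisible(f)
}

## Apply `fun` to an array reshaped so the chosen axis is the first index of a
## matrix (n x prod(other dims)); `fun` must return a matrix of the same shape.
## This is how all the 1D stencils below generalise to 2D/3D.
along_axis <- function(a, axis, fun) {
  d <- dim(a)
  k <- length(d)
  if (is.null(d) || k == 1L) {
    r <- fun(matrix(a, ncol = 1))
    dim(r) <- if (is.null(d)) NULL else d
    return(r)
  }
  perm <- c(axis, setdiff(seq_len(k), axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  r <- fun(m)
  dim(r) <- dm
  aperm(r, order(perm))
}

## Divergence of interior face fluxes along one axis (zero boundary flux).
## `face_flux(mlo, mhi)` receives the two adjacent cell slabs and returns the
## flux through each interior face; the result is (F_right - F_left)/h.
flux_divergence_axis <- function(a, axis, h, face_flux) {
  along_axis(a, axis, function(m) {
    n <- nrow(m)
    f <- face_flux(m[-n, , drop = FALSE], m[-1, , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    out[-n, ] <- f
    out[-1, ] <- out[-1, ] - f
    out / h   # div_i = (F_i - F_{i-1})/h

  })
}

#' Discrete Laplacian with homogeneous Neumann boundaries
#'
#' Second-order central stencil in conservative (face-flux) form: the face
#' gradient is differenced across each interior face and boundary faces carry
#' zero flux (ghost-cell mirroring). Consequently the sum of the result over
#' all cells vanishes to round-off, the discrete footprint of no-flux walls.
#'
#' @param f array with \code{dim = grid$shape}, all entries finite.
#' @param grid an \code{msim_grid}.
#' @return array of the same shape.
#' @export
laplacian <- function(f, grid) {
  check_field(f, grid)
  out <- new_field(grid)
  for (a in seq_len(grid$dim)) {
    h <- grid$spacing[a]
    out <- out + flux_divergence_axis(f, a, h, function(lo, hi) (hi - lo) / h)
  }
  out
}

#' Discrete gradient
#'
#' Central differences at interior cells, one-sided differences at the two
#' boundary cells of each axis.
#'
#' @inheritParams laplacian
#' @return list of \code{grid$dim} arrays, one gradient component per axis.
#' @export
gradient <- function(f, grid) {
  check_field(f, grid)
  lapply(seq_len(grid$dim), function(a) {
    h <- grid$spacing[a]
    along_axis(f, a, function(m) {
      n <- nrow(m)
      out <- m
      out[1, ] <- (m[2, ] - m[1, ]) / h
      out[n, ] <- (m[n, ] - m[n - 1, ]) / h
      if (n > 2)
        out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                               m[1:(n - 2), , drop = FALSE]) / (2 * h)
      out
    })
  })
}

#' Multilinear interpolation of a field at arbitrary points
#'
#' Interpolates from the surrounding cell centres; exact for fields affine in
#' position (near the walls the boundary cell pair is extrapolated linearly,
#' preserving affine exactness).
#'
#' @param f array with \code{dim = grid$shape}.
#' @param grid an \code{msim_grid}.
#' @param x numeric matrix (n_points x dim) of positions in cm, or a single
#'   position vector. All points must lie inside the domain.
#' @return numeric vector of interpolated values.
#' @export
interp_at <- function(f, grid, x) {
  check_field(f, grid)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- grid$dim
  if (ncol(x) != d) stop("positions must have ", d, " columns")
  for (a in seq_len(d)) {
    if (any(x[, a] < grid$extent[1, a] | x[, a] > grid$extent[2, a]))
      stop("interp_at: position outside the domain on axis ", a)
  }
  np <- nrow(x)
  i0 <- matrix(0L, np, d)  # lower cell index of the interpolation pair
  w <- matrix(0, np, d)    # weight of the upper cell
  for (a in seq_len(d)) {
    t <- (x[, a] - grid$extent[1, a]) / grid$spacing[a] - 0.5
    lo <- pmin(pmax(floor(t), 0), grid$shape[a] - 2)
    i0[, a] <- as.integer(lo) + 1L
    w[, a] <- t - lo
  }
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  vals <- numeric(np)
  for (k in seq_len(nrow(corners))) {
    idx <- sweep(i0, 2, as.integer(corners[k, ]), `+`)
    wk <- rep(1, np)
    for (a in seq_len(d))
      wk <- wk * (if (corners[k, a] == 1) w[, a] else 1 - w[, a])
    vals <- vals + wk * f[idx]
  }
  vals
}

#' Total mass of a density field
#'
#' @param f density array (g cm^-3).
#' @param grid an \code{msim_grid}.
#' @return total mass in g: \code{sum(f) * cell volume}.
#' @export
field_mass <- function(f, grid) sum(f) * grid$cell_volume
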