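#' Directional extracellular matrix field
#'
#' A matrix density increasing linearly towards one corner of the domain:
#' the sum of the coordinates is min-max normalised to [0, 1] and affinely
#' mapped to \code{[v_min, v_max]}, so the field attains both bounds exactly
#' at two opposite corners and its gradient is a constant vector with equal
#' components.
#'
#' @param grid an \code{msim_grid}.
#' @param v_min,v_max matrix density bounds (g cm^-3).
#' @return density array on the grid.
#' @export
directional_ecm <- function(grid, v_min = 0.9 * 1.06, v_max = 1.06) {
  if (v_min > v_max) stop("v_min must be <= v_max")
  vbar <- coord_field(grid, function(...) Reduce(`+`, list(...)))
  rng <- range(vbar)
  if (rng[1] == rng[2]) {
    if (v_min == v_max) return(new_field(grid, v_min))
    stop("degenerate coordinate field: cannot normalise")
  }
  vhat <- (vbar - rng[1]) / (rng[2] - rng[1])
  v_min + (v_max - v_min) * vhat
}

#' Hierarchical random extracellular matrix field
#'
#' Emulates heterogeneous tissue: a coarse lattice of i.i.d. standard
#' normal values (default 8 per axis) fixes the large-scale structure; each
#' refinement doubles the resolution by multilinear interpolation of the
#' coarser values plus additive Gaussian noise whose standard deviation
#' halves per level, so the final field preserves the coarse structure
#' while gaining fine-scale texture. The result is min-max normalised and
#' mapped to \code{[v_min, v_max]}. Consumes the global RNG stream.
#'
#' @param grid an \code{msim_grid} whose shape equals
#'   \code{base_size * 2^levels} per axis.
#' @param v_min,v_max matrix density bounds (g cm^-3).
#' @param base_size coarse lattice size per axis (default 8).
#' @param levels number of resolution doublings; default inferred from the
#'   grid shape.
#' @param noise_sd noise standard deviation at the first refinement level.
#' @return density array on the grid.
#' @export
hierarchical_ecm <- function(grid, v_min = 0.9 * 1.06, v_max = 1.06,
                             base_size = 8L, levels = NULL,
                             noise_sd = 0.25) {
  d <- grid$dim
  if (is.null(levels)) {
    ratio <- grid$shape[1] / base_size
    levels <- as.integer(round(log2(ratio)))
  }
  if (!all(grid$shape == base_size * 2^levels))
    stop("grid shape (", paste(grid$shape, collapse = "x"),
         ") must equal base_size * 2^levels (",
         base_size, " * 2^", levels, ") on every axis")
  f <- array(stats::rnorm(base_size^d), dim = rep(base_size, d))
  size <- base_size
  sd_level <- noise_sd
  unit <- function(n) make_grid(c(0, 1), shape = rep(n, d))
  for (l in seq_len(levels)) {
    coarse <- unit(size)
    size <- size * 2L
    fine <- unit(size)
    pts <- as.matrix(do.call(expand.grid,
                             lapply(seq_len(d), function(a) cell_centres(fine, a))))
    vals <- interp_at(f, coarse, pts)
    f <- array(vals + stats::rnorm(length(vals), 0, sd_level),
               dim = rep(size, d))
    sd_level <- sd_level / 2
  }
  rng <- range(f)
  if (rng[1] == rng[2]) return(new_field(grid, v_min))
  v_min + (v_max - v_min) * (f - rng[1]) / (rng[2] - rng[1])
}

#' Spherical tumour initial condition
#'
#' Constant epithelial density on a union of balls (cell-centre membership
#' test), zero outside. Note the quantisation: a ball smaller than half a
#' cell diagonal positioned between cell centres can yield an empty field.
#'
#' @param grid an \code{msim_grid}.
#' @param centres list of ball centre positions (cm), or a single vector.
#' @param radius ball radius (cm).
#' @param density epithelial density inside the balls (g cm^-3).
#' @return density array on the grid.
#' @export
spherical_tumor_ic <- function(grid, centres = list(rep(0, grid$dim)),
                               radius = 0.01, density = 3) {
  if (radius <= 0) stop("radius must be > 0")
  if (!is.list(centres)) centres <- list(centres)
  inside <- new_field(grid)
  axes <- lapply(seq_len(grid$dim), function(a) cell_centres(grid, a))
  pts <- as.matrix(do.call(expand.grid, axes))
  for (ctr in centres) {
    if (any(ctr + radius < grid$extent[1, ] | ctr - radius > grid$extent[2, ]))
      warning("tumour ball entirely outside the domain")
    r2 <- rowSums(sweep(pts, 2, ctr)^2)
    inside <- inside + array(as.numeric(r2 < radius^2), dim = grid$shape)
  }
  density * pmin(inside, 1)
}

#' Random fibroblast initial condition
#'
#' Fibroblasts occupy an exact fraction of the grid cells (selected
#' uniformly without replacement); selected cells draw i.i.d. U(0, hi)
#' densities, all others are zero. Consumes the global RNG stream.
#'
#' @param grid an \code{msim_grid}.
#' @param fraction fraction of cells occupied (default 0.30).
#' @param hi upper bound of the uniform density (g cm^-3).
#' @return density array on the grid.
#' @export
random_caf_ic <- function(grid, fraction = 0.30, hi = 0.001) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- prod(grid$shape)
  k <- round(fraction * n)
  f <- new_field(grid)
  if (k > 0) f[sample.int(n, k)] <- stats::runif(k, 0, hi)
  f
}

#' TGF-beta and MMP initial conditions
#'
#' TGF-beta starts as U(0, b_hi) everywhere except on the tumour support,
#' where it is zero (the signal initially surrounds the tumour); MMP starts
#' as U(0, m_hi) over the whole domain. Consumes the global RNG stream.
#'
#' @param grid an \code{msim_grid}.
#' @param tumour_support logical (or 0/1) array marking the tumour cells.
#' @param b_hi,m_hi upper bounds of the uniform laws (g cm^-3).
#' @return list with arrays \code{b} and \code{m}.
#' @export
tgf_mmp_ic <- function(grid, tumour_support = NULL, b_hi = 0.01,
                       m_hi = 1e-4) {
  n <- prod(grid$shape)
  b <- array(stats::runif(n, 0, b_hi), dim = grid$shape)
  if (!is.null(tumour_support)) {
    check_field(tumour_support, grid, "tumour_support")
    b[tumour_support > 0] <- 0
  }
  m <- array(stats::runif(n, 0, m_hi), dim = grid$shape)
  list(b = b, m = m)
}
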