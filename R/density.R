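#' Density state of one organ
#'
#' Bundles the five scalar fields of the density submodel on one grid:
#' epithelial cancer cells \code{cE}, fibroblasts \code{cF}, TGF-beta
#' \code{b}, MMP \code{m} and matrix \code{v} (all g cm^-3), plus the derived
#' mesenchymal density \code{cM} (regenerated from the agent set before every
#' reaction evaluation, never integrated as a PDE) and the simulation time in
#' days.
#'
#' @param grid an \code{msim_grid}.
#' @param cE,cF,b,m,v initial fields (arrays matching the grid, or scalars).
#' @param time initial time (days).
#' @return a list of class \code{"msim_state"}.
#' @export
density_state <- function(grid, cE = 0, cF = 0, b = 0, m = 0, v = 0,
                          time = 0) {
  as_field <- function(x, nm) {
    if (length(x) == 1L) x <- new_field(grid, x)
    check_field(x, grid, nm)
    if (!all(is.finite(x))) stop("non-finite values in field '", nm, "'")
    x
  }
  structure(list(
    grid = grid,
    cE = as_field(cE, "cE"), cF = as_field(cF, "cF"), b = as_field(b, "b"),
    m = as_field(m, "m"), v = as_field(v, "v"),
    cM = new_field(grid), time = time, clipped_mass = 0
  ), class = "msim_state")
}

#' @export
print.msim_state <- function(x, ...) {
  cat("<msim_state> t =", format(x$time), "d\n")
  for (f in c("cE", "cM", "cF", "b", "m", "v"))
    cat(sprintf("  %-3s total mass %.6g g, max %.4g g/cm^3\n",
                f, field_mass(x[[f]], x$grid), max(x[[f]])))
  invisible(x)
}

#' Porous-medium diffusion term
#'
#' Finite-volume divergence of the degenerate flux \code{D c grad(c)}
#' (porous-medium exponent 2: mobility proportional to the density itself).
#' The interface mobility is the arithmetic mean of the two adjacent cell
#' densities and boundary faces carry zero flux, so the term conserves mass
#' to round-off and is exactly degenerate at \code{c = 0}: compactly
#' supported profiles spread at most one cell per step.
#'
#' @param c_field non-negative density array.
#' @param grid an \code{msim_grid}.
#' @param D diffusion coefficient (cm^2 d^-1).
#' @return array: the rate of change contribution (g cm^-3 d^-1).
#' @export
pme_divergence <- function(c_field, grid, D) {
  check_field(c_field, grid)
  if (any(c_field < 0)) stop("pme_divergence: negative density")
  out <- new_field(grid)
  if (D == 0) return(out)
  for (a in seq_len(grid$dim)) {
    h <- grid$spacing[a]
    out <- out + flux_divergence_axis(c_field, a, h, function(lo, hi)
      D * 0.5 * (lo + hi) * (hi - lo) / h)
  }
  out
}

#' Haptotaxis term
#'
#' Upwind finite-volume advection of a cell density along the matrix
#' gradient. The face velocity is \code{sign * chi *} (face-normal central
#' difference of \code{v}); the advected density is taken from the upwind
#' cell; boundary faces carry zero flux. Returns the rate-of-change
#' contribution \code{-div(c u)}, which conserves mass to round-off.
#' \code{sign = +1} moves cells up the matrix gradient (epithelial cells),
#' \code{sign = -1} down it (fibroblasts).
#'
#' @param c_field non-negative density array.
#' @param v_field matrix density array.
#' @param grid an \code{msim_grid}.
#' @param chi haptotaxis coefficient (cm^2 d^-1).
#' @param sign +1 (up-gradient) or -1 (down-gradient).
#' @return array: rate of change contribution.
#' @export
haptotaxis_divergence <- function(c_field, v_field, grid, chi, sign = 1) {
  check_field(c_field, grid); check_field(v_field, grid)
  out <- new_field(grid)
  if (chi == 0) return(out)
  for (a in seq_len(grid$dim)) {
    out <- out - flux_divergence_axis_2(c_field, v_field, a, grid$spacing[a],
                                        chi, sign)
  }
  out
}

## advective flux divergence for one axis: u = sign*chi*dv/dn at faces,
## flux = u * upwind(c); returns div(c u).
flux_divergence_axis_2 <- function(c_field, v_field, axis, h, chi, sign) {
  d <- dim(c_field)
  k <- if (is.null(d)) 1L else length(d)
  to_mat <- function(x) {
    if (k == 1L) return(matrix(x, ncol = 1))
    perm <- c(axis, setdiff(seq_len(k), axis))
    m <- aperm(x, perm)
    dm <- dim(m); dim(m) <- c(dm[1], prod(dm[-1]))
    m
  }
  from_mat <- function(m) {
    if (k == 1L) { dim(m) <- d; return(m) }
    perm <- c(axis, setdiff(seq_len(k), axis))
    dm <- d[perm]; dim(m) <- dm
    aperm(m, order(perm))
  }
  cm <- to_mat(c_field); vm <- to_mat(v_field)
  n <- nrow(cm)
  u <- sign * chi * (vm[-1, , drop = FALSE] - vm[-n, , drop = FALSE]) / h
  cup <- ifelse(u > 0, cm[-n, , drop = FALSE], cm[-1, , drop = FALSE])
  f <- u * cup
  out <- matrix(0, n, ncol(cm))
  out[-n, ] <- f
  out[-1, ] <- out[-1, ] - f
  from_mat(out / h)
}

#' Reaction terms of the density submodel
#'
#' Evaluates the local (non-transport) rate of change of every field:
#' logistic ECC proliferation with volume competition against all cell
#' phases and the matrix, the EMT sink and MET source exchanged with the
#' agent phase, fibroblast logistic growth boosted by the presence of ECCs
#' and first-order death, TGF-beta and MMP production/decay, and matrix
#' production by fibroblasts with degradation by the agent footprint and the
#' MMP-ECC complex.
#'
#' @param state an \code{msim_state} with \code{cM} refreshed.
#' @param p an \code{msim_params}.
#' @param emt_sink,met_source density rate fields (g cm^-3 d^-1) handed over
#'   by the phenotype-switching step; defaults zero.
#' @param footprint agent footprint indicator field (counts); default zero.
#' @return named list of rate arrays \code{cE, cF, b, m, v}.
#' @export
reactions <- function(state, p, emt_sink = NULL, met_source = NULL,
                      footprint = NULL) {
  g <- state$grid
  zero <- new_field(g)
  if (is.null(emt_sink)) emt_sink <- zero
  if (is.null(met_source)) met_source <- zero
  if (is.null(footprint)) footprint <- zero
  v_comp <- if (isTRUE(p$normalize_carrying_capacity)) state$v / p$v_max else state$v
  room <- 1 - state$cE - state$cM - state$cF - v_comp
  list(
    cE = p$rho_cE * state$cE * room - p$mu_E_EMT * emt_sink +
      p$mu_M_MET * met_source,
    cF = p$rho_cF * state$cF * (1 + state$cE) * room - p$lambda_F * state$cF,
    b  = p$rho_bF * state$cF - p$lambda_b * state$b,
    m  = p$rho_mF * state$cF + p$rho_mE * state$cE - p$lambda_m * state$m,
    v  = p$rho_vF * state$cF -
      (p$lambda_vM * footprint + p$lambda_vE * state$m * state$cE) * state$v
  )
}

#' Stable explicit time step
#'
#' Largest forward-Euler step satisfying the diffusive, advective and
#' reaction stability constraints for the current state, times a safety
#' factor: \code{h^2 / (2 dim Dmax)} with \code{Dmax} the largest effective
#' diffusivity (\code{D_E max(cE)}, \code{D_F max(cF)}, \code{D_b},
#' \code{D_m}), \code{h / umax} for the largest haptotactic face speed, and
#' the inverse of the largest local reaction rate. A degenerate all-zero
#' state returns \code{dt_max}.
#'
#' @param state an \code{msim_state}.
#' @param p an \code{msim_params}.
#' @return time step in days.
#' @export
stable_dt <- function(state, p) {
  g <- state$grid
  h <- min(g$spacing)
  all_zero <- all(state$cE == 0) && all(state$cF == 0) && all(state$b == 0) &&
    all(state$m == 0) && all(state$v == 0)
  if (all_zero) return(p$dt_max)
  D_m_eff <- if (identical(p$mmp_diffusion, "D_E")) p$D_E else p$D_m
  dmax <- max(p$D_E * max(state$cE), p$D_F * max(state$cF), p$D_b, D_m_eff)
  dts <- numeric(0)
  if (dmax > 0) dts <- c(dts, h^2 / (2 * g$dim * dmax))
  gv <- gradient(state$v, g)
  umax <- max(p$chi_E, p$chi_F) * max(vapply(gv, function(x) max(abs(x)),
                                             numeric(1)))
  if (umax > 0) dts <- c(dts, h / umax)
  r <- reactions(state, p)
  dens <- list(state$cE, state$cF, state$b, state$m, state$v)
  rel <- mapply(function(rt, f) {
    pos <- f > 0
    if (!any(pos)) return(0)
    max(abs(rt[pos]) / f[pos])
  }, r, dens)
  rmax <- max(rel, na.rm = TRUE)
  if (rmax > 0) dts <- c(dts, 1 / rmax)
  if (!length(dts)) return(p$dt_max)
  min(p$safety * min(dts), p$dt_max)
}

#' One explicit step of the coupled density system
#'
#' Forward-Euler update combining porous-medium diffusion, haptotaxis and
#' reactions for all five fields. Negative values produced by round-off (or
#' by the upwind advection near steep fronts) are clipped to zero and the
#' clipped mass accumulated in \code{state$clipped_mass}. The MMP field
#' diffuses with \code{D_m} by default (switchable to \code{D_E} via
#' \code{p$mmp_diffusion}); TGF-beta with \code{D_b}; the matrix does not
#' move.
#'
#' @param state an \code{msim_state} (with \code{cM} refreshed from the agent
#'   set if agents are present).
#' @param p an \code{msim_params}.
#' @param dt time step in days (should not exceed \code{stable_dt}).
#' @param emt_sink,met_source,footprint optional coupling fields, see
#'   \code{\link{reactions}}.
#' @param linear_diffusion if TRUE the ECC (and CAF) diffusion is the linear
#'   heat operator \code{D lap(c)} instead of the degenerate porous-medium
#'   form; a validation mode for contrasting infinite versus finite
#'   propagation speed.
#' @return the updated \code{msim_state}.
#' @export
step_density <- function(state, p, dt, emt_sink = NULL, met_source = NULL,
                         footprint = NULL, linear_diffusion = FALSE) {
  g <- state$grid
  r <- reactions(state, p, emt_sink, met_source, footprint)
  if (linear_diffusion) {
    diff_E <- p$D_E * laplacian(state$cE, g)
    diff_F <- p$D_F * laplacian(state$cF, g)
  } else {
    diff_E <- pme_divergence(state$cE, g, p$D_E)
    diff_F <- pme_divergence(state$cF, g, p$D_F)
  }
  D_m_eff <- if (identical(p$mmp_diffusion, "D_E")) p$D_E else p$D_m
  d_cE <- diff_E + haptotaxis_divergence(state$cE, state$v, g, p$chi_E, +1) + r$cE
  d_cF <- diff_F + haptotaxis_divergence(state$cF, state$v, g, p$chi_F, -1) + r$cF
  d_b <- p$D_b * laplacian(state$b, g) + r$b
  d_m <- D_m_eff * laplacian(state$m, g) + r$m
  d_v <- r$v
  upd <- list(cE = state$cE + dt * d_cE, cF = state$cF + dt * d_cF,
              b = state$b + dt * d_b, m = state$m + dt * d_m,
              v = state$v + dt * d_v)
  for (nm in names(upd)) {
    f <- upd[[nm]]
    if (!all(is.finite(f)))
      stop("numerical blow-up in field '", nm, "' at t = ", state$time,
           " d (non-finite values after step)")
    neg <- f < 0
    if (any(neg)) {
      state$clipped_mass <- state$clipped_mass - sum(f[neg]) * g$cell_volume
      f[neg] <- 0
    }
    state[[nm]] <- f
  }
  state$time <- state$time + dt
  state
}

#' Bounding-box support width of a field
#'
#' Number of cells spanned by the support \code{f > tol} along each axis;
#' used to audit the finite-propagation property of the degenerate
#' diffusion.
#'
#' @param f array.
#' @param tol support threshold.
#' @return integer vector (one width per axis), zero for an empty support.
#' @export
support_width <- function(f, tol = 0) {
  d <- dim(f)
  if (is.null(d)) d <- length(f)
  idx <- which(f > tol, arr.ind = TRUE)
  if (length(idx) == 0L) return(integer(length(d)))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  apply(idx, 2, function(i) max(i) - min(i) + 1L)
}
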