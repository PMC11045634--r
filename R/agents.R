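#' Saturated haptotactic drift law
#'
#' Maps the local matrix gradient to a drift velocity whose magnitude
#' saturates at the maximum cell speed: \code{mu(z) = A atan(z / A)} with
#' \code{A = 2 V_thr / pi}, applied to the gradient magnitude with the
#' direction preserved (so the speed is strictly below \code{V_thr} for any
#' finite gradient and tends to it as the gradient blows up). A
#' componentwise variant applies the scalar law to each component
#' independently.
#'
#' @param grad_v numeric matrix (n x dim) of matrix-gradient vectors, or a
#'   single vector.
#' @param V_thr maximum cell speed (cm d^-1).
#' @param mode \code{"magnitude"} (default) or \code{"componentwise"}.
#' @return matrix (n x dim) of drift velocities (cm d^-1).
#' @examples
#' drift_mu(c(0, 0, 0), V_thr = 2.16)          # no gradient, no drift
#' sqrt(sum(drift_mu(c(1e9, 0, 0), 2.16)^2))   # ~ 2.16: saturated
#' @export
drift_mu <- function(grad_v, V_thr, mode = c("magnitude", "componentwise")) {
  mode <- match.arg(mode)
  if (is.null(dim(grad_v))) grad_v <- matrix(grad_v, nrow = 1)
  A <- 2 * V_thr / pi
  if (mode == "componentwise") return(A * atan(grad_v / A))
  z <- sqrt(rowSums(grad_v^2))
  speed <- A * atan(z / A)
  scale <- ifelse(z > 0, speed / z, 0)
  grad_v * scale
}

#' Compound-Poisson jump increment
#'
#' One increment of the compound-Poisson reorientation noise over a step of
#' length \code{tau}: with probability \code{1 - exp(-lam_cpp * tau)} (the
#' probability that at least one Poisson event fell in the step) an
#' independent jump is drawn -- isotropic direction uniform on the unit
#' sphere (or circle) times a half-Gaussian magnitude with standard
#' deviation \code{sqrt(tau)} -- otherwise the zero vector. Consumes the
#' global RNG stream.
#'
#' @param n number of increments to draw.
#' @param dim spatial dimension (2 or 3).
#' @param p an \code{msim_params} (uses \code{lam_cpp}).
#' @param tau step length (days).
#' @return matrix (n x dim) of unscaled jump vectors (multiply by
#'   \code{sigma} for the displacement contribution).
#' @export
cpp_increment <- function(n, dim, p, tau) {
  stopifnot(tau > 0)
  out <- matrix(0, n, dim)
  if (n == 0L || p$lam_cpp == 0) return(out)
  jump <- stats::runif(n) < (1 - exp(-p$lam_cpp * tau))
  nj <- sum(jump)
  if (nj == 0L) return(out)
  dir <- matrix(stats::rnorm(nj * dim), nj, dim)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  dir <- dir / nrm
  mag <- abs(stats::rnorm(nj, 0, sqrt(tau)))
  out[jump, ] <- dir * mag
  out
}

#' Mirror-reflect positions into the domain
#'
#' Coordinates outside the domain are folded back across the violated wall
#' (\code{x -> 2 hi - x} or \code{2 lo - x}), iterated until inside;
#' positions already inside are unchanged. An alternative wall rule,
#' \code{"last_position"}, is applied in \code{\link{step_cells}}.
#'
#' @param x numeric matrix (n x dim) of positions, or a single vector.
#' @param grid an \code{msim_grid}.
#' @return matrix of positions inside the closed domain.
#' @export
reflect <- function(x, grid) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  for (a in seq_len(grid$dim)) {
    lo <- grid$extent[1, a]; hi <- grid$extent[2, a]
    w <- hi - lo
    xa <- x[, a]
    bad <- which(xa < lo | xa > hi)
    for (i in bad) {
      y <- (xa[i] - lo) %% (2 * w)
      xa[i] <- lo + ifelse(y <= w, y, 2 * w - y)
    }
    x[, a] <- xa
  }
  if (single) x[1, ] else x
}

#' One Euler-Maruyama-type step for all solitary cells
#'
#' For every cell the matrix gradient is interpolated at the cell position,
#' the saturated drift and the compound-Poisson jump are combined into a
#' displacement, the implied velocity is rescaled onto the speed cap
#' \code{V_thr} if exceeded, and the new position is folded back into the
#' domain. Masses are unchanged. Consumes the global RNG stream.
#'
#' @param cells an \code{msim_cells} set with all positions inside the
#'   domain.
#' @param v_field matrix density array on \code{grid}.
#' @param grid an \code{msim_grid}.
#' @param p an \code{msim_params} (uses \code{V_thr}, \code{sigma},
#'   \code{lam_cpp}, \code{boundary}, \code{drift_mode}).
#' @param tau step length (days).
#' @return the updated \code{msim_cells} set.
#' @export
step_cells <- function(cells, v_field, grid, p, tau) {
  n <- n_cells(cells)
  if (n == 0L) return(cells)
  gv <- gradient(v_field, grid)
  G <- vapply(gv, function(comp) interp_at(comp, grid, cells$positions),
              numeric(n))
  if (is.null(dim(G))) G <- matrix(G, nrow = n)
  drift <- drift_mu(G, p$V_thr, p$drift_mode)
  Z <- cpp_increment(n, grid$dim, p, tau)
  dx <- drift * tau + p$sigma * Z
  # speed cap: rescale the implied velocity dx/tau onto V_thr if exceeded
  spd <- sqrt(rowSums(dx^2)) / tau
  over <- spd > p$V_thr
  if (any(over)) dx[over, ] <- dx[over, , drop = FALSE] * (p$V_thr / spd[over])
  newpos <- cells$positions + dx
  if (!all(is.finite(newpos))) {
    bad <- cells$ids[!apply(is.finite(newpos), 1, all)]
    stop("non-finite position for cell id(s): ", paste(bad, collapse = ", "))
  }
  if (identical(p$boundary, "last_position")) {
    out <- rep(FALSE, n)
    for (a in seq_len(grid$dim))
      out <- out | newpos[, a] < grid$extent[1, a] |
        newpos[, a] > grid$extent[2, a]
    newpos[out, ] <- cells$positions[out, , drop = FALSE]
  } else {
    newpos <- reflect(newpos, grid)
  }
  cells$positions <- newpos
  cells
}
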