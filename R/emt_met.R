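#' TGF-beta-dependent EMT rate
#'
#' Shifted logistic switch: \code{zeta(b) = L / (1 + exp(-k (b - b_T)))}.
#' Strictly increasing in the TGF-beta density \code{b}, equals \code{L/2}
#' at the threshold \code{b_T}, tends to the ceiling \code{L} for large
#' \code{b} and is numerically zero well below the threshold when the
#' steepness \code{k} is large.
#'
#' @param b TGF-beta density (g cm^-3), scalar or array.
#' @param p an \code{msim_params} (uses \code{L}, \code{k}, \code{b_T}).
#' @return EMT event rate(s) in d^-1.
#' @examples
#' p <- model_params(L = 0.05, k = 1e3, b_T = 0.01)
#' emt_rate(0.01, p)   # L/2 at the threshold
#' @export
emt_rate <- function(b, p) p$L / (1 + exp(-p$k * (b - p$b_T)))

#' Sample EMT event counts per partition cell
#'
#' On each partition cell whose mean epithelial density reaches the gate
#' \code{C_ref}, the number of EMT events in a step of length \code{tau} is
#' Poisson with intensity \code{zeta(mean b) * tau}; gated cells get zero.
#' Counts are capped so that the mass converted (\code{count * m_cell})
#' never exceeds the epithelial mass available on the partition cell.
#' Consumes the global RNG stream.
#'
#' @param cE,b epithelial and TGF-beta density arrays on \code{part$grid}.
#' @param part an \code{msim_partition}.
#' @param p an \code{msim_params} (resolved, i.e. \code{m_cell} numeric).
#' @param tau step length (days).
#' @return integer array of event counts with \code{dim = part$m_shape}.
#' @export
sample_emt_events <- function(cE, b, part, p, tau) {
  stopifnot(tau > 0)
  p <- resolve_params(p, part)
  cE_bar <- block_mean(cE, part)
  b_bar <- block_mean(b, part)
  eligible <- cE_bar >= p$C_ref
  lam <- emt_rate(b_bar, p) * tau
  counts <- array(0L, dim = part$m_shape)
  idx <- which(eligible)
  if (length(idx)) {
    a <- stats::rpois(length(idx), lam[idx])
    avail <- cE_bar[idx] * part$m_volume            # mass on the M-cell
    cap <- floor(avail / p$m_cell)
    counts[idx] <- as.integer(pmin(a, cap))
  }
  counts
}

#' Apply EMT events: density mass becomes solitary cells
#'
#' For every event on a partition cell, \code{mu_E_EMT * m_cell} of
#' epithelial mass is removed from that cell (proportionally to the local
#' density within it, so non-negativity is preserved exactly) and one
#' solitary mesenchymal cell of the same mass materialises at the partition
#' cell barycentre with a fresh id. The combined epithelial + solitary mass
#' is unchanged to round-off.
#'
#' @param state an \code{msim_state}.
#' @param cells an \code{msim_cells} set.
#' @param events integer array from \code{\link{sample_emt_events}}.
#' @param p an \code{msim_params}.
#' @param part an \code{msim_partition}.
#' @return list \code{(state, cells, log)}; \code{log} is a data frame of
#'   events (partition index, count, mass).
#' @export
apply_emt <- function(state, cells, events, p, part) {
  p <- resolve_params(p, part)
  idx <- which(events > 0)
  if (!length(idx))
    return(list(state = state, cells = cells,
                log = data.frame(m_index = integer(0), count = integer(0),
                                 mass = numeric(0))))
  cE_mass <- block_sum(state$cE, part) * part$grid$cell_volume
  bary <- partition_barycentres(part)
  remove_frac <- array(0, dim = part$m_shape)
  newpos <- NULL; newmass <- NULL
  for (i in idx) {
    a <- events[i]
    m_conv <- p$mu_E_EMT * p$m_cell * a
    if (m_conv > cE_mass[i] * (1 + 1e-12))
      stop("EMT events exceed available epithelial mass on partition cell ", i)
    m_conv <- min(m_conv, cE_mass[i])
    remove_frac[i] <- m_conv / cE_mass[i]
    newpos <- rbind(newpos, matrix(rep(bary[i, ], a), nrow = a, byrow = TRUE))
    newmass <- c(newmass, rep(m_conv / a, a))
  }
  state$cE <- state$cE * (1 - block_expand(remove_frac, part))
  cells <- add_cells(cells, newpos, newmass)
  list(state = state, cells = cells,
       log = data.frame(m_index = idx, count = as.integer(events[idx]),
                        mass = as.numeric(remove_frac[idx] * cE_mass[idx])))
}

#' Sample MET decisions for the solitary cells
#'
#' Each solitary cell independently reverts to the epithelial phenotype
#' with probability \code{1 - exp(-r_met * tau)} -- the probability that its
#' fixed-rate Poisson clock fired at least once in the step. Consumes the
#' global RNG stream.
#'
#' @param cells an \code{msim_cells} set.
#' @param p an \code{msim_params} (uses \code{r_met}).
#' @param tau step length (days).
#' @return integer vector of flagged cell ids (possibly empty).
#' @export
sample_met <- function(cells, p, tau) {
  stopifnot(tau > 0)
  n <- n_cells(cells)
  if (n == 0L || p$r_met == 0) return(integer(0))
  flag <- stats::runif(n) < (1 - exp(-p$r_met * tau))
  cells$ids[flag]
}

#' Apply MET: flagged solitary cells become epithelial density
#'
#' The flagged cells are removed from the population and their masses
#' deposited onto the epithelial density field through the
#' solitary-cell-to-density operator (footprint side \code{K}). Total mass
#' is conserved to round-off.
#'
#' @param state an \code{msim_state}.
#' @param cells an \code{msim_cells} set.
#' @param ids integer ids flagged by \code{\link{sample_met}}.
#' @param p an \code{msim_params}.
#' @param part an \code{msim_partition}.
#' @return list \code{(state, cells, log)}.
#' @export
apply_met <- function(state, cells, ids, p, part) {
  if (!length(ids))
    return(list(state = state, cells = cells,
                log = data.frame(cell_id = integer(0), mass = numeric(0))))
  p <- resolve_params(p, part)
  keep_ids <- ids[ids %in% cells$ids]
  if (length(keep_ids) != length(ids))
    stop("apply_met: unknown cell id(s): ",
         paste(setdiff(ids, cells$ids), collapse = ", "))
  sel <- cells$ids %in% ids
  revert <- cell_set(cells$positions[sel, , drop = FALSE],
                     cells$masses[sel], ids = cells$ids[sel])
  dep <- cells_to_density(revert, part, K = p$K)
  state$cE <- state$cE + p$mu_M_MET * dep
  cells <- remove_cells(cells, ids)
  list(state = state, cells = cells,
       log = data.frame(cell_id = ids, mass = revert$masses))
}
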