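#' Partition of the domain into biological-cell-sized blocks
#'
#' The phase-transition operators act on a partition of the domain into equal
#' rectangular cells (usually the size of the biological cell under study).
#' Each partition cell aggregates an integer block of computational cells.
#'
#' @param grid an \code{msim_grid}.
#' @param factor integer coarsening factor per axis (recycled); must divide
#'   the grid shape exactly.
#' @return an object of class \code{"msim_partition"}: the parent grid, the
#'   per-axis factor, partition shape \code{m_shape}, partition cell spacing
#'   \code{m_spacing} (cm) and volume \code{m_volume} (cm^dim), and the
#'   barycentre coordinate vectors \code{centres}.
#' @export
make_partition <- function(grid, factor = 1L) {
  factor <- as.integer(rep_len(factor, grid$dim))
  if (any(factor < 1L)) stop("coarsening factor must be >= 1")
  if (any(grid$shape %% factor != 0L))
    stop("coarsening factor (", paste(factor, collapse = ","),
         ") must divide the grid shape (", paste(grid$shape, collapse = ","),
         ") exactly")
  m_shape <- grid$shape %/% factor
  m_spacing <- grid$spacing * factor
  centres <- lapply(seq_len(grid$dim), function(a)
    grid$extent[1, a] + (seq_len(m_shape[a]) - 0.5) * m_spacing[a])
  structure(list(
    grid = grid, factor = factor, m_shape = m_shape,
    m_spacing = m_spacing, m_volume = prod(m_spacing), centres = centres
  ), class = "msim_partition")
}

## Sum a fine-grid array over the partition blocks -> array of dim m_shape.
block_sum <- function(f, part) {
  d <- part$grid$dim
  if (all(part$factor == 1L)) return(f)
  interleaved <- as.vector(rbind(part$factor, part$m_shape))
  dim(f) <- interleaved
  apply(f, seq_len(2 * d)[c(FALSE, TRUE)], sum)
}

block_mean <- function(f, part) block_sum(f, part) / prod(part$factor)

## Expand a partition-level array back to the fine grid (piecewise constant).
block_expand <- function(fm, part) {
  if (all(part$factor == 1L)) {
    dim(fm) <- part$grid$shape
    return(fm)
  }
  d <- part$grid$dim
  maps <- lapply(seq_len(d), function(a)
    rep(seq_len(part$m_shape[a]), each = part$factor[a]))
  idx <- as.matrix(do.call(expand.grid, maps))
  array(fm[idx], dim = part$grid$shape)
}

## Barycentre coordinates of partition cells, as a (#M x dim) matrix in the
## array's linear order.
partition_barycentres <- function(part) {
  as.matrix(do.call(expand.grid, part$centres))
}

#' Solitary-cell set
#'
#' Constructs the solitary mesenchymal cell population: unique ids, positions
#' (cm, strictly inside the domain) and masses (g).
#'
#' @param positions numeric matrix (n x dim) or NULL for an empty set.
#' @param masses numeric vector of cell masses (> 0).
#' @param ids optional integer ids; defaults to \code{1:n}.
#' @param next_id next id to assign to future cells (never reused).
#' @return a list of class \code{"msim_cells"}.
#' @export
cell_set <- function(positions = NULL, masses = numeric(0), ids = NULL,
                     next_id = NULL) {
  if (is.null(positions)) positions <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  n <- nrow(positions)
  if (length(masses) != n) stop("one mass per cell required")
  if (n && any(masses <= 0)) stop("all cell masses must be > 0")
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  if (is.null(next_id)) next_id <- if (n) max(ids) + 1L else 1L
  structure(list(ids = ids, positions = positions, masses = masses,
                 next_id = as.integer(next_id)),
            class = "msim_cells")
}

#' @export
print.msim_cells <- function(x, ...) {
  cat("<msim_cells> ", length(x$ids), " solitary cells, total mass ",
      format(sum(x$masses)), " g\n", sep = "")
  invisible(x)
}

n_cells <- function(cells) length(cells$ids)

add_cells <- function(cells, positions, masses) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  n_new <- nrow(positions)
  if (n_new == 0L) return(cells)
  new_ids <- cells$next_id + seq_len(n_new) - 1L
  cell_set(rbind(cells$positions, positions),
           c(cells$masses, masses),
           ids = c(cells$ids, new_ids),
           next_id = cells$next_id + n_new)
}

remove_cells <- function(cells, ids) {
  if (!all(ids %in% cells$ids)) stop("unknown cell id(s): ",
                                     paste(setdiff(ids, cells$ids), collapse = ", "))
  keep <- !(cells$ids %in% ids)
  cell_set(cells$positions[keep, , drop = FALSE], cells$masses[keep],
           ids = cells$ids[keep], next_id = cells$next_id)
}

#' Density-to-solitary-cell operator
#'
#' For every partition cell whose integrated mass reaches \code{mass_floor},
#' emits one solitary cell carrying exactly that mass, positioned at the
#' partition-cell barycentre. The conversion is exactly mass conservative over
#' the emitting partition cells (midpoint quadrature on the computational
#' subgrid, exact for the piecewise-constant fields the solver produces).
#'
#' @param c_field non-negative density array on \code{part$grid}.
#' @param part an \code{msim_partition}.
#' @param mass_floor minimum integrated mass (g) for a cell to materialise.
#' @return an \code{msim_cells} set (ids local, starting at 1).
#' @export
density_to_cells <- function(c_field, part, mass_floor = 0) {
  check_field(c_field, part$grid)
  if (any(c_field < 0)) stop("density_to_cells: negative density")
  masses <- as.vector(block_sum(c_field, part)) * part$grid$cell_volume
  emit <- which(masses >= mass_floor & masses > 0)
  if (!length(emit)) return(cell_set(matrix(numeric(0), 0, part$grid$dim),
                                     numeric(0)))
  cell_set(partition_barycentres(part)[emit, , drop = FALSE], masses[emit])
}

## Per-axis overlap of the interval [lo, hi] with the partition cells it
## touches; returns list(idx = partition indices, len = overlap lengths).
axis_overlap <- function(lo, hi, ext_lo, H, n) {
  lo <- max(lo, ext_lo)
  hi <- min(hi, ext_lo + n * H)
  k0 <- max(1L, min(n, as.integer(floor((lo - ext_lo) / H)) + 1L))
  k1 <- max(1L, min(n, as.integer(ceiling((hi - ext_lo) / H))))
  ks <- k0:k1
  left <- ext_lo + (ks - 1) * H
  len <- pmin(hi, left + H) - pmax(lo, left)
  keep <- len > 0
  list(idx = ks[keep], len = len[keep])
}

#' Solitary-cell-to-density operator
#'
#' Each solitary cell occupies a cube of side \code{K} centred at its
#' position; its mass is spread over the partition cells in proportion to the
#' geometric overlap, then expressed as a piecewise-constant density. Cubes
#' protruding through the walls are clipped to the domain and the overlap
#' weights renormalised, so no mass is lost at the boundary; the operator is
#' exactly mass conservative.
#'
#' @param cells an \code{msim_cells} set (all positions inside the domain).
#' @param part an \code{msim_partition}.
#' @param K footprint cube side (cm); defaults to the partition-cell side.
#' @return density array on \code{part$grid} (g cm^-3).
#' @export
cells_to_density <- function(cells, part, K = NULL) {
  g <- part$grid
  if (is.null(K)) K <- min(part$m_spacing)
  m_mass <- array(0, dim = part$m_shape)
  if (n_cells(cells)) {
    for (a in seq_len(g$dim)) {
      pa <- cells$positions[, a]
      if (any(pa < g$extent[1, a] | pa > g$extent[2, a]))
        stop("cells_to_density: cell outside the domain on axis ", a)
    }
    for (p in seq_len(n_cells(cells))) {
      ov <- lapply(seq_len(g$dim), function(a)
        axis_overlap(cells$positions[p, a] - K / 2,
                     cells$positions[p, a] + K / 2,
                     g$extent[1, a], part$m_spacing[a], part$m_shape[a]))
      w <- Reduce(outer, lapply(ov, `[[`, "len"))
      w <- w / sum(w)  # renormalised: wall clipping loses no mass
      idx <- as.matrix(do.call(expand.grid, lapply(ov, `[[`, "idx")))
      m_mass[idx] <- m_mass[idx] + cells$masses[p] * as.vector(w)
    }
  }
  block_expand(m_mass / part$m_volume, part)
}

#' Round-trip audit of the phase-transition operators
#'
#' Converts a density to solitary cells and back, reporting the mass error
#' and the sup-norm field difference. For fields piecewise constant on the
#' partition (with footprint equal to the partition cell) the round trip is
#' the identity.
#'
#' @inheritParams density_to_cells
#' @return list with \code{mass_in}, \code{mass_out}, \code{mass_rel_err},
#'   \code{sup_diff}.
#' @export
roundtrip_check <- function(c_field, part) {
  cells <- density_to_cells(c_field, part)
  back <- cells_to_density(cells, part, K = min(part$m_spacing))
  m_in <- field_mass(c_field, part$grid)
  m_out <- field_mass(back, part$grid)
  list(mass_in = m_in, mass_out = m_out,
       mass_rel_err = if (m_in > 0) abs(m_out - m_in) / m_in else abs(m_out),
       sup_diff = max(abs(back - c_field)))
}

#' Agent footprint indicator field
#'
#' Counts, for every computational cell, how many solitary-cell footprint
#' cubes cover its centre (a sum over cells, not a union): the factor
#' multiplying the matrix degradation rate exerted by solitary cells.
#'
#' @param cells an \code{msim_cells} set.
#' @param grid an \code{msim_grid}.
#' @param K footprint cube side (cm).
#' @return integer-valued array on the grid.
#' @export
footprint_indicator <- function(cells, grid, K) {
  out <- new_field(grid)
  if (!n_cells(cells)) return(out)
  for (p in seq_len(n_cells(cells))) {
    rng <- vector("list", grid$dim)
    empty <- FALSE
    for (a in seq_len(grid$dim)) {
      h <- grid$spacing[a]
      lo <- cells$positions[p, a] - K / 2
      hi <- cells$positions[p, a] + K / 2
      # centres at extent_lo + (i - 1/2) h inside [lo, hi]
      i0 <- ceiling((lo - grid$extent[1, a]) / h + 0.5)
      i1 <- floor((hi - grid$extent[1, a]) / h + 0.5)
      i0 <- max(1L, as.integer(i0)); i1 <- min(grid$shape[a], as.integer(i1))
      if (i0 > i1) {
        # cube smaller than the centre spacing: attribute it to the cell
        # containing the agent so sub-grid footprints are never dropped
        ic <- as.integer(floor((cells$positions[p, a] - grid$extent[1, a]) / h)) + 1L
        i0 <- i1 <- max(1L, min(grid$shape[a], ic))
      }
      rng[[a]] <- i0:i1
    }
    if (empty) next
    idx <- as.matrix(do.call(expand.grid, rng))
    out[idx] <- out[idx] + 1
  }
  out
}
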