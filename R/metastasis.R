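#' One organ of the virtual organism
#'
#' An organ is a rectangular tissue domain carrying one density state, one
#' solitary-cell population and one partition for the phase-transition
#' operators.
#'
#' @param id organ identifier (integer or character).
#' @param grid an \code{msim_grid}.
#' @param state an \code{msim_state}; default all-zero fields.
#' @param cells an \code{msim_cells}; default empty.
#' @param partition an \code{msim_partition}; default factor 1.
#' @return a list of class \code{"msim_organ"}.
#' @export
make_organ <- function(id, grid, state = NULL, cells = NULL,
                       partition = NULL) {
  if (is.null(state)) state <- density_state(grid)
  if (is.null(cells)) cells <- cell_set(matrix(numeric(0), 0, grid$dim),
                                        numeric(0))
  if (is.null(partition)) partition <- make_partition(grid, 1L)
  structure(list(id = id, grid = grid, state = state, cells = cells,
                 partition = partition),
            class = "msim_organ")
}

empty_transit <- function() {
  data.frame(ctc_id = integer(0), origin = integer(0), mass = numeric(0),
             entry_time = numeric(0), status = character(0),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(time = numeric(0), organ = integer(0), kind = character(0),
             count = integer(0), mass = numeric(0), stringsAsFactors = FALSE)
}

#' A virtual organism: organs coupled by a circulatory network
#'
#' @param organs list of \code{msim_organ}.
#' @param connectivity symmetric 0/1 adjacency matrix over organs (no
#'   self-loops by default: a circulating cell does not re-enter its organ
#'   of origin unless a self-loop is set explicitly).
#' @return a list of class \code{"msim_organism"} with the organs, the
#'   connectivity, the in-transit circulating-cell table, an event log and
#'   the audit table.
#' @export
make_organism <- function(organs, connectivity = NULL) {
  n <- length(organs)
  if (is.null(connectivity)) {
    connectivity <- matrix(1, n, n) - diag(n)
  }
  connectivity <- as.matrix(connectivity)
  if (!isTRUE(all.equal(connectivity, t(connectivity))))
    stop("connectivity must be symmetric (bidirectional circulation)")
  structure(list(organs = organs, connectivity = connectivity,
                 transit = empty_transit(), next_ctc_id = 1L,
                 events = empty_events(), audit = NULL, time = 0),
            class = "msim_organism")
}

#' @export
print.msim_organism <- function(x, ...) {
  cat("<msim_organism> ", length(x$organs), " organs, t = ",
      format(x$time), " d, ", sum(x$transit$status == "in_transit"),
      " CTC(s) in transit\n", sep = "")
  invisible(x)
}

#' Sample intravasation departures
#'
#' Every solitary cell independently enters the circulation during a step
#' of length \code{tau} with probability \code{1 - exp(-lam_intra * tau)}
#' (at least one event of its Poisson intravasation clock). Consumes the
#' global RNG stream.
#'
#' @param cells an \code{msim_cells} set.
#' @param p an \code{msim_params} (uses \code{lam_intra}).
#' @param tau step length (days).
#' @return integer vector of departing cell ids.
#' @export
sample_intravasation <- function(cells, p, tau) {
  stopifnot(tau > 0)
  n <- n_cells(cells)
  if (n == 0L || p$lam_intra == 0) return(integer(0))
  flag <- stats::runif(n) < (1 - exp(-p$lam_intra * tau))
  cells$ids[flag]
}

uniform_interior_position <- function(grid) {
  vapply(seq_len(grid$dim), function(a)
    stats::runif(1, grid$extent[1, a], grid$extent[2, a]), numeric(1))
}

#' Resolve circulating tumour cells
#'
#' Every circulating cell that entered the network before the organism's
#' current time is resolved: it survives the circulatory stresses with
#' probability \code{p_survive} (default 0.1\%), otherwise it dies. A
#' survivor extravasates into an organ drawn uniformly among those
#' connected to its organ of origin, arriving as a solitary mesenchymal
#' cell at a uniformly random interior position with its mass intact.
#' Consumes the global RNG stream.
#'
#' @param organism an \code{msim_organism}.
#' @param p an \code{msim_params} (uses \code{p_survive}).
#' @return the updated organism (transit statuses become terminal, arrivals
#'   appended to destination organs, deaths and extravasations logged).
#' @export
resolve_transit <- function(organism, p) {
  tr <- organism$transit
  due <- which(tr$status == "in_transit" & tr$entry_time < organism$time)
  if (!length(due)) return(organism)
  for (orig in unique(tr$origin[due])) {
    if (!any(organism$connectivity[orig, ] > 0))
      stop("organ ", orig,
           " has circulating cells but no circulatory connections")
  }
  surv <- stats::runif(length(due)) < p$p_survive
  died <- due[!surv]
  if (length(died)) {
    tr$status[died] <- "died"
    per_origin <- tapply(tr$mass[died], tr$origin[died], sum)
    cnt <- table(tr$origin[died])
    organism$events <- rbind(organism$events, data.frame(
      time = organism$time, organ = as.integer(names(per_origin)),
      kind = "ctc_death", count = as.integer(cnt[names(per_origin)]),
      mass = as.numeric(per_origin)))
  }
  alive <- due[surv]
  if (length(alive)) {
    dest <- vapply(tr$origin[alive], function(orig) {
      nbr <- which(organism$connectivity[orig, ] > 0)
      if (length(nbr) == 1L) nbr else nbr[sample.int(length(nbr), 1L)]
    }, integer(1))
    tr$status[alive] <- "extravasated"
    for (k in unique(dest)) {
      sel <- dest == k
      org <- organism$organs[[k]]
      pos <- t(vapply(seq_len(sum(sel)), function(i)
        uniform_interior_position(org$grid), numeric(org$grid$dim)))
      org$cells <- add_cells(org$cells, pos, tr$mass[alive[sel]])
      organism$organs[[k]] <- org
      organism$events <- rbind(organism$events, data.frame(
        time = organism$time, organ = k, kind = "extravasation",
        count = sum(sel), mass = sum(tr$mass[alive[sel]])))
    }
  }
  organism$transit <- tr
  organism
}

## One hybrid step for a single organ; returns organ + event rows.
step_organ <- function(org, p, dt, time) {
  part <- org$partition
  pr <- resolve_params(p, part)
  ev <- empty_events()
  # refresh the mesenchymal density and footprint from the agent set
  org$state$cM <- cells_to_density(org$cells, part, K = pr$K)
  fp <- footprint_indicator(org$cells, org$grid, pr$K)
  # transport + reactions; transport conserves mass, so the cE mass change
  # across this call is the logged reaction (proliferation) contribution
  cE0 <- field_mass(org$state$cE, org$grid)
  org$state <- step_density(org$state, pr, dt, footprint = fp)
  reaction_delta <- field_mass(org$state$cE, org$grid) - cE0
  # EMT: density mass -> new solitary cells
  events <- sample_emt_events(org$state$cE, org$state$b, part, pr, dt)
  res <- apply_emt(org$state, org$cells, events, pr, part)
  org$state <- res$state; org$cells <- res$cells
  if (nrow(res$log))
    ev <- rbind(ev, data.frame(time = time + dt, organ = org$id, kind = "EMT",
                               count = sum(res$log$count),
                               mass = sum(res$log$mass)))
  # MET: solitary cells -> density
  ids <- sample_met(org$cells, pr, dt)
  resm <- apply_met(org$state, org$cells, ids, pr, part)
  org$state <- resm$state; org$cells <- resm$cells
  if (nrow(resm$log))
    ev <- rbind(ev, data.frame(time = time + dt, organ = org$id, kind = "MET",
                               count = nrow(resm$log),
                               mass = sum(resm$log$mass)))
  # agent migration
  org$cells <- step_cells(org$cells, org$state$v, org$grid, pr, dt)
  list(organ = org, events = ev, reaction_delta = reaction_delta)
}

#' One global step of the organism
#'
#' Per organ: mesenchymal density refresh, density transport + reactions,
#' EMT, MET, agent migration, intravasation; then the circulating cells that
#' entered at earlier steps are resolved (death or extravasation). An audit
#' row balances the total cancer mass: it may change only through the
#' logged proliferation/clipping of the density step and the logged deaths
#' in circulation.
#'
#' @param organism an \code{msim_organism}.
#' @param p an \code{msim_params}.
#' @param dt time step (days), at most the smallest stable step over organs.
#' @return the updated organism.
#' @export
step_organism <- function(organism, p, dt) {
  t0 <- organism$time
  mass_before <- organism_cancer_mass(organism)
  clip_delta <- 0
  reaction_delta <- 0
  for (k in seq_along(organism$organs)) {
    org <- organism$organs[[k]]
    clip0 <- org$state$clipped_mass
    res <- tryCatch(step_organ(org, p, dt, t0), error = function(e)
      stop("organ ", org$id, ": ", conditionMessage(e)))
    org <- res$organ
    organism$events <- rbind(organism$events, res$events)
    reaction_delta <- reaction_delta + res$reaction_delta
    # intravasation
    dep <- sample_intravasation(org$cells, p, dt)
    if (length(dep)) {
      sel <- org$cells$ids %in% dep
      masses <- org$cells$masses[sel]
      newrec <- data.frame(
        ctc_id = organism$next_ctc_id + seq_along(dep) - 1L,
        origin = k, mass = masses, entry_time = t0 + dt,
        status = "in_transit", stringsAsFactors = FALSE)
      organism$next_ctc_id <- organism$next_ctc_id + length(dep)
      organism$transit <- rbind(organism$transit, newrec)
      org$cells <- remove_cells(org$cells, dep)
      organism$events <- rbind(organism$events, data.frame(
        time = t0 + dt, organ = org$id, kind = "intravasation",
        count = length(dep), mass = sum(masses)))
    }
    organism$organs[[k]] <- org
    clip_delta <- clip_delta + (org$state$clipped_mass - clip0)
  }
  organism$time <- t0 + dt
  organism <- resolve_transit(organism, p)
  mass_after <- organism_cancer_mass(organism)
  died <- sum(subset(organism$events,
                     organism$events$time == organism$time &
                       organism$events$kind == "ctc_death")$mass)
  delta <- mass_after - mass_before
  row <- data.frame(time = organism$time, mass = mass_after,
                    delta = delta, reaction = reaction_delta, died = died,
                    clipped = clip_delta,
                    residual = delta - reaction_delta + died)
  organism$audit <- rbind(organism$audit, row)
  organism
}

#' Total cancer mass of the organism
#'
#' Epithelial density mass plus solitary-cell masses over all organs plus
#' the mass still in transit (in-transit circulating cells only; died and
#' extravasated records are terminal).
#'
#' @param organism an \code{msim_organism}.
#' @return mass in g.
#' @export
organism_cancer_mass <- function(organism) {
  dens <- sum(vapply(organism$organs, function(o)
    field_mass(o$state$cE, o$grid) + sum(o$cells$masses), numeric(1)))
  dens + sum(organism$transit$mass[organism$transit$status == "in_transit"])
}
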