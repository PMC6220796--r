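# Reference (pure R) implementation of the grid state and its single-event
# operations. This is the readable specification of the model's semantics;
# `sim_run()` delegates to a C++ engine with identical behaviour for
# production-size runs. State is held in an environment so the operations
# mutate in place, as the event loop requires.
#
# Internal representation:
#   occ        list of integer vectors, species present in each cell
#              (cells are 0-based linear indices, row-major)
#   pop_sp/pop_cell  flat population index (uniform O(1) sampling,
#              swap-with-last deletion)
#   species table columns (parent, origin, death, death_type, range),
#              species ids are 1-based monotone integers; founder = 1
#   death_type: 0 extant, 1 local extinction of last population,
#              2 pseudoextinction (single-population parent at speciation)

#' Initialize a simulation state
#'
#' Creates the starting state of the model: a single founder species
#' occupying one uniformly random cell at time 0, and an event log holding
#' the founding record.
#'
#' @param params A [sim_params()] object.
#' @return A `divgrid_state` environment with the current clock `t`,
#'   per-cell occupancy, the flat population index and the species table.
#' @seealso [advance_one_event()], [sim_run()]
#' @export
init_simulation <- function(params) {
  stopifnot(inherits(params, "divgrid_params"))
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$t <- 0
  st$occ <- rep(list(integer(0)), params$area)
  st$pop_sp <- integer(0)
  st$pop_cell <- integer(0)
  st$parent <- integer(0)
  st$origin <- numeric(0)
  st$death <- numeric(0)
  st$death_type <- integer(0)
  st$range <- integer(0)
  st$n_extant <- 0L
  st$events <- list()
  class(st) <- "divgrid_state"

  cell0 <- sample.int(params$area, 1L) - 1L
  .st_new_species(st, NA_integer_, 0)
  .st_add_pop(st, 1L, cell0)
  .st_log(st, 0, "speciation", NA_integer_, cell0, daughter = 1L)
  st
}

.st_new_species <- function(st, parent, origin) {
  st$parent <- c(st$parent, parent)
  st$origin <- c(st$origin, origin)
  st$death <- c(st$death, NA_real_)
  st$death_type <- c(st$death_type, 0L)
  st$range <- c(st$range, 0L)
  st$n_extant <- st$n_extant + 1L
  length(st$parent)
}

.st_add_pop <- function(st, sp, cell) {
  st$pop_sp <- c(st$pop_sp, sp)
  st$pop_cell <- c(st$pop_cell, cell)
  st$occ[[cell + 1L]] <- c(st$occ[[cell + 1L]], sp)
  st$range[sp] <- st$range[sp] + 1L
}

.st_remove_pop <- function(st, j) {
  sp <- st$pop_sp[j]; cell <- st$pop_cell[j]
  o <- st$occ[[cell + 1L]]
  st$occ[[cell + 1L]] <- o[-match(sp, o)]
  st$range[sp] <- st$range[sp] - 1L
  n <- length(st$pop_sp)
  st$pop_sp[j] <- st$pop_sp[n]; st$pop_cell[j] <- st$pop_cell[n]
  st$pop_sp <- st$pop_sp[-n]; st$pop_cell <- st$pop_cell[-n]
}

.st_log <- function(st, time, kind, species, cell,
                    daughter = NA_integer_, no_effect = NA) {
  st$events[[length(st$events) + 1L]] <- list(
    time = time, kind = kind, species = species, cell = cell,
    daughter = daughter, no_effect = no_effect)
}

.st_kill <- function(st, sp, type) {
  st$death[sp] <- st$t
  st$death_type[sp] <- type
  st$n_extant <- st$n_extant - 1L
  .st_log(st, st$t, "species_extinction", sp, NA_integer_)
}

#' Total event rate of the current state
#'
#' All three processes are per-population with uniform rates, so the total
#' rate is `N_pop * (lambda + gamma + mu)` where `N_pop` is the current
#' number of populations.
#'
#' @param state A `divgrid_state`.
#' @return The total rate (0 for an extinct clade).
#' @export
total_event_rate <- function(state) {
  p <- state$params
  length(state$pop_sp) * (p$lambda + p$gamma + p$mu)
}

#' Apply one speciation event
#'
#' Point speciation: the chosen population is relabeled as a new species
#' (the daughter, initial range 1), so parent and daughter start with
#' disjoint ranges and the total population count is unchanged. A parent
#' whose only population speciates is recorded as pseudoextinct at the same
#' timestamp.
#'
#' @param state A `divgrid_state`.
#' @param j Index of the population (1-based position in the flat index).
#' @return The daughter species id, invisibly.
#' @export
apply_speciation <- function(state, j) {
  parent <- state$pop_sp[j]; cell <- state$pop_cell[j]
  dau <- .st_new_species(state, parent, state$t)
  o <- state$occ[[cell + 1L]]
  o[match(parent, o)] <- dau
  state$occ[[cell + 1L]] <- o
  state$pop_sp[j] <- dau
  state$range[parent] <- state$range[parent] - 1L
  state$range[dau] <- state$range[dau] + 1L
  .st_log(state, state$t, "speciation", parent, cell, daughter = dau)
  if (state$range[parent] == 0L) .st_kill(state, parent, 2L)
  invisible(dau)
}

#' Apply one colonization event
#'
#' Local dispersal draws one of the four cardinal neighbours uniformly; the
#' event is a no-op (flagged, state unchanged) if the target is off-grid,
#' already contains the species, or is saturated at the local limit. Global
#' dispersal draws uniformly from eligible cells (or, with
#' `global_uniform`, from all cells with no-op semantics).
#'
#' @inheritParams apply_speciation
#' @return `TRUE` if a population was added, `FALSE` for a no-op.
#' @export
apply_colonization <- function(state, j) {
  p <- state$params
  sp <- state$pop_sp[j]; cell <- state$pop_cell[j]
  eligible <- function(cand) {
    o <- state$occ[[cand + 1L]]
    length(o) < p$k_local && !(sp %in% o)
  }
  target <- -1L
  if (p$dispersal == "local") {
    dir <- sample.int(4L, 1L)
    r <- cell %/% p$ncol; cc <- cell %% p$ncol
    if (dir == 1L) r <- r - 1L else if (dir == 2L) r <- r + 1L
    else if (dir == 3L) cc <- cc - 1L else cc <- cc + 1L
    if (r >= 0 && r < p$nrow && cc >= 0 && cc < p$ncol) {
      cand <- r * p$ncol + cc
      if (eligible(cand)) target <- cand
    }
  } else if (p$global_uniform) {
    cand <- sample.int(p$area, 1L) - 1L
    if (eligible(cand)) target <- cand
  } else {
    cands <- which(vapply(0:(p$area - 1L), eligible, logical(1))) - 1L
    if (length(cands) > 0) target <- cands[sample.int(length(cands), 1L)]
  }
  if (target >= 0L) {
    .st_add_pop(state, sp, target)
    .st_log(state, state$t, "colonization", sp, target, no_effect = FALSE)
    TRUE
  } else {
    .st_log(state, state$t, "colonization", sp, cell, no_effect = TRUE)
    FALSE
  }
}

#' Apply one local extinction event
#'
#' Removes the chosen population. If it was the species' last population, a
#' species extinction is recorded at the same timestamp.
#'
#' @inheritParams apply_speciation
#' @return `TRUE` if the species went extinct, else `FALSE`.
#' @export
apply_local_extinction <- function(state, j) {
  sp <- state$pop_sp[j]; cell <- state$pop_cell[j]
  .st_remove_pop(state, j)
  .st_log(state, state$t, "local_extinction", sp, cell)
  if (state$range[sp] == 0L) { .st_kill(state, sp, 1L); TRUE } else FALSE
}

#' Advance the simulation by one Gillespie event
#'
#' Draws an exponential waiting time at the total event rate, picks the
#' event kind with probabilities proportional to (lambda, gamma, mu), picks
#' a population uniformly, and applies the event.
#'
#' @param state A `divgrid_state` with at least one population.
#' @return The kind of the applied event (`"speciation"`, `"colonization"`
#'   or `"local_extinction"`), invisibly.
#' @export
advance_one_event <- function(state) {
  p <- state$params
  n <- length(state$pop_sp)
  stopifnot(n >= 1)
  state$t <- state$t + stats::rexp(1, total_event_rate(state))
  u <- stats::runif(1) * (p$lambda + p$gamma + p$mu)
  j <- sample.int(n, 1L)
  kind <- if (u < p$lambda) {
    apply_speciation(state, j); "speciation"
  } else if (u < p$lambda + p$gamma) {
    apply_colonization(state, j); "colonization"
  } else {
    apply_local_extinction(state, j); "local_extinction"
  }
  invisible(kind)
}

#' Verify the internal consistency of a grid state
#'
#' Checks the dual-index invariants: every per-cell occupant list matches
#' the flat population index, no cell exceeds the local limit, recorded
#' range sizes match occupancy, and every extant species has range >= 1.
#'
#' @param state A `divgrid_state`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
check_grid_state <- function(state) {
  p <- state$params
  occ_sizes <- lengths(state$occ)
  if (any(occ_sizes > p$k_local)) stop("cell over K_L")
  if (sum(occ_sizes) != length(state$pop_sp)) stop("population total mismatch")
  tab <- table(factor(state$pop_sp, levels = seq_along(state$parent)))
  if (!all(as.integer(tab) == state$range)) stop("range index mismatch")
  extant <- is.na(state$death)
  if (any(state$range[extant] < 1L)) stop("extant species with empty range")
  for (j in seq_along(state$pop_sp)) {
    if (!(state$pop_sp[j] %in% state$occ[[state$pop_cell[j] + 1L]]))
      stop("population missing from cell occupant list")
  }
  for (c in seq_along(state$occ)) {
    if (anyDuplicated(state$occ[[c]])) stop("duplicate occupant in cell")
  }
  invisible(TRUE)
}

#' Event log of a reference-engine state as a data frame
#'
#' @param state A `divgrid_state`.
#' @return A data frame with columns `time`, `kind`, `species`, `cell`,
#'   `daughter`, `no_effect`, in event order.
#' @export
state_events <- function(state) {
  ev <- state$events
  data.frame(
    time = vapply(ev, `[[`, numeric(1), "time"),
    kind = vapply(ev, `[[`, character(1), "kind"),
    species = vapply(ev, `[[`, integer(1), "species"),
    cell = vapply(ev, `[[`, integer(1), "cell"),
    daughter = vapply(ev, `[[`, integer(1), "daughter"),
    no_effect = vapply(ev, function(e) as.logical(e$no_effect), logical(1)))
}

#' Species table of a reference-engine state
#'
#' @param state A `divgrid_state`.
#' @return A data frame with one row per species ever created: `id`,
#'   `parent`, `origin`, `death` (`NA` if extant), `death_type`
#'   (0 extant, 1 local-extinction death, 2 pseudoextinction), `range`.
#' @export
state_species <- function(state) {
  data.frame(id = seq_along(state$parent), parent = state$parent,
             origin = state$origin, death = state$death,
             death_type = state$death_type, range = state$range)
}
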