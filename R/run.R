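#' Run one simulation
#'
#' Advances the model from a single founder until the duration `t_max` is
#' reached, the clade goes extinct, or the cumulative species cap is hit
#' (flagged as a truncation, never silent). Identical `(params, seed)`
#' pairs give identical results.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is
#'   called before the run and the seed is recorded in the result.
#' @param record `"species"` (default) records the species table, final
#'   state and event counts; `"full"` additionally keeps every event
#'   (including no-effect colonization attempts) — intended for small runs.
#' @param engine `"C"` (default, compiled event loop) or `"R"` (the pure-R
#'   reference stepper; slow, for validation).
#' @param check_invariants If > 0, the C engine re-verifies the full state
#'   invariants every this many events (and at termination).
#' @return A `divgrid_run` object: list with `params`, `seed`, `species`
#'   (one row per species ever created: `id`, `parent`, `origin`, `death`,
#'   `death_type`, `range`), `populations` (final state: `species`, `cell`,
#'   `row`, `col`; cells 0-based row-major), `t_end`, `termination`
#'   (`"time"`, `"extinct"` or `"max_species"`), `n_extant`, `counts`, and
#'   `events` when recorded in full.
#' @examples
#' p <- sim_params(area = 16, k_local = 2, lambda = 0.3, gamma = 5,
#'                 mu = 0.5, t_max = 10)
#' r <- sim_run(p, seed = 1)
#' r$n_extant
#' @export
sim_run <- function(params, seed = NULL,
                    record = c("species", "full"),
                    engine = c("C", "R"),
                    check_invariants = 0) {
  stopifnot(inherits(params, "divgrid_params"))
  record <- match.arg(record)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)

  if (engine == "C") {
    res <- .engine_run(params$nrow, params$ncol, params$k_local,
                       params$lambda, params$gamma, params$mu, params$t_max,
                       params$dispersal == "global", params$global_uniform,
                       params$max_species, record == "full",
                       as.double(check_invariants))
  } else {
    res <- .run_r_engine(params, record == "full")
  }
  if (res$termination == "max_species") {
    warning(sprintf("run truncated: species cap max_species = %d reached at t = %g",
                    params$max_species, res$t_end))
  }
  pops <- res$populations
  pops$row <- pops$cell %/% params$ncol
  pops$col <- pops$cell %% params$ncol
  out <- list(params = params, seed = seed,
              species = res$species, populations = pops,
              t_end = res$t_end, termination = res$termination,
              n_extant = res$n_extant, counts = res$counts,
              events = res$events)
  class(out) <- "divgrid_run"
  out
}

# R reference engine run loop: same Gillespie semantics as the C engine
# (terminate without applying an event whose waiting time crosses t_max).
.run_r_engine <- function(params, record_full) {
  st <- init_simulation(params)
  term <- NULL
  repeat {
    n <- length(st$pop_sp)
    if (n == 0L) { term <- "extinct"; break }
    dt <- stats::rexp(1, total_event_rate(st))
    if (st$t + dt >= params$t_max) { st$t <- params$t_max; term <- "time"; break }
    st$t <- st$t + dt
    u <- stats::runif(1) * (params$lambda + params$gamma + params$mu)
    j <- sample.int(n, 1L)
    if (u < params$lambda) apply_speciation(st, j)
    else if (u < params$lambda + params$gamma) apply_colonization(st, j)
    else apply_local_extinction(st, j)
    if (length(st$parent) >= params$max_species) { term <- "max_species"; break }
  }
  ev <- state_events(st)
  kinds <- ev$kind
  counts <- c(
    speciation = sum(kinds == "speciation") - 1L,  # founding record excluded
    colonization = sum(kinds == "colonization" & !ev$no_effect),
    colonization_noop = sum(kinds == "colonization" & ev$no_effect),
    local_extinction = sum(kinds == "local_extinction"),
    species_extinction = sum(kinds == "species_extinction"))
  list(species = state_species(st),
       populations = data.frame(species = st$pop_sp, cell = st$pop_cell),
       t_end = st$t, termination = term, n_extant = st$n_extant,
       counts = counts,
       events = if (record_full) ev else NULL)
}

#' @export
print.divgrid_run <- function(x, ...) {
  cat(sprintf("divgrid run: %d species created, %d extant, %d populations\n",
              nrow(x$species), x$n_extant, nrow(x$populations)))
  cat(sprintf("  ended at t = %g (%s); K_R = %d\n",
              x$t_end, x$termination, x$params$k_regional))
  invisible(x)
}

#' Regional richness through time
#'
#' Number of species alive at each requested time, from the species table
#' (a species is alive on `[origin, death)`; extant species have no death).
#'
#' @param run A `divgrid_run`.
#' @param times Numeric vector of times (default unit steps 0..t_end).
#' @return A data frame with `time` and `richness`.
#' @export
richness_series <- function(run, times = seq(0, floor(run$t_end))) {
  sp <- run$species
  death <- ifelse(is.na(sp$death), Inf, sp$death)
  richness <- vapply(times, function(t) sum(sp$origin <= t & death > t),
                     numeric(1))
  data.frame(time = times, richness = richness)
}

#' Local richness per cell in the final state
#'
#' @param run A `divgrid_run`.
#' @return Integer vector of length `area`: species count in each cell
#'   (0-based cell order).
#' @export
local_richness <- function(run) {
  tabulate(run$populations$cell + 1L, nbins = run$params$area)
}

#' Range sizes of extant species in the final state
#'
#' @param run A `divgrid_run`.
#' @return Named integer vector: cells occupied per extant species.
#' @export
range_sizes <- function(run) {
  extant <- run$species[is.na(run$species$death), ]
  stats::setNames(extant$range, extant$id)
}

#' Write run outputs to a directory
#'
#' Writes `final_state.tsv` (species, cell, row, col), `manifest.json`
#' (parameters, seed, termination reason) and, when the run recorded the
#' full log, `events.tsv`.
#'
#' @param run A `divgrid_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$populations,
                     file.path(dir, "final_state.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$species, file.path(dir, "species.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$events)) {
    ev <- run$events
    if (is.numeric(ev$kind)) {
      ev$kind <- c("speciation", "colonization", "local_extinction",
                   "species_extinction")[ev$kind]
    }
    ev$cell_row <- ev$cell %/% run$params$ncol
    ev$cell_col <- ev$cell %% run$params$ncol
    utils::write.table(
      ev[, c("time", "kind", "species", "cell_row", "cell_col",
             "daughter", "no_effect")],
      file.path(dir, "events.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    params = unclass(run$params), seed = run$seed,
    termination = run$termination, t_end = run$t_end,
    n_extant = run$n_extant, counts = as.list(run$counts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Event log with labeled kinds
#'
#' Normalizes a full event log (from either engine) to character event
#' kinds and logical `no_effect`.
#'
#' @param run A `divgrid_run` created with `record = "full"`.
#' @return Data frame of events.
#' @export
run_events <- function(run) {
  if (is.null(run$events)) stop("run was not recorded with record = \"full\"")
  ev <- run$events
  if (is.numeric(ev$kind)) {
    ev$kind <- c("speciation", "colonization", "local_extinction",
                 "species_extinction")[ev$kind]
  }
  ev$no_effect <- as.logical(ev$no_effect)
  ev
}
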