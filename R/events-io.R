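# Rebuilding analysis inputs from a persisted event log.

#' Species table from an event log
#'
#' Reconstructs the species table (id, parent, origin, death, death_type)
#' from a full event record, e.g. one written by [write_run()] and read
#' back. A species extinction that coincides with a speciation event of the
#' same species is classified as a pseudoextinction.
#'
#' @param events Data frame with at least `time`, `kind`, `species`,
#'   `daughter` (character kinds as written by [write_run()], or the
#'   numeric codes of the raw engine log).
#' @return Species table data frame, ordered by id.
#' @export
species_from_events <- function(events) {
  ev <- events
  if (is.numeric(ev$kind)) {
    ev$kind <- c("speciation", "colonization", "local_extinction",
                 "species_extinction")[ev$kind]
  }
  if (any(diff(ev$time) < 0)) stop("corrupt log: events out of time order")
  sp_ev <- ev[ev$kind == "speciation", , drop = FALSE]
  if (nrow(sp_ev) == 0 || !is.na(sp_ev$species[1])) {
    stop("corrupt log: missing founding record")
  }
  out <- data.frame(id = sp_ev$daughter, parent = sp_ev$species,
                    origin = sp_ev$time)
  out <- out[order(out$id), , drop = FALSE]
  if (any(duplicated(out$id))) stop("corrupt log: duplicate species id")
  out$death <- NA_real_
  out$death_type <- 0L
  ex <- ev[ev$kind == "species_extinction", , drop = FALSE]
  i <- match(ex$species, out$id)
  if (anyNA(i)) stop("corrupt log: extinction of unknown species")
  out$death[i] <- ex$time
  # pseudoextinction: the parent's last population was relabeled, so a
  # speciation record of that species exists at the same timestamp
  pseudo_key <- paste(sp_ev$species, sp_ev$time)
  out$death_type[i] <- ifelse(
    paste(ex$species, ex$time) %in% pseudo_key, 2L, 1L)
  rownames(out) <- NULL
  out
}
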