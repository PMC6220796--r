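# Exact master-equation solver for tiny grids: enumerates the reachable
# state space (species labels canonicalized away, since the model is
# neutral), builds the sparse transition-rate generator, and solves for
# mean absorption times and transient distributions. This is a brute-force
# correctness oracle for the stochastic engine; it is only feasible for
# very small (area, k_local).
#
# A state is a multiset of species ranges, each range a set of occupied
# cells (cells stay labeled, 0-based). The canonical key sorts each range
# and then sorts ranges lexicographically. No-op events (failed
# colonization, relabeling speciation of a single-population species) do
# not change the canonical state and never appear as transitions.

.canon_key <- function(ranges) {
  if (length(ranges) == 0) return("")
  parts <- vapply(ranges, function(r) paste(sort(r), collapse = ","),
                  character(1))
  paste(sort(parts), collapse = "|")
}

.key_to_ranges <- function(key) {
  if (identical(key, "")) return(list())
  lapply(strsplit(key, "|", fixed = TRUE)[[1]],
         function(p) as.integer(strsplit(p, ",", fixed = TRUE)[[1]]))
}

# neighbours of 0-based cell on an nrow x ncol grid (cardinal directions)
.neighbours <- function(cell, nrow, ncol) {
  r <- cell %/% ncol; c <- cell %% ncol
  cand <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
  ok <- cand[, 1] >= 0 & cand[, 1] < nrow & cand[, 2] >= 0 & cand[, 2] < ncol
  cand[ok, 1] * ncol + cand[ok, 2]
}

# all transitions out of one canonical state: list(key -> rate)
.state_transitions <- function(key, params) {
  ranges <- .key_to_ranges(key)
  p <- params
  acc_keys <- character(0)
  acc_rates <- numeric(0)
  add <- function(k2, rate) {
    if (identical(k2, key)) return()
    i <- match(k2, acc_keys)
    if (is.na(i)) {
      acc_keys <<- c(acc_keys, k2)
      acc_rates <<- c(acc_rates, rate)
    } else {
      acc_rates[i] <<- acc_rates[i] + rate
    }
  }
  occ_count <- tabulate(unlist(ranges) + 1L, nbins = p$area)
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    for (cell in r) {
      # local extinction: remove (i, cell) at rate mu
      if (p$mu > 0) {
        nr <- ranges
        nr[[i]] <- setdiff(r, cell)
        if (length(nr[[i]]) == 0) nr[[i]] <- NULL
        add(.canon_key(nr), p$mu)
      }
      # speciation: relabel (i, cell) as a new species at rate lambda
      nr <- ranges
      nr[[i]] <- setdiff(r, cell)
      if (length(nr[[i]]) == 0) nr[[i]] <- NULL
      nr <- c(nr, list(cell))
      add(.canon_key(nr), p$lambda)
      # colonization
      if (p$gamma > 0) {
        eligible <- function(tg) occ_count[tg + 1L] < p$k_local && !(tg %in% r)
        if (p$dispersal == "local") {
          for (tg in .neighbours(cell, p$nrow, p$ncol)) {
            if (eligible(tg)) {
              nr <- ranges; nr[[i]] <- c(r, tg)
              add(.canon_key(nr), p$gamma / 4)
            }
          }
        } else {
          elig <- Filter(eligible, 0:(p$area - 1L))
          if (p$global_uniform) {
            for (tg in elig) {
              nr <- ranges; nr[[i]] <- c(r, tg)
              add(.canon_key(nr), p$gamma / p$area)
            }
          } else if (length(elig) > 0) {
            for (tg in elig) {
              nr <- ranges; nr[[i]] <- c(r, tg)
              add(.canon_key(nr), p$gamma / length(elig))
            }
          }
        }
      }
    }
  }
  stats::setNames(acc_rates, acc_keys)
}

#' Enumerate the exact state space of a tiny model
#'
#' Breadth-first enumeration of all canonical states reachable from the
#' founder configurations (one species in one cell, any cell), together
#' with the sparse generator matrix of transition rates. Species labels
#' are treated as exchangeable (the model is neutral), which collapses
#' relabeling-only speciation events into self-loops that are dropped.
#'
#' @param params A [sim_params()] object (small area and local limit).
#' @param max_states Refuse (with the running count) if the reachable set
#'   exceeds this bound (default 1e5).
#' @return A `divgrid_statespace`: list with `keys` (canonical state
#'   labels; `""` is the empty, clade-extinct state), `Q` (sparse
#'   generator, rows sum to zero), `init` (uniform distribution over the
#'   founder states) and `params`.
#' @export
enumerate_states <- function(params, max_states = 1e5) {
  stopifnot(inherits(params, "divgrid_params"))
  init_keys <- vapply(0:(params$area - 1L),
                      function(c) .canon_key(list(c)), character(1))
  seen <- unique(init_keys)
  done <- 0L
  trans <- list()
  while (done < length(seen)) {
    done <- done + 1L
    if (length(seen) > max_states) {
      stop(sprintf("state space exceeds max_states = %d (at least %d states)",
                   as.integer(max_states), length(seen)))
    }
    tr <- .state_transitions(seen[done], params)
    trans[[done]] <- tr
    new <- setdiff(names(tr), seen)
    seen <- c(seen, new)
  }
  ord <- order(seen)
  keys <- seen[ord]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (q in seq_along(seen)) {
    tr <- trans[[q]]
    if (length(tr) > 0) {
      ii <- c(ii, rep(match(seen[q], keys), length(tr)))
      jj <- c(jj, match(names(tr), keys))
      xx <- c(xx, unname(tr))
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(keys), length(keys)))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  init <- numeric(length(keys))
  tab <- table(init_keys)
  init[match(names(tab), keys)] <- as.numeric(tab) / length(init_keys)
  structure(list(keys = keys, Q = Q, init = init, params = params),
            class = "divgrid_statespace")
}

#' Expected time to clade extinction
#'
#' Solves the linear system for the mean absorption time into the empty
#' (clade-extinct) state from each transient state, and returns the value
#' for a given state or averaged over the founder distribution.
#'
#' @param space A `divgrid_statespace`.
#' @param from Canonical state key, or `NULL` (default) for the
#'   founder-distribution average.
#' @return Expected absorption time, or `Inf` with a message attribute if
#'   extinction is unreachable (mu = 0).
#' @export
expected_absorption_time <- function(space, from = NULL) {
  empty <- match("", space$keys)
  if (is.na(empty) || space$params$mu == 0) {
    return(structure(Inf, reason = "extinction absorbing state unreachable"))
  }
  transient <- setdiff(seq_along(space$keys), empty)
  Qtt <- space$Q[transient, transient, drop = FALSE]
  tau <- Matrix::solve(-Qtt, rep(1, length(transient)))
  tau_full <- numeric(length(space$keys))
  tau_full[transient] <- as.numeric(tau)
  if (is.null(from)) {
    sum(space$init * tau_full)
  } else {
    i <- match(from, space$keys)
    if (is.na(i)) stop("unknown state key")
    tau_full[i]
  }
}

#' Exact transient state distribution
#'
#' Probability over canonical states at time `t`, from the matrix
#' exponential of the generator applied to an initial distribution.
#'
#' @param space A `divgrid_statespace`.
#' @param t Time.
#' @param init Initial distribution over states (defaults to the founder
#'   distribution).
#' @return Named numeric vector of state probabilities (sums to 1).
#' @export
transient_distribution <- function(space, t, init = space$init) {
  E <- Matrix::expm(space$Q * t)
  p <- as.numeric(Matrix::t(E) %*% init)
  stats::setNames(p, space$keys)
}

#' Canonical state key of a run's final configuration
#'
#' Maps the final populations of a simulated run to the canonical label
#' used by the oracle, for direct comparison of simulated and exact state
#' distributions.
#'
#' @param run A `divgrid_run`.
#' @return Canonical state key (`""` if the clade is extinct).
#' @export
canonical_state <- function(run) {
  pops <- run$populations
  if (nrow(pops) == 0) return("")
  .canon_key(unname(split(pops$cell, pops$species)))
}
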