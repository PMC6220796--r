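# Shared fixtures, built in code.

# Species table constructor for hand-made lineage histories.
# death_type: 0 extant, 1 local-extinction death, 2 pseudoextinction.
species_table <- function(id, parent, origin, death, death_type = NULL) {
  if (is.null(death_type)) death_type <- ifelse(is.na(death), 0L, 1L)
  data.frame(id = as.integer(id), parent = as.integer(parent),
             origin = origin, death = death,
             death_type = as.integer(death_type),
             range = ifelse(is.na(death), 1L, 0L))
}

# A quickly equilibrating small system for integration-style tests.
small_params <- function(...) {
  defaults <- list(area = 64, k_local = 8, lambda = 0.08, gamma = 80,
                   mu = 1, t_max = 35)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# Grow a reference-engine state to `n` populations by repeated colonization
# of uniformly drawn populations (requires room on the grid).
grow_to <- function(state, n) {
  guard <- 0
  while (length(state$pop_sp) < n) {
    j <- sample.int(length(state$pop_sp), 1)
    apply_colonization(state, j)
    guard <- guard + 1
    if (guard > 10000) stop("could not grow state")
  }
  state
}

# Pure-birth (Yule) lineage-count trajectory sampled at given times,
# starting from n0 lineages: the independent oracle for constant-rate
# diversification.
yule_counts <- function(n0, birth, times) {
  t <- 0
  n <- n0
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    while (TRUE) {
      dt <- stats::rexp(1, birth * n)
      if (t + dt > times[k]) break
      t <- t + dt
      n <- n + 1
    }
    out[k] <- n
    t <- times[k]
  }
  out
}
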