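# Summary statistics: evolutionary turnover, the delta-r diversification
# slowdown statistic, the Yule-normalized Sackin imbalance index, and
# range-size / species-age summaries.

#' Evolutionary turnover per unit-time bin
#'
#' For each bin, the number of species extinctions divided by the number of
#' speciation events. A value of 1 is the dynamic-equilibrium signature
#' (speciation balanced by extinction). Bins without speciation events give
#' `NA` (undefined, never coerced to zero).
#'
#' @param x A `divgrid_run` or species table.
#' @param bin_width Bin width in time units (default 1).
#' @param include_pseudo Count pseudoextinctions (single-population parents
#'   relabeled at speciation) in the extinction tally (default `TRUE`).
#' @param t_end End of the binned interval (defaults to the run's end).
#' @return Data frame with `t0`, `t1`, `speciations`, `extinctions`,
#'   `turnover`.
#' @export
turnover_series <- function(x, bin_width = 1, include_pseudo = TRUE,
                            t_end = NULL) {
  sp <- .species_of(x)
  if (is.null(t_end)) {
    t_end <- if (inherits(x, "divgrid_run")) x$t_end else
      max(sp$origin, sp$death, na.rm = TRUE)
  }
  breaks <- seq(0, t_end, by = bin_width)
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)
  nb <- length(breaks) - 1L
  births <- sp$origin[!is.na(sp$parent)]       # founder is not a speciation
  deaths <- sp$death[!is.na(sp$death) &
                       (include_pseudo | sp$death_type == 1L)]
  bcount <- tabulate(findInterval(births, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE), nbins = nb)
  dcount <- tabulate(findInterval(deaths, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE), nbins = nb)
  data.frame(t0 = breaks[-length(breaks)], t1 = breaks[-1L],
             speciations = bcount, extinctions = dcount,
             turnover = ifelse(bcount > 0, dcount / bcount, NA_real_))
}

#' Diversification-slowdown statistic delta-r
#'
#' Difference between the net diversification of the second and first half
#' of the interval `[t_start, t_end]`, computed from lineage counts at the
#' three anchors. With `normalize = TRUE` (default) each half's log change
#' is divided by its duration, making each half a rate per time unit:
#' \deqn{r_1 = \frac{\ln N(T/2) - \ln N(t_{start})}{T/2 - t_{start}},\quad
#'       r_2 = \frac{\ln N(T) - \ln N(T/2)}{T/2},\quad \Delta r = r_2 - r_1.}
#' With `normalize = FALSE` the raw log changes are differenced. Zero under
#' exponential (constant-rate) growth; negative values indicate a slowdown.
#'
#' @param n_start,n_mid,n_end Lineage counts at `t_start`, the midpoint
#'   `(t_start + t_end)/2`, and `t_end`. All must be >= 1; otherwise `NA`
#'   is returned (clade extinct).
#' @param t_start,t_end Interval bounds (defaults 0 and 1; only their
#'   difference matters when `normalize = TRUE`).
#' @param normalize Divide each half by its duration (default `TRUE`).
#' @return The delta-r value, or `NA_real_` if any anchor count is < 1.
#' @export
delta_r <- function(n_start, n_mid, n_end, t_start = 0, t_end = 1,
                    normalize = TRUE) {
  if (any(is.na(c(n_start, n_mid, n_end))) ||
      n_start < 1 || n_mid < 1 || n_end < 1) {
    return(NA_real_)
  }
  t_mid <- (t_start + t_end) / 2
  r1 <- log(n_mid) - log(n_start)
  r2 <- log(n_end) - log(n_mid)
  if (normalize) {
    r1 <- r1 / (t_mid - t_start)
    r2 <- r2 / (t_end - t_mid)
  }
  r2 - r1
}

#' delta-r of a simulated run
#'
#' Computes [delta_r()] from lineage counts at times `t_start`, `T/2` and
#' `T`. For `type = "full"` the counts are the number of species alive
#' (true richness, including lineages with no surviving descendants); for
#' `type = "reconstructed"` they are the branch counts of the reconstructed
#' tree, i.e. only lineages ancestral to extant species.
#'
#' @param run A `divgrid_run`.
#' @param type `"reconstructed"` or `"full"`.
#' @param t_start Left anchor (default 0, where the count is 1).
#' @param normalize Passed to [delta_r()].
#' @return delta-r, or `NA_real_` if the clade is extinct at any anchor.
#' @export
delta_r_run <- function(run, type = c("reconstructed", "full"),
                        t_start = 0, normalize = TRUE) {
  type <- match.arg(type)
  t_end <- run$params$t_max
  anchors <- c(t_start, (t_start + t_end) / 2, t_end)
  n <- lineage_count(run, anchors, type = type, t_end = t_end)
  delta_r(n[1], n[2], n[3], t_start = t_start, t_end = t_end,
          normalize = normalize)
}

#' Yule-normalized Sackin imbalance index
#'
#' The raw Sackin index is the sum over tips of the number of internal
#' nodes between the tip and the root (inclusive of the root). It is
#' centered by its expectation under the Yule (pure-birth) model,
#' \eqn{E[S_n] = 2n \sum_{j=2}^{n} 1/j}, and scaled by the tip count
#' (Blum–François normalization):
#' \deqn{S = (S_{raw} - E[S_n]) / n.}
#' Zero in expectation under pure birth; larger values mean more
#' imbalanced trees. Topology-only: invariant to branch lengths.
#'
#' @param tree A `phylo`. Trees with fewer than 2 tips give `NA`.
#' @return The normalized index, or `NA_real_`.
#' @export
sackin_normalized <- function(tree) {
  if (inherits(tree, c("divgrid_lineage", "divgrid_empty_tree"))) {
    return(NA_real_)
  }
  n <- length(tree$tip.label)
  if (n < 2) return(NA_real_)
  nn <- n + tree$Nnode
  depth <- integer(nn)
  tr <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + 1L
  }
  s_raw <- sum(depth[seq_len(n)])
  e_yule <- 2 * n * sum(1 / (2:n))
  (s_raw - e_yule) / n
}

#' Range-size and species-age summary at the end of a run
#'
#' Per extant species: range size (cells occupied, >= 1) and age (time
#' since origination, `t_end - origin`). Also reports the moment skewness
#' of the range-size distribution (positive skew = many small-ranged, few
#' widespread species).
#'
#' @param run A `divgrid_run`.
#' @return List with `ranges`, `ages` (named by species id) and
#'   `range_skewness`.
#' @export
range_and_age_summary <- function(run) {
  extant <- run$species[is.na(run$species$death), , drop = FALSE]
  ranges <- stats::setNames(extant$range, extant$id)
  ages <- stats::setNames(run$t_end - extant$origin, extant$id)
  list(ranges = ranges, ages = ages,
       range_skewness = .skewness(as.numeric(ranges)))
}

# moment (population) skewness
.skewness <- function(x) {
  if (length(x) < 3) return(NA_real_)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

#' Per-run metrics summary
#'
#' Computes the scalar summaries used for replicate aggregation: final
#' regional richness, mean local richness, range-size statistics, delta-r
#' on the full and reconstructed lineage counts (both the rate-normalized
#' and raw log-ratio conventions), and the normalized Sackin index of the
#' reconstructed tree. Tree-based metrics are `NA` for extinct clades.
#'
#' @param run A `divgrid_run`.
#' @return One-row data frame.
#' @export
metrics_summary <- function(run) {
  survived <- run$n_extant > 0 && run$termination != "extinct"
  ranges <- as.numeric(range_sizes(run))
  loc <- local_richness(run)
  sack <- NA_real_
  if (survived) {
    sack <- sackin_normalized(reconstructed_tree(run))
  }
  data.frame(
    survived = survived,
    n_species_total = nrow(run$species),
    richness_final = run$n_extant,
    mean_local_richness = mean(loc),
    mean_range = if (length(ranges)) mean(ranges) else NA_real_,
    max_range = if (length(ranges)) max(ranges) else NA_real_,
    range_skewness = .skewness(ranges),
    delta_r_full = if (survived) delta_r_run(run, "full") else NA_real_,
    delta_r_recon = if (survived) delta_r_run(run, "reconstructed") else NA_real_,
    delta_r_full_raw = if (survived)
      delta_r_run(run, "full", normalize = FALSE) else NA_real_,
    delta_r_recon_raw = if (survived)
      delta_r_run(run, "reconstructed", normalize = FALSE) else NA_real_,
    sackin = sack)
}
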