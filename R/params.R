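#' Simulation parameters
#'
#' Construct and validate the full parameterization of one simulation run of
#' the gridded diversification model. The region is a bounded grid of `area`
#' cells, each cell a local assemblage holding at most `k_local` species.
#' Speciation, colonization and local extinction are per-population processes
#' with uniform rates; a population is the presence of one species in one
#' cell.
#'
#' The derived regional diversity ceiling is `k_regional = k_local * area`:
#' the species count reached when every cell is saturated and every species
#' occupies a single cell.
#'
#' @param area Number of grid cells (positive integer). Must be a perfect
#'   square (side `sqrt(area)`) unless `dims` is supplied.
#' @param k_local Local ecological limit: maximum species per cell
#'   (positive integer).
#' @param lambda Per-population speciation rate (> 0, events per time unit).
#' @param gamma Per-population colonization rate (>= 0).
#' @param mu Per-population local extinction rate (>= 0).
#' @param t_max Simulation duration in time units (> 0).
#' @param dispersal `"local"` (colonization targets one of the four cardinal
#'   neighbours) or `"global"` (any eligible cell in the region).
#' @param global_uniform For global dispersal only: if `TRUE` the target is
#'   drawn uniformly from all cells and ineligible targets are no-ops; if
#'   `FALSE` (default) the target is drawn uniformly from eligible cells
#'   (absent species, unsaturated) and the event is a no-op only when no
#'   eligible cell exists.
#' @param max_species Cap on cumulative species created; reaching it
#'   truncates the run with a flag in the result. Default 384000.
#' @param dims Optional `c(nrow, ncol)` grid shape overriding the
#'   perfect-square requirement (`prod(dims)` must equal `area`).
#' @return An object of class `divgrid_params` (a named list with the fields
#'   above plus `nrow`, `ncol` and `k_regional`).
#' @examples
#' p <- sim_params(area = 256, k_local = 16, lambda = 0.08, gamma = 80,
#'                 mu = 1, t_max = 35)
#' p$k_regional  # 4096
#' @export
sim_params <- function(area, k_local, lambda, gamma, mu, t_max,
                       dispersal = c("local", "global"),
                       global_uniform = FALSE,
                       max_species = 384000L,
                       dims = NULL) {
  dispersal <- match.arg(dispersal)
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid simulation parameter `%s`: %s", field, msg),
           call. = FALSE)
    }
  }
  chk(is.numeric(area) && length(area) == 1 && area >= 1 &&
        area == as.integer(area), "area", "must be a positive integer")
  if (is.null(dims)) {
    side <- sqrt(area)
    chk(side == as.integer(side), "area",
        "must be a perfect square (or supply `dims`)")
    dims <- c(as.integer(side), as.integer(side))
  } else {
    chk(is.numeric(dims) && length(dims) == 2 && all(dims >= 1) &&
          all(dims == as.integer(dims)), "dims",
        "must be two positive integers")
    chk(prod(dims) == area, "dims", "prod(dims) must equal area")
    dims <- as.integer(dims)
  }
  chk(is.numeric(k_local) && length(k_local) == 1 && k_local >= 1 &&
        k_local == as.integer(k_local), "k_local",
      "must be a positive integer")
  chk(is.numeric(lambda) && length(lambda) == 1 && lambda > 0,
      "lambda", "must be > 0")
  chk(is.numeric(gamma) && length(gamma) == 1 && gamma >= 0,
      "gamma", "must be >= 0")
  chk(is.numeric(mu) && length(mu) == 1 && mu >= 0, "mu", "must be >= 0")
  chk(is.numeric(t_max) && length(t_max) == 1 && t_max > 0,
      "t_max", "must be > 0")
  chk(is.numeric(max_species) && length(max_species) == 1 && max_species >= 1,
      "max_species", "must be a positive integer")

  structure(list(
    area = as.integer(area), k_local = as.integer(k_local),
    lambda = lambda, gamma = gamma, mu = mu, t_max = t_max,
    dispersal = dispersal, global_uniform = isTRUE(global_uniform),
    max_species = as.integer(max_species),
    nrow = dims[1], ncol = dims[2],
    k_regional = as.integer(k_local) * as.integer(area)
  ), class = "divgrid_params")
}

#' @export
print.divgrid_params <- function(x, ...) {
  cat(sprintf(
    "divgrid parameters: A = %d (%dx%d), K_L = %d (K_R = %d)\n",
    x$area, x$nrow, x$ncol, x$k_local, x$k_regional))
  cat(sprintf(
    "  rates: lambda = %g, gamma = %g, mu = %g; T = %g; dispersal = %s\n",
    x$lambda, x$gamma, x$mu, x$t_max, x$dispersal))
  invisible(x)
}
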