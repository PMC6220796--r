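# Lineage trees from the event record.
#
# Speciation is budding: the parent's branch passes through each speciation
# node unbroken, the daughter branches off with initial range 1. A species'
# branch spans [origin, min(death, t_end)]. The full tree has one tip per
# species ever created; the reconstructed tree keeps only lineages ancestral
# to species extant at the evaluation time, with unary nodes suppressed.

# Latest time at which each species' lineage still has extant descendants:
# d(s) = max(t_end if s extant, origins of daughters d with d(d) >= origin_d).
# A species contributes to the reconstructed tree iff d(s) >= origin(s).
.contrib_deadline <- function(species, t_end) {
  n <- nrow(species)
  d <- rep(-Inf, n)
  d[is.na(species$death)] <- t_end
  if (n >= 2) {
    for (s in n:2) {
      if (d[s] >= species$origin[s]) {
        p <- species$parent[s]
        if (d[p] < species$origin[s]) d[p] <- species$origin[s]
      }
    }
  }
  d
}

.species_of <- function(x) {
  if (inherits(x, "divgrid_run")) x$species
  else if (is.data.frame(x)) x
  else stop("expected a divgrid_run or a species table")
}

.check_species_table <- function(sp) {
  need <- c("id", "parent", "origin", "death")
  if (!all(need %in% names(sp))) stop("species table lacks required columns")
  if (nrow(sp) == 0) stop("empty species table")
  kids <- sp$id[!is.na(sp$parent)]
  if (length(kids) != nrow(sp) - 1L) stop("corrupt log: expected exactly one founder")
  if (!all(sp$parent[!is.na(sp$parent)] %in% sp$id))
    stop("corrupt log: daughter with unknown parent species")
  if (any(!is.na(sp$death) & sp$death < sp$origin))
    stop("corrupt log: extinction before origination")
  invisible(sp)
}

# Build an ape "phylo" for a subset of species rows (upward-closed: every
# non-founder's parent must be present). Tips end at min(death, t_end).
.build_phylo <- function(sp, t_end) {
  n <- nrow(sp)
  idx <- integer(max(sp$id)); idx[sp$id] <- seq_len(n)  # id -> row
  if (n == 1) {
    len <- if (is.na(sp$death)) t_end - sp$origin else sp$death - sp$origin
    return(structure(list(tip = paste0("s", sp$id), origin = sp$origin,
                          length = len, time_end = t_end),
                     class = "divgrid_lineage"))
  }
  nonf <- which(!is.na(sp$parent))
  ord <- nonf[order(sp$origin[nonf])]      # internal nodes by origin time
  node_of <- integer(n)                    # internal node id per non-founder
  node_of[ord] <- n + seq_len(n - 1L)
  node_time <- numeric(2L * n - 1L)
  node_time[n + seq_len(n - 1L)] <- sp$origin[ord]
  end_time <- ifelse(is.na(sp$death), t_end, sp$death)
  node_time[seq_len(n)] <- end_time

  # daughters of each species, sorted by origin (ord is already time-sorted)
  kids <- split(ord, idx[sp$parent[ord]])

  m <- 2L * n - 2L
  e1 <- integer(m); e2 <- integer(m); k <- 0L
  for (i in seq_len(n)) {
    chain <- node_of[kids[[as.character(i)]]]
    if (is.na(sp$parent[i])) seq_nodes <- c(chain, i)
    else seq_nodes <- c(node_of[i], chain, i)
    for (q in seq_along(seq_nodes)[-1L]) {
      k <- k + 1L
      e1[k] <- seq_nodes[q - 1L]; e2[k] <- seq_nodes[q]
    }
  }
  tree <- structure(list(
    edge = cbind(e1, e2, deparse.level = 0),
    edge.length = node_time[e2] - node_time[e1],
    tip.label = paste0("s", sp$id),
    Nnode = n - 1L), class = "phylo")
  tree$root.edge <- node_time[n + 1L] - min(sp$origin)
  attr(tree, "time_end") <- t_end
  attr(tree, "root_time") <- node_time[n + 1L]
  tree
}

#' Build the full lineage tree from a run
#'
#' One tip per species ever created, budding topology (the parent lineage
#' continues through each speciation node), branch lengths in simulation
#' time units. Extinct species end at their extinction time, extant species
#' at `t_end`. The stem segment from time 0 to the first speciation is kept
#' as the `root.edge`.
#'
#' @param x A `divgrid_run`, or a species table with columns `id`,
#'   `parent`, `origin`, `death`.
#' @param t_end End time of the run (defaults to `x$t_end` for runs).
#' @return An ape `phylo` (non-ultrametric when extinctions occurred), or a
#'   `divgrid_lineage` object when only one species ever existed.
#' @export
build_full_tree <- function(x, t_end = NULL) {
  sp <- .check_species_table(.species_of(x))
  if (is.null(t_end)) {
    t_end <- if (inherits(x, "divgrid_run")) x$t_end else
      max(sp$origin, sp$death, na.rm = TRUE)
  }
  .build_phylo(sp, t_end)
}

#' Reconstructed (extant-pruned) tree
#'
#' The subtree spanning only lineages ancestral to species extant at
#' `at_time`; unary nodes created by pruning are suppressed and branch
#' lengths are preserved. The result is ultrametric: every tip ends at
#' `at_time`. If the clade is extinct the result is an explicit empty tree
#' (class `divgrid_empty_tree`), not an error.
#'
#' @param x A `divgrid_run`, a species table, or a `phylo` produced by
#'   [build_full_tree()]/this function.
#' @param at_time Evaluation time (defaults to the run's end time).
#' @return A `phylo`, a single-lineage `divgrid_lineage`, or a
#'   `divgrid_empty_tree`.
#' @export
reconstructed_tree <- function(x, at_time = NULL) {
  if (inherits(x, "phylo")) return(.recon_phylo(x, at_time))
  if (inherits(x, "divgrid_lineage")) {
    if (is.null(at_time)) at_time <- x$time_end
    extant <- x$origin + x$length >= at_time - 1e-12
    if (extant) return(x)
    return(structure(list(time_end = at_time), class = "divgrid_empty_tree"))
  }
  if (inherits(x, "divgrid_empty_tree")) return(x)
  sp <- .check_species_table(.species_of(x))
  if (is.null(at_time)) {
    at_time <- if (inherits(x, "divgrid_run")) x$t_end else
      max(sp$origin, sp$death, na.rm = TRUE)
  }
  alive_at <- sp$origin <= at_time & (is.na(sp$death) | sp$death >= at_time)
  # treat species alive at at_time as extant for the pruning
  sp2 <- sp
  sp2$death[alive_at] <- NA_real_
  d <- .contrib_deadline(sp2, at_time)
  keep <- d >= sp2$origin
  if (!any(keep)) {
    return(structure(list(time_end = at_time), class = "divgrid_empty_tree"))
  }
  sub <- sp2[keep, , drop = FALSE]
  tr <- .build_phylo(sub, at_time)
  .recon_phylo(tr, at_time)
}

.recon_phylo <- function(tree, at_time = NULL) {
  if (inherits(tree, c("divgrid_lineage", "divgrid_empty_tree"))) return(tree)
  t_end <- attr(tree, "time_end")
  if (is.null(at_time)) at_time <- t_end
  root_time <- attr(tree, "root_time")
  depth <- ape::node.depth.edgelength(tree)
  tip_time <- root_time + depth[seq_along(tree$tip.label)]
  extinct <- tip_time < at_time - 1e-9
  if (all(extinct)) {
    return(structure(list(time_end = at_time), class = "divgrid_empty_tree"))
  }
  if (sum(!extinct) == 1L) {
    tip <- tree$tip.label[!extinct]
    return(structure(list(tip = tip, origin = root_time - tree$root.edge,
                          length = at_time - (root_time - tree$root.edge),
                          time_end = at_time), class = "divgrid_lineage"))
  }
  out <- if (any(extinct)) {
    ape::drop.tip(tree, which(extinct), collapse.singles = TRUE)
  } else tree
  # recompute root time from an extant tip
  d2 <- ape::node.depth.edgelength(out)
  new_root_time <- at_time - max(d2[seq_along(out$tip.label)])
  out$root.edge <- new_root_time  # stem back to time 0
  attr(out, "time_end") <- at_time
  attr(out, "root_time") <- new_root_time
  out
}

#' Number of lineages at a time point
#'
#' For `type = "full"`, the number of species alive at `t` (true richness).
#' For `type = "reconstructed"`, the number of branches of the
#' reconstructed tree crossing `t`, i.e. lineages alive at `t` with
#' descendants extant at `t_end`.
#'
#' @param x A `divgrid_run` or species table.
#' @param t Time (scalar or vector).
#' @param type `"full"` or `"reconstructed"`.
#' @param t_end Evaluation horizon for the reconstructed count (defaults to
#'   the run's end time).
#' @return Integer vector of lineage counts.
#' @export
lineage_count <- function(x, t, type = c("full", "reconstructed"),
                          t_end = NULL) {
  type <- match.arg(type)
  sp <- .species_of(x)
  if (is.null(t_end)) {
    t_end <- if (inherits(x, "divgrid_run")) x$t_end else
      max(sp$origin, sp$death, na.rm = TRUE)
  }
  death <- ifelse(is.na(sp$death), Inf, sp$death)
  if (type == "full") {
    vapply(t, function(u) sum(sp$origin <= u & death > u), numeric(1))
  } else {
    d <- .contrib_deadline(sp, t_end)
    vapply(t, function(u) sum(sp$origin <= u & d >= u & death >= u),
           numeric(1))
  }
}

#' Write a tree to a Newick file
#'
#' Branch lengths are in simulation time units; tip labels are species ids
#' (`s<id>`). Refuses to write an empty tree.
#'
#' @param tree A `phylo` or `divgrid_lineage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "divgrid_empty_tree")) {
    stop("cannot write an empty tree (clade extinct)")
  }
  if (inherits(tree, "divgrid_lineage")) {
    writeLines(sprintf("%s:%.12g;", tree$tip, tree$length), path)
  } else {
    ape::write.tree(tree, file = path, digits = 12)
  }
  invisible(path)
}
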