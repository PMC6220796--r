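# Lineage-tree construction, pruning and serialization.

test_that("a single speciation event yields a two-tip tree branching at the event time", {
  sp <- species_table(id = 1:2, parent = c(NA, 1), origin = c(0, 3),
                      death = c(NA, NA))
  tr <- build_full_tree(sp, t_end = 10)
  expect_s3_class(tr, "phylo")
  expect_identical(length(tr$tip.label), 2L)
  expect_identical(tr$Nnode, 1L)
  expect_equal(tr$root.edge, 3)
  expect_equal(sort(tr$edge.length), c(7, 7))

  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_identical(sort(back$tip.label), c("s1", "s2"))
  expect_equal(sort(back$edge.length), c(7, 7), tolerance = 1e-9)
})

test_that("a founder that never speciates is a single lineage", {
  sp <- species_table(1, NA, 0, 4.5)
  tr <- build_full_tree(sp, t_end = 10)
  expect_s3_class(tr, "divgrid_lineage")
  expect_equal(tr$length, 4.5)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  expect_match(readLines(tmp), "^s1:4.5;$")
})

test_that("orphan daughters are rejected as corrupt logs", {
  sp <- species_table(id = c(1, 3), parent = c(NA, 2), origin = c(0, 1),
                      death = c(NA, NA))
  expect_error(build_full_tree(sp, t_end = 5), "parent")
})

test_that("pruning keeps only lineages ancestral to extant species", {
  # two sisters, one extinct: the reconstructed tree is the surviving stem
  sp <- species_table(id = 1:2, parent = c(NA, 1), origin = c(0, 2),
                      death = c(NA, 6))
  rec <- reconstructed_tree(sp, at_time = 10)
  expect_s3_class(rec, "divgrid_lineage")
  expect_equal(rec$length, 10)

  # everything extinct: explicit empty tree, not an error
  sp2 <- species_table(id = 1:2, parent = c(NA, 1), origin = c(0, 2),
                       death = c(5, 6))
  expect_s3_class(reconstructed_tree(sp2, at_time = 10), "divgrid_empty_tree")

  # all species extant: reconstructed equals the full tree
  sp3 <- species_table(id = 1:3, parent = c(NA, 1, 1), origin = c(0, 2, 4),
                       death = c(NA, NA, NA))
  full <- build_full_tree(sp3, t_end = 10)
  rec3 <- reconstructed_tree(sp3, at_time = 10)
  expect_true(ape::all.equal.phylo(full, rec3, use.edge.length = TRUE))
})

test_that("tree structure agrees with the event record on simulated runs", {
  r <- sim_run(small_params(t_max = 12), seed = 31)
  full <- build_full_tree(r)
  # one tip per species ever created = speciation records + founder
  expect_identical(length(full$tip.label), nrow(r$species))
  expect_identical(nrow(r$species),
                   unname(r$counts[["speciation"]]) + 1L)
  # total branch length conservation
  sp <- r$species
  lived <- ifelse(is.na(sp$death), r$t_end, sp$death) - sp$origin
  expect_equal(sum(full$edge.length) + full$root.edge, sum(lived),
               tolerance = 1e-9)
  # reconstructed tips = extant richness from the grid state
  rec <- reconstructed_tree(r)
  expect_identical(length(rec$tip.label), r$n_extant)
  # ultrametric: all root-to-tip depths equal T minus the crown time
  d <- ape::node.depth.edgelength(rec)
  tipd <- d[seq_along(rec$tip.label)]
  expect_lt(diff(range(tipd)), 1e-9)
  expect_equal(attr(rec, "root_time") + tipd[1], r$t_end, tolerance = 1e-9)
  # internal node times of the reconstructed tree are speciation times
  node_times <- attr(rec, "root_time") +
    d[-seq_along(rec$tip.label)]
  expect_true(all(vapply(node_times, function(u)
    any(abs(sp$origin - u) < 1e-9), logical(1))))
})

test_that("pruning is idempotent", {
  r <- sim_run(small_params(t_max = 10), seed = 32)
  rec1 <- reconstructed_tree(r)
  rec2 <- reconstructed_tree(rec1)
  expect_identical(rec1$edge, rec2$edge)
  expect_equal(rec1$edge.length, rec2$edge.length)
  expect_identical(rec1$tip.label, rec2$tip.label)
})

test_that("newick serialization round-trips topology and branch lengths", {
  r <- sim_run(small_params(t_max = 8), seed = 33)
  full <- build_full_tree(r)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(full, tmp)
  back <- ape::read.tree(tmp)
  expect_true(ape::all.equal.phylo(full, back, use.edge.length = TRUE,
                                   tolerance = 1e-9))
  expect_error(write_newick(structure(list(), class = "divgrid_empty_tree"),
                            tmp), "empty")
})

test_that("the species table can be rebuilt from a persisted event log", {
  r <- sim_run(small_params(t_max = 6), seed = 35, record = "full")
  d <- withr::local_tempdir()
  write_run(r, d)
  ev <- utils::read.delim(file.path(d, "events.tsv"))
  ev$cell <- NA_integer_
  sp <- species_from_events(ev)
  cols <- c("id", "parent", "origin", "death", "death_type")
  expect_equal(sp[, cols], r$species[, cols], tolerance = 1e-6)
  expect_error(species_from_events(ev[-1, ]), "founding")
})

test_that("reconstructed lineage counts match the tree and never decrease", {
  r <- sim_run(small_params(t_max = 12), seed = 34)
  ts <- seq(0, 12, by = 0.5)
  n_rec <- lineage_count(r, ts, type = "reconstructed")
  expect_true(all(diff(n_rec) >= 0))
  expect_identical(n_rec[1], 1)                 # the surviving root lineage
  expect_identical(n_rec[length(n_rec)], as.numeric(r$n_extant))
  # independent check at T/2 from the reconstructed tree's coordinates
  rec <- reconstructed_tree(r)
  co <- ape::ltt.plot.coords(rec)
  times <- co[, "time"] + r$t_end               # ape puts the present at 0
  at <- function(u) {                            # N is lagged by one event
    k <- max(which(times <= u + 1e-9))
    co[min(k + 1, nrow(co)), "N"]
  }
  expect_equal(unname(n_rec[ts == 6]), unname(at(6)))
  expect_equal(unname(n_rec[ts == 9]), unname(at(9)))
  # full counts match the richness series
  expect_equal(lineage_count(r, 0:12, type = "full"),
               richness_series(r, 0:12)$richness)
})
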