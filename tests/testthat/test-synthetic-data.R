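test_that("scenario classification follows the decision cascade", {
  expect_equal(classify_scenario(migration_graph(c("P", "P"), c("M1", "M2"))),
               "mS")
  expect_equal(classify_scenario(migration_graph(c("P", "P"), c("M1", "M1"))),
               "pS")
  expect_equal(classify_scenario(
    migration_graph(c("P", "M1", "P"), c("M1", "M2", "M2"))), "pM")
  expect_equal(classify_scenario(
    migration_graph(c("P", "M1"), c("M1", "P"))), "pR")
  # reseeding dominates every other feature
  expect_equal(classify_scenario(
    migration_graph(c("P", "P", "M1"), c("M1", "M1", "P"))), "pR")
  expect_equal(classify_scenario(migration_graph()), "mS")
})

test_that("simulated datasets satisfy their scenario constraints", {
  # mS: every metastasis has in-degree one; no reseeding
  ds <- simulate_dataset(sim_config("mS", sites = 5, seed = 1))
  indeg <- table(ds$graph$to)
  expect_true(all(indeg == 1L))
  expect_false("P" %in% ds$graph$to)
  expect_equal(classify_scenario(ds$graph), "mS")

  # pR: at least one edge terminates at the primary
  for (s in 1:5) {
    dr <- simulate_dataset(sim_config("pR", size_class = "m5", seed = s))
    expect_true("P" %in% dr$graph$to)
  }
  # pS: some metastasis receives >= 2 migrations, all from one source
  dp <- simulate_dataset(sim_config("pS", size_class = "m5", seed = 2))
  counts <- table(dp$graph$to)
  poly <- names(counts)[counts >= 2L]
  expect_gte(length(poly), 1L)
  for (t in poly) {
    expect_length(unique(dp$graph$from[dp$graph$to == t]), 1L)
  }
  # pM: some metastasis is seeded from two or more distinct sources
  dm <- simulate_dataset(sim_config("pM", size_class = "m5", seed = 3))
  nsrc <- tapply(dm$graph$from, dm$graph$to, function(x) length(unique(x)))
  expect_gte(max(nsrc), 2L)
})

test_that("every scenario classifies correctly across many seeds", {
  for (sc in c("mS", "pS", "pM", "pR")) {
    for (s in seq(1, 40)) {
      ds <- simulate_dataset(sim_config(sc, size_class = if (s %% 2) "m8" else "m5",
                                        seed = 1000 + s))
      expect_equal(classify_scenario(ds$graph), sc)
      expect_equal(ds$scenario, sc)
    }
  }
})

test_that("simulated data respect the published size ranges", {
  for (s in 1:15) {
    d5 <- simulate_dataset(sim_config("mS", size_class = "m5", seed = 60 + s))
    expect_true(length(d5$sites) >= 5 && length(d5$sites) <= 7)
    d8 <- simulate_dataset(sim_config("pM", size_class = "m8", seed = 60 + s))
    expect_true(length(d8$sites) >= 8 && length(d8$sites) <= 11)
    for (d in list(d5, d8)) {
      ncl <- length(setdiff(d$tree$leaves, d$germline))
      expect_true(ncl >= 7 && ncl <= 28)
      expect_true(ncol(d$matrix) >= 9 && ncol(d$matrix) <= 99)
      # characters equal total branch length; matrix homoplasy-free
      expect_equal(ncol(d$matrix), sum(d$tree$edge_length))
      expect_true(isTRUE(is_homoplasy_free(d$matrix)))
      # every site holds at least one sampled clone
      obs <- d$leaf_labeling[setdiff(d$tree$leaves, d$germline)]
      expect_setequal(unique(unname(obs)), d$sites)
    }
  }
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_dataset(sim_config("pR", size_class = "m8", seed = 123))
  b <- simulate_dataset(sim_config("pR", size_class = "m8", seed = 123))
  expect_identical(a$tree, b$tree)
  expect_identical(a$truth_labeling, b$truth_labeling)
  expect_identical(unclass(a$graph), unclass(b$graph))
  c_ <- simulate_dataset(sim_config("pR", size_class = "m8", seed = 124))
  expect_false(identical(a$tree, c_$tree))
})

test_that("the true migration graph is derivable from the true labeling", {
  for (s in 1:8) {
    ds <- simulate_dataset(sim_config("pM", size_class = "m5", seed = 80 + s))
    g <- extract_migration_graph(ds$tree, ds$truth_labeling,
                                 germline = ds$germline)
    expect_equal(cloneMig:::edge_counts(g), cloneMig:::edge_counts(ds$graph))
  }
})

test_that("MP reconstruction recovers the true topology from the matrix", {
  skip_if_not_installed("phangorn")
  for (sc in c("mS", "pS", "pM", "pR")) {
    for (s in 1:6) {
      ds <- simulate_dataset(sim_config(sc, size_class = "m5", seed = 40 + s))
      mp <- reconstruct_mp_tree(ds$matrix, germline = ds$germline)
      t1 <- cloneMig:::clone_to_phylo(ds$tree)
      t2 <- cloneMig:::clone_to_phylo(mp)
      expect_equal(suppressWarnings(phangorn::RF.dist(t1, t2)), 0,
                   info = paste(sc, s))
      expect_equal(sum(mp$edge_length), ncol(ds$matrix))
    }
  }
})

test_that("datasets round-trip through a directory and support partial reads", {
  ds <- simulate_dataset(sim_config("pR", size_class = "m5", seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$leaf_labeling[names(ds$leaf_labeling)],
                   ds$leaf_labeling)
  expect_identical(back$truth_labeling[names(ds$truth_labeling)],
                   ds$truth_labeling)
  expect_equal(cloneMig:::edge_counts(back$graph),
               cloneMig:::edge_counts(ds$graph))
  expect_equal(back$scenario, ds$scenario)
  expect_equal(unclass(back$matrix), unclass(ds$matrix), ignore_attr = TRUE)
  expect_equal(back$tree$parent[names(ds$tree$parent)], ds$tree$parent)
  expect_equal(back$tree$edge_length[names(ds$tree$edge_length)],
               ds$tree$edge_length)

  # benchmark-style directory: tree and leaf labeling only
  dir2 <- withr::local_tempdir()
  file.copy(file.path(dir, "T.tree"), dir2)
  file.copy(file.path(dir, "T.labeling"), dir2)
  partial <- read_dataset(dir2)
  expect_null(partial$truth_labeling)
  expect_null(partial$graph)
  expect_setequal(partial$tree$leaves, ds$tree$leaves)

  # missing labeling is an error
  dir3 <- withr::local_tempdir()
  file.copy(file.path(dir, "T.tree"), dir3)
  expect_error(read_dataset(dir3), "missing labeling")
})
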