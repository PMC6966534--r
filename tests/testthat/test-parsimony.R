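test_that("Sankoff minimum migration counts match hand-derived cases", {
  cherry <- parse_tree(c("r A", "r B"), format = "edge-list")
  fit <- sankoff_min_migrations(cherry, c(A = "P", B = "M1"),
                                root_constraint = "P")
  expect_equal(fit$min_migrations, 1)

  # ((A:P,B:M1),(C:M1,D:M1)) root P: checked by enumeration over the 4
  # internal-node labelings in the 2-site alphabet
  tr <- parse_tree("((A,B),(C,D));", format = "newick")
  labs <- c(A = "P", B = "M1", C = "M1", D = "M1")
  oracle <- min(vapply(
    Filter(function(l) l[[tr$root]] == "P",
           enum_full_labelings(tr, labs, c("P", "M1"))),
    function(l) count_mu(tr, l), 1))
  expect_equal(oracle, 2)
  expect_equal(sankoff_min_migrations(tr, labs, "P")$min_migrations, 2)

  allP <- c(A = "P", B = "P", C = "P", D = "P")
  expect_equal(sankoff_min_migrations(tr, allP, "P")$min_migrations, 0)
})

test_that("Sankoff validates inputs", {
  tr <- parse_tree("(A,B);", format = "newick")
  expect_error(sankoff_min_migrations(tr, c(A = "P"), "P"), "no site label")
  expect_error(sankoff_min_migrations(tr, c(A = "P", B = "M1"), "M9"),
               "not in the site alphabet")
})

test_that("optimal labelings are enumerated completely, deterministically, and capped", {
  cherry <- parse_tree(c("r A", "r B"), format = "edge-list")
  fit <- sankoff_min_migrations(cherry, c(A = "P", B = "M1"),
                                root_constraint = NULL)
  labs <- enumerate_optimal_labelings(fit)
  expect_length(labs, 2L) # root P or root M1
  expect_setequal(vapply(labs, `[[`, "", "r"), c("P", "M1"))
  expect_false(attr(labs, "truncated"))

  fit_con <- sankoff_min_migrations(cherry, c(A = "P", B = "M1"), "P")
  expect_length(enumerate_optimal_labelings(fit_con), 1L)

  capped <- enumerate_optimal_labelings(fit, cap = 1L)
  expect_length(capped, 1L)
  expect_true(attr(capped, "truncated"))

  # deterministic order across calls
  expect_identical(enumerate_optimal_labelings(fit),
                   enumerate_optimal_labelings(fit))
})

test_that("comigration counting follows the antichain definition", {
  # two migrations to the same site on sibling branches are simultaneous
  tr <- parse_tree("((A,B),(C,D));", format = "newick")
  lab <- c(A = "M1", B = "P", C = "M1", D = "P")
  full <- c(lab, stats::setNames(c("P", "P", "P"),
                                 setdiff(tr$nodes, tr$leaves)))
  expect_equal(count_comigrations(tr, full), 1L)

  # one P->M1 edge ancestral to another: two separate seeding waves
  tr2 <- parse_tree(c("r u", "u A", "u v", "v B", "v C", "r D"),
                    format = "edge-list")
  full2 <- c(r = "P", u = "M1", v = "P", A = "M1", B = "M1", C = "P",
             D = "P")
  # migrations: r->u (P->M1), u->v (M1->P), v->B (P->M1): P->M1 chain of 2
  expect_equal(count_comigrations(tr2, full2), 3L)

  # distinct site pairs always count separately
  tr3 <- parse_tree("(A,B);", format = "newick")
  full3 <- c(A = "M1", B = "M2", stats::setNames("P", tr3$root))
  expect_equal(count_comigrations(tr3, full3), 2L)

  expect_error(count_comigrations(tr3, full3[-1]), "missing node")
})

test_that("infer_pmh matches the exhaustive oracle on all small trees", {
  sites2 <- c("P", "M1")
  sites3 <- c("P", "M1", "M2")
  n_checked <- 0L
  for (shape in small_tree_shapes) {
    tr <- parse_tree(shape, format = "newick")
    sites <- if (length(tr$leaves) <= 4L) sites3 else sites2
    if (n_nodes(tr) > 8L) next
    for (ll in leaf_labelings_for(tr$leaves, sites, max_cases = 30L)) {
      h <- infer_pmh(tr, ll, root_constraint = "P", sites = sites)
      expect_equal(h$counts, oracle_pmh(tr, ll, sites, "P"),
                   info = paste(shape, paste(ll, collapse = "")))
      hu <- infer_pmh(tr, ll, root_constraint = NULL, sites = sites)
      expect_equal(hu$counts, oracle_pmh(tr, ll, sites, NULL),
                   info = paste("unconstrained", shape,
                                paste(ll, collapse = "")))
      # unconstrained optimum can only be as good or better
      expect_lte(hu$counts[["migrations"]], h$counts[["migrations"]])
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("the returned labeling is lexicographically optimal among co-optima", {
  set.seed(421)
  for (i in 1:20) {
    tr <- random_tree(sample(4:7, 1), seed = 5000 + i)
    sites <- c("P", "M1", "M2")
    ll <- stats::setNames(sample(sites, length(tr$leaves), replace = TRUE),
                          tr$leaves)
    h <- infer_pmh(tr, ll, root_constraint = "P", sites = sites)
    fit <- sankoff_min_migrations(tr, ll, "P", sites)
    for (lab in enumerate_optimal_labelings(fit)) {
      g <- count_comigrations(tr, lab)
      s <- cloneMig:::count_sources(tr, lab)
      better <- g < h$counts[["comigrations"]] ||
        (g == h$counts[["comigrations"]] && s < h$counts[["sources"]])
      expect_false(better)
    }
    # internal consistency of the reported counts
    expect_equal(nrow(h$graph), unname(h$counts[["migrations"]]))
    expect_equal(count_comigrations(tr, h$labeling),
                 unname(h$counts[["comigrations"]]))
  }
})

test_that("migration graph extraction drops concordant edges and the germline", {
  tr <- parse_tree(c("r u", "u A", "u B", "r N"), format = "edge-list")
  lab <- c(r = "P", u = "M1", A = "M1", B = "M2", N = "P")
  g <- extract_migration_graph(tr, lab, germline = "N")
  expect_equal(sort(paste(g$from, g$to)), c("M1 M2", "P M1"))

  conc <- c(r = "P", u = "P", A = "P", B = "P", N = "P")
  expect_equal(nrow(extract_migration_graph(tr, conc)), 0L)

  # a multistep chain P->M1->M2 appears as two edges
  tr2 <- parse_tree(c("r a", "a b", "b L"), format = "edge-list")
  lab2 <- c(r = "P", a = "M1", b = "M2", L = "M2")
  g2 <- extract_migration_graph(tr2, lab2)
  expect_equal(sort(paste(g2$from, g2$to)), c("M1 M2", "P M1"))
})

test_that("single-site data give an empty history", {
  tr <- parse_tree("((A,B),C);", format = "newick")
  h <- infer_pmh(tr, c(A = "P", B = "P", C = "P"))
  expect_equal(unname(h$counts), c(0, 0, 0))
  expect_equal(nrow(h$graph), 0L)
})
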