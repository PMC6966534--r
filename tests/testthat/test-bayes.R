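test_that("transition matrices are row-stochastic and symmetric", {
  mod <- mk_model(c("P", "M1", "M2"))
  for (t in c(0, 0.5, 3, 40)) {
    P <- transition_matrix(mod, t)
    expect_equal(rowSums(P), stats::setNames(rep(1, 3), mod$sites))
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
  }
  # infinite-length limit: uniform
  expect_equal(unname(transition_matrix(mod, 1e6)),
               matrix(1 / 3, 3, 3), tolerance = 1e-9)
  expect_error(mk_model("P"), "at least 2 sites")
})

test_that("a symmetric two-leaf tree has a fifty-fifty root posterior", {
  tr <- parse_tree("(A:2,B:2);", format = "newick")
  post <- marginal_posteriors(tr, c(A = "P", B = "M1"),
                              mk_model(c("P", "M1")))
  expect_equal(unname(post$prob[tr$root, ]), c(0.5, 0.5), tolerance = 1e-12)
  # very long leaf branches leave the root near its uniform prior
  trL <- parse_tree("(A:500,B:500);", format = "newick")
  postL <- marginal_posteriors(trL, c(A = "P", B = "M1"),
                               mk_model(c("P", "M1")))
  expect_equal(unname(postL$prob[trL$root, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("pruning posteriors equal likelihood-weighted enumeration", {
  shapes <- c("((A:1,B:2):1,C:3);", "((A:1,B:1):2,(C:2,D:1):1);",
              "(((A:1,B:3):1,C:1):2,(D:2,E:1):1,F:4);")
  for (shape in shapes) {
    tr <- parse_tree(shape, format = "newick")
    sites <- c("P", "M1", "M2")
    mod <- mk_model(sites)
    for (ll in leaf_labelings_for(tr$leaves, sites, max_cases = 12L)) {
      got <- marginal_posteriors(tr, ll, mod)
      want <- oracle_posteriors(tr, ll, mod)
      expect_equal(got$prob, want, tolerance = 1e-9, info = shape)
      expect_equal(unname(rowSums(got$prob)), rep(1, n_nodes(tr)),
                   tolerance = 1e-9)
    }
  }
})

test_that("posteriors are invariant to leaf input order and site relabeling", {
  tr <- parse_tree("((A:1,B:2):1,(C:1,D:3):2);", format = "newick")
  ll <- c(A = "P", B = "M1", C = "M1", D = "M2")
  mod <- mk_model(c("P", "M1", "M2"))
  p1 <- marginal_posteriors(tr, ll, mod)
  p2 <- marginal_posteriors(tr, rev(ll), mod)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)

  # permuting the site alphabet permutes the posterior columns identically
  perm <- c(P = "M2", M1 = "P", M2 = "M1")
  llp <- stats::setNames(unname(perm[ll]), names(ll))
  p3 <- marginal_posteriors(tr, llp, mod)
  expect_equal(unname(p1$prob[, c("P", "M1", "M2")]),
               unname(p3$prob[, c("M2", "P", "M1")]), tolerance = 1e-12)
})

test_that("Gibbs sampling is seed-reproducible and converges to the exact posterior", {
  tr <- parse_tree("((A:1,B:2):2,(C:1,D:1):1,N:0.1);", format = "newick")
  ll <- c(A = "M1", B = "M1", C = "M2", D = "P", N = "P")
  mod <- mk_model(c("P", "M1", "M2"))
  cfg <- mcmc_config(chains = 2L, generations = 4000, sample_interval = 1L,
                     burnin = 500L, seed = 11L)
  s1 <- mcmc_sample(tr, ll, mod, cfg)
  s2 <- mcmc_sample(tr, ll, mod, cfg)
  expect_identical(s1$prob, s2$prob)
  s3 <- mcmc_sample(tr, ll, mod, mcmc_config(chains = 2L, generations = 4000,
                                             sample_interval = 1L,
                                             burnin = 500L, seed = 12L))
  expect_false(identical(s1$prob, s3$prob))

  exact <- marginal_posteriors(tr, ll, mod)
  # 7000 pooled samples: agree within ~3 Monte-Carlo standard errors
  expect_lt(max(abs(s1$prob - exact$prob)), 3.5 * sqrt(0.25 / s1$n_samples) + 0.01)
  expect_equal(s1$n_samples, 7000L)
  expect_true(is.finite(s1$convergence_spread))
  expect_error(mcmc_config(generations = 100, sample_interval = 1,
                           burnin = 200), "burnin")
})

test_that("MAP assignment breaks ties toward the parent site", {
  # A cherry of two different sites under a P root: the cherry ancestor has
  # symmetric posterior between the two leaf sites only if P is excluded;
  # with P observed above, ties cannot occur, so force one via a star
  tr <- parse_tree("(A:1,B:1,N:0.1);", format = "newick")
  h <- infer_bbm(tr, c(A = "M1", B = "M2", N = "P"), germline = "N")
  # root posterior is symmetric in M1/M2; the parent-of-root is absent, so
  # canonical site order applies and P dominates through the germline
  expect_true(h$labeling[[h$tree$root]] %in% c("P", "M1"))
  expect_equal(unname(h$labeling[["N"]]), "P")
})

test_that("single-site data give an empty graph with concentrated posteriors", {
  tr <- parse_tree("((A:1,B:1):1,N:0.1);", format = "newick")
  h <- infer_bbm(tr, c(A = "P", B = "P", N = "P"), germline = "N")
  expect_equal(nrow(h$graph), 0L)
  expect_true(all(h$posterior[, "P"] > 0.9))
})

test_that("the germline outgroup anchors the root at the primary site", {
  set.seed(31)
  for (i in 1:10) {
    ds <- simulate_dataset(sim_config(sample(c("mS", "pS", "pM", "pR"), 1),
                                      size_class = "m5", seed = 900 + i))
    h <- infer_bbm(ds$tree, ds$leaf_labeling, germline = ds$germline,
                   sites = ds$sites)
    expect_equal(unname(h$labeling[[ds$tree$root]]), "P")
  }
})
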