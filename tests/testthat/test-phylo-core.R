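test_that("newick and edge-list parsing produce the same topology", {
  t1 <- parse_tree("((A,B),C);", format = "newick")
  expect_equal(length(t1$nodes), 5L)
  expect_setequal(t1$leaves, c("A", "B", "C"))

  t2 <- parse_tree(c("r u", "u A", "u B", "r C"), format = "edge-list")
  expect_setequal(t2$leaves, c("A", "B", "C"))
  expect_equal(t2$root, "r")
  # A and B are siblings in both
  expect_equal(t2$parent[["A"]], t2$parent[["B"]])
  expect_equal(t1$parent[["A"]], t1$parent[["B"]])
  expect_false(t1$parent[["C"]] == t1$parent[["A"]])
})

test_that("parse errors are specific: two parents, cycle, duplicate leaf", {
  expect_error(parse_tree(c("r u", "u A", "u B", "r C", "v u"),
                          format = "edge-list"),
               "two parents")
  expect_error(parse_tree(c("a b", "b c", "c a"), format = "edge-list"),
               "cycle")
  expect_error(parse_tree("((A,B),A);", format = "newick"),
               "duplicate leaf")
  expect_error(parse_tree(c("r A", "r A"), format = "edge-list"),
               "two parents")
})

test_that("trees round-trip through both writers", {
  tr <- parse_tree("((A:2,B:1):3,(C:1,D:4):1,E:2);", format = "newick")
  back <- parse_tree(write_tree(tr, "newick"), format = "newick")
  expect_setequal(back$leaves, tr$leaves)
  expect_equal(sum(back$edge_length), sum(tr$edge_length))
  expect_equal(back$edge_length[back$leaves][sort(back$leaves)],
               tr$edge_length[tr$leaves][sort(tr$leaves)])

  el <- write_tree(tr, "edge-list")
  back2 <- parse_tree(el, format = "edge-list")
  expect_equal(sort(names(back2$parent)), sort(names(tr$parent)))
  expect_equal(back2$parent[sort(names(back2$parent))],
               tr$parent[sort(names(tr$parent))])
  expect_equal(back2$edge_length[names(tr$edge_length)], tr$edge_length)
})

test_that("perfect phylogeny reconstruction matches brute-force parsimony", {
  # caterpillar matrix: germline-(A,(B,C)); checked against exhaustive
  # parsimony over all rooted topologies on three leaves
  m <- clone_matrix(rbind(A = c(1, 0, 0), B = c(1, 1, 0), C = c(1, 1, 1),
                          germline = c(0, 0, 0)))
  # brute force: parsimony score of each topology via enumeration of
  # internal genotypes (0/1 per character independently)
  score_topo <- function(newick) {
    tr <- parse_tree(newick, format = "newick")
    total <- 0
    for (ch in colnames(m)) {
      leaf_lab <- stats::setNames(as.character(m[tr$leaves, ch]), tr$leaves)
      labs <- enum_full_labelings(tr, leaf_lab, c("0", "1"))
      labs <- Filter(function(l) l[[tr$root]] == "0", labs)
      total <- total + min(vapply(labs, function(l) count_mu(tr, l), 1))
    }
    total
  }
  topos <- c("(((B,C),A),germline);", "(((A,C),B),germline);",
             "(((A,B),C),germline);")
  scores <- vapply(topos, score_topo, 1)
  expect_equal(unname(which.min(scores)), 1L) # (A,(B,C)) is optimal
  expect_equal(min(scores), 3) # one change per character

  mp <- reconstruct_mp_tree(m)
  expect_equal(sum(mp$edge_length), 3) # parsimony score = n characters
  # B and C share a cherry below the A split
  pB <- mp$parent[["B"]]
  expect_true("C" %in% mp$children[[pB]] ||
                "C" %in% unlist(lapply(mp$children[[pB]],
                                       function(x) mp$children[[x]])))
  expect_true("germline" %in% mp$children[[mp$root]])
})

test_that("single clone and duplicate columns reconstruct correctly", {
  m1 <- clone_matrix(matrix(1, 1, 1, dimnames = list("A", "s1")))
  tr <- reconstruct_mp_tree(m1)
  expect_setequal(tr$leaves, c("A", "germline"))
  expect_equal(sum(tr$edge_length), 1)

  # identical columns merge onto one edge of length 2
  m2 <- clone_matrix(rbind(A = c(1, 1), B = c(0, 0)))
  tr2 <- reconstruct_mp_tree(m2)
  expect_equal(sum(tr2$edge_length), 2)
})

test_that("homoplasy is detected and named", {
  m <- clone_matrix(rbind(A = c(1, 0), B = c(0, 1), C = c(1, 1)))
  ok <- is_homoplasy_free(m)
  expect_false(isTRUE(ok))
  expect_setequal(attr(ok, "conflict"), c("s1", "s2"))
  expect_error(reconstruct_mp_tree(m), "not homoplasy-free.*s1.*s2")
})

test_that("clone matrix TSV round-trips", {
  m <- clone_matrix(rbind(A = c(1, 0, 1), B = c(1, 1, 0),
                          germline = c(0, 0, 0)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clone_matrix(m, f)
  expect_equal(unclass(read_clone_matrix(f)), unclass(m),
               ignore_attr = TRUE)
})

test_that("germline rooting places the outgroup at the root, labeled primary", {
  tr <- parse_tree("((A,B),(C,N));", format = "newick")
  out <- root_with_germline(tr, "N", primary_site = "P")
  expect_true("N" %in% out$tree$children[[out$tree$root]])
  expect_equal(out$labeling[["N"]], "P")
  expect_setequal(out$tree$leaves, tr$leaves)

  # already rooted on the germline: topology untouched
  tr2 <- parse_tree("((A,B),N);", format = "newick")
  out2 <- root_with_germline(tr2, "N")
  expect_identical(out2$tree$parent, tr2$parent)

  expect_error(root_with_germline(tr, "Z"), "not found")
})
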