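# Independent brute-force oracles and small fixture builders. These never
# call the dynamic-programming / pruning code paths they are used to check.

# all full labelings of a tree: leaves fixed, internal nodes free over `sites`
enum_full_labelings <- function(tree, leaf_labels, sites) {
  internal <- setdiff(tree$nodes, tree$leaves)
  grids <- rep(list(sites), length(internal))
  names(grids) <- internal
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    lab <- c(leaf_labels[tree$leaves],
             stats::setNames(as.character(combos[i, ]), internal))
    lab[tree$nodes]
  })
}

count_mu <- function(tree, lab) {
  kids <- names(tree$parent)
  sum(lab[tree$parent[kids]] != lab[kids])
}

# comigrations by explicit partial-order longest chain: ancestor matrix over
# migration edges, then DP over the DAG (independent of the path-walk used in
# the package)
oracle_gamma <- function(tree, lab) {
  kids <- names(tree$parent)
  mig <- kids[lab[tree$parent[kids]] != lab[kids]]
  if (!length(mig)) return(0L)
  anc <- function(v) { # ancestors of v including v
    out <- v
    while (v != tree$root) {
      v <- tree$parent[[v]]
      out <- c(out, v)
    }
    out
  }
  anc_sets <- lapply(stats::setNames(mig, mig), anc)
  total <- 0L
  pairs <- paste(lab[tree$parent[mig]], lab[mig])
  for (pr in unique(pairs)) {
    ee <- mig[pairs == pr]
    # edge a (child id a) ancestral to edge b iff a is an ancestor of b's parent
    prec <- outer(ee, ee, Vectorize(function(a, b) {
      a != b && a %in% anc_sets[[b]][-1L]
    }))
    depth <- rep(1L, length(ee))
    repeat {
      nd <- vapply(seq_along(ee), function(i) {
        below <- which(prec[, i])
        if (length(below)) max(depth[below]) + 1L else 1L
      }, 1L)
      if (identical(nd, depth)) break
      depth <- nd
    }
    total <- total + max(depth)
  }
  total
}

oracle_sigma <- function(tree, lab) {
  kids <- names(tree$parent)
  mig <- kids[lab[tree$parent[kids]] != lab[kids]]
  length(unique(unname(lab[tree$parent[mig]])))
}

# exhaustive (mu, gamma, sigma): min mu, then min gamma, then min sigma
oracle_pmh <- function(tree, leaf_labels, sites, root_constraint = NULL) {
  labs <- enum_full_labelings(tree, leaf_labels, sites)
  if (!is.null(root_constraint)) {
    labs <- Filter(function(l) l[[tree$root]] == root_constraint, labs)
  }
  mus <- vapply(labs, function(l) count_mu(tree, l), 1)
  labs <- labs[mus == min(mus)]
  gs <- vapply(labs, function(l) oracle_gamma(tree, l), 1L)
  labs2 <- labs[gs == min(gs)]
  ss <- vapply(labs2, function(l) oracle_sigma(tree, l), 1L)
  c(migrations = min(mus), comigrations = min(gs), sources = min(ss))
}

# posterior by likelihood-weighted enumeration of full labelings
oracle_posteriors <- function(tree, leaf_labels, model) {
  sites <- model$sites
  labs <- enum_full_labelings(tree, leaf_labels, sites)
  kids <- names(tree$parent)
  w <- vapply(labs, function(l) {
    p <- 1 / model$k # uniform root prior
    for (ch in kids) {
      p <- p * transition_matrix(model, tree$edge_length[[ch]])[
        l[[tree$parent[[ch]]]], l[[ch]]]
    }
    p
  }, 1)
  prob <- matrix(0, length(tree$nodes), length(sites),
                 dimnames = list(tree$nodes, sites))
  for (i in seq_along(labs)) {
    prob[cbind(tree$nodes, labs[[i]][tree$nodes])] <-
      prob[cbind(tree$nodes, labs[[i]][tree$nodes])] + w[i]
  }
  prob / sum(w)
}

# small rooted tree shapes (newick, leaves A..E) spanning 2-5 leaves,
# binary shapes and polytomies, at most 8 nodes
small_tree_shapes <- c(
  "(A,B);",
  "((A,B),C);", "(A,B,C);",
  "((A,B),(C,D));", "(((A,B),C),D);", "((A,B),C,D);", "((A,B,C),D);",
  "(A,B,C,D);",
  "(A,B,C,D,E);", "((A,B),C,D,E);", "((A,B,C,D),E);", "((A,B,C),D,E);",
  "((A,B),(C,D),E);", "(((A,B),C),D,E);", "((A,B,C),(D,E));"
)

# deterministic subsample of all leaf labelings over `sites`
leaf_labelings_for <- function(leaves, sites, max_cases = 90L) {
  grids <- rep(list(sites), length(leaves))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  if (nrow(combos) > max_cases) {
    keep <- seq(1L, nrow(combos), length.out = max_cases)
    combos <- combos[unique(round(keep)), , drop = FALSE]
  }
  lapply(seq_len(nrow(combos)), function(i) {
    stats::setNames(as.character(combos[i, ]), leaves)
  })
}

# random clone tree with integer branch lengths, for property tests
random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  parent <- character(0)
  child <- character(0)
  counter <- 1L
  active <- "n1"
  while (length(active) < n_leaves) {
    v <- sample(active, 1L)
    for (i in 1:2) {
      counter <- counter + 1L
      parent <- c(parent, v)
      child <- c(child, paste0("n", counter))
    }
    active <- c(setdiff(active, v), paste0("n", counter - 1L),
                paste0("n", counter))
  }
  clone_phylogeny(parent, child, sample(1:5, length(child), replace = TRUE))
}
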