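#' Joint polytomy resolution and migration-history inference
#'
#' Resolves every polytomy of the clone phylogeny into binary branching while
#' minimizing the migration objective: among all binary refinements of the
#' input topology (and all ancestral site labelings), the history minimizing
#' (migrations, comigrations, sources) lexicographically is returned. The
#' resolved tree refines the input: every clade of the input tree is
#' preserved, and resolution edges carry zero mutations.
#'
#' Polytomies with at most `max_children` children are searched exhaustively
#' (all (2c-3)!! binary resolutions); larger ones fall back to a greedy local
#' search that repeatedly joins the pair of children reducing the migration
#' count most, unless `local_search = FALSE`, in which case they are an
#' error. When several polytomies coexist and the combined space exceeds
#' `combo_limit`, polytomies are resolved sequentially (each exhaustively,
#' earlier choices held fixed).
#'
#' @inheritParams infer_pmh
#' @param max_children largest polytomy searched exhaustively (default 6).
#' @param combo_limit cap on the joint resolution space searched exhaustively.
#' @param local_search allow greedy resolution of oversized polytomies.
#' @return list with elements `tree` (binary [clone_phylogeny]) and `history`
#'   (a [migration_history], method `"pmh-tr"`).
#' @export
#' @examples
#' star <- parse_tree(c("r A", "r B", "r C"), format = "edge-list")
#' resolve_polytomies_pmh_tr(star, c(A = "P", B = "M1", C = "M1"))$history$counts
resolve_polytomies_pmh_tr <- function(tree, leaf_labels, root_constraint = "P",
                                      cap = 10000L, germline = NULL,
                                      primary = "P", sites = NULL,
                                      max_children = 6L, combo_limit = 3000L,
                                      local_search = TRUE) {
  germ_len <- NULL
  work <- tree
  if (!is.null(germline) && germline %in% tree$leaves) {
    germ_len <- tree$edge_length[[germline]]
    work <- drop_leaf(tree, germline)
    leaf_labels <- leaf_labels[setdiff(names(leaf_labels), germline)]
  }
  if (is.null(sites)) {
    sites <- site_order(c(unname(leaf_labels), root_constraint))
  }

  polys <- names(Filter(function(ch) length(ch) > 2L, work$children))
  if (length(polys)) {
    big <- polys[vapply(polys, function(v) length(work$children[[v]]), 1L) >
                   max_children]
    if (length(big) && !local_search) {
      stop(sprintf("polytomy at '%s' has more than %d children and local search is disabled",
                   big[1L], max_children), call. = FALSE)
    }
    # greedy-join oversized polytomies first, then search the rest
    for (v in big) {
      work <- greedy_resolve(work, v, leaf_labels, root_constraint, sites)
    }
    polys <- names(Filter(function(ch) length(ch) > 2L, work$children))
    if (length(polys)) {
      res_sets <- lapply(polys, function(v) {
        binary_groupings(work$children[[v]])
      })
      n_combo <- prod(vapply(res_sets, length, 1))
      if (n_combo <= combo_limit) {
        work <- best_joint_resolution(work, polys, res_sets, leaf_labels,
                                      root_constraint, cap, primary, sites)
      } else {
        for (i in seq_along(polys)) {
          work <- best_joint_resolution(work, polys[i], res_sets[i],
                                        leaf_labels, root_constraint, cap,
                                        primary, sites)
        }
      }
    }
  }

  full_tree <- work
  if (!is.null(germ_len)) {
    kids <- names(work$parent)
    full_tree <- clone_phylogeny(c(unname(work$parent[kids]), work$root),
                                 c(kids, germline),
                                 c(unname(work$edge_length[kids]), germ_len))
  }
  hist <- infer_pmh(full_tree, c(leaf_labels,
                                 if (!is.null(germ_len))
                                   stats::setNames(primary, germline)),
                    root_constraint = root_constraint, cap = cap,
                    germline = germline, primary = primary, sites = sites)
  hist$method <- "pmh-tr"
  hist$tree <- full_tree
  list(tree = full_tree, history = hist)
}

# all rooted binary groupings of a set of child ids, as nested pair lists;
# generated by inserting each id into every edge of the smaller groupings,
# which yields each shape exactly once
binary_groupings <- function(items) {
  if (length(items) == 1L) return(list(items[[1L]]))
  smaller <- binary_groupings(items[-1L])
  x <- items[[1L]]
  out <- list()
  for (tr in smaller) {
    out <- c(out, insert_leaf(tr, x))
  }
  out
}

insert_leaf <- function(tr, x) {
  out <- list(list(x, tr)) # above the root of this subtree
  if (is.list(tr)) {
    for (side in 1:2) {
      for (sub in insert_leaf(tr[[side]], x)) {
        nt <- tr
        nt[[side]] <- sub
        out <- c(out, list(nt))
      }
    }
  }
  out
}

# rebuild `tree` with polytomy `v` replaced by the binary grouping `struct`;
# new internal nodes get zero-length edges, original subtrees keep theirs
apply_grouping <- function(tree, v, struct) {
  kids <- names(tree$parent)
  keep <- setdiff(kids, tree$children[[v]])
  parent <- unname(tree$parent[keep])
  child <- keep
  len <- unname(tree$edge_length[keep])
  counter <- 0L
  emit <- function(node, s) {
    if (!is.list(s)) {
      parent <<- c(parent, node)
      child <<- c(child, s)
      len <<- c(len, tree$edge_length[[s]])
      return()
    }
    for (side in 1:2) {
      sub <- s[[side]]
      if (is.list(sub)) {
        counter <<- counter + 1L
        id <- sprintf("%s.r%d", v, counter)
        parent <<- c(parent, node)
        child <<- c(child, id)
        len <<- c(len, 0)
        emit(id, sub)
      } else {
        emit(node, sub)
      }
    }
  }
  emit(v, struct)
  clone_phylogeny(parent, child, len)
}

# pick, over the cartesian product of per-polytomy groupings, the resolved
# tree minimizing (mu, gamma, sigma); ties keep the first candidate
best_joint_resolution <- function(tree, polys, res_sets, leaf_labels,
                                  root_constraint, cap, primary, sites) {
  idx <- lapply(res_sets, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  cand_mu <- rep(Inf, nrow(grid))
  cand_trees <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- tree
    for (j in seq_along(polys)) {
      tr <- apply_grouping(tr, polys[j], res_sets[[j]][[grid[i, j]]])
    }
    cand_trees[[i]] <- tr
    cand_mu[i] <- sankoff_min_migrations(tr, leaf_labels, root_constraint,
                                         sites)$min_migrations
  }
  top <- which(cand_mu == min(cand_mu))
  best_tree <- NULL
  best_key <- c(Inf, Inf)
  for (i in top) {
    h <- infer_pmh(cand_trees[[i]], leaf_labels,
                   root_constraint = root_constraint, cap = cap,
                   primary = primary, sites = sites)
    key <- c(h$counts[["comigrations"]], h$counts[["sources"]])
    if (key[1L] < best_key[1L] ||
        (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
      best_tree <- cand_trees[[i]]
      best_key <- key
    }
  }
  best_tree
}

# local search for large polytomies: repeatedly join the pair of children
# whose grouping gives the smallest Sankoff migration count
greedy_resolve <- function(tree, v, leaf_labels, root_constraint, sites) {
  counter <- 0L
  while (length(tree$children[[v]]) > 2L) {
    ch <- tree$children[[v]]
    best_mu <- Inf
    best_pair <- NULL
    for (i in seq_len(length(ch) - 1L)) {
      for (j in seq((i + 1L), length(ch))) {
        cand <- join_children(tree, v, ch[c(i, j)],
                              sprintf("%s.g%d", v, counter + 1L))
        mu <- sankoff_min_migrations(cand, leaf_labels, root_constraint,
                                     sites)$min_migrations
        if (mu < best_mu) {
          best_mu <- mu
          best_pair <- ch[c(i, j)]
        }
      }
    }
    counter <- counter + 1L
    tree <- join_children(tree, v, best_pair, sprintf("%s.g%d", v, counter))
  }
  tree
}

join_children <- function(tree, v, pair, id) {
  kids <- names(tree$parent)
  parent <- tree$parent
  parent[pair] <- id
  clone_phylogeny(c(unname(parent[kids]), v), c(kids, id),
                  c(unname(tree$edge_length[kids]), 0))
}
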