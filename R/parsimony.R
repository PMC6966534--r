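#' Minimum-migration ancestral site assignment (Sankoff dynamic programming)
#'
#' Computes the minimum number of migration events over all assignments of
#' tumor sites to the internal nodes of a clone phylogeny, where a migration
#' is a tree edge whose endpoints carry different sites and every site change
#' has unit cost. The root may be constrained to a given site (usually the
#' primary tumor) or left free, in which case any site may be ancestral.
#'
#' @param tree a [clone_phylogeny] (the germline outgroup, if any, should be
#'   removed first; see [infer_pmh()] which handles it).
#' @param leaf_labels named character vector: site of every leaf.
#' @param root_constraint a site name, or `NULL` for the unconstrained
#'   (classical Sankoff) mode.
#' @param sites optional site alphabet; defaults to the observed labels plus
#'   the constraint.
#' @return a list of class `sankoff_fit`: `min_migrations`, `cost` (node x
#'   site matrix of subtree costs), `sites`, `root_constraint`, `tree`,
#'   `leaf_labels`.
#' @export
#' @examples
#' tr <- parse_tree(c("r A", "r B"), format = "edge-list")
#' sankoff_min_migrations(tr, c(A = "P", B = "M1"), root_constraint = "P")
sankoff_min_migrations <- function(tree, leaf_labels, root_constraint = NULL,
                                   sites = NULL) {
  sites <- site_order(if (is.null(sites)) unname(leaf_labels) else sites)
  missing <- setdiff(tree$leaves, names(leaf_labels))
  if (length(missing)) {
    stop(sprintf("leaf '%s' has no site label", missing[1L]), call. = FALSE)
  }
  if (!is.null(root_constraint) && !(root_constraint %in% sites)) {
    stop(sprintf("root constraint site '%s' not in the site alphabet",
                 root_constraint), call. = FALSE)
  }
  k <- length(sites)
  ord <- postorder(tree)
  cost <- matrix(Inf, nrow = n_nodes(tree), ncol = k,
                 dimnames = list(tree$nodes, sites))
  for (v in ord) {
    ch <- tree$children[[v]]
    if (!length(ch)) {
      lab <- leaf_labels[[v]]
      if (!(lab %in% sites)) {
        stop(sprintf("leaf '%s' labeled with unknown site '%s'", v, lab),
             call. = FALSE)
      }
      cost[v, lab] <- 0
    } else {
      acc <- numeric(k)
      for (c in ch) {
        cc <- cost[c, ]
        best <- min(cc)
        # staying costs cc[s]; switching costs best+1
        acc <- acc + pmin(cc, best + 1)
      }
      cost[v, ] <- acc
    }
  }
  rc <- cost[tree$root, , drop = TRUE]
  min_mu <- if (is.null(root_constraint)) min(rc) else
    rc[[match(root_constraint, sites)]]
  structure(list(min_migrations = unname(min_mu), cost = cost, sites = sites,
                 root_constraint = root_constraint, tree = tree,
                 leaf_labels = leaf_labels),
            class = "sankoff_fit")
}

#' @export
print.sankoff_fit <- function(x, ...) {
  cat(sprintf("Sankoff fit: %d site(s), minimum %g migration(s), root %s\n",
              length(x$sites), x$min_migrations,
              if (is.null(x$root_constraint)) "unconstrained"
              else paste("constrained to", x$root_constraint)))
  invisible(x)
}

#' Enumerate all migration-minimal full site labelings
#'
#' Backtracks through the dynamic-programming tables of
#' [sankoff_min_migrations()] to list every full labeling achieving the
#' minimum migration count. Labelings are produced in a deterministic order:
#' preorder over nodes, sites in canonical order (primary first, then
#' metastases by index).
#'
#' @param fit a `sankoff_fit`.
#' @param cap maximum number of labelings to return (default 10000); when the
#'   optimum set is larger the result carries `truncated = TRUE`.
#' @return list of named character vectors (full labelings), with attributes
#'   `truncated` and `n_found`.
#' @export
enumerate_optimal_labelings <- function(fit, cap = 10000L) {
  stopifnot(inherits(fit, "sankoff_fit"), cap >= 1L)
  tree <- fit$tree
  cost <- fit$cost
  sites <- fit$sites
  rc <- cost[tree$root, ]
  root_sites <- if (is.null(fit$root_constraint)) {
    sites[rc == min(rc)]
  } else {
    fit$root_constraint
  }
  out <- list()
  truncated <- FALSE
  lab <- stats::setNames(character(n_nodes(tree)), tree$nodes)

  assign_node <- function(queue) {
    if (truncated) return()
    if (!length(queue)) {
      if (length(out) >= cap) {
        truncated <<- TRUE
      } else {
        out[[length(out) + 1L]] <<- lab
      }
      return()
    }
    v <- queue[[1L]]
    rest <- queue[-1L]
    ch <- tree$children[[v]]
    if (!length(ch)) {
      lab[v] <<- fit$leaf_labels[[v]]
      assign_node(rest)
      return()
    }
    cc <- cost[v, ]
    if (v == tree$root) {
      opts <- root_sites
    } else {
      ps <- lab[[tree$parent[[v]]]]
      # optimal child sites given the parent's site ps
      opts <- sites[(cc + (sites != ps)) == min(cc + (sites != ps))]
    }
    for (s in opts) {
      if (truncated) break
      lab[v] <<- s
      assign_node(c(rest, ch))
    }
  }
  # preorder queue seeded at root; children appended as sites get fixed
  assign_node(tree$root)
  attr(out, "truncated") <- truncated
  attr(out, "n_found") <- length(out)
  out
}

#' Count comigration events of a full labeling
#'
#' A comigration is a polyclonal seeding event: a group of clones migrating
#' together between the same ordered pair of sites. Migration edges between
#' the same pair that lie on a common root-to-leaf path cannot be
#' simultaneous, so for each ordered site pair the number of comigrations is
#' the length of the longest ancestor-descendant chain among that pair's
#' migration edges (the minimum number of antichains covering them, by
#' Mirsky's theorem). The total is summed over site pairs.
#'
#' @param tree a [clone_phylogeny].
#' @param labeling named character vector over all nodes.
#' @return integer comigration count.
#' @export
count_comigrations <- function(tree, labeling) {
  missing <- setdiff(tree$nodes, names(labeling))
  if (length(missing)) {
    stop(sprintf("labeling missing node '%s'", missing[1L]), call. = FALSE)
  }
  best <- new.env(parent = emptyenv())
  walk <- function(v, counts) {
    for (c in tree$children[[v]]) {
      cnt <- counts
      if (labeling[[v]] != labeling[[c]]) {
        key <- paste0(labeling[[v]], "\r", labeling[[c]])
        cnt[[key]] <- (cnt[[key]] %||% 0L) + 1L
        cur <- best[[key]] %||% 0L
        if (cnt[[key]] > cur) assign(key, cnt[[key]], envir = best)
      }
      walk(c, cnt)
    }
  }
  walk(tree$root, list())
  vals <- as.list(best)
  if (!length(vals)) 0L else sum(unlist(vals))
}

# sigma: number of distinct source sites among migration edges
count_sources <- function(tree, labeling) {
  kids <- names(tree$parent)
  ps <- labeling[tree$parent[kids]]
  cs <- labeling[kids]
  length(unique(unname(ps[ps != cs])))
}

#' Parsimonious migration history
#'
#' Infers a full ancestral tumor-site labeling by Sankoff parsimony, then
#' selects among all migration-minimal labelings the one minimizing the
#' number of comigrations and then the number of distinct seeding source
#' sites (lexicographic in migrations, comigrations, sources). Ties are
#' broken by the deterministic enumeration order. With
#' `root_constraint = NULL` any site may be ancestral at the root
#' (unconstrained Sankoff mode), which can yield many co-optimal solutions;
#' the number found is recorded in the result.
#'
#' @inheritParams sankoff_min_migrations
#' @param cap maximum number of co-optimal labelings examined (default 10000).
#' @param germline name of the germline outgroup leaf, if present in the
#'   tree; it is excluded from the parsimony optimization and labeled with
#'   `primary` in the returned history.
#' @param primary primary tumor site (default `"P"`, also the default root
#'   constraint).
#' @param root_constraint site constrained at the root, or `NULL` for
#'   unconstrained.
#' @return a [migration_history] object.
#' @export
#' @examples
#' tr <- parse_tree("((A,B),(C,D));", format = "newick")
#' h <- infer_pmh(tr, c(A = "P", B = "M1", C = "M1", D = "M1"))
#' h$counts
infer_pmh <- function(tree, leaf_labels, root_constraint = "P", cap = 10000L,
                      germline = NULL, primary = "P", sites = NULL) {
  work <- tree
  if (!is.null(germline) && germline %in% tree$leaves) {
    work <- drop_leaf(tree, germline)
    leaf_labels <- leaf_labels[setdiff(names(leaf_labels), germline)]
  }
  if (is.null(sites)) {
    # the constrained root site belongs to the alphabet even when no
    # sampled clone was taken from it
    sites <- site_order(c(unname(leaf_labels), root_constraint))
  }
  fit <- sankoff_min_migrations(work, leaf_labels, root_constraint, sites)
  labs <- enumerate_optimal_labelings(fit, cap = cap)
  if (!length(labs)) stop("no optimal labeling found", call. = FALSE)
  best <- NULL
  best_key <- c(Inf, Inf)
  for (lab in labs) {
    g <- count_comigrations(work, lab)
    s <- count_sources(work, lab)
    if (g < best_key[1L] || (g == best_key[1L] && s < best_key[2L])) {
      best <- lab
      best_key <- c(g, s)
    }
  }
  full <- best
  if (!is.null(germline) && germline %in% tree$leaves) {
    full[germline] <- primary
  }
  graph <- extract_migration_graph(work, best, primary = primary)
  migration_history(
    tree = tree, labeling = full, graph = graph,
    counts = c(migrations = fit$min_migrations,
               comigrations = best_key[1L], sources = best_key[2L]),
    method = if (is.null(root_constraint)) "pmh-unconstrained" else "pmh-con",
    n_optima = attr(labs, "n_found"),
    truncated = isTRUE(attr(labs, "truncated")))
}
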