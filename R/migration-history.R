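#' Migration history of a clone phylogeny
#'
#' Container returned by the estimators [infer_pmh()], [infer_bbm()] and
#' [resolve_polytomies_pmh_tr()]: a full site labeling of all tree nodes, the
#' migration graph it implies, and the summary counts (migrations mu,
#' comigrations gamma, seeding sources sigma).
#'
#' @param tree the [clone_phylogeny] the history refers to.
#' @param labeling named character vector, site of every node.
#' @param graph a [migration_graph].
#' @param counts named numeric vector `migrations`, `comigrations`, `sources`.
#' @param method estimator name.
#' @param posterior optional per-node posterior matrix (Bayesian estimators).
#' @param ... further fields stored verbatim (e.g. `n_optima`, `truncated`).
#' @return an object of class `migration_history`.
#' @export
migration_history <- function(tree, labeling, graph, counts, method,
                              posterior = NULL, ...) {
  structure(list(tree = tree, labeling = labeling, graph = graph,
                 counts = counts, method = method, posterior = posterior, ...),
            class = "migration_history")
}

#' @export
print.migration_history <- function(x, ...) {
  cat(sprintf("Migration history (%s)\n", x$method))
  cat(sprintf("  migrations: %g   comigrations: %g   sources: %g\n",
              x$counts[["migrations"]], x$counts[["comigrations"]],
              x$counts[["sources"]]))
  if (!is.null(x$n_optima)) {
    cat(sprintf("  co-optimal labelings examined: %d%s\n", x$n_optima,
                if (isTRUE(x$truncated)) " (truncated at cap)" else ""))
  }
  print(x$graph)
  invisible(x)
}

#' @export
summary.migration_history <- function(object, ...) {
  x <- object
  print(x)
  internal <- setdiff(x$tree$nodes, x$tree$leaves)
  df <- data.frame(node = internal, site = unname(x$labeling[internal]),
                   stringsAsFactors = FALSE)
  if (!is.null(x$posterior)) {
    df$posterior <- round(x$posterior[cbind(internal, df$site)], 3)
  }
  cat("\nAncestral sites:\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.migration_history <- function(x, ...) {
  edge_counts(x$graph)
}

#' Plot a migration history or graph
#'
#' Draws the migration multigraph with sites on a circle and one arrow per
#' ordered site pair, labeled with its multiplicity when above one.
#'
#' @param x a `migration_history` or [migration_graph].
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.migration_history <- function(x, ...) {
  plot(x$graph, main = x$method, ...)
}

#' @export
plot.migration_graph <- function(x, main = NULL, ...) {
  tab <- edge_counts(x)
  sites <- site_order(unique(c(tab$from, tab$to, attr(x, "primary"))))
  n <- length(sites)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xs <- stats::setNames(cos(theta), sites)
  ys <- stats::setNames(sin(theta), sites)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1)
  if (!is.null(main)) graphics::title(main = main)
  if (nrow(tab)) {
    shrink <- 0.12
    for (i in seq_len(nrow(tab))) {
      x0 <- xs[tab$from[i]]; y0 <- ys[tab$from[i]]
      x1 <- xs[tab$to[i]]; y1 <- ys[tab$to[i]]
      dx <- x1 - x0; dy <- y1 - y0
      d <- sqrt(dx^2 + dy^2)
      graphics::arrows(x0 + shrink * dx / d, y0 + shrink * dy / d,
                       x1 - shrink * dx / d, y1 - shrink * dy / d,
                       length = 0.08, ...)
      if (tab$n[i] > 1L) {
        graphics::text((x0 + x1) / 2, (y0 + y1) / 2 + 0.07,
                       sprintf("x%d", tab$n[i]), cex = 0.8)
      }
    }
  }
  graphics::text(xs * 1.18, ys * 1.18, sites, font = 2)
  invisible(x)
}

#' Write the full labeling of a migration history as TSV
#'
#' Columns `node`, `site`, and `posterior` (MAP-site posterior probability)
#' when the history carries one.
#'
#' @param history a `migration_history`.
#' @param file path.
#' @export
write_labeling <- function(history, file) {
  nodes <- names(history$labeling)
  df <- data.frame(node = nodes, site = unname(history$labeling),
                   stringsAsFactors = FALSE)
  if (!is.null(history$posterior)) {
    p <- rep(NA_real_, length(nodes))
    in_post <- nodes %in% rownames(history$posterior)
    p[in_post] <- history$posterior[cbind(nodes[in_post],
                                          df$site[in_post])]
    df$posterior <- p
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
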