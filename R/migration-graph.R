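#' Directed multigraph of clone migrations between tumor sites
#'
#' Edges are individual clone migration events between tumor sites; repeated
#' rows encode polyclonal seeding (edge multiplicity). The primary tumor site
#' is carried as an attribute.
#'
#' @param from,to character vectors of source and target sites, one entry per
#'   migration event.
#' @param primary name of the primary tumor site (default `"P"`).
#' @return a data.frame of class `migration_graph` with columns `from`, `to`.
#' @export
migration_graph <- function(from = character(0), to = character(0), primary = "P") {
  df <- data.frame(from = as.character(from), to = as.character(to),
                   stringsAsFactors = FALSE)
  structure(df, class = c("migration_graph", "data.frame"), primary = primary)
}

#' @export
print.migration_graph <- function(x, ...) {
  cat(sprintf("Migration graph (primary %s): %d migration(s)\n",
              attr(x, "primary"), nrow(x)))
  if (nrow(x)) {
    tab <- edge_counts(x)
    cat(paste0("  ", tab$from, " -> ", tab$to,
               ifelse(tab$n > 1L, sprintf("  (x%d)", tab$n), ""),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

# multiplicity per ordered site pair, deterministic order
edge_counts <- function(g) {
  if (!nrow(g)) {
    return(data.frame(from = character(0), to = character(0), n = integer(0)))
  }
  key <- paste(g$from, g$to, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[[`, "", 1L),
                    to = vapply(parts, `[[`, "", 2L),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Derive the migration graph implied by a full site labeling
#'
#' Emits one directed edge (parent site -> child site) for every tree edge
#' whose endpoints are assigned different tumor sites. The branch leading to
#' the germline outgroup, which represents normal tissue rather than a clone
#' migration, is excluded.
#'
#' @param tree a [clone_phylogeny].
#' @param labeling named character vector mapping every node id to a site.
#' @param germline optional germline leaf name to exclude.
#' @param primary primary site name (default `"P"`).
#' @return a [migration_graph].
#' @export
extract_migration_graph <- function(tree, labeling, germline = NULL, primary = "P") {
  kids <- names(tree$parent)
  if (!is.null(germline)) kids <- setdiff(kids, germline)
  missing <- setdiff(c(kids, tree$root), names(labeling))
  if (length(missing)) {
    stop(sprintf("labeling missing node '%s'", missing[1L]), call. = FALSE)
  }
  ps <- labeling[tree$parent[kids]]
  cs <- labeling[kids]
  mig <- ps != cs
  migration_graph(unname(ps[mig]), unname(cs[mig]), primary = primary)
}

#' Classify the seeding scenario of a migration graph
#'
#' Categories, from most to least complex: `pR` when any migration returns to
#' the primary site (reseeding); otherwise `pM` when some site is seeded from
#' two or more distinct source sites (multisource); otherwise `pS` when some
#' site receives two or more migrations from its (single) source (polyclonal
#' single-source); otherwise `mS` (every metastasis seeded by exactly one
#' clone, monoclonal single-source).
#'
#' @param g a [migration_graph].
#' @return one of `"mS"`, `"pS"`, `"pM"`, `"pR"`.
#' @export
#' @examples
#' classify_scenario(migration_graph(c("P", "P"), c("M1", "M2"))) # mS
#' classify_scenario(migration_graph(c("P", "P"), c("M1", "M1"))) # pS
classify_scenario <- function(g) {
  primary <- attr(g, "primary") %||% "P"
  if (any(g$to == primary)) return("pR")
  n_sources <- tapply(g$from, g$to, function(s) length(unique(s)))
  if (length(n_sources) && any(n_sources >= 2L)) return("pM")
  mult <- table(paste(g$from, g$to))
  if (length(mult) && any(mult >= 2L)) return("pS")
  "mS"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a migration graph as an edge-list TSV
#'
#' One `"source target"` line per migration event (multiplicity = repeated
#' lines), matching the truth-graph files written by [write_dataset()].
#'
#' @param file path.
#' @param primary primary site name.
#' @return [read_migration_graph()] returns a [migration_graph].
#' @export
read_migration_graph <- function(file, primary = "P") {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(migration_graph(primary = primary))
  parts <- strsplit(lines, "[ \t]+")
  migration_graph(vapply(parts, `[[`, "", 1L),
                  vapply(parts, `[[`, "", 2L), primary = primary)
}

#' @rdname read_migration_graph
#' @param g a [migration_graph].
#' @export
write_migration_graph <- function(g, file) {
  writeLines(sprintf("%s %s", g$from, g$to), file)
  invisible(file)
}

#' Export a migration graph in Graphviz DOT format
#'
#' @param g a [migration_graph].
#' @param file optional path; the DOT text is returned when `NULL`.
#' @param name graph name.
#' @return DOT text (invisibly when written to a file).
#' @export
write_dot <- function(g, file = NULL, name = "migrations") {
  tab <- edge_counts(g)
  lab <- ifelse(tab$n > 1L, sprintf(" [label=\"%d\"]", tab$n), "")
  txt <- c(sprintf("digraph %s {", name),
           sprintf("  \"%s\" -> \"%s\"%s;", tab$from, tab$to, lab),
           "}")
  if (is.null(file)) return(paste(txt, collapse = "\n"))
  writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}
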