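#' Rooted clone phylogeny
#'
#' A `clone_phylogeny` is a rooted tree whose nodes are tumor clones (sampled
#' clones at the leaves, unsampled ancestral clones at internal nodes) and
#' whose branch lengths are non-negative integer mutation counts. Polytomies
#' are permitted. A germline (normal-cell) taxon may be present as an outgroup
#' leaf; by convention it carries no somatic mutations.
#'
#' @param parent character vector of parent node ids, one per edge.
#' @param child character vector of child node ids, one per edge.
#' @param length numeric vector of branch lengths (mutations per edge);
#'   recycled from 1 if omitted.
#'
#' @return An object of class `clone_phylogeny`: a list with elements
#'   `nodes`, `root`, `parent` (named character, parent of each non-root
#'   node), `children` (named list of character vectors, in insertion order),
#'   `edge_length` (named numeric, keyed by child id), `leaves`.
#' @export
#' @examples
#' tr <- clone_phylogeny(parent = c("r", "r", "u", "u"),
#'                       child  = c("u", "C", "A", "B"))
#' tr$leaves
clone_phylogeny <- function(parent, child, length = NULL) {
  parent <- as.character(parent)
  child <- as.character(child)
  if (length(parent) != length(child)) {
    stop("parent and child must have equal length", call. = FALSE)
  }
  if (is.null(length)) length <- rep(1, length(child))
  if (length(length) == 1L) length <- rep(length, length(child))
  if (any(is.na(length)) || any(length < 0)) {
    stop("branch lengths must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(child)) {
    dup <- child[duplicated(child)][1L]
    stop(sprintf("node '%s' has two parents", dup), call. = FALSE)
  }
  nodes <- unique(c(parent, child))
  roots <- setdiff(nodes, child)
  if (length(roots) == 0L) {
    stop("cycle detected: no root node (every node has a parent)", call. = FALSE)
  }
  if (length(roots) > 1L) {
    stop(sprintf("multiple roots: %s", paste(sort(roots), collapse = ", ")),
         call. = FALSE)
  }
  par_map <- stats::setNames(parent, child)
  # reachability from root guards against disconnected cycles
  seen <- character(0)
  stack <- roots
  kids <- split(child, factor(parent, levels = nodes))
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, kids[[v]])
  }
  if (length(seen) != length(nodes)) {
    bad <- setdiff(nodes, seen)
    stop(sprintf("cycle detected involving node '%s'", bad[1L]), call. = FALSE)
  }
  structure(list(
    nodes = nodes,
    root = roots,
    parent = par_map,
    children = kids,
    edge_length = stats::setNames(as.numeric(length), child),
    leaves = nodes[vapply(kids[nodes], length, 1L) == 0L]
  ), class = "clone_phylogeny")
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat(sprintf("Clone phylogeny: %d nodes (%d leaves), root '%s', total length %g\n",
              length(x$nodes), length(x$leaves), x$root, sum(x$edge_length)))
  cat("Leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(tree) length(tree$nodes)

#' Post-order traversal of node ids
#' @param tree a `clone_phylogeny`.
#' @return character vector of node ids, children before parents.
#' @export
postorder <- function(tree) {
  out <- character(n_nodes(tree))
  i <- 0L
  visit <- function(v) {
    for (c in tree$children[[v]]) visit(c)
    i <<- i + 1L
    out[i] <<- v
  }
  visit(tree$root)
  out
}

internal_nodes <- function(tree) setdiff(tree$nodes, tree$leaves)

#' Parse a clone phylogeny
#'
#' Reads a tree from newick text or from an edge list with one
#' whitespace-separated `"parent child"` pair per line (the format used by
#' published clone-tree benchmark files).
#'
#' @param x a character scalar (newick string or whole edge-list text), or a
#'   character vector of edge-list lines, or a file path.
#' @param format `"newick"` or `"edge-list"`.
#' @return a [clone_phylogeny].
#' @export
#' @examples
#' parse_tree("((A,B),C);", format = "newick")
#' parse_tree(c("r u", "u A", "u B", "r C"), format = "edge-list")
parse_tree <- function(x, format = c("newick", "edge-list")) {
  format <- match.arg(format)
  if (length(x) == 1L && file.exists(x) && !grepl("[(;\n]", x)) {
    x <- readLines(x, warn = FALSE)
    if (format == "newick") x <- paste(x, collapse = "")
  }
  if (format == "newick") {
    ph <- ape::read.tree(text = paste(x, collapse = ""))
    if (is.null(ph)) stop("could not parse newick text", call. = FALSE)
    if (anyDuplicated(ph$tip.label)) {
      stop(sprintf("duplicate leaf name '%s'",
                   ph$tip.label[duplicated(ph$tip.label)][1L]), call. = FALSE)
    }
    return(phylo_to_clone(ph))
  }
  lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge list", call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d: '%s'", bad[1L], lines[bad[1L]]),
         call. = FALSE)
  }
  parent <- vapply(parts, `[[`, "", 1L)
  child <- vapply(parts, `[[`, "", 2L)
  len <- vapply(parts, function(p) {
    if (length(p) >= 3L) as.numeric(p[[3L]]) else 1
  }, 1)
  clone_phylogeny(parent, child, len)
}

#' Write a clone phylogeny
#'
#' @param tree a [clone_phylogeny].
#' @param format `"newick"` or `"edge-list"`.
#' @param file optional path; when `NULL` the text is returned.
#' @param lengths include branch lengths (edge-list gains a third column).
#' @return the serialized text, invisibly when written to a file.
#' @export
write_tree <- function(tree, format = c("newick", "edge-list"), file = NULL,
                       lengths = TRUE) {
  format <- match.arg(format)
  if (format == "newick") {
    ph <- clone_to_phylo(tree)
    txt <- ape::write.tree(ph)
  } else {
    ord <- preorder_edges(tree)
    txt <- if (lengths) {
      sprintf("%s %s %g", tree$parent[ord], ord, tree$edge_length[ord])
    } else {
      sprintf("%s %s", tree$parent[ord], ord)
    }
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# children of each node in stable order, parents before children
preorder_edges <- function(tree) {
  out <- character(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    ch <- tree$children[[v]]
    out <- c(out, ch)
    stack <- c(ch, stack)
  }
  out
}

phylo_to_clone <- function(ph) {
  n_tip <- length(ph$tip.label)
  n_all <- n_tip + ph$Nnode
  labs <- character(n_all)
  labs[seq_len(n_tip)] <- ph$tip.label
  if (!is.null(ph$node.label) && any(nzchar(ph$node.label))) {
    labs[n_tip + seq_len(ph$Nnode)] <- ph$node.label
  }
  empty <- !nzchar(labs)
  labs[empty] <- paste0("node", which(empty))
  if (anyDuplicated(labs)) {
    stop(sprintf("duplicate leaf name '%s'", labs[duplicated(labs)][1L]),
         call. = FALSE)
  }
  len <- if (is.null(ph$edge.length)) rep(1, nrow(ph$edge)) else ph$edge.length
  clone_phylogeny(labs[ph$edge[, 1L]], labs[ph$edge[, 2L]], len)
}

clone_to_phylo <- function(tree) {
  tips <- tree$leaves
  internals <- c(tree$root, setdiff(internal_nodes(tree), tree$root))
  idx <- stats::setNames(seq_along(c(tips, internals)), c(tips, internals))
  ch <- names(tree$parent)
  edge <- cbind(idx[tree$parent[ch]], idx[ch])
  dimnames(edge) <- NULL
  ph <- list(edge = edge,
             tip.label = tips,
             node.label = internals,
             edge.length = unname(tree$edge_length[ch]),
             Nnode = length(internals))
  class(ph) <- "phylo"
  ape::reorder.phylo(ph, "cladewise")
}

#' Root a clone phylogeny with its germline outgroup
#'
#' Ensures the germline taxon sits as a child of the root (re-rooting on the
#' germline-incident edge if necessary) and labels it with the primary tumor
#' site. The germline outgroup encodes the assumption that the clone at the
#' root of the phylogeny resided in the primary tumor.
#'
#' @param tree a [clone_phylogeny].
#' @param germline name of the germline leaf.
#' @param primary_site site label of the primary tumor (default `"P"`).
#' @return a list with elements `tree` (rooted [clone_phylogeny]) and
#'   `labeling` (named character vector labeling the germline leaf).
#' @export
root_with_germline <- function(tree, germline, primary_site = "P") {
  if (!(germline %in% tree$leaves)) {
    stop(sprintf("germline leaf '%s' not found in tree", germline), call. = FALSE)
  }
  if (!identical(unname(tree$parent[germline]), tree$root)) {
    # reroot on the germline-incident edge: ape handles the pivoting
    ph <- clone_to_phylo(tree)
    ph <- ape::root(ph, outgroup = germline, resolve.root = TRUE)
    tree <- phylo_to_clone(ph)
  }
  list(tree = tree,
       labeling = stats::setNames(primary_site, germline))
}
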