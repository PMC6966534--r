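#' Site ranges from an ancestral posterior
#'
#' For event annotation a node may occupy a multi-site range: every site
#' whose marginal posterior probability is at least `threshold` is included,
#' and the maximum-a-posteriori site is always retained.
#'
#' @param posterior an `ancestral_posterior`.
#' @param threshold inclusion probability (default 0.15).
#' @return named list mapping node id to a character vector of sites, in
#'   canonical site order.
#' @export
ranges_from_posterior <- function(posterior, threshold = 0.15) {
  nodes <- rownames(posterior$prob)
  out <- lapply(stats::setNames(nodes, nodes), function(v) {
    p <- posterior$prob[v, ]
    r <- union(posterior$map[[v]], posterior$sites[p >= threshold])
    site_order(r)
  })
  out
}

#' Annotate biogeographic events on a clone phylogeny
#'
#' Maps range changes along the tree onto the three biogeographic event
#' classes: dispersal (a branch gains a site: a clone migrated there),
#' extinction (a branch loses a site: the lineage disappeared from it), and
#' diversification (two or more children of a node retain a shared site:
#' within-site divergence). Events are also serialized in a compact
#' arrow/caret notation: a branch whose range goes from `M1` to `M1 M7` is a
#' dispersal written `M1->M1M7`, a node in `M2` whose children stay in `M2`
#' is a diversification written `M2^M2`.
#'
#' @param tree a [clone_phylogeny].
#' @param ranges named list of site vectors per node (see
#'   [ranges_from_posterior()]); singleton ranges give the plain
#'   dispersal-only annotation of a MAP labeling.
#' @return data.frame with columns `event` (`dispersal`, `extinction`,
#'   `diversification`), `node` (child node of the branch, or the node
#'   itself for diversification), `site` (site gained, lost or retained) and
#'   `label` (serialized notation).
#' @export
annotate_events <- function(tree, ranges) {
  empty <- names(Filter(function(r) length(r) == 0L, ranges[tree$nodes]))
  if (length(empty) || any(!tree$nodes %in% names(ranges))) {
    bad <- c(empty, setdiff(tree$nodes, names(ranges)))[1L]
    stop(sprintf("empty or missing range at node '%s'", bad), call. = FALSE)
  }
  ev <- list()
  add <- function(event, node, site, label) {
    ev[[length(ev) + 1L]] <<- data.frame(event = event, node = node,
                                         site = site, label = label,
                                         stringsAsFactors = FALSE)
  }
  collapse <- function(r) paste(site_order(r), collapse = "")
  for (ch in names(tree$parent)) {
    rp <- ranges[[tree$parent[[ch]]]]
    rc <- ranges[[ch]]
    gained <- setdiff(rc, rp)
    lost <- setdiff(rp, rc)
    for (s in gained) {
      add("dispersal", ch, s, sprintf("%s->%s", collapse(rp), collapse(rc)))
    }
    for (s in lost) {
      add("extinction", ch, s, sprintf("%s->%s", collapse(rp), collapse(rc)))
    }
  }
  for (v in setdiff(tree$nodes, tree$leaves)) {
    ch <- tree$children[[v]]
    if (length(ch) < 2L) next
    shared <- Reduce(intersect, c(list(ranges[[v]]), ranges[ch]))
    for (s in shared) {
      add("diversification", v, s, sprintf("%s^%s", s, s))
    }
  }
  if (!length(ev)) {
    return(data.frame(event = character(0), node = character(0),
                      site = character(0), label = character(0)))
  }
  do.call(rbind, ev)
}
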