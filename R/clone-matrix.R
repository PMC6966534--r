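#' Binary clone genotype matrix
#'
#' Clones x characters matrix of 0/1 genotypes, 0 being the germline base and
#' 1 the somatic substitution. Under the clonal-evolution assumption each
#' character mutates exactly once and never reverts, so a valid matrix is
#' homoplasy-free: the 1-sets of every pair of characters are nested or
#' disjoint, and the matrix admits a perfect phylogeny.
#'
#' @param x a 0/1 matrix with clone rownames and character colnames (generated
#'   when missing).
#' @return an integer matrix of class `clone_matrix`.
#' @export
clone_matrix <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("entries must be 0 or 1", call. = FALSE)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- paste0("clone", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate clone names", call. = FALSE)
  structure(x, class = c("clone_matrix", class(x)))
}

#' Test a clone matrix for homoplasy
#'
#' Checks the pairwise compatibility condition of a perfect phylogeny: for
#' every pair of characters the sets of clones carrying the derived state must
#' be nested or disjoint.
#'
#' @param mat a [clone_matrix] (or plain 0/1 matrix).
#' @return `TRUE` if compatible; otherwise `FALSE` with attribute `conflict`
#'   naming the first offending character pair.
#' @export
is_homoplasy_free <- function(mat) {
  m <- unclass(as.matrix(mat))
  storage.mode(m) <- "integer"
  n1 <- colSums(m)
  both <- crossprod(m) # shared-derived counts per character pair
  conflict <- both > 0L &
    sweep(both, 1L, n1, "<") &
    sweep(both, 2L, n1, "<")
  if (any(conflict)) {
    ij <- sort(which(conflict, arr.ind = TRUE)[1L, ])
    out <- FALSE
    attr(out, "conflict") <- colnames(m)[ij]
    return(out)
  }
  TRUE
}

#' Reconstruct the clone phylogeny from a homoplasy-free matrix
#'
#' Builds the perfect phylogeny of a binary clone matrix, rooted at the
#' germline. Characters with identical clone sets are merged onto one edge, so
#' each edge's branch length equals the number of characters mutating on it
#' and the parsimony score of the returned tree equals the number of
#' characters. With homoplasy-free data this is the (unique) maximum-parsimony
#' tree.
#'
#' @param mat a [clone_matrix]; a germline row of all zeros is used if present
#'   (identified by `germline`), otherwise one is added.
#' @param germline name of the germline taxon (default `"germline"`).
#' @return a [clone_phylogeny] whose leaves are the clones plus the germline
#'   outgroup attached to the root with a zero-length branch.
#' @export
#' @examples
#' m <- clone_matrix(rbind(A = c(1, 0, 0), B = c(1, 1, 0), C = c(1, 1, 1)))
#' reconstruct_mp_tree(m)
reconstruct_mp_tree <- function(mat, germline = "germline") {
  m <- unclass(as.matrix(mat))
  storage.mode(m) <- "integer"
  if (germline %in% rownames(m)) {
    if (any(m[germline, ] != 0L)) {
      stop("germline row must be all zeros", call. = FALSE)
    }
    m <- m[setdiff(rownames(m), germline), , drop = FALSE]
  }
  ok <- is_homoplasy_free(m)
  if (!isTRUE(ok)) {
    pr <- attr(ok, "conflict")
    stop(sprintf("matrix is not homoplasy-free: characters '%s' and '%s' conflict",
                 pr[1L], pr[2L]), call. = FALSE)
  }
  if (any(colSums(m) == 0L)) {
    stop("character with no derived state observed", call. = FALSE)
  }
  clones <- rownames(m)
  n <- length(clones)
  # distinct column patterns define the clades; multiplicity = branch length
  pat <- apply(m, 2L, paste, collapse = "")
  mult <- table(pat)
  upat <- names(mult)
  clades <- lapply(upat, function(p) {
    which(strsplit(p, "")[[1L]] == "1")
  })
  sizes <- vapply(clades, length, 1L)
  ord <- order(-sizes, upat) # big to small; ties deterministic
  clades <- clades[ord]
  lens <- as.integer(mult)[ord]

  root <- ".root"
  node_of <- character(length(clades))
  cur <- rep(root, n) # lowest clade node currently containing each clone
  parent <- character(0)
  child <- character(0)
  elen <- numeric(0)
  for (i in seq_along(clades)) {
    cl <- clades[[i]]
    node_of[i] <- sprintf(".mp%d", i)
    par <- unique(cur[cl])
    stopifnot(length(par) == 1L) # laminarity guarantees a single parent
    parent <- c(parent, par)
    child <- c(child, node_of[i])
    elen <- c(elen, lens[i])
    cur[cl] <- node_of[i]
  }
  parent <- c(parent, cur, root)
  child <- c(child, clones, germline)
  elen <- c(elen, rep(0, n), 0)
  tree <- clone_phylogeny(parent, child, elen)
  contract_unary(tree)
}

# merge internal nodes that have exactly one child into their child's edge
contract_unary <- function(tree) {
  repeat {
    deg1 <- names(Filter(function(ch) length(ch) == 1L, tree$children))
    deg1 <- setdiff(deg1, tree$root)
    deg1 <- setdiff(deg1, tree$leaves)
    if (!length(deg1)) return(tree)
    v <- deg1[[1L]]
    ch <- tree$children[[v]]
    par <- tree$parent[[v]]
    kids <- names(tree$parent)
    newpar <- tree$parent
    newpar[ch] <- par
    newpar <- newpar[setdiff(kids, v)]
    len <- tree$edge_length
    len[ch] <- len[ch] + len[v]
    len <- len[setdiff(kids, v)]
    tree <- clone_phylogeny(unname(newpar), names(newpar), unname(len[names(newpar)]))
  }
}

#' Read / write a clone matrix as TSV
#'
#' Tab-separated file with a header row of character ids and clone names in
#' the first column.
#'
#' @param file path.
#' @return [read_clone_matrix()] returns a [clone_matrix].
#' @export
read_clone_matrix <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  clone_matrix(as.matrix(df))
}

#' @rdname read_clone_matrix
#' @param mat a [clone_matrix].
#' @export
write_clone_matrix <- function(mat, file) {
  df <- data.frame(clone = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
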