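# deterministic site ordering: primary first, then metastases by numeric
# suffix, then anything else alphabetically
site_order <- function(sites, primary = "P") {
  sites <- unique(sites)
  suffix <- suppressWarnings(as.integer(sub("^M", "", sites)))
  key <- ifelse(sites == primary, -1L,
                ifelse(grepl("^M[0-9]+$", sites), suffix, NA_integer_))
  sites[order(is.na(key), key, sites)]
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

drop_leaf <- function(tree, leaf) {
  stopifnot(leaf %in% tree$leaves)
  keep <- setdiff(names(tree$parent), leaf)
  clone_phylogeny(unname(tree$parent[keep]), keep, unname(tree$edge_length[keep]))
}
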