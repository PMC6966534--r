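#' Simulation configuration for metastatic seeding datasets
#'
#' Describes one synthetic dataset: the seeding scenario, the number of tumor
#' sites (directly or through the small/large size classes), clone and
#' mutation budgets, and the random seed. The four scenarios, in increasing
#' complexity, are monoclonal single-source seeding (`mS`: every metastasis
#' founded by exactly one migrating clone from one source), polyclonal
#' single-source (`pS`: some metastasis receives two or more clones, all from
#' the same source), polyclonal multisource (`pM`: some metastasis is seeded
#' from two or more distinct sources) and reseeding (`pR`: at least one clone
#' migrates from a metastasis back to the primary tumor).
#'
#' @param scenario one of `"mS"`, `"pS"`, `"pM"`, `"pR"`.
#' @param size_class `"m5"` (5-7 tumor sites) or `"m8"` (8-11 sites); ignored
#'   when `sites` is given.
#' @param sites explicit number of tumor sites (>= 2), or `NULL`.
#' @param clones_per_site range of sampled clones per site (default 1-4);
#'   totals are kept within 7-28 clones.
#' @param muts_per_branch range of mutations per tree branch (default 1-6);
#'   totals are kept within 9-99 characters.
#' @param polytomy_prob probability that a within-site divergence produces
#'   three daughter clones instead of two (default 0.1).
#' @param reseed_prob for `pR` only: probability of additional reseeding
#'   migrations beyond the guaranteed one (default 0.2).
#' @param seed random seed; the dataset is a deterministic function of the
#'   configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("mS", "pS", "pM", "pR"),
                       size_class = c("m5", "m8"), sites = NULL,
                       clones_per_site = c(1L, 4L),
                       muts_per_branch = c(1L, 6L),
                       polytomy_prob = 0.1, reseed_prob = 0.2, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(sites)) size_class <- match.arg(size_class)
  else if (sites < 2L) stop("site count must be >= 2", call. = FALSE)
  structure(list(scenario = scenario,
                 size_class = if (is.null(sites)) size_class else NULL,
                 sites = sites,
                 clones_per_site = as.integer(clones_per_site),
                 muts_per_branch = as.integer(muts_per_branch),
                 polytomy_prob = polytomy_prob, reseed_prob = reseed_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a metastatic seeding dataset with known migration history
#'
#' Generates a clone phylogeny, a homoplasy-free binary clone matrix, leaf
#' tumor-site labels, the true full (ancestral) labeling, and the true
#' migration graph, under the requested seeding scenario. The generative
#' model works at clone resolution: a site-level seeding skeleton satisfying
#' the scenario constraints is drawn first, then embedded into a growing
#' clone tree in which each migration splits a lineage into a resident and a
#' migrating daughter and within-site divergences supply the remaining
#' sampled clones. Migration source lineages are chosen uniformly. Every
#' branch carries at least one private character, so the true topology is
#' recoverable by perfect-phylogeny reconstruction. Rejection sampling (up to
#' `max_tries` attempts) guarantees the realized migration graph classifies
#' exactly as the requested scenario.
#'
#' @param config a [sim_config].
#' @param max_tries rejection-sampling cap (default 1000).
#' @return an object of class `simulated_dataset`: list with `tree`
#'   (germline-rooted [clone_phylogeny]), `matrix` ([clone_matrix] including
#'   the germline row), `leaf_labeling`, `truth_labeling` (all nodes),
#'   `graph` (true [migration_graph]), `scenario`, `sites`, `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config("mS", sites = 5, seed = 1))
#' classify_scenario(ds$graph)
simulate_dataset <- function(config, max_tries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    for (try in seq_len(max_tries)) {
      ds <- try_simulate(config)
      if (!is.null(ds)) return(ds)
    }
  })
  stop(sprintf("could not satisfy %s constraints in %d attempts; increase the clone budget",
               config$scenario, max_tries), call. = FALSE)
}

try_simulate <- function(config) {
  k <- config$sites %||% switch(config$size_class,
                                m5 = sample(5:7, 1L),
                                m8 = sample(8:11, 1L))
  sites <- c("P", if (k > 1L) paste0("M", seq_len(k - 1L)))
  mets <- setdiff(sites, "P")
  cpmin <- config$clones_per_site[1L]
  cpmax <- config$clones_per_site[2L]

  # --- sampled-clone budget per site -----------------------------------
  # The primary, as the oldest and largest tumor, carries the most sampled
  # clones; seeding sources below are drawn proportional to these counts
  # (the clone-level analogue of seeding proportional to tumor cell counts).
  c_s <- stats::setNames(c(sample(max(2L, cpmin):cpmax, 1L),
                           sample(cpmin:cpmax, k - 1L, replace = TRUE)),
                         sites)
  total_min <- max(7L, k)
  while (sum(c_s) < total_min) {
    room <- which(c_s < cpmax)
    if (!length(room)) return(NULL)
    i <- sample(room, 1L)
    c_s[i] <- c_s[i] + 1L
  }
  while (sum(c_s) > 28L) {
    room <- which(c_s > max(cpmin, 1L))
    if (!length(room)) return(NULL)
    i <- sample(room, 1L)
    c_s[i] <- c_s[i] - 1L
  }

  # --- site-level seeding skeleton -------------------------------------
  placed <- "P"
  edges_from <- character(0)
  edges_to <- character(0)
  pick_source <- function(pool) {
    if (length(pool) == 1L) return(pool)
    sample(pool, 1L, prob = c_s[pool])
  }
  for (m in sample(mets)) {
    src <- pick_source(placed)
    edges_from <- c(edges_from, src)
    edges_to <- c(edges_to, m)
    placed <- c(placed, m)
  }
  add_edge <- function(s, t) {
    edges_from <<- c(edges_from, s)
    edges_to <<- c(edges_to, t)
  }
  in_deg <- function(t) sum(edges_to == t) + (t == "P")
  scen_rank <- match(config$scenario, c("mS", "pS", "pM", "pR"))
  # complexity is cumulative: polyclonal multiplicities appear from pS on,
  # multisource seeding from pM on, reseeding defines pR
  if (scen_rank >= 2L) {
    extras <- 0L
    for (t in sample(mets)) {
      if (stats::runif(1) < 0.4 && in_deg(t) < c_s[t]) {
        add_edge(edges_from[match(t, edges_to)], t)
        extras <- extras + 1L
      }
    }
    if (extras == 0L) {
      ok <- mets[vapply(mets, in_deg, 1L) < c_s[mets]]
      if (!length(ok)) return(NULL)
      t <- sample(ok, 1L)
      add_edge(edges_from[match(t, edges_to)], t)
    }
  }
  if (scen_rank >= 3L) {
    n_multi <- 1L + stats::rbinom(1L, 1L, 0.3)
    # in pR, multisource rides along only part of the time
    if (config$scenario == "pR" && stats::runif(1) < 0.5) n_multi <- 0L
    for (i in seq_len(n_multi)) {
      ok <- mets[vapply(mets, in_deg, 1L) < c_s[mets]]
      if (!length(ok)) {
        if (config$scenario == "pM" && i == 1L) return(NULL) else break
      }
      t <- sample(ok, 1L)
      src1 <- edges_from[match(t, edges_to)]
      pool <- setdiff(sites, c(t, src1))
      if (!length(pool)) {
        if (config$scenario == "pM" && i == 1L) return(NULL) else break
      }
      add_edge(pick_source(pool), t)
    }
  }
  if (config$scenario == "pR") {
    if (in_deg("P") >= c_s[["P"]]) return(NULL)
    add_edge(pick_source(mets), "P")
    while (stats::runif(1) < config$reseed_prob && in_deg("P") < c_s[["P"]]) {
      add_edge(pick_source(mets), "P")
    }
  }
  g_planned <- migration_graph(edges_from, edges_to, primary = "P")
  if (classify_scenario(g_planned) != config$scenario) return(NULL)

  arrivals <- stats::setNames(
    vapply(sites, function(s) sum(edges_to == s) + (s == "P"), 1L), sites)
  # every arriving clone founds at least one sampled descendant at its site
  if (any(arrivals > pmin(c_s, cpmax))) return(NULL)
  if (sum(c_s) > 28L || sum(c_s) < 7L) return(NULL)
  div_s <- c_s - arrivals

  # --- embed into a growing clone tree ---------------------------------
  counter <- 0L
  new_node <- function() {
    counter <<- counter + 1L
    sprintf("N%d", counter)
  }
  root <- new_node()
  node_site <- stats::setNames("P", root)
  parent <- character(0)
  active <- stats::setNames("P", root) # active lineage -> current site
  migs <- data.frame(from = edges_from, to = edges_to,
                     stringsAsFactors = FALSE)
  migs <- migs[sample(nrow(migs)), , drop = FALSE]
  div_left <- div_s
  split_lineage <- function(lin, daughter_sites) {
    kids <- character(length(daughter_sites))
    for (j in seq_along(daughter_sites)) {
      kids[j] <- new_node()
      parent[kids[j]] <<- lin
      node_site[kids[j]] <<- daughter_sites[j]
    }
    active <<- active[setdiff(names(active), lin)]
    active <<- c(active, stats::setNames(daughter_sites, kids))
    kids
  }
  # a tumor grows (diversifies) before seeding onward — migrations leave a
  # site only after its diversifications are spent, and successive seedings
  # depart from distinct resident lineages where possible, emulating random
  # emigrant cells drawn from an established tumor
  emitted <- character(0)
  while (nrow(migs) > 0L || any(div_left > 0L)) {
    feas_div <- names(div_left)[div_left > 0L & names(div_left) %in% active]
    feas_mig <- which(migs$from %in% active & !(migs$from %in% feas_div))
    n_f <- length(feas_mig) + length(feas_div)
    if (n_f == 0L) return(NULL)
    pick <- sample.int(n_f, 1L)
    if (pick <= length(feas_mig)) {
      e <- feas_mig[pick]
      s <- migs$from[e]
      t <- migs$to[e]
      pool <- names(active)[active == s]
      fresh <- setdiff(pool, emitted)
      lin <- if (length(fresh)) sample(fresh, 1L) else sample(pool, 1L)
      kids <- split_lineage(lin, c(s, t))
      emitted <- c(emitted, kids[1L]) # the resident daughter inherits history
      migs <- migs[-e, , drop = FALSE]
    } else {
      s <- feas_div[pick - length(feas_mig)]
      lin <- sample(names(active)[active == s], 1L)
      if (div_left[s] >= 2L && stats::runif(1) < config$polytomy_prob) {
        split_lineage(lin, c(s, s, s))
        div_left[s] <- div_left[s] - 2L
      } else {
        split_lineage(lin, c(s, s))
        div_left[s] <- div_left[s] - 1L
      }
    }
  }

  # rename active lineages to clone names, deterministic by site then id
  leaves <- names(active)
  ord <- order(match(active, sites), as.integer(sub("^N", "", leaves)))
  leaves <- leaves[ord]
  clone_names <- sprintf("C%d", seq_along(leaves))
  rename <- stats::setNames(clone_names, leaves)
  all_kids <- names(parent)
  new_ids <- ifelse(all_kids %in% leaves, rename[all_kids], all_kids)
  new_parent <- stats::setNames(unname(parent), new_ids)
  names(node_site) <- ifelse(names(node_site) %in% leaves,
                             rename[names(node_site)], names(node_site))

  # --- branch lengths and characters -----------------------------------
  lens <- sample(config$muts_per_branch[1L]:config$muts_per_branch[2L],
                 length(new_ids), replace = TRUE)
  while (sum(lens) > 99L) {
    big <- which(lens > 1L)
    if (!length(big)) break
    i <- sample(big, 1L)
    lens[i] <- lens[i] - 1L
  }
  if (sum(lens) > 99L || sum(lens) < 9L) return(NULL)

  germline <- "GL"
  tree <- clone_phylogeny(c(unname(new_parent), root),
                          c(names(new_parent), germline),
                          c(lens, 0))
  truth <- c(node_site, stats::setNames("P", germline))

  # characters: one block per edge, derived state in the clades below it
  edge_children <- names(new_parent)
  desc_leaves <- descendant_leaves(tree)
  m <- matrix(0L, nrow = length(clone_names) + 1L, ncol = sum(lens),
              dimnames = list(c(clone_names, germline),
                              sprintf("s%d", seq_len(sum(lens)))))
  col <- 0L
  for (i in seq_along(edge_children)) {
    dl <- setdiff(desc_leaves[[edge_children[i]]], germline)
    for (j in seq_len(lens[i])) {
      col <- col + 1L
      m[dl, col] <- 1L
    }
  }
  mat <- clone_matrix(m)

  leaf_lab <- truth[tree$leaves]
  graph <- extract_migration_graph(tree, truth, germline = germline)
  if (classify_scenario(graph) != config$scenario) return(NULL)
  if (!all(table(factor(leaf_lab[setdiff(tree$leaves, germline)],
                        levels = sites)) >= 1L)) return(NULL)

  structure(list(tree = tree, matrix = mat, leaf_labeling = leaf_lab,
                 truth_labeling = truth, graph = graph,
                 scenario = config$scenario, sites = sites,
                 germline = germline, config = config),
            class = "simulated_dataset")
}

descendant_leaves <- function(tree) {
  out <- stats::setNames(vector("list", n_nodes(tree)), tree$nodes)
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    out[[v]] <- if (!length(ch)) v else unlist(out[ch], use.names = FALSE)
  }
  out
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated %s dataset: %d sites, %d sampled clones, %d characters\n",
              x$scenario, length(x$sites),
              length(setdiff(x$tree$leaves, x$germline)), ncol(x$matrix)))
  print(x$graph)
  invisible(x)
}

#' Write / read a simulated dataset directory
#'
#' Serializes all components as plain text: `clones.tsv` (binary matrix),
#' `tree.newick` (with branch lengths), `T.tree` (parent-child edge list) and
#' `T.labeling` (leaf sites), `truth.labeling` (all-node sites),
#' `truth_graph.tsv` (one line per migration event) and `meta.json`.
#' [read_dataset()] also accepts benchmark-style directories holding only a
#' `T.tree`/`T.labeling` pair, in which case the truth fields are `NULL`.
#'
#' @param ds a `simulated_dataset`.
#' @param dir directory (created if needed).
#' @return `read_dataset()` returns a `simulated_dataset` (possibly with
#'   truth fields absent).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clone_matrix(ds$matrix, file.path(dir, "clones.tsv"))
  write_tree(ds$tree, "newick", file.path(dir, "tree.newick"))
  write_tree(ds$tree, "edge-list", file.path(dir, "T.tree"), lengths = FALSE)
  writeLines(sprintf("%s %s", names(ds$leaf_labeling), ds$leaf_labeling),
             file.path(dir, "T.labeling"))
  writeLines(sprintf("%s %s", names(ds$truth_labeling), ds$truth_labeling),
             file.path(dir, "truth.labeling"))
  write_migration_graph(ds$graph, file.path(dir, "truth_graph.tsv"))
  meta <- list(scenario = ds$scenario, sites = ds$sites,
               germline = ds$germline,
               config = unclass(ds$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("T.labeling"))) {
    stop(sprintf("missing labeling file in '%s'", dir), call. = FALSE)
  }
  tree <- if (file.exists(p("tree.newick"))) {
    parse_tree(paste(readLines(p("tree.newick"), warn = FALSE), collapse = ""),
               format = "newick")
  } else if (file.exists(p("T.tree"))) {
    parse_tree(readLines(p("T.tree"), warn = FALSE), format = "edge-list")
  } else {
    stop(sprintf("missing tree file in '%s'", dir), call. = FALSE)
  }
  read_lab <- function(f) {
    lines <- trimws(readLines(f, warn = FALSE))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
  }
  leaf_lab <- read_lab(p("T.labeling"))
  meta <- if (file.exists(p("meta.json"))) jsonlite::read_json(p("meta.json"))
  germline <- meta$germline %||%
    (if ("GL" %in% tree$leaves) "GL" else NULL)
  truth <- if (file.exists(p("truth.labeling"))) read_lab(p("truth.labeling"))
  graph <- if (file.exists(p("truth_graph.tsv"))) {
    read_migration_graph(p("truth_graph.tsv"))
  }
  mat <- if (file.exists(p("clones.tsv"))) read_clone_matrix(p("clones.tsv"))
  cfg <- if (!is.null(meta$config)) {
    cf <- meta$config
    sim_config(cf$scenario, size_class = cf$size_class %||% "m5",
               sites = cf$sites,
               clones_per_site = unlist(cf$clones_per_site),
               muts_per_branch = unlist(cf$muts_per_branch),
               polytomy_prob = cf$polytomy_prob, reseed_prob = cf$reseed_prob,
               seed = cf$seed)
  }
  structure(list(tree = tree, matrix = mat, leaf_labeling = leaf_lab,
                 truth_labeling = truth, graph = graph,
                 scenario = meta$scenario %||%
                   (if (!is.null(graph)) classify_scenario(graph)),
                 sites = unlist(meta$sites) %||%
                   site_order(unique(unname(leaf_lab))),
                 germline = germline, config = cfg),
            class = "simulated_dataset")
}
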