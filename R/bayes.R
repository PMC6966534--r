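#' Equal-rate discrete tumor-site substitution model
#'
#' A k-state Markov model of site changes along the clone phylogeny with
#' equal exchange rates between all sites (the k-state generalization of the
#' Jukes-Cantor model), normalized to one expected change per unit branch
#' length. Branch lengths are mutation counts multiplied by `scale` (expected
#' site changes per mutation); zero-length branches receive the pseudo-length
#' `eps` so transition matrices stay non-degenerate.
#'
#' @param sites character vector of tumor sites (k >= 2).
#' @param scale expected site changes per mutation (default 0.05).
#' @param eps pseudo-length, in mutations, for zero-length branches
#'   (default 0.01).
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(sites, scale = 0.05, eps = 0.01) {
  sites <- site_order(sites)
  k <- length(sites)
  if (k < 2L) stop("need at least 2 sites", call. = FALSE)
  structure(list(sites = sites, k = k, scale = scale, eps = eps),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Equal-rate site model: k = %d states, scale = %g changes/mutation, eps = %g\n",
              x$k, x$scale, x$eps))
  invisible(x)
}

#' Transition probability matrix over a branch
#'
#' @param model an [mk_model].
#' @param mutations branch length in mutations.
#' @return k x k row-stochastic matrix; equal rates make it symmetric.
#' @export
transition_matrix <- function(model, mutations) {
  k <- model$k
  t <- max(mutations, model$eps) * model$scale
  e <- exp(-k * t / (k - 1))
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k - e / k
  m <- matrix(p_diff, k, k, dimnames = list(model$sites, model$sites))
  diag(m) <- p_same
  m
}

# transition matrices for every edge, keyed by child id
edge_matrices <- function(tree, model) {
  lapply(stats::setNames(names(tree$parent), names(tree$parent)),
         function(ch) transition_matrix(model, tree$edge_length[[ch]]))
}

#' Exact marginal posteriors of ancestral tumor sites
#'
#' Computes, for every node of the clone phylogeny, the exact marginal
#' posterior distribution over tumor sites under the equal-rate model, by
#' two-pass belief propagation (Felsenstein pruning upward, then a downward
#' pass), with a uniform prior on the root state. The root constraint to the
#' primary site is imposed through the data: include the germline taxon as an
#' outgroup leaf labeled with the primary site on a short branch.
#'
#' @param tree a [clone_phylogeny]; every leaf must appear in `leaf_labels`.
#' @param leaf_labels named character vector of leaf sites (the germline
#'   leaf, when present, labeled with the primary site).
#' @param model an [mk_model]; built from the observed sites when `NULL`.
#' @return an object of class `ancestral_posterior`: list with `prob`
#'   (nodes x sites matrix of marginal posteriors), `map` (named character,
#'   maximum-a-posteriori site per node), `map_prob`, `sites`, `loglik`.
#' @export
#' @examples
#' tr <- parse_tree("(A:1,B:1);", format = "newick")
#' marginal_posteriors(tr, c(A = "P", B = "M1"))$prob
marginal_posteriors <- function(tree, leaf_labels, model = NULL) {
  if (is.null(model)) model <- mk_model(unique(unname(leaf_labels)))
  sites <- model$sites
  k <- model$k
  missing <- setdiff(tree$leaves, names(leaf_labels))
  if (length(missing)) {
    stop(sprintf("leaf '%s' has no site label", missing[1L]), call. = FALSE)
  }
  P <- edge_matrices(tree, model)
  ord <- postorder(tree)
  up <- matrix(0, n_nodes(tree), k, dimnames = list(tree$nodes, sites))
  logscale <- 0
  msg <- list() # child -> message to its parent, sum_t P(s,t) up[c,t]
  for (v in ord) {
    ch <- tree$children[[v]]
    if (!length(ch)) {
      lab <- leaf_labels[[v]]
      if (!(lab %in% sites)) {
        stop(sprintf("leaf '%s' labeled with unknown site '%s'", v, lab),
             call. = FALSE)
      }
      up[v, lab] <- 1
    } else {
      acc <- rep(1, k)
      for (c in ch) {
        msg[[c]] <- as.vector(P[[c]] %*% up[c, ])
        acc <- acc * msg[[c]]
      }
      s <- sum(acc)
      logscale <- logscale + log(s)
      up[v, ] <- acc / s
    }
  }
  for (c in intersect(tree$leaves, names(P))) {
    if (is.null(msg[[c]])) msg[[c]] <- as.vector(P[[c]] %*% up[c, ])
  }
  prior <- rep(1 / k, k)
  down <- matrix(0, n_nodes(tree), k, dimnames = list(tree$nodes, sites))
  down[tree$root, ] <- prior
  for (v in rev(ord)) { # preorder
    ch <- tree$children[[v]]
    if (!length(ch)) next
    base <- down[v, ]
    for (c in ch) {
      sib <- base
      for (b in setdiff(ch, c)) sib <- sib * msg[[b]]
      down[c, ] <- as.vector(sib %*% P[[c]]) # symmetric P: t(P) == P
    }
  }
  prob <- up * down
  prob <- prob / rowSums(prob)
  map <- sites[max.col(prob, ties.method = "first")]
  names(map) <- tree$nodes
  structure(list(prob = prob, map = map,
                 map_prob = stats::setNames(prob[cbind(tree$nodes, map)],
                                            tree$nodes),
                 sites = sites,
                 loglik = logscale + log(sum(prior * up[tree$root, ]))),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat(sprintf("Ancestral site posterior: %d nodes, %d sites, log-likelihood %.4f\n",
              nrow(x$prob), length(x$sites), x$loglik))
  invisible(x)
}

#' MCMC sampler configuration
#'
#' @param chains number of independent chains (default 3).
#' @param generations Gibbs sweeps per chain; one generation updates every
#'   ancestral node once (default 5e6, scale down for routine use).
#' @param sample_interval record a sample every this many generations
#'   (default 1000).
#' @param burnin number of recorded samples discarded per chain
#'   (default 1000).
#' @param seed random seed.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, generations = 5e6, sample_interval = 1000L,
                        burnin = 1000L, seed = 1L) {
  stopifnot(chains >= 1L, generations >= 1, sample_interval >= 1L)
  if (burnin >= generations / sample_interval) {
    stop("burnin must be smaller than the number of recorded samples",
         call. = FALSE)
  }
  structure(list(chains = as.integer(chains), generations = generations,
                 sample_interval = as.integer(sample_interval),
                 burnin = as.integer(burnin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gibbs MCMC over ancestral tumor sites
#'
#' Samples full ancestral site assignments from their joint posterior under
#' the equal-rate model by single-node Gibbs updates (each node's site drawn
#' from its full conditional given its parent and children). Post-burn-in
#' samples are pooled across chains; empirical per-node site frequencies
#' estimate the marginal posteriors. An across-chain convergence diagnostic
#' (the largest spread of any per-node site frequency between chains) is
#' reported.
#'
#' @inheritParams marginal_posteriors
#' @param mcmc an [mcmc_config].
#' @return an `ancestral_posterior` with additional fields `n_samples`
#'   (pooled), `chain_freq` (per-chain frequency arrays) and
#'   `convergence_spread`.
#' @export
mcmc_sample <- function(tree, leaf_labels, model = NULL, mcmc = mcmc_config()) {
  if (is.null(model)) model <- mk_model(unique(unname(leaf_labels)))
  sites <- model$sites
  k <- model$k
  P <- edge_matrices(tree, model)
  nodes <- tree$nodes
  id <- stats::setNames(seq_along(nodes), nodes)
  internal <- setdiff(nodes, tree$leaves)
  state <- integer(length(nodes))
  for (l in tree$leaves) state[id[l]] <- match(leaf_labels[[l]], sites)
  if (anyNA(state[id[tree$leaves]])) {
    stop("leaf labeled with unknown site", call. = FALSE)
  }
  # integer-indexed structures for the inner loop
  upd <- id[internal]
  par_of <- ifelse(internal == tree$root, 0L, id[tree$parent[internal]])
  Ppar <- lapply(internal, function(v) {
    if (v == tree$root) matrix(1 / k, 1, k) else P[[v]]
  })
  kids_of <- lapply(internal, function(v) unname(id[tree$children[[v]]]))
  Pkid <- lapply(internal, function(v) lapply(tree$children[[v]],
                                              function(c) P[[c]]))
  n_keep <- floor(mcmc$generations / mcmc$sample_interval) - mcmc$burnin
  chain_freq <- array(0, dim = c(length(nodes), k, mcmc$chains),
                      dimnames = list(nodes, sites, NULL))
  with_seed(mcmc$seed, {
    for (chain in seq_len(mcmc$chains)) {
      st <- state
      st[upd] <- sample.int(k, length(upd), replace = TRUE)
      counts <- matrix(0, length(nodes), k)
      kept <- 0L
      gen <- 0L
      while (kept < n_keep + mcmc$burnin) {
        for (rep in seq_len(mcmc$sample_interval)) {
          for (i in seq_along(upd)) {
            v <- upd[i]
            w <- if (par_of[i] == 0L) rep(1 / k, k) else Ppar[[i]][st[par_of[i]], ]
            for (jj in seq_along(kids_of[[i]])) {
              w <- w * Pkid[[i]][[jj]][, st[kids_of[[i]][jj]]]
            }
            v_new <- sample.int(k, 1L, prob = w)
            st[v] <- v_new
          }
        }
        gen <- gen + mcmc$sample_interval
        kept <- kept + 1L
        if (kept > mcmc$burnin) {
          counts[cbind(seq_along(nodes), st)] <- counts[cbind(seq_along(nodes), st)] + 1
        }
      }
      chain_freq[, , chain] <- counts / n_keep
    }
  })
  freq <- apply(chain_freq, c(1, 2), mean)
  dimnames(freq) <- list(nodes, sites)
  spread <- if (mcmc$chains > 1L) {
    max(apply(chain_freq, c(1, 2), function(z) diff(range(z))))
  } else {
    NA_real_
  }
  map <- sites[max.col(freq, ties.method = "first")]
  names(map) <- nodes
  structure(list(prob = freq, map = map,
                 map_prob = stats::setNames(freq[cbind(nodes, map)], nodes),
                 sites = sites, loglik = NA_real_,
                 n_samples = n_keep * mcmc$chains,
                 chain_freq = chain_freq,
                 convergence_spread = spread),
            class = "ancestral_posterior")
}

#' Bayesian migration-history inference
#'
#' Estimates ancestral tumor sites under the equal-rate discrete-state model
#' (exact belief propagation by default, or Gibbs MCMC), assigns each
#' internal node its maximum-a-posteriori site, and extracts the implied
#' migration graph. Posterior ties are broken toward the parent's assigned
#' site (minimizing spurious migrations) and then by canonical site order.
#' The root is constrained to the primary tumor through the germline
#' outgroup, which is labeled with the primary site.
#'
#' @inheritParams infer_pmh
#' @param model an [mk_model]; defaults to equal rates over the observed
#'   sites.
#' @param mcmc an [mcmc_config], used when `estimator = "mcmc"`.
#' @param estimator `"exact"` (pruning) or `"mcmc"`.
#' @return a [migration_history] with the per-node posterior matrix attached
#'   (`$posterior`) and the full `ancestral_posterior` in `$fit`.
#' @export
#' @examples
#' tr <- parse_tree("((A:1,B:1):3,(C:1,D:1):3,N:0.1);", format = "newick")
#' labs <- c(A = "M1", B = "M1", C = "M2", D = "M2", N = "P")
#' infer_bbm(tr, labs, germline = "N")$counts
infer_bbm <- function(tree, leaf_labels, model = NULL, mcmc = mcmc_config(),
                      estimator = c("exact", "mcmc"), germline = NULL,
                      primary = "P", sites = NULL) {
  estimator <- match.arg(estimator)
  if (!is.null(germline) && germline %in% tree$leaves &&
      is.na(match(germline, names(leaf_labels)))) {
    leaf_labels[germline] <- primary
  }
  all_sites <- unique(c(unname(leaf_labels), sites, primary))
  if (is.null(model) && length(all_sites) == 1L) {
    # degenerate single-site data: the labeling is certain and no
    # migration can be inferred
    lab <- stats::setNames(rep(all_sites, n_nodes(tree)), tree$nodes)
    prob <- matrix(1, n_nodes(tree), 1L,
                   dimnames = list(tree$nodes, all_sites))
    return(migration_history(
      tree = tree, labeling = lab, graph = migration_graph(primary = primary),
      counts = c(migrations = 0, comigrations = 0, sources = 0),
      method = if (estimator == "exact") "bbm-exact" else "bbm-mcmc",
      posterior = prob))
  }
  if (is.null(model)) model <- mk_model(all_sites)
  post <- if (estimator == "exact") {
    marginal_posteriors(tree, leaf_labels, model)
  } else {
    mcmc_sample(tree, leaf_labels, model, mcmc)
  }
  # MAP assignment, ties toward the parent's assigned site then site order
  lab <- stats::setNames(character(n_nodes(tree)), tree$nodes)
  for (l in tree$leaves) lab[l] <- leaf_labels[[l]]
  for (v in rev(postorder(tree))) {
    if (v %in% tree$leaves) next
    p <- post$prob[v, ]
    top <- model$sites[p >= max(p) - 1e-12]
    if (length(top) > 1L && v != tree$root) {
      ps <- lab[[tree$parent[[v]]]]
      if (ps %in% top) top <- ps
    }
    lab[v] <- top[1L]
  }
  work <- tree
  if (!is.null(germline) && germline %in% tree$leaves) {
    work <- drop_leaf(tree, germline)
  }
  graph <- extract_migration_graph(work, lab, primary = primary)
  migration_history(
    tree = tree, labeling = lab, graph = graph,
    counts = c(migrations = nrow(graph),
               comigrations = count_comigrations(work, lab),
               sources = count_sources(work, lab)),
    method = if (estimator == "exact") "bbm-exact" else "bbm-mcmc",
    posterior = post$prob, fit = post)
}
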