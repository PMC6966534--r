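#' Infer a migration history for a dataset with a chosen method
#'
#' Dispatches to the parsimony or Bayesian estimators: `"pmh-con"` (parsimony
#' with the root constrained to the primary site), `"pmh-unconstrained"`
#' (classical Sankoff, free root), `"pmh-tr"` (parsimony with joint polytomy
#' resolution), `"bbm-exact"` (Bayesian MAP by exact belief propagation) and
#' `"bbm-mcmc"` (Bayesian MAP from Gibbs MCMC frequencies).
#'
#' @param ds a `simulated_dataset` (from [simulate_dataset()] or
#'   [read_dataset()]), or a [clone_phylogeny] if `leaf_labels` is given.
#' @param method estimator name.
#' @param leaf_labels leaf sites when `ds` is a bare tree.
#' @param germline germline leaf name (taken from the dataset when absent).
#' @param mcmc an [mcmc_config] for `"bbm-mcmc"`; the default here is a
#'   scaled-down setting (3 chains of 50000 sweeps sampled every 10).
#' @param ... passed on to the underlying estimator.
#' @return a [migration_history].
#' @export
infer_migration <- function(ds, method = c("pmh-con", "pmh-tr",
                                           "pmh-unconstrained", "bbm-exact",
                                           "bbm-mcmc"),
                            leaf_labels = NULL, germline = NULL,
                            mcmc = NULL, ...) {
  method <- match.arg(method)
  if (inherits(ds, "simulated_dataset")) {
    tree <- ds$tree
    leaf_labels <- leaf_labels %||% ds$leaf_labeling
    germline <- germline %||% ds$germline
    sites <- ds$sites
  } else {
    tree <- ds
    if (is.null(leaf_labels)) stop("leaf_labels required", call. = FALSE)
    sites <- NULL
  }
  switch(method,
    "pmh-con" = infer_pmh(tree, leaf_labels, root_constraint = "P",
                          germline = germline, sites = sites, ...),
    "pmh-unconstrained" = infer_pmh(tree, leaf_labels, root_constraint = NULL,
                                    germline = germline, sites = sites, ...),
    "pmh-tr" = resolve_polytomies_pmh_tr(tree, leaf_labels,
                                         root_constraint = "P",
                                         germline = germline, sites = sites,
                                         ...)$history,
    "bbm-exact" = infer_bbm(tree, leaf_labels, estimator = "exact",
                            germline = germline, sites = sites, ...),
    "bbm-mcmc" = infer_bbm(tree, leaf_labels, estimator = "mcmc",
                           mcmc = mcmc %||% mcmc_config(chains = 3L,
                                                        generations = 50000,
                                                        sample_interval = 10L,
                                                        burnin = 100L),
                           germline = germline, sites = sites, ...))
}

#' Benchmark configuration
#'
#' @param scenarios seeding scenarios to simulate.
#' @param size_classes tumor-count classes (`"m5"`: 5-7 sites, `"m8"`: 8-11).
#' @param n_per_cell datasets per scenario x size-class cell (default 10).
#' @param methods estimators to run (see [infer_migration()]).
#' @param seed master seed; per-dataset seeds are drawn from it.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(scenarios = c("mS", "pS", "pM", "pR"),
                             size_classes = c("m5", "m8"),
                             n_per_cell = 10L,
                             methods = c("pmh-con", "pmh-tr", "bbm-exact"),
                             seed = 1L) {
  stopifnot(n_per_cell >= 1L, length(methods) >= 1L)
  structure(list(scenarios = scenarios, size_classes = size_classes,
                 n_per_cell = as.integer(n_per_cell), methods = methods,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run a simulation benchmark of migration-history estimators
#'
#' Simulates `n_per_cell` datasets for every scenario x size-class cell (or
#' reads existing dataset directories), runs every requested method on each,
#' scores the inferred migration graph against the truth and aggregates the
#' results. Per-dataset failures are logged and skipped so a long run is not
#' lost to one bad case.
#'
#' @param config a [benchmark_config].
#' @param data_dir optional directory of dataset subdirectories (each
#'   readable by [read_dataset()] and carrying a `truth_graph.tsv`); when
#'   given, simulation is skipped and `scenarios`/`size_classes` are ignored.
#' @param keep_data return the simulated datasets and fitted histories.
#' @param quiet suppress per-dataset progress messages.
#' @return object of class `benchmark_result`: list with `reports` (one row
#'   per dataset x method, including per-path-type counts), `summary` (a
#'   `benchmark_summary`), `config`, and optionally `data`.
#' @export
#' @examples
#' \donttest{
#' res <- run_benchmark(benchmark_config(n_per_cell = 2, seed = 7))
#' res$summary$by_scenario
#' }
run_benchmark <- function(config = benchmark_config(), data_dir = NULL,
                          keep_data = FALSE, quiet = TRUE) {
  datasets <- list()
  if (is.null(data_dir)) {
    cells <- expand.grid(size_class = config$size_classes,
                         scenario = config$scenarios,
                         idx = seq_len(config$n_per_cell),
                         stringsAsFactors = FALSE)
    seeds <- with_seed(config$seed,
                       sample.int(.Machine$integer.max, nrow(cells)))
    for (i in seq_len(nrow(cells))) {
      cfg <- sim_config(cells$scenario[i], size_class = cells$size_class[i],
                        seed = seeds[i])
      ds <- tryCatch(simulate_dataset(cfg), error = function(e) {
        message(sprintf("simulation failed (%s %s seed %d): %s",
                        cells$scenario[i], cells$size_class[i], seeds[i],
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(ds)) {
        ds$size_class <- cells$size_class[i]
        datasets[[length(datasets) + 1L]] <- ds
      }
    }
  } else {
    subdirs <- list.dirs(data_dir, recursive = FALSE)
    for (d in subdirs) {
      ds <- tryCatch(read_dataset(d), error = function(e) NULL)
      if (is.null(ds) || is.null(ds$graph)) next
      ds$size_class <- if (length(ds$sites) <= 7L) "m5" else "m8"
      datasets[[length(datasets) + 1L]] <- ds
    }
    if (!length(datasets)) stop("no readable datasets found", call. = FALSE)
  }

  rows <- list()
  fits <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    for (m in config$methods) {
      t0 <- proc.time()[["elapsed"]]
      h <- tryCatch(infer_migration(ds, m), error = function(e) {
        message(sprintf("%s failed on dataset %d (%s): %s", m, di,
                        ds$scenario, conditionMessage(e)))
        NULL
      })
      if (is.null(h)) next
      rep <- evaluate_inference(h, ds$graph)
      info <- data.frame(dataset = di, method = m, scenario = ds$scenario,
                         size_class = ds$size_class,
                         n_sites = length(ds$sites),
                         n_clones = length(setdiff(ds$tree$leaves,
                                                   ds$germline)),
                         migrations = unname(h$counts[["migrations"]]),
                         comigrations = unname(h$counts[["comigrations"]]),
                         sources = unname(h$counts[["sources"]]),
                         stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(info, rep)
      if (keep_data) fits[[paste(di, m, sep = ".")]] <- h
      if (!quiet) {
        message(sprintf("dataset %d %s %s: F1 %.2f (%.2fs)", di, ds$scenario,
                        m, rep$f1, proc.time()[["elapsed"]] - t0))
      }
    }
  }
  if (!length(rows)) stop("all inferences failed", call. = FALSE)
  reports <- do.call(rbind, rows)
  class(reports) <- "data.frame"
  structure(list(reports = reports,
                 summary = aggregate_benchmark(reports),
                 config = config,
                 data = if (keep_data) list(datasets = datasets, fits = fits)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d dataset-method results, methods: %s\n\n",
              nrow(x$reports), paste(unique(x$reports$method), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @export
summary.benchmark_result <- function(object, ...) object$summary

#' Pooled path-type error rates of a benchmark
#'
#' Pools the per-path-type counts over all datasets (micro-average): the FN
#' rate of a type is total misses over total true edges of that type, the FP
#' rate total spurious over total inferred. The per-dataset macro-average of
#' the same rates is included for comparison.
#'
#' @param result a `benchmark_result` (or its `reports` data.frame).
#' @param by grouping columns (default `"method"`).
#' @return data.frame with one row per group x path type.
#' @export
pooled_path_rates <- function(result, by = "method") {
  reports <- if (inherits(result, "benchmark_result")) result$reports else result
  types <- c("PM", "MM", "MP")
  groups <- unique(reports[by])
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(reports))
    for (cn in by) sel <- sel & reports[[cn]] == groups[gi, cn]
    sub <- reports[sel, , drop = FALSE]
    for (ty in types) {
      fp <- sum(sub[[paste0("fp_", ty)]])
      fn <- sum(sub[[paste0("fn_", ty)]])
      n_true <- sum(sub[[paste0("n_true_", ty)]])
      n_inf <- sum(sub[[paste0("n_inferred_", ty)]])
      macro_fn <- mean((sub[[paste0("fn_", ty)]] /
                          sub[[paste0("n_true_", ty)]])[
                            sub[[paste0("n_true_", ty)]] > 0])
      macro_fp <- mean((sub[[paste0("fp_", ty)]] /
                          sub[[paste0("n_inferred_", ty)]])[
                            sub[[paste0("n_inferred_", ty)]] > 0])
      out[[length(out) + 1L]] <- cbind(
        groups[gi, , drop = FALSE],
        data.frame(type = ty, fp = fp, fn = fn, n_true = n_true,
                   n_inferred = n_inf,
                   fp_rate = if (n_inf > 0) fp / n_inf else NaN,
                   fn_rate = if (n_true > 0) fn / n_true else NaN,
                   fp_rate_macro = macro_fp, fn_rate_macro = macro_fn,
                   stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
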