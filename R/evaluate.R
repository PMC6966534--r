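#' Compare an inferred migration graph with the truth
#'
#' Counts correctly inferred migration paths (true positives), paths inferred
#' but absent from the truth (false positives) and true paths missed (false
#' negatives). Under the default multiset semantics edge multiplicity
#' matters: per ordered site pair, TP is the smaller of the two
#' multiplicities and the excess on either side counts as FP or FN. Set
#' semantics reduces both graphs to their support first.
#'
#' @param g inferred [migration_graph].
#' @param g_star true [migration_graph].
#' @param semantics `"multiset"` (default) or `"set"`.
#' @param sites optional site alphabet; sites used by either graph must
#'   belong to it when given.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
#' @examples
#' g <- migration_graph("P", "M1")
#' gs <- migration_graph(c("P", "M1"), c("M1", "M2"))
#' compare_graphs(g, gs)
compare_graphs <- function(g, g_star, semantics = c("multiset", "set"),
                           sites = NULL) {
  semantics <- match.arg(semantics)
  if (!is.null(sites)) {
    used <- unique(c(g$from, g$to, g_star$from, g_star$to))
    bad <- setdiff(used, sites)
    if (length(bad)) {
      stop(sprintf("site '%s' not in the site alphabet", bad[1L]),
           call. = FALSE)
    }
  }
  a <- edge_counts(g)
  b <- edge_counts(g_star)
  if (semantics == "set") {
    a$n <- pmin(a$n, 1L)
    b$n <- pmin(b$n, 1L)
  }
  keys <- union(paste(a$from, a$to), paste(b$from, b$to))
  na <- stats::setNames(rep(0L, length(keys)), keys)
  nb <- na
  na[paste(a$from, a$to)] <- a$n
  nb[paste(b$from, b$to)] <- b$n
  c(tp = sum(pmin(na, nb)), fp = sum(pmax(0L, na - nb)),
    fn = sum(pmax(0L, nb - na)))
}

#' Precision, recall and F1 over migration-graph edges
#'
#' F1 is the harmonic mean of precision TP/(TP+FP) and recall TP/(TP+FN); it
#' is zero when precision and recall are both zero, and equals one exactly
#' when there are no false positives and no false negatives.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector `c(precision, recall, f1)`, or `NULL` (with
#'   a warning) when all three counts are zero.
#' @export
#' @examples
#' f1_score(2, 1, 1)
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    warning("no edges in either graph: F1 undefined")
    return(NULL)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

# classify an edge by endpoint identity with the primary site
path_type <- function(from, to, primary) {
  ifelse(from == primary, paste0(primary, ">M"),
         ifelse(to == primary, paste0("M>", primary), "M>M"))
}

#' Error rates by migration path type
#'
#' Decomposes false positives and false negatives by the three path types:
#' primary to metastasis (P>M), metastasis to metastasis (M>M) and
#' metastasis back to primary (M>P, reseeding). The FN rate of a type is the
#' fraction of true edges of that type that were missed; the FP rate is the
#' fraction of inferred edges of that type that are wrong.
#'
#' @inheritParams compare_graphs
#' @param primary primary site (default the graph's `primary` attribute).
#' @return data.frame with one row per path type: `type`, `tp`, `fp`, `fn`,
#'   `n_true`, `n_inferred`, `fp_rate`, `fn_rate` (rates `NaN` when the
#'   denominator is empty).
#' @export
path_type_rates <- function(g, g_star, primary = NULL,
                            semantics = c("multiset", "set")) {
  semantics <- match.arg(semantics)
  primary <- primary %||% attr(g_star, "primary") %||% "P"
  types <- c(paste0(primary, ">M"), "M>M", paste0("M>", primary))
  out <- lapply(types, function(ty) {
    sel_g <- migration_graph(g$from, g$to, primary)[
      path_type(g$from, g$to, primary) == ty, , drop = FALSE]
    sel_s <- migration_graph(g_star$from, g_star$to, primary)[
      path_type(g_star$from, g_star$to, primary) == ty, , drop = FALSE]
    cc <- compare_graphs(sel_g, sel_s, semantics = semantics)
    data.frame(type = ty, tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]],
               n_true = nrow(sel_s), n_inferred = nrow(sel_g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fp_rate <- out$fp / out$n_inferred
  out$fn_rate <- out$fn / out$n_true
  out
}

#' Evaluate one inferred migration history against the truth
#'
#' @param g inferred [migration_graph] (or a [migration_history], whose graph
#'   is used).
#' @param g_star true [migration_graph].
#' @inheritParams path_type_rates
#' @return one-row data.frame of class `eval_report`: TP/FP/FN, precision,
#'   recall, F1, the entirely-correct flag (graph identical to the truth),
#'   and per-path-type TP/FP/FN and edge totals in wide columns.
#' @export
evaluate_inference <- function(g, g_star, primary = NULL,
                               semantics = c("multiset", "set")) {
  semantics <- match.arg(semantics)
  if (inherits(g, "migration_history")) g <- g$graph
  primary <- primary %||% attr(g_star, "primary") %||% "P"
  cc <- compare_graphs(g, g_star, semantics = semantics)
  pr <- f1_score(cc[["tp"]], cc[["fp"]], cc[["fn"]])
  if (is.null(pr)) pr <- c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  ty <- path_type_rates(g, g_star, primary = primary, semantics = semantics)
  wide <- stats::setNames(
    as.vector(t(as.matrix(ty[, c("tp", "fp", "fn", "n_true", "n_inferred")]))),
    as.vector(t(outer(sub(">", "", c("PM", "MM", "MP")),
                      c("tp", "fp", "fn", "n_true", "n_inferred"),
                      function(a, b) paste(b, a, sep = "_")))))
  out <- data.frame(tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]],
                    precision = pr[["precision"]], recall = pr[["recall"]],
                    f1 = pr[["f1"]],
                    entirely_correct = cc[["fp"]] == 0L && cc[["fn"]] == 0L,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(wide)))
  class(out) <- c("eval_report", class(out))
  out
}

#' Aggregate a benchmark into grouped means and significance tests
#'
#' Averages F1 over datasets within groups (by default method x scenario and
#' method x size class) and tests differences: a two-sample Z-test (unpooled
#' variances) between every pair of seeding scenarios within each method, and
#' Welch's t-test between the two tumor-count classes within each method.
#'
#' @param reports data.frame with at least columns `method`, `scenario`,
#'   `f1`, and optionally `size_class`.
#' @return list of class `benchmark_summary`: `by_scenario`, `by_size`
#'   (grouped mean/sd/n), `scenario_tests` (Z and p per scenario pair and
#'   method), `size_tests` (Welch t per method).
#' @export
aggregate_benchmark <- function(reports) {
  stopifnot(all(c("method", "scenario", "f1") %in% names(reports)))
  agg <- function(keys) {
    out <- stats::aggregate(reports["f1"], reports[keys], function(z) {
      c(mean = mean(z), sd = stats::sd(z), n = length(z))
    })
    cbind(out[keys], as.data.frame(out$f1))
  }
  by_scenario <- agg(c("method", "scenario"))
  by_size <- if ("size_class" %in% names(reports)) {
    agg(c("method", "size_class"))
  }
  ztest <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    z <- if (mx == my) 0 else if (se == 0) sign(mx - my) * Inf else (mx - my) / se
    c(z = z, p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
  }
  scen_tests <- list()
  for (m in unique(reports$method)) {
    scens <- unique(reports$scenario)
    if (length(scens) < 2L) next
    for (i in seq_len(length(scens) - 1L)) {
      for (j in seq((i + 1L), length(scens))) {
        x <- reports$f1[reports$method == m & reports$scenario == scens[i]]
        y <- reports$f1[reports$method == m & reports$scenario == scens[j]]
        if (length(x) < 2L || length(y) < 2L) {
          message(sprintf("skipping test %s %s vs %s: fewer than 2 datasets",
                          m, scens[i], scens[j]))
          next
        }
        zt <- ztest(x, y)
        tt <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
        scen_tests[[length(scen_tests) + 1L]] <-
          data.frame(method = m, scenario_a = scens[i], scenario_b = scens[j],
                     mean_a = mean(x), mean_b = mean(y),
                     z = zt[["z"]], p_z = zt[["p"]], p_t = tt,
                     stringsAsFactors = FALSE)
      }
    }
  }
  scenario_tests <- if (length(scen_tests)) do.call(rbind, scen_tests)
  size_tests <- NULL
  if ("size_class" %in% names(reports) &&
      length(unique(reports$size_class)) == 2L) {
    cls <- sort(unique(reports$size_class))
    rows <- list()
    for (m in unique(reports$method)) {
      x <- reports$f1[reports$method == m & reports$size_class == cls[1L]]
      y <- reports$f1[reports$method == m & reports$size_class == cls[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        message(sprintf("skipping size-class test for %s: fewer than 2 datasets", m))
        next
      }
      tt <- stats::t.test(x, y)
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, class_a = cls[1L], class_b = cls[2L],
                   mean_a = mean(x), mean_b = mean(y),
                   t = unname(tt$statistic), p_t = tt$p.value,
                   stringsAsFactors = FALSE)
    }
    size_tests <- if (length(rows)) do.call(rbind, rows)
  }
  structure(list(by_scenario = by_scenario, by_size = by_size,
                 scenario_tests = scenario_tests, size_tests = size_tests),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Mean F1 by method and scenario:\n")
  print(x$by_scenario, row.names = FALSE)
  if (!is.null(x$by_size)) {
    cat("\nMean F1 by method and tumor-count class:\n")
    print(x$by_size, row.names = FALSE)
  }
  if (!is.null(x$scenario_tests)) {
    cat("\nScenario-pair tests (Z and Welch t, two-sided):\n")
    print(x$scenario_tests, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$size_tests)) {
    cat("\nSize-class tests (Welch t, two-sided):\n")
    print(x$size_tests, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
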