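#' Parameter ranges for Monte-Carlo sampling
#'
#' Builds the range table consumed by [sample_parameters()] and
#' [run_ensemble()]. Each row names one numeric field of a
#' [pathway_spec()] by a dotted path (e.g. `"dhpaas.vmax"`, `"ddc.km"`,
#' `"mao.ki.amine"`, `"k_cond"`) and gives its sampling interval.
#'
#' @param name Character vector of field paths.
#' @param low,high Numeric bounds, `low <= high`.
#' @param scale `"linear"` (uniform) or `"log"` (log-uniform; requires
#'   `low > 0`). Recycled.
#' @return A data frame with columns `name, low, high, scale` of class
#'   `param_ranges`.
#' @examples
#' param_ranges(c("dhpaas.vmax", "k_cond"), c(1, 0.1), c(50, 10), "log")
#' @export
param_ranges <- function(name, low, high, scale = "linear") {
  stopifnot(is.character(name), is.numeric(low), is.numeric(high))
  n <- length(name)
  low <- rep_len(low, n); high <- rep_len(high, n)
  scale <- rep_len(as.character(scale), n)
  if (!all(scale %in% c("linear", "log")))
    stop("'scale' must be \"linear\" or \"log\"")
  if (any(low > high)) stop("'low' must be <= 'high'")
  if (any(scale == "log" & low <= 0))
    stop("log-scale ranges require low > 0")
  structure(data.frame(name = name, low = low, high = high, scale = scale,
                       stringsAsFactors = FALSE),
            class = c("param_ranges", "data.frame"))
}

# Assign `value` into a pathway_spec at a dotted field path. Enzyme ki
# entries may be created; everything else must already exist as a single
# numeric field.
set_spec_field <- function(spec, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  root <- parts[1L]
  if (!root %in% names(spec))
    stop(sprintf("unknown pathway_spec field '%s'", path))
  if (length(parts) == 1L) {
    if (!is.numeric(spec[[root]]) || length(spec[[root]]) != 1L)
      stop(sprintf("field '%s' is not a scalar numeric", path))
    spec[[root]] <- value
    return(spec)
  }
  enz <- spec[[root]]
  if (is.null(enz) || !inherits(enz, "enzyme_params"))
    stop(sprintf("enzyme block '%s' absent from this topology", root))
  if (length(parts) == 2L) {
    if (!parts[2L] %in% c("vmax", "km"))
      stop(sprintf("unknown enzyme field '%s'", path))
    enz[[parts[2L]]] <- value
  } else if (length(parts) == 3L && parts[2L] == "ki") {
    if (!parts[3L] %in% c("dopamine", "DHPAA", "amine"))
      stop(sprintf("unknown inhibitor in '%s'", path))
    ki <- enz$ki
    ki[parts[3L]] <- value
    enz$ki <- ki
  } else stop(sprintf("cannot resolve field path '%s'", path))
  spec[[root]] <- enz
  spec
}

#' Draw one parameter set within the stated ranges
#'
#' Returns a copy of `base` with every field named in `ranges` replaced
#' by a fresh draw: uniform on the linear scale, log-uniform on the log
#' scale. Draws consume the current RNG stream in the listed row order
#' (one uniform deviate per row), which is the reproducibility contract
#' for seeded ensembles.
#'
#' @param ranges A [param_ranges()] table.
#' @param base The template [pathway_spec()].
#' @return A `pathway_spec` with sampled parameter values.
#' @export
sample_parameters <- function(ranges, base) {
  stopifnot(inherits(base, "pathway_spec"), is.data.frame(ranges))
  spec <- base
  for (i in seq_len(nrow(ranges))) {
    u <- stats::runif(1L)
    lo <- ranges$low[i]; hi <- ranges$high[i]
    val <- if (ranges$scale[i] == "log")
      exp(log(lo) + u * (log(hi) - log(lo)))
    else lo + u * (hi - lo)
    spec <- set_spec_field(spec, ranges$name[i], val)
  }
  spec
}

#' Monte-Carlo ensemble specification
#'
#' @param base Template [pathway_spec()].
#' @param ranges [param_ranges()] table of sampled parameters.
#' @param n_iter Number of Monte-Carlo iterations (default 10000).
#' @param t_end Simulation horizon (h), default 50.
#' @param seed Integer RNG seed.
#' @param initial Initial [pathway_state()].
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(base, ranges, n_iter = 10000, t_end = 50,
                          seed = 1L, initial = pathway_state()) {
  stopifnot(inherits(base, "pathway_spec"), is.data.frame(ranges),
            n_iter >= 1)
  # fail fast on unresolvable paths
  for (nm in ranges$name) invisible(set_spec_field(base, nm, 1))
  structure(list(base = base, ranges = ranges, n_iter = as.integer(n_iter),
                 t_end = t_end, seed = as.integer(seed), initial = initial),
            class = "ensemble_spec")
}

#' Run a Monte-Carlo yield ensemble
#'
#' Samples `n_iter` parameter sets within the stated ranges, integrates
#' each model over `[0, t_end]`, and collects the molar THP yield of
#' every successful run. Failed integrations are counted and excluded
#' from the statistics (a warning is raised when they exceed 1% of the
#' iterations; an error when all fail).
#'
#' @param es An [ensemble_spec()].
#' @param n_grid Output-grid size per trajectory (final state only is
#'   needed for the yield, so a coarse grid is the default).
#' @return An object of class `thp_ensemble`: a list with `yields`
#'   (per-iteration %), `summary` (see [summarize_ensemble()]),
#'   `n_failed` and the generating `ensemble_spec`.
#' @export
run_ensemble <- function(es, n_grid = 26) {
  stopifnot(inherits(es, "ensemble_spec"))
  set.seed(es$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, es$n_iter)
  yields <- numeric(0)
  n_failed <- 0L
  for (i in seq_len(es$n_iter)) {
    # each iteration gets its own substream so that two ensembles that
    # share a seed and a common prefix of the range table draw identical
    # values for the shared parameters (common random numbers)
    set.seed(iter_seeds[i])
    spec_i <- sample_parameters(es$ranges, es$base)
    y <- tryCatch({
      traj <- simulate_pathway(spec_i, initial = es$initial,
                               t_end = es$t_end, n_grid = n_grid)
      thp_yield_pct(traj)
    }, error = function(e) NA_real_)
    if (is.na(y)) n_failed <- n_failed + 1L else yields <- c(yields, y)
  }
  if (n_failed == es$n_iter)
    stop("all ensemble integrations failed")
  if (n_failed > 0.01 * es$n_iter)
    warning(sprintf("%d of %d ensemble integrations failed",
                    n_failed, es$n_iter))
  structure(list(yields = yields, summary = summarize_ensemble(yields),
                 n_failed = n_failed, spec = es),
            class = "thp_ensemble")
}

#' Box statistics of an ensemble yield list
#'
#' Quartiles use the linear-interpolation percentile convention
#' (`quantile(..., type = 7)`), matching the usual box-plot definition of
#' the first/second/third quartiles.
#'
#' @param yields Non-empty numeric vector of per-iteration yields (%).
#' @return A list with `median, q1, q3, mean, min, max, n`.
#' @examples
#' summarize_ensemble(c(1, 2, 3, 4))  # median 2.5, q1 1.75, q3 3.25
#' @export
summarize_ensemble <- function(yields) {
  if (!is.numeric(yields) || length(yields) == 0L)
    stop("'yields' must be a non-empty numeric vector")
  q <- unname(stats::quantile(yields, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       mean = mean(yields), min = min(yields), max = max(yields),
       n = length(yields))
}

#' @export
print.thp_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("THP Monte-Carlo ensemble (%s): %d runs, %d failed\n",
              x$spec$base$topology, x$spec$n_iter, x$n_failed))
  cat(sprintf("  yield %%: median %.3g [q1 %.3g, q3 %.3g], mean %.3g, range [%.3g, %.3g]\n",
              s$median, s$q1, s$q3, s$mean, s$min, s$max))
  invisible(x)
}

#' @export
plot.thp_ensemble <- function(x, ...) {
  graphics::boxplot(x$yields, ylab = "predicted THP yield (%)",
                    col = "lightsteelblue", medcol = "forestgreen", ...)
  invisible(x)
}

#' Compare Monte-Carlo scenarios under a shared master seed
#'
#' Runs one ensemble per scenario. The master seed is split into
#' independent per-scenario seeds (a deterministic function of the master
#' seed and the scenario order), so each scenario has its own
#' reproducible stream and adding a scenario does not perturb the others'
#' draws beyond the seed table.
#'
#' @param scenarios Named list of [ensemble_spec()] objects; names are
#'   the scenario labels (duplicates are an error).
#' @param seed Master seed.
#' @return A data frame of class `scenario_comparison` with one row per
#'   scenario (`label, median, q1, q3, mean, min, max, n, n_failed`),
#'   ordered as given; the attribute `"ordering"` lists the labels by
#'   decreasing median yield.
#' @export
compare_scenarios <- function(scenarios, seed = 1L) {
  stopifnot(is.list(scenarios), length(scenarios) >= 2L)
  labels <- names(scenarios)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("'scenarios' must be a named list")
  if (anyDuplicated(labels)) stop("duplicate scenario labels")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    es <- scenarios[[i]]
    stopifnot(inherits(es, "ensemble_spec"))
    es$seed <- sub_seeds[i]
    ens <- run_ensemble(es)
    s <- ens$summary
    rows[[i]] <- data.frame(label = labels[i], median = s$median,
                            q1 = s$q1, q3 = s$q3, mean = s$mean,
                            min = s$min, max = s$max, n = s$n,
                            n_failed = ens$n_failed,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "ordering") <- out$label[order(-out$median)]
  class(out) <- c("scenario_comparison", "data.frame")
  out
}
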