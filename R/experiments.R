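#' Factorial sweep designs
#'
#' A sweep is the full factorial crossing of one or more parameter axes
#' over a base configuration, with `replicates` independent runs per cell.
#' Per-run seeds are drawn once, without replacement, from a stream seeded
#' by `base_seed`, so every (cell, replicate) seed is unique and the whole
#' sweep is reproducible bit-for-bit from `(design, base_seed)`.
#'
#' `design_competition_sweep()` is the main experiment of the model: it
#' crosses pollinator abundance (pollinators per flower) with the nectar
#' refill rate and scent-mark use. `design_cost_sweep()` varies the
#' handling cost at low competition for both strategies.
#'
#' @param base A [sim_config()] used for all non-swept parameters.
#' @param axes Named list: parameter name -> vector of values.
#' @param replicates Runs per cell.
#' @param base_seed Seed of the seed stream.
#' @param ratios,refills,costs Axis values for the convenience designs.
#' @return An object of class `sweep_design`.
#' @examples
#' d <- sweep_design(sim_config(size_map = 15, n_steps = 100),
#'                   axes = list(use_scent = c(TRUE, FALSE)), replicates = 2)
#' tab <- run_sweep(d)
#' @export
sweep_design <- function(base = sim_config(), axes, replicates = 10,
                         base_seed = 1L) {
  stopifnot(inherits(base, "sim_config"), is.list(axes), length(axes) > 0,
            !is.null(names(axes)), all(nzchar(names(axes))), replicates >= 1)
  bad <- setdiff(names(axes), names(formals(sim_config)))
  if (length(bad) > 0)
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(as.integer(base_seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             nrow(cells) * replicates),
                  nrow = nrow(cells))
  structure(list(base = base, axes = axes, cells = cells,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), seeds = seeds),
            class = "sweep_design")
}

#' @rdname sweep_design
#' @export
design_competition_sweep <- function(base = sim_config(),
                                     ratios = c(0.1, 0.3, 0.5, 1, 2),
                                     refills = c(0.001, 0.0025, 0.005),
                                     replicates = 10, base_seed = 1L) {
  sweep_design(base,
               axes = list(pollinator_ratio = ratios, refill_coef = refills,
                           use_scent = c(TRUE, FALSE)),
               replicates = replicates, base_seed = base_seed)
}

#' @rdname sweep_design
#' @export
design_cost_sweep <- function(base = sim_config(pollinator_ratio = 0.1),
                              costs = c(1, 2, 3, 5, 7, 10),
                              replicates = 10, base_seed = 1L) {
  sweep_design(base, axes = list(cost = costs, use_scent = c(TRUE, FALSE)),
               replicates = replicates, base_seed = base_seed)
}

#' @export
print.sweep_design <- function(x, ...) {
  cat(sprintf("Sweep design: %d cells x %d replicates = %d runs (base seed %d)\n",
              nrow(x$cells), x$replicates, nrow(x$cells) * x$replicates,
              x$base_seed))
  cat("  axes:", paste(sprintf("%s (%d values)", names(x$axes),
                               lengths(x$axes)), collapse = ", "), "\n")
  invisible(x)
}

#' Run a sweep
#'
#' Executes every (cell, replicate) run of a [sweep_design()] and returns a
#' tidy table: one row per run with the cell's parameter values, the
#' replicate index, the seed, and all [summarize_run()] metrics. A failing
#' run is recorded as a row of `NA` metrics with the error message in
#' `error`, and does not abort the sweep.
#'
#' @param design A `sweep_design`.
#' @param carryover_window Passed to [summarize_run()].
#' @param progress Print one line per cell as the sweep advances.
#' @return A data.frame of class `sweep_result`.
#' @export
run_sweep <- function(design, carryover_window = Inf, progress = FALSE) {
  stopifnot(inherits(design, "sweep_design"))
  rows <- vector("list", nrow(design$cells) * design$replicates)
  n <- 0L
  for (ci in seq_len(nrow(design$cells))) {
    pars <- as.list(design$cells[ci, , drop = FALSE])
    if (progress)
      message(sprintf("cell %d/%d: %s", ci, nrow(design$cells),
                      paste(names(pars), unlist(pars), sep = "=",
                            collapse = ", ")))
    for (ri in seq_len(design$replicates)) {
      seed <- design$seeds[ci, ri]
      cfg_args <- utils::modifyList(unclass(design$base), c(pars, seed = seed))
      met <- tryCatch({
        res <- run_simulation(do.call(sim_config, cfg_args))
        cbind(summarize_run(res, carryover_window = carryover_window),
              error = NA_character_)
      }, error = function(e) {
        data.frame(n_flowers = NA_integer_, n_pollinators = NA_integer_,
                   n_accepted = NA_integer_, mean_nectar_collected = NA_real_,
                   cv_nectar_collected = NA_real_,
                   mean_nectar_per_visit = NA_real_,
                   mean_nectar_remaining = NA_real_,
                   cv_nectar_remaining = NA_real_,
                   mean_visits_per_flower = NA_real_,
                   cv_visits_per_flower = NA_real_,
                   mean_pollen_transfer = NA_real_,
                   cv_pollen_transfer = NA_real_,
                   error = conditionMessage(e))
      })
      n <- n + 1L
      rows[[n]] <- cbind(data.frame(cell = ci, replicate = ri, seed = seed),
                         design$cells[ci, , drop = FALSE], met,
                         row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Cell means of a sweep table
#'
#' Averages the chosen metric over replicates within each design cell.
#'
#' @param tab A `sweep_result` table.
#' @param metric Name of a metric column.
#' @param by Character vector of cell columns to group by; defaults to all
#'   swept parameters present in the table.
#' @return A data.frame of group keys plus `mean` of the metric.
#' @export
sweep_cell_means <- function(tab, metric, by = NULL) {
  stopifnot(metric %in% names(tab))
  if (is.null(by)) {
    known <- c("pollinator_ratio", "refill_coef", "use_scent", "cost",
               "flower_density", "inertia", "size_map", "n_steps")
    by <- intersect(known, names(tab))
  }
  agg <- stats::aggregate(tab[[metric]], by = tab[by], FUN = mean, na.rm = TRUE)
  names(agg)[ncol(agg)] <- "mean"
  agg
}

#' Sensitivity-analysis design and run
#'
#' Global sensitivity analysis by random sampling: each parameter is drawn
#' i.i.d. uniformly from its variation interval (scent-mark use as a fair
#' Boolean), one simulation is run per sample, and the influence of the
#' parameters on the response (mean nectar collected per pollinator, by
#' default) is ranked by out-of-bag permutation importance from a
#' regression random forest ([rf_regression()]). Defaults follow the full
#' published design: 10,000 samples, 2,000 trees, 3 variables per split,
#' with intervals map size [30, 100], steps [700, 1300], flower density
#' [0.02, 2], refill [0.001, 0.005], pollinators per flower [0.1, 2], cost
#' [1, 10], inertia [0.01, 0.4]. Tests and desk-scale checks use far fewer
#' samples and narrower intervals.
#'
#' @param n_samples Number of parameter samples (= simulations).
#' @param intervals Named list of `c(lo, hi)` intervals for any of
#'   `size_map`, `n_steps`, `flower_density`, `refill_coef`,
#'   `pollinator_ratio`, `cost`, `inertia`; omitted parameters keep the
#'   defaults above. `n_steps` and `cost` are sampled as integers.
#' @param num_trees,mtry Forest settings.
#' @param response Metric column used as the response.
#' @param base_seed Seed for sampling, runs and forest.
#' @param design A `sensitivity_design`.
#' @return `sensitivity_design()`: the design object. `run_sensitivity()`:
#'   a list of class `sensitivity_result` with `samples` (parameters +
#'   response per run), `importance` (named, sorted decreasing),
#'   `ranking`, and `pct_var_explained` (out-of-bag).
#' @export
sensitivity_design <- function(n_samples = 10000, intervals = list(),
                               num_trees = 2000, mtry = 3,
                               response = "mean_nectar_collected",
                               base_seed = 1L) {
  defaults <- list(size_map = c(30, 100), n_steps = c(700, 1300),
                   flower_density = c(0.02, 2), refill_coef = c(0.001, 0.005),
                   pollinator_ratio = c(0.1, 2), cost = c(1, 10),
                   inertia = c(0.01, 0.4))
  bad <- setdiff(names(intervals), names(defaults))
  if (length(bad) > 0)
    stop("unknown sensitivity parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  iv <- utils::modifyList(defaults, intervals)
  for (nm in names(iv))
    stopifnot(length(iv[[nm]]) == 2, iv[[nm]][1] <= iv[[nm]][2])
  structure(list(n_samples = as.integer(n_samples), intervals = iv,
                 num_trees = as.integer(num_trees), mtry = as.integer(mtry),
                 response = response, base_seed = as.integer(base_seed)),
            class = "sensitivity_design")
}

#' @rdname sensitivity_design
#' @export
run_sensitivity <- function(design, progress = FALSE) {
  stopifnot(inherits(design, "sensitivity_design"))
  iv <- design$intervals
  set.seed(design$base_seed)
  n <- design$n_samples
  draw <- function(nm) stats::runif(n, iv[[nm]][1], iv[[nm]][2])
  draw_int <- function(nm) {
    lo <- as.integer(ceiling(iv[[nm]][1])); hi <- as.integer(floor(iv[[nm]][2]))
    if (hi <= lo) rep(lo, n) else lo + (sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
  }
  samp <- data.frame(size_map = draw("size_map"), n_steps = draw_int("n_steps"),
                     flower_density = draw("flower_density"),
                     refill_coef = draw("refill_coef"),
                     pollinator_ratio = draw("pollinator_ratio"),
                     use_scent = stats::runif(n) < 0.5,
                     cost = draw_int("cost"), inertia = draw("inertia"))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  y <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (progress && i %% 50 == 0) message("sensitivity sample ", i, "/", n)
    cfg <- sim_config(size_map = samp$size_map[i], n_steps = samp$n_steps[i],
                      flower_density = samp$flower_density[i],
                      refill_coef = samp$refill_coef[i],
                      pollinator_ratio = samp$pollinator_ratio[i],
                      use_scent = samp$use_scent[i], cost = samp$cost[i],
                      inertia = samp$inertia[i], seed = seeds[i])
    y[i] <- tryCatch(
      summarize_run(run_simulation(cfg))[[design$response]],
      error = function(e) NA_real_)
  }
  samp[[design$response]] <- y
  ok <- !is.na(y)
  if (sum(ok) < 10)
    stop("too few successful simulations for a forest fit; sample table kept",
         call. = FALSE)
  X <- data.matrix(samp[ok, c("size_map", "n_steps", "flower_density",
                              "refill_coef", "pollinator_ratio", "use_scent",
                              "cost", "inertia")])
  fit <- rf_regression(X, y[ok], num_trees = design$num_trees,
                       mtry = design$mtry)
  imp <- sort(fit$importance, decreasing = TRUE)
  structure(list(samples = samp, importance = imp, ranking = names(imp),
                 pct_var_explained = fit$pct_var_explained, forest = fit,
                 design = design),
            class = "sensitivity_result")
}

#' @rdname sensitivity_design
#' @param progress Print progress messages.
#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d samples, %d trees, mtry %d\n",
              x$design$n_samples, x$design$num_trees, x$design$mtry))
  cat(sprintf("  response: %s; OOB %% variance explained: %.1f\n",
              x$design$response, x$pct_var_explained))
  cat("  importance ranking (permutation, OOB):\n")
  for (nm in names(x$importance))
    cat(sprintf("    %-18s %10.4g\n", nm, x$importance[[nm]]))
  invisible(x)
}

#' Sweep figure: metric against pollinator abundance
#'
#' Base-graphics line plot of a cell-mean metric against the pollinator
#' ratio, one line per (refill, scent-use) combination, mirroring the
#' model's main result panels.
#'
#' @param tab A `sweep_result` from a competition sweep.
#' @param metric Metric column to plot.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_competition_sweep <- function(tab, metric = "mean_nectar_collected", ...) {
  cm <- sweep_cell_means(tab, metric,
                         by = intersect(c("pollinator_ratio", "refill_coef",
                                          "use_scent"), names(tab)))
  ratios <- sort(unique(cm$pollinator_ratio))
  grp <- interaction(cm$refill_coef, cm$use_scent, drop = TRUE)
  ymat <- sapply(levels(grp), function(g) {
    sub <- cm[grp == g, ]
    sub$mean[match(ratios, sub$pollinator_ratio)]
  })
  graphics::matplot(ratios, ymat, type = "b", pch = 19, lty = 1,
                    xlab = "pollinators per flower", ylab = metric, ...)
  graphics::legend("topright", legend = levels(grp), col = seq_len(ncol(ymat)),
                   pch = 19, lty = 1, cex = 0.7,
                   title = "refill.use_scent")
  invisible(cm)
}
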