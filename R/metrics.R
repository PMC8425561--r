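#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' heterogeneity measure used for nectar collected, remaining nectar,
#' visits per flower and pollen carryover. Undefined — reported as `NA`,
#' not an error — when fewer than two values are available or the mean is
#' zero (or negative).
#'
#' @param x Numeric vector of non-negative values; `NA`s are dropped.
#' @return The CV, or `NA_real_` when undefined.
#' @examples
#' coef_variation(c(1, 3))        # sqrt(2)/2
#' coef_variation(c(5, 5, 5))     # 0
#' @export
coef_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

#' Pollen carryover per flower
#'
#' Proxy for how widely a flower's pollen is disseminated: for every
#' accepted visit to a focal flower, count the distinct other flowers the
#' same pollinator subsequently visits (accepted visits only) before the
#' end of the run, then average those counts over the focal flower's
#' visits. Flowers never visited have no focal visits and get `NA`.
#'
#' @param events A visit-event log (`step`, `pollinator_id`, `flower_id`,
#'   `accepted`), as in a `sim_result`.
#' @param n_flowers Number of flowers in the run (ids `1:n_flowers`); if
#'   missing, the largest flower id in the log is used.
#' @param carryover_window If finite, only the next `carryover_window`
#'   accepted visits of the pollinator are counted as potential recipients;
#'   default `Inf` counts to the end of the run.
#' @return A data.frame with one row per flower: `flower_id`, `carryover`
#'   (mean over its visits, `NA` if unvisited), `n_visits`.
#' @export
pollen_transfer <- function(events, n_flowers = NULL, carryover_window = Inf) {
  acc <- events[events$accepted == 1, , drop = FALSE]
  if (is.null(n_flowers))
    n_flowers <- if (nrow(acc) > 0) max(acc$flower_id) else 0L
  out <- data.frame(flower_id = seq_len(n_flowers),
                    carryover = NA_real_, n_visits = 0L)
  if (nrow(acc) == 0) return(out)
  acc <- acc[order(acc$step), , drop = FALSE]
  sums <- numeric(n_flowers)
  cnts <- integer(n_flowers)
  for (fseq in split(acc$flower_id, acc$pollinator_id)) {
    k <- length(fseq)
    carry <- integer(k)
    if (is.infinite(carryover_window)) {
      # reverse scan: distinct flowers in the suffix, minus the focal if present
      seen <- logical(n_flowers)
      n_seen <- 0L
      for (i in k:1) {
        f <- fseq[i]
        carry[i] <- n_seen - as.integer(seen[f])
        if (!seen[f]) { seen[f] <- TRUE; n_seen <- n_seen + 1L }
      }
    } else {
      for (i in seq_len(k)) {
        j <- seq(i + 1L, length.out = min(carryover_window, k - i))
        carry[i] <- length(setdiff(unique(fseq[j]), fseq[i]))
      }
    }
    for (i in seq_len(k)) {
      f <- fseq[i]
      sums[f] <- sums[f] + carry[i]
      cnts[f] <- cnts[f] + 1L
    }
  }
  vis <- cnts > 0L
  out$carryover[vis] <- sums[vis] / cnts[vis]
  out$n_visits <- cnts
  out
}

#' Per-run summary metrics
#'
#' The individual- and community-level aggregates of one run: mean and CV
#' of nectar collected over pollinators, mean nectar per accepted visit,
#' mean and CV of nectar remaining over flowers at the end, mean and CV of
#' accepted visits per flower, and mean and CV of pollen carryover over
#' visited flowers. Means of empty sets and CVs with zero mean are `NA`.
#'
#' @param object,result A `sim_result` from [run_simulation()].
#' @param carryover_window Passed to [pollen_transfer()].
#' @param ... Unused.
#' @return `summarize_run()`: a one-row data.frame with the fields above
#'   plus `n_flowers`, `n_pollinators`, `n_accepted`. `summary()` returns
#'   the same row with class `sim_summary` for printing.
#' @export
summarize_run <- function(result, carryover_window = Inf) {
  stopifnot(inherits(result, "sim_result"))
  pp <- result$per_pollinator
  pf <- result$per_flower
  acc <- result$events[result$events$accepted == 1, , drop = FALSE]
  n_acc <- nrow(acc)
  pt <- pollen_transfer(result$events, n_flowers = nrow(pf),
                        carryover_window = carryover_window)
  data.frame(
    n_flowers = nrow(pf),
    n_pollinators = nrow(pp),
    n_accepted = n_acc,
    mean_nectar_collected = if (nrow(pp) > 0) mean(pp$nectar_collected) else NA_real_,
    cv_nectar_collected = coef_variation(pp$nectar_collected),
    mean_nectar_per_visit = if (n_acc > 0) sum(acc$nectar_gained) / n_acc else NA_real_,
    mean_nectar_remaining = mean(pf$nectar),
    cv_nectar_remaining = coef_variation(pf$nectar),
    mean_visits_per_flower = mean(pf$visit_count),
    cv_visits_per_flower = coef_variation(pf$visit_count),
    mean_pollen_transfer = if (any(!is.na(pt$carryover))) {
      mean(pt$carryover, na.rm = TRUE)
    } else NA_real_,
    cv_pollen_transfer = coef_variation(pt$carryover))
}

#' @rdname summarize_run
#' @export
summary.sim_result <- function(object, carryover_window = Inf, ...) {
  s <- summarize_run(object, carryover_window = carryover_window)
  class(s) <- c("sim_summary", class(s))
  s
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("Per-run summary metrics\n")
  cat(sprintf("  %d flowers, %d pollinators, %d accepted visits\n",
              x$n_flowers, x$n_pollinators, x$n_accepted))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf("  nectar collected/pollinator: mean %s, CV %s\n",
              fmt(x$mean_nectar_collected), fmt(x$cv_nectar_collected)))
  cat(sprintf("  nectar per accepted visit:   %s\n", fmt(x$mean_nectar_per_visit)))
  cat(sprintf("  nectar remaining/flower:     mean %s, CV %s\n",
              fmt(x$mean_nectar_remaining), fmt(x$cv_nectar_remaining)))
  cat(sprintf("  accepted visits/flower:      mean %s, CV %s\n",
              fmt(x$mean_visits_per_flower), fmt(x$cv_visits_per_flower)))
  cat(sprintf("  pollen carryover/flower:     mean %s, CV %s\n",
              fmt(x$mean_pollen_transfer), fmt(x$cv_pollen_transfer)))
  invisible(x)
}
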