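#' Run one foraging simulation
#'
#' Initializes a meadow (flowers and pollinators i.i.d. uniform on the
#' torus, flowers full of nectar and unmarked, pollinators searching with
#' uniform headings) and iterates the global schedule for
#' `config$n_steps` steps. Within each step the pollinators act once each
#' in a fresh uniform random permutation — so no agent has systematic
#' priority when two pollinators could claim the same flower — and when
#' all have acted, every previously visited flower advances its refill
#' clock. The whole run is driven by a single RNG stream seeded from
#' `config$seed`, so identical `(config, seed)` replays bit-identically.
#'
#' @param config A [sim_config()] object.
#' @param init Optional fixed initial layout for controlled experiments: a
#'   list with any of `flower_x`, `flower_y`, `poll_x`, `poll_y`,
#'   `heading` (vectors of the realized agent counts). Components left
#'   `NULL` are drawn randomly.
#' @return An object of class `sim_result`: a list with
#'   \describe{
#'     \item{config, seed}{the echoed configuration and seed;}
#'     \item{per_pollinator}{data.frame `id`, `x`, `y`, `nectar_collected`,
#'       `n_accepted`;}
#'     \item{per_flower}{data.frame `id`, `x`, `y`, `nectar`, `scent`,
#'       `time_since_visit` (`NA` if never visited), `visit_count`;}
#'     \item{events}{data.frame with one row per flower encounter:
#'       `step`, `pollinator_id`, `flower_id`, `accepted` (0/1),
#'       `nectar_gained`;}
#'     \item{refill_total}{total nectar regenerated by flowers during the
#'       run, for the conservation identity
#'       `sum(collected) + sum(standing) = n_flowers + refill_total`.}
#'   }
#' @examples
#' res <- run_simulation(sim_config(size_map = 15, flower_density = 0.1,
#'                                  pollinator_ratio = 0.5, n_steps = 200,
#'                                  seed = 7))
#' summary(res)
#' @seealso [summary.sim_result()], [run_sweep()]
#' @export
run_simulation <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_config(config)
  nf <- n_flowers(config)
  np <- n_pollinators(config)
  if (nf < 1) stop("configuration yields zero flowers", call. = FALSE)

  getv <- function(name) if (is.null(init[[name]])) NULL else as.numeric(init[[name]])

  set.seed(config$seed)
  raw <- run_sim_cpp(config$size_map, config$n_steps, nf, np,
                     config$refill_coef, config$use_scent, config$cost,
                     config$detection_radius, config$inertia,
                     config$scent_semantics == "literal",
                     getv("flower_x"), getv("flower_y"),
                     getv("poll_x"), getv("poll_y"), getv("heading"))

  tsv <- raw$time_since_visit
  tsv[tsv < 0] <- NA_integer_
  res <- list(
    config = config,
    seed = config$seed,
    per_pollinator = data.frame(
      id = seq_len(np), x = raw$poll_x, y = raw$poll_y,
      nectar_collected = raw$nectar_collected, n_accepted = raw$n_accepted),
    per_flower = data.frame(
      id = seq_len(nf), x = raw$flower_x, y = raw$flower_y,
      nectar = raw$nectar, scent = raw$scent, time_since_visit = tsv,
      visit_count = raw$visit_count),
    events = data.frame(
      step = raw$ev_step, pollinator_id = raw$ev_pollinator + 1L,
      flower_id = raw$ev_flower + 1L, accepted = raw$ev_accepted,
      nectar_gained = raw$ev_gain),
    refill_total = raw$refill_total)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  nf <- nrow(x$per_flower); np <- nrow(x$per_pollinator)
  acc <- sum(x$events$accepted)
  cat(sprintf("Foraging simulation: %d flowers, %d pollinators, %d steps (seed %d)\n",
              nf, np, x$config$n_steps, x$seed))
  cat(sprintf("  scent marks %s; %d encounters, %d accepted visits\n",
              if (x$config$use_scent) "used" else "ignored",
              nrow(x$events), acc))
  if (np > 0)
    cat(sprintf("  nectar collected: mean %.3f per pollinator (total %.2f)\n",
                mean(x$per_pollinator$nectar_collected),
                sum(x$per_pollinator$nectar_collected)))
  cat(sprintf("  nectar standing: mean %.3f per flower\n", mean(x$per_flower$nectar)))
  invisible(x)
}

#' Map of the meadow at the end of a run
#'
#' Flowers are drawn as circles shaded by standing nectar (dark = empty,
#' light = full) and pollinators as orange crosses.
#'
#' @param x A `sim_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sim_result <- function(x, ...) {
  L <- x$config$size_map
  shade <- grDevices::gray(0.15 + 0.8 * x$per_flower$nectar)
  graphics::plot(x$per_flower$x, x$per_flower$y, pch = 21, bg = shade,
                 xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x", ylab = "y",
                 main = "Meadow at end of run (shade = standing nectar)", ...)
  if (nrow(x$per_pollinator) > 0)
    graphics::points(x$per_pollinator$x, x$per_pollinator$y, pch = 4,
                     col = "darkorange", cex = 0.8)
  invisible(x)
}
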