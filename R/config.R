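#' Simulation configuration
#'
#' Build and validate the configuration of one foraging simulation. The
#' configuration is the single source of truth for a run: together with
#' `seed` it determines every stochastic event (agent placement, update
#' order, turning angles, visit decisions, tie-breaks), so a run can be
#' replayed exactly.
#'
#' The meadow is a square torus of side `size_map`; the realized number of
#' flowers is `round(flower_density * size_map^2)` and the realized number
#' of pollinators is `round(pollinator_ratio * n_flowers)`, both
#' deterministic functions of the configuration.
#'
#' @param size_map Side length of the square toroidal meadow (length units).
#' @param n_steps Foraging duration in time steps; one step is the time for
#'   one pollinator action. `0` is allowed and yields a degenerate run.
#' @param flower_density Flowers per unit area.
#' @param refill_coef Fraction of full nectar capacity regenerated per step;
#'   also the fade rate of the repellent scent mark. The experiment values
#'   0.001, 0.0025 and 0.005 correspond to 1, 2.5 and 5 full refills over a
#'   1000-step run.
#' @param pollinator_ratio Pollinators per flower; the exploitation
#'   competition axis.
#' @param use_scent Logical; do pollinators use scent marks as repellent
#'   cues? Populations are homogeneous within a run.
#' @param cost Handling time: steps spent inside an accepted flower.
#' @param detection_radius Distance within which a searching pollinator
#'   perceives free flowers (length units).
#' @param inertia Directional inertia of the correlated random walk, in
#'   (0, 1); the turning-angle standard deviation is `2 * pi * inertia`
#'   radians, so small values give near-ballistic paths.
#' @param seed Integer RNG seed.
#' @param scent_semantics `"repellent"` (default): probability of accepting
#'   a flower is `1 - scent`, so freshly visited flowers repel.
#'   `"literal"`: probability of accepting equals the scent concentration.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(pollinator_ratio = 0.5, seed = 42)
#' n_flowers(cfg)      # 250
#' n_pollinators(cfg)  # 125
#' @seealso [run_simulation()], [read_config()]
#' @export
sim_config <- function(size_map = 50, n_steps = 1000, flower_density = 0.1,
                       refill_coef = 0.0025, pollinator_ratio = 0.1,
                       use_scent = TRUE, cost = 5, detection_radius = 1,
                       inertia = 0.1, seed = 1L,
                       scent_semantics = c("repellent", "literal")) {
  scent_semantics <- match.arg(scent_semantics)
  cfg <- list(size_map = as.numeric(size_map), n_steps = as.integer(n_steps),
              flower_density = as.numeric(flower_density),
              refill_coef = as.numeric(refill_coef),
              pollinator_ratio = as.numeric(pollinator_ratio),
              use_scent = isTRUE(as.logical(use_scent)),
              cost = as.integer(cost),
              detection_radius = as.numeric(detection_radius),
              inertia = as.numeric(inertia), seed = as.integer(seed),
              scent_semantics = scent_semantics)
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  chk(num1(cfg$size_map) && cfg$size_map > 0, "size_map must be a single value > 0")
  chk(num1(cfg$n_steps) && cfg$n_steps >= 0, "n_steps must be a single integer >= 0")
  chk(num1(cfg$flower_density) && cfg$flower_density > 0,
      "flower_density must be > 0")
  chk(num1(cfg$refill_coef) && cfg$refill_coef > 0 && cfg$refill_coef <= 1,
      "refill_coef must lie in (0, 1]")
  chk(num1(cfg$pollinator_ratio) && cfg$pollinator_ratio >= 0,
      "pollinator_ratio must be >= 0")
  chk(is.logical(cfg$use_scent) && length(cfg$use_scent) == 1L,
      "use_scent must be TRUE or FALSE")
  chk(num1(cfg$cost) && cfg$cost >= 1, "cost must be a single integer >= 1")
  chk(num1(cfg$detection_radius) && cfg$detection_radius > 0,
      "detection_radius must be > 0")
  chk(num1(cfg$inertia) && cfg$inertia > 0 && cfg$inertia < 1,
      "inertia must lie in (0, 1)")
  chk(num1(cfg$seed), "seed must be a single integer")
  chk(cfg$scent_semantics %in% c("repellent", "literal"),
      "scent_semantics must be 'repellent' or 'literal'")
  chk(n_flowers(cfg) >= 1, "configuration yields zero flowers")
  invisible(cfg)
}

#' Realized agent counts
#'
#' @param config A [sim_config()] object.
#' @return Integer count of flowers (`round(flower_density * size_map^2)`)
#'   or pollinators (`round(pollinator_ratio * n_flowers)`).
#' @export
n_flowers <- function(config) {
  as.integer(round(config$flower_density * config$size_map^2))
}

#' @rdname n_flowers
#' @export
n_pollinators <- function(config) {
  as.integer(round(config$pollinator_ratio * n_flowers(config)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Foraging simulation configuration\n")
  cat(sprintf("  meadow: %g x %g torus, %d flowers (density %g)\n",
              x$size_map, x$size_map, n_flowers(x), x$flower_density))
  cat(sprintf("  pollinators: %d (%g per flower), scent marks %s (%s)\n",
              n_pollinators(x), x$pollinator_ratio,
              if (x$use_scent) "used" else "ignored", x$scent_semantics))
  cat(sprintf("  steps: %d, refill %g/step, cost %d, radius %g, inertia %g, seed %d\n",
              x$n_steps, x$refill_coef, x$cost, x$detection_radius,
              x$inertia, x$seed))
  invisible(x)
}

#' Read and write configuration files
#'
#' Configurations are stored as a flat JSON mapping of the [sim_config()]
#' fields. Absent fields take their defaults; unknown fields are an error.
#'
#' @param path Path to a JSON file.
#' @param config A `sim_config` object.
#' @param overrides Named list of field values taking precedence over the
#'   file contents (e.g. parsed command-line flags).
#' @return `read_config()` returns a validated `sim_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.list(vals)) stop("config file must contain a JSON mapping", call. = FALSE)
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
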