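#' Scent-conditional visit decision
#'
#' A pollinator sitting on a flower decides whether to harvest it. Users of
#' the repellent scent mark run a Bernoulli trial whose acceptance
#' probability decreases with the mark's concentration: under the default
#' repellent semantics `P(accept) = 1 - scent`, so a freshly visited flower
#' (scent 1) is always rejected and a fully refilled one (scent 0) always
#' accepted. Non-users always accept. The `"literal"` semantics
#' (`P(accept) = scent`) is exposed for comparison only; it attracts
#' pollinators to just-emptied flowers.
#'
#' @param scent Scent concentration in [0, 1] (vectorized).
#' @param use_scent Logical; non-users skip the trial and always accept.
#' @param semantics `"repellent"` or `"literal"`.
#' @return Logical vector: accept the flower?
#' @export
decide_visit <- function(scent, use_scent = TRUE,
                         semantics = c("repellent", "literal")) {
  semantics <- match.arg(semantics)
  if (any(scent < 0 | scent > 1)) stop("scent must lie in [0, 1]", call. = FALSE)
  if (!use_scent) return(rep(TRUE, length(scent)))
  p_acc <- if (semantics == "repellent") 1 - scent else scent
  stats::runif(length(scent)) < p_acc
}

#' Correlated-random-walk turning
#'
#' While searching, a pollinator's heading deviates from its previous
#' heading by a Gaussian turning angle with mean zero and standard
#' deviation `2 * pi * inertia` radians, mapping the inertia range
#' (0, 1) from near-ballistic to near-diffusive movement.
#'
#' @param heading Current heading in radians (vectorized).
#' @param inertia Directional inertia in (0, 1).
#' @return New heading(s), wrapped to [0, 2*pi).
#' @export
sample_turn <- function(heading, inertia) {
  stopifnot(inertia > 0, inertia < 1)
  (heading + stats::rnorm(length(heading), 0, 2 * pi * inertia)) %% (2 * pi)
}

#' Detect candidate flowers
#'
#' A searching pollinator perceives flowers within its detection radius
#' (torus metric) that are free (no pollinator above or inside, including
#' flowers claimed earlier in the same step) and novel, i.e. not the
#' flower it just left or rejected.
#'
#' @param x,y Pollinator position.
#' @param flowers A flower table (see [make_flowers()]).
#' @param detection_radius Perception distance.
#' @param size_map Torus side.
#' @param last_flower Id of the most recently left or rejected flower
#'   (`NA` for none).
#' @return Integer vector of candidate flower ids (possibly empty).
#' @export
detect_candidates <- function(x, y, flowers, detection_radius, size_map,
                              last_flower = NA_integer_) {
  d <- torus_distance(x, y, flowers$x, flowers$y, size_map)
  ok <- d <= detection_radius & is.na(flowers$occupant)
  if (!is.na(last_flower)) ok <- ok & flowers$id != last_flower
  flowers$id[ok]
}
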