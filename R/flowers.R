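#' Linear nectar refill and scent-mark fade
#'
#' A harvested flower refills nectar linearly at `refill_coef` capacity
#' units per step, capped at full capacity 1; the repellent scent mark left
#' by the visitor starts at 1 and fades on the same linear clock, so the
#' mark is a reliable signal of the refill state: `nectar + scent == 1`
#' exactly while `refill_coef * time_since_visit <= 1`, after which nectar
#' saturates at 1 and scent at 0.
#'
#' @param time_since_visit Steps since the last accepted visit (>= 0).
#' @param refill_coef Refill rate in capacity units per step, in (0, 1].
#' @return Nectar (fraction of capacity) or scent concentration, in [0, 1].
#' @examples
#' nectar_at(1000, 0.001)   # 1: exactly one full refill over a 1000-step run
#' scent_at(200, 0.0025)    # 0.5
#' @export
nectar_at <- function(time_since_visit, refill_coef) {
  if (any(time_since_visit < 0)) stop("negative time_since_visit", call. = FALSE)
  stopifnot(refill_coef > 0, refill_coef <= 1)
  pmin(1, refill_coef * time_since_visit)
}

#' @rdname nectar_at
#' @export
scent_at <- function(time_since_visit, refill_coef) {
  if (any(time_since_visit < 0)) stop("negative time_since_visit", call. = FALSE)
  stopifnot(refill_coef > 0, refill_coef <= 1)
  pmax(0, 1 - refill_coef * time_since_visit)
}

#' Flower state table
#'
#' Reference (R-level) representation of flower state, used by the
#' operation-level functions and tests; the simulation engine keeps the
#' same state in compiled code. `time_since_visit` is `NA` for flowers
#' never visited, which start full of nectar and unmarked; `occupant` is
#' `NA` when no pollinator is on the flower.
#'
#' @param n Number of flowers.
#' @param size_map Torus side; positions are i.i.d. uniform.
#' @param x,y Optional fixed positions (wrapped onto the torus).
#' @return A data.frame with columns `id`, `x`, `y`, `nectar`, `scent`,
#'   `time_since_visit`, `visit_count`, `occupant`.
#' @export
make_flowers <- function(n, size_map, x = NULL, y = NULL) {
  stopifnot(n >= 1)
  if (is.null(x)) x <- stats::runif(n, 0, size_map) else x <- wrap_torus(x, size_map)
  if (is.null(y)) y <- stats::runif(n, 0, size_map) else y <- wrap_torus(y, size_map)
  data.frame(id = seq_len(n), x = x, y = y, nectar = 1, scent = 0,
             time_since_visit = NA_integer_, visit_count = 0L,
             occupant = NA_integer_)
}

#' Harvest a flower
#'
#' An accepted visit takes all standing nectar: the gain is the flower's
#' current nectar, after which nectar is set to 0, the scent mark to 1, the
#' time-since-visit clock to 0, and the accepted-visit count incremented.
#'
#' @param flowers A flower table from [make_flowers()].
#' @param id Flower id to harvest.
#' @param pollinator Id of the harvesting pollinator; harvesting a flower
#'   occupied by another pollinator is an error (the engine prevents it).
#' @return A list with `gain` (nectar harvested) and `flowers` (updated table).
#' @export
harvest_flower <- function(flowers, id, pollinator = NA_integer_) {
  i <- match(id, flowers$id)
  if (is.na(i)) stop("no flower with id ", id, call. = FALSE)
  occ <- flowers$occupant[i]
  if (!is.na(occ) && !identical(as.integer(occ), as.integer(pollinator)))
    stop("flower ", id, " is occupied by another pollinator", call. = FALSE)
  gain <- flowers$nectar[i]
  flowers$nectar[i] <- 0
  flowers$scent[i] <- 1
  flowers$time_since_visit[i] <- 0L
  flowers$visit_count[i] <- flowers$visit_count[i] + 1L
  list(gain = gain, flowers = flowers)
}

#' Advance the flower clock one step
#'
#' Called once per step after all pollinators have acted: every previously
#' visited flower ages one step and recomputes nectar and scent from the
#' linear law; never-visited flowers are untouched (full, unmarked).
#'
#' @param flowers A flower table.
#' @param refill_coef Refill rate per step.
#' @return The updated flower table.
#' @export
tick_flowers <- function(flowers, refill_coef) {
  v <- !is.na(flowers$time_since_visit)
  if (any(v)) {
    tau <- flowers$time_since_visit[v] + 1L
    flowers$time_since_visit[v] <- tau
    flowers$nectar[v] <- nectar_at(tau, refill_coef)
    flowers$scent[v] <- scent_at(tau, refill_coef)
  }
  flowers
}
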