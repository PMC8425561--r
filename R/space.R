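#' Toroidal geometry
#'
#' The meadow is a continuous 2-D torus: a square of side `size_map` whose
#' opposite edges are identified, which removes boundary effects from agent
#' movement. `wrap_torus()` maps coordinates into the fundamental domain
#' `[0, size_map)`; `torus_distance()` is the Euclidean distance under the
#' minimum-image convention.
#'
#' @param x,y,x2,y2 Numeric coordinate vectors (recycled to a common length).
#' @param size_map Side length of the torus, > 0.
#' @return `wrap_torus()`: coordinates congruent to the input modulo
#'   `size_map`, in `[0, size_map)`. `torus_distance()`: non-negative
#'   distances, at most `size_map * sqrt(2) / 2`.
#' @examples
#' wrap_torus(c(51, -1), 50)          # 1, 49
#' torus_distance(0, 0, 49, 0, 50)    # 1: wraps across the edge
#' @export
wrap_torus <- function(x, size_map) {
  if (!is.numeric(size_map) || length(size_map) != 1L || !is.finite(size_map) ||
      size_map <= 0)
    stop("size_map must be a single finite value > 0", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite coordinates", call. = FALSE)
  w <- x %% size_map
  w[w >= size_map] <- 0   # guard against x %% L == L in floating point
  w
}

#' @rdname wrap_torus
#' @export
torus_distance <- function(x, y, x2, y2, size_map) {
  if (!all(is.finite(x), is.finite(y), is.finite(x2), is.finite(y2)))
    stop("non-finite coordinates", call. = FALSE)
  dx <- abs(x - x2)
  dx <- pmin(dx, size_map - dx)
  dy <- abs(y - y2)
  dy <- pmin(dy, size_map - dy)
  sqrt(dx^2 + dy^2)
}
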