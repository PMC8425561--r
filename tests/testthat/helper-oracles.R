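# Independent brute-force oracles and small fixtures, built in code.

# Torus distance by explicit minimization over the 9 periodic images.
brute_torus_distance <- function(x, y, x2, y2, L) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) {
    d <- sqrt((x - (x2 + ix * L))^2 + (y - (y2 + iy * L))^2)
    if (d < best) best <- d
  }
  best
}

# Pollen carryover by direct suffix enumeration over an accepted-visit log.
brute_carryover <- function(events, n_flowers) {
  acc <- events[events$accepted == 1, , drop = FALSE]
  acc <- acc[order(acc$step), , drop = FALSE]
  sums <- numeric(n_flowers); cnts <- integer(n_flowers)
  for (p in unique(acc$pollinator_id)) {
    fseq <- acc$flower_id[acc$pollinator_id == p]
    for (i in seq_along(fseq)) {
      later <- if (i < length(fseq)) fseq[(i + 1):length(fseq)] else integer()
      cnt <- length(setdiff(unique(later), fseq[i]))
      sums[fseq[i]] <- sums[fseq[i]] + cnt
      cnts[fseq[i]] <- cnts[fseq[i]] + 1L
    }
  }
  ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
}

# A small but non-trivial meadow that runs in well under a second.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(size_map = 20, n_steps = 300, flower_density = 0.1,
         pollinator_ratio = 0.5, refill_coef = 0.0025, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# Hand-built event log used across metric tests: 3 pollinators, 4 flowers.
toy_events <- function() {
  data.frame(
    step = c(1L, 5L, 9L, 2L, 6L, 3L),
    pollinator_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    flower_id = c(1L, 2L, 1L, 2L, 3L, 4L),
    accepted = c(1L, 1L, 1L, 1L, 1L, 0L),
    nectar_gained = c(1, 0.5, 0.02, 1, 0.25, 0))
}
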