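# A 1-flower, 1-pollinator meadow with fixed layout: the pollinator starts
# on the flower, so the whole action schedule can be traced by hand.
one_flower_cfg <- function(...) {
  args <- utils::modifyList(
    list(size_map = 10, flower_density = 0.01, pollinator_ratio = 1,
         refill_coef = 0.005, use_scent = FALSE, n_steps = 10, seed = 1L),
    list(...))
  do.call(sim_config, args)
}
one_flower_init <- list(flower_x = 5, flower_y = 5, poll_x = 5, poll_y = 5,
                        heading = 0)

test_that("a traced visit follows land -> assess/harvest -> handle -> leave", {
  res <- run_simulation(one_flower_cfg(), init = one_flower_init)
  ev <- res$events
  # landing consumes step 1; the harvest happens at the assessment step 2
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$step, 2L)
  expect_equal(ev$accepted, 1L)
  expect_equal(ev$nectar_gained, 1)            # never-visited flower is full
  expect_equal(res$per_flower$visit_count, 1L)
  # handling lasts cost = 5 steps (3..7); the flower clock ticks at the end
  # of every step from the harvest on (steps 2..10), so tau = 9 at rate 0.005
  expect_equal(res$per_flower$time_since_visit, 9L)
  expect_equal(res$per_flower$nectar, 0.045)
  expect_equal(res$per_flower$scent, 0.955)
  # after leaving, the just-left flower is excluded, so exactly one visit
  expect_equal(res$per_pollinator$n_accepted, 1L)
  expect_equal(res$per_pollinator$nectar_collected, 1)
})

test_that("after one step on a flower the pollinator is handling and the flower has one refill tick", {
  res <- run_simulation(one_flower_cfg(n_steps = 2), init = one_flower_init)
  expect_equal(res$per_flower$nectar, 0.005)   # one linear step since harvest
  expect_equal(res$per_flower$scent, 0.995)
  expect_equal(res$per_pollinator$nectar_collected, 1)
})

test_that("a fully repellent assessment is rejected and logged, and the flower is not reset", {
  # literal semantics on an unmarked flower: P(accept) = scent = 0
  res <- run_simulation(one_flower_cfg(use_scent = TRUE,
                                       scent_semantics = "literal"),
                        init = one_flower_init)
  ev <- res$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$accepted, 0L)
  expect_equal(ev$nectar_gained, 0)
  expect_equal(res$per_flower$visit_count, 0L)       # rejection doesn't count
  expect_equal(res$per_flower$nectar, 1)             # ... nor reset the flower
  expect_true(is.na(res$per_flower$time_since_visit))
  expect_equal(res$per_pollinator$nectar_collected, 0)
})

test_that("degenerate runs behave: zero steps, zero pollinators", {
  r0 <- run_simulation(quick_config(n_steps = 0))
  expect_equal(nrow(r0$events), 0L)
  expect_equal(r0$per_flower$nectar, rep(1, nrow(r0$per_flower)))

  rp <- run_simulation(quick_config(pollinator_ratio = 0))
  expect_equal(nrow(rp$per_pollinator), 0L)
  expect_equal(nrow(rp$events), 0L)
  expect_equal(rp$per_flower$nectar, rep(1, nrow(rp$per_flower)))
})

test_that("identical (config, seed) replays bit-identically; seeds differ otherwise", {
  cfg <- quick_config(use_scent = TRUE)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$per_flower, b$per_flower)
  expect_identical(a$per_pollinator, b$per_pollinator)

  c <- run_simulation(quick_config(use_scent = TRUE, seed = 43L))
  expect_false(identical(a$events, c$events))
})

test_that("per-run bookkeeping, conservation, time budget and occupancy hold (property)", {
  for (seed in 1:4) {
    cfg <- quick_config(seed = seed, use_scent = seed %% 2 == 0,
                        pollinator_ratio = c(0.3, 1)[1 + seed %% 2])
    res <- run_simulation(cfg)
    acc <- res$events[res$events$accepted == 1, ]

    # event log vs per-agent aggregates (exact)
    expect_equal(sum(acc$nectar_gained),
                 sum(res$per_pollinator$nectar_collected))
    expect_equal(as.integer(table(factor(acc$flower_id,
                                         levels = res$per_flower$id))),
                 res$per_flower$visit_count)

    # nectar conservation: collected + standing = initial stock + refill
    expect_equal(sum(res$per_pollinator$nectar_collected) +
                   sum(res$per_flower$nectar),
                 nrow(res$per_flower) + res$refill_total,
                 tolerance = 1e-10)

    # accepted-visit time budget: 1 assessment + cost handling steps each
    expect_true(all(res$per_pollinator$n_accepted <=
                      cfg$n_steps / (cfg$cost + 1)))

    # occupancy exclusivity: a flower is held for cost steps after a
    # harvest, so accepted visits to one flower are >= cost + 1 steps apart
    gaps <- unlist(tapply(acc$step, acc$flower_id,
                          function(s) diff(sort(s))), use.names = FALSE)
    if (length(gaps) > 0) expect_gte(min(gaps), cfg$cost + 1)
  }
})

test_that("without scent marks every landing is harvested", {
  res <- run_simulation(quick_config(use_scent = FALSE))
  expect_true(all(res$events$accepted == 1L))
})
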