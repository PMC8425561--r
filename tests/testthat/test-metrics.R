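test_that("coefficient of variation: hand values and missing-value contract", {
  expect_equal(coef_variation(c(5, 5, 5)), 0)
  expect_equal(coef_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coef_variation(c(2, 4, 6, 8)), sqrt(20 / 3) / 5)  # ~0.5164
  expect_equal(coef_variation(c(1, NA, 3)), sqrt(2) / 2)
  # undefined cases are NA, not errors
  expect_true(is.na(coef_variation(c(0, 0, 0))))
  expect_true(is.na(coef_variation(3)))
  expect_true(is.na(coef_variation(numeric(0))))
})

test_that("pollen carryover counts distinct downstream flowers (hand cases)", {
  # one pollinator visiting A, B, C
  ev <- data.frame(step = 1:3, pollinator_id = 1L, flower_id = 1:3,
                   accepted = 1L, nectar_gained = 1)
  expect_equal(pollen_transfer(ev, 3)$carryover, c(2, 1, 0))

  # A, B, A, C: revisits count once as recipients, focal excluded
  ev <- data.frame(step = 1:4, pollinator_id = 1L, flower_id = c(1, 2, 1, 3),
                   accepted = 1L, nectar_gained = 1)
  pt <- pollen_transfer(ev, 3)
  expect_equal(pt$carryover, c((2 + 1) / 2, 2, 0))   # A averages its 2 visits
  expect_equal(pt$n_visits, c(2L, 1L, 1L))

  # a single accepted visit, plus rejected events that must be ignored
  ev <- data.frame(step = c(1, 2), pollinator_id = 1L, flower_id = c(1, 2),
                   accepted = c(1L, 0L), nectar_gained = c(1, 0))
  pt <- pollen_transfer(ev, 2)
  expect_equal(pt$carryover, c(0, NA))
  expect_equal(pollen_transfer(ev[0, ], 2)$carryover, c(NA_real_, NA_real_))
})

test_that("pollen carryover matches the brute-force suffix oracle on random logs", {
  set.seed(11)
  for (rep in 1:5) {
    n_fl <- 6L
    ev <- data.frame(step = sample.int(500, 60),
                     pollinator_id = sample.int(4, 60, replace = TRUE),
                     flower_id = sample.int(n_fl, 60, replace = TRUE),
                     accepted = rbinom(60, 1, 0.7), nectar_gained = 0)
    expect_equal(pollen_transfer(ev, n_fl)$carryover, brute_carryover(ev, n_fl))
  }
})

test_that("a finite carryover window restricts the recipient set", {
  ev <- data.frame(step = 1:4, pollinator_id = 1L, flower_id = c(1, 2, 3, 4),
                   accepted = 1L, nectar_gained = 1)
  expect_equal(pollen_transfer(ev, 4, carryover_window = 1)$carryover,
               c(1, 1, 1, 0))
  expect_equal(pollen_transfer(ev, 4, carryover_window = 2)$carryover,
               c(2, 2, 1, 0))
})

test_that("summary metrics match hand computation on a toy run", {
  ev <- toy_events()
  toy <- structure(list(
    config = quick_config(),
    seed = 42L,
    per_pollinator = data.frame(id = 1:3, x = 0, y = 0,
                                nectar_collected = c(1.52, 1.25, 0),
                                n_accepted = c(3L, 2L, 0L)),
    per_flower = data.frame(id = 1:4, x = 0, y = 0,
                            nectar = c(0.1, 0.2, 0.3, 0.4),
                            scent = 0, time_since_visit = NA_integer_,
                            visit_count = c(2L, 2L, 1L, 0L)),
    events = ev, refill_total = 0), class = "sim_result")
  s <- summarize_run(toy)
  expect_equal(s$n_accepted, 5L)
  expect_equal(s$mean_nectar_collected, mean(c(1.52, 1.25, 0)))
  expect_equal(s$cv_nectar_collected,
               stats::sd(c(1.52, 1.25, 0)) / mean(c(1.52, 1.25, 0)))
  expect_equal(s$mean_nectar_per_visit, (1 + 0.5 + 0.02 + 1 + 0.25) / 5)
  expect_equal(s$mean_nectar_remaining, 0.25)
  expect_equal(s$mean_visits_per_flower, 5 / 4)
  # visits-per-flower mean times flower count equals accepted events (exact)
  expect_equal(s$mean_visits_per_flower * s$n_flowers, s$n_accepted)
  # pollen carryover by hand: f1 (1+0)/2, f2 (1+1)/2, f3 0, f4 unvisited
  expect_equal(s$mean_pollen_transfer, mean(c(0.5, 1, 0)))
  expect_equal(s$cv_pollen_transfer, coef_variation(c(0.5, 1, 0)))
})

test_that("summary fields are invariant to agent relabeling", {
  res <- run_simulation(quick_config(use_scent = TRUE, seed = 9L))
  s0 <- summarize_run(res)

  # permute flower and pollinator ids consistently everywhere
  set.seed(1)
  fp <- sample(res$per_flower$id)
  pp <- sample(res$per_pollinator$id)
  rel <- res
  rel$per_flower$id <- fp[res$per_flower$id]
  rel$per_flower <- rel$per_flower[order(rel$per_flower$id), ]
  rel$per_pollinator$id <- pp[res$per_pollinator$id]
  rel$per_pollinator <- rel$per_pollinator[order(rel$per_pollinator$id), ]
  rel$events$flower_id <- fp[res$events$flower_id]
  rel$events$pollinator_id <- pp[res$events$pollinator_id]
  expect_equal(summarize_run(rel), s0)
})

test_that("empty-run summaries report missing where undefined", {
  res <- run_simulation(quick_config(pollinator_ratio = 0))
  s <- summarize_run(res)
  expect_equal(s$mean_nectar_remaining, 1)
  expect_equal(s$mean_visits_per_flower, 0)
  expect_true(is.na(s$mean_nectar_per_visit))
  expect_true(is.na(s$mean_pollen_transfer))
  expect_equal(s$cv_nectar_remaining, 0)          # all flowers still full
  expect_true(is.na(s$cv_visits_per_flower))      # zero mean: CV undefined
})
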