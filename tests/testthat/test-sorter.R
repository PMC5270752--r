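demo_calls <- function(n = 12, label = "carotenoid") {
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
             x = seq_len(n) * 10, y = rep(0, n), label = label,
             stringsAsFactors = FALSE)
}

test_that("a 12-well chip reserves two control wells and ten targets", {
  layout <- chip_layout()
  expect_identical(layout$n_wells, 12L)
  expect_identical(nrow(layout$controls), 2L)
  expect_setequal(layout$controls$role,
                  c("negative_control", "positive_control"))
  expect_identical(length(layout$target_wells), 10L)
  expect_error(chip_layout(2), "non-control")
})

test_that("plans fill wells round-robin, never touching control wells", {
  plan <- build_sort_plan(demo_calls(10), layout = chip_layout(),
                          cells_per_well = 1)
  expect_identical(nrow(plan$targets), 10L)
  expect_identical(sort(unique(plan$targets$well)), chip_layout()$target_wells)
  expect_false(any(plan$targets$well %in% plan$controls$well))
  # occupancy respects the scalar cap
  plan2 <- build_sort_plan(demo_calls(10), cells_per_well = 4)
  expect_true(all(table(plan2$targets$well) <= 4))
  expect_identical(length(unique(plan2$targets$well)), 3L)
})

test_that("an explicit 1/1/1/3/5/8/8 multi-well composition ejects 27 cells", {
  plan <- build_sort_plan(demo_calls(30),
                          cells_per_well = c(1, 1, 1, 3, 5, 8, 8))
  expect_identical(nrow(plan$targets), 27L)
  occupancy <- as.integer(table(factor(plan$targets$well,
                                       levels = unique(plan$targets$well))))
  expect_identical(occupancy, c(1L, 1L, 1L, 3L, 5L, 8L, 8L))
})

test_that("capacity and occupancy limits raise config errors", {
  expect_error(build_sort_plan(demo_calls(5), cells_per_well = 0), "\\[1, 8\\]")
  expect_error(build_sort_plan(demo_calls(5), cells_per_well = 9), "\\[1, 8\\]")
  expect_error(build_sort_plan(demo_calls(90), cells_per_well = 1),
               "capacity error")
  expect_error(build_sort_plan(demo_calls(30),
                               cells_per_well = rep(1, 11)),
               "capacity error")
})

test_that("an empty selection yields a valid controls-only plan", {
  plan <- build_sort_plan(demo_calls(5, label = "typical"),
                          query = "label == 'carotenoid'")
  expect_identical(nrow(plan$targets), 0L)
  expect_identical(nrow(plan$controls), 2L)
  manifest <- simulate_session(plan, seed = 1)
  expect_identical(unname(manifest$totals["attempted"]), 0L)
})

test_that("plan building is deterministic and orders cells ascending", {
  calls <- demo_calls(8)
  shuffled <- calls[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  a <- build_sort_plan(calls)
  b <- build_sort_plan(shuffled)
  expect_identical(a$targets, b$targets)
  expect_identical(a$targets$cell_id, sort(a$targets$cell_id))
})

test_that("session outcomes follow the Bernoulli model and spacing contract", {
  plan <- build_sort_plan(demo_calls(6))
  all_ok <- simulate_session(plan, seed = 3, success_prob = 1)
  expect_true(all(all_ok$records$outcome == "collected"))
  none <- simulate_session(plan, seed = 3, success_prob = 0)
  expect_true(all(none$records$outcome == "failed"))
  expect_identical(nrow(none$records), 6L)
  expect_true(all(diff(all_ok$records$t_offset) >= 5))
  expect_false(any(duplicated(all_ok$records$cell_id)))
})

test_that("the empirical collection rate converges to success_prob", {
  # 3000 seeded attempts at the published 7/30 ejection+WGA success rate
  big <- build_sort_plan(demo_calls(3000), layout = chip_layout(503),
                         cells_per_well = 8)
  m <- simulate_session(big, seed = 11, success_prob = 7 / 30)
  p <- 7 / 30
  expect_lt(abs(m$totals[["collected"]] / 3000 - p),
            3 * sqrt(p * (1 - p) / 3000))
})

test_that("the negative-control well never receives a cell", {
  for (seed in 1:3) {
    plan <- build_sort_plan(demo_calls(10))
    m <- simulate_session(plan, seed = seed, success_prob = 0.5)
    neg <- plan$controls$well[plan$controls$role == "negative_control"]
    expect_identical(unname(m$well_counts[neg]), 0L)
    expect_false(any(m$records$well %in% plan$controls$well))
  }
})
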