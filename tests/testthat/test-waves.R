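test_that("module mean profiles average member trajectories", {
  times <- default_times
  base <- at_times(times, `60` = 1, `120` = 2, `240` = 2)
  rows <- list(a = base, b = -base, c = 2 * base)
  r <- make_ratios(rows)
  expect_equal(module_mean_profile(r, "a"), colMeans(r["a", , drop = FALSE]))
  expect_equal(unname(module_mean_profile(r, c("a", "b"))),
               rep(0, length(times)))
  expect_equal(module_mean_profile(r, c("a", "a")),
               module_mean_profile(r, "a"))
  expect_error(module_mean_profile(r, "missing"), "no module member")
})

test_that("smoothing reproduces constants and linear data, and shrinks noise", {
  times <- default_times
  const <- smooth_profile(times, rep(0.7, length(times)))
  expect_lt(max(abs(const$value - 0.7)), 1e-9)
  lin <- smooth_profile(times, times / 100, p = 1)
  expect_lt(max(abs(lin$value - lin$time / 100)), 1e-9)
  set.seed(3)
  noisy <- sin(times / 300) + rnorm(length(times), 0, 0.5)
  heavy <- smooth_profile(times, noisy, p = 1e-4)
  expect_lt(var(heavy$value[match(times, heavy$time)]), var(noisy))
})

test_that("dynamics classes follow the first crossing and the final level", {
  g <- seq(0, 2880, 60)
  mk <- function(v) structure(list(time = g, value = v, p = 1, id = NULL),
                              class = "smooth_profile")
  rise <- mk(2 / (1 + exp(-(g - 200) / 40)))
  pulse <- mk(2 * exp(-((g - 300) / 150)^2))
  flatp <- mk(0.9 * sin(g / 400))
  expect_equal(classify_dynamics(rise), list(dynamics = "monotonic", direction = "up"))
  expect_equal(classify_dynamics(pulse), list(dynamics = "transient", direction = "up"))
  drop <- mk(-2 / (1 + exp(-(g - 200) / 40)))
  expect_equal(classify_dynamics(drop)$direction, "down")
  expect_equal(classify_dynamics(flatp)$dynamics, "flat")
  expect_error(crossing_timestamp(flatp), "never crosses")
})

test_that("crossing timestamps are analytic for a linear ramp and monotone in threshold", {
  g <- seq(0, 120, 1)
  ramp <- structure(list(time = g, value = g / 30, p = 1, id = NULL),
                    class = "smooth_profile")
  expect_equal(crossing_timestamp(ramp, 1), 30)
  expect_equal(crossing_timestamp(ramp, 2), 60)
  step <- smooth_profile(seq(0, 100, 1), 2 * (seq(0, 100, 1) >= 45), p = 1)
  expect_lt(abs(crossing_timestamp(step, 1) - 45), 1)
  set.seed(5)
  for (i in 1:10) {
    v <- cumsum(abs(rnorm(100, 0.05)))
    sp <- structure(list(time = seq_along(v), value = v, p = 1, id = NULL),
                    class = "smooth_profile")
    expect_gte(crossing_timestamp(sp, 2), crossing_timestamp(sp, 1))
  }
})

test_that("stage labels reproduce the printed timestamp-to-stage pairs", {
  # regulator table anchors: 12 min -> early, 44 min (NRR1) -> mid,
  # 109 min (CGL107) -> late
  expect_equal(assign_stage(12), "early")
  expect_equal(assign_stage(44), "mid")
  expect_equal(assign_stage(109), "late")
  # closed upper boundaries and the beyond-8-h convention
  expect_equal(assign_stage(c(18, 19, 60, 61, 480, 2000)),
               c("early", "mid", "mid", "late", "late", "late"))
  expect_error(assign_stage(-1), "non-negative")
})

test_that("waves group by class, direction and quantized timestamp", {
  mt <- data.frame(module_id = c("A", "B", "C", "D"),
                   dynamics = c("monotonic", "monotonic", "transient", "monotonic"),
                   direction = c("up", "up", "up", "up"),
                   timestamp = c(24.3, 25.1, 24.3, 130),
                   stringsAsFactors = FALSE)
  g <- group_into_waves(mt, default_times)
  w <- setNames(g$wave_id, g$module_id)
  expect_equal(w[["A"]], w[["B"]])              # both quantize to 24 min
  expect_false(w[["A"]] == w[["C"]])            # class separates waves
  expect_false(w[["A"]] == w[["D"]])
  expect_equal(g$quantized_time[g$module_id == "A"], 24)
  expect_equal(g$quantized_time[g$module_id == "D"], 120)
  empty <- group_into_waves(mt[0, ], default_times)
  expect_equal(nrow(empty), 0)
})

test_that("planted wave classes and timestamps are recovered without noise", {
  sim <- simulate_expression(simulation_spec(sigma = 0, n_decoys = 0, seed = 21))
  ratios <- compute_log_ratios(sim$expr)
  res <- build_waves(ratios, sim$modules)
  m <- merge(res$modules, sim$truth$modules, by = "module_id")
  dyn <- m$dynamics.y != "flat"
  expect_equal(mean(m$dynamics.x[dyn] == m$dynamics.y[dyn]), 1)
  expect_equal(mean(m$direction.x[dyn] == m$direction.y[dyn]), 1)
  expect_lt(max(abs(m$timestamp.x[dyn] - m$timestamp.y[dyn])), 2)
  # waves partition the non-flat modules
  grouped <- res$modules[res$modules$dynamics != "flat", ]
  expect_true(all(!is.na(grouped$wave_id)))
  expect_equal(anyDuplicated(grouped$module_id), 0)
  # deterministic ordering
  expect_false(is.unsorted(res$waves$timestamp_min))
})
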