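gridded_logistic <- function(t0 = 120, s = 25, A = 2, g = seq(0, 1440, 1)) {
  A / (1 + exp(-(g - t0) / s))
}

test_that("max-abs normalization rescales and rejects degenerate profiles", {
  v <- c(-2, 1, 0.5)
  expect_equal(normalize_profile(v), v / 2)
  expect_equal(max(abs(normalize_profile(v))), 1)
  already <- c(0.2, -1, 0.4)
  expect_equal(normalize_profile(already), already)
  expect_error(normalize_profile(rep(0, 10)), "degenerate")
  sp <- smooth_profile(default_times, at_times(default_times, `120` = 2, `240` = 2))
  expect_equal(max(abs(normalize_profile(sp)$value)), 1)
})

test_that("lagged distance is zero for shifted copies and assigns signs", {
  g <- seq(0, 1440, 1)
  mod <- normalize_profile(gridded_logistic(t0 = 300, g = g))
  tr <- normalize_profile(gridded_logistic(t0 = 270, g = g))  # leads by 30 min
  hit <- lagged_distance(tr, mod, 30)
  expect_lt(hit$distance, 1e-9)
  expect_equal(hit$sign, "activation")
  anti <- lagged_distance(-tr, mod, 30)
  expect_lt(anti$distance, 1e-9)
  expect_equal(anti$sign, "repression")
  # the planted lag minimizes the distance over the whole scan (exhaustive)
  dists <- sapply(seq(15, 90, 15), function(l) lagged_distance(tr, mod, l)$distance)
  expect_equal(seq(15, 90, 15)[which.min(dists)], 30)
  expect_error(lagged_distance(tr, mod, 7.5), "multiple of grid_step")
  expect_error(lagged_distance(tr, mod, 1439), "insufficient overlap")
})

test_that("distance is symmetric under joint negation; sign flips under single negation", {
  set.seed(13)
  g <- seq(0, 720, 1)
  for (i in 1:5) {
    mod <- normalize_profile(smooth_profile(default_times,
      rnorm(length(default_times)), p = 1)$value[seq_along(g)])
    tr <- normalize_profile(smooth_profile(default_times,
      rnorm(length(default_times)), p = 1)$value[seq_along(g)])
    d1 <- lagged_distance(tr, mod, 30)
    d2 <- lagged_distance(-tr, -mod, 30)
    d3 <- lagged_distance(-tr, mod, 30)
    expect_equal(d1$distance, d2$distance)
    expect_equal(d1$sign, d2$sign)
    expect_equal(d1$distance, d3$distance)
    expect_false(d1$sign == d3$sign)
  }
})

test_that("best lag scans the window and honors its bounds", {
  g <- seq(0, 1440, 1)
  mod <- normalize_profile(gridded_logistic(t0 = 400, s = 30, g = g))
  tr45 <- normalize_profile(gridded_logistic(t0 = 355, s = 30, g = g))
  bl <- best_lag(tr45, mod)
  expect_equal(bl$lag, 45)
  expect_lt(bl$distance, 1e-9)
  # a 120-min shift lies outside the window: best in-window distance > 0
  tr120 <- normalize_profile(gridded_logistic(t0 = 280, s = 30, g = g))
  bl2 <- best_lag(tr120, mod)
  expect_gt(bl2$distance, 1e-3)
  # no shift at all: best in-window distance > 0 for a non-constant profile
  bl3 <- best_lag(mod, mod)
  expect_gt(bl3$distance, 1e-3)
})

test_that("inferred edges agree with the pairwise best-lag primitive", {
  set.seed(17)
  g <- seq(0, 1440, 1)
  mods <- list(ma = gridded_logistic(t0 = 300, g = g),
               mb = 2 * exp(-((g - 400) / 180)^2))
  trs <- list(ta = gridded_logistic(t0 = 270, g = g),
              tb = rnorm(length(g), 0, 0.1))
  e <- suppressWarnings(infer_influences(trs, mods, percentile = 100))
  bd <- attr(e, "best_distances")
  for (tr in names(trs)) for (mod in names(mods)) {
    ref <- best_lag(normalize_profile(trs[[tr]]), normalize_profile(mods[[mod]]))
    expect_equal(unname(bd[tr, mod]), ref$distance, tolerance = 1e-12)
  }
})

test_that("edge sets are invariant to relabeling and input order, and nested in the percentile", {
  sim <- simulate_expression(simulation_spec(sigma = 0.1, n_decoys = 0, seed = 31))
  ratios <- compute_log_ratios(sim$expr)
  t <- expr_times(ratios)
  res <- build_waves(ratios, sim$modules)
  nonflat <- res$modules$module_id[res$modules$dynamics != "flat"]
  hz <- which(res$profiles[[1]]$time <= 1440)
  trp <- lapply(sprintf("TR%02d", 1:10), function(id)
    smooth_profile(t, as.numeric(ratios[id, ]))$value[hz])
  names(trp) <- sprintf("TR%02d", 1:10)
  mp <- lapply(res$profiles[nonflat], function(p) p$value[hz])
  ev <- t[t <= 1440]
  e1 <- infer_influences(trp, mp, eval_times = ev)
  e2 <- infer_influences(trp, mp[rev(seq_along(mp))], eval_times = ev)
  expect_equal(e1, e2, ignore_attr = TRUE)
  relabeled <- trp
  names(relabeled) <- paste0("X", names(trp))
  e3 <- infer_influences(relabeled, mp, eval_times = ev)
  expect_equal(paste0("X", e1$tr_id), e3$tr_id)
  expect_equal(e1$distance, e3$distance)
  # nestedness in the percentile threshold
  e10 <- infer_influences(trp, mp, percentile = 10, eval_times = ev)
  expect_true(all(paste(e1$tr_id, e1$module_id) %in%
                  paste(e10$tr_id, e10$module_id)))
  # degenerate thresholds
  e0 <- infer_influences(trp, mp, percentile = 0, eval_times = ev)
  expect_equal(nrow(e0), 0)
  expect_equal(nrow(suppressWarnings(infer_influences(trp, list()))), 0)
})

test_that("degenerate regulator profiles are dropped with a warning", {
  g <- seq(0, 1440, 1)
  trs <- list(zero = rep(0, length(g)),
              live = gridded_logistic(g = g))
  mods <- list(m = gridded_logistic(t0 = 150, g = g))
  expect_warning(e <- infer_influences(trs, mods, percentile = 100),
                 "degenerate")
  expect_false("zero" %in% e$tr_id)
  w <- capture_warnings(infer_influences(list(z = rep(0, length(g))), mods))
  expect_true(any(grepl("no scorable", w)))
})
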