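test_that("log2 ratios follow the pseudocount formula exactly", {
  times <- default_times
  x <- matrix(50, 3, length(times), dimnames = list(c("a", "b", "c"), NULL))
  x["b", ] <- 1
  x["b", -1] <- 3                       # log2(4/2) = 1
  x["c", 1] <- 1500
  x["c", -1] <- 0                       # log2(1/1501), the CAH1-style collapse
  r <- compute_log_ratios(expression_matrix(x, times))
  expect_equal(unname(r["a", ]), rep(0, length(times)))
  expect_equal(unname(r["b", -1]), rep(1, length(times) - 1))
  expect_equal(unname(r["c", 2]), log2(1 / 1501))
  expect_equal(unname(r["c", 2]), -10.552, tolerance = 1e-4)
  expect_true(all(r[, 1] == 0))
})

test_that("log2 ratios match a per-element brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    expr <- random_expr(n = 15)
    r <- compute_log_ratios(expr)
    # independent elementwise loop
    oracle <- matrix(NA_real_, nrow(expr), ncol(expr))
    for (a in seq_len(nrow(expr))) {
      for (b in seq_len(ncol(expr))) {
        oracle[a, b] <- log2((expr[a, b] + 1) / (expr[a, 1] + 1))
      }
    }
    expect_lt(max(abs(unclass(r) - oracle)), 1e-12)
  }
})

test_that("invalid expression input is rejected", {
  times <- default_times
  x <- matrix(1, 2, length(times), dimnames = list(c("a", "b"), NULL))
  expect_error(expression_matrix(x, times - 1), "first time")
  xneg <- x; xneg[1, 3] <- -1
  expect_error(expression_matrix(xneg, times), "non-negative")
  xdup <- x; rownames(xdup) <- c("a", "a")
  expect_error(expression_matrix(xdup, times), "duplicate")
  expect_error(expression_matrix(x[, 1:2], times[1:2]), "3 timepoints")
})

test_that("retention rules fire as specified", {
  times <- default_times
  lip <- c("480", "720", "1440", "2880")
  rows <- list(
    null = at_times(times),
    rule1_both = at_times(times, `480` = 1.5, `720` = 1.5, `1440` = 1.5, `2880` = 1.5),
    rule1_only = at_times(times, `480` = 1.5, `720` = -1.5, `1440` = 1.5, `2880` = -1.5),
    rule2_run = at_times(times, `24` = 1.5, `30` = 1.5, `45` = 1.5, `60` = 1.5),
    rule2_short = at_times(times, `24` = 1.5, `30` = 1.5),     # span 6 < 30
    rule2_sign_flip = at_times(times, `24` = 1.5, `30` = -1.5, `45` = 1.5, `60` = -1.5),
    single_point = at_times(times, `120` = 5))
  rep <- filter_transcripts(make_ratios(rows))
  got <- setNames(rep$rule, rep$transcript_id)
  expect_equal(got[["null"]], "none")
  expect_equal(got[["rule1_both"]], "both")   # the lipid run itself spans >= 30 min
  expect_equal(got[["rule1_only"]], "1")      # alternating signs break rule 2
  expect_equal(got[["rule2_run"]], "2")       # span 36 min >= 30
  expect_equal(got[["rule2_short"]], "none")
  expect_equal(got[["rule2_sign_flip"]], "none")
  expect_equal(got[["single_point"]], "none") # isolated timepoint never qualifies
  expect_setequal(kept_transcripts(rep),
                  c("rule1_both", "rule1_only", "rule2_run"))
  fp <- setNames(rep$first_pass_time_min, rep$transcript_id)
  expect_equal(fp[["rule2_run"]], 24)
  expect_equal(fp[["rule1_only"]], 480)
})

test_that("lipid rule mode 'any' admits a single lipid timepoint", {
  times <- default_times
  rows <- list(one_lipid = at_times(times, `1440` = 1.5))
  strict <- filter_transcripts(make_ratios(rows), filter_config())
  loose <- filter_transcripts(make_ratios(rows),
                              filter_config(lipid_rule_mode = "any"))
  expect_false(strict$kept)
  expect_true(loose$kept)
})

test_that("filtering is monotone in the fold threshold", {
  set.seed(7)
  r <- compute_log_ratios(random_expr(n = 60))
  thresholds <- c(0.5, 1, 1.5, 2.5)
  kept_sets <- lapply(thresholds, function(th)
    kept_transcripts(filter_transcripts(r, filter_config(fold_threshold = th))))
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(kept_sets[[i]] %in% kept_sets[[i - 1]]))
  }
})

test_that("rule 2 is preserved under grid refinement", {
  curve <- function(t) 2 / (1 + exp(-(t - 40) / 8))   # crosses 1 near 40 min
  g1 <- default_times
  g2 <- sort(unique(c(g1, g1[-length(g1)] + diff(g1) / 2)))  # midpoint refinement
  for (g in list(g1, g2)) {
    rows <- list(x = curve(g) - curve(0))
    rep <- filter_transcripts(make_ratios(rows, g))
    expect_true(rep$kept, info = sprintf("grid of %d points", length(g)))
    expect_true(rep$rule %in% c("2", "both"))
  }
})

test_that("planted filter decisions are recovered perfectly without noise", {
  sim <- simulate_expression(simulation_spec(sigma = 0, n_decoys = 100, seed = 11))
  rep <- filter_transcripts(compute_log_ratios(sim$expr))
  truth <- sim$truth$transcripts
  m <- merge(rep, truth, by = "transcript_id")
  expect_equal(mean(m$kept.x == m$kept.y), 1)
  expect_equal(mean(m$rule.x == m$rule.y), 1)
})
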