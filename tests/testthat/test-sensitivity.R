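test_that("one-way analysis pairs endpoints and sorts by cost swing", {
  dsa <- run_dsa(base_params, std_lt)
  expect_equal(nrow(dsa), 2 * 13)
  counts <- table(dsa$parameter)
  expect_true(all(counts == 2))
  # sorted by swing, pairs kept together
  expect_true(all(diff(dsa$swing[seq(1, nrow(dsa), 2)]) <= 1e-9))
  expect_equal(dsa$swing[seq(1, nrow(dsa), 2)], dsa$swing[seq(2, nrow(dsa), 2)])
})

test_that("the published range endpoints produce exactly five zero-benefit scenarios", {
  dsa <- run_dsa(base_params, std_lt)
  zero <- dsa[abs(dsa$delta_qalys) < 1e-10, ]
  expect_equal(nrow(zero), 5)
  expect_setequal(
    paste(zero$parameter, zero$direction),
    c("hr_high_vs_low high",        # no effect of serum levels (HR = 1)
      "utility_dfs low",            # utilities equal at 0.73
      "utility_rd high",            # utilities equal at 0.80
      "p_high_start high",          # everyone already adequate (0.94)
      "p_high_after_escalation low" # nobody improves after escalation (0.76)
    )
  )
  expect_true(all(is.na(zero$icer)))
  # testing is still paid for; the utility scenarios keep their cost savings
  # (occupancy still shifts), the exposure scenarios do not
  structural <- zero$parameter %in% c("hr_high_vs_low", "p_high_start",
                                      "p_high_after_escalation")
  expect_true(all(zero$delta_cost[structural] > 0))
  expect_true(all(zero$delta_cost[!structural] < 0))
  # no scenario is both more effective and more costly
  pos <- dsa[dsa$delta_qalys > 1e-10, ]
  expect_true(all(pos$icer < 0))
})

test_that("PSA draws honour their distributions, truncation and the seed", {
  n <- 4000
  d1 <- sample_psa(base_params, n, seed = 123)
  d2 <- sample_psa(base_params, n, seed = 123)
  expect_identical(d1, d2)
  expect_false(identical(d1$hr_high_vs_low,
                         sample_psa(base_params, n, seed = 124)$hr_high_vs_low))

  expect_true(all(d1$hr_high_vs_low <= 1))
  expect_true(all(d1$utility_rd <= d1$utility_dfs))
  expect_true(all(d1$p_high_start >= 0 & d1$p_high_start <= 1))
  expect_true(all(d1$p_high_after_escalation >= 0 &
                    d1$p_high_after_escalation <= 1))
  expect_true(all(d1[c("cost_dfs_annual", "cost_rd_annual",
                       "cost_death_once", "cost_test")] >= 0))

  # beta(14.8, 4.7) mean 0.759, sd 0.0945 -> 3-sigma band for the mean
  expect_lt(abs(mean(d1$p_high_start) - 14.8 / 19.5), 3 * 0.0945 / sqrt(n))
  # mass clipped at HR 1 ~ upper normal tail of 0.301/0.153
  p_clip <- pnorm(0.301 / 0.153, lower.tail = FALSE)
  expect_lt(abs(mean(d1$hr_clipped) - p_clip),
            3 * sqrt(p_clip * (1 - p_clip) / n))
})

test_that("survival pairs are drawn jointly through the requested correlation", {
  d <- sample_psa(base_params, 4000, seed = 5, survival_correlation = 0.9)
  expect_lt(abs(cor(d$dfs_low_intercept, d$dfs_low_log_scale) - 0.9), 0.05)
  expect_lt(abs(cor(d$bcmort_intercept, d$bcmort_log_scale) - 0.9), 0.05)
  d0 <- sample_psa(base_params, 4000, seed = 5)
  expect_lt(abs(cor(d0$dfs_low_intercept, d0$dfs_low_log_scale)), 0.06)
  # drawn SEs match the published ranges: sd ~ (high - low)/3.92
  expect_lt(abs(sd(d0$dfs_low_intercept) - (3.37 - 3.20) / 3.92), 0.005)
  expect_error(
    sample_psa(base_params, 10, seed = 1,
               survival_correlation = list(dfs = matrix(c(1, 2, 2, 1), 2))),
    class = "tdm_argument_error"
  )
})

test_that("the PSA is reproducible and its CEAC follows the NMB geometry", {
  d <- sample_psa(base_params, 150, seed = 9)
  psa1 <- run_psa(base_params, d, std_lt, wtp_grid = c(0, 20000, 80000))
  psa2 <- run_psa(base_params, d, std_lt, wtp_grid = c(0, 20000, 80000))
  expect_identical(psa1$trials, psa2$trials)
  expect_identical(psa1$ceac, psa2$ceac)

  # CEAC at any wtp equals the fraction of trials left of the wtp ray,
  # recomputed independently from the per-trial cloud
  for (i in seq_along(psa1$wtp_grid)) {
    w <- psa1$wtp_grid[i]
    expect_equal(psa1$ceac$probability[i],
                 mean(w * psa1$trials$delta_qalys - psa1$trials$delta_cost > 0))
  }
  expect_equal(psa1$ceac$probability[1], mean(psa1$trials$delta_cost < 0))
  expect_true(all(psa1$ceac$probability >= 0 & psa1$ceac$probability <= 1))
  expect_error(run_psa(base_params, d, std_lt, wtp_grid = numeric()),
               class = "tdm_argument_error")
})

test_that("constructed draws pin the CEAC at its extremes", {
  d <- sample_psa(base_params, 6, seed = 1)
  # force a clear benefit in every trial
  d$hr_high_vs_low <- 0.6
  d$p_high_start <- 0.7
  d$p_high_after_escalation <- 0.95
  d$utility_dfs <- 0.85
  d$utility_rd <- 0.7
  d$cost_rd_annual <- 20000
  d$cost_dfs_annual <- 2000
  psa <- run_psa(base_params, d, std_lt, wtp_grid = c(0, 50000))
  expect_equal(psa$ceac$probability, c(1, 1))
  # and no benefit at all: positive test costs, zero QALY gain
  d$hr_high_vs_low <- 1
  psa0 <- run_psa(base_params, d, std_lt, wtp_grid = c(0, 50000))
  expect_equal(psa0$ceac$probability, c(0, 0))
  expect_true(all(psa0$trials$delta_cost > 0))
})

test_that("zero-QALY trials are exactly the clipped or non-converting draws", {
  d <- sample_psa(base_params, 400, seed = 77)
  psa <- run_psa(base_params, d, std_lt, wtp_grid = 20000)
  no_benefit <- abs(psa$trials$delta_qalys) < 1e-10
  clipped <- d$hr_clipped | d$utility_rd_clipped | d$conversion_clipped
  expect_identical(no_benefit, clipped)
})

test_that("tidy and glance expose the PSA cloud", {
  d <- sample_psa(base_params, 50, seed = 3)
  psa <- run_psa(base_params, d, std_lt, wtp_grid = c(0, 20000))
  expect_identical(tidy(psa), psa$trials)
  g <- glance(psa)
  expect_equal(g$n_trials, 50)
  expect_equal(g$prob_cost_saving, mean(psa$trials$delta_cost < 0))
})
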