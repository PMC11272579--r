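test_that("the progress likelihood-ratio test is calibrated and powered", {
  # null: abandonment depends on sv only; progress is an independent draw
  set.seed(51)
  rejections <- 0
  for (i in 1:60) {
    sv <- rnorm(800, 0, 3)
    d <- data.frame(abandon = rbinom(800, 1, plogis(-1 + sv)),
                    sv_tree_search = sv, progress = runif(800))
    res <- progress_bias_test(d)
    expect_gte(res$chi2, 0)
    if (res$p < 0.05) rejections <- rejections + 1
  }
  # 60 null repeats at alpha = .05: binomial 99% upper bound
  expect_lte(rejections, qbinom(0.995, 60, 0.05))
  # alternative: progress directly suppresses abandonment
  set.seed(52)
  sv <- rnorm(2000, 0, 3)
  pr <- runif(2000)
  d1 <- data.frame(abandon = rbinom(2000, 1, plogis(-0.5 + sv - 2.5 * pr)),
                   sv_tree_search = sv, progress = pr)
  res1 <- progress_bias_test(d1)
  expect_lt(res1$p, 0.05)
  expect_lt(res1$b_progress, 0)
})

test_that("attention analysis recovers status differences and slopes", {
  sch <- small_schedule(n_blocks = 10, n_trials = 40, seed = 53)
  cfg <- ts_config(n_rollouts = 20)
  set.seed(54)
  coh <- gen_cohort(cohort_hyperparams(n = 8))
  log <- simulate_cohort_decisions(coh, sch, cfg, max_trials = 150)
  sp <- simulate_cohort_attention(coh, log)
  res <- attention_analysis(sp)
  expect_equal(nrow(res$per_participant), 8)
  # goal advantage: positive mean attention bias, negative goal slope
  expect_gt(mean(res$per_participant$atten_bias), 0)
  expect_lt(mean(res$per_participant$slope_goal),
            mean(res$per_participant$slope_alt))
  expect_gt(mean(res$per_participant$mean_rt_alt),
            mean(res$per_participant$mean_rt_goal))
  # error metric equals the recomputed Euclidean distance
  expect_equal(sp$error, sqrt((sp$reported_x - sp$true_x)^2 +
                              (sp$reported_y - sp$true_y)^2))
})

test_that("bias correlation reports rho, p and a Fisher interval", {
  set.seed(55)
  x <- rnorm(40)
  expect_equal(bias_correlation(x, x)$rho, 1)
  coh <- gen_cohort(cohort_hyperparams(n = 200, target_rho = 0.5))
  res <- bias_correlation(coh$atten_bias, coh$ip_bias)
  expect_gt(res$rho, 0.3)
  expect_lt(res$p, 0.001)
  expect_true(res$ci[1] < res$rho && res$rho < res$ci[2])
  expect_error(bias_correlation(rep(1, 10), rnorm(10)), "ties")
  expect_error(bias_correlation(rnorm(4), rnorm(4)), ">= 5")
})

test_that("performance is mean trials per completed net", {
  log <- data.frame(block = rep(1:3, times = c(4, 6, 8)),
                    block_trial = c(1:4, 1:6, 1:8),
                    completed = FALSE)
  log$completed[cumsum(c(4, 6, 8))] <- TRUE
  expect_equal(performance_metric(log), 6)
  # incomplete trailing block is excluded
  log2 <- rbind(log, data.frame(block = 4, block_trial = 1:3,
                                completed = FALSE))
  expect_equal(performance_metric(log2), 6)
  expect_gte(performance_metric(log), 1)
  expect_error(performance_metric(log[!log$completed, ]), "undefined")
})

test_that("permutation mean tests behave at the extremes and under the null", {
  set.seed(56)
  a <- rnorm(8, 100)
  b <- rnorm(8, 0)
  res <- perm_test_means(a, b, n_perm = 999, side = "greater")
  expect_equal(res$p, 1 / 1000)  # add-one convention at the extreme
  two <- perm_test_means(a, b, n_perm = 999, side = "two.sided")
  expect_gte(two$p, res$p)
  expect_warning(perm_test_means(a, b, n_perm = 50), "coarse")
  # null calibration
  set.seed(57)
  rej <- 0
  for (i in 1:100) {
    g1 <- rnorm(10)
    g2 <- rnorm(10)
    if (perm_test_means(g1, g2, n_perm = 200, side = "greater")$p < 0.05) {
      rej <- rej + 1
    }
  }
  expect_lte(rej, qbinom(0.995, 100, 0.05))
  expect_gte(rej, qbinom(0.005, 100, 0.05))
  expect_error(perm_test_means(numeric(0), b), "empty")
})

test_that("value-by-progress fits are invariant to alternative relabeling", {
  fix <- small_cohort_dataset(n = 5, max_trials = 120, seed = 58)
  res <- value_progress_interaction(fix$dataset)
  expect_true(all(c("b_altval_x_progress", "b_goalval_x_progress") %in%
                  names(res$per_participant)))
  # relabel goods B <-> C throughout the log: sv and values are unchanged
  log2 <- fix$log
  map <- c(A = "A", B = "C", C = "B")
  log2$choice <- unname(map[log2$choice])
  log2$current_good <- ifelse(is.na(log2$current_good), NA,
                              unname(map[log2$current_good]))
  tmpB <- log2$offer_B
  log2$offer_B <- log2$offer_C
  log2$offer_C <- tmpB
  set.seed(59)
  ds_a <- build_dataset(fix$log, ts_config(n_rollouts = 5))
  set.seed(59)
  ds_b <- build_dataset(log2, ts_config(n_rollouts = 5))
  expect_equal(ds_a$sv_offer_max, ds_b$sv_offer_max)
  expect_equal(ds_a$sv_myopic, ds_b$sv_myopic)
  expect_equal(ds_a$sv_prospective, ds_b$sv_prospective)
  expect_equal(ds_a$abandon, ds_b$abandon)
})
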