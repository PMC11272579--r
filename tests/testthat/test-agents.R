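state_with <- function(net, offers, acc, goal = "A") {
  task_state(net, offers, accumulated = acc, current_good = goal,
             trial_index = 2, trials_invested = 1)
}

test_that("offer-max values equal raw offers regardless of net contents", {
  s1 <- state_with(20, c(5, 2, 7), 0)
  s2 <- state_with(20, c(5, 2, 7), 15)
  expect_equal(unname(offer_max_values(s1)$values), c(5, 2, 7))
  expect_equal(offer_max_values(s1)$values, offer_max_values(s2)$values)
  expect_equal(unname(offer_max_values(state_with(20, c(-1, -1, -1), 3))$values),
               c(-1, -1, -1))
  expect_equal(offer_max_values(s1)$sv_abandon, 7 - 5)
})

test_that("myopic values add accumulated contents to the goal", {
  s <- state_with(40, c(4, 12, 3), 10)
  v <- myopic_values(s)
  expect_equal(unname(v$values), c(14, 12, 3))
  expect_equal(v$sv_abandon, -2)  # greedy persists
  s2 <- state_with(40, c(4, 9, 1), 2)
  expect_equal(myopic_values(s2)$sv_abandon, 3)  # greedy abandons
  # empty net: same ranking as offer-max
  s3 <- state_with(40, c(4, 9, 1), 0)
  expect_equal(order(myopic_values(s3)$values), order(offer_max_values(s3)$values))
  st1 <- task_state(40, c(1, 2, 3))
  expect_error(myopic_values(st1), "current goal")
})

test_that("prospective values are proportions with the negative-offer rules", {
  s <- state_with(20, c(5, 8, 1), 10)
  v <- prospective_values(s)
  expect_equal(v$values[["A"]], 5 / 10)     # offer / remaining net
  expect_equal(v$values[["B"]], 8 / 20)     # offer / whole net
  expect_equal(v$sv_abandon, 0.4 - 0.5)
  # negative goal offer: proportion of progress lost
  sneg <- state_with(20, c(-4, 8, 1), 10)
  expect_equal(prospective_values(sneg)$values[["A"]], -0.4)
  # negative alternative offer: raw
  salt <- state_with(20, c(5, -3, 1), 10)
  expect_equal(prospective_values(salt)$values[["B"]], -3)
  # negative goal offer with empty net: worth 0 (nothing can be lost)
  s0 <- state_with(20, c(-4, 8, 1), 0)
  expect_equal(prospective_values(s0)$values[["A"]], 0)
})

test_that("tree-search values equal the closed form when offers are frozen", {
  cfg <- ts_config(n_rollouts = 3, params = frozen_params())
  set.seed(21)
  for (i in 1:20) {
    net <- round(runif(1, 10, 60))
    acc <- runif(1, 0, net - 1)
    offers <- round(runif(3, 1, 9), 2)
    st <- state_with(net, offers, acc, goal = "A")
    v <- tree_search_values(st, cfg)$values
    expect_equal(v[["A"]], -ceiling((net - acc) / offers[1]))
    expect_equal(v[["B"]], -ceiling(net / offers[2]))
    expect_equal(v[["C"]], -ceiling(net / offers[3]))
  }
})

test_that("tree-search values are censored at the horizon and symmetric", {
  cfg <- ts_config(n_rollouts = 400, max_horizon = 50)
  set.seed(22)
  st <- task_state(60, c(4, 4, 4))  # trial 1, empty net, equal offers
  v <- tree_search_values(st, cfg)$values
  expect_true(all(v >= -50))
  expect_lt(max(v) - min(v), 1.5)  # symmetric state, Monte-Carlo error only
  # impossible net: every rollout censors
  stbad <- task_state(1e6, c(-5, -5, -5))
  vbad <- tree_search_values(stbad, ts_config(n_rollouts = 5, max_horizon = 30,
                                              params = frozen_params()))$values
  expect_equal(unname(vbad), rep(-30, 3))
})

test_that("raising the goal offer weakly decreases sv_abandon in every model", {
  set.seed(23)
  cfg <- ts_config(n_rollouts = 200)
  for (i in 1:5) {
    net <- round(runif(1, 20, 60))
    acc <- runif(1, 0, net / 2)
    base <- runif(3, 2, 8)
    lo <- state_with(net, base, acc)
    hi_off <- base + c(2, 0, 0)
    hi <- state_with(net, hi_off, acc)
    for (fn in list(offer_max_values, myopic_values, prospective_values)) {
      expect_lte(fn(hi)$sv_abandon, fn(lo)$sv_abandon)
    }
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    sv_lo <- tree_search_values(lo, cfg)$sv_abandon
    set.seed(seed)
    sv_hi <- tree_search_values(hi, cfg)$sv_abandon
    # Monte-Carlo estimates: allow noise at the rollout-mean s.e. scale
    expect_lte(sv_hi, sv_lo + 0.3)
  }
})

test_that("Monte-Carlo values converge with rollout count", {
  st <- state_with(12, c(8, 9, 8), 6)
  set.seed(24)
  v1 <- tree_search_values(st, ts_config(n_rollouts = 1000))$values
  v2 <- tree_search_values(st, ts_config(n_rollouts = 10000))$values
  expect_lt(max(abs(v1 - v2)), 0.2)
})

test_that("greedy offer-max always takes the largest offer", {
  sch <- small_schedule(n_blocks = 3, n_trials = 30, seed = 25)
  set.seed(26)
  log <- simulate_agent(sch, model = "offer_max", policy = "greedy")
  offers <- as.matrix(log[, c("offer_A", "offer_B", "offer_C")])
  expect_equal(log$choice, c("A", "B", "C")[max.col(offers, "first")])
})

test_that("a steep softmax reproduces greedy choices", {
  sch <- small_schedule(n_blocks = 3, n_trials = 30, seed = 27)
  set.seed(28)
  greedy <- simulate_agent(sch, model = "myopic", policy = "greedy")
  set.seed(28)
  steep <- simulate_agent(sch, model = "myopic", policy = c(0, 60))
  expect_equal(steep$choice, greedy$choice)
})

test_that("agent simulation is deterministic under a seed", {
  sch <- small_schedule(n_blocks = 2, n_trials = 25, seed = 29)
  cfg <- ts_config(n_rollouts = 20)
  set.seed(30)
  a <- simulate_agent(sch, model = "tree_search", policy = c(-1, 1), cfg = cfg)
  set.seed(30)
  b <- simulate_agent(sch, model = "tree_search", policy = c(-1, 1), cfg = cfg)
  expect_identical(a, b)
  expect_error(simulate_agent(sch, model = "tree_search", policy = "argmax"),
               "policy")
})
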