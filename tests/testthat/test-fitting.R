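test_that("the dataset builder reproduces abandonment and trial counts", {
  sch <- small_schedule(n_blocks = 5, n_trials = 40, seed = 41)
  set.seed(42)
  log <- simulate_agent(sch, model = "offer_max", policy = "greedy")
  ds <- build_dataset(log, ts_config(n_rollouts = 10), schedule = sch)
  # non-first trials only: one row fewer than trials per block entered
  expect_equal(nrow(ds), nrow(log) - length(unique(paste(log$block))))
  # greedy offer-max abandons exactly when the goal lacks the max offer
  offers <- as.matrix(log[, c("offer_A", "offer_B", "offer_C")])
  lacks_max <- c("A", "B", "C")[max.col(offers, "first")] != log$current_good
  expect_equal(ds$abandon, as.integer(lacks_max[!is.na(log$current_good)]))
  expect_true(all(ds$sv_offer_max[ds$abandon == 1] >= 0))
  # a never-switching agent yields all-zero abandonment
  set.seed(43)
  stay <- simulate_agent(sch, model = "offer_max", policy = c(-50, 0))
  ds_stay <- build_dataset(stay, ts_config(n_rollouts = 5))
  expect_true(all(ds_stay$abandon == 0))
  # tampered offers are a data-integrity error
  bad <- log
  bad$offer_A <- bad$offer_A + 1
  expect_error(build_dataset(bad, ts_config(n_rollouts = 5), schedule = sch),
               "match")
})

test_that("logistic fitting recovers known coefficients and matches glm", {
  set.seed(44)
  sv <- rnorm(1e4, 0, 3)
  y <- rbinom(1e4, 1, plogis(-2 + 1 * sv))
  d <- data.frame(abandon = y, sv_tree_search = sv)
  f <- fit_persistence(d)
  expect_true(f$converged)
  expect_lt(abs(f$beta0 - (-2)), 0.15)
  expect_lt(abs(f$beta1 - 1), 0.15)
  # independent route: glm maximum likelihood agrees to the ridge scale
  g <- glm(y ~ sv, binomial())
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-4)
})

test_that("degenerate fits are flagged", {
  d_const <- data.frame(abandon = rep(0, 50), sv_tree_search = rnorm(50))
  expect_warning(f <- fit_persistence(d_const), "separation")
  expect_false(f$converged)
  d_sv0 <- data.frame(abandon = rbinom(50, 1, 0.5), sv_tree_search = 0)
  expect_warning(f2 <- fit_persistence(d_sv0), "degenerate")
  expect_false(f2$converged)
})

test_that("indifference points follow -beta0/beta1 and scale equivariance", {
  f <- structure(list(beta0 = -2, beta1 = 1), class = "persistence_fit")
  expect_equal(indifference_point(f), 2)
  f0 <- structure(list(beta0 = 0, beta1 = 2), class = "persistence_fit")
  expect_equal(indifference_point(f0), 0)
  expect_error(indifference_point(structure(list(beta0 = 1, beta1 = 1e-9),
                                            class = "persistence_fit")),
               "undefined")
  set.seed(45)
  sv <- rnorm(2000, 1, 2)
  y <- rbinom(2000, 1, plogis(-1.5 + 0.8 * sv))
  fit <- fit_persistence(data.frame(abandon = y, sv_tree_search = sv))
  # P(abandon) at the IP is exactly one half
  expect_equal(predict(fit, indifference_point(fit)), 0.5, tolerance = 1e-6)
  # rescaling sv by c rescales beta1 by 1/c and the IP by c
  c_scale <- 4
  fit_s <- fit_persistence(data.frame(abandon = y, sv_tree_search = sv * c_scale))
  expect_equal(fit_s$beta1 * c_scale, fit$beta1, tolerance = 1e-3)
  expect_equal(indifference_point(fit_s) / c_scale, indifference_point(fit),
               tolerance = 1e-3)
})

test_that("IRLS matches a brute-force likelihood grid on a small dataset", {
  set.seed(46)
  sv <- rnorm(50, 0, 2)
  y <- rbinom(50, 1, plogis(-1 + 0.7 * sv))
  d <- data.frame(abandon = y, sv_tree_search = sv)
  f <- fit_persistence(d)
  lam <- 1e-4
  pen_ll <- function(b0, b1) {
    eta <- b0 + b1 * sv
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      lam / 2 * (b0^2 + b1^2)
  }
  grid <- expand.grid(b0 = seq(-3, 1, by = 0.01), b1 = seq(-1, 2.5, by = 0.01))
  ll <- mapply(pen_ll, grid$b0, grid$b1)
  best <- grid[which.max(ll), ]
  expect_lt(abs(f$beta0 - best$b0), 0.011)
  expect_lt(abs(f$beta1 - best$b1), 0.011)
})

test_that("leave-one-out comparison is bounded and rewards true structure", {
  set.seed(47)
  # synthetic multi-participant dataset straight from the logistic rule
  make_pid <- function(pid, beta0, beta1) {
    sv <- rnorm(150, 0, 3)
    data.frame(pid = pid, abandon = rbinom(150, 1, plogis(beta0 + beta1 * sv)),
               sv_tree_search = sv, sv_offer_max = rnorm(150))
  }
  ds <- do.call(rbind, lapply(1:6, function(p) make_pid(p, -1.5, 1)))
  cv <- loo_cv_compare(ds, models = c("offer_max", "tree_search"))
  expect_true(all(as.matrix(cv$accuracy[, -1]) >= 0 &
                  as.matrix(cv$accuracy[, -1]) <= 1))
  expect_equal(cv$winner, "tree_search")
  # an all-persist participant predicted at ~0 scores accuracy ~1
  stay <- data.frame(pid = 99, abandon = 0,
                     sv_tree_search = rnorm(100, -8, 1),
                     sv_offer_max = rnorm(100, -8, 1))
  cv2 <- loo_cv_compare(rbind(ds, stay), models = c("tree_search"))
  acc99 <- cv2$accuracy[cv2$accuracy$pid == 99, "tree_search"]
  expect_gt(acc99, 0.95)
  expect_error(loo_cv_compare(ds[ds$pid == 1, ]), ">= 2")
})

test_that("persistence-fit methods print, predict and summarize", {
  set.seed(48)
  sv <- rnorm(400, 0, 2)
  y <- rbinom(400, 1, plogis(-1 + sv))
  d <- data.frame(abandon = y, sv_tree_search = sv)
  f <- fit_persistence(d)
  expect_output(print(f), "indifference point", ignore.case = TRUE)
  s <- summary(f)
  expect_output(print(s), "Std. Error")
  expect_equal(predict(f, d), plogis(f$beta0 + f$beta1 * sv))
  expect_silent(grDevices::pdf(NULL))
  plot(f, data = d)
  grDevices::dev.off()
})
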