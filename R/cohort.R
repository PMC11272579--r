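#' Cohort hyperparameters for synthetic participants
#'
#' Population-level settings from which [gen_cohort()] draws participant
#' profiles. Persistence bias (`ip_*`) is in units of tree-search abandonment
#' value (trials); inverse temperature is log-normal; `target_rho` is the
#' across-participant Spearman correlation between the attention-bias and
#' persistence-bias parameters, induced through a shared Gaussian latent
#' factor. Attenuation parameters scale how strongly goal progress mutes the
#' influence of each value source on choice, with alternative value attenuated
#' more than current-goal value on average. Spatial parameters are in
#' normalized screen units; reaction times in seconds.
#'
#' @param n Number of participants (>= 2).
#' @param ip_mean,ip_sd Persistence-bias population mean and s.d.
#' @param inv_temp_log_mean,inv_temp_log_sd Log-scale parameters of the
#'   inverse-temperature distribution.
#' @param target_rho Target Spearman correlation between attention bias and
#'   persistence bias, in (-1, 1).
#' @param atten_cur_mean,atten_alt_mean,atten_sd Means and s.d. of the
#'   progress-attenuation slopes for the current-goal and alternative value
#'   weights (clamped to `[0, 1]`).
#' @param atten_bias_mean,atten_bias_sd Population distribution of the
#'   attention-bias parameter (expected spatial-error advantage for the goal
#'   stimulus, screen units).
#' @param sp_base_sd Baseline spatial report noise s.d. (screen units).
#' @param sp_floor Minimum report noise s.d.
#' @param sp_goal_slope_mean,sp_goal_slope_sd Per-trial-invested change in the
#'   goal-stimulus report s.d. (clamped <= 0).
#' @param sp_alt_slope_sd S.d. of the alternative-stimulus slope (mean 0).
#' @param rt_log_mean,rt_log_sd Log-normal reaction-time parameters.
#' @param rt_goal_shift_mean,rt_goal_shift_sd Additive RT shift for the goal
#'   stimulus (clamped <= 0), seconds.
#' @return An object of class `cohort_hyperparams`.
#' @export
cohort_hyperparams <- function(n = 30, ip_mean = 3, ip_sd = 1.5,
                               inv_temp_log_mean = log(0.75),
                               inv_temp_log_sd = 0.5,
                               target_rho = 0.5,
                               atten_cur_mean = 0.3, atten_alt_mean = 0.6,
                               atten_sd = 0.1,
                               atten_bias_mean = 0.04, atten_bias_sd = 0.02,
                               sp_base_sd = 0.12, sp_floor = 0.02,
                               sp_goal_slope_mean = -0.008,
                               sp_goal_slope_sd = 0.003,
                               sp_alt_slope_sd = 0.002,
                               rt_log_mean = log(0.9), rt_log_sd = 0.3,
                               rt_goal_shift_mean = -0.08,
                               rt_goal_shift_sd = 0.03) {
  stopifnot(n >= 2, abs(target_rho) < 1, ip_sd >= 0, sp_base_sd > 0,
            sp_floor > 0)
  structure(as.list(environment()), class = "cohort_hyperparams")
}

#' Generate a cohort of synthetic participant profiles
#'
#' Persistence bias and the attention-bias parameter both load on a shared
#' standard-normal latent factor (a Gaussian copula), so their induced
#' across-participant Spearman correlation approximates `h$target_rho`; the
#' Pearson loading is `2*sin(pi*rho_s/6)`, the inverse of the
#' bivariate-normal rank-correlation map. Inverse temperature is log-normal
#' and independent of the latent factor; attenuation slopes are truncated
#' normals with the alternative slope larger in expectation.
#'
#' @param h A [cohort_hyperparams()] object.
#' @return A data frame of class `gp_cohort`, one row per participant.
#' @export
gen_cohort <- function(h = cohort_hyperparams()) {
  stopifnot(inherits(h, "cohort_hyperparams"))
  n <- h$n
  r_pearson <- 2 * sin(pi * h$target_rho / 6)
  lam <- sqrt(abs(r_pearson))
  z <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  g_ip <- lam * z + sqrt(1 - lam^2) * e1
  g_at <- sign(r_pearson) * lam * z + sqrt(1 - lam^2) * e2
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  out <- data.frame(
    pid = seq_len(n),
    ip_bias = h$ip_mean + h$ip_sd * g_ip,
    inv_temp = exp(stats::rnorm(n, h$inv_temp_log_mean, h$inv_temp_log_sd)),
    atten_cur = clamp(stats::rnorm(n, h$atten_cur_mean, h$atten_sd), 0, 1),
    atten_alt = clamp(stats::rnorm(n, h$atten_alt_mean, h$atten_sd), 0, 1),
    atten_bias = h$atten_bias_mean + h$atten_bias_sd * g_at,
    sp_base_sd = h$sp_base_sd,
    sp_goal_slope = pmin(0, stats::rnorm(n, h$sp_goal_slope_mean,
                                         h$sp_goal_slope_sd)),
    sp_alt_slope = stats::rnorm(n, 0, h$sp_alt_slope_sd),
    rt_goal_shift = pmin(0, stats::rnorm(n, h$rt_goal_shift_mean,
                                         h$rt_goal_shift_sd)),
    latent_z = z
  )
  attr(out, "hyperparams") <- h
  class(out) <- c("gp_cohort", "data.frame")
  out
}

#' Simulate one participant's choices
#'
#' Plays the schedule with the stochastic tree-search choice model. On each
#' non-first trial the planner's current-goal and best-alternative values are
#' computed, goal progress `p = accumulated / net_size` attenuates each value
#' weight, and the participant abandons with probability
#' `plogis(inv_temp * ((1 - atten_alt*p) * V_altbest
#'                     - (1 - atten_cur*p) * V_goal - ip_bias))`,
#' switching to the best alternative when abandoning. A block's first trial
#' is a greedy fresh choice.
#'
#' @param profile One row of a [gen_cohort()] data frame (or a list with the
#'   same fields).
#' @param schedule A [gen_schedule()] schedule.
#' @param ts_cfg A [ts_config()].
#' @param max_trials Session horizon (trials); defaults to the whole schedule.
#' @return A `gp_choices` data frame (see [simulate_agent()]).
#' @export
simulate_decisions <- function(profile, schedule, ts_cfg = ts_config(),
                               max_trials = NULL) {
  g_trial <- 0L
  rows <- vector("list", 512)
  n_row <- 0L
  for (b in seq_along(schedule$blocks)) {
    blk <- schedule$blocks[[b]]
    state <- task_state(blk$net_size, blk$offers[1, ], block_id = blk$block_id)
    for (bt in seq_len(nrow(blk$offers))) {
      if (!is.null(max_trials) && g_trial >= max_trials) break
      g_trial <- g_trial + 1L
      state$offers <- stats::setNames(blk$offers[bt, ], c("A", "B", "C"))
      state$trial_index <- bt
      val <- tree_search_values(state, ts_cfg)
      first <- is.na(state$current_good)
      if (first) {
        choice <- greedy_pick(val$values)
        sv <- NA_real_
      } else {
        p <- state$accumulated / state$net_size
        v_goal <- val$values[[state$current_good]]
        alts <- setdiff(c("A", "B", "C"), state$current_good)
        v_alt <- max(val$values[alts])
        sv <- profile$inv_temp *
          ((1 - profile$atten_alt * p) * v_alt -
           (1 - profile$atten_cur * p) * v_goal - profile$ip_bias)
        if (stats::runif(1) < stats::plogis(sv)) {
          choice <- alts[which.max(val$values[alts])]
        } else {
          choice <- state$current_good
        }
      }
      nxt <- apply_choice(state, choice)
      n_row <- n_row + 1L
      if (n_row > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[n_row]] <- data.frame(
        participant = profile$pid, block = blk$block_id, block_trial = bt,
        trial = g_trial, net_size = state$net_size,
        accumulated = state$accumulated,
        current_good = state$current_good,
        trials_invested = state$trials_invested,
        offer_A = state$offers[[1]], offer_B = state$offers[[2]],
        offer_C = state$offers[[3]], choice = choice,
        abandon = if (first) NA else as.integer(choice != state$current_good),
        V_goal = if (first) NA_real_ else val$values[[state$current_good]],
        V_altbest = if (first) NA_real_ else
          max(val$values[setdiff(c("A", "B", "C"), state$current_good)]),
        completed = nxt$completed, model = "tree_search",
        stringsAsFactors = FALSE)
      if (nxt$completed) break
      state <- nxt
    }
    if (!is.null(max_trials) && g_trial >= max_trials) break
  }
  out <- do.call(rbind, rows[seq_len(n_row)])
  class(out) <- c("gp_choices", "data.frame")
  attr(out, "model") <- "tree_search"
  attr(out, "policy") <- "participant"
  out
}

#' Simulate the whole cohort's choice data
#'
#' Convenience wrapper running [simulate_decisions()] for every profile and
#' row-binding the logs.
#'
#' @param cohort A [gen_cohort()] data frame.
#' @param schedule,ts_cfg,max_trials Passed to [simulate_decisions()].
#' @return A `gp_choices` data frame covering all participants.
#' @export
simulate_cohort_decisions <- function(cohort, schedule, ts_cfg = ts_config(),
                                      max_trials = NULL) {
  logs <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_decisions(cohort[i, ], schedule, ts_cfg, max_trials)
  })
  out <- do.call(rbind, logs)
  class(out) <- c("gp_choices", "data.frame")
  out
}

#' Simulate the interleaved spatial-attention task
#'
#' For every decision trial the three stimuli flash at uniform random screen
#' locations and are each probed; the reported location is the true location
#' plus isotropic Gaussian noise. The goal stimulus's noise s.d. starts below
#' baseline by the participant's attention bias (converted from a mean-error
#' advantage via the Rayleigh factor `sqrt(pi/2)`) and shrinks further with
#' trials invested (`sp_goal_slope`); alternative stimuli use the baseline
#' s.d. and `sp_alt_slope`. All s.d.s are floored at `sp_floor`. Reaction
#' times are log-normal with an additive negative shift for the goal
#' stimulus. First trials of blocks carry `NA` status (no goal yet) and are
#' excluded by [attention_analysis()].
#'
#' @param profile One row of a [gen_cohort()] data frame.
#' @param choice_log The participant's `gp_choices` log.
#' @return A data frame of class `gp_spatial`, three rows (stimuli) per
#'   decision trial: locations, Euclidean report error (normalized screen
#'   units) and reaction time (s).
#' @export
simulate_attention <- function(profile, choice_log) {
  h <- attr(profile, "hyperparams")
  sp_floor <- if (!is.null(h)) h$sp_floor else 0.02
  cl <- choice_log[choice_log$participant == profile$pid, ]
  n <- nrow(cl)
  status <- c(vapply(seq_len(n), function(i) {
    if (is.na(cl$current_good[i])) rep(NA_character_, 3)
    else ifelse(c("A", "B", "C") == cl$current_good[i], "goal", "alt")
  }, character(3)))
  invested <- rep(cl$trials_invested, each = 3)
  goal_base <- profile$sp_base_sd - profile$atten_bias / sqrt(pi / 2)
  sd_vec <- ifelse(!is.na(status) & status == "goal",
                   goal_base + profile$sp_goal_slope * invested,
                   profile$sp_base_sd + profile$sp_alt_slope * invested)
  sd_vec <- pmax(sp_floor, sd_vec)
  m <- 3L * n
  true_x <- stats::runif(m)
  true_y <- stats::runif(m)
  rep_x <- true_x + stats::rnorm(m, 0, sd_vec)
  rep_y <- true_y + stats::rnorm(m, 0, sd_vec)
  rt_log_mean <- if (!is.null(h)) h$rt_log_mean else log(0.9)
  rt_log_sd <- if (!is.null(h)) h$rt_log_sd else 0.3
  rt <- stats::rlnorm(m, rt_log_mean, rt_log_sd) +
    ifelse(!is.na(status) & status == "goal", profile$rt_goal_shift, 0)
  out <- data.frame(
    pid = profile$pid,
    block = rep(cl$block, each = 3),
    trial = rep(cl$trial, each = 3),
    stimulus = rep(c("A", "B", "C"), times = n),
    stimulus_status = status,
    trials_invested = invested,
    true_x = true_x, true_y = true_y,
    reported_x = rep_x, reported_y = rep_y,
    error = sqrt((rep_x - true_x)^2 + (rep_y - true_y)^2),
    rt = pmax(0.05, rt)
  )
  class(out) <- c("gp_spatial", "data.frame")
  out
}

#' Simulate the whole cohort's spatial-attention data
#'
#' @param cohort A [gen_cohort()] data frame.
#' @param choice_log A `gp_choices` log covering the cohort.
#' @return A `gp_spatial` data frame for all participants.
#' @export
simulate_cohort_attention <- function(cohort, choice_log) {
  h <- attr(cohort, "hyperparams")
  logs <- lapply(seq_len(nrow(cohort)), function(i) {
    pr <- cohort[i, ]
    attr(pr, "hyperparams") <- h
    simulate_attention(pr, choice_log)
  })
  out <- do.call(rbind, logs)
  class(out) <- c("gp_spatial", "data.frame")
  out
}
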