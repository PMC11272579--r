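#' Goal-progress effect on abandonment beyond tree-search value
#'
#' Likelihood-ratio test between the pooled logistic models
#' `abandon ~ sv_tree_search` and `abandon ~ sv_tree_search + progress`:
#' does the proportion of the net already completed predict abandonment on
#' top of the planner's abandonment value? A negative progress coefficient
#' with a significant test means persistence bias grows with goal progress.
#'
#' @param dataset A `gp_dataset` (pooled across participants).
#' @return List with `chi2` (deviance difference), `df` (1), `p`, and the
#'   progress coefficient `b_progress`.
#' @export
progress_bias_test <- function(dataset) {
  m0 <- stats::glm(abandon ~ sv_tree_search, binomial(), dataset)
  m1 <- stats::glm(abandon ~ sv_tree_search + progress, binomial(), dataset)
  chi2 <- as.numeric(m0$deviance - m1$deviance)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       b_progress = unname(stats::coef(m1)["progress"]))
}

#' Value-by-progress interaction fits (temptation vs frustration)
#'
#' Per participant, fits a logistic regression of abandonment on the
#' tree-search current-goal value, the best-alternative value, goal progress,
#' and each value's interaction with progress. Values enter unstandardized:
#' under the attenuated choice rule the two interaction coefficients are
#' `-inv_temp * atten_alt` and `+inv_temp * atten_cur`, sharing the
#' participant's inverse temperature, so they are directly comparable —
#' within-participant standardization would rescale them by each value's own
#' s.d. and break the comparison. Because the current-goal value pushes
#' *against* abandonment, its influence fades through a positive interaction
#' coefficient while the alternative's fades through a negative one; the
#' comparable "influence-loss" slopes are `loss_alt = -b_altval_x_progress`
#' and `loss_goal = +b_goalval_x_progress`. Cohort-level two-sided t-tests
#' ask whether each interaction coefficient differs from zero, and a paired
#' t-test compares the two loss slopes: `loss_alt > loss_goal` means the pull
#' of temptation fades faster over goal pursuit than the push of
#' frustration.
#'
#' @param dataset A `gp_dataset`.
#' @return An object of class `gp_interaction`: per-participant coefficients
#'   (raw and loss-slope form) and the cohort-level tests, including
#'   `t_paired_loss` (two-sided) and `p_loss_onesided` for the directional
#'   hypothesis `loss_alt > loss_goal`.
#' @export
value_progress_interaction <- function(dataset) {
  pids <- unique(dataset$pid)
  rows <- lapply(pids, function(p) {
    d <- dataset[dataset$pid == p, ]
    if (length(unique(d$abandon)) < 2) return(NULL)
    fit <- suppressWarnings(
      stats::glm(abandon ~ v_altbest_ts + v_goal_ts + progress +
                   v_altbest_ts:progress + v_goal_ts:progress,
                 binomial(), d))
    if (!fit$converged || any(abs(stats::coef(fit)) > 1e3)) return(NULL)
    co <- stats::coef(fit)
    data.frame(pid = p, b_altval = co[["v_altbest_ts"]],
               b_goalval = co[["v_goal_ts"]],
               b_altval_x_progress = co[["v_altbest_ts:progress"]],
               b_goalval_x_progress = co[["v_goal_ts:progress"]],
               loss_alt = -co[["v_altbest_ts:progress"]],
               loss_goal = co[["v_goal_ts:progress"]])
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 3) {
    stop("too few participants with identifiable interaction fits")
  }
  t_alt <- stats::t.test(per$b_altval_x_progress)
  t_goal <- stats::t.test(per$b_goalval_x_progress)
  t_loss <- stats::t.test(per$loss_alt, per$loss_goal, paired = TRUE)
  p_one <- stats::t.test(per$loss_alt, per$loss_goal, paired = TRUE,
                         alternative = "greater")$p.value
  # logistic interaction estimates are heavy-tailed near quasi-separation;
  # the signed-rank test is the robust companion to the paired t
  w_loss <- suppressWarnings(
    stats::wilcox.test(per$loss_alt, per$loss_goal, paired = TRUE))
  p_one_w <- suppressWarnings(
    stats::wilcox.test(per$loss_alt, per$loss_goal, paired = TRUE,
                       alternative = "greater")$p.value)
  structure(list(per_participant = per,
                 n_excluded = length(pids) - nrow(per),
                 t_alt_x_progress = t_alt, t_goal_x_progress = t_goal,
                 t_paired_loss = t_loss, p_loss_onesided = p_one,
                 wilcox_paired_loss = w_loss,
                 p_loss_onesided_wilcox = p_one_w),
            class = "gp_interaction")
}

#' @export
print.gp_interaction <- function(x, ...) {
  cat(sprintf("Value x progress interaction (%d participants, %d excluded)\n",
              nrow(x$per_participant), x$n_excluded))
  cat(sprintf("  alt value x progress : mean %0.3f, t = %0.2f, p = %0.4g\n",
              mean(x$per_participant$b_altval_x_progress),
              x$t_alt_x_progress$statistic, x$t_alt_x_progress$p.value))
  cat(sprintf("  goal value x progress: mean %0.3f, t = %0.2f, p = %0.4g\n",
              mean(x$per_participant$b_goalval_x_progress),
              x$t_goal_x_progress$statistic, x$t_goal_x_progress$p.value))
  cat(sprintf("  influence-loss paired: t = %0.2f, p = %0.4g (one-sided p = %0.4g)\n",
              x$t_paired_loss$statistic, x$t_paired_loss$p.value,
              x$p_loss_onesided))
  invisible(x)
}

#' Spatial-attention metrics and goal-oriented attention bias
#'
#' Per participant (excluding first trials of blocks, where no goal exists):
#' mean report error and reaction time by stimulus status; OLS slopes of
#' error on trials invested, separately for the current-goal and alternative
#' stimuli; and the attention bias `mean_err_alt - mean_err_goal` (positive =
#' goal advantage). Cohort-level paired t-tests compare error, RT and slopes
#' between statuses.
#'
#' @param spatial_log A `gp_spatial` data frame.
#' @return An object of class `gp_attention`: `per_participant` metrics and
#'   paired tests (`t_error`, `t_rt`, `t_slopes`); participants with fewer
#'   than 2 usable trials of either status are flagged and excluded.
#' @export
attention_analysis <- function(spatial_log) {
  d <- spatial_log[!is.na(spatial_log$stimulus_status), ]
  pids <- unique(d$pid)
  rows <- lapply(pids, function(p) {
    dp <- d[d$pid == p, ]
    g <- dp[dp$stimulus_status == "goal", ]
    a <- dp[dp$stimulus_status == "alt", ]
    if (nrow(g) < 2 || nrow(a) < 2) return(NULL)
    slope <- function(dd) unname(stats::coef(
      stats::lm(error ~ trials_invested, dd))[2])
    data.frame(pid = p,
               mean_err_goal = mean(g$error), mean_err_alt = mean(a$error),
               atten_bias = mean(a$error) - mean(g$error),
               slope_goal = slope(g), slope_alt = slope(a),
               mean_rt_goal = mean(g$rt), mean_rt_alt = mean(a$rt))
  })
  per <- do.call(rbind, rows)
  structure(list(per_participant = per,
                 n_flagged = length(pids) - nrow(per),
                 t_error = stats::t.test(per$mean_err_alt, per$mean_err_goal,
                                         paired = TRUE),
                 t_rt = stats::t.test(per$mean_rt_alt, per$mean_rt_goal,
                                      paired = TRUE),
                 t_slope_goal = stats::t.test(per$slope_goal),
                 t_slope_alt = stats::t.test(per$slope_alt),
                 t_slopes = stats::t.test(per$slope_goal, per$slope_alt,
                                          paired = TRUE)),
            class = "gp_attention")
}

#' @export
print.gp_attention <- function(x, ...) {
  cat(sprintf("Attention analysis (%d participants, %d flagged)\n",
              nrow(x$per_participant), x$n_flagged))
  cat(sprintf("  mean attention bias (alt - goal error): %0.4f (t = %0.2f, p = %0.4g)\n",
              mean(x$per_participant$atten_bias), x$t_error$statistic,
              x$t_error$p.value))
  cat(sprintf("  goal-stimulus error slope: %0.5f per trial (t = %0.2f, p = %0.4g)\n",
              mean(x$per_participant$slope_goal), x$t_slope_goal$statistic,
              x$t_slope_goal$p.value))
  cat(sprintf("  alt-stimulus error slope : %0.5f per trial (t = %0.2f, p = %0.4g)\n",
              mean(x$per_participant$slope_alt), x$t_slope_alt$statistic,
              x$t_slope_alt$p.value))
  invisible(x)
}

#' Attention-persistence correlation across participants
#'
#' Spearman rank correlation between per-participant goal-oriented attention
#' bias and persistence bias (indifference point), with a two-sided p-value
#' and an approximate confidence interval from the Fisher transform of the
#' rank correlation (`se = 1/sqrt(n - 3)`).
#'
#' @param atten_bias,ip Numeric vectors, one value per participant.
#' @param conf_level Confidence level for the interval.
#' @return List with `rho`, `p`, `ci`, `n`.
#' @export
bias_correlation <- function(atten_bias, ip, conf_level = 0.95) {
  keep <- is.finite(atten_bias) & is.finite(ip)
  x <- atten_bias[keep]
  y <- ip[keep]
  if (length(x) < 5) stop("need >= 5 participants")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("ties-only input: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(length(x) - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, p = ct$p.value, ci = tanh(c(z - q * se, z + q * se)),
       n = length(x))
}

#' Mean trials to complete a goal
#'
#' Performance metric: the mean number of trials taken to complete a net,
#' over completed nets only (an unfinished final block is excluded). Lower
#' is better.
#'
#' @param choice_log A `gp_choices` data frame (one participant).
#' @return Mean trials per completed net.
#' @export
performance_metric <- function(choice_log) {
  done <- choice_log[choice_log$completed, ]
  if (nrow(done) == 0) stop("no completed nets: performance undefined")
  mean(done$block_trial)
}

#' Permutation test for a difference in group means
#'
#' Label-shuffling permutation test with the add-one convention
#' `p = (b + 1) / (n_perm + 1)`, where `b` counts permuted statistics at
#' least as extreme as the observed `mean(a) - mean(b)` in the tested
#' direction.
#'
#' @param group_a,group_b Numeric vectors.
#' @param n_perm Number of permutations.
#' @param side `"greater"` (mean of `group_a` larger), `"less"`, or
#'   `"two.sided"`.
#' @return List with `p`, `observed` difference in means, `n_perm`.
#' @export
perm_test_means <- function(group_a, group_b, n_perm = 10000,
                            side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  if (n_perm < 100) warning("n_perm < 100: permutation p will be coarse")
  pooled <- c(group_a, group_b)
  n_a <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pooled), n_a)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  b <- switch(side,
              greater = sum(perm >= obs),
              less = sum(perm <= obs),
              two.sided = sum(abs(perm) >= abs(obs)))
  list(p = (b + 1) / (n_perm + 1), observed = obs, n_perm = n_perm)
}
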