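#' Build a model-value dataset from a choice log
#'
#' Recomputes all four valuation models at every non-first trial of every
#' block in the log (first trials have no current goal, so persist/abandon is
#' undefined there and they are excluded). For each model `m`, `sv_m` is the
#' model's best-alternative value minus its current-goal value. Tree-search
#' values are recomputed by fresh Monte-Carlo rollouts under `ts_cfg`.
#'
#' @param choice_log A `gp_choices` data frame (may cover many participants).
#' @param ts_cfg A [ts_config()].
#' @param schedule Optional: the schedule the log was recorded against; when
#'   supplied, logged offers are checked against it and a mismatch is a
#'   data-integrity error.
#' @param use_logged_values If `TRUE`, the tree-search columns
#'   (`v_goal_ts`, `v_altbest_ts`, `sv_tree_search`) are taken from the
#'   planner values recorded in the log at choice time instead of being
#'   recomputed by fresh rollouts. Recomputation mimics analysis of real
#'   data (where the choice-generating values are unobservable); logged
#'   values give an exactly specified regression for calibration studies.
#' @return A data frame of class `gp_dataset` with columns `pid`, `block`,
#'   `trial`, `abandon`, `sv_offer_max`, `sv_myopic`, `sv_prospective`,
#'   `sv_tree_search`, `v_goal_ts`, `v_altbest_ts`, `progress`,
#'   `trials_invested`.
#' @export
build_dataset <- function(choice_log, ts_cfg = ts_config(), schedule = NULL,
                          use_logged_values = FALSE) {
  if (!is.null(schedule)) {
    for (i in seq_len(nrow(choice_log))) {
      blk <- Filter(function(b) b$block_id == choice_log$block[i],
                    schedule$blocks)[[1]]
      logged <- c(choice_log$offer_A[i], choice_log$offer_B[i],
                  choice_log$offer_C[i])
      if (max(abs(logged - blk$offers[choice_log$block_trial[i], ])) > 1e-8) {
        stop("choice log does not match schedule (offers differ)")
      }
    }
  }
  d <- choice_log[!is.na(choice_log$current_good), ]
  n <- nrow(d)
  offers <- as.matrix(d[, c("offer_A", "offer_B", "offer_C")])
  goal_idx <- match(d$current_good, c("A", "B", "C"))
  goal_off <- offers[cbind(seq_len(n), goal_idx)]
  alt_off <- matrix(offers[cbind(rep(seq_len(n), 2),
                                 c(ifelse(goal_idx == 1, 2, 1),
                                   ifelse(goal_idx == 3, 2, 3)))],
                    ncol = 2)
  # offer-max: raw offers
  sv_offer_max <- pmax(alt_off[, 1], alt_off[, 2]) - goal_off
  # myopic: goal worth accumulated + offer
  sv_myopic <- pmax(alt_off[, 1], alt_off[, 2]) - (d$accumulated + goal_off)
  # prospective: proportion-of-net values with the negative-offer rules
  p_alt <- ifelse(alt_off >= 0, alt_off / d$net_size, alt_off)
  v_goal_pro <- ifelse(goal_off >= 0,
                       goal_off / (d$net_size - d$accumulated),
                       ifelse(d$accumulated > 0, goal_off / d$accumulated, 0))
  sv_prospective <- pmax(p_alt[, 1], p_alt[, 2]) - v_goal_pro
  if (use_logged_values) {
    v_goal_ts <- d$V_goal
    v_alt_ts <- d$V_altbest
    if (anyNA(v_goal_ts)) stop("log lacks recorded planner values")
  } else {
    # tree-search: fresh rollouts per trial
    p <- ts_cfg$params
    walk_sd <- sqrt(p$walk_var)
    v_goal_ts <- numeric(n)
    v_alt_ts <- numeric(n)
    for (i in seq_len(n)) {
      vals <- .ts_values_cpp(offers[i, ], d$accumulated[i], goal_idx[i] - 1L,
                             d$net_size[i], walk_sd, p$p_jump_up,
                             p$p_jump_down, p$jump_lo, p$jump_hi,
                             ts_cfg$n_rollouts, ts_cfg$max_horizon)
      v_goal_ts[i] <- vals[goal_idx[i]]
      v_alt_ts[i] <- max(vals[-goal_idx[i]])
    }
  }
  out <- data.frame(
    pid = d$participant, block = d$block, trial = d$trial,
    abandon = d$abandon,
    sv_offer_max = sv_offer_max, sv_myopic = sv_myopic,
    sv_prospective = sv_prospective, sv_tree_search = v_alt_ts - v_goal_ts,
    v_goal_ts = v_goal_ts, v_altbest_ts = v_alt_ts,
    progress = d$accumulated / d$net_size,
    trials_invested = d$trials_invested
  )
  class(out) <- c("gp_dataset", "data.frame")
  out
}
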