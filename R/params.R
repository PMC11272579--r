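#' Generative parameters of the offer schedule
#'
#' The task presents three goods whose offered quantities drift from trial to
#' trial as independent Gaussian random walks, with an independent chance on
#' every trial of an offer jumping to a level well above or below the option's
#' block-start offer. Net sizes (the quantity a block's net must accumulate
#' before it completes) are drawn uniformly. The defaults are the task's
#' standard settings: initial offers N(6, 1), walk variance 0.8 points^2, jump
#' probabilities 0.1 up / 0.1 down with magnitude U(3, 9) points relative to
#' the block-start offer, and net sizes between 12 and 72 points.
#'
#' @param init_mean Mean of the trial-1 offer distribution (points).
#' @param init_var Variance of the trial-1 offer distribution (points^2).
#' @param walk_var Per-trial Gaussian walk variance (points^2).
#' @param p_jump_up,p_jump_down Per-trial, per-option jump probabilities.
#' @param jump_lo,jump_hi Jump magnitude bounds (points); a jump lands
#'   uniformly between `jump_lo` and `jump_hi` points above (or below) the
#'   option's block-start offer.
#' @param net_lo,net_hi Net-size bounds (points).
#' @return An object of class `gp_params`.
#' @examples
#' p <- gp_params()
#' p$walk_var
#' @export
gp_params <- function(init_mean = 6, init_var = 1, walk_var = 0.8,
                      p_jump_up = 0.1, p_jump_down = 0.1,
                      jump_lo = 3, jump_hi = 9,
                      net_lo = 12, net_hi = 72) {
  stopifnot(init_var >= 0, walk_var >= 0,
            p_jump_up >= 0, p_jump_down >= 0,
            p_jump_up + p_jump_down <= 1,
            jump_lo <= jump_hi, net_lo <= net_hi)
  structure(list(init_mean = init_mean, init_var = init_var,
                 walk_var = walk_var,
                 p_jump_up = p_jump_up, p_jump_down = p_jump_down,
                 jump_lo = jump_lo, jump_hi = jump_hi,
                 net_lo = net_lo, net_hi = net_hi),
            class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat("Goal-pursuit generative parameters\n")
  cat(sprintf("  initial offers : N(%g, %g)\n", x$init_mean, x$init_var))
  cat(sprintf("  walk variance  : %g\n", x$walk_var))
  cat(sprintf("  jumps          : P(up) = %g, P(down) = %g, magnitude U(%g, %g)\n",
              x$p_jump_up, x$p_jump_down, x$jump_lo, x$jump_hi))
  cat(sprintf("  net size       : U(%g, %g)\n", x$net_lo, x$net_hi))
  invisible(x)
}

#' Tree-search planner configuration
#'
#' The tree-search model values each good by Monte-Carlo rollouts of future
#' offer trajectories under the task's own generative statistics (see
#' [tree_search_values()]).
#'
#' @param n_rollouts Number of Monte-Carlo rollouts per candidate good.
#' @param max_horizon Rollout censoring horizon (trials); rollouts that have
#'   not filled the net by then contribute `max_horizon` trials.
#' @param params A [gp_params()] object used to evolve offers inside rollouts.
#' @return An object of class `ts_config`.
#' @export
ts_config <- function(n_rollouts = 100, max_horizon = 200,
                      params = gp_params()) {
  stopifnot(n_rollouts >= 1, max_horizon >= 1, inherits(params, "gp_params"))
  structure(list(n_rollouts = as.integer(n_rollouts),
                 max_horizon = as.integer(max_horizon),
                 params = params),
            class = "ts_config")
}
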