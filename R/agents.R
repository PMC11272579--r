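#' Valuation models for the goal-pursuit task
#'
#' Four models of how an agent values the three goods on a trial:
#'
#' * **offer-max** — each good is worth its raw on-screen offer, regardless of
#'   the net contents.
#' * **myopic** — the current goal is worth the accumulated contents plus its
#'   offer; alternatives are worth their raw offers (maximizes value on the
#'   current trial only).
#' * **prospective** — each positive offer is valued as the proportion of net
#'   it fills: the goal offer relative to the *remaining* unfilled net, an
#'   alternative offer relative to the whole net. Negative alternative offers
#'   keep their raw (negative) value; a negative goal offer is valued as the
#'   proportion of accumulated progress it would destroy (offer divided by the
#'   accumulated value; 0 when the net is empty).
#' * **tree-search** — Monte-Carlo planner; see [tree_search_values()].
#'
#' Each function returns a `gp_valuation`: a list with `model_name`, `values`
#' (named length-3) and `sv_abandon` (best-alternative value minus
#' current-goal value; `NA` when there is no current goal).
#'
#' @param state A [task_state()].
#' @return A `gp_valuation` list.
#' @name valuation
NULL

new_valuation <- function(model_name, values, state) {
  sv <- NA_real_
  if (!is.na(state$current_good)) {
    alts <- setdiff(c("A", "B", "C"), state$current_good)
    sv <- max(values[alts]) - values[[state$current_good]]
  }
  list(model_name = model_name, values = values, sv_abandon = sv)
}

#' @rdname valuation
#' @export
offer_max_values <- function(state) {
  new_valuation("offer_max", state$offers, state)
}

#' @rdname valuation
#' @export
myopic_values <- function(state) {
  if (is.na(state$current_good)) {
    stop("myopic values are undefined without a current goal")
  }
  values <- state$offers
  values[state$current_good] <- state$accumulated + values[state$current_good]
  new_valuation("myopic", values, state)
}

#' @rdname valuation
#' @export
prospective_values <- function(state) {
  if (is.na(state$current_good)) {
    stop("prospective values are undefined without a current goal")
  }
  values <- prospective_alt(state$offers, state$net_size)
  goal <- state$current_good
  off <- state$offers[[goal]]
  values[goal] <- if (off >= 0) {
    off / (state$net_size - state$accumulated)
  } else if (state$accumulated > 0) {
    off / state$accumulated
  } else 0
  new_valuation("prospective", values, state)
}

# alternative-good rule: positive offers as proportion of the whole net,
# negative offers raw
prospective_alt <- function(offers, net_size) {
  ifelse(offers >= 0, offers / net_size, offers)
}

#' Monte-Carlo tree-search valuation
#'
#' For each candidate good the planner simulates `n_rollouts` futures in which
#' the agent picks the candidate now (forfeiting net contents if it is not the
#' current goal) and commits to it on every later trial, with the candidate's
#' offer evolving under the task's own generative statistics (walk + jumps;
#' the jump reference is the offer level at rollout start). The value of a
#' good is minus the mean number of trials until the net fills, censored at
#' `max_horizon`, so the greedy planner picks the good forecast to fill the
#' net fastest.
#'
#' @param state A [task_state()]. Works on a block's first trial too, where
#'   every candidate starts an empty net.
#' @param cfg A [ts_config()].
#' @return A `gp_valuation` list (see [valuation]).
#' @export
tree_search_values <- function(state, cfg = ts_config()) {
  p <- cfg$params
  cur <- if (is.na(state$current_good)) {
    -1L
  } else {
    match(state$current_good, c("A", "B", "C")) - 1L
  }
  vals <- .ts_values_cpp(as.numeric(state$offers), state$accumulated, cur,
                         state$net_size, sqrt(p$walk_var),
                         p$p_jump_up, p$p_jump_down, p$jump_lo, p$jump_hi,
                         cfg$n_rollouts, cfg$max_horizon)
  new_valuation("tree_search", stats::setNames(vals, c("A", "B", "C")), state)
}

# Dispatch a model name to its valuation; on a block's first trial every good
# is a fresh choice, so the heuristic models fall back to their
# empty-net/alternative rules.
model_values <- function(state, model, cfg) {
  if (model == "tree_search") return(tree_search_values(state, cfg))
  if (is.na(state$current_good)) {
    values <- switch(model,
      offer_max = state$offers,
      myopic = state$offers,
      prospective = prospective_alt(state$offers, state$net_size),
      stop("unknown model: ", model))
    return(new_valuation(model, values, state))
  }
  switch(model,
         offer_max = offer_max_values(state),
         myopic = myopic_values(state),
         prospective = prospective_values(state),
         stop("unknown model: ", model))
}

greedy_pick <- function(values) {
  idx <- which(values == max(values))
  if (length(idx) > 1) idx <- sample(idx, 1)
  c("A", "B", "C")[idx]
}

#' Simulate an agent playing a schedule
#'
#' Plays the session trial by trial under one of the four valuation models.
#' The greedy policy picks the argmax-value good (uniform random tie-break);
#' the softmax policy abandons the current goal with probability
#' `plogis(beta0 + beta1 * sv_abandon)` and, when abandoning, picks the best
#' alternative. A block's first trial is always a greedy fresh choice.
#'
#' @param schedule A [gen_schedule()] schedule.
#' @param model One of `"tree_search"`, `"offer_max"`, `"myopic"`,
#'   `"prospective"`.
#' @param policy `"greedy"`, or a numeric `c(beta0, beta1)` for softmax.
#' @param cfg A [ts_config()] (used by the tree-search model).
#' @param max_trials Optional session horizon; the concatenated blocks are
#'   truncated after this many trials.
#' @param pid Participant identifier stored in the log.
#' @return A `gp_choices` data frame, one row per trial, recording the
#'   pre-choice state, the model's current-goal and best-alternative values,
#'   the choice, and whether it abandoned the current goal.
#' @export
simulate_agent <- function(schedule, model = "tree_search",
                           policy = "greedy", cfg = ts_config(),
                           max_trials = NULL, pid = 1L) {
  model <- match.arg(model,
                     c("tree_search", "offer_max", "myopic", "prospective"))
  softmax <- is.numeric(policy)
  if (!softmax && !identical(policy, "greedy")) {
    stop("policy must be \"greedy\" or numeric c(beta0, beta1)")
  }
  if (softmax && length(policy) != 2) stop("softmax policy needs c(beta0, beta1)")
  rows <- vector("list", 512)
  n_row <- 0L
  g_trial <- 0L
  for (b in seq_along(schedule$blocks)) {
    blk <- schedule$blocks[[b]]
    state <- task_state(blk$net_size, blk$offers[1, ], block_id = blk$block_id)
    for (bt in seq_len(nrow(blk$offers))) {
      if (!is.null(max_trials) && g_trial >= max_trials) break
      g_trial <- g_trial + 1L
      state$offers <- stats::setNames(blk$offers[bt, ], c("A", "B", "C"))
      state$trial_index <- bt
      val <- model_values(state, model, cfg)
      first <- is.na(state$current_good)
      if (first || !softmax) {
        choice <- greedy_pick(val$values)
      } else {
        p_ab <- stats::plogis(policy[1] + policy[2] * val$sv_abandon)
        if (stats::runif(1) < p_ab) {
          alts <- setdiff(c("A", "B", "C"), state$current_good)
          choice <- alts[which.max(val$values[alts])]
        } else {
          choice <- state$current_good
        }
      }
      nxt <- apply_choice(state, choice)
      n_row <- n_row + 1L
      if (n_row > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[n_row]] <- data.frame(
        participant = pid, block = blk$block_id, block_trial = bt,
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
        completed = nxt$completed, model = model,
        stringsAsFactors = FALSE)
      if (nxt$completed) break
      state <- nxt
    }
    if (!is.null(max_trials) && g_trial >= max_trials) break
  }
  out <- do.call(rbind, rows[seq_len(n_row)])
  class(out) <- c("gp_choices", "data.frame")
  attr(out, "model") <- model
  attr(out, "policy") <- if (softmax) policy else "greedy"
  out
}
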