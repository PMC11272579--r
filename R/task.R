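#' Construct a task state
#'
#' The state an agent evaluates on a given trial: the net being filled, the
#' good currently accumulating in it (none on a block's first trial), the
#' quantity already accumulated, and the three offers on screen.
#'
#' @param net_size Net size (points).
#' @param offers Numeric length-3 current offers, named A/B/C.
#' @param accumulated Points currently in the net (>= 0).
#' @param current_good `"A"`, `"B"`, `"C"` or `NA` (no goal yet).
#' @param trial_index Trial index within the block (>= 1).
#' @param trials_invested Consecutive trials spent on the current good.
#' @param block_id Block identifier.
#' @return An object of class `task_state`.
#' @export
task_state <- function(net_size, offers, accumulated = 0,
                       current_good = NA_character_, trial_index = 1L,
                       trials_invested = 0L, block_id = 1L) {
  stopifnot(length(offers) == 3, accumulated >= 0)
  if (!is.na(current_good) && !current_good %in% c("A", "B", "C")) {
    stop("unknown good label: ", current_good)
  }
  if (is.na(current_good) && trial_index != 1L) {
    stop("current_good may be NA only on trial 1 of a block")
  }
  offers <- stats::setNames(as.numeric(offers), c("A", "B", "C"))
  structure(list(block_id = block_id, trial_index = as.integer(trial_index),
                 net_size = net_size, accumulated = accumulated,
                 current_good = current_good,
                 trials_invested = as.integer(trials_invested),
                 offers = offers, completed = FALSE),
            class = "task_state")
}

#' Apply a choice to a task state
#'
#' Persisting adds the chosen offer to the net; switching forfeits the net
#' contents before the new goods are added. The net is floored at zero (once
#' empty, nothing more can be lost, so a negative offer leads to no change),
#' and the block completes as soon as the accumulated quantity reaches the
#' net size (overshoot counts as complete).
#'
#' @param state A [task_state()].
#' @param chosen `"A"`, `"B"` or `"C"`.
#' @param offer The chosen good's current offer; defaults to the offer stored
#'   in `state`.
#' @return The post-choice `task_state` (trial index advanced); its
#'   `completed` field is `TRUE` if the net was filled by this choice.
#' @export
apply_choice <- function(state, chosen, offer = state$offers[[chosen]]) {
  if (!chosen %in% c("A", "B", "C")) stop("unknown good label: ", chosen)
  persist <- !is.na(state$current_good) && chosen == state$current_good
  if (persist || is.na(state$current_good)) {
    acc <- max(0, state$accumulated + offer)
    invested <- state$trials_invested + 1L
  } else {
    acc <- max(0, offer)
    invested <- 1L
  }
  out <- state
  out$accumulated <- acc
  out$current_good <- chosen
  out$trials_invested <- invested
  out$trial_index <- state$trial_index + 1L
  out$completed <- acc >= state$net_size
  out
}
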