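#' Advance the three offers by one trial
#'
#' Independently per option: with probability `p_jump_up` the next offer jumps
#' to `start_offer + U(jump_lo, jump_hi)`, with probability `p_jump_down` to
#' `start_offer - U(jump_lo, jump_hi)`; otherwise it takes a Gaussian step of
#' variance `walk_var` from its current level. After a jump the walk continues
#' from the new value. Offers are not clipped and may become negative.
#'
#' @param offers Numeric length-3, current offers.
#' @param start_offers Numeric length-3, the block's trial-1 offers (the jump
#'   reference).
#' @param params A [gp_params()] object.
#' @return Numeric length-3, the next trial's offers.
#' @export
step_offers <- function(offers, start_offers, params = gp_params()) {
  stopifnot(length(offers) == 3, length(start_offers) == 3)
  u <- stats::runif(3)
  nxt <- offers + stats::rnorm(3, 0, sqrt(params$walk_var))
  mag <- stats::runif(3, params$jump_lo, params$jump_hi)
  up <- u < params$p_jump_up
  down <- !up & u < params$p_jump_up + params$p_jump_down
  nxt[up] <- start_offers[up] + mag[up]
  nxt[down] <- start_offers[down] - mag[down]
  nxt
}

#' Generate one task block
#'
#' Draws a net size uniformly between `net_lo` and `net_hi` (rounded to the
#' nearest integer; nets are discrete quantities on screen), trial-1 offers
#' i.i.d. normal, and subsequent offers via [step_offers()].
#'
#' @param params A [gp_params()] object.
#' @param n_trials Number of trials in the block (>= 1).
#' @param block_id Identifier stored on the block.
#' @return An object of class `gp_block`: a list with `block_id`, `net_size`,
#'   `good_labels`, `offers` (an `n_trials` x 3 matrix) and `start_offers`.
#' @export
gen_block <- function(params = gp_params(), n_trials = 100, block_id = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  net_size <- round(stats::runif(1, params$net_lo, params$net_hi))
  offers <- matrix(NA_real_, nrow = n_trials, ncol = 3,
                   dimnames = list(NULL, c("A", "B", "C")))
  offers[1, ] <- stats::rnorm(3, params$init_mean, sqrt(params$init_var))
  if (n_trials > 1) {
    for (t in 2:n_trials) {
      offers[t, ] <- step_offers(offers[t - 1, ], offers[1, ], params)
    }
  }
  structure(list(block_id = block_id, net_size = net_size,
                 good_labels = c("A", "B", "C"),
                 offers = offers, start_offers = offers[1, ]),
            class = "gp_block")
}

#' Tree-search block acceptance filter
#'
#' Simulates a greedy tree-search agent on the block and accepts the block iff
#' the agent completes the net in strictly more than `t_min` and strictly
#' fewer than `t_max` trials, so that completing the net is non-trivial yet
#' feasible.
#'
#' @param block A [gen_block()] block.
#' @param ts_cfg A [ts_config()] used for the acceptance agent.
#' @param t_min,t_max Exclusive bounds on trials-to-completion (defaults 3
#'   and 15).
#' @return List with `accepted` (logical) and `trials_to_complete` (integer,
#'   `NA` if the net was never filled within the block).
#' @export
accept_block <- function(block, ts_cfg = ts_config(), t_min = 3, t_max = 15) {
  run <- simulate_agent(as_schedule(block), model = "tree_search",
                        policy = "greedy", cfg = ts_cfg)
  done <- run$completed & !is.na(run$completed)
  if (!any(done)) {
    return(list(accepted = FALSE, trials_to_complete = NA_integer_))
  }
  t_complete <- run$block_trial[which(done)[1]]
  list(accepted = t_complete > t_min && t_complete < t_max,
       trials_to_complete = as.integer(t_complete))
}

#' Generate a full task schedule by rejection sampling
#'
#' Repeatedly generates candidate blocks and keeps those passing
#' [accept_block()], until `n_blocks` accepted blocks are collected. The
#' standard session consists of 45 accepted blocks of 100 trials each.
#'
#' @param params A [gp_params()] object.
#' @param n_blocks Number of accepted blocks required.
#' @param n_trials_per_block Trials generated per block.
#' @param ts_cfg Acceptance-agent configuration ([ts_config()]).
#' @param max_reject Maximum candidate blocks tried per accepted block.
#' @return An object of class `gp_schedule`: list of blocks plus per-block
#'   `trials_to_complete` recorded from the acceptance simulation.
#' @export
gen_schedule <- function(params = gp_params(), n_blocks = 45,
                         n_trials_per_block = 100, ts_cfg = ts_config(),
                         max_reject = 10000) {
  stopifnot(n_blocks >= 1)
  blocks <- vector("list", n_blocks)
  t_complete <- integer(n_blocks)
  accepted <- 0L
  tried <- 0L
  while (accepted < n_blocks) {
    if (tried >= max_reject * n_blocks) {
      stop("schedule generation failed: rejection limit reached")
    }
    tried <- tried + 1L
    cand <- gen_block(params, n_trials_per_block, block_id = accepted + 1L)
    acc <- accept_block(cand, ts_cfg)
    if (acc$accepted) {
      accepted <- accepted + 1L
      blocks[[accepted]] <- cand
      t_complete[accepted] <- acc$trials_to_complete
    }
  }
  structure(list(blocks = blocks, trials_to_complete = t_complete,
                 params = params, n_trials_per_block = n_trials_per_block),
            class = "gp_schedule")
}

# Wrap a single block as a one-block schedule (used by the acceptance filter).
as_schedule <- function(block) {
  structure(list(blocks = list(block), trials_to_complete = NA_integer_,
                 params = NULL, n_trials_per_block = nrow(block$offers)),
            class = "gp_schedule")
}

#' @export
print.gp_schedule <- function(x, ...) {
  cat(sprintf("Goal-pursuit schedule: %d blocks x %d trials\n",
              length(x$blocks), x$n_trials_per_block))
  if (!all(is.na(x$trials_to_complete))) {
    cat(sprintf("  acceptance-agent trials to completion: %d-%d (median %g)\n",
                min(x$trials_to_complete), max(x$trials_to_complete),
                stats::median(x$trials_to_complete)))
  }
  invisible(x)
}

#' Write / read a schedule as long-format CSV
#'
#' Columns `block,trial,net_size,offer_A,offer_B,offer_C`; a JSON sidecar
#' (`<path>.json`) stores the generative parameters.
#'
#' @param schedule A `gp_schedule`.
#' @param path CSV output path.
#' @return `write_schedule()` the path, invisibly; `read_schedule()` a
#'   `gp_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  rows <- do.call(rbind, lapply(schedule$blocks, function(b) {
    data.frame(block = b$block_id, trial = seq_len(nrow(b$offers)),
               net_size = b$net_size,
               offer_A = b$offers[, 1], offer_B = b$offers[, 2],
               offer_C = b$offers[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  side <- list(params = unclass(schedule$params),
               n_trials_per_block = schedule$n_trials_per_block,
               trials_to_complete = schedule$trials_to_complete)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  rows <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  params <- NULL
  t_complete <- NA_integer_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$params)) params <- do.call(gp_params, side$params)
    if (!is.null(side$trials_to_complete)) {
      t_complete <- as.integer(side$trials_to_complete)
    }
  }
  blocks <- lapply(split(rows, rows$block), function(d) {
    d <- d[order(d$trial), ]
    offers <- as.matrix(d[, c("offer_A", "offer_B", "offer_C")])
    dimnames(offers) <- list(NULL, c("A", "B", "C"))
    structure(list(block_id = d$block[1], net_size = d$net_size[1],
                   good_labels = c("A", "B", "C"),
                   offers = offers, start_offers = offers[1, ]),
              class = "gp_block")
  })
  blocks <- blocks[order(vapply(blocks, `[[`, 0, "block_id"))]
  structure(list(blocks = unname(blocks), trials_to_complete = t_complete,
                 params = params,
                 n_trials_per_block = nrow(blocks[[1]]$offers)),
            class = "gp_schedule")
}
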