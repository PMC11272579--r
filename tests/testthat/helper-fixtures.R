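# Shared fixtures, built in code at test time.

# deterministic offers: zero variance, no jumps
frozen_params <- function(init_mean = 6) {
  gp_params(init_mean = init_mean, init_var = 0, walk_var = 0,
            p_jump_up = 0, p_jump_down = 0)
}

# a small schedule suitable for fast agent simulations
small_schedule <- function(n_blocks = 4, n_trials = 40, seed = 101,
                           n_rollouts = 30) {
  set.seed(seed)
  gen_schedule(n_blocks = n_blocks, n_trials_per_block = n_trials,
               ts_cfg = ts_config(n_rollouts = n_rollouts))
}

# hand-built one-block schedule with fully specified offers
fixed_block_schedule <- function(offers, net_size) {
  blk <- structure(list(block_id = 1L, net_size = net_size,
                        good_labels = c("A", "B", "C"),
                        offers = offers, start_offers = offers[1, ]),
                   class = "gp_block")
  structure(list(blocks = list(blk), trials_to_complete = NA_integer_,
                 params = NULL, n_trials_per_block = nrow(offers)),
            class = "gp_schedule")
}

# simulate a small cohort and build its model-value dataset
small_cohort_dataset <- function(n = 6, max_trials = 80, seed = 202,
                                 n_rollouts = 30, ...) {
  set.seed(seed)
  cfg <- ts_config(n_rollouts = n_rollouts)
  sch <- gen_schedule(n_blocks = 20, n_trials_per_block = 50, ts_cfg = cfg)
  coh <- gen_cohort(cohort_hyperparams(n = n, ...))
  log <- simulate_cohort_decisions(coh, sch, cfg, max_trials = max_trials)
  list(cohort = coh, schedule = sch, log = log,
       dataset = build_dataset(log, cfg))
}
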