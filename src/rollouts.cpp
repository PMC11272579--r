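#include <Rcpp.h>
using namespace Rcpp;

// Offer update shared by schedule generation and rollouts: with probability
// p_up / p_down the offer jumps to start +/- U(jump_lo, jump_hi); otherwise it
// takes a Gaussian step of sd walk_sd from its current level. Offers are not
// clipped and may go negative.
static inline double step_offer(double cur, double start,
                                double walk_sd, double p_up, double p_down,
                                double jump_lo, double jump_hi) {
    double u = unif_rand();
    if (u < p_up) {
        return start + jump_lo + (jump_hi - jump_lo) * unif_rand();
    } else if (u < p_up + p_down) {
        return start - (jump_lo + (jump_hi - jump_lo) * unif_rand());
    }
    return cur + walk_sd * norm_rand();
}

// Monte-Carlo tree-search valuation of the three goods. For each candidate g
// the agent is assumed to pick g now (forfeiting net contents if g is not the
// current goal) and commit to it on every simulated future trial; offers for g
// evolve with the task's own generative statistics. value(g) is minus the mean
// number of trials until the net fills, censored at max_horizon. The jump
// reference inside a rollout is the offer level at rollout start.
// current is the 0-based index of the current goal, or -1 for none (trial 1).
// [[Rcpp::export(name = ".ts_values_cpp")]]
NumericVector ts_values_cpp(NumericVector offers, double accumulated,
                            int current, double net_size,
                            double walk_sd, double p_up, double p_down,
                            double jump_lo, double jump_hi,
                            int n_rollouts, int max_horizon) {
    NumericVector vals(3);
    for (int g = 0; g < 3; ++g) {
        double total = 0.0;
        // first step is deterministic (today's offers are known)
        double acc0 = (current < 0 || g == current) ? accumulated + offers[g]
                                                    : offers[g];
        if (acc0 < 0.0) acc0 = 0.0;
        for (int r = 0; r < n_rollouts; ++r) {
            double acc = acc0;
            double off = offers[g];
            double start = offers[g];
            int t = 1;
            while (acc < net_size && t < max_horizon) {
                off = step_offer(off, start, walk_sd, p_up, p_down,
                                 jump_lo, jump_hi);
                acc += off;
                if (acc < 0.0) acc = 0.0;
                ++t;
            }
            total += t;
        }
        vals[g] = -total / n_rollouts;
    }
    return vals;
}
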