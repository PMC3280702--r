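# Shared builders for small, fully specified models.

# Identity-style quantizer: codes 0..(n_bins-1) with unit bins from 0.
unit_quantizer <- function(n_bins) {
  structure(list(bin_edges = seq(0, n_bins, by = 1),
                 n_bins = as.integer(n_bins)),
            class = "quantizer")
}

# History-free two-state model over a small alphabet.
toy_model <- function(alpha0 = log(1.5), alpha1 = log(4), rho = 0.1,
                      p0 = 1, n_bins = 3, M = 50) {
  hmm_glm_model(rho,
                list(alpha = alpha0, betas = numeric(0)),
                list(alpha = alpha1, betas = numeric(0)),
                unit_quantizer(n_bins), P0 = c(p0, 1 - p0), M = M)
}

# One-lag model matching the synthetic study conditions at a small horizon.
toy_lag_model <- function(rho = 0.05, M = 50) {
  hmm_glm_model(rho,
                list(alpha = log(3), betas = 0.05),
                list(alpha = log(8), betas = 0.03),
                unit_quantizer(30), M = M)
}

# Manual constant-threshold policy (for degenerate detection checks).
constant_policy <- function(threshold, M, gamma = 0.3, rho = 0.01) {
  structure(list(pi_grid = seq(0, 1, length.out = 101),
                 F = rep(threshold, M),
                 cost = cost_spec(gamma = gamma, horizon_M = M, rho = rho),
                 J0 = NULL, value_table = NULL, n_symbols = NA_integer_,
                 nonconvex_stages = integer(0)),
            class = "qd_policy")
}
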