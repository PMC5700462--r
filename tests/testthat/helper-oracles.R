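# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Long-run time fraction per state: stationary eigenvector of the embedded
# exit chain (via eigen decomposition, not the package's linear solve),
# weighted by destination-averaged mean dwells.
oracle_stationary_percent <- function(P, tau) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_embed <- Re(ev$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  mean_dwell <- rowSums(P * ifelse(P > 0, tau, 0))
  w <- pi_embed * unname(mean_dwell)
  100 * w / sum(w)
}

# expand a state path to the per-sample label sequence used by render_trace
expand_states <- function(path, rate = 28.8) {
  counts <- pmax(diff(c(0L, ceiling(cumsum(path$duration_ms) * rate))), 1L)
  rep(path$state, times = counts)
}

# expand an idealized path whose durations are exact sample multiples
expand_decoded <- function(path, rate = 28.8) {
  rep(path$state, times = round(path$duration_ms * rate))
}

# a tiny strictly-alternating two-state model for forced-path tests
forced_two_state <- function(tau_lo = 4, tau_hi = 1, ...) {
  kinetic_model(
    levels = c(0, 3),
    P = matrix(c(0, 1, 1, 0), 2),
    tau = matrix(c(NA, tau_hi, tau_lo, NA), 2),
    states = c("low", "high"),
    ...
  )
}
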