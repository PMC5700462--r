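#' Construct a semi-Markov kinetic model for a fluctuating conductance trace
#'
#' A kinetic model describes a probe molecule that hops between `k` ordered
#' conductance states. Exits from state `i` land in state `j` with probability
#' `P[i, j]`, and the sojourn that *ends* in `j` has an exponentially
#' distributed duration with mean `tau[i, j]` milliseconds. Resolving the mean
#' dwell by destination (a semi-Markov rather than a plain continuous-time
#' Markov chain) is what lets the same state show two different lifetimes
#' depending on the conformation that follows it, as observed in hairpin-DNA
#' hybridization recordings.
#'
#' @param levels Numeric vector of per-state current levels in nA, strictly
#'   increasing. For the canonical three-state hybridization model the duplex
#'   ("low") level is negative, the hairpin ("intermediate") level is 0 and the
#'   single-stranded ("high") level is positive.
#' @param P Square matrix of destination-resolved exit probabilities.
#'   `P[i, j]` is the probability that an exit from state `i` lands in state
#'   `j`; the diagonal must be zero and every row must sum to 1.
#' @param tau Square matrix of mean dwell times in ms; `tau[i, j]` is the mean
#'   duration of a sojourn in state `i` that ends in state `j`. Must be
#'   positive wherever `P > 0` (the diagonal is ignored).
#' @param states Character vector of state labels, ordered by level. Defaults
#'   to `c("low", "intermediate", "high")` for 3 states and
#'   `c("low", "high")` for 2.
#' @param noise_sd Standard deviation of additive Gaussian current noise, nA.
#' @param pink_amplitude RMS amplitude of an optional 1/f background, nA
#'   (0 disables it).
#' @param sample_rate Sampling rate in kSa/s (samples per ms).
#' @param filter_cutoff Single-pole low-pass cutoff applied to the noise when
#'   rendering, in kHz. `Inf` disables filtering.
#'
#' @return An object of class `kinetic_model`.
#' @examples
#' m <- kinetic_model(
#'   levels = c(-3, 0, 3),
#'   P = matrix(c(0, .9, .1, .8, 0, .2, .3, .7, 0), 3, byrow = TRUE),
#'   tau = matrix(c(NA, 10, 20, 2, NA, 3, 1, .5, NA), 3, byrow = TRUE)
#' )
#' stationary_occupancy(m)
#' @seealso [allele_models()] for the four published parameter sets,
#'   [simulate_state_path()] and [render_trace()].
#' @export
kinetic_model <- function(levels, P, tau,
                          states = NULL,
                          noise_sd = 0.5,
                          pink_amplitude = 0,
                          sample_rate = 28.8,
                          filter_cutoff = 5) {
  P <- as.matrix(P)
  tau <- as.matrix(tau)
  k <- length(levels)
  if (is.null(states)) {
    states <- switch(as.character(k),
      "2" = c("low", "high"),
      "3" = c("low", "intermediate", "high"),
      paste0("state", seq_len(k))
    )
  }
  if (length(states) != k || nrow(P) != k || ncol(P) != k ||
    nrow(tau) != k || ncol(tau) != k) {
    abort("`levels`, `states`, `P` and `tau` must agree on the number of states.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (anyDuplicated(states) > 0) {
    abort("state labels must be unique.", class = "hairpinkinetics_parameter_error")
  }
  if (any(!is.finite(levels)) || any(diff(levels) <= 0)) {
    abort("`levels` must be finite and strictly increasing.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (any(diag(P) != 0)) {
    abort("`P` must have a zero diagonal (self-transitions are not exits).",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    abort("each row of `P` must be a probability distribution over the other states.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  bad_tau <- P > 0 & (!is.finite(tau) | tau <= 0)
  if (any(bad_tau)) {
    abort("`tau` must be positive and finite wherever `P` > 0.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (noise_sd < 0 || pink_amplitude < 0 || sample_rate <= 0 || filter_cutoff <= 0) {
    abort("`noise_sd`/`pink_amplitude` must be >= 0; `sample_rate`/`filter_cutoff` > 0.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  dimnames(P) <- dimnames(tau) <- list(states, states)
  structure(
    list(
      states = states,
      levels = setNames(as.numeric(levels), states),
      P = P,
      tau = tau,
      noise_sd = noise_sd,
      pink_amplitude = pink_amplitude,
      sample_rate = sample_rate,
      filter_cutoff = filter_cutoff
    ),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", length(x$states), " states: ",
    paste(x$states, collapse = ", "), "\n",
    sep = ""
  )
  cat("levels (nA):", paste(signif(x$levels, 4), collapse = ", "), "\n")
  cat("exit probabilities P[i,j]:\n")
  print(round(x$P, 4))
  cat("mean dwells tau[i,j] (ms):\n")
  print(round(x$tau, 3))
  cat(sprintf(
    "noise_sd %.3g nA, 1/f %.3g nA, %.4g kSa/s, low-pass %.4g kHz\n",
    x$noise_sd, x$pink_amplitude, x$sample_rate, x$filter_cutoff
  ))
  invisible(x)
}

# stationary distribution of the embedded (exit) chain, by linear solve
embedded_stationary <- function(P) {
  k <- nrow(P)
  # solve pi (I - P) = 0 with sum(pi) = 1: replace last column by ones
  A <- t(diag(k) - P)
  A[k, ] <- 1
  b <- c(rep(0, k - 1), 1)
  as.numeric(solve(A, b))
}

#' Closed-form long-run state occupancy of a kinetic model
#'
#' The long-run fraction of time spent in each state equals the stationary
#' distribution of the embedded exit chain weighted by each state's
#' destination-averaged mean dwell, `sum_j P[i, j] * tau[i, j]`, and
#' renormalized. This is the analytic counterpart of the time-weighted
#' occupancy that [occupancy()] measures on a simulated or idealized path.
#'
#' @param model A [kinetic_model()].
#' @return A tibble with columns `state` and `percent` (summing to 100).
#' @examples
#' stationary_occupancy(allele_models()[["WT-C"]])
#' @export
stationary_occupancy <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  pi_embed <- embedded_stationary(model$P)
  mean_dwell <- rowSums(model$P * ifelse(model$P > 0, model$tau, 0))
  w <- pi_embed * unname(mean_dwell)
  tibble(state = model$states, percent = 100 * w / sum(w))
}
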