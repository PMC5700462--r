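#' Simulate a semi-Markov state path
#'
#' Draws a sequence of sojourns from a [kinetic_model()]: from state `i` a
#' destination `j` is drawn with probability `P[i, j]`, then the sojourn
#' duration is drawn from an exponential distribution with mean `tau[i, j]`
#' ms. The initial state is drawn from the stationary distribution of the
#' embedded exit chain so long runs start in equilibrium.
#'
#' @param model A [kinetic_model()].
#' @param n_exits Number of completed sojourns to generate (each row of the
#'   result is one sojourn that ends with an observed exit).
#' @param seed Optional integer seed; when given, the call is reproducible and
#'   leaves the global RNG state untouched.
#' @return A tibble with one row per sojourn and columns `state`, `start_ms`
#'   and `duration_ms`; consecutive rows always have different states.
#' @examples
#' m <- allele_models()[["WT-C"]]
#' path <- simulate_state_path(m, n_exits = 100, seed = 1)
#' occupancy(path)
#' @export
simulate_state_path <- function(model, n_exits, seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.numeric(n_exits) || length(n_exits) != 1 || n_exits < 1) {
    abort("`n_exits` must be a single integer >= 1.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  n_exits <- as.integer(n_exits)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  k <- length(model$states)
  cumP <- t(apply(model$P, 1, cumsum))
  idx <- integer(n_exits + 1L)
  idx[1L] <- 1L + sum(runif(1) > cumsum(embedded_stationary(model$P)))
  u <- runif(n_exits)
  for (t in seq_len(n_exits)) {
    idx[t + 1L] <- 1L + sum(u[t] > cumP[idx[t], ])
  }
  from <- idx[seq_len(n_exits)]
  to <- idx[seq_len(n_exits) + 1L]
  durations <- rexp(n_exits) * model$tau[cbind(from, to)]
  tibble(
    state = model$states[from],
    start_ms = cumsum(c(0, durations[-n_exits])),
    duration_ms = durations
  )
}

# 1/f (pink) background by spectral synthesis: random phases, 1/sqrt(f)
# magnitudes, rescaled to the requested RMS amplitude.
pink_noise <- function(n, amplitude) {
  if (n < 4) {
    return(rnorm(n, 0, amplitude))
  }
  half <- (n - 1L) %/% 2L
  mag <- 1 / sqrt(seq_len(half))
  ph <- runif(half, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[1L + seq_len(half)] <- complex(modulus = mag, argument = ph)
  if (n %% 2L == 0L) spec[n / 2L + 1L] <- 1 / sqrt(n / 2)
  spec[n + 1L - seq_len(half)] <- Conj(spec[1L + seq_len(half)])
  x <- Re(fft(spec, inverse = TRUE))
  amplitude * (x - mean(x)) / sd(x)
}

# single-pole recursive low-pass; dt_ms per sample, cutoff in kHz
lowpass_single_pole <- function(x, dt_ms, cutoff_khz) {
  nyquist <- 1 / (2 * dt_ms) # kHz
  if (!is.finite(cutoff_khz) || cutoff_khz >= nyquist) {
    return(x)
  }
  rc <- 1 / (2 * pi * cutoff_khz) # ms
  alpha <- dt_ms / (rc + dt_ms)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive"))
}

#' Render a state path into a sampled current trace
#'
#' Converts a dwell sequence into a uniformly sampled current recording:
#' each sojourn contributes its state's current level for its duration,
#' sampled at `model$sample_rate`; additive Gaussian noise (`noise_sd`) and an
#' optional 1/f background (`pink_amplitude`) are then passed through a
#' single-pole low-pass filter at `model$filter_cutoff` and added. The filter
#' is applied to the noise only, so the level signal stays exactly
#' piecewise-constant and a noiseless rendering takes values exactly in the
#' level set.
#'
#' Sojourns shorter than one sampling interval are kept for a single sample
#' (with a warning); at 28.8 kSa/s and millisecond-scale lifetimes this is
#' rare.
#'
#' @param path A state-path tibble (`state`, `duration_ms`), e.g. from
#'   [simulate_state_path()] or [idealize_trace()].
#' @param model The [kinetic_model()] supplying levels, sampling rate and the
#'   noise model.
#' @inheritParams simulate_state_path
#' @return A tibble with columns `time_ms` (sample midpoints) and
#'   `current_nA`.
#' @examples
#' m <- allele_models()[["WT-C"]]
#' trace <- render_trace(simulate_state_path(m, 50, seed = 1), m, seed = 2)
#' @export
render_trace <- function(path, model, seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.data.frame(path) || nrow(path) == 0) {
    abort("`path` must be a nonempty state-path data frame.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!all(path$state %in% model$states)) {
    abort("`path` contains states absent from `model`.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  dt <- 1 / model$sample_rate # ms per sample
  n_per <- diff(c(0L, ceiling(cumsum(path$duration_ms) * model$sample_rate)))
  if (any(n_per < 1L)) {
    warn(sprintf(
      "%d dwell(s) shorter than one sample (%.4g ms) kept for a single sample.",
      sum(n_per < 1L), dt
    ))
    n_per <- pmax(n_per, 1L)
  }
  values <- rep(model$levels[path$state], times = n_per)
  n <- length(values)

  noise <- numeric(n)
  if (model$noise_sd > 0) noise <- noise + rnorm(n, 0, model$noise_sd)
  if (model$pink_amplitude > 0) noise <- noise + pink_noise(n, model$pink_amplitude)
  if (any(noise != 0)) noise <- lowpass_single_pole(noise, dt, model$filter_cutoff)

  tibble(
    time_ms = (seq_len(n) - 0.5) * dt,
    current_nA = as.numeric(values) + noise
  )
}

#' Simulate control recordings
#'
#' Two controls bracket the three-level hybridization signal: a probe-only
#' (or non-complementary target) device shows a *two-level* fluctuation from
#' hairpin folding/unfolding, and a blank device with no tethered probe shows
#' a flat recording with only Gaussian plus 1/f noise.
#'
#' @param kind `"two_level"` (hairpin folding/unfolding) or `"blank"`.
#' @param duration_ms Total recording length in ms.
#' @param params Optional overrides: for `"two_level"`, `levels` (2 values,
#'   nA), `tau_ms` (2 values: mean dwell in the folded and unfolded state),
#'   `noise_sd`; for `"blank"`, `noise_sd` and `pink_amplitude`. Sampling
#'   fields `sample_rate` and `filter_cutoff` apply to both.
#' @inheritParams simulate_state_path
#' @return A trace tibble (`time_ms`, `current_nA`).
#' @examples
#' ctrl <- simulate_control_trace("two_level", duration_ms = 200, seed = 3)
#' @export
simulate_control_trace <- function(kind, duration_ms = 2000, params = list(),
                                   seed = NULL) {
  if (!is.character(kind) || length(kind) != 1 ||
    !kind %in% c("two_level", "blank")) {
    abort('`kind` must be "two_level" or "blank".',
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  sample_rate <- params$sample_rate %||% 28.8
  filter_cutoff <- params$filter_cutoff %||% 5

  if (kind == "two_level") {
    tau_ms <- params$tau_ms %||% c(5, 5)
    m <- kinetic_model(
      levels = params$levels %||% c(0, 2.5),
      P = matrix(c(0, 1, 1, 0), 2),
      tau = matrix(c(NA, tau_ms[2], tau_ms[1], NA), 2),
      states = c("low", "high"),
      noise_sd = params$noise_sd %||% 0.5,
      pink_amplitude = params$pink_amplitude %||% 0,
      sample_rate = sample_rate,
      filter_cutoff = filter_cutoff
    )
    mean_dwell <- mean(tau_ms)
    n_exits <- max(2L, ceiling(2 * duration_ms / mean_dwell))
    path <- simulate_state_path(m, n_exits)
    keep <- cumsum(path$duration_ms) - path$duration_ms < duration_ms
    path <- path[keep, , drop = FALSE]
    over <- sum(path$duration_ms) - duration_ms
    if (over > 0) path$duration_ms[nrow(path)] <- path$duration_ms[nrow(path)] - over
    return(render_trace(path, m))
  }

  # blank device: constant zero level, noise only
  noise_sd <- params$noise_sd %||% 0.5
  pink_amplitude <- params$pink_amplitude %||% 0.3
  dt <- 1 / sample_rate
  n <- ceiling(duration_ms * sample_rate)
  noise <- numeric(n)
  if (noise_sd > 0) noise <- noise + rnorm(n, 0, noise_sd)
  if (pink_amplitude > 0) noise <- noise + pink_noise(n, pink_amplitude)
  if (any(noise != 0)) noise <- lowpass_single_pole(noise, dt, filter_cutoff)
  tibble(time_ms = (seq_len(n) - 0.5) * dt, current_nA = noise)
}

#' Simulate a normalized two-state melting curve
#'
#' Generates normalized 260 nm absorbance versus temperature for a two-state
#' (folded/unfolded) transition: the unfolded fraction follows the sigmoid
#' `1 / (1 + exp((t_m - T) / slope))`, plus additive Gaussian noise.
#'
#' @param t_m Melting temperature (sigmoid midpoint), degrees C.
#' @param slope Transition width parameter, degrees C (> 0).
#' @param temps Measurement temperatures, degrees C, strictly ascending.
#'   Defaults to 15-80 degrees C in 5-degree steps.
#' @param noise_sd Standard deviation of the additive noise on the normalized
#'   absorbance.
#' @inheritParams simulate_state_path
#' @return A tibble with columns `temp_c` and `absorbance`.
#' @examples
#' simulate_melting_curve(59.6, noise_sd = 0, seed = 1)
#' @export
simulate_melting_curve <- function(t_m, slope = 2.5, temps = seq(15, 80, by = 5),
                                   noise_sd = 0.02, seed = NULL) {
  if (!is.numeric(slope) || slope <= 0) {
    abort("`slope` must be > 0.", class = "hairpinkinetics_parameter_error")
  }
  if (length(temps) == 0 || any(diff(temps) <= 0)) {
    abort("`temps` must be nonempty and strictly ascending.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  frac <- 1 / (1 + exp((t_m - temps) / slope))
  tibble(
    temp_c = as.numeric(temps),
    absorbance = frac + rnorm(length(temps), 0, noise_sd)
  )
}

#' Check that a probe sequence can fold into a hairpin with a given stem
#'
#' A hairpin (molecular-beacon-style) probe requires its first `stem_len`
#' bases to be the reverse complement of its last `stem_len` bases so that the
#' two ends hybridize into the stem duplex.
#'
#' @param sequence DNA string over the uppercase alphabet ACGT.
#' @param stem_len Stem length in bases (> 0, with `2 * stem_len <=
#'   nchar(sequence)`).
#' @return `TRUE` if the ends are reverse-complementary, else `FALSE`.
#' @examples
#' validate_hairpin_stem("TGAGGATGGATAGATGCTTGCCTCA", 5)
#' @export
validate_hairpin_stem <- function(sequence, stem_len) {
  if (!is.character(sequence) || length(sequence) != 1 ||
    !grepl("^[ACGT]+$", sequence)) {
    abort("`sequence` must be a single uppercase ACGT string.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!is.numeric(stem_len) || length(stem_len) != 1 || stem_len <= 0 ||
    2 * stem_len > nchar(sequence)) {
    abort("`stem_len` must satisfy 0 < 2 * stem_len <= nchar(sequence).",
      class = "hairpinkinetics_parameter_error"
    )
  }
  stem_len <- as.integer(stem_len)
  five <- substr(sequence, 1L, stem_len)
  three <- substr(sequence, nchar(sequence) - stem_len + 1L, nchar(sequence))
  revcomp <- paste(rev(strsplit(chartr("ACGT", "TGCA", three), "")[[1]]),
    collapse = ""
  )
  identical(five, revcomp)
}
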