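#' Plot a current trace
#'
#' @param trace A trace tibble (`time_ms`, `current_nA`).
#' @param max_points Traces longer than this are thinned by regular
#'   subsampling before plotting.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, max_points = 20000) {
  if (nrow(trace) > max_points) {
    trace <- trace[unique(round(seq(1, nrow(trace), length.out = max_points))), ]
  }
  ggplot(trace, aes(.data$time_ms, .data$current_nA)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (ms)", y = expression(Delta * I[D] ~ "(nA)")) +
    theme_minimal()
}

#' @describeIn fit_amplitude_histogram Amplitude histogram with the fitted
#'   Gaussian components overlaid (Freedman-Diaconis bins).
#' @param trace The trace the fit was computed from (its `current_nA` samples
#'   make the histogram).
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, trace, ...) {
  x <- trace$current_nA
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    grid <- seq(min(x), max(x), length.out = 400)
    tibble(
      current_nA = grid,
      density = object$weights[j] * dnorm(grid, object$means_raw[j], object$sds[j]),
      component = object$labels[j]
    )
  })
  ggplot() +
    geom_histogram(
      data = tibble(current_nA = x),
      aes(.data$current_nA, ggplot2::after_stat(density)),
      binwidth = max(bw, 1e-6), fill = "grey80", colour = "grey60"
    ) +
    geom_line(
      data = comp,
      aes(.data$current_nA, .data$density, colour = .data$component)
    ) +
    labs(x = expression(Delta * I[D] ~ "(nA)"), y = "density", colour = "state") +
    theme_minimal()
}

#' Dwell-time histogram with the fitted exponential decay
#'
#' @param dwells A dwell tibble from [extract_dwells()].
#' @param state,next_state The direction to plot.
#' @param ... Passed to [fit_exponential()].
#' @return A ggplot object.
#' @export
plot_dwell_histogram <- function(dwells, state, next_state, ...) {
  d <- dwells$duration_ms[dwells$state == state & dwells$next_state == next_state]
  fit <- fit_exponential(d, ...)
  bw <- 2 * stats::IQR(d) / length(d)^(1 / 3)
  ggplot(tibble(duration_ms = d), aes(.data$duration_ms)) +
    geom_histogram(
      aes(y = ggplot2::after_stat(density)),
      binwidth = max(bw, 1e-6),
      fill = "grey80", colour = "grey60"
    ) +
    stat_function(
      fun = function(t) exp(-t / fit$tau_ms) / fit$tau_ms,
      colour = "firebrick"
    ) +
    labs(
      x = "dwell duration (ms)", y = "density",
      title = sprintf(
        "%s → %s: τ = %.2f ms (n = %d)",
        state, next_state, fit$tau_ms, fit$n
      )
    ) +
    theme_minimal()
}

#' Bar chart of state occupancies, optionally across alleles
#'
#' The occupancy comparison plot: per-state time percentages with error bars
#' when dispersions are available, the visual on which low-state (duplex)
#' allele discrimination rests.
#'
#' @param occ An [occupancy()] table, an [aggregate_occupancy()], or a long
#'   tibble with `state`, `percent` (or `mean_percent`/`sd_percent`) and
#'   optionally an `allele` column for grouped bars.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ) {
  df <- as_tibble(occ)
  if (!"percent" %in% names(df) && "mean_percent" %in% names(df)) {
    df <- rename(df, percent = "mean_percent")
  }
  df$state <- state_factor(df$state)
  has_allele <- "allele" %in% names(df)
  p <- ggplot(df, aes(.data$state, .data$percent,
    fill = if (has_allele) .data$allele else NULL
  )) +
    geom_col(position = if (has_allele) "dodge" else "stack") +
    labs(x = "state", y = "occupancy (%)", fill = "allele") +
    theme_minimal()
  if ("sd_percent" %in% names(df)) {
    p <- p + geom_errorbar(
      aes(
        ymin = .data$percent - .data$sd_percent,
        ymax = .data$percent + .data$sd_percent
      ),
      width = 0.2,
      position = if (has_allele) ggplot2::position_dodge(width = 0.9) else "identity"
    )
  }
  p
}

#' @describeIn fit_melting_curve Measured points with the fitted sigmoid.
#' @method autoplot melting_fit
#' @export
autoplot.melting_fit <- function(object, ...) {
  grid <- seq(min(object$data$temp_c), max(object$data$temp_c), length.out = 200)
  lo <- object$baselines[["lower"]]
  hi <- object$baselines[["upper"]]
  line <- tibble(
    temp_c = grid,
    absorbance = lo + (hi - lo) / (1 + exp((object$t_m - grid) / object$slope))
  )
  ggplot(object$data, aes(.data$temp_c, .data$absorbance)) +
    geom_point() +
    geom_line(data = line, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_m, linetype = 2, colour = "grey40") +
    labs(
      x = "temperature (°C)", y = "normalized A260",
      title = sprintf("t_m = %.1f °C", object$t_m)
    ) +
    theme_minimal()
}
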