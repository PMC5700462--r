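#' Fit a two-state sigmoid to a melting curve
#'
#' Fits `A(T) = lo + (hi - lo) / (1 + exp((t_m - T) / slope))` to normalized
#' absorbance versus temperature by Levenberg-Marquardt least squares. The
#' midpoint `t_m` is the melting temperature; `lo` and `hi` are the folded and
#' unfolded baselines, so the baseline-free unfolded fraction is available at
#' any temperature via [unfolded_fraction()]. Curves recorded with decreasing
#' orientation (absorbance falling with temperature) are re-oriented before
#' fitting and flagged.
#'
#' @param curve A data frame with columns `temp_c` (strictly ascending) and
#'   `absorbance`.
#' @return A `melting_fit` object: `t_m`, `slope`, `baselines` (lower, upper),
#'   `resid_norm`, `decreasing` flag, `n`, plus the input and fitted values.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' curve <- simulate_melting_curve(59.6, noise_sd = 0, seed = 1)
#' fit_melting_curve(curve)
#' @export
fit_melting_curve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("temp_c", "absorbance") %in% names(curve))) {
    abort("`curve` must have `temp_c` and `absorbance` columns.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (nrow(curve) < 6) {
    abort("need >= 6 points spanning the transition.",
      class = "hairpinkinetics_insufficient_data"
    )
  }
  if (any(diff(curve$temp_c) <= 0)) {
    abort("`temp_c` must be strictly ascending.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  temp <- curve$temp_c
  y <- curve$absorbance
  decreasing <- coef(lm(y ~ temp))[[2]] < 0
  if (decreasing) y <- max(y) + min(y) - y

  # starts: baselines from extremes, midpoint from half-crossing
  lo0 <- min(y)
  hi0 <- max(y)
  mid <- (lo0 + hi0) / 2
  tm0 <- tryCatch(
    approx(y, temp, xout = mid, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(tm0)) tm0 <- median(temp)
  s0 <- diff(range(temp)) / 10

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lo + (hi - lo) / (1 + exp((tm - temp) / s)),
      data = data.frame(temp = temp, y = y),
      start = list(lo = lo0, hi = hi0, tm = tm0, s = s0),
      lower = c(lo = -Inf, hi = -Inf, tm = min(temp) - 100, s = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(
        paste0(
          "sigmoid fit failed (no two-state transition in the data?): ",
          conditionMessage(e)
        ),
        class = "hairpinkinetics_fit_error"
      )
    }
  )
  cf <- coef(fit)
  lo <- min(cf[["lo"]], cf[["hi"]])
  hi <- max(cf[["lo"]], cf[["hi"]])
  if (hi - lo < 1e-8) {
    abort("fitted transition has zero amplitude: no sigmoid signal.",
      class = "hairpinkinetics_fit_error"
    )
  }
  t_m <- cf[["tm"]]
  if (t_m < min(temp) || t_m > max(temp)) {
    warn(sprintf(
      "fitted t_m (%.1f C) lies outside the measured span [%.1f, %.1f] C.",
      t_m, min(temp), max(temp)
    ))
  }
  structure(
    list(
      t_m = t_m,
      slope = cf[["s"]],
      baselines = c(lower = lo, upper = hi),
      resid_norm = sqrt(sum(residuals(fit)^2)),
      decreasing = decreasing,
      n = length(y),
      data = tibble(temp_c = temp, absorbance = y),
      fitted = as.numeric(predict(fit))
    ),
    class = "melting_fit"
  )
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf(
    "<melting_fit> t_m = %.2f C, slope = %.2f C (%d points%s)\n",
    x$t_m, x$slope, x$n,
    if (x$decreasing) ", re-oriented from decreasing input" else ""
  ))
  invisible(x)
}

#' @describeIn fit_melting_curve One-row tibble of the fitted parameters.
#' @param x,object A `melting_fit`.
#' @param ... Unused.
#' @method tidy melting_fit
#' @export
tidy.melting_fit <- function(x, ...) {
  tibble(
    t_m = x$t_m, slope = x$slope,
    baseline_lower = x$baselines[["lower"]],
    baseline_upper = x$baselines[["upper"]]
  )
}

#' @describeIn fit_melting_curve Fit diagnostics: residual norm, point count,
#'   orientation flag.
#' @method glance melting_fit
#' @export
glance.melting_fit <- function(x, ...) {
  tibble(resid_norm = x$resid_norm, n = x$n, decreasing = x$decreasing)
}

#' Unfolded fraction at a temperature
#'
#' Evaluates the baseline-free two-state sigmoid of a [fit_melting_curve()]
#' fit: 0 far below the melting temperature, 0.5 at `t_m`, 1 far above. At the
#' working temperature of a hybridization assay this is the duplex unwinding
#' probability implied by the melting curve.
#'
#' @param fit A `melting_fit`.
#' @param temperature Temperature(s), degrees C.
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' fit <- fit_melting_curve(simulate_melting_curve(59.6, noise_sd = 0))
#' unfolded_fraction(fit, 45)
#' @export
unfolded_fraction <- function(fit, temperature) {
  stopifnot(inherits(fit, "melting_fit"))
  1 / (1 + exp((fit$t_m - temperature) / fit$slope))
}
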