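canonical_states <- c("low", "intermediate", "high")

state_factor <- function(x) {
  lv <- unique(c(canonical_states[canonical_states %in% x], sort(setdiff(x, canonical_states))))
  factor(x, levels = lv)
}

#' Extract direction-resolved dwell records from a state path
#'
#' Returns one record per *interior* sojourn: the first sojourn has no
#' observed beginning and the last no observed exit, so both are censored and
#' excluded from dwell statistics (they still count toward [occupancy()],
#' which uses the whole path). Each record carries the destination state, so
#' dwell distributions can be split by the conformation that follows -- the
#' same state can show different lifetimes depending on where it exits to.
#'
#' @param path A state-path tibble (`state`, `duration_ms`), with consecutive
#'   rows in different states.
#' @return A tibble with columns `state`, `duration_ms`, `next_state`; empty
#'   (with a message) if the path has fewer than 3 sojourns.
#' @examples
#' path <- tibble::tibble(
#'   state = c("low", "intermediate", "low"),
#'   duration_ms = c(5, 2, 3)
#' )
#' extract_dwells(path)
#' @export
extract_dwells <- function(path) {
  if (!is.data.frame(path) || !all(c("state", "duration_ms") %in% names(path))) {
    abort("`path` must have `state` and `duration_ms` columns.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (nrow(path) >= 2 && any(path$state[-1] == path$state[-nrow(path)])) {
    abort("consecutive path entries must have different states.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (nrow(path) < 3) {
    message("path has fewer than 3 sojourns; no uncensored dwells to extract.")
    return(tibble(
      state = character(), duration_ms = numeric(),
      next_state = character()
    ))
  }
  tibble(
    state = path$state,
    duration_ms = path$duration_ms,
    next_state = lead(path$state)
  ) %>%
    slice(2:(nrow(path) - 1L))
}

#' Fit a single-exponential lifetime to dwell durations
#'
#' The maximum-likelihood estimate of an exponential mean is the sample mean;
#' a nonparametric bootstrap supplies the confidence interval. A binned
#' least-squares fit of `A * exp(-t / tau)` to the dwell-time histogram
#' (Freedman-Diaconis bins) is also reported as the classical
#' histogram-decay cross-check.
#'
#' @param durations Dwell durations, ms (all > 0).
#' @param n_min Minimum number of durations required.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @param conf Confidence level.
#' @param binned Also compute the binned least-squares estimate?
#' @param dead_time_ms Optional first-order dead-time correction: detection
#'   systems miss sojourns shorter than their dead time, which biases the
#'   sample mean low by about that amount; the correction simply adds it back.
#'   Default 0 (off).
#' @inheritParams simulate_state_path
#' @return An `exp_fit` object with components `tau_ms`, `ci` (length 2),
#'   `se`, `n`, and `tau_binned_ms` (NA if not computed or not converged).
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' fit_exponential(rexp(200, rate = 1 / 18.45), seed = 1)
#' @export
fit_exponential <- function(durations, n_min = 10, n_boot = 1000, conf = 0.95,
                            binned = TRUE, dead_time_ms = 0, seed = NULL) {
  durations <- as.numeric(durations)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    abort("`durations` must be positive and finite.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  n <- length(durations)
  if (n < n_min) {
    abort(sprintf("need >= %d durations for a lifetime fit (got %d).", n_min, n),
      class = "hairpinkinetics_insufficient_data", n = n
    )
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  tau <- mean(durations) + dead_time_ms
  boot <- vapply(
    seq_len(n_boot),
    function(i) mean(durations[sample.int(n, n, replace = TRUE)]) + dead_time_ms,
    numeric(1)
  )
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha)))

  tau_binned <- NA_real_
  if (binned && n >= 30) {
    brk <- pretty(range(durations), n = max(5, grDevices::nclass.FD(durations)))
    h <- graphics::hist(durations, breaks = brk, plot = FALSE)
    keep <- h$counts > 0
    tau_binned <- tryCatch(
      {
        fit <- minpack.lm::nlsLM(
          counts ~ A * exp(-mid / tb),
          data = data.frame(counts = h$counts[keep], mid = h$mids[keep]),
          start = list(A = max(h$counts), tb = tau)
        )
        unname(coef(fit)[["tb"]])
      },
      error = function(e) {
        warn(paste("binned exponential fit did not converge:", conditionMessage(e)))
        NA_real_
      }
    )
  }

  structure(
    list(
      tau_ms = tau, ci = ci, se = sd(boot), n = n, conf = conf,
      tau_binned_ms = tau_binned
    ),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> tau = %.4g ms [%.4g, %.4g] (%d dwells, %.0f%% bootstrap CI)\n",
    x$tau_ms, x$ci[1], x$ci[2], x$n, 100 * x$conf
  ))
  invisible(x)
}

#' @describeIn fit_exponential One-row tibble with the estimate, CI bounds,
#'   bootstrap SE, dwell count and the binned cross-check.
#' @param x A fitted `exp_fit`.
#' @param ... Unused.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(
    tau_ms = x$tau_ms, conf_low = x$ci[1], conf_high = x$ci[2],
    se = x$se, n = x$n, tau_binned_ms = x$tau_binned_ms
  )
}

#' Estimate the transition-probability / lifetime matrix from dwell records
#'
#' For every observed direction `i -> j`, the exit probability is the count
#' fraction `P_hat[i, j] = n(i -> j) / n(exits from i)` and the mean lifetime
#' is a [fit_exponential()] fit to that direction's durations. Directions with
#' fewer than `n_min` dwells keep their counts and probabilities but report no
#' lifetime.
#'
#' @param dwells A dwell tibble from [extract_dwells()].
#' @inheritParams fit_exponential
#' @return A tibble of class `kinetic_matrix` with columns `state`,
#'   `next_state`, `n_dwells`, `p_hat`, `tau_ms`, `tau_conf_low`,
#'   `tau_conf_high`. Each state's `p_hat` values sum to 1 over its observed
#'   destinations.
#' @examples
#' path <- simulate_state_path(allele_models()[["WT-C"]], 500, seed = 1)
#' kinetic_summary(extract_dwells(path))
#' @export
kinetic_summary <- function(dwells, n_min = 10, n_boot = 1000, seed = NULL) {
  if (!is.data.frame(dwells) || nrow(dwells) == 0) {
    abort("`dwells` must be a nonempty dwell data frame.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  out <- dwells %>%
    group_by(.data$state, .data$next_state) %>%
    summarise(
      n_dwells = n(),
      durations = list(.data$duration_ms),
      .groups = "drop_last"
    ) %>%
    mutate(p_hat = .data$n_dwells / sum(.data$n_dwells)) %>%
    ungroup()

  fits <- purrr::map(out$durations, function(d) {
    if (length(d) < n_min) {
      return(list(tau = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    f <- fit_exponential(d, n_min = n_min, n_boot = n_boot, binned = FALSE)
    list(tau = f$tau_ms, lo = f$ci[1], hi = f$ci[2])
  })
  out <- out %>%
    mutate(
      tau_ms = purrr::map_dbl(fits, "tau"),
      tau_conf_low = purrr::map_dbl(fits, "lo"),
      tau_conf_high = purrr::map_dbl(fits, "hi")
    ) %>%
    select(-"durations") %>%
    arrange(state_factor(.data$state), state_factor(.data$next_state)) %>%
    mutate(
      state = as.character(.data$state),
      next_state = as.character(.data$next_state)
    )
  class(out) <- c("kinetic_matrix", class(out))
  out
}

#' Time-weighted state occupancy of a path
#'
#' Fraction of the total recorded time spent in each state, in percent. All
#' sojourns count, including the censored first and last ones -- occupancy is
#' a whole-trace statistic, unlike the dwell analysis of [extract_dwells()].
#'
#' @inheritParams extract_dwells
#' @return A tibble of class `occupancy_table` with columns `state` and
#'   `percent` (summing to 100) and attribute `total_time_ms`.
#' @examples
#' occupancy(simulate_state_path(allele_models()[["WT-C"]], 100, seed = 1))
#' @export
occupancy <- function(path) {
  if (!is.data.frame(path) || nrow(path) == 0) {
    abort("`path` must be a nonempty state-path data frame.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  total <- sum(path$duration_ms)
  if (!is.finite(total) || total <= 0) {
    abort("path has zero total duration.", class = "hairpinkinetics_parameter_error")
  }
  out <- path %>%
    group_by(.data$state) %>%
    summarise(time_ms = sum(.data$duration_ms), .groups = "drop") %>%
    mutate(percent = 100 * .data$time_ms / total) %>%
    arrange(state_factor(.data$state)) %>%
    mutate(state = as.character(.data$state)) %>%
    select("state", "percent")
  attr(out, "total_time_ms") <- total
  class(out) <- c("occupancy_table", class(out))
  out
}
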