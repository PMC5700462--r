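#' Aggregate occupancy tables across devices
#'
#' Single-molecule devices differ in absolute current amplitude, but the
#' *fraction of time* spent in each conformational state is comparable across
#' devices, so allele discrimination averages occupancies over independent
#' recordings. Computes the arithmetic mean and sample standard deviation of
#' the per-state percentages.
#'
#' @param tables Either a list of [occupancy()] tables (all sharing the same
#'   state set) or a long data frame with columns `state`, `percent` and a
#'   `device` identifier column.
#' @return A tibble of class `aggregate_occupancy` with columns `state`,
#'   `mean_percent`, `sd_percent` and `n_devices`. Values are kept at full
#'   precision; the print method rounds to one decimal.
#' @examples
#' wtc <- dplyr::filter(device_occupancy(), allele == "WT-C")
#' aggregate_occupancy(wtc)
#' @export
aggregate_occupancy <- function(tables) {
  if (is.data.frame(tables)) {
    df <- tables
    if (!all(c("state", "percent") %in% names(df))) {
      abort("data frame input must have `state` and `percent` columns.",
        class = "hairpinkinetics_parameter_error"
      )
    }
    if (!"device" %in% names(df)) df$device <- 1L
  } else if (is.list(tables) && length(tables) >= 1) {
    sets <- purrr::map(tables, function(t) sort(unique(t$state)))
    if (length(unique(purrr::map_chr(sets, paste, collapse = "|"))) != 1) {
      abort("all occupancy tables must share the same state set.",
        class = "hairpinkinetics_parameter_error"
      )
    }
    df <- bind_rows(purrr::map(tables, as_tibble), .id = "device")
  } else {
    abort("`tables` must be a data frame or a nonempty list of occupancy tables.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  out <- df %>%
    group_by(.data$state) %>%
    summarise(
      mean_percent = mean(.data$percent),
      sd_percent = if (n() > 1) sd(.data$percent) else 0,
      n_devices = n(),
      .groups = "drop"
    ) %>%
    arrange(state_factor(.data$state)) %>%
    mutate(state = as.character(.data$state))
  class(out) <- c("aggregate_occupancy", class(out))
  out
}

#' @export
print.aggregate_occupancy <- function(x, ...) {
  cat("<aggregate_occupancy> over", max(x$n_devices), "device(s)\n")
  y <- as_tibble(x) %>%
    mutate(
      mean_percent = round(.data$mean_percent, 1),
      sd_percent = round(.data$sd_percent, 1)
    )
  print(y)
  invisible(x)
}

# coerce occupancy_table / aggregate_occupancy / plain df to (state, percent)
as_occupancy_profile <- function(x) {
  df <- as_tibble(x)
  if ("percent" %in% names(df)) {
    return(df %>% select("state", "percent"))
  }
  if ("mean_percent" %in% names(df)) {
    return(df %>% select("state", percent = "mean_percent"))
  }
  abort("cannot interpret input as an occupancy profile.",
    class = "hairpinkinetics_parameter_error"
  )
}

#' Call the allele of an observed occupancy profile
#'
#' Compares an observed state-occupancy profile with labelled reference
#' profiles and calls the nearest one. The distance is Euclidean on the
#' vector of state percentages, with each coordinate standardized by the
#' reference profile's across-device dispersion (floored at `sd_floor`
#' percentage points so near-zero dispersions cannot dominate). States absent
#' from one side are treated as 0%. Ties are broken toward the profile with
#' the larger low-state (duplex) percentage and flagged.
#'
#' @param observed An [occupancy()] table, an [aggregate_occupancy()], or any
#'   data frame with `state` and `percent` (or `mean_percent`) columns.
#' @param references A long data frame like [reference_occupancy()] (columns
#'   `allele`, `state`, `mean_percent`, `sd_percent`), or a named list of
#'   profiles accepted by `observed`.
#' @param sd_floor Lower bound for the standardizing dispersion, percentage
#'   points.
#' @return An `allele_call` object: `call` (the winning label), `tie` flag,
#'   `distances` tibble (one row per reference, ascending), and the observed
#'   profile. [tidy()] returns the distance table.
#' @examples
#' obs <- tibble::tibble(
#'   state = c("low", "intermediate", "high"),
#'   percent = c(78.5, 20.2, 1.3)
#' )
#' call_allele(obs)
#' @export
call_allele <- function(observed, references = reference_occupancy(),
                        sd_floor = 0.5) {
  obs <- as_occupancy_profile(observed)
  if (is.data.frame(references)) {
    refs <- as_tibble(references)
    if (!all(c("allele", "state", "mean_percent") %in% names(refs))) {
      abort("reference data frame needs `allele`, `state`, `mean_percent` columns.",
        class = "hairpinkinetics_parameter_error"
      )
    }
    if (!"sd_percent" %in% names(refs)) refs$sd_percent <- 0
    ref_list <- split(refs, refs$allele)
  } else {
    if (!is.list(references) || length(references) == 0 ||
      is.null(names(references)) || any(names(references) == "")) {
      abort("`references` must be nonempty and named.",
        class = "hairpinkinetics_parameter_error"
      )
    }
    ref_list <- purrr::map(references, function(r) {
      p <- as_occupancy_profile(r)
      p$mean_percent <- p$percent
      p$sd_percent <- if ("sd_percent" %in% names(as_tibble(r))) {
        as_tibble(r)$sd_percent
      } else {
        0
      }
      p
    })
  }

  dist_tbl <- purrr::map_dfr(names(ref_list), function(lab) {
    r <- ref_list[[lab]]
    states <- union(obs$state, r$state)
    o <- setNames(rep(0, length(states)), states)
    o[obs$state] <- obs$percent
    mu <- setNames(rep(0, length(states)), states)
    mu[r$state] <- r$mean_percent
    s <- setNames(rep(sd_floor, length(states)), states)
    s[r$state] <- pmax(r$sd_percent, sd_floor)
    low <- if ("low" %in% r$state) mu[["low"]] else NA_real_
    tibble(
      allele = lab,
      distance = sqrt(sum(((o - mu) / s)^2)),
      ref_low_percent = low
    )
  }) %>%
    arrange(.data$distance, dplyr::desc(.data$ref_low_percent))

  tie <- nrow(dist_tbl) > 1 &&
    isTRUE(abs(dist_tbl$distance[1] - dist_tbl$distance[2]) < 1e-12)
  structure(
    list(
      call = dist_tbl$allele[1],
      tie = tie,
      distances = dist_tbl,
      observed = obs
    ),
    class = "allele_call"
  )
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf(
    "<allele_call> %s%s (low state %.1f%%)\n",
    x$call, if (x$tie) " [TIE]" else "",
    if ("low" %in% x$observed$state) {
      x$observed$percent[x$observed$state == "low"]
    } else {
      NA_real_
    }
  ))
  print(x$distances)
  invisible(x)
}

#' @describeIn call_allele Distance table with the called allele flagged.
#' @param x An `allele_call`.
#' @param ... Unused.
#' @method tidy allele_call
#' @export
tidy.allele_call <- function(x, ...) {
  x$distances %>% mutate(called = .data$allele == x$call, tie = x$tie)
}

#' Rank alleles by duplex stability and unwinding probability
#'
#' Orders labelled kinetic matrices by two signatures of probe-target duplex
#' stability: (a) the destination-averaged mean lifetime of the low (duplex)
#' state, `sum_j P_hat[low, j] * tau_hat[low, j]`, descending -- the
#' well-matched target forms the longest-lived duplex; and (b) the unwinding
#' probability `P_hat(low -> high)`, descending -- the least stable duplex
#' most often dissociates directly to the single-stranded state.
#'
#' @param matrices Named list of [kinetic_summary()] results.
#' @return A tibble with one row per label: `allele`, `low_lifetime_ms`
#'   (destination-averaged), `p_low_high`, `rank_lifetime`, `rank_unwinding`
#'   and tie flags. Labels without complete low-state lifetime estimates are
#'   dropped with a warning.
#' @examples
#' paths <- lapply(allele_models(), simulate_state_path, n_exits = 2000, seed = 5)
#' mats <- lapply(paths, function(p) kinetic_summary(extract_dwells(p)))
#' rank_stability(mats)
#' @export
rank_stability <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0 || is.null(names(matrices))) {
    abort("`matrices` must be a nonempty named list of kinetic matrices.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  rows <- purrr::map(names(matrices), function(lab) {
    m <- as_tibble(matrices[[lab]]) %>% filter(.data$state == "low")
    if (nrow(m) == 0 || any(is.na(m$tau_ms))) {
      warn(sprintf("'%s' lacks complete low-state lifetime estimates; excluded.", lab))
      return(NULL)
    }
    tibble(
      allele = lab,
      low_lifetime_ms = sum(m$p_hat * m$tau_ms),
      p_low_high = if ("high" %in% m$next_state) {
        m$p_hat[m$next_state == "high"]
      } else {
        0
      }
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no label had usable low-state estimates.",
      class = "hairpinkinetics_insufficient_data"
    )
  }
  out %>%
    mutate(
      rank_lifetime = rank(-.data$low_lifetime_ms, ties.method = "min"),
      rank_unwinding = rank(-.data$p_low_high, ties.method = "min"),
      tie_lifetime = duplicated(.data$low_lifetime_ms) |
        duplicated(.data$low_lifetime_ms, fromLast = TRUE),
      tie_unwinding = duplicated(.data$p_low_high) |
        duplicated(.data$p_low_high, fromLast = TRUE)
    ) %>%
    arrange(.data$rank_lifetime)
}
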