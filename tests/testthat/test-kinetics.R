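test_that("dwell extraction censors the first and last sojourns", {
  path <- tibble::tibble(
    state = c("low", "intermediate", "low"),
    duration_ms = c(5, 2, 3)
  )
  dw <- extract_dwells(path)
  expect_equal(nrow(dw), 1)
  expect_equal(dw$state, "intermediate")
  expect_equal(dw$duration_ms, 2)
  expect_equal(dw$next_state, "low")

  expect_message(
    empty <- extract_dwells(tibble::tibble(state = "low", duration_ms = 10)),
    "fewer than 3"
  )
  expect_equal(nrow(empty), 0)

  # a long simulated path populates all 6 direction groups
  dw6 <- extract_dwells(wtc_path_20k())
  expect_equal(nrow(dplyr::distinct(dw6, state, next_state)), 6)
  expect_equal(nrow(dw6), nrow(wtc_path_20k()) - 2)

  expect_error(
    extract_dwells(tibble::tibble(state = c("low", "low"), duration_ms = c(1, 1))),
    class = "hairpinkinetics_parameter_error"
  )
})

test_that("exponential lifetime fitting is the sample mean, with sane CI and scale equivariance", {
  expect_equal(fit_exponential(rep(3.5, 20), binned = FALSE)$tau_ms, 3.5)

  withr::with_seed(99, d <- rexp(10000, rate = 1 / 18.45))
  fit <- fit_exponential(d, seed = 1)
  # SE(tau_hat) = tau / sqrt(n) ~ 0.18 ms, so 2% is > 10 SE slack at this n
  expect_lt(abs(fit$tau_ms - 18.45) / 18.45, 0.02)
  expect_lt(fit$ci[1], fit$tau_ms)
  expect_gt(fit$ci[2], fit$tau_ms)
  # the binned histogram fit agrees with the MLE to a few percent
  expect_lt(abs(fit$tau_binned_ms - fit$tau_ms) / fit$tau_ms, 0.1)

  scaled <- fit_exponential(d * 7, seed = 1)
  expect_equal(scaled$tau_ms, fit$tau_ms * 7)

  err <- expect_error(fit_exponential(rexp(5), n_min = 10),
    class = "hairpinkinetics_insufficient_data"
  )
  expect_equal(err$n, 5)
  expect_error(fit_exponential(c(1, -2, 3)),
    class = "hairpinkinetics_parameter_error"
  )
})

test_that("kinetic summary recovers the generating P and tau matrices", {
  m <- allele_models()[["WT-C"]]
  dwells <- extract_dwells(wtc_path_20k())
  ks <- kinetic_summary(dwells, n_boot = 100, seed = 5)

  # rows sum to 1 over observed destinations, by construction
  sums <- tapply(ks$p_hat, ks$state, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  for (r in seq_len(nrow(ks))) {
    p <- m$P[ks$state[r], ks$next_state[r]]
    n_exit <- sum(ks$n_dwells[ks$state == ks$state[r]])
    expect_lt(abs(ks$p_hat[r] - p), 3 * sqrt(p * (1 - p) / n_exit))
    true_tau <- m$tau[ks$state[r], ks$next_state[r]]
    expect_lt(
      abs(ks$tau_ms[r] - true_tau) / true_tau,
      3 / sqrt(ks$n_dwells[r]) + 0.01
    )
  }

  # single observed destination gives p_hat = 1
  solo <- kinetic_summary(
    tibble::tibble(
      state = rep("low", 12), duration_ms = rexp(12, 1),
      next_state = rep("intermediate", 12)
    ),
    n_boot = 20
  )
  expect_equal(solo$p_hat, 1)
})

test_that("occupancy is time-weighted over the whole path", {
  eq <- occupancy(tibble::tibble(
    state = c("low", "intermediate", "high"),
    duration_ms = c(1, 1, 1)
  ))
  expect_equal(eq$percent, rep(100 / 3, 3))
  expect_equal(sum(eq$percent), 100, tolerance = 1e-4)

  expect_error(occupancy(tibble::tibble(state = character(), duration_ms = numeric())),
    class = "hairpinkinetics_parameter_error"
  )
  expect_error(
    occupancy(tibble::tibble(state = "low", duration_ms = 0)),
    class = "hairpinkinetics_parameter_error"
  )
})

test_that("long-run occupancy matches the closed-form stationary fractions", {
  m <- allele_models()[["WT-C"]]
  occ <- occupancy(wtc_path_50k())
  oracle <- oracle_stationary_percent(m$P, m$tau)
  expect_true(all(abs(occ$percent - oracle) < 1)) # within 1 percentage point
})
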