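test_that("simulated paths alternate states, are reproducible, and censor nothing", {
  m <- allele_models()[["WT-C"]]
  p1 <- simulate_state_path(m, 500, seed = 7)
  p2 <- simulate_state_path(m, 500, seed = 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 500)
  expect_true(all(p1$duration_ms > 0))
  expect_true(all(p1$state[-1] != p1$state[-500]))
  expect_equal(p1$start_ms, cumsum(c(0, p1$duration_ms[-500])))

  # forced alternation
  forced <- simulate_state_path(forced_two_state(), 20, seed = 1)
  expect_true(all(forced$state == rep_len(forced$state[1:2], 20)))

  expect_error(simulate_state_path(m, 0), class = "hairpinkinetics_parameter_error")
})

test_that("exit-destination frequencies converge to P within 3 binomial SE", {
  m <- allele_models()[["WT-C"]]
  path <- wtc_path_20k()
  dwells <- extract_dwells(path)
  tab <- table(dwells$state, dwells$next_state)
  for (i in m$states) {
    n_i <- sum(tab[i, ])
    for (j in setdiff(m$states, i)) {
      p <- m$P[i, j]
      se <- sqrt(p * (1 - p) / n_i)
      expect_lt(abs(tab[i, j] / n_i - p), 3 * se + 1e-12)
    }
  }
})

test_that("per-direction dwell means converge to tau", {
  m <- allele_models()[["WT-C"]]
  dwells <- extract_dwells(wtc_path_50k())
  agg <- aggregate(duration_ms ~ state + next_state, dwells, function(d) {
    c(mean = mean(d), n = length(d))
  })
  for (r in seq_len(nrow(agg))) {
    true_tau <- m$tau[agg$state[r], agg$next_state[r]]
    rel_err <- abs(agg$duration_ms[r, "mean"] - true_tau) / true_tau
    if (agg$duration_ms[r, "n"] >= 5000) expect_lt(rel_err, 0.05)
    expect_lt(rel_err, 3 / sqrt(agg$duration_ms[r, "n"]) + 0.01)
  }
})

test_that("noiseless rendering takes values exactly in the level set and inverts", {
  m <- allele_models(noise_sd = 0)[["WT-C"]]
  path <- simulate_state_path(m, 80, seed = 3)
  trace <- suppressWarnings(render_trace(path, m))
  expect_setequal(unique(trace$current_nA), unname(m$levels))

  # total sample count: ceiling(total duration x rate) when no dwell needs
  # clamping to one sample
  fixed <- tibble::tibble(
    state = c("low", "intermediate", "low"),
    start_ms = c(0, 10, 15.3),
    duration_ms = c(10, 5.3, 7.21)
  )
  expect_equal(
    nrow(render_trace(fixed, m)),
    ceiling(sum(fixed$duration_ms) * m$sample_rate)
  )

  # nearest-level assignment recovers the generating per-sample states
  nearest <- m$states[
    apply(abs(outer(trace$current_nA, m$levels, "-")), 1, which.min)
  ]
  expect_identical(nearest, expand_states(path, m$sample_rate))
})

test_that("rendered noise behaves: single-state mean near level, mixture recoverable", {
  m <- forced_two_state(noise_sd = 0.5)
  one_state <- tibble::tibble(state = "low", start_ms = 0, duration_ms = 500)
  tr <- render_trace(one_state, m, seed = 9)
  n <- nrow(tr)
  expect_lt(abs(mean(tr$current_nA) - m$levels[["low"]]), 3 * 0.5 / sqrt(n))

  # three-level trace with >= 1e5 samples: mixture recovers level means +-0.1 nA
  mw <- allele_models()[["WT-C"]]
  path <- simulate_state_path(mw, 450, seed = 10)
  tr3 <- suppressWarnings(render_trace(path, mw, seed = 11))
  expect_gte(nrow(tr3), 1e5)
  fit <- fit_amplitude_histogram(tr3)
  expect_equal(fit$k, 3)
  expect_true(all(abs(fit$means_raw - unname(mw$levels)) < 0.1))
})

test_that("control traces have the expected level structure", {
  two <- simulate_control_trace("two_level", duration_ms = 800, seed = 5)
  expect_equal(fit_amplitude_histogram(two)$k, 2)

  blank <- simulate_control_trace("blank", duration_ms = 800, seed = 6)
  expect_equal(fit_amplitude_histogram(blank)$k, 1)

  silent <- simulate_control_trace("blank",
    duration_ms = 50,
    params = list(noise_sd = 0, pink_amplitude = 0)
  )
  expect_true(all(silent$current_nA == 0))

  expect_error(simulate_control_trace("three_level"),
    class = "hairpinkinetics_parameter_error"
  )
})

test_that("melting-curve simulation follows the two-state sigmoid", {
  curve <- simulate_melting_curve(59.6, noise_sd = 0)
  expect_equal(nrow(curve), 14) # 15..80 C in 5 C steps
  exact <- simulate_melting_curve(50, slope = 3, temps = c(30, 50, 70, 90),
    noise_sd = 0
  )
  expect_equal(exact$absorbance[2], 0.5)
  expect_lt(exact$absorbance[1], 0.01)
  expect_gt(exact$absorbance[4], 0.99)
  expect_error(
    simulate_melting_curve(50, temps = c(40, 30)),
    class = "hairpinkinetics_parameter_error"
  )
  expect_error(
    simulate_melting_curve(50, slope = -1),
    class = "hairpinkinetics_parameter_error"
  )
})

test_that("hairpin stem validation checks reverse complementarity", {
  expect_true(validate_hairpin_stem("TGAGGATGGATAGATGCTTGCCTCA", 5))
  expect_false(validate_hairpin_stem("AAAAATTTTTGGGGG", 5))
  expect_true(validate_hairpin_stem("ACGTACGT", 4)) # whole-sequence palindrome
  expect_error(validate_hairpin_stem("ACGT", 0),
    class = "hairpinkinetics_parameter_error"
  )
  expect_error(validate_hairpin_stem("ACGU", 1),
    class = "hairpinkinetics_parameter_error"
  )
  expect_error(validate_hairpin_stem("ACGT", 3),
    class = "hairpinkinetics_parameter_error"
  )
})
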