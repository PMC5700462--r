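test_that("amplitude-histogram fitting selects the true level count and re-centers the baseline", {
  m <- allele_models()[["WT-C"]]
  path <- simulate_state_path(m, 300, seed = 21)
  trace <- suppressWarnings(render_trace(path, m, seed = 22))
  fit <- fit_amplitude_histogram(trace)
  expect_equal(fit$k, 3)
  # baseline = middle component for k = 3, reported mean exactly 0,
  # low negative / high positive
  expect_identical(fit$baseline_index, 2L)
  expect_identical(fit$means[2], 0)
  expect_lt(fit$means[1], 0)
  expect_gt(fit$means[3], 0)
  expect_identical(fit$labels, c("low", "intermediate", "high"))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)

  # k = 2: lowest component is the baseline
  two <- simulate_control_trace("two_level", duration_ms = 600, seed = 23)
  fit2 <- fit_amplitude_histogram(two)
  expect_equal(fit2$k, 2)
  expect_identical(fit2$baseline_index, 1L)
  expect_identical(fit2$means[1], 0)

  expect_error(
    fit_amplitude_histogram(tibble::tibble(time_ms = 1:10, current_nA = rnorm(10))),
    class = "hairpinkinetics_insufficient_data"
  )
})

test_that("model selection degrades monotonically as noise swamps the level spacing", {
  m_mid <- allele_models(noise_sd = 1.0)[["WT-C"]]
  m_big <- allele_models(noise_sd = 3.0)[["WT-C"]] # ~level spacing, peaks merge
  path <- simulate_state_path(m_mid, 200, seed = 31)
  k_mid <- fit_amplitude_histogram(
    suppressWarnings(render_trace(path, m_mid, seed = 32))
  )$k
  k_big <- fit_amplitude_histogram(
    suppressWarnings(render_trace(path, m_big, seed = 32))
  )$k
  expect_equal(k_mid, 3)
  expect_lt(k_big, 3)
})

test_that("noiseless traces are idealized back to the generating path", {
  m <- allele_models(noise_sd = 0)[["WT-C"]]
  path <- simulate_state_path(m, 120, seed = 41)
  trace <- suppressWarnings(render_trace(path, m))
  # mixture fitting needs spread; supply the exact generative fit instead
  fit <- structure(
    list(
      k = 3L,
      means = unname(m$levels) - m$levels[["intermediate"]],
      means_raw = unname(m$levels),
      sds = rep(0.1, 3),
      weights = rep(1 / 3, 3),
      baseline_index = 2L,
      labels = m$states,
      bic = tibble::tibble(k = 3L, bic = NA_real_),
      n = nrow(trace)
    ),
    class = "mixture_fit"
  )
  ide <- idealize_trace(trace, fit, min_dwell_samples = 1)
  truth <- expand_states(path, m$sample_rate)
  decoded <- expand_decoded(ide, m$sample_rate)
  expect_identical(decoded, truth)
  # dwell count matches up to clamped sub-sample dwells
  n_short <- sum(path$duration_ms < 1 / m$sample_rate)
  expect_gte(nrow(ide), nrow(path) - 2 * n_short)
})

test_that("noisy roundtrip recovers >99% of samples and >=95% of resolvable dwells", {
  m <- allele_models()[["WT-C"]] # noise_sd 0.5
  path <- simulate_state_path(m, 300, seed = 51)
  trace <- suppressWarnings(render_trace(path, m, seed = 52))
  fit <- fit_amplitude_histogram(trace)
  expect_equal(fit$k, 3)
  ide <- idealize_trace(trace, fit)

  truth <- expand_states(path, m$sample_rate)
  decoded <- expand_decoded(ide, m$sample_rate)
  n <- min(length(truth), length(decoded))
  accuracy <- mean(truth[seq_len(n)] == decoded[seq_len(n)])
  expect_gt(accuracy, 0.99)

  # dwells of >= 5 samples should nearly all be recovered
  dt <- 1 / m$sample_rate
  long_true <- sum(path$duration_ms >= 5 * dt)
  expect_gte(nrow(ide) / long_true, 0.95)

  # occupancy agrees between the generating and idealized paths
  expect_equal(occupancy(ide)$percent, occupancy(path)$percent, tolerance = 0.02)
})

test_that("a single-component fit refuses idealization (blank device)", {
  blank <- simulate_control_trace("blank", duration_ms = 500, seed = 61)
  fit <- fit_amplitude_histogram(blank)
  expect_equal(fit$k, 1)
  expect_error(idealize_trace(blank, fit), class = "hairpinkinetics_no_dynamics")
})

test_that("sub-threshold dwells are merged into the longer neighbor, ties to the left", {
  # states: 1(x6) 2(x1) 1(x4): run of one sample is absorbed by the left run
  merged <- hairpinkinetics:::merge_short_runs(c(rep(1L, 6), 2L, rep(1L, 4)), 2)
  expect_identical(merged, rep(1L, 11))
  # tie between neighbors of equal length goes to the preceding run
  tie <- hairpinkinetics:::merge_short_runs(c(1L, 1L, 3L, 2L, 2L), 2)
  expect_identical(tie, c(1L, 1L, 1L, 2L, 2L))
})
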