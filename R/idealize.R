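# fit a k-component unequal-variance Gaussian mixture to raw samples with
# mclust's EM, from several deterministic initializations (range-spread and
# quantile-spread means; two variance scales), keeping the best likelihood.
# A default (single, quantile-based) initialization can drop a component that
# holds only ~1% of the samples, which the three-level traces routinely have.
# Returns NULL if no initialization converges.
fit_gmm_k <- function(x, k) {
  n <- length(x)
  if (sd(x) < 1e-12) {
    if (k > 1) {
      return(NULL)
    }
    return(list(
      k = 1L, means = mean(x), sds = 0, weights = 1,
      loglik = Inf, bic = Inf
    ))
  }
  if (k == 1) {
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    ll <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
    return(list(
      k = 1L, means = mu, sds = sqrt(s2), weights = 1,
      loglik = ll, bic = 2 * ll - 2 * log(n)
    ))
  }
  mean_starts <- list(
    seq(min(x), max(x), length.out = k),
    as.numeric(quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
  )
  var_starts <- c(stats::var(x) / k^2, stats::var(x) / 4)
  best <- NULL
  for (mu0 in mean_starts) {
    for (s20 in var_starts) {
      f <- tryCatch(
        mclust::emV(
          data = x,
          parameters = list(
            pro = rep(1 / k, k), mean = mu0,
            variance = list(
              modelName = "V", d = 1, G = k,
              sigmasq = rep(s20, k)
            )
          )
        ),
        error = function(e) NULL
      )
      if (is.null(f) || !is.finite(f$loglik)) next
      if (any(!is.finite(f$parameters$mean)) ||
        any(f$parameters$variance$sigmasq <= 0) ||
        any(!is.finite(f$parameters$pro))) {
        next
      }
      if (is.null(best) || f$loglik > best$loglik) {
        best <- list(
          k = as.integer(k),
          means = as.numeric(f$parameters$mean),
          sds = sqrt(rep_len(f$parameters$variance$sigmasq, k)),
          weights = as.numeric(f$parameters$pro),
          loglik = f$loglik
        )
      }
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  best$bic <- 2 * best$loglik - (3 * k - 1) * log(n)
  best
}

#' Fit the amplitude histogram of a trace with a Gaussian mixture
#'
#' Fits Gaussian mixtures with 1 to `k_max` components to the raw current
#' samples (unequal variances) and selects the number of components by BIC.
#' The chosen `k` doubles as the level count used to classify recordings:
#' 3 for three-state hybridization traces, 2 for the hairpin folding/unfolding
#' control and 1 for a blank device.
#'
#' One component is designated the conductance baseline ("0") and all reported
#' means are re-centered on it: for `k = 3` the *middle* component (the
#' hairpin/intermediate level sits at 0 between the negative duplex and
#' positive single-strand excursions), for `k <= 2` the *lowest* component
#' (for a two-level trace the low-conductance state is the baseline).
#'
#' @param trace A trace tibble with columns `time_ms` and `current_nA`.
#' @param k_max Maximum number of components to consider (1-3).
#' @return A `mixture_fit` object: number of components `k`, component
#'   `means` (re-centered, ascending) with `means_raw`, `sds`, `weights`,
#'   `baseline_index`, per-`k` BIC table, and state `labels` by sorted mean.
#'   Has [tidy()] and [glance()] methods and an [autoplot()] method.
#' @examples
#' m <- allele_models()[["WT-C"]]
#' tr <- render_trace(simulate_state_path(m, 200, seed = 1), m, seed = 2)
#' fit <- fit_amplitude_histogram(tr)
#' fit$k
#' @export
fit_amplitude_histogram <- function(trace, k_max = 3) {
  if (!is.data.frame(trace) || !"current_nA" %in% names(trace)) {
    abort("`trace` must be a data frame with a `current_nA` column.",
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (!k_max %in% 1:3) {
    abort("`k_max` must be 1, 2 or 3.", class = "hairpinkinetics_parameter_error")
  }
  x <- trace$current_nA
  if (length(x) < 100) {
    abort(sprintf("need >= 100 samples to fit the amplitude histogram (got %d).", length(x)),
      class = "hairpinkinetics_insufficient_data"
    )
  }
  fits <- purrr::map(seq_len(k_max), function(k) fit_gmm_k(x, k))
  ok <- !purrr::map_lgl(fits, is.null)
  if (!any(ok)) {
    abort("mixture fitting failed for every candidate k.",
      class = "hairpinkinetics_fit_error"
    )
  }
  if (!all(ok)) {
    warn(sprintf(
      "mixture fit did not converge for k = %s; excluded from model selection.",
      paste(which(!ok), collapse = ", ")
    ))
  }
  bic_tbl <- tibble(
    k = which(ok),
    bic = purrr::map_dbl(fits[ok], "bic")
  )
  best <- fits[[bic_tbl$k[which.max(bic_tbl$bic)]]]

  k <- best$k
  ord <- order(best$means)
  means_raw <- best$means[ord]
  sds <- best$sds[ord]
  weights <- best$weights[ord]

  baseline_index <- if (k == 3) 2L else 1L
  labels <- switch(as.character(k),
    "1" = "baseline",
    "2" = c("low", "high"),
    "3" = c("low", "intermediate", "high")
  )
  structure(
    list(
      k = k,
      means = means_raw - means_raw[baseline_index],
      means_raw = means_raw,
      sds = sds,
      weights = weights,
      baseline_index = baseline_index,
      labels = labels,
      bic = bic_tbl,
      n = length(x)
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> k = %d component(s) on %d samples (BIC-selected)\n",
    x$k, x$n
  ))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_amplitude_histogram One row per mixture component:
#'   `component`, `label`, `mean` (baseline-re-centered), `mean_raw`, `sd`,
#'   `weight`, `baseline` flag.
#' @param x,object A `mixture_fit`.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$k),
    label = x$labels,
    mean = x$means,
    mean_raw = x$means_raw,
    sd = x$sds,
    weight = x$weights,
    baseline = seq_len(x$k) == x$baseline_index
  )
}

#' @describeIn fit_amplitude_histogram One-row summary: selected `k`, its
#'   BIC, and the sample count.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    k = x$k,
    bic = x$bic$bic[match(x$k, x$bic$k)],
    n = x$n
  )
}

# ---- Gaussian-emission HMM internals (fixed emissions) ----------------------

# forward-backward with per-step scaling; returns updated transition matrix,
# initial distribution and log-likelihood
hmm_em_step <- function(dens, A, init) {
  n <- nrow(dens)
  k <- ncol(dens)
  f <- matrix(0, n, k)
  scl <- numeric(n)
  v <- init * dens[1L, ]
  scl[1L] <- sum(v)
  f[1L, ] <- v / scl[1L]
  for (t in 2:n) {
    v <- as.numeric(f[t - 1L, ] %*% A) * dens[t, ]
    scl[t] <- sum(v)
    f[t, ] <- v / scl[t]
  }
  b <- rep(1, k)
  xi <- matrix(0, k, k)
  for (t in (n - 1L):1L) {
    w <- A * rep(dens[t + 1L, ] * b, each = k) # w[i,j] = A[i,j] d_{t+1,j} b_j
    xi <- xi + (f[t, ] * w) / scl[t + 1L]
    b <- as.numeric(w %*% rep(1, k)) / scl[t + 1L]
  }
  gamma1 <- init * dens[1L, ] * b / scl[1L]
  list(
    A = xi / pmax(rowSums(xi), .Machine$double.xmin),
    init = gamma1 / sum(gamma1),
    loglik = sum(log(scl))
  )
}

hmm_viterbi <- function(logdens, logA, loginit) {
  n <- nrow(logdens)
  k <- ncol(logdens)
  psi <- matrix(0L, n, k)
  delta <- loginit + logdens[1L, ]
  for (t in 2:n) {
    m <- delta + logA # m[i, j]
    arg <- max.col(t(m), ties.method = "first")
    psi[t, ] <- arg
    delta <- m[cbind(arg, seq_len(k))] + logdens[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

# iteratively absorb runs shorter than min_len samples into a neighbor
# (the longer one; ties go to the preceding run)
merge_short_runs <- function(states, min_len) {
  repeat {
    r <- rle(states)
    short <- which(r$lengths < min_len)
    if (length(short) == 0 || length(r$lengths) == 1) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -1
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1
    target <- if (left >= right) i - 1L else i + 1L
    pos <- cumsum(r$lengths)
    idx_start <- if (i == 1) 1L else pos[i - 1L] + 1L
    states[idx_start:pos[i]] <- r$values[target]
  }
  states
}

#' Idealize a noisy trace into a state path
#'
#' Decodes the most likely state sequence of a Gaussian-emission hidden Markov
#' model whose emission means and standard deviations come from a
#' [fit_amplitude_histogram()] fit. The transition matrix is estimated by
#' expectation-maximization (Baum-Welch, emissions held fixed) from a
#' near-diagonal initialization, the path is decoded with the Viterbi
#' algorithm, consecutive identical states are merged into dwells, and dwells
#' shorter than `min_dwell_samples` are absorbed into the longer neighbor
#' (ties go to the preceding dwell). This plays the role of interactive
#' idealization software in a scripted, reproducible form.
#'
#' @inheritParams fit_amplitude_histogram
#' @param fit A `mixture_fit` with `k >= 2`.
#' @param min_dwell_samples Minimum dwell length in samples; the default 2
#'   (about 0.07 ms at 28.8 kSa/s) matches the rise-time scale of a 5 kHz
#'   filter.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A state-path tibble with columns `state`, `start_ms` and
#'   `duration_ms`.
#' @examples
#' m <- allele_models()[["WT-C"]]
#' tr <- render_trace(simulate_state_path(m, 200, seed = 1), m, seed = 2)
#' path <- idealize_trace(tr, fit_amplitude_histogram(tr))
#' @export
idealize_trace <- function(trace, fit, min_dwell_samples = 2,
                           max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k < 2) {
    abort("mixture fit has a single component: no dynamics to idealize (blank device?).",
      class = "hairpinkinetics_no_dynamics"
    )
  }
  x <- trace$current_nA
  n <- length(x)
  dt <- if (n >= 2) median(diff(trace$time_ms)) else 1
  k <- fit$k

  dens <- vapply(
    seq_len(k),
    function(j) dnorm(x, fit$means_raw[j], fit$sds[j]),
    numeric(n)
  )
  dens <- pmax(dens, 1e-300)

  A <- matrix(0.01 / (k - 1), k, k)
  diag(A) <- 0.99
  init <- fit$weights
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    step <- hmm_em_step(dens, A, init)
    A <- step$A
    init <- step$init
    if (is.finite(ll_old) &&
      abs(step$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      break
    }
    ll_old <- step$loglik
  }

  decoded <- hmm_viterbi(log(dens), log(pmax(A, 1e-12)), log(pmax(init, 1e-12)))
  decoded <- merge_short_runs(decoded, min_dwell_samples)
  r <- rle(decoded)
  start <- (cumsum(r$lengths) - r$lengths) * dt
  tibble(
    state = fit$labels[r$values],
    start_ms = start,
    duration_ms = r$lengths * dt
  )
}
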