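#' Frequency grid for Fourier regression on a non-uniform time grid
#'
#' Frequency selection is not obvious for non-uniformly spaced time points.
#' The grid consists of harmonics `l / T` of a fundamental period
#' `T = span(times) * fundamental_factor`; `fundamental_factor > 1` lets the
#' longest admissible period exceed the observation window, which is needed
#' when (as here) barely one cycle is observed. Two extremes are excluded
#' because they mask other frequencies in the g-statistic: periods much
#' longer than the fundamental (none are generated) and periods near the
#' sampling rate — every retained period is at least `max_freq_factor` times
#' the median sampling interval, which also keeps all frequencies strictly
#' below `1 / (max_freq_factor * min spacing)`. The number of harmonics is
#' additionally capped at `(N - 2) / 2` so the regression stays
#' overdetermined.
#'
#' @param times sample times (days); at least 6 distinct values.
#' @param fundamental_factor multiple of the span used as fundamental
#'   period. The default 1.05 puts the fundamental of the bundled synthetic
#'   grid (span 30 d) at 31.5 d, near one full hair cycle.
#' @param max_freq_factor shortest admissible period, in multiples of the
#'   median sampling interval.
#' @return list of class `frequency_grid` with `frequencies` (cycles/day,
#'   increasing), `periods`, `fundamental_period`, `L`.
#' @export
build_frequency_grid <- function(times, fundamental_factor = 1.05,
                                 max_freq_factor = 3) {
  ut <- sort(unique(times))
  if (length(ut) < 6)
    stop_hw("need at least 6 distinct time points",
            class = "hairwave_grid_error")
  span <- diff(range(ut))
  dt <- diff(ut)
  fundamental <- span * fundamental_factor
  shortest <- max_freq_factor * max(min(dt), stats::median(dt))
  l_max <- floor(fundamental / shortest)
  l_cap <- floor((length(times) - 2) / 2)
  l_max <- min(l_max, l_cap)
  if (l_max < 2)
    stop_hw("fewer than 2 admissible frequencies for this time grid",
            class = "hairwave_grid_error")
  freqs <- seq_len(l_max) / fundamental
  structure(list(frequencies = freqs, periods = 1 / freqs,
                 fundamental_period = fundamental, L = l_max),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> L = %d harmonics of %.3g d: periods %s d\n",
              x$L, x$fundamental_period,
              paste(signif(x$periods, 4), collapse = ", ")))
  invisible(x)
}

# Design matrix [1 | cos(2 pi f_l t) | sin(2 pi f_l t)].
fourier_design <- function(times, grid) {
  wt <- outer(times, 2 * pi * grid$frequencies)
  cbind(intercept = 1, cos(wt), sin(wt))
}

# IRLS core with Tukey's biweight; shared by the user-facing fit and the
# permutation loop. The loop runs ~1e6 times during permutation testing, so
# it uses .lm.fit and plain vector arithmetic; rank checks are done once by
# the caller.
tukey_irls <- function(X, y, c_tukey = 4.685, tol = 1e-8, max_iter = 100L) {
  beta <- .lm.fit(X, y)$coefficients
  w <- rep(1, length(y))
  converged <- FALSE
  it <- 0L
  y_scale <- stats::median(abs(y))
  for (it in seq_len(max_iter)) {
    r <- as.vector(y - X %*% beta)
    s <- 1.4826 * stats::median(abs(r))
    if (s < .Machine$double.eps^0.5 * (1 + y_scale)) {
      # the bulk of the data is fitted exactly: the scale collapses and the
      # current weights (1 on the bulk, 0 on any rejected outliers) stand
      converged <- TRUE
      break
    }
    u <- r / (c_tukey * s)
    w <- (1 - u * u)^2 * (abs(u) < 1)
    if (sum(w > 0) < ncol(X)) { w <- rep(1, length(y)); break }
    sw <- sqrt(w)
    beta_new <- .lm.fit(X * sw, y * sw)$coefficients
    if (anyNA(beta_new)) break
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  list(beta = beta, weights = w, iter = it, converged = converged)
}

#' Robust Fourier-series fit of one expression signal
#'
#' Fits `x(t) = a0 + sum_l a_l cos(2 pi f_l t) + b_l sin(2 pi f_l t)` over
#' the pre-selected frequencies by an M-estimator with Tukey's biweight
#' (tuning constant 4.685; scale = 1.4826 x median absolute residual,
#' re-estimated at each iteration), so single gross outliers barely perturb
#' the coefficients. With no outliers all robust weights are 1 and the fit
#' equals ordinary least squares.
#'
#' @param signal numeric vector (log2 expression recommended).
#' @param times sample times, same length; must exceed `2L + 1`.
#' @param grid a [build_frequency_grid()].
#' @param c_tukey,tol,max_iter IRLS controls.
#' @return Object of class `fourier_fit`: coefficients (`a0`, `a`, `b`),
#'   `fitted`, `residuals`, robust `weights`, `r2`, `mad` (median absolute
#'   deviation of residuals), convergence info, and the grid.
#' @export
fit_fourier_robust <- function(signal, times, grid, c_tukey = 4.685,
                               tol = 1e-8, max_iter = 100L) {
  stopifnot(length(signal) == length(times))
  if (length(signal) <= 2 * grid$L + 1)
    stop_hw("need more samples than 2L+1 coefficients",
            class = "hairwave_fit_error")
  X <- fourier_design(times, grid)
  if (qr(X)$rank < ncol(X))
    stop_hw("rank-deficient Fourier design", class = "hairwave_fit_error")
  res <- tukey_irls(X, signal, c_tukey, tol, max_iter)
  beta <- res$beta
  L <- grid$L
  fitted <- drop(X %*% beta)
  r <- signal - fitted
  ss_tot <- sum((signal - mean(signal))^2)
  structure(list(a0 = unname(beta[1]),
                 a = unname(beta[1 + seq_len(L)]),
                 b = unname(beta[1 + L + seq_len(L)]),
                 fitted = fitted, residuals = r, weights = res$weights,
                 r2 = if (ss_tot > 0) 1 - sum(r^2) / ss_tot else NA_real_,
                 mad = stats::median(abs(r)),
                 n = length(signal), times = times,
                 converged = res$converged, iter = res$iter, grid = grid),
            class = "fourier_fit")
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("<fourier_fit> L = %d, a0 = %.4g, r2 = %.3f, mad = %.3g%s\n",
              x$grid$L, x$a0, x$r2, x$mad,
              if (x$converged) "" else " (IRLS not converged)"))
  invisible(x)
}

#' Power spectrum of a fitted Fourier series
#'
#' `S(f_l) = (N / 4) * (a_l^2 + b_l^2)`. The constant factor is the
#' classical periodogram normalization for a fitted harmonic; it cancels in
#' the g-statistic and is immaterial to all downstream inference.
#'
#' @param fit a [fit_fourier_robust()] result.
#' @param N number of points in the signal (defaults to the fitted length).
#' @return numeric vector of length `L`.
#' @export
power_spectrum <- function(fit, N = fit$n) {
  (N / 4) * (fit$a^2 + fit$b^2)
}

#' Fisher's g-statistic
#'
#' The relative power of the principal periodic component:
#' `g = max(S) / sum(S)`, in (0, 1]. Invariant to any positive rescaling of
#' the spectrum.
#'
#' @param spectrum nonnegative vector with a positive sum.
#' @return The g-statistic.
#' @export
g_statistic <- function(spectrum) {
  tot <- sum(spectrum)
  if (tot <= 0)
    stop_hw("all-zero spectrum: g undefined",
            class = "hairwave_statistic_error")
  max(spectrum) / tot
}

#' Principal periodic component of a Fourier fit
#'
#' The dominant-frequency term of the series: the frequency with maximal
#' spectral power (ties resolved to the lowest frequency), with amplitude
#' `sqrt(a^2 + b^2)` and phase `atan2(b, a)`, so the component is
#' `A cos(2 pi f t - phase)`.
#'
#' @param fit a [fit_fourier_robust()] result.
#' @return list `frequency`, `period`, `amplitude`, `phase` (radians).
#' @export
principal_component <- function(fit) {
  S <- power_spectrum(fit)
  if (sum(S) <= 0)
    stop_hw("zero spectrum: no principal component",
            class = "hairwave_statistic_error")
  l <- which.max(S)  # first maximum = lowest frequency on ties
  list(frequency = fit$grid$frequencies[l],
       period = 1 / fit$grid$frequencies[l],
       amplitude = sqrt(fit$a[l]^2 + fit$b[l]^2),
       phase = atan2(fit$b[l], fit$a[l]))
}

#' Phase shift as time to the next maximum
#'
#' Converts a principal-component phase to days: the smallest `t* >= t_ref`
#' at which `A cos(2 pi f t - phase)` attains its maximum, reported as
#' `t* - t_ref` in `[0, period)`.
#'
#' @param ppc a [principal_component()] result (or any list with
#'   `frequency` and `phase`).
#' @param t_ref reference day (typically the first merged sampling day).
#' @return Shift in days.
#' @export
phase_shift_days <- function(ppc, t_ref = 0) {
  period <- 1 / ppc$frequency
  t_max <- ppc$phase / (2 * pi * ppc$frequency)
  ((t_max - t_ref) %% period)
}
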