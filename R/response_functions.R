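# Pupil response-function (RF) kernels.
#
# Two gamma-shaped families are supported: the Erlang gamma function
# h(t) = t^n exp(-n t / t_max), whose peak time is controlled by the single
# parameter t_max, and the gamma probability density
# d(t) = c / (theta^k Gamma(k)) t^(k-1) exp(-t / theta), where k and theta
# jointly set timing and shape. Both are preceded by a fixed onset delay
# during which the pupil has not yet started to respond (default 200 ms).

#' Erlang gamma response-function parameters
#'
#' @param n Shape/width parameter (> 0, dimensionless). Larger `n` gives a
#'   narrower response around the peak; the peak time itself does not move.
#' @param t_max Time of peak response in seconds (> 0).
#' @param amplitude Peak response amplitude. The sampled kernel is
#'   peak-normalized before this gain is applied, so `amplitude` is directly
#'   interpretable as the response at `delay + t_max` (otherwise the overall
#'   scale would be confounded with `n` and `t_max`).
#' @param delay Onset latency in seconds before the pupil starts responding
#'   (default 0.2 s).
#' @return An object of class `erlang_params`.
#' @seealso [erlang_rf()], [gamma_pdf_params()]
#' @export
erlang_params <- function(n = 10, t_max = 0.3, amplitude = 1, delay = 0.2) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("Erlang parameter 'n' must be a positive number")
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) || t_max <= 0)
    stop("Erlang parameter 't_max' must be a positive number (seconds)")
  if (!is.numeric(delay) || delay < 0)
    stop("'delay' must be >= 0")
  structure(list(n = n, t_max = t_max, amplitude = amplitude, delay = delay),
            class = c("erlang_params", "rf_params"))
}

#' Gamma probability-density response-function parameters
#'
#' @param c Peak-amplitude scale; the kernel integrates to `c` over an
#'   unbounded support.
#' @param k Shape parameter (> 0).
#' @param theta Scale parameter in seconds (> 0). For `k > 1` the kernel
#'   peaks at `delay + (k - 1) * theta`.
#' @param delay Onset latency in seconds (default 0.2 s).
#' @return An object of class `gamma_pdf_params`.
#' @export
gamma_pdf_params <- function(c = 1, k = 4, theta = 0.1, delay = 0.2) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("gamma-density parameter 'k' must be a positive number")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("gamma-density parameter 'theta' must be a positive number (seconds)")
  if (!is.numeric(delay) || delay < 0)
    stop("'delay' must be >= 0")
  structure(list(c = c, k = k, theta = theta, delay = delay),
            class = c("gamma_pdf_params", "rf_params"))
}

#' Sample a response-function kernel
#'
#' Generic over the two parameter families; returns the kernel sampled on a
#' regular grid `0, dt, 2*dt, ...` up to `duration` seconds.
#'
#' @param params An `erlang_params` or `gamma_pdf_params` object.
#' @param dt Sampling step in seconds (the event-trace step).
#' @param duration Kernel support in seconds (default 4 s).
#' @return Numeric vector of kernel values; zero for all samples at or before
#'   the onset delay.
#' @export
rf_kernel <- function(params, dt, duration = 4) UseMethod("rf_kernel")

#' @export
rf_kernel.erlang_params <- function(params, dt, duration = 4) {
  erlang_rf(params, dt, duration)
}

#' @export
rf_kernel.gamma_pdf_params <- function(params, dt, duration = 4) {
  gamma_pdf_rf(params, dt, duration)
}

rf_check_grid <- function(params, dt, duration) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (duration <= params$delay)
    stop("'duration' must exceed the onset delay")
}

#' Sampled Erlang gamma kernel
#'
#' Evaluates `amplitude * (tau / t_max)^n * exp(n * (1 - tau / t_max))` for
#' `tau = i * dt - delay` where `tau > 0`, and 0 elsewhere. This is the
#' Erlang gamma shape peak-normalized to 1 at `tau = t_max` and scaled by the
#' amplitude; computed in log space so large shape values do not overflow.
#'
#' @inheritParams rf_kernel
#' @export
erlang_rf <- function(params, dt, duration = 4) {
  if (!inherits(params, "erlang_params")) params <- do.call(erlang_params, params)
  rf_check_grid(params, dt, duration)
  tau <- seq(0, duration, by = dt) - params$delay
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- exp(params$n * (log(tau[pos] / params$t_max) + 1 - tau[pos] / params$t_max))
  params$amplitude * out
}

#' Sampled gamma probability-density kernel
#'
#' Evaluates `c * dgamma(tau, shape = k, scale = theta)` for
#' `tau = i * dt - delay > 0`, zero elsewhere. Its discrete integral
#' (`dt * sum(kernel)`) converges to `c` as the support grows.
#'
#' @inheritParams rf_kernel
#' @export
gamma_pdf_rf <- function(params, dt, duration = 4) {
  if (!inherits(params, "gamma_pdf_params")) params <- do.call(gamma_pdf_params, params)
  rf_check_grid(params, dt, duration)
  tau <- seq(0, duration, by = dt) - params$delay
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- params$c * stats::dgamma(tau[pos], shape = params$k, scale = params$theta)
  out
}

#' Scale a kernel to a maximum of 1
#'
#' @param kernel Numeric vector with a positive maximum.
#' @return The kernel divided by its maximum.
#' @export
normalize_peak <- function(kernel) {
  m <- max(kernel)
  if (!is.finite(m) || m <= 0)
    stop("degenerate kernel: no positive maximum to normalize")
  kernel / m
}
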