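# Event-related benchmark pipelines: discrete luminance-event detection,
# epoch extraction with baseline correction, percentile binning by event
# magnitude, the two-LTI epoch model, and the pooled polynomial fit.

#' Detect discrete luminance events in a change trace
#'
#' Keeps samples whose absolute change is at least `threshold`, then scans
#' in time order and greedily drops any event closer than `min_separation`
#' to the previously kept one (reducing crosstalk between epochs).
#'
#' @param lum_change Signed luminance-change series (cd/m^2 per step).
#' @param dt Sampling step in seconds (ignored when `timestamps` given).
#' @param timestamps Optional explicit sample times.
#' @param threshold Detection threshold in cd/m^2 (default 3, i.e. changes
#'   below +-3 cd/m^2 are discarded).
#' @param min_separation Minimum inter-event interval in seconds (default 1).
#' @return Data frame with columns `index`, `time`, `magnitude`, `direction`
#'   (`"brighter"`/`"darker"`).
#' @export
detect_events <- function(lum_change, dt = NULL, timestamps = NULL,
                          threshold = 3, min_separation = 1) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (is.null(timestamps)) {
    if (is.null(dt)) stop("supply 'dt' or 'timestamps'")
    timestamps <- (seq_along(lum_change) - 1) * dt
  }
  cand <- which(abs(lum_change) >= threshold)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (timestamps[i] - last >= min_separation) {
      keep <- c(keep, i)
      last <- timestamps[i]
    }
  }
  data.frame(index = keep, time = timestamps[keep],
             magnitude = lum_change[keep],
             direction = ifelse(lum_change[keep] > 0, "brighter", "darker"))
}

#' Extract event-related pupil epochs
#'
#' Segments the pupil recording into fixed-length windows time-locked to
#' each event (nearest pupil sample to the event time), subtracts the mean
#' of the first `baseline_window` seconds of each epoch (the pupil has not
#' yet started responding there), and divides all epochs by their pooled
#' standard deviation.
#'
#' @param rec A [recording()].
#' @param events Data frame from [detect_events()] (or any frame with a
#'   `time` column).
#' @param window Epoch length in seconds (default 3).
#' @param baseline_window Baseline interval after onset in seconds
#'   (default 0.25).
#' @return A `pupil_epochs` object: `epochs` (events x samples, baseline
#'   corrected and pooled-SD scaled), `times` (within-epoch times), `events`
#'   (rows actually used), `pooled_sd`, `n_skipped`.
#' @export
extract_epochs <- function(rec, events, window = 3, baseline_window = 0.25) {
  dtp <- 1 / rec$rate
  n_samp <- round(window / dtp)
  times <- (seq_len(n_samp) - 1) * dtp
  bmask <- times < baseline_window
  rows <- list(); used <- integer(0)
  for (j in seq_len(nrow(events))) {
    start <- which.min(abs(rec$timestamps - events$time[j]))
    idx <- start + seq_len(n_samp) - 1L
    if (max(idx) > length(rec$pupil)) {
      message(sprintf("epoch at t=%.2fs overruns the recording; skipped",
                      events$time[j]))
      next
    }
    seg <- rec$pupil[idx]
    rows[[length(rows) + 1L]] <- seg - mean(seg[bmask])
    used <- c(used, j)
  }
  if (length(rows) == 0L) stop("no epochs fit inside the recording")
  E <- do.call(rbind, rows)
  pooled_sd <- stats::sd(as.numeric(E))
  if (pooled_sd > 0) E <- E / pooled_sd
  structure(list(epochs = E, times = times,
                 events = events[used, , drop = FALSE],
                 pooled_sd = pooled_sd,
                 n_skipped = nrow(events) - length(used)),
            class = "pupil_epochs")
}

#' Bin events by luminance-change magnitude
#'
#' Splits the signed magnitudes at their 20/40/60/80th percentiles (for the
#' default five bins) and averages the epochs per bin; bin 1 holds the
#' largest darkenings and the last bin the largest brightenings. Values
#' falling exactly on a boundary go to the lower bin.
#'
#' @param epochs A `pupil_epochs` object.
#' @param n_bins Number of percentile bins (default 5).
#' @return List with `bin` (per event), `breaks`, `mean_epochs`
#'   (`n_bins x n_samples`), `counts`, `times`.
#' @export
bin_by_magnitude <- function(epochs, n_bins = 5) {
  mag <- epochs$events$magnitude
  if (length(mag) < n_bins) stop("need at least as many events as bins")
  br <- stats::quantile(mag, probs = seq(0, 1, length.out = n_bins + 1))
  if (anyDuplicated(br)) stop("tied percentile boundaries; too few distinct magnitudes")
  bin <- cut(mag, breaks = br, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  sums <- rowsum(epochs$epochs, bin)
  counts <- tabulate(bin, n_bins)
  list(bin = bin, breaks = br,
       mean_epochs = sums / counts[as.integer(rownames(sums))],
       counts = counts, times = epochs$times)
}

# simplex fit of one RF shape to a target trace; the amplitude is profiled
# out in closed form (ordinary least squares given the shape)
fit_rf_shape <- function(target, dt, family, cumulative, delay, baseline_window,
                         init, lower, upper, maxit = 600) {
  n <- length(target)
  duration <- (n - 1) * dt
  bmask <- (seq_len(n) - 1) * dt < baseline_window
  shape_of <- function(p) {
    kern <- if (family == "erlang")
      erlang_rf(erlang_params(p[1L], p[2L], 1, delay), dt, duration)
    else
      gamma_pdf_rf(gamma_pdf_params(1, p[1L], p[2L], delay), dt, duration)
    s <- if (cumulative) cumsum(kern) * dt else kern
    s - mean(s[bmask])
  }
  obj <- function(theta) {
    s <- shape_of(to_constrained(theta, lower, upper))
    ss <- sum(s * s)
    a <- if (ss > 0) sum(target * s) / ss else 0
    sqrt(mean((target - a * s)^2))
  }
  res <- stats::optim(to_unconstrained(init, lower, upper), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  p <- to_constrained(res$par, lower, upper)
  s <- shape_of(p)
  ss <- sum(s * s)
  a <- if (ss > 0) sum(target * s) / ss else 0
  list(shape_par = p, amplitude = a, pred = a * s,
       converged = res$convergence == 0L)
}

#' Two-LTI epoch model of event-related pupil responses
#'
#' Fits the sustained response function through its cumulative to the grand
#' mean of dilation epochs (LTI1), then fits a second, transient response
#' function to the difference between the constriction grand mean and the
#' sign-inverted dilation model (the constriction "overshoot", LTI2). The
#' LTI2 weight is the least-squares scalar on the constriction
#' reconstruction `-dilation_model + weight * RF2 response`.
#'
#' @param dilation,constriction Grand-mean event-related pupil responses
#'   (baseline-corrected, dilation positive), sampled at `dt`.
#' @param dt Sampling step in seconds.
#' @param family `"gamma_pdf"` (default) or `"erlang"`.
#' @param delay RF onset delay in seconds.
#' @param baseline_window Baseline interval used during correction (s).
#' @return List with `rf1`, `rf2` (fitted parameter objects), `weight`,
#'   `r2_dilation`, `r2_constriction`, `dilation_pred`, `constriction_pred`.
#' @export
fit_korn_bach <- function(dilation, constriction, dt,
                          family = c("gamma_pdf", "erlang"), delay = 0.2,
                          baseline_window = 0.25) {
  family <- match.arg(family)
  if (stats::sd(dilation) == 0 || stats::sd(constriction) == 0)
    stop("degenerate grand means: no variance to fit")
  init <- if (family == "gamma_pdf") c(10, 0.05) else c(10, 0.3)
  lower <- if (family == "gamma_pdf") c(1.1, 0.005) else c(0.5, 0.05)
  upper <- c(40, 2)
  f1 <- fit_rf_shape(dilation, dt, family, cumulative = TRUE, delay,
                     baseline_window, init, lower, upper)
  dil_pred <- f1$pred
  r2_dil <- evaluate(dil_pred, dilation, zscore_first = FALSE)[["r2"]]
  diff_trace <- constriction - (-dil_pred)
  init2 <- if (family == "gamma_pdf") c(4, 0.15) else c(3, 0.5)
  f2 <- fit_rf_shape(diff_trace, dt, family, cumulative = FALSE, delay,
                     baseline_window, init2, lower, upper)
  rf2_resp <- f2$pred
  ss2 <- sum(rf2_resp^2)
  weight <- if (ss2 > 1e-12) sum(diff_trace * rf2_resp) / ss2 else 0
  con_pred <- -dil_pred + weight * rf2_resp
  r2_con <- evaluate(con_pred, constriction, zscore_first = FALSE)[["r2"]]
  rf1 <- if (family == "gamma_pdf")
    gamma_pdf_params(f1$amplitude, f1$shape_par[1L], f1$shape_par[2L], delay)
  else erlang_params(f1$shape_par[1L], f1$shape_par[2L], f1$amplitude, delay)
  rf2 <- if (family == "gamma_pdf")
    gamma_pdf_params(f2$amplitude, f2$shape_par[1L], f2$shape_par[2L], delay)
  else erlang_params(f2$shape_par[1L], f2$shape_par[2L], f2$amplitude, delay)
  list(rf1 = rf1, rf2 = rf2, weight = weight,
       r2_dilation = r2_dil, r2_constriction = r2_con,
       dilation_pred = dil_pred, constriction_pred = con_pred,
       family = family)
}

#' Pooled polynomial benchmark
#'
#' Fits one polynomial in within-trial time, with a single coefficient set,
#' jointly to the (z-scored) pupil traces of all trials -- a prior-less
#' reference model with as many free parameters as the contrast-response
#' model.
#'
#' @param recordings List of [recording()] objects (>= 2).
#' @param degree Polynomial degree (default 5, a quintic).
#' @return List with `coefficients`, `r2` (pooled), `degree`, `fit` (the
#'   underlying `lm`).
#' @export
polynomial_benchmark <- function(recordings, degree = 5) {
  if (length(recordings) < 2L) stop("need at least two trials")
  df <- do.call(rbind, lapply(recordings, function(r) {
    ok <- r$valid & is.finite(r$pupil)
    data.frame(time = r$timestamps[ok] - r$timestamps[1L],
               pupil = zscore(r$pupil[ok]))
  }))
  fitlm <- if (degree == 0) stats::lm(pupil ~ 1, data = df)
  else stats::lm(pupil ~ stats::poly(time, degree, raw = TRUE), data = df)
  r2 <- 1 - sum(stats::residuals(fitlm)^2) /
    sum((df$pupil - mean(df$pupil))^2)
  list(coefficients = unname(stats::coef(fitlm)), r2 = r2, degree = degree,
       fit = fitlm)
}
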