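# Forward model: convolve event traces with response functions, cumulate the
# sustained luminance component, apply regional weights, and combine the
# components into a predicted pupil trace.
#
# Sign convention: predicted pupil traces are oriented so that constriction
# is negative. A positive (brighter) luminance change therefore drives the
# prediction downwards, and the contrast component -- which responds to the
# magnitude of change regardless of direction -- is always constrictive.

#' Causal discrete convolution, truncated to the input length
#'
#' `y[i] = sum_j kernel[j] * x[i - j + 1]`, evaluated by `stats::filter`
#' (direct summation in C, exact to double precision).
#'
#' @param x Numeric vector or matrix (columns convolved independently).
#' @param kernel Numeric kernel sampled at the trace step.
#' @return Same shape as `x`.
#' @export
convolve_trace <- function(x, kernel) {
  m <- length(kernel)
  if (m == 0L) stop("empty kernel")
  if (is.matrix(x)) {
    if (nrow(x) == 0L) return(x)
    pad <- rbind(matrix(0, m - 1L, ncol(x)), x)
    y <- apply(pad, 2L, function(col)
      as.numeric(stats::filter(col, kernel, sides = 1)))
    return(y[m - 1L + seq_len(nrow(x)), , drop = FALSE])
  }
  if (length(x) == 0L) return(numeric(0))
  y <- stats::filter(c(rep(0, m - 1L), x), kernel, sides = 1)
  as.numeric(y)[m - 1L + seq_along(x)]
}

#' Cumulate a transient response into a sustained response
#'
#' Running cumulative sum scaled by the sampling step: the discrete integral
#' of the transient trace. A transient response to a luminance change thus
#' becomes a lasting offset in predicted pupil size.
#'
#' @param transient Numeric vector or matrix (columns cumulated separately).
#' @param dt Sampling step in seconds.
#' @return Same shape as `transient`.
#' @export
sustained_response <- function(transient, dt) {
  if (is.matrix(transient)) apply(transient, 2L, cumsum) * dt
  else cumsum(transient) * dt
}

#' z-standardize a trace
#'
#' Centers and scales to unit *population* variance (denominator `n`), so a
#' z-scored series has mean exactly 0 and root-mean-square exactly 1.
#' Non-finite entries are ignored for the moments and preserved in place.
#' A zero-variance trace returns all zeros with attribute
#' `zero_variance = TRUE`.
#'
#' @param x Numeric vector.
#' @return z-scored vector.
#' @export
zscore <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) stop("no finite samples to standardize")
  mu <- mean(x[ok])
  s <- sqrt(mean((x[ok] - mu)^2))
  if (s < 1e-12) {
    out <- x
    out[ok] <- 0
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  (x - mu) / s
}

#' Regional weights
#'
#' One nonnegative weight per visual-field weight group W1-W6. W1 (the
#' top-central group) is the reference and fixed to 1: after z-scoring the
#' prediction a common scale on all weights is unidentifiable, so only the
#' five remaining weights are free parameters.
#'
#' @param w Numeric vector of length 6 (optionally named W1-W6).
#' @return A named `regional_weights` vector.
#' @export
regional_weights <- function(w = c(W1 = 1, W2 = 1, W3 = 1, W4 = 1, W5 = 1, W6 = 1)) {
  w <- as.numeric(w)
  if (length(w) != 6L || anyNA(w)) stop("need six finite regional weights")
  if (abs(w[1L] - 1) > 1e-12) stop("W1 is the reference weight and must equal 1")
  if (any(w < 0)) stop("regional weights must be nonnegative")
  structure(stats::setNames(w, paste0("W", 1:6)), class = "regional_weights")
}

#' Model specification
#'
#' @param rf_family `"erlang"` or `"gamma_pdf"`; which response-function
#'   family the fitted kernels come from.
#' @param components Any of `"sustained_luminance"` (cumulated response to
#'   signed luminance change) and `"transient_contrast"` (direct response to
#'   unsigned contrast change). At least one must be present.
#' @param contrast_weight Gain of the contrast component relative to the
#'   luminance component.
#' @param use_regions Fit the five free regional weights W2-W6?
#' @param use_gaze Extract events gaze-contingently (informational flag).
#' @param delay Response-function onset delay in seconds.
#' @param kernel_duration Kernel support in seconds (default 4 s, covering a
#'   3-s response epoch plus onset delay).
#' @return A `model_spec` object.
#' @export
model_spec <- function(rf_family = c("erlang", "gamma_pdf"),
                       components = c("sustained_luminance", "transient_contrast"),
                       contrast_weight = 0.5,
                       use_regions = FALSE, use_gaze = FALSE,
                       delay = 0.2, kernel_duration = 4) {
  rf_family <- match.arg(rf_family)
  components <- match.arg(components, several.ok = TRUE)
  if (length(components) < 1L) stop("at least one model component is required")
  structure(list(rf_family = rf_family, components = components,
                 contrast_weight = contrast_weight,
                 use_regions = use_regions, use_gaze = use_gaze,
                 delay = delay, kernel_duration = kernel_duration),
            class = "model_spec")
}

weights_per_region <- function(weights, grid) {
  w <- as.numeric(weights)
  if (length(w) != 6L) stop("expected six group weights")
  w[grid$groups]
}

#' Predict a pupil trace from event traces
#'
#' Per region, the sustained component is the cumulated convolution of the
#' signed luminance change with the luminance response function; the
#' transient component is the convolution of the (nonnegative) contrast
#' change with the contrast response function. Regions are summed with their
#' group weights, the components combined as
#' `luminance + contrast_weight * contrast`, negated so that constriction is
#' negative, and z-standardized.
#'
#' @param traces An [event_traces()] object.
#' @param lum_params Response-function parameters for the luminance
#'   component (required when `"sustained_luminance"` is in the spec).
#' @param contrast_params Parameters for the contrast component.
#' @param spec A [model_spec()].
#' @param weights A [regional_weights()] vector (or any length-6 nonnegative
#'   numeric vector).
#' @return A `pupil_prediction` object with fields `timestamps`, `combined`,
#'   `luminance_only`, `contrast_only` (each z-standardized) and
#'   `combined_raw` (pre-standardization, for linearity diagnostics).
#' @export
predict_pupil <- function(traces, lum_params = NULL, contrast_params = NULL,
                          spec = model_spec(), weights = regional_weights()) {
  grid <- traces$grid
  if (ncol(traces$luminance_change) != grid$rows * grid$cols)
    stop("event-trace region count does not match the grid")
  ts <- traces$timestamps
  dt <- if (length(ts) > 1L) ts[2L] - ts[1L] else 1 / traces$fps
  wr <- weights_per_region(weights, grid)
  n <- length(ts)
  lum_raw <- con_raw <- numeric(n)
  if ("sustained_luminance" %in% spec$components) {
    if (is.null(lum_params)) stop("'lum_params' required for the sustained-luminance component")
    kl <- rf_kernel(lum_params, dt, spec$kernel_duration)
    lum_raw <- sustained_response(
      convolve_trace(as.numeric(traces$luminance_change %*% wr), kl), dt)
  }
  if ("transient_contrast" %in% spec$components) {
    if (is.null(contrast_params)) stop("'contrast_params' required for the transient-contrast component")
    kc <- rf_kernel(contrast_params, dt, spec$kernel_duration)
    con_raw <- convolve_trace(as.numeric(traces$contrast_change %*% wr), kc)
  }
  combined_raw <- -(lum_raw + spec$contrast_weight * con_raw)
  structure(list(timestamps = ts,
                 combined = zscore(combined_raw),
                 luminance_only = zscore(-lum_raw),
                 contrast_only = zscore(-con_raw),
                 combined_raw = combined_raw,
                 spec = spec),
            class = "pupil_prediction")
}

#' @export
print.pupil_prediction <- function(x, ...) {
  cat(sprintf("pupil_prediction: %d samples, components: %s\n",
              length(x$timestamps), paste(x$spec$components, collapse = " + ")))
  invisible(x)
}
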