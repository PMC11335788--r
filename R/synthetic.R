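# Synthetic stimuli and recordings with known ground truth: programmatic
# piecewise-constant videos, gaze traces at an eye-tracker rate, and pupil
# traces produced by the package's own forward model plus white noise.
# Every downstream module is testable against these without external data.

#' Piecewise-constant video specification
#'
#' @param width,height Resolution in pixels (defaults 64 x 48).
#' @param fps Frame rate in Hz (default 25).
#' @param duration Duration in seconds (default 60).
#' @param segments List of `list(start, end, gray)` entries tiling
#'   `[0, duration)` without overlap; `gray` is either a scalar 8-bit gray
#'   level or a `grid$rows x grid$cols` matrix of per-region levels.
#' @param grid [region_grid()] used to map per-region gray matrices to
#'   pixels.
#' @return A `video_spec` object.
#' @export
video_spec <- function(width = 64, height = 48, fps = 25, duration = 60,
                       segments = list(list(start = 0, end = duration, gray = 128)),
                       grid = region_grid()) {
  starts <- vapply(segments, `[[`, numeric(1L), "start")
  ends <- vapply(segments, `[[`, numeric(1L), "end")
  o <- order(starts)
  segments <- segments[o]; starts <- starts[o]; ends <- ends[o]
  if (starts[1L] != 0 || ends[length(ends)] < duration ||
      (length(starts) > 1L && any(abs(starts[-1L] - ends[-length(ends)]) > 1e-9)))
    stop("segments must tile [0, duration) without gaps or overlap")
  for (s in segments) {
    g <- s$gray
    if (any(g < 0 | g > 255)) stop("gray levels must lie in [0, 255]")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration = duration, segments = segments,
                 grid = grid),
            class = "video_spec")
}

#' Random step-stimulus specification
#'
#' Draws `n_steps` luminance steps at jittered, near-equally spaced times
#' (at least `min_separation` seconds apart) with independently sampled
#' gray levels -- uniform across the screen or independently per region.
#'
#' @param n_steps Number of luminance steps (default 10).
#' @param seed RNG seed (the spec is deterministic given the seed).
#' @param per_region Sample an independent gray level per grid region?
#' @param gray_range Inclusive 8-bit range the levels are drawn from.
#' @param min_separation Minimum spacing between steps in seconds.
#' @inheritParams video_spec
#' @return A [video_spec()].
#' @export
random_video_spec <- function(n_steps = 10, seed = 1, per_region = FALSE,
                              gray_range = c(20, 235), min_separation = 2,
                              width = 64, height = 48, fps = 25,
                              duration = 60, grid = region_grid()) {
  set.seed(seed)
  spacing <- duration / (n_steps + 1)
  if (spacing < min_separation)
    stop("duration too short for the requested number of separated steps")
  jit <- max(0, (spacing - min_separation) / 2)
  times <- seq_len(n_steps) * spacing + stats::runif(n_steps, -jit, jit)
  bounds <- c(0, sort(times), duration)
  draw_gray <- function() {
    if (per_region)
      matrix(sample(gray_range[1L]:gray_range[2L], grid$rows * grid$cols,
                    replace = TRUE), grid$rows, grid$cols)
    else sample(gray_range[1L]:gray_range[2L], 1L)
  }
  segments <- lapply(seq_len(length(bounds) - 1L), function(i)
    list(start = bounds[i], end = bounds[i + 1L], gray = draw_gray()))
  video_spec(width, height, fps, duration, segments, grid)
}

#' Generate a frame source from a video specification
#'
#' Frames are produced deterministically on demand; identical frames within
#' a segment share a cache key so the event extractor converts each distinct
#' frame once. Round-tripping the result through [extract_event_traces()]
#' yields the analytically known luminance changes of the specification.
#'
#' @param spec A [video_spec()].
#' @return A [frame_source()].
#' @export
generate_video <- function(spec) {
  n <- round(spec$duration * spec$fps)
  seg_starts <- vapply(spec$segments, `[[`, numeric(1L), "start")
  seg_of_frame <- function(i) findInterval((i - 1) / spec$fps, seg_starts)
  ri <- partition_index(spec$height, spec$grid$rows)
  ci <- partition_index(spec$width, spec$grid$cols)
  make_frame <- function(i) {
    g <- spec$segments[[seg_of_frame(i)]]$gray
    pix <- if (is.matrix(g)) g[ri, ci, drop = FALSE]
    else matrix(g, spec$height, spec$width)
    array(rep(pix, 3L), dim = c(spec$height, spec$width, 3L))
  }
  frame_source(make_frame, n, spec$fps, spec$width, spec$height,
               frame_key = seg_of_frame)
}

#' Generate a synthetic gaze trace
#'
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz (default 500, a typical eye tracker; must
#'   be at least the video frame rate for downsampling).
#' @param pattern `"fixate_center"`, `"fixate_point"` (requires `point`), or
#'   `"smooth_drift"` (a smoothed, screen-clamped random walk).
#' @param seed RNG seed for the drift pattern.
#' @param resolution Screen size `c(width, height)` in pixels.
#' @param point Fixation point `c(x, y)` for `"fixate_point"`.
#' @param gap Optional `c(start, end)` seconds marked invalid (a simulated
#'   track loss).
#' @return A [gaze_trace()].
#' @export
generate_gaze <- function(duration, rate = 500,
                          pattern = c("fixate_center", "fixate_point", "smooth_drift"),
                          seed = 1, resolution = c(64, 48), point = NULL,
                          gap = NULL) {
  pattern <- match.arg(pattern)
  ts <- seq(0, duration, by = 1 / rate)
  cx <- (resolution[1L] + 1) / 2; cy <- (resolution[2L] + 1) / 2
  if (pattern == "fixate_center") {
    x <- rep(cx, length(ts)); y <- rep(cy, length(ts))
  } else if (pattern == "fixate_point") {
    if (is.null(point)) stop("'point' required for pattern 'fixate_point'")
    x <- rep(point[1L], length(ts)); y <- rep(point[2L], length(ts))
  } else {
    set.seed(seed)
    step <- resolution[1L] / rate            # drift spans the screen in ~1 s bursts
    x <- cx + cumsum(stats::rnorm(length(ts), 0, step))
    y <- cy + cumsum(stats::rnorm(length(ts), 0, step * resolution[2L] / resolution[1L]))
    smooth <- function(v) as.numeric(stats::filter(v, rep(1 / 25, 25), sides = 1))
    x <- fill_forward(smooth(x), cx); y <- fill_forward(smooth(y), cy)
    x <- pmin(pmax(x, 1), resolution[1L]); y <- pmin(pmax(y, 1), resolution[2L])
  }
  valid <- rep(TRUE, length(ts))
  if (!is.null(gap)) valid[ts >= gap[1L] & ts < gap[2L]] <- FALSE
  gaze_trace(ts, x, y, valid)
}

#' Ground-truth simulation parameters
#'
#' Defaults are the package's reference operating point for naturalistic
#' stimuli: an Erlang luminance response peaking at 0.28 s with shape 13.7,
#' a broader contrast response peaking at 0.53 s with shape 3.0, and a
#' contrast-to-luminance weight of 0.42, with uniform regional weights.
#'
#' @param lum_params,contrast_params Response-function parameter objects.
#' @param contrast_weight Relative gain of the contrast component.
#' @param weights A [regional_weights()] vector (or plain length-6 vector).
#' @param noise_sd SD of additive white Gaussian noise in z units (>= 0).
#' @param seed Seed for the noise.
#' @return A `simulation_truth` object.
#' @export
simulation_truth <- function(lum_params = erlang_params(n = 13.7, t_max = 0.28),
                             contrast_params = erlang_params(n = 3.0, t_max = 0.53),
                             contrast_weight = 0.42,
                             weights = regional_weights(),
                             noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(lum_params = lum_params, contrast_params = contrast_params,
                 contrast_weight = contrast_weight, weights = weights,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_truth")
}

truth_spec <- function(truth) {
  model_spec(rf_family = if (inherits(truth$lum_params, "erlang_params"))
    "erlang" else "gamma_pdf",
    contrast_weight = truth$contrast_weight,
    delay = truth$lum_params$delay)
}

#' Generate a pupil recording from event traces under known truth
#'
#' Runs the forward model under the truth parameters, upsamples the z-scored
#' combined prediction to the pupil sampling rate by linear interpolation,
#' and adds i.i.d. Gaussian noise.
#'
#' @param traces An [event_traces()] object.
#' @param truth A [simulation_truth()].
#' @param pupil_rate Pupil sampling rate in Hz (default 100).
#' @param seed Noise seed (defaults to `truth$seed`).
#' @return A [recording()].
#' @export
generate_pupil <- function(traces, truth = simulation_truth(),
                           pupil_rate = 100, seed = truth$seed) {
  pred <- predict_pupil(traces, truth$lum_params, truth$contrast_params,
                        truth_spec(truth), truth$weights)
  tp <- seq(0, max(traces$timestamps), by = 1 / pupil_rate)
  base <- stats::approx(traces$timestamps, pred$combined, xout = tp,
                        rule = 2)$y
  set.seed(seed)
  recording(tp, base + stats::rnorm(length(tp), 0, truth$noise_sd))
}

#' Simulate a set of movie-viewing trials
#'
#' Convenience wrapper chaining [random_video_spec()], [generate_video()],
#' [extract_event_traces()] and [generate_pupil()] with per-trial seeds
#' derived from `seed`.
#'
#' @param n_trials Number of trials.
#' @param truth A [simulation_truth()].
#' @param seed Master seed.
#' @param gaze_pattern `NULL` for screen-based extraction, otherwise a
#'   pattern accepted by [generate_gaze()].
#' @param pupil_rate Pupil sampling rate in Hz.
#' @param config An [event_config()].
#' @param ... Passed to [random_video_spec()] (e.g. `n_steps`, `duration`,
#'   `per_region`).
#' @return List of [plr_trial()] objects.
#' @export
simulate_trials <- function(n_trials = 6, truth = simulation_truth(), seed = 1,
                            gaze_pattern = NULL, pupil_rate = 100,
                            config = event_config(), ...) {
  args <- list(...)
  lapply(seq_len(n_trials), function(i) {
    vs <- do.call(random_video_spec,
                  c(list(seed = seed + 101L * i, grid = config$grid), args))
    g <- if (!is.null(gaze_pattern))
      generate_gaze(vs$duration, pattern = gaze_pattern, seed = seed + i,
                    resolution = c(vs$width, vs$height))
    traces <- extract_event_traces(generate_video(vs), g, config)
    rec <- generate_pupil(traces, truth, pupil_rate, seed = seed + 7919L * i)
    plr_trial(traces, rec, id = i)
  })
}
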