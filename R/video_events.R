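# Visual event extraction: decode frames, convert to physical luminance,
# optionally re-project onto a gaze-contingent canvas, and emit per-region
# luminance-change and contrast-change traces.

#' Convert an RGB frame to CIELAB lightness
#'
#' Converts an 8-bit sRGB frame (D65 white point) to CIELAB and returns the
#' L* channel rescaled to 0-255, i.e. black maps to 0 and white to 255.
#' Frames with few distinct colours (cartoons, synthetic stimuli) are
#' collapsed to their unique colours before conversion.
#'
#' @param frame Numeric or integer array `height x width x 3` with values in
#'   0-255.
#' @return Matrix `height x width` of lightness values on the 0-255 scale.
#' @export
rgb_to_lightness <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an RGB frame with exactly three channels")
  m <- matrix(as.integer(round(as.numeric(frame))), ncol = 3L)
  if (anyNA(m) || any(m < 0L | m > 255L))
    stop("RGB values must lie in [0, 255]")
  code <- (m[, 1L] * 256L + m[, 2L]) * 256L + m[, 3L]
  u <- unique(code)
  if (length(u) <= length(code) %/% 4L) {
    # convert each distinct colour once
    Lu <- grDevices::convertColor(m[match(u, code), , drop = FALSE] / 255,
                                  from = "sRGB", to = "Lab")[, 1L]
    L <- Lu[match(code, u)]
  } else {
    L <- grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")[, 1L]
  }
  matrix(L * 255 / 100, nrow = d[1L], ncol = d[2L])
}

#' Map display lightness to physical luminance
#'
#' Applies the display's power-law (gamma) transfer function:
#' `max_luminance * (L / 255) ^ gamma`, yielding luminance in cd/m^2.
#'
#' @param L Lightness values on the 0-255 scale.
#' @param gamma Display gamma exponent (> 0); 2.2 is typical for OLED panels.
#' @param max_luminance Luminance emitted at full drive, in cd/m^2.
#' @return Luminance in cd/m^2, same shape as `L`; strictly increasing in `L`.
#' @export
lightness_to_luminance <- function(L, gamma = 2.2, max_luminance = 212) {
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be positive")
  if (!is.numeric(max_luminance) || max_luminance <= 0)
    stop("'max_luminance' must be positive")
  if (any(!is.finite(L)) || any(L < 0 | L > 255))
    stop("lightness values must lie in [0, 255]")
  max_luminance * (L / 255)^gamma
}

#' Visual-field region grid
#'
#' Tiles the (canvas) image into `rows x cols` equally sized rectangles and
#' assigns each region to one of six weight groups W1-W6: a top/bottom split
#' crossed with three eccentricity rings defined by column distance from the
#' vertical midline (central, middle, peripheral). W1 is the top-central
#' group; the mapping is symmetric about the vertical midline.
#'
#' @param rows,cols Grid dimensions (defaults 6 x 8).
#' @return A `region_grid` object with fields `rows`, `cols`, `groups`
#'   (integer 1-6 per region, regions indexed row-major from the top-left)
#'   and `labels`.
#' @export
region_grid <- function(rows = 6, cols = 8) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("grid needs at least 2 rows and 2 columns")
  top <- seq_len(rows) <= ceiling(rows / 2)
  d <- abs(seq_len(cols) - (cols + 1) / 2)
  ud <- sort(unique(d))
  ring <- ceiling(3 * match(d, ud) / length(ud))       # 1 central .. 3 peripheral
  groups <- integer(rows * cols)
  for (i in seq_len(rows)) {
    groups[(i - 1L) * cols + seq_len(cols)] <- ring + if (top[i]) 0L else 3L
  }
  structure(list(rows = rows, cols = cols, groups = groups,
                 labels = paste0("W", 1:6)),
            class = "region_grid")
}

# block index per pixel: equal blocks of floor(total/k), last absorbs remainder
partition_index <- function(total, k) {
  size <- total %/% k
  if (size < 1L) stop("canvas too small for the requested grid")
  pmin(((seq_len(total) - 1L) %/% size) + 1L, k)
}

#' Per-region mean luminance
#'
#' @param canvas Luminance matrix (cd/m^2).
#' @param grid A [region_grid()].
#' @return Numeric vector of length `rows * cols` (row-major from top-left)
#'   with the mean luminance of each rectangle.
#' @export
region_means <- function(canvas, grid = region_grid()) {
  ri <- partition_index(nrow(canvas), grid$rows)
  ci <- partition_index(ncol(canvas), grid$cols)
  sums <- t(rowsum(t(rowsum(canvas, ri)), ci))         # rows x cols block sums
  cnt <- outer(tabulate(ri, grid$rows), tabulate(ci, grid$cols))
  as.vector(t(sums / cnt))
}

# pixel areas of the regions, row-major (needed for area-weighted aggregates)
region_areas <- function(height, width, grid) {
  as.vector(t(outer(tabulate(partition_index(height, grid$rows), grid$rows),
                    tabulate(partition_index(width, grid$cols), grid$cols))))
}

canvas_offsets <- function(width, height, canvas_scale, gaze) {
  cw <- round(canvas_scale * width); ch <- round(canvas_scale * height)
  gx <- min(max(gaze[1L], 1), width)                   # clamp off-screen gaze
  gy <- min(max(gaze[2L], 1), height)
  list(cw = cw, ch = ch,
       ox = round((cw + 1) / 2 - gx), oy = round((ch + 1) / 2 - gy))
}

#' Place a frame on a gaze-contingent canvas
#'
#' In screen mode (`gaze = NULL`) the canvas is the frame itself. In
#' gaze-contingent mode the frame is placed on a zero-luminance (black)
#' canvas `canvas_scale` times the screen size such that the gaze pixel
#' coincides with the canvas center; content falling outside the canvas is
#' cropped. Gaze positions off the screen are clamped to the screen bounds.
#'
#' @param frame_luminance Luminance matrix of the screen frame (cd/m^2).
#' @param gaze Optional `c(x, y)` gaze position in screen pixels (origin
#'   top-left, x rightwards, y downwards).
#' @param canvas_scale Canvas-to-screen size ratio (>= 1, default 1.5).
#' @return Luminance matrix of the canvas.
#' @export
build_canvas <- function(frame_luminance, gaze = NULL, canvas_scale = 1.5) {
  if (canvas_scale < 1) stop("'canvas_scale' must be >= 1")
  if (is.null(gaze)) return(frame_luminance)
  h <- nrow(frame_luminance); w <- ncol(frame_luminance)
  off <- canvas_offsets(w, h, canvas_scale, gaze)
  canvas <- matrix(0, off$ch, off$cw)
  cols <- seq_len(w) + off$ox
  rows <- seq_len(h) + off$oy
  kc <- cols >= 1L & cols <= off$cw
  kr <- rows >= 1L & rows <= off$ch
  canvas[rows[kr], cols[kc]] <- frame_luminance[kr, kc, drop = FALSE]
  canvas
}

#' Gaze trace constructor
#'
#' @param timestamp Sample times in seconds.
#' @param x,y Gaze position in screen pixels (origin top-left).
#' @param valid Logical validity mask (blinks/track loss are `FALSE`).
#' @return A `gaze_trace` data frame.
#' @export
gaze_trace <- function(timestamp, x, y, valid = rep(TRUE, length(timestamp))) {
  stopifnot(length(x) == length(timestamp), length(y) == length(timestamp),
            length(valid) == length(timestamp))
  structure(data.frame(timestamp = timestamp, x = x, y = y, valid = valid),
            class = c("gaze_trace", "data.frame"))
}

# carry last observation forward; leading NAs filled with `lead`
fill_forward <- function(x, lead) {
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- if (i == 1L) lead else x[i - 1L]
  }
  x
}

#' Downsample a gaze trace to the video frame rate
#'
#' Each frame interval `[t_f, t_f + 1/fps)` receives the mean of the valid
#' gaze samples falling inside it. Intervals with no valid sample carry the
#' last valid position forward (screen center before the first valid sample)
#' and are flagged invalid.
#'
#' @param gaze A [gaze_trace()] sampled at (at least) the frame rate.
#' @param frame_times Frame timestamps in seconds.
#' @param resolution Screen size `c(width, height)` in pixels, used for the
#'   screen-center fallback.
#' @return A `gaze_trace` with one sample per frame.
#' @export
downsample_gaze <- function(gaze, frame_times, resolution) {
  n <- length(frame_times)
  dt <- if (n > 1L) stats::median(diff(frame_times)) else 1
  breaks <- c(frame_times, frame_times[n] + dt)
  ok <- gaze$valid & is.finite(gaze$x) & is.finite(gaze$y)
  bin <- findInterval(gaze$timestamp, breaks)
  use <- ok & bin >= 1L & bin <= n
  x <- y <- rep(NA_real_, n)
  if (any(use)) {
    mx <- tapply(gaze$x[use], bin[use], mean)
    my <- tapply(gaze$y[use], bin[use], mean)
    idx <- as.integer(names(mx))
    x[idx] <- mx; y[idx] <- my
  }
  valid <- !is.na(x)
  cx <- (resolution[1L] + 1) / 2; cy <- (resolution[2L] + 1) / 2
  gaze_trace(frame_times, fill_forward(x, cx), fill_forward(y, cy), valid)
}

#' Frame source
#'
#' Lazy accessor for a sequence of RGB frames, so long stimuli never need to
#' be held in memory at once. `frame_key` may map a frame index to a cache
#' key: frames sharing a key are guaranteed identical, letting the extractor
#' convert repeated frames (e.g. piecewise-constant synthetic stimuli) once.
#'
#' @param get_frame `function(i)` returning frame `i` as a
#'   `height x width x 3` array with values 0-255.
#' @param n_frames Number of frames.
#' @param fps Frame rate in Hz.
#' @param width,height Frame size in pixels.
#' @param frame_key Optional `function(i)` returning a scalar cache key.
#' @return A `frame_source` object.
#' @export
frame_source <- function(get_frame, n_frames, fps, width, height,
                         frame_key = NULL) {
  stopifnot(is.function(get_frame), n_frames >= 1, fps > 0)
  structure(list(get_frame = get_frame, n_frames = as.integer(n_frames),
                 fps = fps, width = as.integer(width),
                 height = as.integer(height), frame_key = frame_key),
            class = "frame_source")
}

#' Coerce to a frame source
#'
#' Accepts a `frame_source`, a list of RGB arrays, or a directory containing
#' a PNG image sequence (frames in lexicographic filename order; requires the
#' \pkg{png} package).
#'
#' @param x Object to coerce.
#' @param fps Frame rate in Hz, for inputs that do not carry one.
#' @return A [frame_source()].
#' @export
as_frame_source <- function(x, fps = 25) {
  if (inherits(x, "frame_source")) return(x)
  if (is.list(x) && length(x) >= 1L && is.array(x[[1L]])) {
    d <- dim(x[[1L]])
    return(frame_source(function(i) x[[i]], length(x), fps,
                        width = d[2L], height = d[1L]))
  }
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames found in ", x)
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG image sequences requires the 'png' package")
    read1 <- function(i) {
      a <- png::readPNG(files[i])
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
      a[, , 1:3, drop = FALSE] * 255
    }
    d <- dim(read1(1L))
    return(frame_source(read1, length(files), fps, width = d[2L], height = d[1L]))
  }
  stop("cannot interpret 'x' as a frame source")
}

#' Event-extraction configuration
#'
#' @param gamma,max_luminance Display transfer function, see
#'   [lightness_to_luminance()].
#' @param grid Visual-field [region_grid()].
#' @param canvas_scale Gaze-contingent canvas scale (default 1.5).
#' @param lag Frame lag of the sliding luminance difference. The default 2
#'   compares frames 80 ms apart at 25 Hz, approximating the integration
#'   time of the visual system, while still emitting one value per frame.
#' @return An `event_config` list.
#' @export
event_config <- function(gamma = 2.2, max_luminance = 212,
                         grid = region_grid(), canvas_scale = 1.5, lag = 2L) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be >= 1")
  structure(list(gamma = gamma, max_luminance = max_luminance, grid = grid,
                 canvas_scale = canvas_scale, lag = lag),
            class = "event_config")
}

#' Event-trace container
#'
#' @param timestamps Event sample times in seconds (one per frame).
#' @param luminance_change Signed per-region luminance change, matrix
#'   `n_steps x n_regions` in cd/m^2 per step.
#' @param mode `"screen"` or `"gaze_contingent"`.
#' @param grid The [region_grid()] the columns refer to.
#' @param fps Source frame rate (Hz).
#' @param width,height Source resolution in pixels.
#' @param gaze Optional per-frame `gaze_trace`.
#' @return An `event_traces` object; the contrast-change matrix is the
#'   elementwise absolute value of the luminance-change matrix.
#' @export
event_traces <- function(timestamps, luminance_change, mode = "screen",
                         grid = region_grid(), fps = 25,
                         width = NA_integer_, height = NA_integer_,
                         gaze = NULL) {
  luminance_change <- as.matrix(luminance_change)
  if (nrow(luminance_change) != length(timestamps))
    stop("'luminance_change' must have one row per timestamp")
  if (ncol(luminance_change) != grid$rows * grid$cols)
    stop("'luminance_change' must have one column per grid region")
  structure(list(timestamps = timestamps,
                 luminance_change = luminance_change,
                 contrast_change = abs(luminance_change),
                 mode = mode, grid = grid, fps = fps,
                 width = width, height = height, gaze = gaze),
            class = "event_traces")
}

#' Extract luminance- and contrast-change traces from a video
#'
#' For every frame the RGB image is converted to CIELAB lightness, mapped to
#' physical luminance through the display gamma, optionally re-projected onto
#' a gaze-contingent black canvas, and averaged per visual-field region. The
#' signed luminance change at frame `t` is the region mean at `t` minus the
#' region mean at `t - lag`; the first `lag` frames are referenced against a
#' homogeneously black image. The contrast change is the absolute luminance
#' change.
#'
#' @param video A [frame_source()] or anything [as_frame_source()] accepts.
#' @param gaze Optional [gaze_trace()] covering the video duration; when
#'   supplied it is downsampled to the frame rate and events are extracted in
#'   the gaze-contingent canvas.
#' @param config An [event_config()].
#' @return An [event_traces()] object.
#' @export
extract_event_traces <- function(video, gaze = NULL, config = event_config()) {
  fs <- as_frame_source(video)
  n <- fs$n_frames
  ts <- (seq_len(n) - 1) / fs$fps
  mode <- if (is.null(gaze)) "screen" else "gaze_contingent"
  g <- if (!is.null(gaze))
    downsample_gaze(gaze, ts, c(fs$width, fs$height))
  grid <- config$grid
  R <- grid$rows * grid$cols
  M <- matrix(0, n, R)
  lum_cache <- new.env(parent = emptyenv())
  mean_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- if (!is.null(fs$frame_key)) as.character(fs$frame_key(i))
    mkey <- if (!is.null(key)) {
      if (mode == "screen") key else {
        off <- canvas_offsets(fs$width, fs$height, config$canvas_scale,
                              c(g$x[i], g$y[i]))
        paste(key, off$ox, off$oy)
      }
    }
    if (!is.null(mkey) && !is.null(mean_cache[[mkey]])) {
      M[i, ] <- mean_cache[[mkey]]
      next
    }
    lum <- if (!is.null(key) && !is.null(lum_cache[[key]])) {
      lum_cache[[key]]
    } else {
      fr <- tryCatch(fs$get_frame(i), error = function(e)
        stop(sprintf("frame %d could not be decoded: %s", i, conditionMessage(e))))
      if (is.null(fr)) stop(sprintf("frame %d could not be decoded", i))
      l <- lightness_to_luminance(rgb_to_lightness(fr),
                                  config$gamma, config$max_luminance)
      if (!is.null(key)) lum_cache[[key]] <- l
      l
    }
    canvas <- if (mode == "screen") lum else
      build_canvas(lum, c(g$x[i], g$y[i]), config$canvas_scale)
    M[i, ] <- region_means(canvas, grid)
    if (!is.null(mkey)) mean_cache[[mkey]] <- M[i, ]
  }
  lag <- min(config$lag, n)
  ref <- rbind(matrix(0, lag, R),
               M[seq_len(n - lag), , drop = FALSE])   # black reference first
  event_traces(ts, M - ref, mode = mode, grid = grid, fps = fs$fps,
               width = fs$width, height = fs$height, gaze = g)
}

#' Area-weighted overall luminance change
#'
#' Collapses per-region changes to the whole-canvas mean change (used by the
#' discrete event-detection benchmarks).
#'
#' @param traces An [event_traces()] object.
#' @return Numeric vector, one signed cd/m^2 change per frame.
#' @export
overall_change <- function(traces) {
  h <- traces$height; w <- traces$width
  areas <- if (is.na(h) || is.na(w)) rep(1, ncol(traces$luminance_change))
  else region_areas(h, w, traces$grid)
  as.numeric(traces$luminance_change %*% (areas / sum(areas)))
}
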