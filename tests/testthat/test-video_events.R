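test_that("lightness extraction matches the CIE formula at the extremes and in between", {
  expect_equal(rgb_to_lightness(gray_frame(0, 4, 4)),
               matrix(0, 4, 4), tolerance = 1e-6)
  expect_equal(rgb_to_lightness(gray_frame(255, 4, 4)),
               matrix(255, 4, 4), tolerance = 1e-6)
  fr <- array(0, dim = c(2, 2, 3))
  fr[, , 1] <- 100; fr[, , 2] <- 150; fr[, , 3] <- 200
  L <- rgb_to_lightness(fr)
  expect_lt(max(abs(L - oracle_lightness(c(100, 150, 200)))), 1)
  expect_error(rgb_to_lightness(matrix(0, 4, 4)), "three channels")
})

test_that("display gamma mapping follows the power law and is monotone", {
  expect_equal(lightness_to_luminance(255, 2.2, 212), 212)
  expect_equal(lightness_to_luminance(0, 2.2, 212), 0)
  expect_equal(lightness_to_luminance(127.5, 2.2, 212), 212 * 0.5^2.2)
  L <- sort(runif(50, 0, 255))
  expect_true(all(diff(lightness_to_luminance(L, 1.8, 100)) > 0))
  expect_error(lightness_to_luminance(300), "\\[0, 255\\]")
  expect_error(lightness_to_luminance(100, gamma = 0), "positive")
})

test_that("the weight-group layout is mirror-symmetric with W1 top-central", {
  g <- region_grid()
  gm <- matrix(g$groups, nrow = g$rows, byrow = TRUE)
  expect_equal(gm, gm[, rev(seq_len(g$cols))])      # vertical-midline symmetry
  expect_equal(gm[1, 4:5], c(1L, 1L))               # W1 covers top-central
  expect_equal(gm[1, c(1, 8)], c(3L, 3L))           # top-peripheral is W3
  expect_equal(gm[6, 4:5], c(4L, 4L))               # bottom-central is W4
  expect_setequal(unique(g$groups), 1:6)
})

test_that("region means equal brute-force rectangle averages and conserve total luminance", {
  grid <- region_grid()
  expect_equal(region_means(matrix(50, 48, 64), grid), rep(50, 48))
  half <- cbind(matrix(0, 48, 32), matrix(100, 48, 32))
  m <- matrix(region_means(half, grid), nrow = 6, byrow = TRUE)
  expect_true(all(m[, 1:4] == 0) && all(m[, 5:8] == 100))
  set.seed(42)
  cv <- matrix(runif(48 * 64, 0, 212), 48, 64)
  expect_equal(region_means(cv, grid), oracle_region_means(cv, 6, 8),
               tolerance = 1e-12)
  areas <- plrconv:::region_areas(48, 64, grid)
  expect_equal(sum(region_means(cv, grid) * areas), sum(cv), tolerance = 1e-8)
})

test_that("gaze-contingent canvas placement crops and centres correctly", {
  fr <- matrix(runif(48 * 64, 0, 100), 48, 64)
  expect_identical(build_canvas(fr), fr)             # screen mode
  centred <- build_canvas(fr, gaze = c(32.5, 24.5), canvas_scale = 1.5)
  expect_equal(dim(centred), c(72, 96))
  expect_equal(mean(centred), mean(fr) / 2.25, tolerance = 1e-12)
  expect_equal(build_canvas(fr, gaze = c(32.5, 24.5), canvas_scale = 1), fr)
  # 4x4 toy frame, gaze in the top-left corner: brute-force placement.
  # Canvas is 6x6; its centre (3.5, 3.5) rounds half-to-even to pixel (3, 3),
  # so the frame origin lands at offset +2 and the far side is cropped.
  toy <- matrix(1:16, 4, 4)
  cv <- build_canvas(toy, gaze = c(1, 1), canvas_scale = 1.5)
  oracle <- matrix(0, 6, 6)
  for (r in 1:4) for (cc in 1:4) {
    rr <- r + 2; ccc <- cc + 2
    if (rr <= 6 && ccc <= 6) oracle[rr, ccc] <- toy[r, cc]
  }
  expect_equal(cv, oracle)
  # off-screen gaze is clamped, not an error
  expect_silent(build_canvas(toy, gaze = c(-5, 99), canvas_scale = 1.5))
})

test_that("gaze downsampling averages valid samples per frame interval", {
  ft <- (0:9) / 25
  g <- generate_gaze(10 / 25, rate = 500, pattern = "fixate_point",
                     point = c(10, 20), resolution = c(64, 48))
  d <- downsample_gaze(g, ft, c(64, 48))
  expect_equal(nrow(d), 10)
  expect_true(all(d$x == 10) && all(d$y == 20) && all(d$valid))
  # interval-assignment oracle on drifting gaze (samples offset half a step
  # so none sits on a frame boundary)
  set.seed(7)
  ts <- seq(0.001, 10 / 25, by = 1 / 500)
  gx <- runif(length(ts), 1, 64)
  g2 <- gaze_trace(ts, gx, rep(24, length(ts)))
  d2 <- downsample_gaze(g2, ft, c(64, 48))
  for (f in 1:10) {
    inb <- ts >= ft[f] & ts < ft[f] + 1 / 25
    expect_equal(d2$x[f], mean(gx[inb]))
  }
  # all-invalid trace falls back to the screen centre, flagged invalid
  g3 <- gaze_trace(ts, gx, rep(24, length(ts)), valid = rep(FALSE, length(ts)))
  d3 <- downsample_gaze(g3, ft, c(64, 48))
  expect_true(all(!d3$valid))
  expect_true(all(d3$x == 65 / 2) && all(d3$y == 49 / 2))
})

test_that("event extraction applies the black reference and the lag-2 sliding difference", {
  cfg <- event_config()
  # constant video: change only at the first two steps, equal to region means
  frames <- replicate(6, gray_frame(100, 24, 32), simplify = FALSE)
  tr <- extract_event_traces(as_frame_source(frames, fps = 25), config = cfg)
  lum100 <- lightness_to_luminance(rgb_to_lightness(gray_frame(100, 24, 32)),
                                   cfg$gamma, cfg$max_luminance)
  m <- region_means(lum100, cfg$grid)
  expect_equal(tr$luminance_change[1, ], m)
  expect_equal(tr$luminance_change[2, ], m)
  expect_equal(tr$luminance_change[3:6, ], matrix(0, 4, 48), tolerance = 1e-12)
  # step 30 -> 120 at frame 11: +delta at frames 11 and 12, zero elsewhere
  vs <- video_spec(width = 32, height = 24, fps = 25, duration = 20 / 25,
                   segments = list(list(start = 0, end = 10 / 25, gray = 30),
                                   list(start = 10 / 25, end = 20 / 25, gray = 120)))
  tr2 <- extract_event_traces(generate_video(vs), config = cfg)
  lum <- function(g) lightness_to_luminance(
    rgb_to_lightness(gray_frame(g, 24, 32))[1, 1], cfg$gamma, cfg$max_luminance)
  delta <- lum(120) - lum(30)
  expect_equal(tr2$luminance_change[11, ], rep(delta, 48), tolerance = 1e-9)
  expect_equal(tr2$luminance_change[12, ], rep(delta, 48), tolerance = 1e-9)
  expect_equal(tr2$luminance_change[c(3:10, 13:20), ], matrix(0, 16, 48),
               tolerance = 1e-12)
  expect_equal(tr2$contrast_change, abs(tr2$luminance_change))
})

test_that("gaze-contingent extraction with centred gaze equals screen extraction of the padded video", {
  cfg <- event_config()
  vs <- random_video_spec(n_steps = 3, seed = 9, per_region = TRUE,
                          width = 64, height = 48, duration = 8)
  fs <- generate_video(vs)
  gz <- generate_gaze(8, rate = 100, pattern = "fixate_center",
                      resolution = c(64, 48))
  tr_gc <- extract_event_traces(fs, gz, cfg)
  # independently composed canvas: frame centred on a 96x72 black border
  pad_frames <- lapply(seq_len(fs$n_frames), function(i) {
    fr <- fs$get_frame(i)
    big <- array(0, dim = c(72, 96, 3))
    big[13:60, 17:80, ] <- fr
    big
  })
  tr_pad <- extract_event_traces(as_frame_source(pad_frames, fps = 25),
                                 config = cfg)
  expect_equal(tr_gc$luminance_change, tr_pad$luminance_change,
               tolerance = 1e-9)
  expect_equal(tr_gc$mode, "gaze_contingent")
})
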