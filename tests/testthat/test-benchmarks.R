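test_that("event detection applies the threshold and greedy separation rules", {
  expect_equal(nrow(detect_events(numeric(100), dt = 0.04)), 0)
  # two +5 impulses 0.5 s apart with 1-s separation: only the first survives
  x <- numeric(50); x[1] <- 5; x[13] <- 5          # dt 1/24 -> 0.5 s apart
  ev <- detect_events(x, dt = 0.5 / 12)
  expect_equal(ev$index, 1)
  # sub-threshold changes (+-2.9 against 3) never trigger
  y <- rep(c(2.9, -2.9), 50)
  expect_equal(nrow(detect_events(y, dt = 0.04, threshold = 3)), 0)
  # trailing zeros do not change the outcome
  z <- rnorm(60, sd = 4)
  e1 <- detect_events(z, dt = 0.04)
  e2 <- detect_events(c(z, numeric(40)), dt = 0.04)
  expect_equal(e1$index, e2$index)
  # random traces match the brute-force oracle and keep gaps >= separation
  set.seed(5)
  for (i in 1:20) {
    w <- rnorm(80, sd = 4)
    ev <- detect_events(w, dt = 0.1, threshold = 3, min_separation = 1)
    expect_equal(ev$index, oracle_detect(w, 0.1, 3, 1))
    if (nrow(ev) > 1) expect_true(all(diff(ev$time) >= 1))
  }
})

test_that("epochs are baseline-corrected over the first 250 ms and pooled-SD scaled", {
  ts <- seq(0, 20, by = 1 / 500)
  rec_const <- recording(ts, rep(3, length(ts)))
  ev <- data.frame(time = c(2, 6, 10))
  ep0 <- extract_epochs(rec_const, ev)
  expect_true(all(ep0$epochs == 0))
  # linear ramp: epoch is the ramp minus the mean of its first 125 samples
  rec_ramp <- recording(ts, ts)
  ep <- extract_epochs(rec_ramp, data.frame(time = 5))
  raw <- ep$times + 5 - mean((ep$times + 5)[seq_len(125)])
  expect_equal(ep$epochs[1, ], raw / ep$pooled_sd, tolerance = 1e-9)
  expect_equal(abs(mean(ep$epochs[1, ep$times < 0.25])), 0, tolerance = 1e-12)
  # pooled SD after the z-step is exactly 1
  set.seed(6)
  rec_noise <- recording(ts, rnorm(length(ts)))
  epn <- extract_epochs(rec_noise, ev)
  expect_equal(sd(as.numeric(epn$epochs)), 1, tolerance = 1e-12)
  # an epoch overrunning the recording is skipped with a message
  expect_message(ep_skip <- extract_epochs(rec_noise, data.frame(time = c(2, 19.5))),
                 "overruns")
  expect_equal(ep_skip$n_skipped, 1)
})

test_that("magnitude binning uses percentile boundaries with ties going down", {
  ts <- seq(0, 30, by = 1 / 100)
  rec <- recording(ts, rnorm(length(ts)))
  ev <- data.frame(time = seq(1, 25, length.out = 5),
                   magnitude = c(-10, -5, 0, 5, 10))
  ep <- extract_epochs(rec, ev)
  b <- bin_by_magnitude(ep, n_bins = 5)
  expect_equal(b$bin, 1:5)                          # one magnitude per bin
  expect_equal(b$counts, rep(1L, 5))
  # bins are ordered darker -> brighter
  expect_true(all(diff(tapply(ev$magnitude, b$bin, mean)) > 0))
  # 100 uniform magnitudes: 20 per bin up to ties
  ev2 <- data.frame(time = seq(1, 28, length.out = 100),
                    magnitude = runif(100, -40, 40))
  ep2 <- extract_epochs(rec, ev2, window = 1)
  b2 <- bin_by_magnitude(ep2, n_bins = 5)
  expect_true(all(abs(b2$counts - 20) <= 1))
  expect_error(bin_by_magnitude(ep, n_bins = 10), "at least as many")
})

test_that("the two-LTI epoch model recovers a known generating kernel", {
  dt <- 0.002
  gen <- gamma_pdf_params(c = 0.04, k = 14.1, theta = 0.05, delay = 0.2)
  kern <- gamma_pdf_rf(gen, dt, duration = 2.998)
  dil <- cumsum(kern) * dt
  dil <- dil - mean(dil[(seq_along(dil) - 1) * dt < 0.25])
  kb <- fit_korn_bach(dil, -dil, dt, family = "gamma_pdf")
  expect_lt(abs(kb$rf1$k - gen$k) / gen$k, 0.05)
  expect_lt(abs(kb$rf1$theta - gen$theta) / gen$theta, 0.05)
  expect_gt(kb$r2_dilation, 0.99)
  # constriction that is exactly the mirrored dilation leaves nothing for LTI2
  expect_equal(kb$weight, 0, tolerance = 1e-8)
  # an overshoot in the constriction is captured by a weighted second RF
  over <- gamma_pdf_rf(gamma_pdf_params(c = 1.23, k = 4.7, theta = 0.14), dt, 2.998)
  kb2 <- fit_korn_bach(dil, -dil + over, dt, family = "gamma_pdf")
  expect_gt(kb2$r2_constriction, 0.99)
  expect_equal(kb2$weight, 1, tolerance = 0.05)
  expect_error(fit_korn_bach(rep(0, 100), rep(0, 100), dt), "degenerate")
})

test_that("the pooled polynomial benchmark behaves at its limits", {
  ts <- seq(0, 10, by = 0.02)
  quintic <- function(t) 0.01 * t^5 - 0.2 * t^4 + 1.1 * t^3 - 2 * t^2 + t - 3
  recs <- list(recording(ts, quintic(ts)), recording(ts, quintic(ts)))
  pb <- polynomial_benchmark(recs, degree = 5)
  expect_gt(pb$r2, 1 - 1e-6)
  set.seed(8)
  noise <- lapply(1:4, function(i) recording(ts, rnorm(length(ts))))
  pbn <- polynomial_benchmark(noise, degree = 5)
  expect_lt(pbn$r2, 0.05)
  pb0 <- polynomial_benchmark(noise, degree = 0)
  df_pooled <- unlist(lapply(noise, function(r) zscore(r$pupil)))
  expect_equal(pb0$coefficients[1], mean(df_pooled), tolerance = 1e-10)
  expect_error(polynomial_benchmark(noise[1]), "two trials")
})
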