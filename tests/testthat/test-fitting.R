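test_that("the loss is zero at the generating parameters and one for a flat prediction", {
  truth <- simulation_truth(noise_sd = 0)
  vs <- random_video_spec(n_steps = 4, seed = 3, duration = 15)
  tr <- extract_event_traces(generate_video(vs))
  rec <- generate_pupil(tr, truth)
  trial <- plr_trial(tr, rec, 1)
  expect_lt(loss(list(trial), truth$lum_params, truth$contrast_params,
                 plrconv:::truth_spec(truth)), 1e-8)
  # all-zero events give a zero-variance (flat) prediction; against a
  # unit-variance target the RMSE is exactly 1
  flat <- plr_trial(single_region_traces(numeric(length(tr$timestamps))), rec, 1)
  expect_equal(loss(list(flat), truth$lum_params, truth$contrast_params,
                    plrconv:::truth_spec(truth)), 1, tolerance = 1e-10)
})

test_that("evaluate returns exact closed forms and near-zero for independent noise", {
  x <- c(0.3, -1.2, 2.2, 0.7, -0.4)
  expect_equal(evaluate(x, x), c(r2 = 1, r = 1, rmse = 0))
  # a z-scored series against its negation: SS_res = 4 SS_tot
  z <- zscore(x)
  m <- evaluate(-z, z)
  expect_equal(unname(m), c(-3, -1, 2), tolerance = 1e-12)
  # an independent unit-variance predictor: r ~ 0, and under the
  # 1 - SS_res/SS_tot definition R^2 -> -1 (residual variance is doubled)
  set.seed(11)
  n <- 1e5
  m2 <- evaluate(rnorm(n), rnorm(n))
  expect_equal(m2[["r2"]], -1, tolerance = 0.05)
  expect_lt(abs(m2[["r"]]), 0.02)
  expect_lt(abs(m2[["r"]]^2), 0.02)                 # correlation-based variance ~ 0
  # zero-variance observation is flagged undefined
  m3 <- evaluate(rnorm(5), rep(2, 5))
  expect_true(isTRUE(attr(m3, "undefined")))
  expect_true(is.na(m3[["r2"]]))
  expect_error(evaluate(1:3, 1:4), "equal length")
})

test_that("the BIC follows n log(rss/n) + k log(n)", {
  expect_equal(bic(100, 100, 0), 0)
  expect_equal(bic(2.5, 100, 5) - bic(2.5, 100, 3), 2 * log(100))
  expect_equal(bic(2.5, 100, 5), 100 * log(0.025) + 5 * log(100))
  expect_error(bic(0, 10, 1), "positive")
  expect_error(bic(1, 3, 5), "exceed")
})

test_that("random splits are reproducible, sized 14/6 for twenty trials, and seed-sensitive", {
  cfg <- fit_config(seed = 42)
  f1 <- make_folds(1:20, cfg)
  expect_length(f1, 5)
  for (fl in f1) {
    expect_length(fl$train, 14)
    expect_length(fl$test, 6)
    expect_setequal(c(fl$train, fl$test), 1:20)
  }
  f2 <- make_folds(1:20, cfg)
  expect_identical(f1, f2)
  f3 <- make_folds(1:20, fit_config(seed = 43))
  expect_false(identical(f1, f3))
  expect_error(fit_config(train_fraction = 1), "strictly between")
  expect_error(make_folds(1:2, fit_config(train_fraction = 0.9)),
               "empty training or testing")
})

test_that("simplex fitting recovers the generating parameters from noiseless data", {
  truth <- simulation_truth(noise_sd = 0)
  trials <- simulate_trials(n_trials = 4, truth = truth, seed = 11,
                            n_steps = 6, duration = 30)
  f <- fit(trials, model_spec(), fit_config(n_folds = 2, seed = 5, maxit = 800))
  p <- colMeans(f$param_per_fold)
  expect_lt(abs(p[["lum_tmax"]] - truth$lum_params$t_max), 0.05)
  expect_lt(abs(p[["con_tmax"]] - truth$contrast_params$t_max), 0.05)
  expect_lt(abs(p[["contrast_weight"]] - truth$contrast_weight), 0.05)
  expect_gt(f$summary$test_r2_mean, 0.99)
  # observation noise degrades fit quality but not recovery beyond +-20%
  truthn <- simulation_truth(noise_sd = 0.5)
  trialsn <- simulate_trials(n_trials = 4, truth = truthn, seed = 11,
                             n_steps = 6, duration = 30)
  fn <- fit(trialsn, model_spec(), fit_config(n_folds = 2, seed = 5, maxit = 800))
  pn <- colMeans(fn$param_per_fold)
  expect_lt(fn$summary$test_r2_mean, f$summary$test_r2_mean)
  expect_lt(abs(pn[["lum_tmax"]] - 0.28) / 0.28, 0.2)
  expect_lt(abs(pn[["con_tmax"]] - 0.53) / 0.53, 0.2)
  expect_lt(abs(pn[["contrast_weight"]] - 0.42) / 0.42, 0.2)
  # training-set metrics agree algebraically with the loss: RMSE^2 = SS_res/n
  fl <- f$folds[[1]]
  p1 <- plrconv:::params_from_vector(f$param_per_fold[1, ], f$spec)
  sp1 <- f$spec
  sp1$contrast_weight <- p1$contrast_weight
  l <- loss(trials[fl$train], p1$lum_params, p1$contrast_params, sp1,
            weights = p1$weights)
  rmse1 <- f$per_fold$rmse[f$per_fold$fold == 1 & f$per_fold$set == "train"]
  expect_equal(l, rmse1, tolerance = 1e-10)
})

test_that("adding the contrast component never hurts the training fit on contrast-bearing data", {
  truth <- simulation_truth(noise_sd = 0.2)
  trials <- simulate_trials(n_trials = 3, truth = truth, seed = 17,
                            n_steps = 5, duration = 20)
  cfg <- fit_config(n_folds = 1, seed = 2, maxit = 600)
  f_lum <- fit(trials, model_spec(components = "sustained_luminance"), cfg)
  f_full <- fit(trials, model_spec(), cfg)
  train_r2 <- function(f) f$per_fold$r2[f$per_fold$set == "train"]
  expect_gte(f_full$summary$test_r2_mean, -1)       # sanity
  expect_gte(mean(train_r2(f_full)), mean(train_r2(f_lum)) - 1e-6)
})

test_that("pupil gaps are bridged briefly and masked when long", {
  ts <- seq(0, 10, by = 0.01)
  p <- sin(ts)
  valid <- rep(TRUE, length(ts))
  valid[ts > 2 & ts < 2.3] <- FALSE                 # 300 ms: interpolate
  valid[ts > 5 & ts < 6.5] <- FALSE                 # 1.5 s: mask
  p[!valid] <- NA
  rec <- recording(ts, p, valid)
  at <- seq(0.02, 9.98, by = 0.04)
  y <- interpolate_pupil(rec, at, max_gap = 0.5)
  expect_true(all(is.finite(y[at > 2 & at < 2.3])))
  expect_true(all(is.na(y[at > 5.1 & at < 6.4])))
  expect_equal(y[at < 2], sin(at[at < 2]), tolerance = 1e-3)
})
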