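#!/usr/bin/env Rscript
# Thin command-line front end over the plrconv package.
#
#   Rscript scripts/plrconv.R simulate --out DIR [--seed N] [--trials N]
#                                      [--duration S] [--steps N] [--noise SD]
#   Rscript scripts/plrconv.R extract  --frames DIR --movie NAME --subject NAME
#                                      [--gaze CSV] [--fps N] [--out DIR]
#   Rscript scripts/plrconv.R fit      --cache JSON --pupil CSV --movie NAME
#                                      --subject NAME [--regions] [--out DIR]
#
# `simulate` emits gaze/pupil CSVs, an event-trace cache, a PNG frame
# sequence and a ground-truth JSON; `extract` builds the event cache from a
# PNG frame directory; `fit` estimates the model and writes the parameter
# and prediction CSVs.

suppressPackageStartupMessages({
  library(plrconv)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L)
  stop("usage: plrconv.R <simulate|extract|fit> [options]", call. = FALSE)
cmd <- argv[1L]

common <- list(
  make_option("--out", type = "character", default = ".",
              help = "output directory"),
  make_option("--seed", type = "integer", default = 1L)
)

if (cmd == "simulate") {
  spec <- c(common, list(
    make_option("--trials", type = "integer", default = 1L),
    make_option("--duration", type = "double", default = 60),
    make_option("--steps", type = "integer", default = 10L),
    make_option("--noise", type = "double", default = 0.5),
    make_option("--write-frames", action = "store_true", default = FALSE,
                dest = "write_frames", help = "also dump PNG frames")))
  o <- parse_args(OptionParser(option_list = spec), argv[-1L])
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  truth <- simulation_truth(noise_sd = o$noise)
  trials <- simulate_trials(n_trials = o$trials, truth = truth, seed = o$seed,
                            n_steps = o$steps, duration = o$duration)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    name <- sprintf("trial%02d", i)
    write_event_cache(tr$traces, name, "sim",
                      dir = file.path(o$out, "Visual events"))
    utils::write.csv(data.frame(timestamp = tr$recording$timestamps,
                                pupil = tr$recording$pupil),
                     file.path(o$out, paste0(name, "_pupil.csv")),
                     row.names = FALSE)
    if (o$write_frames && requireNamespace("png", quietly = TRUE)) {
      fdir <- file.path(o$out, paste0(name, "_frames"))
      dir.create(fdir, showWarnings = FALSE)
      vs <- random_video_spec(n_steps = o$steps, seed = o$seed + 101L * i,
                              duration = o$duration)
      fs <- generate_video(vs)
      for (k in seq_len(fs$n_frames))
        png::writePNG(fs$get_frame(k) / 255,
                      file.path(fdir, sprintf("frame%05d.png", k)))
    }
  }
  jsonlite::write_json(
    list(lum = unclass(truth$lum_params), con = unclass(truth$contrast_params),
         contrast_weight = truth$contrast_weight,
         weights = as.numeric(truth$weights), noise_sd = truth$noise_sd),
    file.path(o$out, "truth.json"), auto_unbox = TRUE, digits = NA)
  cat("simulated", length(trials), "trial(s) into", o$out, "\n")

} else if (cmd == "extract") {
  spec <- c(common, list(
    make_option("--frames", type = "character"),
    make_option("--gaze", type = "character", default = NULL),
    make_option("--fps", type = "double", default = 25),
    make_option("--movie", type = "character", default = "movie"),
    make_option("--subject", type = "character", default = "subject"),
    make_option("--gamma", type = "double", default = 2.2),
    make_option("--max-luminance", type = "double", default = 212,
                dest = "max_luminance")))
  o <- parse_args(OptionParser(option_list = spec), argv[-1L])
  if (is.null(o$frames)) stop("--frames is required")
  cfg <- event_config(gamma = o$gamma, max_luminance = o$max_luminance)
  gaze <- if (!is.null(o$gaze)) read_gaze_csv(o$gaze)$gaze
  traces <- extract_event_traces(as_frame_source(o$frames, fps = o$fps),
                                 gaze, cfg)
  path <- write_event_cache(traces, o$movie, o$subject,
                            dir = file.path(o$out, "Visual events"))
  cat("event cache written to", path, "\n")

} else if (cmd == "fit") {
  spec <- c(common, list(
    make_option("--cache", type = "character"),
    make_option("--pupil", type = "character"),
    make_option("--movie", type = "character", default = "movie"),
    make_option("--subject", type = "character", default = "subject"),
    make_option("--family", type = "character", default = "erlang"),
    make_option("--regions", action = "store_true", default = FALSE)))
  o <- parse_args(OptionParser(option_list = spec), argv[-1L])
  if (is.null(o$cache) || is.null(o$pupil))
    stop("--cache and --pupil are required (comma-separated lists, one entry per trial)")
  caches <- strsplit(o$cache, ",")[[1L]]
  pupils <- strsplit(o$pupil, ",")[[1L]]
  if (length(caches) != length(pupils))
    stop("--cache and --pupil must list the same number of trials")
  if (length(caches) < 2L)
    stop("the cross-validated fit needs at least two trials")
  trials <- lapply(seq_along(caches), function(i) {
    traces <- read_event_cache(caches[i])
    pdf <- utils::read.csv(pupils[i])
    plr_trial(traces,
              recording(pdf$timestamp, pdf$pupil, valid = is.finite(pdf$pupil)),
              id = i)
  })
  msp <- model_spec(rf_family = o$family, use_regions = o$regions)
  fres <- fit(trials, msp, fit_config(seed = o$seed))
  out <- file.path(o$out, "csv results")
  write_parameters_csv(fres, o$movie, o$subject, dir = out)
  pred <- predict_pupil(trials[[1L]]$traces, fres$params$lum_params,
                        fres$params$contrast_params, msp,
                        fres$params$weights)
  write_prediction_csv(pred, trials[[1L]]$recording, o$movie, o$subject,
                       dir = out)
  print(fres)

} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
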