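# Parameter estimation: minimize the RMSE between z-scored predicted and
# observed pupil traces by Nelder-Mead simplex search, with repeated random
# train/test splits and model-comparison metrics.

#' Pupil recording constructor
#'
#' @param timestamps Sample times in seconds.
#' @param pupil Pupil size (arbitrary units; z-scored internally).
#' @param valid Logical mask; invalid samples (blinks, track loss) are
#'   bridged by interpolation or excluded from the loss.
#' @return A `recording` object.
#' @export
recording <- function(timestamps, pupil, valid = rep(TRUE, length(timestamps))) {
  stopifnot(length(pupil) == length(timestamps),
            length(valid) == length(timestamps))
  rate <- if (length(timestamps) > 1L)
    1 / stats::median(diff(timestamps)) else NA_real_
  structure(list(timestamps = timestamps, pupil = pupil, valid = valid,
                 rate = rate),
            class = "recording")
}

#' One movie-viewing trial: event traces plus the aligned pupil recording
#'
#' @param traces An [event_traces()] object.
#' @param recording A [recording()] covering the same time span.
#' @param id Trial identifier.
#' @return A `plr_trial` object.
#' @export
plr_trial <- function(traces, recording, id = NULL) {
  structure(list(traces = traces, recording = recording, id = id),
            class = "plr_trial")
}

#' Fitting configuration
#'
#' @param train_fraction Fraction of trials assigned to the training set of
#'   each fold (default 0.7); must be strictly between 0 and 1.
#' @param n_folds Number of independent random train/test splits (default 5).
#' @param seed Seed controlling the splits (the optimizer itself is
#'   deterministic).
#' @param maxit,reltol Nelder-Mead control settings.
#' @param n_restarts Number of simplex restarts from the incumbent solution
#'   (restarting rebuilds the simplex and helps escape premature collapse;
#'   default 1).
#' @param init,bounds Optional named numeric vectors overriding per-parameter
#'   initial values and `c(lower, upper)` bound rows (see
#'   [fit_param_table()]).
#' @param max_gap Longest pupil gap in seconds bridged by linear
#'   interpolation; longer gaps stay masked out of the loss (default 0.5 s).
#' @param fit_amplitude Also fit a common response amplitude. With z-scored
#'   losses the overall scale is unidentifiable, so this matters only for
#'   un-standardized outputs; default `FALSE`.
#' @return A `fit_config` object.
#' @export
fit_config <- function(train_fraction = 0.7, n_folds = 5, seed = 1,
                       maxit = 1000, reltol = 1e-9, n_restarts = 1,
                       init = NULL, bounds = NULL, max_gap = 0.5,
                       fit_amplitude = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("'train_fraction' must lie strictly between 0 and 1")
  if (n_folds < 1) stop("'n_folds' must be >= 1")
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), maxit = maxit, reltol = reltol,
                 n_restarts = as.integer(n_restarts), init = init,
                 bounds = bounds, max_gap = max_gap,
                 fit_amplitude = isTRUE(fit_amplitude)),
            class = "fit_config")
}

#' Free-parameter layout for a model specification
#'
#' Returns the name, initial value and box bounds of every free parameter
#' implied by `spec`: shape and peak-time of each enabled response function,
#' the contrast weight, and (when `use_regions`) the regional weights W2-W6.
#' Defaults: shape in `[0.5, 40]`, peak time in `[0.05, 2]` s (`theta` in
#' `[0.005, 2]` s for the gamma-density family), weights in `[0, 10]`.
#'
#' @param spec A [model_spec()].
#' @param config A [fit_config()]; `config$init` / `config$bounds` override
#'   individual entries by name.
#' @return Data frame with columns `name`, `init`, `lower`, `upper`.
#' @export
fit_param_table <- function(spec, config = fit_config()) {
  rows <- list()
  add <- function(name, init, lower, upper)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, init = init,
                                             lower = lower, upper = upper)
  erlang <- spec$rf_family == "erlang"
  if ("sustained_luminance" %in% spec$components) {
    if (erlang) {
      add("lum_n", 10, 0.5, 40); add("lum_tmax", 0.3, 0.05, 2)
    } else {
      add("lum_k", 10, 0.5, 40); add("lum_theta", 0.03, 0.005, 2)
    }
  }
  if ("transient_contrast" %in% spec$components) {
    if (erlang) {
      add("con_n", 3, 0.5, 40); add("con_tmax", 0.5, 0.05, 2)
    } else {
      add("con_k", 3, 0.5, 40); add("con_theta", 0.25, 0.005, 2)
    }
    if (length(spec$components) > 1L)
      add("contrast_weight", 0.5, 0, 10)
  }
  if (isTRUE(spec$use_regions))
    for (w in paste0("W", 2:6)) add(w, 1, 0, 10)
  if (isTRUE(config$fit_amplitude))
    add("amplitude", 1, 0.01, 100)
  tab <- do.call(rbind, rows)
  if (!is.null(config$init)) {
    i <- match(names(config$init), tab$name)
    tab$init[i[!is.na(i)]] <- config$init[!is.na(i)]
  }
  if (!is.null(config$bounds)) {
    for (nm in rownames(config$bounds)) {
      j <- match(nm, tab$name)
      if (!is.na(j)) { tab$lower[j] <- config$bounds[nm, 1L]; tab$upper[j] <- config$bounds[nm, 2L] }
    }
  }
  tab
}

# logistic box transform: simplex searches an unconstrained space
to_unconstrained <- function(p, lo, hi) {
  u <- (p - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  stats::qlogis(u)
}
to_constrained <- function(x, lo, hi) lo + (hi - lo) * stats::plogis(x)

params_from_vector <- function(p, spec) {
  amp <- if ("amplitude" %in% names(p)) p[["amplitude"]] else 1
  has <- function(nm) nm %in% names(p)
  lum <- con <- NULL
  if (spec$rf_family == "erlang") {
    if (has("lum_n"))
      lum <- erlang_params(p[["lum_n"]], p[["lum_tmax"]], amp, spec$delay)
    if (has("con_n"))
      con <- erlang_params(p[["con_n"]], p[["con_tmax"]], amp, spec$delay)
  } else {
    if (has("lum_k"))
      lum <- gamma_pdf_params(amp, p[["lum_k"]], p[["lum_theta"]], spec$delay)
    if (has("con_k"))
      con <- gamma_pdf_params(amp, p[["con_k"]], p[["con_theta"]], spec$delay)
  }
  cw <- if ("contrast_weight" %in% names(p)) p[["contrast_weight"]]
  else spec$contrast_weight
  w <- rep(1, 6)
  for (i in 2:6) {
    nm <- paste0("W", i)
    if (nm %in% names(p)) w[i] <- p[[nm]]
  }
  list(lum_params = lum, contrast_params = con, contrast_weight = cw,
       weights = w)
}

# linear interpolation of the pupil trace onto `at`, masking long gaps
interpolate_pupil <- function(rec, at, max_gap = 0.5) {
  ok <- rec$valid & is.finite(rec$pupil)
  if (!any(ok)) stop("recording contains no valid pupil samples")
  tok <- rec$timestamps[ok]
  y <- stats::approx(tok, rec$pupil[ok], xout = at, rule = 2)$y
  if (length(tok) > 1L) {
    i <- findInterval(at, tok)
    interior <- i >= 1L & i < length(tok)
    gap <- rep(0, length(at))
    gap[interior] <- tok[i[interior] + 1L] - tok[i[interior]]
    y[interior & gap > max_gap & at > tok[pmax(i, 1L)]] <- NA_real_
  }
  y
}

# per-trial precomputation: group-summed event matrices + z-scored target
prepare_trials <- function(trials, config = fit_config()) {
  lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (!inherits(tr, "plr_trial")) stop("'trials' must be a list of plr_trial objects")
    grid <- tr$traces$grid
    grp <- grid$groups
    Glum <- t(rowsum(t(tr$traces$luminance_change), grp))
    Gcon <- t(rowsum(t(tr$traces$contrast_change), grp))
    obs <- interpolate_pupil(tr$recording, tr$traces$timestamps, config$max_gap)
    valid <- is.finite(obs)
    if (sum(valid) < 2L) stop("trial has fewer than two valid pupil samples")
    oz <- rep(NA_real_, length(obs))
    oz[valid] <- zscore(obs[valid])
    ts <- tr$traces$timestamps
    list(id = if (is.null(tr$id)) i else tr$id,
         Glum = Glum, Gcon = Gcon, obs_z = oz, valid = valid,
         dt = if (length(ts) > 1L) ts[2L] - ts[1L] else 1 / tr$traces$fps)
  })
}

predict_prepared <- function(prep1, kl, kc, cw, w6, components) {
  pred <- numeric(nrow(prep1$Glum))
  if ("sustained_luminance" %in% components)
    pred <- pred + sustained_response(
      convolve_trace(as.numeric(prep1$Glum %*% w6), kl), prep1$dt)
  if ("transient_contrast" %in% components)
    pred <- pred + cw * convolve_trace(as.numeric(prep1$Gcon %*% w6), kc)
  -pred
}

loss_prepared <- function(prep, kl, kc, cw, w6, components) {
  se <- 0; nn <- 0L
  for (p in prep) {
    raw <- predict_prepared(p, kl, kc, cw, w6, components)
    v <- p$valid
    e <- zscore(raw[v]) - p$obs_z[v]
    se <- se + sum(e * e)
    nn <- nn + length(e)
  }
  if (nn == 0L) stop("no valid samples to compute the loss")
  sqrt(se / nn)
}

make_loss_fn <- function(prep, spec, tab) {
  dt <- prep[[1L]]$dt
  function(theta) {
    p <- stats::setNames(to_constrained(theta, tab$lower, tab$upper), tab$name)
    pl <- params_from_vector(p, spec)
    kl <- if (!is.null(pl$lum_params))
      rf_kernel(pl$lum_params, dt, spec$kernel_duration)
    kc <- if (!is.null(pl$contrast_params))
      rf_kernel(pl$contrast_params, dt, spec$kernel_duration)
    loss_prepared(prep, kl, kc, pl$contrast_weight, pl$weights, spec$components)
  }
}

#' Pooled RMSE between predicted and observed pupil traces
#'
#' The root mean squared error over all valid samples of all supplied
#' trials, with both the per-trial prediction and the per-trial observation
#' z-standardized first.
#'
#' @param trials List of [plr_trial()] objects.
#' @param lum_params,contrast_params Response-function parameters.
#' @param spec A [model_spec()].
#' @param weights Regional weights (length-6 vector).
#' @param config A [fit_config()] (interpolation settings).
#' @return The pooled RMSE (scalar).
#' @export
loss <- function(trials, lum_params = NULL, contrast_params = NULL,
                 spec = model_spec(), weights = regional_weights(),
                 config = fit_config()) {
  prep <- prepare_trials(trials, config)
  dt <- prep[[1L]]$dt
  kl <- if (!is.null(lum_params)) rf_kernel(lum_params, dt, spec$kernel_duration)
  kc <- if (!is.null(contrast_params)) rf_kernel(contrast_params, dt, spec$kernel_duration)
  loss_prepared(prep, kl, kc, spec$contrast_weight, as.numeric(weights),
                spec$components)
}

#' Goodness-of-fit between a predicted and an observed trace
#'
#' @param pred,obs Numeric vectors of equal length (>= 2 finite pairs).
#' @param zscore_first z-standardize both series before comparing
#'   (default `TRUE`).
#' @return Named vector `c(r2, r, rmse)` where
#'   `r2 = 1 - SS_res / SS_tot`, `r` is the Pearson correlation and `rmse`
#'   the root mean squared error. A zero-variance observation yields `NA`
#'   for `r2`/`r` with attribute `undefined = TRUE`.
#' @export
evaluate <- function(pred, obs, zscore_first = TRUE) {
  if (length(pred) != length(obs)) stop("'pred' and 'obs' must have equal length")
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(obs) < 2L) stop("need at least two finite sample pairs")
  if (stats::sd(obs) == 0) {
    out <- c(r2 = NA_real_, r = NA_real_,
             rmse = sqrt(mean((pred - obs)^2)))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (zscore_first) {
    obs <- zscore(obs)
    pred <- zscore(pred)
  }
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  c(r2 = 1 - ss_res / ss_tot,
    r = suppressWarnings(stats::cor(pred, obs)),
    rmse = sqrt(mean((obs - pred)^2)))
}

#' Bayesian information criterion from a residual sum of squares
#'
#' `n * log(rss / n) + k * log(n)` -- the Gaussian-likelihood BIC up to an
#' additive constant shared by models fitted on the same samples.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_samples Number of samples (> `k_params`).
#' @param k_params Number of free parameters.
#' @return The BIC value.
#' @export
bic <- function(rss, n_samples, k_params) {
  if (rss <= 0) stop("'rss' must be positive")
  if (n_samples <= k_params) stop("'n_samples' must exceed 'k_params'")
  n_samples * log(rss / n_samples) + k_params * log(n_samples)
}

#' Random train/test fold assignments
#'
#' Draws `n_folds` independent random splits of the trial ids into a
#' training fraction and its complement (repeated random sub-sampling, not a
#' partition: a trial may appear in several or no test sets).
#'
#' @param trial_ids Vector of trial identifiers (>= 2).
#' @param config A [fit_config()] providing `train_fraction`, `n_folds` and
#'   `seed`.
#' @return List of `n_folds` lists with elements `fold`, `train`, `test`.
#' @export
make_folds <- function(trial_ids, config = fit_config()) {
  n <- length(trial_ids)
  if (n < 2L) stop("need at least two trials to split")
  n_train <- round(config$train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("'train_fraction' leaves an empty training or testing set")
  set.seed(config$seed)
  lapply(seq_len(config$n_folds), function(f) {
    tr <- sample(trial_ids, n_train)
    list(fold = f, train = sort(tr), test = sort(setdiff(trial_ids, tr)))
  })
}

pooled_metrics <- function(prep, ids, kl, kc, cw, w6, components) {
  keep <- vapply(prep, function(p) p$id %in% ids, logical(1L))
  pz <- oz <- list()
  for (p in prep[keep]) {
    raw <- predict_prepared(p, kl, kc, cw, w6, components)
    v <- p$valid
    pz[[length(pz) + 1L]] <- zscore(raw[v])
    oz[[length(oz) + 1L]] <- p$obs_z[v]
  }
  evaluate(unlist(pz), unlist(oz), zscore_first = FALSE)
}

#' Fit the convolution model to pupil recordings
#'
#' For each random train/test fold the free parameters (see
#' [fit_param_table()]) are estimated on the training trials by Nelder-Mead
#' search on the pooled z-scored RMSE, then evaluated on the held-out
#' trials. Reported parameters are the across-fold means; reported metrics
#' are pooled per set and summarized across folds.
#'
#' @param trials List of [plr_trial()] objects sharing sampling step and
#'   region layout.
#' @param spec A [model_spec()].
#' @param config A [fit_config()]. The result is deterministic given
#'   `config$seed`.
#' @return A `plr_fit` object: `params` (fitted parameter objects),
#'   `param_per_fold`, `per_fold` metric table, `summary` (test-set means and
#'   SDs plus mean BIC), `n_free`, `converged`.
#' @export
fit <- function(trials, spec = model_spec(), config = fit_config()) {
  prep <- prepare_trials(trials, config)
  ids <- vapply(prep, function(p) p$id, numeric(1L))
  tab <- fit_param_table(spec, config)
  folds <- make_folds(ids, config)
  k <- nrow(tab)
  par_mat <- matrix(NA_real_, length(folds), k,
                    dimnames = list(NULL, tab$name))
  rows <- list()
  conv <- logical(length(folds))
  for (f in seq_along(folds)) {
    fl <- folds[[f]]
    train_prep <- prep[vapply(prep, function(p) p$id %in% fl$train, logical(1L))]
    obj <- make_loss_fn(train_prep, spec, tab)
    theta <- to_unconstrained(tab$init, tab$lower, tab$upper)
    res <- stats::optim(theta, obj, method = "Nelder-Mead",
                        control = list(maxit = config$maxit, reltol = config$reltol))
    for (r in seq_len(config$n_restarts)) {
      res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                          control = list(maxit = config$maxit, reltol = config$reltol))
    }
    conv[f] <- res$convergence == 0L
    p <- stats::setNames(to_constrained(res$par, tab$lower, tab$upper), tab$name)
    par_mat[f, ] <- p
    pl <- params_from_vector(p, spec)
    dt <- prep[[1L]]$dt
    kl <- if (!is.null(pl$lum_params)) rf_kernel(pl$lum_params, dt, spec$kernel_duration)
    kc <- if (!is.null(pl$contrast_params)) rf_kernel(pl$contrast_params, dt, spec$kernel_duration)
    for (set in c("train", "test")) {
      m <- pooled_metrics(prep, fl[[set]], kl, kc, pl$contrast_weight,
                          pl$weights, spec$components)
      n_set <- sum(vapply(prep, function(q)
        (q$id %in% fl[[set]]) * sum(q$valid), numeric(1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, set = set, r2 = m[["r2"]], r = m[["r"]], rmse = m[["rmse"]],
        n = n_set,
        bic = bic(m[["rmse"]]^2 * n_set, n_set, k))
    }
  }
  per_fold <- do.call(rbind, rows)
  p_mean <- stats::setNames(colMeans(par_mat), tab$name)
  params <- params_from_vector(p_mean, spec)
  params$weights <- regional_weights(params$weights)
  test <- per_fold[per_fold$set == "test", ]
  structure(list(params = params,
                 param_per_fold = par_mat,
                 per_fold = per_fold,
                 summary = list(test_r2_mean = mean(test$r2),
                                test_r2_sd = stats::sd(test$r2),
                                test_r_mean = mean(test$r),
                                test_rmse_mean = mean(test$rmse),
                                test_bic_mean = mean(test$bic)),
                 n_free = k, converged = conv, folds = folds,
                 spec = spec, config = config),
            class = "plr_fit")
}

#' @export
print.plr_fit <- function(x, ...) {
  cat("Convolution-model fit (", x$spec$rf_family, " response functions)\n", sep = "")
  cat(sprintf("  free parameters: %d; folds: %d%s\n", x$n_free,
              length(x$converged),
              if (all(x$converged)) "" else " [not all folds converged]"))
  p <- colMeans(x$param_per_fold)
  cat("  across-fold mean parameters:\n")
  for (nm in names(p)) cat(sprintf("    %-16s %.4f\n", nm, p[[nm]]))
  cat(sprintf("  test R^2 = %.3f (SD %.3f), r = %.3f, RMSE = %.3f, BIC = %.1f\n",
              x$summary$test_r2_mean, x$summary$test_r2_sd,
              x$summary$test_r_mean, x$summary$test_rmse_mean,
              x$summary$test_bic_mean))
  invisible(x)
}
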