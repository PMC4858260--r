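# Measurement protocols on the test system: AV and temporal-frequency
# sweeps, rectification comparison, invariance reports, and curve fitting
# with adjusted R-squared.

#' Default log-spaced angular-velocity grid
#'
#' @param from,to Grid limits in deg/s (defaults 10 and 1000).
#' @param per_decade Grid density (default 10 points per decade).
#' @return Strictly increasing numeric grid including both limits.
#' @export
av_grid <- function(from = 10, to = 1000, per_decade = 10) {
  n <- ceiling(log10(to / from) * per_decade) + 1
  10^seq(log10(from), log10(to), length.out = n)
}

#' Default log-spaced temporal-frequency grid
#'
#' @param from,to Grid limits in Hz (defaults 0.25 and 100).
#' @param per_decade Grid density (default 10 points per decade).
#' @return Strictly increasing numeric grid including both limits.
#' @export
tf_grid <- function(from = 0.25, to = 100, per_decade = 10) {
  n <- ceiling(log10(to / from) * per_decade) + 1
  10^seq(log10(from), log10(to), length.out = n)
}

#' Measure the steady-state detector response to a grating
#'
#' Runs the test system on a moving grating for `duration` seconds from a
#' fresh (zero) state and returns the time-mean over the final `window`
#' seconds of the smoothed array output `S`, and of the pre-division fast and
#' slow subunit population means.
#'
#' @param system An [build_test_system()] result (or an [avdu_params()], in
#'   which case the default geometry is used).
#' @param stimulus A [grating()].
#' @param duration Simulation length in seconds (default 2).
#' @param window Averaging window in seconds, counted from the end (default
#'   1).
#' @param dt Step in ms (default 0.1).
#' @return Named numeric vector with `S`, `fast` and `slow`.
#' @export
measure_response <- function(system, stimulus, duration = 2, window = 1,
                             dt = 0.1) {
  if (inherits(system, "avdu_params")) system <- build_test_system(system)
  stopifnot(inherits(system, "avdu_test_system"), inherits(stimulus, "grating"))
  geom <- system$geom
  n <- round(duration * 1000 / dt)
  tt <- (seq_len(n) - 1) * dt / 1000
  lum <- sample_test_array(geom, stimulus, tt)
  out <- run_avdu_array(lum, geom$from, geom$to, system$params, dt)
  idx <- tt >= duration - window
  res <- c(S = mean(out$S[idx]), fast = mean(out$mean_fast[idx]),
           slow = mean(out$mean_slow[idx]))
  if (any(!is.finite(res)))
    stop(sprintf("non-finite response for wavelength %g deg, AV %g deg/s",
                 stimulus$wavelength, stimulus$angular_velocity))
  res
}

new_response_curve <- function(df, kind, stimulus) {
  structure(df, kind = kind, stimulus = stimulus,
            class = c("avdu_response_curve", "data.frame"))
}

#' Sweep the detector response over angular velocity
#'
#' One [measure_response()] per grid point, each from a fresh detector
#' state.
#'
#' @param params An [avdu_params()].
#' @param wavelength Grating spatial wavelength in degrees (default 38, the
#'   tuning stimulus).
#' @param contrast Michelson contrast (default 1).
#' @param grid Angular-velocity grid in deg/s (default [av_grid()]).
#' @param waveform Grating waveform (default `"square"`).
#' @param ... Passed to [measure_response()].
#' @return An `avdu_response_curve` data frame with columns `av`, `response`
#'   (mean `S`), `fast` and `slow`.
#' @export
sweep_av <- function(params, wavelength = 38, contrast = 1, grid = av_grid(),
                     waveform = "square", ...) {
  system <- build_test_system(params)
  rows <- vapply(grid, function(av) {
    measure_response(system, grating(waveform, wavelength, av, contrast), ...)
  }, numeric(3))
  new_response_curve(
    data.frame(av = grid, response = rows["S", ], fast = rows["fast", ],
               slow = rows["slow", ]),
    kind = "angular_velocity",
    stimulus = list(waveform = waveform, wavelength = wavelength,
                    contrast = contrast))
}

#' Sweep the pre-division subunit responses over temporal frequency
#'
#' For each wavelength, drives the test system with square-wave gratings at
#' angular velocity `tf * wavelength` and records the population-mean fast
#' and slow correlator outputs before the division stage. These are the
#' curves compared with optomotor-neuron temporal-frequency tuning.
#'
#' @param params An [avdu_params()].
#' @param wavelengths Spatial wavelengths in degrees (default 11, 19, 38).
#' @param grid Temporal-frequency grid in Hz (default [tf_grid()]).
#' @param contrast Michelson contrast (default 1).
#' @param ... Passed to [measure_response()].
#' @return An `avdu_response_curve` data frame with columns `wavelength`,
#'   `tf`, `fast`, `slow`.
#' @export
sweep_tf_subunits <- function(params, wavelengths = c(11, 19, 38),
                              grid = tf_grid(), contrast = 1, ...) {
  system <- build_test_system(params)
  out <- do.call(rbind, lapply(wavelengths, function(wl) {
    rows <- vapply(grid, function(tf) {
      measure_response(system, grating("square", wl, tf * wl, contrast), ...)
    }, numeric(3))
    data.frame(wavelength = wl, tf = grid, fast = rows["fast", ],
               slow = rows["slow", ])
  }))
  new_response_curve(out, kind = "temporal_frequency",
                     stimulus = list(waveform = "square",
                                     wavelengths = wavelengths,
                                     contrast = contrast))
}

#' Temporal frequency of peak subunit response
#'
#' @param curve A [sweep_tf_subunits()] curve.
#' @param subunit `"fast"` or `"slow"`.
#' @return Named vector: per wavelength, the grid frequency (Hz) at which the
#'   subunit's mean response is maximal.
#' @export
peak_frequency <- function(curve, subunit = c("fast", "slow")) {
  subunit <- match.arg(subunit)
  vapply(split(curve, curve$wavelength), function(d) d$tf[which.max(d[[subunit]])],
         numeric(1))
}

#' @export
print.avdu_response_curve <- function(x, ...) {
  cat(sprintf("Detector response curve (%s), %d points\n", attr(x, "kind"),
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.avdu_response_curve <- function(x, ...) {
  if (attr(x, "kind") == "angular_velocity") {
    graphics::plot(x$av, x$response, log = "x", type = "b",
                   xlab = "angular velocity (deg/s)", ylab = "mean S", ...)
  } else {
    wls <- unique(x$wavelength)
    graphics::matplot(matrix(x$tf, ncol = length(wls)),
                      matrix(x$fast, ncol = length(wls)), log = "x",
                      type = "b", pch = 1, xlab = "temporal frequency (Hz)",
                      ylab = "mean fast subunit response", ...)
    graphics::legend("topleft", legend = paste(wls, "deg"), lty = seq_along(wls),
                     col = seq_along(wls), bty = "n")
  }
  invisible(x)
}

#' Fit linear, logarithmic and exponential forms to a response curve
#'
#' Ordinary least squares of `response` on the grid (linear), on `log(grid)`
#' (logarithmic), and of `log(response)` on the grid (exponential; positive
#' responses only). Model choice is by adjusted R-squared,
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`. The AV-tuned neurons this detector
#' models are best described as log-linear, so the logarithmic form winning
#' is the model-selection signature of a well-tuned detector.
#'
#' @param curve An `avdu_response_curve` from [sweep_av()], or a data frame
#'   with the independent variable in column 1 and the response in column 2.
#' @param nls_exp Also refine the exponential form by nonlinear least squares
#'   (`y = a * exp(b * x)`) started from the log-scale fit (default FALSE).
#' @return An object of class `avdu_fits`: the three `lm` fits, a summary
#'   table of adjusted R-squared values, and `best`, the winning form.
#' @export
fit_forms <- function(curve, nls_exp = FALSE) {
  x <- curve[[1]]
  y <- curve[[if ("response" %in% names(curve)) "response" else 2L]]
  if (length(x) < 4) stop("need at least 4 points to compare fits")
  d <- data.frame(x = x, y = y)
  fits <- list(linear = stats::lm(y ~ x, data = d),
               logarithmic = stats::lm(y ~ log(x), data = d))
  pos <- y > 0
  if (sum(pos) >= 4) {
    dpos <- data.frame(x = x[pos], ly = log(y[pos]))
    fits$exponential <- stats::lm(ly ~ x, data = dpos)
    if (nls_exp) {
      st <- stats::coef(fits$exponential)
      fits$exponential_nls <- stats::nls(
        y ~ a * exp(b * x), data = d[pos, , drop = FALSE],
        start = list(a = exp(st[1]), b = st[2]))
    }
  }
  adj <- vapply(fits, function(f) {
    if (inherits(f, "lm")) summary(f)$adj.r.squared else NA_real_
  }, numeric(1))
  forms <- c("linear", "logarithmic", "exponential")
  tab <- data.frame(form = forms,
                    adj_r_squared = adj[forms],
                    available = forms %in% names(fits), row.names = NULL)
  best <- tab$form[which.max(tab$adj_r_squared)]
  structure(list(fits = fits, table = tab, best = best, n = length(x)),
            class = "avdu_fits")
}

#' @export
print.avdu_fits <- function(x, ...) {
  cat("Response-form comparison (adjusted R-squared):\n")
  print(transform(x$table, adj_r_squared = round(adj_r_squared, 4)))
  cat("best form:", x$best, "\n")
  invisible(x)
}

#' @export
coef.avdu_fits <- function(object, form = object$best, ...) {
  stats::coef(object$fits[[form]])
}

#' Compare the four rectification modes
#'
#' Runs an AV sweep for each rectifier setting of the photoreceptor output
#' and fits the three response forms to each.
#'
#' @param params An [avdu_params()]; its `rect_mode` is overridden.
#' @param ... Passed to [sweep_av()].
#' @return A list of class `avdu_rectification_comparison` with one
#'   `$curves[[mode]]` and one `$fits[[mode]]` per mode.
#' @export
rectification_comparison <- function(params, ...) {
  modes <- c("none", "onset_only", "offset_only", "full")
  curves <- lapply(modes, function(m) {
    pm <- params; pm$rect_mode <- m
    sweep_av(pm, ...)
  })
  names(curves) <- modes
  structure(list(curves = curves, fits = lapply(curves, fit_forms)),
            class = "avdu_rectification_comparison")
}

#' @export
print.avdu_rectification_comparison <- function(x, ...) {
  for (m in names(x$fits)) {
    tab <- x$fits[[m]]$table
    cat(sprintf("%-12s best %-12s (adjR2 %.3f); S at top of sweep %.3f\n", m,
                x$fits[[m]]$best, max(tab$adj_r_squared, na.rm = TRUE),
                x$curves[[m]]$response[nrow(x$curves[[m]])]))
  }
  invisible(x)
}

#' Spatial-frequency and contrast invariance report
#'
#' Measures the mean detector response on a grid of angular velocities for a
#' contrast series (at a fixed 19-degree wavelength) and a wavelength series
#' (at fixed contrast 1), and reports the coefficient of variation of the
#' response across each series per angular velocity, plus the
#' reversed-direction response ratio at 100 deg/s.
#'
#' @param params An [avdu_params()].
#' @param avs Angular velocities in deg/s (default 50, 100, 200, 500).
#' @param contrasts Contrast series (default 0.25, 0.5, 1).
#' @param wavelengths Wavelength series in degrees (default 11, 19, 38).
#' @param ... Passed to [measure_response()].
#' @return A list of class `avdu_invariance_report` with data frames
#'   `contrast` and `wavelength` (columns `av`, `cov`) and the scalar
#'   `reversal_ratio`.
#' @export
invariance_report <- function(params, avs = c(50, 100, 200, 500),
                              contrasts = c(0.25, 0.5, 1),
                              wavelengths = c(11, 19, 38), ...) {
  system <- build_test_system(params)
  resp <- function(wl, av, ct)
    measure_response(system, grating("square", wl, av, ct), ...)[["S"]]
  cov_of <- function(v) stats::sd(v) / mean(v)
  ctab <- data.frame(av = avs, cov = vapply(avs, function(av)
    cov_of(vapply(contrasts, function(ct) resp(19, av, ct), 0)), 0))
  wtab <- data.frame(av = avs, cov = vapply(avs, function(av)
    cov_of(vapply(wavelengths, function(wl) resp(wl, av, 1), 0)), 0))
  rev_ratio <- resp(19, -100, 1) / resp(19, 100, 1)
  structure(list(contrast = ctab, wavelength = wtab,
                 reversal_ratio = rev_ratio,
                 grids = list(avs = avs, contrasts = contrasts,
                              wavelengths = wavelengths)),
            class = "avdu_invariance_report")
}

#' @export
print.avdu_invariance_report <- function(x, ...) {
  cat("Coefficient of variation of mean S across contrasts",
      sprintf("{%s}", paste(x$grids$contrasts, collapse = ", ")), "\n")
  print(transform(x$contrast, cov = signif(cov, 3)))
  cat("Across wavelengths", sprintf("{%s} deg",
                                    paste(x$grids$wavelengths, collapse = ", ")), "\n")
  print(transform(x$wavelength, cov = signif(cov, 3)))
  cat(sprintf("Reversed/preferred response at 100 deg/s: %.3f\n",
              x$reversal_ratio))
  invisible(x)
}
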