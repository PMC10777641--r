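# Input-output recruitment functions: spline interpolation, linear fit,
# threshold extrapolation, normalization, and the MT:ECAPT ratio.

#' Input-output curve
#'
#' Ordered (current, amplitude) pairs from the first offline-observable
#' ECAP up to the motor threshold, tagged with the stimulation parameters.
#'
#' @param current_ma Strictly increasing currents in mA, all <= `mt`.
#' @param amplitude_mv ECAP amplitudes in mV (N1-to-P2).
#' @param mt Motor threshold current in mA.
#' @param frequency_hz,pulse_width_us Stimulation parameter tags.
#' @return An object of class `io_curve`.
#' @export
io_curve <- function(current_ma, amplitude_mv, mt,
                     frequency_hz = 50, pulse_width_us = 200) {
  stopifnot(length(current_ma) == length(amplitude_mv))
  if (length(current_ma) < 3)
    stop("at least 3 points are required to fit an IO curve")
  if (any(diff(current_ma) <= 0))
    stop("currents must be strictly increasing")
  if (any(current_ma > mt + 1e-12))
    stop("all currents must be <= mt")
  structure(list(current_ma = as.numeric(current_ma),
                 amplitude_mv = as.numeric(amplitude_mv),
                 mt = mt, frequency_hz = frequency_hz,
                 pulse_width_us = pulse_width_us),
            class = "io_curve")
}

# Smoothing-spline interpolation stage. The smoothing parameter p follows
# the penalized least-squares convention p * RSS + (1 - p) * roughness:
# p = 1 interpolates, p -> 0 tends to the least-squares line. It is mapped
# onto stats::smooth.spline via lambda = (1 - p) / p. With fewer than four
# distinct currents a natural interpolating spline is used instead.
io_interpolate <- function(curve, smoothing = 0.95, n_interp = 200) {
  x <- curve$current_ma
  y <- curve$amplitude_mv
  xo <- seq(min(x), max(x), length.out = n_interp)
  if (length(unique(x)) >= 4 && smoothing < 1) {
    fit <- stats::smooth.spline(x, y, lambda = (1 - smoothing) / smoothing,
                                all.knots = TRUE)
    yo <- stats::predict(fit, xo)$y
  } else {
    yo <- stats::spline(x, y, xout = xo, method = "natural")$y
  }
  data.frame(current_ma = xo, amplitude_mv = yo)
}

#' Fit an input-output recruitment function
#'
#' Reproduces the offline IO analysis: raw (current, amplitude) points are
#' interpolated with a cubic smoothing spline (smoothing parameter 0.95 on
#' a 0-1 scale where 1 is pure interpolation), a dense grid of points is
#' sampled from the spline, and an ordinary least-squares line is fit to
#' the interpolated points. The line's slope is the recruitment slope
#' (mV/mA), its x-intercept is the extrapolated ECAP threshold (ECAPT),
#' and R-squared is taken from the linear stage. Currents are additionally
#' rescaled so that 0 corresponds to the extrapolated ECAPT and 1 to the
#' motor threshold.
#'
#' Note the regression is deliberately performed on the spline-interpolated
#' points, not the raw points, mirroring the original offline pipeline.
#'
#' @param curve An [io_curve()].
#' @param smoothing Spline smoothing parameter in (0, 1]; default 0.95.
#' @param n_interp Number of interpolated points (default 200).
#' @return An object of class `io_fit`: list with `slope` (mV/mA),
#'   `ecapt_extrapolated` (mA), `r_squared`, `normalized_points`
#'   (data.frame `scaled_current`, `amplitude_mv`), `interp`
#'   (the interpolated grid), `smoothing`, `mt`, and the input `curve`.
#' @export
fit_io <- function(curve, smoothing = 0.95, n_interp = 200) {
  stopifnot(inherits(curve, "io_curve"))
  stopifnot(smoothing > 0, smoothing <= 1)
  interp <- io_interpolate(curve, smoothing, n_interp)
  lm_fit <- stats::lm(amplitude_mv ~ current_ma, data = interp)
  slope <- unname(stats::coef(lm_fit)[2])
  intercept <- unname(stats::coef(lm_fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate recruitment: non-positive IO slope")
  ecapt <- -intercept / slope
  if (ecapt >= curve$mt)
    warning("inconsistent thresholds: extrapolated ECAPT >= MT")
  r2 <- 1 - sum(stats::residuals(lm_fit)^2) /
    sum((interp$amplitude_mv - mean(interp$amplitude_mv))^2)
  scaled <- (interp$current_ma - ecapt) / (curve$mt - ecapt)
  structure(list(slope = slope,
                 ecapt_extrapolated = ecapt,
                 r_squared = r2,
                 normalized_points = data.frame(
                   scaled_current = scaled,
                   amplitude_mv = interp$amplitude_mv),
                 interp = interp,
                 smoothing = smoothing,
                 mt = curve$mt,
                 curve = curve),
            class = "io_fit")
}

#' @export
print.io_fit <- function(x, ...) {
  cat(sprintf(paste0("<io_fit> slope %.2f mV/mA, extrapolated ECAPT %.4f mA,",
                     " MT %.4f mA, R^2 %.3f\n"),
              x$slope, x$ecapt_extrapolated, x$mt, x$r_squared))
  invisible(x)
}

#' Rescale a current onto the ECAPT-to-MT axis
#'
#' @param current_ma Current(s) in mA.
#' @param fit An [fit_io()] result (or any list with `ecapt_extrapolated`
#'   and `mt`).
#' @return Scaled current: 0 at the extrapolated ECAPT, 1 at MT.
#' @export
normalize_current <- function(current_ma, fit) {
  (current_ma - fit$ecapt_extrapolated) / (fit$mt - fit$ecapt_extrapolated)
}

#' Visually-observed ECAP threshold surrogate
#'
#' The smallest current in an ascending staircase whose extracted features
#' pass [is_detectable()]. This mirrors the threshold read off the
#' recording screen during IO collection, which is used to set the
#' closed-loop stimulation intensity. By default the detection must be
#' *sustained*: the threshold is the first current from which every higher
#' current in the staircase is also detectable, which is what an observer
#' confirms on screen and which discards isolated noise flickers below the
#' true threshold (above threshold recruitment is monotone, so a genuine
#' ECAP never disappears again). With `sustained = FALSE` the first
#' detectable current is returned regardless of what follows.
#'
#' @param currents_ma Ascending currents, mA.
#' @param features A data.frame with one row per current (in the same
#'   order) carrying `amplitude`, `noise_sd`, `n_averaged` and the three
#'   latency columns from [extract_features()].
#' @param k Detectability multiplier (default 3).
#' @param sustained Require detectability to persist to the top of the
#'   staircase (default TRUE).
#' @return The threshold current in mA, or `NA_real_` (with a warning) if
#'   no current produced a detectable ECAP.
#' @export
observed_ecapt <- function(currents_ma, features, k = 3,
                           sustained = TRUE) {
  stopifnot(nrow(features) == length(currents_ma))
  if (is.unsorted(currents_ma))
    stop("currents must be ascending")
  det <- vapply(seq_len(nrow(features)), function(i)
    is_detectable(features[i, ], k = k), logical(1))
  if (!any(det)) {
    warning("no detectable ECAP in the current staircase")
    return(NA_real_)
  }
  if (sustained) {
    run_ok <- rev(cumprod(rev(det))) == 1   # TRUE through the top
    if (!any(run_ok)) {
      warning("no sustained detectable ECAP in the current staircase")
      return(NA_real_)
    }
    return(currents_ma[which(run_ok)[1]])
  }
  currents_ma[which(det)[1]]
}

#' MT:ECAPT ratio
#'
#' Relative current required to produce a motor response compared to the
#' current at which an ECAP first appears; > 1 whenever a usable window
#' between the two thresholds exists.
#'
#' @param mt Motor threshold, mA.
#' @param ecapt ECAP threshold, mA (> 0).
#' @return `mt / ecapt`.
#' @export
mt_ecapt_ratio <- function(mt, ecapt) {
  if (any(ecapt <= 0)) stop("undefined ratio: ecapt must be > 0")
  mt / ecapt
}

#' Express a stimulation current relative to the thresholds
#'
#' Utility reporting a stimulus intensity both as a percentage of the
#' motor threshold and as a multiple of the ECAP threshold (the two
#' conventions used to describe preclinical stimulation doses).
#'
#' @param current_ma Stimulation current, mA.
#' @param ecapt ECAP threshold, mA (> 0).
#' @param mt Motor threshold, mA (> 0).
#' @return List with `percent_of_mt` and `times_ecapt`.
#' @examples
#' stimulus_intensity(0.034, ecapt = 0.024, mt = 0.049)
#' @export
stimulus_intensity <- function(current_ma, ecapt, mt) {
  stopifnot(mt > 0, ecapt > 0)
  list(percent_of_mt = 100 * current_ma / mt,
       times_ecapt = current_ma / ecapt)
}
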