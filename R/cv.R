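# Conduction velocity from N1 latency differences across contacts.

#' Estimate conduction velocity from multi-contact N1 latencies
#'
#' Fits an ordinary least-squares line of N1 latency (ms) against contact
#' distance (mm) and reports the conduction velocity as the reciprocal
#' slope; mm/ms is numerically equal to m/s. Because only latency
#' *differences* across contacts enter the slope, any fixed utilisation
#' (onset) delay common to all contacts cancels — a single-channel latency
#' alone would overestimate the travel time.
#'
#' The N1 peak is used as the timing landmark, and per-pulse latencies are
#' expected to have been averaged per channel (as [feature_table()] does).
#' By convention the estimate uses the recording contacts closest to the
#' stimulation contact on the antidromic side (three by default).
#'
#' @param features A data.frame with columns `distance_mm`,
#'   `n1_latency_ms` and optionally `detectable` (rows with
#'   `detectable == FALSE` are dropped), e.g. from [feature_table()];
#'   alternatively supply `latency_ms` and `distance_mm` directly.
#' @param geometry Optional [lead_geometry()]; when given together with a
#'   `channel` column, rows are restricted to the `n_channels` antidromic
#'   contacts closest to the stimulation contact.
#' @param n_channels Number of closest antidromic contacts used
#'   (default 3).
#' @return An object of class `cv_estimate`: list with `velocity_m_s`,
#'   `latency_points` (data.frame distance/latency), and `residual_rms_ms`.
#' @examples
#' f <- data.frame(distance_mm = c(4, 8, 12),
#'                 n1_latency_ms = c(1.40, 1.60, 1.80))
#' estimate_cv(f)$velocity_m_s  # 20 m/s
#' @export
estimate_cv <- function(features, geometry = NULL, n_channels = 3) {
  f <- as.data.frame(features)
  if (!"n1_latency_ms" %in% names(f) && "latency_ms" %in% names(f))
    f$n1_latency_ms <- f$latency_ms
  stopifnot(all(c("distance_mm", "n1_latency_ms") %in% names(f)))
  if ("detectable" %in% names(f)) f <- f[isTRUE_vec(f$detectable), ]
  if (!is.null(geometry) && "channel" %in% names(f)) {
    keep <- antidromic_channels(geometry, n_channels)
    f <- f[f$channel %in% keep, ]
  } else if (nrow(f) > n_channels) {
    f <- f[order(f$distance_mm), ][seq_len(n_channels), ]
  }
  f <- f[stats::complete.cases(f[, c("distance_mm", "n1_latency_ms")]), ]
  if (nrow(f) < 2)
    stop("insufficient data: need >= 2 contacts with detected ECAPs")
  fit <- stats::lm(n1_latency_ms ~ distance_mm, data = f)
  slope <- unname(stats::coef(fit)[2])   # ms per mm
  if (!is.finite(slope) || slope <= 0)
    stop("propagation-direction error: latency does not increase with distance")
  res <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(velocity_m_s = 1 / slope,
                 latency_points = f[, c("distance_mm", "n1_latency_ms")],
                 residual_rms_ms = res),
            class = "cv_estimate")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("<cv_estimate> %.2f m/s from %d contacts (RMS %.4f ms)\n",
              x$velocity_m_s, nrow(x$latency_points), x$residual_rms_ms))
  invisible(x)
}

#' Conduction velocity straight from a recording
#'
#' Convenience wrapper: extracts pulse-averaged features on the antidromic
#' contacts of a recording and estimates the conduction velocity.
#'
#' @param recording A `multichannel_recording`.
#' @param n_channels Number of closest antidromic contacts (default 3).
#' @param ... Passed to [feature_table()].
#' @return A `cv_estimate`.
#' @export
cv_from_recording <- function(recording, n_channels = 3, ...) {
  ft <- feature_table(recording, ...)
  estimate_cv(ft, geometry = recording$geometry, n_channels = n_channels)
}
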