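# Synthetic plant: linear recruitment, distance attenuation, posture gain,
# and triphasic sweep synthesis.

#' Linear recruitment of the ECAP amplitude above threshold
#'
#' The ECAP amplitude at the reference recording contact grows linearly
#' with stimulation current once the ECAP threshold is exceeded and is zero
#' below it:
#' \deqn{A(I) = g \cdot s \cdot \max(I - I_{ECAPT}, 0)}
#' where `s` is the recruitment slope (mV/mA) and `g` a multiplicative
#' posture gain.
#'
#' @param current_ma Stimulation current in mA (scalar or vector, >= 0).
#' @param gt An [ground_truth()] object.
#' @param gain Multiplicative gain, > 0 (scalar or vector recycled against
#'   `current_ma`).
#' @return ECAP amplitude(s) in mV at the reference (closest) contact.
#' @export
recruitment_amplitude <- function(current_ma, gt, gain = 1) {
  stopifnot(inherits(gt, "ecap_ground_truth"))
  if (any(current_ma < 0)) stop("current_ma must be non-negative")
  if (any(gain <= 0)) stop("gain must be positive")
  gain * gt$slope * pmax(current_ma - gt$ecapt_true, 0)
}

#' Calibrate the exponential distance-decay length
#'
#' Fits the single-exponential attenuation model
#' \eqn{A(d) = A_{ref} e^{-(d - d_{ref})/\lambda}} by least squares to a
#' reference attenuation profile. The default profile is the example
#' propagation measurement (0.63, 0.20, 0.09, 0.08) mV at (4, 8, 12, 16) mm
#' from the stimulation contact, giving a decay length of about 3.9 mm.
#'
#' @param distances_mm Distances of the reference measurements in mm.
#' @param amplitudes_mv Amplitudes at those distances in mV.
#' @param ref_distance_mm Reference distance (amplitude is anchored there).
#' @return Decay length lambda in mm.
#' @export
calibrate_decay_length <- function(distances_mm = c(4, 8, 12, 16),
                                   amplitudes_mv = c(0.63, 0.20, 0.09, 0.08),
                                   ref_distance_mm = 4) {
  stopifnot(length(distances_mm) == length(amplitudes_mv),
            length(distances_mm) >= 2)
  a_ref <- amplitudes_mv[which(distances_mm == ref_distance_mm)[1]]
  sse <- function(lam)
    sum((a_ref * exp(-(distances_mm - ref_distance_mm) / lam) -
           amplitudes_mv)^2)
  stats::optimize(sse, interval = c(0.1, 100))$minimum
}

#' Attenuation of the ECAP amplitude with distance
#'
#' Single-exponential fall-off anchored at the reference distance (the
#' closest recording contact, 4 mm by default):
#' \eqn{A(d) = A_{ref} e^{-(d - d_{ref})/\lambda}}.
#'
#' @param amplitude_at_ref Amplitude at the reference distance, mV.
#' @param distance_mm Distance from the stimulation contact, mm
#'   (>= `ref_distance_mm`).
#' @param gt A [ground_truth()] providing `decay_length_mm`.
#' @param ref_distance_mm Reference distance, mm.
#' @return Attenuated amplitude(s) in mV, non-increasing in distance.
#' @export
distance_attenuation <- function(amplitude_at_ref, distance_mm, gt,
                                 ref_distance_mm = 4) {
  stopifnot(inherits(gt, "ecap_ground_truth"))
  if (gt$decay_length_mm <= 0) stop("decay_length_mm must be positive")
  if (any(distance_mm < ref_distance_mm))
    stop("distance_mm must be >= ref_distance_mm")
  amplitude_at_ref * exp(-(distance_mm - ref_distance_mm) / gt$decay_length_mm)
}

#' Posture-gain disturbance trace
#'
#' Generates one multiplicative gain value per pulse, emulating the slow
#' change in electrode-to-fibre coupling as a freely behaving animal alters
#' posture. The log gain follows a discretised mean-reverting
#' (Ornstein-Uhlenbeck) process with stationary SD `volatility` and
#' correlation time `tau_s`; the gain is its exponential with a
#' \eqn{-\sigma^2/2} correction so the stationary mean is exactly 1.
#' The trace is strictly positive and, at `volatility = 0`, identically 1.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param frequency_hz Pulse rate in Hz (> 0).
#' @param volatility Stationary SD of the log gain (>= 0).
#' @param tau_s Correlation time in seconds (> 0).
#' @param seed Optional integer seed.
#' @param init Optional initial log-gain deviation (defaults to a draw from
#'   the stationary distribution).
#' @return Numeric vector of length `round(duration_s * frequency_hz)`.
#' @export
gain_trace <- function(duration_s, frequency_hz, volatility = 0.2,
                       tau_s = 5, seed = NULL, init = NULL) {
  stopifnot(duration_s > 0, frequency_hz > 0, volatility >= 0, tau_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * frequency_hz))
  if (volatility == 0) return(rep(1, n))
  dt <- 1 / frequency_hz
  phi <- exp(-dt / tau_s)
  innov_sd <- volatility * sqrt(1 - phi^2)
  x0 <- if (is.null(init)) stats::rnorm(1, 0, volatility) else init
  e <- stats::rnorm(n, 0, innov_sd)
  x <- as.numeric(stats::filter(e, phi, method = "recursive",
                                init = x0))
  exp(x - volatility^2 / 2)
}

# Triphasic template of unit N1-to-P2 amplitude.
#
# Three Gaussian lobes (positive P1, negative N1, positive P2). Returned as
# a closure w(t_ms) with its minimum (the N1 lobe) at exactly t = 0 and
# peak-to-peak N1->P2 amplitude exactly 1. Latencies of the flanking maxima
# are carried as attributes (ms relative to N1).
ecap_template <- function(sigma_ms = 0.12, lobe_sep_ms = 0.35,
                          p1_frac = 0.35, p2_frac = 0.55) {
  raw <- function(t)
    p1_frac * exp(-(t + lobe_sep_ms)^2 / (2 * sigma_ms^2)) -
      exp(-t^2 / (2 * sigma_ms^2)) +
      p2_frac * exp(-(t - lobe_sep_ms)^2 / (2 * sigma_ms^2))
  # centre the N1 minimum at zero (lobe overlap shifts it slightly)
  tmin <- stats::optimize(raw, c(-lobe_sep_ms, lobe_sep_ms))$minimum
  span <- lobe_sep_ms + 5 * sigma_ms
  p1_t <- stats::optimize(function(t) -raw(t + tmin),
                          c(-span, -sigma_ms / 2))$minimum
  p2_t <- stats::optimize(function(t) -raw(t + tmin),
                          c(sigma_ms / 2, span))$minimum
  n1_v <- raw(tmin)
  p2_v <- raw(p2_t + tmin)
  scale <- 1 / (p2_v - n1_v)
  f <- function(t_ms) scale * raw(t_ms + tmin)
  attr(f, "support_ms") <- span
  attr(f, "p1_offset_ms") <- p1_t
  attr(f, "p2_offset_ms") <- p2_t
  attr(f, "n1_value") <- n1_v * scale
  attr(f, "p2_value") <- p2_v * scale
  f
}

# Stimulation artifact: sharp decaying transient at t >= 0, essentially
# extinguished by 0.5 ms. Largest on the stimulation channel.
stim_artifact <- function(t_ms, current_ma, on_stim_channel, distance_mm) {
  amp <- if (on_stim_channel) 400 * current_ma else
    40 * current_ma * exp(-distance_mm / 8)
  ifelse(t_ms >= 0, amp * exp(-t_ms / 0.06), 0)
}

#' Synthesize a stimulus-aligned multi-channel recording
#'
#' Produces per-pulse, per-channel voltage sweeps aligned to stimulus onset
#' at time 0, sampled at 30 kHz by default. Each non-stimulation channel
#' contains a triphasic ECAP (positive P1, negative N1, positive P2) whose
#' N1-to-P2 amplitude is `recruitment_amplitude()` at the pulse current and
#' posture gain, attenuated with distance by `distance_attenuation()`, and
#' whose N1 latency is `onset_delay_ms + distance / cv_true`; white noise
#' of SD `noise_sd` is added. The stimulation channel carries a large
#' artifact transient, and a small artifact residue is present on recording
#' channels inside the first ~0.5 ms. All randomness is fixed by `seed`.
#'
#' The returned object carries a `truth` attribute with the per-pulse gains
#' and the per-channel true N1 latencies and per-pulse true amplitudes, for
#' use as an oracle in tests.
#'
#' @param gt A [ground_truth()].
#' @param geometry A [lead_geometry()].
#' @param program A [stimulus_program()].
#' @param seed Integer seed fixing noise and the gain trace.
#' @param sample_rate Samples per second (default 30000).
#' @param window_ms Sweep length in ms after stimulus onset (default 8, or
#'   the inter-pulse interval if shorter).
#' @param gain Optional per-pulse gain vector; by default drawn by
#'   [gain_trace()] from the `gt` gain process.
#' @param artifact Include the stimulation artifact (default TRUE).
#' @return An object of class `multichannel_recording`: a list with
#'   `sweeps` (array `[n_pulses, n_channels, n_samples]`, mV), `time_ms`,
#'   `sample_rate`, `geometry`, `program`.
#' @export
synth_sweep <- function(gt, geometry = lead_geometry(),
                        program = stimulus_program(),
                        seed = NULL, sample_rate = 30000,
                        window_ms = 8, gain = NULL, artifact = TRUE) {
  stopifnot(inherits(gt, "ecap_ground_truth"),
            inherits(geometry, "lead_geometry"),
            inherits(program, "stimulus_program"))
  if (!is.null(seed)) set.seed(seed)
  window_ms <- min(window_ms, 1000 / program$frequency_hz)
  n_samp <- as.integer(floor(window_ms * sample_rate / 1000))
  t_ms <- (seq_len(n_samp) - 1) / sample_rate * 1000
  tmpl <- ecap_template()
  dists <- contact_distances(geometry)
  max_lat <- gt$onset_delay_ms + max(dists) / gt$cv_true
  if (max_lat + attr(tmpl, "support_ms") > window_ms)
    stop("sweep window too short for the N1 latency implied by cv_true")
  if (is.null(gain))
    gain <- gain_trace(program$duration_s, program$frequency_hz,
                       gt$gain_volatility, gt$gain_tau_s)
  stopifnot(length(gain) == program$n_pulses)

  n_p <- program$n_pulses
  n_ch <- geometry$n_contacts
  sweeps <- array(0, dim = c(n_p, n_ch, n_samp))
  amp_ref <- recruitment_amplitude(program$current_ma, gt, gain)
  n1_lat <- gt$onset_delay_ms + dists / gt$cv_true
  true_amp <- matrix(0, n_p, n_ch)
  for (ch in seq_len(n_ch)) {
    is_stim <- ch == geometry$stim_index
    base <- numeric(n_samp)
    if (!is_stim) {
      shape <- tmpl(t_ms - n1_lat[ch])
      att <- distance_attenuation(1, max(dists[ch], 4), gt)
      amps <- amp_ref * att
      true_amp[, ch] <- amps
      sweeps[, ch, ] <- outer(amps, shape)
    }
    if (artifact) {
      for (p in seq_len(n_p)) {
        sweeps[p, ch, ] <- sweeps[p, ch, ] +
          stim_artifact(t_ms, program$current_ma[p], is_stim, dists[ch])
      }
    }
    if (gt$noise_sd > 0)
      sweeps[, ch, ] <- sweeps[, ch, ] +
        matrix(stats::rnorm(n_p * n_samp, 0, gt$noise_sd), n_p, n_samp)
  }
  structure(list(sweeps = sweeps, time_ms = t_ms,
                 sample_rate = sample_rate,
                 geometry = geometry, program = program),
            class = "multichannel_recording",
            truth = list(gain = gain, n1_latency_ms = n1_lat,
                         amplitude_mv = true_amp, gt = gt))
}

#' @export
print.multichannel_recording <- function(x, ...) {
  d <- dim(x$sweeps)
  cat(sprintf("<multichannel_recording> %d pulses x %d channels x %d samples @ %g kHz\n",
              d[1], d[2], d[3], x$sample_rate / 1000))
  invisible(x)
}

#' Synthesize an input-output current sweep and extract its IO curve
#'
#' Runs the full generative + analysis path for one animal: for each
#' current in an ascending staircase from 0 to the motor threshold, a short
#' pulse train is synthesized with [synth_sweep()], features are extracted
#' on the contact closest to the stimulation contact (antidromic side) with
#' [extract_features()] averaging across pulses, and the points from the
#' sustained observed threshold (see [observed_ecapt()]) up to MT are
#' assembled into an [io_curve()].
#'
#' A full staircase takes on the order of seconds, far less than the
#' posture-gain correlation time, and the animal is habituated and still
#' during IO collection; the posture gain is therefore held frozen at its
#' calibration reference (1) by default, so IO fixtures carry additive
#' recording noise only. Set `gain_process = TRUE` to let the gain drift
#' across the staircase instead.
#'
#' @param gt A [ground_truth()].
#' @param currents_ma Ascending currents in mA; default a 21-step staircase
#'   from 0 to `mt_true`.
#' @param n_pulses Pulses averaged per current step (default 5).
#' @param geometry,frequency_hz,pulse_width_us Recording setup.
#' @param seed Integer seed.
#' @param k Detectability multiplier passed to [is_detectable()].
#' @param gain_process Simulate posture-gain drift over the staircase
#'   (default FALSE: gain frozen at 1).
#' @return A list with `curve` (an `io_curve` or NULL if nothing was
#'   detectable), `features` (per-current feature table), and
#'   `observed_ecapt` (mA, NA if none detectable).
#' @export
synth_io_curve <- function(gt, currents_ma = NULL, n_pulses = 5,
                           geometry = lead_geometry(),
                           frequency_hz = 50, pulse_width_us = 200,
                           seed = NULL, k = 3, gain_process = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(currents_ma))
    currents_ma <- seq(0, gt$mt_true, length.out = 21)
  stopifnot(!is.unsorted(currents_ma))
  ch <- antidromic_channels(geometry, 1)
  n_steps <- length(currents_ma)
  gains <- if (gain_process)
    gain_trace(n_steps * n_pulses / frequency_hz, frequency_hz,
               gt$gain_volatility, gt$gain_tau_s) else
    rep(1, n_steps * n_pulses)
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    prog <- stimulus_program(frequency_hz, pulse_width_us,
                             duration_s = n_pulses / frequency_hz,
                             current_ma = currents_ma[i])
    rec <- synth_sweep(gt, geometry, prog,
                       gain = gains[(i - 1) * n_pulses + seq_len(n_pulses)])
    f <- extract_features(rec, channel = ch, average = TRUE)
    f$current_ma <- currents_ma[i]
    rows[[i]] <- f
  }
  feats <- do.call(rbind, rows)
  feats$detectable <- vapply(seq_len(nrow(feats)), function(i)
    is_detectable(feats[i, ], k = k), logical(1))
  obs <- observed_ecapt(feats$current_ma, feats, k = k)
  curve <- NULL
  if (!is.na(obs)) {
    keep <- feats$current_ma >= obs & feats$current_ma <= gt$mt_true
    if (sum(keep) >= 3)
      curve <- io_curve(feats$current_ma[keep], feats$amplitude[keep],
                        mt = gt$mt_true, frequency_hz = frequency_hz,
                        pulse_width_us = pulse_width_us)
  }
  list(curve = curve, features = feats, observed_ecapt = obs)
}
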