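#' Epidural lead geometry
#'
#' Describes a multi-contact epidural lead: number of contacts, the
#' centre-to-centre spacing between adjacent contacts, and which contact is
#' used for stimulation. The default is the six-contact lead spaced 4 mm
#' apart spanning vertebral levels T11-L3, with stimulation delivered from
#' the contact over T13 and recording from the remaining contacts in the
#' antidromic (caudal) direction.
#'
#' @param n_contacts Integer number of contacts (>= 2).
#' @param spacing_mm Distance in mm between adjacent contacts (> 0).
#' @param stim_index 1-based index of the stimulation contact.
#' @param contact_labels Optional character vector of vertebral-level labels,
#'   one per contact (ordered rostral to caudal).
#' @return An object of class `lead_geometry`.
#' @examples
#' geom <- lead_geometry()
#' contact_distances(geom)
#' @export
lead_geometry <- function(n_contacts = 6L, spacing_mm = 4,
                          stim_index = 5L,
                          contact_labels = NULL) {
  n_contacts <- as.integer(n_contacts)
  stim_index <- as.integer(stim_index)
  stopifnot(n_contacts >= 2L, spacing_mm > 0,
            stim_index >= 1L, stim_index <= n_contacts)
  if (is.null(contact_labels)) {
    labs <- c("T11", "T12", "T13", "L1", "L2", "L3")
    contact_labels <- if (n_contacts == 6L) rev(labs) else
      paste0("ch", seq_len(n_contacts))
  }
  stopifnot(length(contact_labels) == n_contacts)
  structure(list(n_contacts = n_contacts,
                 spacing_mm = spacing_mm,
                 stim_index = stim_index,
                 contact_labels = contact_labels),
            class = "lead_geometry")
}

#' Distance of every contact from the stimulation contact
#'
#' @param geometry A [lead_geometry()].
#' @return Numeric vector of distances in mm (0 for the stimulation contact).
#' @export
contact_distances <- function(geometry) {
  stopifnot(inherits(geometry, "lead_geometry"))
  abs(seq_len(geometry$n_contacts) - geometry$stim_index) * geometry$spacing_mm
}

#' Antidromic recording contacts
#'
#' Contacts caudal to the stimulation contact, ordered by increasing
#' distance. With the default lead (stimulation at T13, index 5, labels
#' running caudal to rostral) these are the contacts on which propagating
#' ECAPs are measured.
#'
#' @param geometry A [lead_geometry()].
#' @param n Maximum number of contacts to return (default all).
#' @return Integer vector of 1-based channel indices.
#' @export
antidromic_channels <- function(geometry, n = Inf) {
  stopifnot(inherits(geometry, "lead_geometry"))
  idx <- seq_len(geometry$n_contacts)
  caudal <- idx[idx < geometry$stim_index]
  caudal <- caudal[order(geometry$stim_index - caudal)]
  if (length(caudal) == 0L) caudal <- idx[idx > geometry$stim_index]
  utils::head(caudal, n)
}

#' Stimulation program
#'
#' A constant-parameter pulse train: frequency in Hz, pulse width in
#' microseconds, duration in seconds and per-pulse current in mA (scalar,
#' recycled, or one value per pulse). The two presets used for input-output
#' collection are 2 Hz / 200 us and 50 Hz / 200 us.
#'
#' @param frequency_hz Pulses per second (> 0).
#' @param pulse_width_us Pulse width in microseconds (> 0).
#' @param duration_s Train duration in seconds (> 0).
#' @param current_ma Current in mA, scalar or vector of length
#'   `frequency_hz * duration_s`; all values must be >= 0.
#' @return An object of class `stimulus_program` with an `n_pulses` field.
#' @examples
#' stimulus_program(50, 200, duration_s = 60, current_ma = 0.03)
#' @export
stimulus_program <- function(frequency_hz = 50, pulse_width_us = 200,
                             duration_s = 1, current_ma = 0) {
  stopifnot(frequency_hz > 0, pulse_width_us > 0, duration_s > 0)
  n_pulses <- as.integer(round(frequency_hz * duration_s))
  stopifnot(n_pulses >= 1L)
  if (any(current_ma < 0)) stop("current_ma must be non-negative")
  if (!length(current_ma) %in% c(1L, n_pulses))
    stop("current_ma must be scalar or one value per pulse")
  structure(list(frequency_hz = frequency_hz,
                 pulse_width_us = pulse_width_us,
                 duration_s = duration_s,
                 current_ma = rep_len(current_ma, n_pulses),
                 n_pulses = n_pulses),
            class = "stimulus_program")
}

#' Generative ground truth for a synthetic animal
#'
#' Parameters of the synthetic plant: linear recruitment slope above the
#' ECAP threshold, true ECAP threshold (ECAPT) and motor threshold (MT)
#' currents, conduction velocity, exponential distance-decay length,
#' additive recording noise, a fixed utilisation (onset) delay between the
#' stimulus and the start of conduction, and the posture-gain process
#' parameters.
#'
#' Defaults correspond to a sham (uninjured) animal: slope 20.53 mV/mA,
#' ECAPT 0.038 mA, MT 0.082 mA, conduction velocity 20 m/s. The decay
#' length defaults to the least-squares calibration of a single exponential
#' to the reference attenuation profile (0.63, 0.20, 0.09, 0.08) mV at
#' (4, 8, 12, 16) mm; see [calibrate_decay_length()].
#'
#' @param slope Recruitment slope in mV/mA (> 0).
#' @param ecapt_true ECAP threshold current in mA (0 < ecapt_true < mt_true).
#' @param mt_true Motor threshold current in mA.
#' @param cv_true Conduction velocity in m/s (> 0).
#' @param decay_length_mm Distance constant in mm of the exponential
#'   amplitude fall-off with distance from the stimulation contact.
#' @param noise_sd Additive white recording noise SD in mV (>= 0).
#' @param onset_delay_ms Fixed delay in ms between stimulus onset and the
#'   start of conduction (so single-channel latency alone does not give the
#'   conduction velocity).
#' @param gain_volatility Stationary SD of the log posture gain (>= 0).
#' @param gain_tau_s Correlation time in seconds of the posture-gain
#'   process (> 0).
#' @return An object of class `ecap_ground_truth`.
#' @seealso [gt_sham()], [gt_sni()] for presets.
#' @export
ground_truth <- function(slope = 20.53,
                         ecapt_true = 0.038,
                         mt_true = 0.082,
                         cv_true = 20,
                         decay_length_mm = calibrate_decay_length(),
                         noise_sd = 0.01,
                         onset_delay_ms = 1.2,
                         gain_volatility = 0.2,
                         gain_tau_s = 5) {
  stopifnot(slope > 0, ecapt_true > 0, mt_true > ecapt_true,
            cv_true > 0, noise_sd >= 0, onset_delay_ms >= 0,
            gain_volatility >= 0, gain_tau_s > 0)
  if (decay_length_mm <= 0) stop("decay_length_mm must be positive")
  structure(list(slope = slope, ecapt_true = ecapt_true, mt_true = mt_true,
                 cv_true = cv_true, decay_length_mm = decay_length_mm,
                 noise_sd = noise_sd, onset_delay_ms = onset_delay_ms,
                 gain_volatility = gain_volatility, gain_tau_s = gain_tau_s),
            class = "ecap_ground_truth")
}

#' Ground-truth presets
#'
#' `gt_sham()` parameterises an uninjured control at the cohort means
#' reported for sham animals (slope 20.53 mV/mA, ECAPT 0.038 mA, MT
#' 0.082 mA, CV 20 m/s). `gt_sni()` parameterises a nerve-injured animal:
#' lower thresholds (ECAPT 0.026 mA, MT 0.065 mA), steeper slope
#' (23.56 mV/mA) and slower conduction (15 m/s).
#'
#' @param ... Overrides passed on to [ground_truth()].
#' @return An `ecap_ground_truth`.
#' @export
gt_sham <- function(...) {
  args <- utils::modifyList(list(slope = 20.53, ecapt_true = 0.038,
                                 mt_true = 0.082, cv_true = 20), list(...))
  do.call(ground_truth, args)
}

#' @rdname gt_sham
#' @export
gt_sni <- function(...) {
  args <- utils::modifyList(list(slope = 23.56, ecapt_true = 0.026,
                                 mt_true = 0.065, cv_true = 15), list(...))
  do.call(ground_truth, args)
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat(sprintf("<lead_geometry> %d contacts, %.1f mm spacing, stim at #%d (%s)\n",
              x$n_contacts, x$spacing_mm, x$stim_index,
              x$contact_labels[x$stim_index]))
  invisible(x)
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat(sprintf("<stimulus_program> %g Hz / %g us, %g s (%d pulses), current %s mA\n",
              x$frequency_hz, x$pulse_width_us, x$duration_s, x$n_pulses,
              if (length(unique(x$current_ma)) == 1L)
                format(x$current_ma[1]) else "per-pulse"))
  invisible(x)
}

#' @export
print.ecap_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ecap_ground_truth> slope %.2f mV/mA, ECAPT %.3f mA, ",
                     "MT %.3f mA, CV %.1f m/s\n"),
              x$slope, x$ecapt_true, x$mt_true, x$cv_true))
  invisible(x)
}
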