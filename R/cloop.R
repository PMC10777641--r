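# Closed-loop (ECAP-controlled) and open-loop stimulation sessions against
# the synthetic plant, and session summaries with 3-SD outlier exclusion.

#' Integral controller update
#'
#' One pulse-on-pulse adjustment of the stimulation current from the
#' amplitude error (target minus measured, mV). The update is an
#' integral-style step `current + gain_i * error`, magnitude-limited to
#' `step_cap` mA per pulse and clamped into `[0, cap]`. With a constant
#' plant of recruitment slope `s`, the loop converges geometrically to the
#' fixed point whenever `0 < gain_i * s < 2`. The commercial controller's
#' law is unpublished; this minimal law reproduces its documented
#' behaviour (one adjustment per pulse, constant activation) and can be
#' swapped via the `controller` argument of [run_session()].
#'
#' @param error Amplitude error in mV (target - measured); must be finite.
#' @param current_ma Present current in mA.
#' @param params List with `gain_i` (mA per mV), `step_cap` (mA, > 0) and
#'   `cap` (mA, upper clamp).
#' @return Next current in mA.
#' @export
controller_update <- function(error, current_ma, params) {
  if (!is.finite(error)) stop("error must be finite")
  step <- params$gain_i * error
  step <- max(min(step, params$step_cap), -params$step_cap)
  min(max(current_ma + step, 0), params$cap)
}

#' Simulate an open- or closed-loop stimulation session
#'
#' Runs a session against the synthetic plant. At every pulse the plant
#' produces a measured ECAP amplitude from the delivered current, the
#' posture-gain trace and additive measurement noise:
#' `a = gain * slope * max(I - ecapt, 0) + noise`. In closed-loop (CL)
#' mode the controller performs exactly one current update per pulse from
#' the amplitude error before the next pulse (50 adjustments per second at
#' 50 Hz); in open-loop (OL) mode the current is held fixed. All
#' randomness (gain trace and measurement noise) is fixed by `seed`, and
#' two sessions run with the same seed share identical disturbance and
#' noise realisations — the basis for paired OL/CL comparisons.
#'
#' @param mode "CL" or "OL".
#' @param gt A [ground_truth()] describing the plant.
#' @param program A [stimulus_program()]; the default is the therapy
#'   program, 30 min at 50 Hz / 200 us.
#' @param target_mv Target ECAP amplitude in mV; must lie strictly between
#'   0 and the plant amplitude at the motor threshold.
#' @param controller List of controller parameters (`gain_i`, `step_cap`,
#'   `cap`); defaults: `gain_i = 0.4 / gt$slope` (loop gain 0.4),
#'   `step_cap = 0.005` mA, `cap = gt$mt_true` (currents never exceed the
#'   motor threshold).
#' @param amp_noise_sd Measurement noise SD on the amplitude, mV
#'   (default 0.01).
#' @param seed Integer seed.
#' @param start_current_ma Initial current; defaults to the ECAP threshold
#'   in CL mode. In OL mode the current is `ol_current_ma` throughout.
#' @param ol_current_ma Open-loop current; defaults to the current whose
#'   nominal (gain = 1) amplitude equals the target.
#' @param gain Optional per-pulse gain vector overriding the gain trace.
#' @param update_fn Controller update function with the signature of
#'   [controller_update()].
#' @return An object of class `cl_session_log`: data.frame with columns
#'   `time_s`, `current_ma`, `amplitude_mv` (one row per pulse) and
#'   attributes `mode`, `target_mv`, `ecapt`, `mt_current`,
#'   `mt_amplitude`, `n_updates`, `frequency_hz`, `saturated`.
#' @export
run_session <- function(mode = c("CL", "OL"), gt,
                        program = stimulus_program(50, 200, 1800, 0),
                        target_mv, controller = list(),
                        amp_noise_sd = 0.01, seed = NULL,
                        start_current_ma = NULL, ol_current_ma = NULL,
                        gain = NULL, update_fn = controller_update) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ecap_ground_truth"))
  mt_amplitude <- gt$slope * (gt$mt_true - gt$ecapt_true)
  if (target_mv <= 0 || target_mv >= mt_amplitude)
    stop("target_mv must lie strictly between 0 and the amplitude at MT")
  ctl <- utils::modifyList(list(gain_i = 0.4 / gt$slope,
                                step_cap = 0.005,
                                cap = gt$mt_true), controller)
  saturated <- target_mv > gt$slope * (ctl$cap - gt$ecapt_true)
  if (!is.null(seed)) set.seed(seed)
  n <- program$n_pulses
  if (is.null(gain))
    gain <- gain_trace(program$duration_s, program$frequency_hz,
                       gt$gain_volatility, gt$gain_tau_s)
  stopifnot(length(gain) == n)
  noise <- if (amp_noise_sd > 0) stats::rnorm(n, 0, amp_noise_sd) else
    numeric(n)

  current <- numeric(n)
  amplitude <- numeric(n)
  n_updates <- 0L
  if (mode == "OL") {
    I0 <- if (is.null(ol_current_ma))
      gt$ecapt_true + target_mv / gt$slope else ol_current_ma
    current[] <- I0
    amplitude <- gain * gt$slope * pmax(current - gt$ecapt_true, 0) + noise
  } else {
    I <- if (is.null(start_current_ma)) gt$ecapt_true else start_current_ma
    for (i in seq_len(n)) {
      current[i] <- I
      amplitude[i] <- gain[i] * gt$slope * max(I - gt$ecapt_true, 0) +
        noise[i]
      I <- update_fn(target_mv - amplitude[i], I, ctl)
      n_updates <- n_updates + 1L
    }
  }
  log <- data.frame(time_s = (seq_len(n) - 1) / program$frequency_hz,
                    current_ma = current, amplitude_mv = amplitude)
  structure(log, class = c("cl_session_log", "data.frame"),
            mode = mode, target_mv = target_mv, ecapt = gt$ecapt_true,
            mt_current = gt$mt_true, mt_amplitude = mt_amplitude,
            n_updates = n_updates, frequency_hz = program$frequency_hz,
            saturated = saturated)
}

#' Summarize a stimulation session
#'
#' Applies a single-pass 3-SD outlier rule independently to the measured
#' amplitudes and the delivered currents (a record is excluded if it is an
#' outlier on either variable), then reports summary statistics and the
#' two standard frequency distributions: the error between measured and
#' target amplitude, and the margin between delivered current and the ECAP
#' threshold. The mean amplitude is also expressed as a percentage of the
#' ECAP amplitude at the motor threshold.
#'
#' @param log A `cl_session_log` from [run_session()] (or a data.frame
#'   with `current_ma`/`amplitude_mv` plus the same attributes).
#' @param sd_mult Outlier multiplier (default 3).
#' @param breaks Passed to [graphics::hist()]-style binning via
#'   [base::cut()]; number of bins for the two histograms (default 30).
#' @return An object of class `session_summary`: list with
#'   `mean_amplitude`, `sd_amplitude`, `mean_current`, `sd_current`,
#'   `n_records`, `n_included`, `n_excluded`, `percent_of_mt`,
#'   `amplitude_error_hist` and `current_minus_ecapt_hist` (each a
#'   data.frame `mid`, `count`), `mode`, `target_mv`.
#' @export
summarize_session <- function(log, sd_mult = 3, breaks = 30) {
  stopifnot(nrow(log) > 0)
  a <- log$amplitude_mv
  i <- log$current_ma
  out_a <- abs(a - mean(a)) > sd_mult * stats::sd(a)
  out_i <- abs(i - mean(i)) > sd_mult * stats::sd(i)
  out_a[is.na(out_a)] <- FALSE   # sd = NA for n = 1
  out_i[is.na(out_i)] <- FALSE
  keep <- !(out_a | out_i)
  if (!any(keep)) stop("degenerate session: all records excluded")
  a_k <- a[keep]; i_k <- i[keep]
  target <- attr(log, "target_mv")
  ecapt <- attr(log, "ecapt")
  mt_amp <- attr(log, "mt_amplitude")
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  structure(list(
    mean_amplitude = mean(a_k), sd_amplitude = stats::sd(a_k),
    mean_current = mean(i_k), sd_current = stats::sd(i_k),
    n_records = length(a), n_included = sum(keep),
    n_excluded = sum(!keep),
    percent_of_mt = if (is.null(mt_amp)) NA_real_ else
      100 * mean(a_k) / mt_amp,
    amplitude_error_hist = if (is.null(target)) NULL else
      hist_of(a_k - target),
    current_minus_ecapt_hist = if (is.null(ecapt)) NULL else
      hist_of(i_k - ecapt),
    mode = attr(log, "mode"), target_mv = target),
    class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(paste0("<session_summary> %s: amplitude %.4f +/- %.4f mV",
                     " (%.1f%% of MT), current %.4f +/- %.4f mA, ",
                     "%d/%d records (%d excluded)\n"),
              x$mode %||% "?", x$mean_amplitude, x$sd_amplitude,
              x$percent_of_mt, x$mean_current, x$sd_current,
              x$n_included, x$n_records, x$n_excluded))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
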