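# Synthetic behavioural tables: 6 treatment groups x 7 timepoints with
# SNI-induced hypersensitivity and a stimulation-dependent rescue.

#' Effect configuration for the behavioural generator
#'
#' Per-cell (group x timepoint) means and dispersions for the log von Frey
#' threshold and the acetone withdrawal latency. The default configuration
#' states the hypersensitivity design:
#' \itemize{
#'   \item All groups share a healthy baseline at BS1 (log threshold ~5.0,
#'     latency ~0.2 s).
#'   \item At BS2 (post-injury) the SNI-family groups drop to the reported
#'     cohort means (SNI 3.13, SNI SCS-OFF 3.48, SNI SCS-ON 3.76 log
#'     units; latencies near 20-26 s) while sham groups remain high
#'     (5.01, 5.11, 5.23 log units).
#'   \item During stimulation (15 and 30 min) only SNI SCS-ON is partially
#'     rescued (towards ~4.8 log units, latency ~5 s), washing out after
#'     termination (45, 60 min).
#' }
#' Dispersions default to 0.25 log units for von Frey and 2 s (SNI) /
#' 0.1 s (sham) for acetone, on the order of the SEM-implied cohort SDs.
#'
#' @param null If TRUE, return a zero-effect configuration in which every
#'   cell shares one distribution (log threshold mean 4.0, latency mean
#'   5 s) — the null generator for type-I-error calibration.
#' @param vf_sd,acetone_sd_sni,acetone_sd_sham Optional dispersion
#'   overrides.
#' @return An object of class `behavior_effect_config`: list of matrices
#'   `vf_mean`, `vf_sd`, `ace_mean`, `ace_sd` (groups x timepoints).
#' @export
behavior_effect_config <- function(null = FALSE, vf_sd = 0.25,
                                   acetone_sd_sni = 2,
                                   acetone_sd_sham = 0.1) {
  g <- behavior_groups()
  tp <- behavior_timepoints()
  mk <- function(x) matrix(x, length(g), length(tp), byrow = TRUE,
                           dimnames = list(g, tp))
  if (null) {
    return(structure(list(vf_mean = mk(4.0), vf_sd = mk(vf_sd),
                          ace_mean = mk(5.0), ace_sd = mk(acetone_sd_sni)),
                     class = "behavior_effect_config"))
  }
  vf <- rbind(
    `sham`        = c(5.00, 5.01, 5.01, 5.01, 5.01, 5.01, 5.01),
    `sham SCS-OFF`= c(5.00, 5.11, 5.11, 5.11, 5.11, 5.11, 5.11),
    `sham SCS-ON` = c(5.00, 5.23, 5.23, 5.23, 5.23, 5.23, 5.23),
    `SNI`         = c(5.00, 3.13, 3.13, 3.13, 3.13, 3.13, 3.13),
    `SNI SCS-OFF` = c(5.00, 3.48, 3.48, 3.48, 3.48, 3.48, 3.48),
    `SNI SCS-ON`  = c(5.00, 3.76, 3.76, 4.80, 4.80, 4.20, 3.90))
  ace <- rbind(
    `sham`        = c(0.20, 0.18, 0.18, 0.18, 0.18, 0.18, 0.18),
    `sham SCS-OFF`= c(0.20, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    `sham SCS-ON` = c(0.20, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    `SNI`         = c(0.20, 26.07, 26.0, 26.0, 26.0, 26.0, 26.0),
    `SNI SCS-OFF` = c(0.20, 19.66, 19.7, 19.7, 19.7, 19.7, 19.7),
    `SNI SCS-ON`  = c(0.20, 19.82, 19.8, 5.0, 5.0, 10.0, 14.0))
  dimnames(vf) <- dimnames(ace) <- list(g, tp)
  ace_sd <- mk(acetone_sd_sham)
  ace_sd[grepl("^SNI", g), ] <- acetone_sd_sni
  structure(list(vf_mean = vf, vf_sd = mk(vf_sd),
                 ace_mean = ace, ace_sd = ace_sd),
            class = "behavior_effect_config")
}

#' Generate a synthetic behavioural table
#'
#' Draws per-animal von Frey log thresholds and acetone latencies from
#' normal distributions with the cell means and SDs of an effect
#' configuration. Log thresholds are clamped at the 26 g cutoff (on the
#' log scale) and latencies truncated at 0 s. Each animal contributes one
#' row per timepoint (a repeated-measures design).
#'
#' @param config A [behavior_effect_config()].
#' @param n_per_group Animals per group (>= 2; default 6).
#' @param seed Integer seed.
#' @return A `behavior_table`: data.frame with `animal_id`, `group`,
#'   `timepoint`, `vf_log_threshold`, `acetone_latency`.
#' @export
synth_behavior <- function(config = behavior_effect_config(),
                           n_per_group = 6, seed = NULL) {
  stopifnot(inherits(config, "behavior_effect_config"))
  if (n_per_group < 2)
    stop("n_per_group must be >= 2 for the downstream ANOVA")
  if (!is.null(seed)) set.seed(seed)
  g <- behavior_groups()
  tp <- behavior_timepoints()
  rows <- list()
  aid <- 0L
  for (gi in seq_along(g)) {
    for (a in seq_len(n_per_group)) {
      aid <- aid + 1L
      vf <- stats::rnorm(length(tp), config$vf_mean[gi, ],
                         config$vf_sd[gi, ])
      ace <- stats::rnorm(length(tp), config$ace_mean[gi, ],
                          config$ace_sd[gi, ])
      rows[[aid]] <- data.frame(
        animal_id = sprintf("a%03d", aid),
        group = g[gi], timepoint = tp,
        vf_log_threshold = pmin(vf, vf_log_cutoff()),
        acetone_latency = pmax(ace, 0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("behavior_table", "data.frame")
  out
}
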