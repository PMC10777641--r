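# Behavioural endpoints (von Frey, acetone) and the statistical pipeline:
# repeated-measures two-way ANOVA, Welch post-hocs with Bonferroni
# correction, and windowed AUC one-way ANOVAs.

#' Treatment groups and assessment timepoints
#'
#' The six treatment groups and seven assessment timepoints of the
#' hypersensitivity design. BS1 is the baseline before nerve injury, BS2
#' the baseline after injury but before lead implantation, and 0-60 min
#' bracket the 30-min stimulation period (stimulation on during 0-30 min).
#'
#' @return Character vector of levels.
#' @export
behavior_groups <- function() {
  c("sham", "sham SCS-OFF", "sham SCS-ON", "SNI", "SNI SCS-OFF",
    "SNI SCS-ON")
}

#' @rdname behavior_groups
#' @export
behavior_timepoints <- function() {
  c("BS1", "BS2", "0", "15", "30", "45", "60")
}

#' Von Frey cutoff on the log scale
#'
#' The 26.0 g cutoff filament, after the x10,000 log10 transform.
#'
#' @return log10(26 * 10000).
#' @export
vf_log_cutoff <- function() log10(26 * 10000)

#' Mechanical withdrawal threshold from per-filament response counts
#'
#' Ascending von Frey filaments are applied five times each; the threshold
#' is the bending force of the first filament that evokes a withdrawal on
#' at least 3 of 5 applications (a 60% response rate). If no filament
#' qualifies, the 26.0 g cutoff force is returned.
#'
#' @param responses Integer withdrawal counts out of 5, one per filament,
#'   in the same (ascending-force) order as `forces_g`.
#' @param forces_g Ascending filament bending forces in grams; default the
#'   standard 13-filament series from 0.07 g to 26 g.
#' @param cutoff_g Cutoff force returned when no filament reaches 3/5.
#' @return Threshold force in grams.
#' @examples
#' withdrawal_threshold(c(0, 1, 2, 3, 5), c(0.07, 0.16, 0.4, 0.6, 1.0))
#' @export
withdrawal_threshold <- function(responses,
                                 forces_g = c(0.07, 0.16, 0.4, 0.6, 1.0,
                                              1.4, 2.0, 4.0, 6.0, 8.0,
                                              10.0, 15.0, 26.0),
                                 cutoff_g = 26.0) {
  forces_g <- forces_g[seq_along(responses)]
  if (length(responses) > length(forces_g))
    stop("more response counts than filaments")
  if (any(is.na(responses)) || any(responses < 0) || any(responses > 5) ||
      any(responses != round(responses)))
    stop("responses must be integer counts in 0..5")
  if (is.unsorted(forces_g, strictly = TRUE))
    stop("forces_g must be strictly ascending")
  hit <- which(responses >= 3)
  if (length(hit) == 0) return(cutoff_g)
  forces_g[hit[1]]
}

#' Log transform of a withdrawal threshold
#'
#' Thresholds in grams are multiplied by 10,000 and log10-transformed to
#' obtain a linear (Weber's-law-conforming) scale.
#'
#' @param threshold_g Threshold in grams (> 0).
#' @return Threshold in log10 units.
#' @export
log_transform <- function(threshold_g) {
  if (any(threshold_g <= 0)) stop("threshold must be positive")
  log10(threshold_g * 10000)
}

#' @rdname log_transform
#' @param log_units Value in log10 units.
#' @export
inv_log_transform <- function(log_units) 10^log_units / 10000

#' Two-way repeated-measures ANOVA with Welch post-hoc contrasts
#'
#' Reproduces the hypersensitivity analysis: a two-way ANOVA of the
#' endpoint against treatment group (between-subjects) and timepoint
#' (within-subjects, animal as error stratum), reporting the group-by-time
#' interaction, followed by planned Welch (unequal-variance) two-sample
#' t-tests between groups at specified timepoints with Bonferroni
#' correction over the family of planned contrasts. Welch tests are used
#' because the reported post-hoc degrees of freedom are fractional.
#'
#' @param table A `behavior_table` from [synth_behavior()] or
#'   [read_behavior_table()] (long data.frame with `animal_id`, `group`,
#'   `timepoint` and the endpoint columns).
#' @param endpoint Column name, `"vf_log_threshold"` or
#'   `"acetone_latency"`.
#' @param contrasts Data.frame with columns `group1`, `group2`,
#'   `timepoint` defining the planned contrasts; default
#'   [default_contrasts()]. The Bonferroni family size is the number of
#'   rows.
#' @return List with `interaction` (named vector `F`, `df1`, `df2`, `p`)
#'   and `posthoc` (data.frame with the contrast, Welch `t`, `df`, raw and
#'   Bonferroni-corrected `p`).
#' @export
anova_timegroup <- function(table,
                            endpoint = c("vf_log_threshold",
                                         "acetone_latency"),
                            contrasts = default_contrasts()) {
  endpoint <- match.arg(endpoint)
  df <- as.data.frame(table)
  need <- c("animal_id", "group", "timepoint", endpoint)
  stopifnot(all(need %in% names(df)))
  df$group <- factor(df$group, levels = behavior_groups())
  df$timepoint <- factor(df$timepoint, levels = behavior_timepoints())
  if (any(is.na(df$group)) || any(is.na(df$timepoint)))
    stop("unknown group or timepoint labels")
  cell_n <- table(df$group, df$timepoint)
  if (any(cell_n < 2))
    stop("design error: every group x timepoint cell needs >= 2 animals")
  df$y <- df[[endpoint]]
  df$animal_id <- factor(df$animal_id)
  fit <- stats::aov(y ~ group * timepoint + Error(animal_id), data = df)
  within <- summary(fit)[["Error: Within"]][[1]]
  ix <- grep("group:timepoint", rownames(within))
  inter <- c(F = within[ix, "F value"],
             df1 = within[ix, "Df"],
             df2 = within[nrow(within), "Df"],
             p = within[ix, "Pr(>F)"])
  names(inter) <- c("F", "df1", "df2", "p")

  m <- nrow(contrasts)
  ph <- lapply(seq_len(m), function(i) {
    g1 <- contrasts$group1[i]; g2 <- contrasts$group2[i]
    tp <- as.character(contrasts$timepoint[i])
    x <- df$y[df$group == g1 & df$timepoint == tp]
    y <- df$y[df$group == g2 & df$timepoint == tp]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(group1 = g1, group2 = g2, timepoint = tp,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonf = min(1, tt$p.value * m))
  })
  list(interaction = inter, posthoc = do.call(rbind, ph))
}

#' Default planned contrast family
#'
#' The planned comparisons reported for the hypersensitivity endpoints:
#' the three sham-vs-SNI pairs at both baselines, and the stimulation
#' rescue contrasts (SNI SCS-ON against SNI and against SNI SCS-OFF) at
#' every post-implantation timepoint.
#'
#' @return Data.frame with columns `group1`, `group2`, `timepoint`.
#' @export
default_contrasts <- function() {
  base <- expand.grid(
    pair = c("sham|SNI", "sham SCS-OFF|SNI SCS-OFF",
             "sham SCS-ON|SNI SCS-ON"),
    timepoint = c("BS1", "BS2"), stringsAsFactors = FALSE)
  rescue <- expand.grid(
    pair = c("SNI SCS-ON|SNI", "SNI SCS-ON|SNI SCS-OFF"),
    timepoint = c("0", "15", "30", "45", "60"), stringsAsFactors = FALSE)
  all <- rbind(base, rescue)
  parts <- strsplit(all$pair, "|", fixed = TRUE)
  data.frame(group1 = vapply(parts, `[`, "", 1),
             group2 = vapply(parts, `[`, "", 2),
             timepoint = all$timepoint,
             stringsAsFactors = FALSE)
}

#' Trapezoidal area under the curve
#'
#' @param values Endpoint values at the timepoints.
#' @param times_min Numeric timepoints in minutes (ascending).
#' @return Trapezoidal integral (endpoint units x min).
#' @examples
#' auc(c(3, 5, 3), c(0, 15, 30))  # 120
#' @export
auc <- function(values, times_min) {
  stopifnot(length(values) == length(times_min), length(values) >= 2)
  if (any(is.na(values)) || any(is.na(times_min)))
    stop("missing timepoint or value")
  if (is.unsorted(times_min, strictly = TRUE))
    stop("times must be strictly ascending")
  sum(diff(times_min) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' One-way ANOVA on per-animal AUCs over a time window
#'
#' Computes the trapezoidal AUC of an endpoint for every animal over a
#' window of the stimulation session (0-30 min during stimulation, or
#' 30-60 min after termination), then runs a one-way ANOVA across
#' treatment groups with Bonferroni-corrected pooled-variance post-hoc
#' t-tests (using the ANOVA residual degrees of freedom, matching the
#' integer post-hoc dfs reported for this analysis).
#'
#' @param table A behavior table (see [anova_timegroup()]).
#' @param endpoint `"vf_log_threshold"` or `"acetone_latency"`.
#' @param window Length-2 numeric, `c(0, 30)` or `c(30, 60)`.
#' @param contrasts Data.frame with columns `group1`, `group2`; default
#'   the rescue contrasts (SNI SCS-ON vs SNI and vs SNI SCS-OFF).
#' @return List with `auc` (per-animal data.frame), `anova` (named vector
#'   `F`, `df1`, `df2`, `p`) and `posthoc` (data.frame).
#' @export
auc_anova <- function(table,
                      endpoint = c("vf_log_threshold", "acetone_latency"),
                      window = c(0, 30),
                      contrasts = data.frame(
                        group1 = "SNI SCS-ON",
                        group2 = c("SNI", "SNI SCS-OFF"))) {
  endpoint <- match.arg(endpoint)
  df <- as.data.frame(table)
  tp_num <- suppressWarnings(as.numeric(as.character(df$timepoint)))
  inside <- !is.na(tp_num) & tp_num >= window[1] & tp_num <= window[2]
  need_tp <- seq(window[1], window[2], by = 15)
  df <- df[inside, ]
  df$tp_num <- tp_num[inside]
  per <- split(df, df$animal_id, drop = TRUE)
  rows <- lapply(per, function(d) {
    d <- d[order(d$tp_num), ]
    if (!all(need_tp %in% d$tp_num))
      stop("missing timepoint inside the AUC window")
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               auc = auc(d[[endpoint]], d$tp_num))
  })
  aucs <- do.call(rbind, rows)
  aucs$group <- factor(aucs$group, levels = behavior_groups())
  fit <- stats::aov(auc ~ group, data = aucs)
  s <- summary(fit)[[1]]
  res <- c(F = s["group", "F value"], df1 = s["group", "Df"],
           df2 = s["Residuals", "Df"], p = s["group", "Pr(>F)"])
  names(res) <- c("F", "df1", "df2", "p")
  mse <- s["Residuals", "Mean Sq"]
  dfr <- s["Residuals", "Df"]
  m <- nrow(contrasts)
  ph <- lapply(seq_len(m), function(i) {
    x <- aucs$auc[aucs$group == contrasts$group1[i]]
    y <- aucs$auc[aucs$group == contrasts$group2[i]]
    se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
    tval <- (mean(x) - mean(y)) / se
    p <- 2 * stats::pt(-abs(tval), dfr)
    data.frame(group1 = contrasts$group1[i], group2 = contrasts$group2[i],
               t = tval, df = dfr, p_raw = p, p_bonf = min(1, p * m))
  })
  list(auc = aucs, anova = res, posthoc = do.call(rbind, ph))
}
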