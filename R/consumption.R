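# Per-chamber oxygen time series, consumption metrics and group comparisons.

#' Assemble per-chamber oxygen series
#'
#' Joins per-chamber mean oxygen values (from [analyze_oxygen()]) with group
#' assignments, keeping only spheroid-occupied chambers: empty chambers are
#' references, not samples. Chambers missing timepoints are flagged
#' incomplete but retained.
#'
#' @param chamber_means data frame with columns chamber_id, occupancy,
#'   timepoint_min, mean_o2_pct (as produced by [analyze_oxygen()]).
#' @param groups optional named vector `chamber_id -> group label`; chambers
#'   without an entry get `"untreated"`.
#' @return Data frame of class `oxygen_series` with columns chamber_id,
#'   group, timepoint_min, o2, and attribute `incomplete` (chamber ids with
#'   missing timepoints).
#' @export
assemble_series <- function(chamber_means, groups = NULL) {
  stopifnot(all(c("chamber_id", "occupancy", "timepoint_min", "mean_o2_pct")
                %in% names(chamber_means)))
  df <- chamber_means[chamber_means$occupancy == "spheroid", , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- data.frame(chamber_id = integer(), group = character(),
                      timepoint_min = numeric(), o2 = numeric())
    attr(out, "incomplete") <- integer()
    class(out) <- c("oxygen_series", "data.frame")
    return(out)
  }
  grp <- rep("untreated", nrow(df))
  if (!is.null(groups)) {
    hit <- match(as.character(df$chamber_id), names(groups))
    grp[!is.na(hit)] <- unname(groups[hit[!is.na(hit)]])
  }
  out <- data.frame(chamber_id = df$chamber_id, group = grp,
                    timepoint_min = df$timepoint_min, o2 = df$mean_o2_pct)
  out <- out[order(out$chamber_id, out$timepoint_min), ]
  rownames(out) <- NULL
  n_tp <- table(out$chamber_id)
  incomplete <- as.integer(names(n_tp)[n_tp < max(n_tp)])
  attr(out, "incomplete") <- incomplete
  class(out) <- c("oxygen_series", "data.frame")
  out
}

#' Consumption metrics for one chamber series
#'
#' The trajectory splits into a rapid-decline phase and a stable plateau.
#' The initial rate is the negated least-squares slope over the first
#' `rate_window` points (default 5, i.e. 0-20 min at 5 min intervals); the
#' plateau is the mean of the last `plateau_window` points (default 7, i.e.
#' 30-60 min); time-to-plateau is the first timepoint whose oxygen is within
#' `plateau_tol` of the plateau (flagged censored if that never happens
#' within the observed window); total drop is O2(0) minus the plateau.
#'
#' @param o2 oxygen tension per timepoint (% O2), or a data frame with
#'   columns `timepoint_min` and `o2`.
#' @param timepoints acquisition times in minutes (ignored when `o2` is a
#'   data frame).
#' @param rate_window number of initial points in the rate fit.
#' @param plateau_window number of final points averaged into the plateau.
#' @param plateau_tol tolerance band around the plateau in % O2.
#' @return A one-row data frame of class `consumption_metrics`: initial_rate
#'   (% O2/min), plateau_o2, time_to_plateau (min, NA when censored),
#'   censored, total_drop.
#' @export
compute_metrics <- function(o2, timepoints = NULL, rate_window = 5L,
                            plateau_window = 7L, plateau_tol = 0.5) {
  if (is.data.frame(o2)) {
    timepoints <- o2$timepoint_min
    o2 <- o2$o2
  }
  stopifnot(length(o2) == length(timepoints), rate_window >= 2L,
            plateau_window >= 1L)
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (length(o2) < rate_window + plateau_window)
    stop("series too short for the requested rate and plateau windows")
  head_idx <- seq_len(rate_window)
  fit <- stats::lm.fit(cbind(1, timepoints[head_idx]), o2[head_idx])
  initial_rate <- -unname(fit$coefficients[2])
  plateau_o2 <- mean(utils::tail(o2, plateau_window))
  within <- which(abs(o2 - plateau_o2) <= plateau_tol)
  censored <- length(within) == 0L
  structure(data.frame(
    initial_rate = initial_rate, plateau_o2 = plateau_o2,
    time_to_plateau = if (censored) NA_real_ else timepoints[min(within)],
    censored = censored,
    total_drop = o2[1] - plateau_o2
  ), class = c("consumption_metrics", "data.frame"))
}

#' Consumption metrics for every chamber in a series table
#'
#' @param series an `oxygen_series` data frame from [assemble_series()].
#' @param ... passed to [compute_metrics()].
#' @return Data frame with one row per chamber (chamber_id, group, metrics).
#' @export
metrics_by_chamber <- function(series, ...) {
  ids <- unique(series$chamber_id)
  rows <- lapply(ids, function(id) {
    s <- series[series$chamber_id == id, ]
    cbind(data.frame(chamber_id = id, group = s$group[1]),
          compute_metrics(s$o2, s$timepoint_min, ...))
  })
  do.call(rbind, rows)
}

#' Molar oxygen-consumption rate
#'
#' Converts the initial rate in % O2/min to mol/min using the chamber volume
#' and the oxygen solubility of the medium:
#' `rate = initial_rate / 20.9 * solubility * volume`. The default solubility,
#' 200 uM for air-equilibrated aqueous buffer at 37 C, is overridable.
#'
#' @param initial_rate consumption rate in % O2 per minute (or a
#'   `consumption_metrics` row).
#' @param volume_nl chamber volume in nanolitres (see [chamber_volume()]).
#' @param solubility_um dissolved oxygen concentration at ambient (20.9% O2)
#'   in micromolar.
#' @return Consumption rate in mol/min.
#' @export
molar_rate <- function(initial_rate, volume_nl, solubility_um = 200) {
  if (is.data.frame(initial_rate)) initial_rate <- initial_rate$initial_rate
  stopifnot(solubility_um > 0, volume_nl >= 0)
  initial_rate / 20.9 * (solubility_um * 1e-6) * (volume_nl * 1e-9)
}

#' Per-timepoint group comparison
#'
#' Two-sided two-sample Student's t-test (equal variance by default, Welch
#' behind a flag) at every timepoint shared by both groups, with group means,
#' SDs, and a significance flag at p < 0.05. No multiple-testing correction
#' is applied by default, matching per-timepoint starring conventions; a
#' Bonferroni option is available.
#'
#' @param series_a,series_b `oxygen_series` data frames (or any data frame
#'   with chamber_id, timepoint_min, o2), one per group.
#' @param var_equal use the classical equal-variance Student's t-test
#'   (default TRUE).
#' @param bonferroni adjust p-values across timepoints before flagging.
#' @param alpha significance level.
#' @return Data frame with one row per timepoint: means, SDs, counts per
#'   group, t statistic, p value, and `significant`.
#' @export
compare_groups <- function(series_a, series_b, var_equal = TRUE,
                           bonferroni = FALSE, alpha = 0.05) {
  tps <- intersect(unique(series_a$timepoint_min), unique(series_b$timepoint_min))
  tps <- sort(tps)
  if (length(tps) == 0L) stop("groups share no timepoints")
  rows <- lapply(tps, function(tp) {
    a <- series_a$o2[series_a$timepoint_min == tp]
    b <- series_b$o2[series_b$timepoint_min == tp]
    if (length(a) < 2L || length(b) < 2L)
      stop("each group needs at least 2 series per compared timepoint")
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(timepoint_min = tp,
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  p_used <- if (bonferroni) stats::p.adjust(out$p, "bonferroni") else out$p
  out$significant <- p_used < alpha
  out
}
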