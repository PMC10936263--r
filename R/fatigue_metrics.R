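#' Threshold limit value curve for localized muscle fatigue
#'
#' A decreasing power-law family for the occupational-hygiene threshold
#' limit value (TLV) on normalized muscle effort as a function of duty
#' cycle, anchored so that `tlv(anchor_dc) == anchor_tlv`. The shipped
#' default is calibrated to 20 %MVC at a 50% duty cycle, the anchor implied
#' by the guideline that a 2 %MVC amplitude reduction equals at least a 10%
#' reduction relative to the TLV at 50% duty cycle.
#'
#' @param exponent power-law decay exponent (> 0).
#' @param anchor_dc,anchor_tlv calibration anchor: duty cycle in (0, 1] and
#'   its TLV in %MVC.
#' @param dc_floor minimum duty cycle evaluated; lower (nonzero) duty cycles
#'   are evaluated at the floor so the curve stays bounded.
#' @param cap maximum %MVC returned (default 100).
#' @return object of class `tlv_curve`.
#' @export
tlv_curve <- function(exponent = 0.5, anchor_dc = 0.5, anchor_tlv = 20,
                      dc_floor = 0.02, cap = 100) {
  stopifnot(exponent > 0, anchor_dc > 0, anchor_dc <= 1, anchor_tlv > 0,
            dc_floor > 0, dc_floor < 1, cap >= anchor_tlv)
  structure(
    list(exponent = exponent, anchor_dc = anchor_dc,
         anchor_tlv = anchor_tlv, dc_floor = dc_floor, cap = cap),
    class = "tlv_curve"
  )
}

#' Evaluate a TLV curve at a duty cycle
#'
#' @param dc duty cycle, vectorized, each in \[0, 1\]. A duty cycle of
#'   exactly 0 (muscle never active) returns the cap: no finite fatigue
#'   limit applies to an inactive muscle. Values in (0, dc_floor) are
#'   evaluated at the floor.
#' @param curve a [tlv_curve()].
#' @return TLV in %MVC, same length as `dc`.
#' @export
tlv <- function(dc, curve = tlv_curve()) {
  stopifnot(inherits(curve, "tlv_curve"), is.numeric(dc))
  if (any(is.na(dc)) || any(dc < 0 | dc > 1)) {
    stop("duty cycle must be within [0, 1]", call. = FALSE)
  }
  val <- curve$anchor_tlv *
    (pmax(dc, curve$dc_floor) / curve$anchor_dc) ^ (-curve$exponent)
  val <- pmin(val, curve$cap)
  val[dc == 0] <- curve$cap
  val
}

#' Activity mask from a normalized series
#'
#' An interval is active when its normalized amplitude strictly exceeds the
#' activity threshold (default 5 %MVC).
#'
#' @param series a [interval_series()] result (or plain numeric %MVC
#'   vector).
#' @param threshold activity threshold in %MVC (>= 0).
#' @return logical vector, one element per interval.
#' @export
activity_mask <- function(series, threshold = 5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  values <- if (inherits(series, "normalized_series")) series$values
            else series
  values > threshold
}

#' Duty cycle: fraction of work time a muscle is active
#'
#' @param mask logical activity mask (nonempty).
#' @return fraction in \[0, 1\].
#' @export
duty_cycle <- function(mask) {
  stopifnot(is.logical(mask))
  if (!length(mask)) stop("empty activity mask", call. = FALSE)
  sum(mask) / length(mask)
}

#' Mean active EMG amplitude
#'
#' Mean of the normalized interval amplitudes over active intervals only.
#' When no interval is active the amplitude is undefined and `NA` is
#' returned (never 0: an inactive muscle has no active amplitude).
#'
#' @param series a [interval_series()] result or numeric %MVC vector.
#' @param mask logical activity mask, same length.
#' @return mean active amplitude in %MVC, or `NA_real_`.
#' @export
mean_active_amplitude <- function(series, mask) {
  values <- if (inherits(series, "normalized_series")) series$values
            else series
  stopifnot(is.logical(mask), length(values) == length(mask))
  if (!any(mask)) return(NA_real_)
  mean(values[mask])
}

#' Fatigue risk value
#'
#' Mean active amplitude minus the TLV at the observed duty cycle, in %MVC.
#' Positive values indicate effort above the fatigue threshold limit.
#'
#' @param maa mean active amplitude in %MVC (`NA` propagates).
#' @param tlv_value TLV in %MVC.
#' @return FRV in %MVC.
#' @export
fatigue_risk <- function(maa, tlv_value) {
  stopifnot(is.numeric(maa), is.numeric(tlv_value))
  maa - tlv_value
}

#' Compute all fatigue metrics for one normalized series
#'
#' @param series a [interval_series()] result.
#' @param threshold activity threshold in %MVC.
#' @param curve a [tlv_curve()].
#' @return object of class `muscle_fatigue_metrics`: list with
#'   `mean_active_amplitude`, `duty_cycle`, `tlv`, `fatigue_risk_value`,
#'   `n_active`, `n_total`, `muscle`, `side`.
#' @export
muscle_fatigue_metrics <- function(series, threshold = 5,
                                   curve = tlv_curve()) {
  mask <- activity_mask(series, threshold)
  dc <- duty_cycle(mask)
  maa <- mean_active_amplitude(series, mask)
  tlv_value <- tlv(dc, curve)
  structure(
    list(
      mean_active_amplitude = maa,
      duty_cycle = dc,
      tlv = tlv_value,
      fatigue_risk_value = fatigue_risk(maa, tlv_value),
      n_active = sum(mask),
      n_total = length(mask),
      muscle = if (inherits(series, "normalized_series")) series$muscle
               else NA_character_,
      side = if (inherits(series, "normalized_series")) series$side
             else NA_character_
    ),
    class = "muscle_fatigue_metrics"
  )
}

#' @export
print.muscle_fatigue_metrics <- function(x, ...) {
  cat(sprintf(
    "<muscle_fatigue_metrics> %s/%s: maa=%.2f %%MVC dc=%.3f tlv=%.2f frv=%.2f (%d/%d active)\n",
    x$muscle, x$side, x$mean_active_amplitude, x$duty_cycle, x$tlv,
    x$fatigue_risk_value, x$n_active, x$n_total))
  invisible(x)
}

#' Reduce left/right channels to one analysis-level value per muscle
#'
#' Shoulder and arm muscles (anterior deltoid, biceps brachii, upper
#' trapezius) retain the higher of the two sides: the per-metric maximum of
#' mean active amplitude and duty cycle is taken, the TLV is re-evaluated at
#' the retained duty cycle, and the fatigue risk value is recomputed from
#' the retained amplitude and TLV (so FRV = amplitude - TLV holds on the
#' reduced record, and the reduced FRV is never below either side's). The
#' lumbar erector spinae is a bilateral postural muscle: its two normalized
#' series are averaged elementwise first and the metrics computed on the
#' averaged series.
#'
#' @param left,right [interval_series()] results for the two sides.
#' @param muscle muscle name; `"lumbar_erector_spinae"` selects the
#'   averaging rule.
#' @param threshold activity threshold in %MVC.
#' @param curve a [tlv_curve()].
#' @return `muscle_fatigue_metrics` with `side` set to `"analysis"` (max
#'   rule) or `"bilateral_mean"` (averaging rule).
#' @export
bilateral_reduce <- function(left, right, muscle, threshold = 5,
                             curve = tlv_curve()) {
  stopifnot(inherits(left, "normalized_series"),
            inherits(right, "normalized_series"))
  if (length(left$values) != length(right$values)) {
    stop("left/right series must have equal length", call. = FALSE)
  }
  if (identical(muscle, "lumbar_erector_spinae")) {
    avg <- left
    avg$values <- (left$values + right$values) / 2
    avg$muscle <- muscle
    avg$side <- "bilateral_mean"
    return(muscle_fatigue_metrics(avg, threshold, curve))
  }
  ml <- muscle_fatigue_metrics(left, threshold, curve)
  mr <- muscle_fatigue_metrics(right, threshold, curve)
  maa <- if (is.na(ml$mean_active_amplitude) &&
             is.na(mr$mean_active_amplitude)) NA_real_
         else max(ml$mean_active_amplitude, mr$mean_active_amplitude,
                  na.rm = TRUE)
  dc <- max(ml$duty_cycle, mr$duty_cycle)
  tlv_value <- tlv(dc, curve)
  structure(
    list(
      mean_active_amplitude = maa,
      duty_cycle = dc,
      tlv = tlv_value,
      fatigue_risk_value = fatigue_risk(maa, tlv_value),
      n_active = max(ml$n_active, mr$n_active),
      n_total = ml$n_total,
      muscle = muscle,
      side = "analysis"
    ),
    class = "muscle_fatigue_metrics"
  )
}

#' Exoskeleton benefit category from paired fatigue risk values
#'
#' Processes are grouped by whether exoskeleton use meaningfully reduced the
#' fatigue risk value (FRV) and where the FRV sits relative to the TLV:
#' \describe{
#'   \item{1}{meaningful reduction, but still above the TLV with the
#'     exoskeleton (`frv_with > 0`)}
#'   \item{2}{meaningful reduction from above to at-or-below the TLV}
#'   \item{3}{meaningful reduction, but already at-or-below the TLV without
#'     the exoskeleton}
#'   \item{4}{minimal change or increase (reduction below the meaningful
#'     threshold)}
#' }
#' An FRV of exactly 0 counts as at-or-below the TLV (only positive FRVs
#' indicate effort above the limit).
#'
#' @param frv_without,frv_with FRVs in %MVC (vectorized; `NA` propagates).
#' @param meaningful minimum FRV reduction in %MVC considered meaningful
#'   (> 0, default 2).
#' @return integer category 1--4, same length as inputs.
#' @export
categorize <- function(frv_without, frv_with, meaningful = 2) {
  stopifnot(is.numeric(frv_without), is.numeric(frv_with),
            length(frv_without) == length(frv_with),
            is.numeric(meaningful), length(meaningful) == 1L, meaningful > 0)
  reduction <- frv_without - frv_with
  out <- rep(NA_integer_, length(reduction))
  meaningful_red <- !is.na(reduction) & reduction >= meaningful
  out[meaningful_red & frv_with > 0] <- 1L
  out[meaningful_red & frv_with <= 0 & frv_without > 0] <- 2L
  out[meaningful_red & frv_with <= 0 & frv_without <= 0] <- 3L
  out[!is.na(reduction) & reduction < meaningful] <- 4L
  out
}

#' Collapse member-level values to process-level means
#'
#' Field sessions are recorded per team member; analysis operates on the
#' assembly process, so member-level values are averaged within each
#' process (arithmetic mean, `NA` dropped).
#'
#' @param data data.frame with a process id column and one or more numeric
#'   value columns.
#' @param values character vector of value column names.
#' @param process_col name of the process id column (default `"process"`).
#' @return data.frame with one row per process, ordered by process id.
#' @export
collapse_by_process <- function(data, values, process_col = "process") {
  stopifnot(is.data.frame(data), process_col %in% names(data),
            all(values %in% names(data)), nrow(data) >= 1L)
  agg <- stats::aggregate(
    data[values],
    by = stats::setNames(list(data[[process_col]]), process_col),
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  )
  agg[order(agg[[process_col]]), , drop = FALSE]
}

#' Percent time at or above shoulder-elevation thresholds
#'
#' Converts a per-process posture breakdown (seconds at shoulder elevations
#' at or above 60, 90, 135, 180 degrees, plus the process cycle time) into
#' percent-of-cycle-time values for the 60/90/135-degree thresholds.
#'
#' @param pb data.frame with columns `process_id`, `cycle_time_s`,
#'   `sec_ge60`, `sec_ge90`, `sec_ge135`, `sec_ge180`.
#' @return `pb` with added columns `pct_ge60`, `pct_ge90`, `pct_ge135`.
#' @export
posture_percentages <- function(pb) {
  need <- c("process_id", "cycle_time_s", "sec_ge60", "sec_ge90",
            "sec_ge135", "sec_ge180")
  stopifnot(is.data.frame(pb), all(need %in% names(pb)))
  if (any(pb$cycle_time_s <= 0)) {
    stop("cycle_time_s must be > 0", call. = FALSE)
  }
  sec <- as.matrix(pb[c("sec_ge60", "sec_ge90", "sec_ge135", "sec_ge180")])
  if (any(sec < 0)) stop("posture seconds must be >= 0", call. = FALSE)
  if (any(sec[, -1, drop = FALSE] > sec[, -4, drop = FALSE] + 1e-9)) {
    stop("posture seconds must be non-increasing with elevation threshold",
         call. = FALSE)
  }
  if (any(sec[, 1] > pb$cycle_time_s + 1e-9)) {
    stop("posture seconds cannot exceed the cycle time", call. = FALSE)
  }
  pb$pct_ge60 <- 100 * pb$sec_ge60 / pb$cycle_time_s
  pb$pct_ge90 <- 100 * pb$sec_ge90 / pb$cycle_time_s
  pb$pct_ge135 <- 100 * pb$sec_ge135 / pb$cycle_time_s
  pb
}

#' Unweighted group means of posture percentages
#'
#' @param pct data.frame from [posture_percentages()].
#' @param grouping named vector/list mapping `process_id` to a group label
#'   (e.g. benefit-category groups).
#' @return data.frame with one row per group and the mean percent time at
#'   each elevation threshold.
#' @export
group_posture_means <- function(pct, grouping) {
  stopifnot(is.data.frame(pct),
            all(c("pct_ge60", "pct_ge90", "pct_ge135") %in% names(pct)))
  g <- unlist(grouping[as.character(pct$process_id)])
  if (anyNA(g)) {
    stop("grouping must cover every process_id", call. = FALSE)
  }
  agg <- stats::aggregate(
    pct[c("pct_ge60", "pct_ge90", "pct_ge135")],
    by = list(group = g), FUN = mean
  )
  agg[order(agg$group), , drop = FALSE]
}
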