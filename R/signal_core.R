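# Muscles monitored in upper-body exoskeleton field evaluations and the
# channel naming convention used throughout: "<muscle>_<side>".
EMG_MUSCLES <- c("anterior_deltoid", "biceps_brachii", "upper_trapezius",
                 "lumbar_erector_spinae")
EMG_SIDES <- c("left", "right")

#' Default channel map: all four muscles, both sides
#'
#' @return data.frame with columns `muscle` and `side`, one row per channel,
#'   in canonical order.
#' @export
default_channel_map <- function() {
  data.frame(
    muscle = rep(EMG_MUSCLES, each = 2L),
    side = rep(EMG_SIDES, times = 4L),
    stringsAsFactors = FALSE
  )
}

channel_names <- function(channel_map) {
  paste(channel_map$muscle, channel_map$side, sep = "_")
}

#' Construct a multi-channel surface EMG recording
#'
#' @param samples named list of numeric vectors (one per channel, equal
#'   length), in consistent voltage units.
#' @param fs sampling frequency in Hz (> 0).
#' @param channel_map data.frame with columns `muscle`, `side`; channel
#'   `<muscle>_<side>` must exist in `samples`.
#' @param meta list of session metadata: `participant`, `process`,
#'   `condition` (one of `"with_exo"`, `"without_exo"`), free-form extras.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_map = default_channel_map(),
                          meta = list()) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  wanted <- channel_names(channel_map)
  missing <- setdiff(wanted, names(samples))
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[wanted]
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length", call. = FALSE)
  }
  if (!is.null(meta$duration_s)) {
    if (abs(lens[[1]] / fs - meta$duration_s) > 1 / fs) {
      stop("channel length does not match stated duration", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, fs = fs, channels = channel_map, meta = meta),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<emg_recording> %d channel(s) x %d samples (%.1f s @ %g Hz)\n",
              length(x$samples), n, n / x$fs, x$fs))
  cat("  channels:", paste(names(x$samples), collapse = ", "), "\n")
  if (length(x$meta)) {
    m <- x$meta[intersect(c("participant", "process", "condition"),
                          names(x$meta))]
    if (length(m)) {
      cat("  meta:", paste(names(m), unlist(m), sep = "=", collapse = " "),
          "\n")
    }
  }
  invisible(x)
}

#' Read a signal CSV into an EMG recording
#'
#' Expects one header row with a `time_s` column followed by one column per
#' channel named `<muscle>_<side>`, numeric body, decimal point, UTF-8.
#'
#' @param path path to a delimited text file.
#' @param channel_map data.frame with columns `muscle`, `side` naming the
#'   channels that must be present.
#' @param fs sampling frequency in Hz; if `NULL`, inferred from the median
#'   spacing of `time_s`.
#' @param meta session metadata list attached to the recording.
#' @return [emg_recording()] object.
#' @export
read_recording <- function(path, channel_map = default_channel_map(),
                           fs = NULL, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = TRUE, showProgress = FALSE)
    ),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L || ncol(dt) == 0L) {
    stop("parse error: '", path, "' has no data rows", call. = FALSE)
  }
  wanted <- channel_names(channel_map)
  missing <- setdiff(wanted, names(dt))
  if (length(missing)) {
    stop("missing channel(s) in '", path, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cn in c(intersect("time_s", names(dt)), wanted)) {
    col <- dt[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("parse error in '", path, "', column '", cn, "': non-numeric ",
           "value at data row ", if (length(bad)) bad[1] else NA,
           call. = FALSE)
    }
  }
  if (is.null(fs)) {
    if (!"time_s" %in% names(dt) || nrow(dt) < 2L) {
      stop("cannot infer fs: no usable time_s column", call. = FALSE)
    }
    fs <- 1 / stats::median(diff(dt[["time_s"]]))
  }
  samples <- lapply(wanted, function(cn) as.numeric(dt[[cn]]))
  names(samples) <- wanted
  emg_recording(samples, fs = fs, channel_map = channel_map, meta = meta)
}

#' Write an EMG recording to a signal CSV
#'
#' Inverse of [read_recording()]: writes `time_s` plus one column per
#' channel.
#'
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- length(rec$samples[[1]])
  dt <- data.table::as.data.table(
    c(list(time_s = (seq_len(n) - 1L) / rec$fs), rec$samples)
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Remove nonphysiological spikes by robust thresholding
#'
#' Flags samples that are both (a) larger in absolute value than `k` times
#' the robust scale of the rectified signal (median absolute deviation
#' scaled to a normal-sigma equivalent) and (b) isolated: at least
#' `isolation` times larger than every neighbor within `halo` samples.
#' Flagged samples are replaced by linear interpolation between the nearest
#' retained neighbors. Sensor-contact artifacts in field EMG are isolated
#' single-sample excursions, whereas genuine activation bursts are
#' band-limited and therefore strongly correlated with their neighbors;
#' the isolation criterion keeps burst peaks of a bursty task signal out of
#' the spike set even though the baseline-dominated robust scale is small.
#'
#' @param samples numeric vector, length >= 100.
#' @param k threshold multiplier (> 1; default 25).
#' @param isolation required ratio between a spike and its largest
#'   neighbor (default 3).
#' @param halo neighborhood half-width in samples (default 3).
#' @return list with `samples` (cleaned vector), `replaced` (integer indices
#'   of replaced samples) and `threshold` (the absolute-amplitude cutoff).
#' @export
remove_spikes <- function(samples, k = 25, isolation = 3, halo = 3L) {
  stopifnot(is.numeric(samples))
  if (length(samples) < 100L) {
    stop("remove_spikes requires at least 100 samples", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 1) {
    stop("`k` must be a single number > 1", call. = FALSE)
  }
  stopifnot(isolation > 1, halo >= 1)
  scale <- stats::mad(abs(samples))
  if (scale == 0) {
    warning("zero robust scale (constant signal); no spikes removed",
            call. = FALSE)
    return(list(samples = samples, replaced = integer(0), threshold = Inf))
  }
  threshold <- k * scale
  n <- length(samples)
  ax <- abs(samples)
  candidates <- which(ax > threshold)
  idx <- candidates[vapply(candidates, function(i) {
    nb <- c(max(1L, i - halo):max(1L, i - 1L),
            min(n, i + 1L):min(n, i + halo))
    nb <- setdiff(unique(nb), i)
    ax[i] > isolation * max(ax[nb])
  }, logical(1))]
  if (length(idx)) {
    good <- setdiff(seq_len(n), idx)
    samples[idx] <- stats::approx(good, samples[good], xout = idx,
                                  rule = 2)$y
  }
  list(samples = samples, replaced = idx, threshold = threshold)
}

# Effective-order zero-phase Butterworth design. `order` counts the
# magnitude roll-off order of the forward-backward cascade: one pass uses a
# design of half the effective order. A band-pass section doubles the
# prototype order again, hence the divide-by-four there.
zero_phase_butter <- function(order, w, type) {
  if (type == "pass") {
    if (order %% 4 != 0) {
      stop("band-pass effective order must be a multiple of 4", call. = FALSE)
    }
    n <- order / 4L
  } else {
    if (order %% 2 != 0) {
      stop("low-pass effective order must be even", call. = FALSE)
    }
    n <- order / 2L
  }
  signal::butter(n, w, type = type)
}

#' Zero-lag Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]), giving zero phase lag and an effective magnitude
#' order of `order`. Defaults follow standard surface-EMG conditioning:
#' 20--450 Hz, fourth order.
#'
#' @param samples numeric vector.
#' @param fs sampling frequency in Hz.
#' @param f_lo,f_hi band edges in Hz; `0 < f_lo < f_hi < fs/2`.
#' @param order effective filter order (multiple of 4 for a band-pass).
#' @return filtered numeric vector, same length as input.
#' @export
bandpass <- function(samples, fs, f_lo = 20, f_hi = 450, order = 4) {
  stopifnot(is.numeric(samples), fs > 0)
  if (!(f_lo > 0 && f_lo < f_hi)) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  if (f_hi >= fs / 2) {
    stop("f_hi must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  if (all(samples == 0)) return(samples)
  bt <- zero_phase_butter(order, c(f_lo, f_hi) / (fs / 2), "pass")
  as.numeric(signal::filtfilt(bt, samples))
}

#' Full-wave rectification
#'
#' @param samples numeric vector.
#' @return elementwise absolute value.
#' @export
rectify <- function(samples) abs(samples)

#' Linear envelope: zero-lag low-pass of a rectified signal
#'
#' Low-pass filters a rectified EMG signal forward and backward to produce
#' the linear envelope. Output is clamped at zero: an amplitude envelope is
#' non-negative by definition and the clamp removes the small filter
#' undershoot near sharp onsets.
#'
#' @param samples rectified numeric vector.
#' @param fs sampling frequency in Hz.
#' @param f_c low-pass cutoff in Hz (default 10).
#' @param order effective filter order (even; default 4).
#' @return envelope vector, same length, all values >= 0.
#' @export
envelope <- function(samples, fs, f_c = 10, order = 4) {
  stopifnot(is.numeric(samples), fs > 0)
  if (!(f_c > 0 && f_c < fs / 2)) {
    stop("need 0 < f_c < fs/2", call. = FALSE)
  }
  if (all(samples == 0)) return(samples)
  bt <- zero_phase_butter(order, f_c / (fs / 2), "low")
  pmax(as.numeric(signal::filtfilt(bt, samples)), 0)
}

#' Condition one raw channel into its linear envelope
#'
#' Convenience chain: spike removal, band-pass, rectification, envelope,
#' with the conventional defaults for each stage.
#'
#' @param samples raw numeric vector.
#' @param fs sampling frequency in Hz.
#' @param spike_k spike threshold multiplier; `NULL` skips spike removal.
#' @param f_lo,f_hi band-pass edges in Hz.
#' @param band_order effective band-pass order.
#' @param f_c envelope low-pass cutoff in Hz.
#' @param env_order effective envelope order.
#' @return envelope vector.
#' @export
process_signal <- function(samples, fs, spike_k = 25, f_lo = 20, f_hi = 450,
                           band_order = 4, f_c = 10, env_order = 4) {
  if (!is.null(spike_k)) {
    samples <- remove_spikes(samples, k = spike_k)$samples
  }
  x <- bandpass(samples, fs, f_lo = f_lo, f_hi = f_hi, order = band_order)
  envelope(rectify(x), fs, f_c = f_c, order = env_order)
}

#' MVIC reference amplitude from an envelope
#'
#' Slides a window of `window_s` seconds across the envelope of a maximum
#' voluntary isometric contraction trial, one sample at a time, and returns
#' the highest windowed mean. This is the per-channel 100 %MVC reference.
#'
#' @param envelope_samples envelope numeric vector (from [envelope()]).
#' @param fs sampling frequency in Hz.
#' @param window_s window length in seconds (default 1).
#' @return single numeric reference amplitude.
#' @export
mvic_reference <- function(envelope_samples, fs, window_s = 1) {
  stopifnot(is.numeric(envelope_samples), fs > 0, window_s > 0)
  n <- length(envelope_samples)
  n_w <- as.integer(round(window_s * fs))
  if (n < n_w) {
    stop("signal shorter than the MVIC window", call. = FALSE)
  }
  cs <- c(0, cumsum(envelope_samples))
  means <- (cs[(n_w + 1L):(n + 1L)] - cs[1L:(n - n_w + 1L)]) / n_w
  max(means)
}

#' Normalized 1-s interval amplitude series
#'
#' Averages the envelope over consecutive non-overlapping intervals of
#' `interval_s` seconds and expresses each interval mean in %MVC relative to
#' the MVIC reference. A trailing partial interval is discarded. The first
#' and last intervals are flagged (`edge`) as potentially affected by filter
#' transients; they are kept in the series so total work time is preserved.
#'
#' @param envelope_samples envelope numeric vector.
#' @param fs sampling frequency in Hz.
#' @param mvic MVIC reference amplitude (> 0), same units as the envelope.
#' @param interval_s interval length in seconds (default 1).
#' @param muscle,side optional channel labels carried on the result.
#' @return object of class `normalized_series`: list with `values` (%MVC),
#'   `interval_s`, `muscle`, `side`, `n_intervals`, `edge` (logical flags).
#' @export
interval_series <- function(envelope_samples, fs, mvic, interval_s = 1,
                            muscle = NA_character_, side = NA_character_) {
  stopifnot(is.numeric(envelope_samples), fs > 0, interval_s > 0)
  if (!is.numeric(mvic) || length(mvic) != 1L || is.na(mvic) || mvic <= 0) {
    stop("normalization error: MVIC reference must be > 0", call. = FALSE)
  }
  spp <- as.integer(round(fs * interval_s))
  n_int <- length(envelope_samples) %/% spp
  if (n_int < 1L) {
    stop("signal shorter than one interval", call. = FALSE)
  }
  m <- matrix(envelope_samples[seq_len(n_int * spp)], nrow = spp)
  values <- 100 * colMeans(m) / mvic
  edge <- rep(FALSE, n_int)
  edge[c(1L, n_int)] <- TRUE
  structure(
    list(values = values, interval_s = interval_s, muscle = muscle,
         side = side, n_intervals = n_int, edge = edge),
    class = "normalized_series"
  )
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> %s/%s: %d x %.3g-s intervals, %.1f-%.1f %%MVC\n",
              x$muscle, x$side, x$n_intervals, x$interval_s,
              min(x$values), max(x$values)))
  invisible(x)
}
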