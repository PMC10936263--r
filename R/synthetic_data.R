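# MVIC postures and the muscle each one targets.
MVIC_POSTURES <- c(
  shoulder_flexion = "anterior_deltoid",
  elbow_flexion = "biceps_brachii",
  shoulder_abduction = "upper_trapezius",
  spinal_extension = "lumbar_erector_spinae"
)

#' Band-limited Gaussian carrier noise
#'
#' White Gaussian noise filtered to the surface-EMG band (default
#' 20--450 Hz) with a zero-phase Butterworth band-pass, then scaled to unit
#' RMS. Amplitude modulation of this carrier is the amplitude model for all
#' synthetic EMG in the package.
#'
#' @param n number of samples.
#' @param fs sampling frequency in Hz (> 900, so 450 Hz content exists).
#' @param f_lo,f_hi band edges in Hz.
#' @return numeric vector of length `n`, unit RMS.
#' @export
band_limited_noise <- function(n, fs, f_lo = 20, f_hi = 450) {
  stopifnot(n > 0, fs > 900)
  x <- stats::rnorm(n)
  bt <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bt, x))
  x / sqrt(mean(x^2))
}

# Piecewise-constant %MVC modulation for one cycle, with cosine ramps of
# width ramp_s at burst edges.
cycle_modulation <- function(profile, baseline_pct, cycle_time_s, fs,
                             ramp_s) {
  n <- as.integer(round(cycle_time_s * fs))
  t <- (seq_len(n) - 0.5) / fs
  m <- rep(baseline_pct, n)
  for (burst in profile) {
    on <- burst$onset * cycle_time_s
    off <- burst$offset * cycle_time_s
    s <- numeric(n)
    up <- t >= on & t < on + ramp_s
    s[up] <- 0.5 * (1 - cos(pi * (t[up] - on) / ramp_s))
    s[t >= on + ramp_s & t <= off - ramp_s] <- 1
    down <- t > off - ramp_s & t <= off
    s[down] <- 0.5 * (1 - cos(pi * (off - t[down]) / ramp_s))
    m <- m + (burst$plateau - baseline_pct) * s
  }
  m
}

#' Specification of a synthetic cyclic assembly-task session
#'
#' Parameterizes a cyclic work session: each cycle contains, per muscle, one
#' activation burst (onset/offset as cycle fractions, plateau amplitude in
#' %MVC) over a low resting baseline, with cosine-smoothed transitions,
#' occasional nonphysiological single-sample spikes, and band-limited
#' Gaussian carrier noise. Defaults emulate a repetitive overhead assembly
#' process: roughly 70-s cycles repeated for about 10 minutes, an anterior
#' deltoid plateau of 40 %MVC over 30% of the cycle, and lighter arm/trunk
#' involvement elsewhere.
#'
#' @param cycle_time_s cycle time in seconds.
#' @param n_cycles number of cycles in the session.
#' @param fs sampling frequency in Hz (> 900).
#' @param baseline_pct resting amplitude in %MVC.
#' @param profiles named list (by muscle) of lists with `onset`, `offset`
#'   (cycle fractions, 0 <= onset < offset <= 1) and `plateau` (%MVC).
#' @param sides sides simulated for every muscle.
#' @param ramp_s cosine transition width in seconds.
#' @param spike_rate_per_min expected nonphysiological spikes per minute.
#' @param spike_magnitude spike amplitude as a multiple of channel RMS.
#' @param amplitude_scale voltage scale of a 100 %MVC contraction
#'   (arbitrary units; cancels under MVIC normalization).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param meta session metadata list passed to [emg_recording()].
#' @return object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(cycle_time_s = 70, n_cycles = 9, fs = 1926,
                                baseline_pct = 2,
                                profiles = list(
                                  anterior_deltoid = list(onset = 0.1, offset = 0.4, plateau = 40),
                                  biceps_brachii = list(onset = 0.15, offset = 0.35, plateau = 20),
                                  upper_trapezius = list(onset = 0.1, offset = 0.35, plateau = 25),
                                  lumbar_erector_spinae = list(onset = 0.2, offset = 0.6, plateau = 15)
                                ),
                                sides = c("left", "right"), ramp_s = 0.1,
                                spike_rate_per_min = 2,
                                spike_magnitude = 30,
                                amplitude_scale = 1e-3, seed = NULL,
                                meta = list()) {
  stopifnot(cycle_time_s > 0, n_cycles >= 1, fs > 900, baseline_pct >= 0,
            ramp_s > 0, spike_rate_per_min >= 0, spike_magnitude > 1,
            amplitude_scale > 0)
  stopifnot(length(profiles) >= 1, all(names(profiles) %in% EMG_MUSCLES))
  for (mn in names(profiles)) {
    b <- profiles[[mn]]
    if (!(b$onset >= 0 && b$onset < b$offset && b$offset <= 1)) {
      stop("profile '", mn, "': need 0 <= onset < offset <= 1",
           call. = FALSE)
    }
    if (!(b$plateau > baseline_pct)) {
      stop("profile '", mn, "': plateau must exceed the baseline",
           call. = FALSE)
    }
    if ((b$offset - b$onset) * cycle_time_s < 2 * ramp_s) {
      stop("profile '", mn, "': burst shorter than two transition ramps",
           call. = FALSE)
    }
  }
  structure(
    list(cycle_time_s = cycle_time_s, n_cycles = n_cycles, fs = fs,
         baseline_pct = baseline_pct, profiles = profiles, sides = sides,
         ramp_s = ramp_s, spike_rate_per_min = spike_rate_per_min,
         spike_magnitude = spike_magnitude,
         amplitude_scale = amplitude_scale, seed = seed, meta = meta),
    class = "synthetic_task_spec"
  )
}

#' Closed-form ground truth for a synthetic task spec
#'
#' Duty cycle and mean active amplitude implied by the piecewise modulation
#' profile at a given activity threshold, integrating the cosine transition
#' ramps exactly. The baseline must sit below the threshold.
#'
#' @param spec a [synthetic_task_spec()].
#' @param threshold activity threshold in %MVC (default 5).
#' @return data.frame with one row per muscle: `muscle`, `true_duty`,
#'   `true_maa` (`NA` when the muscle never crosses the threshold).
#' @export
session_ground_truth <- function(spec, threshold = 5) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  if (spec$baseline_pct >= threshold) {
    stop("ground truth assumes baseline below the activity threshold",
         call. = FALSE)
  }
  rows <- lapply(names(spec$profiles), function(mn) {
    b <- spec$profiles[[mn]]
    if (b$plateau <= threshold) {
      return(data.frame(muscle = mn, true_duty = 0, true_maa = NA_real_,
                        stringsAsFactors = FALSE))
    }
    T_cyc <- spec$cycle_time_s
    w <- spec$ramp_s
    base <- spec$baseline_pct
    delta <- b$plateau - base
    burst_len <- (b$offset - b$onset) * T_cyc
    # threshold crossing inside the cosine ramp
    u_star <- (threshold - base) / delta
    tau <- (w / pi) * acos(1 - 2 * u_star)
    active_len <- burst_len - 2 * tau
    # integral of the ramp shape s(t) over the active part of one ramp
    int_s <- 0.5 * ((w - tau) + (w / pi) * sin(pi * tau / w))
    int_ramp <- base * (w - tau) + delta * int_s
    int_plateau <- b$plateau * (burst_len - 2 * w)
    data.frame(
      muscle = mn,
      true_duty = active_len / T_cyc,
      true_maa = (2 * int_ramp + int_plateau) / active_len,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Inject isolated single-sample spikes; returns samples + indices.
inject_spikes <- function(samples, fs, rate_per_min, magnitude) {
  dur_min <- length(samples) / fs / 60
  n_spikes <- stats::rpois(1, rate_per_min * dur_min)
  if (n_spikes == 0) {
    return(list(samples = samples, spike_idx = integer(0)))
  }
  margin <- 100L
  idx <- sort(sample((margin + 1L):(length(samples) - margin), n_spikes))
  # keep spikes isolated so detection ground truth is unambiguous
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 10L)]
  rms <- sqrt(mean(samples^2))
  samples[idx] <- sign(stats::runif(n_spikes) - 0.5) * magnitude * rms
  list(samples = samples, spike_idx = idx)
}

#' Simulate a maximum voluntary isometric contraction trial
#'
#' A 5-s trial: the first 2 s ramp linearly up to maximum contraction and
#' the last 3 s hold the maximum. The plateau modulation level defines the
#' 100 %MVC reference scale for the posture's target muscle; non-target
#' channels carry light (5 %MVC) activity.
#'
#' @param muscle target muscle for this posture.
#' @param fs sampling frequency in Hz (> 900).
#' @param seed integer seed, or `NULL`.
#' @param channel_map channels present in the trial.
#' @param amplitude_scale voltage scale of a 100 %MVC contraction; must
#'   match the session generator for normalization to cancel.
#' @param meta metadata list.
#' @return [emg_recording()] of 5 s.
#' @export
simulate_mvic_trial <- function(muscle, fs = 1926, seed = NULL,
                                channel_map = default_channel_map(),
                                amplitude_scale = 1e-3, meta = list()) {
  stopifnot(muscle %in% EMG_MUSCLES, fs > 900)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(5 * fs))
  t <- (seq_len(n) - 0.5) / fs
  m_target <- ifelse(t < 2, t / 2, 1)
  m_rest <- 0.05 * m_target
  samples <- lapply(seq_len(nrow(channel_map)), function(i) {
    m <- if (channel_map$muscle[i] == muscle) m_target else m_rest
    amplitude_scale * m * band_limited_noise(n, fs)
  })
  names(samples) <- channel_names(channel_map)
  meta$posture_muscle <- muscle
  emg_recording(samples, fs = fs, channel_map = channel_map, meta = meta)
}

#' Simulate one cyclic work session with known ground truth
#'
#' Generates a multi-channel recording whose per-channel amplitude follows
#' the spec's %MVC modulation profile (relative to the MVIC plateau scale),
#' riding on independent band-limited Gaussian carriers, with
#' nonphysiological spikes injected at the stated rate.
#'
#' @param spec a [synthetic_task_spec()].
#' @return list with `recording` ([emg_recording()]), `truth`
#'   ([session_ground_truth()] at 5 %MVC), and `spike_idx` (named list of
#'   injected spike indices per channel).
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  muscles <- names(spec$profiles)
  channel_map <- data.frame(
    muscle = rep(muscles, each = length(spec$sides)),
    side = rep(spec$sides, times = length(muscles)),
    stringsAsFactors = FALSE
  )
  n_cycle <- as.integer(round(spec$cycle_time_s * spec$fs))
  n <- n_cycle * spec$n_cycles
  mods <- lapply(muscles, function(mn) {
    rep(cycle_modulation(spec$profiles[mn], spec$baseline_pct,
                         spec$cycle_time_s, spec$fs, spec$ramp_s),
        spec$n_cycles)
  })
  names(mods) <- muscles
  samples <- vector("list", nrow(channel_map))
  spike_idx <- vector("list", nrow(channel_map))
  for (i in seq_len(nrow(channel_map))) {
    carrier <- band_limited_noise(n, spec$fs)
    x <- spec$amplitude_scale * (mods[[channel_map$muscle[i]]] / 100) *
      carrier
    sp <- inject_spikes(x, spec$fs, spec$spike_rate_per_min,
                        spec$spike_magnitude)
    samples[[i]] <- sp$samples
    spike_idx[[i]] <- sp$spike_idx
  }
  names(samples) <- channel_names(channel_map)
  names(spike_idx) <- names(samples)
  rec <- emg_recording(samples, fs = spec$fs, channel_map = channel_map,
                       meta = spec$meta)
  list(recording = rec, truth = session_ground_truth(spec),
       spike_idx = spike_idx)
}

#' Specification of a paired with/without-exoskeleton cohort
#'
#' Emulates the field-study shape: `n_processes` assembly processes, most
#' performed by two team members and the rest by one, each member recorded
#' once with and once without the exoskeleton. The exoskeleton effect on a
#' muscle's plateau amplitude is drawn per process (mean + between-process
#' SD) with an additional within-process (member) component.
#'
#' @param n_processes number of assembly processes (default 16).
#' @param members_per_process integer vector of team members per process;
#'   default 2 members for three quarters of the processes and 1 for the
#'   rest.
#' @param effects named list (by muscle) of lists with `mean`,
#'   `between_sd`, `within_sd`, the exoskeleton-induced plateau change in
#'   %MVC. Muscles not named get no effect.
#' @param base_plateau named list (by muscle) of `c(min, max)` ranges the
#'   without-exoskeleton plateau is drawn from (uniform, per process).
#' @param active_fraction `c(min, max)` range of the per-process burst
#'   fraction of the cycle.
#' @param cycle_time_s,n_cycles,fs,sides,baseline_pct session parameters
#'   passed to [synthetic_task_spec()].
#' @param muscles muscles to simulate.
#' @param seed integer seed for the whole cohort.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_processes = 16,
                                  members_per_process = NULL,
                                  effects = list(
                                    anterior_deltoid = list(mean = -5, between_sd = 5, within_sd = 2)
                                  ),
                                  base_plateau = list(
                                    anterior_deltoid = c(20, 45),
                                    biceps_brachii = c(10, 30),
                                    upper_trapezius = c(12, 35),
                                    lumbar_erector_spinae = c(8, 25)
                                  ),
                                  active_fraction = c(0.2, 0.5),
                                  cycle_time_s = 70, n_cycles = 9,
                                  fs = 1926, sides = c("left", "right"),
                                  baseline_pct = 2,
                                  muscles = EMG_MUSCLES, seed = 1L) {
  stopifnot(n_processes >= 2)
  if (is.null(members_per_process)) {
    n2 <- round(0.75 * n_processes)
    members_per_process <- rep(c(2L, 1L), c(n2, n_processes - n2))
  }
  stopifnot(length(members_per_process) == n_processes,
            all(members_per_process >= 1))
  for (ef in effects) {
    stopifnot(ef$between_sd >= 0, ef$within_sd >= 0)
  }
  stopifnot(all(muscles %in% EMG_MUSCLES),
            all(names(effects) %in% EMG_MUSCLES))
  structure(
    list(n_processes = n_processes,
         members_per_process = as.integer(members_per_process),
         effects = effects, base_plateau = base_plateau,
         active_fraction = active_fraction, cycle_time_s = cycle_time_s,
         n_cycles = n_cycles, fs = fs, sides = sides,
         baseline_pct = baseline_pct, muscles = muscles,
         seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
}

#' Simulate a paired with/without-exoskeleton cohort
#'
#' Draws per-process task parameters and exoskeleton effects, then
#' generates paired sessions (and one MVIC trial per posture per
#' participant). With `dir` given, signal CSVs, MVIC CSVs, a
#' `manifest.yaml` and a `truth.csv` are written there (paths in the
#' manifest are relative to `dir`); otherwise recordings are returned in
#' memory (only sensible at reduced session sizes).
#'
#' @param cspec a [synthetic_cohort_spec()].
#' @param dir output directory, or `NULL` for in-memory results.
#' @return list with `truth` (data.frame: process, member, muscle,
#'   plateau_without, plateau_with, delta), `manifest` (session/MVIC
#'   bookkeeping), and, in memory mode, `sessions` and `mvic` recordings.
#' @export
simulate_cohort <- function(cspec, dir = NULL) {
  stopifnot(inherits(cspec, "synthetic_cohort_spec"))
  set.seed(cspec$seed)
  np <- cspec$n_processes
  # per-process task draws
  frac <- stats::runif(np, cspec$active_fraction[1], cspec$active_fraction[2])
  base <- lapply(cspec$muscles, function(mn) {
    rng <- cspec$base_plateau[[mn]]
    if (is.null(rng)) rng <- c(10, 30)
    stats::runif(np, rng[1], rng[2])
  })
  names(base) <- cspec$muscles
  proc_effect <- lapply(cspec$muscles, function(mn) {
    ef <- cspec$effects[[mn]]
    if (is.null(ef)) rep(0, np)
    else stats::rnorm(np, ef$mean, ef$between_sd)
  })
  names(proc_effect) <- cspec$muscles
  # independent sub-seeds for each session/trial
  max_members <- max(cspec$members_per_process)
  seed_pool <- sample.int(.Machine$integer.max - 1L,
                          np * max_members * 10L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seed_pool[seed_i]
  }

  if (!is.null(dir)) {
    dir.create(file.path(dir, "signals"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "mvic"), showWarnings = FALSE)
  }
  sessions <- list()
  mvic <- list()
  manifest_sessions <- list()
  manifest_mvic <- list()
  truth <- list()

  for (p in seq_len(np)) {
    onset <- 0.1
    offset <- min(1, onset + frac[p])
    for (m in seq_len(cspec$members_per_process[p])) {
      pid <- sprintf("P%02dM%d", p, m)
      member_shift <- vapply(cspec$muscles, function(mn) {
        ef <- cspec$effects[[mn]]
        if (is.null(ef) || ef$within_sd == 0) 0
        else stats::rnorm(1, 0, ef$within_sd)
      }, numeric(1))
      for (cond in c("without_exo", "with_exo")) {
        profiles <- list()
        for (mn in cspec$muscles) {
          plateau <- base[[mn]][p]
          if (cond == "with_exo") {
            plateau <- plateau + proc_effect[[mn]][p] + member_shift[[mn]]
          }
          plateau <- max(cspec$baseline_pct + 1, plateau)
          profiles[[mn]] <- list(onset = onset, offset = offset,
                                 plateau = plateau)
          truth[[length(truth) + 1L]] <- data.frame(
            process = p, member = m, muscle = mn, condition = cond,
            plateau = plateau, active_fraction = offset - onset,
            stringsAsFactors = FALSE
          )
        }
        spec <- synthetic_task_spec(
          cycle_time_s = cspec$cycle_time_s, n_cycles = cspec$n_cycles,
          fs = cspec$fs, baseline_pct = cspec$baseline_pct,
          profiles = profiles, sides = cspec$sides, seed = next_seed(),
          meta = list(participant = pid, process = p, condition = cond)
        )
        sim <- simulate_session(spec)
        entry <- list(participant = pid, process = p, member = m,
                      condition = cond)
        if (is.null(dir)) {
          sessions[[length(sessions) + 1L]] <-
            c(entry, list(recording = sim$recording, truth = sim$truth))
        } else {
          rel <- file.path("signals", paste0(pid, "_", cond, ".csv"))
          write_recording(sim$recording, file.path(dir, rel))
          entry$signal <- rel
          manifest_sessions[[length(manifest_sessions) + 1L]] <- entry
        }
      }
      cm <- data.frame(
        muscle = rep(cspec$muscles, each = length(cspec$sides)),
        side = rep(cspec$sides, times = length(cspec$muscles)),
        stringsAsFactors = FALSE
      )
      for (posture in names(MVIC_POSTURES)) {
        mn <- MVIC_POSTURES[[posture]]
        if (!mn %in% cspec$muscles) next
        trial <- simulate_mvic_trial(mn, fs = cspec$fs, seed = next_seed(),
                                     channel_map = cm,
                                     meta = list(participant = pid))
        if (is.null(dir)) {
          mvic[[length(mvic) + 1L]] <-
            list(participant = pid, muscle = mn, recording = trial)
        } else {
          rel <- file.path("mvic", paste0(pid, "_", posture, ".csv"))
          write_recording(trial, file.path(dir, rel))
          manifest_mvic[[length(manifest_mvic) + 1L]] <-
            list(participant = pid, file = rel, muscles = list(mn))
        }
      }
    }
  }

  truth <- do.call(rbind, truth)
  # paired delta per (process, member, muscle)
  wide <- merge(
    truth[truth$condition == "without_exo",
          c("process", "member", "muscle", "plateau", "active_fraction")],
    truth[truth$condition == "with_exo",
          c("process", "member", "muscle", "plateau")],
    by = c("process", "member", "muscle"),
    suffixes = c("_without", "_with")
  )
  wide$delta <- wide$plateau_with - wide$plateau_without
  wide <- wide[order(wide$process, wide$member, wide$muscle), ]
  rownames(wide) <- NULL

  manifest <- list(
    fs = cspec$fs,
    muscles = as.list(cspec$muscles),
    sides = as.list(cspec$sides),
    sessions = manifest_sessions,
    mvic = manifest_mvic
  )
  if (!is.null(dir)) {
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    data.table::fwrite(wide, file.path(dir, "truth.csv"))
    return(invisible(list(truth = wide, manifest = manifest, dir = dir)))
  }
  list(truth = wide, manifest = manifest, sessions = sessions, mvic = mvic)
}

#' Metrics-level paired cohort draws
#'
#' Draws paired per-process metric values (e.g. fatigue risk values)
#' directly at the metrics level: the paired difference for each process is
#' `effect_mean` plus between-process normal noise. A reduced-scale
#' surrogate for full signal-level cohorts, used for operating-
#' characteristic studies of the comparison stage.
#'
#' @param n_processes number of paired processes.
#' @param effect_mean mean with-minus-without difference (%MVC).
#' @param between_sd between-process SD of the difference (%MVC).
#' @param level_mean,level_sd distribution of the without-exoskeleton
#'   level.
#' @param seed integer seed, or `NULL`.
#' @return data.frame with columns `process`, `without`, `with_`.
#' @export
simulate_metric_pairs <- function(n_processes = 16, effect_mean = -5,
                                  between_sd = 5, level_mean = 5,
                                  level_sd = 5, seed = NULL) {
  stopifnot(n_processes >= 2, between_sd >= 0, level_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  without <- stats::rnorm(n_processes, level_mean, level_sd)
  diffs <- stats::rnorm(n_processes, effect_mean, between_sd)
  data.frame(process = seq_len(n_processes), without = without,
             with_ = without + diffs)
}
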