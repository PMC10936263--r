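# Shared fixtures and independent oracles for the test suite.

# Bare normalized series with known values (bypasses the signal chain).
make_series <- function(values, muscle = "anterior_deltoid",
                        side = "left", interval_s = 1) {
  n <- length(values)
  edge <- rep(FALSE, n)
  edge[c(1L, n)] <- TRUE
  structure(
    list(values = values, interval_s = interval_s, muscle = muscle,
         side = side, n_intervals = n, edge = edge),
    class = "normalized_series"
  )
}

# Digital frequency response |H(f)| of a signal::butter filter.
filter_gain <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  abs(sum(filt$b * z^(seq_along(filt$b) - 1)) /
        sum(filt$a * z^(seq_along(filt$a) - 1)))
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (independent of the package's dynamic-programming route).
wilcoxon_enum_p <- function(diffs) {
  d <- diffs[diffs != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Tiny two-channel map used where the full eight-channel layout is not the
# point.
small_map <- function() {
  data.frame(muscle = "anterior_deltoid", side = c("left", "right"),
             stringsAsFactors = FALSE)
}

# One-sided deltoid recording, MVIC trial and recovered metrics; the core
# recovery fixture used by several files.
recover_deltoid <- function(seed, plateau = 40, onset = 0.1, offset = 0.4,
                            cycle_time_s = 10, n_cycles = 6) {
  spec <- synthetic_task_spec(
    cycle_time_s = cycle_time_s, n_cycles = n_cycles,
    profiles = list(anterior_deltoid = list(onset = onset, offset = offset,
                                            plateau = plateau)),
    sides = "left", seed = seed
  )
  sim <- simulate_session(spec)
  mv <- simulate_mvic_trial(
    "anterior_deltoid", seed = seed + 5000L,
    channel_map = data.frame(muscle = "anterior_deltoid", side = "left")
  )
  ref <- mvic_reference(process_signal(mv$samples[[1]], mv$fs), mv$fs)
  env <- process_signal(sim$recording$samples[["anterior_deltoid_left"]],
                        spec$fs)
  series <- interval_series(env, spec$fs, ref,
                            muscle = "anterior_deltoid", side = "left")
  list(metrics = muscle_fatigue_metrics(series), truth = sim$truth,
       series = series, sim = sim)
}
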