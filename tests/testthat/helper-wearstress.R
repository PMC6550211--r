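# shared fixture builders (all fixtures are generated in code)

# schedule with explicit per-minute levels, bypassing the random generator
make_schedule <- function(level_per_min, activity = NULL) {
  n <- length(level_per_min)
  if (is.null(activity)) activity <- integer(n)
  structure(list(days = n / 1440, level = as.integer(level_per_min),
                 activity = as.integer(activity), duration_s = n * 60),
            class = "latent_schedule")
}

# canonical SCR kernel: 1-s linear rise, exponential decay (tau = 4 s)
scr_kernel <- function(amp, fs, len_s = 20) {
  kt <- (0:(len_s * fs - 1)) / fs
  amp * ifelse(kt < 1, kt, exp(-(kt - 1) / 4))
}

# constant signal with SCR bumps injected at given onset times
sc_with_bumps <- function(dur_s, fs, onsets_s, amps, base = 2) {
  x <- rep(base, dur_s * fs)
  for (e in seq_along(onsets_s)) {
    k <- scr_kernel(amps[e], fs)
    idx <- round(onsets_s[e] * fs) + seq_along(k)
    idx <- idx[idx <= length(x)]
    x[idx] <- x[idx] + k[seq_along(idx)]
  }
  x
}

# minimal labeled feature-row table for the assembly/filter tests
make_rows <- function(subject_id, window_start, state,
                      quality = 1, acc_sd = 0.01, ema_id = 1L, value = 0) {
  n <- length(window_start)
  df <- data.frame(subject_id = subject_id, window_start = window_start,
                   state = state, quality = quality, acc_sd = acc_sd,
                   ema_id = ema_id, stringsAsFactors = FALSE)
  for (f in feature_names()) df[[f]] <- value
  df
}

# brute-force Benjamini-Hochberg step-up rejection set (enumeration oracle)
bh_brute_force <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m)) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# a short clean subject (1-hour recordings) for windowing/cadence tests
make_hour_subject <- function(seed = 5, level = 1) {
  cfg <- sim_config()
  sched <- make_schedule(rep(level, 60))
  prof <- subject_profile("SX01", "responsive", seed = seed, config = cfg)
  list(profile = prof,
       schedule = sched,
       beats = simulate_beats(prof, sched, seed + 1, cfg),
       sc = simulate_sc(prof, sched, seed + 2, cfg),
       st = simulate_st(prof, sched, seed + 3, cfg),
       acc = simulate_acc(prof, sched, seed + 4, cfg))
}
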