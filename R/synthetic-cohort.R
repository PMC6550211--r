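#' Simulation configuration for the synthetic cohort
#'
#' Returns the full set of tunable parameters driving the synthetic cohort
#' generator. Defaults emulate a free-living ambulatory monitoring study:
#' five recording days, skin conductance processed at 8 Hz, skin temperature
#' at 1 Hz, accelerometer magnitude at 32 Hz, and EMA prompted 12 times per
#' day at least 30 minutes apart during waking hours. The daytime latent
#' stress distribution is skewed towards "no stress" (50.4\% level 1; the
#' three highest levels jointly 14.3\%, with 0.3\% at the extreme level).
#'
#' Stress-reactivity phenotypes: \emph{responsive} subjects have a large
#' physiological response to latent stress on every channel (heart rate up,
#' skin-conductance response rate up, skin temperature down), while
#' \emph{blunted} subjects respond weakly. Effect ranges are disjoint so the
#' responsive effect strictly dominates the blunted one on every channel.
#'
#' @param fs_sc,fs_st,fs_acc sampling rates (Hz) for skin conductance, skin
#'   temperature and accelerometer magnitude.
#' @param day_level_probs probabilities of latent stress levels 1..5 during
#'   daytime blocks; must sum to 1.
#' @param block_minutes duration of one piecewise-constant latent stress
#'   block, in minutes.
#' @param night_hours two clock hours \code{c(start, end)} delimiting the
#'   night interval (latent level forced to 1).
#' @param waking_hours clock-hour window within which EMA prompts are sent.
#' @param prompts_per_day number of EMA prompts per day.
#' @param min_prompt_gap_min minimum spacing between prompts, minutes.
#' @param misreport_prob probability that a reported stress level deviates by
#'   one Likert step (symmetric, clipped to 1..5) from the latent level.
#' @param hr_baseline_mean,hr_baseline_sd population distribution of resting
#'   heart rate, beats/min.
#' @param hr_night_dip additive nocturnal change in heart rate, beats/min.
#' @param hr_effect_responsive,hr_effect_blunted ranges (length-2) of the
#'   heart-rate increase (bpm) at maximal latent stress, by phenotype.
#' @param hr_wander_sd slow heart-rate wander, bpm.
#' @param lf_mod,hf_mod relative amplitudes of the 0.1 Hz and 0.3 Hz
#'   RR-interval modulations.
#' @param rr_noise_ms white beat-to-beat noise, milliseconds.
#' @param sc_tonic_mean mean daytime tonic skin conductance, microsiemens.
#' @param sc_night_shift additive nocturnal tonic shift, microsiemens.
#' @param sc_tonic_wander_sd slow tonic wander, microsiemens.
#' @param scr_rate_base baseline skin-conductance-response rate, events/min.
#' @param scr_rate_responsive,scr_rate_blunted ranges of the additional SCR
#'   rate (events/min) at maximal latent stress, by phenotype.
#' @param scr_amp_meanlog,scr_amp_sdlog log-normal SCR amplitude parameters
#'   (microsiemens).
#' @param scr_rise_s,scr_decay_s SCR shape: linear rise time and exponential
#'   decay time constant, seconds.
#' @param sc_noise_sd white sensor noise on skin conductance, microsiemens.
#' @param st_baseline_mean,st_baseline_sd population distribution of daytime
#'   skin temperature, degrees Celsius.
#' @param st_night_shift additive nocturnal skin-temperature shift, Celsius.
#' @param st_effect_responsive,st_effect_blunted ranges of the (negative)
#'   skin-temperature change at maximal latent stress, by phenotype.
#' @param st_wander_sd,st_noise_sd slow wander and white noise on skin
#'   temperature, Celsius.
#' @param acc_noise_sd accelerometer magnitude noise at rest, g.
#' @param acc_active_sd accelerometer magnitude noise during activity
#'   bouts, g (chosen above the 0.04 activity threshold).
#' @param activity_bouts_per_day number of high-intensity activity bouts per
#'   day.
#' @param activity_bout_minutes range of bout durations, minutes.
#' @return a named list of class \code{"sim_config"}.
#' @export
sim_config <- function(fs_sc = 8, fs_st = 1, fs_acc = 32,
                       day_level_probs = c(0.504, 0.353, 0.100, 0.040, 0.003),
                       block_minutes = 30,
                       night_hours = c(0, 6),
                       waking_hours = c(8, 22),
                       prompts_per_day = 12,
                       min_prompt_gap_min = 30,
                       misreport_prob = 0.1,
                       hr_baseline_mean = 70, hr_baseline_sd = 5,
                       hr_night_dip = -10,
                       hr_effect_responsive = c(8, 12),
                       hr_effect_blunted = c(1, 3),
                       hr_wander_sd = 2,
                       lf_mod = 0.03, hf_mod = 0.025,
                       rr_noise_ms = 10,
                       sc_tonic_mean = 1.7,
                       sc_night_shift = 1.1,
                       sc_tonic_wander_sd = 0.15,
                       scr_rate_base = 1,
                       scr_rate_responsive = c(2.4, 3.6),
                       scr_rate_blunted = c(0.3, 0.8),
                       scr_amp_meanlog = log(0.3), scr_amp_sdlog = 0.4,
                       scr_rise_s = 1, scr_decay_s = 4,
                       sc_noise_sd = 0.01,
                       st_baseline_mean = 31.4, st_baseline_sd = 0.8,
                       st_night_shift = 1.7,
                       st_effect_responsive = c(-1.0, -0.6),
                       st_effect_blunted = c(-0.25, -0.05),
                       st_wander_sd = 0.3, st_noise_sd = 0.05,
                       acc_noise_sd = 0.015, acc_active_sd = 0.08,
                       activity_bouts_per_day = 3,
                       activity_bout_minutes = c(20, 40)) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$day_level_probs) == 5L,
            abs(sum(cfg$day_level_probs) - 1) < 1e-8,
            all(cfg$day_level_probs >= 0))
  class(cfg) <- "sim_config"
  cfg
}

## bounded integer score helper (questionnaire instruments)
.score <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(rnorm(n, mean, sd))))
}

.derive_seed <- function(seed, i, salt = 0L) {
  as.integer((abs(seed) %% 1000000L) * 2017L + i * 7919L + salt * 104729L) %%
    2000000000L
}

#' Is a time-of-day inside the night interval?
#'
#' @param t_sec time in seconds since the start of day 0 (midnight).
#' @param night_hours clock hours delimiting the night, default 00:00-06:00.
#' @return logical vector.
#' @export
is_night <- function(t_sec, night_hours = c(0, 6)) {
  clock <- (t_sec %% 86400) / 3600
  clock >= night_hours[1] & clock < night_hours[2]
}

#' Create a synthetic subject profile
#'
#' Draws a latent stress-reactivity phenotype together with baseline
#' physiology and intake-questionnaire scores. Responsive subjects have
#' strictly larger physiological stress effects than blunted subjects on
#' every channel (the phenotype effect ranges in \code{\link{sim_config}} are
#' disjoint); blunted subjects score worse on the psychological baseline
#' (higher PSS, DASS and PSQI), mirroring the association between blunted
#' physiological reactivity and poorer self-reported health.
#'
#' @param subject_id opaque identifier string.
#' @param phenotype \code{"responsive"} or \code{"blunted"}.
#' @param seed integer RNG seed.
#' @param config a \code{\link{sim_config}}.
#' @return a list of class \code{"subject_profile"} with fields
#'   \code{subject_id}, \code{phenotype}, \code{baseline_hr},
#'   \code{baseline_sc}, \code{baseline_st}, \code{stress_effect} (list with
#'   \code{hr}, \code{scr_rate}, \code{st}), questionnaire scores
#'   (\code{pss}, \code{dass_depression}, \code{dass_anxiety},
#'   \code{dass_stress}, \code{psqi}), \code{age} and \code{gender}.
#' @export
subject_profile <- function(subject_id, phenotype = c("responsive", "blunted"),
                            seed = 1L, config = sim_config()) {
  phenotype <- match.arg(phenotype)
  set.seed(seed)
  resp <- phenotype == "responsive"
  eff_rng <- function(rng) runif(1, rng[1], rng[2])
  stress_effect <- list(
    hr = eff_rng(if (resp) config$hr_effect_responsive else config$hr_effect_blunted),
    scr_rate = eff_rng(if (resp) config$scr_rate_responsive else config$scr_rate_blunted),
    st = eff_rng(if (resp) config$st_effect_responsive else config$st_effect_blunted)
  )
  ## intake questionnaire: blunted reactivity associates with worse scores
  q <- if (resp) {
    list(pss = c(10.5, 5.5), dep = c(1.4, 2.1), anx = c(1.0, 1.7),
         str = c(3.1, 3.2), psqi = c(4.1, 2.3), age = c(41.7, 10))
  } else {
    list(pss = c(17.1, 5.6), dep = c(3.5, 3.4), anx = c(2.6, 2.9),
         str = c(6.5, 3.9), psqi = c(5.3, 2.5), age = c(38.6, 10))
  }
  profile <- list(
    subject_id = as.character(subject_id),
    phenotype = phenotype,
    baseline_hr = rnorm(1, config$hr_baseline_mean, config$hr_baseline_sd),
    baseline_sc = max(0.3, rnorm(1, config$sc_tonic_mean, 0.4)),
    baseline_st = rnorm(1, config$st_baseline_mean, config$st_baseline_sd),
    stress_effect = stress_effect,
    pss = .score(1, q$pss[1], q$pss[2], 0, 40),
    dass_depression = .score(1, q$dep[1], q$dep[2], 0, 21),
    dass_anxiety = .score(1, q$anx[1], q$anx[2], 0, 21),
    dass_stress = .score(1, q$str[1], q$str[2], 0, 21),
    psqi = .score(1, q$psqi[1], q$psqi[2], 0, 21),
    age = .score(1, q$age[1], q$age[2], 18, 65),
    gender = sample(c("F", "M"), 1)
  )
  class(profile) <- "subject_profile"
  profile
}

#' Simulate a latent stress schedule
#'
#' Piecewise-constant latent stress level (Likert 1..5) at one-minute
#' resolution over a multi-day horizon, plus a binary high-intensity activity
#' trace. The night interval (by default 00:00-06:00) is forced to level 1;
#' daytime blocks draw their level independently from
#' \code{config$day_level_probs}.
#'
#' @param days number of simulated days (>= 1).
#' @param seed integer RNG seed.
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{"latent_schedule"}: list with \code{days},
#'   \code{level} (integer per minute), \code{activity} (0/1 per minute) and
#'   \code{duration_s}.
#' @export
simulate_latent_schedule <- function(days, seed = 1L, config = sim_config()) {
  stopifnot(days >= 1)
  set.seed(seed)
  n_min <- days * 1440L
  blocks_per_day <- 1440L %/% config$block_minutes
  n_blocks <- days * blocks_per_day
  block_levels <- sample(1:5, n_blocks, replace = TRUE,
                         prob = config$day_level_probs)
  level <- rep(block_levels, each = config$block_minutes)[seq_len(n_min)]
  t_min <- seq_len(n_min) - 1L
  night <- is_night(t_min * 60, config$night_hours)
  level[night] <- 1L

  activity <- integer(n_min)
  wk <- config$waking_hours
  for (d in seq_len(days) - 1L) {
    for (b in seq_len(config$activity_bouts_per_day)) {
      dur <- round(runif(1, config$activity_bout_minutes[1],
                         config$activity_bout_minutes[2]))
      start <- d * 1440L + round(runif(1, wk[1] * 60, wk[2] * 60 - dur))
      idx <- (start + 1L):min(start + dur, n_min)
      activity[idx] <- 1L
    }
  }
  structure(list(days = days, level = level, activity = activity,
                 duration_s = n_min * 60),
            class = "latent_schedule")
}

#' Latent stress level / activity at given times
#'
#' @param schedule a \code{\link{simulate_latent_schedule}} object.
#' @param t_sec times in seconds from the recording start.
#' @return integer latent levels (or activity indicator).
#' @export
schedule_level <- function(schedule, t_sec) {
  idx <- pmin(floor(t_sec / 60) + 1L, length(schedule$level))
  schedule$level[pmax(idx, 1L)]
}

#' @rdname schedule_level
#' @export
schedule_activity <- function(schedule, t_sec) {
  idx <- pmin(floor(t_sec / 60) + 1L, length(schedule$activity))
  schedule$activity[pmax(idx, 1L)]
}

## smooth slow wander: spline through knots every `knot_s` seconds
.wander <- function(duration_s, sd, knot_s = 600, at = NULL) {
  kt <- seq(0, duration_s, by = knot_s)
  kv <- rnorm(length(kt), 0, sd)
  xout <- if (is.null(at)) seq(0, duration_s - 1) else at
  spline(kt, kv, xout = xout)$y
}

#' Construct a beat series from R-peak times
#'
#' @param times strictly increasing R-peak times, seconds.
#' @return list of class \code{"beat_series"} with \code{times} and derived
#'   \code{rr_ms} (successive differences, milliseconds).
#' @export
beat_series <- function(times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("R-peak times must be strictly increasing")
  structure(list(times = times, rr_ms = diff(times) * 1000),
            class = "beat_series")
}

#' Simulate an R-peak beat series
#'
#' Instantaneous heart rate is the subject baseline plus a phenotype-scaled
#' latent-stress effect, a nocturnal circadian dip and a slow wander. Beat
#' times are obtained by inverting the cumulative beat rate; RR intervals are
#' then modulated by 0.1 Hz (LF) and 0.3 Hz (HF) sinusoids plus white noise,
#' giving a tachogram with realistic low/high-frequency variability.
#'
#' @param profile a \code{\link{subject_profile}}.
#' @param schedule a \code{\link{simulate_latent_schedule}} object.
#' @param seed integer RNG seed.
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{beat_series}}.
#' @export
simulate_beats <- function(profile, schedule, seed = 1L, config = sim_config()) {
  set.seed(seed)
  dur <- schedule$duration_s
  t_sec <- seq(0, dur - 1)
  level <- schedule$level[floor(t_sec / 60) + 1L]
  hr <- profile$baseline_hr +
    profile$stress_effect$hr * (level - 1) / 4 +
    config$hr_night_dip * is_night(t_sec, config$night_hours) +
    .wander(dur, config$hr_wander_sd)
  hr <- pmax(hr, 35)
  ## invert the cumulative rate to obtain base beat times
  crate <- cumsum(hr / 60)
  n_beats <- floor(crate[length(crate)])
  base_t <- approx(c(0, crate), c(0, t_sec + 1), xout = seq_len(n_beats))$y
  rr <- diff(base_t)
  tmid <- base_t[-1]
  ph <- runif(2, 0, 2 * pi)
  rr <- rr * (1 + config$lf_mod * sin(2 * pi * 0.1 * tmid + ph[1]) +
                config$hf_mod * sin(2 * pi * 0.3 * tmid + ph[2])) +
    rnorm(length(rr), 0, config$rr_noise_ms / 1000)
  rr <- pmax(rr, 0.25)
  beat_series(base_t[1] + c(0, cumsum(rr)))
}

#' Construct a uniformly sampled channel recording
#'
#' @param channel one of \code{"SC"}, \code{"ST"}, \code{"ACC_MAG"}.
#' @param fs sampling rate, Hz.
#' @param samples numeric sample vector.
#' @param units unit string.
#' @param start start time in seconds (default 0).
#' @return list of class \code{"channel_recording"}.
#' @export
channel_recording <- function(channel = c("SC", "ST", "ACC_MAG"), fs, samples,
                              units = "", start = 0) {
  channel <- match.arg(channel)
  structure(list(channel = channel, fs = fs, start = start,
                 samples = as.numeric(samples), units = units),
            class = "channel_recording")
}

#' Duration of a channel recording in seconds
#' @param rec a \code{\link{channel_recording}}.
#' @return numeric seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Simulate skin conductance
#'
#' Tonic level = subject baseline + nocturnal shift + slow wander; phasic
#' component = superposed skin-conductance responses (SCRs) arriving as an
#' inhomogeneous Poisson process whose rate increases with latent stress
#' (phenotype-scaled). Each SCR rises linearly over \code{scr_rise_s} seconds
#' and decays exponentially with time constant \code{scr_decay_s}; amplitudes
#' are log-normal. White sensor noise is added and the result clipped at 0.
#'
#' @inheritParams simulate_beats
#' @return a \code{\link{channel_recording}} (channel \code{"SC"},
#'   microsiemens) with attribute \code{"scr_times"} holding ground-truth
#'   SCR onset times.
#' @export
simulate_sc <- function(profile, schedule, seed = 1L, config = sim_config()) {
  set.seed(seed)
  fs <- config$fs_sc
  dur <- schedule$duration_s
  n <- dur * fs
  t_min <- seq_len(dur / 60) - 1L
  tonic <- profile$baseline_sc +
    config$sc_night_shift * is_night((0:(n - 1)) / fs, config$night_hours) +
    .wander(dur, config$sc_tonic_wander_sd, knot_s = 1200,
            at = (0:(n - 1)) / fs)
  tonic <- pmax(tonic, 0.05)

  ## SCR arrivals: per-minute Poisson with stress-dependent rate
  rate_min <- config$scr_rate_base +
    profile$stress_effect$scr_rate * (schedule$level[t_min + 1L] - 1) / 4
  counts <- rpois(length(rate_min), rate_min)
  onsets <- rep(t_min * 60, counts) + runif(sum(counts), 0, 60)
  amps <- rlnorm(length(onsets), config$scr_amp_meanlog, config$scr_amp_sdlog)

  ## canonical SCR kernel: linear rise, exponential decay
  klen <- ceiling((config$scr_rise_s + 8 * config$scr_decay_s) * fs)
  kt <- (0:(klen - 1)) / fs
  kernel <- ifelse(kt < config$scr_rise_s, kt / config$scr_rise_s,
                   exp(-(kt - config$scr_rise_s) / config$scr_decay_s))
  phasic <- numeric(n)
  oi <- floor(onsets * fs) + 1L
  for (e in seq_along(oi)) {
    idx <- oi[e]:min(oi[e] + klen - 1L, n)
    phasic[idx] <- phasic[idx] + amps[e] * kernel[seq_along(idx)]
  }
  x <- pmax(tonic + phasic + rnorm(n, 0, config$sc_noise_sd), 0)
  rec <- channel_recording("SC", fs, x, units = "uS")
  attr(rec, "scr_times") <- onsets
  rec
}

#' Simulate skin temperature
#'
#' 1 Hz skin temperature: subject baseline, higher at night, decreased under
#' latent stress for responsive profiles, plus slow wander and white noise.
#'
#' @inheritParams simulate_beats
#' @return a \code{\link{channel_recording}} (channel \code{"ST"}, Celsius).
#' @export
simulate_st <- function(profile, schedule, seed = 1L, config = sim_config()) {
  set.seed(seed)
  fs <- config$fs_st
  dur <- schedule$duration_s
  t <- (0:(dur * fs - 1)) / fs
  level <- schedule$level[floor(t / 60) + 1L]
  x <- profile$baseline_st +
    config$st_night_shift * is_night(t, config$night_hours) +
    profile$stress_effect$st * (level - 1) / 4 +
    .wander(dur, config$st_wander_sd, knot_s = 1800, at = t) +
    rnorm(length(t), 0, config$st_noise_sd)
  channel_recording("ST", fs, x, units = "degC")
}

#' Simulate accelerometer magnitude
#'
#' 32 Hz magnitude of the 3-axis acceleration around 1 g; the per-sample
#' noise SD follows the schedule's activity trace so that high-intensity
#' bouts exceed the 0.04 windowed-SD activity threshold and rest periods stay
#' below it.
#'
#' @inheritParams simulate_beats
#' @return a \code{\link{channel_recording}} (channel \code{"ACC_MAG"}, g).
#' @export
simulate_acc <- function(profile, schedule, seed = 1L, config = sim_config()) {
  set.seed(seed)
  fs <- config$fs_acc
  dur <- schedule$duration_s
  sd_min <- ifelse(schedule$activity == 1L, config$acc_active_sd,
                   config$acc_noise_sd)
  x <- 1 + rnorm(dur * fs, 0, rep(sd_min, each = 60 * fs))
  channel_recording("ACC_MAG", fs, x, units = "g")
}

#' Simulate EMA stress self-reports
#'
#' Prompts are placed at random times within the waking window, at least
#' \code{min_prompt_gap_min} minutes apart, at most \code{prompts_per_day}
#' per day. The reported stress equals the latent level at the prompt time
#' with symmetric one-step misreport noise; pleasure is negatively coupled to
#' stress, arousal positively.
#'
#' @inheritParams simulate_beats
#' @return data.frame with columns \code{prompt_time} (s), \code{stress}
#'   (1..5), \code{pleasure}, \code{arousal}, \code{dominance} (1..9),
#'   \code{activity}, \code{consumption}.
#' @export
simulate_ema <- function(profile, schedule, seed = 1L, config = sim_config()) {
  set.seed(seed)
  gap_s <- config$min_prompt_gap_min * 60
  wk_s <- config$waking_hours * 3600
  npd <- config$prompts_per_day
  free <- (wk_s[2] - wk_s[1]) - (npd - 1) * gap_s
  stopifnot(free > 0)
  prompt_time <- unlist(lapply(seq_len(schedule$days) - 1L, function(d) {
    u <- sort(runif(npd, 0, free))
    d * 86400 + wk_s[1] + u + (seq_len(npd) - 1) * gap_s
  }))
  latent <- schedule_level(schedule, prompt_time)
  flip <- runif(length(latent)) < config$misreport_prob
  stress <- latent + ifelse(flip, sample(c(-1L, 1L), length(latent),
                                         replace = TRUE), 0L)
  stress <- pmin(5L, pmax(1L, stress))
  pleasure <- pmin(9L, pmax(1L, round(7 - 0.9 * stress +
                                        rnorm(length(stress), 0, 1))))
  arousal <- pmin(9L, pmax(1L, round(2 + 0.9 * stress +
                                       rnorm(length(stress), 0, 1))))
  dominance <- sample(3:7, length(stress), replace = TRUE)
  act <- schedule_activity(schedule, prompt_time)
  activity <- ifelse(act == 1L,
                     sample(c("walking", "running", "biking"), length(act),
                            replace = TRUE),
                     sample(c("sitting", "standing", "lying"), length(act),
                            replace = TRUE))
  consumption <- sample(c("none", "caffeine", "snack", "lunch", "dinner"),
                        length(stress), replace = TRUE,
                        prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
  data.frame(prompt_time = prompt_time, stress = as.integer(stress),
             pleasure = pleasure, arousal = arousal, dominance = dominance,
             activity = activity, consumption = consumption,
             stringsAsFactors = FALSE)
}

#' Simulate one complete subject
#'
#' @param profile a \code{\link{subject_profile}}.
#' @param days number of recording days.
#' @param seed integer RNG seed (sub-seeds are derived per component).
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{profile}, \code{schedule}, \code{beats},
#'   \code{sc}, \code{st}, \code{acc}, \code{ema}.
#' @export
simulate_subject <- function(profile, days = 5, seed = 1L,
                             config = sim_config()) {
  schedule <- simulate_latent_schedule(days, .derive_seed(seed, 1L), config)
  list(profile = profile,
       schedule = schedule,
       beats = simulate_beats(profile, schedule, .derive_seed(seed, 2L), config),
       sc = simulate_sc(profile, schedule, .derive_seed(seed, 3L), config),
       st = simulate_st(profile, schedule, .derive_seed(seed, 4L), config),
       acc = simulate_acc(profile, schedule, .derive_seed(seed, 5L), config),
       ema = simulate_ema(profile, schedule, .derive_seed(seed, 6L), config))
}

#' Generate a synthetic cohort
#'
#' Deterministically (given \code{seed}) generates \code{n_subjects} subjects
#' with known ground-truth phenotypes: the first
#' \code{round(responsive_fraction * n_subjects)} are responsive, the rest
#' blunted. Each subject carries multi-day SC/ST/ACC recordings, an R-peak
#' beat series and an EMA table.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out
#'   evaluation is undefined below that).
#' @param responsive_fraction fraction of responsive subjects in [0, 1].
#' @param seed integer master seed; per-subject sub-seeds are derived.
#' @param days recording days per subject.
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"wear_cohort"} of per-subject lists (see
#'   \code{\link{simulate_subject}}), with the generation settings stored in
#'   attributes.
#' @export
generate_cohort <- function(n_subjects, responsive_fraction = 0.5, seed = 1L,
                            days = 5, config = sim_config()) {
  if (n_subjects < 2) stop("n_subjects must be >= 2 (LOSO undefined)")
  if (responsive_fraction < 0 || responsive_fraction > 1)
    stop("responsive_fraction must be in [0, 1]")
  n_resp <- round(responsive_fraction * n_subjects)
  cohort <- lapply(seq_len(n_subjects), function(i) {
    phen <- if (i <= n_resp) "responsive" else "blunted"
    prof <- subject_profile(sprintf("S%03d", i), phen,
                            seed = .derive_seed(seed, i, 1L), config = config)
    simulate_subject(prof, days = days, seed = .derive_seed(seed, i, 2L),
                     config = config)
  })
  structure(cohort, class = "wear_cohort", seed = seed, days = days,
            n_subjects = n_subjects, responsive_fraction = responsive_fraction)
}

#' Artifact specification for \code{\link{inject_artifacts}}
#'
#' Rates are events per hour; each event corrupts an interval of the given
#' duration. Supported types: \code{sc_flatline} (signal drops below the
#' 0.001 uS lost threshold), \code{sc_jump} (a step violating the +20\%/s
#' slew rule), \code{st_excursion} (out of the 20-40 C range), \code{rr_gap}
#' (beats removed to create a gap > 3 s), \code{rr_ectopic} (a beat moved to
#' create a max/min RR ratio >= 2.2).
#'
#' @param sc_flatline,sc_jump,st_excursion,rr_gap,rr_ectopic event rates per
#'   hour.
#' @param flatline_s,flatline_value flatline duration (s) and level (uS).
#' @param jump_factor multiplicative step height for \code{sc_jump}.
#' @param jump_s duration of the jumped interval, seconds.
#' @param excursion_s,excursion_value ST excursion duration (s) and value (C).
#' @param gap_s RR gap length, seconds (> 3 to violate the gap rule).
#' @return named list of class \code{"artifact_spec"}.
#' @export
artifact_spec <- function(sc_flatline = 0, sc_jump = 0, st_excursion = 0,
                          rr_gap = 0, rr_ectopic = 0,
                          flatline_s = 10, flatline_value = 5e-4,
                          jump_factor = 1.5, jump_s = 5,
                          excursion_s = 10, excursion_value = 45,
                          gap_s = 3.5) {
  spec <- as.list(environment())
  class(spec) <- "artifact_spec"
  spec
}

#' Inject ground-truth artifacts into a recording or beat series
#'
#' Corrupts the input with the artifact types named in \code{spec} and
#' returns the corrupted object together with the ground-truth artifact
#' intervals, so quality-indicator sensitivity can be measured against a
#' known truth. Zero rates return the input unchanged.
#'
#' @param x a \code{\link{channel_recording}} or \code{\link{beat_series}}.
#' @param spec an \code{\link{artifact_spec}}.
#' @param seed integer RNG seed.
#' @return list with \code{data} (same type as \code{x}) and \code{truth}
#'   (data.frame \code{type}, \code{start}, \code{end} in seconds).
#' @export
inject_artifacts <- function(x, spec = artifact_spec(), seed = 1L) {
  if (!inherits(spec, "artifact_spec")) stop("unknown artifact specification")
  set.seed(seed)
  truth <- data.frame(type = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  add_truth <- function(type, start, end) {
    truth <<- rbind(truth, data.frame(type = type, start = start, end = end,
                                      stringsAsFactors = FALSE))
  }
  n_events <- function(rate, dur) rpois(1, rate * dur / 3600)

  if (inherits(x, "channel_recording")) {
    dur <- recording_duration(x)
    fs <- x$fs
    if (x$channel == "SC") {
      for (k in seq_len(n_events(spec$sc_flatline, dur))) {
        s <- runif(1, 0, dur - spec$flatline_s)
        idx <- (floor(s * fs) + 1L):min(floor((s + spec$flatline_s) * fs), length(x$samples))
        x$samples[idx] <- spec$flatline_value
        add_truth("sc_flatline", s, s + spec$flatline_s)
      }
      for (k in seq_len(n_events(spec$sc_jump, dur))) {
        s <- runif(1, 0, dur - spec$jump_s)
        idx <- (floor(s * fs) + 1L):min(floor((s + spec$jump_s) * fs), length(x$samples))
        x$samples[idx] <- x$samples[idx] * spec$jump_factor
        add_truth("sc_jump", s, s + spec$jump_s)
      }
    } else if (x$channel == "ST") {
      for (k in seq_len(n_events(spec$st_excursion, dur))) {
        s <- runif(1, 0, dur - spec$excursion_s)
        idx <- (floor(s * fs) + 1L):min(floor((s + spec$excursion_s) * fs), length(x$samples))
        x$samples[idx] <- spec$excursion_value
        add_truth("st_excursion", s, s + spec$excursion_s)
      }
    }
    return(list(data = x, truth = truth))
  }

  if (inherits(x, "beat_series")) {
    times <- x$times
    dur <- max(times) - min(times)
    for (k in seq_len(n_events(spec$rr_gap, dur))) {
      s <- runif(1, min(times), max(times) - spec$gap_s)
      times <- times[times <= s | times >= s + spec$gap_s]
      add_truth("rr_gap", s, s + spec$gap_s)
    }
    for (k in seq_len(n_events(spec$rr_ectopic, dur))) {
      i <- sample(3:(length(times) - 2), 1)
      rr_prev <- times[i] - times[i - 1]
      shifted <- times[i - 1] + 0.25 * rr_prev   # 0.25/1.75 split, ratio 7
      add_truth("rr_ectopic", times[i - 1], times[i + 1])
      times[i] <- shifted
    }
    return(list(data = beat_series(sort(times)), truth = truth))
  }
  stop("unsupported input type for artifact injection")
}

#' Write a cohort to per-subject CSV files
#'
#' Writes, per subject, \code{sc.csv}/\code{st.csv}/\code{acc.csv}
#' (\code{time_s,value}), \code{beats.csv} (\code{r_peak_time_s}) and
#' \code{ema.csv}, plus a cohort-level \code{profiles.csv} and a
#' \code{manifest.yml} recording the generation settings.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profs <- do.call(rbind, lapply(cohort, function(s) {
    p <- s$profile
    data.frame(subject_id = p$subject_id, phenotype = p$phenotype,
               baseline_hr = p$baseline_hr, baseline_sc = p$baseline_sc,
               baseline_st = p$baseline_st,
               effect_hr = p$stress_effect$hr,
               effect_scr_rate = p$stress_effect$scr_rate,
               effect_st = p$stress_effect$st,
               pss = p$pss, dass_depression = p$dass_depression,
               dass_anxiety = p$dass_anxiety, dass_stress = p$dass_stress,
               psqi = p$psqi, age = p$age, gender = p$gender,
               stringsAsFactors = FALSE)
  }))
  write.csv(profs, file.path(dir, "profiles.csv"), row.names = FALSE)
  for (s in cohort) {
    sdir <- file.path(dir, s$profile$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (ch in c("sc", "st", "acc")) {
      rec <- s[[ch]]
      write.csv(data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                           value = rec$samples),
                file.path(sdir, paste0(ch, ".csv")), row.names = FALSE)
    }
    write.csv(data.frame(r_peak_time_s = s$beats$times),
              file.path(sdir, "beats.csv"), row.names = FALSE)
    write.csv(s$ema, file.path(sdir, "ema.csv"), row.names = FALSE)
  }
  yaml::write_yaml(list(n_subjects = attr(cohort, "n_subjects"),
                        days = attr(cohort, "days"),
                        seed = attr(cohort, "seed"),
                        responsive_fraction = attr(cohort, "responsive_fraction")),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read a cohort from per-subject CSV files
#'
#' Inverse of \code{\link{write_cohort}}; also the entry point for real
#' recordings laid out in the same format (per-channel \code{time_s,value}
#' CSVs, a beats CSV and an EMA CSV per subject directory, plus a
#' cohort-level \code{profiles.csv}). Sampling rates are inferred from the
#' time column. Profile fields absent from \code{profiles.csv} are left
#' \code{NA}; the latent schedule is not recoverable from disk and is
#' \code{NULL}.
#'
#' @param dir directory written by \code{\link{write_cohort}}.
#' @return list of class \code{"wear_cohort"} of per-subject lists.
#' @export
read_cohort <- function(dir) {
  profs <- read.csv(file.path(dir, "profiles.csv"),
                    stringsAsFactors = FALSE)
  read_channel <- function(path, channel, units) {
    d <- read.csv(path)
    fs <- round(1 / median(diff(d$time_s)))
    channel_recording(channel, fs, d$value, units)
  }
  cohort <- lapply(seq_len(nrow(profs)), function(i) {
    p <- as.list(profs[i, ])
    p$stress_effect <- list(hr = p$effect_hr, scr_rate = p$effect_scr_rate,
                            st = p$effect_st)
    p$effect_hr <- p$effect_scr_rate <- p$effect_st <- NULL
    class(p) <- "subject_profile"
    sdir <- file.path(dir, p$subject_id)
    list(profile = p,
         schedule = NULL,
         beats = beat_series(read.csv(file.path(sdir, "beats.csv"))$r_peak_time_s),
         sc = read_channel(file.path(sdir, "sc.csv"), "SC", "uS"),
         st = read_channel(file.path(sdir, "st.csv"), "ST", "degC"),
         acc = read_channel(file.path(sdir, "acc.csv"), "ACC_MAG", "g"),
         ema = read.csv(file.path(sdir, "ema.csv"), stringsAsFactors = FALSE))
  })
  manifest <- file.path(dir, "manifest.yml")
  att <- if (file.exists(manifest)) yaml::read_yaml(manifest) else list()
  structure(cohort, class = "wear_cohort",
            seed = att$seed, days = att$days,
            n_subjects = length(cohort),
            responsive_fraction = att$responsive_fraction)
}
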