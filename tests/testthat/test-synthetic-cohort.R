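test_that("cohort generation is deterministic and partitions phenotypes", {
  c1 <- generate_cohort(4, responsive_fraction = 0.5, seed = 7, days = 1)
  c2 <- generate_cohort(4, responsive_fraction = 0.5, seed = 7, days = 1)
  phen <- vapply(c1, function(s) s$profile$phenotype, character(1))
  expect_equal(sum(phen == "responsive"), 2)
  expect_identical(c1[[2]]$beats$times, c2[[2]]$beats$times)
  expect_identical(c1[[3]]$sc$samples, c2[[3]]$sc$samples)
  expect_identical(c1[[4]]$ema, c2[[4]]$ema)

  c3 <- generate_cohort(2, responsive_fraction = 1, seed = 1, days = 1)
  expect_true(all(vapply(c3, function(s) s$profile$phenotype, character(1)) ==
                    "responsive"))
  expect_error(generate_cohort(0, 0.5, 1), "n_subjects")
  expect_error(generate_cohort(1, 0.5, 1), "n_subjects")
  expect_error(generate_cohort(4, 1.2, 1), "responsive_fraction")
})

test_that("subject profiles respect instrument ranges and phenotype margins", {
  profs <- lapply(1:20, function(i)
    subject_profile(i, if (i %% 2) "responsive" else "blunted", seed = i))
  for (p in profs) {
    expect_true(p$pss >= 0 && p$pss <= 40)
    expect_true(all(c(p$dass_depression, p$dass_anxiety, p$dass_stress) >= 0))
    expect_true(all(c(p$dass_depression, p$dass_anxiety, p$dass_stress) <= 21))
    expect_true(p$psqi >= 0 && p$psqi <= 21)
  }
  eff <- function(sel, ch) vapply(profs[sel], function(p)
    abs(p$stress_effect[[ch]]), numeric(1))
  resp <- seq(1, 20, 2); blnt <- seq(2, 20, 2)
  for (ch in c("hr", "scr_rate", "st"))
    expect_gt(min(eff(resp, ch)), max(eff(blnt, ch)))
})

test_that("latent schedule forces night to level 1 and matches the configured daytime mix", {
  sched <- simulate_latent_schedule(5, seed = 3)
  t_min <- seq_along(sched$level) - 1
  night <- is_night(t_min * 60)
  expect_true(all(sched$level[night] == 1L))
  expect_identical(sched$level,
                   simulate_latent_schedule(5, seed = 3)$level)

  ## daytime block frequencies vs the configured multinomial
  cfg <- sim_config()
  sched <- simulate_latent_schedule(60, seed = 11, config = cfg)
  day_lv <- sched$level[!is_night((seq_along(sched$level) - 1) * 60)]
  ## one level value per 30-min block
  blocks <- day_lv[seq(1, length(day_lv), by = cfg$block_minutes)]
  n <- length(blocks)
  for (k in 1:5) {
    phat <- mean(blocks == k)
    se <- sqrt(cfg$day_level_probs[k] * (1 - cfg$day_level_probs[k]) / n)
    expect_lt(abs(phat - cfg$day_level_probs[k]), 4 * se + 2 / n)
  }
})

test_that("beat simulation recovers the configured stress effect and circadian dip", {
  cfg <- sim_config(hr_night_dip = 0, hr_wander_sd = 0.5)
  ## half the day at level 1, half at level 5, no night in [06:00, 18:00)x2
  lv <- rep(rep(c(1L, 5L), each = 30), 24)   # alternating 30-min blocks
  sched <- make_schedule(lv)
  prof <- subject_profile("A", "responsive", seed = 2, config = cfg)
  prof$stress_effect$hr <- 10
  beats <- simulate_beats(prof, sched, seed = 9, config = cfg)
  t <- beats$times[-1]
  inst_hr <- 60000 / beats$rr_ms
  lv_at <- schedule_level(sched, t)
  d <- mean(inst_hr[lv_at == 5]) - mean(inst_hr[lv_at == 1])
  expect_lt(abs(d - 10), 1.5)

  ## zero effect: no detectable difference
  prof0 <- prof; prof0$stress_effect$hr <- 0
  b0 <- simulate_beats(prof0, sched, seed = 9, config = cfg)
  hr0 <- 60000 / b0$rr_ms
  lv0 <- schedule_level(sched, b0$times[-1])
  expect_lt(abs(mean(hr0[lv0 == 5]) - mean(hr0[lv0 == 1])), 1.5)

  ## circadian dip with default config
  prof$stress_effect$hr <- 0
  schedn <- make_schedule(rep(1L, 1440))
  cfgd <- sim_config(hr_night_dip = -10, hr_wander_sd = 0.5)
  bn <- simulate_beats(prof, schedn, seed = 4, config = cfgd)
  hrn <- 60000 / bn$rr_ms
  night <- is_night(bn$times[-1])
  expect_lt(mean(hrn[night]), mean(hrn[!night]) - 5)
})

test_that("SCR arrivals follow the configured Poisson rates", {
  sched <- make_schedule(rep(1L, 720))   # 12 h, all level 1 (daytime only test)
  prof <- subject_profile("A", "blunted", seed = 5)
  prof$stress_effect$scr_rate <- 0

  cfg1 <- sim_config(scr_rate_base = 1)
  cfg2 <- sim_config(scr_rate_base = 2)
  n1 <- length(attr(simulate_sc(prof, sched, 3, cfg1), "scr_times"))
  n2 <- length(attr(simulate_sc(prof, sched, 3, cfg2), "scr_times"))
  ## expected 720 and 1440 events; ratio 2 within Poisson error
  expect_lt(abs(n1 - 720), 4 * sqrt(720))
  expect_lt(abs(n2 - 1440), 4 * sqrt(1440))

  ## responsive profile: SCR rate under high stress > under no stress
  lv <- rep(rep(c(1L, 5L), each = 30), 12)
  scheds <- make_schedule(lv)
  profr <- subject_profile("B", "responsive", seed = 6)
  on <- attr(simulate_sc(profr, scheds, 8), "scr_times")
  lv_at <- schedule_level(scheds, on)
  rate5 <- sum(lv_at == 5) / sum(lv == 5)
  rate1 <- sum(lv_at == 1) / sum(lv == 1)
  expect_gt(rate5, rate1)

  ## zero-rate limit: phasic power at the noise floor
  cfg0 <- sim_config(scr_rate_base = 0)
  rec0 <- simulate_sc(prof, make_schedule(rep(1L, 60)), 2, cfg0)
  dec <- sc_decompose(rec0$samples, cfg0$fs_sc)
  expect_lt(mean(dec$phasic^2), 4 * cfg0$sc_noise_sd^2)
})

test_that("skin temperature and accelerometer follow their configured structure", {
  cfg <- sim_config()
  sched <- make_schedule(rep(1L, 1440))
  prof <- subject_profile("A", "responsive", seed = 3, config = cfg)
  st <- simulate_st(prof, sched, 4, cfg)
  night <- is_night((seq_along(st$samples) - 1) / st$fs)
  expect_gt(mean(st$samples[night]), mean(st$samples[!night]) + 0.5)

  ## zero activity: windowed ACC SD stays near the sensor noise floor
  acc <- simulate_acc(prof, make_schedule(rep(1L, 120)), 5, cfg)
  w <- sliding_windows(recording_duration(acc))
  sds <- vapply(seq_len(nrow(w)), function(i)
    sd(acc$samples[(w$start[i] * cfg$fs_acc + 1):(w$end[i] * cfg$fs_acc)]),
    numeric(1))
  expect_true(all(sds < 0.04))
  expect_lt(abs(mean(sds) - cfg$acc_noise_sd), 0.005)

  ## configured activity bouts push windowed ACC SD above 0.04
  sched_a <- make_schedule(rep(1L, 120), activity = rep(c(0L, 1L), each = 60))
  acc_a <- simulate_acc(prof, sched_a, 5, cfg)
  sd_act <- sd(acc_a$samples[(3900 * cfg$fs_acc):(4200 * cfg$fs_acc)])
  expect_gt(sd_act, 0.04)
})

test_that("artifact injection records ground truth and zero rates are the identity", {
  rec <- channel_recording("SC", 8, rep(2, 8 * 600), "uS")
  out0 <- inject_artifacts(rec, artifact_spec(), seed = 1)
  expect_identical(out0$data$samples, rec$samples)
  expect_equal(nrow(out0$truth), 0)

  out <- inject_artifacts(rec, artifact_spec(sc_flatline = 30), seed = 2)
  expect_gt(nrow(out$truth), 0)
  for (i in seq_len(nrow(out$truth))) {
    idx <- (floor(out$truth$start[i] * 8) + 2):(floor(out$truth$end[i] * 8) - 1)
    expect_true(all(out$data$samples[idx] < 0.001))
  }
  expect_error(inject_artifacts(rec, list(bogus = 1), seed = 1), "unknown")

  beats <- beat_series(cumsum(rep(1, 600)))
  outg <- inject_artifacts(beats, artifact_spec(rr_gap = 30), seed = 3)
  expect_gt(nrow(outg$truth), 0)
  expect_gt(max(diff(outg$data$times)), 3)
})

test_that("EMA schedule constraints hold and misreport noise behaves", {
  cfg <- sim_config()
  sched <- simulate_latent_schedule(5, seed = 2, cfg)
  prof <- subject_profile("A", "responsive", seed = 1, cfg)
  for (s in 1:10) {
    ema <- simulate_ema(prof, sched, seed = s, cfg)
    expect_true(all(diff(ema$prompt_time) >= 30 * 60))
    expect_true(all(table(floor(ema$prompt_time / 86400)) <= 12))
    expect_true(all(ema$stress %in% 1:5))
    expect_true(all(ema$pleasure %in% 1:9))
  }
  ## zero misreport noise: reported stress equals the latent level
  cfg0 <- sim_config(misreport_prob = 0)
  ema0 <- simulate_ema(prof, sched, seed = 4, cfg0)
  expect_identical(as.integer(ema0$stress),
                   as.integer(schedule_level(sched, ema0$prompt_time)))
  ## pleasure is negatively coupled to stress
  ema_all <- do.call(rbind, lapply(1:20, function(s)
    simulate_ema(prof, sched, seed = s, cfg)))
  expect_lt(spearman_cor(ema_all$stress, ema_all$pleasure), 0)
})

test_that("cohort CSV round trip preserves recordings, beats and EMA", {
  cohort <- generate_cohort(2, responsive_fraction = 0.5, seed = 13, days = 1)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$profile$subject_id, cohort[[1]]$profile$subject_id)
  expect_equal(back[[1]]$profile$phenotype, cohort[[1]]$profile$phenotype)
  expect_equal(back[[2]]$beats$times, cohort[[2]]$beats$times,
               tolerance = 1e-9)
  expect_equal(back[[1]]$sc$samples, cohort[[1]]$sc$samples,
               tolerance = 1e-9)
  expect_equal(back[[1]]$sc$fs, cohort[[1]]$sc$fs)
  expect_equal(back[[2]]$ema$stress, cohort[[2]]$ema$stress)
  ## the reloaded cohort feeds extraction identically
  ft1 <- extract_features(cohort[[1]])
  ft2 <- extract_features(back[[1]])
  expect_equal(ft1[, feature_names()], ft2[, feature_names()],
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
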