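test_that("stress-level merging maps 5 Likert levels onto 3 states", {
  expect_equal(merge_stress_levels(1), "S1")
  expect_equal(merge_stress_levels(2), "S2")
  expect_equal(merge_stress_levels(c(3, 4, 5)), rep("S3", 3))
  expect_error(merge_stress_levels(0))
  expect_error(merge_stress_levels(6))
  expect_error(merge_stress_levels(2.5))
})

test_that("EMA labels propagate onto the hour preceding each prompt", {
  ft <- data.frame(subject_id = "A", window_start = seq(0, 86100, 60))
  ## one prompt at 10:00 labels window starts in [09:00, 10:00)
  ema <- data.frame(prompt_time = 36000, stress = 3L)
  lab <- propagate_labels(ema, ft)
  sel <- !is.na(lab$stress_likert)
  expect_equal(sum(sel), 60)
  expect_true(all(lab$window_start[sel] >= 32400 &
                    lab$window_start[sel] < 36000))

  ## no EMA: nothing labeled
  lab0 <- propagate_labels(ema[0, ], ft)
  expect_true(all(is.na(lab0$stress_likert)))

  ## two prompts 30 min apart: later wins the overlap; 90 labeled rows
  ema2 <- data.frame(prompt_time = c(36000, 37800), stress = c(2L, 5L))
  lab2 <- propagate_labels(ema2, ft)
  expect_equal(sum(!is.na(lab2$stress_likert)), 90)
  overlap <- lab2$window_start >= 36000 - 1800 & lab2$window_start < 36000
  expect_true(all(lab2$stress_likert[overlap] == 5L))
  expect_true(all(lab2$ema_id[overlap] == 2L))
})

test_that("day/night states follow the clock convention", {
  rows <- data.frame(subject_id = "A",
                     window_start = c(3 * 3600, 6 * 3600, 23.5 * 3600,
                                      5.99 * 3600, 86400 + 3600),
                     stress_likert = c(NA, 1L, 4L, NA, NA))
  out <- day_night_states(rows)
  expect_equal(out$state, c("N", "S1", "S3", "N", "N"))
})

test_that("filtering applies the quality, activity, 10-min and two-state rules", {
  ## hour with only 9 surviving rows is dropped entirely
  a_good <- make_rows("A", seq(0, 59 * 60, 60) + 10 * 3600, "S1",
                      ema_id = 1L)
  a_good$state[1:30] <- "S2"; a_good$ema_id[1:30] <- 2L
  a_short <- make_rows("A", seq(0, 8 * 60, 60) + 14 * 3600, "S3",
                       ema_id = 3L)
  rows <- rbind(a_good, a_short)
  out <- filter_rows(rows)
  expect_equal(nrow(out), 60)
  expect_false(any(out$ema_id == 3L))

  ## quality exactly 0.8 is excluded (strict >)
  r <- make_rows("A", c(10, 11, 12) * 3600, c("S1", "S2", "S1"),
                 quality = c(0.81, 0.8, 0.79))
  r$ema_id <- 1:3
  r2 <- rbind(r, make_rows("A", seq(0, 59 * 60, 60) + 15 * 3600,
                           rep(c("S1", "S2"), 30), ema_id = 4L))
  out2 <- filter_rows(r2, min_minutes = 1)
  expect_true(all(out2$quality > 0.8))
  expect_equal(sum(out2$ema_id %in% 1:3), 1)

  ## ACC SD 0.05 dropped, 0.04 kept (non-strict <=)
  r3 <- make_rows("A", c(10, 11, 12, 13) * 3600, c("S1", "S2", "S2", "S1"),
                  acc_sd = c(0.04, 0.05, 0.03, 0.01))
  r3$ema_id <- 1:4
  out3 <- filter_rows(r3, min_minutes = 1)
  expect_equal(sort(out3$acc_sd), c(0.01, 0.03, 0.04))

  ## single-state subjects are discarded; night rows don't rescue them
  r4 <- rbind(make_rows("B", seq(0, 19 * 60, 60) + 10 * 3600, "S1",
                        ema_id = 1L),
              make_rows("B", seq(0, 19 * 60, 60) + 2 * 3600, "N",
                        ema_id = NA))
  expect_equal(nrow(filter_rows(r4)), 0)

  ## idempotence
  out_all <- filter_rows(rows)
  expect_identical(filter_rows(out_all), out_all)
})

test_that("per-subject z-scoring centers and scales retained rows", {
  set.seed(31)
  rows <- make_rows(rep(c("A", "B"), each = 50), rep(1:50 * 60, 2),
                    "S1")
  for (f in feature_names()) rows[[f]] <- rnorm(100, mean = runif(1, -5, 5))
  rows$st_sd <- 7   # constant feature -> zero-variance rule
  z <- zscore_per_subject(rows)
  for (sid in c("A", "B")) {
    sel <- z$subject_id == sid
    expect_equal(mean(z$ecg_mean_hr[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(z$ecg_mean_hr[sel]), 1, tolerance = 1e-9)
  }
  expect_true(all(z$st_sd == 0))
})

test_that("correlation pruning drops duplicates and keeps independent noise", {
  set.seed(17)
  n <- 1000
  rows <- data.frame(matrix(rnorm(n * 18), n))
  names(rows) <- feature_names()
  rows$ecg_rmssd <- rows$ecg_mean_hr          # exact duplicate
  kept <- prune_correlated(rows)
  expect_true("ecg_mean_hr" %in% kept)
  expect_false("ecg_rmssd" %in% kept)         # later duplicate dropped
  expect_equal(sort(kept), sort(setdiff(feature_names(), "ecg_rmssd")))

  ## row order invariance
  kept2 <- prune_correlated(rows[sample(n), ])
  expect_identical(kept, kept2)
})

test_that("stay-location clustering and anonymization behave", {
  ## 90 min of points within 200 m: one stay location
  set.seed(2)
  t1 <- seq(0, 90 * 60, by = 60)
  stay_pts <- data.frame(t = t1, x = rnorm(length(t1), 0, 100),
                         y = rnorm(length(t1), 0, 100))
  res <- cluster_stay_locations(stay_pts)
  expect_equal(nrow(res$stays), 1)
  expect_true(all(res$label == "stay"))

  ## 50-min dwell: commuting
  t2 <- seq(0, 50 * 60, by = 60)
  short <- data.frame(t = t2, x = rnorm(length(t2), 0, 100),
                      y = rnorm(length(t2), 0, 100))
  res2 <- cluster_stay_locations(short)
  expect_equal(nrow(res2$stays), 0)
  expect_true(all(res2$label == "commuting"))

  ## empty track
  res0 <- cluster_stay_locations(data.frame(t = numeric(0), x = numeric(0),
                                            y = numeric(0)))
  expect_equal(nrow(res0$stays), 0)

  ## rigid anonymization preserves pairwise distances
  trk <- data.frame(t = 1:20, x = rnorm(20, 0, 500), y = rnorm(20, 0, 500))
  an <- anonymize_locations(trk, seed = 9)
  expect_equal(as.numeric(dist(an[, c("x", "y")])),
               as.numeric(dist(trk[, c("x", "y")])), tolerance = 1e-9)
  expect_gt(max(abs(an$x - trk$x)), 1)   # actually moved
})

test_that("dataset assembly joins, filters and normalizes a small cohort", {
  cohort <- generate_cohort(3, responsive_fraction = 1, seed = 21, days = 1)
  feats <- do.call(rbind, lapply(cohort, extract_features))
  ema_list <- setNames(lapply(cohort, `[[`, "ema"),
                       vapply(cohort, function(s) s$profile$subject_id,
                              character(1)))
  ds <- assemble_dataset(feats, ema_list)
  expect_s3_class(ds, "labeled_dataset")
  expect_true(all(ds$rows$quality > 0.8))
  expect_true(all(ds$rows$acc_sd <= 0.04))
  expect_true(all(ds$rows$state %in% c("N", "S1", "S2", "S3")))
  expect_true(all(ds$features %in% feature_names()))
  ## z-normalization holds on the retained rows
  for (sid in unique(ds$rows$subject_id)) {
    x <- ds$rows$st_median[ds$rows$subject_id == sid]
    if (sum(!is.na(x)) > 2 && sd(x, na.rm = TRUE) > 0) {
      expect_lt(abs(mean(x, na.rm = TRUE)), 1e-9)
      expect_lt(abs(sd(x, na.rm = TRUE) - 1), 1e-9)
    }
  }
})
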