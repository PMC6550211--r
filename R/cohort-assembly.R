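#' Merge 5-point stress reports into three states
#'
#' Self-reported stress is highly imbalanced, so the three highest Likert
#' levels are merged: 1 -> S1 (no stress), 2 -> S2 (light stress),
#' 3/4/5 -> S3 (high stress).
#'
#' @param likert integer vector of Likert stress levels in 1..5.
#' @return character vector of states \code{"S1"}, \code{"S2"}, \code{"S3"}.
#' @export
merge_stress_levels <- function(likert) {
  if (any(is.na(likert)) || any(likert < 1 | likert > 5) ||
      any(likert != round(likert)))
    stop("stress levels must be integers in 1..5")
  c("S1", "S2", "S3")[pmin(as.integer(likert), 3L)]
}

#' Propagate EMA stress labels onto feature rows
#'
#' Each EMA report describes the hour preceding its prompt, so its stress
#' value is assigned to the feature rows (one per minute) whose window start
#' lies in \code{[prompt - lookback, prompt)}. Where the lookback intervals
#' of two prompts overlap, the later prompt wins. Rows covered by no prompt
#' stay unlabeled.
#'
#' @param ema EMA data.frame for one subject (\code{prompt_time},
#'   \code{stress}).
#' @param features feature table for the same subject (\code{window_start}).
#' @param lookback labeling lookback, seconds.
#' @return \code{features} with added columns \code{stress_likert} and
#'   \code{ema_id} (row index of the labeling prompt), \code{NA} where
#'   unlabeled.
#' @export
propagate_labels <- function(ema, features, lookback = 3600) {
  features$stress_likert <- NA_integer_
  features$ema_id <- NA_integer_
  if (nrow(ema)) {
    ord <- order(ema$prompt_time)
    for (j in ord) {
      sel <- features$window_start >= ema$prompt_time[j] - lookback &
        features$window_start < ema$prompt_time[j]
      features$stress_likert[sel] <- as.integer(ema$stress[j])
      features$ema_id[sel] <- j
    }
  }
  features
}

#' Tag day/night states
#'
#' Rows whose window start falls in the night interval (default
#' 00:00-06:00, half-open) get state \code{"N"} regardless of any EMA label;
#' daytime rows get the merged stress state of their label, or \code{NA}
#' when unlabeled.
#'
#' @param rows feature rows with \code{window_start} and
#'   \code{stress_likert}.
#' @param night_hours clock hours delimiting the night.
#' @return \code{rows} with an added \code{state} column.
#' @export
day_night_states <- function(rows, night_hours = c(0, 6)) {
  night <- is_night(rows$window_start, night_hours)
  state <- rep(NA_character_, nrow(rows))
  lab <- !is.na(rows$stress_likert)
  state[lab & !night] <- merge_stress_levels(rows$stress_likert[lab & !night])
  state[night] <- "N"
  rows$state <- state
  rows
}

#' Apply the analysis inclusion rules
#'
#' Retains rows with overall window quality above \code{quality_min} and
#' ACC SD at or below \code{acc_max}; drops any EMA hour whose surviving
#' rows span fewer than \code{min_minutes} minutes; drops subjects whose
#' surviving daytime labels contain only one stress state. Night rows pass
#' the quality/activity rules only (they carry no EMA hour). The operation
#' is idempotent.
#'
#' @param rows labeled rows with \code{subject_id}, \code{state},
#'   \code{ema_id}, \code{quality}, \code{acc_sd}.
#' @param quality_min inclusion threshold on window quality (strict >).
#' @param acc_max inclusion threshold on ACC SD (non-strict <=).
#' @param min_minutes minimal surviving rows per EMA hour.
#' @return the filtered rows.
#' @export
filter_rows <- function(rows, quality_min = 0.8, acc_max = 0.04,
                        min_minutes = 10) {
  keep <- !is.na(rows$state) & rows$quality > quality_min &
    rows$acc_sd <= acc_max
  rows <- rows[keep, , drop = FALSE]
  ## 10-minute rule per EMA hour (daytime labeled rows only)
  daytime <- rows$state != "N" & !is.na(rows$ema_id)
  if (any(daytime)) {
    key <- paste(rows$subject_id, rows$ema_id)
    cnt <- table(key[daytime])
    drop_hour <- daytime & cnt[key] < min_minutes
    drop_hour[is.na(drop_hour)] <- FALSE
    rows <- rows[!drop_hour, , drop = FALSE]
  }
  ## subjects must report at least two distinct daytime states
  day_states <- tapply(rows$state[rows$state != "N"],
                       rows$subject_id[rows$state != "N"],
                       function(s) length(unique(s)))
  ok_subj <- names(day_states)[!is.na(day_states) & day_states >= 2]
  rows[rows$subject_id %in% ok_subj, , drop = FALSE]
}

#' Per-subject z-normalization
#'
#' Centers and scales each feature by the subject's own mean and SD over the
#' retained rows. A feature with zero variance for a subject is set to 0 for
#' that subject (neutral value).
#'
#' @param rows feature rows with \code{subject_id}.
#' @param features feature columns to normalize.
#' @return \code{rows} with the feature columns z-scored within subject.
#' @export
zscore_per_subject <- function(rows, features = feature_names()) {
  for (sid in unique(rows$subject_id)) {
    sel <- rows$subject_id == sid
    for (f in features) {
      x <- rows[[f]][sel]
      m <- mean(x, na.rm = TRUE)
      s <- sd(x, na.rm = TRUE)
      rows[[f]][sel] <- if (is.na(s) || s == 0) ifelse(is.na(x), NA, 0)
        else (x - m) / s
    }
  }
  rows
}

#' Remove correlated (redundant) features
#'
#' Greedy pruning on the pooled rows: features are visited in the documented
#' canonical order and kept only if their absolute Spearman correlation with
#' every previously kept feature is at most \code{r_max}. The result depends
#' only on the correlation matrix and the feature order, not on row order.
#'
#' @param rows pooled (normalized) feature rows.
#' @param features candidate features, in canonical order.
#' @param r_max maximal allowed absolute Spearman correlation.
#' @return character vector of retained feature names.
#' @export
prune_correlated <- function(rows, features = feature_names(), r_max = 0.7) {
  keep <- character(0)
  for (f in features) {
    x <- rows[[f]]
    if (all(is.na(x))) next
    ok <- TRUE
    for (g in keep) {
      r <- suppressWarnings(cor(x, rows[[g]], method = "spearman",
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > r_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, f)
  }
  keep
}

#' Assemble the labeled analysis dataset
#'
#' Full cohort assembly: per subject, EMA labels are propagated onto the
#' feature rows, day/night states attached, the overall window quality set
#' to the minimum of the per-channel quality fractions, the inclusion rules
#' applied (\code{\link{filter_rows}}), features z-normalized per subject
#' and redundant features pruned on the pooled normalized rows.
#'
#' @param features combined feature table (all subjects).
#' @param ema_list named list of per-subject EMA data.frames (names =
#'   subject ids).
#' @param quality_min,acc_max,min_minutes,r_max inclusion thresholds, see
#'   \code{\link{filter_rows}} and \code{\link{prune_correlated}}.
#' @param night_hours clock hours delimiting the night.
#' @param lookback EMA labeling lookback, seconds.
#' @return list of class \code{"labeled_dataset"}: \code{rows} (filtered,
#'   z-scored), \code{features} (retained feature names), \code{n_subjects}.
#' @export
assemble_dataset <- function(features, ema_list, quality_min = 0.8,
                             acc_max = 0.04, min_minutes = 10, r_max = 0.7,
                             night_hours = c(0, 6), lookback = 3600) {
  parts <- lapply(split(features, features$subject_id), function(fx) {
    ema <- ema_list[[fx$subject_id[1]]]
    if (is.null(ema)) ema <- data.frame(prompt_time = numeric(0),
                                        stress = integer(0))
    day_night_states(propagate_labels(ema, fx, lookback), night_hours)
  })
  rows <- do.call(rbind, parts)
  rownames(rows) <- NULL
  rows$quality <- pmin(rows$qual_ecg, rows$qual_sc, rows$qual_st)
  rows <- filter_rows(rows, quality_min, acc_max, min_minutes)
  rows <- zscore_per_subject(rows)
  kept <- prune_correlated(rows, feature_names(), r_max)
  structure(list(rows = rows, features = kept,
                 n_subjects = length(unique(rows$subject_id))),
            class = "labeled_dataset")
}

#' Cluster stay locations from a coordinate track
#'
#' Greedy stay-point detection on a timestamped planar track: a maximal
#' time-contiguous run of points each within \code{radius} meters of the
#' run's running centroid becomes a stay location if it lasts longer than
#' \code{min_dwell_s}; all other points are labeled commuting.
#'
#' @param track data.frame with \code{t} (seconds), \code{x}, \code{y}
#'   (meters, planar projection).
#' @param radius stay radius, meters.
#' @param min_dwell_s minimal dwell, seconds (default 60 min).
#' @return list with \code{stays} (data.frame \code{cx}, \code{cy},
#'   \code{t_start}, \code{t_end}, \code{dwell_s}) and \code{label}
#'   (\code{"stay"}/\code{"commuting"} per point).
#' @export
cluster_stay_locations <- function(track, radius = 1000, min_dwell_s = 3600) {
  n <- nrow(track)
  label <- rep("commuting", n)
  stays <- data.frame(cx = numeric(0), cy = numeric(0), t_start = numeric(0),
                      t_end = numeric(0), dwell_s = numeric(0))
  if (n == 0L) return(list(stays = stays, label = character(0)))
  i <- 1L
  while (i <= n) {
    j <- i
    cx <- track$x[i]; cy <- track$y[i]
    while (j < n) {
      nx <- (cx * (j - i + 1) + track$x[j + 1]) / (j - i + 2)
      ny <- (cy * (j - i + 1) + track$y[j + 1]) / (j - i + 2)
      if (sqrt((track$x[j + 1] - nx)^2 + (track$y[j + 1] - ny)^2) > radius)
        break
      cx <- nx; cy <- ny; j <- j + 1L
    }
    dwell <- track$t[j] - track$t[i]
    if (dwell > min_dwell_s) {
      label[i:j] <- "stay"
      stays <- rbind(stays, data.frame(cx = cx, cy = cy,
                                       t_start = track$t[i],
                                       t_end = track$t[j], dwell_s = dwell))
    }
    i <- j + 1L
  }
  list(stays = stays, label = label)
}

#' Anonymize a location track by a random rigid transform
#'
#' Applies one random rotation plus translation per call; pairwise distances
#' are preserved exactly, so stay-location structure is unaffected.
#'
#' @param track data.frame with \code{x}, \code{y} (meters).
#' @param seed integer RNG seed.
#' @return \code{track} with transformed coordinates.
#' @export
anonymize_locations <- function(track, seed = 1L) {
  set.seed(seed)
  th <- runif(1, 0, 2 * pi)
  dx <- runif(2, -1e5, 1e5)
  x <- track$x * cos(th) - track$y * sin(th) + dx[1]
  y <- track$x * sin(th) + track$y * cos(th) + dx[2]
  track$x <- x
  track$y <- y
  track
}
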