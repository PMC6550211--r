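#' Sliding-window specification
#'
#' The feature-extraction windows are 5 minutes long with 4 minutes overlap
#' (60-s hop), aligned to the recording start, yielding one feature row per
#' minute of interior recording.
#'
#' @param window_s window length, seconds.
#' @param hop_s hop between window starts, seconds.
#' @return list of class \code{"window_spec"}.
#' @export
window_spec <- function(window_s = 300, hop_s = 60) {
  stopifnot(window_s > 0, hop_s > 0)
  structure(list(window_s = window_s, hop_s = hop_s), class = "window_spec")
}

#' Enumerate sliding windows over a recording
#'
#' @param duration recording duration, seconds.
#' @param spec a \code{\link{window_spec}}.
#' @return data.frame with columns \code{start}, \code{end} (half-open);
#'   empty if \code{duration < window_s}.
#' @export
sliding_windows <- function(duration, spec = window_spec()) {
  if (duration < spec$window_s)
    return(data.frame(start = numeric(0), end = numeric(0)))
  start <- seq(0, duration - spec$window_s, by = spec$hop_s)
  data.frame(start = start, end = start + spec$window_s)
}

## least-squares slope of y on t (closed form)
.ls_slope <- function(t, y) {
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) return(0)
  sum(tc * (y - mean(y))) / denom
}

#' Band power of the RR tachogram
#'
#' Cubic-spline interpolation of the RR series (seconds) to a uniform
#' \code{fs} Hz grid, linear detrend, Hann window and one-segment
#' periodogram; band power is the integral of the one-sided power spectral
#' density over each band, in squared seconds.
#'
#' @param t beat times (seconds) of the RR values (time of the closing beat).
#' @param rr_s RR intervals, seconds.
#' @param fs resampling rate, Hz.
#' @param bands named list of \code{c(lo, hi)} frequency bands, Hz.
#' @return named numeric band powers.
#' @export
rr_band_power <- function(t, rr_s, fs = 4,
                          bands = list(lf = c(0.04, 0.15),
                                       hf = c(0.15, 0.40))) {
  out <- setNames(rep(NA_real_, length(bands)), names(bands))
  if (length(rr_s) < 8L || diff(range(t)) < 10) return(out)
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  x <- spline(t, rr_s, xout = grid)$y
  n <- length(x)
  tt <- grid - grid[1]
  x <- x - mean(x) - .ls_slope(tt, x) * (tt - mean(tt))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))   # Hann
  xw <- x * w
  ## one-sided PSD normalized for window power so band powers integrate to
  ## the signal variance (Parseval)
  X <- fft(xw)
  psd <- (Mod(X)^2) / (fs * sum(w^2))
  nf <- floor(n / 2) + 1L
  psd <- psd[seq_len(nf)]
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  freq <- (seq_len(nf) - 1) * fs / n
  df <- fs / n
  for (b in names(bands)) {
    sel <- freq >= bands[[b]][1] & freq < bands[[b]][2]
    out[b] <- sum(psd[sel]) * df
  }
  out
}

#' ECG window features
#'
#' Six heart-rate / heart-rate-variability features from the beats falling
#' inside one window: mean HR (60000 / mean RR ms), RMSSD (root mean square
#' of successive RR differences, ms), SDNN (SD of RR, ms), LF and HF band
#' powers of the interpolated tachogram (0.04-0.15 and 0.15-0.40 Hz, s^2)
#' and their ratio LF/HF. Fewer than two beats yields all-missing features;
#' HF = 0 yields a missing ratio.
#'
#' @param beat_times R-peak times (seconds) inside the window.
#' @return named numeric vector \code{ecg_mean_hr}, \code{ecg_rmssd},
#'   \code{ecg_sdnn}, \code{ecg_lf}, \code{ecg_hf}, \code{ecg_lfhf}.
#' @export
ecg_features <- function(beat_times) {
  out <- setNames(rep(NA_real_, 6),
                  c("ecg_mean_hr", "ecg_rmssd", "ecg_sdnn",
                    "ecg_lf", "ecg_hf", "ecg_lfhf"))
  if (length(beat_times) < 2L) return(out)
  rr_ms <- diff(beat_times) * 1000
  out["ecg_mean_hr"] <- 60000 / mean(rr_ms)
  out["ecg_rmssd"] <- if (length(rr_ms) >= 2L)
    sqrt(mean(diff(rr_ms)^2)) else NA_real_
  out["ecg_sdnn"] <- if (length(rr_ms) >= 2L) sd(rr_ms) else NA_real_
  bp <- rr_band_power(beat_times[-1], rr_ms / 1000)
  out["ecg_lf"] <- bp["lf"]
  out["ecg_hf"] <- bp["hf"]
  out["ecg_lfhf"] <- if (!is.na(bp["hf"]) && bp["hf"] > 0)
    bp["lf"] / bp["hf"] else NA_real_
  out
}

#' Tonic/phasic decomposition of a skin-conductance window
#'
#' The tonic component is a zero-phase second-order Butterworth low-pass
#' (cutoff 0.05 Hz) of the signal; the phasic component is the residual, so
#' tonic + phasic reconstructs the input exactly. Skin-conductance responses
#' (SCRs) are detected on the (lightly smoothed) phasic trace as
#' trough-to-peak rises of at least \code{amp_min} microsiemens completed
#' within \code{max_rise_s} seconds.
#'
#' @param x skin-conductance samples, microsiemens.
#' @param fs sampling rate, Hz.
#' @param amp_min minimal SCR amplitude, microsiemens.
#' @param max_rise_s maximal trough-to-peak rise time, seconds.
#' @param cutoff_hz tonic low-pass cutoff, Hz.
#' @return list of class \code{"sc_decomposition"}: \code{tonic},
#'   \code{phasic} (vectors), \code{events} (data.frame \code{onset_idx},
#'   \code{peak_idx}, \code{recovery_idx}, \code{amplitude}, \code{area}),
#'   \code{detect_trace} (the smoothed phasic trace used for detection and
#'   area integration), \code{fs}.
#' @export
sc_decompose <- function(x, fs, amp_min = 0.01, max_rise_s = 5,
                         cutoff_hz = 0.05) {
  stopifnot(length(x) > 0)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  ## reflective padding suppresses the zero-phase filter's edge transients,
  ## which would otherwise dominate the phasic residual near the boundaries
  n <- length(x)
  p <- min(n - 1L, ceiling(3 / cutoff_hz * fs))
  if (p > 0L) {
    xa <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
    tonic <- as.numeric(signal::filtfilt(bf, xa))[(p + 1L):(p + n)]
  } else {
    tonic <- as.numeric(signal::filtfilt(bf, x))
  }
  phasic <- x - tonic

  ## detect SCRs on a lightly smoothed phasic trace (noise suppression only)
  ks <- max(1L, round(fs / 2))
  ph <- if (ks > 1L)
    as.numeric(stats::filter(phasic, rep(1 / ks, ks), sides = 2)) else phasic
  ph[is.na(ph)] <- 0
  d <- diff(ph)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  troughs <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (length(peaks) && length(troughs)) {
    ti <- findInterval(peaks - 1L, troughs)       # last trough before peak
    onset <- ifelse(ti >= 1L, troughs[pmax(ti, 1L)], 1L)
    amp <- ph[peaks] - ph[onset]
    keep <- amp >= amp_min & (peaks - onset) / fs <= max_rise_s
    peaks <- peaks[keep]; onset <- onset[keep]; amp <- amp[keep]
  } else {
    peaks <- onset <- integer(0); amp <- numeric(0)
  }
  ## area: integrate the phasic excursion above the onset level until the
  ## trace recovers to it (search capped at 60 s past the peak)
  recovery <- vapply(seq_along(peaks), function(e) {
    p <- peaks[e]; tr <- onset[e]
    horizon <- min(p + 60L * fs, length(ph))
    rec_rel <- which(ph[p:horizon] <= ph[tr])
    as.integer(if (length(rec_rel)) p + rec_rel[1] - 1L else horizon)
  }, integer(1))
  area <- vapply(seq_along(peaks), function(e) {
    seg <- pmax(ph[onset[e]:recovery[e]] - ph[onset[e]], 0)
    sum((seg[-1] + seg[-length(seg)]) / 2) / fs
  }, numeric(1))
  events <- data.frame(onset_idx = as.integer(onset),
                       peak_idx = as.integer(peaks),
                       recovery_idx = as.integer(recovery),
                       amplitude = amp, area = area)
  structure(list(tonic = tonic, phasic = phasic, events = events,
                 detect_trace = ph, fs = fs),
            class = "sc_decomposition")
}

#' Skin-conductance window features
#'
#' Eight electrodermal features: \code{sc_mean} (mean tonic level),
#' \code{sc_phasic} (mean squared phasic amplitude, i.e. phasic power),
#' \code{sc_area} (summed area under the detected SCRs, uS*s),
#' \code{sc_scr_count}, \code{sc_diff1}/\code{sc_diff2} (mean absolute
#' first/second difference of the raw signal), \code{sc_slope}
#' (least-squares slope of the tonic component, uS/s) and \code{sc_sd}.
#'
#' @param x raw skin-conductance samples of the window.
#' @param fs sampling rate, Hz.
#' @param decomp a \code{\link{sc_decompose}} result for the same window.
#' @return named numeric vector of the 8 features.
#' @export
sc_features <- function(x, fs, decomp = sc_decompose(x, fs)) {
  t <- (seq_along(x) - 1) / fs
  c(sc_mean = mean(decomp$tonic),
    sc_phasic = mean(decomp$phasic^2),
    sc_area = sum(decomp$events$area),
    sc_scr_count = as.numeric(nrow(decomp$events)),
    sc_diff1 = mean(abs(diff(x))),
    sc_diff2 = if (length(x) > 2L) mean(abs(diff(x, differences = 2))) else NA_real_,
    sc_slope = .ls_slope(t, decomp$tonic),
    sc_sd = sd(x))
}

#' Skin-temperature window features
#'
#' @param x ST samples of the window, Celsius.
#' @param fs sampling rate, Hz.
#' @return named numeric vector \code{st_mean}, \code{st_median},
#'   \code{st_slope} (Celsius per second) and \code{st_sd}.
#' @export
st_features <- function(x, fs = 1) {
  t <- (seq_along(x) - 1) / fs
  c(st_mean = mean(x), st_median = median(x),
    st_slope = .ls_slope(t, x), st_sd = sd(x))
}

#' Accelerometer activity index
#'
#' Standard deviation of the accelerometer magnitude in the window; the
#' conventional low-activity inclusion threshold is ACC SD <= 0.04 g.
#'
#' @param x accelerometer-magnitude samples, g.
#' @return numeric SD.
#' @export
acc_sd <- function(x) sd(x)

#' Canonical feature order
#'
#' The documented column order of the 18 physiological features; used as the
#' tie-break order by \code{\link{prune_correlated}}.
#'
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c("ecg_mean_hr", "ecg_rmssd", "ecg_sdnn", "ecg_lf", "ecg_hf", "ecg_lfhf",
    "sc_mean", "sc_phasic", "sc_area", "sc_scr_count", "sc_diff1",
    "sc_diff2", "sc_slope", "sc_sd",
    "st_mean", "st_median", "st_slope", "st_sd")
}

## windowed sums via cumulative sums: x at rate fs, windows [start, start+len)
.window_stat <- function(x, fs, starts, len, fun = c("mean", "sd")) {
  fun <- match.arg(fun)
  cs <- c(0, cumsum(x))
  i1 <- round(starts * fs) + 1L
  i2 <- pmin(round((starts + len) * fs), length(x))
  n <- i2 - i1 + 1
  s <- cs[i2 + 1L] - cs[i1]
  if (fun == "mean") return(s / n)
  cs2 <- c(0, cumsum(x^2))
  s2 <- cs2[i2 + 1L] - cs2[i1]
  sqrt(pmax(s2 - s^2 / n, 0) / (n - 1))
}

#' Extract the windowed feature table for one subject
#'
#' Runs the 5-min / 4-min-overlap sliding windows over the subject's
#' time-aligned recordings and computes the 18 physiological features, the
#' accelerometer activity index and the per-channel window quality fractions
#' (from \code{\link{aggregate_window_quality}}). Features of a channel
#' whose window quality fraction does not exceed \code{quality_min} are set
#' to missing; ECG features are also missing when fewer than two beats fall
#' in the window. The skin-conductance tonic/phasic decomposition is
#' computed once over the whole recording and sliced per window.
#'
#' @param subject a \code{\link{simulate_subject}}-style list (fields
#'   \code{profile}, \code{beats}, \code{sc}, \code{st}, \code{acc}).
#' @param masks optional list with \code{ecg}, \code{sc}, \code{st} quality
#'   masks; computed from the subject if \code{NULL}.
#' @param spec a \code{\link{window_spec}}.
#' @param quality_min per-channel quality gate for feature validity.
#' @return data.frame: \code{subject_id}, \code{window_start}, the 18
#'   features (see \code{\link{feature_names}}), \code{acc_sd},
#'   \code{qual_ecg}, \code{qual_sc}, \code{qual_st}.
#' @export
extract_features <- function(subject, masks = NULL, spec = window_spec(),
                             quality_min = 0.8) {
  dur <- min(recording_duration(subject$sc), recording_duration(subject$st),
             recording_duration(subject$acc))
  if (!isTRUE(all.equal(recording_duration(subject$sc), dur)) ||
      !isTRUE(all.equal(recording_duration(subject$st), dur)) ||
      !isTRUE(all.equal(recording_duration(subject$acc), dur)))
    stop("channels are not aligned to a common duration")
  win <- sliding_windows(dur, spec)
  n_win <- nrow(win)
  if (n_win == 0L) stop("recording shorter than one window")

  if (is.null(masks)) {
    masks <- list(ecg = ecg_quality_mask(subject$beats, dur),
                  sc = sc_quality_mask(subject$sc),
                  st = st_quality_mask(subject$st))
  }

  feats <- matrix(NA_real_, n_win, 18,
                  dimnames = list(NULL, feature_names()))

  ## ECG: slice beats per window (beats are sorted; use interval search)
  bt <- subject$beats$times
  b1 <- findInterval(win$start, bt, left.open = TRUE) + 1L
  b2 <- findInterval(win$end, bt, left.open = TRUE)
  for (w in seq_len(n_win)) {
    if (b2[w] >= b1[w])
      feats[w, 1:6] <- ecg_features(bt[b1[w]:b2[w]])
  }

  ## SC: whole-record decomposition, sliced per window
  fs_sc <- subject$sc$fs
  dec <- sc_decompose(subject$sc$samples, fs_sc)
  ev_t <- (dec$events$peak_idx - 1) / fs_sc
  x_sc <- subject$sc$samples
  t_rel <- (seq_len(spec$window_s * fs_sc) - 1) / fs_sc
  for (w in seq_len(n_win)) {
    i1 <- round(win$start[w] * fs_sc) + 1L
    i2 <- min(round(win$end[w] * fs_sc), length(x_sc))
    idx <- i1:i2
    in_ev <- ev_t >= win$start[w] & ev_t < win$end[w]
    xs <- x_sc[idx]
    tonic <- dec$tonic[idx]
    feats[w, "sc_mean"] <- mean(tonic)
    feats[w, "sc_phasic"] <- mean(dec$phasic[idx]^2)
    feats[w, "sc_area"] <- sum(dec$events$area[in_ev])
    feats[w, "sc_scr_count"] <- sum(in_ev)
    feats[w, "sc_diff1"] <- mean(abs(diff(xs)))
    feats[w, "sc_diff2"] <- mean(abs(diff(xs, differences = 2)))
    feats[w, "sc_slope"] <- .ls_slope(t_rel[seq_along(idx)], tonic)
    feats[w, "sc_sd"] <- sd(xs)
  }

  ## ST: direct per-window stats
  fs_st <- subject$st$fs
  x_st <- subject$st$samples
  for (w in seq_len(n_win)) {
    i1 <- round(win$start[w] * fs_st) + 1L
    i2 <- min(round(win$end[w] * fs_st), length(x_st))
    feats[w, 15:18] <- st_features(x_st[i1:i2], fs_st)
  }

  ## ACC SD via cumulative sums (32 Hz windows are large)
  accsd <- .window_stat(subject$acc$samples, subject$acc$fs, win$start,
                        spec$window_s, "sd")

  qual_ecg <- vapply(seq_len(n_win), function(w)
    aggregate_window_quality(masks$ecg, win$start[w], win$end[w]), numeric(1))
  qual_sc <- vapply(seq_len(n_win), function(w)
    aggregate_window_quality(masks$sc, win$start[w], win$end[w]), numeric(1))
  qual_st <- vapply(seq_len(n_win), function(w)
    aggregate_window_quality(masks$st, win$start[w], win$end[w]), numeric(1))

  ## quality gating: a failed channel blanks only that channel's features
  feats[qual_ecg <= quality_min, 1:6] <- NA_real_
  feats[qual_sc <= quality_min, 7:14] <- NA_real_
  feats[qual_st <= quality_min, 15:18] <- NA_real_

  data.frame(subject_id = subject$profile$subject_id,
             window_start = win$start, feats,
             acc_sd = accsd, qual_ecg = qual_ecg, qual_sc = qual_sc,
             qual_st = qual_st, stringsAsFactors = FALSE)
}
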