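#' Adaptive RR-pattern template for ECG quality assessment
#'
#' Running template used by the ECG quality indicator. The template is the
#' mean resampled RR profile of the last \code{k} accepted 10-s segments; a
#' new segment must match it (normalized RMS-distance statistic, see
#' \code{\link{ecg_segment_quality}}) on top of passing the three interval
#' rules. The first segment passing the rules seeds the template.
#'
#' @param k number of accepted segments retained.
#' @param m resampled profile length.
#' @param threshold minimal match statistic for acceptance.
#' @return object of class \code{"qrs_template"}.
#' @export
qrs_template <- function(k = 5L, m = 10L, threshold = 0.66) {
  structure(list(profiles = matrix(numeric(0), nrow = 0, ncol = m),
                 k = k, m = m, threshold = threshold),
            class = "qrs_template")
}

## resample an RR sequence to fixed length m by linear interpolation
.rr_profile <- function(rr, m) {
  if (length(rr) == 1L) return(rep(rr, m))
  approx(seq_along(rr), rr, xout = seq(1, length(rr), length.out = m))$y
}

#' ECG segment quality indicator
#'
#' Rule-based quality verdict for one 10-s segment of an R-peak beat series:
#' the segment is bad if (i) the segment mean heart rate is outside
#' 40-180 bpm, (ii) any gap between successive R-peaks exceeds 3 s, (iii) the
#' ratio of the maximum to the minimum beat-to-beat interval is 2.2 or more,
#' or (iv) the segment's RR profile fails the adaptive template match.
#' Segments with fewer than two beats are bad (no heart rate can be
#' extracted and the implied gap exceeds 3 s over a 10-s segment). The
#' template updates only from accepted segments.
#'
#' The match statistic is \code{1 - RMS(profile - template) / mean(template)}
#' (clipped at 0): a scale-normalized distance between the segment's
#' resampled RR profile and the running template, compared against
#' \code{template$threshold}. A correlation statistic is degenerate for
#' near-constant clean RR profiles, so a distance statistic is used instead.
#'
#' @param beat_times R-peak times (seconds) falling inside the segment.
#' @param seg_start segment start time, seconds.
#' @param seg_len segment length, seconds (default 10).
#' @param template a \code{\link{qrs_template}}.
#' @return list with \code{good} (logical), \code{template} (updated) and
#'   \code{match} (the match statistic, \code{NA} if the rules already
#'   failed or the template is empty).
#' @export
ecg_segment_quality <- function(beat_times, seg_start = 0, seg_len = 10,
                                template = qrs_template()) {
  res <- list(good = FALSE, template = template, match = NA_real_)
  if (length(beat_times) < 2L) return(res)
  rr <- diff(beat_times)
  mean_hr <- 60 / mean(rr)
  if (mean_hr < 40 || mean_hr > 180) return(res)
  if (max(rr) > 3) return(res)
  if (max(rr) / min(rr) >= 2.2) return(res)

  profile <- .rr_profile(rr, template$m)
  if (nrow(template$profiles) == 0L) {
    ## bootstrap: first rule-passing segment seeds the template
    template$profiles <- matrix(profile, nrow = 1)
    return(list(good = TRUE, template = template, match = NA_real_))
  }
  tmpl <- colMeans(template$profiles)
  match <- max(0, 1 - sqrt(mean((profile - tmpl)^2)) / mean(tmpl))
  if (match < template$threshold) {
    res$match <- match
    return(res)
  }
  template$profiles <- rbind(template$profiles, profile)
  if (nrow(template$profiles) > template$k)
    template$profiles <- template$profiles[-1, , drop = FALSE]
  list(good = TRUE, template = template, match = match)
}

#' Quality mask container
#'
#' A mask is a uniform tiling of a recording into fixed-length segments with
#' one good/bad verdict per segment. Final partial segments are discarded
#' (marked bad).
#'
#' @param channel channel name.
#' @param seg_len segment length, seconds.
#' @param good logical verdict vector, one per segment.
#' @param t0 mask start time, seconds.
#' @return object of class \code{"quality_mask"}.
#' @export
quality_mask <- function(channel, seg_len, good, t0 = 0) {
  structure(list(channel = channel, seg_len = seg_len,
                 good = as.logical(good), t0 = t0),
            class = "quality_mask")
}

#' ECG quality mask over a whole beat series
#'
#' Applies \code{\link{ecg_segment_quality}} sequentially to consecutive
#' 10-s segments, carrying the adaptive template across segments.
#'
#' @param beats a \code{\link{beat_series}}.
#' @param duration recording duration, seconds.
#' @param seg_len segment length, seconds.
#' @param template starting \code{\link{qrs_template}}.
#' @return a \code{\link{quality_mask}} for channel \code{"ECG"}.
#' @export
ecg_quality_mask <- function(beats, duration, seg_len = 10,
                             template = qrs_template()) {
  n_seg <- floor(duration / seg_len)
  seg_of <- floor(beats$times / seg_len) + 1L
  by_seg <- split(beats$times, factor(seg_of, levels = seq_len(n_seg)))
  good <- logical(n_seg)
  for (s in seq_len(n_seg)) {
    r <- ecg_segment_quality(by_seg[[s]], (s - 1) * seg_len, seg_len, template)
    good[s] <- r$good
    template <- r$template
  }
  ## the per-segment rules only see within-segment gaps; additionally mark
  ## every segment overlapped by a series-level gap > 3 s (including leading
  ## and trailing beat-free stretches) as bad
  t <- beats$times
  gaps <- cbind(c(0, t[-length(t)], max(t)),
                c(t[1], t[-1], duration))
  gaps <- gaps[gaps[, 2] - gaps[, 1] > 3, , drop = FALSE]
  for (g in seq_len(nrow(gaps))) {
    s1 <- max(1L, floor(gaps[g, 1] / seg_len) + 1L)
    s2 <- min(n_seg, ceiling(gaps[g, 2] / seg_len))
    if (s1 <= s2) good[s1:s2] <- FALSE
  }
  quality_mask("ECG", seg_len, good)
}

## per-window SC rule evaluation on 1-s aggregates:
## relative change between adjacent within-window 1-s means
.sc_slew_bad <- function(sec_means) {
  if (length(sec_means) < 2L) return(FALSE)
  denom <- pmax(sec_means[-length(sec_means)], 1e-9)
  rel <- sec_means[-1] / denom - 1
  any(rel > 0.20 | rel < -0.10)
}

#' Skin-conductance window quality indicator
#'
#' A 5-s window is bad if the fraction of lost samples (value below
#' 0.001 uS) exceeds 0.9, or if between any two adjacent 1-s aggregates
#' within the window the signal rises by more than 20\% or falls by more
#' than 10\%. Empty windows are bad.
#'
#' @param x sample vector of one window.
#' @param fs sampling rate, Hz.
#' @return logical: \code{TRUE} if the window is of good quality.
#' @export
sc_window_quality <- function(x, fs) {
  if (length(x) == 0L) return(FALSE)
  if (mean(x < 0.001) > 0.9) return(FALSE)
  n_sec <- floor(length(x) / fs)
  if (n_sec >= 2L) {
    sec_means <- colMeans(matrix(x[seq_len(n_sec * fs)], nrow = fs))
    if (.sc_slew_bad(sec_means)) return(FALSE)
  }
  TRUE
}

#' Skin-conductance quality mask over a whole recording
#'
#' Vectorized application of \code{\link{sc_window_quality}} to consecutive
#' 5-s windows.
#'
#' @param rec a \code{\link{channel_recording}} with channel \code{"SC"}.
#' @param win_len window length, seconds.
#' @return a \code{\link{quality_mask}}.
#' @export
sc_quality_mask <- function(rec, win_len = 5) {
  fs <- rec$fs
  x <- rec$samples
  n_win <- floor(length(x) / (fs * win_len))
  npw <- fs * win_len
  xm <- matrix(x[seq_len(n_win * npw)], nrow = npw)
  lost_bad <- colMeans(xm < 0.001) > 0.9

  ## 1-s means, then relative change between adjacent seconds within a window
  n_sec <- n_win * win_len
  sec_means <- colMeans(matrix(x[seq_len(n_sec * fs)], nrow = fs))
  rel <- sec_means[-1] / pmax(sec_means[-n_sec], 1e-9) - 1
  viol <- rel > 0.20 | rel < -0.10
  ## diff at position j compares seconds j and j+1; it is within-window iff
  ## j+1 is not the first second of the next window
  within <- (seq_len(n_sec - 1) %% win_len) != 0
  viol_win <- as.logical(tapply(viol & within,
                                rep(seq_len(n_win), each = win_len)[-n_sec],
                                any))
  quality_mask("SC", win_len, !(lost_bad | viol_win))
}

#' Skin-temperature sample quality indicator
#'
#' A wrist skin-temperature sample is of good quality iff it lies inside the
#' physiological range 20-40 degrees Celsius (boundaries inclusive);
#' non-finite values are bad.
#'
#' @param x numeric vector of ST samples (Celsius).
#' @return logical vector.
#' @export
st_sample_quality <- function(x) {
  is.finite(x) & x >= 20 & x <= 40
}

#' Skin-temperature quality mask over a whole recording
#'
#' @param rec a \code{\link{channel_recording}} with channel \code{"ST"}.
#' @return a per-sample \code{\link{quality_mask}}.
#' @export
st_quality_mask <- function(rec) {
  quality_mask("ST", 1 / rec$fs, st_sample_quality(rec$samples))
}

#' Window-level quality fraction
#'
#' Time-weighted fraction of a window covered by good mask segments. The
#' downstream inclusion rule is \code{quality_fraction > 0.8}.
#'
#' @param mask a \code{\link{quality_mask}}.
#' @param start,end window boundaries, seconds (half-open).
#' @return numeric in [0, 1].
#' @export
aggregate_window_quality <- function(mask, start, end) {
  n_seg <- length(mask$good)
  cover_end <- mask$t0 + n_seg * mask$seg_len
  if (start < mask$t0 - 1e-9 || end > cover_end + 1e-9)
    stop("window not covered by quality mask")
  i1 <- floor((start - mask$t0) / mask$seg_len) + 1L
  i2 <- ceiling((end - mask$t0) / mask$seg_len)
  i2 <- min(i2, n_seg)
  idx <- i1:i2
  seg_start <- mask$t0 + (idx - 1) * mask$seg_len
  seg_end <- seg_start + mask$seg_len
  w <- pmin(end, seg_end) - pmax(start, seg_start)
  sum(w * mask$good[idx]) / (end - start)
}
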