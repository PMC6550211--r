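#' Benjamini-Hochberg adjustment and rejection set
#'
#' Step-up BH procedure at FDR level \code{q}: returns monotone adjusted
#' p-values and the rejection set (adjusted p <= q, identical to the
#' classical largest-i step-up rule).
#'
#' @param p p-values in [0, 1].
#' @param q FDR level.
#' @return list with \code{adjusted} and logical \code{reject}.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' State-wise median-difference matrix
#'
#' For each feature, the population median of the normalized rows is
#' computed per state (N, S1, S2, S3) and the six pairwise differences
#' N-S1, N-S2, N-S3, S1-S2, S2-S3, S1-S3 are reported, together with a
#' Wilcoxon rank-sum p-value per pair, BH-adjusted across the whole
#' feature-by-pair family, and a significance tier (* p<0.05, ** p<0.005,
#' *** p<0.0005 on the adjusted values). Pairs involving a state with no
#' rows are marked unavailable.
#'
#' @param rows normalized rows with a \code{state} column, already
#'   restricted to good-quality low-activity windows.
#' @param features feature names.
#' @param q FDR level for the BH correction.
#' @return data.frame of class \code{"state_matrix"}: \code{feature},
#'   \code{pair}, \code{diff}, \code{p}, \code{p_adj}, \code{sig}.
#' @export
state_median_matrix <- function(rows, features = feature_names(), q = 0.05) {
  states <- c("N", "S1", "S2", "S3")
  pairs <- list(c("N", "S1"), c("N", "S2"), c("N", "S3"),
                c("S1", "S2"), c("S2", "S3"), c("S1", "S3"))
  by_state <- lapply(setNames(states, states), function(s)
    rows[rows$state %in% s, , drop = FALSE])
  out <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(pairs, function(pr) {
      xa <- by_state[[pr[1]]][[f]]; xb <- by_state[[pr[2]]][[f]]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (!length(xa) || !length(xb)) {
        return(data.frame(feature = f, pair = paste(pr, collapse = "-"),
                          diff = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      data.frame(feature = f, pair = paste(pr, collapse = "-"),
                 diff = median(xa) - median(xb),
                 p = suppressWarnings(wilcox.test(xa, xb)$p.value),
                 stringsAsFactors = FALSE)
    }))
  }))
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok], q)$adjusted
  out$sig <- ifelse(is.na(out$p_adj), "",
                    ifelse(out$p_adj < 0.0005, "***",
                           ifelse(out$p_adj < 0.005, "**",
                                  ifelse(out$p_adj < 0.05, "*", ""))))
  class(out) <- c("state_matrix", "data.frame")
  out
}

#' Per-state population summary
#'
#' Population mean and central 95\% interval (2.5th-97.5th percentiles of
#' the pooled distribution) per feature per state. The interval is a
#' population spread measure, not a standard error of the mean.
#'
#' @param rows rows with a \code{state} column.
#' @param features feature names.
#' @param probs interval probabilities.
#' @return data.frame \code{feature}, \code{state}, \code{mean}, \code{lo},
#'   \code{hi}, \code{n}.
#' @export
population_summary <- function(rows, features = feature_names(),
                               probs = c(0.025, 0.975)) {
  states <- intersect(c("N", "S1", "S2", "S3"), unique(rows$state))
  do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(states, function(s) {
      x <- rows[[f]][rows$state %in% s]
      x <- x[!is.na(x)]
      n <- length(x)
      data.frame(feature = f, state = s,
                 mean = if (n) mean(x) else NA_real_,
                 lo = if (n >= 2) quantile(x, probs[1], names = FALSE) else NA_real_,
                 hi = if (n >= 2) quantile(x, probs[2], names = FALSE) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
  }))
}

#' Spearman rank correlation
#'
#' Rank transform with midranks for ties, then Pearson correlation of the
#' ranks (computed via \code{stats::cor}).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in [-1, 1].
#' @export
spearman_cor <- function(x, y) {
  cor(x, y, method = "spearman", use = "complete.obs")
}
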