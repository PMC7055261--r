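#' Confidence-response count table
#'
#' Cross-tabulates ground truth (old / new) against the six recognition
#' response codes 31..36 for one session's recognition trials.
#'
#' @param trials Recognition-phase trials with `new_old_label` (0 old, 1 new)
#'   and `response_value` in 31..36.
#' @return 2 x 6 integer matrix, rows `old`, `new`; columns `"31"`..`"36"`.
#' @export
confidence_counts <- function(trials) {
  if (any(trials$phase != "recognition")) {
    stop("confidence_counts expects recognition trials only")
  }
  if (anyNA(trials$new_old_label)) stop("recognition trials lack labels")
  truth <- factor(ifelse(trials$new_old_label == 0L, "old", "new"),
                  levels = c("old", "new"))
  resp <- factor(trials$response_value, levels = 31:36)
  as.matrix(table(truth, resp))
}

#' Confidence-ROC points
#'
#' Sweeps the decision threshold over the six confidence codes: for
#' `t = 36, 35, ..., 31`, the hit rate is `P(response >= t | old)` and the
#' false-alarm rate is `P(response >= t | new)`. The first point (threshold
#' 36, "old, confident") has the lowest false-alarm rate; the last point
#' (threshold 31) is always (1, 1).
#'
#' @param counts 2 x 6 table from [confidence_counts()].
#' @return data.frame with columns `threshold`, `fa`, `hit`, most conservative
#'   threshold first.
#' @export
roc_points <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 2, ncol(counts) == 6)
  n_old <- sum(counts["old", ])
  n_new <- sum(counts["new", ])
  if (n_old == 0 || n_new == 0) stop("both old and new trials are required")
  # response >= t, t descending 36..31 <=> reversed cumulative sums
  hit <- rev(cumsum(rev(counts["old", ]))) / n_old
  fa <- rev(cumsum(rev(counts["new", ]))) / n_new
  data.frame(threshold = 36:31, fa = rev(fa), hit = rev(hit))
}

#' Area under the confidence ROC (trapezoid rule)
#'
#' @param points ROC points from [roc_points()] (must be coordinate-wise
#'   nondecreasing; the curve is anchored at (0, 0)).
#' @return AUC in `[0, 1]`; 0.5 is chance.
#' @export
auc_trapezoid <- function(points) {
  fa <- c(0, points$fa)
  hit <- c(0, points$hit)
  if (any(diff(fa) < 0) || any(diff(hit) < 0)) {
    stop("ROC points must be nondecreasing in both coordinates")
  }
  sum(diff(fa) * (hit[-1] + hit[-length(hit)]) / 2)
}

#' zROC slope and bootstrap confidence interval
#'
#' Probit-transforms the interior ROC points (those with both coordinates
#' strictly inside (0, 1)) and fits a least-squares line of `qnorm(hit)` on
#' `qnorm(fa)`. Under an equal-variance strength model the slope is 1; a slope
#' below 1 is the classic asymmetric-ROC signature of declarative memory
#' (old-item strength more variable than new-item strength). The confidence
#' interval is a percentile bootstrap over trials.
#'
#' @param trials Recognition trials (used for the bootstrap resampling).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level of the interval (default 0.95).
#' @return List with `slope`, `ci` (two-element vector), `asymmetric`
#'   (`TRUE` iff the CI excludes 1) and `defined` (`FALSE` when fewer than 2
#'   interior points are usable, in which case the others are `NA`).
#' @export
zroc_slope <- function(trials, n_boot = 1000L, seed = 1L, conf = 0.95) {
  slope_of <- function(tr) {
    pts <- roc_points(confidence_counts(tr))
    keep <- pts$fa > 0 & pts$fa < 1 & pts$hit > 0 & pts$hit < 1
    if (sum(keep) < 2) return(NA_real_)
    stats::coef(stats::lm(stats::qnorm(hit) ~ stats::qnorm(fa),
                          data = pts[keep, ]))[[2]]
  }
  slope <- slope_of(trials)
  if (is.na(slope)) {
    return(list(slope = NA_real_, ci = c(NA_real_, NA_real_),
                asymmetric = NA, defined = FALSE))
  }
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      slope_of(trials[sample.int(nrow(trials), replace = TRUE), ])
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  list(slope = slope, ci = ci, asymmetric = ci[1] > 1 || ci[2] < 1,
       defined = TRUE)
}

#' Accuracy split by response confidence
#'
#' Compares old/new judgment accuracy between high- and low-confidence
#' responses. A judgment is correct when an old item (label 0) receives an
#' "old" response (code >= 34) or a new item (label 1) a "new" response
#' (code <= 33). The default grouping takes the two "confident" codes
#' {31, 36} as high confidence and the rest as low.
#'
#' @param trials Recognition trials with labels and responses.
#' @param high_codes Response codes counted as high confidence.
#' @return List with `acc_high`, `acc_low`, `n_high`, `n_low`; an empty group
#'   yields `NA` accuracy for that group.
#' @export
confidence_accuracy_split <- function(trials, high_codes = c(31L, 36L)) {
  code <- trials$response_value
  lab <- trials$new_old_label
  correct <- (lab == 0L & code >= 34L) | (lab == 1L & code <= 33L)
  hi <- code %in% high_codes
  list(acc_high = if (any(hi)) mean(correct[hi]) else NA_real_,
       acc_low = if (any(!hi)) mean(correct[!hi]) else NA_real_,
       n_high = sum(hi), n_low = sum(!hi))
}

#' Per-session behavioral summary
#'
#' @param trials Recognition trials of one session.
#' @param n_boot,seed Passed to [zroc_slope()].
#' @return One-row data.frame: `auc`, `zroc_slope`, `acc_high`, `acc_low`,
#'   `n_trials`.
#' @export
session_behavior_summary <- function(trials, n_boot = 1000L, seed = 1L) {
  rec <- trials[trials$phase == "recognition", ]
  auc <- auc_trapezoid(roc_points(confidence_counts(rec)))
  z <- zroc_slope(rec, n_boot = n_boot, seed = seed)
  acc <- confidence_accuracy_split(rec)
  data.frame(auc = auc, zroc_slope = z$slope,
             acc_high = acc$acc_high, acc_low = acc$acc_low,
             n_trials = nrow(rec))
}
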