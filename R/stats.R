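# Paired statistical comparison machinery: Mann-Whitney AUC, DeLong's test
# for correlated AUCs (midrank placements), the Diebold-Mariano test with
# the mean-absolute-deviation criterion in its exchangeable (lag-0) form,
# and seeded percentile bootstrap confidence intervals.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted 0.5; computed from midranks in O(n log n).
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stop_if(length(labels) != length(scores), "labels and scores lengths differ")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stop_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: V10[i] = fraction of negatives outscored by positive i
# (ties 0.5); V01[j] = fraction of positives outscoring negative j,
# complemented. mean(V10) = mean(V01) = AUC.
placements <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(n1)] - rank(pos)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(neg)) / n1
  list(v10 = v10, v01 = v01)
}

#' DeLong's test for two correlated AUCs
#'
#' Paired nonparametric comparison of the AUCs of two score vectors over
#' the same subjects, using midrank placement values for the variance of
#' the difference; two-sided p from the standard normal.
#'
#' @param labels Binary 0/1 outcome vector.
#' @param scores_a,scores_b Scores of the two models on the same subjects.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, and a `degenerate` flag
#'   (TRUE when the difference and its variance are both zero, in which
#'   case `p = 1`).
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  stop_if(length(scores_a) != length(scores_b) ||
            length(labels) != length(scores_a),
          "inputs must have equal lengths")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stop_if(n1 == 0 || n0 == 0, "both classes must be present")
  if (length(labels) < 10)
    warning("fewer than 10 subjects; normal approximation is crude")
  pa <- placements(labels, scores_a)
  pb <- placements(labels, scores_b)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  delta <- auc_a - auc_b
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (v <= .Machine$double.eps) {
    if (abs(delta) <= .Machine$double.eps^0.5) {
      return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1,
                  degenerate = TRUE))
    }
    stop("zero variance with a nonzero AUC difference", call. = FALSE)
  }
  z <- delta / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Diebold-Mariano test with the mean-absolute-deviation criterion
#'
#' Compares two models' per-subject prediction errors through the loss
#' differential `d_i = |e_a_i| - |e_b_i|`. Subjects are treated as
#' exchangeable (lag-0 variance), making the statistic a paired z-test on
#' absolute errors: `mean(d) / sqrt(var(d) / n)`, two-sided normal p.
#'
#' @param errors_a,errors_b Per-subject prediction errors of the two
#'   models (same subjects, same order).
#' @return List with `statistic`, `p`, `degenerate` flag.
#' @export
diebold_mariano <- function(errors_a, errors_b) {
  stop_if(length(errors_a) != length(errors_b), "error vectors differ in length")
  n <- length(errors_a)
  stop_if(n < 2, "need at least 2 subjects")
  if (n < 10) warning("fewer than 10 subjects; normal approximation is crude")
  d <- abs(errors_a) - abs(errors_b)
  v <- var(d)
  if (v <= .Machine$double.eps) {
    if (abs(mean(d)) <= .Machine$double.eps^0.5)
      return(list(statistic = 0, p = 1, degenerate = TRUE))
    stop("zero variance with a nonzero mean loss differential", call. = FALSE)
  }
  stat <- mean(d) / sqrt(v / n)
  list(statistic = stat, p = 2 * pnorm(-abs(stat)), degenerate = FALSE)
}

#' Seeded percentile bootstrap confidence interval
#'
#' Subject-level resampling with replacement; the interval is the 2.5/97.5
#' percentile range of the resampled metric and the point estimate is the
#' metric on the full data. Resamples on which the metric is undefined
#' (error or NA, e.g. a single-class AUC resample) are redrawn up to a cap.
#'
#' @param metric_fn Function of one data argument returning a scalar.
#' @param data A vector, or a data frame resampled by rows.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param redraw_cap Maximum total redraws before giving up.
#' @return List with `point`, `lo`, `hi`, `n_resamples`, `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_resamples = 2000, seed = 1,
                         conf = 0.95, redraw_cap = 10 * n_resamples) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stop_if(n == 0, "empty data")
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  point <- metric_fn(data)
  vals <- numeric(n_resamples)
  n_redrawn <- 0
  local_seed(seed, {
    for (k in seq_len(n_resamples)) {
      repeat {
        v <- tryCatch(metric_fn(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (!is.na(v)) break
        n_redrawn <- n_redrawn + 1
        stop_if(n_redrawn > redraw_cap,
                "bootstrap redraw cap exceeded (", n_redrawn, " failures)")
      }
      vals[k] <- v
    }
  })
  alpha <- (1 - conf) / 2
  qs <- quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  list(point = point, lo = qs[1], hi = qs[2],
       n_resamples = n_resamples, n_redrawn = n_redrawn)
}
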