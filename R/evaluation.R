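#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion from Beta quantiles:
#' lower bound `qbeta(alpha/2, k, n - k + 1)` (0 when k = 0), upper bound
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when k = n).
#'
#' @param k number of successes, 0 <= k <= n.
#' @param n number of trials, n >= 1.
#' @param conf confidence level in (0, 1).
#' @return Numeric `c(lo, hi)`.
#' @examples
#' clopper_pearson(32, 32)  # upper bound 1, lower bound 0.025^(1/32)
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  abort_if(n < 1 || k < 0 || k > n || conf <= 0 || conf >= 1,
           "need 0 <= k <= n, n >= 1 and 0 < conf < 1")
  a <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

metric_ci <- function(estimate, n, conf = 0.95) {
  ci <- clopper_pearson(round(estimate * n), n, conf)
  structure(list(estimate = estimate, ci_low = ci[["lo"]],
                 ci_high = ci[["hi"]], n = n, conf = conf),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.4f (%d%% CI %.4f, %.4f; n = %d)\n", x$estimate,
              round(x$conf * 100), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Per-class accuracy with exact confidence interval
#'
#' The proportion of targets whose true score equals `class` that are
#' predicted correctly, with a Clopper-Pearson interval on that
#' proportion.
#'
#' @param predicted,true aligned numeric score vectors.
#' @param class the true score selecting the stratum.
#' @param conf confidence level.
#' @return A `metric_ci`, or `NULL` when the class is absent.
#' @export
accuracy_by_class <- function(predicted, true, class, conf = 0.95) {
  abort_if(length(predicted) != length(true), "length mismatch")
  sel <- true == class
  if (!any(sel)) return(NULL)
  metric_ci(mean(predicted[sel] == true[sel]), sum(sel), conf)
}

#' Pooled micro-averaged F1 with precision and recall
#'
#' For a multi-class scorer, micro-averaged F1 over the three score
#' classes (which equals overall accuracy when every instance receives
#' exactly one prediction). For a binary scorer, F1 of the positive merged
#' class {0.5, 1}. Confidence intervals treat the statistic as a
#' proportion with the evaluation-set size as n (exact Clopper-Pearson),
#' mirroring common reporting practice; a seeded bootstrap interval is
#' also returned as the statistically conventional alternative.
#'
#' @param predicted,true aligned label vectors (scores, or binary 0/1).
#' @param positive `NULL` for micro-averaged multi-class; otherwise the
#'   positive label of the binary problem.
#' @param conf confidence level.
#' @param bootstrap number of bootstrap resamples (0 disables).
#' @param seed seed for the bootstrap.
#' @return A list of class `f1_metric`: `f1`, `precision`, `recall` (each
#'   a `metric_ci`), plus `f1_boot_ci` when bootstrapping.
#' @export
f1_pooled <- function(predicted, true, positive = NULL, conf = 0.95,
                      bootstrap = 0, seed = 1) {
  abort_if(length(predicted) != length(true), "length mismatch")
  n <- length(true)
  f1_of <- function(pred, tr) {
    if (is.null(positive)) {
      # micro average: pooled TP / FP / FN over classes
      tp <- sum(pred == tr)
      fp <- sum(pred != tr)  # each error is one FP and one FN
      fn <- fp
    } else {
      tp <- sum(pred == positive & tr == positive)
      fp <- sum(pred == positive & tr != positive)
      fn <- sum(pred != positive & tr == positive)
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    c(f1 = f1, precision = prec, recall = rec)
  }
  est <- f1_of(predicted, true)
  out <- list(f1 = metric_ci(est[["f1"]], n, conf),
              precision = metric_ci(est[["precision"]], n, conf),
              recall = metric_ci(est[["recall"]], n, conf))
  if (bootstrap > 0) {
    set.seed(stage_seed(seed, "f1_boot"))
    bs <- replicate(bootstrap, {
      i <- sample.int(n, n, replace = TRUE)
      f1_of(predicted[i], true[i])[["f1"]]
    })
    out$f1_boot_ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                      na.rm = TRUE, names = FALSE)
  }
  class(out) <- "f1_metric"
  out
}

#' @export
print.f1_metric <- function(x, ...) {
  cat("F1:        "); print(x$f1)
  cat("precision: "); print(x$precision)
  cat("recall:    "); print(x$recall)
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the normalized Mann-Whitney U statistic: the fraction
#' of positive-negative pairs ranked concordantly, ties counted one half.
#'
#' @param probs predicted probabilities of the positive class.
#' @param truth binary ground truth (logical or 0/1).
#' @param conf confidence level for the Clopper-Pearson-style interval
#'   (statistic treated as a proportion with the evaluation size as n).
#' @return A `metric_ci`.
#' @export
auc_mw <- function(probs, truth, conf = 0.95) {
  abort_if(length(probs) != length(truth), "length mismatch")
  truth <- as.logical(truth > 0 | truth == TRUE)
  n1 <- sum(truth); n0 <- sum(!truth)
  abort_if(n1 == 0 || n0 == 0,
           "undefined AUC: both classes must be present")
  r <- rank(probs, ties.method = "average")
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  metric_ci(auc, length(truth), conf)
}

#' Filtering outcome report
#'
#' Tabulates how many images the lenient and strict algorithms filtered,
#' how many of those filtered verdicts agree with ground truth (hits), and
#' the overall filtering rate.
#'
#' @param verdicts character vector of filter verdicts ("FILTERED_FAIL",
#'   "FILTERED_PASS", "NEEDS_HUMAN").
#' @param truth_passed logical vector of ground-truth ACR verdicts.
#' @return A list of class `filtering_report` with fields `n_images`,
#'   `n_true_pass`, `n_true_fail`, `lenient` and `strict`
#'   (predictions and hits), `total_filtered`, `total_hits`,
#'   `filtering_rate`, `predictive_value`.
#' @export
filtering_report <- function(verdicts, truth_passed) {
  abort_if(length(verdicts) != length(truth_passed), "length mismatch")
  lp <- verdicts == "FILTERED_FAIL"
  sp <- verdicts == "FILTERED_PASS"
  rep <- list(
    n_images = length(verdicts),
    n_true_pass = sum(truth_passed),
    n_true_fail = sum(!truth_passed),
    lenient = c(predictions = sum(lp), hits = sum(lp & !truth_passed)),
    strict = c(predictions = sum(sp), hits = sum(sp & truth_passed)),
    total_filtered = sum(lp | sp)
  )
  rep$total_hits <- rep$lenient[["hits"]] + rep$strict[["hits"]]
  rep$filtering_rate <- rep$total_filtered / rep$n_images
  rep$predictive_value <- if (rep$total_filtered > 0)
    rep$total_hits / rep$total_filtered else NA_real_
  class(rep) <- "filtering_report"
  rep
}

#' @export
print.filtering_report <- function(x, ...) {
  cat(sprintf("filtering_report: %d images (%d pass / %d fail)\n",
              x$n_images, x$n_true_pass, x$n_true_fail))
  cat(sprintf("  lenient: %d/%d hits, strict: %d/%d hits\n",
              x$lenient[["hits"]], x$lenient[["predictions"]],
              x$strict[["hits"]], x$strict[["predictions"]]))
  cat(sprintf("  total filtered %d/%d (%.0f%%), predictive value %s\n",
              x$total_filtered, x$n_images, 100 * x$filtering_rate,
              if (is.na(x$predictive_value)) "n/a"
              else sprintf("%.0f%%", 100 * x$predictive_value)))
  invisible(x)
}
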