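#' Threshold pair of the two-step score assignment
#'
#' @param t_bcc probability threshold on the binary head's visible-class
#'   probability (step 1: score 0 vs score 0.5-or-1).
#' @param t_mcc probability threshold on the three-class head's score-1
#'   probability (step 2: score 0.5 vs score 1).
#' @return A list of class `pfa_thresholds`.
#' @export
pfa_thresholds <- function(t_bcc, t_mcc) {
  check_prob(c(t_bcc, t_mcc), "thresholds")
  structure(list(t_bcc = t_bcc, t_mcc = t_mcc), class = "pfa_thresholds")
}

#' Two-step probability-to-score assignment
#'
#' Step 1 uses the binary head: if the visible-class probability is below
#' `t$t_bcc` the target scores 0. Step 2 uses the three-class head's
#' score-1 probability: at or above `t$t_mcc` the target scores 1,
#' otherwise 0.5. Both comparisons use the >= (clear-the-threshold)
#' convention. Vectorized over targets.
#'
#' @param bcc_prob probability of the merged class {0.5, 1}.
#' @param mcc_prob_score1 probability of score 1 from the 3-class head.
#' @param t a [pfa_thresholds()] pair.
#' @return Numeric score(s) in {0, 0.5, 1}.
#' @export
assign_score <- function(bcc_prob, mcc_prob_score1, t) {
  check_prob(bcc_prob, "bcc_prob")
  check_prob(mcc_prob_score1, "mcc_prob_score1")
  abort_if(!inherits(t, "pfa_thresholds"), "t must be pfa_thresholds")
  ifelse(bcc_prob < t$t_bcc, 0, ifelse(mcc_prob_score1 >= t$t_mcc, 1, 0.5))
}

#' Lenient/strict filter decision for one phantom image
#'
#' Scores all 16 targets twice -- once with the lenient (low) thresholds
#' and once with the strict (high) thresholds -- and converts both score
#' sets into ACR verdicts. An image that fails even under lenient scoring
#' is a definite fail (`FILTERED_FAIL`); one that passes even under strict
#' scoring is a definite pass (`FILTERED_PASS`); everything else goes to
#' the human reading queue (`NEEDS_HUMAN`). With lenient thresholds
#' componentwise at or below the strict ones, the two filtered verdicts are
#' mutually exclusive.
#'
#' @param outputs data.frame with one row per target: columns `kind`,
#'   `rank`, `bcc_prob` and `p1` (score-1 probability of the 3-class
#'   head); exactly 16 rows covering all kinds/ranks.
#' @param lenient,strict [pfa_thresholds()] pairs,
#'   `lenient <= strict` componentwise.
#' @param stop_at_zero passed to the ACR subtotal rule.
#' @return A list of class `filter_decision`: `verdict` (one of
#'   "FILTERED_FAIL", "FILTERED_PASS", "NEEDS_HUMAN"), `lenient_score` and
#'   `strict_score` ([image_passfail()] objects).
#' @export
filter_image <- function(outputs, lenient, strict, stop_at_zero = TRUE) {
  abort_if(!inherits(lenient, "pfa_thresholds") ||
             !inherits(strict, "pfa_thresholds"),
           "lenient and strict must be pfa_thresholds")
  abort_if(lenient$t_bcc > strict$t_bcc || lenient$t_mcc > strict$t_mcc,
           "invalid configuration: lenient thresholds exceed strict ones")
  abort_if(nrow(outputs) != 16, "need exactly 16 target outputs")
  key <- paste(outputs$kind, outputs$rank)
  want <- c(paste("fiber", 1:6), paste("speck_group", 1:5),
            paste("mass", 1:5))
  abort_if(!setequal(key, want) || anyDuplicated(key) > 0,
           "outputs must cover each of the 16 targets exactly once")

  score_with <- function(t) {
    sc <- outputs
    sc$score <- assign_score(outputs$bcc_prob, outputs$p1, t)
    score_image(sc, stop_at_zero)
  }
  len <- score_with(lenient)
  str <- score_with(strict)
  verdict <- if (!len$passed) "FILTERED_FAIL"
             else if (str$passed) "FILTERED_PASS"
             else "NEEDS_HUMAN"
  structure(list(verdict = verdict, lenient_score = len, strict_score = str),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(sprintf("filter_decision: %s (lenient %s, strict %s)\n", x$verdict,
              if (x$lenient_score$passed) "pass" else "fail",
              if (x$strict_score$passed) "pass" else "fail"))
  invisible(x)
}

#' Apply the filtering algorithm to a table of many images
#'
#' @param outputs data.frame as in [filter_image()] plus an `image_id`
#'   column; 16 rows per image.
#' @inheritParams filter_image
#' @return A data.frame with one row per image: `image_id`, `verdict`,
#'   lenient and strict subtotals and pass flags.
#' @export
filter_images <- function(outputs, lenient, strict, stop_at_zero = TRUE) {
  ids <- unique(outputs$image_id)
  rows <- lapply(ids, function(id) {
    d <- filter_image(outputs[outputs$image_id == id, , drop = FALSE],
                      lenient, strict, stop_at_zero)
    data.frame(image_id = id, verdict = d$verdict,
               lenient_fibers = d$lenient_score$fiber_subtotal,
               lenient_specks = d$lenient_score$speck_subtotal,
               lenient_masses = d$lenient_score$mass_subtotal,
               lenient_passed = d$lenient_score$passed,
               strict_fibers = d$strict_score$fiber_subtotal,
               strict_specks = d$strict_score$speck_subtotal,
               strict_masses = d$strict_score$mass_subtotal,
               strict_passed = d$strict_score$passed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grid search for the lenient and strict threshold pairs
#'
#' Evaluates every combination of candidate lenient and strict threshold
#' pairs on a development set, computing for each the number of filtered
#' images and the pooled predictive value (hits over predictions, where a
#' hit is a filtered verdict agreeing with the ground-truth ACR verdict;
#' lenient and strict predictions are pooled, matching a
#' predictive-value-first selection policy). The combination with the
#' highest predictive value wins; ties break toward more filtered images,
#' then toward lower thresholds. Combinations that filter nothing have
#' undefined predictive value and are never selected over defined ones.
#'
#' @param outputs per-target probability table as in [filter_images()].
#' @param truth data.frame with columns `image_id` and `passed` (logical
#'   ground-truth ACR verdict).
#' @param lenient_grid,strict_grid data.frames of candidate `t_bcc`,
#'   `t_mcc` values; defaults are the 0.1-step grids over the lenient
#'   range 0.3-0.4 (BCC) x 0.3-0.5 (MCC) and the strict range 0.6-0.7 x
#'   0.4-0.6.
#' @param stop_at_zero passed to the ACR subtotal rule.
#' @return A list with `lenient` and `strict` (selected
#'   [pfa_thresholds()]), `report` (one row per combination with counts,
#'   per-algorithm and pooled hit rates) and `selected` (the winning row).
#' @export
threshold_search <- function(outputs, truth,
                             lenient_grid = expand.grid(t_bcc = c(0.3, 0.4),
                                                        t_mcc = c(0.3, 0.4, 0.5)),
                             strict_grid = expand.grid(t_bcc = c(0.6, 0.7),
                                                       t_mcc = c(0.4, 0.5, 0.6)),
                             stop_at_zero = TRUE) {
  abort_if(nrow(lenient_grid) == 0 || nrow(strict_grid) == 0,
           "threshold grids must be non-empty")
  abort_if(!all(c("image_id", "passed") %in% names(truth)),
           "truth needs image_id and passed columns")
  ids <- unique(outputs$image_id)
  abort_if(!all(ids %in% truth$image_id),
           "every image needs a ground-truth verdict")
  truth_pass <- truth$passed[match(ids, truth$image_id)]

  combos <- merge(cbind(lenient_grid, .l = seq_len(nrow(lenient_grid))),
                  cbind(strict_grid, .s = seq_len(nrow(strict_grid))),
                  by = NULL, suffixes = c("_len", "_str"))
  report <- combos[, c("t_bcc_len", "t_mcc_len", "t_bcc_str", "t_mcc_str")]
  report$feasible <- report$t_bcc_len <= report$t_bcc_str &
    report$t_mcc_len <= report$t_mcc_str
  report$n_filtered <- NA_integer_
  report$n_hits <- NA_integer_
  report$predictive_value <- NA_real_
  report$lenient_predictions <- report$lenient_hits <- NA_integer_
  report$strict_predictions <- report$strict_hits <- NA_integer_

  for (i in seq_len(nrow(report))) {
    # combinations where a lenient threshold exceeds its strict counterpart
    # void the definite-pass/definite-fail guarantee and are not evaluated
    if (!report$feasible[i]) next
    len <- pfa_thresholds(report$t_bcc_len[i], report$t_mcc_len[i])
    str <- pfa_thresholds(report$t_bcc_str[i], report$t_mcc_str[i])
    dec <- filter_images(outputs, len, str, stop_at_zero)
    dec <- dec[match(ids, dec$image_id), ]
    lp <- dec$verdict == "FILTERED_FAIL"
    sp <- dec$verdict == "FILTERED_PASS"
    report$lenient_predictions[i] <- sum(lp)
    report$lenient_hits[i] <- sum(lp & !truth_pass)
    report$strict_predictions[i] <- sum(sp)
    report$strict_hits[i] <- sum(sp & truth_pass)
    report$n_filtered[i] <- sum(lp | sp)
    report$n_hits[i] <- report$lenient_hits[i] + report$strict_hits[i]
    report$predictive_value[i] <- if (report$n_filtered[i] > 0)
      report$n_hits[i] / report$n_filtered[i] else NA_real_
  }

  abort_if(!any(report$feasible), "no feasible threshold combination")
  ord <- order(-ifelse(is.na(report$predictive_value), -Inf,
                       report$predictive_value),
               -ifelse(is.na(report$n_filtered), 0L, report$n_filtered),
               report$t_bcc_len, report$t_mcc_len,
               report$t_bcc_str, report$t_mcc_str)
  best <- report[ord[1], ]
  list(lenient = pfa_thresholds(best$t_bcc_len, best$t_mcc_len),
       strict = pfa_thresholds(best$t_bcc_str, best$t_mcc_str),
       selected = best, report = report)
}
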