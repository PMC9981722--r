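#' ACR subtotal of one target series
#'
#' Applies the standard ACR counting rule to a rank-ordered series of
#' per-target visibility scores: scores are summed from the largest target
#' onward and counting stops before the first fully invisible target
#' (score 0); anything beyond contributes nothing. A plain-sum mode is
#' provided for the alternative reading of the rule.
#'
#' @param scores numeric vector of scores in {0, 0.5, 1}, ordered rank 1
#'   (largest) to K (smallest).
#' @param stop_at_zero logical; `FALSE` sums all scores.
#' @return The subtotal, a multiple of 0.5 in [0, K].
#' @examples
#' shape_subtotal(c(1, 1, 1, 1, 0, 1))  # 4
#' @export
shape_subtotal <- function(scores, stop_at_zero = TRUE) {
  abort_if(length(scores) == 0 || !all(scores %in% SCORE_LEVELS),
           "invalid score: each score must be 0, 0.5 or 1")
  if (stop_at_zero) {
    z <- which(scores == 0)
    if (length(z) > 0) scores <- scores[seq_len(z[1] - 1L)]
  }
  sum(scores)
}

#' Image-level ACR pass/fail verdict
#'
#' An image passes when, at minimum, the four largest fibers, the three
#' largest speck groups and the three largest masses are visible:
#' fiber subtotal >= 4, speck subtotal >= 3 and mass subtotal >= 3.
#'
#' @param fiber_subtotal,speck_subtotal,mass_subtotal subtotals from
#'   [shape_subtotal()]; multiples of 0.5 within [0, 6], [0, 5], [0, 5].
#' @return An object of class `image_score`: list with the three subtotals
#'   and `passed`.
#' @export
image_passfail <- function(fiber_subtotal, speck_subtotal, mass_subtotal) {
  subs <- c(fiber_subtotal, speck_subtotal, mass_subtotal)
  abort_if(any(subs < 0) || any(subs * 2 != round(subs * 2)) ||
             fiber_subtotal > 6 || speck_subtotal > 5 || mass_subtotal > 5,
           "subtotals must be multiples of 0.5 within range")
  structure(list(fiber_subtotal = fiber_subtotal,
                 speck_subtotal = speck_subtotal,
                 mass_subtotal = mass_subtotal,
                 passed = fiber_subtotal >= 4 && speck_subtotal >= 3 &&
                   mass_subtotal >= 3),
            class = "image_score")
}

#' @export
print.image_score <- function(x, ...) {
  cat(sprintf("image_score: fibers %.1f, specks %.1f, masses %.1f -> %s\n",
              x$fiber_subtotal, x$speck_subtotal, x$mass_subtotal,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Score a full 16-target score table
#'
#' Convenience wrapper from a per-target score table (columns `kind`,
#' `rank`, `score`) to the image-level [image_passfail()] verdict.
#'
#' @param scores data.frame with columns `kind`, `rank`, `score`.
#' @param stop_at_zero passed to [shape_subtotal()].
#' @return An `image_score`.
#' @export
score_image <- function(scores, stop_at_zero = TRUE) {
  subs <- vapply(TARGET_KINDS, function(k) {
    s <- scores[scores$kind == k, ]
    abort_if(nrow(s) == 0, sprintf("no scores for kind %s", k))
    shape_subtotal(s$score[order(s$rank)], stop_at_zero)
  }, 0)
  image_passfail(subs[["fiber"]], subs[["speck_group"]], subs[["mass"]])
}
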