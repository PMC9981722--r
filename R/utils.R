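#' Derive a stage-specific random seed from a global seed
#'
#' All randomness in the package flows from one global seed through named
#' substreams, so that independent pipeline stages draw from decoupled but
#' reproducible streams. The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. "generate", "split", "train").
#' @param index optional integer distinguishing repeated draws in one stage.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + as.numeric(index) * 31) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' @keywords internal
check_prob <- function(p, what = "probability") {
  abort_if(any(!is.finite(p) | p < 0 | p > 1),
           sprintf("%s must lie in [0, 1]", what))
  invisible(p)
}

TARGET_KINDS <- c("fiber", "speck_group", "mass")
SCORE_LEVELS <- c(0, 0.5, 1)
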