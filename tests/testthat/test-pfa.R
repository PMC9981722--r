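make_outputs <- function(bcc, p1, image_id = "img1") {
  data.frame(image_id = image_id,
             kind = c(rep("fiber", 6), rep("speck_group", 5), rep("mass", 5)),
             rank = c(1:6, 1:5, 1:5),
             bcc_prob = bcc, p1 = p1, stringsAsFactors = FALSE)
}

test_that("two-step assignment follows the BCC-then-MCC rule", {
  la <- pfa_thresholds(0.3, 0.3)
  sa <- pfa_thresholds(0.7, 0.5)
  expect_equal(assign_score(0.2, 0.9, la), 0)    # step 1 gates everything
  expect_equal(assign_score(0.9, 0.8, la), 1)
  expect_equal(assign_score(0.65, 0.45, sa), 0)  # below strict BCC gate
  expect_equal(assign_score(0.65, 0.45, la), 1)  # clears both lenient gates
  # boundary: >= convention at both steps
  expect_equal(assign_score(0.3, 0.29, la), 0.5)
  expect_equal(assign_score(0.3, 0.3, la), 1)
  expect_equal(assign_score(0.29999, 1, la), 0)
  expect_error(assign_score(1.2, 0.5, la), "bcc_prob")
  expect_error(assign_score(0.5, -0.1, la), "mcc_prob")
})

test_that("assign_score is monotone and lenient scores dominate strict", {
  set.seed(42)
  la <- pfa_thresholds(0.3, 0.3)
  sa <- pfa_thresholds(0.7, 0.5)
  b <- runif(5000); p <- runif(5000)
  s_len <- assign_score(b, p, la)
  s_str <- assign_score(b, p, sa)
  expect_true(all(s_len >= s_str))
  # monotone non-decreasing in both probabilities
  eps <- 0.05
  expect_true(all(assign_score(pmin(b + eps, 1), p, la) >= s_len))
  expect_true(all(assign_score(b, pmin(p + eps, 1), la) >= s_len))
})

test_that("filter verdicts follow the definite-fail/definite-pass rule", {
  la <- pfa_thresholds(0.3, 0.3)
  sa <- pfa_thresholds(0.7, 0.5)
  expect_equal(filter_image(make_outputs(rep(1, 16), rep(1, 16)), la, sa)$verdict,
               "FILTERED_PASS")
  expect_equal(filter_image(make_outputs(rep(0, 16), rep(0, 16)), la, sa)$verdict,
               "FILTERED_FAIL")
  # lenient passes (all scores at least 0.5 with p >= 0.3) but the strict
  # pass needs full ones; here strict assigns 0.5 everywhere -> fail
  mid <- make_outputs(rep(0.9, 16), rep(0.45, 16))
  d <- filter_image(mid, la, sa)
  expect_equal(d$verdict, "NEEDS_HUMAN")
  expect_true(d$lenient_score$passed)
  expect_false(d$strict_score$passed)
})

test_that("incomplete tables and inverted thresholds are rejected", {
  la <- pfa_thresholds(0.3, 0.3)
  sa <- pfa_thresholds(0.7, 0.5)
  out <- make_outputs(rep(1, 16), rep(1, 16))
  expect_error(filter_image(out[-1, ], la, sa), "16")
  dup <- out; dup$rank[2] <- 1L
  expect_error(filter_image(dup, la, sa), "exactly once")
  expect_error(filter_image(out, sa, la), "invalid configuration")
})

test_that("definite-fail and definite-pass are mutually exclusive", {
  set.seed(7)
  n <- 2000
  for (i in seq_len(n)) {
    sa <- pfa_thresholds(runif(1, 0.5, 1), runif(1, 0.5, 1))
    la <- pfa_thresholds(runif(1, 0, sa$t_bcc), runif(1, 0, sa$t_mcc))
    out <- make_outputs(runif(16), runif(16))
    d <- filter_image(out, la, sa)
    both <- !d$lenient_score$passed && d$strict_score$passed
    if (both) fail(sprintf("lenient-fail and strict-pass at case %d", i))
  }
  succeed()
})

test_that("threshold search matches an independent brute-force evaluation", {
  set.seed(19)
  n_img <- 40
  outputs <- do.call(rbind, lapply(seq_len(n_img), function(i)
    make_outputs(runif(16), runif(16), sprintf("img%02d", i))))
  truth <- data.frame(image_id = sprintf("img%02d", seq_len(n_img)),
                      passed = sample(c(TRUE, FALSE), n_img, replace = TRUE))
  res <- threshold_search(outputs, truth)

  # independent re-evaluation: plain loops, no package filtering code
  eval_combo <- function(lb, lm, sb, sm) {
    preds <- 0; hits <- 0
    for (i in seq_len(n_img)) {
      o <- outputs[outputs$image_id == truth$image_id[i], ]
      sc <- function(tb, tm) {
        s <- ifelse(o$bcc_prob < tb, 0, ifelse(o$p1 >= tm, 1, 0.5))
        subs <- sapply(split(s, o$kind), function(v) {
          z <- which(v == 0)
          sum(v[seq_len(if (length(z)) z[1] - 1 else length(v))])
        })
        subs[["fiber"]] >= 4 && subs[["speck_group"]] >= 3 &&
          subs[["mass"]] >= 3
      }
      lp <- sc(lb, lm); sp <- sc(sb, sm)
      if (!lp) { preds <- preds + 1; hits <- hits + !truth$passed[i] }
      else if (sp) { preds <- preds + 1; hits <- hits + truth$passed[i] }
    }
    c(preds, hits)
  }
  for (i in seq_len(nrow(res$report))) {
    row <- res$report[i, ]
    if (!row$feasible) next
    bf <- eval_combo(row$t_bcc_len, row$t_mcc_len, row$t_bcc_str, row$t_mcc_str)
    expect_equal(row$n_filtered, bf[1], info = paste("combo", i))
    expect_equal(row$n_hits, bf[2], info = paste("combo", i))
  }
  # the selected combination attains the maximal predictive value
  pv <- res$report$predictive_value
  expect_equal(res$selected$predictive_value, max(pv, na.rm = TRUE))
})

test_that("perfect classifiers tie-break toward more filtering, then lower thresholds", {
  set.seed(23)
  n_img <- 30
  rows <- lapply(seq_len(n_img), function(i) {
    passed <- i %% 2 == 0
    s <- if (passed) rep(1, 16) else rep(0, 16)
    make_outputs(s, s, sprintf("img%02d", i))
  })
  outputs <- do.call(rbind, rows)
  truth <- data.frame(image_id = sprintf("img%02d", seq_len(n_img)),
                      passed = seq_len(n_img) %% 2 == 0)
  res <- threshold_search(outputs, truth)
  feas <- res$report[res$report$feasible, ]
  expect_true(all(feas$predictive_value == 1))
  expect_equal(res$selected$n_filtered, n_img)
  # all combos filter everything, so the lexicographically lowest wins
  expect_equal(c(res$lenient$t_bcc, res$lenient$t_mcc), c(0.3, 0.3))
  expect_equal(c(res$strict$t_bcc, res$strict$t_mcc), c(0.6, 0.4))
})

test_that("combinations that filter nothing are recorded as undefined, never selected", {
  # probabilities landing every target at lenient-pass / strict-fail
  outputs <- do.call(rbind, lapply(1:6, function(i)
    make_outputs(rep(0.5, 16), rep(0.35, 16), sprintf("img%02d", i))))
  truth <- data.frame(image_id = sprintf("img%02d", 1:6), passed = TRUE)
  res <- threshold_search(
    outputs, truth,
    lenient_grid = data.frame(t_bcc = c(0.3, 0.6), t_mcc = c(0.3, 0.3)),
    strict_grid = data.frame(t_bcc = 0.7, t_mcc = 0.5))
  rep <- res$report
  undef <- rep$feasible & rep$n_filtered == 0
  expect_true(any(undef))
  expect_true(all(is.na(rep$predictive_value[undef])))
  expect_equal(res$selected$t_bcc_len, 0.6)  # the defined combination wins
})
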