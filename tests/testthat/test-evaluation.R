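test_that("Clopper-Pearson matches closed forms at the boundaries", {
  expect_equal(clopper_pearson(0, 10)[["lo"]], 0)
  expect_equal(clopper_pearson(10, 10)[["hi"]], 1)
  ci <- clopper_pearson(32, 32)
  expect_equal(ci[["hi"]], 1)
  expect_equal(ci[["lo"]], 0.025^(1 / 32), tolerance = 1e-10)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(0, 0), "n >= 1")
})

test_that("Clopper-Pearson agrees with binom.test for every (k, n), n <= 25", {
  for (n in 1:25) for (k in 0:n) {
    ref <- binom.test(k, n)$conf.int
    got <- clopper_pearson(k, n)
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10,
                 info = sprintf("k=%d n=%d", k, n))
  }
})

test_that("Clopper-Pearson bounds invert the exact binomial tails", {
  # independent enumeration oracle: the upper bound is the p solving
  # P(X <= k) = alpha/2 and the lower bound solves P(X >= k) = alpha/2,
  # with the exact tail computed by summing binomial pmf terms.
  tail_le <- function(p, k, n) sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - 0:k))
  for (n in c(5, 12, 25)) for (k in 0:n) {
    ci <- clopper_pearson(k, n)
    if (k < n) {
      hi <- uniroot(function(p) tail_le(p, k, n) - 0.025, c(1e-12, 1 - 1e-12),
                    tol = 1e-12)$root
      expect_equal(ci[["hi"]], hi, tolerance = 1e-6)
    }
    if (k > 0) {
      lo <- uniroot(function(p) (1 - tail_le(p, k - 1, n)) - 0.025,
                    c(1e-12, 1 - 1e-12), tol = 1e-12)$root
      expect_equal(ci[["lo"]], lo, tolerance = 1e-6)
    }
  }
})

test_that("interval width shrinks with n at a fixed success ratio", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- clopper_pearson(round(0.7 * n), n)
    ci[["hi"]] - ci[["lo"]]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("per-class accuracy counts the right stratum", {
  pred <- c(1, 1, 0.5, 0, 0, 1, 1, 1)
  true <- c(1, 1, 1, 0, 0.5, 1, 1, 1)
  m <- accuracy_by_class(pred, true, class = 1)
  expect_equal(m$estimate, 5 / 6)
  expect_equal(m$n, 6)
  ci <- clopper_pearson(5, 6)
  expect_equal(c(m$ci_low, m$ci_high), unname(ci))
  m34 <- accuracy_by_class(c(1, 1, 1, 0), c(1, 1, 1, 1), class = 1)
  expect_equal(m34$estimate, 0.75)
  expect_equal(c(m34$ci_low, m34$ci_high), unname(clopper_pearson(3, 4)))
  expect_null(accuracy_by_class(pred, true, class = 2))
})

test_that("pooled F1 reproduces hand-computed confusion counts", {
  perfect <- f1_pooled(c(0, 0.5, 1, 1), c(0, 0.5, 1, 1))
  expect_equal(perfect$f1$estimate, 1)
  # binary with TP=9, FP=1, FN=1
  pred <- c(rep(1, 10), rep(0, 10))
  true <- c(rep(1, 9), 0, rep(0, 9), 1)
  b <- f1_pooled(pred, true, positive = 1)
  expect_equal(b$precision$estimate, 0.9)
  expect_equal(b$recall$estimate, 0.9)
  expect_equal(b$f1$estimate, 0.9)
  # micro-averaged multi-class F1 equals plain accuracy
  set.seed(3)
  p <- sample(c(0, 0.5, 1), 60, replace = TRUE)
  t <- sample(c(0, 0.5, 1), 60, replace = TRUE)
  expect_equal(f1_pooled(p, t)$f1$estimate, mean(p == t))
  # bootstrap interval is returned when requested and brackets the estimate
  bb <- f1_pooled(pred, true, positive = 1, bootstrap = 200)
  expect_length(bb$f1_boot_ci, 2L)
  expect_true(bb$f1_boot_ci[1] <= 0.9 && bb$f1_boot_ci[2] >= 0.9)
})

test_that("AUC equals brute-force pair counting with half ties", {
  expect_equal(auc_mw(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$estimate, 1)
  expect_equal(auc_mw(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))$estimate, 0.5)
  expect_equal(auc_mw(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$estimate, 0.75)
  expect_error(auc_mw(c(0.1, 0.2), c(1, 1)), "both classes")
  brute_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg)
      s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_mw(p, y)$estimate, brute_auc(p, y),
                 info = paste("case", i))
  }
})

test_that("filtering reports tally verdicts against ground truth", {
  none <- filtering_report(rep("NEEDS_HUMAN", 8), rep(TRUE, 8))
  expect_equal(none$total_filtered, 0)
  expect_equal(none$filtering_rate, 0)
  expect_true(is.na(none$predictive_value))

  v <- c("FILTERED_FAIL", "FILTERED_FAIL", "FILTERED_PASS", "NEEDS_HUMAN",
         "FILTERED_PASS", "FILTERED_FAIL", "NEEDS_HUMAN", "FILTERED_PASS",
         "FILTERED_FAIL", "NEEDS_HUMAN")
  t <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  r <- filtering_report(v, t)
  expect_equal(unname(r$lenient), c(4L, 3L))   # fails predicted / correct
  expect_equal(unname(r$strict), c(3L, 2L))    # passes predicted / correct
  expect_equal(r$total_filtered, 7L)
  expect_equal(r$total_hits, 5L)
  expect_equal(r$filtering_rate, 0.7)
  expect_equal(r$predictive_value, 5 / 7)
  # conservation: filtered plus human-queue images cover the cohort
  expect_equal(r$total_filtered + sum(v == "NEEDS_HUMAN"), r$n_images)
  expect_error(filtering_report(v, t[-1]), "mismatch")
})
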