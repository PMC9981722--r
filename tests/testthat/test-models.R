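test_that("heads have the right output structure", {
  crops <- make_class_crops(8)
  mcc <- train_dps("MCC", crops, config = fast_config(epochs = 3))
  bcc <- train_dps("BCC", crops, config = fast_config(epochs = 3))
  P <- predict_dps(mcc, crops)
  expect_equal(dim(P), c(24L, 3L))
  expect_equal(colnames(P), c("p0", "p0.5", "p1"))
  expect_equal(rowSums(P), rep(1, 24), tolerance = 1e-6)
  expect_true(all(P >= 0))
  p <- predict_dps(bcc, crops)
  expect_length(p, 24L)
  expect_true(all(p >= 0 & p <= 1))
  # single-crop prediction matches the batch row
  expect_equal(predict_dps(bcc, crops[[1]]), p[1])
})

test_that("separable data is learned to perfect training accuracy", {
  crops <- make_class_crops(20, amps = c(`0` = 0, `1` = 0.8),
                            scores = c(0, 1), noise_sd = 0.02)
  bcc <- train_dps("BCC", crops, config = fast_config())
  expect_equal(nrow(bcc$history), 10L)
  expect_equal(bcc$history$accuracy[10], 1.0)
  # training loss decreases over early epochs on separable data
  expect_lt(bcc$history$loss[10], bcc$history$loss[1])
})

test_that("training is reproducible under a fixed seed", {
  crops <- make_class_crops(10)
  val <- make_class_crops(4, seed = 123)
  a <- train_dps("MCC", crops, val, fast_config(epochs = 5))
  b <- train_dps("MCC", crops, val, fast_config(epochs = 5))
  expect_equal(a$history, b$history)
  expect_equal(a$weights, b$weights)
  expect_equal(a$history$val_accuracy[5], b$history$val_accuracy[5])
  c <- train_dps("MCC", crops, val, fast_config(epochs = 5, seed = 7))
  expect_false(identical(a$weights, c$weights))
})

test_that("degenerate labels and kind mismatches are rejected", {
  one_class <- make_class_crops(6, scores = 1)
  expect_error(train_dps("MCC", one_class, config = fast_config()),
               "degenerate")
  crops <- make_class_crops(6)
  mixed <- c(crops, make_class_crops(3, kind = "fiber"))
  expect_error(train_dps("BCC", mixed, config = fast_config()), "one kind")
  bcc <- train_dps("BCC", crops, config = fast_config(epochs = 2))
  expect_error(predict_dps(bcc, make_class_crops(2, kind = "fiber")),
               "kind")
})

test_that("models survive a save/load round trip", {
  crops <- make_class_crops(8)
  m <- train_dps("MCC", crops, config = fast_config(epochs = 4))
  f <- withr::local_tempfile(fileext = ".json")
  save_dps(m, f)
  m2 <- load_dps(f)
  expect_equal(m2$head_type, "MCC")
  expect_equal(m2$kind, m$kind)
  expect_equal(predict_dps(m2, crops), predict_dps(m, crops),
               tolerance = 1e-10)
  expect_equal(m2$history$accuracy, m$history$accuracy, tolerance = 1e-12)
})

test_that("binary thresholding uses the >= convention", {
  expect_equal(as.character(classify_bcc(0.5)), "0.5|1")
  expect_equal(as.character(classify_bcc(0.49)), "0")
  expect_equal(as.character(classify_bcc(1.0)), "0.5|1")
  expect_equal(as.character(classify_bcc(c(0, 0.7), threshold = 0.7)),
               c("0", "0.5|1"))
  expect_error(classify_bcc(1.2), "bcc_prob")
})

test_that("the 3-class prediction is the argmax, ties to the lower score", {
  expect_equal(mcc_predicted_score(c(0.2, 0.3, 0.5)), 1)
  expect_equal(mcc_predicted_score(c(0.5, 0.3, 0.2)), 0)
  expect_equal(mcc_predicted_score(c(0.4, 0.4, 0.2)), 0)
  P <- rbind(c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4))
  expect_equal(mcc_predicted_score(P), c(0.5, 1))
})

test_that("an independent learner confirms the synthetic task is separable", {
  skip_if_not_installed("nnet")
  crops <- make_class_crops(15, amps = c(`0` = 0, `1` = 0.8),
                            scores = c(0, 1), noise_sd = 0.02)
  X <- t(vapply(crops, function(cr) as.vector(cr$pixels / 65535),
                numeric(256)))
  y <- vapply(crops, `[[`, 0, "truth_score")
  fit <- nnet::nnet(X, y, size = 4, maxit = 200, trace = FALSE,
                    MaxNWts = 2000)
  expect_equal(as.numeric(predict(fit, X) > 0.5), y)
  ours <- train_dps("BCC", crops, config = fast_config())
  expect_equal(as.numeric(predict_dps(ours, crops) >= 0.5), y)
})
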