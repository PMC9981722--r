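# Shared fixtures: all built in code, cached per test run.

.fixtures <- new.env(parent = emptyenv())

fix_layout <- function(scale = 0.25) default_layout(scale)

# memoized default render at the reference exposure
fix_image <- function(mAs = 140, kVp = 28, seed = 11, scale = 0.25) {
  key <- sprintf("img_%g_%g_%d_%g", mAs, kVp, seed, scale)
  if (is.null(.fixtures[[key]])) {
    img <- render_phantom(fix_layout(scale),
                          acquisition_params(mAs, kVp, scale = scale,
                                             seed = seed))
    img$truth_scores <- visibility_scores(img)
    img$image_id <- key
    .fixtures[[key]] <- img
  }
  .fixtures[[key]]
}

# Synthetic, trivially separable crops for classifier unit tests: a soft
# disc of class-dependent amplitude over Gaussian noise.
make_class_crops <- function(n_per_class, side = 16, kind = "mass",
                             amps = c(`0` = 0, `0.5` = 0.35, `1` = 0.7),
                             noise_sd = 0.04, seed = 99,
                             scores = c(0, 0.5, 1)) {
  set.seed(seed)
  ctr <- (side + 1) / 2
  d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`))
  disc <- pmin(pmax((side / 4 - d) / 2 + 0.5, 0), 1)
  crops <- list()
  for (s in scores) {
    amp <- amps[[as.character(s)]]
    for (i in seq_len(n_per_class)) {
      p <- 0.4 + amp * disc + matrix(rnorm(side^2, sd = noise_sd), side)
      crops[[length(crops) + 1L]] <- shape_crop(
        matrix(as.integer(round(pmin(pmax(p, 0), 1) * 65535)), side),
        kind = kind, rank = 1L, image_id = sprintf("syn%03d", length(crops)),
        truth_score = s)
    }
  }
  crops
}

# lightweight crops (no meaningful pixels) for partition bookkeeping tests
make_stub_crops <- function(n, kind = "fiber") {
  lapply(seq_len(n), function(i)
    shape_crop(matrix(0L, 2, 2), kind = kind, rank = 1L,
               image_id = sprintf("stub%05d", i), truth_score = 1))
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(input_side = 8, hidden = 8, epochs = 10, batch_size = 16,
         learning_rate = 0.01, augment = FALSE, seed = 42),
    list(...))
  do.call(dps_config, args)
}

# shared desk-scale study for pipeline-level tests (trained once)
fix_small_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- run_phantom_study(
      seed = 5, n_dev = 60, n_external = 20,
      config = dps_config(epochs = 15))
  }
  .fixtures$study
}
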