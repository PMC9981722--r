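#' Extract, normalise and label the 16 crops of one image
#'
#' The per-image preprocessing step of the pipeline: reference-point
#' localisation, ROI extraction and percentile intensity rescaling.
#'
#' @param image a scored `phantom_image`.
#' @param crop_size crop side, pixels.
#' @param p_low,p_high rescaling percentiles.
#' @return List of 16 rescaled [shape_crop()] objects.
#' @export
preprocess_image <- function(image, crop_size = 56, p_low = 1, p_high = 99) {
  crops <- extract_rois(image, crop_size = crop_size)
  lapply(crops, rescale_intensity, p_low = p_low, p_high = p_high)
}

image_truth_verdict <- function(truth_scores, stop_at_zero = TRUE) {
  score_image(truth_scores, stop_at_zero)$passed
}

#' Run the full phantom-QA study pipeline
#'
#' End-to-end desk-scale analogue of the full workflow: synthesize a
#' development cohort over the mAs/kVp protocol, preprocess it into
#' per-target crops, partition per kind (80:20 holdout, then 80:20
#' validation), train the binary and three-class scoring heads per kind,
#' measure pooled holdout performance, tune the lenient/strict filtering
#' thresholds on the development images, and apply the tuned filter to a
#' fresh external-style cohort.
#'
#' All randomness derives from `seed` through named substreams, so a rerun
#' with the same arguments reproduces every artifact.
#'
#' @param seed global seed.
#' @param n_dev development-cohort size.
#' @param n_external external-cohort size.
#' @param layout phantom layout (desk scale by default).
#' @param physics renderer constants.
#' @param crop_size crop side in pixels (56 at desk scale, matching a
#'   224-pixel crop at full scale).
#' @param config classifier configuration ([dps_config()]); its seed field
#'   is overridden by derived substream seeds.
#' @param lenient_grid,strict_grid candidate threshold grids for
#'   [threshold_search()].
#' @param verbose print stage-level progress counts.
#' @return A list with elements `models`, `split_sizes`, `holdout`
#'   (pooled BCC F1/AUC and MCC F1 metrics), `search` (threshold-search
#'   result), `dev_report`, `external` (filter decisions and
#'   [filtering_report()]), and bookkeeping counts.
#' @export
run_phantom_study <- function(seed = 1, n_dev = 543, n_external = 61,
                              layout = default_layout(0.25),
                              physics = phantom_physics(),
                              crop_size = 56,
                              config = dps_config(),
                              lenient_grid = expand.grid(t_bcc = c(0.3, 0.4),
                                                         t_mcc = c(0.3, 0.4, 0.5)),
                              strict_grid = expand.grid(t_bcc = c(0.6, 0.7),
                                                        t_mcc = c(0.4, 0.5, 0.6)),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d development images", n_dev)
  dev <- generate_study_set(n_dev, seed = stage_seed(seed, "dev"),
                            layout = layout, physics = physics,
                            transform = function(img)
                              list(image_id = img$image_id,
                                   truth = img$truth_scores,
                                   crops = preprocess_image(img, crop_size)))
  dev_crops <- unlist(lapply(dev, `[[`, "crops"), recursive = FALSE)
  dev_truth <- data.frame(
    image_id = vapply(dev, `[[`, "", "image_id"),
    passed = vapply(dev, function(d) image_truth_verdict(d$truth), TRUE),
    stringsAsFactors = FALSE)
  say("extracted %d crops from %d images (%d excluded)",
      length(dev_crops), length(dev), attr(dev, "n_excluded"))

  models <- list()
  split_sizes <- list()
  holdout_crops <- list()
  for (k in TARGET_KINDS) {
    kc <- Filter(function(cr) cr$kind == k, dev_crops)
    split <- partition_dataset(kc, seed = stage_seed(seed, paste0("split_", k)))
    split_sizes[[k]] <- split$sizes
    cfg_b <- config; cfg_b$seed <- stage_seed(seed, paste0("bcc_", k))
    cfg_m <- config; cfg_m$seed <- stage_seed(seed, paste0("mcc_", k))
    say("training %s models on %d crops", k, split$sizes[["training"]])
    models[[k]] <- list(
      bcc = train_dps("BCC", split$training, split$validation, cfg_b),
      mcc = train_dps("MCC", split$training, split$validation, cfg_m))
    holdout_crops[[k]] <- split$holdout
  }

  ho <- unlist(holdout_crops, recursive = FALSE)
  ho_tab <- score_crops(models, ho)
  ho_truth_bin <- as.numeric(ho_tab$truth_score > 0)
  ho_pred_bin <- as.numeric(ho_tab$bcc_prob >= 0.5)
  holdout <- list(
    bcc_f1 = f1_pooled(ho_pred_bin, ho_truth_bin, positive = 1),
    bcc_auc = auc_mw(ho_tab$bcc_prob, ho_truth_bin),
    mcc_f1 = f1_pooled(mcc_predicted_score(as.matrix(
      ho_tab[, c("p0", "p0.5", "p1")])), ho_tab$truth_score),
    n = nrow(ho_tab))
  say("holdout: BCC F1 %.3f, AUC %.3f, MCC F1 %.3f",
      holdout$bcc_f1$f1$estimate, holdout$bcc_auc$estimate,
      holdout$mcc_f1$f1$estimate)

  say("tuning thresholds on %d development images", nrow(dev_truth))
  dev_tab <- score_crops(models, dev_crops)
  search <- threshold_search(dev_tab, dev_truth, lenient_grid, strict_grid)
  dev_dec <- filter_images(dev_tab, search$lenient, search$strict)
  dev_report <- filtering_report(
    dev_dec$verdict[match(dev_truth$image_id, dev_dec$image_id)],
    dev_truth$passed)
  say("selected LA (%.1f, %.1f) / SA (%.1f, %.1f), dev predictive value %.0f%%",
      search$lenient$t_bcc, search$lenient$t_mcc,
      search$strict$t_bcc, search$strict$t_mcc,
      100 * dev_report$predictive_value)

  say("generating %d external-style images", n_external)
  ext <- generate_external_set(n_external, seed = stage_seed(seed, "external"),
                               layout = layout, physics = physics,
                               transform = function(img)
                                 list(image_id = img$image_id,
                                      truth = img$truth_scores,
                                      crops = preprocess_image(img, crop_size)))
  ext_crops <- unlist(lapply(ext, `[[`, "crops"), recursive = FALSE)
  ext_truth <- data.frame(
    image_id = vapply(ext, `[[`, "", "image_id"),
    passed = vapply(ext, function(d) image_truth_verdict(d$truth), TRUE),
    stringsAsFactors = FALSE)
  ext_tab <- score_crops(models, ext_crops)
  ext_dec <- filter_images(ext_tab, search$lenient, search$strict)
  ext_report <- filtering_report(
    ext_dec$verdict[match(ext_truth$image_id, ext_dec$image_id)],
    ext_truth$passed)
  say("external: filtered %d/%d (%.0f%%)", ext_report$total_filtered,
      ext_report$n_images, 100 * ext_report$filtering_rate)

  list(models = models, split_sizes = split_sizes, holdout = holdout,
       search = search, dev_report = dev_report,
       dev_truth = dev_truth,
       external = list(decisions = ext_dec, truth = ext_truth,
                       report = ext_report),
       counts = list(n_dev = length(dev), n_dev_crops = length(dev_crops),
                     n_external = length(ext)))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param seed global seed.
#' @param n_dev,n_external cohort sizes.
#' @param scale layout/raster scale.
#' @param crop_size crop side, pixels.
#' @param classifier list of [dps_config()] overrides.
#' @param lenient_grid,strict_grid threshold grids (data.frames with
#'   `t_bcc`, `t_mcc`); both are required.
#' @param out_dir output directory for [run_pipeline()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_dev = 543, n_external = 61, scale = 0.25,
                       crop_size = 56, classifier = list(),
                       lenient_grid = expand.grid(t_bcc = c(0.3, 0.4),
                                                  t_mcc = c(0.3, 0.4, 0.5)),
                       strict_grid = expand.grid(t_bcc = c(0.6, 0.7),
                                                 t_mcc = c(0.4, 0.5, 0.6)),
                       out_dir = "phantomqa_run") {
  cfg <- list(seed = seed, n_dev = n_dev, n_external = n_external,
              scale = scale, crop_size = crop_size, classifier = classifier,
              lenient_grid = lenient_grid, strict_grid = strict_grid,
              out_dir = out_dir)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param config a configuration list.
#' @export
validate_run_config <- function(config) {
  abort_if(is.null(config$lenient_grid) || is.null(config$strict_grid) ||
             NROW(config$lenient_grid) == 0 || NROW(config$strict_grid) == 0,
           "configuration error: threshold grids are required")
  for (g in c("lenient_grid", "strict_grid")) {
    gg <- as.data.frame(config[[g]])
    attr(gg, "out.attrs") <- NULL
    rownames(gg) <- NULL
    abort_if(!all(c("t_bcc", "t_mcc") %in% names(gg)),
             sprintf("configuration error: %s needs t_bcc and t_mcc", g))
    config[[g]] <- gg
  }
  abort_if(is.null(config$seed), "configuration error: seed is required")
  config$n_dev <- config$n_dev %||% 543
  config$n_external <- config$n_external %||% 61
  config$scale <- config$scale %||% 0.25
  config$crop_size <- config$crop_size %||% 56
  config$classifier <- config$classifier %||% list()
  config$out_dir <- config$out_dir %||% "phantomqa_run"
  structure(config, class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), sprintf("no config at %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' Execute the pipeline from a configuration and persist its artifacts
#'
#' Runs [run_phantom_study()] and writes the stage artifacts under the
#' configured output directory: split manifest, holdout metrics, the full
#' threshold-search report, selected thresholds, external filter verdicts
#' and the filtering report (CSV/JSON).
#'
#' @param config a [run_config()] (validated before any compute).
#' @return The [run_phantom_study()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  cls <- do.call(dps_config, config$classifier)
  res <- run_phantom_study(
    seed = config$seed, n_dev = config$n_dev,
    n_external = config$n_external,
    layout = default_layout(config$scale),
    crop_size = config$crop_size, config = cls,
    lenient_grid = config$lenient_grid, strict_grid = config$strict_grid)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  splits <- do.call(rbind, lapply(names(res$split_sizes), function(k)
    data.frame(kind = k, t(res$split_sizes[[k]]))))
  utils::write.csv(splits, file.path(config$out_dir, "split_sizes.csv"),
                   row.names = FALSE)
  utils::write.csv(res$search$report,
                   file.path(config$out_dir, "threshold_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$external$decisions,
                   file.path(config$out_dir, "external_verdicts.csv"),
                   row.names = FALSE)
  metrics <- list(
    holdout = list(
      bcc_f1 = res$holdout$bcc_f1$f1$estimate,
      bcc_f1_ci = c(res$holdout$bcc_f1$f1$ci_low,
                    res$holdout$bcc_f1$f1$ci_high),
      bcc_auc = res$holdout$bcc_auc$estimate,
      bcc_auc_ci = c(res$holdout$bcc_auc$ci_low, res$holdout$bcc_auc$ci_high),
      mcc_f1 = res$holdout$mcc_f1$f1$estimate,
      n = res$holdout$n),
    thresholds = list(lenient = unclass(res$search$lenient),
                      strict = unclass(res$search$strict)),
    dev_predictive_value = res$dev_report$predictive_value,
    external = list(
      filtered = res$external$report$total_filtered,
      n = res$external$report$n_images,
      filtering_rate = res$external$report$filtering_rate,
      lenient = as.list(res$external$report$lenient),
      strict = as.list(res$external$report$strict)))
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  for (k in names(res$models)) {
    save_dps(res$models[[k]]$bcc,
             file.path(config$out_dir, sprintf("bcc_%s.json", k)))
    save_dps(res$models[[k]]$mcc,
             file.path(config$out_dir, sprintf("mcc_%s.json", k)))
  }
  invisible(res)
}
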