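#' Acquisition-settings grid
#'
#' Enumerates the (mAs, kVp) exposure settings of a step-wise acquisition
#' protocol. The mAs range is half-open (`[lo, hi)`) in steps of `mAs_step`
#' and the kVp range inclusive, so the defaults (mAs 60-220 in steps of 2,
#' kVp 22-32 in steps of 1) give 80 x 11 = 880 settings.
#'
#' @param mAs_range numeric (lo, hi), half-open.
#' @param mAs_step step of the tube-current grid, mAs.
#' @param kVp_range numeric (lo, hi), inclusive.
#' @param kVp_step step of the tube-voltage grid, kVp.
#' @return A data.frame with columns `mAs` and `kVp`, one row per setting.
#' @export
acquisition_grid <- function(mAs_range = c(60, 220), mAs_step = 2,
                             kVp_range = c(22, 32), kVp_step = 1) {
  abort_if(mAs_range[1] >= mAs_range[2] || kVp_range[1] > kVp_range[2] ||
             mAs_step <= 0 || kVp_step <= 0, "empty acquisition grid")
  n_mAs <- ceiling((mAs_range[2] - mAs_range[1]) / mAs_step - 1e-9)
  mAs <- mAs_range[1] + mAs_step * (seq_len(n_mAs) - 1)
  n_kVp <- floor((kVp_range[2] - kVp_range[1]) / kVp_step + 1e-9) + 1
  kVp <- kVp_range[1] + kVp_step * (seq_len(n_kVp) - 1)
  abort_if(length(mAs) == 0 || length(kVp) == 0, "empty acquisition grid")
  g <- expand.grid(mAs = mAs, kVp = kVp, KEEP.OUT.ATTRS = FALSE)
  g[order(g$kVp, g$mAs), , drop = FALSE]
}

#' Low-exposure acquisition grid emulating a weekly-QC external cohort
#'
#' A restriction of [acquisition_grid()] to the low-mAs / high-kVp corner
#' of the protocol, so that a cohort sampled uniformly from it fails ACR
#' scoring at roughly the rate seen in routine external quality control
#' (about three images in five).
#'
#' @inheritParams acquisition_grid
#' @return A data.frame with columns `mAs` and `kVp`.
#' @export
external_acquisition_grid <- function(mAs_range = c(60, 190), mAs_step = 2,
                                      kVp_range = c(24, 32), kVp_step = 1) {
  acquisition_grid(mAs_range, mAs_step, kVp_range, kVp_step)
}

render_one <- function(layout, mAs, kVp, seed, physics, image_id,
                       jitter_px = 0L) {
  acq <- acquisition_params(mAs = mAs, kVp = kVp, scale = layout$scale,
                            seed = seed, jitter_px = jitter_px)
  img <- render_phantom(layout, acq, physics)
  img$truth_scores <- visibility_scores(img)
  img$image_id <- image_id
  img
}

#' Generate a synthetic phantom dataset over an acquisition grid
#'
#' Renders `images_per_cell` phantom images for every setting of the
#' acquisition grid, attaches ground-truth visibility scores to each, and
#' drops images failing the exposure-adequacy check
#' ([is_exposure_acceptable()]). Fully deterministic given `seed`.
#'
#' @param layout a [default_layout()].
#' @inheritParams acquisition_grid
#' @param images_per_cell number of images rendered per grid setting.
#' @param seed global seed; per-image seeds are derived substreams.
#' @param physics a [phantom_physics()].
#' @param transform optional function applied to each image as it is
#'   produced; when given, the returned list holds the transformed values
#'   instead of full images (keeps memory bounded for large runs).
#' @param lo_frac,hi_frac exposure-acceptance band.
#' @return A list of `phantom_image` (or transformed) objects with
#'   attributes `n_excluded` (count of exposure-excluded images) and
#'   `settings` (data.frame of retained image_id, mAs, kVp, seed).
#' @export
generate_dataset <- function(layout = default_layout(0.25),
                             mAs_range = c(60, 220), mAs_step = 2,
                             kVp_range = c(22, 32), kVp_step = 1,
                             images_per_cell = 1, seed = 1,
                             physics = phantom_physics(),
                             transform = NULL,
                             lo_frac = 0.05, hi_frac = 0.95) {
  abort_if(images_per_cell < 1, "images_per_cell must be at least 1")
  validate_layout(layout)
  grid <- acquisition_grid(mAs_range, mAs_step, kVp_range, kVp_step)
  grid <- grid[rep(seq_len(nrow(grid)), each = images_per_cell), , drop = FALSE]
  render_settings(grid, layout, seed, physics, transform, lo_frac, hi_frac)
}

render_settings <- function(grid, layout, seed, physics, transform,
                            lo_frac = 0.05, hi_frac = 0.95) {
  out <- vector("list", nrow(grid))
  keep <- logical(nrow(grid))
  settings <- cbind(image_id = sprintf("img%04d", seq_len(nrow(grid))),
                    grid, seed = NA_integer_)
  for (i in seq_len(nrow(grid))) {
    s <- stage_seed(seed, "render", i)
    settings$seed[i] <- s
    img <- render_one(layout, grid$mAs[i], grid$kVp[i], s, physics,
                      settings$image_id[i])
    if (!is_exposure_acceptable(img, lo_frac, hi_frac)) next
    keep[i] <- TRUE
    out[[i]] <- if (is.null(transform)) img else transform(img)
  }
  res <- out[keep]
  attr(res, "n_excluded") <- sum(!keep)
  attr(res, "settings") <- settings[keep, , drop = FALSE]
  res
}

#' Generate a development study set of synthetic phantom images
#'
#' Samples `n_images` settings without replacement from the acquisition
#' grid (seeded) and renders one scored image per setting, emulating a
#' development cohort collected by step-wise mAs/kVp adjustment.
#'
#' @param n_images number of images to draw; at most `nrow(grid)`.
#' @param seed global seed.
#' @param layout a [default_layout()].
#' @param physics a [phantom_physics()].
#' @param grid settings pool, by default the full [acquisition_grid()].
#' @param transform optional per-image transform (see [generate_dataset()]).
#' @return As [generate_dataset()].
#' @export
generate_study_set <- function(n_images = 543, seed = 1,
                               layout = default_layout(0.25),
                               physics = phantom_physics(),
                               grid = acquisition_grid(),
                               transform = NULL) {
  abort_if(n_images < 1, "n_images must be at least 1")
  abort_if(n_images > nrow(grid), "n_images exceeds the settings pool")
  validate_layout(layout)
  set.seed(stage_seed(seed, "study_sample"))
  grid <- grid[sample.int(nrow(grid), n_images), , drop = FALSE]
  render_settings(grid, layout, seed, physics, transform)
}

#' Generate an external-style validation set
#'
#' As [generate_study_set()] but sampling (with replacement, since the pool
#' is small) from the low-exposure [external_acquisition_grid()], producing
#' a cohort in which roughly three images in five fail ACR scoring.
#'
#' @inheritParams generate_study_set
#' @export
generate_external_set <- function(n_images = 61, seed = 2,
                                  layout = default_layout(0.25),
                                  physics = phantom_physics(),
                                  grid = external_acquisition_grid(),
                                  transform = NULL) {
  abort_if(n_images < 1, "n_images must be at least 1")
  validate_layout(layout)
  set.seed(stage_seed(seed, "external_sample"))
  grid <- grid[sample.int(nrow(grid), n_images, replace = TRUE), ,
               drop = FALSE]
  render_settings(grid, layout, seed, physics, transform)
}
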