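#' Acquisition parameters for a synthetic phantom exposure
#'
#' Bundles the exposure factors and detector geometry of one synthetic
#' acquisition. The physical field of view of the emulated unit is
#' 18 x 24 cm sampled at 0.0703125 mm/pixel (2560 x 3328 pixels at full
#' scale); `scale` shrinks the raster linearly, so the desk-scale default
#' `scale = 0.25` renders 640 x 832 pixel images.
#'
#' @param mAs tube current-time product; controls photon count, hence noise
#'   (higher mAs, less noise) and background signal.
#' @param kVp tube voltage; controls beam energy, hence target contrast
#'   (higher kVp, lower contrast).
#' @param scale linear raster scale factor; must match the layout scale.
#' @param pixel_pitch detector sampling pitch in mm/pixel (fixed by the
#'   emulated detector; the raster is shrunk through `image_shape`).
#' @param image_shape integer (rows, cols); defaults to the full field of
#'   view at `scale`.
#' @param seed integer seed for the quantum-noise realization.
#' @param jitter_px maximum absolute phantom placement jitter in pixels
#'   (seeded, integer offsets); 0 disables jitter.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(mAs, kVp, scale = 0.25,
                               pixel_pitch = 180 / 2560,
                               image_shape = NULL, seed = 1L,
                               jitter_px = 0L) {
  abort_if(!is.numeric(mAs) || mAs <= 0, "mAs must be positive")
  abort_if(!is.numeric(kVp) || kVp <= 0, "kVp must be positive")
  abort_if(scale <= 0, "scale must be positive")
  if (is.null(image_shape))
    image_shape <- c(round(2560 * scale), round(3328 * scale))
  abort_if(length(image_shape) != 2L || any(image_shape < 8),
           "image_shape must be (rows, cols) with at least 8 pixels each")
  structure(list(mAs = mAs, kVp = kVp, scale = scale,
                 pixel_pitch = pixel_pitch,
                 image_shape = as.integer(image_shape),
                 seed = as.integer(seed), jitter_px = as.integer(jitter_px)),
            class = "acquisition_params")
}

#' Pixel-model constants of the synthetic renderer
#'
#' The renderer uses a minimal monotone exposure model: phantom background
#' `b0 * (1 - exp(-mAs / tau))` of the 16-bit dynamic range, target contrast
#' multiplied by `(kVp_ref / kVp)^gamma`, and additive Gaussian quantum
#' noise with standard deviation `sigma0 / sqrt(mAs)` (as a fraction of the
#' dynamic range). No spectra, scatter or detector MTF are modelled.
#'
#' @param b0 asymptotic background level, fraction of dynamic range.
#' @param tau exposure saturation constant, mAs.
#' @param kVp_ref reference tube voltage at which contrast equals the
#'   layout's base contrast.
#' @param gamma exponent of the voltage-contrast law.
#' @param sigma0 noise scale: noise sd = sigma0 / sqrt(mAs), fraction of
#'   dynamic range.
#' @param border_level intensity of the unexposed border, fraction of
#'   dynamic range.
#' @param c_partial,c_full CNR thresholds of the truth-score rule: a target
#'   scores 1 when CNR >= c_full, 0.5 when c_partial <= CNR < c_full,
#'   else 0.
#' @param edge_frac relative width of the soft edge of mass targets.
#' @param supersample subpixel supersampling factor for target coverage.
#' @return A list of class `phantom_physics`.
#' @export
phantom_physics <- function(b0 = 0.82, tau = 80, kVp_ref = 28, gamma = 3,
                            sigma0 = 0.18, border_level = 0.02,
                            c_partial = 3, c_full = 5,
                            edge_frac = 0.2, supersample = 4L) {
  abort_if(c_partial >= c_full, "c_partial must be below c_full")
  structure(list(b0 = b0, tau = tau, kVp_ref = kVp_ref, gamma = gamma,
                 sigma0 = sigma0, border_level = border_level,
                 c_partial = c_partial, c_full = c_full,
                 edge_frac = edge_frac, supersample = as.integer(supersample)),
            class = "phantom_physics")
}

background_level <- function(mAs, physics) {
  physics$b0 * (1 - exp(-mAs / physics$tau))
}

contrast_factor <- function(kVp, physics) {
  (physics$kVp_ref / kVp)^physics$gamma
}

noise_sd <- function(mAs, physics) {
  physics$sigma0 / sqrt(mAs)
}

# Subpixel coverage of one target over a local window.
# Returns list(rows, cols, cov) where cov is the fraction of each pixel
# covered by the target, computed by supersampling the indicator function.
target_coverage <- function(target, origin_mm, pitch, image_shape, ss,
                            edge_frac) {
  cx <- origin_mm[1] + target$x_mm
  cy <- origin_mm[2] + target$y_mm
  half <- switch(target$kind,
    fiber = target$length_mm / 2 + target$nominal_size,
    speck_group = target$pattern_radius_mm + target$nominal_size,
    mass = target$nominal_size / 2 * (1 + edge_frac) + pitch
  )
  r0 <- max(1L, floor((cy - half) / pitch))
  r1 <- min(image_shape[1], ceiling((cy + half) / pitch) + 1L)
  c0 <- max(1L, floor((cx - half) / pitch))
  c1 <- min(image_shape[2], ceiling((cx + half) / pitch) + 1L)
  if (r0 > r1 || c0 > c1) return(NULL)

  rows <- r0:r1; cols <- c0:c1
  # subpixel sample centres in mm
  sub <- (seq_len(ss) - 0.5) / ss
  ys <- as.vector(outer(rows - 1, sub, `+`)) * pitch
  xs <- as.vector(outer(cols - 1, sub, `+`)) * pitch

  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))

  ind <- switch(target$kind,
    fiber = {
      th <- target$angle_deg * pi / 180
      ux <- cos(th); uy <- sin(th)
      dx <- X - cx; dy <- Y - cy
      t <- dx * ux + dy * uy
      t <- pmin(pmax(t, -target$length_mm / 2), target$length_mm / 2)
      px <- cx + t * ux; py <- cy + t * uy
      d <- sqrt((X - px)^2 + (Y - py)^2)
      (d <= target$nominal_size / 2) * 1
    },
    speck_group = {
      rs <- target$nominal_size / 2
      pr <- target$pattern_radius_mm
      ang <- pi / 2 + (0:4) * 2 * pi / 5
      centres <- rbind(cbind(cx + pr * cos(ang), cy + pr * sin(ang)),
                       c(cx, cy))
      acc <- matrix(0, nrow(X), ncol(X))
      for (i in seq_len(nrow(centres))) {
        d <- sqrt((X - centres[i, 1])^2 + (Y - centres[i, 2])^2)
        acc <- pmax(acc, (d <= rs) * 1)
      }
      acc
    },
    mass = {
      r <- target$nominal_size / 2
      e <- edge_frac * r
      d <- sqrt((X - cx)^2 + (Y - cy)^2)
      pmin(pmax((r + e / 2 - d) / e, 0), 1)
    }
  )

  # average the ss x ss subpixel samples back to pixel resolution
  nr <- length(rows); nc <- length(cols)
  dim(ind) <- c(nr, ss, nc, ss)
  cov <- apply(ind, c(1, 3), mean)
  list(rows = rows, cols = cols, cov = cov,
       center_px = c(row = cy / pitch + 0.5, col = cx / pitch + 0.5))
}

#' Render a synthetic phantom radiograph
#'
#' Draws the phantom background and all 16 targets at exposure-dependent
#' contrast, then adds seeded Gaussian quantum noise and quantizes to
#' 16 bits. The render is fully deterministic given (layout, acquisition,
#' physics): identical inputs give bit-identical images.
#'
#' Background intensity increases monotonically with mAs, rendered target
#' contrast decreases monotonically with kVp, and the noise standard
#' deviation is proportional to 1/sqrt(mAs).
#'
#' @param layout a [default_layout()] object; its scale must match the
#'   acquisition scale.
#' @param acq an [acquisition_params()] object.
#' @param physics a [phantom_physics()] configuration.
#' @param noise logical; set `FALSE` for the noiseless render used by
#'   oracle computations.
#' @return An object of class `phantom_image`: list with `pixels`
#'   (integer matrix, values 0..65535), `acquisition`, `layout`, `physics`,
#'   `origin_px` (1-based top-left pixel of the phantom rectangle),
#'   `target_stats` (per-target rendered amplitude, effective coverage and
#'   CNR) and optional `truth_scores`.
#' @export
render_phantom <- function(layout, acq, physics = phantom_physics(),
                           noise = TRUE) {
  abort_if(!inherits(layout, "phantom_layout"), "layout must be a phantom_layout")
  abort_if(!inherits(acq, "acquisition_params"),
           "acq must be acquisition_params")
  shape <- acq$image_shape
  pitch <- acq$pixel_pitch
  fov_mm <- c(width = shape[2] * pitch, height = shape[1] * pitch)
  ext <- layout$phantom_extent
  abort_if(ext["width"] > fov_mm["width"] || ext["height"] > fov_mm["height"],
           "phantom does not fit in the field of view: check layout/acq scales")

  set.seed(acq$seed)
  jit <- c(0L, 0L)
  if (acq$jitter_px > 0)
    jit <- sample(seq(-acq$jitter_px, acq$jitter_px), 2L, replace = TRUE)

  # phantom rectangle, centred in the field of view (plus optional jitter)
  orig_px <- c(row = floor((shape[1] - ext[["height"]] / pitch) / 2) + jit[1],
               col = floor((shape[2] - ext[["width"]] / pitch) / 2) + jit[2])
  # the phantom occupies rows/cols orig_px .. orig_px + extent - 1, so the
  # top-left pixel's leading edge in mm is (orig_px - 1) * pitch
  origin_mm <- (c(orig_px[["col"]], orig_px[["row"]]) - 1) * pitch  # (x, y)

  B <- background_level(acq$mAs, physics)
  kf <- contrast_factor(acq$kVp, physics)
  sd <- noise_sd(acq$mAs, physics)

  img <- matrix(physics$border_level, shape[1], shape[2])
  pr <- orig_px[["row"]] + seq_len(round(ext[["height"]] / pitch)) - 1L
  pc <- orig_px[["col"]] + seq_len(round(ext[["width"]] / pitch)) - 1L
  pr <- pr[pr >= 1 & pr <= shape[1]]
  pc <- pc[pc >= 1 & pc <= shape[2]]
  img[pr, pc] <- B

  tg <- layout$targets
  stats <- data.frame(kind = tg$kind, rank = tg$rank,
                      amp = NA_real_, w_eff = NA_real_,
                      row_px = NA_real_, col_px = NA_real_,
                      cnr_num = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tg))) {
    tc <- target_coverage(tg[i, ], origin_mm, pitch, shape,
                          physics$supersample, physics$edge_frac)
    ctr_r <- (origin_mm[2] + tg$y_mm[i]) / pitch + 0.5
    ctr_c <- (origin_mm[1] + tg$x_mm[i]) / pitch + 0.5
    abort_if(is.null(tc) || ctr_r < 1 || ctr_r > shape[1] ||
               ctr_c < 1 || ctr_c > shape[2],
             sprintf("target %s rank %d falls outside the image",
                     tg$kind[i], tg$rank[i]))
    amp <- tg$base_contrast[i] * kf * B
    img[tc$rows, tc$cols] <- img[tc$rows, tc$cols] + amp * tc$cov
    s <- sum(tc$cov)
    stats$amp[i] <- amp
    stats$w_eff[i] <- if (s > 0) sum(tc$cov^2) / s else 0
    stats$row_px[i] <- ctr_r
    stats$col_px[i] <- ctr_c
    # truth CNR from the rendered (display-clipped) noiseless signal:
    # coverage-weighted mean amplitude over the target's own window
    a <- pmax(pmin(B + amp * tc$cov, 1) - B, 0)
    stats$cnr_num[i] <- if (sum(a) > 0) sum(a^2) / sum(a) else 0
  }

  if (noise) img <- img + matrix(stats::rnorm(length(img), sd = sd),
                                 nrow(img), ncol(img))
  pix <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * 65535)),
                nrow(img), ncol(img))

  stats$cnr <- ifelse(stats$cnr_num > 0,
                      if (sd > 0) stats$cnr_num / sd else Inf, 0)

  structure(list(pixels = pix, acquisition = acq, layout = layout,
                 physics = physics, origin_px = orig_px,
                 target_stats = stats, truth_scores = NULL,
                 image_id = NA_character_),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image: %d x %d px, mAs=%g kVp=%g seed=%d%s\n",
              nrow(x$pixels), ncol(x$pixels), x$acquisition$mAs,
              x$acquisition$kVp, x$acquisition$seed,
              if (!is.null(x$truth_scores)) ", scored" else ""))
  invisible(x)
}

#' Ground-truth visibility scores from the contrast-to-noise ratio
#'
#' Stands in for the radiologists' consensus reading: each target is scored
#' from the CNR of its noiseless rendering against the local background,
#' CNR = amplitude x effective coverage / noise sd, with the thresholds
#' `c_partial` and `c_full` of the image's [phantom_physics()]. Scores are
#' monotone non-decreasing in mAs and non-increasing in target rank at
#' fixed acquisition.
#'
#' @param image a `phantom_image` carrying its layout and acquisition.
#' @return A data.frame with columns `kind`, `rank`, `cnr`, `score`
#'   (score in {0, 0.5, 1}), ordered fibers 1-6, specks 1-5, masses 1-5.
#' @export
visibility_scores <- function(image) {
  abort_if(!inherits(image, "phantom_image") || is.null(image$layout) ||
             is.null(image$target_stats),
           "image must be a phantom_image with layout metadata")
  st <- image$target_stats
  ph <- image$physics
  score <- ifelse(st$cnr >= ph$c_full, 1,
                  ifelse(st$cnr >= ph$c_partial, 0.5, 0))
  data.frame(kind = st$kind, rank = st$rank, cnr = st$cnr, score = score,
             stringsAsFactors = FALSE)
}

#' Exposure-adequacy check
#'
#' Flags images that are too dark or too saturated for reading: the mean
#' background intensity of the phantom region must fall inside
#' `[lo_frac, hi_frac]` of the 16-bit dynamic range. When the image carries
#' no layout metadata the mean is taken over the whole frame.
#'
#' @param image a `phantom_image`.
#' @param lo_frac,hi_frac acceptance band as fractions of dynamic range.
#' @return `TRUE` if the exposure is acceptable.
#' @export
is_exposure_acceptable <- function(image, lo_frac = 0.05, hi_frac = 0.95) {
  abort_if(!(lo_frac >= 0 && lo_frac < hi_frac && hi_frac <= 1),
           "need 0 <= lo_frac < hi_frac <= 1")
  pix <- image$pixels
  m <- if (!is.null(image$origin_px) && !is.null(image$layout)) {
    pitch <- image$acquisition$pixel_pitch
    ext <- image$layout$phantom_extent
    pr <- image$origin_px[["row"]] + seq_len(round(ext[["height"]] / pitch)) - 1L
    pc <- image$origin_px[["col"]] + seq_len(round(ext[["width"]] / pitch)) - 1L
    pr <- pr[pr >= 1 & pr <= nrow(pix)]
    pc <- pc[pc >= 1 & pc <= ncol(pix)]
    mean(pix[pr, pc])
  } else mean(pix)
  m >= lo_frac * 65535 && m <= hi_frac * 65535
}
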