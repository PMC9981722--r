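#' Construct a shape crop
#'
#' A square patch around one phantom target, the unit the scoring
#' classifiers operate on.
#'
#' @param pixels square integer matrix (16-bit intensities).
#' @param kind target kind: "fiber", "speck_group" or "mass".
#' @param rank size rank within the kind (1 = largest).
#' @param image_id identifier of the source image.
#' @param truth_score optional ground-truth visibility score in
#'   {0, 0.5, 1}.
#' @return An object of class `shape_crop`.
#' @export
shape_crop <- function(pixels, kind, rank, image_id = NA_character_,
                       truth_score = NA_real_) {
  abort_if(!is.matrix(pixels) || nrow(pixels) != ncol(pixels),
           "crop pixels must be a square matrix")
  abort_if(!kind %in% TARGET_KINDS, "unknown target kind")
  abort_if(!is.na(truth_score) && !truth_score %in% SCORE_LEVELS,
           "truth_score must be 0, 0.5 or 1")
  structure(list(pixels = pixels, kind = kind, rank = as.integer(rank),
                 image_id = image_id, truth_score = truth_score),
            class = "shape_crop")
}

#' Locate the phantom reference point
#'
#' Finds the phantom within the frame by global Otsu thresholding followed
#' by largest-connected-component selection, and returns the top-left
#' corner of that component's bounding box (1-based row, col). With
#' placement jitter disabled this equals the renderer's phantom origin.
#'
#' @param image a `phantom_image` or a plain intensity matrix.
#' @return Integer vector `c(row, col)`.
#' @export
locate_reference_point <- function(image) {
  pix <- if (inherits(image, "phantom_image")) image$pixels else image
  abort_if(!is.matrix(pix), "image must carry a pixel matrix")
  x <- pix / 65535
  if (max(x) - min(x) < 1e-6)
    stop("localization failure: uniform image, no phantom found",
         call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- EBImage::bwlabel(EBImage::Image(x > thr))
  m <- EBImage::imageData(mask)
  if (max(m) == 0)
    stop("localization failure: no foreground component", call. = FALSE)
  sizes <- tabulate(m[m > 0])
  lab <- which.max(sizes)
  if (sizes[lab] < 0.1 * length(pix))
    stop("localization failure: foreground component below 10% of frame",
         call. = FALSE)
  idx <- which(m == lab, arr.ind = TRUE)
  c(row = min(idx[, 1]), col = min(idx[, 2]))
}

#' Extract one crop per phantom target
#'
#' Crops a square patch centred on each of the 16 target positions, mapped
#' from layout millimetres to pixels via the image's reference point.
#' Output order is fibers rank 1-6, speck groups 1-5, masses 1-5; truth
#' scores are propagated when the image carries them.
#'
#' @param image a `phantom_image`.
#' @param layout the phantom layout; defaults to the image's own.
#' @param crop_size side of the square crop, pixels.
#' @param reference_point optional `c(row, col)` override; by default
#'   computed with [locate_reference_point()].
#' @return A list of 16 [shape_crop()] objects.
#' @export
extract_rois <- function(image, layout = image$layout, crop_size = 56,
                         reference_point = NULL) {
  abort_if(!inherits(image, "phantom_image"), "image must be a phantom_image")
  validate_layout(layout)
  pix <- image$pixels
  abort_if(crop_size > min(dim(pix)),
           "crop_size exceeds the image dimensions")
  ref <- reference_point %||% locate_reference_point(image)
  pitch <- image$acquisition$pixel_pitch
  tg <- layout$targets
  truth <- image$truth_scores
  half_lo <- floor((crop_size - 1) / 2)
  out <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    r <- (ref[["row"]] - 1) + round(tg$y_mm[i] / pitch)
    c <- (ref[["col"]] - 1) + round(tg$x_mm[i] / pitch)
    r0 <- r - half_lo; c0 <- c - half_lo
    r1 <- r0 + crop_size - 1; c1 <- c0 + crop_size - 1
    abort_if(r0 < 1 || c0 < 1 || r1 > nrow(pix) || c1 > ncol(pix),
             sprintf("crop for %s rank %d exceeds image bounds",
                     tg$kind[i], tg$rank[i]))
    ts <- NA_real_
    if (!is.null(truth)) {
      hit <- truth$kind == tg$kind[i] & truth$rank == tg$rank[i]
      if (any(hit)) ts <- truth$score[hit][1]
    }
    out[[i]] <- shape_crop(pix[r0:r1, c0:c1], tg$kind[i], tg$rank[i],
                           image$image_id %||% NA_character_, ts)
  }
  out
}

#' Percentile-based intensity rescaling
#'
#' Linearly maps the `p_low` percentile of the crop to 0 and the `p_high`
#' percentile to the 16-bit maximum, clipping outside; this is the contrast
#' normalisation applied before classification. A constant-valued crop maps
#' to all zeros.
#'
#' @param crop a [shape_crop()] (or plain matrix).
#' @param p_low,p_high percentiles in [0, 100], `p_low < p_high`.
#' @return The rescaled crop (same class as the input).
#' @export
rescale_intensity <- function(crop, p_low = 1, p_high = 99) {
  abort_if(!(p_low >= 0 && p_low < p_high && p_high <= 100),
           "need 0 <= p_low < p_high <= 100")
  pix <- if (inherits(crop, "shape_crop")) crop$pixels else crop
  q <- stats::quantile(pix, c(p_low, p_high) / 100, names = FALSE, type = 7)
  new <- if (q[2] <= q[1]) {
    matrix(0L, nrow(pix), ncol(pix))
  } else {
    v <- (pix - q[1]) / (q[2] - q[1])
    matrix(as.integer(round(pmin(pmax(v, 0), 1) * 65535)),
           nrow(pix), ncol(pix))
  }
  if (inherits(crop, "shape_crop")) { crop$pixels <- new; crop } else new
}

#' Seeded training/validation/holdout partition
#'
#' Shuffles the crops uniformly (seeded), then sets aside
#' `ceiling(0.2 N)` as holdout and `ceiling(0.2 (N - holdout))` of the
#' remainder as validation, the rest being training -- the 80:20 then 80:20
#' rule. Every crop lands in exactly one set. Applied to 3258 crops this
#' yields 2084/522/652 and to 2715 crops 1737/435/543.
#'
#' @param crops non-empty list of [shape_crop()] objects, all of one kind.
#' @param seed integer seed for the shuffle.
#' @param holdout_frac,validation_frac held-out fractions of each stage.
#' @param stratify logical; when `TRUE`, the shuffle-and-slice is applied
#'   within each truth-score stratum.
#' @return A list with elements `training`, `validation`, `holdout` (lists
#'   of crops) and `sizes`.
#' @export
partition_dataset <- function(crops, seed = 1, holdout_frac = 0.2,
                              validation_frac = 0.2, stratify = FALSE) {
  abort_if(length(crops) == 0, "cannot partition an empty crop list")
  kinds <- unique(vapply(crops, `[[`, "", "kind"))
  abort_if(length(kinds) > 1,
           "crops must all be of a single kind; partition each kind separately")
  idx_groups <- if (stratify) {
    scores <- vapply(crops, `[[`, 0, "truth_score")
    split(seq_along(crops), scores)
  } else list(seq_along(crops))

  set.seed(stage_seed(seed, "split"))
  tr <- va <- ho <- integer(0)
  for (g in idx_groups) {
    g <- g[sample.int(length(g))]
    n <- length(g)
    n_ho <- ceiling(holdout_frac * n)
    n_va <- ceiling(validation_frac * (n - n_ho))
    ho <- c(ho, g[seq_len(n_ho)])
    va <- c(va, g[n_ho + seq_len(n_va)])
    tr <- c(tr, g[-seq_len(n_ho + n_va)])
  }
  list(training = crops[tr], validation = crops[va], holdout = crops[ho],
       sizes = c(training = length(tr), validation = length(va),
                 holdout = length(ho)))
}

#' Flip augmentation
#'
#' Returns the crop and its horizontal, vertical and double flips (4
#' variants), labels preserved; the flip group used to enlarge the
#' training set.
#'
#' @param crop a [shape_crop()].
#' @return A list of 4 [shape_crop()] objects.
#' @export
augment <- function(crop) {
  abort_if(!inherits(crop, "shape_crop"), "augment expects a shape_crop")
  flips <- list(
    identity = crop$pixels,
    hflip = crop$pixels[, rev(seq_len(ncol(crop$pixels))), drop = FALSE],
    vflip = crop$pixels[rev(seq_len(nrow(crop$pixels))), , drop = FALSE],
    hvflip = crop$pixels[rev(seq_len(nrow(crop$pixels))),
                         rev(seq_len(ncol(crop$pixels))), drop = FALSE]
  )
  lapply(flips, function(p) {
    out <- crop; out$pixels <- p; out
  })
}
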