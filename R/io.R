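#' Write a phantom image to disk
#'
#' Images are stored as 16-bit grayscale TIFF (the canonical format; TIFF
#' round-trips the full 16-bit range exactly). Acquisition metadata travels
#' in the dataset's sidecar CSV, not in the image file.
#'
#' @param image a `phantom_image`.
#' @param path output path (".tif"/".tiff").
#' @return `path`, invisibly.
#' @export
write_phantom_image <- function(image, path) {
  abort_if(!inherits(image, "phantom_image"), "image must be a phantom_image")
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a phantom image from disk
#'
#' Reads 16-bit grayscale TIFF or PNG. 8-bit inputs are promoted to the
#' 16-bit range (value x 257) with a warning. Acquisition metadata (mAs,
#' kVp, seed) can be supplied from a sidecar record to rebuild a scored
#' image.
#'
#' @param path image file path.
#' @param mAs,kVp,seed optional acquisition metadata.
#' @param layout optional [default_layout()] to attach.
#' @param physics optional [phantom_physics()] to attach.
#' @return A `phantom_image` (with `NULL` layout when none is supplied;
#'   such images support cropping only with an explicit reference point).
#' @export
read_phantom_image <- function(path, mAs = NA, kVp = NA, seed = NA,
                               layout = NULL, physics = phantom_physics()) {
  abort_if(!file.exists(path), sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = FALSE),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s': %s", ext, path),
         call. = FALSE)
  )
  if (length(dim(x)) == 3) x <- x[, , 1]
  pix <- round(x * 65535)
  if (ext == "png") {
    # readPNG scales both depths to [0, 1]; detect 8-bit payloads by the
    # coarse value grid and promote them.
    vals <- unique(as.vector(round(x * 255, 9)))
    if (all(abs(vals - round(vals)) < 1e-9) && length(vals) > 1) {
      warning("8-bit PNG promoted to 16-bit range", call. = FALSE)
      pix <- round(x * 255) * 257
    }
  }
  acq <- if (!is.na(mAs) && !is.na(kVp)) {
    acquisition_params(mAs, kVp, scale = if (!is.null(layout)) layout$scale
                       else 0.25,
                       image_shape = dim(pix),
                       seed = if (is.na(seed)) 0L else as.integer(seed))
  } else NULL
  structure(list(pixels = matrix(as.integer(pix), nrow(pix), ncol(pix)),
                 acquisition = acq, layout = layout, physics = physics,
                 origin_px = NULL, target_stats = NULL, truth_scores = NULL,
                 image_id = basename(path)),
            class = "phantom_image")
}

#' Write a dataset of phantom images with its sidecar manifest
#'
#' Writes each image as 16-bit TIFF plus one sidecar CSV with columns
#' `image_id`, `file`, `mAs`, `kVp`, `seed`, `target_kind`, `rank`,
#' `truth_score` (one row per target).
#'
#' @param images list of scored `phantom_image` objects.
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(images, function(img) {
    file <- paste0(img$image_id, ".tif")
    write_phantom_image(img, file.path(dir, file))
    ts <- img$truth_scores
    data.frame(image_id = img$image_id, file = file,
               mAs = img$acquisition$mAs, kVp = img$acquisition$kVp,
               seed = img$acquisition$seed,
               target_kind = ts$kind, rank = ts$rank,
               truth_score = ts$score, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return The manifest data.frame.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  abort_if(!file.exists(path), sprintf("no manifest at %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "file", "mAs", "kVp", "seed", "target_kind",
            "rank", "truth_score")
  abort_if(!all(need %in% names(m)),
           "manifest is missing required columns")
  m
}
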