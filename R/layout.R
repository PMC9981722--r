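#' Geometric template of the ACR-156 style phantom
#'
#' The accreditation phantom embeds 16 targets in a wax insert: 6 nylon
#' fibers, 5 simulated micro-calcification speck groups and 5 tumour-like
#' masses, each series ordered by strictly decreasing size and conspicuity.
#' `default_layout()` returns the template used by the synthetic renderer;
#' `scale = 1` corresponds to the physical phantom (10.2 x 10.8 cm insert
#' face), smaller scales shrink all geometry linearly for desk-scale work.
#'
#' Targets are laid out on a 4 x 4 grid inside the insert: fibers occupy the
#' first six cells, speck groups the next five, masses the last five,
#' mirroring the reading order of the physical phantom. Nominal sizes follow
#' the ACR series (fiber diameters 1.56 down to 0.40 mm, speck diameters
#' 0.54 down to 0.16 mm, mass diameters 9.5 down to 3.2 mm). Base contrasts
#' decrease with rank within each kind and are expressed as relative
#' attenuation against the phantom background.
#'
#' @param scale positive scalar; linear scale factor applied to every
#'   geometric quantity (positions and nominal sizes).
#' @return An object of class `phantom_layout`: a list with
#'   `targets` (data.frame with columns `kind`, `rank`, `x_mm`, `y_mm`,
#'   `nominal_size`, `base_contrast`, plus per-kind drawing extras),
#'   `phantom_extent` (width, height in mm) and `wax_insert_origin`.
#' @examples
#' lay <- default_layout()
#' table(lay$targets$kind)
#' @export
default_layout <- function(scale = 1.0) {
  abort_if(!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
             scale <= 0, "scale must be a positive number")

  # 4 x 4 grid, 20 mm pitch, origin of the insert region at (15, 18) mm
  grid_xy <- expand.grid(col = 0:3, row = 0:3)
  xs <- 15 + 20 * grid_xy$col
  ys <- 18 + 20 * grid_xy$row

  kind <- c(rep("fiber", 6), rep("speck_group", 5), rep("mass", 5))
  rank <- c(1:6, 1:5, 1:5)

  nominal_size <- c(
    c(1.56, 1.12, 0.89, 0.75, 0.54, 0.40),  # fiber diameter, mm
    c(0.54, 0.40, 0.32, 0.24, 0.16),        # individual speck diameter, mm
    c(9.5, 7.9, 6.3, 4.8, 3.2)              # mass diameter, mm
  )
  # Relative attenuation, calibrated so that the pooled truth-score
  # distribution over the full acquisition grid resembles a clinical
  # phantom-reading cohort (most top-rank targets visible, bottom ranks
  # invisible, a partial-visibility band in between that is widest for
  # masses and narrowest for specks).
  base_contrast <- c(
    c(0.5962, 0.3413, 0.2258, 0.1669, 0.0812, 0.0316),  # fibers
    c(0.7696, 0.6788, 0.6009, 0.4918, 0.1552),          # specks
    c(0.2412, 0.1690, 0.1210, 0.0632, 0.0270)           # masses
  )

  targets <- data.frame(
    kind = kind, rank = rank,
    x_mm = xs * scale, y_mm = ys * scale,
    nominal_size = nominal_size * scale,
    base_contrast = base_contrast,
    stringsAsFactors = FALSE
  )
  # fibers alternate orientation like the physical insert
  targets$angle_deg <- ifelse(targets$kind == "fiber",
                              ifelse(targets$rank %% 2 == 1, 45, 135), NA)
  targets$length_mm <- ifelse(targets$kind == "fiber", 10 * scale, NA)
  # speck groups: pentagon + centre dot, 2.5 mm pattern radius
  targets$pattern_radius_mm <- ifelse(targets$kind == "speck_group",
                                      2.5 * scale, NA)

  structure(
    list(
      targets = targets,
      phantom_extent = c(width = 102 * scale, height = 108 * scale),
      wax_insert_origin = c(x = 15 * scale, y = 18 * scale),
      scale = scale
    ),
    class = "phantom_layout"
  )
}

#' Validate a phantom layout
#'
#' Checks the structural invariants of a [default_layout()] object: exactly
#' 6 fibers, 5 speck groups and 5 masses; within each kind, nominal size and
#' base contrast strictly decreasing with rank; every target inside the
#' phantom extent.
#'
#' @param layout a `phantom_layout`.
#' @return `layout`, invisibly; errors if any invariant fails.
#' @export
validate_layout <- function(layout) {
  abort_if(!inherits(layout, "phantom_layout"), "not a phantom_layout")
  tg <- layout$targets
  counts <- table(factor(tg$kind, levels = TARGET_KINDS))
  abort_if(!all(counts == c(6, 5, 5)),
           "layout must contain 6 fibers, 5 speck groups and 5 masses")
  for (k in TARGET_KINDS) {
    sub <- tg[tg$kind == k, ]
    sub <- sub[order(sub$rank), ]
    abort_if(!identical(sub$rank, seq_len(nrow(sub))),
             sprintf("%s ranks must be 1..%d", k, nrow(sub)))
    abort_if(any(diff(sub$nominal_size) >= 0),
             sprintf("%s nominal sizes must strictly decrease with rank", k))
    abort_if(any(diff(sub$base_contrast) >= 0),
             sprintf("%s base contrasts must strictly decrease with rank", k))
  }
  abort_if(any(tg$nominal_size <= 0), "nominal sizes must be positive")
  abort_if(any(tg$base_contrast <= 0 | tg$base_contrast > 1),
           "base contrasts must lie in (0, 1]")
  ext <- layout$phantom_extent
  abort_if(any(tg$x_mm < 0 | tg$x_mm > ext["width"] |
                 tg$y_mm < 0 | tg$y_mm > ext["height"]),
           "all targets must lie inside the phantom extent")
  invisible(layout)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("phantom_layout: %d targets (%s), extent %.1f x %.1f mm, scale %g\n",
              nrow(x$targets),
              paste(table(factor(x$targets$kind, levels = TARGET_KINDS)),
                    collapse = "/"),
              x$phantom_extent["width"], x$phantom_extent["height"], x$scale))
  invisible(x)
}
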