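#' Construct a coronal section image
#'
#' A `section_image` couples one 2D grayscale raster with the physical
#' metadata needed to place it in the brain: the pixel size, the section
#' thickness (100 micrometers for standard coronal sectioning) and the
#' 0-based rostro-caudal index (rostral = 0). Pixels are stored `[row, col]`
#' with row 1 at the image top; physical position is index times pixel size.
#'
#' @param pixels Numeric matrix of non-negative intensity counts.
#' @param bit_depth Integer, 8 or 16.
#' @param pixel_size Micrometers per pixel (> 0).
#' @param thickness Section thickness in micrometers (> 0).
#' @param rc_index Integer rostro-caudal position, 0-based.
#' @return An object of class `section_image`.
#' @export
section_image <- function(pixels, bit_depth = 16L, pixel_size = 4,
                          thickness = 100, rc_index = 0L) {
  assert_matrix(pixels, "pixels")
  if (!bit_depth %in% c(8L, 16L)) {
    stop_sectionmap("bit_depth must be 8 or 16", "format_error")
  }
  if (any(pixels < 0)) stop_sectionmap("pixels must be non-negative", "value_error")
  if (any(pixels > 2^bit_depth - 1)) {
    stop_sectionmap("pixels exceed the representable range for bit_depth", "value_error")
  }
  if (pixel_size <= 0 || thickness <= 0) {
    stop_sectionmap("pixel_size and thickness must be positive", "value_error")
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size, thickness = thickness,
                 rc_index = as.integer(rc_index)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %d-bit, %.3g um/px, %.3g um thick, rc_index %d\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size,
              x$thickness, x$rc_index))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "section_image")) x$pixels else {
    assert_matrix(x)
    x
  }
}

#' Maximum intensity projection of virtual Z-planes
#'
#' Collapses a list of equally shaped rasters to their elementwise maximum,
#' the standard reduction of per-section virtual Z-stacks to a single plane.
#'
#' @param planes List of numeric matrices with identical dimensions.
#' @return A matrix, `out[r, c] = max over planes of plane[r, c]`.
#' @export
max_project <- function(planes) {
  if (!is.list(planes) || length(planes) < 1L) {
    stop_sectionmap("planes must be a non-empty list of matrices", "value_error")
  }
  dims <- dim(planes[[1L]])
  for (p in planes) {
    assert_matrix(p, "plane")
    if (!identical(dim(p), dims)) {
      stop_sectionmap("all planes must share the same dimensions", "dimension_error")
    }
  }
  out <- planes[[1L]]
  for (p in planes[-1L]) out <- pmax(out, p)
  out
}

#' Read a stack of coronal section images
#'
#' Reads one file per section, in rostro-caudal order. Files may be
#' single-page TIFFs or multi-page TIFFs holding virtual Z-planes; multi-page
#' inputs are collapsed to a maximum intensity projection. Physical metadata
#' comes from the arguments (run configuration), never from vendor headers.
#'
#' @param paths Character vector of TIFF paths, rostral first.
#' @param pixel_size,thickness Physical metadata shared by all sections.
#' @return List of [section_image] with `rc_index` assigned in list order.
#' @export
read_section_stack <- function(paths, pixel_size = 4, thickness = 100) {
  if (length(paths) < 1L) stop_sectionmap("no input paths", "io_error")
  depths <- integer(length(paths))
  sections <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    if (!file.exists(p)) stop_sectionmap(sprintf("cannot read file: %s", p), "io_error")
    pages <- tryCatch(tiff::readTIFF(p, all = TRUE, as.is = TRUE),
                      error = function(e) {
                        stop_sectionmap(sprintf("cannot decode TIFF: %s", p), "io_error")
                      })
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1L]], "bits.per.sample") %||%
      (if (max(vapply(pages, max, 0)) > 255) 16L else 8L)
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # grayscale plane of gray TIFFs
      pg
    })
    depths[k] <- as.integer(bits)
    sections[[k]] <- max_project(pages)
  }
  if (length(unique(depths)) > 1L) {
    stop_sectionmap("mixed bit depths across sections", "format_error")
  }
  lapply(seq_along(sections), function(k) {
    section_image(sections[[k]], bit_depth = depths[1L], pixel_size = pixel_size,
                  thickness = thickness, rc_index = k - 1L)
  })
}

#' Write a raster (or section image) as grayscale TIFF
#'
#' Values are quantized to the integer grid of the given bit depth on export;
#' in-memory pyramids stay at floating precision.
#'
#' @param x Matrix or [section_image].
#' @param path Output path.
#' @param bit_depth 8 or 16; defaults to the section's depth, else 16.
#' @export
write_section_tiff <- function(x, path, bit_depth = NULL) {
  bit_depth <- bit_depth %||% (if (inherits(x, "section_image")) x$bit_depth else 16L)
  px <- as_pixels(x)
  maxv <- 2^bit_depth - 1
  px <- pmin(pmax(round(px), 0), maxv)
  tiff::writeTIFF(px / maxv, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Build the mean-pyramid representation of a section
#'
#' Level 0 is the image itself; each further level is the non-overlapping
#' 2x2 block mean of the previous one (window M = N = 2, stride 2), the
#' standard mean pyramid used to view and analyze slide-scanner sections at
#' multiple resolutions. Odd dimensions are padded by edge replication before
#' averaging, and pixel size doubles per level.
#'
#' @param section A [section_image] or plain matrix.
#' @param max_level Highest level L to compute (L >= 0).
#' @return An object of class `pyramid` with fields `levels` (list of
#'   matrices, level 0 first), `factor_m`, `factor_n`, `max_level`, and
#'   `pixel_sizes` when the input carried one.
#' @export
build_pyramid <- function(section, max_level = 3L) {
  if (max_level < 0) stop_sectionmap("max_level must be >= 0", "value_error")
  px <- as_pixels(section)
  ps0 <- if (inherits(section, "section_image")) section$pixel_size else NA_real_
  levels <- vector("list", max_level + 1L)
  levels[[1L]] <- px
  cur <- px
  for (l in seq_len(max_level)) {
    cur <- block_mean2(cur)
    levels[[l + 1L]] <- cur
  }
  structure(list(levels = levels, factor_m = 2L, factor_n = 2L,
                 max_level = as.integer(max_level),
                 pixel_sizes = ps0 * 2^(0:max_level)),
            class = "pyramid")
}

# One pyramid reduction step: 2x2 block mean with edge-replication padding
# for odd dimensions. Vectorized; output dims are ceiling(dim / 2).
block_mean2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 2L == 1L) m <- rbind(m, m[nr, , drop = FALSE])
  if (nc %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  nr <- nrow(m); nc <- ncol(m)
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   m[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   m[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE] +
   m[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]) / 4
}

#' @export
print.pyramid <- function(x, ...) {
  cat(sprintf("<pyramid> %d level(s):\n", length(x$levels)))
  for (l in seq_along(x$levels)) {
    cat(sprintf("  l=%d: %d x %d\n", l - 1L, nrow(x$levels[[l]]), ncol(x$levels[[l]])))
  }
  invisible(x)
}
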