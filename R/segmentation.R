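#' Median filter a section image
#'
#' Each output pixel is the median of its `window x window` neighborhood,
#' with edge replication at the borders. This removes isolated saturated
#' (shot-noise) pixels and smooths soma edges before thresholding and
#' segmentation.
#'
#' @param image Matrix or [section_image].
#' @param window Odd window size (>= 1); 1 is the identity.
#' @return Filtered matrix (same dimensions).
#' @export
median_filter <- function(image, window = 3L) {
  px <- as_pixels(image)
  if (window < 1L || window %% 2L == 0L) {
    stop_sectionmap("median window must be an odd integer >= 1", "value_error")
  }
  if (window == 1L) return(px)
  k <- (window - 1L) %/% 2L
  padded <- pad_replicate(px, k)
  f <- if (window == 3L) median9(padded) else {
    scale <- max(px, 1)
    m <- EBImage::medianFilter(padded / scale, k) * scale
    m <- matrix(as.numeric(m), nrow(padded), ncol(padded))
    # the engine quantizes internally; integer input has an integer median
    if (all(px == round(px))) m <- round(m)
    m
  }
  f[(k + 1L):(k + nrow(px)), (k + 1L):(k + ncol(px)), drop = FALSE]
}

# 3x3 median via a 19-exchange sorting network on the nine shifted planes;
# vectorized over all pixels. Input is the padded image; output keeps the
# padding ring (values there are not used by the caller).
median9 <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  q <- vector("list", 9L)
  i <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    i <- i + 1L
    q[[i]] <- p[ri + dr, ci + dc]
  }
  sw <- function(a, b) list(pmin(q[[a]], q[[b]]), pmax(q[[a]], q[[b]]))
  net <- list(c(2L,3L), c(5L,6L), c(8L,9L), c(1L,2L), c(4L,5L), c(7L,8L),
              c(2L,3L), c(5L,6L), c(8L,9L), c(1L,4L), c(6L,9L), c(5L,8L),
              c(4L,7L), c(2L,5L), c(3L,6L), c(5L,8L), c(5L,3L), c(7L,5L),
              c(5L,3L))
  for (e in net) {
    s <- sw(e[1L], e[2L])
    q[[e[1L]]] <- s[[1L]]
    q[[e[2L]]] <- s[[2L]]
  }
  out <- p
  out[ri, ci] <- q[[5L]]
  out
}

mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels else {
    assert_matrix(mask, "mask")
    mask
  }
}

# Connected-component labels. 4-connectivity comes from EBImage::bwlabel;
# 8-connectivity additionally merges labels that touch diagonally (components
# of the label-adjacency graph). Labels are renumbered 1..K in order of each
# component's first pixel in row-major (top-left) order, so results are
# deterministic and independent of the labeling engine.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) {
    stop_sectionmap("connectivity must be 4 or 8", "value_error")
  }
  m <- mask_pixels(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(m != 0)), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab > 0L && connectivity == 8L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- NULL
    for (off in list(c(1L, 1L), c(1L, -1L))) {
      r <- seq_len(nr - 1L)
      cs <- if (off[2L] == 1L) seq_len(nc - 1L) else 2:nc
      a <- lab[r, cs, drop = FALSE]
      b <- lab[r + 1L, cs + off[2L], drop = FALSE]
      keep <- a > 0L & b > 0L & a != b
      if (any(keep)) pairs <- rbind(pairs, cbind(a[keep], b[keep]))
    }
    if (!is.null(pairs)) {
      g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
      memb <- igraph::components(g)$membership
      lab[lab > 0L] <- memb[lab[lab > 0L]]
    }
  }
  if (max(lab) > 0L) {
    # renumber by first appearance in row-major order
    ord <- order(row(lab)[lab > 0L], col(lab)[lab > 0L])
    first_seen <- unique(lab[lab > 0L][ord])
    remap <- integer(max(lab))
    remap[first_seen] <- seq_along(first_seen)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Group contiguous foreground pixels
#'
#' Partitions the foreground of a binary mask into connected components
#' (nearest-neighbor pixel grouping). Two pixels share a group iff they are
#' connected under the chosen connectivity.
#'
#' @param mask A `binary_mask` or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `pixel_groups`: list with `labels` (integer matrix,
#'   0 = background) and `groups` (list of `n x 2` matrices of (row, col)
#'   coordinates, one per component, ordered by first top-left pixel).
#' @export
group_pixels <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  groups <- if (n == 0L) list() else {
    fg <- which(lab > 0L)
    coords <- cbind(row = ((fg - 1L) %% nrow(lab)) + 1L,
                    col = ((fg - 1L) %/% nrow(lab)) + 1L)
    lapply(split.data.frame(coords, lab[fg]), as.matrix)
  }
  structure(list(labels = lab, groups = unname(groups)), class = "pixel_groups")
}

# Clockwise Moore neighborhood starting at west: W NW N NE E SE S SW.
.moore_off <- cbind(c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                    c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))

# Trace the outer contour of the single object containing `start` (row, col)
# in binary matrix m, clockwise, with Jacob's stopping criterion: terminate
# on re-entering the start pixel from the same backtrack as the initial one.
moore_trace <- function(m, start) {
  nr <- nrow(m); nc <- ncol(m)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc
  b0 <- c(start[1L], start[2L] - 1L)   # entered scanning row-major, from west
  contour <- matrix(start, 1L, 2L)
  p <- start; b <- b0
  max_steps <- 4L * (nr * nc + 4L)
  for (step in seq_len(max_steps)) {
    db <- b - p
    k0 <- which(.moore_off[, 1L] == db[1L] & .moore_off[, 2L] == db[2L])
    found <- FALSE
    for (s in seq_len(8L)) {
      k <- ((k0 - 1L + s) %% 8L) + 1L
      q <- p + .moore_off[k, ]
      if (inside(q[1L], q[2L]) && m[q[1L], q[2L]] != 0) {
        kb <- ((k - 2L) %% 8L) + 1L
        b <- p + .moore_off[kb, ]
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) return(contour)          # isolated pixel
    if (p[1L] == start[1L] && p[2L] == start[2L] &&
        b[1L] == b0[1L] && b[2L] == b0[2L]) {
      return(contour)
    }
    contour <- rbind(contour, p)
  }
  contour
}

#' Trace outer object boundaries (Moore-Neighbor tracing)
#'
#' Walks the 8-neighborhood around each foreground object to produce an
#' ordered, closed, clockwise outer contour, starting from the object's
#' top-left-most pixel, with Jacob's stopping criterion. Holes inside
#' objects are not traced (the tissue silhouette is what alignment needs).
#'
#' @param mask A `binary_mask` or 0/1 matrix.
#' @param rc_index Optional rostro-caudal index stored on each boundary.
#' @return List of `tissue_boundary` objects: `contour` (`n x 2` matrix of
#'   (row, col)), `shape` (mask dimensions), `rc_index`. Empty mask gives an
#'   empty list.
#' @export
trace_boundary <- function(mask, rc_index = NA_integer_) {
  m <- mask_pixels(mask)
  lab <- label_components(m, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- vector("list", n)
  for (id in seq_len(n)) {
    obj <- lab == id
    fg <- which(obj)
    rows <- ((fg - 1L) %% nrow(m)) + 1L
    cols <- ((fg - 1L) %/% nrow(m)) + 1L
    o <- order(rows, cols)
    start <- c(rows[o[1L]], cols[o[1L]])
    # crop to the bounding box (plus 1 px guard) for speed
    r0 <- max(1L, min(rows) - 1L); r1 <- min(nrow(m), max(rows) + 1L)
    c0 <- max(1L, min(cols) - 1L); c1 <- min(ncol(m), max(cols) + 1L)
    sub <- obj[r0:r1, c0:c1, drop = FALSE]
    ct <- moore_trace(sub, start - c(r0 - 1L, c0 - 1L))
    ct[, 1L] <- ct[, 1L] + r0 - 1L
    ct[, 2L] <- ct[, 2L] + c0 - 1L
    dimnames(ct) <- list(NULL, c("row", "col"))
    out[[id]] <- structure(list(contour = ct, shape = dim(m),
                                rc_index = rc_index),
                           class = "tissue_boundary")
  }
  out
}

# Closed contour length: unit steps count 1, diagonal steps sqrt(2).
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  steps <- pmax(abs(nxt[, 1L] - contour[, 1L]), abs(nxt[, 2L] - contour[, 2L]))
  diag <- (nxt[, 1L] != contour[, 1L]) & (nxt[, 2L] != contour[, 2L])
  sum(ifelse(diag, sqrt(2), 1) * (steps > 0))
}

# Circularity 4*pi*A / P^2 from the sqrt(2)-weighted traced contour length,
# capped at 1 (the staircase length of a digital disc already matches the
# isoperimetric value closely; tiny shapes would otherwise exceed 1).
# Strictly decreasing as a shape elongates at fixed area.
shape_circularity <- function(area, perimeter) {
  if (perimeter <= 0) return(1)
  min(1, 4 * pi * area / perimeter^2)
}

#' Shape-filter pixel groups into detected cells
#'
#' Keeps groups whose pixel count lies in `[min_area, max_area]` and whose
#' circularity `4*pi*A/P^2` (perimeter from the traced outer contour, with a
#' half-pixel boundary offset) reaches `min_roundness`. Small groups are
#' processes or noise; oversized groups are clumps of overlapping cells that
#' cannot be parsed into individual somata — dropping them is the mechanism
#' behind undercounting at high label density.
#'
#' @param groups A [group_pixels()] result.
#' @param intensity Optional original-intensity matrix for per-cell means.
#' @param min_area,max_area Pixel-count limits (inclusive).
#' @param min_roundness Minimum circularity in `[0, 1]`.
#' @return `data.frame` with one row per detected cell: `row`, `col`
#'   (centroid, pixel units), `area_px`, `roundness`, `mean_intensity`.
#' @export
filter_components <- function(groups, intensity = NULL, min_area = 4L,
                              max_area = 37L, min_roundness = 0.4) {
  if (min_area > max_area) stop_sectionmap("min_area > max_area", "value_error")
  lab <- groups$labels
  empty <- data.frame(row = numeric(0), col = numeric(0), area_px = integer(0),
                      roundness = numeric(0), mean_intensity = numeric(0))
  n <- length(groups$groups)
  if (n == 0L) return(empty)
  areas <- vapply(groups$groups, nrow, 0L)
  keep <- which(areas >= min_area & areas <= max_area)
  rows <- lapply(keep, function(id) {
    px <- groups$groups[[id]]
    bbox_mask <- {
      r0 <- min(px[, 1L]); c0 <- min(px[, 2L])
      m <- matrix(0L, max(px[, 1L]) - r0 + 3L, max(px[, 2L]) - c0 + 3L)
      m[cbind(px[, 1L] - r0 + 2L, px[, 2L] - c0 + 2L)] <- 1L
      m
    }
    fg <- which(bbox_mask == 1L)
    rr <- ((fg - 1L) %% nrow(bbox_mask)) + 1L
    cc <- ((fg - 1L) %/% nrow(bbox_mask)) + 1L
    o <- order(rr, cc)
    ct <- moore_trace(bbox_mask, c(rr[o[1L]], cc[o[1L]]))
    roundness <- shape_circularity(nrow(px), contour_perimeter(ct))
    if (roundness < min_roundness) return(NULL)
    data.frame(row = mean(px[, 1L]), col = mean(px[, 2L]),
               area_px = nrow(px), roundness = roundness,
               mean_intensity = if (is.null(intensity)) NA_real_ else
                 mean(intensity[px]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Default cell-detection parameters
#'
#' Area limits are given in square micrometers and converted to pixel counts
#' through the section's pixel size; the defaults bracket a single granule-
#' cell soma and exclude both sub-somatic specks and unresolvable clumps.
#'
#' @param median_window Median pre-filter window (odd).
#' @param connectivity Pixel-grouping connectivity (4 or 8).
#' @param min_area_um2,max_area_um2 Soma area limits, square micrometers.
#' @param min_roundness Minimum circularity.
#' @return List of parameters for [find_cells()].
#' @export
cell_params <- function(median_window = 3L, connectivity = 8L,
                        min_area_um2 = 60, max_area_um2 = 600,
                        min_roundness = 0.4) {
  list(median_window = median_window, connectivity = connectivity,
       min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
       min_roundness = min_roundness)
}

empty_cells_df <- function() {
  data.frame(rc_index = integer(0), row = numeric(0), col = numeric(0),
             x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             area_px = integer(0), roundness = numeric(0),
             mean_intensity = numeric(0))
}

#' Detect labeled somata in one section
#'
#' The full per-section cell-finding composition: median filter, threshold at
#' the labeled-cell gray value, restriction to the region of interest,
#' nearest-neighbor pixel grouping, and morphological (area and roundness)
#' filtering. Cells outside the ROI are never emitted. Coordinates are
#' reported both in pixels and micrometers (`x` = medial-lateral = column,
#' `y` = dorsal-ventral = row, `z` = rc_index x thickness).
#'
#' @param section A [section_image].
#' @param cell_threshold Gray value separating somata from tissue; `NA`
#'   (transition not found) yields an empty result.
#' @param roi_mask Optional matrix; only pixels where it is non-zero are kept.
#' @param params A [cell_params()] list.
#' @param filtered Optional precomputed median-filtered pixels (callers that
#'   already filtered the section, e.g. [process_stack()], avoid refiltering).
#' @return `data.frame`, one row per detected cell.
#' @export
find_cells <- function(section, cell_threshold, roi_mask = NULL,
                       params = cell_params(), filtered = NULL) {
  stopifnot(inherits(section, "section_image"))
  if (is.na(cell_threshold)) return(empty_cells_df())
  if (!is.null(roi_mask) && !identical(dim(roi_mask), dim(section$pixels))) {
    stop_sectionmap("roi_mask dimensions differ from the section", "value_error")
  }
  filtered <- filtered %||% median_filter(section$pixels, params$median_window)
  mask <- threshold_image(filtered, cell_threshold, section$bit_depth)$pixels
  if (!is.null(roi_mask)) mask[roi_mask == 0] <- 0L
  grp <- group_pixels(mask, params$connectivity)
  px_area <- section$pixel_size^2
  cells <- filter_components(
    grp, intensity = section$pixels,
    min_area = max(1L, round(params$min_area_um2 / px_area)),
    max_area = max(1L, round(params$max_area_um2 / px_area)),
    min_roundness = params$min_roundness)
  if (nrow(cells) == 0L) return(empty_cells_df())
  data.frame(rc_index = section$rc_index,
             row = cells$row, col = cells$col,
             x_um = cells$col * section$pixel_size,
             y_um = cells$row * section$pixel_size,
             z_um = section$rc_index * section$thickness,
             area_px = cells$area_px, roundness = cells$roundness,
             mean_intensity = cells$mean_intensity)
}

#' Rasterize and Gaussian-smooth a traced boundary
#'
#' The contour is rasterized to a binary edge image and convolved with an
#' isotropic Gaussian (kernel truncated at 4 sigma), which makes the
#' subsequent alignment correlation insensitive to pixel-level noise on the
#' edge. `sigma = 0` returns the rasterized contour unchanged.
#'
#' @param boundary A `tissue_boundary` (from [trace_boundary()]).
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Numeric matrix of the smoothed edge image.
#' @export
smooth_boundary <- function(boundary, sigma = 2) {
  if (sigma < 0) stop_sectionmap("sigma must be >= 0", "value_error")
  stopifnot(inherits(boundary, "tissue_boundary"))
  m <- matrix(0, boundary$shape[1L], boundary$shape[2L])
  m[boundary$contour] <- 1
  if (sigma == 0) return(m)
  g <- EBImage::gblur(m, sigma = sigma, radius = 2L * ceiling(4 * sigma) + 1L)
  matrix(as.numeric(EBImage::imageData(g)), nrow(m), ncol(m))
}
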