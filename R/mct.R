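#' Threshold an image at a gray value
#'
#' Produces the binary indicator mask `y` with `y = 1` exactly where the
#' pixel value is strictly greater than `i` (the convention used throughout
#' the package: `n_above[i]` counts pixels above `i`).
#'
#' @param image Matrix or [section_image].
#' @param i Gray value; must lie in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Used only for range validation when `image` is a plain
#'   matrix; inferred from a [section_image].
#' @return Object of class `binary_mask`: list with `pixels` (0/1 integer
#'   matrix) and `threshold`.
#' @export
threshold_image <- function(image, i, bit_depth = NULL) {
  bit_depth <- bit_depth %||%
    (if (inherits(image, "section_image")) image$bit_depth else 16L)
  px <- as_pixels(image)
  if (i < 0 || i > 2^bit_depth - 1) {
    stop_sectionmap("threshold outside the representable gray range", "value_error")
  }
  m <- matrix(0L, nrow(px), ncol(px))
  m[px > i] <- 1L
  structure(list(pixels = m, threshold = i), class = "binary_mask")
}

#' Gray-level histogram of an image
#'
#' Counts `n_j` of pixels at each gray value `j` in `[0, 2^bit_depth - 1]`,
#' with the image mean and total pixel count; the sufficient statistics the
#' correlation curve is computed from.
#'
#' @inheritParams threshold_image
#' @return Object of class `gray_histogram`: `counts` (length `2^bit_depth`,
#'   index `j + 1` holds `n_j`), `mean_intensity`, `total_pixels`, `bit_depth`.
#' @export
gray_histogram <- function(image, bit_depth = NULL) {
  bit_depth <- bit_depth %||%
    (if (inherits(image, "section_image")) image$bit_depth else 16L)
  px <- as_pixels(image)
  v <- round(as.vector(px))
  if (any(v < 0) || any(v > 2^bit_depth - 1)) {
    stop_sectionmap("pixel values outside gray range for bit_depth", "value_error")
  }
  counts <- tabulate(v + 1L, nbins = 2^bit_depth)
  structure(list(counts = counts,
                 mean_intensity = mean(v),
                 total_pixels = length(v),
                 bit_depth = as.integer(bit_depth)),
            class = "gray_histogram")
}

#' Maximum-correlation-thresholding curve
#'
#' For every gray value `i`, the Pearson correlation between the original
#' intensities and the binary mask obtained by thresholding at `i`. The
#' correlation is computed in closed form from the gray histogram:
#' numerator `sum_{j>i} n_j (j - xbar)`; denominator
#' `sqrt(sum_j n_j (j - xbar)^2) * sqrt(N_i (N_m - N_i) / N_m)`,
#' where `N_i` counts pixels above `i` and `N_m` all pixels. The curve's
#' first finite difference (`deriv`) exposes the transitions at the tissue
#' edge and at the labeled-cell intensities. Entries where the mask would be
#' constant (`N_i` equal to 0 or `N_m`) are undefined and flagged `NA`.
#'
#' @inheritParams threshold_image
#' @return Object of class `correlation_curve`: data frame fields
#'   `threshold`, `corr`, `deriv`, `n_above` plus attributes `mean_intensity`,
#'   `total_pixels`, `bit_depth`.
#' @export
correlation_curve <- function(image, bit_depth = NULL) {
  h <- if (inherits(image, "gray_histogram")) image else gray_histogram(image, bit_depth)
  maxg <- 2^h$bit_depth - 1L
  j <- 0:maxg
  nj <- h$counts
  if (sum(nj > 0) < 2L) {
    stop_sectionmap("image is constant: correlation undefined (zero variance)",
                    "degenerate_input_error")
  }
  xbar <- h$mean_intensity
  nm <- h$total_pixels
  ss <- sum(nj * (j - xbar)^2)
  # S_i = sum over j > i of n_j (j - xbar); N_i = number of pixels above i
  cj <- nj * (j - xbar)
  s_above <- rev(cumsum(rev(cj))) - cj          # exclude level i itself
  n_above <- as.numeric(rev(cumsum(rev(as.numeric(nj)))) - nj)
  denom <- sqrt(ss) * sqrt(n_above * (nm - n_above) / nm)
  corr <- ifelse(n_above == 0L | n_above == nm, NA_real_, s_above / denom)
  deriv <- c(NA_real_, diff(corr))
  out <- data.frame(threshold = j, corr = corr, deriv = deriv,
                    n_above = as.integer(n_above))
  attr(out, "mean_intensity") <- xbar
  attr(out, "total_pixels") <- nm
  attr(out, "bit_depth") <- h$bit_depth
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Optimal threshold: argmax of the correlation curve
#'
#' Returns the smallest gray value attaining the maximum defined correlation
#' (ties broken toward the lowest threshold, which favors inclusion).
#'
#' @param curve A [correlation_curve()].
#' @return A single gray value (integer).
#' @export
optimal_threshold <- function(curve) {
  ok <- which(!is.na(curve$corr))
  if (length(ok) == 0L) {
    stop_sectionmap("correlation undefined at every threshold", "degenerate_input_error")
  }
  best <- ok[which.max(curve$corr[ok])]   # which.max takes the first maximum
  curve$threshold[best]
}

# Local extrema (strict sign change of the first difference) of a vector;
# returns indices. Flat runs produce no extremum.
local_extrema_idx <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  which(d[-(n - 1L)] * d[-1L] < 0) + 1L
}

#' Tissue-edge and labeled-cell transition thresholds
#'
#' Locates transitions in the correlation curve. The smoothed derivative is
#' scanned for its largest-magnitude local extrema (each marks an intensity
#' population: tissue autofluorescence, labeled somata); extrema closer than
#' `min_separation` gray levels to a stronger one are suppressed. Each
#' selected extremum is then mapped to a reported threshold placed in the
#' sparse histogram gap below it: the middle of the first minimal-count run
#' of gray levels between the previous extremum (or the start of the defined
#' range) and the extremum. Thresholding at the lowest transition reproduces
#' the tissue silhouette, at the highest only labeled somata survive.
#'
#' @param curve A [correlation_curve()].
#' @param n_transitions Number of transitions sought (default 2).
#' @param smooth_window Moving-average window for the derivative (gray levels).
#' @param min_separation Minimum gray-level distance between selected extrema.
#' @return Object of class `threshold_selection`: `optimal`,
#'   `tissue_threshold`, `cell_threshold` (NA when not found), `transitions`
#'   (ascending), `extrema` (gray values of the selected derivative extrema),
#'   `missing` (number of requested transitions not found).
#' @export
transition_thresholds <- function(curve, n_transitions = 2L, smooth_window = 5L,
                                  min_separation = 5L) {
  ok <- which(!is.na(curve$deriv) & !is.na(curve$corr))
  if (length(ok) < 3L) {
    stop_sectionmap("correlation curve defined on too small a range",
                    "degenerate_input_error")
  }
  lo <- min(ok); hi <- max(ok)
  d <- as.numeric(moving_average(curve$deriv[lo:hi], smooth_window))
  cand <- local_extrema_idx(d)
  cand <- cand[abs(d[cand]) > 0]
  cand <- cand[order(abs(d[cand]), decreasing = TRUE)]
  # histogram reconstructed from n_above: n_0 = N_m - N_0, n_j = N_{j-1} - N_j
  nm <- attr(curve, "total_pixels")
  nj <- c(nm - curve$n_above[1L], -diff(curve$n_above))
  nj_smooth <- as.numeric(moving_average(nj, smooth_window))
  hist_at <- function(idx) nj_smooth[lo + idx - 1L]
  # Candidates are accepted in order of derivative magnitude. Besides the
  # separation rule, a candidate must mark a population distinct from those
  # already accepted: the histogram must dip between them (valley below half
  # the smaller flanking height). Sampling ripples inside one population
  # fail this bimodality check and never consume a transition slot.
  picked <- integer(0)
  for (idx in cand) {
    if (length(picked) == n_transitions) break
    if (!all(abs(idx - picked) >= min_separation)) next
    distinct <- TRUE
    for (p in picked) {
      gap <- (min(idx, p) + 1L):(max(idx, p) - 1L)
      v <- min(nj_smooth[lo + gap - 1L])
      if (v > 0.5 * min(hist_at(idx), hist_at(p))) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) picked <- c(picked, idx)
  }
  extrema <- sort(curve$threshold[lo:hi][picked])
  transitions <- integer(0)
  prev <- curve$threshold[lo]
  for (g in extrema) {
    gap <- which(curve$threshold > prev & curve$threshold < g)
    if (length(gap) == 0L) {
      transitions <- c(transitions, g - 1L)
    } else {
      counts <- nj[gap]
      mn <- min(counts)
      runs <- rle(counts == mn)
      first_len <- runs$lengths[which(runs$values)[1L]]
      first_off <- if (which(runs$values)[1L] == 1L) 0L else
        sum(runs$lengths[seq_len(which(runs$values)[1L] - 1L)])
      pickg <- gap[first_off + (first_len + 1L) %/% 2L]
      transitions <- c(transitions, curve$threshold[pickg])
    }
    prev <- g
  }
  n_found <- length(transitions)
  structure(list(
    optimal = optimal_threshold(curve),
    tissue_threshold = if (n_found >= 1L) transitions[1L] else NA_integer_,
    cell_threshold = if (n_found == n_transitions) transitions[n_found] else NA_integer_,
    transitions = transitions,
    extrema = extrema,
    missing = n_transitions - n_found
  ), class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> optimal %s | tissue %s | cell %s (%d missing)\n",
              format(x$optimal), format(x$tissue_threshold),
              format(x$cell_threshold), x$missing))
  invisible(x)
}

#' Correlation curves for every section of a stack
#'
#' Computes one curve per section, on the median-filtered image (the same
#' image the segmentation stages consume). Sections whose curve is degenerate
#' (for example, empty tissue) are flagged rather than aborting the stack;
#' their entry is `NULL` and listed in the `failed` attribute.
#'
#' @param stack List of [section_image].
#' @param median_window Median pre-filter window (odd; 1 disables).
#' @return List of [correlation_curve()] (or `NULL` where degenerate), with
#'   attribute `failed` holding the 1-based indices of flagged sections.
#' @export
per_section_curves <- function(stack, median_window = 3L) {
  if (length(stack) == 0L) stop_sectionmap("empty stack", "value_error")
  failed <- integer(0)
  out <- vector("list", length(stack))
  for (k in seq_along(stack)) {
    s <- stack[[k]]
    px <- if (median_window > 1L) median_filter(s$pixels, median_window) else s$pixels
    out[[k]] <- tryCatch(correlation_curve(px, bit_depth = s$bit_depth),
                         sectionmap_error = function(e) NULL)
    if (is.null(out[[k]])) failed <- c(failed, k)
  }
  attr(out, "failed") <- failed
  out
}

#' Export a correlation curve as CSV
#'
#' Columns: `threshold`, `corr`, `deriv`, `n_above`.
#' @param curve A [correlation_curve()].
#' @param path Output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$threshold, x$corr, type = "l", xlab = "threshold",
                 ylab = "correlation", ...)
  graphics::plot(x$threshold, x$deriv, type = "l", xlab = "threshold",
                 ylab = "d corr / d threshold", ...)
  invisible(x)
}
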