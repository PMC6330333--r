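# Circular cross-covariance of two equal-size matrices via FFT; entry
# [dr+1, dc+1] (0-based shifts, wrapped) is sum(a * shift(b, dr, dc)).
cross_cov_fft <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
}

#' Align a section stack by tissue-boundary correlation
#'
#' Section 0 is fixed; every subsequent section receives the integer
#' translation (within `search_radius` pixels) that maximizes the Pearson
#' correlation between its smoothed boundary raster and the previous aligned
#' section's. Because the boundary rasters have fixed variance under
#' translation, the correlation-maximizing shift equals the maximum of the
#' mean-removed cross-covariance, which is searched exhaustively over all
#' integer shifts via FFT and then restricted to the search radius. Ties
#' break toward the smallest shift (L1 norm, then row, then column), so
#' already-aligned stacks map to the identity. Transforms compose
#' cumulatively. Sections with an empty boundary raster inherit the previous
#' transform and are flagged.
#'
#' @param boundaries List of smoothed boundary rasters (equal-size matrices),
#'   rostral first (e.g. from [smooth_boundary()]).
#' @param search_radius Maximum |shift| per axis, pixels.
#' @return `data.frame` with one row per section: `rc_index`, `d_row`,
#'   `d_col` (translation applied to the section), `score` (boundary
#'   correlation against the previous aligned section; `NA` for section 0),
#'   `flagged`.
#' @export
align_stack <- function(boundaries, search_radius = 50L) {
  n <- length(boundaries)
  if (n < 2L) stop_sectionmap("need at least 2 sections to align", "value_error")
  dims <- dim(boundaries[[1L]])
  nr <- dims[1L]; nc <- dims[2L]
  wrap <- function(k, n) ifelse(k > n %/% 2L, k - n, k)
  d_row <- integer(n); d_col <- integer(n)
  score <- rep(NA_real_, n); flagged <- logical(n)
  ref <- boundaries[[1L]]
  if (sum(ref != 0) == 0L) flagged[1L] <- TRUE
  for (k in 2:n) {
    cur <- boundaries[[k]]
    if (!identical(dim(cur), dims)) {
      stop_sectionmap("boundary rasters must share dimensions", "value_error")
    }
    if (sum(cur != 0) == 0L) {
      d_row[k] <- d_row[k - 1L]; d_col[k] <- d_col[k - 1L]
      flagged[k] <- TRUE
      next
    }
    cc <- cross_cov_fft(ref - mean(ref), cur - mean(cur))
    dr <- wrap(row(cc) - 1L, nr)
    dc <- wrap(col(cc) - 1L, nc)
    ok <- abs(dr) <= search_radius & abs(dc) <= search_radius
    best <- max(cc[ok])
    cand <- which(ok & cc >= best - 1e-9 * abs(best))
    cand <- cand[order(abs(dr[cand]) + abs(dc[cand]), dr[cand], dc[cand])][1L]
    d_row[k] <- dr[cand]; d_col[k] <- dc[cand]
    shifted <- shift_matrix(cur, d_row[k], d_col[k])
    score[k] <- suppressWarnings(stats::cor(as.vector(ref), as.vector(shifted)))
    ref <- shifted
  }
  data.frame(rc_index = seq_len(n) - 1L, d_row = d_row, d_col = d_col,
             score = score, flagged = flagged)
}

#' Apply alignment transforms to boundary rasters
#'
#' @param boundaries List of boundary rasters.
#' @param transforms [align_stack()] result.
#' @return List of shifted rasters.
#' @export
apply_transforms <- function(boundaries, transforms) {
  lapply(seq_along(boundaries), function(k) {
    shift_matrix(boundaries[[k]], transforms$d_row[k], transforms$d_col[k])
  })
}

#' Validate alignment by cross-section boundary correlation
#'
#' For each edge thickness `t`, every aligned boundary raster is dilated with
#' a disc of radius `t` and all pairwise Pearson correlations between
#' sections are computed. On a well-aligned stack with smoothly varying
#' anatomy, adjacent sections correlate strongly and correlation falls off
#' with rostro-caudal distance; thicker edges are a more tolerant comparison
#' and raise correlations at any fixed lag.
#'
#' @param boundaries List of aligned binary boundary rasters.
#' @param thicknesses Integer dilation radii (pixels) to test.
#' @return Object of class `alignment_report`: `thicknesses` and `matrices`
#'   (one symmetric correlation matrix per thickness, unit diagonal).
#' @export
validate_alignment <- function(boundaries, thicknesses = c(1L, 2L, 4L, 8L)) {
  n <- length(boundaries)
  if (n < 2L) stop_sectionmap("need at least 2 sections", "value_error")
  mats <- lapply(thicknesses, function(t) {
    dil <- lapply(boundaries, function(b) {
      bb <- (b != 0) * 1
      if (t > 0) {
        brush <- EBImage::makeBrush(2L * as.integer(t) + 1L, shape = "disc")
        bb <- EBImage::imageData(EBImage::dilate(bb, brush))
      }
      as.vector(bb)
    })
    m <- stats::cor(do.call(cbind, dil))
    dimnames(m) <- NULL
    m
  })
  structure(list(thicknesses = thicknesses, matrices = mats),
            class = "alignment_report")
}

#' Mean correlation at each rostro-caudal lag
#'
#' Summarizes an [validate_alignment()] matrix as mean correlation by
#' |section distance|, the curve that shows adjacent sections correlating
#' highly and distant ones falling off.
#'
#' @param report An `alignment_report`.
#' @param thickness_index Which tested thickness to summarize.
#' @return `data.frame` with `lag` and `mean_corr`.
#' @export
lag_correlation <- function(report, thickness_index = 1L) {
  m <- report$matrices[[thickness_index]]
  n <- nrow(m)
  lags <- 1:(n - 1L)
  mc <- vapply(lags, function(l) {
    mean(m[cbind(1:(n - l), (1 + l):n)])
  }, 0)
  data.frame(lag = lags, mean_corr = mc)
}
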