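# Synthetic whole-brain section stacks with complete ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# sections are nested-ellipse phantoms (tissue silhouette, labeled anatomical
# regions, a granule-cell layer nested inside the bulb), imaged as two
# intensity populations (dim tissue autofluorescence, bright labeled somata)
# over a dark off-tissue background, with isolated saturated shot-noise
# pixels, a smooth multiplicative rostral-to-caudal decline in fluorescence,
# optional dense overlapping injection-site clusters, and optional per-section
# rigid shifts. Every random draw is fixed by the seed.

ellipse_mask_fun <- function(shape, center, axes) {
  if (any(axes <= 0)) return(matrix(FALSE, shape[1L], shape[2L]))
  r2 <- ((seq_len(shape[1L]) - center[1L]) / axes[1L])^2
  c2 <- ((seq_len(shape[2L]) - center[2L]) / axes[2L])^2
  outer(r2, c2, `+`) <= 1
}

# Smooth axis-scale profile across a region's section span: a raised-sine
# bump makes rostral/caudal ends of a structure smaller, so stacked sections
# vary smoothly and nested layers are non-spherical.
span_profile <- function(k, span_len, lo) {
  lo + (1 - lo) * sin(pi * (k + 0.5) / span_len)
}

region_def <- function(name, label, sections, center, axes,
                       hemisphere = "ipsi", is_olfactory_cortex = FALSE,
                       profile_lo = 1, exclude = NULL) {
  list(name = name, label = as.integer(label), sections = as.integer(sections),
       center = center, axes = axes, hemisphere = hemisphere,
       is_olfactory_cortex = is_olfactory_cortex, profile_lo = profile_lo,
       exclude = exclude)
}

region_axes_at <- function(reg, t) {
  if (reg$profile_lo >= 1) return(reg$axes)
  k <- match(t, reg$sections) - 1L
  reg$axes * span_profile(k, length(reg$sections), reg$profile_lo)
}

#' Construct a synthetic-brain specification
#'
#' Collects the geometry (per-section tissue ellipse and labeled-region
#' ellipses, axes varying smoothly along the rostro-caudal axis), per-region
#' cell counts, the intensity/noise model and injected per-section shifts.
#' All sizes are in pixels of the stated `pixel_size`.
#'
#' @param n_sections Number of coronal sections.
#' @param section_shape `c(rows, cols)` in pixels.
#' @param pixel_size,thickness Physical scale, micrometers.
#' @param bit_depth 8 or 16.
#' @param tissue List: `center`, `axes`, `profile_lo` for the outer tissue
#'   ellipse.
#' @param regions List of region definitions (internal `region_def` lists).
#' @param counts Named integer vector of cells per region (names = region
#'   names); alternatively give `proportions` and `n_cells`.
#' @param proportions Named numeric vector summing to 1.
#' @param n_cells Total cells, apportioned by `proportions` with largest
#'   remainders (fixture counts are exact, not a multinomial draw).
#' @param per_section_counts Optional named list: for a region, explicit
#'   per-section cell counts (overrides the area-proportional split).
#' @param intensity List: `background_mean`, `background_sd`, `tissue_mean`,
#'   `tissue_sd`, `soma_amplitude`, `soma_amplitude_sd`, `soma_radius_px`,
#'   `soma_sigma_px`, `rc_decay` (per-section multiplicative decay rate,
#'   intensities scale as `exp(-rc_decay * rc_index)`), `shot_noise_rate`
#'   (fraction of pixels saturated).
#' @param injection List: `region` (name receiving clustered injection-site
#'   label), `overlap_fraction` (fraction of that region's cells drawn from a
#'   dense Gaussian cluster so somata deliberately touch; scalar or one value
#'   per section), `cluster_sd_px`.
#' @param min_separation_px Minimum center separation enforced for
#'   non-clustered cells.
#' @param shifts `n_sections x 2` integer matrix of per-section (row, col)
#'   shifts applied to the rendered images.
#' @param seed Integer seed fixing every random draw.
#' @return Object of class `synthetic_brain_spec`.
#' @export
synthetic_brain_spec <- function(n_sections = 24L,
                                 section_shape = c(512L, 512L),
                                 pixel_size = 4, thickness = 100,
                                 bit_depth = 8L,
                                 tissue = list(center = c(256, 256),
                                               axes = c(235, 245),
                                               profile_lo = 0.95),
                                 regions = list(),
                                 counts = NULL, proportions = NULL,
                                 n_cells = NULL, per_section_counts = NULL,
                                 intensity = list(),
                                 injection = list(region = NULL,
                                                  overlap_fraction = 0,
                                                  cluster_sd_px = 8),
                                 min_separation_px = 8L,
                                 shifts = NULL, seed = 0L) {
  intensity <- utils::modifyList(list(
    background_mean = 0, background_sd = 0,
    tissue_mean = 60, tissue_sd = 5,
    soma_amplitude = 180, soma_amplitude_sd = 15,
    soma_radius_px = 2.5, soma_sigma_px = 1.25,
    rc_decay = 0.01, shot_noise_rate = 2e-4), intensity)
  if (is.null(counts)) {
    if (is.null(proportions) || is.null(n_cells)) {
      counts <- integer(0)
    } else {
      stopifnot(abs(sum(proportions) - 1) < 1e-9)
      counts <- stats::setNames(apportion_counts(n_cells, proportions),
                                names(proportions))
    }
  }
  if (is.null(shifts)) shifts <- matrix(0L, n_sections, 2L)
  spec <- list(n_sections = as.integer(n_sections),
               section_shape = as.integer(section_shape),
               pixel_size = pixel_size, thickness = thickness,
               bit_depth = as.integer(bit_depth),
               tissue = tissue, regions = regions,
               counts = counts, proportions = proportions,
               per_section_counts = per_section_counts,
               intensity = intensity, injection = injection,
               min_separation_px = as.integer(min_separation_px),
               shifts = shifts, seed = as.integer(seed))
  class(spec) <- "synthetic_brain_spec"
  spec
}

#' @export
print.synthetic_brain_spec <- function(x, ...) {
  cat(sprintf("<synthetic_brain_spec> %d sections %dx%d px, %d regions, %d cells, seed %d\n",
              x$n_sections, x$section_shape[1L], x$section_shape[2L],
              length(x$regions), sum(x$counts), x$seed))
  invisible(x)
}

tissue_mask_at <- function(spec, t, shrink = 0) {
  sc <- span_profile(t, spec$n_sections, spec$tissue$profile_lo)
  ellipse_mask_fun(spec$section_shape, spec$tissue$center,
                   pmax(spec$tissue$axes * sc - shrink, 0))
}

region_mask_at <- function(spec, reg, t, shrink = 0) {
  ax <- region_axes_at(reg, t)
  m <- ellipse_mask_fun(spec$section_shape, reg$center, pmax(ax - shrink, 0)) &
    tissue_mask_at(spec, t, shrink = 6)
  if (!is.null(reg$exclude)) {
    ex <- spec$regions[[which(vapply(spec$regions, `[[`, "", "name") == reg$exclude)]]
    m <- m & !ellipse_mask_fun(spec$section_shape, ex$center,
                               region_axes_at(ex, t) + shrink)
  }
  m
}

#' Region name table of a spec
#'
#' @param spec A [synthetic_brain_spec()].
#' @return `data.frame`: `label`, `name`, `is_olfactory_cortex`, `hemisphere`.
#' @export
region_name_table <- function(spec) {
  data.frame(
    label = vapply(spec$regions, `[[`, 0L, "label"),
    name = vapply(spec$regions, `[[`, "", "name"),
    is_olfactory_cortex = vapply(spec$regions, `[[`, TRUE, "is_olfactory_cortex"),
    hemisphere = vapply(spec$regions, `[[`, "", "hemisphere"))
}

# Separated placement: sample sites without replacement from a randomly
# phased square grid of pitch = min_separation restricted to the placement
# mask, guaranteeing pairwise (Chebyshev) center distances >= pitch so that
# rendered somata never touch.
place_separated <- function(mask, n, pitch) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  ph <- sample.int(pitch, 2L)
  rows <- seq(ph[1L], nrow(mask), by = pitch)
  cols <- seq(ph[2L], ncol(mask), by = pitch)
  sites <- as.matrix(expand.grid(row = rows, col = cols))
  sites <- sites[mask[sites], , drop = FALSE]
  if (nrow(sites) < n) {
    stop_sectionmap(sprintf(
      "capacity error: %d cells requested but only %d separated sites available",
      n, nrow(sites)), "capacity_error")
  }
  sites[sample.int(nrow(sites), n), , drop = FALSE]
}

# Clustered (injection-site) placement: Gaussian around the mask centroid,
# resampled into the mask, no separation constraint -- somata overlap.
place_clustered <- function(mask, n, sd_px) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  fg <- which(mask)
  ctr <- c(mean(((fg - 1L) %% nrow(mask)) + 1L),
           mean(((fg - 1L) %/% nrow(mask)) + 1L))
  out <- matrix(0, n, 2L)
  k <- 0L
  while (k < n) {
    m <- (n - k) * 2L
    cand <- cbind(round(stats::rnorm(m, ctr[1L], sd_px)),
                  round(stats::rnorm(m, ctr[2L], sd_px)))
    ok <- cand[, 1L] >= 1 & cand[, 1L] <= nrow(mask) &
      cand[, 2L] >= 1 & cand[, 2L] <= ncol(mask)
    ok[ok] <- mask[cand[ok, , drop = FALSE]]
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n - k)
    if (take > 0L) {
      out[(k + 1L):(k + take), ] <- cand[seq_len(take), , drop = FALSE]
      k <- k + take
    }
  }
  out
}

# Precomputed truncated-Gaussian soma stamp: offsets within soma_radius_px
# and the radial falloff exp(-d^2 / (2 sigma^2)).
soma_stamp <- function(radius, sigma) {
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- off$dr^2 + off$dc^2
  keep <- d2 <= radius^2
  list(dr = off$dr[keep], dc = off$dc[keep],
       f = exp(-d2[keep] / (2 * sigma^2)))
}

#' Generate a synthetic brain from a specification
#'
#' Deterministic given the seed (each section uses a seed derived from the
#' global one). Somata are rendered as truncated Gaussian blobs, shot noise
#' as isolated saturated pixels, and the rostro-caudal decline is applied
#' multiplicatively to all tissue and soma intensities. Region label masks
#' are emitted in the aligned (unshifted) frame; the rendered images carry
#' the spec's per-section shifts.
#'
#' @param spec A [synthetic_brain_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return Object of class `synthetic_brain`: `stack` (list of
#'   [section_image]), `region_labels` (list of integer label matrices),
#'   `name_table`, and `truth` (class `ground_truth`: `cells` data frame with
#'   true centroids and region labels, `masks`, `shifts`, `section_means`).
#' @export
generate_brain <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_brain_spec"))
  seed <- as.integer(seed %||% spec$seed)
  shape <- spec$section_shape
  its <- spec$intensity
  maxv <- 2^spec$bit_depth - 1
  decay <- exp(-its$rc_decay * (seq_len(spec$n_sections) - 1L))
  name_table <- region_name_table(spec)

  # --- region label masks (aligned frame) ---
  masks <- lapply(seq_len(spec$n_sections) - 1L, function(t) {
    lab <- matrix(0L, shape[1L], shape[2L])
    for (reg in spec$regions) {
      if (!(t %in% reg$sections)) next
      lab[region_mask_at(spec, reg, t)] <- reg$label
    }
    lab
  })

  # --- cell placement ---
  region_names <- vapply(spec$regions, `[[`, "", "name")
  cells <- vector("list", length(spec$regions))
  for (ri in seq_along(spec$regions)) {
    reg <- spec$regions[[ri]]
    total <- if (reg$name %in% names(spec$counts)) spec$counts[[reg$name]] else 0L
    if (is.na(total)) total <- 0L
    psc <- spec$per_section_counts[[reg$name]]
    place_masks <- lapply(reg$sections, function(t) {
      region_mask_at(spec, reg, t, shrink = 4)
    })
    per_sec <- if (!is.null(psc)) as.integer(psc) else {
      areas <- vapply(place_masks, sum, 0L)
      if (total > 0L && sum(areas) == 0L) {
        stop_sectionmap(sprintf("capacity error: region %s has no placement area",
                                reg$name), "capacity_error")
      }
      if (total == 0L) rep(0L, length(reg$sections)) else
        apportion_counts(total, areas)
    }
    ov <- spec$injection$overlap_fraction
    ov <- if (identical(spec$injection$region, reg$name)) {
      if (length(ov) == 1L) rep(ov, length(reg$sections)) else ov
    } else rep(0, length(reg$sections))
    placed <- vector("list", length(reg$sections))
    for (k in seq_along(reg$sections)) {
      t <- reg$sections[k]
      set.seed(seed + 7919L * t + 131L * reg$label)
      n_clu <- round(per_sec[k] * ov[k])
      n_sep <- per_sec[k] - n_clu
      pts <- rbind(
        place_separated(place_masks[[k]], n_sep, spec$min_separation_px),
        place_clustered(place_masks[[k]], n_clu, spec$injection$cluster_sd_px))
      if (nrow(pts) > 0L) {
        placed[[k]] <- data.frame(rc_index = t, row = pts[, 1L], col = pts[, 2L],
                                  label = reg$label, region = reg$name,
                                  clustered = rep(c(FALSE, TRUE),
                                                  c(n_sep, n_clu)))
      }
    }
    cells[[ri]] <- do.call(rbind, placed[!vapply(placed, is.null, TRUE)])
  }
  cells <- do.call(rbind, cells[!vapply(cells, is.null, TRUE)])
  if (is.null(cells)) {
    cells <- data.frame(rc_index = integer(0), row = numeric(0),
                        col = numeric(0), label = integer(0),
                        region = character(0), clustered = logical(0))
  }
  cells <- cells[order(cells$rc_index, cells$label, cells$row, cells$col), ]
  rownames(cells) <- NULL

  # --- render sections ---
  stamp <- soma_stamp(its$soma_radius_px, its$soma_sigma_px)
  stack <- vector("list", spec$n_sections)
  section_means <- numeric(spec$n_sections)
  for (t in seq_len(spec$n_sections) - 1L) {
    set.seed(seed + 7919L * t)
    # nonzero background models scattered light / residual autofluorescence,
    # which scales with overall fluorescence, hence also decays along RC
    img <- if (its$background_sd > 0 || its$background_mean > 0) {
      matrix(pmax(stats::rnorm(prod(shape), its$background_mean,
                               its$background_sd), 0), shape[1L],
             shape[2L]) * decay[t + 1L]
    } else matrix(0, shape[1L], shape[2L])
    tm <- tissue_mask_at(spec, t)
    ntis <- sum(tm)
    img[tm] <- pmax(stats::rnorm(ntis, its$tissue_mean, its$tissue_sd), 0) *
      decay[t + 1L]
    section_means[t + 1L] <- its$tissue_mean * decay[t + 1L]
    sec_cells <- cells[cells$rc_index == t, , drop = FALSE]
    if (nrow(sec_cells) > 0L) {
      amp <- pmax(stats::rnorm(nrow(sec_cells), its$soma_amplitude,
                               its$soma_amplitude_sd), 0) * decay[t + 1L]
      for (ci in seq_len(nrow(sec_cells))) {
        rr <- sec_cells$row[ci] + stamp$dr
        cc <- sec_cells$col[ci] + stamp$dc
        ok <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
        idx <- cbind(rr[ok], cc[ok])
        img[idx] <- img[idx] + amp[ci] * stamp$f[ok]
      }
    }
    img <- round(pmin(pmax(img, 0), maxv))
    n_hot <- round(its$shot_noise_rate * prod(shape))
    if (n_hot > 0L) img[sample.int(prod(shape), n_hot)] <- maxv
    img <- shift_matrix(img, spec$shifts[t + 1L, 1L], spec$shifts[t + 1L, 2L])
    stack[[t + 1L]] <- section_image(img, bit_depth = spec$bit_depth,
                                     pixel_size = spec$pixel_size,
                                     thickness = spec$thickness, rc_index = t)
  }

  truth <- structure(list(cells = cells, masks = masks, shifts = spec$shifts,
                          section_means = section_means,
                          name_table = name_table),
                     class = "ground_truth")
  structure(list(stack = stack, region_labels = masks,
                 name_table = name_table, truth = truth, spec = spec,
                 seed = seed),
            class = "synthetic_brain")
}

#' @export
print.synthetic_brain <- function(x, ...) {
  cat(sprintf("<synthetic_brain> %d sections, %d true cells, seed %d\n",
              length(x$stack), nrow(x$truth$cells), x$seed))
  invisible(x)
}
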