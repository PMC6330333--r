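# 3D assembly and quantification of aligned sections and detected cells.
#
# Coordinate semantics, used everywhere: medial-lateral (ML, x) is the image
# column axis, dorsal-ventral (DV, y) the row axis, rostro-caudal (RC, z) the
# section index; physical position is pixel index times pixel size, and
# z = rc_index * thickness.

#' Assemble a brain reconstruction
#'
#' Maps every detected cell through its section's alignment transform, scales
#' to micrometers, attaches tissue masks and region label masks (label masks
#' are in the aligned frame, as produced by atlas annotation or the synthetic
#' generator). Cells falling outside their section's tissue mask are flagged,
#' not dropped.
#'
#' @param stack List of [section_image].
#' @param transforms [align_stack()] result (or `NULL` for identity).
#' @param tissue_masks List of 0/1 tissue masks, image frame, one per section.
#' @param cells `data.frame` of detected cells (from [find_cells()], image
#'   frame), all sections concatenated.
#' @param region_labels List of integer label matrices (aligned frame).
#' @param name_table `data.frame` with `label`, `name`,
#'   `is_olfactory_cortex`, `hemisphere`.
#' @return Object of class `brain_reconstruction`; `cells` gains aligned
#'   pixel coordinates, micrometer coordinates, `region`/`label` and
#'   `inside_tissue`.
#' @export
build_reconstruction <- function(stack, transforms = NULL, tissue_masks = NULL,
                                 cells, region_labels = NULL,
                                 name_table = NULL) {
  n <- length(stack)
  rc <- vapply(stack, `[[`, 0L, "rc_index")
  if (is.null(transforms)) {
    transforms <- data.frame(rc_index = rc, d_row = 0L, d_col = 0L,
                             score = NA_real_, flagged = FALSE)
  }
  if (nrow(cells) > 0L &&
      !all(cells$rc_index %in% transforms$rc_index)) {
    stop_sectionmap("cells reference sections with no transform", "structural_error")
  }
  ps <- stack[[1L]]$pixel_size
  th <- stack[[1L]]$thickness
  cells <- cells[order(cells$rc_index, cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  tr_row <- transforms$d_row[match(cells$rc_index, transforms$rc_index)]
  tr_col <- transforms$d_col[match(cells$rc_index, transforms$rc_index)]
  cells$arow <- cells$row + tr_row
  cells$acol <- cells$col + tr_col
  cells$x_um <- cells$acol * ps
  cells$y_um <- cells$arow * ps
  cells$z_um <- cells$rc_index * th
  cells$inside_tissue <- rep(NA, nrow(cells))
  if (!is.null(tissue_masks)) {
    for (k in seq_len(n)) {
      sel <- which(cells$rc_index == rc[k])
      if (length(sel) == 0L) next
      shifted <- shift_matrix(tissue_masks[[k]], transforms$d_row[k],
                              transforms$d_col[k])
      rr <- pmin(pmax(round(cells$arow[sel]), 1L), nrow(shifted))
      cc <- pmin(pmax(round(cells$acol[sel]), 1L), ncol(shifted))
      cells$inside_tissue[sel] <- shifted[cbind(rr, cc)] != 0
    }
  }
  cells$label <- rep(0L, nrow(cells))
  if (!is.null(region_labels)) {
    for (k in seq_len(n)) {
      sel <- which(cells$rc_index == rc[k])
      if (length(sel) == 0L) next
      if (is.null(region_labels[[k]])) {
        stop_sectionmap("missing region label mask for a section carrying cells",
                        "structural_error")
      }
      lab <- region_labels[[k]]
      rr <- pmin(pmax(round(cells$arow[sel]), 1L), nrow(lab))
      cc <- pmin(pmax(round(cells$acol[sel]), 1L), ncol(lab))
      cells$label[sel] <- lab[cbind(rr, cc)]
    }
  }
  cells$region <- if (!is.null(name_table)) {
    ifelse(cells$label == 0L, NA_character_,
           name_table$name[match(cells$label, name_table$label)])
  } else rep(NA_character_, nrow(cells))
  structure(list(sections = stack, transforms = transforms,
                 tissue_masks = tissue_masks, cells = cells,
                 region_labels = region_labels, name_table = name_table,
                 pixel_size = ps, thickness = th),
            class = "brain_reconstruction")
}

#' @export
print.brain_reconstruction <- function(x, ...) {
  cat(sprintf("<brain_reconstruction> %d sections, %d cells (%d assigned to %d regions)\n",
              length(x$sections), nrow(x$cells), sum(x$cells$label > 0L),
              length(unique(x$cells$label[x$cells$label > 0L]))))
  invisible(x)
}

region_cells <- function(recon, region) {
  recon$cells[!is.na(recon$cells$region) & recon$cells$region %in% region, ,
              drop = FALSE]
}

#' Injection-site precision report
#'
#' The injection-site center of mass is the arithmetic mean of the (x, y, z)
#' positions of all labeled cells within the organ (here, the bulb: the
#' organ region plus its nested target layer), and precision is the fraction
#' of those cells inside the target-layer mask.
#'
#' @param recon A [build_reconstruction()] result.
#' @param organ_region Region name of the organ shell (e.g. bulb outside the
#'   layer); organ membership is the union of `organ_region` and
#'   `layer_region` since the layer is nested inside the organ.
#' @param layer_region Region name of the injection-target layer.
#' @return Object of class `injection_site_report`: `center_of_mass` (x, y, z
#'   micrometers), `n_inside`, `n_outside`, `fraction_inside`, `empty`.
#' @export
injection_site_report <- function(recon, organ_region, layer_region) {
  known <- recon$name_table$name
  if (!all(c(organ_region, layer_region) %in% known)) {
    stop_sectionmap("unknown region name", "value_error")
  }
  organ <- region_cells(recon, c(organ_region, layer_region))
  if (nrow(organ) == 0L) {
    return(structure(list(center_of_mass = c(x = NA_real_, y = NA_real_,
                                             z = NA_real_),
                          n_inside = 0L, n_outside = 0L,
                          fraction_inside = NA_real_, empty = TRUE),
                     class = "injection_site_report"))
  }
  n_in <- sum(organ$region == layer_region)
  structure(list(
    center_of_mass = c(x = mean(organ$x_um), y = mean(organ$y_um),
                       z = mean(organ$z_um)),
    n_inside = n_in, n_outside = nrow(organ) - n_in,
    fraction_inside = n_in / nrow(organ), empty = FALSE),
    class = "injection_site_report")
}

#' @export
print.injection_site_report <- function(x, ...) {
  if (x$empty) cat("<injection_site_report> no cells in organ\n") else
    cat(sprintf("<injection_site_report> %d inside / %d outside (%.1f%%), COM (%.0f, %.0f, %.0f) um\n",
                x$n_inside, x$n_outside, 100 * x$fraction_inside,
                x$center_of_mass[1L], x$center_of_mass[2L], x$center_of_mass[3L]))
  invisible(x)
}

axis_values <- function(cells, axis) {
  switch(axis,
         ML = cells$x_um, DV = cells$y_um, RC = cells$z_um,
         stop_sectionmap("axis must be ML, DV or RC", "value_error"))
}

#' Cell distribution along an anatomical axis
#'
#' Normalized histogram of cell positions along the medial-lateral,
#' dorsal-ventral or rostro-caudal axis, restricted to one region (or all
#' assigned cells).
#'
#' @param recon A reconstruction.
#' @param region Region name, or `NULL` for all cells.
#' @param axis `"ML"`, `"DV"` or `"RC"`.
#' @param n_bins Number of equal-width bins over the occupied range.
#' @return List: `breaks`, `counts`, `prob` (sums to 1), `axis`, `empty`.
#' @export
axis_distribution <- function(recon, region = NULL, axis = "DV", n_bins = 20L) {
  cells <- if (is.null(region)) recon$cells else region_cells(recon, region)
  v <- axis_values(cells, axis)
  if (length(v) == 0L) {
    return(list(breaks = numeric(0), counts = integer(0), prob = numeric(0),
                axis = axis, empty = TRUE))
  }
  rng <- range(v)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- as.integer(table(cut(v, breaks, include.lowest = TRUE)))
  list(breaks = breaks, counts = counts, prob = counts / sum(counts),
       axis = axis, empty = FALSE)
}

#' 2D cell-density map
#'
#' Bins cell positions in the chosen projection plane (the third axis is
#' projected out): `sagittal` keeps (RC, DV), `coronal` keeps (ML, DV),
#' `horizontal` keeps (ML, RC). Optionally the injection-site center of mass
#' is subtracted from all coordinates first ("normalized to injection site").
#'
#' @param recon A reconstruction.
#' @param plane Projection plane.
#' @param bin_um Bin width, micrometers.
#' @param normalize_to Optional [injection_site_report()] whose center of
#'   mass becomes the origin.
#' @param region Optional region restriction.
#' @return List: `counts` (matrix, rows = first axis), `h_breaks`,
#'   `v_breaks`, `plane`.
#' @export
density_map <- function(recon, plane = "coronal", bin_um = 100,
                        normalize_to = NULL, region = NULL) {
  if (bin_um <= 0) stop_sectionmap("bin_um must be > 0", "value_error")
  cells <- if (is.null(region)) recon$cells else region_cells(recon, region)
  ax <- switch(plane, sagittal = c("RC", "DV"), coronal = c("ML", "DV"),
               horizontal = c("ML", "RC"),
               stop_sectionmap("plane must be sagittal, coronal or horizontal",
                               "value_error"))
  h <- axis_values(cells, ax[1L])
  v <- axis_values(cells, ax[2L])
  if (!is.null(normalize_to)) {
    com <- normalize_to$center_of_mass
    off <- c(ML = unname(com["x"]), DV = unname(com["y"]), RC = unname(com["z"]))
    h <- h - off[ax[1L]]
    v <- v - off[ax[2L]]
  }
  if (length(h) == 0L) {
    return(list(counts = matrix(0L, 0L, 0L), h_breaks = numeric(0),
                v_breaks = numeric(0), plane = plane))
  }
  brk <- function(x) {
    lo <- floor(min(x) / bin_um) * bin_um
    hi <- ceiling((max(x) + 1e-9) / bin_um) * bin_um
    seq(lo, max(hi, lo + bin_um), by = bin_um)
  }
  hb <- brk(h); vb <- brk(v)
  counts <- table(cut(h, hb, include.lowest = TRUE),
                  cut(v, vb, include.lowest = TRUE))
  list(counts = unname(matrix(as.integer(counts), nrow(counts), ncol(counts))),
       h_breaks = hb, v_breaks = vb, plane = plane)
}

#' Region assignment summary
#'
#' Counts detected cells per anatomical region (each cell takes the label
#' under its centroid pixel) and reports percentages over assigned cells;
#' unassigned cells (label 0) are reported separately.
#'
#' @param recon A reconstruction with region labels.
#' @return Object of class `distribution_report`: `table` (`data.frame`:
#'   `label`, `name`, `is_olfactory_cortex`, `hemisphere`, `n`, `percent`),
#'   `n_assigned`, `n_unassigned`.
#' @export
region_assignment <- function(recon) {
  if (is.null(recon$region_labels)) {
    stop_sectionmap("reconstruction carries no region label masks",
                    "structural_error")
  }
  nt <- recon$name_table
  n <- vapply(nt$label, function(l) sum(recon$cells$label == l), 0L)
  assigned <- sum(n)
  tab <- data.frame(label = nt$label, name = nt$name,
                    is_olfactory_cortex = nt$is_olfactory_cortex,
                    hemisphere = nt$hemisphere, n = n,
                    percent = if (assigned > 0L) 100 * n / assigned else
                      rep(NA_real_, length(n)))
  structure(list(table = tab, n_assigned = assigned,
                 n_unassigned = sum(recon$cells$label == 0L)),
            class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("<distribution_report> %d assigned, %d unassigned\n",
              x$n_assigned, x$n_unassigned))
  print(x$table[order(-x$table$n), c("name", "n", "percent")], row.names = FALSE)
  invisible(x)
}

#' Two-compartment cell ratio
#'
#' Counts cells in two adjacent compartments (e.g. main vs accessory
#' olfactory bulb granule layers) and reports the first compartment's share
#' of their total, the spillover control for injection-site placement.
#'
#' @param recon A reconstruction.
#' @param region_a,region_b Region names.
#' @return List: `n_a`, `n_b`, `share_a_percent` (100 * a / (a + b); `NA` and
#'   `undefined = TRUE` when both counts are zero).
#' @export
compartment_ratio <- function(recon, region_a, region_b) {
  known <- recon$name_table$name
  if (!all(c(region_a, region_b) %in% known)) {
    stop_sectionmap("unknown region name", "value_error")
  }
  n_a <- nrow(region_cells(recon, region_a))
  n_b <- nrow(region_cells(recon, region_b))
  list(n_a = n_a, n_b = n_b,
       share_a_percent = if (n_a + n_b == 0L) NA_real_ else
         100 * n_a / (n_a + n_b),
       undefined = n_a + n_b == 0L)
}
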