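# End-to-end orchestration: ingest -> threshold -> segment -> align ->
# reconstruct -> quantify -> validate (when ground truth is available).

#' Default pipeline parameters
#'
#' One flat list covering every stage; all entries can be overridden from a
#' run configuration.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    threshold_mode = "auto",      # auto | manual
    manual_values = NULL,         # per-section cell thresholds when manual
    n_transitions = 2L, smooth_window = 5L, min_separation = 5L,
    median_window = 3L, connectivity = 8L,
    min_area_um2 = 60, max_area_um2 = 600, min_roundness = 0.4,
    boundary_sigma = 2, search_radius = 50L, align_level = 2L,
    thicknesses = c(1L, 2L, 4L, 8L),
    axis_bins = 20L, density_bin_um = 100)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0L) {
    stop_sectionmap(sprintf("unknown parameter(s): %s",
                            paste(bad, collapse = ", ")), "config_error")
  }
  utils::modifyList(p, over)
}

# Tissue mask, traced silhouette and smoothed boundary raster of one section.
section_boundary <- function(section, tissue_threshold, median_window,
                             sigma, filtered = NULL) {
  filtered <- filtered %||% median_filter(section$pixels, median_window)
  if (is.na(tissue_threshold)) {
    return(list(mask = matrix(0L, nrow(filtered), ncol(filtered)),
                boundary = NULL, smoothed = matrix(0, nrow(filtered),
                                                   ncol(filtered))))
  }
  mask <- threshold_image(filtered, tissue_threshold, section$bit_depth)$pixels
  bnds <- trace_boundary(mask, rc_index = section$rc_index)
  if (length(bnds) == 0L) {
    return(list(mask = mask, boundary = NULL,
                smoothed = matrix(0, nrow(mask), ncol(mask))))
  }
  main <- bnds[[which.max(vapply(bnds, function(b) nrow(b$contour), 0L))]]
  list(mask = mask, boundary = main, smoothed = smooth_boundary(main, sigma))
}

#' Run the reconstruction pipeline on a section stack
#'
#' The core engine behind [run_pipeline()]: computes per-section correlation
#' curves and threshold selections (MCT), traces and smooths tissue
#' boundaries, aligns the stack (alignment runs on mean-pyramid level
#' `align_level`, recovered shifts rescaled to full resolution), detects
#' cells at each section's labeled-cell threshold restricted to the region
#' masks, and assembles the 3D reconstruction with region assignment.
#'
#' @param stack List of [section_image].
#' @param region_labels Optional list of integer label masks (aligned frame);
#'   their union also serves as the detection ROI.
#' @param name_table Region name table matching `region_labels`.
#' @param params A [pipeline_params()] list.
#' @return List: `curves`, `selections`, `boundaries` (per-section tissue
#'   mask + contour + smoothed raster), `transforms`, `alignment`
#'   (correlation report), `cells`, `recon`.
#' @export
process_stack <- function(stack, region_labels = NULL, name_table = NULL,
                          params = pipeline_params()) {
  n <- length(stack)
  filtered <- lapply(stack, function(s) {
    if (params$median_window > 1L) median_filter(s$pixels, params$median_window)
    else s$pixels
  })
  curves <- lapply(seq_len(n), function(k) {
    tryCatch(correlation_curve(filtered[[k]], bit_depth = stack[[k]]$bit_depth),
             sectionmap_error = function(e) NULL)
  })
  attr(curves, "failed") <- which(vapply(curves, is.null, TRUE))
  selections <- lapply(seq_len(n), function(k) {
    if (is.null(curves[[k]])) return(NULL)
    sel <- transition_thresholds(curves[[k]], params$n_transitions,
                                 params$smooth_window, params$min_separation)
    if (identical(params$threshold_mode, "manual") &&
        !is.null(params$manual_values)) {
      sel$cell_threshold <- params$manual_values[[k]]
    }
    sel
  })
  boundaries <- lapply(seq_len(n), function(k) {
    tt <- if (is.null(selections[[k]])) NA_integer_ else
      selections[[k]]$tissue_threshold
    section_boundary(stack[[k]], tt, params$median_window,
                     params$boundary_sigma, filtered = filtered[[k]])
  })
  smoothed <- lapply(boundaries, `[[`, "smoothed")
  transforms <- if (n >= 2L) {
    lvl <- params$align_level
    coarse <- if (lvl > 0L) {
      lapply(smoothed, function(m) build_pyramid(m, lvl)$levels[[lvl + 1L]])
    } else smoothed
    tr <- align_stack(coarse, search_radius = params$search_radius)
    tr$d_row <- as.integer(tr$d_row * 2^lvl)
    tr$d_col <- as.integer(tr$d_col * 2^lvl)
    tr$rc_index <- vapply(stack, `[[`, 0L, "rc_index")
    tr
  } else NULL
  aligned_edges <- lapply(seq_len(n), function(k) {
    b <- boundaries[[k]]$boundary
    m <- matrix(0L, nrow(stack[[k]]$pixels), ncol(stack[[k]]$pixels))
    if (!is.null(b)) m[b$contour] <- 1L
    if (!is.null(transforms)) {
      m <- shift_matrix(m, transforms$d_row[k], transforms$d_col[k])
    }
    m
  })
  alignment <- if (n >= 2L) {
    validate_alignment(aligned_edges, params$thicknesses)
  } else NULL
  cparams <- cell_params(params$median_window, params$connectivity,
                         params$min_area_um2, params$max_area_um2,
                         params$min_roundness)
  cells <- lapply(seq_len(n), function(k) {
    ct <- if (is.null(selections[[k]])) NA_integer_ else
      selections[[k]]$cell_threshold
    roi <- NULL
    if (!is.null(region_labels)) {
      roi <- (region_labels[[k]] > 0L) * 1L
      if (!is.null(transforms)) {
        roi <- shift_matrix(roi, -transforms$d_row[k], -transforms$d_col[k])
      }
    }
    find_cells(stack[[k]], ct, roi_mask = roi, params = cparams,
               filtered = filtered[[k]])
  })
  cells <- do.call(rbind, cells)
  recon <- build_reconstruction(stack, transforms,
                                lapply(boundaries, `[[`, "mask"),
                                cells, region_labels, name_table)
  list(curves = curves, selections = selections, boundaries = boundaries,
       transforms = transforms, alignment = alignment, cells = cells,
       recon = recon)
}

config_schema <- function() {
  list(input = c("preset", "n_cells", "paths", "mask_paths", "name_table",
                 "pixel_size", "thickness"),
       seed = NULL,
       threshold = c("mode", "manual_values", "n_transitions",
                     "smooth_window", "min_separation"),
       segment = c("median_window", "connectivity", "min_area_um2",
                   "max_area_um2", "min_roundness", "boundary_sigma"),
       align = c("search_radius", "pyramid_level", "thicknesses"),
       quantify = c("organ_region", "layer_region", "compartment",
                    "axis_bins", "density_bin_um"),
       log_level = NULL)
}

#' Validate a run configuration
#'
#' Rejects unknown keys (top level and nested) before any computation.
#'
#' @param config Nested list (e.g. parsed from YAML).
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad) > 0L) {
    stop_sectionmap(sprintf("unknown config key(s): %s",
                            paste(bad, collapse = ", ")), "config_error")
  }
  for (sec in names(config)) {
    allowed <- schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad) > 0L) {
      stop_sectionmap(sprintf("unknown config key(s) under %s: %s", sec,
                              paste(bad, collapse = ", ")), "config_error")
    }
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_to_params <- function(config) {
  pipeline_params(
    threshold_mode = config$threshold$mode %||% "auto",
    manual_values = config$threshold$manual_values,
    n_transitions = config$threshold$n_transitions %||% 2L,
    smooth_window = config$threshold$smooth_window %||% 5L,
    min_separation = config$threshold$min_separation %||% 5L,
    median_window = config$segment$median_window %||% 3L,
    connectivity = config$segment$connectivity %||% 8L,
    min_area_um2 = config$segment$min_area_um2 %||% 60,
    max_area_um2 = config$segment$max_area_um2 %||% 600,
    min_roundness = config$segment$min_roundness %||% 0.4,
    boundary_sigma = config$segment$boundary_sigma %||% 2,
    search_radius = config$align$search_radius %||% 50L,
    align_level = config$align$pyramid_level %||% 2L,
    thicknesses = config$align$thicknesses %||% c(1L, 2L, 4L, 8L),
    axis_bins = config$quantify$axis_bins %||% 20L,
    density_bin_um = config$quantify$density_bin_um %||% 100)
}

log_line <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, msg)
  writeLines(line, con)
  message(line)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Executes ingest (preset generation or TIFF reading), thresholding,
#' segmentation, alignment, reconstruction, quantification and, when ground
#' truth is available, validation. Every stage writes its artifact (CSV/JSON)
#' under `output_dir` together with a line-oriented log and a manifest;
#' rerunning with an identical configuration reproduces identical reports.
#'
#' @param config Run configuration (list, or path to a YAML file).
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(output_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  manifest <- list(config = config, artifacts = list())
  params <- config_to_params(config)

  # --- ingest ---
  truth <- NULL
  if (!is.null(config$input$preset)) {
    spec <- preset(config$input$preset, n_cells = config$input$n_cells)
    brain <- generate_brain(spec, seed = config$seed %||% spec$seed)
    stack <- brain$stack
    region_labels <- brain$region_labels
    name_table <- brain$name_table
    truth <- brain$truth
    log_line(con, "INFO", sprintf("ingest: preset %s, %d sections, seed %d",
                                  config$input$preset, length(stack), brain$seed))
  } else {
    stack <- read_section_stack(config$input$paths,
                                pixel_size = config$input$pixel_size %||% 4,
                                thickness = config$input$thickness %||% 100)
    region_labels <- NULL
    name_table <- NULL
    if (!is.null(config$input$mask_paths)) {
      region_labels <- lapply(config$input$mask_paths, function(p) {
        m <- tiff::readTIFF(p, as.is = TRUE)
        matrix(as.integer(m), nrow(m), ncol(m))
      })
      name_table <- if (!is.null(config$input$name_table)) {
        as.data.frame(jsonlite::read_json(config$input$name_table,
                                          simplifyVector = TRUE))
      } else NULL
    }
    log_line(con, "INFO", sprintf("ingest: %d sections from files", length(stack)))
  }

  # --- threshold / segment / align / reconstruct ---
  res <- process_stack(stack, region_labels, name_table, params)
  thr <- data.frame(
    rc_index = vapply(stack, `[[`, 0L, "rc_index"),
    optimal = vapply(res$selections, function(s) if (is.null(s)) NA_integer_ else as.integer(s$optimal), 0L),
    tissue_threshold = vapply(res$selections, function(s) if (is.null(s)) NA_integer_ else as.integer(s$tissue_threshold), 0L),
    cell_threshold = vapply(res$selections, function(s) if (is.null(s)) NA_integer_ else as.integer(s$cell_threshold), 0L))
  utils::write.csv(thr, file.path(output_dir, "thresholds.csv"), row.names = FALSE)
  log_line(con, "INFO", sprintf("threshold: %d/%d sections with cell threshold",
                                sum(!is.na(thr$cell_threshold)), nrow(thr)))
  utils::write.csv(res$cells, file.path(output_dir, "cells.csv"), row.names = FALSE)
  log_line(con, "INFO", sprintf("segment: %d cells detected", nrow(res$cells)))
  if (!is.null(res$transforms)) {
    utils::write.csv(res$transforms, file.path(output_dir, "transforms.csv"),
                     row.names = FALSE)
    log_line(con, "INFO", sprintf("align: max |shift| %d px",
                                  max(abs(c(res$transforms$d_row,
                                            res$transforms$d_col)))))
  }

  # --- quantify ---
  reports <- list()
  if (!is.null(region_labels)) {
    dist <- region_assignment(res$recon)
    utils::write.csv(dist$table, file.path(output_dir, "region_distribution.csv"),
                     row.names = FALSE)
    reports$distribution <- list(table = dist$table,
                                 n_assigned = dist$n_assigned,
                                 n_unassigned = dist$n_unassigned)
    log_line(con, "INFO", sprintf("quantify: %d assigned / %d unassigned",
                                  dist$n_assigned, dist$n_unassigned))
    q <- config$quantify
    if (!is.null(q$organ_region) && !is.null(q$layer_region)) {
      inj <- injection_site_report(res$recon, q$organ_region, q$layer_region)
      reports$injection <- inj[c("center_of_mass", "n_inside", "n_outside",
                                 "fraction_inside", "empty")]
    }
    if (!is.null(q$compartment)) {
      reports$compartment <- compartment_ratio(res$recon, q$compartment[[1L]],
                                               q$compartment[[2L]])
    }
  }

  # --- validate (truth available) ---
  if (!is.null(truth)) {
    rc <- vapply(stack, `[[`, 0L, "rc_index")
    true_n <- vapply(rc, function(t) sum(truth$cells$rc_index == t), 0L)
    auto_n <- vapply(rc, function(t) sum(res$cells$rc_index == t), 0L)
    if (stats::var(true_n) > 0 && stats::var(auto_n) > 0) {
      cmp <- compare_counts(true_n, auto_n)
      reports$validation <- list(r_squared = cmp$r_squared, slope = cmp$slope,
                                 intercept = cmp$intercept)
      utils::write.csv(cmp$data, file.path(output_dir, "count_comparison.csv"),
                       row.names = FALSE)
      log_line(con, "INFO", sprintf("validate: R^2 = %.3f", cmp$r_squared))
    }
  }

  write_report_json(reports, file.path(output_dir, "reports.json"))
  manifest$artifacts <- list.files(output_dir)
  write_report_json(manifest, file.path(output_dir, "manifest.json"))
  log_line(con, "INFO", "done")
  invisible(list(results = res, reports = reports, truth = truth,
                 output_dir = output_dir))
}
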