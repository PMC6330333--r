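# Shared fixtures and independent oracles for the test suite.

# Cache for expensive fixture runs shared between test files (test_dir runs
# all files in one session).
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Brute-force Pearson correlation between image and thresholded mask at every
# gray value: literally builds each mask (independent oracle for the
# histogram closed form).
brute_force_curve <- function(img, maxg = 255L) {
  x <- as.vector(img)
  vapply(0:maxg, function(i) {
    y <- as.numeric(x > i)
    if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  }, 0)
}

# Union-find oracle for connected-component grouping.
union_find_components <- function(coords, connectivity) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      dr <- abs(coords[i, 1] - coords[j, 1])
      dc <- abs(coords[i, 2] - coords[j, 2])
      adjacent <- if (connectivity == 8L) max(dr, dc) == 1L else dr + dc == 1L
      if (adjacent) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# Paint a disc of constant intensity (plus per-pixel noise) onto an image.
paint_disc <- function(img, center, radius, value, noise_sd = 0) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) {
        img[r, c] <- value + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
      }
    }
  }
  img
}

# Three-population phantom: background 0, tissue ~N(50, 5) disc, bright
# somata ~N(200, 10) discs.
three_population_image <- function(seed = 1, n_cells = 12,
                                   shape = c(96L, 96L)) {
  set.seed(seed)
  img <- matrix(0, shape[1], shape[2])
  ctr <- shape / 2
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    if ((r - ctr[1])^2 / (0.42 * shape[1])^2 +
        (c - ctr[2])^2 / (0.42 * shape[2])^2 <= 1) {
      img[r, c] <- max(0, stats::rnorm(1, 50, 5))
    }
  }
  pos <- cbind(stats::runif(n_cells, ctr[1] - 20, ctr[1] + 20),
               stats::runif(n_cells, ctr[2] - 20, ctr[2] + 20))
  for (k in seq_len(n_cells)) {
    img <- paint_disc(img, pos[k, ], 2.2, 200, noise_sd = 10)
  }
  round(pmin(img, 255))
}

# Small synthetic brain for unit tests: 256x256 sections, one elliptical ROI,
# well separated cells.
small_brain_spec <- function(n_sections = 3L, n_cells = 60L, seed = 1L,
                             rc_decay = 0.02, shifts = NULL,
                             profile_lo = 0.97) {
  synthetic_brain_spec(
    n_sections = n_sections, section_shape = c(256L, 256L),
    tissue = list(center = c(128, 128), axes = c(105, 115),
                  profile_lo = profile_lo),
    regions = list(sectionmap:::region_def("ROI", 1L, seq_len(n_sections) - 1L,
                                           c(128, 128), c(75, 85))),
    counts = c(ROI = n_cells),
    intensity = list(rc_decay = rc_decay),
    shifts = shifts, seed = seed)
}

run_preset_pipeline <- function(name, n_cells = NULL, seed = NULL) {
  spec <- preset(name, n_cells = n_cells)
  b <- generate_brain(spec, seed = seed)
  res <- process_stack(b$stack, b$region_labels, b$name_table)
  list(brain = b, res = res)
}

per_section_counts_of <- function(brain, cells) {
  rc <- vapply(brain$stack, `[[`, 0L, "rc_index")
  list(true = vapply(rc, function(t) sum(brain$truth$cells$rc_index == t), 0L),
       auto = vapply(rc, function(t) sum(cells$rc_index == t), 0L))
}
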