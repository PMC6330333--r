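# A hand-built reconstruction: tiny sections, label masks, known cells.
toy_recon <- function(cells, shape = c(100L, 100L), n_sections = 3L,
                      labels = NULL, transforms = NULL) {
  stack <- lapply(seq_len(n_sections) - 1L, function(t) {
    section_image(matrix(0, shape[1], shape[2]), bit_depth = 8L,
                  pixel_size = 1, thickness = 100, rc_index = t)
  })
  if (is.null(labels)) {
    lab <- matrix(1L, shape[1], shape[2])
    labels <- rep(list(lab), n_sections)
  }
  nt <- data.frame(label = 1:2, name = c("A", "B"),
                   is_olfactory_cortex = c(TRUE, FALSE),
                   hemisphere = c("ipsi", "ipsi"))
  build_reconstruction(stack, transforms, NULL, cells, labels, nt)
}

cells_df <- function(rc, row, col) {
  n <- length(rc)
  data.frame(rc_index = rc, row = row, col = col,
             x_um = col, y_um = row, z_um = rc * 100,
             area_px = rep(10L, n), roundness = rep(0.9, n),
             mean_intensity = rep(100, n))
}

test_that("reconstruction maps cells through transforms into micrometers", {
  cells <- cells_df(c(0L, 1L), c(10, 20), c(30, 40))
  r <- toy_recon(cells)
  expect_equal(r$cells$z_um, c(0, 100))
  expect_equal(r$cells$x_um, c(30, 40))
  tr <- data.frame(rc_index = 0:2, d_row = c(0L, 10L, 0L),
                   d_col = c(0L, -5L, 0L), score = NA, flagged = FALSE)
  r2 <- toy_recon(cells, transforms = tr)
  expect_equal(r2$cells$arow[2], 30)   # 20 + 10
  expect_equal(r2$cells$acol[2], 35)   # 40 - 5
  expect_equal(r2$cells$arow[1], 10)   # identity on section 0
  expect_error(toy_recon(cells_df(9L, 1, 1)), "transform")
})

test_that("center of mass and inside-layer fraction follow their definitions", {
  # two cells at (0,0,0) and (10,10,100): COM at (5,5,50)
  cells <- cells_df(c(0L, 1L), c(0, 10), c(0, 10))
  r <- toy_recon(cells)
  rep <- injection_site_report(r, "B", "A")   # layer A holds every cell
  expect_equal(unname(rep$center_of_mass), c(5, 5, 50))
  expect_equal(rep$fraction_inside, 1)
  expect_identical(rep$n_inside, 2L)
  # half the cells in the layer mask
  lab <- matrix(1L, 100, 100); lab[, 51:100] <- 2L
  cells <- cells_df(rep(0L, 4), c(10, 20, 30, 40), c(10, 20, 80, 90))
  r <- toy_recon(cells, labels = rep(list(lab), 3))
  rep <- injection_site_report(r, "B", "A")
  expect_equal(rep$fraction_inside, 0.5)
  expect_identical(rep$n_inside + rep$n_outside, 4L)
  empty <- injection_site_report(toy_recon(cells_df(integer(0), numeric(0),
                                                    numeric(0))), "B", "A")
  expect_true(empty$empty)
  expect_error(injection_site_report(r, "Nope", "A"), "region")
})

test_that("axis histograms are normalized, uniform for uniform cells, and flag empties", {
  set.seed(21)
  n <- 10000L
  cells <- cells_df(rep(0L, n), stats::runif(n, 1, 99), stats::runif(n, 1, 99))
  r <- toy_recon(cells, n_sections = 1L)
  h <- axis_distribution(r, region = "A", axis = "ML", n_bins = 10L)
  expect_equal(sum(h$prob), 1)
  expect_identical(sum(h$counts), n)
  gof <- stats::chisq.test(h$counts)
  expect_gt(gof$p.value, 0.01)
  # all cells on one plane -> single occupied bin
  flat <- toy_recon(cells_df(rep(0L, 5), rep(42, 5), 1:5), n_sections = 1L)
  hf <- axis_distribution(flat, axis = "DV", n_bins = 8L)
  expect_identical(sum(hf$counts > 0L), 1L)
  expect_true(axis_distribution(r, region = "B", axis = "ML")$empty)
  # a ventrally weighted population puts the histogram mode ventrally
  set.seed(22)
  skew <- cells_df(rep(0L, 2000), 99 * stats::rbeta(2000, 4, 1.5),
                   stats::runif(2000, 1, 99))
  hs <- axis_distribution(toy_recon(skew, n_sections = 1L), axis = "DV",
                          n_bins = 10L)
  expect_gt(which.max(hs$counts), 5L)
})

test_that("density maps conserve cells and expose ventral concentration", {
  cells <- cells_df(0L, 30, 70)
  r <- toy_recon(cells, n_sections = 1L)
  dm <- density_map(r, "coronal", bin_um = 10)
  expect_identical(sum(dm$counts), 1L)
  set.seed(23)
  n <- 3000L
  ventral <- cells_df(rep(0L, n),
                      ifelse(stats::runif(n) < 0.9, stats::runif(n, 60, 99),
                             stats::runif(n, 1, 40)),
                      stats::runif(n, 1, 99))
  r2 <- toy_recon(ventral, n_sections = 1L)
  dm2 <- density_map(r2, "coronal", bin_um = 5)
  expect_identical(sum(dm2$counts), n)
  below <- dm2$v_breaks[-1] > 50   # DV midline of the 100-row section
  expect_gt(sum(dm2$counts[, below]) / n, 0.8)
  # normalization to the injection site recenters the occupied bins
  inj <- injection_site_report(r2, "B", "A")
  dmn <- density_map(r2, "coronal", bin_um = 5, normalize_to = inj)
  expect_lt(min(abs(dmn$v_breaks)), 1e-9 + 5)
  expect_error(density_map(r2, "coronal", bin_um = 0), "bin_um")
})

test_that("region assignment conserves cells and computes percentages", {
  lab <- matrix(0L, 100, 100); lab[1:50, ] <- 1L; lab[81:100, ] <- 2L
  cells <- cells_df(rep(0L, 10), c(5, 10, 15, 20, 25, 30, 85, 90, 95, 65),
                    rep(50, 10))
  r <- toy_recon(cells, labels = rep(list(lab), 3))
  da <- region_assignment(r)
  expect_identical(da$n_assigned, 9L)
  expect_identical(da$n_unassigned, 1L)
  expect_identical(da$n_assigned + da$n_unassigned, nrow(r$cells))
  expect_equal(sum(da$table$percent), 100, tolerance = 1e-9)
  expect_equal(da$table$percent[da$table$name == "A"], 100 * 6 / 9)
  # single-region case: that region carries 100%
  one <- toy_recon(cells_df(rep(0L, 4), 1:4 * 10, 1:4 * 10))
  expect_equal(region_assignment(one)$table$percent, c(100, 0))
})

test_that("percentages are stable under subsampling and rigid translation", {
  run <- cached("fig5_5000", function() run_preset_pipeline("fig5_distribution"))
  recon <- run$res$recon
  da <- region_assignment(recon)
  full <- da$table$percent[da$table$name == "AON_ipsi"]
  set.seed(31)
  for (rep in 1:3) {
    sub <- recon
    keep <- sample.int(nrow(recon$cells), 2000L)
    sub$cells <- recon$cells[keep, ]
    ps <- region_assignment(sub)$table
    expect_lt(abs(ps$percent[ps$name == "AON_ipsi"] - full), 3)
  }
  # translating sections and masks together leaves every report unchanged
  cells <- cells_df(rep(0L, 6), c(10, 20, 30, 40, 50, 85),
                    c(15, 25, 35, 45, 55, 85))
  lab <- matrix(0L, 100, 100); lab[1:60, 1:60] <- 1L; lab[70:100, 70:100] <- 2L
  r0 <- toy_recon(cells, labels = rep(list(lab), 3))
  shift <- c(7L, -4L)
  cells2 <- cells
  cells2$row <- cells2$row + shift[1]; cells2$col <- cells2$col + shift[2]
  cells2$y_um <- cells2$row; cells2$x_um <- cells2$col
  lab2 <- sectionmap:::shift_matrix(lab, shift[1], shift[2])
  r1 <- toy_recon(cells2, labels = rep(list(lab2), 3))
  t0 <- region_assignment(r0)$table; t1 <- region_assignment(r1)$table
  expect_identical(t0$n, t1$n)
  expect_equal(t0$percent, t1$percent)
})

test_that("compartment ratios handle both regular and degenerate cases", {
  lab <- matrix(0L, 100, 100); lab[, 1:50] <- 1L; lab[, 51:100] <- 2L
  cells <- cells_df(rep(0L, 5), rep(50, 5), c(10, 20, 30, 40, 90))
  r <- toy_recon(cells, labels = rep(list(lab), 3))
  cr <- compartment_ratio(r, "A", "B")
  expect_identical(cr$n_a, 4L)
  expect_identical(cr$n_b, 1L)
  expect_equal(cr$share_a_percent, 80)
  only_a <- toy_recon(cells_df(rep(0L, 3), rep(10, 3), c(10, 20, 30)),
                      labels = rep(list(lab), 3))
  expect_equal(compartment_ratio(only_a, "A", "B")$share_a_percent, 100)
  none <- toy_recon(cells_df(integer(0), numeric(0), numeric(0)),
                    labels = rep(list(lab), 3))
  expect_true(compartment_ratio(none, "A", "B")$undefined)
})

test_that("the center of mass lies inside the convex hull of the cells", {
  set.seed(33)
  cells <- cells_df(rep(0L, 50), stats::runif(50, 10, 90),
                    stats::runif(50, 10, 90))
  r <- toy_recon(cells, n_sections = 1L)
  rep <- injection_site_report(r, "B", "A")
  com <- rep$center_of_mass
  expect_gte(com["x"], min(cells$col)); expect_lte(com["x"], max(cells$col))
  expect_gte(com["y"], min(cells$row)); expect_lte(com["y"], max(cells$row))
})
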