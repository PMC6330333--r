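test_that("thresholding uses a strict greater-than rule", {
  img <- matrix(c(0, 100, 200, 255), 2, 2, byrow = TRUE)
  m <- threshold_image(img, 100, bit_depth = 8L)
  expect_identical(m$pixels, matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE))
  expect_true(all(threshold_image(img, 255, 8L)$pixels == 0L))
  expect_identical(threshold_image(img, 0, 8L)$pixels,
                   matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE))
  expect_error(threshold_image(img, -1, 8L), "range")
})

test_that("histogram closed form reproduces brute-force Pearson at every threshold", {
  imgs <- list(matrix(0:8, 3, 3))
  set.seed(11)
  for (k in 1:6) {
    imgs <- c(imgs, list(matrix(sample(0:255, 48 * 48, TRUE), 48, 48)))
  }
  # bimodal Gaussian mixture (means 60/180, sd 10)
  set.seed(5)
  v <- round(c(stats::rnorm(1500, 60, 10), stats::rnorm(548, 180, 10)))
  imgs <- c(imgs, list(matrix(pmin(pmax(v, 0), 255), 32, 64)))
  for (img in imgs) {
    cv <- correlation_curve(img, bit_depth = 8L)
    bf <- brute_force_curve(img)
    expect_lt(max(abs(cv$corr - bf), na.rm = TRUE), 1e-9)
    expect_identical(is.na(cv$corr), is.na(bf))
    expect_identical(optimal_threshold(cv), (0:255)[which.max(bf)])
    # bounds and count monotonicity
    expect_true(all(abs(cv$corr) <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(diff(cv$n_above) <= 0))
    expect_identical(cv$n_above[1], sum(img > 0))
  }
})

test_that("a binary image correlates perfectly at every defined threshold", {
  set.seed(3)
  img <- matrix(sample(c(0, 255), 400, TRUE), 20, 20)
  cv <- correlation_curve(img, bit_depth = 8L)
  expect_true(all(abs(cv$corr[1:255] - 1) < 1e-12))
  expect_identical(optimal_threshold(cv), 0L)   # tie-break: lowest threshold
})

test_that("adding a constant shifts thresholds but not correlation values", {
  set.seed(7)
  img <- matrix(sample(0:100, 30 * 30, TRUE), 30, 30)
  cv0 <- correlation_curve(img, bit_depth = 8L)
  cv1 <- correlation_curve(img + 50, bit_depth = 8L)
  expect_equal(cv1$corr[51:200], cv0$corr[1:150], tolerance = 1e-12)
  expect_identical(optimal_threshold(cv1), optimal_threshold(cv0) + 50L)
})

test_that("constant images are rejected as degenerate", {
  expect_error(correlation_curve(matrix(42, 5, 5), bit_depth = 8L),
               "constant")
})

test_that("derivative excursions sit at the intensity populations", {
  img <- three_population_image(seed = 2)
  cv <- correlation_curve(img, bit_depth = 8L)
  d <- as.numeric(sectionmap:::moving_average(cv$deriv[-1], 5))
  ex <- sectionmap:::local_extrema_idx(d)
  ex <- ex[order(abs(d[ex]), decreasing = TRUE)]
  top2 <- sort(cv$threshold[-1][ex[1:2]])
  expect_gt(top2[1], 35); expect_lt(top2[1], 65)    # tissue population ~50
  expect_gt(top2[2], 160); expect_lt(top2[2], 220)  # soma population ~200
})

test_that("transition thresholds separate the populations", {
  img <- three_population_image(seed = 4)
  sel <- transition_thresholds(correlation_curve(img, bit_depth = 8L))
  expect_identical(sel$missing, 0L)
  expect_lt(sel$tissue_threshold, sel$cell_threshold)
  expect_gt(sel$tissue_threshold, 5)
  expect_lt(sel$tissue_threshold, 45)
  expect_gt(sel$cell_threshold, 55)
  expect_lt(sel$cell_threshold, 190)
  # thresholding at the tissue transition reproduces the tissue silhouette,
  # at the cell transition only somata survive
  sil <- threshold_image(img, sel$tissue_threshold, 8L)$pixels
  expect_equal(sum(sil), sum(img > 0), tolerance = 0.02 * sum(img > 0))
  somata <- threshold_image(img, sel$cell_threshold, 8L)$pixels
  expect_lt(sum(somata), 0.1 * sum(sil))
  expect_gt(sum(somata), 0)
})

test_that("single-population images flag the missing cell transition", {
  set.seed(8)
  img <- matrix(0, 40, 40)
  img[10:30, 10:30] <- round(stats::rnorm(441, 120, 8))
  sel <- transition_thresholds(correlation_curve(img, bit_depth = 8L))
  expect_identical(sel$missing, 1L)
  expect_false(is.na(sel$tissue_threshold))
  expect_true(is.na(sel$cell_threshold))
})

test_that("per-section curves flag degenerate sections without aborting", {
  s1 <- section_image(three_population_image(1), bit_depth = 8L, rc_index = 0L)
  blank <- section_image(matrix(0, 96, 96), bit_depth = 8L, rc_index = 1L)
  s3 <- section_image(three_population_image(9), bit_depth = 8L, rc_index = 2L)
  curves <- per_section_curves(list(s1, blank, s3))
  expect_identical(attr(curves, "failed"), 2L)
  expect_null(curves[[2]])
  expect_s3_class(curves[[1]], "correlation_curve")
  # identical sections give identical curves
  curves2 <- per_section_curves(list(s1, s1))
  expect_identical(curves2[[1]]$corr, curves2[[2]]$corr)
})

test_that("optimal thresholds decay along a declining fluorescence gradient", {
  b <- cached("fig2", function() generate_brain(preset("fig2_gradient")))
  curves <- per_section_curves(b$stack)
  opt <- vapply(curves, optimal_threshold, 0L)
  expect_lt(stats::cor(opt, seq_along(opt), method = "spearman"), -0.8)
  means <- vapply(b$stack, function(s) mean(s$pixels), 0)
  expect_true(all(diff(means) < 0))
})
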