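test_that("median filter removes shot noise and honors its contract", {
  hot <- matrix(0, 9, 9); hot[5, 5] <- 255
  expect_true(all(median_filter(hot, 3) == 0))
  const <- matrix(13, 7, 7)
  expect_identical(median_filter(const, 3), const)
  set.seed(1)
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_identical(median_filter(img, 1), img)
  expect_error(median_filter(img, 4), "odd")
  # window 5 agrees with a direct edge-replicated oracle
  orc <- function(m, k) {
    p <- sectionmap:::pad_replicate(m, k)
    o <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      o[i, j] <- stats::median(p[i:(i + 2 * k), j:(j + 2 * k)])
    }
    o
  }
  expect_equal(median_filter(img, 5), orc(img, 2))
  expect_equal(median_filter(img, 3), orc(img, 1))
})

test_that("Moore tracing yields closed clockwise outer contours", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  b <- trace_boundary(one)
  expect_equal(length(b), 1L)
  expect_equal(unname(b[[1]]$contour), matrix(c(3, 3), 1, 2))
  sq <- matrix(0L, 6, 6); sq[2:4, 2:4] <- 1L
  ct <- trace_boundary(sq)[[1]]$contour
  expect_equal(nrow(ct), 8L)   # the 8 perimeter pixels of a 3x3 square
  expect_equal(unname(ct),
               matrix(c(2, 2, 2, 3, 2, 4, 3, 4, 4, 4, 4, 3, 4, 2, 3, 2),
                      ncol = 2, byrow = TRUE))  # clockwise from top-left
  two <- matrix(0L, 8, 8); two[2:3, 2:3] <- 1L; two[6:7, 6:7] <- 1L
  expect_equal(length(trace_boundary(two)), 2L)
  expect_equal(length(trace_boundary(matrix(0L, 4, 4))), 0L)
  # every contour pixel is foreground with a 4-neighborhood background pixel
  set.seed(2)
  blob <- matrix(0L, 20, 20)
  blob[5:15, 4:16] <- 1L; blob[8:10, 8:12] <- 1L
  ct <- trace_boundary(blob)[[1]]$contour
  for (i in seq_len(nrow(ct))) {
    r <- ct[i, 1]; c <- ct[i, 2]
    expect_identical(blob[r, c], 1L)
    nb <- c(blob[r - 1, c], blob[r + 1, c], blob[r, c - 1], blob[r, c + 1])
    expect_true(any(nb == 0L))
  }
})

test_that("boundary smoothing preserves mass and rewards shape agreement", {
  one <- matrix(0L, 21, 21); one[11, 11] <- 1L
  b <- trace_boundary(one)[[1]]
  expect_identical(smooth_boundary(b, 0), {
    m <- matrix(0, 21, 21); m[11, 11] <- 1; m
  })
  sm <- smooth_boundary(b, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_error(smooth_boundary(b, -1), "sigma")
  # jittered vs clean circle: smoothing raises the correlation
  disc <- function(jit, seed = 1) {
    set.seed(seed)
    m <- matrix(0L, 41, 41)
    th <- seq(0, 2 * pi, length.out = 120)
    r <- 14 + if (jit) sample(-1:1, 120, TRUE) else 0
    m[cbind(round(21 + r * sin(th)), round(21 + r * cos(th)))] <- 1L
    m
  }
  clean <- disc(FALSE); jitt <- disc(TRUE)
  raw_cor <- stats::cor(as.vector(clean), as.vector(jitt))
  blur <- function(m) {
    sectionmap:::mask_pixels(m)
    bd <- structure(list(contour = which(m == 1L, arr.ind = TRUE),
                         shape = dim(m), rc_index = 0L),
                    class = "tissue_boundary")
    smooth_boundary(bd, 2)
  }
  expect_gt(stats::cor(as.vector(blur(clean)), as.vector(blur(jitt))), raw_cor)
})

test_that("pixel grouping follows the requested connectivity", {
  expect_equal(length(group_pixels(matrix(0L, 5, 5))$groups), 0L)
  diagpx <- matrix(0L, 4, 4); diagpx[1, 1] <- 1L; diagpx[2, 2] <- 1L
  expect_equal(length(group_pixels(diagpx, 8L)$groups), 1L)
  expect_equal(length(group_pixels(diagpx, 4L)$groups), 2L)
  # random sparse masks against a union-find oracle, both connectivities
  set.seed(9)
  for (rep in 1:4) {
    m <- matrix(0L, 24, 24)
    m[sample.int(576, 100)] <- 1L
    coords <- which(m == 1L, arr.ind = TRUE)
    for (conn in c(4L, 8L)) {
      grp <- group_pixels(m, conn)
      expect_equal(length(grp$groups), union_find_components(coords, conn))
      # partition: group areas sum to the foreground count
      expect_identical(sum(vapply(grp$groups, nrow, 0L)), sum(m))
    }
  }
})

test_that("shape filters keep somata and reject specks, lines and clumps", {
  m <- matrix(0L, 40, 80)
  m[5, 5] <- 1L                      # 1-px speck
  m[20, 10:39] <- 1L                 # 1x30 line
  for (r in 1:40) for (c in 1:80) {  # radius-3 disc at (30, 60)
    if ((r - 30)^2 + (c - 60)^2 <= 9) m[r, c] <- 1L
  }
  grp <- group_pixels(m, 8L)
  cells <- filter_components(grp, min_area = 5L, max_area = 60L,
                             min_roundness = 0.5)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$row, 30, tolerance = 0.1)
  expect_equal(cells$col, 60, tolerance = 0.1)
  # an oversized blob is removed entirely (the high-density undercount path)
  big <- matrix(0L, 30, 30); big[5:25, 5:25] <- 1L
  expect_equal(nrow(filter_components(group_pixels(big), min_area = 4L,
                                      max_area = 60L, min_roundness = 0)), 0L)
  expect_error(filter_components(grp, min_area = 10L, max_area = 5L), "min_area")
})

test_that("circularity is ~1 for discs and decreases with elongation", {
  disc_mask <- function(radius) {
    n <- 2L * radius + 5L
    m <- matrix(0L, n, n)
    ctr <- (n + 1) / 2
    for (r in seq_len(n)) for (c in seq_len(n)) {
      if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) m[r, c] <- 1L
    }
    m
  }
  for (radius in c(3, 5, 9)) {
    g <- group_pixels(disc_mask(radius))
    cells <- filter_components(g, min_area = 1L, max_area = 10000L,
                               min_roundness = 0)
    expect_gt(cells$roundness, 0.85)
    expect_lte(cells$roundness, 1)
  }
  # fixed area, growing aspect ratio -> strictly decreasing circularity
  rect <- function(h, w) {
    m <- matrix(0L, h + 4L, w + 4L); m[3:(2 + h), 3:(2 + w)] <- 1L
    filter_components(group_pixels(m), min_area = 1L, max_area = 10000L,
                      min_roundness = 0)$roundness
  }
  vals <- c(rect(6, 6), rect(4, 9), rect(3, 12), rect(2, 18), rect(1, 36))
  expect_true(all(diff(vals) < 0))
})

test_that("find_cells recovers well-separated synthetic somata", {
  b <- cached("small3", function() generate_brain(small_brain_spec()))
  s <- b$stack[[1]]
  sel <- transition_thresholds(correlation_curve(median_filter(s$pixels, 3),
                                                 bit_depth = 8L))
  roi <- (b$region_labels[[1]] > 0L) * 1L
  cells <- find_cells(s, sel$cell_threshold, roi_mask = roi)
  truth <- b$truth$cells[b$truth$cells$rc_index == 0L, ]
  expect_equal(nrow(cells), nrow(truth))
  d <- vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((cells$row - truth$row[i])^2 + (cells$col - truth$col[i])^2))
  }, 0)
  expect_lt(max(d), 2)
  # ROI covering the left half keeps only the left-half cells
  half <- roi; half[, 129:256] <- 0L
  left <- find_cells(s, sel$cell_threshold, roi_mask = half)
  expect_equal(nrow(left), sum(cells$col <= 128))
  expect_true(all(left$col <= 128))
  # blank section yields an empty frame; NA threshold likewise
  blank <- section_image(matrix(0, 64, 64), bit_depth = 8L)
  expect_equal(nrow(find_cells(blank, 10)), 0L)
  expect_equal(nrow(find_cells(s, NA)), 0L)
  # determinism: identical inputs give identical cell tables
  expect_identical(find_cells(s, sel$cell_threshold, roi_mask = roi), cells)
})

test_that("low-density sections are counted exactly in almost all seeds", {
  hits <- vapply(1:100, function(seed) {
    spec <- small_brain_spec(n_sections = 1L, n_cells = 40L, seed = seed)
    b <- generate_brain(spec)
    s <- b$stack[[1]]
    sel <- transition_thresholds(correlation_curve(median_filter(s$pixels, 3),
                                                   bit_depth = 8L))
    cells <- find_cells(s, sel$cell_threshold,
                        roi_mask = (b$region_labels[[1]] > 0L) * 1L)
    nrow(cells) == 40L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
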