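test_that("grid construction enforces geometry and value invariants", {
  expect_error(scalar_grid(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "strictly positive")
  expect_error(scalar_grid(array(NA_real_, c(2, 2))), "finite")
  expect_error(scalar_grid(array(-1, c(2, 2)), unit = "Gy"), "non-negative")
  g <- scalar_grid(array(0, c(3, 4, 5)), origin = c(1, 2, 3), spacing = c(3, 3, 3))
  expect_equal(grid_geometry(g)$shape, c(3L, 4L, 5L))
  # voxel-centre convention: centre of voxel (i,j,k) = origin + (i-1)*spacing
  pts <- dosemedium:::voxel_centers(g)
  expect_equal(pts[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(pts[2, ], c(4, 2, 3), ignore_attr = TRUE)
})

test_that("NRRD write/read round-trips grids in both encodings", {
  set.seed(7)
  for (enc in c("raw", "ascii")) {
    g <- scalar_grid(array(runif(60, 0, 80), c(5, 4, 3)),
                     origin = c(-10, 5, 2.5), spacing = c(3, 3, 2.5),
                     unit = "Gy")
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_grid(g, f, encoding = enc)
    g2 <- read_grid(f)
    expect_equal(g2$values, g$values, tolerance = 1e-6)
    expect_equal(g2$origin, g$origin)
    expect_equal(g2$spacing, g$spacing)
    expect_identical(g2$unit, "Gy")
  }
  # 2-D planes and the percent unit round-trip too
  p <- scalar_grid(matrix(seq(-5, 5, length.out = 12), 3, 4),
                   spacing = c(2, 2), unit = "percent")
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_grid(p, f)
  expect_equal(read_grid(f)$values, p$values)
  expect_identical(read_grid(f)$unit, "percent")
  # degenerate sizes
  one <- scalar_grid(array(1.0, c(1, 1, 1)), unit = "Gy")
  f1 <- withr::local_tempfile(fileext = ".nrrd")
  write_grid(one, f1)
  expect_identical(read_grid(f1)$values[1], 1.0)
  zero <- scalar_grid(array(0, c(4, 4, 4)), unit = "Gy")
  f0 <- withr::local_tempfile(fileext = ".nrrd")
  write_grid(zero, f0)
  expect_identical(sum(read_grid(f0)$values), 0)
})

test_that("NRRD reader handles detached headers and flags broken geometry", {
  g <- scalar_grid(array(1:24 / 10, c(4, 3, 2)), spacing = c(2, 2, 2))
  dir <- withr::local_tempdir()
  raw_file <- file.path(dir, "payload.raw")
  con <- file(raw_file, "wb")
  writeBin(as.numeric(g$values), con, size = 8, endian = "little")
  close(con)
  hdr <- file.path(dir, "grid.nhdr")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 4 3 2",
               "encoding: raw", "endian: little", "space dimension: 3",
               "space directions: (2,0,0) (0,2,0) (0,0,2)",
               "space origin: (0,0,0)", "data file: payload.raw", ""), hdr)
  expect_equal(read_grid(hdr)$values, g$values)

  # header without any spacing information -> geometry error
  bad <- file.path(dir, "bad.nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 2 2",
               "encoding: ascii", "", paste(rep("1", 8), collapse = " ")), bad)
  expect_error(read_grid(bad), "geometry error")
  expect_error(read_grid(file.path(dir, "nothere.nrrd")), "not found")
})

test_that("resampling is the identity on matching geometry and preserves constants", {
  g <- scalar_grid(array(runif(8 * 7 * 6), c(8, 7, 6)), spacing = c(3, 3, 3))
  expect_equal(resample_to(g, grid_geometry(g))$values, g$values,
               tolerance = 1e-12)
  const <- scalar_grid(array(2.5, c(8, 8, 8)), spacing = c(3, 3, 3))
  fine <- geometry(c(10, 10, 10), origin = c(2, 2, 2), spacing = c(1.5, 1.5, 1.5))
  expect_equal(resample_to(const, fine)$values, array(2.5, c(10, 10, 10)),
               tolerance = 1e-12)
})

test_that("trilinear resampling reproduces affine fields exactly in the interior", {
  geom <- geometry(c(9, 9, 9), spacing = c(2, 2, 2))
  pts <- dosemedium:::voxel_centers(geom)
  affine <- function(p) 1.5 + 0.25 * p[, 1] - 0.1 * p[, 2] + 0.05 * p[, 3]
  g <- scalar_grid(array(affine(pts), geom$shape), spacing = geom$spacing)
  half <- geometry(c(15, 15, 15), origin = c(0.5, 0.5, 0.5), spacing = c(1, 1, 1))
  res <- resample_to(g, half)
  expected <- array(affine(dosemedium:::voxel_centers(half)), half$shape)
  expect_equal(res$values, expected, tolerance = 1e-9)
  # outside-extent voxels are zero-filled and flagged
  wide <- geometry(c(5, 5, 5), origin = c(-10, -10, -10), spacing = c(2, 2, 2))
  rw <- resample_to(g, wide)
  expect_true(any(attr(rw, "outside")))
  expect_true(all(rw$values[attr(rw, "outside")] == 0))
})

test_that("plane extraction matches voxel values and affine closed forms", {
  geom <- geometry(c(7, 6, 5), origin = c(0, 0, 0), spacing = c(2, 2, 3))
  pts <- dosemedium:::voxel_centers(geom)
  f <- 2 + 0.1 * pts[, 1] + 0.2 * pts[, 2] + 0.3 * pts[, 3]
  g <- scalar_grid(array(f, geom$shape), spacing = geom$spacing)
  pl <- extract_plane(g, "z", 6)          # through the k = 3 voxel centres
  expect_equal(pl$values, g$values[, , 3], tolerance = 1e-12)
  pl2 <- extract_plane(g, "z", 4.5)       # between slices: affine => exact
  p2 <- dosemedium:::voxel_centers(grid_geometry(pl2))
  expect_equal(as.numeric(pl2$values),
               2 + 0.1 * p2[, 1] + 0.2 * p2[, 2] + 0.3 * 4.5, tolerance = 1e-9)
  expect_error(extract_plane(g, "z", 99), "geometry error")
  const <- scalar_grid(array(4, c(4, 4, 4)), spacing = c(2, 2, 2))
  expect_equal(extract_plane(const, "x", 3)$values, matrix(4, 4, 4))
})

test_that("contour rasterisation follows the voxel-centre even-odd rule", {
  geom <- geometry(c(20, 20, 3), origin = c(0.5, 0.5, 0), spacing = c(1, 1, 3))
  square <- list(points = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)), z = 3)
  ss <- rasterize_contours(list(ROI = list(square)), geom)
  # 10 x 10 mm square on a 1 mm grid: edges fall between centres -> 100 voxels
  expect_identical(sum(ss$rois$ROI[, , 2]), 100L)
  expect_identical(sum(ss$rois$ROI[, , c(1, 3)]), 0L)
  # half-voxel shift keeps 100 voxels under the centre rule
  shifted <- list(points = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)) + 0.5, z = 3)
  ss2 <- rasterize_contours(list(ROI = list(shifted)), geom)
  expect_identical(sum(ss2$rois$ROI), 100L)
  # a hole carved by a nested contour on the same slice
  hole <- list(points = cbind(c(8, 12, 12, 8), c(8, 8, 12, 12)), z = 3)
  ss3 <- rasterize_contours(list(ROI = list(square, hole)), geom)
  expect_identical(sum(ss3$rois$ROI), 100L - 16L)
  # empty contour list and off-grid contours
  expect_identical(length(rasterize_contours(list(), geom)$rois), 0L)
  expect_warning(rasterize_contours(
    list(R = list(list(points = square$points, z = 99))), geom), "empty")
})

test_that("rasterisation agrees with a winding-number oracle on random polygons", {
  geom <- geometry(c(15, 15, 1), origin = c(0, 0, 0), spacing = c(2, 2, 2))
  xs <- (0:14) * 2; ys <- (0:14) * 2
  set.seed(11)
  for (rep in 1:10) {
    # star-shaped (hence simple) polygon around a random centre
    cx <- runif(1, 8, 20); cy <- runif(1, 8, 20)
    ang <- sort(runif(8, 0, 2 * pi))
    rad <- runif(8, 3, 10)
    poly <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
    ss <- rasterize_contours(list(P = list(list(points = poly, z = 0))), geom)
    expected <- outer(seq_along(xs), seq_along(ys), Vectorize(function(i, j)
      oracle_inside(xs[i], ys[j], poly)))
    expect_identical(ss$rois$P[, , 1], expected)
  }
})
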