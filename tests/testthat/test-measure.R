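# Segmentation, erosion, Feret geometry and shape descriptors.

test_that("segmentation thresholds, filters and relabels", {
  p <- matrix(0, 32, 32)
  expect_identical(segment(p)$n_objects, 0L)
  p[5:14, 5:14] <- 1
  m <- segment(p, min_size = 4)
  expect_identical(m$n_objects, 1L)
  expect_identical(sum(m$labels == 1L), 100L)
  # a 2x2 speck below min_size disappears
  p[20:21, 20:21] <- 1
  expect_identical(segment(p, min_size = 5)$n_objects, 1L)
  expect_identical(segment(p, min_size = 4)$n_objects, 2L)
  expect_error(segment(p, threshold = 0), "threshold")
})

test_that("corner-touching blocks are one object under 8-connectivity", {
  p <- matrix(0, 16, 16)
  p[2:5, 2:5] <- 1
  p[6:9, 6:9] <- 1
  expect_identical(segment(p, min_size = 1)$n_objects, 1L)
  # the 4-connectivity oracle sees two components
  expect_identical(max(label_components4(p >= 0.5)), 2L)
})

test_that("erosion follows closed-form cases and drops emptied objects", {
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
  mask <- label_mask(m)
  e <- erode_objects(mask, 1)
  expected <- matrix(0L, 9, 9); expected[4:6, 4:6] <- 1L
  expect_identical(e$labels, expected)  # 5x5 -> 3x3
  expect_identical(erode_objects(mask, 0), mask)  # identity
  m2 <- m; m2[2:3, 8:9] <- 2L  # a 2x2 object vanishes under erosion
  mask2 <- label_mask(m2)
  e2 <- erode_objects(mask2, 1)
  expect_identical(e2$n_objects, 1L)
  expect_identical(e2$dropped, 2L)
})

test_that("rotating-calipers Feret equals the brute-force corner maximum exactly", {
  expect_identical(feret_diameter(cbind(1L, 1L)), sqrt(2))
  rect <- as.matrix(expand.grid(1:3, 1:4))
  expect_identical(feret_diameter(rect), 5)
  for (s in 1:50) {
    px <- make_random_blob(sample(3:60, 1), seed = s)
    expect_identical(feret_diameter(px), brute_force_feret(px))
  }
  expect_error(feret_diameter(matrix(numeric(), 0, 2)), "empty")
})

test_that("shape descriptors match closed forms for disks and squares", {
  disk <- which(make_disk_mask(20L), arr.ind = TRUE)
  d <- shape_descriptors(disk)
  expect_gte(d$form_factor, 0.9)
  expect_lte(d$form_factor, 1.1)
  expect_lt(abs(d$major_nm - d$minor_nm) / d$major_nm, 0.02)
  expect_equal(d$eqdiam_nm, sqrt(4 * nrow(disk) / pi))
  # square form factor tends to pi/4 from above as the side grows
  ff <- vapply(c(10L, 30L, 100L), function(s)
    shape_descriptors(which(make_square_mask(s), arr.ind = TRUE))$form_factor,
    numeric(1))
  expect_true(all(diff(ff) < 0))
  expect_true(all(ff > pi / 4))
  expect_lt(ff[3] - pi / 4, 0.01)
})

test_that("form factor stays within its discretization bound on arbitrary blobs", {
  for (s in 1:30) {
    px <- make_random_blob(sample(4:80, 1), seed = 100 + s)
    d <- shape_descriptors(px)
    expect_gt(d$form_factor, 0)
    expect_lte(d$form_factor, 1.1)
    expect_gte(d$major_nm, d$minor_nm)
    expect_gt(d$minor_nm, 0)
  }
})

test_that("axis ordering holds on agglomerate-shaped objects", {
  # the moment axes use the ellipse-equivalent convention, so the ordering
  # Feret >= major >= minor is asserted on compact objects like the ones
  # the generator produces (it can be violated by pathological thin snakes)
  for (s in 1:3) {
    sc <- generate_scene(small_scene_spec(seed = 80 + s))
    rec <- measure_all(label_mask(sc$truth$object_map), sc$image)
    expect_true(all(rec$feret_nm >= rec$major_nm))
    expect_true(all(rec$major_nm >= rec$minor_nm))
    expect_true(all(rec$minor_nm > 0))
    expect_true(all(rec$form_factor > 0 & rec$form_factor <= 1.1))
  }
})

test_that("measure_all reports physical units and validates shapes", {
  p <- matrix(0, 32, 32); p[4:8, 4:8] <- 1
  img <- stem_image(p, pixel_size = 10)
  empty <- measure_all(segment(matrix(0, 32, 32)), img)
  expect_identical(nrow(empty), 0L)
  rec <- measure_all(segment(p), img)
  expect_identical(rec$area_nm2, 25 * 100)  # 5x5 px at 10 nm/px
  expect_identical(rec$object_id, 1L)
  expect_error(measure_all(segment(matrix(0, 16, 16)),
                           stem_image(matrix(0.1, 32, 32), 10)), "shapes")
})

test_that("segmenting a clean class map reproduces ground-truth measurements", {
  sc <- generate_scene(small_scene_spec(seed = 31))
  p <- matrix(as.numeric(sc$truth$class_map == 1L), 128, 128)
  rec <- measure_all(segment(p), sc$image)
  tt <- sc$truth$object_table
  expect_identical(nrow(rec), nrow(tt))
  # match by centroid and compare Feret in nm
  for (i in seq_len(nrow(rec))) {
    j <- which.min((tt$centroid_row - rec$centroid_row[i])^2 +
                     (tt$centroid_col - rec$centroid_col[i])^2)
    expect_equal(rec$feret_nm[i], tt$true_feret_nm[j])
  }
})

test_that("per-object area and Feret are non-increasing under erosion", {
  for (s in 1:5) {
    px <- make_random_blob(60, seed = 200 + s)
    m <- matrix(0L, 30, 30); m[px] <- 1L
    mask <- label_mask(m)
    img <- stem_image(matrix(0.5, 30, 30), pixel_size = 30)
    prev_area <- Inf; prev_feret <- Inf
    for (n_px in 0:2) {
      e <- erode_objects(mask, n_px)
      if (e$n_objects == 0L) break
      rec <- measure_all(e, img)
      expect_lte(rec$area_nm2, prev_area)
      expect_lte(rec$feret_nm, prev_feret)
      prev_area <- rec$area_nm2; prev_feret <- rec$feret_nm
    }
  }
})

test_that("all lengths scale linearly and areas quadratically with pixel size", {
  px <- make_random_blob(50, seed = 301)
  a <- shape_descriptors(px, pixel_size = 30)
  b <- shape_descriptors(px, pixel_size = 60)
  for (col in c("feret_nm", "perimeter_nm", "major_nm", "minor_nm", "eqdiam_nm"))
    expect_identical(b[[col]], 2 * a[[col]])
  expect_identical(b$area_nm2, 4 * a$area_nm2)
  expect_identical(b$form_factor, a$form_factor)
})

test_that("measurement tables round-trip through CSV", {
  p <- matrix(0, 32, 32); p[4:8, 4:12] <- 1
  rec <- measure_all(segment(p), stem_image(p + 0.1, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, path)
  back <- read_measurements(path)
  expect_equal(back$feret_nm, rec$feret_nm)
  expect_identical(names(back), names(rec))
})
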