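# Synthetic scene generator: determinism, ground-truth consistency, and the
# scribble / blot-subsampling utilities.

test_that("empty scene is a constant background with an empty object table", {
  sp <- scene_spec(image_shape = c(64, 64), n_agglomerates = 0, n_salt = 0,
                   noise_sigma = 0, illumination_gradient = 0, seed = 1)
  sc <- generate_scene(sp)
  expect_equal(sc$image$pixels,
               matrix(sp$background_level, 64, 64))
  expect_identical(nrow(sc$truth$object_table), 0L)
  expect_true(all(sc$truth$class_map == 0L))
})

test_that("the same spec and seed reproduce the scene bit for bit", {
  sp <- small_scene_spec(seed = 7, n_salt = 2)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("fixed-diameter disks rasterize to their nominal Feret diameter", {
  sp <- scene_spec(image_shape = c(512, 512), pixel_size = 30,
                   n_agglomerates = 20,
                   diameter_law = list(type = "fixed", diameters_nm = 1000),
                   disks_per_agglomerate = c(1, 1), n_salt = 0, seed = 5)
  sc <- generate_scene(sp)
  expect_identical(nrow(sc$truth$object_table), 20L)
  # rasterized disk Feret (corner convention) within 2 px of the analytic
  # diameter
  expect_true(all(abs(sc$truth$object_table$true_feret_nm - 1000) <= 2 * 30))
})

test_that("ground truth is self-consistent across random scenes", {
  for (s in 1:4) {
    sc <- generate_scene(small_scene_spec(seed = s, n_salt = 1))
    tab <- sc$truth$object_table
    # connected components of the agglomerate class match the table
    lab <- agglomsizer:::label_components8(sc$truth$class_map == 1L)
    expect_identical(max(lab), nrow(tab))
    # mass conservation: total class area equals the summed per-object area
    expect_identical(sum(sc$truth$class_map == 1L) * sc$truth$pixel_size^2,
                     sum(tab$true_area_nm2))
    # salt pixels are never labelled agglomerate
    expect_true(all(sc$truth$class_map[sc$truth$object_map > 0L] == 1L))
  }
})

test_that("overcrowded scenes fail placement with an informative error", {
  sp <- scene_spec(image_shape = c(64, 64), n_agglomerates = 200,
                   diameter_law = list(type = "fixed", diameters_nm = 300),
                   seed = 1)
  expect_error(generate_scene(sp), "attempts|fit")
})

test_that("degenerate image shapes are rejected", {
  expect_error(scene_spec(image_shape = c(0, 0)), "image_shape")
  expect_error(scene_spec(image_shape = c(16, 16)), "image_shape")
})

test_that("scene specs round-trip through YAML", {
  sp <- small_scene_spec(seed = 3, n_salt = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_spec(sp, path)
  sp2 <- read_scene_spec(path)
  expect_equal(sp2, sp)
  expect_identical(generate_scene(sp2)$image$pixels,
                   generate_scene(sp)$image$pixels)
})

test_that("scene files are written in plain exchange formats", {
  sc <- generate_scene(small_scene_spec(seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, name = "s1")
  expect_true(all(file.exists(paths)))
  img <- read_stem_image(paths[["image"]], pixel_size = 30)
  expect_identical(dim(img$pixels), dim(sc$image$pixels))
  cls <- round(png::readPNG(paths[["class_map"]]) * 255)
  expect_identical(cls, matrix(as.numeric(sc$truth$class_map), 128, 128))
  tab <- utils::read.csv(paths[["object_table"]])
  expect_identical(names(tab), c("object_id", "centroid_row", "centroid_col",
                                 "true_feret_nm", "true_area_nm2"))
})

test_that("scribbles cover both classes, respect the salt rule and avoid halos", {
  sc <- generate_scene(small_scene_spec(seed = 9, n_salt = 2))
  scr <- generate_scribbles(sc$truth, fraction = 0.1, seed = 4)
  expect_setequal(unique(scr$class), c("agglomerate", "background"))
  # identical on repeat
  expect_identical(as.data.frame(generate_scribbles(sc$truth, 0.1, seed = 4)),
                   as.data.frame(scr))
  idx <- cbind(scr$row, scr$col)
  # every scribble on a salt pixel is labelled background
  on_salt <- sc$truth$class_map[idx] == 2L
  expect_true(any(on_salt))  # salts are explicitly represented
  expect_true(all(scr$class[on_salt] == "background"))
  # agglomerate scribbles only on agglomerate pixels
  expect_true(all(sc$truth$class_map[idx[scr$class == "agglomerate", , drop = FALSE]] == 1L))
  # the ambiguous halo annulus is never sampled
  expect_false(any(sc$truth$halo_map[idx]))
})

test_that("scribble generation fails when a class is absent", {
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_agglomerates = 0,
                                  n_salt = 0, seed = 1))
  expect_error(generate_scribbles(sc$truth, 0.5), "agglomerate")
})

test_that("blot subsampling keeps everything at 1 and nothing at 0", {
  sc <- generate_scene(small_scene_spec(seed = 11))
  t1 <- simulate_blot_subsample(sc$truth, keep_prob = 1, seed = 2)
  expect_equal(t1$object_table, sc$truth$object_table)
  expect_identical(t1$class_map, sc$truth$class_map)
  t0 <- simulate_blot_subsample(sc$truth, keep_prob = 0, seed = 2)
  expect_identical(nrow(t0$object_table), 0L)
  expect_true(all(t0$object_map == 0L))
})

test_that("blot retention count is binomial", {
  # 200 independent single-pixel objects on a grid; retention at p = 0.5
  # must land inside the 99.9% binomial interval
  n <- 200L
  rows <- 3L * (seq_len(n) - 1L) %/% 42L + 2L
  cols <- 3L * ((seq_len(n) - 1L) %% 42L) + 2L
  cm <- matrix(0L, 130, 130); om <- matrix(0L, 130, 130)
  cm[cbind(rows, cols)] <- 1L
  om[cbind(rows, cols)] <- seq_len(n)
  truth <- structure(
    list(class_map = cm, object_map = om,
         halo_map = matrix(FALSE, 130, 130), halo_width = 0L,
         object_table = data.frame(object_id = seq_len(n),
                                   centroid_row = rows - 0.5,
                                   centroid_col = cols - 0.5,
                                   true_feret_nm = sqrt(2) * 30,
                                   true_area_nm2 = 900),
         pixel_size = 30),
    class = "ground_truth")
  kept <- vapply(1:20, function(s)
    nrow(simulate_blot_subsample(truth, 0.5, seed = s)$object_table), integer(1))
  lo <- qbinom(5e-4, n, 0.5); hi <- qbinom(1 - 5e-4, n, 0.5)
  expect_true(all(kept >= lo & kept <= hi))
  # and the thinned maps stay consistent
  t5 <- simulate_blot_subsample(truth, 0.5, seed = 1)
  expect_identical(sum(t5$object_map > 0L), nrow(t5$object_table))
})
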