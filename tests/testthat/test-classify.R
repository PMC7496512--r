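# Feature bank and random-forest pixel classification.

test_that("constant images produce zero derivative features", {
  img <- matrix(0.4, 32, 32)
  fs <- compute_features(img, scales = c(1, 3))
  arr <- fs$features
  for (nm in fs$names) {
    sl <- arr[, , match(nm, fs$names)]
    if (grepl("^int", nm)) expect_equal(sl, matrix(0.4, 32, 32), tolerance = 1e-12)
    else if (grepl("^var", nm)) expect_lt(max(abs(sl)), 1e-12)
    else expect_identical(max(abs(sl)), 0)  # gradients, Laplacian, eigenvalues
  }
})

test_that("gradient magnitude peaks on a step edge", {
  img <- cbind(matrix(0.2, 32, 16), matrix(0.8, 32, 16))
  fs <- compute_features(img, scales = 1)
  gm <- fs$features[, , match("gradmag_s1", fs$names)]
  peak_cols <- apply(gm, 1L, which.max)
  expect_true(all(abs(peak_cols - 16.5) <= 2))
  # finite-difference oracle at the edge: smoothed step derivative
  expect_gt(max(gm), 10 * mean(gm[, c(1:8, 25:32)]))
})

test_that("feature computation is deterministic and validates inputs", {
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(compute_features(img, c(1, 2))$features,
                   compute_features(img, c(1, 2))$features)
  expect_error(compute_features(img, numeric()), "non-empty")
  expect_error(compute_features(img, c(1, -1)), "> 0")
})

# a linearly separable scene: bright blob on dark background, slight noise
make_separable <- function(seed, fg = 200 / 255, bg = 50 / 255, noise = 5 / 255) {
  withr_seed(seed, {
    m <- matrix(bg, 64, 64)
    truth <- matrix(FALSE, 64, 64)
    truth[20:40, 15:35] <- TRUE
    truth[45:55, 45:58] <- TRUE
    m[truth] <- fg
    m <- m + noise * matrix(rnorm(64 * 64), 64, 64)
    list(img = stem_image(pmax(m, 0), 30), truth = truth)
  })
}

sep_scribbles <- function(truth, n_per_class, seed) {
  withr_seed(seed, {
    fgpx <- which(truth, arr.ind = TRUE)
    bgpx <- which(!truth, arr.ind = TRUE)
    fgpx <- fgpx[sample.int(nrow(fgpx), n_per_class), ]
    bgpx <- bgpx[sample.int(nrow(bgpx), n_per_class), ]
    scribble_set(c(fgpx[, 1], bgpx[, 1]), c(fgpx[, 2], bgpx[, 2]),
                 rep(c("agglomerate", "background"), each = n_per_class))
  })
}

test_that("a separable scene is classified almost perfectly from 50 scribbles", {
  sc <- make_separable(1)
  scr <- sep_scribbles(sc$truth, 50, seed = 2)
  model <- train_pixel_classifier(sc$img, scr, seed = 3, scales = c(0.7, 1, 1.6))
  pm <- predict(model, sc$img)
  held_out <- !logical(length(sc$truth))
  held_out[cbind(scr$row, scr$col)] <- FALSE
  pred <- pm$prob >= 0.5
  acc <- mean(pred[held_out] == sc$truth[held_out])
  expect_gte(acc, 0.99)
  # scribbled agglomerate pixels get probability > 0.5 nearly always
  agg <- scr$class == "agglomerate"
  expect_gte(mean(pm$prob[cbind(scr$row, scr$col)][agg] > 0.5), 0.95)
  # training metadata records the fit
  expect_gte(model$meta$train_accuracy, 0.99)
})

test_that("training and prediction are deterministic under a fixed seed", {
  sc <- make_separable(4)
  scr <- sep_scribbles(sc$truth, 30, seed = 5)
  m1 <- train_pixel_classifier(sc$img, scr, seed = 9, scales = c(1, 2))
  m2 <- train_pixel_classifier(sc$img, scr, seed = 9, scales = c(1, 2))
  expect_identical(predict(m1, sc$img)$prob, predict(m2, sc$img)$prob)
})

test_that("probabilities are well-formed and background-only images score low", {
  sc <- make_separable(6)
  scr <- sep_scribbles(sc$truth, 30, seed = 7)
  model <- train_pixel_classifier(sc$img, scr, seed = 8, scales = c(1, 2))
  pm <- predict(model, sc$img)
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  bg_img <- stem_image(matrix(50 / 255, 64, 64) +
                         (2 / 255) * matrix(withr_seed(10, rnorm(64 * 64)), 64), 30)
  expect_lt(mean(predict(model, bg_img)$prob), 0.5)
})

test_that("training validates scribbles", {
  sc <- make_separable(11)
  fg <- which(sc$truth, arr.ind = TRUE)[1:20, ]
  one_class <- scribble_set(fg[, 1], fg[, 2], rep("agglomerate", 20))
  expect_error(train_pixel_classifier(sc$img, one_class, scales = 1),
               "background")
  oob <- scribble_set(c(fg[1:10, 1], 999), c(fg[1:10, 2], 999),
                      c(rep("agglomerate", 10), "background"))
  expect_error(train_pixel_classifier(sc$img, oob, scales = 1, min_labels = 1),
               "bounds")
  few <- sep_scribbles(sc$truth, 5, seed = 1)
  expect_error(train_pixel_classifier(sc$img, few, scales = 1), "at least")
  expect_error(scribble_set(c(1, 1), c(1, 1), c("agglomerate", "background")),
               "conflicting")
})

test_that("batch prediction preserves order and names failing images", {
  sc <- make_separable(12)
  scr <- sep_scribbles(sc$truth, 30, seed = 13)
  model <- train_pixel_classifier(sc$img, scr, seed = 1, scales = c(1, 2))
  expect_identical(batch_predict(model, list()), list())
  im2 <- sc$img; im2$id <- "second"
  out <- batch_predict(model, list(sc$img, im2, sc$img))
  expect_length(out, 3L)
  expect_identical(out[[2]]$image_id, "second")
  bad <- sc$img; bad$pixels <- matrix(NaN, 4, 4); bad$id <- "corrupt_one"
  expect_error(batch_predict(model, list(sc$img, bad)), "corrupt_one")
})

test_that("a serialized classifier round-trips through disk", {
  sc <- make_separable(14)
  scr <- sep_scribbles(sc$truth, 30, seed = 15)
  model <- train_pixel_classifier(sc$img, scr, seed = 2, scales = c(1, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_pixel_classifier(model, path)
  m2 <- load_pixel_classifier(path)
  expect_identical(predict(m2, sc$img)$prob, predict(model, sc$img)$prob)
  saveRDS(list(a = 1), path)
  expect_error(load_pixel_classifier(path), "not a serialized")
})

test_that("adding correct scribbles does not degrade held-out accuracy", {
  sc <- generate_scene(small_scene_spec(seed = 17))
  truth <- sc$truth$class_map == 1L
  held_mask <- !sc$truth$halo_map  # halo pixels are ambiguous by design
  acc <- vapply(c(0.03, 0.1, 0.3), function(fr) {
    scr <- generate_scribbles(sc$truth, fr, seed = 21)
    model <- train_pixel_classifier(sc$image, scr, seed = 5, scales = c(1, 2, 4))
    pred <- predict(model, sc$image)$prob >= 0.5
    held <- held_mask
    held[cbind(scr$row, scr$col)] <- FALSE
    mean(pred[held] == truth[held])
  }, numeric(1))
  expect_true(all(diff(acc) > -0.02))
})

test_that("texture lets the classifier beat any global threshold on salty scenes", {
  # salt intensity overlaps the agglomerate band, so the best global
  # threshold must trade salt false positives against recall; the forest
  # uses texture and wins on pixel precision
  sp <- small_scene_spec(seed = 23, n_salt = 2, salt_intensity = 0.75)
  sc <- generate_scene(sp)
  img <- correct_illumination(sc$image, estimate_illumination(sc$image))
  scr <- generate_scribbles(sc$truth, 0.08, seed = 24)
  model <- train_pixel_classifier(img, scr, seed = 6)
  truth <- sc$truth$class_map == 1L
  pred <- predict(model, img)$prob >= 0.5
  prec_ml <- sum(pred & truth) / sum(pred)
  tb <- threshold_baseline(img, truth)
  pred_thr <- img$pixels >= tb$threshold
  prec_thr <- sum(pred_thr & truth) / sum(pred_thr)
  expect_gt(prec_ml, prec_thr)
})
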