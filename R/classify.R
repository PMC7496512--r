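# Sparse-annotation two-class pixel classification. A multi-scale filter
# bank turns each pixel into a feature vector; a random forest trained on a
# handful of scribbled pixels then predicts a per-pixel agglomerate
# probability for whole images. This is the interactive pixel-classification
# idiom (scribbles -> live probability map -> batch processing) run
# non-interactively.

PIXEL_CLASSES <- c("agglomerate", "background")

#' Default feature scales (px) for pixel classification
#'
#' The conventional geometric ladder of Gaussian scales used by interactive
#' pixel-classification tools.
#' @export
default_feature_scales <- function() c(0.7, 1.0, 1.6, 3.5, 5.0, 10.0)

#' Construct a scribble set
#'
#' Sparse pixel-coordinate training labels in two classes.
#'
#' @param row,col integer pixel coordinates (1-based matrix indices).
#' @param class character vector in `{"agglomerate", "background"}`.
#' @param image_id source image identifier.
#' @return an object of class `scribble_set`: a `data.frame` with columns
#'   `row`, `col`, `class` and attribute `image_id`.
#' @export
scribble_set <- function(row, col, class, image_id = "image") {
  if (length(row) != length(col) || length(row) != length(class))
    stop("row, col and class must have equal length")
  class <- as.character(class)
  if (!all(class %in% PIXEL_CLASSES))
    stop("scribble classes must be 'agglomerate' or 'background'")
  df <- data.frame(row = as.integer(row), col = as.integer(col),
                   class = class, stringsAsFactors = FALSE)
  key <- paste(df$row, df$col)
  dup <- duplicated(key)
  if (any(dup)) {
    # a coordinate may be listed twice with the same class, never with both
    conflict <- tapply(df$class, key, function(x) length(unique(x)) > 1L)
    if (any(conflict))
      stop("duplicate scribble coordinates with conflicting classes")
    df <- df[!dup, , drop = FALSE]
  }
  structure(df, image_id = as.character(image_id), class = c("scribble_set", "data.frame"))
}

#' Read/write scribbles as CSV (`row,col,class`)
#' @param path CSV path.
#' @param scribbles a [scribble_set()].
#' @param image_id identifier for the reader.
#' @return the scribbles (reader) or `path` invisibly (writer).
#' @export
read_scribbles <- function(path, image_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scribble_set(df$row, df$col, df$class, image_id = image_id)
}

#' @rdname read_scribbles
#' @export
write_scribbles <- function(scribbles, path) {
  utils::write.csv(as.data.frame(scribbles), path, row.names = FALSE)
  invisible(path)
}

feature_names_for <- function(scales) {
  base <- c("int", "gradmag", "laplace", "st_hi", "st_lo",
            "hess_hi", "hess_lo", "var")
  as.vector(vapply(scales, function(s) paste0(base, "_s", s),
                   character(length(base))))
}

#' Compute the multi-scale pixel feature stack
#'
#' At each Gaussian scale sigma the bank computes: smoothed intensity,
#' gradient magnitude, Laplacian, the two structure-tensor eigenvalues
#' (gradient outer products smoothed at the same scale), the two Hessian
#' eigenvalues, and local variance (`E[x^2] - E[x]^2` under the Gaussian
#' window). Derivatives are central differences of the smoothed image, so on
#' a constant image every derivative-type feature is exactly zero.
#'
#' @param img a [stem_image()] or matrix.
#' @param scales positive Gaussian scales in px; default
#'   [default_feature_scales()].
#' @return an object of class `feature_stack`: list with `features` (array
#'   rows x cols x n_features), `names`, `scales`, `dim`.
#' @export
compute_features <- function(img, scales = default_feature_scales()) {
  m <- as_pixels(img)
  if (length(scales) == 0L) stop("`scales` must be non-empty")
  if (any(scales <= 0)) stop("all feature scales must be > 0")
  nr <- nrow(m); nc <- ncol(m)
  feats <- vector("list", 8L * length(scales))
  i <- 0L
  for (s in scales) {
    g <- gauss_smooth(m, s)
    gx <- deriv_row(g); gy <- deriv_col(g)
    gxx <- deriv_row2(g); gyy <- deriv_col2(g); gxy <- deriv_col(gx)
    st <- sym_eigen2(gauss_smooth(gx * gx, s), gauss_smooth(gy * gy, s),
                     gauss_smooth(gx * gy, s))
    he <- sym_eigen2(gxx, gyy, gxy)
    v <- pmax(gauss_smooth(m * m, s) - g * g, 0)
    feats[[i + 1L]] <- g
    feats[[i + 2L]] <- sqrt(gx^2 + gy^2)
    feats[[i + 3L]] <- gxx + gyy
    feats[[i + 4L]] <- st$hi
    feats[[i + 5L]] <- st$lo
    feats[[i + 6L]] <- he$hi
    feats[[i + 7L]] <- he$lo
    feats[[i + 8L]] <- v
    i <- i + 8L
  }
  arr <- array(unlist(feats, use.names = FALSE), dim = c(nr, nc, length(feats)))
  if (!all(is.finite(arr))) stop("non-finite feature values")
  structure(list(features = arr, names = feature_names_for(scales),
                 scales = scales, dim = c(nr, nc)),
            class = "feature_stack")
}

features_at <- function(stack, row, col) {
  nf <- dim(stack$features)[3L]
  out <- matrix(0, length(row), nf)
  npix <- prod(stack$dim)
  base <- (row - 1L) + (col - 1L) * stack$dim[1L]
  for (f in seq_len(nf)) out[, f] <- stack$features[base + (f - 1L) * npix + 1L]
  colnames(out) <- stack$names
  out
}

#' Train the random-forest pixel classifier
#'
#' Fits a probability random forest (100 trees by default, balanced
#' per-class case weights) on the feature vectors of the scribbled pixels.
#' Training is reproducible under a fixed seed (single-threaded forest).
#'
#' @param features a `feature_stack` from [compute_features()], or a
#'   [stem_image()] (features are computed with `scales`).
#' @param scribbles a [scribble_set()]; both classes must be present with at
#'   least `min_labels` pixels each, and all coordinates in bounds.
#' @param seed integer RNG seed.
#' @param scales feature scales, used when `features` is an image.
#' @param num_trees forest size.
#' @param min_labels per-class label floor; default 10.
#' @return an object of class `pixel_classifier`: the fitted forest plus
#'   `scales`, `classes` and training `meta` (labels per class, seed,
#'   training accuracy on the scribbled pixels).
#' @export
train_pixel_classifier <- function(features, scribbles, seed = 1L,
                                   scales = default_feature_scales(),
                                   num_trees = 100L, min_labels = 10L) {
  if (inherits(features, "stem_image") || is.matrix(features))
    features <- compute_features(features, scales)
  stopifnot(inherits(features, "feature_stack"))
  stopifnot(inherits(scribbles, "scribble_set"))
  sc <- as.data.frame(scribbles)
  for (cl in PIXEL_CLASSES) {
    n_cl <- sum(sc$class == cl)
    if (n_cl == 0L) stop("no scribbles for class '", cl, "'")
    if (n_cl < min_labels)
      stop("class '", cl, "' has ", n_cl, " labels; at least ",
           min_labels, " required")
  }
  if (any(sc$row < 1L | sc$row > features$dim[1L] |
          sc$col < 1L | sc$col > features$dim[2L]))
    stop("scribble coordinates out of image bounds")
  X <- features_at(features, sc$row, sc$col)
  y <- factor(sc$class, levels = PIXEL_CLASSES)
  w <- 1 / table(y)[y]
  dat <- data.frame(X, check.names = FALSE)
  dat$.class <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = dat,
    num.trees = num_trees, probability = TRUE,
    case.weights = as.numeric(w), seed = as.integer(seed),
    num.threads = 1L, respect.unordered.factors = "order"
  )
  pr <- stats::predict(fit, data.frame(X, check.names = FALSE),
                       num.threads = 1L)$predictions
  train_acc <- mean(PIXEL_CLASSES[max.col(pr)] == sc$class)
  structure(
    list(forest = fit, scales = features$scales, classes = PIXEL_CLASSES,
         feature_names = features$names,
         meta = list(n_labels = as.list(table(sc$class)), seed = as.integer(seed),
                     num_trees = num_trees, train_accuracy = train_acc,
                     image_id = attr(scribbles, "image_id"))),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  nl <- x$meta$n_labels
  cat(sprintf(paste0("<pixel_classifier> %d trees, %d features @ scales {%s}, ",
                     "labels: %s, train acc %.3f\n"),
              x$meta$num_trees, length(x$feature_names),
              paste(x$scales, collapse = ", "),
              paste(names(nl), unlist(nl), sep = "=", collapse = ", "),
              x$meta$train_accuracy))
  invisible(x)
}

#' Construct a probability map object
#' @param prob numeric matrix in `[0, 1]` (agglomerate-class probability).
#' @param image_id,model_id provenance identifiers.
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(prob, image_id = "image", model_id = "model") {
  if (!is.matrix(prob) || any(!is.finite(prob)) || any(prob < 0 | prob > 1))
    stop("probability map must be a finite matrix in [0, 1]")
  structure(list(prob = prob, image_id = image_id, model_id = model_id),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s: %d x %d px, mean p = %.3f\n",
              x$image_id, nrow(x$prob), ncol(x$prob), mean(x$prob)))
  invisible(x)
}

#' Predict a per-pixel agglomerate probability map
#'
#' @param object a trained [train_pixel_classifier()] model.
#' @param img a [stem_image()] (or matrix) to classify.
#' @param ... unused.
#' @return a [probability_map()]; per-pixel class probabilities sum to 1, so
#'   only the agglomerate probability is stored.
#' @export
predict.pixel_classifier <- function(object, img, ...) {
  if (is.null(object$forest)) stop("classifier has no trained forest")
  stack <- compute_features(img, object$scales)
  nr <- stack$dim[1L]; nc <- stack$dim[2L]
  X <- matrix(stack$features, nr * nc, dim(stack$features)[3L])
  colnames(X) <- stack$names
  pr <- stats::predict(object$forest, data.frame(X, check.names = FALSE),
                       num.threads = 1L)$predictions
  p_agg <- matrix(pr[, "agglomerate"], nr, nc)
  image_id <- if (inherits(img, "stem_image")) img$id else "image"
  probability_map(p_agg, image_id = image_id,
                  model_id = sprintf("rf_seed%d", object$meta$seed))
}

#' Batch prediction over a list of images
#'
#' Applies [predict.pixel_classifier()] to each image, preserving order. A
#' failure on any image is reported with that image's identifier.
#'
#' @param model a `pixel_classifier`.
#' @param images list of [stem_image()] objects.
#' @return list of [probability_map()]s, in input order.
#' @export
batch_predict <- function(model, images) {
  stopifnot(inherits(model, "pixel_classifier"))
  lapply(seq_along(images), function(i) {
    id <- if (inherits(images[[i]], "stem_image")) images[[i]]$id
          else sprintf("image_%d", i)
    tryCatch(predict(model, images[[i]]),
             error = function(e) stop("prediction failed for image '", id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
}

#' Save/load a trained pixel classifier
#'
#' Serializes the classifier (with a format version tag) so training and
#' batch prediction can run as separate steps.
#'
#' @param model a `pixel_classifier`.
#' @param path file path (`.rds`).
#' @return `path` invisibly (save); the classifier (load).
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(list(format = "agglomsizer_pixel_classifier_v1", model = model), path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "agglomsizer_pixel_classifier_v1"))
    stop("not a serialized agglomsizer pixel classifier: ", path)
  x$model
}

#' Write a probability map as 32-bit float TIFF
#' @param pmap a [probability_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(pmap, path) {
  tiff::writeTIFF(pmap$prob, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
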