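# End-to-end orchestration: synth -> correct -> train -> predict -> measure
# -> stats -> validate, from one config, with per-stage derived seeds so
# every run is reproducible bit for bit.

#' Build a pipeline configuration
#'
#' Two modes share one config. In synthetic mode (the default) `n_images`
#' scenes are generated from `scene` with per-image derived seeds and ground
#' truth flows into training scribbles and validation. In file mode,
#' `image_paths` supplies the images and `scribble_paths` supplies CSV
#' scribbles (`row,col,class`) for the training images; the validate stage is
#' then skipped unless reference masks exist.
#'
#' @param out_dir output directory for all artifacts.
#' @param scene a [scene_spec()] template (its seed is overridden per image).
#' @param n_images number of synthetic images to generate.
#' @param image_paths,scribble_paths file-mode inputs (`scribble_paths`
#'   aligned with the first `n_train_images` images).
#' @param pixel_size nm/px for file-mode images.
#' @param n_train_images images used for training (first of the set; the
#'   workflow convention is a small subset, <10% of a real dataset).
#' @param scribble_fraction fraction of interior class pixels scribbled per
#'   training image (synthetic mode).
#' @param feature_scales Gaussian feature scales in px.
#' @param illumination_scale smoothing scale for [estimate_illumination()];
#'   `NULL` = image width / 8.
#' @param threshold,min_size segmentation parameters, see [segment()].
#' @param erode_px halo-correction erosion rounds, see [erode_objects()].
#' @param bin_width_nm histogram bin width.
#' @param seed master seed; all stage seeds derive from it.
#' @param stages character subset of
#'   `c("synth","correct","train","predict","measure","stats","validate")`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scene = scene_spec(),
                            n_images = 8L,
                            image_paths = NULL,
                            scribble_paths = NULL,
                            pixel_size = NULL,
                            n_train_images = 2L,
                            scribble_fraction = 0.05,
                            feature_scales = default_feature_scales(),
                            illumination_scale = NULL,
                            threshold = 0.5,
                            min_size = 4L,
                            erode_px = 1L,
                            bin_width_nm = 100,
                            seed = 1L,
                            stages = c("synth", "correct", "train", "predict",
                                       "measure", "stats", "validate")) {
  all_stages <- c("synth", "correct", "train", "predict", "measure",
                  "stats", "validate")
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (erode_px < 0) stop("`erode_px` must be >= 0")
  if (bin_width_nm <= 0) stop("`bin_width_nm` must be > 0")
  if (n_train_images < 1L) stop("`n_train_images` must be >= 1")
  structure(
    list(out_dir = out_dir, scene = scene, n_images = as.integer(n_images),
         image_paths = image_paths, scribble_paths = scribble_paths,
         pixel_size = pixel_size,
         n_train_images = as.integer(n_train_images),
         scribble_fraction = scribble_fraction,
         feature_scales = feature_scales,
         illumination_scale = illumination_scale,
         threshold = threshold, min_size = as.integer(min_size),
         erode_px = as.integer(erode_px), bin_width_nm = bin_width_nm,
         seed = as.integer(seed), stages = stages),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [pipeline_config()] arguments, with
#'   `scene` given as a nested [scene_spec()] mapping.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$scene)) x$scene <- do.call(scene_spec, x$scene)
  do.call(pipeline_config, x)
}

derive_seed <- function(master, k) {
  (as.integer(master) * 1009L + as.integer(k)) %% 2147483647L
}

#' Run the full agglomerate-sizing pipeline
#'
#' Executes the enabled stages in order and writes all artifacts under
#' `cfg$out_dir`: `images/` (synthetic scenes + ground truth), `corrected/`,
#' `model/classifier.rds`, `probmaps/`, `masks/`, `measurements.csv`,
#' `summary.csv`, `histogram.csv`, `validation.csv`/`.txt` and
#' `manifest.json` (inputs, outputs, parameters, derived seeds, package
#' version and per-stage timing). A stage failure aborts with the stage name
#' and leaves a `FAILED` marker file next to the partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the run manifest, invisibly (a list; also serialized to
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("agglomsizer")),
    master_seed = cfg$seed,
    parameters = cfg[c("n_images", "n_train_images", "scribble_fraction",
                       "feature_scales", "threshold", "min_size", "erode_px",
                       "bin_width_nm")],
    stages = list()
  )
  failed_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)),
                                  res)
    invisible(NULL)
  }

  images <- list()
  truths <- list()
  scribbles <- list()

  run_stage("synth", function() {
    if (!is.null(cfg$image_paths)) {
      if (is.null(cfg$pixel_size))
        stop("`pixel_size` is required when reading images from files")
      images <<- lapply(cfg$image_paths, read_stem_image,
                        pixel_size = cfg$pixel_size)
      return(list(mode = "files", n_images = length(images),
                  inputs = cfg$image_paths))
    }
    dir_img <- file.path(cfg$out_dir, "images")
    paths <- character()
    for (i in seq_len(cfg$n_images)) {
      sp <- cfg$scene
      sp$seed <- derive_seed(cfg$seed, i)
      sc <- generate_scene(sp)
      sc$image$id <- sprintf("scene_%03d", i)
      images[[i]] <<- sc$image
      truths[[i]] <<- sc$truth
      paths <- c(paths, write_scene(sc, dir_img, name = sc$image$id)[["image"]])
    }
    truth_tab <- do.call(rbind, lapply(seq_len(cfg$n_images), function(i)
      cbind(data.frame(image_id = images[[i]]$id),
            truths[[i]]$object_table)))
    p_truth <- file.path(cfg$out_dir, "truth_objects.csv")
    utils::write.csv(truth_tab, p_truth, row.names = FALSE)
    list(mode = "synthetic", n_images = cfg$n_images,
         scene_seeds = vapply(seq_len(cfg$n_images),
                              function(i) derive_seed(cfg$seed, i), integer(1)),
         outputs = paths, truth_table = p_truth)
  })
  if (length(images) == 0L)
    stop("pipeline has no input images (enable the synth stage or pass image_paths)")

  run_stage("correct", function() {
    dir_cor <- file.path(cfg$out_dir, "corrected")
    dir.create(dir_cor, showWarnings = FALSE)
    paths <- character(length(images))
    for (i in seq_along(images)) {
      field <- estimate_illumination(images[[i]],
                                     smoothing_scale = cfg$illumination_scale)
      images[[i]] <<- correct_illumination(images[[i]], field)
      paths[i] <- file.path(dir_cor, paste0(images[[i]]$id, ".tif"))
      write_stem_image(images[[i]], paths[i])
    }
    list(outputs = paths)
  })

  model <- NULL
  run_stage("train", function() {
    n_train <- min(cfg$n_train_images, length(images))
    for (i in seq_len(n_train)) {
      if (!is.null(cfg$scribble_paths)) {
        p <- cfg$scribble_paths[i]
        if (is.na(p) || !file.exists(p))
          stop("scribble file not found: ", p)
        scribbles[[i]] <<- read_scribbles(p, image_id = images[[i]]$id)
      } else {
        if (length(truths) < i)
          stop("no ground truth available to synthesize scribbles ",
               "(run the synth stage or pass scribble_paths)")
        scribbles[[i]] <<- generate_scribbles(truths[[i]], cfg$scribble_fraction,
                                              seed = derive_seed(cfg$seed, 500L + i),
                                              image_id = images[[i]]$id)
      }
    }
    # one model trained on the pooled scribbles of the training images
    feats <- compute_features(images[[1L]], cfg$feature_scales)
    X <- do.call(rbind, lapply(seq_len(n_train), function(i) {
      fi <- if (i == 1L) feats else compute_features(images[[i]], cfg$feature_scales)
      sci <- as.data.frame(scribbles[[i]])
      cbind(as.data.frame(features_at(fi, sci$row, sci$col)), .class = sci$class)
    }))
    model <<- train_on_features(X, cfg$feature_scales,
                                seed = derive_seed(cfg$seed, 900L))
    dir_model <- file.path(cfg$out_dir, "model")
    dir.create(dir_model, showWarnings = FALSE)
    p <- file.path(dir_model, "classifier.rds")
    save_pixel_classifier(model, p)
    list(n_train_images = n_train,
         n_labels = as.list(table(X$.class)),
         train_accuracy = model$meta$train_accuracy, output = p)
  })

  pmaps <- list()
  run_stage("predict", function() {
    if (is.null(model)) stop("no trained classifier (enable the train stage)")
    dir_pm <- file.path(cfg$out_dir, "probmaps")
    dir.create(dir_pm, showWarnings = FALSE)
    pmaps <<- batch_predict(model, images)
    paths <- vapply(pmaps, function(pm) {
      p <- file.path(dir_pm, paste0(pm$image_id, "_prob.tif"))
      write_probability_map(pm, p)
      p
    }, character(1))
    list(outputs = paths)
  })

  records <- NULL
  run_stage("measure", function() {
    if (length(pmaps) == 0L) stop("no probability maps (enable the predict stage)")
    dir_mask <- file.path(cfg$out_dir, "masks")
    dir.create(dir_mask, showWarnings = FALSE)
    recs <- vector("list", length(pmaps))
    for (i in seq_along(pmaps)) {
      mask <- segment(pmaps[[i]], cfg$threshold, cfg$min_size)
      mask <- erode_objects(mask, cfg$erode_px)
      write_label_mask(mask, file.path(dir_mask,
                                       paste0(images[[i]]$id, "_mask.tif")))
      recs[[i]] <- measure_all(mask, images[[i]])
    }
    records <<- do.call(rbind, recs)
    p <- file.path(cfg$out_dir, "measurements.csv")
    write_measurements(records, p)
    list(n_objects = nrow(records), output = p)
  })

  run_stage("stats", function() {
    if (is.null(records)) stop("no measurements (enable the measure stage)")
    if (nrow(records) == 0L) stop("no objects were measured")
    summ <- summarize_measurements(records, group = "pipeline")
    p1 <- file.path(cfg$out_dir, "summary.csv")
    utils::write.csv(summ, p1, row.names = FALSE)
    hist <- size_histogram(number_summary(records$feret_nm), cfg$bin_width_nm)
    p2 <- file.path(cfg$out_dir, "histogram.csv")
    utils::write.csv(hist, p2, row.names = FALSE)
    list(summary = as.list(summ), outputs = c(p1, p2))
  })

  run_stage("validate", function() {
    if (length(truths) == 0L)
      return(list(skipped = "no ground truth available"))
    if (length(pmaps) == 0L) stop("no probability maps to validate")
    ious <- numeric(); n_ref <- 0L; n_test <- 0L
    for (i in seq_along(pmaps)) {
      mask <- erode_objects(segment(pmaps[[i]], cfg$threshold, cfg$min_size),
                            cfg$erode_px)
      mt <- match_objects(truths[[i]]$object_map, mask$labels)
      ious <- c(ious, mt$pairs$iou)
      n_ref <- n_ref + mt$n_ref
      n_test <- n_test + mt$n_test
    }
    s <- list(mean_iou = mean(ious), sd_iou = stats::sd(ious),
              n_scored = length(ious), count_ratio = n_test / n_ref,
              n_ref = n_ref, n_test = n_test)
    p <- file.path(cfg$out_dir, "validation.csv")
    utils::write.csv(as.data.frame(s), p, row.names = FALSE)
    c(s, list(output = p))
  })

  manifest$stages_run <- names(manifest$stages)
  p_manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# internal: train on an already-assembled feature data.frame (pooled
# multi-image scribbles); mirrors train_pixel_classifier
train_on_features <- function(X, scales, seed, num_trees = 100L) {
  y <- factor(X$.class, levels = PIXEL_CLASSES)
  dat <- X[, setdiff(names(X), ".class"), drop = FALSE]
  dat$.class <- y
  w <- 1 / table(y)[y]
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = dat,
    num.trees = num_trees, probability = TRUE,
    case.weights = as.numeric(w), seed = as.integer(seed),
    num.threads = 1L, respect.unordered.factors = "order"
  )
  pr <- stats::predict(fit, dat[, setdiff(names(dat), ".class"), drop = FALSE],
                       num.threads = 1L)$predictions
  acc <- mean(PIXEL_CLASSES[max.col(pr)] == as.character(y))
  structure(
    list(forest = fit, scales = scales, classes = PIXEL_CLASSES,
         feature_names = setdiff(names(X), ".class"),
         meta = list(n_labels = as.list(table(y)), seed = as.integer(seed),
                     num_trees = num_trees, train_accuracy = acc,
                     image_id = "pooled")),
    class = "pixel_classifier"
  )
}
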