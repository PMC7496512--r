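# Seeded generator of synthetic dark-field STEM scenes with full ground
# truth. The generator emulates the phenomenology of dark-field images of
# plunge-frozen, vacuum-dried nanoparticle suspensions: bright quasi-circular
# agglomerates (unions of overlapping disks) on a dark support film, focal
# halos extending a few pixels beyond object edges, mid-intensity salt
# precipitates with speckled internal texture, a smooth multiplicative
# illumination field and additive detector noise. It is phenomenological:
# no electron-optical simulation is attempted.

#' Specify a synthetic dark-field STEM scene
#'
#' Defaults describe the stock benchmarking condition used throughout the
#' package: a 256 x 256 px field at 30 nm/px (a ~7.7 um field of view),
#' a dozen well-separated agglomerates with lognormal diameters (median
#' 600 nm), 2-px focal halos at 30% of object contrast, optional salt
#' precipitates whose intensity overlaps the agglomerate intensity so that
#' only texture separates the two, a mild illumination gradient and additive
#' Gaussian noise. Gray levels are normalized to `[0, 1]`.
#'
#' @param image_shape integer (rows, cols), each >= 32.
#' @param pixel_size nm per pixel, > 0.
#' @param n_agglomerates number of agglomerate objects, >= 0.
#' @param diameter_law either `list(type = "lognormal", median_nm, sigma)` or
#'   `list(type = "fixed", diameters_nm = c(...))` (recycled over objects).
#' @param agglomerate_intensity mean gray level of agglomerate pixels.
#' @param halo_width halo annulus width in px, >= 0.
#' @param halo_intensity_fraction halo contrast as a fraction of object
#'   contrast above background, in `[0, 1]`.
#' @param n_salt number of salt precipitates, >= 0.
#' @param salt_intensity mean gray level of salt pixels.
#' @param salt_speckle_sigma relative multiplicative speckle of salt texture.
#' @param salt_diameter_nm typical salt extent in nm.
#' @param illumination_gradient relative amplitude of the smooth
#'   multiplicative illumination field, in `[0, 1)`.
#' @param noise_sigma additive Gaussian noise s.d. in gray levels, >= 0.
#' @param background_level background gray level.
#' @param disks_per_agglomerate integer range (lo, hi) of overlapping disks
#'   per object; `c(1, 1)` gives single spheres.
#' @param seed integer RNG seed; the full scene is a pure function of the
#'   spec including this seed.
#' @return an object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(n_agglomerates = 5, seed = 7)
#' sc <- generate_scene(sp)
#' sc$truth$object_table
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_size = 30,
                       n_agglomerates = 12L,
                       diameter_law = list(type = "lognormal",
                                           median_nm = 600, sigma = 0.35),
                       agglomerate_intensity = 0.75,
                       halo_width = 2L,
                       halo_intensity_fraction = 0.3,
                       n_salt = 0L,
                       salt_intensity = 0.7,
                       salt_speckle_sigma = 0.25,
                       salt_diameter_nm = 700,
                       illumination_gradient = 0.2,
                       noise_sigma = 0.02,
                       background_level = 0.08,
                       disks_per_agglomerate = c(1L, 4L),
                       seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 32L))
    stop("`image_shape` must be two integers >= 32")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (n_agglomerates < 0 || n_salt < 0) stop("object counts must be >= 0")
  if (halo_width < 0) stop("`halo_width` must be >= 0")
  if (halo_intensity_fraction < 0 || halo_intensity_fraction > 1)
    stop("`halo_intensity_fraction` must be in [0, 1]")
  if (illumination_gradient < 0 || illumination_gradient >= 1)
    stop("`illumination_gradient` must be in [0, 1)")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (!diameter_law$type %in% c("lognormal", "fixed"))
    stop("`diameter_law$type` must be 'lognormal' or 'fixed'")
  if (diameter_law$type == "lognormal") {
    if (diameter_law$median_nm <= 0 || diameter_law$sigma < 0)
      stop("lognormal diameter law needs median_nm > 0 and sigma >= 0")
  } else if (any(diameter_law$diameters_nm <= 0)) {
    stop("fixed diameters must be strictly positive")
  }
  disks_per_agglomerate <- as.integer(disks_per_agglomerate)
  if (length(disks_per_agglomerate) != 2L || disks_per_agglomerate[1L] < 1L ||
      disks_per_agglomerate[2L] < disks_per_agglomerate[1L])
    stop("`disks_per_agglomerate` must be an increasing integer pair >= 1")
  structure(
    list(image_shape = image_shape, pixel_size = pixel_size,
         n_agglomerates = as.integer(n_agglomerates),
         diameter_law = diameter_law,
         agglomerate_intensity = agglomerate_intensity,
         halo_width = as.integer(halo_width),
         halo_intensity_fraction = halo_intensity_fraction,
         n_salt = as.integer(n_salt), salt_intensity = salt_intensity,
         salt_speckle_sigma = salt_speckle_sigma,
         salt_diameter_nm = salt_diameter_nm,
         illumination_gradient = illumination_gradient,
         noise_sigma = noise_sigma, background_level = background_level,
         disks_per_agglomerate = disks_per_agglomerate,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec> %d x %d px @ %g nm/px, %d agglomerates, ",
                     "%d salts, halo %d px @ %.2f, seed %d\n"),
              x$image_shape[1L], x$image_shape[2L], x$pixel_size,
              x$n_agglomerates, x$n_salt, x$halo_width,
              x$halo_intensity_fraction, x$seed))
  invisible(x)
}

MAX_PLACEMENT_ATTEMPTS <- 10000L

draw_diameters <- function(law, n) {
  if (n == 0L) return(numeric())
  if (law$type == "fixed") rep_len(law$diameters_nm, n)
  else law$median_nm * exp(law$sigma * stats::rnorm(n))
}

# rasterize a union of disks: pixel (r, c) is inside if its centre
# (r - 0.5, c - 0.5) lies within any disk
raster_disks <- function(shape, centers, radii) {
  inside <- matrix(FALSE, shape[1L], shape[2L])
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1L]; c0 <- centers[k, 2L]; rad <- radii[k]
    rs <- max(1L, floor(r0 - rad)):min(shape[1L], ceiling(r0 + rad + 1))
    cs <- max(1L, floor(c0 - rad)):min(shape[2L], ceiling(c0 + rad + 1))
    dr <- (rs - 0.5 - r0)^2
    dc <- (cs - 0.5 - c0)^2
    inside[rs, cs] <- inside[rs, cs] | outer(dr, dc, `+`) <= rad^2
  }
  inside
}

# rasterize a simple polygon (vertices in px coordinates) by the even-odd
# rule applied to pixel centres
raster_polygon <- function(shape, verts) {
  rs <- max(1L, floor(min(verts[, 1L]))):min(shape[1L], ceiling(max(verts[, 1L])) + 1L)
  cs <- max(1L, floor(min(verts[, 2L]))):min(shape[2L], ceiling(max(verts[, 2L])) + 1L)
  grid <- expand.grid(r = rs - 0.5, c = cs - 0.5)
  nv <- nrow(verts)
  inside <- rep(FALSE, nrow(grid))
  j <- nv
  for (i in seq_len(nv)) {
    yi <- verts[i, 1L]; xi <- verts[i, 2L]
    yj <- verts[j, 1L]; xj <- verts[j, 2L]
    crosses <- ((yi > grid$r) != (yj > grid$r)) &
      (grid$c < (xj - xi) * (grid$r - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  out <- matrix(FALSE, shape[1L], shape[2L])
  out[cbind(rep(rs, times = length(cs))[inside],
            rep(cs, each = length(rs))[inside])] <- TRUE
  out
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: objects are placed by
#' rejection sampling so that no two objects (including halo annuli) touch,
#' keeping per-object ground truth unambiguous. Agglomerates are unions of
#' 1 to `disks_per_agglomerate[2]` overlapping disks; salts are speckled
#' convex polygons; halos are raised-intensity annuli obtained by dilating
#' each object by `halo_width` px. The smooth multiplicative illumination
#' field and additive noise are applied last; the ground truth reflects the
#' clean pre-noise geometry.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `image` (a [stem_image()]) and `truth`, an
#'   object of class `ground_truth` holding `class_map` (0 background,
#'   1 agglomerate, 2 salt), `object_map` (per-agglomerate labels),
#'   `halo_map` (logical), `object_table` (`object_id`, `centroid_row`,
#'   `centroid_col`, `true_feret_nm`, `true_area_nm2`) and `pixel_size`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    shp <- spec$image_shape
    nr <- shp[1L]; nc <- shp[2L]
    class_map <- matrix(0L, nr, nc)
    object_map <- matrix(0L, nr, nc)
    img <- matrix(spec$background_level, nr, nc)

    # illumination orientation is drawn first so scenes sharing a seed share
    # the same background field regardless of object content
    illum_theta <- stats::runif(1, 0, 2 * pi)

    diam_nm <- draw_diameters(spec$diameter_law, spec$n_agglomerates)
    diam_px <- diam_nm / spec$pixel_size
    placed_centers <- matrix(numeric(), 0L, 2L)
    placed_envelopes <- numeric()

    # halos are rendered by repeated 3x3 dilation, which reaches
    # sqrt(2) * halo_width diagonally; margins must respect that
    halo_reach <- ceiling(sqrt(2) * spec$halo_width)

    place_center <- function(envelope) {
      margin <- envelope + halo_reach + 2
      if (2 * margin >= min(nr, nc))
        stop("object of envelope radius ", round(envelope, 1),
             " px cannot fit in a ", nr, "x", nc, " image")
      for (att in seq_len(MAX_PLACEMENT_ATTEMPTS)) {
        ctr <- c(stats::runif(1, margin, nr - margin),
                 stats::runif(1, margin, nc - margin))
        if (nrow(placed_centers) == 0L) return(ctr)
        dists <- sqrt(rowSums((placed_centers - matrix(ctr, nrow(placed_centers), 2L,
                                                       byrow = TRUE))^2))
        if (all(dists > placed_envelopes + envelope + 2 * halo_reach + 2))
          return(ctr)
      }
      stop("could not place object after ", MAX_PLACEMENT_ATTEMPTS,
           " attempts: scene too dense for non-overlapping placement")
    }

    # agglomerates: unions of overlapping disks inside the drawn envelope
    for (i in seq_len(spec$n_agglomerates)) {
      R <- diam_px[i] / 2
      if (R < 0.71) R <- 0.71  # at least one pixel centre inside
      k <- sample(seq.int(spec$disks_per_agglomerate[1L],
                          spec$disks_per_agglomerate[2L]), 1L)
      ctr <- place_center(R)
      if (k == 1L) {
        centers <- matrix(ctr, 1L, 2L)
        radii <- R
      } else {
        # sub-disk centres within 0.65 R of the object centre, radii chosen
        # so the union stays inside the envelope exactly and stays connected
        off <- matrix(stats::runif(2L * k, -R / 2, R / 2), k, 2L)
        off[1L, ] <- 0
        off_norm <- sqrt(rowSums(off^2))
        too_far <- off_norm > 0.65 * R
        if (any(too_far))
          off[too_far, ] <- off[too_far, , drop = FALSE] *
            (0.65 * R / off_norm[too_far])
        centers <- matrix(ctr, k, 2L, byrow = TRUE) + off
        radii <- R - sqrt(rowSums(off^2))
      }
      b <- raster_disks(shp, centers, radii)
      b[class_map != 0L] <- FALSE  # safety; placement margin should prevent this
      if (!any(b)) next
      class_map[b] <- AGGLOMERATE_CLASS
      object_map[b] <- i
      img[b] <- spec$agglomerate_intensity
      placed_centers <- rbind(placed_centers, ctr)
      placed_envelopes <- c(placed_envelopes, R)
    }

    # salt precipitates: convex-ish speckled polygons, classed 2
    salt_R <- spec$salt_diameter_nm / spec$pixel_size / 2
    for (i in seq_len(spec$n_salt)) {
      ctr <- place_center(salt_R)
      nv <- sample(5:9, 1L)
      ang <- sort(stats::runif(nv, 0, 2 * pi))
      rad <- salt_R * stats::runif(nv, 0.55, 1)
      verts <- cbind(ctr[1L] + rad * sin(ang), ctr[2L] + rad * cos(ang))
      b <- raster_polygon(shp, verts)
      b[class_map != 0L] <- FALSE
      if (!any(b)) next
      class_map[b] <- SALT_CLASS
      speckle <- 1 + spec$salt_speckle_sigma * stats::rnorm(sum(b))
      img[b] <- pmax(spec$salt_intensity * speckle, 0)
      placed_centers <- rbind(placed_centers, ctr)
      placed_envelopes <- c(placed_envelopes, salt_R)
    }

    # focal halos: annulus of width halo_width around each agglomerate
    halo_map <- matrix(FALSE, nr, nc)
    if (spec$halo_width > 0L && any(object_map > 0L)) {
      obj <- object_map > 0L
      halo_map <- dilate_bin_n(obj, spec$halo_width) & !obj & class_map == 0L
      img[halo_map] <- spec$background_level +
        spec$halo_intensity_fraction *
          (spec$agglomerate_intensity - spec$background_level)
    }

    # relabel agglomerates contiguously (an object can be skipped only in
    # pathological raster cases) and build the truth table from the raster
    object_map <- relabel_filter(object_map, 0L)
    n_obj <- max(object_map, 0L)
    object_table <- if (n_obj == 0L) {
      data.frame(object_id = integer(), centroid_row = numeric(),
                 centroid_col = numeric(), true_feret_nm = numeric(),
                 true_area_nm2 = numeric())
    } else {
      idx <- which(object_map > 0L, arr.ind = TRUE)
      ids <- object_map[object_map > 0L]
      do.call(rbind, lapply(seq_len(n_obj), function(id) {
        px <- idx[ids == id, , drop = FALSE]
        data.frame(object_id = id,
                   centroid_row = mean(px[, 1L] - 0.5),
                   centroid_col = mean(px[, 2L] - 0.5),
                   true_feret_nm = feret_diameter(px, spec$pixel_size),
                   true_area_nm2 = nrow(px) * spec$pixel_size^2)
      }))
    }

    # smooth multiplicative illumination (tilted plane, random orientation)
    if (spec$illumination_gradient > 0) {
      theta <- illum_theta
      u <- (seq_len(nr) - 0.5) / nr - 0.5
      v <- (seq_len(nc) - 0.5) / nc - 0.5
      ramp <- outer(u * cos(theta), v * sin(theta), `+`) / max(abs(cos(theta)) / 2 + abs(sin(theta)) / 2, 1e-9)
      field <- 1 + spec$illumination_gradient * ramp / 2
      img <- img * field
    }

    if (spec$noise_sigma > 0)
      img <- img + spec$noise_sigma * matrix(stats::rnorm(nr * nc), nr, nc)
    img <- pmax(img, 0)

    truth <- structure(
      list(class_map = class_map, object_map = object_map,
           halo_map = halo_map, halo_width = spec$halo_width,
           object_table = object_table, pixel_size = spec$pixel_size),
      class = "ground_truth"
    )
    list(image = stem_image(img, spec$pixel_size,
                            id = sprintf("synthetic_seed%d", spec$seed)),
         truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d px, %d agglomerates, %d salt px\n",
              nrow(x$class_map), ncol(x$class_map),
              nrow(x$object_table), sum(x$class_map == SALT_CLASS)))
  invisible(x)
}

#' Synthesize sparse scribble annotations from ground truth
#'
#' Emulates manual two-class pixel labelling: a fraction of the interior
#' pixels of each class is sampled as labelled training pixels. Salt pixels
#' are labelled `background` (the workflow's two-class convention: salts
#' belong to the background class). Halo-annulus pixels are never sampled —
#' they are ambiguous by construction, and an annotator avoids them.
#'
#' @param truth a `ground_truth` from [generate_scene()].
#' @param fraction fraction of available interior pixels to sample per class,
#'   in (0, 1]; at least one pixel per class is always drawn.
#' @param seed integer RNG seed.
#' @param image_id identifier attached to the scribbles.
#' @return a [scribble_set()].
#' @export
generate_scribbles <- function(truth, fraction, seed = 1L,
                               image_id = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  interior_or_all <- function(b) {
    e <- erode_bin(b)
    if (any(e)) e else b
  }
  agg <- truth$class_map == AGGLOMERATE_CLASS
  bg <- truth$class_map == 0L & !truth$halo_map
  salt <- truth$class_map == SALT_CLASS
  if (!any(agg)) stop("class 'agglomerate' has no pixels to scribble")
  if (!any(bg)) stop("class 'background' has no pixels to scribble")
  with_seed(seed, {
    pick <- function(b) {
      px <- which(interior_or_all(b), arr.ind = TRUE)
      n <- max(1L, round(fraction * nrow(px)))
      px[sample.int(nrow(px), n), , drop = FALSE]
    }
    agg_px <- pick(agg)
    bg_px <- pick(bg)
    coords <- rbind(agg_px, bg_px)
    classes <- c(rep("agglomerate", nrow(agg_px)),
                 rep("background", nrow(bg_px)))
    if (any(salt)) {  # salts are explicitly labelled as background
      salt_px <- pick(salt)
      coords <- rbind(coords, salt_px)
      classes <- c(classes, rep("background", nrow(salt_px)))
    }
    scribble_set(coords[, 1L], coords[, 2L], classes, image_id = image_id)
  })
}

#' Randomly thin ground-truth objects
#'
#' Models the loss of objects to the pre-freezing blotting step as
#' independent random retention of each object with probability `keep_prob`.
#' The class and object maps are updated consistently (halos of removed
#' objects are removed too).
#'
#' @param truth a `ground_truth`.
#' @param keep_prob retention probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a thinned `ground_truth` with contiguously relabelled objects.
#' @export
simulate_blot_subsample <- function(truth, keep_prob, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (keep_prob < 0 || keep_prob > 1) stop("`keep_prob` must be in [0, 1]")
  n <- nrow(truth$object_table)
  if (n == 0L) return(truth)
  with_seed(seed, {
    keep <- stats::runif(n) <= keep_prob
    drop_ids <- which(!keep)
    object_map <- truth$object_map
    class_map <- truth$class_map
    halo_map <- truth$halo_map
    if (length(drop_ids)) {
      gone <- matrix(object_map %in% drop_ids, nrow(object_map), ncol(object_map))
      object_map[gone] <- 0L
      class_map[gone] <- 0L
      if (any(halo_map)) {
        # halos belong to their object: keep only halo pixels within the
        # halo width of a surviving object
        w <- if (is.null(truth$halo_width)) 2L else truth$halo_width
        obj <- object_map > 0L
        halo_map <- halo_map & if (any(obj)) dilate_bin_n(obj, w) else obj
      }
    }
    object_map <- relabel_filter(object_map, 0L)
    tab <- truth$object_table[keep, , drop = FALSE]
    if (nrow(tab)) tab$object_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    structure(
      list(class_map = class_map, object_map = object_map,
           halo_map = halo_map, halo_width = truth$halo_width,
           object_table = tab, pixel_size = truth$pixel_size),
      class = "ground_truth"
    )
  })
}

#' Round-trip a scene spec through YAML
#' @param spec a [scene_spec()].
#' @param path YAML file path.
#' @return `path` invisibly for the writer; a [scene_spec()] for the reader.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scene_spec, x)
}

#' Write a scene (image + ground truth) to a directory
#'
#' Image as 16-bit TIFF, class map as an integer-coded PNG (0 background,
#' 1 agglomerate, 2 salt), object table as CSV with header
#' `object_id,centroid_row,centroid_col,true_feret_nm,true_area_nm2`.
#'
#' @param scene list from [generate_scene()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named character vector of the paths written, invisibly.
#' @export
write_scene <- function(scene, dir, name = scene$image$id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(name, ".tif"))
  p_cls <- file.path(dir, paste0(name, "_classmap.png"))
  p_tab <- file.path(dir, paste0(name, "_objects.csv"))
  write_stem_image(scene$image, p_img, bits = 16L)
  png::writePNG(scene$truth$class_map / 255, p_cls)
  utils::write.csv(scene$truth$object_table, p_tab, row.names = FALSE)
  invisible(c(image = p_img, class_map = p_cls, object_table = p_tab))
}
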