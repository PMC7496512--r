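# Object identification and per-agglomerate measurement.
#
# Coordinate conventions used throughout: matrices are indexed (row, col)
# with the origin at the top-left. For geometric measurements a pixel at
# (r, c) occupies the unit square [r-1, r] x [c-1, c], so its four corners
# sit on the integer lattice. Object extent therefore includes pixel extent:
# a single pixel has a Feret diameter of sqrt(2) px.

AGGLOMERATE_CLASS <- 1L
SALT_CLASS <- 2L

#' Construct a label mask
#'
#' @param labels integer matrix of per-pixel object ids, 0 = background; ids
#'   must be contiguous `1..N`.
#' @param provenance free-text provenance string.
#' @param dropped integer vector of object ids removed by upstream steps
#'   (e.g. emptied by erosion), for the record.
#' @return an object of class `label_mask` with elements `labels`,
#'   `n_objects`, `connectivity` (always 8), `provenance`, `dropped`.
#' @export
label_mask <- function(labels, provenance = "", dropped = integer()) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(labels, 0L)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("object ids must be contiguous 1..N")
  structure(
    list(labels = labels, n_objects = n, connectivity = 8L,
         provenance = provenance, dropped = as.integer(dropped)),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d objects (8-connectivity)%s\n",
              nrow(x$labels), ncol(x$labels), x$n_objects,
              if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped)) else ""))
  invisible(x)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonally touching labels are merged afterwards with a union-find pass.
label_components8 <- function(binary) {
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- matrix(as.integer(EBImage::bwlabel(b)), nrow(b), ncol(b))
  n <- max(lab, 0L)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) with (i+1, j+1), and (i+1, j) with (i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- relab[out[out > 0L]]
  out
}

# drop components smaller than min_size px and relabel contiguously,
# preserving ascending id order
relabel_filter <- function(lab, min_size = 1L) {
  min_size <- max(as.integer(min_size), 1L)
  if (max(lab, 0L) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  out <- lab
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Segment a probability map into labelled objects
#'
#' Thresholds the per-pixel agglomerate probability at `threshold`, labels
#' 8-connected components of the super-threshold set, removes components
#' smaller than `min_size` pixels and relabels ids contiguously.
#'
#' @param prob a [probability_map()] or a numeric matrix in `[0, 1]`.
#' @param threshold decision threshold in (0, 1); pixels with `p >= threshold`
#'   are foreground. Default 0.5, the symmetric two-class decision.
#' @param min_size minimum object area in pixels; default 4 (a 2x2 object).
#' @return a [label_mask()].
#' @examples
#' p <- matrix(0, 32, 32); p[5:14, 5:14] <- 1
#' segment(p)
#' @export
segment <- function(prob, threshold = 0.5, min_size = 4L) {
  m <- if (inherits(prob, "probability_map")) prob$prob else as_pixels(prob)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)")
  lab <- label_components8(m >= threshold)
  lab <- relabel_filter(lab, min_size)
  label_mask(lab, provenance = sprintf("segment(threshold=%g, min_size=%d)",
                                       threshold, as.integer(min_size)))
}

#' Erode labelled objects to strip focal halos
#'
#' Applies `n_px` rounds of binary morphological erosion (3x3 box structuring
#' element) to each object independently. Because labels are already
#' spatially separated, per-object erosion cannot create new touching
#' objects. Objects emptied by erosion are dropped (their ids are recorded in
#' the mask's `dropped` field) and remaining ids are relabelled contiguously.
#' This is the halo-correction step: bright focal halos extend segmented
#' outlines beyond the true object edge, and shrinking every object by one
#' pixel removes most of that bias.
#'
#' @param mask a [label_mask()].
#' @param n_px number of 1-px erosion rounds; default 1; 0 is the identity.
#' @return a [label_mask()].
#' @export
erode_objects <- function(mask, n_px = 1L) {
  stopifnot(inherits(mask, "label_mask"))
  n_px <- as.integer(n_px)
  if (n_px < 0L) stop("`n_px` must be >= 0")
  if (n_px == 0L || mask$n_objects == 0L) return(mask)
  lab <- mask$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  dropped <- integer()
  for (id in seq_len(mask$n_objects)) {
    b <- lab == id
    for (k in seq_len(n_px)) b <- erode_bin(b)
    if (!any(b)) dropped <- c(dropped, id) else out[b] <- id
  }
  out <- relabel_filter(out, 0L)
  label_mask(out,
             provenance = paste0(mask$provenance,
                                 sprintf(" | erode_objects(n_px=%d)", n_px)),
             dropped = dropped)
}

# pixel set (n x 2 matrix of row, col) -> unique integer corner points
pixel_corners <- function(px) {
  r <- px[, 1L]; c <- px[, 2L]
  unique(rbind(cbind(r - 1, c - 1), cbind(r - 1, c),
               cbind(r, c - 1), cbind(r, c)))
}

# counter-clockwise convex hull vertices (chull returns clockwise order)
hull_ccw <- function(pts) {
  h <- grDevices::chull(pts)
  pts[rev(h), , drop = FALSE]
}

#' Maximum Feret (caliper) diameter of an object
#'
#' The Feret diameter is the maximum edge-to-edge caliper distance over all
#' orientations. It is computed by rotating calipers over the convex hull of
#' the corner points of the object's pixels (each pixel contributes its unit
#' square), times the physical pixel size. Because the corner points lie on
#' the integer lattice, the result equals the brute-force maximum over all
#' corner pairs exactly.
#'
#' @param pixels an n x 2 matrix of (row, col) pixel indices, or a logical
#'   matrix mask.
#' @param pixel_size nm per pixel; default 1 returns the diameter in px.
#' @return Feret diameter in nm (or px for `pixel_size = 1`).
#' @examples
#' feret_diameter(cbind(1, 1))              # single pixel: sqrt(2)
#' px <- as.matrix(expand.grid(1:3, 1:4))
#' feret_diameter(px)                       # 3x4 rectangle: 5
#' @export
feret_diameter <- function(pixels, pixel_size = 1) {
  if (is.logical(pixels)) pixels <- which(pixels, arr.ind = TRUE)
  if (!is.matrix(pixels) || nrow(pixels) == 0L)
    stop("empty pixel set has no Feret diameter")
  pts <- pixel_corners(pixels)
  H <- hull_ccw(pts)
  m <- nrow(H)
  d2 <- function(i, j) sum((H[i, ] - H[j, ])^2)
  if (m == 1L) return(0)
  if (m == 2L) return(sqrt(d2(1L, 2L)) * pixel_size)
  cross_dir <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]
  best <- 0
  j <- 2L
  for (i in seq_len(m)) {
    ni <- i %% m + 1L
    repeat {
      nj <- j %% m + 1L
      if (cross_dir(H[ni, ] - H[i, ], H[nj, ] - H[j, ]) > 0) j <- nj else break
    }
    best <- max(best, d2(i, j), d2(ni, j))
  }
  sqrt(best) * pixel_size
}

# isotropy-corrected diagonal step weight: with straight steps weighted 1,
# this value makes the boundary-walk length of a digitized circle unbiased
# (average over edge orientations), while axis-aligned rectangles stay exact.
DIAG_WEIGHT <- 1 + (pi / 4 - sqrt(2) / 2) / (1 - sqrt(2) / 2)

# Moore-neighbour boundary tracing of one 8-connected object with Jacob's
# stopping criterion (terminate on re-entering the start pixel from the
# start direction). Returns the ordered, closed sequence of boundary pixel
# coordinates; thin arms are traversed on both sides, as a boundary walk
# should. Written here because generic contour tracers in the installed
# stack mis-trace diagonally connected shapes.
trace_boundary <- function(b) {
  px <- which(b, arr.ind = TRUE)
  if (nrow(px) == 1L) return(px)
  start <- px[order(px[, 1L], px[, 2L])[1L], ]
  # 8 neighbour offsets in clockwise order starting West
  offs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2L, byrow = TRUE)
  nr <- nrow(b); nc <- ncol(b)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && b[r, c]
  cur <- start
  back <- 1L  # start is topmost-leftmost, so its West neighbour is background
  second <- NULL
  cap <- 4L * nrow(px) + 8L
  contour <- matrix(0L, cap, 2L)
  contour[1L, ] <- cur
  n_pts <- 1L
  repeat {
    new_cur <- NULL
    for (k in seq_len(8L)) {
      idx <- (back - 1L + k - 1L) %% 8L + 1L
      r <- cur[1L] + offs[idx, 1L]; c <- cur[2L] + offs[idx, 2L]
      if (fg(r, c)) {
        new_cur <- c(r, c)
        # new backtrack: the neighbour scanned just before the hit, as seen
        # from the new pixel (it is always an 8-neighbour of the new pixel)
        prev_idx <- (idx - 2L) %% 8L + 1L
        d <- c(cur[1L] + offs[prev_idx, 1L] - r, cur[2L] + offs[prev_idx, 2L] - c)
        back <- which(offs[, 1L] == d[1L] & offs[, 2L] == d[2L])
        break
      }
    }
    if (is.null(new_cur)) return(contour[seq_len(n_pts), , drop = FALSE])
    # the transition is a deterministic function of the ordered pixel pair,
    # so the walk closes exactly when (start -> second) is about to repeat
    if (!is.null(second) && all(cur == start) && all(new_cur == second))
      return(contour[seq_len(n_pts - 1L), , drop = FALSE])
    if (is.null(second)) second <- new_cur
    n_pts <- n_pts + 1L
    if (n_pts > cap) return(contour[seq_len(cap), , drop = FALSE])
    contour[n_pts, ] <- new_cur
    cur <- new_cur
  }
}

# Perimeter estimate in px: closed Moore boundary walk through pixel
# centres, steps weighted 1 (orthogonal) / DIAG_WEIGHT (diagonal), plus pi
# for the half-pixel outward offset from pixel centres to the true object
# boundary (offsetting a simple closed curve by r adds 2*pi*r). A single
# pixel falls back to its unit-square crack perimeter 4.
perimeter_px <- function(binary) {
  npix <- sum(binary)
  if (npix == 0L) stop("empty object has no perimeter")
  if (npix == 1L) return(4)
  oc <- trace_boundary(binary)
  if (nrow(oc) < 2L) return(4)
  p <- rbind(oc, oc[1L, , drop = FALSE])
  d <- abs(diff(p))
  steps <- d[, 1L] + d[, 2L]
  walk <- sum(ifelse(steps == 2L, DIAG_WEIGHT, 1)[steps > 0L])
  walk + pi
}

#' Size and shape descriptors of one object
#'
#' Computes the standard per-object attributes in physical units:
#' area (pixel count x `pixel_size`^2), perimeter (weighted boundary-walk
#' estimator), form factor `4*pi*area/perimeter^2` (1 for a perfect circle),
#' major/minor axis lengths of the ellipse with matching second central
#' moments (pixel-center moments plus the 1/12 unit-square term), equivalent
#' circular diameter `sqrt(4*area/pi)`, Feret diameter and centroid.
#'
#' @inheritParams feret_diameter
#' @return a one-row `data.frame` with columns `feret_nm`, `area_nm2`,
#'   `perimeter_nm`, `form_factor`, `major_nm`, `minor_nm`, `eqdiam_nm`,
#'   `centroid_row`, `centroid_col` (centroid in px, 0-based pixel-centre
#'   coordinates).
#' @export
shape_descriptors <- function(pixels, pixel_size = 1) {
  if (is.logical(pixels)) pixels <- which(pixels, arr.ind = TRUE)
  if (!is.matrix(pixels) || nrow(pixels) == 0L)
    stop("empty pixel set has no shape")
  n <- nrow(pixels)
  rr <- pixels[, 1L] - 0.5  # pixel-centre coordinates, 0-based frame
  cc <- pixels[, 2L] - 0.5
  area_px <- n
  # local raster for boundary tracing
  r0 <- min(pixels[, 1L]); c0 <- min(pixels[, 2L])
  b <- matrix(FALSE, max(pixels[, 1L]) - r0 + 3L, max(pixels[, 2L]) - c0 + 3L)
  b[cbind(pixels[, 1L] - r0 + 2L, pixels[, 2L] - c0 + 2L)] <- TRUE
  per_px <- perimeter_px(b)
  # second central moments with the per-pixel 1/12 unit-square variance
  mu_rr <- sum((rr - mean(rr))^2) / n + 1 / 12
  mu_cc <- sum((cc - mean(cc))^2) / n + 1 / 12
  mu_rc <- sum((rr - mean(rr)) * (cc - mean(cc))) / n
  ev <- sym_eigen2(mu_rr, mu_cc, mu_rc)
  major_px <- 4 * sqrt(max(ev$hi, 0))
  minor_px <- 4 * sqrt(max(ev$lo, 0))
  area <- area_px * pixel_size^2
  per <- per_px * pixel_size
  data.frame(
    feret_nm = feret_diameter(pixels, pixel_size),
    area_nm2 = area,
    perimeter_nm = per,
    form_factor = 4 * pi * area / per^2,
    major_nm = major_px * pixel_size,
    minor_nm = minor_px * pixel_size,
    eqdiam_nm = sqrt(4 * area / pi),
    centroid_row = mean(rr),
    centroid_col = mean(cc)
  )
}

#' Measure every object in a label mask
#'
#' @param mask a [label_mask()].
#' @param img the [stem_image()] the mask was derived from; supplies the
#'   physical pixel size and the image identifier. Shapes must match.
#' @return a `data.frame` with one row per object: `image_id`, `object_id`,
#'   then the [shape_descriptors()] columns.
#' @export
measure_all <- function(mask, img) {
  stopifnot(inherits(mask, "label_mask"))
  if (!inherits(img, "stem_image")) stop("`img` must be a stem_image")
  if (!identical(dim(mask$labels), dim(img$pixels)))
    stop("mask and image shapes differ")
  if (mask$n_objects == 0L) {
    return(data.frame(image_id = character(), object_id = integer(),
                      feret_nm = numeric(), area_nm2 = numeric(),
                      perimeter_nm = numeric(), form_factor = numeric(),
                      major_nm = numeric(), minor_nm = numeric(),
                      eqdiam_nm = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  }
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  ids <- mask$labels[mask$labels > 0L]
  rows <- lapply(seq_len(mask$n_objects), function(id) {
    rec <- shape_descriptors(idx[ids == id, , drop = FALSE], img$pixel_size)
    cbind(data.frame(image_id = img$id, object_id = id), rec)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a measurement table to CSV
#'
#' Column layout: `image_id,object_id,feret_nm,area_nm2,perimeter_nm,
#' form_factor,major_nm,minor_nm,eqdiam_nm,centroid_row,centroid_col`.
#'
#' @param records measurement `data.frame` from [measure_all()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#' @param path CSV path.
#' @return measurement `data.frame`.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a label mask as a 16-bit TIFF
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
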