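# Illumination correction. Dark-field STEM shading is gain-like (detector
# and beam-current variation multiply the signal), so the background field is
# estimated and divided out rather than subtracted.

#' Estimate the smooth illumination field of an image
#'
#' Estimates the slowly varying multiplicative background of a dark-field
#' image while ignoring bright objects. Bright pixels are down-weighted by
#' rank (weight zero above a robust threshold), and the field is then a
#' locally weighted plane fit: at every pixel a first-order polynomial is fit
#' to the surviving pixels under a Gaussian window of scale
#' `smoothing_scale`, via closed-form normal equations assembled from
#' separable convolutions. The local plane fit reproduces linear ramps
#' exactly, including at image borders where plain smoothing is biased.
#'
#' @param img a [stem_image()] or numeric matrix.
#' @param smoothing_scale Gaussian window scale in px; must be >= 5 and
#'   smaller than the image. Default `ncol/8`.
#' @param bright_quantile rank threshold above which pixels get zero weight
#'   in the fit (objects must not inflate the field); default 0.75.
#' @return a [stem_image()] holding the strictly positive field, same shape
#'   as the input.
#' @export
estimate_illumination <- function(img, smoothing_scale = NULL,
                                  bright_quantile = 0.75) {
  m <- as_pixels(img)
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(smoothing_scale)) smoothing_scale <- nc / 8
  if (smoothing_scale < 5) stop("`smoothing_scale` must be >= 5 px")
  if (smoothing_scale >= min(nr, nc))
    stop("`smoothing_scale` exceeds the image size")
  # coordinates centred mid-image, unit px
  x <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  y <- matrix(rep(seq_len(nc) - (nc + 1) / 2, each = nr), nr, nc)
  k <- gauss_kernel(smoothing_scale,
                    radius = min(as.integer(ceiling(2.5 * smoothing_scale)),
                                 min(nr, nc) - 1L))
  sm <- function(z) filter_sep(z, k, k)

  # weighted local first-order fit: solve the 3x3 normal system per pixel
  local_plane_fit <- function(w) {
    S00 <- sm(w);        S10 <- sm(w * x);     S01 <- sm(w * y)
    S20 <- sm(w * x^2);  S11 <- sm(w * x * y); S02 <- sm(w * y^2)
    T0 <- sm(w * m);     T1 <- sm(w * x * m);  T2 <- sm(w * y * m)
    # centre the moments at each pixel: shift x -> x - x0, y -> y - y0
    # (x0, y0 are the pixel's own coordinates)
    A00 <- S00
    A10 <- S10 - x * S00
    A01 <- S01 - y * S00
    A20 <- S20 - 2 * x * S10 + x^2 * S00
    A11 <- S11 - x * S01 - y * S10 + x * y * S00
    A02 <- S02 - 2 * y * S01 + y^2 * S00
    B0 <- T0
    B1 <- T1 - x * T0
    B2 <- T2 - y * T0
    # ridge for numerically empty windows
    eps <- 1e-9
    A20 <- A20 + eps; A02 <- A02 + eps; A00 <- A00 + eps
    det3 <- A00 * (A20 * A02 - A11^2) - A10 * (A10 * A02 - A11 * A01) +
      A01 * (A10 * A11 - A20 * A01)
    det3[abs(det3) < 1e-12] <- 1e-12
    # Cramer's rule for the intercept (the fitted value at the window centre)
    num <- B0 * (A20 * A02 - A11^2) - A10 * (B1 * A02 - A11 * B2) +
      A01 * (B1 * A11 - A20 * B2)
    field <- num / det3
    fallback <- stats::median(m[w > 0])
    field[!is.finite(field) | field <= 0] <- fallback
    pmax(field, 0.05 * fallback)
  }

  # pass 1: global rank mask. A fixed quantile cut bites into background
  # noise wherever the background approaches the cut, which biases the fit;
  # pass 2 therefore re-masks relative to the fitted field (keep pixels
  # within ~4 robust s.d. above it) and refits.
  thr <- stats::quantile(m, bright_quantile, names = FALSE)
  w <- matrix(as.numeric(m <= thr), nr, nc)
  field <- local_plane_fit(w)
  rel_res <- (m - field) / field
  s_rob <- stats::mad(rel_res[w > 0])
  if (is.finite(s_rob) && s_rob > 0) {
    w2 <- matrix(as.numeric(rel_res <= 4 * s_rob), nr, nc)
    if (mean(w2) > 0.1) field <- local_plane_fit(w2)
  }
  out_id <- if (inherits(img, "stem_image")) paste0(img$id, "_illum") else "illum"
  ps <- if (inherits(img, "stem_image")) img$pixel_size else 1
  stem_image(field, ps, id = out_id)
}

#' Divide out an illumination field
#'
#' Computes `pixels / field`, rescaled so the median intensity of the output
#' equals the median intensity of the input (the background level is
#' preserved rather than normalized to 1).
#'
#' @param img a [stem_image()] or matrix.
#' @param field the field from [estimate_illumination()]; same shape,
#'   strictly positive.
#' @return a corrected [stem_image()].
#' @export
correct_illumination <- function(img, field) {
  m <- as_pixels(img)
  f <- as_pixels(field)
  if (!identical(dim(m), dim(f))) stop("image and field shapes differ")
  if (any(f <= 0)) stop("illumination field must be strictly positive")
  ratio <- m / f
  med_ratio <- stats::median(ratio)
  scale <- if (med_ratio > 0) stats::median(m) / med_ratio else 1
  out <- ratio * scale
  ps <- if (inherits(img, "stem_image")) img$pixel_size else 1
  out_id <- if (inherits(img, "stem_image")) img$id else "image"
  stem_image(out, ps, id = out_id)
}
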