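# Fixture builders shared across the suite. Everything is generated in code;
# no image files ship with the package.

# rasterized disk of radius r px centred in an (2r+5)^2 canvas
make_disk_mask <- function(r, pad = 5L) {
  n <- 2L * r + pad
  cc <- (n + 1) / 2
  x <- (seq_len(n) - cc)^2
  outer(x, x, `+`) <= r^2
}

# solid s x s square in an (s+2)^2 canvas
make_square_mask <- function(s) {
  m <- matrix(FALSE, s + 2L, s + 2L)
  m[2:(s + 1L), 2:(s + 1L)] <- TRUE
  m
}

# random connected 8-connected blob: union of a random walk of pixels
make_random_blob <- function(n_px, seed) {
  withr_seed(seed, {
    p <- c(15L, 15L)
    px <- matrix(p, 1L, 2L)
    while (nrow(unique(px)) < n_px) {
      p <- pmax(pmin(p + sample(c(-1L, 0L, 1L), 2L, replace = TRUE), 28L), 2L)
      px <- rbind(px, p)
    }
    unique(px)
  })
}

# local seeded evaluation that restores the RNG stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force Feret oracle: O(n^2) max over all pixel-corner pairs
brute_force_feret <- function(px, pixel_size = 1) {
  r <- px[, 1L]; c <- px[, 2L]
  pts <- unique(rbind(cbind(r - 1, c - 1), cbind(r - 1, c),
                      cbind(r, c - 1), cbind(r, c)))
  sqrt(max(dist(pts)^2)) * pixel_size
}

# 4-connected component labelling oracle (contrasts with the package's
# 8-connectivity); EBImage::bwlabel is 4-connected
label_components4 <- function(binary) {
  m <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
}

cv <- function(x) stats::sd(x) / mean(x)

# small stock scene for unit tests (fast); acceptance tests use the package
# defaults instead
small_scene_spec <- function(seed, n_agglomerates = 5L, n_salt = 0L, ...) {
  scene_spec(image_shape = c(128L, 128L), n_agglomerates = n_agglomerates,
             diameter_law = list(type = "lognormal", median_nm = 450, sigma = 0.3),
             n_salt = n_salt, seed = seed, ...)
}
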