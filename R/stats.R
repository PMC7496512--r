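# Distribution statistics over agglomerate Feret diameters. Three weightings
# of the same diameters are reported: number (each object counts once),
# volume (objects weighted by their spherical volume, d^3) and simulated
# light-scattering intensity (d^6 — the weighting dynamic light scattering
# applies, which is why DLS distributions of polydisperse samples sit far
# above the number distribution).

#' Number-weighted summary of a diameter sample
#'
#' Arithmetic mean, standard error of the mean (`sd/sqrt(n)`), median and
#' interquartile range of the Feret diameters.
#'
#' @param diameters positive diameters in nm, `n >= 1`.
#' @return an object of class `size_distribution`: list with `diameters`,
#'   `weighting`, `n`, `mean`, `sem`, `median`, `iqr`.
#' @examples
#' number_summary(c(100, 200))
#' @export
number_summary <- function(diameters) {
  check_diameters(diameters)
  n <- length(diameters)
  structure(
    list(diameters = diameters, weighting = "number", n = n,
         mean = mean(diameters),
         sem = if (n > 1L) stats::sd(diameters) / sqrt(n) else 0,
         median = stats::median(diameters),
         iqr = stats::IQR(diameters)),
    class = "size_distribution"
  )
}

check_diameters <- function(d) {
  if (length(d) == 0L) stop("empty diameter sample")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameters must be finite and strictly positive")
  invisible(d)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %s-weighted, n = %d: mean %.4g nm (SEM %.3g), median %.4g, IQR %.4g\n",
              x$weighting, x$n, x$mean, x$sem, x$median, x$iqr))
  invisible(x)
}

#' Volume-averaged diameter
#'
#' The diameter of the sphere whose volume equals the mean per-object
#' spherical volume: each object is treated as a sphere of diameter equal to
#' its Feret diameter, the volumes `pi/6 d^3` are averaged, and the result is
#' converted back to a diameter — the constant cancels, leaving
#' `(mean(d^3))^(1/3)`. By the power-mean inequality this is always >= the
#' number mean. With `mode = "weighted_mean"` the alternative reading
#' `sum(d^4)/sum(d^3)` (the volume-weighted mean diameter) is returned
#' instead; the cube-root-of-mean-cube form is the default.
#'
#' @param diameters positive diameters in nm.
#' @param mode `"mean_volume"` (default) or `"weighted_mean"`.
#' @return diameter in nm.
#' @examples
#' volume_average_diameter(c(100, 200))  # 165.1
#' @export
volume_average_diameter <- function(diameters, mode = c("mean_volume", "weighted_mean")) {
  check_diameters(diameters)
  mode <- match.arg(mode)
  if (mode == "mean_volume") mean(diameters^3)^(1 / 3)
  else sum(diameters^4) / sum(diameters^3)
}

#' Simulated light-scattering (intensity-weighted) summary
#'
#' Weights every diameter by `d^6`, the scattering-intensity weighting of
#' dynamic light scattering for Rayleigh-regime particles, and reports the
#' weighted mean plus weighted median/IQR. On a sample with a few large
#' objects among many small ones the weighted mean is dominated by the large
#' ones — the mechanism behind the EM-versus-DLS size discrepancy.
#'
#' @param diameters positive diameters in nm.
#' @return a `size_distribution` with `weighting = "intensity"`; `mean` is
#'   `sum(d^7)/sum(d^6)`.
#' @export
intensity_weighted_summary <- function(diameters) {
  check_diameters(diameters)
  w <- diameters^6
  w <- w / sum(w)
  m <- sum(diameters * w)
  # weighted quantiles (type-1 step interpolation of the weighted ECDF)
  o <- order(diameters)
  dw <- diameters[o]; ww <- cumsum(w[o])
  wq <- function(p) dw[which(ww >= p - 1e-12)[1L]]
  structure(
    list(diameters = diameters, weighting = "intensity",
         n = length(diameters), mean = m,
         sem = sqrt(sum(w * (diameters - m)^2) / length(diameters)),
         median = wq(0.5), iqr = wq(0.75) - wq(0.25)),
    class = "size_distribution"
  )
}

#' Welch two-sample comparison of diameter distributions
#'
#' Unpaired two-sample t-test in the unequal-variance (Welch) form:
#' `t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value. Used to
#' ask whether machine and manual size measurements differ. Degenerate
#' zero-variance inputs are defined explicitly: equal constant samples give
#' `t = 0, p = 1`; unequal constants give `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric diameter samples, each `n >= 2`.
#' @return an object of class `comparison_result`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_summaries`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  gs <- data.frame(group = c("a", "b"), n = c(length(a), length(b)),
                   mean = c(mean(a), mean(b)), sd = sqrt(c(va, vb)))
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t_statistic = 0, degrees_of_freedom = NA_real_, p_value = 1)
    } else {
      res <- list(t_statistic = sign(mean(a) - mean(b)) * Inf,
                  degrees_of_freedom = NA_real_, p_value = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(res, list(group_summaries = gs)), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> Welch t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Histogram of a size distribution
#'
#' Fixed-width half-open bins `[lo, hi)` anchored at multiples of
#' `bin_width`; a value on a bin edge falls in the upper bin. Counts conserve
#' `n` exactly (number weighting) or total weight (intensity weighting).
#'
#' @param dist a `size_distribution` (or a bare numeric diameter vector).
#' @param bin_width bin width in nm, > 0.
#' @return `data.frame` with `bin_lo`, `bin_hi`, `count` (and `weight` for
#'   intensity weighting).
#' @export
size_histogram <- function(dist, bin_width) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  d <- if (inherits(dist, "size_distribution")) dist$diameters else dist
  check_diameters(d)
  weighting <- if (inherits(dist, "size_distribution")) dist$weighting else "number"
  lo <- floor(min(d) / bin_width)
  hi <- floor(max(d) / bin_width)
  breaks <- seq(lo, hi + 1L) * bin_width
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L])
  out$count <- tabulate(idx, nbins = nrow(out))
  if (weighting == "intensity") {
    w <- d^6 / sum(d^6)
    out$weight <- vapply(seq_len(nrow(out)),
                         function(i) sum(w[idx == i]), numeric(1))
  }
  out
}

#' Summarize a measurement table into the standard group summary row
#'
#' @param records measurement `data.frame` from [measure_all()] (uses
#'   `feret_nm`).
#' @param group group label.
#' @return one-row `data.frame`: `group,n,mean_nm,sem_nm,median_nm,
#'   vol_avg_nm,intensity_avg_nm`.
#' @export
summarize_measurements <- function(records, group = "sample") {
  d <- records$feret_nm
  ns <- number_summary(d)
  data.frame(group = group, n = ns$n, mean_nm = ns$mean, sem_nm = ns$sem,
             median_nm = ns$median,
             vol_avg_nm = volume_average_diameter(d),
             intensity_avg_nm = intensity_weighted_summary(d)$mean)
}
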