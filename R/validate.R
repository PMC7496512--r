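# Agreement between two segmentations of the same field: object counts,
# per-object Jaccard (IoU) agreement via greedy matching, and the
# best-possible global-threshold baseline that machine-learning segmentation
# is compared against on salt-bearing images.

#' Match objects between a reference and a test segmentation
#'
#' Computes the intersection-over-union of every overlapping (reference,
#' test) object pair and matches pairs greedily in descending IoU order
#' (ties broken by reference id then test id), so each object appears in at
#' most one pair. Pairs below `iou_min` stay unmatched.
#'
#' @param ref,test [label_mask()]s (or label matrices) of identical shape.
#' @param iou_min minimum IoU for a valid match, in `[0, 1]`; default 0.2.
#' @return an object of class `match_table`: list with `pairs` (`data.frame`
#'   `ref_id`, `test_id`, `intersection_px`, `union_px`, `iou`),
#'   `unmatched_ref`, `unmatched_test`, `n_ref`, `n_test`.
#' @export
match_objects <- function(ref, test, iou_min = 0.2) {
  r <- if (inherits(ref, "label_mask")) ref$labels else ref
  t_ <- if (inherits(test, "label_mask")) test$labels else test
  if (!identical(dim(r), dim(t_))) stop("mask shapes differ")
  n_ref <- max(r, 0L); n_test <- max(t_, 0L)
  area_ref <- tabulate(r[r > 0L], nbins = n_ref)
  area_test <- tabulate(t_[t_ > 0L], nbins = n_test)
  both <- r > 0L & t_ > 0L
  pairs <- data.frame(ref_id = integer(), test_id = integer(),
                      intersection_px = integer(), union_px = integer(),
                      iou = numeric())
  if (any(both)) {
    key <- paste(r[both], t_[both])
    tab <- table(key)
    ids <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    cand <- data.frame(ref_id = as.integer(ids[, 1L]),
                       test_id = as.integer(ids[, 2L]),
                       intersection_px = as.integer(tab))
    cand$union_px <- area_ref[cand$ref_id] + area_test[cand$test_id] -
      cand$intersection_px
    cand$iou <- cand$intersection_px / cand$union_px
    cand <- cand[cand$iou >= iou_min, , drop = FALSE]
    cand <- cand[order(-cand$iou, cand$ref_id, cand$test_id), , drop = FALSE]
    used_ref <- logical(n_ref); used_test <- logical(n_test)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ri <- cand$ref_id[i]; ti <- cand$test_id[i]
      if (!used_ref[ri] && !used_test[ti]) {
        keep[i] <- TRUE
        used_ref[ri] <- TRUE
        used_test[ti] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(
    list(pairs = pairs,
         unmatched_ref = setdiff(seq_len(n_ref), pairs$ref_id),
         unmatched_test = setdiff(seq_len(n_test), pairs$test_id),
         n_ref = n_ref, n_test = n_test),
    class = "match_table"
  )
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d/%d ref and %d/%d test objects matched\n",
              nrow(x$pairs), x$n_ref, nrow(x$pairs), x$n_test))
  invisible(x)
}

#' Summarize segmentation agreement
#'
#' Mean and s.d. of the matched per-object IoUs, number of objects scored,
#' and the object-count ratio `n_test / n_ref`.
#'
#' @param matches a `match_table` from [match_objects()].
#' @return list with `mean_iou`, `sd_iou` (NA when fewer than 2 matches),
#'   `n_scored`, `count_ratio` (`Inf` when the reference is empty and the
#'   test is not; `NaN` when both are empty), `n_ref`, `n_test`,
#'   `n_unmatched_ref`, `n_unmatched_test`.
#' @export
agreement_summary <- function(matches) {
  stopifnot(inherits(matches, "match_table"))
  n <- nrow(matches$pairs)
  list(
    mean_iou = if (n > 0L) mean(matches$pairs$iou) else NA_real_,
    sd_iou = if (n > 1L) stats::sd(matches$pairs$iou) else NA_real_,
    n_scored = n,
    count_ratio = matches$n_test / matches$n_ref,
    n_ref = matches$n_ref, n_test = matches$n_test,
    n_unmatched_ref = length(matches$unmatched_ref),
    n_unmatched_test = length(matches$unmatched_test)
  )
}

#' Object-level precision of a test segmentation against a reference
#'
#' Fraction of test objects matched to a reference object at `iou_min` or
#' better — the operating statistic for the salt-rejection comparison (false
#' salt detections lower it).
#'
#' @inheritParams match_objects
#' @return precision in `[0, 1]`; `NaN` for an empty test mask.
#' @export
object_precision <- function(ref, test, iou_min = 0.2) {
  m <- match_objects(ref, test, iou_min)
  nrow(m$pairs) / m$n_test
}

#' Best-case global-threshold segmentation baseline
#'
#' The classical alternative to learned pixel classification: a single
#' global intensity threshold. To make the comparison as hard as possible
#' for the learned classifier, the threshold is chosen by exhaustive sweep
#' maximizing the pixel F1 score against the ground-truth agglomerate mask —
#' an oracle upper bound no real threshold picker could beat. Components are
#' then extracted exactly as in [segment()].
#'
#' @param img a [stem_image()] or matrix.
#' @param truth_mask logical (or 0/1) matrix of true agglomerate pixels.
#' @param n_thresholds number of candidate thresholds swept over the image's
#'   intensity range.
#' @param min_size minimum object size in px, as in [segment()].
#' @return list with `mask` (a [label_mask()]), `threshold`, `f1`.
#' @export
threshold_baseline <- function(img, truth_mask, n_thresholds = 128L,
                               min_size = 4L) {
  m <- as_pixels(img)
  tr <- truth_mask != 0
  if (!identical(dim(m), dim(tr))) stop("image and truth shapes differ")
  qs <- stats::quantile(m, probs = seq(0.01, 0.999, length.out = n_thresholds),
                        names = FALSE)
  qs <- unique(qs)
  n_true <- sum(tr)
  if (n_true == 0L) {
    # nothing to detect: the optimal operating point is an empty mask
    empty <- label_mask(matrix(0L, nrow(m), ncol(m)),
                        provenance = "threshold_baseline(empty truth)")
    return(list(mask = empty, threshold = Inf, f1 = 0))
  }
  best_f1 <- -1; best_thr <- qs[1L]
  for (thr in qs) {
    pred <- m >= thr
    tp <- sum(pred & tr)
    fp <- sum(pred) - tp
    fn <- n_true - tp
    f1 <- if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1) { best_f1 <- f1; best_thr <- thr }
  }
  lab <- relabel_filter(label_components8(m >= best_thr), min_size)
  list(mask = label_mask(lab, provenance = sprintf("threshold_baseline(%.5g)", best_thr)),
       threshold = best_thr, f1 = best_f1)
}

#' Write a validation report
#'
#' Emits the agreement summary as a one-row CSV plus a short human-readable
#' text log listing unmatched objects.
#'
#' @param matches a `match_table`.
#' @param dir output directory.
#' @param name file stem.
#' @return named vector of paths, invisibly.
#' @export
write_validation_report <- function(matches, dir, name = "validation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- agreement_summary(matches)
  p_csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(s), p_csv, row.names = FALSE)
  p_txt <- file.path(dir, paste0(name, ".txt"))
  lines <- c(
    sprintf("objects: ref %d, test %d (ratio %.3f)", s$n_ref, s$n_test, s$count_ratio),
    sprintf("matched: %d, mean IoU %.3f +/- %.3f", s$n_scored,
            s$mean_iou, if (is.na(s$sd_iou)) 0 else s$sd_iou),
    sprintf("unmatched ref: %s", paste(matches$unmatched_ref, collapse = " ")),
    sprintf("unmatched test: %s", paste(matches$unmatched_test, collapse = " "))
  )
  writeLines(lines, p_txt)
  invisible(c(csv = p_csv, log = p_txt))
}
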