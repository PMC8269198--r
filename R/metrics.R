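#' Intersection over Union (Jaccard index) of two binary masks
#'
#' IoU = |P ∩ T| / |P ∪ T| for a predicted foreground mask `P` against a
#' ground-truth mask `T`. By convention two empty masks score 1 (a perfect
#' background prediction is not penalized) and exactly one empty mask scores 0.
#'
#' @param predicted,truth [binary_mask()] objects (or logical matrices) of
#'   identical shape. Label masks are binarized first.
#' @return A fraction in \[0, 1\].
#' @seealso [dice()], [sbd()]
#' @export
iou <- function(predicted, truth) {
  p <- as_fg(predicted); t <- as_fg(truth)
  check_same_shape(p, t)
  inter <- sum(p & t)
  uni <- sum(p | t)
  if (uni == 0L) return(1)
  inter / uni
}

#' Dice score of two binary masks
#'
#' Dice = 2|P ∩ T| / (|P| + |T|); a monotone transform of IoU
#' (`dice = 2 iou / (1 + iou)`) that penalizes the worst cases less.
#' Empty-mask conventions match [iou()].
#'
#' @inheritParams iou
#' @return A fraction in \[0, 1\].
#' @export
dice <- function(predicted, truth) {
  p <- as_fg(predicted); t <- as_fg(truth)
  check_same_shape(p, t)
  tot <- sum(p) + sum(t)
  if (tot == 0L) return(1)
  2 * sum(p & t) / tot
}

as_fg <- function(m) {
  if (inherits(m, "label_mask")) return(unclass(m) > 0L)
  if (is.logical(m)) return(unclass(m))
  unclass(m) != 0
}

#' Best Dice of one labeling against another
#'
#' For each instance of `a`, find the instance of `b` with the highest
#' instance-wise Dice (computed on pixel sets), and average these maxima over
#' the instances of `a`. Best Dice is not commutative: `best_dice(a, b)` and
#' `best_dice(b, a)` generally differ, which [sbd()] resolves by taking the
#' minimum.
#'
#' @param a,b [label_mask()] objects of identical shape. `a` must contain at
#'   least one instance; if `b` has none the score is 0.
#' @return A fraction in \[0, 1\].
#' @export
best_dice <- function(a, b) {
  check_same_shape(a, b)
  sa <- instance_pixel_sets(a)
  if (!length(sa)) stop("best_dice: first mask has zero instances (mean undefined)")
  sb <- instance_pixel_sets(b)
  if (!length(sb)) return(0)
  # Restrict to b-instances that actually intersect each a-instance via the
  # label values of b under a's pixels; non-intersecting pairs have dice 0.
  bpix <- unclass(b)
  sizes_b <- lengths(sb)
  names(sizes_b) <- names(sb)
  vals <- vapply(sa, function(pa) {
    hits <- bpix[pa]
    hits <- hits[hits > 0L]
    if (!length(hits)) return(0)
    tab <- table(hits)
    ids <- names(tab)
    max(2 * as.numeric(tab) / (length(pa) + sizes_b[ids]))
  }, numeric(1))
  mean(vals)
}

#' Symmetric Best Dice (SBD)
#'
#' `sbd(a, b) = min(best_dice(a, b), best_dice(b, a))`: the instance-separation
#' quality metric. Symmetric by construction and equal to 1 exactly when the
#' two masks induce identical pixel partitions. If both masks are empty of
#' instances the score is 1; if exactly one is empty, 0.
#'
#' @inheritParams best_dice
#' @return A fraction in \[0, 1\].
#' @export
sbd <- function(a, b) {
  check_same_shape(a, b)
  na <- n_instances(a); nb <- n_instances(b)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  min(best_dice(a, b), best_dice(b, a))
}

#' Evaluate a dataset of predicted/truth mask pairs
#'
#' Computes per-image IoU (on the binarized foregrounds, so semantic and
#' instance strategies share one IoU definition) and SBD, then aggregates to
#' dataset mean and per-image sample standard deviation, reported on the
#' percent scale.
#'
#' @param pairs A list of `list(predicted =, truth =)` pairs of
#'   [label_mask()]s, optionally with an `id` element per pair.
#' @param model,strategy Optional strings recorded in the report.
#' @return A `metric_report`: list with `per_image` (data.frame `id`, `iou`,
#'   `sbd` as fractions) and `iou_mean`, `iou_stdev`, `sbd_mean`, `sbd_stdev`
#'   on the percent scale.
#' @export
evaluate_dataset <- function(pairs, model = NA_character_, strategy = NA_character_) {
  if (!length(pairs)) stop("evaluate_dataset: empty pair list")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    check_same_shape(p$predicted, p$truth, sprintf("pair %d masks", i))
    data.frame(
      id = if (!is.null(p$id)) as.character(p$id) else sprintf("image_%03d", i),
      iou = iou(p$predicted, p$truth),
      sbd = sbd(p$predicted, p$truth),
      stringsAsFactors = FALSE
    )
  })
  per_image <- do.call(rbind, rows)
  sdev <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  rep <- list(
    model = model, strategy = strategy,
    per_image = per_image,
    iou_mean = 100 * mean(per_image$iou),
    iou_stdev = 100 * sdev(per_image$iou),
    sbd_mean = 100 * mean(per_image$sbd),
    sbd_stdev = 100 * sdev(per_image$sbd)
  )
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report (%d images)%s\n", nrow(x$per_image),
              if (!is.na(x$model)) sprintf(" — %s / %s", x$model, x$strategy) else ""))
  cat(sprintf("  IoU  %.4f ± %.2f %%\n", x$iou_mean, x$iou_stdev))
  cat(sprintf("  SBD  %.4f ± %.2f %%\n", x$sbd_mean, x$sbd_stdev))
  invisible(x)
}

#' Serialize a metric report
#'
#' `write_metric_report_json()` writes the full report (per-image rows plus
#' aggregates); `write_metric_report_csv()` appends one summary row per report
#' in the column layout `model, strategy, iou_mean, iou_stdev, sbd_mean,
#' sbd_stdev` (percent-scale values, 4 decimals).
#'
#' @param report A `metric_report` or (for CSV) a list of them.
#' @param path Output file.
#' @return `path`, invisibly. `read_metric_report_json()` returns the report.
#' @export
write_metric_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_metric_report_json
#' @export
read_metric_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_image <- as.data.frame(x$per_image, stringsAsFactors = FALSE)
  if (is.null(x$model)) x$model <- NA_character_
  if (is.null(x$strategy)) x$strategy <- NA_character_
  class(x) <- "metric_report"
  x
}

#' @rdname write_metric_report_json
#' @export
write_metric_report_csv <- function(report, path) {
  if (inherits(report, "metric_report")) report <- list(report)
  rows <- do.call(rbind, lapply(report, function(r)
    data.frame(model = r$model, strategy = r$strategy,
               iou_mean = round(r$iou_mean, 4), iou_stdev = round(r$iou_stdev, 4),
               sbd_mean = round(r$sbd_mean, 4), sbd_stdev = round(r$sbd_stdev, 4),
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
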