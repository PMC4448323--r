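#' Match point annotations to segments
#'
#' An annotation matches the segment whose label covers its pixel;
#' annotations falling on background are recorded as unmatched (likely
#' missed nuclei) and logged rather than folded into any rate.
#'
#' @param labels integer label matrix.
#' @param annotations data.frame with 0-based `x`, `y` columns (and
#'   optionally `label`).
#' @return list with `segment_of` (per-annotation segment id, 0 =
#'   background), `counts` (per-segment annotation counts, length
#'   `max(labels)`), `n_background` (annotations on background).
#' @export
match_annotations <- function(labels, annotations) {
  labels <- as.matrix(labels)
  if (nrow(annotations)) {
    xi <- round(annotations$x); yi <- round(annotations$y)
    if (any(xi < 0 | xi >= ncol(labels) | yi < 0 | yi >= nrow(labels)))
      stop("annotation outside image bounds")
    seg <- labels[cbind(yi + 1L, xi + 1L)]
  } else seg <- integer(0)
  k <- max(labels)
  counts <- tabulate(seg[seg > 0L], nbins = k)
  nbg <- sum(seg == 0L)
  if (nbg) pcna_log("evaluate", "%d annotation(s) fell on background", nbg)
  list(segment_of = seg, counts = counts, n_background = nbg)
}

#' Segmentation quality rates
#'
#' From the annotation-to-segment matching, computes the rates used to judge
#' cluster splitting: the over-segmentation rate is the number of fragments
#' without a matching annotation divided by the total number of annotated
#' nuclei; the under-segmentation rate is the number of segments with more
#' than one matching annotation divided by the total number of nuclei;
#' correct = 1 - over - under. The rates are reported exactly as defined —
#' `correct` can leave `[0, 1]` in pathological cases (more spurious
#' fragments than nuclei) — with clipped companions (`*_clipped`) alongside;
#' the unclipped values are canonical.
#'
#' @param match result of [match_annotations()].
#' @return object of class `pcna_segeval` with fields `n_annotations`,
#'   `n_fragments_unmatched`, `n_multimatched_segments`, `n_background`,
#'   `correct`, `over_seg`, `under_seg` and clipped versions.
#' @export
segmentation_rates <- function(match) {
  n_ann <- length(match$segment_of)
  if (n_ann < 1L) stop("segmentation rates need at least one annotation")
  new_segeval(n_ann, sum(match$counts == 0L), sum(match$counts > 1L),
              match$n_background)
}

new_segeval <- function(n_ann, unmatched, multi, bg) {
  over <- unmatched / n_ann
  under <- multi / n_ann
  correct <- 1 - over - under
  structure(list(n_annotations = n_ann,
                 n_fragments_unmatched = unmatched,
                 n_multimatched_segments = multi,
                 n_background = bg,
                 correct = correct, over_seg = over, under_seg = under,
                 correct_clipped = min(1, max(0, correct)),
                 over_seg_clipped = min(1, over),
                 under_seg_clipped = min(1, under)),
            class = "pcna_segeval")
}

#' @export
print.pcna_segeval <- function(x, ...) {
  cat(sprintf(
    "segmentation: %d nuclei | correct %.3f  over %.3f  under %.3f (%d on background)\n",
    x$n_annotations, x$correct, x$over_seg, x$under_seg, x$n_background))
  invisible(x)
}

#' Per-class precision and recall, overall accuracy
#'
#' For each class C: `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`
#' where tp counts nuclei correctly assigned to C, fp those erroneously
#' assigned to C, fn those of C assigned elsewhere. Overall accuracy is the
#' number of correctly classified nuclei over the total,
#' `trace(cm) / sum(cm)`. A class never predicted has undefined precision,
#' reported as 0 and flagged.
#'
#' @param cm confusion matrix (square, rows = true, columns = predicted).
#' @return list with `precision`, `recall` (named per class),
#'   `undefined_precision` (logical per class), `accuracy`.
#' @export
precision_recall <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  undef <- (tp + fp) == 0
  precision <- ifelse(undef, 0, tp / (tp + fp))
  recall <- ifelse((tp + fn) == 0, 0, tp / (tp + fn))
  cls <- rownames(cm)
  list(precision = stats::setNames(precision, cls),
       recall = stats::setNames(recall, cls),
       undefined_precision = stats::setNames(undef, cls),
       accuracy = sum(tp) / sum(cm))
}

#' Evaluate a prediction run against point annotations
#'
#' Joins predicted phase labels (keyed by segment id) to annotation labels
#' via [match_annotations()]: segments matched by exactly one annotation
#' enter the confusion matrix; unmatched fragments and multi-matched
#' segments are excluded from classification scoring and counted in the
#' segmentation rates instead.
#'
#' Segments touching the image border are excluded from the confusion matrix
#' by default (configurable): partial nuclei corrupt texture features.
#'
#' @param predictions data.frame with columns `segment_id` and `label`.
#' @param annotations data.frame with `x`, `y`, `label`.
#' @param labels integer label matrix.
#' @param exclude_border drop segments touching the image border from
#'   classification scoring (default TRUE).
#' @return object of class `pcna_report`: `confusion`, `precision_recall`,
#'   `segmentation`, `n_evaluated`, `n_excluded`, `n_border_excluded`.
#' @export
evaluate_run <- function(predictions, annotations, labels,
                         exclude_border = TRUE) {
  labels <- as.matrix(labels)
  match <- match_annotations(labels, annotations)
  seg_rates <- segmentation_rates(match)
  one <- which(match$counts == 1L)
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- border[border > 0L]
  if (exclude_border && length(border)) {
    pcna_log("evaluate", "excluding %d border-touching segment(s)",
             length(intersect(one, border)))
    one <- setdiff(one, border)
  }
  ann_idx <- match(one, match$segment_of)     # the single annotation of each
  pred_idx <- match(one, predictions$segment_id)
  ok <- !is.na(pred_idx)
  if (!any(ok)) stop("no evaluable (singly matched, predicted) segments")
  truth <- parse_phase(annotations$label[ann_idx[ok]])
  pred <- parse_phase(predictions$label[pred_idx[ok]])
  cm <- table(true = truth, predicted = pred)
  structure(list(confusion = cm, precision_recall = precision_recall(cm),
                 segmentation = seg_rates,
                 n_evaluated = sum(ok),
                 n_excluded = max(labels) - sum(ok),
                 n_border_excluded = if (exclude_border)
                   length(border) else 0L),
            class = "pcna_report")
}

#' @export
print.pcna_report <- function(x, ...) {
  cat("== pcnaphase evaluation report ==\n")
  print(x$segmentation)
  cat(sprintf("classification: %d nuclei evaluated, %d excluded; accuracy %.3f\n",
              x$n_evaluated, x$n_excluded, x$precision_recall$accuracy))
  print(x$confusion)
  pr <- x$precision_recall
  for (cl in names(pr$precision))
    cat(sprintf("  %-8s precision %.3f%s  recall %.3f\n", cl,
                pr$precision[cl],
                if (pr$undefined_precision[cl]) "*" else " ",
                pr$recall[cl]))
  if (any(pr$undefined_precision))
    cat("  (* class never predicted: precision undefined, reported as 0)\n")
  invisible(x)
}

#' Write an evaluation report to files
#'
#' @param report a [evaluate_run()] result.
#' @param dir output directory; writes `report.txt`, `confusion.csv`,
#'   `rates.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt")
  sink(con); print(report); sink()
  close(con)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  s <- report$segmentation
  utils::write.csv(data.frame(metric = c("correct", "over_seg", "under_seg",
                                         "accuracy"),
                              value = c(s$correct, s$over_seg, s$under_seg,
                                        report$precision_recall$accuracy)),
                   file.path(dir, "rates.csv"), row.names = FALSE)
  invisible(dir)
}
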