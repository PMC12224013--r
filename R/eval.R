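#' Construct detection and ground-truth tables
#'
#' Detections are data frames with columns `image_id`, `class_id`,
#' `confidence` (in `[0, 1]`) and corner coordinates `x1, y1, x2, y2`;
#' ground truths are the same without `confidence`.
#'
#' @param image_id,class_id,confidence,x1,y1,x2,y2 Column vectors.
#' @return A data frame.
#' @export
detections <- function(image_id, class_id, confidence, x1, y1, x2, y2) {
  if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1)) {
    stop("confidence must be finite and in [0, 1]", call. = FALSE)
  }
  data.frame(image_id = as.character(image_id), class_id = as.integer(class_id),
             confidence = confidence, x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' @rdname detections
#' @export
ground_truths <- function(image_id, class_id, x1, y1, x2, y2) {
  data.frame(image_id = as.character(image_id), class_id = as.integer(class_id),
             x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Greedy detection-to-ground-truth matching
#'
#' For one class: detections are sorted by descending confidence (ties kept
#' in input order) and each is greedily matched, within its image, to the
#' unmatched ground truth of highest IoU at or above `iou_threshold`.
#' Matched detections are true positives, the rest false positives;
#' ground truths left unmatched are false negatives.
#'
#' @param dets Detection data frame (see [detections()]).
#' @param gts Ground-truth data frame (see [ground_truths()]).
#' @param iou_threshold IoU threshold in `(0, 1]`; default 0.5.
#' @param class_id Class to evaluate.
#' @return A list with `flags` (logical TP indicator per detection of the
#'   class, in descending-confidence order), `confidence` (the matching
#'   order), `n_gt`, and `fn` (unmatched ground-truth count).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5, class_id = 0L) {
  if (!is.finite(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must be in (0, 1]", call. = FALSE)
  }
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  g <- gts[gts$class_id == class_id, , drop = FALSE]
  ord <- order(-d$confidence)     # stable: ties keep input order
  d <- d[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(g))
  flags <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    cand <- which(!matched & g$image_id == d$image_id[i])
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(j) {
      box_iou(c(d$x1[i], d$y1[i], d$x2[i], d$y2[i]),
              c(g$x1[j], g$y1[j], g$x2[j], g$y2[j]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched[cand[best]] <- TRUE
      flags[i] <- TRUE
    }
  }
  list(flags = flags, confidence = d$confidence, n_gt = nrow(g),
       fn = sum(!matched))
}

#' Precision-recall curve from match flags
#'
#' Cumulative precision and recall over detections ranked by descending
#' confidence: at rank k, `precision = TP_k / k` and `recall = TP_k / n_gt`.
#'
#' @param flags Logical TP indicator per detection, already in
#'   descending-confidence order.
#' @param n_gt Number of ground truths of the class.
#' @return A list of class `"pr_curve"` with `recalls` and `precisions`.
#' @export
precision_recall_curve <- function(flags, n_gt) {
  if (length(flags) > 0L && n_gt < 1L) {
    message("detections present but no ground truth; empty curve (AP = 0)")
    return(structure(list(recalls = numeric(0), precisions = numeric(0)),
                     class = "pr_curve"))
  }
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  structure(list(recalls = if (n_gt > 0) tp / n_gt else numeric(0),
                 precisions = if (length(flags)) tp / (tp + fp) else numeric(0)),
            class = "pr_curve")
}

#' Average precision (area under the P-R curve)
#'
#' All-point interpolation: the precision at each recall level is replaced
#' by the maximum precision at any equal-or-higher recall (the monotone
#' non-increasing envelope), and that envelope is integrated over recall.
#'
#' @param curve A [precision_recall_curve()].
#' @return AP in `[0, 1]`; an empty curve gives 0.
#' @export
average_precision <- function(curve) {
  r <- curve$recalls
  p <- curve$precisions
  if (length(r) == 0L) return(0)
  env <- rev(cummax(rev(p)))
  sum(diff(c(0, r)) * env)
}

#' Mean average precision
#'
#' @param per_class_aps Numeric vector of per-class AP values (one per
#'   evaluated class).
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(per_class_aps) {
  if (length(per_class_aps) == 0L) stop("no per-class APs", call. = FALSE)
  mean(per_class_aps)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`; 0 when both are 0.
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Mean detection time
#'
#' @param times_seconds Nonnegative per-image detection times.
#' @return Their arithmetic mean (seconds).
#' @export
mean_detection_time <- function(times_seconds) {
  if (length(times_seconds) == 0L) stop("no detection times", call. = FALSE)
  if (any(times_seconds < 0)) stop("times must be nonnegative", call. = FALSE)
  mean(times_seconds)
}

#' Full detection evaluation
#'
#' Per class: AP over all confidences (greedy matching at `iou_threshold`,
#' all-point interpolated area under the P-R curve), plus precision, recall
#' and F1 of the detections at or above `conf_threshold`. mAP is the
#' arithmetic mean of the per-class APs.
#'
#' @param dets Detection data frame.
#' @param gts Ground-truth data frame.
#' @param classes Integer class ids to evaluate; defaults to every class
#'   present in the ground truth. Detections of classes outside the
#'   evaluated set are rejected.
#' @param iou_threshold Matching IoU threshold (default 0.5).
#' @param conf_threshold Confidence threshold for the P/R/F1 operating point
#'   (default 0.25).
#' @param times_seconds Optional per-image detection times; reported as mDT.
#' @return A list of class `"eval_report"`: `per_class` data frame
#'   (`class_id`, `ap`, `precision`, `recall`, `f1`, `n_gt`, `n_det`),
#'   `map`, and `mdt` (NA if no times given).
#' @export
evaluate_detections <- function(dets, gts, classes = NULL,
                                iou_threshold = 0.5, conf_threshold = 0.25,
                                times_seconds = NULL) {
  if (is.null(classes)) classes <- sort(unique(gts$class_id))
  unknown <- setdiff(unique(dets$class_id), classes)
  if (length(unknown) > 0L) {
    stop("detections contain class ids outside the evaluated set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(classes, function(cl) {
    m <- match_detections(dets, gts, iou_threshold, cl)
    ap <- if (m$n_gt == 0L && length(m$flags) > 0L) 0 else {
      average_precision(precision_recall_curve(m$flags, m$n_gt))
    }
    keep <- m$confidence >= conf_threshold
    tp <- sum(m$flags[keep]); fp <- sum(!m$flags[keep])
    # recall at the operating point counts only GTs matchable above threshold
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (m$n_gt > 0) tp / m$n_gt else 0
    data.frame(class_id = cl, ap = ap, precision = p, recall = r,
               f1 = f1_score(p, r), n_gt = m$n_gt, n_det = length(m$flags))
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class, map = mean_ap(per_class$ap),
                 mdt = if (is.null(times_seconds)) NA_real_ else
                   mean_detection_time(times_seconds),
                 iou_threshold = iou_threshold,
                 conf_threshold = conf_threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report: mAP %.4f over %d class(es) (IoU %.2f, conf %.2f)%s>\n",
              x$map, nrow(x$per_class), x$iou_threshold, x$conf_threshold,
              if (is.na(x$mdt)) "" else sprintf(", mDT %.4fs", x$mdt)))
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Read and write detection CSV files
#'
#' Column layout `image_id, class, confidence, x1, y1, x2, y2`, where
#' `class` is the registry name.
#'
#' @param path CSV path.
#' @param registry Class registry.
#' @export
read_detections_csv <- function(path, registry = pest_classes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detections(df$image_id, class_index(df$class, registry), df$confidence,
             df$x1, df$y1, df$x2, df$y2)
}

#' @param dets Detection data frame.
#' @rdname read_detections_csv
#' @export
write_detections_csv <- function(dets, path, registry = pest_classes()) {
  out <- data.frame(image_id = dets$image_id,
                    class = class_name(dets$class_id, registry),
                    confidence = dets$confidence,
                    x1 = dets$x1, y1 = dets$y1, x2 = dets$x2, y2 = dets$y2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(map = report$map, mdt = report$mdt,
              iou_threshold = report$iou_threshold,
              conf_threshold = report$conf_threshold,
              per_class = report$per_class)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
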