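#' Collect labeled-box dimensions from a dataset
#'
#' One `(w, h)` pair per labeled box, in pixels. Input may be a directory of
#' VOC XML files, a character vector of XML paths, or a list of annotation
#' metadata (as from [read_voc_xml()]).
#'
#' @param dataset Directory, paths, or metadata list.
#' @param rescale_to Optional side length: if given, each image's boxes are
#'   rescaled as if the image were resized (aspect-free) to
#'   `rescale_to x rescale_to`. Default keeps native resolution.
#' @param registry Class registry used when parsing XML.
#' @return A numeric matrix with columns `w`, `h`, one row per box, in
#'   stable (file, object) order.
#' @export
collect_box_dims <- function(dataset, rescale_to = NULL,
                             registry = pest_classes()) {
  if (is.character(dataset) && length(dataset) == 1L && dir.exists(dataset)) {
    dataset <- list.files(dataset, pattern = "\\.xml$", full.names = TRUE)
  }
  if (is.character(dataset)) {
    dataset <- lapply(dataset, read_voc_xml, registry = registry)
  }
  rows <- lapply(dataset, function(meta) {
    lb <- meta$labels
    if (nrow(lb) == 0L) return(NULL)
    w <- lb$x2 - lb$x1
    h <- lb$y2 - lb$y1
    if (!is.null(rescale_to)) {
      w <- w * rescale_to / meta$width
      h <- h * rescale_to / meta$height
    }
    cbind(w = w, h = h)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("dataset contains no labeled boxes", call. = FALSE)
  }
  out
}

# 1 - IoU between a (w, h) box and each center, both anchored at the origin
one_minus_iou_dist <- function(dims, centers) {
  iw <- outer(dims[, 1L], centers[, 1L], pmin)
  ih <- outer(dims[, 2L], centers[, 2L], pmin)
  inter <- iw * ih
  un <- outer(dims[, 1L] * dims[, 2L], centers[, 1L] * centers[, 2L], `+`) - inter
  1 - inter / un
}

euclid_dist2 <- function(dims, centers) {
  outer(dims[, 1L], centers[, 1L], `-`)^2 + outer(dims[, 2L], centers[, 2L], `-`)^2
}

anchor_dist <- function(dims, centers, metric) {
  if (metric == "1-iou") one_minus_iou_dist(dims, centers)
  else sqrt(euclid_dist2(dims, centers))
}

#' K-means anchor optimization
#'
#' Clusters labeled-box dimensions into `k` anchor boxes with Lloyd
#' iterations under either the YOLO-family `"1-iou"` distance (one minus the
#' IoU of the two width/height boxes co-anchored at the origin) or plain
#' Euclidean distance. Initialization is k-means++ under the given seed;
#' clusters that empty out are re-seeded to the point farthest from its
#' center. Iteration stops when no center moves more than `tol` (in px of
#' width/height) or after `max_iter` rounds.
#'
#' The update step is the within-cluster minimizer of the chosen objective,
#' which keeps the recorded objective non-increasing across iterations:
#' under `"euclidean"` centers move to the member mean and the objective is
#' the mean squared distance to the assigned center; under `"1-iou"` centers
#' move to the member medoid (the member minimizing total 1-IoU distance to
#' its cluster, so anchors are actual box dimensions) and the objective is
#' the mean 1-IoU distance.
#'
#' @param dims Matrix of box `(w, h)` rows, e.g. from [collect_box_dims()].
#' @param k Number of anchors (default 9).
#' @param metric `"1-iou"` (default) or `"euclidean"`.
#' @param max_iter,tol Convergence controls.
#' @param seed Integer seed (k-means++ draws).
#' @param nstart Number of independent k-means++ starts; the run with the
#'   lowest final objective is kept. Multiple starts are the standard guard
#'   against Lloyd's local optima.
#' @return An object of class `"anchor_set"`: a list with `anchors` (k x 2
#'   matrix sorted by ascending area), `groups` (three triplets, when
#'   `k = 9`), `assignment`, `objective` (the metric's Lloyd objective after
#'   each assignment step; non-increasing), `metric`, `iterations`,
#'   `converged`.
#' @export
fit_anchors <- function(dims, k = 9L, metric = c("1-iou", "euclidean"),
                        max_iter = 300L, tol = 1e-6, seed = 0L, nstart = 10L) {
  metric <- match.arg(metric)
  dims <- as.matrix(dims)
  storage.mode(dims) <- "double"
  n <- nrow(dims)
  if (n < k) stop("need at least k box dimensions", call. = FALSE)
  if (any(dims <= 0)) stop("box dimensions must be positive", call. = FALSE)

  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, nstart))
  best <- NULL
  for (s in sub_seeds) {
    run <- lloyd_run(dims, k, metric, max_iter, tol, s)
    if (is.null(best) || utils::tail(run$objective, 1) <
          utils::tail(best$objective, 1)) {
      best <- run
    }
  }
  centers <- best$centers

  ord <- order(centers[, 1L] * centers[, 2L])
  anchors <- round(centers[ord, , drop = FALSE], 6)
  colnames(anchors) <- c("w", "h")
  res <- list(anchors = anchors,
              groups = if (k == 9L) group_anchors(anchors) else NULL,
              assignment = match(max.col(-anchor_dist(dims, centers, metric),
                                         ties.method = "first"), ord),
              objective = best$objective, metric = metric,
              iterations = best$iterations, converged = best$converged)
  structure(res, class = "anchor_set")
}

# one k-means++ initialization followed by Lloyd iteration
lloyd_run <- function(dims, k, metric, max_iter, tol, seed) {
  n <- nrow(dims)
  centers <- withr::with_seed(as.integer(seed), {
    # k-means++: first center uniform, then proportional to squared distance
    ctr <- dims[sample.int(n, 1L), , drop = FALSE]
    while (nrow(ctr) < k) {
      d <- anchor_dist(dims, ctr, metric)
      dmin <- apply(d, 1L, min)
      w <- dmin^2
      if (sum(w) <= 0) w <- rep(1, n)
      ctr <- rbind(ctr, dims[sample.int(n, 1L, prob = w), ])
    }
    ctr
  })

  objective <- numeric(0)
  assign_old <- rep(0L, n)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- anchor_dist(dims, centers, metric)
    assign_new <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(n), assign_new)]
    objective <- c(objective,
                   if (metric == "euclidean") mean(dmin^2) else mean(dmin))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- which(assign_new == j)
      if (length(members) > 0L) {
        new_centers[j, ] <- if (metric == "euclidean") {
          colMeans(dims[members, , drop = FALSE])
        } else {
          # medoid: member minimizing total 1-IoU distance within the cluster
          mm <- dims[members, , drop = FALSE]
          mm[which.min(colSums(one_minus_iou_dist(mm, mm))), ]
        }
      } else {
        new_centers[j, ] <- dims[which.max(dmin), ]
      }
    }
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol || identical(assign_new, assign_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    assign_old <- assign_new
  }
  list(centers = centers, objective = objective, iterations = iter,
       converged = converged)
}

#' Group nine anchors into three detection scales
#'
#' Sorts the nine `(w, h)` pairs by ascending area and chunks them into three
#' ordered triplets (small, medium, large detection scales).
#'
#' @param anchors A 9 x 2 matrix (or list of 9 `(w, h)` pairs).
#' @return A list of three 3 x 2 matrices.
#' @export
group_anchors <- function(anchors) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 9L || ncol(anchors) != 2L) {
    stop("exactly nine (w, h) anchors are required", call. = FALSE)
  }
  ord <- order(anchors[, 1L] * anchors[, 2L])
  sorted <- anchors[ord, , drop = FALSE]
  colnames(sorted) <- c("w", "h")
  lapply(1:3, function(g) sorted[(3L * g - 2L):(3L * g), , drop = FALSE])
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set: %d anchors, metric '%s', %d iteration(s)%s>\n",
              nrow(x$anchors), x$metric, x$iterations,
              if (x$converged) ", converged" else ""))
  if (!is.null(x$groups)) {
    for (g in 1:3) {
      cat(sprintf("  scale %d: %s\n", g,
                  paste(sprintf("(%g,%g)", x$groups[[g]][, 1L],
                                x$groups[[g]][, 2L]), collapse = " ")))
    }
  } else {
    print(x$anchors)
  }
  invisible(x)
}

#' Write grouped anchors to JSON
#'
#' @param aset An `"anchor_set"` (or a 9 x 2 anchor matrix).
#' @param path Output path.
#' @export
write_anchors_json <- function(aset, path) {
  if (inherits(aset, "anchor_set")) {
    anchors <- aset$anchors
    groups <- aset$groups
    metric <- aset$metric
  } else {
    anchors <- as.matrix(aset)
    groups <- if (nrow(anchors) == 9L) group_anchors(anchors) else NULL
    metric <- NA_character_
  }
  as_pairs <- function(m) unname(apply(m, 1L, as.list))
  obj <- list(metric = metric, anchors = as_pairs(anchors))
  if (!is.null(groups)) obj$groups <- lapply(groups, as_pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
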