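#' Scene specification for synthetic labeled images
#'
#' Describes the synthetic scenes the fixture generator emits: colored
#' elliptical "pests" on a textured background, with an object-size law
#' weighted toward small objects the way field pest imagery is (most labeled
#' boxes fall under the COCO small-object cutoff of 32^2 px).
#'
#' @param size Image side length in px (square images), default 640.
#' @param n_objects Objects per scene.
#' @param class_probs Probability over the 12 registry classes (sums to 1);
#'   default uniform.
#' @param small_frac Fraction of objects drawn from the small-size law.
#' @param small_range,large_range Uniform side-length ranges (px) for small
#'   and medium/large objects.
#' @param seed Integer seed.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(size = 640L, n_objects = 5L,
                       class_probs = rep(1 / 12, 12),
                       small_frac = 0.8,
                       small_range = c(8, 30), large_range = c(40, 120),
                       seed = 0L) {
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    stop("class_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  if (size < 8L) stop("size too small", call. = FALSE)
  structure(list(size = as.integer(size), n_objects = as.integer(n_objects),
                 class_probs = class_probs, small_frac = small_frac,
                 small_range = small_range, large_range = large_range,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# 12 visually distinct RGB colors, one per registry class
class_palette <- function() {
  matrix(c(200, 40, 40,   40, 200, 40,   40, 40, 200,  200, 200, 40,
           200, 40, 200,  40, 200, 200,  240, 140, 20, 140, 70, 20,
           120, 120, 120, 250, 180, 180, 100, 20, 60,  20, 100, 60),
         ncol = 3L, byrow = TRUE)
}

#' Generate a synthetic labeled scene
#'
#' Places non-overlapping colored ellipses ("pests") on a textured
#' background; each ellipse yields one labeled box (its bounding box).
#' Pure function of spec + seed. If non-overlapping placement fails after
#' bounded retries, fewer objects are placed and a message is emitted.
#'
#' @param spec A [scene_spec()].
#' @param source_id Identifier for the scene.
#' @return An [annotated_image()].
#' @export
gen_scene <- function(spec = scene_spec(), source_id = "scene") {
  S <- spec$size
  pal <- class_palette()
  withr::with_seed(spec$seed, {
    # textured background: green base + coarse noise
    base <- c(70, 110, 60)
    noise <- array(stats::runif(S * S * 3, -25, 25), dim = c(S, S, 3L))
    px <- array(rep(base, each = S * S), dim = c(S, S, 3L)) + noise
    placed <- list()
    labels <- empty_labels()
    for (i in seq_len(spec$n_objects)) {
      ok <- FALSE
      for (try in 1:40) {
        small <- stats::runif(1) < spec$small_frac
        rng <- if (small) spec$small_range else spec$large_range
        w <- stats::runif(1, rng[1L], rng[2L])
        h <- stats::runif(1, rng[1L], rng[2L])
        if (w >= S - 2 || h >= S - 2) next
        x1 <- stats::runif(1, 1, S - w - 1)
        y1 <- stats::runif(1, 1, S - h - 1)
        b <- c(x1, y1, x1 + w, y1 + h)
        clash <- any(vapply(placed, function(p) box_iou(p, b) > 0, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) next
      placed[[length(placed) + 1L]] <- b
      cid <- sample.int(12L, 1L, prob = spec$class_probs) - 1L
      # fill the inscribed ellipse with the class color
      cx <- (b[1L] + b[3L]) / 2; cy <- (b[2L] + b[4L]) / 2
      ax <- (b[3L] - b[1L]) / 2; ay <- (b[4L] - b[2L]) / 2
      rs <- max(1L, ceiling(b[2L])):min(S, floor(b[4L]) + 1L)
      cs <- max(1L, ceiling(b[1L])):min(S, floor(b[3L]) + 1L)
      xs <- (cs - 0.5 - cx) / ax
      ys <- (rs - 0.5 - cy) / ay
      mask <- outer(ys^2, xs^2, `+`) <= 1
      col <- pal[cid + 1L, ]
      for (ch in 1:3) {
        plane <- px[rs, cs, ch]
        plane[mask] <- col[ch]
        px[rs, cs, ch] <- plane
      }
      labels <- rbind(labels, make_labels(cid, b[1L], b[2L], b[3L], b[4L]))
    }
    if (nrow(labels) < spec$n_objects) {
      message("placed ", nrow(labels), " of ", spec$n_objects,
              " objects (packing limit)")
    }
    rownames(labels) <- NULL
    annotated_image(pmin(pmax(round(px), 0), 255), labels, source_id)
  })
}

# brute-force AP from a TP/FP flag sequence: enumerate every confidence
# threshold, collect (recall, precision) points by explicit counting, then
# integrate max-precision-at-recall>=r over the achieved recall levels
ap_flags_bruteforce <- function(flags, n_gt) {
  n <- length(flags)
  if (n == 0L || n_gt < 1L) return(0)
  pts <- t(vapply(seq_len(n), function(k) {
    tp <- sum(flags[seq_len(k)])
    c(r = tp / n_gt, p = tp / k)
  }, numeric(2)))
  rs <- sort(unique(pts[, 1L]))
  ap <- 0
  prev <- 0
  for (r in rs) {
    if (r > 0) ap <- ap + (r - prev) * max(pts[pts[, 1L] >= r, 2L])
    prev <- r
  }
  ap
}

#' Generate a planted evaluation set with known metric values
#'
#' Constructs ground truths and detections whose greedy matching at IoU 0.5
#' reproduces, per class, a prescribed TP/FP flag sequence exactly, and
#' stores the AP each sequence implies (computed by a brute-force threshold
#' sweep). The object is self-verifying: running the evaluation stack on it
#' must reproduce the stored flags and APs.
#'
#' @param flags_per_class Named list: class id (as character) to a logical
#'   vector, `TRUE` for TP, `FALSE` for FP, in descending-confidence order.
#' @param n_gt_per_class Named integer vector (same names): ground-truth
#'   count per class; must be at least the TP count of its flag sequence.
#' @param seed Integer seed (kept for interface uniformity; the construction
#'   is deterministic).
#' @return A list of class `"planted_eval"` with `gts`, `dets`, `flags`,
#'   `aps` (named per class), and `map`.
#' @export
gen_planted_eval <- function(flags_per_class, n_gt_per_class, seed = 0L) {
  cls <- names(flags_per_class)
  if (is.null(cls) || !setequal(cls, names(n_gt_per_class))) {
    stop("flags_per_class and n_gt_per_class must share class names", call. = FALSE)
  }
  gt_rows <- list(); det_rows <- list()
  aps <- stats::setNames(numeric(length(cls)), cls)
  for (ci in seq_along(cls)) {
    cl <- as.integer(cls[ci])
    flags <- as.logical(flags_per_class[[cls[ci]]])
    n_gt <- as.integer(n_gt_per_class[[cls[ci]]])
    if (sum(flags) > n_gt) {
      stop("class ", cl, ": more TP flags than ground truths", call. = FALSE)
    }
    y0 <- 200 * ci
    if (n_gt > 0L) {
      gt_rows[[ci]] <- ground_truths("img1", cl,
                                     x1 = 100 * seq_len(n_gt), y1 = y0,
                                     x2 = 100 * seq_len(n_gt) + 40, y2 = y0 + 40)
    }
    if (length(flags) > 0L) {
      conf <- seq(0.95, 0.5, length.out = max(2L, length(flags)))[seq_along(flags)]
      tp_seen <- 0L; fp_seen <- 0L
      xs <- numeric(length(flags)); ys <- numeric(length(flags))
      for (k in seq_along(flags)) {
        if (flags[k]) {
          tp_seen <- tp_seen + 1L
          xs[k] <- 100 * tp_seen + 2   # overlaps GT tp_seen with IoU ~0.9
          ys[k] <- y0
        } else {
          fp_seen <- fp_seen + 1L
          xs[k] <- 100 * fp_seen       # empty band: no GT within reach
          ys[k] <- y0 + 100
        }
      }
      det_rows[[ci]] <- detections("img1", cl, conf,
                                   x1 = xs, y1 = ys, x2 = xs + 40, y2 = ys + 40)
    }
    aps[ci] <- ap_flags_bruteforce(flags, n_gt)
  }
  gts <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    ground_truths(character(0), integer(0), numeric(0), numeric(0), numeric(0), numeric(0))
  dets <- if (length(det_rows)) do.call(rbind, det_rows) else
    detections(character(0), integer(0), numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
  structure(list(gts = gts, dets = dets, flags = flags_per_class,
                 n_gt = n_gt_per_class, aps = aps, map = mean(aps),
                 seed = as.integer(seed)),
            class = "planted_eval")
}

#' Generate box pairs by law
#'
#' Deterministic mixes of box-pair geometries for property tests:
#' `"identical"` (IoU 1), `"nested"`, `"equal-size"` (offset copies, zero
#' point-line penalty), `"disjoint"` (IoU 0), `"random"`, or `"mixed"`
#' (cycles through all laws).
#'
#' @param n Number of pairs.
#' @param law Pair law (see above).
#' @param seed Integer seed.
#' @param range Coordinate range the boxes are drawn in.
#' @return A list with matrices `c_boxes`, `g_boxes` (n x 4) and the
#'   per-pair `law` tags.
#' @export
gen_box_pairs <- function(n, law = c("mixed", "identical", "nested",
                                     "equal-size", "disjoint", "random"),
                          seed = 0L, range = c(0, 100)) {
  law <- match.arg(law)
  laws <- c("identical", "nested", "equal-size", "disjoint", "random")
  tags <- if (law == "mixed") laws[(seq_len(n) - 1L) %% 5L + 1L] else rep(law, n)
  withr::with_seed(seed, {
    cb <- matrix(0, n, 4L); gb <- matrix(0, n, 4L)
    for (i in seq_len(n)) {
      w <- stats::runif(1, 5, 30); h <- stats::runif(1, 5, 30)
      x <- stats::runif(1, range[1L], range[2L] - w)
      y <- stats::runif(1, range[1L], range[2L] - h)
      a <- c(x, y, x + w, y + h)
      b <- switch(tags[i],
        identical = a,
        nested = a + c(w / 4, h / 4, -w / 4, -h / 4),
        `equal-size` = a + rep(stats::runif(2, -20, 20), each = 1L)[c(1, 2, 1, 2)],
        disjoint = {
          off <- c(w, h) + stats::runif(2, 5, 20)
          a + off[c(1, 2, 1, 2)]
        },
        random = {
          w2 <- stats::runif(1, 5, 30); h2 <- stats::runif(1, 5, 30)
          x2 <- stats::runif(1, range[1L], range[2L] - w2)
          y2 <- stats::runif(1, range[1L], range[2L] - h2)
          c(x2, y2, x2 + w2, y2 + h2)
        })
      cb[i, ] <- a; gb[i, ] <- b
    }
    colnames(cb) <- colnames(gb) <- c("x1", "y1", "x2", "y2")
    list(c_boxes = cb, g_boxes = gb, law = tags)
  })
}

#' Generate a clustered box-dimension mixture
#'
#' Gaussian width/height samples (truncated at 1 px) around planted centers,
#' for anchor-recovery tests.
#'
#' @param centers Matrix of planted `(w, h)` centers.
#' @param sigma Noise standard deviation in px.
#' @param n_per Samples per center.
#' @param seed Integer seed.
#' @return A matrix of `(w, h)` rows, grouped by center.
#' @export
gen_anchor_mixture <- function(centers, sigma = 1, n_per = 100L, seed = 0L) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("need at least one center", call. = FALSE)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
      cbind(w = pmax(1, stats::rnorm(n_per, centers[j, 1L], sigma)),
            h = pmax(1, stats::rnorm(n_per, centers[j, 2L], sigma)))
    }))
    out
  })
}
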