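#' Mosaic augmentation configuration
#'
#' @param out_size Output size, `c(height, width)` or a single side length.
#' @param n_tiles 4 (classic 2x2 mosaic) or 9 (3x3 mosaic).
#' @param jitter Fractional jitter of the cell boundaries, in `[0, 0.4]`:
#'   each interior boundary is shifted uniformly within
#'   `+/- jitter * out_size` of the even grid.
#' @param min_box_area_px Remapped boxes whose clipped area falls below this
#'   threshold (or whose clipped width/height falls below 2 px) are dropped.
#' @param seed Integer seed for the jitter draws.
#' @return A list of class `"mosaic_config"`.
#' @export
mosaic_config <- function(out_size = 640L, n_tiles = 4L, jitter = 0,
                          min_box_area_px = 4, seed = 0L) {
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  if (any(out_size < 1L)) stop("out_size must be positive", call. = FALSE)
  if (!n_tiles %in% c(4L, 9L)) stop("n_tiles must be 4 or 9", call. = FALSE)
  if (jitter < 0 || jitter > 0.4) stop("jitter must be in [0, 0.4]", call. = FALSE)
  structure(list(out_size = as.integer(out_size), n_tiles = as.integer(n_tiles),
                 jitter = jitter, min_box_area_px = min_box_area_px,
                 seed = as.integer(seed)),
            class = "mosaic_config")
}

#' Mixup configuration
#'
#' @param alpha Shape of the symmetric Beta distribution from which the
#'   mixing ratio lambda is drawn. The default 8 keeps lambda tight around
#'   0.5, which mixes both images visibly.
#' @param fixed_lambda Optional fixed mixing ratio in `[0, 1]` (overrides the
#'   Beta draw; useful for exact tests).
#' @param seed Integer seed for the lambda draw.
#' @return A list of class `"mixup_config"`.
#' @export
mixup_config <- function(alpha = 8, fixed_lambda = NULL, seed = 0L) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.null(fixed_lambda) && (fixed_lambda < 0 || fixed_lambda > 1)) {
    stop("fixed_lambda must be in [0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, fixed_lambda = fixed_lambda,
                 seed = as.integer(seed)),
            class = "mixup_config")
}

#' Clip labels to a viewport and drop slivers
#'
#' Each box is intersected with the viewport; boxes whose clipped area is
#' below `min_area_px`, or whose clipped width or height is below
#' `min_side_px`, are dropped. Surviving boxes lie within the viewport.
#'
#' @param labels Label data frame.
#' @param viewport A normalized box `c(x1, y1, x2, y2)`.
#' @param min_area_px Minimum clipped area in px^2.
#' @param min_side_px Minimum clipped width/height in px.
#' @return The clipped, filtered label data frame.
#' @export
clip_and_filter_labels <- function(labels, viewport, min_area_px = 4,
                                   min_side_px = 2) {
  if (nrow(labels) == 0L) return(labels)
  x1 <- pmax(labels$x1, viewport[[1L]]); y1 <- pmax(labels$y1, viewport[[2L]])
  x2 <- pmin(labels$x2, viewport[[3L]]); y2 <- pmin(labels$y2, viewport[[4L]])
  w <- pmax(0, x2 - x1); h <- pmax(0, y2 - y1)
  keep <- (w * h >= min_area_px) & (w >= min_side_px) & (h >= min_side_px)
  out <- labels[keep, , drop = FALSE]
  out$x1 <- x1[keep]; out$y1 <- y1[keep]; out$x2 <- x2[keep]; out$y2 <- y2[keep]
  rownames(out) <- NULL
  out
}

# nearest-neighbour resize with a fixed index mapping:
# output pixel center (i - 0.5) maps to source pixel ceiling((i - 0.5) * s)
nn_resize <- function(pixels, out_h, out_w) {
  d <- dim(pixels)
  ri <- pmin(d[1L], pmax(1L, ceiling((seq_len(out_h) - 0.5) * d[1L] / out_h)))
  ci <- pmin(d[2L], pmax(1L, ceiling((seq_len(out_w) - 0.5) * d[2L] / out_w)))
  pixels[ri, ci, , drop = FALSE]
}

# place a source image (resized aspect-free) into cell rows r1..r2, cols c1..c2
# of `canvas`; remap its labels by the same affine. Returns canvas + labels.
place_tile <- function(canvas, labels_acc, img, r1, r2, c1, c2) {
  ch <- r2 - r1 + 1L; cw <- c2 - c1 + 1L
  canvas[r1:r2, c1:c2, ] <- nn_resize(img$pixels, ch, cw)
  if (nrow(img$labels) > 0L) {
    d <- dim(img$pixels)
    sx <- cw / d[2L]; sy <- ch / d[1L]
    lb <- img$labels
    lb$x1 <- lb$x1 * sx + (c1 - 1L); lb$x2 <- lb$x2 * sx + (c1 - 1L)
    lb$y1 <- lb$y1 * sy + (r1 - 1L); lb$y2 <- lb$y2 * sy + (r1 - 1L)
    labels_acc <- rbind(labels_acc, lb)
  }
  list(canvas = canvas, labels = labels_acc)
}

#' Mosaic (4-image) augmentation
#'
#' Stitches four labeled images into one: a jittered center point splits the
#' output into a 2x2 layout, each source is resized (aspect-free) to its
#' cell, and its labels are remapped by the same affine, then clipped and
#' sliver-filtered. With `jitter = 0` the four cells are equal quadrants.
#'
#' @param images List of four [annotated_image()]s.
#' @param cfg A [mosaic_config()] with `n_tiles = 4`.
#' @return An [annotated_image()] of size `cfg$out_size`.
#' @export
mosaic <- function(images, cfg = mosaic_config(n_tiles = 4L)) {
  if (cfg$n_tiles != 4L) stop("cfg$n_tiles must be 4 for mosaic()", call. = FALSE)
  if (!is.list(images) || length(images) < 4L) {
    stop("mosaic needs four images", call. = FALSE)
  }
  images <- images[1:4]
  H <- cfg$out_size[1L]; W <- cfg$out_size[2L]
  ctr <- withr::with_seed(cfg$seed, {
    c(round(H * (0.5 + stats::runif(1, -cfg$jitter, cfg$jitter))),
      round(W * (0.5 + stats::runif(1, -cfg$jitter, cfg$jitter))))
  })
  cy <- min(H - 1L, max(1L, ctr[1L])); cx <- min(W - 1L, max(1L, ctr[2L]))
  canvas <- array(0, dim = c(H, W, 3L))
  labels <- empty_labels()
  cells <- list(c(1L, cy, 1L, cx), c(1L, cy, cx + 1L, W),
                c(cy + 1L, H, 1L, cx), c(cy + 1L, H, cx + 1L, W))
  for (i in 1:4) {
    z <- cells[[i]]
    res <- place_tile(canvas, labels, images[[i]], z[1L], z[2L], z[3L], z[4L])
    canvas <- res$canvas; labels <- res$labels
  }
  labels <- clip_and_filter_labels(labels, c(0, 0, W, H), cfg$min_box_area_px)
  annotated_image(canvas, labels, source_id = "mosaic4")
}

#' Mosaic-9 augmentation
#'
#' The 9-image extension of mosaic: a 3x3 grid whose two interior x- and
#' y-boundaries are jittered uniformly within `+/- jitter * out_size` of the
#' even grid. Every tile follows the same rule: its source is resized
#' (aspect-free) to fill the cell and the labels are remapped by the same
#' affine, then clipped and sliver-filtered. With `jitter = 0` the nine
#' cells partition the output exactly.
#'
#' @param images List of nine [annotated_image()]s.
#' @param cfg A [mosaic_config()] with `n_tiles = 9`.
#' @return An [annotated_image()] of size `cfg$out_size`.
#' @export
mosaic9 <- function(images, cfg = mosaic_config(n_tiles = 9L)) {
  if (cfg$n_tiles != 9L) stop("cfg$n_tiles must be 9 for mosaic9()", call. = FALSE)
  if (!is.list(images) || length(images) < 9L) {
    stop("mosaic9 needs nine images", call. = FALSE)
  }
  images <- images[1:9]
  H <- cfg$out_size[1L]; W <- cfg$out_size[2L]
  bounds <- withr::with_seed(cfg$seed, {
    list(y = H * (c(1, 2) / 3 + stats::runif(2, -cfg$jitter, cfg$jitter)),
         x = W * (c(1, 2) / 3 + stats::runif(2, -cfg$jitter, cfg$jitter)))
  })
  yb <- pmin(H - 1L, pmax(1L, sort(round(bounds$y))))
  xb <- pmin(W - 1L, pmax(1L, sort(round(bounds$x))))
  if (yb[2L] <= yb[1L]) yb[2L] <- yb[1L] + 1L
  if (xb[2L] <= xb[1L]) xb[2L] <- xb[1L] + 1L
  rows <- rbind(c(1L, yb[1L]), c(yb[1L] + 1L, yb[2L]), c(yb[2L] + 1L, H))
  cols <- rbind(c(1L, xb[1L]), c(xb[1L] + 1L, xb[2L]), c(xb[2L] + 1L, W))
  canvas <- array(0, dim = c(H, W, 3L))
  labels <- empty_labels()
  k <- 0L
  for (r in 1:3) for (cc in 1:3) {
    k <- k + 1L
    res <- place_tile(canvas, labels, images[[k]],
                      rows[r, 1L], rows[r, 2L], cols[cc, 1L], cols[cc, 2L])
    canvas <- res$canvas; labels <- res$labels
  }
  labels <- clip_and_filter_labels(labels, c(0, 0, W, H), cfg$min_box_area_px)
  annotated_image(canvas, labels, source_id = "mosaic9")
}

#' Mixup augmentation
#'
#' Mixes two equally sized labeled images as
#' `pixels = lambda * a + (1 - lambda) * b`, computed in floating point and
#' rounded half-up to 8 bits; the labels are the union of both label lists
#' with classes preserved. `lambda` is drawn from `Beta(alpha, alpha)` under
#' the configured seed unless `fixed_lambda` is given.
#'
#' @param a,b [annotated_image()]s of identical pixel dimensions.
#' @param cfg A [mixup_config()].
#' @return An [annotated_image()]; attribute `"lambda"` records the ratio.
#' @export
mixup <- function(a, b, cfg = mixup_config()) {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stop("mixup inputs must have identical shapes (resize first)", call. = FALSE)
  }
  lam <- if (!is.null(cfg$fixed_lambda)) cfg$fixed_lambda else {
    withr::with_seed(cfg$seed, stats::rbeta(1, cfg$alpha, cfg$alpha))
  }
  px <- floor(lam * a$pixels + (1 - lam) * b$pixels + 0.5)  # round half up
  out <- annotated_image(px, rbind(a$labels, b$labels),
                         source_id = paste0(a$source_id, "+", b$source_id))
  attr(out, "lambda") <- lam
  out
}

#' Static (offline) augmentations with exact label remapping
#'
#' The registry of per-image transforms used to expand a detection dataset:
#' `"scale"` (size scaling), `"grayscale"`, `"center_crop"`, `"random_crop"`,
#' `"random_crop_scale"` (random crop then resize back), `"pad"` (edge
#' padding), `"rotate"` (random or fixed rotation), `"hflip"`, `"vflip"`,
#' `"color_jitter"` (color dithering) and `"affine"`. Geometric kinds remap
#' boxes exactly (rotation and affine map a box to the axis-aligned bounding
#' box of its four transformed corners) and then clip/sliver-filter them;
#' photometric kinds leave labels untouched.
#'
#' Parameters per kind (all optional, with defaults):
#' \describe{
#'   \item{scale}{`fx`, `fy` scale factors (default 2, 2) or `size = c(h, w)`.}
#'   \item{center_crop / random_crop / random_crop_scale}{`size = c(h, w)`,
#'     default half the image.}
#'   \item{pad}{`pad` in px (scalar or `c(top, bottom, left, right)`),
#'     default 16; edge pixels are replicated.}
#'   \item{rotate}{`angle` in degrees (clockwise, y down); if missing, drawn
#'     uniformly from `range` (default `c(-30, 30)`) under `seed`.}
#'   \item{color_jitter}{`strength` in (0, 1], default 0.2: per-channel gain
#'     in `1 +/- strength` and a brightness offset within
#'     `+/- strength * 64`, drawn under `seed`.}
#'   \item{affine}{`A` (2x2 matrix) and `t` (length-2 shift), forward map
#'     `(x', y') = A (x, y) + t`.}
#' }
#'
#' @param img An [annotated_image()].
#' @param kind Transform name (see above).
#' @param params Named list of parameters for the kind.
#' @param seed Integer seed for the stochastic kinds.
#' @param min_box_area_px Sliver threshold applied after geometric remapping.
#' @return An [annotated_image()].
#' @export
static_transform <- function(img, kind, params = list(), seed = 0L,
                             min_box_area_px = 4) {
  d <- dim(img$pixels); H <- d[1L]; W <- d[2L]
  lb <- img$labels
  kinds <- c("scale", "grayscale", "center_crop", "random_crop",
             "random_crop_scale", "pad", "rotate", "hflip", "vflip",
             "color_jitter", "affine")
  if (!kind %in% kinds) {
    stop("unknown transform kind: ", kind, call. = FALSE)
  }
  clipf <- function(labels, w, h) {
    clip_and_filter_labels(labels, c(0, 0, w, h), min_box_area_px)
  }
  out <- switch(kind,
    scale = {
      if (!is.null(params$size)) {
        oh <- params$size[1L]; ow <- params$size[2L]
      } else {
        fx <- params$fx %||% 2; fy <- params$fy %||% fx
        oh <- round(H * fy); ow <- round(W * fx)
      }
      px <- nn_resize(img$pixels, oh, ow)
      sx <- ow / W; sy <- oh / H
      lb[c("x1", "x2")] <- lb[c("x1", "x2")] * sx
      lb[c("y1", "y2")] <- lb[c("y1", "y2")] * sy
      annotated_image(px, clipf(lb, ow, oh), img$source_id)
    },
    grayscale = {
      lum <- round(0.299 * img$pixels[, , 1L] + 0.587 * img$pixels[, , 2L] +
                     0.114 * img$pixels[, , 3L])
      annotated_image(array(rep(lum, 3L), dim = d), lb, img$source_id)
    },
    center_crop = {
      sz <- params$size %||% c(H %/% 2L, W %/% 2L)
      r1 <- (H - sz[1L]) %/% 2L; c1 <- (W - sz[2L]) %/% 2L
      crop_apply(img, r1, c1, sz[1L], sz[2L], clipf)
    },
    random_crop = {
      sz <- params$size %||% c(H %/% 2L, W %/% 2L)
      off <- withr::with_seed(seed, c(sample.int(H - sz[1L] + 1L, 1L) - 1L,
                                      sample.int(W - sz[2L] + 1L, 1L) - 1L))
      crop_apply(img, off[1L], off[2L], sz[1L], sz[2L], clipf)
    },
    random_crop_scale = {
      sz <- params$size %||% c(H %/% 2L, W %/% 2L)
      off <- withr::with_seed(seed, c(sample.int(H - sz[1L] + 1L, 1L) - 1L,
                                      sample.int(W - sz[2L] + 1L, 1L) - 1L))
      cropped <- crop_apply(img, off[1L], off[2L], sz[1L], sz[2L], clipf)
      static_transform(cropped, "scale", list(size = c(H, W)),
                       min_box_area_px = min_box_area_px)
    },
    pad = {
      p <- params$pad %||% 16L
      if (length(p) == 1L) p <- rep(p, 4L)  # top, bottom, left, right
      oh <- H + p[1L] + p[2L]; ow <- W + p[3L] + p[4L]
      ri <- pmin(H, pmax(1L, seq_len(oh) - p[1L]))
      ci <- pmin(W, pmax(1L, seq_len(ow) - p[3L]))
      px <- img$pixels[ri, ci, , drop = FALSE]
      lb[c("x1", "x2")] <- lb[c("x1", "x2")] + p[3L]
      lb[c("y1", "y2")] <- lb[c("y1", "y2")] + p[1L]
      annotated_image(px, lb, img$source_id)
    },
    rotate = {
      ang <- params$angle
      if (is.null(ang)) {
        rg <- params$range %||% c(-30, 30)
        ang <- withr::with_seed(seed, stats::runif(1, rg[1L], rg[2L]))
      }
      rotate_apply(img, ang, clipf)
    },
    hflip = {
      px <- img$pixels[, W:1, , drop = FALSE]
      new_x1 <- W - lb$x2; new_x2 <- W - lb$x1
      lb$x1 <- new_x1; lb$x2 <- new_x2
      annotated_image(px, lb, img$source_id)
    },
    vflip = {
      px <- img$pixels[H:1, , , drop = FALSE]
      new_y1 <- H - lb$y2; new_y2 <- H - lb$y1
      lb$y1 <- new_y1; lb$y2 <- new_y2
      annotated_image(px, lb, img$source_id)
    },
    color_jitter = {
      s <- params$strength %||% 0.2
      jit <- withr::with_seed(seed, list(gain = stats::runif(3, 1 - s, 1 + s),
                                         off = stats::runif(1, -64 * s, 64 * s)))
      px <- img$pixels
      for (ch in 1:3) px[, , ch] <- px[, , ch] * jit$gain[ch] + jit$off
      annotated_image(pmin(pmax(round(px), 0), 255), lb, img$source_id)
    },
    affine = {
      A <- params$A %||% diag(2)
      t <- params$t %||% c(0, 0)
      affine_apply(img, A, t, clipf)
    }
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

crop_apply <- function(img, r_off, c_off, h, w, clipf) {
  px <- img$pixels[r_off + seq_len(h), c_off + seq_len(w), , drop = FALSE]
  lb <- img$labels
  lb[c("x1", "x2")] <- lb[c("x1", "x2")] - c_off
  lb[c("y1", "y2")] <- lb[c("y1", "y2")] - r_off
  annotated_image(px, clipf(lb, w, h), img$source_id)
}

# rotate about the image center, clockwise for positive angles (y axis down);
# output keeps the input size, out-of-frame pixels are black
rotate_apply <- function(img, angle, clipf) {
  d <- dim(img$pixels); H <- d[1L]; W <- d[2L]
  th <- angle * pi / 180
  cx <- W / 2; cy <- H / 2
  # inverse map each output pixel center to a source pixel
  xo <- rep(seq_len(W) - 0.5, each = H) - cx
  yo <- rep(seq_len(H) - 0.5, times = W) - cy
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  rs <- ceiling(ys); cs <- ceiling(xs)
  ok <- rs >= 1L & rs <= H & cs >= 1L & cs <= W
  px <- array(0, dim = d)
  idx_out <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[idx_out[ok, , drop = FALSE]] <- img$pixels[cbind(rs[ok], cs[ok], ch)]
    px[, , ch] <- plane
  }
  lb <- img$labels
  if (nrow(lb) > 0L) {
    for (i in seq_len(nrow(lb))) {
      xs4 <- c(lb$x1[i], lb$x2[i], lb$x1[i], lb$x2[i]) - cx
      ys4 <- c(lb$y1[i], lb$y1[i], lb$y2[i], lb$y2[i]) - cy
      xr <- cos(th) * xs4 - sin(th) * ys4 + cx
      yr <- sin(th) * xs4 + cos(th) * ys4 + cy
      lb$x1[i] <- min(xr); lb$x2[i] <- max(xr)
      lb$y1[i] <- min(yr); lb$y2[i] <- max(yr)
    }
  }
  annotated_image(px, clipf(lb, W, H), img$source_id)
}

# forward map (x', y') = A %*% (x, y) + t; pixels via the inverse map
affine_apply <- function(img, A, t, clipf) {
  d <- dim(img$pixels); H <- d[1L]; W <- d[2L]
  Ai <- solve(A)
  xo <- rep(seq_len(W) - 0.5, each = H) - t[1L]
  yo <- rep(seq_len(H) - 0.5, times = W) - t[2L]
  xs <- Ai[1L, 1L] * xo + Ai[1L, 2L] * yo
  ys <- Ai[2L, 1L] * xo + Ai[2L, 2L] * yo
  rs <- ceiling(ys); cs <- ceiling(xs)
  ok <- rs >= 1L & rs <= H & cs >= 1L & cs <= W
  px <- array(0, dim = d)
  idx_out <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[idx_out[ok, , drop = FALSE]] <- img$pixels[cbind(rs[ok], cs[ok], ch)]
    px[, , ch] <- plane
  }
  lb <- img$labels
  if (nrow(lb) > 0L) {
    for (i in seq_len(nrow(lb))) {
      xs4 <- c(lb$x1[i], lb$x2[i], lb$x1[i], lb$x2[i])
      ys4 <- c(lb$y1[i], lb$y1[i], lb$y2[i], lb$y2[i])
      xr <- A[1L, 1L] * xs4 + A[1L, 2L] * ys4 + t[1L]
      yr <- A[2L, 1L] * xs4 + A[2L, 2L] * ys4 + t[2L]
      lb$x1[i] <- min(xr); lb$x2[i] <- max(xr)
      lb$y1[i] <- min(yr); lb$y2[i] <- max(yr)
    }
  }
  annotated_image(px, clipf(lb, W, H), img$source_id)
}
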