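#' Normalize an axis-aligned box
#'
#' Boxes live in continuous pixel coordinates with the origin at the top-left
#' corner, x increasing rightwards and y downwards. A box is a numeric vector
#' `c(x1, y1, x2, y2)`; normalization reorders the corners so that
#' `x1 <= x2` and `y1 <= y2`. Degenerate (zero-width or zero-height) boxes
#' are allowed and have zero area.
#'
#' @param x1,y1,x2,y2 Finite corner coordinates. Alternatively `x1` may be a
#'   length-4 numeric vector holding all four.
#' @return A named numeric vector `c(x1, y1, x2, y2)` with ordered corners.
#' @examples
#' normalize_box(10, 10, 0, 0)
#' @export
normalize_box <- function(x1, y1 = NULL, x2 = NULL, y2 = NULL) {
  if (is.null(y1) && length(x1) == 4L) {
    v <- as.numeric(x1)
  } else {
    v <- c(x1, y1, x2, y2)
  }
  if (length(v) != 4L || !all(is.finite(v))) {
    stop("box corners must be four finite numbers", call. = FALSE)
  }
  c(x1 = min(v[1L], v[3L]), y1 = min(v[2L], v[4L]),
    x2 = max(v[1L], v[3L]), y2 = max(v[2L], v[4L]))
}

#' Box area
#'
#' @param b A normalized box (see [normalize_box()]).
#' @return `(x2 - x1) * (y2 - y1)`, always `>= 0` for a normalized box.
#' @export
box_area <- function(b) {
  (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
}

#' Box center
#'
#' @param b A normalized box.
#' @return Numeric `c(x, y)`, the centroid of the rectangle.
#' @export
box_center <- function(b) {
  c(x = (b[[1L]] + b[[3L]]) / 2, y = (b[[2L]] + b[[4L]]) / 2)
}

#' Minimum enclosing box
#'
#' The smallest axis-aligned rectangle containing both input boxes.
#'
#' @param c_box,g_box Normalized boxes (prediction and target).
#' @return A normalized box.
#' @export
min_enclosing_box <- function(c_box, g_box) {
  c(x1 = min(c_box[[1L]], g_box[[1L]]), y1 = min(c_box[[2L]], g_box[[2L]]),
    x2 = max(c_box[[3L]], g_box[[3L]]), y2 = max(c_box[[4L]], g_box[[4L]]))
}

#' Intersection over Union of two boxes
#'
#' Intersection area divided by union area, in `[0, 1]`. Coordinates are
#' continuous (area = width x height, no pixel offset). When the union has
#' zero area (both boxes degenerate) the IoU is defined as 0.
#'
#' @param c_box,g_box Normalized boxes.
#' @return A scalar in `[0, 1]`.
#' @examples
#' box_iou(normalize_box(0, 0, 2, 2), normalize_box(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(c_box, g_box) {
  iw <- max(0, min(c_box[[3L]], g_box[[3L]]) - max(c_box[[1L]], g_box[[1L]]))
  ih <- max(0, min(c_box[[4L]], g_box[[4L]]) - max(c_box[[2L]], g_box[[2L]]))
  inter <- iw * ih
  un <- box_area(c_box) + box_area(g_box) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Line through two points
#'
#' Returns the coefficients `(alpha, beta, lambda)` of the line through `p`
#' and `q`, with `alpha = q_y - p_y`, `beta = q_x - p_x` and
#' `lambda = q_x * p_y - p_x * q_y`. Under the evaluation
#' `alpha * x - beta * y + lambda` both defining points lie on the line
#' (the expression is 0 there); see the methods vignette for the derivation
#' of the sign in front of `beta`.
#'
#' Coincident points give `alpha = beta = 0` and are flagged degenerate.
#' Points closer than about 1e-9 times the coordinate magnitude are also
#' flagged: a line through two nearly identical points is numerically
#' meaningless and would make the distance penalty blow up on rounding
#' noise.
#'
#' @param p,q Numeric `c(x, y)` points.
#' @return A list with `alpha`, `beta`, `lam` and logical `degenerate`.
#' @export
line_through <- function(p, q) {
  if (!all(is.finite(c(p, q)))) stop("points must be finite", call. = FALSE)
  alpha <- q[[2L]] - p[[2L]]
  beta <- q[[1L]] - p[[1L]]
  lam <- q[[1L]] * p[[2L]] - p[[1L]] * q[[2L]]
  scale <- max(1, abs(p), abs(q))
  list(alpha = alpha, beta = beta, lam = lam,
       degenerate = sqrt(alpha^2 + beta^2) <= 1e-9 * scale)
}

#' Squared point-line distance penalty
#'
#' The penalty term of the PLDIoU loss: the squared Euclidean distance from a
#' point to a line, `(alpha*x - beta*y + lam)^2 / (alpha^2 + beta^2)`. For a
#' degenerate line (coincident defining points) the penalty is 0 by
#' convention.
#'
#' @param line A line as returned by [line_through()].
#' @param p Numeric `c(x, y)`.
#' @return A nonnegative scalar (pixel^2).
#' @export
point_line_penalty <- function(line, p) {
  if (isTRUE(line$degenerate)) return(0)
  den <- line$alpha^2 + line$beta^2
  num <- line$alpha * p[[1L]] - line$beta * p[[2L]] + line$lam
  num^2 / den
}

#' Loss configuration for PLDIoU
#'
#' @param eta Nonnegative penalty weight; default 10.
#' @param normalize_penalty If `TRUE`, the squared point-line distance is
#'   divided by the squared diagonal of the minimum enclosing box, making the
#'   penalty scale-invariant (DIoU-style). The default `FALSE` keeps the raw
#'   pixel^2 penalty.
#' @return A list of class `"pldiou_config"`.
#' @export
loss_config <- function(eta = 10, normalize_penalty = FALSE) {
  if (!is.finite(eta) || eta < 0) stop("eta must be >= 0", call. = FALSE)
  structure(list(eta = eta, normalize_penalty = isTRUE(normalize_penalty)),
            class = "pldiou_config")
}

# penalty R for a box pair: squared distance from the enclosing-box center to
# the line through the two box centers, optionally / diag^2 of the enclosure
pldiou_penalty <- function(c_box, g_box, cfg = loss_config()) {
  pc <- box_center(c_box)
  pg <- box_center(g_box)
  a <- min_enclosing_box(c_box, g_box)
  r <- point_line_penalty(line_through(pc, pg), box_center(a))
  if (cfg$normalize_penalty) {
    d2 <- (a[[3L]] - a[[1L]])^2 + (a[[4L]] - a[[2L]])^2
    r <- if (d2 > 0) r / d2 else 0
  }
  r
}

#' PLDIoU score and loss
#'
#' The point-line-distance IoU penalizes the misalignment of a prediction box
#' `C` and a target box `G` by the squared distance `d^2` from the center of
#' their minimum enclosing box to the line through the two box centers:
#' `PLDIoU = IoU - eta * d^2` and `L = 1 - IoU + eta * d^2`. When the two
#' boxes have equal size the enclosing-box center lies on the line and the
#' penalty vanishes, so PLDIoU reduces to plain IoU. The score is unbounded
#' below for distant boxes under the raw penalty; no clamping is applied.
#'
#' @param c_box,g_box Normalized boxes (prediction and target).
#' @param cfg A [loss_config()].
#' @return `pldiou()`: a scalar `<= IoU`; `pldiou_loss()`: a scalar
#'   `>= 1 - IoU >= 0`.
#' @examples
#' c_box <- normalize_box(0, 0, 4, 4)
#' g_box <- normalize_box(6, 0, 8, 2)
#' pldiou(c_box, g_box, loss_config(eta = 10))       # -10 * 4/26
#' pldiou_loss(c_box, g_box, loss_config(eta = 10))  # 1 + 40/26
#' @export
pldiou <- function(c_box, g_box, cfg = loss_config()) {
  box_iou(c_box, g_box) - cfg$eta * pldiou_penalty(c_box, g_box, cfg)
}

#' @rdname pldiou
#' @export
pldiou_loss <- function(c_box, g_box, cfg = loss_config()) {
  1 - box_iou(c_box, g_box) + cfg$eta * pldiou_penalty(c_box, g_box, cfg)
}

#' Elementwise PLDIoU loss over paired boxes
#'
#' @param c_boxes,g_boxes Matrices with one box per row (columns
#'   `x1, y1, x2, y2`), equal row counts. Rows are normalized internally.
#' @param cfg A [loss_config()].
#' @return A numeric vector of losses, one per pair, in input order.
#' @export
batch_pldiou_loss <- function(c_boxes, g_boxes, cfg = loss_config()) {
  c_boxes <- as_box_matrix(c_boxes)
  g_boxes <- as_box_matrix(g_boxes)
  if (nrow(c_boxes) != nrow(g_boxes)) {
    stop("c_boxes and g_boxes must pair up row by row", call. = FALSE)
  }
  if (nrow(c_boxes) == 0L) return(numeric(0))
  vapply(seq_len(nrow(c_boxes)), function(i) {
    pldiou_loss(normalize_box(c_boxes[i, ]), normalize_box(g_boxes[i, ]), cfg)
  }, numeric(1))
}

as_box_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) == 0L) return(matrix(numeric(0), ncol = 4L))
    x <- matrix(as.numeric(x), ncol = 4L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop("boxes need 4 columns: x1, y1, x2, y2", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Analytic gradient of the PLDIoU loss
#'
#' Gradient of [pldiou_loss()] with respect to the eight corner coordinates
#' `(cx1, cy1, cx2, cy2, gx1, gy1, gx2, gy2)`. The loss is piecewise smooth;
#' at the (measure-zero) kinks where corners tie or the intersection collapses
#' a one-sided subgradient is returned.
#'
#' @inheritParams pldiou
#' @return A named numeric vector of length 8.
#' @export
pldiou_loss_grad <- function(c_box, g_box, cfg = loss_config()) {
  a1 <- c_box[[1L]]; b1 <- c_box[[2L]]; a2 <- c_box[[3L]]; b2 <- c_box[[4L]]
  e1 <- g_box[[1L]]; f1 <- g_box[[2L]]; e2 <- g_box[[3L]]; f2 <- g_box[[4L]]

  ## ---- IoU term -------------------------------------------------------
  iw <- min(a2, e2) - max(a1, e1)
  ih <- min(b2, f2) - max(b1, f1)
  inter <- max(0, iw) * max(0, ih)
  areaC <- (a2 - a1) * (b2 - b1)
  areaG <- (e2 - e1) * (f2 - f1)
  un <- areaC + areaG - inter

  # d(inter)/d(corner): only active when the overlap is positive
  dI <- numeric(8)
  if (iw > 0 && ih > 0) {
    dI[1] <- if (a1 > e1) -ih else 0      # cx1
    dI[3] <- if (a2 < e2)  ih else 0      # cx2
    dI[5] <- if (e1 > a1) -ih else 0      # gx1
    dI[7] <- if (e2 < a2)  ih else 0      # gx2
    dI[2] <- if (b1 > f1) -iw else 0      # cy1
    dI[4] <- if (b2 < f2)  iw else 0      # cy2
    dI[6] <- if (f1 > b1) -iw else 0      # gy1
    dI[8] <- if (f2 < b2)  iw else 0      # gy2
  }
  dAreaC <- c(-(b2 - b1), -(a2 - a1), (b2 - b1), (a2 - a1), 0, 0, 0, 0)
  dAreaG <- c(0, 0, 0, 0, -(f2 - f1), -(e2 - e1), (f2 - f1), (e2 - e1))
  dU <- dAreaC + dAreaG - dI
  dIoU <- if (un > 0) (dI * un - inter * dU) / un^2 else numeric(8)

  ## ---- penalty term ---------------------------------------------------
  px <- (a1 + a2) / 2; py <- (b1 + b2) / 2
  qx <- (e1 + e2) / 2; qy <- (f1 + f2) / 2
  X1 <- min(a1, e1); Y1 <- min(b1, f1); X2 <- max(a2, e2); Y2 <- max(b2, f2)
  x <- (X1 + X2) / 2; y <- (Y1 + Y2) / 2

  alpha <- qy - py; beta <- qx - px
  lam <- qx * py - px * qy
  D <- alpha^2 + beta^2
  N <- alpha * x - beta * y + lam

  dR <- numeric(8)
  ctr_scale <- max(1, abs(px), abs(py), abs(qx), abs(qy))
  if (sqrt(D) > 1e-9 * ctr_scale) {
    # partials of N and D w.r.t. the intermediate quantities
    dN <- c(px = -qy + y,                      # dalpha=0, dbeta=-1, dlam=-qy
            py = -x + qx,                      # dalpha=-1, dlam=qx
            qx = -y + py,                      # dbeta=1, dlam=py
            qy = x - px,                       # dalpha=1, dlam=-px
            x = alpha, y = -beta)
    dD <- c(px = -2 * beta, py = -2 * alpha, qx = 2 * beta, qy = 2 * alpha,
            x = 0, y = 0)
    dRmid <- (2 * N * dN * D - N^2 * dD) / D^2

    # chain to the eight corners; enclosing-box center is piecewise linear
    J <- matrix(0, nrow = 6, ncol = 8)  # rows: px py qx qy x y
    J[1, c(1, 3)] <- 0.5
    J[2, c(2, 4)] <- 0.5
    J[3, c(5, 7)] <- 0.5
    J[4, c(6, 8)] <- 0.5
    J[5, 1] <- 0.5 * (a1 <= e1); J[5, 5] <- 0.5 * (e1 < a1)
    J[5, 3] <- 0.5 * (a2 >= e2); J[5, 7] <- 0.5 * (e2 > a2)
    J[6, 2] <- 0.5 * (b1 <= f1); J[6, 6] <- 0.5 * (f1 < b1)
    J[6, 4] <- 0.5 * (b2 >= f2); J[6, 8] <- 0.5 * (f2 > b2)
    dR <- as.numeric(dRmid %*% J)

    if (cfg$normalize_penalty) {
      d2 <- (X2 - X1)^2 + (Y2 - Y1)^2
      dd2 <- numeric(8)
      dd2[1] <- -2 * (X2 - X1) * (a1 <= e1); dd2[5] <- -2 * (X2 - X1) * (e1 < a1)
      dd2[3] <-  2 * (X2 - X1) * (a2 >= e2); dd2[7] <-  2 * (X2 - X1) * (e2 > a2)
      dd2[2] <- -2 * (Y2 - Y1) * (b1 <= f1); dd2[6] <- -2 * (Y2 - Y1) * (f1 < b1)
      dd2[4] <-  2 * (Y2 - Y1) * (b2 >= f2); dd2[8] <-  2 * (Y2 - Y1) * (f2 > b2)
      R <- N^2 / D
      dR <- if (d2 > 0) (dR * d2 - R * dd2) / d2^2 else numeric(8)
    }
  }

  g <- -dIoU + cfg$eta * dR
  names(g) <- c("cx1", "cy1", "cx2", "cy2", "gx1", "gy1", "gx2", "gy2")
  g
}
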