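# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: IoU by counting raster cells, the
# point-line penalty by nearest-point search along the line, AP by a
# brute-force threshold sweep, gradients by central finite differences.

# IoU of two integer-corner boxes by counting unit raster cells
iou_raster_oracle <- function(a, b) {
  lo_x <- floor(min(a[1], b[1])); hi_x <- ceiling(max(a[3], b[3]))
  lo_y <- floor(min(a[2], b[2])); hi_y <- ceiling(max(a[4], b[4]))
  xs <- seq(lo_x + 1, hi_x)  # cell i covers [i-1, i]
  ys <- seq(lo_y + 1, hi_y)
  in_box <- function(box) {
    outer(ys > box[2] & ys <= box[4], xs > box[1] & xs <= box[3], `&`)
  }
  ia <- in_box(a); ib <- in_box(b)
  inter <- sum(ia & ib); un <- sum(ia) + sum(ib) - inter
  if (un == 0) 0 else inter / un
}

# squared distance from the enclosing-box center to the line through the two
# box centers, by coarse-to-fine search over points on the line
penalty_search_oracle <- function(c_box, g_box) {
  p <- pestkit::box_center(c_box)
  q <- pestkit::box_center(g_box)
  if (all(p == q)) return(0)
  a <- pestkit::box_center(pestkit::min_enclosing_box(c_box, g_box))
  d2_at <- function(t) (p[1] + t * (q[1] - p[1]) - a[1])^2 +
    (p[2] + t * (q[2] - p[2]) - a[2])^2
  t_coarse <- seq(-10, 11, by = 0.005)
  t0 <- t_coarse[which.min(d2_at(t_coarse))]
  t_fine <- seq(t0 - 0.01, t0 + 0.01, length.out = 20001)
  min(d2_at(t_fine))
}

# central finite differences of pldiou_loss w.r.t. the 8 corner coordinates
fd_loss_grad <- function(c_box, g_box, cfg, h = 1e-5) {
  coords <- c(c_box, g_box)
  vapply(1:8, function(i) {
    up <- coords; up[i] <- up[i] + h
    dn <- coords; dn[i] <- dn[i] - h
    (pestkit::pldiou_loss(up[1:4], up[5:8], cfg) -
       pestkit::pldiou_loss(dn[1:4], dn[5:8], cfg)) / (2 * h)
  }, numeric(1))
}

# AP by brute-force sweep: every confidence rank yields a (recall, precision)
# point by explicit counting; the area under the monotone envelope is then
# summed over the achieved recall levels straight from its definition
ap_sweep_oracle <- function(flags, n_gt) {
  n <- length(flags)
  if (n == 0 || n_gt < 1) return(0)
  recs <- numeric(n); precs <- numeric(n)
  for (k in 1:n) {
    tp <- sum(flags[1:k])
    recs[k] <- tp / n_gt
    precs[k] <- tp / k
  }
  ap <- 0; prev <- 0
  for (r in sort(unique(recs))) {
    if (r > 0) ap <- ap + (r - prev) * max(precs[recs >= r])
    prev <- r
  }
  ap
}

# random box pairs that stay clear of the loss function's kinks (corner ties,
# vanishing overlap, coincident centers), where gradients are well defined
gen_smooth_pairs <- function(n, seed, margin = 1e-2) {
  out <- vector("list", n)
  got <- 0L
  trial <- 0L
  while (got < n) {
    trial <- trial + 1L
    bp <- pestkit::gen_box_pairs(1, law = "random", seed = seed + trial)
    cb <- bp$c_boxes[1, ]; gb <- bp$g_boxes[1, ]
    iw <- min(cb[3], gb[3]) - max(cb[1], gb[1])
    ih <- min(cb[4], gb[4]) - max(cb[2], gb[2])
    corner_gaps <- abs(c(cb[1] - gb[1], cb[2] - gb[2], cb[3] - gb[3], cb[4] - gb[4]))
    ctr_gap <- sum((pestkit::box_center(cb) - pestkit::box_center(gb))^2)
    if (all(corner_gaps > margin) && abs(iw) > margin && abs(ih) > margin &&
        ctr_gap > margin) {
      got <- got + 1L
      out[[got]] <- list(c_box = cb, g_box = gb)
    }
  }
  out
}
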