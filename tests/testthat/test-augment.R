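solid_image <- function(h, w, rgb, labels = NULL, id = "img") {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  annotated_image(px, labels %||% pestkit:::empty_labels(), id)
}

central_box_labels <- function(h, w, class_id = 0L) {
  pestkit:::make_labels(class_id, w / 4, h / 4, 3 * w / 4, 3 * h / 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clip_and_filter keeps inside boxes, drops outside and slivers", {
  lb <- pestkit:::make_labels(c(0L, 1L, 2L),
                              x1 = c(10, 200, 95), y1 = c(10, 200, 10),
                              x2 = c(30, 220, 140), y2 = c(30, 220, 12.5))
  out <- clip_and_filter_labels(lb, c(0, 0, 100, 100), min_area_px = 4)
  # box 1 untouched; box 2 fully outside; box 3 clips to 5 x 2.5 but is a
  # 2.5-px-high sliver kept only because both sides are >= 2 and area >= 4
  expect_equal(out$class_id, c(0L, 2L))
  expect_equal(out[out$class_id == 0L, c("x1", "y1", "x2", "y2")],
               lb[1, c("x1", "y1", "x2", "y2")], ignore_attr = TRUE)
  expect_equal(unlist(out[out$class_id == 2L, c("x1", "y1", "x2", "y2")]),
               c(x1 = 95, y1 = 10, x2 = 100, y2 = 12.5))
  # tighter area threshold drops the clipped box
  out2 <- clip_and_filter_labels(lb, c(0, 0, 100, 100), min_area_px = 20)
  expect_equal(out2$class_id, 0L)
})

test_that("mosaic stitches four sources into quadrants with remapped labels", {
  cols <- list(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255), c(255, 255, 0))
  imgs <- lapply(1:4, function(i) {
    solid_image(32, 32, cols[[i]], central_box_labels(32, 32, i - 1L),
                id = paste0("src", i))
  })
  cfg <- mosaic_config(out_size = 64L, n_tiles = 4L, jitter = 0, seed = 1)
  out <- mosaic(imgs, cfg)
  expect_equal(dim(out$pixels), c(64, 64, 3))
  expect_equal(nrow(out$labels), 4L)
  # pixel provenance: each quadrant carries its source color
  expect_equal(unname(out$pixels[1, 1, ]), cols[[1]])
  expect_equal(unname(out$pixels[1, 64, ]), cols[[2]])
  expect_equal(unname(out$pixels[64, 1, ]), cols[[3]])
  expect_equal(unname(out$pixels[64, 64, ]), cols[[4]])
  # labels remap by the per-cell affine: source box (8,8,24,24) in a 32-px
  # tile maps to (8,8,24,24) within its 32-px quadrant
  tl <- out$labels[out$labels$class_id == 0L, ]
  expect_equal(unlist(tl[c("x1", "y1", "x2", "y2")]),
               c(x1 = 8, y1 = 8, x2 = 24, y2 = 24))
  br <- out$labels[out$labels$class_id == 3L, ]
  expect_equal(unlist(br[c("x1", "y1", "x2", "y2")]),
               c(x1 = 40, y1 = 40, x2 = 56, y2 = 56))
  # determinism under seed
  expect_identical(mosaic(imgs, cfg)$pixels, out$pixels)
  expect_error(mosaic(imgs[1:3], cfg), "four")
})

test_that("mosaic-9 tiles partition the canvas and conserve labels at jitter 0", {
  cols <- lapply(1:9, function(i) c(i * 20, 255 - i * 20, i * 10))
  imgs <- lapply(1:9, function(i) {
    solid_image(30, 30, cols[[i]], central_box_labels(30, 30, (i - 1L) %% 12L),
                id = paste0("src", i))
  })
  cfg <- mosaic_config(out_size = 96L, n_tiles = 9L, jitter = 0, seed = 2)
  out <- mosaic9(imgs, cfg)
  expect_equal(dim(out$pixels), c(96, 96, 3))
  expect_equal(nrow(out$labels), 9L)
  # grid provenance: sample the center of each 32-px tile
  k <- 0
  for (r in 1:3) for (cc in 1:3) {
    k <- k + 1
    expect_equal(unname(out$pixels[(r - 1) * 32 + 16, (cc - 1) * 32 + 16, ]),
                 cols[[k]])
  }
  # with jitter 0 the nine tiles cover every pixel (no black gaps): every
  # pixel equals one of the nine source colors
  seen <- unique(matrix(out$pixels, ncol = 3))
  expect_true(nrow(seen) == 9)
  # all label boxes inside bounds
  expect_true(all(out$labels$x1 >= 0 & out$labels$y1 >= 0 &
                    out$labels$x2 <= 96 & out$labels$y2 <= 96))
  expect_error(mosaic9(imgs[1:8], cfg), "nine")

  # all-black inputs give an all-black output
  blacks <- lapply(1:9, function(i) solid_image(20, 20, c(0, 0, 0)))
  expect_true(all(mosaic9(blacks, cfg)$pixels == 0))
})

test_that("jittered mosaics stay deterministic and in-bounds", {
  imgs <- lapply(1:9, function(i) {
    sp <- scene_spec(size = 48, n_objects = 3, seed = 400 + i)
    gen_scene(sp, paste0("s", i))
  })
  for (seed in 1:5) {
    cfg <- mosaic_config(out_size = 80L, n_tiles = 9L, jitter = 0.3,
                         seed = seed)
    a <- mosaic9(imgs, cfg)
    b <- mosaic9(imgs, cfg)
    expect_identical(a$pixels, b$pixels)
    expect_identical(a$labels, b$labels)
    lb <- a$labels
    expect_true(all(lb$x1 >= 0 & lb$y1 >= 0 & lb$x2 <= 80 & lb$y2 <= 80))
    expect_true(all((lb$x2 - lb$x1) * (lb$y2 - lb$y1) >= 4))
    cfg4 <- mosaic_config(out_size = 80L, n_tiles = 4L, jitter = 0.3,
                          seed = seed)
    m4 <- mosaic(imgs[1:4], cfg4)
    expect_identical(m4$pixels, mosaic(imgs[1:4], cfg4)$pixels)
    expect_true(all(m4$labels$x2 <= 80 & m4$labels$y2 <= 80))
  }
})

test_that("mixup is an exact convex combination with union labels", {
  a <- solid_image(10, 12, c(0, 0, 0), central_box_labels(10, 12, 1L), "a")
  b <- solid_image(10, 12, c(255, 255, 255), central_box_labels(10, 12, 5L), "b")

  m1 <- mixup(a, b, mixup_config(fixed_lambda = 1))
  expect_identical(m1$pixels, a$pixels)
  expect_equal(nrow(m1$labels), 2L)
  expect_setequal(m1$labels$class_id, c(1L, 5L))

  # 0.5 * 0 + 0.5 * 255 = 127.5 rounds half-up to 128
  mh <- mixup(a, b, mixup_config(fixed_lambda = 0.5))
  expect_true(all(mh$pixels == 128))

  # quantization never moves a pixel more than 0.5 from the float value
  ra <- gen_scene(scene_spec(size = 32, n_objects = 2, seed = 31), "ra")
  rb <- gen_scene(scene_spec(size = 32, n_objects = 2, seed = 32), "rb")
  lam <- 1 / 3
  mx <- mixup(ra, rb, mixup_config(fixed_lambda = lam))
  expect_lte(max(abs(mx$pixels - (lam * ra$pixels + (1 - lam) * rb$pixels))), 0.5)
  expect_equal(nrow(mx$labels), nrow(ra$labels) + nrow(rb$labels))
  expect_equal(mx$labels$class_id, c(ra$labels$class_id, rb$labels$class_id))

  # Beta draw is seed-deterministic
  m_a <- mixup(ra, rb, mixup_config(seed = 7))
  m_b <- mixup(ra, rb, mixup_config(seed = 7))
  expect_identical(m_a$pixels, m_b$pixels)
  expect_equal(attr(m_a, "lambda"), attr(m_b, "lambda"))
  expect_error(mixup(a, gen_scene(scene_spec(size = 16, seed = 1)),
                     mixup_config()), "identical shapes")
})

test_that("flips and scaling remap boxes by the mirror/scale arithmetic", {
  img <- solid_image(50, 100, c(10, 20, 30),
                     pestkit:::make_labels(0L, 10, 20, 30, 40))
  hf <- static_transform(img, "hflip")
  expect_equal(unlist(hf$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = 70, y1 = 20, x2 = 90, y2 = 40))
  # involution
  expect_identical(static_transform(hf, "hflip")$labels, img$labels)

  vf <- static_transform(img, "vflip")
  expect_equal(unlist(vf$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = 10, y1 = 10, x2 = 30, y2 = 30))

  img2 <- solid_image(20, 20, c(1, 2, 3), pestkit:::make_labels(0L, 5, 5, 10, 10))
  sc <- static_transform(img2, "scale", list(fx = 2))
  expect_equal(dim(sc$pixels), c(40, 40, 3))
  expect_equal(unlist(sc$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = 10, y1 = 10, x2 = 20, y2 = 20))
})

test_that("rotation maps boxes to the bounding box of rotated corners", {
  img <- solid_image(40, 40, c(100, 100, 100),
                     pestkit:::make_labels(2L, 10, 20, 30, 40))
  rot <- static_transform(img, "rotate", list(angle = 90))
  # corner-transform oracle: rotate the four corners about (20, 20) and
  # re-box; computed independently of the implementation
  th <- pi / 2
  xs <- c(10, 30, 10, 30) - 20; ys <- c(20, 20, 40, 40) - 20
  xr <- cos(th) * xs - sin(th) * ys + 20
  yr <- sin(th) * xs + cos(th) * ys + 20
  expect_equal(unlist(rot$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = min(xr), y1 = min(yr), x2 = max(xr), y2 = max(yr)))
  # a 90-degree rotation of a square image permutes pixels exactly:
  # plant a marker and follow it
  px <- img$pixels
  px[5, 8, ] <- c(9, 9, 9)
  img_m <- annotated_image(px, img$labels, "m")
  rot_m <- static_transform(img_m, "rotate", list(angle = 90))
  # pixel center (7.5, 4.5) -> x' = 20 - (4.5 - 20) = 35.5, y' = 7.5 - 20 + 20
  expect_equal(unname(rot_m$pixels[8, 36, ]), c(9, 9, 9))

  # arbitrary-angle rotations keep labels in bounds and are seeded
  r1 <- static_transform(img, "rotate", seed = 5)
  r2 <- static_transform(img, "rotate", seed = 5)
  expect_identical(r1$pixels, r2$pixels)
  expect_true(all(r1$labels$x1 >= 0 & r1$labels$x2 <= 40))
})

test_that("crops, padding and affine remap labels exactly", {
  img <- solid_image(40, 60, c(50, 60, 70),
                     pestkit:::make_labels(1L, 20, 10, 40, 30))
  cc <- static_transform(img, "center_crop", list(size = c(20, 30)))
  expect_equal(dim(cc$pixels), c(20, 30, 3))
  # crop offset (10, 15): box shifts to (5, 0, 25, 20)
  expect_equal(unlist(cc$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = 5, y1 = 0, x2 = 25, y2 = 20))

  pd <- static_transform(img, "pad", list(pad = 8L))
  expect_equal(dim(pd$pixels), c(56, 76, 3))
  expect_equal(unlist(pd$labels[c("x1", "y1", "x2", "y2")]),
               c(x1 = 28, y1 = 18, x2 = 48, y2 = 38))
  # edge replication fills the border with the (solid) edge color
  expect_equal(unname(pd$pixels[1, 1, ]), c(50, 60, 70))

  rc1 <- static_transform(img, "random_crop", seed = 9)
  rc2 <- static_transform(img, "random_crop", seed = 9)
  expect_identical(rc1$pixels, rc2$pixels)

  rcs <- static_transform(img, "random_crop_scale", seed = 9)
  expect_equal(dim(rcs$pixels), dim(img$pixels))

  A <- matrix(c(1.5, 0, 0.2, 0.8), 2, 2)  # column-major: shear + scale
  af <- static_transform(img, "affine", list(A = A, t = c(3, -2)))
  xs <- c(20, 40, 20, 40); ys <- c(10, 10, 30, 30)
  xr <- A[1, 1] * xs + A[1, 2] * ys + 3
  yr <- A[2, 1] * xs + A[2, 2] * ys - 2
  want <- clip_and_filter_labels(
    pestkit:::make_labels(1L, min(xr), min(yr), max(xr), max(yr)),
    c(0, 0, 60, 40))
  expect_equal(af$labels, want)
})

test_that("photometric transforms leave labels untouched", {
  img <- gen_scene(scene_spec(size = 48, n_objects = 3, seed = 77), "p")
  gs <- static_transform(img, "grayscale")
  expect_identical(gs$labels, img$labels)
  expect_equal(gs$pixels[, , 1], gs$pixels[, , 2])
  cj1 <- static_transform(img, "color_jitter", seed = 4)
  cj2 <- static_transform(img, "color_jitter", seed = 4)
  expect_identical(cj1$pixels, cj2$pixels)
  expect_identical(cj1$labels, img$labels)
  expect_true(all(cj1$pixels >= 0 & cj1$pixels <= 255))
  expect_error(static_transform(img, "warp"), "unknown transform")
})
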