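test_that("greedy matching implements the single-match, per-class rule", {
  gt <- ground_truths("i1", 0L, 10, 10, 50, 50)
  d1 <- detections("i1", 0L, 0.9, 11, 11, 51, 51)
  m <- match_detections(d1, gt, 0.5, 0L)
  expect_equal(m$flags, TRUE)
  expect_equal(m$fn, 0L)

  # two overlapping detections: only the higher-confidence one matches
  d2 <- detections(c("i1", "i1"), 0L, c(0.6, 0.9),
                   c(12, 11), c(12, 11), c(52, 51), c(52, 51))
  m2 <- match_detections(d2, gt, 0.5, 0L)
  expect_equal(m2$flags, c(TRUE, FALSE))     # descending-confidence order
  expect_equal(m2$confidence, c(0.9, 0.6))
  expect_equal(m2$fn, 0L)

  # wrong-class detection: FP for its class, FN for the ground truth's
  d3 <- detections("i1", 1L, 0.8, 10, 10, 50, 50)
  m_c1 <- match_detections(d3, gt, 0.5, 1L)
  expect_equal(m_c1$flags, FALSE)
  expect_equal(m_c1$n_gt, 0L)
  m_c0 <- match_detections(d3, gt, 0.5, 0L)
  expect_length(m_c0$flags, 0L)
  expect_equal(m_c0$fn, 1L)

  # image ids partition the matching
  d4 <- detections("i2", 0L, 0.9, 10, 10, 50, 50)
  expect_equal(match_detections(d4, gt, 0.5, 0L)$flags, FALSE)
  expect_error(match_detections(d1, gt, 1.5, 0L), "iou_threshold")
})

test_that("precision-recall curves follow cumulative counting", {
  c1 <- precision_recall_curve(TRUE, 1L)
  expect_equal(c1$precisions, 1)
  expect_equal(c1$recalls, 1)

  c2 <- precision_recall_curve(c(TRUE, FALSE, TRUE), 2L)
  expect_equal(c2$precisions, c(1, 1 / 2, 2 / 3))
  expect_equal(c2$recalls, c(1 / 2, 1 / 2, 1))

  c3 <- precision_recall_curve(c(FALSE, FALSE), 3L)
  expect_equal(c3$precisions, c(0, 0))
  expect_equal(c3$recalls, c(0, 0))

  expect_message(c4 <- precision_recall_curve(c(TRUE), 0L), "no ground truth")
  expect_length(c4$recalls, 0)
  expect_equal(average_precision(c4), 0)
})

test_that("AP integrates the monotone envelope (worked cases)", {
  expect_equal(average_precision(precision_recall_curve(TRUE, 1L)), 1)
  expect_equal(average_precision(precision_recall_curve(c(TRUE, FALSE, TRUE), 2L)),
               5 / 6)
  expect_equal(average_precision(precision_recall_curve(c(FALSE, FALSE, FALSE), 2L)),
               0)
  # a later high-precision run lifts earlier envelope values
  expect_equal(average_precision(precision_recall_curve(
    c(TRUE, FALSE, TRUE, TRUE), 3L)), 1 / 3 + 2 / 3 * 3 / 4)
})

test_that("AP equals the brute-force threshold-sweep oracle on random flags", {
  cases <- withr::with_seed(41, {
    lapply(1:200, function(i) {
      n <- sample(1:25, 1)
      flags <- runif(n) < runif(1, 0.2, 0.8)
      n_gt <- sum(flags) + sample(0:5, 1)
      list(flags = flags, n_gt = max(1L, n_gt))
    })
  })
  for (cs in cases) {
    expect_equal(average_precision(precision_recall_curve(cs$flags, cs$n_gt)),
                 ap_sweep_oracle(cs$flags, cs$n_gt), tolerance = 1e-9)
  }
})

test_that("AP is rank-based and responds correctly to extra flags", {
  withr::with_seed(43, {
    for (i in 1:25) {
      n <- sample(2:20, 1)
      flags <- runif(n) < 0.5
      n_gt <- max(1L, sum(flags) + sample(0:3, 1))
      ap <- average_precision(precision_recall_curve(flags, n_gt))
      # appending a lowest-confidence FP never increases AP
      ap_fp <- average_precision(precision_recall_curve(c(flags, FALSE), n_gt))
      expect_lte(ap_fp, ap + 1e-12)
      # a TP at any rank never decreases final recall
      k <- sample(seq_len(n + 1), 1)
      with_tp <- append(flags, TRUE, after = k - 1)
      r0 <- max(precision_recall_curve(flags, n_gt + 1L)$recalls, 0)
      r1 <- max(precision_recall_curve(with_tp, n_gt + 1L)$recalls)
      expect_gte(r1, r0)
    }
  })
})

test_that("AP is invariant to order-preserving confidence transforms", {
  pe <- gen_planted_eval(list(`0` = c(TRUE, FALSE, TRUE, TRUE, FALSE)),
                         c(`0` = 4L))
  base <- evaluate_detections(pe$dets, pe$gts)$per_class$ap
  warped <- pe$dets
  warped$confidence <- plogis(5 * warped$confidence)  # monotone warp
  expect_equal(evaluate_detections(warped, pe$gts)$per_class$ap, base)
})

test_that("scalar metrics: mAP, F1, mDT", {
  expect_equal(mean_ap(1), 1)
  expect_equal(mean_ap(c(0.5, 1)), 0.75)
  expect_equal(mean_ap(rep(0.37, 12)), 0.37)
  expect_error(mean_ap(numeric(0)), "no per-class")

  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.8, 0.6), 2 * 0.8 * 0.6 / 1.4)
  # harmonic <= arithmetic mean
  withr::with_seed(13, {
    p <- runif(50); r <- runif(50)
    expect_true(all(f1_score(p, r) <= (p + r) / 2 + 1e-12))
  })

  expect_equal(mean_detection_time(rep(0.0072, 1200)), 0.0072)
  expect_equal(mean_detection_time(c(1, 2, 3)), 2)
  expect_equal(mean_detection_time(5), 5)
  expect_error(mean_detection_time(numeric(0)), "no detection times")
})

test_that("evaluate_detections composes the per-class report", {
  # perfect detector: detections identical to ground truth at confidence 1
  gt <- ground_truths(rep(c("i1", "i2"), each = 3), rep(0:2, 2),
                      x1 = rep(c(10, 100, 200), 2), y1 = 10,
                      x2 = rep(c(50, 140, 240), 2), y2 = 50)
  det <- detections(gt$image_id, gt$class_id, 1, gt$x1, gt$y1, gt$x2, gt$y2)
  rep1 <- evaluate_detections(det, gt)
  expect_equal(rep1$map, 1)
  expect_true(all(rep1$per_class$f1 == 1))
  expect_true(is.na(rep1$mdt))

  # no detections at all
  none <- detections(character(0), integer(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), numeric(0))
  rep0 <- evaluate_detections(none, gt)
  expect_equal(rep0$map, 0)
  expect_true(all(rep0$per_class$recall == 0))

  # unknown class rejected
  bad <- detections("i1", 7L, 0.9, 10, 10, 50, 50)
  expect_error(evaluate_detections(bad, gt), "outside the evaluated set")

  # conf_threshold gates the P/R/F1 operating point but not AP
  pe <- gen_planted_eval(list(`0` = c(TRUE, TRUE, FALSE)), c(`0` = 2L))
  r_all <- evaluate_detections(pe$dets, pe$gts, conf_threshold = 0)
  r_top <- evaluate_detections(pe$dets, pe$gts, conf_threshold = 0.9)
  expect_equal(r_all$per_class$ap, r_top$per_class$ap)
  expect_equal(r_top$per_class$precision, 1)     # only the top TP survives
  expect_equal(r_top$per_class$recall, 0.5)
  expect_equal(r_all$per_class$precision, 2 / 3)

  # mDT pass-through
  rep_t <- evaluate_detections(det, gt, times_seconds = rep(0.0072, 10))
  expect_equal(rep_t$mdt, 0.0072)
})

test_that("detection CSV and report JSON round-trip", {
  pe <- gen_planted_eval(list(`0` = c(TRUE, FALSE), `3` = TRUE),
                         c(`0` = 1L, `3` = 2L))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "dets.csv")
  write_detections_csv(pe$dets, csv)
  back <- read_detections_csv(csv)
  expect_equal(back, pe$dets)

  rp <- evaluate_detections(pe$dets, pe$gts)
  out <- file.path(dir, "report.json")
  write_eval_report(rp, out)
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(parsed$map, rp$map)
  expect_equal(parsed$per_class$ap, rp$per_class$ap)
})
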