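test_that("preprocessing stretches contrast without destroying the lumen", {
  const <- matrix(100, 60, 40)
  expect_equal(preprocess_frame(const), const)
  # salt-and-pepper noise inside a disk is strongly suppressed
  set.seed(1)
  m <- disk_frame()
  noisy <- m
  hit <- sample(length(m), length(m) %/% 10)
  noisy[hit] <- sample(c(0, 255), length(hit), replace = TRUE)
  yy <- 5 + (1:300 - 0.5) * 0.1; xx <- -14.4 + (1:96 - 0.5) * 0.3
  core <- outer((yy - 23)^2, (xx - 0)^2, "+") <= 2^2
  sm <- preprocess_frame(noisy, c(0.1, 0.3), sigma_mm = 0.5)
  expect_gt(stats::var(noisy[core]) / stats::var(sm[core]), 10)
  # lumen/background contrast is not reduced on a speckle phantom
  tr <- phantom_truth(center_x = 0, center_y = 23, radius = 3, seed = 21)
  fr <- make_phantom_sequence(tr, n_frames = 1)$frames[, , 1]
  pf <- preprocess_frame(fr, c(0.1, 0.3))
  contrast <- function(img) mean(img[!core]) - mean(img[core])
  expect_gte(contrast(pf), contrast(fr))
})

test_that("CHT finds a noise-free dark disk at the right place and size", {
  for (r in c(2.2, 3.0, 3.9)) {
    m <- disk_frame(cx = 1.5, cy = 24, r = r)
    cands <- detect_dark_circles(m, pixel_spacing_mm = c(0.1, 0.3),
                                 depth_origin_mm = 5, lateral_origin_mm = -14.4)
    expect_equal(nrow(cands), 1)
    expect_lt(abs(cands$x_mm - 1.5), 0.15)   # within one working pixel
    expect_lt(abs(cands$y_mm - 24), 0.15)
    expect_lte(abs(cands$r_mm - r), 0.15)    # within one radius bin
  }
})

test_that("CHT respects the radius search range and rejects empty images", {
  u <- matrix(128, 300, 96)
  expect_equal(nrow(detect_dark_circles(u, pixel_spacing_mm = c(0.1, 0.3))), 0)
  # a 5 mm disk must not appear among candidates limited to 4 mm
  m <- disk_frame(cx = 0, cy = 23, r = 5)
  cands <- detect_dark_circles(m, r_min_mm = 2.1, r_max_mm = 4.0,
                               pixel_spacing_mm = c(0.1, 0.3),
                               depth_origin_mm = 5, lateral_origin_mm = -14.4)
  if (nrow(cands) > 0) {
    hit <- abs(cands$y_mm - 23) < 0.5 & abs(cands$x_mm - 0) < 0.5
    expect_false(any(hit))
  }
  expect_error(detect_dark_circles(u, r_min_mm = 0.1, r_max_mm = 0.2,
                                   pixel_spacing_mm = c(0.1, 0.3)), "2 pixels")
})

test_that("detection is translation equivariant and intensity-scale invariant", {
  m <- disk_frame(cx = 0, cy = 23, r = 3)
  base <- detect_dark_circles(m, pixel_spacing_mm = c(0.1, 0.3),
                              depth_origin_mm = 5, lateral_origin_mm = -14.4)
  # shift by 6 axial px (0.6 mm) and 2 lateral px (0.6 mm)
  m2 <- disk_frame(cx = 0.6, cy = 23.6, r = 3)
  sh <- detect_dark_circles(m2, pixel_spacing_mm = c(0.1, 0.3),
                            depth_origin_mm = 5, lateral_origin_mm = -14.4)
  expect_equal(sh$x_mm[1] - base$x_mm[1], 0.6, tolerance = 1e-9)
  expect_equal(sh$y_mm[1] - base$y_mm[1], 0.6, tolerance = 1e-9)
  # global affine intensity rescaling changes nothing
  m3 <- 0.4 * m + 30
  aff <- detect_dark_circles(m3, pixel_spacing_mm = c(0.1, 0.3),
                             depth_origin_mm = 5, lateral_origin_mm = -14.4)
  expect_equal(aff[, c("x_mm", "y_mm", "r_mm")], base[, c("x_mm", "y_mm", "r_mm")])
})

test_that("the darkest candidate is elected with deterministic tie-breaks", {
  fr <- matrix(100, 200, 96)
  yy <- (1:200 - 0.5) * 0.1; xx <- (1:96 - 0.5) * 0.3 - 14.4
  fr[outer((yy - 8)^2, (xx + 5)^2, "+") <= 4] <- 10   # darker
  fr[outer((yy - 15)^2, (xx - 5)^2, "+") <= 4] <- 50
  cands <- data.frame(x_mm = c(-5, 5), y_mm = c(8, 15), r_mm = c(2, 2),
                      score = c(1, 1), darkness = NA_real_, frame_index = NA_integer_)
  best <- select_darkest(fr, cands, c(0.1, 0.3), 0, -14.4)
  expect_equal(best$x_mm, -5)
  expect_lt(best$darkness, 15)
  expect_equal(select_darkest(fr, cands[2, , drop = FALSE], c(0.1, 0.3), 0, -14.4)$x_mm, 5)
  expect_null(select_darkest(fr, cands[0, ], c(0.1, 0.3)))
  expect_null(select_darkest(fr, NULL))
})

test_that("consensus selects the modal quantized triad and flags weak support", {
  mk <- function(x, y, r, frames) {
    data.frame(x_mm = x, y_mm = y, r_mm = r, score = 1, darkness = 10,
               frame_index = frames)
  }
  same <- mk(2.03, 23.1, 2.55, 1:15)
  d <- consensus(same)
  expect_equal(d$status, "ok")
  expect_equal(d$n_supporting_frames, 15)
  expect_equal(c(d$xc, d$yc, d$rc), c(2.03, 23.1, 2.55))
  # 8 vs 7 majority
  ab <- rbind(mk(2.03, 23.1, 2.55, 1:8), mk(5.0, 20.0, 3.0, 9:15))
  d2 <- consensus(ab)
  expect_equal(d2$xc, 2.03)
  expect_equal(d2$n_supporting_frames, 8)
  # quantization: jittered triads within a bin still agree
  jit <- mk(c(2.06, 2.08, 2.10), 23.1, 2.55, 1:3)
  d3 <- consensus(jit)
  expect_equal(d3$status, "ok")
  # the returned triad quantizes to the modal bin
  expect_equal(round(d3$xc / 0.3), round(2.08 / 0.3))
  expect_equal(consensus(mk(1, 20, 3, 1:2))$status, "failed")
  expect_equal(consensus(same[0, ])$status, "failed")
  expect_equal(consensus(NULL)$status, "failed")
})

test_that("full-sequence segmentation localizes phantom lumens to sub-pixel accuracy", {
  errs <- numeric(0)
  for (s in 1:5) {
    set.seed(s)
    cx <- runif(1, -6, 6); cy <- runif(1, 19, 28); r <- runif(1, 2.2, 3.9)
    tr <- phantom_truth(center_x = cx, center_y = cy, radius = r, seed = s + 300)
    det <- segment_sequence(make_phantom_sequence(tr, n_frames = 15))
    expect_equal(det$status, "ok")
    errs <- c(errs, distance_error(c(det$xc, det$yc), c(cx, cy)))
  }
  expect_lt(rms_error(errs), 0.43)
  # mildly elliptical lumen (15 degree tilt) is still found within 1 mm
  trt <- phantom_truth(center_x = -2, center_y = 24, radius = 3, seed = 77,
                       axis_ratio = 1 / cos(15 * pi / 180))
  dett <- segment_sequence(make_phantom_sequence(trt, n_frames = 15))
  expect_equal(dett$status, "ok")
  expect_lt(distance_error(c(dett$xc, dett$yc), c(-2, 24)), 1)
})

test_that("sequences without a credible lumen fail cleanly", {
  tr <- phantom_truth(center_x = 0, center_y = 23, radius = 3, seed = 5)
  det <- segment_sequence(make_phantom_sequence(tr, n_frames = 15, contrast_db = 0))
  expect_equal(det$status, "failed")
  expect_true(is.na(det$xc))
})
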