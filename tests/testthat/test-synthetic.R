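test_that("forward model and triangulation are exact inverses", {
  geom <- nominal_geom(); cfg <- nominal_cfg()
  set.seed(1)
  Vx <- runif(100, -2, 2); Vz <- runif(100, -2, 2)
  f <- forward_doppler_freqs(Vx, Vz, geom, cfg)
  v <- triangulate(f$fdr, f$fdl, geom, cfg)
  expect_equal(v$Vx, Vx, tolerance = 1e-12)
  expect_equal(v$Vz, Vz, tolerance = 1e-12)
  # and in the other direction, on the frequency pair
  f2 <- forward_doppler_freqs(v$Vx, v$Vz, geom, cfg)
  expect_equal(f2$fdr, f$fdr, tolerance = 1e-12)
  expect_equal(f2$fdl, f$fdl, tolerance = 1e-12)
})

test_that("forward model reproduces the worked dual-beam shifts", {
  geom <- nominal_geom(); cfg <- nominal_cfg()
  f <- forward_doppler_freqs(0.34, 0, geom, cfg)
  expect_equal(f$fdr, 857.1, tolerance = 1e-3)  # 2 ftx/c * 0.34 * sin(15 deg)
  expect_equal(f$fdl, -857.1, tolerance = 1e-3)
  # purely axial motion hits both beams identically
  fz <- forward_doppler_freqs(0, 0.2, geom, cfg)
  expect_equal(fz$fdr, fz$fdl)
  f0 <- forward_doppler_freqs(0, 0, geom, cfg)
  expect_equal(c(f0$fdr, f0$fdl), c(0, 0))
})

test_that("parabolic profile has centreline maximum and vanishes at the wall", {
  expect_equal(parabolic_profile(0, 3, 0.5), 0.5)
  expect_equal(parabolic_profile(3, 3, 0.5), 0)
  expect_equal(parabolic_profile(1.5, 3, 1), 0.75)
  expect_equal(parabolic_profile(4, 3, 1), 0)
  expect_equal(parabolic_profile(c(0, 2.9, 3.1), 3, 1, shape = "plug"), c(1, 1, 0))
})

test_that("pulsatile waveform peaks at the requested velocity with one systole per beat", {
  w <- pulsatile_waveform(0.67, beats_per_min = 60, duration_s = 2)
  expect_equal(max(w$velocity), 0.67)
  expect_true(min(w$velocity) >= 0)
  # count systolic maxima: upward crossings of 80% of the peak
  above <- w$velocity > 0.8 * 0.67
  expect_equal(sum(diff(above) == 1), 2)
  # steady mode
  ws <- pulsatile_waveform(0.34, beats_per_min = 0, duration_s = 1)
  expect_true(all(ws$velocity == 0.34))
  expect_error(pulsatile_waveform(1, duration_s = 0), "positive")
})

test_that("phantom sequences have the requested shape and record their truth", {
  tr <- phantom_truth(center_x = 1, center_y = 22, radius = 2.8, seed = 3)
  seq <- make_phantom_sequence(tr, n_frames = 15)
  expect_s3_class(seq, "bmode_sequence")
  expect_equal(dim(seq$frames)[3], 15)
  expect_identical(attr(seq, "truth"), tr)
  expect_true(all(seq$frames >= 0 & seq$frames <= 255))
  # frames are distinct speckle realizations
  expect_gt(mean(abs(seq$frames[, , 1] - seq$frames[, , 2])), 1)
  expect_error(make_phantom_sequence(phantom_truth(center_y = 4)), "outside")
})

test_that("an anechoic lumen is rendered black away from the boundary", {
  tr <- phantom_truth(center_x = 0, center_y = 23, radius = 3, seed = 9)
  seq <- make_phantom_sequence(tr, n_frames = 1, contrast_db = -Inf)
  yy <- seq$depth_origin_mm + (seq_len(dim(seq$frames)[1]) - 0.5) * seq$pixel_spacing_mm[1]
  xx <- seq$lateral_origin_mm + (seq_len(dim(seq$frames)[2]) - 0.5) * seq$pixel_spacing_mm[2]
  core <- outer((yy - 23)^2, (xx - 0)^2, "+") <= (0.5 * 3)^2
  expect_lt(mean(seq$frames[, , 1][core]), 1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  tr <- phantom_truth(seed = 17)
  expect_identical(make_phantom_sequence(tr, n_frames = 2),
                   make_phantom_sequence(tr, n_frames = 2))
  geom <- nominal_geom(); cfg <- nominal_cfg()
  a <- simulate_iq_pair(steady_flow(), 23, geom, cfg, seed = 5, duration_s = 0.1)
  b <- simulate_iq_pair(steady_flow(), 23, geom, cfg, seed = 5, duration_s = 0.1)
  expect_identical(a$left$samples, b$left$samples)
  expect_identical(a$right$samples, b$right$samples)
  c <- simulate_iq_pair(steady_flow(), 23, geom, cfg, seed = 6, duration_s = 0.1)
  expect_false(identical(a$left$samples, c$left$samples))
})

test_that("simulated gates carry the forward-model frequency and clutter is removable", {
  geom <- nominal_geom(); cfg <- nominal_cfg()
  iq <- simulate_iq_pair(steady_flow(v = 0.34, R = 3), 23, geom, cfg,
                         snr_db = Inf, clutter_db = -Inf, seed = 2, duration_s = 0.5)
  fm <- frequency_map(iq$right, cfg)
  ctr <- which.min(abs(fm$gate_depths_mm - 23))
  f_true <- forward_doppler_freqs(0.34, 0, geom, cfg)$fdr
  bin <- cfg$prf_per_beam / cfg$packet_size
  expect_lt(max(abs(fm$fd[, ctr] - f_true)), bin)
  # clutter+noise-only gates: post-filter power approaches the noise power
  iq2 <- simulate_iq_pair(steady_flow(), 23, geom, cfg,
                          snr_db = 20, clutter_db = 40, seed = 3, duration_s = 0.5)
  far <- which(abs(gate_depths(iq2$left) - 23) > 5)    # outside the lumen
  sub <- duodop:::subset_gates(iq2$left, far)
  filt <- clutter_filter(sub, cfg$clutter_cutoff)
  # discard the (padded) leading edge before measuring residual power
  resid <- mean(Mod(filt$samples[, -(1:500)])^2)
  noise_power <- 10^(-20 / 10)
  expect_lt(abs(10 * log10(resid / noise_power)), 1)
})
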