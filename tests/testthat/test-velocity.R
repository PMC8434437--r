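test_that("ROI selection centres a 6 mm window on the mean lumen depth", {
  gates <- seq(10, 40, by = 0.2)
  roi <- select_roi(20.2, 20.2, gates, 6)
  expect_equal(range(gates[roi]), c(17.2, 23.2))
  roi2 <- select_roi(20, 22, gates, 6)
  expect_equal(range(gates[roi2]), c(18, 24))
  # clamping at the shallow end preserves the extent
  roi3 <- select_roi(10.5, 10.5, gates, 6)
  expect_equal(gates[roi3][1], 10)
  expect_equal(diff(range(gates[roi3])), 6)
  expect_error(select_roi(80, 80, gates, 6), "outside")
})

test_that("triangulation inverts the worked example and handles symmetry", {
  geom <- nominal_geom(); cfg <- nominal_cfg()
  v <- triangulate(857.128, -857.128, geom, cfg)
  expect_equal(v$Vx, 0.34, tolerance = 1e-4)
  expect_equal(v$Vz, 0, tolerance = 1e-12)
  vs <- triangulate(500, 500, geom, cfg)
  expect_equal(vs$Vx, 0)
  v0 <- triangulate(0, 0, geom, cfg)
  expect_equal(c(v0$Vx, v0$Vz), c(0, 0))
  expect_true(is.na(triangulate(NA_real_, 100, geom, cfg)$Vx))
})

test_that("velocity magnitude is the Euclidean norm", {
  expect_equal(velocity_magnitude(3, 4), 5)
  expect_equal(velocity_magnitude(-0.7, 0), 0.7)
  expect_equal(velocity_magnitude(0, 0), 0)
})

test_that("peak extraction takes the maximum over defined cells only", {
  vmap <- structure(list(
    Vx = matrix(c(0.1, 0.3, NA, 0.67, 0.2, 0.1), 2),
    Vz = matrix(0, 2, 3),
    V = matrix(c(0.1, 0.3, NA, 0.67, 0.2, 0.1), 2),
    packet_times = c(0.1, 0.2), gate_depths_mm = c(20, 21, 22)
  ), class = "velocity_map")
  res <- peak_velocity(vmap)
  expect_equal(res$peak_velocity, 0.67)
  expect_equal(res$peak_time, 0.2)
  expect_equal(res$peak_depth_mm, 21)
  expect_equal(res$status, "ok")
  # single defined cell
  vone <- vmap; vone$V[] <- NA; vone$V[1, 3] <- 0.5; vone$Vx <- vone$V
  expect_equal(peak_velocity(vone)$peak_velocity, 0.5)
  vnone <- vmap; vnone$V[] <- NA_real_
  expect_equal(peak_velocity(vnone)$status, "discarded")
  expect_equal(peak_velocity(vnone)$discard_reason, "no signal")
})

test_that("validation discards wrong-direction and implausible measurements", {
  mk_map <- function(vx) {
    structure(list(Vx = matrix(vx, 1), Vz = matrix(0, 1, length(vx)),
                   V = matrix(abs(vx), 1), packet_times = 0.1,
                   gate_depths_mm = seq_along(vx) + 19),
              class = "velocity_map")
  }
  geom <- nominal_geom(); cfg <- nominal_cfg()
  # jugular-like flow: lateral velocity opposite to expectation
  vm <- mk_map(c(-0.5, -0.6, -0.55))
  res <- validate_measurement(peak_velocity(vm), vm, expected_flow_sign = 1,
                              geom = geom, cfg = cfg)
  expect_equal(res$status, "discarded")
  expect_equal(res$discard_reason, "wrong direction")
  # above the full-PRF geometric limit (~3.17 m/s at 75 degrees)
  vfast <- mk_map(c(5, 0.2, 0.2))
  resf <- validate_measurement(peak_velocity(vfast), vfast, geom = geom, cfg = cfg)
  expect_equal(resf$status, "discarded")
  expect_equal(resf$discard_reason, "implausible")
  # normal carotid-like flow passes
  vok <- mk_map(c(0.3, 0.34, 0.32))
  resk <- validate_measurement(peak_velocity(vok), vok, geom = geom, cfg = cfg)
  expect_equal(resk$status, "ok")
  # below the noise floor
  vlow <- mk_map(c(0.01, 0.02, 0.01))
  resl <- validate_measurement(peak_velocity(vlow), vlow, geom = geom, cfg = cfg)
  expect_equal(resl$discard_reason, "implausible")
})

test_that("peak over the map is invariant under packet permutation", {
  set.seed(3)
  V <- matrix(runif(50, 0, 0.8), 10, 5)
  mk <- function(V) structure(list(Vx = V, Vz = 0 * V, V = V,
                                   packet_times = seq_len(nrow(V)) * 8e-3,
                                   gate_depths_mm = seq_len(ncol(V)) + 20),
                              class = "velocity_map")
  p1 <- peak_velocity(mk(V))
  perm <- sample(nrow(V))
  p2 <- peak_velocity(mk(V[perm, , drop = FALSE]))
  expect_equal(p1$peak_velocity, p2$peak_velocity)
  expect_equal(p1$peak_depth_mm, p2$peak_depth_mm)
})
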