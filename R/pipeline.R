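# End-to-end orchestration: the phases a scanner would run automatically
# (B-mode grab -> lumen localization -> Doppler ROI -> spectral processing ->
# triangulation -> peak extraction -> validity checks), plus the simulation
# campaigns that emulate the phantom experiment series.

# Tiny polynomial hash of the effective configuration, embedded in results so
# a measurement can be traced to the exact parameters that produced it.
config_digest <- function(...) {
  s <- jsonlite::toJSON(lapply(list(...), unclass), auto_unbox = TRUE, digits = 10)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full automatic measurement
#'
#' Segments both B-mode sequences, averages the two lumen depths to place the
#' Doppler region of interest, computes the centroid-frequency maps of both
#' beams over the ROI gates, triangulates them into the angle-corrected
#' velocity map, extracts the peak and applies the validity checks.
#'
#' @param bmode_left,bmode_right [bmode_sequence()]s from the two arrays.
#' @param iq_left,iq_right [iq_ensemble()]s from the two beams (same gate
#'   grid).
#' @param geom A [probe_geometry()].
#' @param cfg An [acquisition_config()].
#' @param expected_flow_sign Expected sign of the lateral velocity (+1/-1).
#' @param seg_params Parameter overrides for [segment_sequence()].
#' @param centroid_params Parameter overrides for [centroid_frequency()].
#' @param keep_intermediate Attach detections, frequency maps and the
#'   velocity map to the result (`$details`).
#' @return A [measurement_result()]; when segmentation fails on either side
#'   the result is discarded with reason `"segmentation failed"`.
#' @export
run_measurement <- function(bmode_left, bmode_right, iq_left, iq_right,
                            geom, cfg, expected_flow_sign = 1,
                            seg_params = list(), centroid_params = list(),
                            keep_intermediate = FALSE) {
  stopifnot(inherits(iq_left, "iq_ensemble"), inherits(iq_right, "iq_ensemble"),
            isTRUE(all.equal(gate_depths(iq_left), gate_depths(iq_right))))
  det_l <- segment_sequence(bmode_left, seg_params)
  det_r <- segment_sequence(bmode_right, seg_params)
  prov <- list(config = config_digest(geom, cfg))
  if (det_l$status != "ok" || det_r$status != "ok") {
    res <- measurement_result(NA_real_, status = "discarded",
                              discard_reason = "segmentation failed",
                              provenance = prov)
    if (keep_intermediate) res$details <- list(det_left = det_l, det_right = det_r)
    return(res)
  }
  roi <- select_roi(det_l$yc, det_r$yc, gate_depths(iq_left),
                    roi_extent_mm = cfg$roi_extent * 1e3)
  fm_l <- frequency_map(subset_gates(iq_left, roi), cfg, centroid_params)
  fm_r <- frequency_map(subset_gates(iq_right, roi), cfg, centroid_params)
  vmap <- velocity_map(fm_l, fm_r, geom, cfg)
  res <- peak_velocity(vmap)
  res <- validate_measurement(res, vmap, expected_flow_sign,
                              geom = geom, cfg = cfg)
  res$provenance <- prov
  if (keep_intermediate) {
    res$details <- list(det_left = det_l, det_right = det_r,
                        roi_gates = roi, vmap = vmap)
  }
  res
}

#' Simulate one complete dual-beam acquisition
#'
#' Generates everything the measurement pipeline consumes: two 15-frame
#' B-mode sequences of the same lumen (independent speckle per array) and the
#' dual-beam IQ ensembles of the flow inside it. All randomness derives from
#' `seed`.
#'
#' @param truth A [phantom_truth()] (its `seed` field is overridden by the
#'   derived per-array seeds).
#' @param flow A [flow_truth()].
#' @param geom,cfg Geometry and acquisition configuration.
#' @param snr_db,clutter_db Doppler signal conditions, see
#'   [simulate_iq_pair()].
#' @param seed Master integer seed.
#' @param ... Further arguments to [make_phantom_sequence()]
#'   (`contrast_db`, `speckle_params`, ...).
#' @return List: `bmode_left`, `bmode_right`, `iq_left`, `iq_right`, `truth`.
#' @export
simulate_acquisition <- function(truth, flow, geom, cfg,
                                 snr_db = 20, clutter_db = 40, seed = 1L, ...) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(flow, "flow_truth"))
  set.seed(seed)
  sub <- sample.int(2^31 - 2, 3)
  t_l <- truth; t_l$side <- "left"; t_l$seed <- sub[1]
  t_r <- truth; t_r$side <- "right"; t_r$seed <- sub[2]
  bl <- make_phantom_sequence(t_l, n_frames = cfg$bmode_frames, ...)
  br <- make_phantom_sequence(t_r, n_frames = cfg$bmode_frames, ...)
  iq <- simulate_iq_pair(flow, truth$center_y, geom, cfg,
                         snr_db = snr_db, clutter_db = clutter_db, seed = sub[3])
  list(bmode_left = bl, bmode_right = br,
       iq_left = iq$left, iq_right = iq$right,
       truth = list(phantom = truth, flow = flow, seed = seed,
                    snr_db = snr_db, clutter_db = clutter_db))
}

#' Campaign specification
#'
#' Describes one series of simulated probe-positioning experiments. The
#' default grids mirror the in-vitro series: tilt -15..+15 degrees, rotation
#' 0..20 degrees, random lateral translation, and lumen depth 19-30 mm.
#'
#' @param series `"tilt"`, `"rotation"`, `"translation"`, or `"depth"`.
#' @param grid Numeric parameter grid; `NULL` for the series default.
#' @param n_repeats Acquisitions per grid point.
#' @param base_seed Master seed; everything downstream derives from it.
#' @param flow A [flow_truth()].
#' @param phantom Base [phantom_truth()] that the series transforms.
#' @param geom,cfg Geometry and acquisition configuration.
#' @param snr_db,clutter_db Doppler signal conditions.
#' @param with_doppler Run the full velocity measurement (`TRUE`) or
#'   segmentation only.
#' @return Object of class `campaign_spec`.
#' @export
campaign_spec <- function(series = c("tilt", "rotation", "translation", "depth"),
                          grid = NULL, n_repeats = 1L, base_seed = 1L,
                          flow = flow_truth(pulsatile_waveform(0.34, beats_per_min = 0)),
                          phantom = phantom_truth(),
                          geom = probe_geometry(), cfg = acquisition_config(),
                          snr_db = 20, clutter_db = 40, with_doppler = TRUE) {
  series <- match.arg(series)
  if (is.null(grid)) {
    grid <- switch(series,
      tilt = c(-15, -10, -6, 0, 6, 10, 15),
      rotation = c(0, 3, 6, 12, 16, 20),
      translation = NA_real_,     # drawn at random per repeat
      depth = c(19, 21, 23, 25, 27, 30)
    )
  }
  structure(
    list(series = series, grid = grid, n_repeats = as.integer(n_repeats),
         base_seed = as.integer(base_seed), flow = flow, phantom = phantom,
         geom = geom, cfg = cfg, snr_db = snr_db, clutter_db = clutter_db,
         with_doppler = with_doppler),
    class = "campaign_spec"
  )
}

#' Run a simulation campaign
#'
#' For every grid point and repeat, applies the series' geometric transform
#' to the phantom truth (tilt/rotation -> mild ellipticity, translation ->
#' lateral centre moves, depth -> centre depth), simulates the acquisition,
#' runs the measurement, and scores segmentation (both arrays, merged) and
#' velocity against the ground truth. Deterministic given `base_seed`.
#'
#' @param spec A [campaign_spec()].
#' @param out_csv Optional path; the per-experiment records are written as
#'   CSV.
#' @return List: `records` (one row per experiment: grid value, seed,
#'   left/right localization errors `De_left`/`De_right` in mm, measured peak
#'   `VM` in m/s, `status`) and `summary` (a [evaluate_campaign()]
#'   `summary_stats` over the merged left+right localization records with the
#'   velocity statistics, or `NULL` when `n_repeats` is 0).
#' @export
run_campaign <- function(spec, out_csv = NULL) {
  stopifnot(inherits(spec, "campaign_spec"))
  if (spec$n_repeats < 1 || length(spec$grid) == 0) {
    return(list(records = data.frame(), summary = NULL))
  }
  set.seed(spec$base_seed)
  cases <- expand.grid(rep = seq_len(spec$n_repeats), value = spec$grid)
  seeds <- sample.int(2^31 - 2, nrow(cases))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    tr <- spec$phantom
    val <- cases$value[i]
    if (spec$series %in% c("tilt", "rotation")) {
      tr$axis_ratio <- 1 / cos(deg2rad(val))
    } else if (spec$series == "translation") {
      val <- stats::runif(1, -8, 8)
      tr$center_x <- val
    } else if (spec$series == "depth") {
      tr$center_y <- val
    }
    acq <- simulate_acquisition(tr, spec$flow, spec$geom, spec$cfg,
                                snr_db = spec$snr_db,
                                clutter_db = spec$clutter_db,
                                seed = seeds[i])
    det_l <- segment_sequence(acq$bmode_left)
    det_r <- segment_sequence(acq$bmode_right)
    de <- function(det) {
      if (det$status == "ok") {
        distance_error(c(det$xc, det$yc), c(tr$center_x, tr$center_y))
      } else NA_real_
    }
    vm <- NA_real_; status <- "segmentation only"
    if (spec$with_doppler) {
      res <- run_measurement(acq$bmode_left, acq$bmode_right,
                             acq$iq_left, acq$iq_right, spec$geom, spec$cfg)
      vm <- if (res$status == "ok") res$peak_velocity else NA_real_
      status <- if (res$status == "ok") "ok" else res$discard_reason
    }
    rows[[i]] <- data.frame(series = spec$series, value = val,
                            rep = cases$rep[i], seed = seeds[i],
                            De_left = de(det_l), De_right = de(det_r),
                            VM = vm, status = status)
  }
  records <- do.call(rbind, rows)
  merged <- data.frame(
    De = c(records$De_left, records$De_right),
    VM = rep(records$VM, 2)
  )
  merged$De[!is.finite(merged$De)] <- Inf  # failed segmentations count as discards
  summary <- evaluate_campaign(merged, VR = spec$flow$peak_velocity)
  if (!is.null(out_csv)) utils::write.csv(records, out_csv, row.names = FALSE)
  list(records = records, summary = summary)
}
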