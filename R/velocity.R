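#' Doppler region-of-interest gate selection
#'
#' The lumen depths found independently on the two B-mode sequences are
#' averaged and used as the centre of an axial region of interest of total
#' extent `roi_extent_mm` (default 6 mm), within which the maximum velocity is
#' presumed to lie. The window is clamped to the available gates while
#' preserving its extent when possible.
#'
#' @param depth_left_mm,depth_right_mm Lumen depths from the two arrays (mm).
#' @param gate_depths_mm Depths of the available gates (mm), ascending.
#' @param roi_extent_mm Total ROI extent (mm).
#' @return Integer vector of contiguous gate indices.
#' @export
select_roi <- function(depth_left_mm, depth_right_mm, gate_depths_mm,
                       roi_extent_mm = 6) {
  stopifnot(is.finite(depth_left_mm), is.finite(depth_right_mm),
            length(gate_depths_mm) >= 1, roi_extent_mm > 0)
  ctr <- (depth_left_mm + depth_right_mm) / 2
  lo <- ctr - roi_extent_mm / 2
  hi <- ctr + roi_extent_mm / 2
  gmin <- gate_depths_mm[1]; gmax <- gate_depths_mm[length(gate_depths_mm)]
  if (hi < gmin || lo > gmax) stop("ROI entirely outside the gated depth range")
  if (lo < gmin) { hi <- hi + (gmin - lo); lo <- gmin }
  if (hi > gmax) { lo <- max(gmin, lo - (hi - gmax)); hi <- gmax }
  idx <- which(gate_depths_mm >= lo - 1e-9 & gate_depths_mm <= hi + 1e-9)
  if (length(idx) == 0) idx <- which.min(abs(gate_depths_mm - ctr))
  idx
}

#' Dual-beam velocity triangulation
#'
#' Combines the centroid frequencies seen by the right and left beams at the
#' same depth and time into the 2-D velocity vector:
#' `Vx = c (fdr - fdl) / (4 ftx sin(theta/2))`,
#' `Vz = c (fdr + fdl) / (4 ftx cos(theta/2))`.
#' Exact inverse of [forward_doppler_freqs()].
#'
#' @param fdr,fdl Doppler centroid frequencies of the right and left beams
#'   (Hz); vectorized, `NA` propagates.
#' @param geom A [probe_geometry()] (inter-angle must be in (0, 90)).
#' @param cfg An [acquisition_config()] (sound speed).
#' @return List with `Vx`, `Vz` (m/s).
#' @export
triangulate <- function(fdr, fdl, geom, cfg) {
  stopifnot(inherits(geom, "probe_geometry"), inherits(cfg, "acquisition_config"))
  th2 <- deg2rad(geom$inter_angle_theta) / 2
  if (sin(th2) < 1e-12) stop("inter-angle of zero: lateral component undefined")
  k <- cfg$sound_speed_c / (4 * geom$tx_frequency_ftx)
  list(Vx = k * (fdr - fdl) / sin(th2),
       Vz = k * (fdr + fdl) / cos(th2))
}

#' Angle-corrected velocity magnitude
#'
#' @param Vx,Vz Velocity components (m/s); vectorized.
#' @return `sqrt(Vx^2 + Vz^2)` (m/s), non-negative.
#' @export
velocity_magnitude <- function(Vx, Vz) sqrt(Vx^2 + Vz^2)

#' Angle-corrected velocity map from two frequency maps
#'
#' Packet k of the right map is paired with packet k of the left map (the
#' two beams are interleaved fast enough that the sub-sample offset is
#' negligible at cardiac time scales). Cells where either side's centroid is
#' undefined are undefined in the map (strict intersection).
#'
#' @param fmap_left,fmap_right [frequency_map()]s of the left and right
#'   beams over the same ROI gates.
#' @param geom,cfg Geometry and acquisition configuration.
#' @return Object of class `velocity_map`: matrices `Vx`, `Vz`, `V`
#'   (`n_packets x n_gates`, m/s), `packet_times`, `gate_depths_mm`.
#' @export
velocity_map <- function(fmap_left, fmap_right, geom, cfg) {
  stopifnot(inherits(fmap_left, "frequency_map"),
            inherits(fmap_right, "frequency_map"),
            all(dim(fmap_left$fd) == dim(fmap_right$fd)))
  v <- triangulate(fmap_right$fd, fmap_left$fd, geom, cfg)
  structure(
    list(Vx = v$Vx, Vz = v$Vz, V = velocity_magnitude(v$Vx, v$Vz),
         packet_times = fmap_right$packet_times,
         gate_depths_mm = fmap_right$gate_depths_mm),
    class = "velocity_map"
  )
}

#' Peak-velocity extraction
#'
#' The single output of the measurement: the maximum angle-corrected velocity
#' magnitude over all defined (packet, gate) cells, with the time and depth
#' where it occurs. Undefined cells are ignored; ties resolve to the earliest
#' packet, then the shallowest gate.
#'
#' @param vmap A [velocity_map()].
#' @return Object of class `measurement_result`: `peak_velocity` (m/s),
#'   `peak_time` (s), `peak_depth_mm`, `status` (`"ok"`/`"discarded"`),
#'   `discard_reason`.
#' @export
peak_velocity <- function(vmap) {
  stopifnot(inherits(vmap, "velocity_map"))
  V <- vmap$V
  if (!any(is.finite(V))) {
    return(measurement_result(NA_real_, NA_real_, NA_real_,
                              status = "discarded", discard_reason = "no signal"))
  }
  mx <- max(V, na.rm = TRUE)
  w <- which(V == mx, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
  measurement_result(mx,
                     peak_time = vmap$packet_times[w[1]],
                     peak_depth_mm = vmap$gate_depths_mm[w[2]],
                     status = "ok")
}

#' Measurement result
#'
#' @param peak_velocity Peak velocity (m/s).
#' @param peak_time Time of the peak (s).
#' @param peak_depth_mm Depth of the peak (mm).
#' @param status `"ok"` or `"discarded"`.
#' @param discard_reason Reason when discarded.
#' @param provenance Optional list (config digest, seeds).
#' @return Object of class `measurement_result`.
#' @export
measurement_result <- function(peak_velocity, peak_time = NA_real_,
                               peak_depth_mm = NA_real_,
                               status = c("ok", "discarded"),
                               discard_reason = NA_character_,
                               provenance = NULL) {
  status <- match.arg(status)
  structure(
    list(peak_velocity = peak_velocity, peak_time = peak_time,
         peak_depth_mm = peak_depth_mm, status = status,
         discard_reason = discard_reason, provenance = provenance),
    class = "measurement_result"
  )
}

#' @export
print.measurement_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Peak velocity %.3f m/s at t = %.3f s, depth %.1f mm\n",
                x$peak_velocity, x$peak_time, x$peak_depth_mm))
  } else {
    cat(sprintf("Measurement discarded: %s\n", x$discard_reason))
  }
  invisible(x)
}

#' Plausibility and flow-direction checks
#'
#' Basic automatic rejection of obviously incorrect measurements. If the sign
#' of the lateral velocity at the peak and the sign of the map-median lateral
#' velocity both contradict the expected flow direction (as happens when the
#' probe locks on the jugular vein, whose flow is counter to the carotid),
#' the result is discarded with reason `"wrong direction"`. A peak outside
#' the plausibility band (default 0.05 m/s to the full-PRF geometric limit)
#' is discarded as `"implausible"`.
#'
#' @param result A [measurement_result()] from [peak_velocity()].
#' @param vmap The [velocity_map()] the result came from.
#' @param expected_flow_sign +1 or -1; the device orientation on the neck
#'   fixes it (default +1: flow from the left array toward the right array).
#' @param v_min Lower plausibility bound (m/s).
#' @param v_max Upper plausibility bound (m/s); defaults to
#'   [max_detectable_velocity()] at the first Doppler angle when `geom` and
#'   `cfg` are supplied, else 3 m/s.
#' @param geom,cfg Optional geometry/configuration for the default `v_max`.
#' @return The (possibly discarded) `measurement_result`.
#' @export
validate_measurement <- function(result, vmap, expected_flow_sign = 1,
                                 v_min = 0.05, v_max = NULL,
                                 geom = NULL, cfg = NULL) {
  stopifnot(inherits(result, "measurement_result"), inherits(vmap, "velocity_map"))
  if (result$status != "ok") return(result)
  if (is.null(v_max)) {
    v_max <- if (!is.null(geom) && !is.null(cfg)) {
      max_detectable_velocity(cfg, geom, doppler_angles(geom)[1])
    } else 3.0
  }
  ip <- which(vmap$packet_times == result$peak_time)[1]
  ig <- which(vmap$gate_depths_mm == result$peak_depth_mm)[1]
  vx_peak <- vmap$Vx[ip, ig]
  vx_med <- stats::median(vmap$Vx[is.finite(vmap$Vx)])
  if (sign(vx_peak) == -expected_flow_sign && sign(vx_med) == -expected_flow_sign) {
    result$status <- "discarded"
    result$discard_reason <- "wrong direction"
    return(result)
  }
  if (result$peak_velocity < v_min || result$peak_velocity > v_max) {
    result$status <- "discarded"
    result$discard_reason <- "implausible"
  }
  result
}

#' Write a measurement result as JSON
#'
#' @param result A [measurement_result()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_json <- function(result, path) {
  stopifnot(inherits(result, "measurement_result"))
  doc <- list(peak_velocity_m_s = result$peak_velocity,
              peak_time_s = result$peak_time,
              peak_depth_mm = result$peak_depth_mm,
              status = result$status,
              discard_reason = result$discard_reason,
              provenance = result$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
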