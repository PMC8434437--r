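#' Dual-array probe geometry
#'
#' Describes the transversal dual linear-array probe: two identical arrays
#' whose depth axes form an inter-angle `inter_angle_theta`, so that the two
#' Doppler beams interrogate the flow from two known directions and the 2-D
#' velocity vector can be recovered without manual angle correction.
#'
#' All lengths are in metres, frequencies in Hz, angles in degrees at the
#' interface (converted to radians internally).
#'
#' @param n_elements Number of transducer elements per array.
#' @param active_elements Number of elements used in the active aperture.
#' @param pitch Element pitch (m).
#' @param inter_angle_theta Angle between the two array axes (degrees),
#'   strictly inside (0, 90).
#' @param array_gap Gap between the two arrays at the skin plane (m).
#' @param cross_depth Depth at which the two beam axes cross (m). Taken as
#'   the authoritative geometric given; the beam-origin separation is derived
#'   from it (see [beam_origin_separation()]).
#' @param tx_frequency_ftx Transmission frequency (Hz).
#' @param tx_cycles Number of sinusoidal cycles per Doppler transmission.
#' @param elevation_focus Elevation focus depth (m).
#'
#' @return An object of class `probe_geometry`.
#' @examples
#' geom <- probe_geometry()
#' doppler_angles(geom)
#' @export
probe_geometry <- function(n_elements = 128L,
                           active_elements = 96L,
                           pitch = 300e-6,
                           inter_angle_theta = 30,
                           array_gap = 11e-3,
                           cross_depth = 23e-3,
                           tx_frequency_ftx = 7.5e6,
                           tx_cycles = 3L,
                           elevation_focus = 20e-3) {
  stopifnot(
    inter_angle_theta > 0, inter_angle_theta < 90,
    pitch > 0,
    active_elements <= n_elements, active_elements >= 0,
    tx_frequency_ftx > 0,
    tx_cycles >= 1
  )
  structure(
    list(
      n_elements = as.integer(n_elements),
      active_elements = as.integer(active_elements),
      pitch = pitch,
      inter_angle_theta = inter_angle_theta,
      array_gap = array_gap,
      cross_depth = cross_depth,
      tx_frequency_ftx = tx_frequency_ftx,
      tx_cycles = as.integer(tx_cycles),
      elevation_focus = elevation_focus
    ),
    class = "probe_geometry"
  )
}

#' Acquisition configuration
#'
#' Parameters of the combined B-mode + multigate Doppler acquisition. The PRF
#' is per beam: the two arrays are interleaved so the combined transmission
#' rate is twice `prf_per_beam`.
#'
#' @param sound_speed_c Speed of sound in tissue (m/s). Default 1540 m/s,
#'   the standard soft-tissue value.
#' @param prf_per_beam Pulse repetition frequency for each beam (Hz).
#' @param packet_size Slow-time samples per spectral estimation packet.
#' @param packet_overlap Fractional overlap between consecutive packets,
#'   in \[0, 1).
#' @param clutter_cutoff Wall-filter cutoff frequency (Hz).
#' @param n_gates Number of depth gates of the multigate ensemble.
#' @param gate_spacing Axial spacing between consecutive gates (m).
#' @param roi_extent Total axial extent of the Doppler region of interest (m).
#' @param bmode_frames Number of B-mode frames acquired per array.
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sound_speed_c = 1540,
                               prf_per_beam = 8000,
                               packet_size = 128L,
                               packet_overlap = 0.5,
                               clutter_cutoff = 100,
                               n_gates = 512L,
                               gate_spacing = 0.2e-3,
                               roi_extent = 6e-3,
                               bmode_frames = 15L) {
  stopifnot(
    sound_speed_c > 0,
    prf_per_beam > 0,
    packet_size >= 2,
    packet_overlap >= 0, packet_overlap < 1,
    prf_per_beam > 2 * clutter_cutoff,
    n_gates >= 1, gate_spacing > 0,
    roi_extent > 0, bmode_frames >= 1
  )
  structure(
    list(
      sound_speed_c = sound_speed_c,
      prf_per_beam = prf_per_beam,
      packet_size = as.integer(packet_size),
      packet_overlap = packet_overlap,
      clutter_cutoff = clutter_cutoff,
      n_gates = as.integer(n_gates),
      gate_spacing = gate_spacing,
      roi_extent = roi_extent,
      bmode_frames = as.integer(bmode_frames)
    ),
    class = "acquisition_config"
  )
}

deg2rad <- function(deg) deg * pi / 180

#' Doppler angles of the two beams
#'
#' For a vessel running parallel to the skin, each beam makes a Doppler angle
#' of 90 degrees minus (or plus) half the inter-angle with the flow axis:
#' `(90 - theta/2, 90 + theta/2)`.
#'
#' @param geom A [probe_geometry()].
#' @return Numeric vector of two angles (degrees), summing to 180.
#' @export
doppler_angles <- function(geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  half <- geom$inter_angle_theta / 2
  c(90 - half, 90 + half)
}

#' Maximum unambiguous depth
#'
#' The echo from one transmission must return before the next transmission of
#' the same beam: depth limit `c / (2 * PRF)`.
#'
#' @param cfg An [acquisition_config()].
#' @return Depth (m).
#' @export
max_unambiguous_depth <- function(cfg) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (cfg$prf_per_beam <= 0) stop("PRF must be positive")
  cfg$sound_speed_c / (2 * cfg$prf_per_beam)
}

#' Maximum detectable velocity
#'
#' Velocity corresponding to the largest measurable Doppler shift at the given
#' beam-to-flow angle. With `limit = "full"` the whole PRF range is exploited
#' (maximum shift = PRF), giving `c * PRF / (2 * ftx * |cos(angle)|)`; with
#' `limit = "nyquist"` the conventional +/- PRF/2 limit is used (half the
#' full-range value).
#'
#' @param cfg An [acquisition_config()].
#' @param geom A [probe_geometry()].
#' @param angle Doppler angle between beam and flow (degrees); must not be
#'   exactly 90 (cosine zero).
#' @param limit `"full"` (default) or `"nyquist"`.
#' @return Velocity (m/s).
#' @export
max_detectable_velocity <- function(cfg, geom, angle, limit = c("full", "nyquist")) {
  stopifnot(inherits(cfg, "acquisition_config"), inherits(geom, "probe_geometry"))
  limit <- match.arg(limit)
  cosa <- abs(cos(deg2rad(angle)))
  if (cosa < 1e-12) stop("Doppler angle of 90 degrees: velocity undefined")
  fd_max <- if (limit == "full") cfg$prf_per_beam else cfg$prf_per_beam / 2
  cfg$sound_speed_c * fd_max / (2 * geom$tx_frequency_ftx * cosa)
}

#' Axial extent of the Doppler sample volume
#'
#' A burst of `tx_cycles` cycles at `ftx` occupies `tx_cycles * c / ftx`
#' axially (one wavelength per cycle).
#'
#' @inheritParams max_detectable_velocity
#' @return Length (m).
#' @export
sample_volume_axial_extent <- function(geom, cfg) {
  stopifnot(inherits(geom, "probe_geometry"), inherits(cfg, "acquisition_config"))
  geom$tx_cycles * cfg$sound_speed_c / geom$tx_frequency_ftx
}

#' Active aperture length
#'
#' @param n_active Number of active elements.
#' @param pitch Element pitch (m).
#' @return Aperture length (m).
#' @examples
#' active_aperture(96, 300e-6) # 28.8 mm
#' @export
active_aperture <- function(n_active, pitch) {
  stopifnot(n_active >= 0, pitch > 0)
  n_active * pitch
}

#' Depth at which the two beam axes cross
#'
#' For beam origins separated by `s` at the skin plane and tilted towards each
#' other with inter-angle `theta`, the axes meet at depth `s / (2 tan(theta/2))`.
#'
#' @param beam_origin_separation Separation of the two beam origins at the
#'   skin plane (m).
#' @param theta Inter-angle between the beam axes (degrees), > 0.
#' @return Crossing depth (m).
#' @export
beam_cross_depth <- function(beam_origin_separation, theta) {
  if (theta <= 0) stop("parallel beams never cross (theta must be > 0)")
  beam_origin_separation / (2 * tan(deg2rad(theta) / 2))
}

#' Beam-origin separation implied by the crossing depth
#'
#' Inverse of [beam_cross_depth()]: the nominal crossing depth is treated as
#' the authoritative geometric given and the origin separation derived from it.
#'
#' @param geom A [probe_geometry()].
#' @return Separation (m).
#' @export
beam_origin_separation <- function(geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  2 * geom$cross_depth * tan(deg2rad(geom$inter_angle_theta) / 2)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("Dual-array probe geometry\n")
  cat(sprintf("  %d elements/array (%d active), pitch %.0f um -> aperture %.1f mm\n",
              x$n_elements, x$active_elements, x$pitch * 1e6,
              active_aperture(x$active_elements, x$pitch) * 1e3))
  cat(sprintf("  inter-angle %.1f deg, axes cross at %.1f mm\n",
              x$inter_angle_theta, x$cross_depth * 1e3))
  cat(sprintf("  ftx %.2f MHz, %d TX cycles\n", x$tx_frequency_ftx / 1e6, x$tx_cycles))
  invisible(x)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("Acquisition configuration\n")
  cat(sprintf("  c = %g m/s, PRF %g Hz/beam, packets %d @ %.0f%% overlap\n",
              x$sound_speed_c, x$prf_per_beam, x$packet_size, 100 * x$packet_overlap))
  cat(sprintf("  clutter cutoff %g Hz, %d gates @ %.3f mm, ROI %.1f mm, %d B-mode frames\n",
              x$clutter_cutoff, x$n_gates, x$gate_spacing * 1e3,
              x$roi_extent * 1e3, x$bmode_frames))
  invisible(x)
}

#' Write / read geometry and acquisition configuration as JSON
#'
#' One JSON document holds both objects; keys mirror the field names and a
#' `units` sub-object states the unit of every field.
#'
#' @param geom A [probe_geometry()].
#' @param cfg An [acquisition_config()].
#' @param path Output file path.
#' @return `write_config_json` returns `path` invisibly; `read_config_json`
#'   returns `list(geometry =, acquisition =)`.
#' @export
write_config_json <- function(geom, cfg, path) {
  stopifnot(inherits(geom, "probe_geometry"), inherits(cfg, "acquisition_config"))
  doc <- list(
    geometry = unclass(geom),
    acquisition = unclass(cfg),
    units = list(
      pitch = "m", array_gap = "m", cross_depth = "m", elevation_focus = "m",
      inter_angle_theta = "deg", tx_frequency_ftx = "Hz",
      sound_speed_c = "m/s", prf_per_beam = "Hz", clutter_cutoff = "Hz",
      gate_spacing = "m", roi_extent = "m"
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- do.call(probe_geometry, doc$geometry)
  cfg <- do.call(acquisition_config, doc$acquisition)
  list(geometry = geom, acquisition = cfg)
}
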