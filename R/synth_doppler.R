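#' Flow waveform and flow ground truth
#'
#' `pulsatile_waveform()` builds a simple periodic carotid-like velocity
#' waveform: one smooth systolic peak per beat over a low diastolic baseline.
#' The waveform is normalized so its maximum equals `peak` exactly and its
#' minimum stays non-negative. With `beats_per_min = 0` the waveform is the
#' constant `peak` (steady pump flow, as in an in-vitro phantom).
#'
#' @param peak Peak velocity (m/s), > 0.
#' @param beats_per_min Heart rate; 0 gives steady flow.
#' @param duration_s Duration (s), > 0.
#' @param baseline_frac Diastolic baseline as a fraction of `peak`.
#' @param dt Sampling step of the stored waveform (s).
#' @return Object of class `flow_waveform`: sampled `time`/`velocity` vectors
#'   plus a vectorized evaluator `fun(t)`.
#' @examples
#' w <- pulsatile_waveform(0.67, 60, 2)
#' max(w$velocity)
#' @export
pulsatile_waveform <- function(peak, beats_per_min = 60, duration_s = 2,
                               baseline_frac = 0.15, dt = 1e-3) {
  stopifnot(peak > 0, beats_per_min >= 0, baseline_frac >= 0, baseline_frac < 1)
  if (duration_s <= 0) stop("duration must be positive")
  if (beats_per_min == 0) {
    fun <- function(t) rep(peak, length(t))
  } else {
    period <- 60 / beats_per_min
    base <- baseline_frac * peak
    fun <- function(t) {
      phase <- (t %% period) / period
      base + (peak - base) * exp(-0.5 * ((phase - 0.25) / 0.06)^2)
    }
  }
  tt <- seq(0, duration_s, by = dt)
  structure(
    list(time = tt, velocity = fun(tt), fun = fun,
         peak = peak, beats_per_min = beats_per_min, duration_s = duration_s),
    class = "flow_waveform"
  )
}

#' @describeIn pulsatile_waveform Flow ground truth: waveform + geometry of
#'   the velocity field. `direction` is the flow axis as a unit vector in the
#'   x-z plane (default `(1, 0)`: parallel to the skin, the nominal carotid
#'   orientation); `profile_radius` is the vessel radius R (mm) and
#'   `profile_shape` the radial velocity profile.
#' @param waveform A `flow_waveform`.
#' @param direction Length-2 numeric, flow axis `(x, z)`; normalized
#'   internally.
#' @param profile_radius Vessel radius R (mm), > 0.
#' @param profile_shape `"parabolic"` (laminar) or `"plug"`.
#' @export
flow_truth <- function(waveform, direction = c(1, 0),
                       profile_radius = 3, profile_shape = c("parabolic", "plug")) {
  stopifnot(inherits(waveform, "flow_waveform"), profile_radius > 0,
            length(direction) == 2, any(direction != 0))
  profile_shape <- match.arg(profile_shape)
  structure(
    list(waveform = waveform,
         direction = direction / sqrt(sum(direction^2)),
         profile_radius = profile_radius,
         profile_shape = profile_shape,
         peak_velocity = max(waveform$velocity)),
    class = "flow_truth"
  )
}

#' Radial velocity profile
#'
#' Laminar (parabolic) profile `Vmax * (1 - (r/R)^2)` for `r <= R`, zero
#' outside; or plug flow (`Vmax` inside, 0 outside).
#'
#' @param r Radial distance from the vessel axis (mm); vectorized.
#' @param R Vessel radius (mm), > 0.
#' @param Vmax Centreline velocity (m/s).
#' @param shape `"parabolic"` or `"plug"`.
#' @return Velocity at `r` (m/s).
#' @export
parabolic_profile <- function(r, R, Vmax, shape = c("parabolic", "plug")) {
  stopifnot(R > 0)
  shape <- match.arg(shape)
  w <- if (shape == "parabolic") pmax(0, 1 - (r / R)^2) else as.numeric(abs(r) <= R)
  Vmax * w
}

#' Forward Doppler model: velocity vector to dual-beam shifts
#'
#' The two beams are tilted by +/- theta/2 about the depth axis, so a velocity
#' `(Vx, Vz)` produces shifts
#' `fdr = (2 ftx / c) (Vx sin(theta/2) + Vz cos(theta/2))` and
#' `fdl = (2 ftx / c) (-Vx sin(theta/2) + Vz cos(theta/2))`.
#' This is the exact algebraic inverse of [triangulate()].
#'
#' @param Vx,Vz Velocity components (m/s); vectorized.
#' @param geom A [probe_geometry()].
#' @param cfg An [acquisition_config()].
#' @return List with numeric `fdr`, `fdl` (Hz).
#' @export
forward_doppler_freqs <- function(Vx, Vz, geom, cfg) {
  stopifnot(inherits(geom, "probe_geometry"), inherits(cfg, "acquisition_config"))
  th2 <- deg2rad(geom$inter_angle_theta) / 2
  k <- 2 * geom$tx_frequency_ftx / cfg$sound_speed_c
  list(fdr = k * (Vx * sin(th2) + Vz * cos(th2)),
       fdl = k * (-Vx * sin(th2) + Vz * cos(th2)))
}

#' Multigate IQ ensemble
#'
#' Complex slow-time samples for a stack of depth gates along one beam.
#'
#' @param samples Complex matrix, `n_gates x n_slow_time`.
#' @param prf Pulse repetition frequency of this beam (Hz).
#' @param gate_spacing_mm Axial gate spacing (mm).
#' @param first_gate_depth_mm Depth of the first gate (mm).
#' @param side `"left"` or `"right"`.
#' @return Object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(samples, prf, gate_spacing_mm, first_gate_depth_mm,
                        side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(is.matrix(samples), is.complex(samples), prf > 0, gate_spacing_mm > 0)
  structure(
    list(samples = samples, prf = prf,
         gate_spacing_mm = gate_spacing_mm,
         first_gate_depth_mm = first_gate_depth_mm,
         side = side),
    class = "iq_ensemble"
  )
}

#' Depths of the gates of an ensemble (mm)
#' @param ens An [iq_ensemble()].
#' @return Numeric vector of gate depths (mm).
#' @export
gate_depths <- function(ens) {
  stopifnot(inherits(ens, "iq_ensemble"))
  ens$first_gate_depth_mm + (seq_len(nrow(ens$samples)) - 1) * ens$gate_spacing_mm
}

#' @export
print.iq_ensemble <- function(x, ...) {
  cat(sprintf("IQ ensemble (%s beam): %d gates x %d slow-time samples @ %g Hz\n",
              x$side, nrow(x$samples), ncol(x$samples), x$prf))
  cat(sprintf("  gates %.1f-%.1f mm, spacing %.3f mm\n",
              x$first_gate_depth_mm, max(gate_depths(x)), x$gate_spacing_mm))
  invisible(x)
}

# Subset an ensemble to a contiguous gate index range.
subset_gates <- function(ens, idx) {
  iq_ensemble(ens$samples[idx, , drop = FALSE], ens$prf, ens$gate_spacing_mm,
              first_gate_depth_mm = gate_depths(ens)[idx[1]], side = ens$side)
}

#' Simulate a dual-beam multigate Doppler acquisition
#'
#' For every depth gate intersecting the lumen, each beam receives a
#' narrowband complex exponential whose instantaneous frequency follows the
#' forward Doppler model for the local profile velocity, amplitude-weighted by
#' the profile. All gates additionally carry a strong near-DC clutter tone
#' (tissue/wall echo) and circular white noise. The two beams are modelled as
#' synchronous ensembles at `prf_per_beam` each.
#'
#' @param flow A [flow_truth()].
#' @param lumen_depth_mm Depth of the vessel axis (mm); must lie inside
#'   `depth_range_mm`.
#' @param geom A [probe_geometry()].
#' @param cfg An [acquisition_config()].
#' @param snr_db Signal-to-noise ratio (dB) of a unit-amplitude gate signal.
#' @param clutter_db Clutter power above the unit signal (dB).
#' @param seed Integer seed; identical seeds give bit-identical ensembles.
#' @param duration_s Slow-time duration (s), default 2 s.
#' @param depth_range_mm Depth range covered by the gates (mm); gates are laid
#'   at `cfg$gate_spacing` over this range.
#' @param clutter_band_hz Clutter tone frequencies are drawn uniformly from
#'   `+/- clutter_band_hz`. The default (10 Hz) matches the Doppler shift of
#'   slow tissue motion (~1 mm/s at 7.5 MHz) and lies deep inside the
#'   wall-filter stop band.
#' @return List with elements `left`, `right` (two [iq_ensemble()]) and
#'   `truth` (the simulation parameters, including the flow truth).
#' @export
simulate_iq_pair <- function(flow, lumen_depth_mm, geom, cfg,
                             snr_db = 20, clutter_db = 40, seed = NULL,
                             duration_s = 2, depth_range_mm = c(10, 40),
                             clutter_band_hz = 10) {
  stopifnot(inherits(flow, "flow_truth"))
  gd <- seq(depth_range_mm[1], depth_range_mm[2], by = cfg$gate_spacing * 1e3)
  if (lumen_depth_mm < gd[1] || lumen_depth_mm > gd[length(gd)]) {
    stop("lumen depth outside gated depth range")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * cfg$prf_per_beam)
  tt <- (seq_len(n) - 1) / cfg$prf_per_beam
  v_t <- flow$waveform$fun(tt)                      # centreline speed (m/s)
  cum_v <- cumsum(v_t) / cfg$prf_per_beam           # integral of speed (m)
  w <- parabolic_profile(abs(gd - lumen_depth_mm), flow$profile_radius, 1,
                         shape = flow$profile_shape)
  # per-unit-speed Doppler rates for the two beams
  k <- forward_doppler_freqs(flow$direction[1], flow$direction[2], geom, cfg)
  sig_amp <- 1
  noise_sd <- sig_amp * 10^(-snr_db / 20) / sqrt(2)  # per real/imag component
  clut_amp <- sig_amp * 10^(clutter_db / 20)
  ng <- length(gd)

  one_side <- function(k_side, side) {
    m <- matrix(complex(real = stats::rnorm(ng * n, sd = noise_sd),
                        imaginary = stats::rnorm(ng * n, sd = noise_sd)), ng, n)
    fc <- stats::runif(ng, -clutter_band_hz, clutter_band_hz)
    ph0 <- stats::runif(ng, 0, 2 * pi)
    for (g in seq_len(ng)) {
      m[g, ] <- m[g, ] + clut_amp * exp(1i * (2 * pi * fc[g] * tt + ph0[g]))
      if (w[g] > 0) {
        phase <- 2 * pi * k_side * w[g] * cum_v
        m[g, ] <- m[g, ] + sig_amp * w[g] * exp(1i * phase)
      }
    }
    iq_ensemble(m, cfg$prf_per_beam, cfg$gate_spacing * 1e3, gd[1], side)
  }
  left <- one_side(k$fdl, "left")
  right <- one_side(k$fdr, "right")
  list(left = left, right = right,
       truth = list(flow = flow, lumen_depth_mm = lumen_depth_mm,
                    snr_db = snr_db, clutter_db = clutter_db,
                    seed = seed, duration_s = duration_s))
}
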