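# Shared fixtures: the nominal device configuration and small synthetic
# images/signals built in code.

nominal_geom <- function() probe_geometry()
nominal_cfg <- function() acquisition_config()

# Noise-free image of a dark disk on a uniform background, on the B-mode
# pixel grid (0.1 x 0.3 mm), with physical origins matching the default
# phantom field of view.
disk_frame <- function(cx = 0, cy = 23, r = 3, bg = 200, fg = 10,
                       nr = 300, nc = 96, dy = 0.1, dx = 0.3,
                       y0 = 5, x0 = -14.4) {
  yy <- y0 + (seq_len(nr) - 0.5) * dy
  xx <- x0 + (seq_len(nc) - 0.5) * dx
  m <- matrix(bg, nr, nc)
  m[outer((yy - cy)^2, (xx - cx)^2, "+") <= r^2] <- fg
  m
}

# Complex tone ensemble: one gate, a single frequency, optional white noise.
tone_ensemble <- function(f, prf = 8000, n = 16000, amp = 1, noise_sd = 0,
                          side = "left", n_gates = 1) {
  tt <- (seq_len(n) - 1) / prf
  x <- amp * exp(2i * pi * f * tt)
  m <- matrix(x, n_gates, n, byrow = TRUE)
  if (noise_sd > 0) {
    m <- m + matrix(complex(real = rnorm(n_gates * n, sd = noise_sd / sqrt(2)),
                            imaginary = rnorm(n_gates * n, sd = noise_sd / sqrt(2))),
                    n_gates, n)
  }
  iq_ensemble(m, prf, gate_spacing_mm = 0.2, first_gate_depth_mm = 20, side = side)
}

# Mean power of an ensemble's samples.
ens_power <- function(ens) mean(Mod(ens$samples)^2)

steady_flow <- function(v = 0.34, R = 3) {
  flow_truth(pulsatile_waveform(v, beats_per_min = 0), profile_radius = R)
}
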