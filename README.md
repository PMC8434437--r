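# duodop

Automatic measurement of the peak blood velocity in the common carotid
artery (CCA) from a dual angled-array transversal ultrasound acquisition —
the processing chain of an operator-free carotid exam, plus a synthetic-data
generator that stands in for the probe and scanner hardware.

## The problem and who this is for

Carotid peak systolic velocity is a routine clinical measurement, but it
normally requires an expert sonographer and a full echograph. A probe made
of **two linear arrays** whose axes form a fixed inter-angle θ (30° by
default), placed transversally on the neck, removes both requirements: the
wide field of view makes it easy to intercept the vessel blindly, and the
two beams see the flow from two known directions so the Doppler angle is
corrected automatically. This package is for researchers developing or
evaluating such unsupervised vector-Doppler systems: it implements the full
signal chain as composable R functions, and every stage can be driven with
simulated data with known ground truth.

## The method

1. **Lumen localization** — each array grabs a 15-frame B-mode sequence;
   every frame is contrast-stretched, strongly Gaussian-filtered, and a
   gradient circular Hough transform detects dark circles with radii in
   2.1–4 mm. Per frame the darkest circle is elected; across frames the most
   frequent quantized (x, y, r) triad wins (`segment_sequence()`).
2. **ROI placement** — the lumen depths from the two arrays are averaged and
   a 6 mm Doppler region of interest is centred there (`select_roi()`).
3. **Spectral processing** — multigate IQ ensembles (8 kHz PRF per beam) are
   wall-filtered at 100 Hz, split into 128-sample packets with 50 % overlap,
   Fourier-transformed, and each spectrum reduced to a centroid frequency by
   a modified centre-of-mass with noise-floor subtraction
   (`frequency_map()`).
4. **Triangulation and peak** — per-cell frequency pairs (f_dr, f_dl) become
   the velocity vector

       Vx = c (f_dr − f_dl) / (4 f_tx sin(θ/2)),
       Vz = c (f_dr + f_dl) / (4 f_tx cos(θ/2)),   |V| = √(Vx² + Vz²)

   and the single output is the maximum of |V| over depth and time, after
   automatic direction and plausibility checks (`peak_velocity()`,
   `validate_measurement()`).

The evaluation statistics of segmentation/velocity campaigns (distance
error, r.m.s., signed relative error, coefficient of variation, the 1 mm
discard rule) are in `distance_error()`, `rms_error()`,
`relative_error_pct()`, `cv_pct()` and `evaluate_campaign()`.

## Worked example

Simulate a complete pulsatile acquisition (two B-mode sequences, two IQ
ensembles; true peak velocity 0.67 m/s at 23 mm depth) and run the
measurement:

```r
library(duodop)
geom <- probe_geometry()          # 2 x 128 elements, theta = 30 deg
cfg  <- acquisition_config()      # 8 kHz/beam, 128-pt packets, 100 Hz wall filter

flow <- flow_truth(pulsatile_waveform(0.67, beats_per_min = 60, duration_s = 2),
                   profile_radius = 3)
acq  <- simulate_acquisition(phantom_truth(center_x = 1.2, center_y = 23, radius = 3),
                             flow, geom, cfg, snr_db = 20, seed = 42)

segment_sequence(acq$bmode_left)
#> Lumen detected at (x = 1.15, y = 22.86) mm, r = 2.52 mm (5 frames agree)

run_measurement(acq$bmode_left, acq$bmode_right,
                acq$iq_left, acq$iq_right, geom, cfg)
#> Peak velocity 0.669 m/s at t = 1.248 s, depth 23.0 mm
```

The lumen centre is found within ~0.15 mm of the true (1.2, 23) mm and the
peak estimate is within 0.2 % of the 0.67 m/s ground truth; the reported
time falls on the second simulated systole. The detected radius reads low
(a known bias of edge detection on log-compressed speckle — see the methods
vignette); the centre, which is what the measurement uses, is unbiased.

Operating limits of the default configuration:

```r
doppler_angles(geom)                          # 75 105   (deg)
max_unambiguous_depth(cfg) * 1e2              # 9.625    (cm)
max_detectable_velocity(cfg, geom, 75)        # 3.17     (m/s, full PRF range)
sample_volume_axial_extent(geom, cfg) * 1e3   # 0.616    (mm)
```

A thin command-line front end over the same functions is installed at
`inst/cli/duodop.R` (`synth-bmode`, `synth-doppler`, `segment`, `measure`,
`campaign` subcommands).

## Scope

Reproduced abstractly: the acquisition phases, signal processing and
evaluation statistics. Out of scope: scanner control and real-time
operation, beamforming/IQ demodulation of channel data, probe-holder
mechanics, volume-flow integration, wall/intima–media measurements, and any
clinical interpretation. See `vignettes/duodop-methods.Rmd` for the models,
parameter defaults, design decisions and limitations.
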