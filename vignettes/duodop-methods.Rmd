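---
title: "Automatic carotid peak-velocity measurement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic carotid peak-velocity measurement: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duodop)
```

## The measurement problem

Carotid peak systolic velocity is normally measured by an expert sonographer
with a clinical echograph: the operator finds the vessel in the B-mode image,
places the Doppler sample volume in the lumen, and corrects the measured
Doppler shift for the beam-to-flow angle. `duodop` implements the processing
chain of an *operator-free* version of this exam, built around a probe made
of two linear arrays whose depth axes form a fixed inter-angle $\theta$
(default $30^\circ$). Placed transversally on the neck, the two beams see the
common carotid artery from two known directions, so the in-plane velocity
vector can be recovered by triangulation with no manual angle correction, and
the wide lateral field of view means a non-expert only has to put the probe
roughly over the vessel.

The chain has four stages, each exposed as package functions and composed by
`run_measurement()`:

1. **Lumen localization** (`segment_sequence()`): the lumen is found in a
   short B-mode sequence from each array as the most recurrent dark circle.
2. **ROI placement** (`select_roi()`): the two lumen depths are averaged and
   a 6 mm axial Doppler region of interest is centred there.
3. **Spectral processing** (`frequency_map()`): multigate IQ ensembles from
   both beams are wall-filtered, split into short-time packets, and reduced
   to a centroid Doppler frequency per (time, depth) cell.
4. **Triangulation and peak extraction** (`triangulate()`,
   `peak_velocity()`, `validate_measurement()`): the per-cell frequency
   pairs become angle-corrected velocities; the single output is their
   maximum over depth and time, after direction and plausibility checks.

## Geometry model

For a vessel parallel to the skin, the two Doppler angles are
$90^\circ \pm \theta/2$ ($75^\circ$ and $105^\circ$ at the default
$\theta = 30^\circ$). A velocity with lateral (along-flow) component $V_x$
and axial component $V_z$ produces the beam frequencies

$$
f_{dr} = \frac{2 f_{tx}}{c}\left(V_x \sin\tfrac{\theta}{2} + V_z \cos\tfrac{\theta}{2}\right),
\qquad
f_{dl} = \frac{2 f_{tx}}{c}\left(-V_x \sin\tfrac{\theta}{2} + V_z \cos\tfrac{\theta}{2}\right),
$$

inverted exactly by

$$
V_x = \frac{c\,(f_{dr} - f_{dl})}{4 f_{tx} \sin(\theta/2)}, \qquad
V_z = \frac{c\,(f_{dr} + f_{dl})}{4 f_{tx} \cos(\theta/2)}, \qquad
|V| = \sqrt{V_x^2 + V_z^2}.
$$

`forward_doppler_freqs()` and `triangulate()` implement the two directions;
their composition is the identity to machine precision, which the test suite
asserts on random velocity vectors. The same module provides the closed-form
operating limits of a configuration: maximum unambiguous depth $c/(2\,PRF)$,
maximum detectable velocity $c\,PRF / (2 f_{tx} |\cos\alpha|)$ when the full
PRF range is exploited (the conventional $\pm PRF/2$ Nyquist limit is
available via `limit = "nyquist"`), and the axial sample-volume extent
$n_{cyc}\, c / f_{tx}$.

Angles are degrees at every interface and radians internally; lengths are SI
metres in the geometry/acquisition objects and millimetres in image and gate
coordinates, matching how each community quotes them. The sound speed
defaults to 1540 m/s, the standard soft-tissue value.

One geometric datum is internally inconsistent in the device description:
the array gap quoted at the skin plane and the quoted 23 mm axis-crossing
depth cannot both hold under a naive centre-to-centre construction. The
package treats the **crossing depth as authoritative** (it is the clinically
meaningful quantity — it should sit at the typical carotid depth) and
derives the beam-origin separation from it (`beam_origin_separation()`).

## Lumen segmentation

Each frame is preprocessed (`preprocess_frame()`) by a linear stretch
between the 1st and 99th intensity percentiles followed by an isotropic
Gaussian filter of $\sigma = 0.5$ mm. The stretch makes detection invariant
to global affine intensity rescaling; the smoothing is deliberately strong —
it destroys speckle grain and thin structures while preserving a lumen of
radius $\ge 2.1$ mm. A constant frame passes through unchanged.

`detect_dark_circles()` is a two-stage gradient circular Hough transform
(CHT). The frame is resampled to an isotropic 0.15 mm working grid (the
native pixels are anisotropic), Sobel gradients are computed, and the
strongest 8 % of gradient magnitudes are taken as edges. Each edge pixel
votes, for every radius bin (1 working pixel steps across 2.1-4.0 mm), at
the point one radius *inward* along its gradient: the intensity gradient of
a dark-interior circle points outward, so votes of a hypoechoic disk
converge on its centre while bright-interior structures do not accumulate.
The package's CHT dialect adds four stabilizers, each motivated by the
speckle statistics of log-compressed ultrasound:

* votes are weighted by gradient magnitude, so the strong lumen boundary
  dominates weak speckle edges;
* accumulator slices are box-smoothed and additionally smoothed across the
  radius dimension, because a blurred boundary spreads its votes over
  neighbouring radius bins;
* the accumulator is normalized to its global peak and rounded, so plateau
  ties are exact and peak picking commutes with image translation and
  intensity rescaling (asserted as properties in the tests);
* candidates whose centres (nearly) coincide are non-max-suppressed across
  radii: they are one structure seen at several radii, and keeping the
  nested sub-circles would corrupt the darkest-interior election below,
  since a smaller circle inside the lumen is always at least as dark.

Candidates above 0.7 of the accumulator peak survive. The 0.7 threshold was
fixed during development on synthetic speckle phantoms: at looser thresholds
the election is dominated by spurious sub-circles nested in the lumen and
the localization error grows several-fold, while between 0.7 and 0.8 the
result is insensitive to the exact value.

Per frame, the candidate with the darkest interior (mean intensity within
0.9 of its radius, evaluated on the preprocessed frame) is elected; whether
darkness is computed on the raw or preprocessed frame is configurable, and
preprocessed is the default because the election should see the same image
the detector saw. Ties break deterministically: lowest darkness, then
smallest depth, then smallest lateral offset. Across the sequence (15 frames
by default), `consensus()` quantizes the elected triads $(x_c, y_c, r_c)$
and returns the mean of the modal bin — averaging within the bin keeps the
modal quantized triad while reducing per-frame jitter. The quantum is 0.3 mm
(the native lateral pixel, two working pixels): per-frame jitter of a
genuine detection is about one working pixel, so finer bins fragment the
mode, while random candidates in no-vessel sequences essentially never agree
three times in a 0.3 mm bin. A detection is only valid when at least
`min_support = 3` frames contributed candidates *and* the modal triad itself
recurs in at least 3 frames; otherwise the status is `"failed"` and the
downstream measurement is discarded with reason `"segmentation failed"`.

A consequence worth knowing: the detected radius is biased low by roughly
half a millimetre on log-compressed speckle, because log compression makes
the dark-to-bright edge asymmetric and the gradient peaks slightly inside
the geometric boundary. The centre — the quantity the measurement actually
uses — is unaffected (the bias is radially symmetric).

## Spectral processing

`clutter_filter()` is a 4th-order high-pass Butterworth along slow time per
gate with a 100 Hz cutoff, applied to the real and imaginary parts (the stop
band therefore covers $|f| < 100$ Hz on the two-sided axis). The start-up
transient is handled by odd-reflection padding of the leading edge, which is
filtered and discarded. An alternative is to discard the first output
samples instead; padding was preferred because it preserves the sample
count, and with it the packet arithmetic: a 2 s ensemble at 8 kHz yields
exactly $\lfloor(16000 - 128)/64\rfloor + 1 = 249$ packets of 128 samples at
50 % overlap — one velocity profile every 64 transmissions.

Each packet is Hann-windowed and Fourier-transformed at its own length (no
zero padding), giving 62.5 Hz bins at the default configuration.
`centroid_frequency()` then implements a *modified* centre of mass. The
unmodified centroid is badly biased toward zero by the noise floor, so three
modifications are applied, with all parameters exposed:

1. the noise floor, estimated as the mean of the lowest quartile of bins,
   is subtracted and negative residuals clipped;
2. residual bins below 10 % of the residual peak are excluded from the mass;
3. spectra whose raw peak is below 12 times the mean bin power are declared
   **undefined** (`NA`).

The third rule is the package's resolution of the one genuinely open point
of the processing chain (the reference describing the original modification
is not reproduced here): for 128-bin spectra of pure noise the peak-to-mean
ratio concentrates near $\ln 128 \approx 4.9$, while a tone at 20 dB SNR
exceeds 50, so a threshold of 12 separates the regimes with wide margin.
The rule matters because a noise-only centroid is roughly uniform over
$\pm PRF/2$: fed into the map maximum it would dominate the output. Under
the threshold, the probability that a noise-only cell is defined is about
$10^{-3}$ — and since `velocity_map()` takes the *strict intersection* of
the two beams (a cell is defined only when both sides are), a spurious
defined pair occurs with probability $\sim 10^{-6}$ per cell, negligible
over the $\sim 7500$ cells of an acquisition. Undefined cells are excluded
from every downstream maximum and never zero-filled. No aliasing unwrapping
is attempted: the centroid lives on $[-PRF/2, PRF/2)$ as is.

## Velocity extraction and validity checks

`select_roi()` centres the 6 mm window on the mean of the two lumen depths,
clamping at the gate range while preserving the extent. Packet $k$ of one
beam pairs with packet $k$ of the other: the hardware interleaves the two
beams at twice the per-beam PRF, and the resulting half-sample (62.5 µs)
offset is negligible at cardiac time scales, so the simulator generates the
two ensembles as synchronous. The output is the maximum of $|V|$ over all
defined cells — no temporal smoothing is applied before the maximum by
default (an optional median filter was considered and rejected: the raw
maximum is the declared output of the method). Ties resolve to the earliest
packet, then the shallowest gate.

`validate_measurement()` encodes the automatic rejection rules: if the sign
of $V_x$ at the peak *and* the map-median sign both contradict the
configured flow direction, the measurement is discarded as
`"wrong direction"` (this is what happens when the probe locks onto the
jugular vein, whose flow runs counter to the carotid); a peak outside
0.05 m/s to the full-PRF geometric limit (about 3.17 m/s at default
configuration) is `"implausible"`. The maximum is taken on $|V|$ with the
direction check applied separately, rather than on direction-gated
velocities: the discard semantics ("measurement failed, repeat it") fit the
intended unsupervised use better than silently ignoring reversed cells.

## What the synthetic generator emulates — and what it does not

`make_phantom_sequence()` produces fully developed speckle: a complex
circular Gaussian scatterer field, attenuated inside the lumen disk by
-25 dB (amplitude) by default, convolved with an anisotropic Gaussian PSF
(0.15 mm axial, 0.4 mm lateral $\sigma$ — axial finer than the 0.6 mm
sample volume, lateral comparable to the element pitch at the focus),
envelope-detected and log-compressed to 8 bits over 50 dB. Frames are
independent speckle realizations of a fixed geometry. Probe tilt or rotation
is emulated as mild lumen ellipticity ($1/\cos$ of the angle). Pixels are
0.1 mm axial x 0.3 mm lateral (the element pitch).

`simulate_iq_pair()` gives every gate inside the lumen a narrowband complex
exponential at the forward-model frequency of the local profile velocity
(parabolic by default — laminar flow; the actual profile shape of the
phantom experiments is not documented, so it is configurable), with
amplitude weighted by the same profile. All gates carry clutter (a strong
near-DC tone, +40 dB over the unit signal, frequency drawn within
$\pm 10$ Hz — the tissue-motion scale) and circular white noise at the
configured SNR (20 dB default). Default duration 2 s at 8 kHz per beam;
gates at 0.2 mm spacing over 10-40 mm.

Passing tests on these data therefore demonstrate the *processing chain*:
geometry inversion, filtering, spectral estimation, consensus logic,
discard rules, and their composition. They do not exercise: acoustic
propagation and beam shape, element directivity, intrinsic (transit-time)
spectral broadening — a real centroid sees a broadened spectrum, not a
tone —, tissue motion and probe-pressure artifacts, wall echoes with
realistic spectra, or the anatomical variability of real carotid walls
(the in-vivo analogue of our speckle phantom is known to be harder by
roughly a factor 1.5 in localization error). Velocity accuracy numbers
obtained in simulation are accordingly better than hardware experiments;
the acceptance campaign treats the published experimental figures as upper
bounds, not as values to reproduce.

## Problem sizes, determinism, degenerate inputs

The shipped campaigns use 20 seeded acquisitions for the accuracy statistic,
10 for repeatability, and 50 fifteen-frame sequences (lumen radius uniform
in 2.2-3.9 mm) for segmentation, with the 1 mm discard rule applied before
the r.m.s. — sizes chosen to estimate the statistics to well under their
acceptance margins while keeping a full run in minutes on one core. All
generators consume explicit integer seeds; campaign drivers derive sub-seeds
via `sample.int()` from a single master seed, so every result is
bit-reproducible. Degenerate inputs have defined behaviour throughout:
constant frames pass preprocessing unchanged, uniform images yield no
candidates, all-`NA` velocity maps yield a discarded result with reason
`"no signal"`, empty campaigns return empty records, and a waveform of zero
duration is an error.

## Known limitations

* Single circular (mildly elliptical) lumen assumption; bifurcations and
  adjacent vessels are handled only through the darkest-election and the
  direction check, as in the underlying method.
* The centroid estimator is narrowband-calibrated; with strong intrinsic
  broadening it underestimates the true maximum velocity relative to
  envelope-based estimators (the method accepts this trade for robustness).
* Radius output is biased low on log-compressed data (see above); use the
  centre, not the radius, as the quantitative output.
* The simulator's idealizations listed in the previous section bound what
  simulation-based validation can claim about hardware performance.
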