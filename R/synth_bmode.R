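#' Phantom ground truth for a synthetic B-mode lumen
#'
#' Records where the simulated vessel lumen is placed, so that segmentation
#' results can be scored against a known reference.
#'
#' @param center_x,center_y Lumen centre (mm): lateral offset and depth.
#' @param radius Lumen radius (mm); the default detection range of the
#'   segmenter is 2.1-4.0 mm.
#' @param side `"left"` or `"right"` array.
#' @param seed Integer RNG seed for the speckle realizations.
#' @param axis_ratio Lateral/axial semi-axis ratio; values slightly above 1
#'   emulate the mild ellipticity produced by probe tilt or rotation
#'   (a cylinder cut at angle `a` has ratio `1 / cos(a)`).
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(center_x = 0, center_y = 23, radius = 3,
                          side = c("left", "right"), seed = 1L,
                          axis_ratio = 1) {
  side <- match.arg(side)
  stopifnot(radius > 0, axis_ratio >= 1)
  structure(
    list(center_x = center_x, center_y = center_y, radius = radius,
         side = side, seed = as.integer(seed), axis_ratio = axis_ratio),
    class = "phantom_truth"
  )
}

#' Simulate a speckled B-mode sequence with a hypoechoic circular lumen
#'
#' Minimal fully-developed-speckle model sufficient for testing circle
#' detection: a complex circular Gaussian scatterer field, attenuated inside
#' the lumen disk by `contrast_db`, is smoothed by an anisotropic Gaussian
#' point-spread function, envelope-detected, and log-compressed to 8 bits over
#' a fixed dynamic range. Each frame is an independent speckle realization of
#' the same geometry, emulating the 15-frame sequence the scanner grabs before
#' switching to Doppler mode.
#'
#' @param truth A [phantom_truth()].
#' @param n_frames Number of frames (default 15).
#' @param contrast_db Scatterer amplitude of the lumen interior relative to
#'   the background (dB, negative = darker; `-Inf` = anechoic).
#' @param speckle_params List: `psf_axial_mm`, `psf_lateral_mm` (Gaussian PSF
#'   sigmas), `dynamic_range_db` (log-compression range).
#' @param pixel_spacing_mm `(axial, lateral)` pixel spacing in mm.
#' @param depth_range_mm Depth extent of the image (mm).
#' @param lateral_extent_mm Lateral field of view, centred on the array (mm).
#' @return A [bmode_sequence()] with the truth attached as attribute
#'   `"truth"`.
#' @examples
#' seq <- make_phantom_sequence(phantom_truth(seed = 7), n_frames = 3)
#' dim(seq$frames)
#' @export
make_phantom_sequence <- function(truth,
                                  n_frames = 15L,
                                  contrast_db = -25,
                                  speckle_params = list(),
                                  pixel_spacing_mm = c(0.1, 0.3),
                                  depth_range_mm = c(5, 35),
                                  lateral_extent_mm = 28.8) {
  stopifnot(inherits(truth, "phantom_truth"), n_frames >= 1)
  sp <- utils::modifyList(
    list(psf_axial_mm = 0.15, psf_lateral_mm = 0.4, dynamic_range_db = 50),
    speckle_params
  )
  dy <- pixel_spacing_mm[1]; dx <- pixel_spacing_mm[2]
  nr <- floor(diff(depth_range_mm) / dy)
  nc <- floor(lateral_extent_mm / dx)
  y0 <- depth_range_mm[1]; x0 <- -lateral_extent_mm / 2
  ry <- truth$radius; rx <- truth$radius * truth$axis_ratio
  if (truth$center_y - ry < y0 || truth$center_y + ry > y0 + nr * dy ||
      truth$center_x - rx < x0 || truth$center_x + rx > x0 + nc * dx) {
    stop("lumen circle lies (partly) outside the field of view")
  }
  yy <- y0 + (seq_len(nr) - 0.5) * dy
  xx <- x0 + (seq_len(nc) - 0.5) * dx
  inside <- outer(yy, xx, function(y, x) {
    ((y - truth$center_y) / ry)^2 + ((x - truth$center_x) / rx)^2 <= 1
  })
  amp <- matrix(1, nr, nc)
  amp[inside] <- if (is.infinite(contrast_db)) 0 else 10^(contrast_db / 20)
  sigma_px <- c(sp$psf_axial_mm / dy, sp$psf_lateral_mm / dx)
  dr <- sp$dynamic_range_db

  set.seed(truth$seed)
  frames <- array(0, dim = c(nr, nc, n_frames))
  for (k in seq_len(n_frames)) {
    field <- matrix(complex(real = stats::rnorm(nr * nc),
                            imaginary = stats::rnorm(nr * nc)), nr, nc) * amp
    env <- Mod(gauss_smooth(field, sigma_px, pad_mode = "zero"))
    ref <- stats::quantile(env, 0.999, names = FALSE)
    if (ref <= 0) ref <- 1
    db <- 20 * log10(pmax(env / ref, 1e-30))
    frames[, , k] <- round(255 * pmin(pmax((db + dr) / dr, 0), 1))
  }
  out <- bmode_sequence(frames, pixel_spacing_mm,
                        depth_origin_mm = y0, lateral_origin_mm = x0,
                        side = truth$side)
  attr(out, "truth") <- truth
  out
}
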