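# Small image helpers shared by the speckle simulator and the segmentation
# front end. Kept dependency-free: images here are a few hundred pixels per
# side, so padded FFT convolution and per-line linear interpolation are ample.

# Replicate-pad a matrix by (pr, pc) pixels on each side.
pad_replicate <- function(m, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(m)), rep(ncol(m), pc))
  m[ri, ci, drop = FALSE]
}

# Gaussian smoothing with per-axis sigma in pixels (rows, cols), via a single
# padded 2-D FFT. Works for real or complex input; replicate boundary.
gauss_smooth <- function(m, sigma, pad_mode = c("replicate", "zero")) {
  pad_mode <- match.arg(pad_mode)
  sigma <- rep_len(sigma, 2)
  if (all(sigma < 1e-3)) return(m)
  kr <- max(1L, ceiling(3 * sigma[1]))
  kc <- max(1L, ceiling(3 * sigma[2]))
  mp <- if (pad_mode == "replicate") {
    pad_replicate(m, kr, kc)
  } else {
    z <- matrix(0 + 0i * m[1], nrow(m) + 2 * kr, ncol(m) + 2 * kc)
    z[kr + seq_len(nrow(m)), kc + seq_len(ncol(m))] <- m
    z
  }
  nr <- nrow(mp); nc <- ncol(mp)
  g1 <- function(n, k, s) {
    if (s < 1e-3) { v <- numeric(n); v[1] <- 1; return(v) }
    idx <- c(0:k, rev(seq_len(k)) * -1) # offsets 0..k, -k..-1
    v <- numeric(n)
    v[(idx %% n) + 1] <- exp(-0.5 * (idx / s)^2)
    v / sum(v)
  }
  Kf <- outer(stats::fft(g1(nr, kr, sigma[1])), stats::fft(g1(nc, kc, sigma[2])))
  out <- stats::fft(stats::fft(mp) * Kf, inverse = TRUE) / (nr * nc)
  if (!is.complex(m)) out <- Re(out)
  out[kr + seq_len(nrow(m)), kc + seq_len(ncol(m)), drop = FALSE]
}

# Bilinear resampling of a matrix from anisotropic pixel spacing
# (spacing = c(row, col), same physical unit) to an isotropic target spacing.
# Pixel centres sit at (i - 0.5) * spacing from the grid origin; the physical
# extent is preserved (last partial pixel dropped).
resample_iso <- function(m, spacing, target) {
  spacing <- rep_len(spacing, 2)
  nr2 <- max(2L, floor(nrow(m) * spacing[1] / target))
  nc2 <- max(2L, floor(ncol(m) * spacing[2] / target))
  y_src <- (seq_len(nrow(m)) - 0.5) * spacing[1]
  x_src <- (seq_len(ncol(m)) - 0.5) * spacing[2]
  y_dst <- (seq_len(nr2) - 0.5) * target
  x_dst <- (seq_len(nc2) - 0.5) * target
  # rows first
  tmp <- apply(m, 2, function(col) {
    stats::approx(y_src, col, xout = y_dst, rule = 2)$y
  })
  out <- t(apply(tmp, 1, function(row) {
    stats::approx(x_src, row, xout = x_dst, rule = 2)$y
  }))
  list(m = out, spacing = target)
}

# 3x3 box smoothing by shift-and-add (used on Hough accumulator slices).
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_replicate(m, 1L, 1L)
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
  }
  acc / 9
}
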