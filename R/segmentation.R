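#' Preprocess a B-mode frame for lumen detection
#'
#' Brightness/contrast optimization by a linear stretch between two intensity
#' percentiles (default 1st-99th), followed by a strong isotropic Gaussian
#' filter (sigma in physical units) that suppresses speckle grain while
#' preserving vessel-scale structure. A constant frame passes through
#' unchanged (the stretch degenerates to the identity).
#'
#' @param frame Numeric matrix (depth x lateral), 0-255 intensity.
#' @param pixel_spacing_mm `(axial, lateral)` pixel spacing (mm).
#' @param sigma_mm Gaussian sigma (mm), isotropic in physical units.
#' @param stretch_quantiles Lower/upper percentiles of the contrast stretch.
#' @return Preprocessed frame, same dimensions, 0-255 range.
#' @export
preprocess_frame <- function(frame, pixel_spacing_mm = c(0.1, 0.3),
                             sigma_mm = 0.5, stretch_quantiles = c(0.01, 0.99)) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  q <- stats::quantile(frame, stretch_quantiles, names = FALSE)
  f <- if (q[2] > q[1]) {
    255 * pmin(pmax((frame - q[1]) / (q[2] - q[1]), 0), 1)
  } else {
    frame
  }
  gauss_smooth(f, sigma_mm / pixel_spacing_mm)
}

# Sobel gradients (rows = depth/y, cols = lateral/x); replicate boundary.
sobel_gradients <- function(m) {
  p <- pad_replicate(m, 1L, 1L)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) p[dr + seq_len(nr), dc + seq_len(nc)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  list(gx = gx / 8, gy = gy / 8)
}

#' Detect dark circles with a gradient circular Hough transform
#'
#' The (preprocessed) frame is resampled to an isotropic working grid, edges
#' are extracted as the strongest Sobel gradient magnitudes, and each edge
#' pixel votes, for every radius bin, at the point one radius inward along its
#' gradient (the gradient of a dark-interior circle points outward, so the
#' votes of a hypoechoic disk converge on its centre). Accumulator slices are
#' lightly smoothed, normalized by radius (votes scale with circumference) and
#' all local maxima above a fraction of the global peak are returned as
#' candidates in physical (mm) coordinates.
#'
#' @param frame Numeric matrix (depth x lateral), typically the output of
#'   [preprocess_frame()].
#' @param r_min_mm,r_max_mm Radius search range (mm), `r_min_mm < r_max_mm`.
#' @param pixel_spacing_mm `(axial, lateral)` pixel spacing of `frame` (mm).
#' @param depth_origin_mm,lateral_origin_mm Physical coordinates of the top /
#'   left image edge (mm).
#' @param working_spacing_mm Isotropic grid used for the transform (mm);
#'   also the radius bin width and the centre quantization step.
#' @param edge_quantile Gradient-magnitude percentile above which a pixel
#'   counts as an edge.
#' @param accumulator_threshold Candidate cut as a fraction of the global
#'   accumulator maximum.
#' @param max_candidates Cap on the number of returned candidates.
#' @return Data frame with columns `x_mm`, `y_mm`, `r_mm`, `score`,
#'   `darkness` (`NA` until [select_darkest()]), `frame_index` (`NA` here);
#'   zero rows when nothing is found.
#' @export
detect_dark_circles <- function(frame, r_min_mm = 2.1, r_max_mm = 4.0,
                                pixel_spacing_mm = c(0.1, 0.3),
                                depth_origin_mm = 0, lateral_origin_mm = 0,
                                working_spacing_mm = 0.15,
                                edge_quantile = 0.92,
                                accumulator_threshold = 0.7,
                                max_candidates = 10L) {
  stopifnot(r_min_mm < r_max_mm, working_spacing_mm > 0)
  ws <- working_spacing_mm
  if (r_min_mm / ws < 2) stop("radius range below 2 pixels at the working spacing")
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0), r_mm = numeric(0),
                      score = numeric(0), darkness = numeric(0),
                      frame_index = integer(0))
  rs <- resample_iso(frame, pixel_spacing_mm, ws)$m
  if (diff(range(rs)) < 1e-9) return(empty)
  g <- sobel_gradients(rs)
  mag <- sqrt(g$gx^2 + g$gy^2)
  thr <- stats::quantile(mag, edge_quantile, names = FALSE)
  idx <- which(mag > thr & mag > 1e-6 * diff(range(rs)))
  if (length(idx) == 0) return(empty)
  nr <- nrow(rs); nc <- ncol(rs)
  er <- ((idx - 1) %% nr) + 1
  ec <- ((idx - 1) %/% nr) + 1
  uy <- g$gy[idx] / mag[idx]
  ux <- g$gx[idx] / mag[idx]
  radii_px <- seq(r_min_mm / ws, r_max_mm / ws, by = 1)
  slices <- vector("list", length(radii_px))
  for (ri in seq_along(radii_px)) {
    r <- radii_px[ri]
    cy <- round(er - r * uy)   # vote inward: against the outward gradient
    cx <- round(ec - r * ux)
    ok <- cy >= 1 & cy <= nr & cx >= 1 & cx <= nc
    lin <- (cx[ok] - 1) * nr + cy[ok]
    a <- matrix(0, nr, nc)
    vote <- rowsum(mag[idx][ok], lin)
    a[as.integer(rownames(vote))] <- vote
    slices[[ri]] <- box3(a)
  }
  # smooth across the radius dimension (blurred edges spread votes over
  # neighbouring radius bins), then normalize by circumference
  nri <- length(radii_px)
  acc_max <- 0
  if (nri > 1) {
    raw <- slices
    for (ri in seq_len(nri)) {
      lo <- raw[[max(1L, ri - 1L)]]; hi <- raw[[min(nri, ri + 1L)]]
      slices[[ri]] <- (lo + 2 * raw[[ri]] + hi) / 4
    }
  }
  for (ri in seq_len(nri)) {
    slices[[ri]] <- slices[[ri]] / radii_px[ri]
    acc_max <- max(acc_max, max(slices[[ri]]))
  }
  if (acc_max <= 0) return(empty)
  # normalize to the global peak and round so that genuine plateau ties are
  # exact: peak picking then commutes with image translation and with global
  # affine intensity rescaling
  for (ri in seq_len(nri)) slices[[ri]] <- round(slices[[ri]] / acc_max, 9)
  cut <- accumulator_threshold
  cands <- list()
  for (ri in seq_along(radii_px)) {
    a <- slices[[ri]]
    p <- pad_replicate(a, 1L, 1L)
    is_max <- a >= cut
    for (dr in 0:2) for (dc in 0:2) {
      if (dr == 1 && dc == 1) next
      is_max <- is_max & (a >= p[dr + seq_len(nr), dc + seq_len(nc)])
    }
    w <- which(is_max)
    if (length(w)) {
      cands[[length(cands) + 1]] <- data.frame(
        row = ((w - 1) %% nr) + 1,
        col = ((w - 1) %/% nr) + 1,
        r_px = radii_px[ri],
        score = a[w]
      )
    }
  }
  if (!length(cands)) return(empty)
  d <- do.call(rbind, cands)
  d <- d[order(-d$score), , drop = FALSE]
  # non-max suppression: candidates with (near-)coincident centres are the
  # same structure seen at different radii; keep the best-scoring one
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    if (i < nrow(d)) {
      j <- (i + 1):nrow(d)
      dup <- keep[j] &
        (abs(d$row[j] - d$row[i]) <= 3) & (abs(d$col[j] - d$col[i]) <= 3)
      keep[j][dup] <- FALSE
    }
  }
  d <- d[keep, , drop = FALSE]
  d <- utils::head(d, max_candidates)
  data.frame(
    x_mm = lateral_origin_mm + (d$col - 0.5) * ws,
    y_mm = depth_origin_mm + (d$row - 0.5) * ws,
    r_mm = d$r_px * ws,
    score = d$score,
    darkness = NA_real_,
    frame_index = NA_integer_
  )
}

#' Elect the darkest candidate circle
#'
#' Computes the mean intensity of each candidate's interior (pixels within
#' 0.9 of its radius) on the supplied frame and returns the candidate with
#' the lowest value. Deterministic tie-break: lowest darkness, then smallest
#' depth, then smallest |lateral offset|.
#'
#' @param frame Frame on which darkness is evaluated (by default the
#'   preprocessed frame of the same acquisition).
#' @param candidates Data frame from [detect_dark_circles()].
#' @param pixel_spacing_mm,depth_origin_mm,lateral_origin_mm Pixel grid of
#'   `frame`.
#' @param interior_fraction Fraction of the radius defining the interior.
#' @return One-row data frame (with `darkness` filled in), or `NULL` when
#'   `candidates` is empty.
#' @export
select_darkest <- function(frame, candidates,
                           pixel_spacing_mm = c(0.1, 0.3),
                           depth_origin_mm = 0, lateral_origin_mm = 0,
                           interior_fraction = 0.9) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  yy <- depth_origin_mm + (seq_len(nrow(frame)) - 0.5) * pixel_spacing_mm[1]
  xx <- lateral_origin_mm + (seq_len(ncol(frame)) - 0.5) * pixel_spacing_mm[2]
  dark <- vapply(seq_len(nrow(candidates)), function(i) {
    cy <- candidates$y_mm[i]; cx <- candidates$x_mm[i]
    r <- interior_fraction * candidates$r_mm[i]
    msk <- outer((yy - cy)^2, (xx - cx)^2, "+") <= r^2
    if (!any(msk)) return(Inf)
    mean(frame[msk])
  }, numeric(1))
  candidates$darkness <- dark
  ord <- order(dark, candidates$y_mm, abs(candidates$x_mm))
  candidates[ord[1], , drop = FALSE]
}

#' Multi-frame consensus on the candidate circles
#'
#' Quantizes the per-frame candidate triads (centres to the working grid,
#' radii to the radius bin) and selects the most frequent triad; returns the
#' mean of the triads in the modal bin, which preserves the quantized mode
#' while averaging down per-frame jitter.
#'
#' @param per_frame Data frame of per-frame elected candidates (rows may come
#'   from [select_darkest()] with `frame_index` set); may have zero rows.
#' @param quantum_mm Quantization step for centres and radii (mm). The
#'   default (0.3 mm, the native lateral pixel) is two working pixels: coarse
#'   enough that per-frame jitter of a genuine detection stays in one bin,
#'   fine enough that agreement of random candidates stays rare.
#' @param min_support Minimum number of frames that must contribute a
#'   candidate for the detection to be valid.
#' @return Object of class `lumen_detection`: `xc`, `yc`, `rc` (mm),
#'   `n_supporting_frames` (frames in the modal bin), `status`
#'   (`"ok"`/`"failed"`), `per_frame`.
#' @export
consensus <- function(per_frame, quantum_mm = 0.3, min_support = 3L) {
  failed <- structure(
    list(xc = NA_real_, yc = NA_real_, rc = NA_real_,
         n_supporting_frames = 0L, status = "failed", per_frame = per_frame),
    class = "lumen_detection"
  )
  if (is.null(per_frame) || nrow(per_frame) == 0) return(failed)
  if (length(unique(per_frame$frame_index)) < min_support) return(failed)
  key <- paste(round(per_frame$x_mm / quantum_mm),
               round(per_frame$y_mm / quantum_mm),
               round(per_frame$r_mm / quantum_mm))
  tab <- table(key)
  # a detection is only credible when the modal triad itself recurs: random
  # per-frame candidates (no true circle in view) almost never agree
  if (max(tab) < min_support) return(failed)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    # tie: prefer the darkest, then shallowest, then most central group
    stats_by <- t(vapply(top, function(k) {
      rows <- per_frame[key == k, , drop = FALSE]
      c(mean(rows$darkness), mean(rows$y_mm), mean(abs(rows$x_mm)))
    }, numeric(3)))
    top <- top[order(stats_by[, 1], stats_by[, 2], stats_by[, 3])][1]
  }
  rows <- per_frame[key == top, , drop = FALSE]
  structure(
    list(xc = mean(rows$x_mm), yc = mean(rows$y_mm), rc = mean(rows$r_mm),
         n_supporting_frames = nrow(rows), status = "ok",
         per_frame = per_frame),
    class = "lumen_detection"
  )
}

#' @export
print.lumen_detection <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Lumen detected at (x = %.2f, y = %.2f) mm, r = %.2f mm (%d frames agree)\n",
                x$xc, x$yc, x$rc, x$n_supporting_frames))
  } else {
    cat("Lumen detection failed\n")
  }
  invisible(x)
}

#' Segment a B-mode sequence
#'
#' Runs preprocess -> circle detection -> darkest-candidate election on every
#' frame, then takes the multi-frame consensus. All tunables of the stages are
#' exposed through `params`.
#'
#' @param seq A [bmode_sequence()].
#' @param params Named list overriding any of: `r_min_mm`, `r_max_mm`,
#'   `sigma_mm`, `stretch_quantiles`, `working_spacing_mm`, `edge_quantile`,
#'   `accumulator_threshold`, `max_candidates`, `interior_fraction`,
#'   `min_support`, `consensus_quantum_mm`, `darkness_on_preprocessed`
#'   (default `TRUE`: darkness is evaluated on the preprocessed frame).
#' @return A `lumen_detection` (see [consensus()]) in mm, in the sequence's
#'   coordinate frame.
#' @export
segment_sequence <- function(seq, params = list()) {
  stopifnot(inherits(seq, "bmode_sequence"))
  p <- utils::modifyList(
    list(r_min_mm = 2.1, r_max_mm = 4.0, sigma_mm = 0.5,
         stretch_quantiles = c(0.01, 0.99), working_spacing_mm = 0.15,
         edge_quantile = 0.92, accumulator_threshold = 0.7,
         max_candidates = 10L, interior_fraction = 0.9, min_support = 3L,
         consensus_quantum_mm = 0.3, darkness_on_preprocessed = TRUE),
    params
  )
  nfr <- dim(seq$frames)[3]
  rows <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    raw <- seq$frames[, , k]
    pf <- preprocess_frame(raw, seq$pixel_spacing_mm, p$sigma_mm,
                           p$stretch_quantiles)
    cands <- detect_dark_circles(
      pf, p$r_min_mm, p$r_max_mm, seq$pixel_spacing_mm,
      seq$depth_origin_mm, seq$lateral_origin_mm,
      p$working_spacing_mm, p$edge_quantile, p$accumulator_threshold,
      p$max_candidates
    )
    dframe <- if (p$darkness_on_preprocessed) pf else raw
    best <- select_darkest(dframe, cands, seq$pixel_spacing_mm,
                           seq$depth_origin_mm, seq$lateral_origin_mm,
                           p$interior_fraction)
    if (!is.null(best)) {
      best$frame_index <- k
      rows[[k]] <- best
    }
  }
  per_frame <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  consensus(per_frame, quantum_mm = p$consensus_quantum_mm,
            min_support = p$min_support)
}

#' Write a lumen detection as JSON
#'
#' @param det A `lumen_detection`.
#' @param path Output path.
#' @param per_frame_csv Optional path for the per-frame candidate table.
#' @return `path`, invisibly.
#' @export
write_detection_json <- function(det, path, per_frame_csv = NULL) {
  stopifnot(inherits(det, "lumen_detection"))
  doc <- list(xc_mm = det$xc, yc_mm = det$yc, rc_mm = det$rc,
              n_supporting_frames = det$n_supporting_frames,
              status = det$status)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(per_frame_csv) && !is.null(det$per_frame)) {
    utils::write.csv(det$per_frame, per_frame_csv, row.names = FALSE)
  }
  invisible(path)
}
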