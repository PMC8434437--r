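#' B-mode frame sequence
#'
#' Container for a short sequence of grayscale transversal B-mode frames from
#' one array, with the physical pixel grid needed to express detections in mm.
#' Frames are stored as a `depth x lateral x frame` numeric array with 8-bit
#' intensity range (0-255). The coordinate convention is: `x` = lateral offset
#' from the array centre (mm, positive rightward), `y` = depth from the
#' transducer face (mm, positive downward); pixel centres, so pixel `(i, j)`
#' sits at `y = depth_origin_mm + (i - 0.5) * dy`,
#' `x = lateral_origin_mm + (j - 0.5) * dx`.
#'
#' @param frames Numeric 3-D array (`depth x lateral x n_frames`) or a matrix
#'   (single frame).
#' @param pixel_spacing_mm Length-2 numeric `(axial, lateral)` pixel spacing
#'   in mm.
#' @param depth_origin_mm Depth of the top edge of the image (mm).
#' @param lateral_origin_mm Lateral coordinate of the left edge (mm).
#' @param side `"left"` or `"right"` array.
#' @return An object of class `bmode_sequence`.
#' @export
bmode_sequence <- function(frames, pixel_spacing_mm,
                           depth_origin_mm = 0, lateral_origin_mm = 0,
                           side = c("left", "right")) {
  side <- match.arg(side)
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3, all(pixel_spacing_mm > 0),
            length(pixel_spacing_mm) == 2)
  structure(
    list(
      frames = frames,
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      depth_origin_mm = depth_origin_mm,
      lateral_origin_mm = lateral_origin_mm,
      side = side
    ),
    class = "bmode_sequence"
  )
}

#' @export
print.bmode_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "B-mode sequence (%s array): %d frames of %d x %d px (%.2f x %.2f mm/px)\n",
    x$side, d[3], d[1], d[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  cat(sprintf("  depth %.1f-%.1f mm, lateral %.1f-%.1f mm\n",
              x$depth_origin_mm, x$depth_origin_mm + d[1] * x$pixel_spacing_mm[1],
              x$lateral_origin_mm, x$lateral_origin_mm + d[2] * x$pixel_spacing_mm[2]))
  invisible(x)
}

# Physical coordinates of pixel centres (mm).
bmode_depths <- function(seq) {
  seq$depth_origin_mm + (seq_len(dim(seq$frames)[1]) - 0.5) * seq$pixel_spacing_mm[1]
}
bmode_laterals <- function(seq) {
  seq$lateral_origin_mm + (seq_len(dim(seq$frames)[2]) - 0.5) * seq$pixel_spacing_mm[2]
}

#' Write / read a B-mode sequence as multi-page TIFF with JSON sidecar
#'
#' The frames go to an 8-bit multi-page TIFF; pixel spacing, origins, side and
#' (when present) the phantom ground truth go to `<path>.json`.
#'
#' @param seq A [bmode_sequence()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @param truth Optional list recorded verbatim in the sidecar under `truth`
#'   (e.g. a [phantom_truth()]).
#' @return `write_bmode_tiff` returns `path` invisibly; `read_bmode_tiff`
#'   returns a [bmode_sequence()] with the sidecar's `truth` (if any) attached
#'   as attribute `"truth"`.
#' @export
write_bmode_tiff <- function(seq, path, truth = attr(seq, "truth")) {
  stopifnot(inherits(seq, "bmode_sequence"))
  pages <- lapply(seq_len(dim(seq$frames)[3]), function(k) {
    seq$frames[, , k] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(
    pixel_spacing_mm = seq$pixel_spacing_mm,
    depth_origin_mm = seq$depth_origin_mm,
    lateral_origin_mm = seq$lateral_origin_mm,
    side = seq$side,
    n_frames = dim(seq$frames)[3]
  )
  if (!is.null(truth)) meta$truth <- unclass(truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bmode_tiff
#' @export
read_bmode_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    frames[, , k] <- round(p * 255)
  }
  out <- bmode_sequence(frames, meta$pixel_spacing_mm,
                        meta$depth_origin_mm, meta$lateral_origin_mm, meta$side)
  if (!is.null(meta$truth)) attr(out, "truth") <- meta$truth
  out
}
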