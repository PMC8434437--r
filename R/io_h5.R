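#' Write / read a dual-beam IQ acquisition as HDF5
#'
#' Groups `/left` and `/right` each hold the ensemble as paired `re`/`im`
#' double datasets (`n_gates x n_slow_time`) plus `prf`, `gate_spacing_mm`,
#' `first_gate_depth_mm` and `side` attributes; simulation ground truth, when
#' given, goes to a `/truth` group. Requires the `rhdf5` package.
#'
#' @param pair List with `left`/`right` [iq_ensemble()]s (and optionally
#'   `truth`), as returned by [simulate_iq_pair()].
#' @param path HDF5 file path (overwritten).
#' @param geom,cfg Optional geometry/configuration whose key acoustic fields
#'   (`ftx`, `c`) are stored as file attributes.
#' @return `path`, invisibly.
#' @export
write_iq_h5 <- function(pair, path, geom = NULL, cfg = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 I/O")
  }
  stopifnot(inherits(pair$left, "iq_ensemble"), inherits(pair$right, "iq_ensemble"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (side in c("left", "right")) {
    ens <- pair[[side]]
    grp <- paste0("/", side)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(Re(ens$samples), path, paste0(grp, "/re"))
    rhdf5::h5write(Im(ens$samples), path, paste0(grp, "/im"))
    rhdf5::h5write(ens$prf, path, paste0(grp, "/prf"))
    rhdf5::h5write(ens$gate_spacing_mm, path, paste0(grp, "/gate_spacing_mm"))
    rhdf5::h5write(ens$first_gate_depth_mm, path, paste0(grp, "/first_gate_depth_mm"))
  }
  if (!is.null(pair$truth)) {
    rhdf5::h5createGroup(path, "/truth")
    tr <- pair$truth
    rhdf5::h5write(tr$lumen_depth_mm, path, "/truth/lumen_depth_mm")
    rhdf5::h5write(tr$snr_db, path, "/truth/snr_db")
    rhdf5::h5write(tr$clutter_db, path, "/truth/clutter_db")
    if (!is.null(tr$seed)) rhdf5::h5write(tr$seed, path, "/truth/seed")
    if (!is.null(tr$flow)) {
      rhdf5::h5write(tr$flow$peak_velocity, path, "/truth/peak_velocity")
      rhdf5::h5write(tr$flow$direction, path, "/truth/direction")
      rhdf5::h5write(tr$flow$profile_radius, path, "/truth/profile_radius_mm")
    }
  }
  if (!is.null(geom)) rhdf5::h5write(geom$tx_frequency_ftx, path, "/ftx")
  if (!is.null(cfg)) rhdf5::h5write(cfg$sound_speed_c, path, "/c")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_iq_h5
#' @return `read_iq_h5` returns a list with `left`/`right` [iq_ensemble()]s
#'   and `truth` (a list, or `NULL` when absent).
#' @export
read_iq_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 I/O")
  }
  read_side <- function(side) {
    grp <- paste0("/", side)
    re <- rhdf5::h5read(path, paste0(grp, "/re"))
    im <- rhdf5::h5read(path, paste0(grp, "/im"))
    iq_ensemble(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)),
                prf = as.numeric(rhdf5::h5read(path, paste0(grp, "/prf"))),
                gate_spacing_mm = as.numeric(rhdf5::h5read(path, paste0(grp, "/gate_spacing_mm"))),
                first_gate_depth_mm = as.numeric(rhdf5::h5read(path, paste0(grp, "/first_gate_depth_mm"))),
                side = side)
  }
  contents <- rhdf5::h5ls(path)
  truth <- NULL
  if ("truth" %in% contents$name[contents$group == "/"]) {
    tnames <- contents$name[contents$group == "/truth"]
    truth <- stats::setNames(
      lapply(tnames, function(nm) as.vector(rhdf5::h5read(path, paste0("/truth/", nm)))),
      tnames
    )
  }
  out <- list(left = read_side("left"), right = read_side("right"), truth = truth)
  rhdf5::h5closeAll()
  out
}
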