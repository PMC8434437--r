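#' Lumen-center localization error
#'
#' Euclidean distance between the automatically measured lumen center `CM`
#' and the expert reference center `CR`, both in mm image coordinates
#' (lateral, depth).
#'
#' @param CM Numeric length-2 vector `(x, y)` in mm, measured center.
#' @param CR Numeric length-2 vector `(x, y)` in mm, reference center.
#' @return Distance (mm), >= 0.
#' @examples
#' distance_error(c(0, 0), c(3, 4)) # 5
#' @export
distance_error <- function(CM, CR) {
  stopifnot(length(CM) == 2, length(CR) == 2, all(is.finite(CM)), all(is.finite(CR)))
  sqrt(sum((CM - CR)^2))
}

#' Root-mean-square localization error
#'
#' Campaign summary of per-experiment distance errors:
#' `sqrt(mean(De^2))`.
#'
#' @param De Numeric vector of distance errors (mm), non-empty.
#' @return r.m.s. error (mm).
#' @export
rms_error <- function(De) {
  if (length(De) == 0) stop("empty error list")
  sqrt(mean(De^2))
}

#' Signed relative velocity error
#'
#' `100 * (VM - VR) / VR`: percent deviation of a measured peak velocity
#' from the reference.
#'
#' @param VM Measured velocity (any consistent unit).
#' @param VR Reference velocity, non-zero.
#' @return Signed percent error.
#' @examples
#' relative_error_pct(19.5, 18) # +8.33
#' @export
relative_error_pct <- function(VM, VR) {
  if (any(VR == 0)) stop("reference velocity must be non-zero")
  100 * (VM - VR) / VR
}

#' Coefficient of variation
#'
#' `100 * sd(VM) / mean(VM)` with the sample (n-1) standard deviation;
#' the repeatability statistic of a sequence of measurements.
#'
#' @param VM Numeric vector of at least two measurements with non-zero mean.
#' @return CV (percent), >= 0 for positive-mean data.
#' @export
cv_pct <- function(VM) {
  if (length(VM) < 2) stop("need at least two measurements")
  m <- mean(VM)
  if (m == 0) stop("zero mean")
  100 * stats::sd(VM) / m
}

#' Evaluate a measurement campaign
#'
#' Applies the localization discard rule (distance error above
#' `discard_threshold`, default 1 mm, marks the experiment unsuccessful),
#' then summarizes the survivors: Min/Max/mean/r.m.s. of the distance error
#' and, when measured velocities are supplied, the mean peak, the mean signed
#' relative error and the coefficient of variation.
#'
#' @param records Data frame with columns `CMx`, `CMy`, `CRx`, `CRy` (mm) —
#'   or a precomputed `De` column — and optionally `VM` (measured peak
#'   velocity). Rows with `NA` in `VM` count as velocity failures.
#' @param VR Reference velocity for the relative error (same unit as `VM`);
#'   `NULL` to skip accuracy statistics.
#' @param discard_threshold Localization discard threshold (mm).
#' @return A list of class `summary_stats`: `N`, `n_discarded`, `min_De`,
#'   `max_De`, `mean_De`, `rms_De` (the localization r.m.s.), and when
#'   velocities are present `mean_peak`, `err_pct`, `cv_pct`, `sd_VM`
#'   (CV is `NA` with fewer than two surviving velocities).
#' @export
evaluate_campaign <- function(records, VR = NULL, discard_threshold = 1) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  De <- if ("De" %in% names(records)) {
    records$De
  } else {
    sqrt((records$CMx - records$CRx)^2 + (records$CMy - records$CRy)^2)
  }
  keep <- is.finite(De) & De <= discard_threshold
  if (!any(keep)) stop("all experiments discarded")
  Dek <- De[keep]
  out <- list(
    N = sum(keep),
    n_discarded = sum(!keep),
    min_De = min(Dek),
    max_De = max(Dek),
    mean_De = mean(Dek),
    rms_De = rms_error(Dek)
  )
  if (!is.null(VR) && "VM" %in% names(records)) {
    VM <- records$VM[keep]
    VM <- VM[is.finite(VM)]
    out$mean_peak <- if (length(VM)) mean(VM) else NA_real_
    out$err_pct <- if (length(VM)) mean(relative_error_pct(VM, VR)) else NA_real_
    out$cv_pct <- if (length(VM) >= 2) cv_pct(VM) else NA_real_
    out$sd_VM <- if (length(VM) >= 2) stats::sd(VM) else NA_real_
    out$VR <- VR
  }
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Campaign summary: N = %d (%d discarded)\n", x$N, x$n_discarded))
  cat(sprintf("  De min/max %.2f/%.2f mm, mean %.2f mm, r.m.s. %.2f mm\n",
              x$min_De, x$max_De, x$mean_De, x$rms_De))
  if (!is.null(x$mean_peak)) {
    cat(sprintf("  mean peak %.3g, Err%% %+.1f, CV%% %.1f\n",
                x$mean_peak, x$err_pct, x$cv_pct))
  }
  invisible(x)
}
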