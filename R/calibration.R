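#' Check extracorporal air calibration
#'
#' Scanner HU calibration is verified on the air surrounding the patient:
#' the mean HU over all voxels outside the body, excluding the patient-table
#' region (the lowest rows of each slice), should sit at -1000 HU. The
#' original acquisition protocol does not describe its control procedure in
#' detail, so the region definition here is a documented reconstruction:
#' everything outside the body mask minus a configurable bottom fraction of
#' image rows.
#'
#' @param volume A [ct_volume()].
#' @param body_mask A [label_volume()] with body voxels labelled 1. If
#'   `NULL`, [segment_body()] is run.
#' @param tolerance Accepted deviation of the extracorporal air mean from
#'   -1000 HU, in HU. Default 6 HU, a typical scanner QA band.
#' @param table_fraction Fraction of the lowest (most posterior) image rows
#'   excluded as the patient-table region. Default 0.15.
#' @return A `calibration_report` with fields `extracorporal_air_mean`,
#'   `extracorporal_air_sd`, `passed`, `tolerance` and `n_voxels`.
#' @export
check_air_calibration <- function(volume, body_mask = NULL, tolerance = 6,
                                  table_fraction = 0.15) {
  stopifnot(inherits(volume, "ct_volume"), tolerance > 0,
            table_fraction >= 0, table_fraction < 1)
  if (is.null(body_mask)) body_mask <- segment_body(volume)
  check_same_grid(volume, body_mask, "CT and body mask")
  d <- grid_dim(volume)
  keep_rows <- seq_len(d[2]) <= floor(d[2] * (1 - table_fraction))
  sel <- !mask_array(body_mask)
  sel[, !keep_rows, ] <- FALSE
  if (!any(sel))
    stop("degenerate input: no extracorporal air voxels outside body and table region",
         call. = FALSE)
  v <- volume$values[sel]
  m <- mean(v)
  structure(
    list(extracorporal_air_mean = m,
         extracorporal_air_sd = if (length(v) > 1L) sd(v) else 0,
         passed = abs(m - (-1000)) <= tolerance,
         tolerance = tolerance,
         n_voxels = length(v)),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> extracorporal air %.1f +/- %.1f HU over %d voxels: %s (tolerance %g HU)\n",
              x$extracorporal_air_mean, x$extracorporal_air_sd, x$n_voxels,
              if (x$passed) "PASSED" else "FAILED", x$tolerance))
  invisible(x)
}
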