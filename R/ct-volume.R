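#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield unit (HU) values together
#' with its voxel geometry. The in-memory axis order is fixed as
#' (slice, row, column): slice 1 is the most superior slice, rows run
#' anterior to posterior and columns run across the patient. All masks in
#' the package share the grid of their CT volume and no resampling is
#' performed anywhere in the pipeline.
#'
#' @param values 3D numeric array of HU values (typically -1024..3071).
#'   Must be finite everywhere.
#' @param spacing Numeric length-3, voxel edge lengths in mm for the
#'   (slice, row, column) axes; strictly positive.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `ct_volume` with fields `values`, `spacing`,
#'   `origin` and `axis_order`.
#' @seealso [label_volume()], [read_volume()], [voxel_volume_ml()]
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("CT values must be finite (no NA/NaN/Inf)", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel edge lengths in mm", call. = FALSE)
  origin <- as.double(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 numeric", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         axis_order = c("slice", "row", "column")),
    class = "ct_volume")
}

#' Integer label volume container
#'
#' Carrier for lung, airway, body and exclusion masks: a 3D array of
#' non-negative integer labels on the same grid as its CT volume, with 0
#' meaning background everywhere.
#'
#' @param labels 3D array of non-negative integers.
#' @inheritParams ct_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (is.logical(labels)) storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("labels must be integers", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0L)) stop("labels must be non-negative", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values", call. = FALSE)
  structure(
    list(labels = labels, spacing = spacing, origin = as.double(origin),
         axis_order = c("slice", "row", "column")),
    class = "label_volume")
}

#' Voxel volume in millilitres
#'
#' @param x A `ct_volume` or `label_volume`.
#' @return `prod(spacing) / 1000`, the volume of one voxel in ml.
#' @export
voxel_volume_ml <- function(x) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "label_volume"))
  prod(x$spacing) / 1000
}

grid_dim <- function(x) {
  dim(if (inherits(x, "ct_volume")) x$values else x$labels)
}

# Every combined use of a CT volume and a mask goes through this check:
# same shape and same spacing (to within 1e-6 mm).
check_same_grid <- function(a, b, what = "volumes") {
  da <- grid_dim(a); db <- grid_dim(b)
  if (!identical(da, db))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("spacing mismatch between %s", what), call. = FALSE)
  invisible(TRUE)
}

mask_array <- function(x) {
  if (inherits(x, "label_volume")) x$labels > 0L
  else if (is.logical(x)) x
  else stop("expected a label_volume or logical array", call. = FALSE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (slice x row x column)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm (voxel %.4g ml)\n",
              x$spacing[1], x$spacing[2], x$spacing[3], voxel_volume_ml(x)))
  cat(sprintf("  HU range: [%.0f, %.0f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("<label_volume> %d x %d x %d voxels, labels: {%s}\n",
              d[1], d[2], d[3],
              if (length(tab)) paste(names(tab), collapse = ", ") else "none"))
  invisible(x)
}
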