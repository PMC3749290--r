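#' Compute the emphysema density mask
#'
#' A lung voxel is assigned to emphysema if its density is equal to or
#' below the threshold (inclusive comparison, default -950 HU, the
#' standard inspiratory emphysema threshold). The inclusive comparison is
#' deliberate and documented because implementations differ.
#'
#' @param volume A [ct_volume()].
#' @param lung_mask A [label_volume()]; any nonzero label is lung.
#' @param threshold HU threshold, default -950.
#' @return A [label_volume()] with emphysema voxels labelled 1.
#' @export
compute_density_mask <- function(volume, lung_mask, threshold = -950) {
  stopifnot(inherits(volume, "ct_volume"))
  check_same_grid(volume, lung_mask, "CT and lung mask")
  lung <- mask_array(lung_mask)
  if (!any(lung))
    stop("degenerate input: empty lung mask", call. = FALSE)
  emph <- lung & (volume$values <= threshold)
  out <- label_volume(array(as.integer(emph), grid_dim(volume)),
                      volume$spacing, volume$origin)
  attr(out, "threshold") <- threshold
  out
}

#' Exclusion set for manual lesion correction
#'
#' Sacculations, abscesses, cysts and bronchiectases contain air that the
#' density mask would otherwise count as emphysema; their voxels are
#' collected here and subtracted from the emphysema mask (never from the
#' lung mask, so LV, MLD and the 15th percentile are unaffected).
#'
#' @param mask A [label_volume()]; nonzero voxels are excluded.
#' @param source `"manual"` or `"file"`.
#' @param note Free-text provenance note.
#' @return An `exclusion_set`.
#' @export
exclusion_set <- function(mask, source = c("manual", "file"), note = "") {
  stopifnot(inherits(mask, "label_volume"))
  structure(list(mask = mask, source = match.arg(source), note = note),
            class = "exclusion_set")
}

#' Subtract an exclusion set from an emphysema mask
#'
#' @param emphysema_mask A [label_volume()] from [compute_density_mask()].
#' @param exclusions An [exclusion_set()] (or a [label_volume()]).
#' @return The emphysema mask minus excluded voxels; the voxel count never
#'   increases.
#' @export
apply_exclusions <- function(emphysema_mask, exclusions) {
  stopifnot(inherits(emphysema_mask, "label_volume"))
  excl_mask <- if (inherits(exclusions, "exclusion_set")) exclusions$mask else exclusions
  stopifnot(inherits(excl_mask, "label_volume"))
  check_same_grid(emphysema_mask, excl_mask, "emphysema mask and exclusions")
  keep <- mask_array(emphysema_mask) & !mask_array(excl_mask)
  out <- label_volume(array(as.integer(keep), grid_dim(emphysema_mask)),
                      emphysema_mask$spacing, emphysema_mask$origin)
  attr(out, "threshold") <- attr(emphysema_mask, "threshold")
  out
}

# 15th-percentile rule: the smallest observed HU value h such that the
# fraction of lung voxels with HU strictly below h is at least `p`. With a
# constant lung no value qualifies and the maximum is returned.
hu_percentile <- function(values, p = 0.15) {
  n <- length(values)
  ux <- sort(unique(values))
  cnt <- tabulate(match(values, ux), nbins = length(ux))
  frac_below <- c(0, cumsum(cnt)[-length(cnt)]) / n
  hit <- which(frac_below >= p)
  if (length(hit) == 0L) ux[length(ux)] else ux[hit[1]]
}

scope_mask <- function(lung_mask, scope) {
  labs <- lung_mask$labels
  switch(scope,
         whole = labs > 0L,
         right = labs == 1L,
         left  = labs == 2L)
}

#' Densitometry report
#'
#' Computes the full densitometric panel over the selected lung scope:
#' * LV: segmented lung volume (ml),
#' * EV: emphysema volume (ml), voxels at or below the threshold,
#' * EI: emphysema index EV/LV (stored as a fraction of 1),
#' * MLD: mean lung density (HU),
#' * perc15: 15th percentile of the density histogram (HU) — the threshold
#'   value below which 15% of lung voxels fall (inverse empirical CDF, no
#'   interpolation),
#' * LW: lung weight (g) via the linear water-air density model,
#'   `sum(max(0, (HU + 1000)/1000)) * voxel_volume_ml`, clamped at -1000 HU
#'   (the source protocol does not state its mass formula; this standard
#'   reconstruction is documented in the methods vignette).
#'
#' MLD and perc15 are computed over the lung mask before any exclusion
#' subtraction; exclusions affect only EV/EI.
#'
#' @param volume A [ct_volume()].
#' @param lung_mask A [label_volume()] with right lung = 1, left lung = 2.
#' @param emphysema_mask A [label_volume()] from [compute_density_mask()],
#'   possibly after [apply_exclusions()]. If `NULL` it is computed at
#'   `threshold`.
#' @param scope `"whole"`, `"right"` or `"left"`.
#' @param threshold HU threshold recorded in the report (and used when
#'   `emphysema_mask` is `NULL`).
#' @param bin_width Histogram bin width in HU.
#' @param exclusions_applied Recorded flag.
#' @return A `densitometry_report`.
#' @export
compute_report <- function(volume, lung_mask, emphysema_mask = NULL,
                           scope = c("whole", "right", "left"),
                           threshold = -950, bin_width = 1,
                           exclusions_applied = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(volume, "ct_volume"))
  check_same_grid(volume, lung_mask, "CT and lung mask")
  if (is.null(emphysema_mask)) {
    emphysema_mask <- compute_density_mask(volume, lung_mask, threshold)
  } else {
    check_same_grid(volume, emphysema_mask, "CT and emphysema mask")
    thr_attr <- attr(emphysema_mask, "threshold")
    if (!is.null(thr_attr)) threshold <- thr_attr
  }
  sel <- scope_mask(lung_mask, scope)
  n_lung <- sum(sel)
  if (n_lung == 0L)
    stop(sprintf("degenerate input: no lung voxels in scope '%s'", scope), call. = FALSE)
  vv <- voxel_volume_ml(volume)
  hu <- volume$values[sel]
  n_emph <- sum(mask_array(emphysema_mask) & sel)
  LV <- n_lung * vv
  EV <- n_emph * vv
  structure(
    list(threshold = threshold,
         LV = LV, EV = EV, EI = EV / LV,
         MLD = mean(hu),
         LW = sum(pmax(0, (hu + 1000) / 1000)) * vv,
         perc15 = hu_percentile(hu, 0.15),
         histogram = density_histogram(volume, lung_mask, bin_width = bin_width,
                                       scope = scope),
         scope = scope,
         exclusions_applied = isTRUE(exclusions_applied),
         n_lung_voxels = n_lung, n_emphysema_voxels = n_emph),
    class = "densitometry_report")
}

#' Lung density histogram
#'
#' Uniform-width histogram of lung HU values over `[-1024, 200]`; values
#' outside the range are clipped into the edge bins with a warning.
#'
#' @inheritParams compute_report
#' @param bin_width Bin width in HU (> 0), default 1.
#' @param range HU range covered by the bins.
#' @return A `density_histogram` with `bin_edges`, `counts` and `total`.
#' @export
density_histogram <- function(volume, lung_mask, bin_width = 1,
                              range = c(-1024, 200),
                              scope = c("whole", "right", "left")) {
  scope <- match.arg(scope)
  stopifnot(bin_width > 0)
  check_same_grid(volume, lung_mask, "CT and lung mask")
  sel <- scope_mask(lung_mask, scope)
  if (!any(sel))
    stop("degenerate input: empty lung mask", call. = FALSE)
  hu <- volume$values[sel]
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, edges[length(edges)] + bin_width)
  top <- edges[length(edges)]
  if (any(hu < edges[1]) || any(hu > top))
    warning("HU values outside histogram range were clipped into edge bins",
            call. = FALSE)
  hu <- pmin(pmax(hu, edges[1]), top)
  idx <- findInterval(hu, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, total = length(hu)),
            class = "density_histogram")
}

#' Minimum intensity projection (MinIP)
#'
#' Sliding-slab minimum along one axis; the output grid matches the input,
#' each voxel holding the minimum over a slab of the requested physical
#' thickness centred on it (truncated at the volume edges). MinIP slabs of
#' a few mm accentuate low-attenuation emphysema against parenchyma.
#'
#' @param volume A [ct_volume()].
#' @param slab_thickness_mm Slab thickness in mm; must be at least one
#'   voxel along `axis`.
#' @param axis Axis to project along: 1 = slice, 2 = row, 3 = column.
#' @return A [ct_volume()] of projected values.
#' @export
render_minip <- function(volume, slab_thickness_mm = 5, axis = 1) {
  stopifnot(inherits(volume, "ct_volume"), axis %in% 1:3)
  sp <- volume$spacing[axis]
  if (slab_thickness_mm < sp)
    stop(sprintf("slab thickness %g mm is thinner than one voxel (%g mm) along axis %d",
                 slab_thickness_mm, sp, axis), call. = FALSE)
  w <- max(1L, as.integer(round(slab_thickness_mm / sp)))
  d <- grid_dim(volume)
  lo <- floor((w - 1L) / 2L)
  hi <- w - 1L - lo
  out <- volume$values
  v <- volume$values
  for (off in seq(-lo, hi)) {
    if (off == 0L) next
    src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    shifted <- switch(axis,
                      v[src, , , drop = FALSE],
                      v[, src, , drop = FALSE],
                      v[, , src, drop = FALSE])
    out <- pmin(out, shifted)
  }
  ct_volume(out, volume$spacing, volume$origin)
}

#' @export
print.densitometry_report <- function(x, ...) {
  cat(sprintf("<densitometry_report> scope: %s (threshold %g HU%s)\n",
              x$scope, x$threshold,
              if (x$exclusions_applied) ", exclusions applied" else ""))
  cat(sprintf("  LV %.0f ml | EV %.0f ml | EI %.1f%%\n", x$LV, x$EV, 100 * x$EI))
  cat(sprintf("  MLD %.1f HU | 15th percentile %.0f HU | LW %.0f g\n",
              x$MLD, x$perc15, x$LW))
  invisible(x)
}

#' Flatten a densitometry report to a one-row data frame
#'
#' Convenience for assembling cohort tables from per-subject reports.
#'
#' @param report A `densitometry_report`.
#' @param id Optional subject identifier.
#' @return A one-row `data.frame` with LV, EV, EI, MLD, LW, perc15.
#' @export
report_row <- function(report, id = NA_character_) {
  stopifnot(inherits(report, "densitometry_report"))
  data.frame(id = id, scope = report$scope, threshold = report$threshold,
             LV = report$LV, EV = report$EV, EI = report$EI,
             MLD = report$MLD, LW = report$LW, perc15 = report$perc15,
             stringsAsFactors = FALSE)
}
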