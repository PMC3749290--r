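#' Segmentation parameters
#'
#' Classical threshold / region-growing / morphological-closing lung
#' segmentation is fully parameterised here, and the parameters actually
#' used are recorded in every [segmentation_result] for reproducibility.
#'
#' @param air_threshold HU threshold below which voxels are lung-air
#'   candidates; must be negative. Default -500 HU.
#' @param trachea_seed Optional manual trachea seed as voxel coordinates
#'   `c(slice, row, column)`; `NULL` requests automatic seeding.
#' @param airway_leak_volume_step_ml Volume jump (ml) between successive
#'   region-growing thresholds that flags an airway leak. Default 20 ml.
#' @param closing_radius_mm Radius (mm) of the ball used for per-lung
#'   morphological closing, reincorporating vessels and septa. Default 2 mm.
#' @param min_lung_volume_ml Minimum connected-component volume (ml)
#'   retained as a lung candidate. Default 50 ml.
#' @return A `segmentation_params` list.
#' @export
segment_params <- function(air_threshold = -500, trachea_seed = NULL,
                           airway_leak_volume_step_ml = 20,
                           closing_radius_mm = 2, min_lung_volume_ml = 50) {
  if (!is.numeric(air_threshold) || air_threshold >= 0)
    stop("`air_threshold` must be negative (HU)", call. = FALSE)
  if (closing_radius_mm < 0) stop("`closing_radius_mm` must be >= 0", call. = FALSE)
  if (airway_leak_volume_step_ml <= 0) stop("`airway_leak_volume_step_ml` must be > 0", call. = FALSE)
  if (!is.null(trachea_seed)) {
    trachea_seed <- as.integer(trachea_seed)
    if (length(trachea_seed) != 3L || any(trachea_seed < 1L))
      stop("`trachea_seed` must be c(slice, row, column) voxel indices", call. = FALSE)
  }
  structure(list(air_threshold = air_threshold, trachea_seed = trachea_seed,
                 airway_leak_volume_step_ml = airway_leak_volume_step_ml,
                 closing_radius_mm = closing_radius_mm,
                 min_lung_volume_ml = min_lung_volume_ml),
            class = "segmentation_params")
}

# Voxel offsets (dz, dy, dx) of a ball of physical radius `radius_mm`,
# anisotropy-aware. Excludes the centre for dilation symmetry it does not
# matter; includes it for erosion correctness, so keep it.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2 <=
    radius_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

close_mask <- function(mask, dim3, offs) {
  if (nrow(offs) <= 1L) return(mask)
  array(erode_3d(dilate_3d(as.logical(mask), dim3, offs), dim3, offs), dim = dim3)
}

#' Segment the body from a chest CT
#'
#' The body is the largest 26-connected component of voxels above -200 HU,
#' with holes (lungs, airways, gas) filled in-plane so the mask is solid.
#'
#' @param volume A [ct_volume()].
#' @return A [label_volume()] with body voxels labelled 1.
#' @export
segment_body <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- grid_dim(volume)
  dense <- volume$values > -200
  if (!any(dense))
    stop("degenerate input: no voxel above -200 HU (all-air volume?)", call. = FALSE)
  labs <- cc_label_3d(as.logical(dense), d, 26L)
  tab <- tabulate(labs)
  body <- array(labs == which.max(tab), dim = d)
  body <- array(fill_holes_slicewise(as.logical(body), d), dim = d)
  label_volume(array(as.integer(body), dim = d), volume$spacing, volume$origin)
}

#' Segment the central airways by leak-checked region growing
#'
#' Grows a 6-connected region from a trachea seed over voxels strictly
#' below a threshold, relaxing the threshold in 10 HU steps from -990 HU up
#' to `air_threshold`. When the grown volume jumps by more than
#' `airway_leak_volume_step_ml` between steps the growth has leaked into
#' the parenchyma and the last pre-leak mask is returned. The whole grown
#' tree is later excluded from the lung so airway lumen air is never
#' counted as emphysema.
#'
#' Automatic seeding looks in the top third of slices for a round low-HU
#' (< -900) in-body 2D component with an area of 50-500 mm^2.
#'
#' @param volume A [ct_volume()].
#' @param params A [segment_params()] list.
#' @param body Optional precomputed body mask.
#' @return A [label_volume()] with airway lumen labelled 1. Attribute
#'   `seed` records the seed voxel used.
#' @export
segment_airways <- function(volume, params = segment_params(), body = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(body)) body <- segment_body(volume)
  check_same_grid(volume, body, "CT and body mask")
  d <- grid_dim(volume)
  seed <- params$trachea_seed
  if (is.null(seed)) seed <- find_trachea_seed(volume, body)
  if (any(seed > d))
    stop("trachea seed outside the volume", call. = FALSE)
  seed_flat <- (seed[1] - 1L) + d[1] * ((seed[2] - 1L) + d[2] * (seed[3] - 1L))
  vv <- voxel_volume_ml(volume)
  vals <- as.double(volume$values)
  thresholds <- seq(-990, params$air_threshold, by = 10)
  prev_mask <- NULL
  prev_vol <- NA_real_
  for (thr in thresholds) {
    m <- region_grow_3d(vals, d, seed_flat, thr, 6L)
    vol <- sum(m) * vv
    if (!is.na(prev_vol) && (vol - prev_vol) > params$airway_leak_volume_step_ml) {
      m <- prev_mask
      break
    }
    prev_mask <- m
    prev_vol <- vol
  }
  out <- label_volume(array(as.integer(m), dim = d), volume$spacing, volume$origin)
  attr(out, "seed") <- seed
  out
}

# Round, appropriately-sized 2D air component search on the top third of
# slices. Errors with class "lungdens_seed_error" if nothing qualifies so
# callers can fall back to a manual seed.
find_trachea_seed <- function(volume, body) {
  d <- grid_dim(volume)
  area_vox <- volume$spacing[2] * volume$spacing[3]
  bodym <- mask_array(body)
  for (z in seq_len(max(1L, floor(d[1] / 3)))) {
    sl <- volume$values[z, , ] < -900 & bodym[z, , ]
    if (!any(sl)) next
    sl3 <- array(sl, dim = c(1L, d[2], d[3]))
    labs <- array(cc_label_3d(as.logical(sl3), dim(sl3), 26L), dim = dim(sl3))
    for (lab in seq_len(max(labs))) {
      idx <- which(labs[1, , ] == lab, arr.ind = TRUE)
      area <- nrow(idx) * area_vox
      if (area < 50 || area > 500) next
      ry <- diff(range(idx[, 1])) + 1L
      rx <- diff(range(idx[, 2])) + 1L
      aspect <- max(ry, rx) / max(1L, min(ry, rx))
      fill <- nrow(idx) / (ry * rx)
      if (aspect > 2 || fill < 0.4) next
      centroid <- round(colMeans(idx))
      return(c(z, centroid[1], centroid[2]))
    }
  }
  stop(structure(class = c("lungdens_seed_error", "error", "condition"),
                 list(message = "no trachea-like seed found in the top third of slices; supply `trachea_seed` manually",
                      call = NULL)))
}

#' Segment left and right lungs from a chest CT
#'
#' Lung candidates are in-body voxels below `air_threshold` minus the grown
#' airway tree. 26-connected components of at least `min_lung_volume_ml`
#' are retained (at most the two largest); each lung is morphologically
#' closed to reincorporate vessels and septa; labels are assigned by
#' centre-of-mass column (right lung = smaller column index = label 1,
#' patient supine). A single component spanning the midline is split by
#' iterative erosion until two cores appear, then voxels are re-assigned to
#' the nearer core by breadth-first growth (ties to the right lung).
#'
#' @inheritParams segment_airways
#' @param calibration_tolerance HU tolerance for the extracorporal air
#'   check run alongside segmentation; a failed check logs a warning and
#'   proceeds.
#' @return A `segmentation_result` with `lung_mask` (1 = right, 2 = left),
#'   `airway_mask`, `params_used` and `calibration`.
#' @export
segment_lungs <- function(volume, params = segment_params(),
                          calibration_tolerance = 6) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- grid_dim(volume)
  vv <- voxel_volume_ml(volume)
  body <- segment_body(volume)
  calib <- tryCatch(
    check_air_calibration(volume, body, tolerance = calibration_tolerance),
    error = function(e) NULL)
  if (!is.null(calib) && !calib$passed)
    warning(sprintf("air calibration failed: extracorporal mean %.1f HU (tolerance %g)",
                    calib$extracorporal_air_mean, calib$tolerance), call. = FALSE)
  airway <- tryCatch(segment_airways(volume, params, body),
                     lungdens_seed_error = function(e) NULL)
  awm <- if (is.null(airway)) array(FALSE, d) else mask_array(airway)
  cand <- mask_array(body) & (volume$values < params$air_threshold) & !awm
  labs <- array(cc_label_3d(as.logical(cand), d, 26L), dim = d)
  if (max(labs) == 0L)
    stop("segmentation failure: no lung candidate voxels below air threshold",
         call. = FALSE)
  counts <- tabulate(labs[labs > 0L])
  keep <- which(counts * vv >= params$min_lung_volume_ml)
  if (length(keep) == 0L)
    stop(sprintf("segmentation failure: no component reaches min_lung_volume_ml = %g ml",
                 params$min_lung_volume_ml), call. = FALSE)
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  keep <- head(keep, 2L)

  cols <- slice.index(array(0, d), 3)
  lungs <- vector("list", 2L)
  if (length(keep) == 2L) {
    lungs[[1]] <- labs == keep[1]
    lungs[[2]] <- labs == keep[2]
  } else {
    comp <- labs == keep[1]
    split <- split_touching_lungs(comp, d, cols, mask_array(body))
    lungs <- split
  }
  lungs <- Filter(Negate(is.null), lungs)

  # closing per lung; stay inside the body, off the airway, and off the
  # previously committed lung so masks remain disjoint and deterministic
  offs <- ball_offsets(params$closing_radius_mm, volume$spacing)
  out <- array(0L, d)
  coms <- numeric(length(lungs))
  for (i in seq_along(lungs)) {
    m <- close_mask(lungs[[i]], d, offs)
    m <- m & mask_array(body) & !awm
    if (i == 2L) m <- m & !(out > 0L)
    out[m] <- i
    coms[i] <- mean(cols[m])
  }
  # right lung (smaller column centre of mass) gets label 1
  if (length(lungs) == 2L && coms[1] > coms[2]) {
    relab <- out
    relab[out == 1L] <- 2L
    relab[out == 2L] <- 1L
    out <- relab
  }
  structure(
    list(lung_mask = label_volume(out, volume$spacing, volume$origin),
         airway_mask = label_volume(array(as.integer(awm), d), volume$spacing, volume$origin),
         params_used = params,
         calibration = calib),
    class = "segmentation_result")
}

# Split a single candidate component that spans the midline: erode until
# two cores appear, then grow both cores back through the component (BFS,
# ties to the lower label which is assigned to the smaller-column core).
split_touching_lungs <- function(comp, d, cols, bodym) {
  com_col <- mean(cols[bodym])
  rng <- range(cols[comp])
  if (!(rng[1] < com_col && rng[2] > com_col))
    return(list(comp, NULL))
  offs1 <- matrix(c(0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                  ncol = 3, byrow = TRUE)
  er <- comp
  cores <- NULL
  for (iter in seq_len(25L)) {
    er <- array(erode_3d(as.logical(er), d, offs1), dim = d)
    if (!any(er)) break
    labs <- array(cc_label_3d(as.logical(er), d, 26L), dim = d)
    if (max(labs) >= 2L) {
      counts <- tabulate(labs[labs > 0L])
      top <- order(counts, decreasing = TRUE)[1:2]
      com1 <- mean(cols[labs == top[1]])
      com2 <- mean(cols[labs == top[2]])
      right_first <- com1 <= com2
      seeds <- array(0L, d)
      seeds[labs == top[if (right_first) 1 else 2]] <- 1L
      seeds[labs == top[if (right_first) 2 else 1]] <- 2L
      cores <- seeds
      break
    }
  }
  if (is.null(cores)) return(list(comp, NULL))
  grown <- array(grow_labels_3d(cores, as.logical(comp), d, 6L), dim = d)
  # voxels unreachable by 6-connectivity (rare diagonal links): nearest core label
  grown[comp & grown == 0L] <- 1L
  list(comp & grown == 1L, comp & grown == 2L)
}

#' @export
print.segmentation_result <- function(x, ...) {
  vv <- voxel_volume_ml(x$lung_mask)
  n1 <- sum(x$lung_mask$labels == 1L)
  n2 <- sum(x$lung_mask$labels == 2L)
  cat(sprintf("<segmentation_result> right lung %.0f ml, left lung %.0f ml, airway %.0f ml\n",
              n1 * vv, n2 * vv, sum(x$airway_mask$labels > 0L) * vv))
  invisible(x)
}
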