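#' Phantom specification
#'
#' Full parameterisation of the digital chest phantom: a soft-tissue body
#' ellipsoid in exterior air containing two lung ellipsoids, an optional
#' blind-ending trachea/main-bronchus tube, emphysema lesions placed to a
#' voxel-exact target fraction, and optional thin-walled cysts. Geometry is
#' expressed relative to the grid extent so phantoms scale with resolution.
#'
#' @param grid_shape Voxels per axis (slice, row, column). Default 64^3.
#' @param spacing Voxel edge lengths in mm. Default 3 mm isotropic.
#' @param body_hu Soft-tissue HU. Default +40.
#' @param parenchyma_hu_mean Lung parenchyma HU. Default -850.
#' @param parenchyma_hu_sd Parenchymal texture SD in HU (pre-noise).
#' @param emphysema_hu_mean Emphysematous-voxel HU. Default -980; must be
#'   below -950 while `parenchyma_hu_mean` is above it.
#' @param emphysema_fraction Designed fraction of lung voxels assigned to
#'   emphysema, in `[0, 0.5]`.
#' @param emphysema_pattern `"subpleural"`, `"bronchovascular"`,
#'   `"centrilobular"` or `"diffuse"` — spatial priors mirroring the lesion
#'   distributions seen in CF lungs.
#' @param airway Logical, include the airway tube.
#' @param airway_radius_mm Trachea tube radius in mm.
#' @param cysts List of cysts, each
#'   `list(center = c(z, y, x) relative offsets in [-1, 1] lung coords,
#'   lung = 1 or 2, radius_mm, wall_hu = 0, wall_thickness_mm = 3,
#'   lumen_hu = -1000)`.
#' @param noise_sd Additive Gaussian HU noise SD applied last.
#' @param exterior_hu HU outside the body. Default -1000.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = c(3, 3, 3),
                         body_hu = 40, parenchyma_hu_mean = -850,
                         parenchyma_hu_sd = 0, emphysema_hu_mean = -980,
                         emphysema_fraction = 0,
                         emphysema_pattern = c("centrilobular", "subpleural",
                                               "bronchovascular", "diffuse"),
                         airway = TRUE, airway_radius_mm = 8,
                         cysts = list(), noise_sd = 0, exterior_hu = -1000,
                         seed = 1L) {
  emphysema_pattern <- match.arg(emphysema_pattern)
  if (!(emphysema_hu_mean < -950 && -950 < parenchyma_hu_mean))
    stop("need emphysema_hu_mean < -950 < parenchyma_hu_mean", call. = FALSE)
  if (emphysema_fraction < 0 || emphysema_fraction > 0.5)
    stop("`emphysema_fraction` must be in [0, 0.5]", call. = FALSE)
  if (noise_sd < 0 || parenchyma_hu_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.double(spacing),
         body_hu = body_hu, parenchyma_hu_mean = parenchyma_hu_mean,
         parenchyma_hu_sd = parenchyma_hu_sd,
         emphysema_hu_mean = emphysema_hu_mean,
         emphysema_fraction = emphysema_fraction,
         emphysema_pattern = emphysema_pattern,
         airway = isTRUE(airway), airway_radius_mm = airway_radius_mm,
         cysts = cysts, noise_sd = noise_sd, exterior_hu = exterior_hu,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# voxel-centre physical coordinates along each axis
axis_coords <- function(d, sp) lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * sp[a])

# membership array of an axis-aligned ellipsoid, plus the normalised radial
# coordinate u in [0, 1] inside it
ellipsoid_fields <- function(d, co, centre, semi) {
  tz <- ((co[[1]] - centre[1]) / semi[1])^2
  ty <- ((co[[2]] - centre[2]) / semi[2])^2
  tx <- ((co[[3]] - centre[3]) / semi[3])^2
  r2 <- outer(outer(tz, ty, "+"), tx, "+")
  list(inside = r2 <= 1, u = sqrt(pmin(r2, 1)))
}

# squared distance from every voxel centre to a segment p0-p1
segment_dist2 <- function(d, co, p0, p1) {
  Z <- array(rep(co[[1]], times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(co[[2]], each = d[1]), times = d[3]), dim = d)
  X <- array(rep(co[[3]], each = d[1] * d[2]), dim = d)
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- if (len2 == 0) 0 else pmin(pmax(
    ((Z - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (X - p0[3]) * v[3]) / len2, 0), 1)
  (Z - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 + (X - (p0[3] + t * v[3]))^2
}

#' Generate a digital chest phantom
#'
#' Builds the CT volume and exact ground-truth masks (body, lungs,
#' airway, emphysema, cysts). Masks are constructed before noise is added,
#' so every downstream accuracy claim can be checked against them. The
#' emphysema ground truth holds exactly `round(fraction * n_lung_voxels)`
#' voxels: spherical lesions (radius 2-8 mm) are placed under the
#' pattern's spatial prior until the target is exceeded, then trimmed back
#' voxel-exactly by seeded random removal.
#'
#' @param spec A [phantom_spec()].
#' @return A `ct_phantom` list: `volume` (a [ct_volume()]), `truth` (a list
#'   of [label_volume()]s: `body`, `lung` with right = 1 / left = 2,
#'   `airway`, `emphysema`, `cysts`), `achieved_fraction`, and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  ext <- d * sp
  ctr <- ext / 2
  co <- axis_coords(d, sp)

  body_semi <- c(0.44, 0.33, 0.45) * ext
  body <- ellipsoid_fields(d, co, ctr, body_semi)$inside

  lung_semi <- c(0.78 * body_semi[1], 0.60 * body_semi[2], 0.34 * body_semi[3])
  lung_centres <- list(
    right = c(ctr[1], ctr[2], ctr[3] - 0.50 * body_semi[3]),
    left  = c(ctr[1], ctr[2], ctr[3] + 0.50 * body_semi[3]))
  lf_r <- ellipsoid_fields(d, co, lung_centres$right, lung_semi)
  lf_l <- ellipsoid_fields(d, co, lung_centres$left, lung_semi)

  # blind-ending trachea plus two main bronchi dipping into the lungs
  airway_mask <- array(FALSE, d)
  carina <- c(ctr[1] - 0.10 * body_semi[1], ctr[2], ctr[3])
  top <- c(ctr[1] - 0.88 * body_semi[1], ctr[2], ctr[3])
  if (spec$airway) {
    r2t <- spec$airway_radius_mm^2
    airway_mask <- airway_mask | (segment_dist2(d, co, top, carina) <= r2t)
    rb <- max(spec$airway_radius_mm * 0.6, min(sp) * 0.8)
    for (lc in lung_centres) {
      tip <- carina + 0.55 * (lc - carina)
      airway_mask <- airway_mask | (segment_dist2(d, co, carina, tip) <= rb^2)
    }
    airway_mask <- airway_mask & body
  }

  lung_r <- lf_r$inside & !airway_mask
  lung_l <- lf_l$inside & !airway_mask
  lung_any <- lung_r | lung_l
  n_lung <- sum(lung_any)

  # cysts: lumen + wall, carved inside the lungs; truth cyst mask = lumina
  cyst_lumen <- array(FALSE, d)
  cyst_wall <- array(FALSE, d)
  cyst_parts <- lapply(spec$cysts, function(cy) {
    lungc <- if (identical(cy$lung, 2) || identical(cy$lung, 2L)) lung_centres$left
    else lung_centres$right
    centre <- lungc + (cy$center %||% c(0, 0, 0)) * 0.5 * lung_semi
    rad <- cy$radius_mm
    wt <- cy$wall_thickness_mm %||% 3
    d2 <- segment_dist2(d, co, centre, centre)
    list(lumen = d2 <= rad^2 & lung_any,
         wall = d2 > rad^2 & d2 <= (rad + wt)^2 & lung_any,
         wall_hu = cy$wall_hu %||% 0, lumen_hu = cy$lumen_hu %||% -1000)
  })
  for (cp in cyst_parts) {
    cyst_lumen <- cyst_lumen | cp$lumen
    cyst_wall <- cyst_wall | cp$wall
  }

  out <- with_seed(spec$seed, {
    emph <- place_emphysema(spec, d, sp, co, lung_any & !cyst_lumen & !cyst_wall,
                            lf_r, lf_l, carina, top, n_lung)
    values <- array(spec$exterior_hu, d)
    values[body] <- spec$body_hu
    values[lung_any] <- spec$parenchyma_hu_mean
    if (spec$parenchyma_hu_sd > 0)
      values[lung_any] <- values[lung_any] + rnorm(n_lung, 0, spec$parenchyma_hu_sd)
    values[airway_mask] <- -1000
    values[emph] <- spec$emphysema_hu_mean
    for (cp in cyst_parts) {
      # wall first so the lumen re-carves its interior
      values[cp$wall] <- cp$wall_hu
      values[cp$lumen] <- cp$lumen_hu
    }
    if (spec$noise_sd > 0)
      values <- values + array(rnorm(prod(d), 0, spec$noise_sd), d)
    list(values = values, emph = emph)
  })

  lung_labels <- array(0L, d)
  lung_labels[lung_r] <- 1L
  lung_labels[lung_l] <- 2L
  mk <- function(m) label_volume(array(as.integer(m), d), sp)
  structure(
    list(volume = ct_volume(out$values, sp),
         truth = list(body = mk(body),
                      lung = label_volume(lung_labels, sp),
                      airway = mk(airway_mask),
                      emphysema = mk(out$emph),
                      cysts = mk(cyst_lumen)),
         achieved_fraction = sum(out$emph) / n_lung,
         spec = spec),
    class = "ct_phantom")
}

# Lesion placement under the pattern's spatial prior. Runs inside the
# spec-seeded RNG scope.
place_emphysema <- function(spec, d, sp, co, candidates, lf_r, lf_l,
                            carina, top, n_lung) {
  emph <- array(FALSE, d)
  target <- round(spec$emphysema_fraction * n_lung)
  if (target == 0L) return(emph)
  cand_idx <- which(candidates)
  if (target > length(cand_idx))
    stop(sprintf("generation error: emphysema fraction %.3f unreachable; achievable maximum %.3f",
                 spec$emphysema_fraction, length(cand_idx) / n_lung), call. = FALSE)
  u <- pmin(lf_r$u, lf_l$u)[cand_idx]  # radial coordinate within the nearer lung
  weights <- switch(spec$emphysema_pattern,
    diffuse = rep(1, length(cand_idx)),
    subpleural = u^6 + 1e-6,
    centrilobular = exp(-((u - 0.5) / 0.25)^2) + 1e-6,
    bronchovascular = {
      d2 <- segment_dist2(d, co, top, carina)[cand_idx]
      dist <- sqrt(d2)
      guard <- spec$airway_radius_mm + 2 * max(sp)
      w <- exp(-pmax(dist - guard, 0) / 25)
      w[dist < guard] <- 1e-6
      w + 1e-6
    })
  if (spec$emphysema_pattern == "diffuse") {
    emph[sample(cand_idx, target)] <- TRUE
    return(emph)
  }
  coords <- arrayInd(cand_idx, d)
  for (iter in seq_len(5000L)) {
    count <- sum(emph)
    if (count >= target) break
    ci <- sample.int(length(cand_idx), 1L, prob = weights)
    centre <- (coords[ci, ] - 0.5) * sp
    rad <- runif(1, 2, 8)
    dz <- (coords[, 1] - 0.5) * sp[1] - centre[1]
    dy <- (coords[, 2] - 0.5) * sp[2] - centre[2]
    dx <- (coords[, 3] - 0.5) * sp[3] - centre[3]
    hit <- cand_idx[dz^2 + dy^2 + dx^2 <= rad^2]
    emph[hit] <- TRUE
  }
  count <- sum(emph)
  if (count < target) {
    # pattern prior saturated; top up voxel-wise under the same prior
    remaining <- which(candidates & !emph)
    need <- target - count
    if (need > length(remaining))
      stop(sprintf("generation error: emphysema fraction %.3f unreachable; achievable maximum %.3f",
                   spec$emphysema_fraction, (count + length(remaining)) / n_lung),
           call. = FALSE)
    emph[sample(remaining, need)] <- TRUE
  } else if (count > target) {
    drop <- sample(which(emph), count - target)
    emph[drop] <- FALSE
  }
  emph
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %s voxels, emphysema fraction %.4f (pattern %s, noise SD %g HU)\n",
              paste(grid_dim(x$volume), collapse = "x"), x$achieved_fraction,
              x$spec$emphysema_pattern, x$spec$noise_sd))
  invisible(x)
}
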