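test_that("the density-mask threshold is inclusive at exactly -950 HU", {
  bx <- box_lung_volume(lung_hu = -800)
  v <- bx$volume
  idx <- which(bx$lung$labels > 0)
  v$values[idx[1]] <- -950        # exactly at threshold: counted
  v$values[idx[2]] <- -949.999    # just above: not counted
  emph <- compute_density_mask(v, bx$lung, threshold = -950)
  expect_equal(sum(emph$labels), 1L)
  expect_equal(which(emph$labels > 0), idx[1])
})

test_that("an all -800 HU lung yields an empty mask at -950", {
  bx <- box_lung_volume(lung_hu = -800)
  emph <- compute_density_mask(bx$volume, bx$lung)
  expect_equal(sum(emph$labels), 0L)
  expect_error(compute_density_mask(bx$volume,
                                    label_volume(array(0L, dim(bx$lung$labels)),
                                                 bx$lung$spacing)),
               "degenerate")
})

test_that("a uniform -850 HU lung matches the closed-form panel", {
  bx <- box_lung_volume(lung_hu = -850)
  rep <- compute_report(bx$volume, bx$lung)
  n <- sum(bx$lung$labels > 0)
  vv <- voxel_volume_ml(bx$volume)
  expect_equal(rep$LV, n * vv)
  expect_equal(rep$EV, 0)
  expect_equal(rep$EI, 0)
  expect_equal(rep$MLD, -850)
  expect_equal(rep$LW, n * vv * 0.150)   # (HU + 1000)/1000 = 0.150 g/ml
  expect_equal(rep$perc15, -850)
})

test_that("perc15 follows the inverse empirical CDF without interpolation", {
  # 15 voxels at -1000 and 85 at -800: fraction below -800 is exactly 0.15
  vals <- array(40, c(4, 5, 5))
  lung <- array(0L, c(4, 5, 5))
  lung[, , ] <- 1L
  vals[seq_len(100) <= 15] <- -1000
  vals[seq_len(100) > 15] <- -800
  v <- ct_volume(vals, c(2, 2, 2))
  rep <- compute_report(v, label_volume(lung, c(2, 2, 2)))
  expect_equal(rep$perc15, -800)
  # 15 at -1000, 5 at -900, 80 at -800: already 15% strictly below -900
  vals2 <- vals; vals2[16:20] <- -900
  rep2 <- compute_report(ct_volume(vals2, c(2, 2, 2)),
                         label_volume(lung, c(2, 2, 2)))
  expect_equal(rep2$perc15, -900)
})

test_that("a designed 20% low-attenuation fraction gives EI 0.20", {
  vals <- array(40, c(10, 5, 4))
  lung <- array(1L, c(10, 5, 4))
  vals[seq_len(200) <= 40] <- -980
  vals[seq_len(200) > 40] <- -850
  rep <- compute_report(ct_volume(vals, c(2, 2, 2)),
                        label_volume(lung, c(2, 2, 2)))
  expect_equal(rep$EI, 0.20)
})

test_that("EV is monotone in the threshold", {
  ph <- small_phantom(emphysema_fraction = 0.1, noise_sd = 7, seed = 30)
  seg_lung <- ph$truth$lung
  evs <- vapply(c(-990, -960, -950, -920, -880), function(thr)
    compute_report(ph$volume, seg_lung, threshold = thr)$EV, numeric(1))
  expect_true(all(diff(evs) >= 0))
})

test_that("MLD and perc15 are shift-covariant; EV shifts with the threshold", {
  ph <- small_phantom(emphysema_fraction = 0.08, noise_sd = 4, seed = 31)
  lung <- ph$truth$lung
  base <- compute_report(ph$volume, lung, threshold = -950)
  for (c_shift in c(-25, 10)) {
    shifted <- ct_volume(ph$volume$values + c_shift, ph$volume$spacing)
    rep <- compute_report(shifted, lung, threshold = -950 + c_shift)
    expect_equal(rep$MLD, base$MLD + c_shift, tolerance = 1e-12)
    expect_equal(rep$perc15, base$perc15 + c_shift, tolerance = 1e-12)
    expect_equal(rep$EV, base$EV)
  }
})

test_that("per-lung scopes partition the whole-lung quantities", {
  ph <- small_phantom(emphysema_fraction = 0.1, seed = 32)
  lung <- ph$truth$lung
  emph <- compute_density_mask(ph$volume, lung)
  whole <- compute_report(ph$volume, lung, emph, scope = "whole")
  right <- compute_report(ph$volume, lung, emph, scope = "right")
  left <- compute_report(ph$volume, lung, emph, scope = "left")
  expect_equal(right$LV + left$LV, whole$LV)
  expect_equal(right$EV + left$EV, whole$EV)
  expect_equal((right$MLD * right$LV + left$MLD * left$LV) / whole$LV, whole$MLD)
})

test_that("exclusions only ever remove voxels, by exactly the overlap", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(48, 48, 48), spacing = c(4, 4, 4),
    emphysema_fraction = 0.08, seed = 33,
    cysts = list(list(center = c(0, 0, 0), lung = 1, radius_mm = 14,
                      wall_thickness_mm = 6))))
  lung <- ph$truth$lung
  emph <- compute_density_mask(ph$volume, lung)
  excl <- exclusion_set(ph$truth$cysts, source = "file")
  overlap <- sum(emph$labels > 0 & ph$truth$cysts$labels > 0)
  expect_gt(overlap, 0)  # the cyst lumen must actually fall in the mask
  corrected <- apply_exclusions(emph, excl)
  expect_equal(sum(emph$labels) - sum(corrected$labels), overlap)

  # identity and annihilation
  none <- exclusion_set(label_volume(array(0L, dim(lung$labels)), lung$spacing))
  expect_identical(apply_exclusions(emph, none)$labels, emph$labels)
  all_excl <- exclusion_set(label_volume(array(1L, dim(lung$labels)), lung$spacing))
  expect_equal(sum(apply_exclusions(emph, all_excl)$labels), 0L)

  # EI never increases under exclusion
  ei_before <- compute_report(ph$volume, lung, emph)$EI
  ei_after <- compute_report(ph$volume, lung, corrected,
                             exclusions_applied = TRUE)$EI
  expect_lte(ei_after, ei_before)
})

test_that("exclusion grids must match the emphysema grid", {
  ph <- small_phantom(emphysema_fraction = 0.05, seed = 34)
  emph <- compute_density_mask(ph$volume, ph$truth$lung)
  wrong <- label_volume(array(0L, c(8, 8, 8)), ph$volume$spacing)
  expect_error(apply_exclusions(emph, exclusion_set(wrong)), "grid mismatch")
})

test_that("histogram counts are conserved and localise a uniform lung", {
  bx <- box_lung_volume(lung_hu = -850)
  h <- density_histogram(bx$volume, bx$lung)
  expect_equal(sum(h$counts), h$total)
  expect_equal(h$total, sum(bx$lung$labels > 0))
  nz <- which(h$counts > 0)
  expect_length(nz, 1L)
  expect_lte(h$bin_edges[nz], -850)
  expect_gt(h$bin_edges[nz + 1L], -850)
})

test_that("perc15 from the 1-HU histogram agrees with raw values within 1 HU", {
  ph <- small_phantom(emphysema_fraction = 0.1, noise_sd = 6, seed = 35)
  lung <- ph$truth$lung
  rep <- compute_report(ph$volume, lung)
  h <- rep$histogram
  cum <- cumsum(h$counts) / h$total
  # smallest bin edge with at least 15% of voxels in strictly lower bins
  frac_below <- c(0, head(cum, -1))
  p15_hist <- h$bin_edges[which(frac_below >= 0.15)[1]]
  expect_lte(abs(p15_hist - rep$perc15), 1)
})

test_that("values outside the histogram range are clipped with a warning", {
  bx <- box_lung_volume(lung_hu = -850)
  v <- bx$volume
  v$values[which(bx$lung$labels > 0)[1]] <- 500
  expect_warning(h <- density_histogram(v, bx$lung), "clipped")
  expect_equal(sum(h$counts), h$total)
})

test_that("MinIP reduces to identity, embedded minima, and global minima", {
  ph <- small_phantom(grid = c(16, 16, 16), spacing = c(2, 2, 2),
                      airway = FALSE, seed = 36)
  one <- render_minip(ph$volume, slab_thickness_mm = 2, axis = 1)
  expect_equal(one$values, ph$volume$values)

  # a single dark voxel spreads over the slab width along the axis
  v <- ct_volume(array(-850, c(16, 8, 8)), c(2, 2, 2))
  v$values[8, 4, 4] <- -980
  m <- render_minip(v, slab_thickness_mm = 10, axis = 1)  # 5 voxels
  expect_equal(m$values[8, 4, 4], -980)
  expect_equal(m$values[6, 4, 4], -980)
  expect_equal(m$values[10, 4, 4], -980)
  expect_equal(m$values[12, 4, 4], -850)

  # slab spanning the whole axis (from both ends) gives per-column minima
  g <- render_minip(v, slab_thickness_mm = 2 * 16 * 2, axis = 1)
  expect_equal(g$values[1, 4, 4], -980)
  expect_equal(g$values[16, 4, 4], -980)
  expect_error(render_minip(v, slab_thickness_mm = 1, axis = 1), "thinner")
})
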