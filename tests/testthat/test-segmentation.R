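test_that("body segmentation recovers the phantom body and tolerates noise", {
  ph <- small_phantom(airway = FALSE, seed = 4)
  body <- segment_body(ph$volume)
  expect_gte(dice_coef(body$labels > 0, ph$truth$body$labels > 0), 0.99)

  phn <- small_phantom(airway = FALSE, noise_sd = 5, seed = 4)
  body_n <- segment_body(phn$volume)
  expect_gte(dice_coef(body_n$labels > 0, body$labels > 0), 0.99)
})

test_that("an all-air volume is a degenerate body input", {
  vol <- ct_volume(array(-1000, c(8, 8, 8)), c(2, 2, 2))
  expect_error(segment_body(vol), "degenerate")
})

test_that("airway growing covers the tube and spares the parenchyma", {
  ph <- small_phantom(grid = c(48, 48, 48), spacing = c(3.5, 3.5, 3.5), seed = 6)
  aw <- segment_airways(ph$volume)
  tube <- ph$truth$airway$labels > 0
  lung <- ph$truth$lung$labels > 0
  expect_gte(sum(aw$labels > 0 & tube) / sum(tube), 0.90)
  expect_lte(sum(aw$labels > 0 & lung) / sum(lung), 0.01)
})

test_that("leak detection halts growth from a parenchymal seed", {
  ph <- small_phantom(airway = FALSE, seed = 9)
  lung_idx <- which(ph$truth$lung$labels == 1L, arr.ind = TRUE)
  seed_vox <- lung_idx[which.min(abs(lung_idx[, 1] - mean(lung_idx[, 1]))), ]
  params <- segment_params(trachea_seed = seed_vox)
  aw <- segment_airways(ph$volume, params)
  grown_ml <- sum(aw$labels > 0) * voxel_volume_ml(aw)
  expect_lte(grown_ml, params$airway_leak_volume_step_ml)
})

test_that("airway segmentation is deterministic", {
  ph <- small_phantom(grid = c(44, 44, 44), seed = 10)
  a1 <- segment_airways(ph$volume)
  a2 <- segment_airways(ph$volume)
  expect_identical(a1$labels, a2$labels)
})

test_that("absent trachea-like component raises a seed error", {
  # air cavity far too large (cross-section >> 500 mm^2) to pass as trachea
  dims <- c(20, 20, 20)
  vals <- array(-1000, dims)
  vals[2:19, 2:19, 2:19] <- 40
  vals[4:17, 4:17, 4:17] <- -850
  vol <- ct_volume(vals, c(4, 4, 4))
  expect_error(segment_airways(vol), class = "lungdens_seed_error")
})

test_that("lung segmentation recovers both lungs with correct sidedness", {
  for (noise in c(0, 3, 7)) {
    ph <- generate_phantom(phantom_spec(noise_sd = noise, seed = 20 + noise))
    seg <- segment_lungs(ph$volume)
    truth <- ph$truth$lung$labels
    for (lab in 1:2)
      expect_gte(dice_coef(seg$lung_mask$labels == lab, truth == lab), 0.95)
    # right lung label 1 must sit at smaller column indices
    cols <- slice.index(truth, 3)
    expect_lt(mean(cols[seg$lung_mask$labels == 1L]),
              mean(cols[seg$lung_mask$labels == 2L]))
    # lung volume within 5% of ground truth
    lv_seg <- sum(seg$lung_mask$labels > 0) * voxel_volume_ml(ph$volume)
    lv_truth <- sum(truth > 0) * voxel_volume_ml(ph$volume)
    expect_lt(abs(lv_seg - lv_truth) / lv_truth, 0.05)
  }
})

test_that("lung and airway masks are always disjoint", {
  ph <- small_phantom(grid = c(48, 48, 48), spacing = c(3.5, 3.5, 3.5), seed = 13)
  seg <- segment_lungs(ph$volume)
  expect_equal(sum(seg$lung_mask$labels > 0 & seg$airway_mask$labels > 0), 0)
})

test_that("raising the air threshold never shrinks the lung-candidate set", {
  ph <- small_phantom(noise_sd = 5, seed = 14, airway = FALSE)
  body <- segment_body(ph$volume)$labels > 0
  sizes <- vapply(c(-700, -500, -300), function(thr)
    sum(body & ph$volume$values < thr), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("segmentation is bit-deterministic for identical inputs", {
  ph <- small_phantom(noise_sd = 3, seed = 15)
  s1 <- segment_lungs(ph$volume)
  s2 <- segment_lungs(ph$volume)
  expect_identical(s1$lung_mask$labels, s2$lung_mask$labels)
  expect_identical(s1$airway_mask$labels, s2$airway_mask$labels)
})

test_that("touching lungs are split into two sided components", {
  # two air boxes joined by a thin bridge across the midline: a single
  # 26-connected candidate that erosion can split at the neck
  dims <- c(20, 20, 30)
  vals <- array(-1000, dims)
  vals[2:19, 2:19, 2:29] <- 40
  vals[6:15, 6:15, 5:14] <- -850
  vals[6:15, 6:15, 17:26] <- -850
  vals[10:11, 10:11, 15:16] <- -850  # bridge
  vol <- ct_volume(vals, c(4, 4, 4))
  seg <- segment_lungs(vol, segment_params(min_lung_volume_ml = 20))
  labs <- sort(unique(as.vector(seg$lung_mask$labels)))
  expect_identical(labs, c(0L, 1L, 2L))
  cols <- slice.index(seg$lung_mask$labels, 3)
  expect_lt(mean(cols[seg$lung_mask$labels == 1L]),
            mean(cols[seg$lung_mask$labels == 2L]))
})
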