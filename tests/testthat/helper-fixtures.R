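# Small fixture builders shared across the suite. Everything is generated
# in code; no binary fixtures on disk.

# compact phantom for fast unit tests
small_phantom <- function(..., grid = c(40, 40, 40), spacing = c(4, 4, 4)) {
  generate_phantom(phantom_spec(grid_shape = grid, spacing = spacing, ...))
}

# a bare uniform-lung volume: a box lung of constant HU inside a body slab,
# for closed-form densitometry checks
box_lung_volume <- function(lung_hu = -850, dims = c(12, 12, 12),
                            spacing = c(2, 2, 2)) {
  vals <- array(40, dims)
  lung <- array(0L, dims)
  core <- 4:9
  vals[core, core, core] <- lung_hu
  lung[core, core, core] <- 1L
  list(volume = ct_volume(vals, spacing),
       lung = label_volume(lung, spacing))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Naive per-voxel triple-loop densitometry: the independent oracle for the
# production (vectorised) path. Deliberately written as explicit loops.
naive_densitometry <- function(volume, lung_mask, emphysema_mask, threshold = -950) {
  d <- dim(volume$values)
  vv <- prod(volume$spacing) / 1000
  n_lung <- 0L; n_emph <- 0L; hu_sum <- 0; lw_sum <- 0
  hu_list <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (lung_mask$labels[i, j, k] > 0L) {
      hu <- volume$values[i, j, k]
      n_lung <- n_lung + 1L
      hu_sum <- hu_sum + hu
      lw_sum <- lw_sum + max(0, (hu + 1000) / 1000)
      hu_list[n_lung] <- hu
      if (emphysema_mask$labels[i, j, k] > 0L) n_emph <- n_emph + 1L
    }
  }
  # inverse empirical CDF without interpolation, by explicit counting over
  # the sorted values (first element of each tie run has i-1 values below)
  xs <- sort(hu_list)
  p15 <- xs[n_lung]
  i <- 1L
  while (i <= n_lung) {
    if ((i - 1L) / n_lung >= 0.15) { p15 <- xs[i]; break }
    j <- i
    while (j <= n_lung && xs[j] == xs[i]) j <- j + 1L
    i <- j
  }
  list(n_lung = n_lung, n_emph = n_emph,
       LV = n_lung * vv, EV = n_emph * vv, EI = n_emph / n_lung,
       MLD = hu_sum / n_lung, LW = lw_sum * vv, perc15 = p15)
}
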