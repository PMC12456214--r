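# Programmatic fixtures shared across the test files.

iso_spacing <- c(1.15, 1.15, 1.15)

# digitized ball of radius `r_vox` voxels, centred in a cube with `pad`
# empty voxels around it
digitized_sphere <- function(r_vox, pad = 3L, spacing = iso_spacing) {
  n <- as.integer(2 * ceiling(r_vox) + 2 * pad + 1L)
  cc <- (n - 1) / 2
  z <- array(rep(0:(n - 1), times = n * n), c(n, n, n))
  y <- array(rep(rep(0:(n - 1), each = n), times = n), c(n, n, n))
  x <- array(rep(0:(n - 1), each = n * n), c(n, n, n))
  a <- array(0L, c(n, n, n))
  a[(z - cc)^2 + (y - cc)^2 + (x - cc)^2 <= r_vox^2] <- 1L
  label_stack(a, spacing)
}

# solid cube of `side` voxels, optionally flush with the z = 0 face
digitized_cube <- function(side = 40L, pad = 3L, touch_border = FALSE,
                           spacing = iso_spacing) {
  n <- as.integer(side + 2L * pad)
  a <- array(0L, c(n, n, n))
  if (touch_border) a[1:side, pad + 1:side, pad + 1:side] <- 1L
  else a[pad + 1:side, pad + 1:side, pad + 1:side] <- 1L
  label_stack(a, spacing)
}

# hand-planted cell table for the QC filters: 3 border cells, 2 small,
# 1 aspherical, 4 clean
planted_qc_table <- function() {
  data.frame(
    label_id = 1:10,
    voxel_count = c(8000, 9000, 7000, 4999, 1200, 6000, 5000, 8000, 9000, 10000),
    volume = NA_real_,
    sphericity = c(0.8, 0.7, 0.9, 0.8, 0.8, 0.30, 0.35, 0.62, 0.64, 0.9),
    touches_border = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       FALSE, FALSE)
  )
}

# tiny two-label toy for IoU: label A = 4x4x4 block, B = same block shifted
# so that it overlaps half of A (IoU = 1/3)
shifted_block_pair <- function() {
  a <- array(0L, c(10, 10, 10))
  b <- array(0L, c(10, 10, 10))
  a[2:5, 2:5, 2:5] <- 1L
  b[2:5, 2:5, 4:7] <- 1L
  list(truth = label_stack(a, iso_spacing), pred = label_stack(b, iso_spacing))
}

# shape for a diameter draw at a given bulk fill fraction (mirrors the
# internal auto sizing, exposed for tests)
auto_shape_for <- function(diameters, fill, spacing = iso_spacing) {
  adipo3d:::auto_shape(diameters, spacing, fill)
}
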