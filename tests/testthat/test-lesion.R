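grid3 <- function(vals, dims = c(4L, 4L, 4L), vox = c(1, 1, 1),
                  kind = "probability") {
  volume_grid(array(vals, dim = dims), vox, kind = kind)
}

test_that("volume_grid validates its invariants", {
  expect_error(grid3(-0.1), "\\[0, 1\\]")
  expect_error(grid3(0.5, kind = "binary"), "0 or 1")
  expect_error(volume_grid(matrix(0, 2, 2), c(1, 1, 1)), "3-D")
  expect_error(grid3(0.5, vox = c(1, -1, 1)), "positive")
})

test_that("map thresholding is inclusive and counts exactly", {
  expect_equal(sum(threshold_map(grid3(0.05))$data), 64)
  expect_equal(sum(threshold_map(grid3(0.049))$data), 0)
  expect_error(threshold_map(grid3(0.5), 0), "\\(0, 1\\]")
  expect_error(threshold_map(grid3(0.5), 1.5), "\\(0, 1\\]")
  expect_error(threshold_map(threshold_map(grid3(0.5))), "probability")

  # counting oracle on random values
  set.seed(41)
  vals <- runif(27)
  g <- volume_grid(array(vals, c(3L, 3L, 3L)), c(1, 1, 1))
  expect_equal(sum(threshold_map(g, 0.3)$data), sum(vals >= 0.3))
})

test_that("overlap volumes, units, and error messages", {
  set.seed(42)
  dims <- c(10L, 10L, 10L)
  a <- volume_grid(array(rbinom(1000, 1, 0.5), dims), c(1, 1, 1),
                   kind = "binary")
  b <- volume_grid(array(rbinom(1000, 1, 0.5), dims), c(1, 1, 1),
                   kind = "binary")
  ov <- lesion_overlap(a, b)
  expect_equal(ov$n_overlap_voxels, sum(a$data * b$data))
  expect_lte(ov$overlap_volume, min(ov$network_volume, ov$lesion_volume))

  # disjoint masks
  left <- array(0, dims); left[1:5, , ] <- 1
  right <- array(0, dims); right[6:10, , ] <- 1
  expect_equal(lesion_overlap(
    volume_grid(left, c(1, 1, 1), kind = "binary"),
    volume_grid(right, c(1, 1, 1), kind = "binary"))$overlap_volume, 0)

  # unit conversion: 1000 voxels of 1 mm^3 inside the network = 1 cm^3
  inside <- array(0, dims); inside[1:10, 1:10, 1:10] <- 1
  net <- volume_grid(inside, c(1, 1, 1), kind = "binary")
  expect_equal(lesion_overlap(net, net)$overlap_volume, 1.0)

  # grid mismatch errors name the attribute
  small <- volume_grid(array(1, c(5L, 5L, 5L)), c(1, 1, 1), kind = "binary")
  expect_error(lesion_overlap(a, small), "shape")
  b2 <- volume_grid(b$data, c(2, 2, 2), kind = "binary")
  expect_error(lesion_overlap(a, b2), "voxel_dims")
  b3 <- volume_grid(b$data, c(1, 1, 1), affine = diag(c(1, 1, 1, 1)) + 0.001,
                    kind = "binary")
  expect_error(lesion_overlap(a, b3), "affine")
})

test_that("random-mask overlap matches the binomial independence oracle", {
  set.seed(43)
  n <- 30L^3
  p <- 0.3; q <- 0.4
  a <- volume_grid(array(rbinom(n, 1, p), c(30L, 30L, 30L)), c(1, 1, 1),
                   kind = "binary")
  b <- volume_grid(array(rbinom(n, 1, q), c(30L, 30L, 30L)), c(1, 1, 1),
                   kind = "binary")
  ov <- lesion_overlap(a, b)
  expect_lt(abs(ov$n_overlap_voxels - p * q * n),
            3 * sqrt(n * p * q * (1 - p * q)))
})

test_that("overlap is subadditive over networks and scales with voxel size", {
  set.seed(44)
  dims <- c(8L, 8L, 8L)
  lesion <- volume_grid(array(rbinom(512, 1, 0.4), dims), c(1, 1, 1),
                        kind = "binary")
  a <- array(rbinom(512, 1, 0.3), dims)
  b <- array(rbinom(512, 1, 0.3), dims)
  vg <- function(x, vox = c(1, 1, 1)) {
    volume_grid(x, vox, kind = "binary")
  }
  union_ov <- lesion_overlap(lesion, vg(pmax(a, b)))$overlap_volume
  expect_lte(union_ov, lesion_overlap(lesion, vg(a))$overlap_volume +
               lesion_overlap(lesion, vg(b))$overlap_volume)
  # equality for disjoint networks
  b_disj <- b * (1 - a)
  expect_equal(
    lesion_overlap(lesion, vg(pmax(a, b_disj)))$overlap_volume,
    lesion_overlap(lesion, vg(a))$overlap_volume +
      lesion_overlap(lesion, vg(b_disj))$overlap_volume)
  # doubling voxel dims multiplies volumes by exactly 8
  l2 <- volume_grid(lesion$data, c(2, 2, 2), kind = "binary")
  a2 <- volume_grid(a, c(2, 2, 2), kind = "binary")
  expect_equal(lesion_overlap(l2, a2)$overlap_volume,
               8 * lesion_overlap(lesion, vg(a))$overlap_volume)
})

test_that("NIfTI round trip preserves data, voxel dims and affine", {
  vols <- generate_toy_volumes(c(12L, 10L, 8L), c(2, 2.5, 3), seed = 5,
                               n_participants = 2)
  for (g in list(vols$prob_map_lang, vols$lesion_masks[[1]])) {
    path <- withr::local_tempfile(fileext = ".nii")
    write_nifti(g, path)
    back <- read_nifti(path)
    expect_equal(dim(back$data), dim(g$data))
    expect_equal(back$voxel_dims, g$voxel_dims, tolerance = 1e-6)
    expect_equal(back$affine, g$affine, tolerance = 1e-6)
    expect_equal(back$kind, g$kind)
    tol <- if (g$kind == "binary") 0 else 1e-6
    expect_lt(max(abs(back$data - g$data)), tol + 1e-12)
  }
  # and the end-to-end table is identical whether computed in memory or
  # through files
  direct <- lesion_volume_table(vols$lesion_masks, vols$prob_map_lang,
                                vols$prob_map_md)
  dir <- withr::local_tempdir()
  paths <- vapply(names(vols$lesion_masks), function(id) {
    p <- file.path(dir, paste0(id, ".nii"))
    write_nifti(vols$lesion_masks[[id]], p)
    p
  }, character(1))
  reread <- lapply(paths, read_nifti)
  via_files <- lesion_volume_table(reread, vols$prob_map_lang,
                                   vols$prob_map_md)
  expect_equal(via_files$lesion_vol_lang, direct$lesion_vol_lang,
               tolerance = 1e-6)
})
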