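test_that("region growing matches the exhaustive flood-fill oracle", {
  set.seed(101)
  for (i in 1:80) {
    conn <- if (i %% 2) 6L else 26L
    rv <- random_volume_with_seed()
    seg <- region_grow_3d(rv$volume, rv$seed, connectivity = conn)
    include <- rv$volume$voxels >= -450 & rv$volume$voxels <= 1500
    expect_identical(seg$mask, flood_oracle(include, rv$seed, conn))
    expect_identical(seg$voxel_count, sum(seg$mask))
    expect_equal(seg$volume_mm3, seg$voxel_count * 1)
    # every masked voxel is in-interval
    expect_true(all(rv$volume$voxels[seg$mask] >= -450 &
                    rv$volume$voxels[seg$mask] <= 1500))
  }
})

test_that("a small in-interval block is segmented exactly", {
  vox <- array(-800L, c(3, 3, 3))
  vox[1:2, 1:2, 2] <- 50L
  vol <- ct_volume(vox, c(1, 1, 1))
  seg <- region_grow_3d(vol, c(0, 0, 1))
  expect_equal(seg$voxel_count, 4L)
  expect_identical(seg$mask, vox == 50L)
})

test_that("the inclusion interval is [-450, 1500] with inclusive endpoints", {
  vol <- line_volume(c(0, -450, 1500, -451))
  seg <- region_grow_3d(vol, c(0, 1, 1))  # no interval given: defaults apply
  expect_identical(as.vector(seg$mask[, 2, 2]), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(seg$hu_interval, c(-450, 1500))
})

test_that("seed preconditions are enforced", {
  vol <- line_volume(c(0, 10))
  expect_error(region_grow_3d(vol, c(0, 0, 0)), "outside inclusion interval")
  expect_error(region_grow_3d(vol, c(9, 0, 0)), "outside lattice")
  expect_error(region_grow_3d(vol, c(0, 1, 1), slice_range = c(2, 3)),
               "seed slice")
})

test_that("slice_range is half-open in slice indices", {
  vox <- array(0L, c(2, 2, 4))
  vol <- ct_volume(vox, c(1, 1, 1))
  seg <- region_grow_3d(vol, c(0, 0, 1), slice_range = c(1, 3))
  expect_true(all(seg$mask[, , 2:3]))
  expect_false(any(seg$mask[, , c(1, 4)]))
})

test_that("enlarging the HU interval never shrinks the mask", {
  set.seed(77)
  for (i in 1:25) {
    rv <- random_volume_with_seed()
    hu <- rv$volume$voxels[rv$seed[1] + 1, rv$seed[2] + 1, rv$seed[3] + 1]
    small <- region_grow_3d(rv$volume, rv$seed,
                            hu_interval = c(hu - 100, hu + 100))
    big <- region_grow_3d(rv$volume, rv$seed,
                          hu_interval = c(hu - 600, hu + 1200))
    expect_true(all(big$mask[small$mask]))
  }
})

test_that("structure subtraction removes excluded voxels and keeps the seed component", {
  seg0 <- region_grow_3d(line_volume(c(10, 20, 30, 40, 50)), c(0, 1, 1))
  # empty exclusion is the identity
  same <- subtract_structures(seg0, array(FALSE, dim(seg0$mask)))
  expect_identical(same$mask, seg0$mask)
  # splitting the mask keeps only the seed-containing component
  excl <- array(FALSE, dim(seg0$mask)); excl[3, 2, 2] <- TRUE
  cut <- subtract_structures(seg0, excl)
  expect_identical(which(cut$mask), which(seg0$mask)[1:2])
  expect_equal(cut$voxel_count, 2L)
  # removing the seed voxel is an error
  excl2 <- array(FALSE, dim(seg0$mask)); excl2[1, 2, 2] <- TRUE
  expect_error(subtract_structures(seg0, excl2), "seed removed")
  expect_error(subtract_structures(seg0, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("vessel subtraction recovers the phantom ground truth exactly", {
  spec <- phantom_spec("malignant", 7, rng_seed = 11,
                       vessel = list(direction = "+x", radius_mm = 1.5,
                                     hu = 60))
  truth <- generate_phantom(spec)
  seg <- region_grow_3d(truth$volume, round(spec$center))
  # the vessel is attached: growth leaks into it
  expect_gt(seg$voxel_count, sum(truth$mask))
  clean <- subtract_structures(seg, truth$vessel_mask)
  expect_identical(clean$mask, truth$mask)
})

test_that("nodule volume is voxel count times voxel volume", {
  seg <- region_grow_3d(line_volume(c(1, 2, 3, 4)), c(0, 1, 1))
  expect_equal(nodule_volume(seg, c(1, 1, 1)), 4)
  expect_equal(nodule_volume(seg, c(0.5, 0.5, 1.0)), 1)
  # 10-voxel example at anisotropic spacing
  seg10 <- region_grow_3d(line_volume(1:10), c(0, 1, 1))
  expect_equal(nodule_volume(seg10, c(0.5, 0.5, 1.0)), 2.5)
  expect_error(nodule_volume(seg, c(0, 1, 1)), "positive")
})

test_that("a voxelised sphere's volume approximates the analytic volume", {
  spec <- phantom_spec("benign", 5, dims = c(20L, 20L, 16L),
                       spacing = c(1, 1, 1), rng_seed = 3)
  truth <- generate_phantom(spec)
  seg <- region_grow_3d(truth$volume, round(spec$center))
  analytic <- 4 / 3 * pi * 125
  expect_lt(abs(nodule_volume(seg, c(1, 1, 1)) - analytic) / analytic, 0.10)
})

test_that("volume doubling time follows the closed form and the stability rule", {
  g <- volume_doubling_time(100, 200, 100)
  expect_equal(g$vdt_days, 100)
  expect_false(g$stable)

  g2 <- volume_doubling_time(500, 550, 365)
  expect_equal(g2$vdt_days, 365 * log(2) / log(550 / 500), tolerance = 1e-12)
  expect_equal(round(g2$vdt_days), 2654)
  expect_true(g2$stable)

  g3 <- volume_doubling_time(500, 500, 365)
  expect_identical(g3$vdt_days, Inf)
  expect_true(g3$stable)
  # shrinkage is stable too
  expect_true(volume_doubling_time(500, 400, 100)$stable)

  expect_error(volume_doubling_time(0, 1, 1), "positive")
  expect_error(volume_doubling_time(1, 1, -5), "positive")
})

test_that("VDT is antitone in the follow-up volume", {
  v2 <- seq(501, 1200, by = 50)
  vdt <- vapply(v2, function(v) volume_doubling_time(500, v, 365)$vdt_days, 0)
  expect_false(is.unsorted(rev(vdt)))
})
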