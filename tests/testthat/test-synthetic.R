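test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- phantom_spec("malignant", 6, rng_seed = 42)
  a <- generate_phantom(spec); b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  spec2 <- phantom_spec("malignant", 6, rng_seed = 43)
  expect_false(identical(a$volume$voxels,
                         generate_phantom(spec2)$volume$voxels))
  # cohorts with different master seeds differ voxelwise
  c1 <- generate_cohort(1, 1, master_seed = 1)
  c2 <- generate_cohort(1, 1, master_seed = 2)
  expect_false(identical(c1[[1]]$volume$voxels, c2[[1]]$volume$voxels))
  # and the same master seed reproduces the cohort
  c3 <- generate_cohort(1, 1, master_seed = 1)
  expect_identical(c1[[2]]$volume$voxels, c3[[2]]$volume$voxels)
})

test_that("noiseless background is exactly the background level", {
  spec <- phantom_spec("benign", 5, background_noise_sd = 0, rng_seed = 9)
  truth <- generate_phantom(spec)
  expect_true(all(truth$volume$voxels[!truth$mask] == -800L))
})

test_that("phantom invariants hold: disjoint masks, in-interval nodule HU", {
  for (s in 1:5) {
    truth <- generate_phantom(noduletex:::cohort_spec(s, "malignant", 77))
    expect_false(any(truth$mask & truth$vessel_mask))
    hu <- truth$volume$voxels[truth$mask]
    expect_true(all(hu > -450 & hu < 1500))
    bg <- truth$volume$voxels[!truth$mask & !truth$vessel_mask]
    expect_true(all(bg < -450))
  }
})

test_that("segmentation plus subtraction recovers every ground-truth mask exactly", {
  for (i in 1:8) {
    lb <- if (i %% 2) "benign" else "malignant"
    truth <- generate_phantom(noduletex:::cohort_spec(i, lb, 321))
    seg <- region_grow_3d(truth$volume, round(truth$spec$center))
    seg <- subtract_structures(seg, truth$vessel_mask)
    expect_identical(seg$mask, truth$mask)
  }
})

test_that("sampled phantom moments match the family's analytic moments", {
  # spec'd example: malignant defaults, radius 8 mm, fixed seed
  truth <- generate_phantom(phantom_spec("malignant", 8, rng_seed = 7))
  st <- stats_from_voxels(truth$volume, truth$mask)
  an <- texture_family_moments(truth$spec$texture)
  expect_lt(abs(st$SKW - an[["skew"]]), 0.3)
  expect_lt(abs(st$MEN - an[["mean"]]), 5)

  # large-sample check of the sampler against the closed-form moments
  tex <- default_texture("benign")
  x <- noduletex:::with_seed(123,
    noduletex:::rtexture_unit(2e5, tex$beta, tex$p, tex$mu_t, tex$sigma_t))
  an2 <- noduletex:::mixture_shape_moments(tex$beta, tex$p, tex$mu_t,
                                           tex$sigma_t)
  expect_lt(abs(mean(x) - an2[["mean"]]), 0.02)
  expect_lt(abs(mean((x - mean(x))^2) - an2[["var"]]), 0.05)
  sk <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_lt(abs(sk - an2[["skew"]]), 0.1)
})

test_that("the tail solver hits requested skewness/kurtosis targets", {
  for (tgt in list(c(1.0, 2.0), c(1.73, 3.37), c(2.07, 5.88), c(2.5, 8.0))) {
    for (beta in c(1.15, 5.5)) {
      sol <- noduletex:::solve_tail_params(beta, 0.6, tgt[1], tgt[2])
      expect_true(sol$ok)
      got <- noduletex:::mixture_shape_moments(beta, sol$p, sol$mu_t, 0.6)
      expect_equal(got[["skew"]], tgt[1], tolerance = 1e-3)
      expect_equal(got[["kurtosis"]], tgt[2], tolerance = 1e-3)
    }
  }
})

test_that("spec validation enforces the SPN size bound and lattice fit", {
  expect_error(phantom_spec("benign", 16), "SPN")
  expect_error(phantom_spec("benign", 0), "SPN")
  expect_error(phantom_spec("benign", 14, dims = c(20L, 20L, 20L)),
               "fit inside")
  expect_error(generate_cohort(0, 5, master_seed = 1), ">= 1")
})

test_that("growth pairs encode the requested volume doubling time", {
  spec <- phantom_spec("benign", 6, background_noise_sd = 0, rng_seed = 5,
                       dims = c(48L, 48L, 34L))
  # infinite VDT: identical nodule volumes
  same <- generate_growth_pair(spec, Inf, 365)
  expect_equal(sum(same[[1]]$mask), sum(same[[2]]$mask))
  # vdt = delta_t: the ground-truth volume doubles (up to voxelisation)
  dbl <- generate_growth_pair(spec, 2000, 2000)
  expect_equal(sum(dbl[[2]]$mask) / sum(dbl[[1]]$mask), 2, tolerance = 0.05)
  # full pipeline recovery within 15%
  pair <- generate_growth_pair(spec, 400, 365)
  vols <- vapply(pair, function(t) {
    seg <- region_grow_3d(t$volume, round(t$spec$center))
    nodule_volume(seg)
  }, 0)
  g <- volume_doubling_time(vols[1], vols[2], 365)
  expect_lt(abs(g$vdt_days - 400) / 400, 0.15)
  expect_false(g$stable)
  # growth that no longer fits the lattice is refused
  expect_error(generate_growth_pair(phantom_spec("benign", 10, rng_seed = 1),
                                    100, 365), "exceeds lattice")
})

test_that("small cohorts carry the right labels and structure", {
  co <- generate_cohort(2, 3, master_seed = 6)
  expect_length(co, 5)
  expect_identical(vapply(co, `[[`, "", "label"),
                   c("benign", "benign", rep("malignant", 3)))
  ft <- cohort_feature_table(3, 3, master_seed = 6)
  expect_equal(nrow(ft), 6)
  expect_true(all(c("KUR", "SKW", "shape_label", "volume_mm3") %in%
                  names(ft)))
})
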