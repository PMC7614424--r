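test_that("phantom has brain-like structure with zero background", {
  v <- generate_phantom(1, shape = c(64, 64, 48))
  expect_true(all(v$voxels >= 0))
  expect_true(any(v$voxels > 0))
  expect_gt(mean(v$voxels == 0), 0.30)
  # compartment ordering: cortical shell > white matter > ventricles
  an <- v$anatomy
  expect_gt(an$uptake_cortex, an$uptake_white)
  expect_gt(an$uptake_white, an$uptake_ventricle)
  expect_setequal(unique(as.vector(v$voxels)),
                  c(0, an$uptake_ventricle, an$uptake_white,
                    an$uptake_cortex))
})

test_that("degenerate anatomy with equal uptakes is constant inside head", {
  an <- anatomy_params(uptake_cortex = 2, uptake_white = 2,
                       uptake_ventricle = 2)
  v <- generate_phantom(7, shape = c(32, 32, 32), anatomy = an)
  inside <- v$voxels[v$voxels > 0]
  expect_true(all(inside == 2))
})

test_that("phantom generation is deterministic and validates input", {
  a <- generate_phantom(3, shape = c(32, 32, 32),
                        anatomy = anatomy_params(texture_sd = 0.1))
  b <- generate_phantom(3, shape = c(32, 32, 32),
                        anatomy = anatomy_params(texture_sd = 0.1))
  expect_identical(a$voxels, b$voxels)
  expect_error(generate_phantom(1, shape = c(16, 64, 64)), ">= 32")
  expect_error(anatomy_params(uptake_white = -1), "positive")
})

test_that("count thinning conserves expected totals", {
  v <- generate_phantom(2, shape = c(48, 48, 32))
  # one draw at the full count level: total within 5 SD of 1e6
  tot <- sum(simulate_dose_fraction(v, 1e6, 1.0, seed = 11))
  expect_lt(abs(tot - 1e6), 5 * sqrt(1e6))
  expect_error(simulate_dose_fraction(v, 1e6, 0, seed = 1), "fraction")
  expect_error(simulate_dose_fraction(v, 1e6, 1.5, seed = 1), "fraction")
  zero <- array(0, dim = c(32, 32, 32))
  expect_error(simulate_dose_fraction(zero, 1e6, 0.5, seed = 1), "support")
})

test_that("resolution loss grows as the count fraction falls", {
  expect_gt(dose_fwhm_mm(0.005), dose_fwhm_mm(0.05))
  expect_gt(dose_fwhm_mm(0.05), dose_fwhm_mm(1))
  # the smoothing mechanism: a wider kernel suppresses white noise more
  noise <- array(rnorm(32^3), dim = c(32, 32, 32))
  s_narrow <- petqc:::gaussian_smooth_3d(noise, rep(0.8, 3))
  s_wide <- petqc:::gaussian_smooth_3d(noise, rep(2.0, 3))
  expect_lt(var(as.vector(s_wide)), var(as.vector(s_narrow)))
  expect_lt(var(as.vector(s_narrow)), var(as.vector(noise)))
  # kernel preserves total mass away from the boundary
  blob <- array(0, dim = c(32, 32, 32)); blob[16, 16, 16] <- 100
  expect_equal(sum(petqc:::gaussian_smooth_3d(blob, rep(1.5, 3))), 100,
               tolerance = 1e-8)
})

test_that("normalisation maps to [0, 1] with max exactly 1", {
  const <- array(4, dim = c(2, 2, 2))
  expect_true(all(normalize_volume(const) == 1))
  v <- array(runif(64, 0, 250), dim = c(4, 4, 4))
  v[1] <- 250
  expect_equal(normalize_volume(v), v / 250)
  expect_identical(normalize_volume(normalize_volume(v)),
                   normalize_volume(v))
  expect_error(normalize_volume(array(0, dim = c(2, 2, 2))), "all-zero")
})
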