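test_that("phantom specs reject inconsistent geometry", {
  expect_error(phantom_spec("slab", extent = 100, thickness = 60),
               "4x the largest feature")
  expect_error(phantom_spec("foam", extent = 300, vf = 1.2, corr_length = 30),
               "volume fraction")
  expect_error(phantom_spec("cortical_plate", extent = 900, thickness = 100,
                            pore_radius = 120, n_pores = 2L),
               "pore radius")
  expect_error(phantom_spec("nonsense", extent = 100))
})

test_that("closed-form ground truths match the reference shapes", {
  slab <- make_phantom(phantom_spec("slab", extent = 300, thickness = 60))
  expect_equal(slab$ground_truth$thickness, 60)
  expect_equal(slab$ground_truth$smi, 0)
  tor <- make_phantom(phantom_spec("torus", extent = 1200,
                                   major_radius = 100, minor_radius = 40))
  expect_equal(tor$ground_truth$euler, 0)
  expect_equal(tor$ground_truth$connectivity, 1)
})

test_that("foam quantile calibration hits the target volume fraction", {
  ph <- make_phantom(phantom_spec("foam", extent = 300, seed = 7, vf = 0.35,
                                  corr_length = 26))
  vol <- rasterize_phantom(ph, 2)
  expect_lt(abs(mean(vol$data) - 0.35), 0.02)
})

test_that("rasterized volume fraction converges as voxel size shrinks", {
  ph <- make_phantom(phantom_spec("foam", extent = 300, seed = 5, vf = 0.4,
                                  corr_length = 30))
  errs <- vapply(c(10.4, 4.35, 2), function(h) {
    abs(mean(rasterize_phantom(ph, h)$data) - 0.4)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 1e-12)
})

test_that("noise-free acquisition mixes exactly two grey classes", {
  ph <- make_phantom(phantom_spec("slab", extent = 261, thickness = 60.9))
  acq <- acquisition_spec(4.35, psf_sigma = 0, noise_sd = 0, supersample = 1)
  g <- simulate_acquisition(ph, acq)
  expect_setequal(unique(as.vector(g$data)), c(40, 220))
})

test_that("half-covered boundary voxels take the midpoint grey level", {
  # slab spanning 13 voxel layers plus half a layer on each side
  ph <- make_phantom(phantom_spec("slab", extent = 61 * 4.35,
                                  thickness = 14 * 4.35))
  acq <- acquisition_spec(4.35, psf_sigma = 0, noise_sd = 0, supersample = 4)
  g <- simulate_acquisition(ph, acq)
  # odd grid: slab of even layer count centered on a voxel -> two boundary
  # layers half covered
  col <- g$data[31, 31, ]
  expect_true(any(abs(col - 130) < 1e-9))
  expect_equal(sort(unique(round(col, 6))), c(40, 130, 220))
})

test_that("acquisition is deterministic given the seed", {
  ph <- make_phantom(phantom_spec("foam", extent = 250, seed = 2, vf = 0.3,
                                  corr_length = 30))
  a <- simulate_acquisition(ph, acq_in_vivo(seed = 9))
  b <- simulate_acquisition(ph, acq_in_vivo(seed = 9))
  expect_identical(a$data, b$data)
  c <- simulate_acquisition(ph, acq_in_vivo(seed = 10))
  expect_false(identical(a$data, c$data))
})

test_that("mean grey of a noise-free volume is affine in volume fraction", {
  acq <- acquisition_spec(10.4, psf_sigma = 10.4, noise_sd = 0,
                          supersample = 2)
  fracs <- vapply(c(0.25, 0.45), function(v) {
    ph <- make_phantom(phantom_spec("foam", extent = 300, seed = 4, vf = v,
                                    corr_length = 30))
    mean(simulate_acquisition(ph, acq)$data)
  }, numeric(1))
  # grey = 40 + vf * 180 up to discretization of the covered fraction
  expect_lt(abs(fracs[1] - (40 + 0.25 * 180)), 2)
  expect_lt(abs(fracs[2] - (40 + 0.45 * 180)), 2)
})

test_that("acquisition guards reject invalid requests", {
  ph <- make_phantom(phantom_spec("slab", extent = 261, thickness = 60))
  expect_error(acquisition_spec(4.35, supersample = 0), "supersampling")
  expect_error(acquisition_spec(4.35, noise_sd = -1), "noise")
  expect_error(acquisition_spec(-1), "voxel size")
  expect_error(simulate_acquisition(ph, acq_ex_vivo(), max_voxels = 1000),
               "voxel-count cap")
})

test_that("paired cohorts are reproducible and carry the group contrast", {
  a <- generate_paired_cohort(n_per_group = 2L, seed = 3, keep_volumes = FALSE)
  b <- generate_paired_cohort(n_per_group = 2L, seed = 3, keep_volumes = FALSE)
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 4L)
  expect_setequal(unique(a$manifest$group), c("SHAM", "DMM"))

  eff <- generate_paired_cohort(n_per_group = 4L, seed = 3,
                                group_effects = list(corr_scale = 1.08),
                                keep_volumes = FALSE)
  none <- generate_paired_cohort(n_per_group = 4L, seed = 3,
                                 keep_volumes = FALSE)
  ratio <- mean(eff$manifest$corr_length[eff$manifest$group == "DMM"]) /
    mean(none$manifest$corr_length[none$manifest$group == "DMM"])
  expect_equal(ratio, 1.08, tolerance = 1e-9)
  # without effects the two groups share one generator: group means differ
  # by less than the between-animal SD
  m <- none$manifest
  expect_lt(abs(mean(m$vf[m$group == "SHAM"]) - mean(m$vf[m$group == "DMM"])),
            sd(m$vf) + 1e-12)
})

test_that("a thickness-scale effect shows up in rasterized foam thickness", {
  th <- vapply(c(1, 1.15), function(scale) {
    vols <- vapply(c(3, 11), function(s) {
      f <- rasterize_phantom(make_phantom(phantom_spec(
        "foam", extent = 320, seed = s, vf = 0.35,
        corr_length = 30 * scale)), 4.35)
      local_thickness(f)$mean_um
    }, numeric(1))
    mean(vols)
  }, numeric(1))
  expect_equal(th[2] / th[1], 1.15, tolerance = 0.06)
})
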