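test_that("Gaussian smoothing matches the truncated renormalized kernel", {
  const <- grey_volume(array(7, c(9, 9, 9)), 1)
  expect_equal(gaussian_smooth(const)$data, const$data)

  # unit impulse reproduces the normalized 3^3 kernel of sigma 0.65
  imp <- array(0, c(9, 9, 9))
  imp[5, 5, 5] <- 1
  out <- gaussian_smooth(grey_volume(imp, 1))$data
  w <- outer(outer(exp(-(-1:1)^2 / (2 * 0.65^2)),
                   exp(-(-1:1)^2 / (2 * 0.65^2))),
             exp(-(-1:1)^2 / (2 * 0.65^2)))
  w <- w / sum(w)
  expect_equal(out[4:6, 4:6, 4:6], w, tolerance = 1e-12)
  # total intensity of an interior-supported image is conserved
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("histogram threshold finds the midpoint of the two peaks", {
  # two-delta histogram: modes at grey 50 and 200
  v <- grey_volume(array(rep(c(50, 200), c(3000, 2000)), c(10, 50, 10)), 1)
  thr <- histogram_peak_threshold(v)
  expect_equal(as.numeric(thr), 125, tolerance = diff(range(v$data)) / 256)

  # simulated acquisition with PSF: peaks stay at the pure-class levels
  ph <- make_phantom(phantom_spec("foam", extent = 300, seed = 8, vf = 0.4,
                                  corr_length = 30))
  g <- simulate_acquisition(ph, acquisition_spec(4.35, noise_sd = 0,
                                                 background = 40, bone = 220))
  thr2 <- histogram_peak_threshold(g)
  expect_lt(abs(as.numeric(thr2) - 130), (220 - 40) / 256 + 1e-9)

  # unimodal input is rejected
  uni <- grey_volume(array(rnorm(8000, 100, 10), c(20, 20, 20)), 1)
  expect_error(histogram_peak_threshold(uni), "not bimodal")
})

test_that("threshold is equivariant under affine grey rescaling", {
  ph <- make_phantom(phantom_spec("foam", extent = 300, seed = 12, vf = 0.35,
                                  corr_length = 30))
  g <- simulate_acquisition(ph, acq_ex_vivo(seed = 4))
  thr <- as.numeric(histogram_peak_threshold(g))
  g2 <- grey_volume(3 * g$data + 17, g$spacing, g$origin)
  thr2 <- as.numeric(histogram_peak_threshold(g2))
  expect_equal(thr2, 3 * thr + 17, tolerance = 1e-6)
})

test_that("apply_threshold is the elementwise >= comparison", {
  set.seed(1)
  v <- grey_volume(array(runif(27000, 0, 255), c(30, 30, 30)), 1)
  expect_true(all(apply_threshold(v, -1)$data))
  expect_false(any(apply_threshold(v, 256)$data))
  b <- apply_threshold(v, 128)
  expect_identical(b$data, array(v$data >= 128, dim(v$data)))
})

test_that("6-connectivity separates diagonal contact and respects volume", {
  arr <- array(FALSE, c(10, 10, 10))
  arr[1:3, 1:3, 1:3] <- TRUE
  arr[4:6, 4:6, 4:6] <- TRUE   # touches the first cube only at a corner
  bin <- binary_volume(arr, 1)
  kept <- filter_components(bin, "largest")
  expect_equal(sum(kept$data), 27)

  # 9- vs 10-voxel islands under the strict < 10 rule
  arr2 <- array(FALSE, c(12, 12, 6))
  arr2[1:3, 1:3, 1] <- TRUE          # 9 voxels
  arr2[7:11, 7:8, 1] <- TRUE         # 10 voxels
  d <- despeckle(binary_volume(arr2, 1))
  expect_equal(sum(d$data), 10)
  expect_true(all(d$data[7:11, 7:8, 1]))
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(42)
  for (rep in 1:3) {
    arr <- array(runif(14^3) < 0.25, c(14, 14, 14))
    lab <- array(bonemorph:::label3d_cpp(arr, dim(arr), 6L), dim(arr))
    expect_equal(max(lab), flood_count(arr, 6))
  }
})

test_that("filter_components and despeckle are idempotent", {
  set.seed(7)
  arr <- array(runif(16^3) < 0.3, c(16, 16, 16))
  bin <- binary_volume(arr, 1)
  once <- despeckle(bin)
  twice <- despeckle(once)
  expect_identical(once$data, twice$data)
  empty <- binary_volume(array(FALSE, c(4, 4, 4)), 1)
  expect_warning(filter_components(empty, "largest"), "empty")
  expect_false(any(despeckle(empty)$data))
})

test_that("rigid transforms compose and invert consistently", {
  t <- rigid_transform(c(5, 3, -4), c(20, -15, 8), c(50, 50, 50))
  id <- compose_transforms(t, invert_transform(t))
  expect_equal(id$angles, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("resampling reproduces the input and exact integer shifts", {
  set.seed(3)
  v <- grey_volume(array(runif(20^3, 0, 100), c(20, 20, 20)), 2)
  out <- resample(v, rigid_transform(), background = 0)
  expect_equal(out$data, v$data, tolerance = 1e-6)

  # integer-voxel translation: exact shifted copy in the overlap
  sh <- resample(v, rigid_transform(translation_um = c(2 * 3, 0, 0)),
                 background = NA)
  expect_equal(sh$data[1:17, , ], v$data[4:20, , ], tolerance = 1e-6)
})

test_that("Lanczos beats trilinear on a smooth image under subvoxel shift", {
  n <- 40
  f <- function(x) sin(x / 3) + 0.5 * cos(x / 5)
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  v <- grey_volume(array(f(g$x) * f(g$y + 2) * f(g$z + 4), c(n, n, n)), 1)
  t <- rigid_transform(translation_um = c(0.4, 0.3, -0.45))
  truth <- array(f(g$x + 0.4) * f(g$y + 2 + 0.3) * f(g$z + 4 - 0.45),
                 c(n, n, n))
  core <- 8:32
  lan <- resample(v, t, method = "lanczos")$data
  tri <- resample(v, t, method = "trilinear")$data
  err_l <- max(abs((lan - truth)[core, core, core]))
  err_t <- max(abs((tri - truth)[core, core, core]))
  expect_lt(err_l, err_t)
})

test_that("self-similarity maximizes normalized mutual information", {
  set.seed(5)
  v <- small_foam(seed = 6, extent = 300)
  g <- grey_volume(v$data + 0, v$spacing, v$origin)
  nmi <- bonemorph:::nmi_metric
  self <- nmi(g$data, g$data)
  for (shift in c(2, 5)) {
    mis <- resample(g, rigid_transform(translation_um = c(shift * g$spacing,
                                                          0, 0)),
                    background = NaN)
    expect_gt(self, nmi(mis$data, g$data))
  }
})

test_that("a known rigid transform is recovered by registration", {
  spec <- phantom_spec("composite_epiphysis", extent = 420, seed = 5,
                       vf = 0.35, corr_length = 24, plate_thickness = 100)
  ph <- make_phantom(spec)
  fixed <- simulate_acquisition(ph, acquisition_spec(6, noise_sd = 4,
                                                     seed = 2))
  center <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing / 2
  t_true <- rigid_transform(c(5, 3, -4), c(20, -15, 8), center)
  moving <- resample(fixed, invert_transform(t_true), grid = fixed,
                     background = 40)
  t_est <- rigid_register(moving, fixed)
  expect_lt(max(abs(t_est$angles - t_true$angles)), 0.5)
  expect_lt(max(abs(t_est$translation - t_true$translation)),
            0.5 * fixed$spacing)
})
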