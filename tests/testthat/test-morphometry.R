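test_that("bone volume fraction equals exhaustive voxel counting", {
  set.seed(11)
  arr <- array(runif(20^3) < 0.4, c(20, 20, 20))
  roi <- array(runif(20^3) < 0.7, c(20, 20, 20))
  bin <- binary_volume(arr, 4.35)
  expect_equal(bone_volume_fraction(bin, roi), sum(arr & roi) / sum(roi))
  expect_equal(bone_volume_fraction(binary_volume(roi, 1), roi), 1)
  expect_equal(bone_volume_fraction(binary_volume(roi & FALSE, 1), roi), 0)
  expect_error(bone_volume_fraction(bin, roi & FALSE), "empty ROI")
})

test_that("isosurface area matches closed forms for sphere and slab", {
  sph <- ball_volume(20, spacing = 4.35)
  a <- bone_surface(sph)$area_um2
  expect_lt(abs(a / (4 * pi * 87^2) - 1), 0.03)

  # slab with faces interior to the grid: 2A + perimeter * t (wide enough
  # that smoothing-rounded rim edges are a negligible area fraction)
  slab <- slab_volume(14, nx = 170, spacing = 4.35, pad = 6)
  arr <- slab$data
  arr[c(1:5, 166:170), , ] <- FALSE
  arr[, c(1:5, 166:170), ] <- FALSE
  slab <- binary_volume(arr, 4.35)
  side <- 160 * 4.35
  t <- 14 * 4.35
  expected <- 2 * side^2 + 4 * side * t
  expect_lt(abs(bone_surface(slab)$area_um2 / expected - 1), 0.03)
})

test_that("surface area obeys the quadratic scaling law", {
  a1 <- bone_surface(ball_volume(10, spacing = 4.35))$area_um2
  a2 <- bone_surface(ball_volume(20, spacing = 4.35))$area_um2
  expect_equal(a2 / a1, 4, tolerance = 0.03)
})

test_that("local thickness recovers slab, sphere and cylinder diameters", {
  slab <- slab_volume(14, spacing = 4.35)
  expect_lt(abs(local_thickness(slab)$mean_um - 14 * 4.35), 4.35 / 2)

  sph <- ball_volume(20, spacing = 4.35)
  lt <- local_thickness(sph)
  expect_lt(abs(lt$mean_um - 174), 4.35 / 2)
  # every bone voxel within one voxel of the diameter
  vals <- lt$map[sph$data]
  expect_lt(max(abs(vals - 174)), 2 * 4.35)

  n <- 53
  g <- expand.grid(x = 1:n, y = 1:n)
  disc <- (g$x - 27)^2 + (g$y - 27)^2 <= 12^2
  cyl <- binary_volume(array(rep(disc, 40), c(n, n, 40)), 4.35)
  core <- local_thickness(cyl)$map[, , 10:30]
  mask <- array(rep(disc, 21), c(n, n, 21))
  expect_lt(abs(mean(core[mask]) - 104.4), 4.35 / 2)
})

test_that("separation is the thickness of the complement phase", {
  stack <- rasterize_phantom(make_phantom(phantom_spec(
    "plate_stack", extent = 600, thickness = 43.5, gap = 87)), 4.35)
  roi <- array(TRUE, dim(stack$data))
  expect_lt(abs(separation(stack, roi) - 87), 4.35)

  # complement symmetry by construction
  set.seed(2)
  f <- small_foam(seed = 9, extent = 300)
  roi <- array(TRUE, dim(f$data))
  comp <- binary_volume(roi & !f$data, f$spacing)
  expect_equal(separation(f, roi), local_thickness(comp)$mean_um)

  # empty bone: the separation map peaks at the largest inscribed sphere
  # of the ROI (a box's inscribed diameter is its smallest side)
  box <- array(FALSE, c(40, 40, 40))
  box[3:34, 5:28, 2:39] <- TRUE
  lt <- local_thickness(binary_volume(box, 4.35))
  expect_lt(abs(max(lt$map) - 24 * 4.35), 4.35 + 1e-9)
})

test_that("trabecular number follows the BV/TV over Tb.Th convention", {
  expect_equal(round(trabecular_number(0.333, 69), 1), 4.8)
  expect_equal(round(trabecular_number(0.362, 66.2), 1), 5.5)
  expect_equal(trabecular_number(0, 50), 0)
  expect_error(trabecular_number(0.3, 0), "positive")
})

test_that("fabric anisotropy separates isotropic, stretched and layered", {
  iso <- small_foam(seed = 3, extent = 400, corr_length = 30)
  da_iso <- degree_of_anisotropy(iso)
  expect_gte(da_iso$da, 1)
  expect_lte(da_iso$da, 1.15)

  sph <- ball_volume(18, spacing = 4.35, pad = 8)
  da_sph <- degree_of_anisotropy(binary_volume(sph$data, 4.35))
  expect_lte(da_sph$da, 1.1)

  stack <- rasterize_phantom(make_phantom(phantom_spec(
    "plate_stack", extent = 600, thickness = 40, gap = 80)), 4.35)
  da_pl <- degree_of_anisotropy(stack)
  expect_gt(da_pl$da, 2)
  # principal (longest-intercept) axes lie in-plane; the shortest-intercept
  # axis aligns with the plate normal within 5 degrees
  normal <- da_pl$axes[, 3]
  angle <- acos(min(1, abs(normal[3]))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("structure model index classifies plate, rod and sphere", {
  slab <- slab_volume(14, nx = 60, spacing = 4.35)
  expect_lt(abs(structure_model_index(slab) - 0), 0.3)

  n <- 53
  g <- expand.grid(x = 1:n, y = 1:n)
  disc <- (g$x - 27)^2 + (g$y - 27)^2 <= 12^2
  cyl <- binary_volume(array(rep(disc, 60), c(n, n, 60)), 4.35)
  expect_lt(abs(structure_model_index(cyl) - 3), 0.3)

  sph <- ball_volume(20, spacing = 4.35)
  expect_lt(abs(structure_model_index(sph) - 4), 0.4)
})

test_that("topology: ball, torus and lattice connectivity are exact", {
  sph <- ball_volume(12, spacing = 10)
  cd <- connectivity_density(sph)
  expect_equal(cd$euler, 1)
  expect_equal(cd$connectivity, 0)
  expect_equal(cd$conn_d, 0)

  tor <- rasterize_phantom(make_phantom(phantom_spec(
    "torus", extent = 1128, major_radius = 100, minor_radius = 40)), 8)
  cdt <- connectivity_density(tor)
  expect_equal(cdt$euler, 0)
  expect_equal(cdt$connectivity, 1)
  # solid torus inside a 1 mm^3 ROI has Conn.D of 1 per mm^3
  roi1mm <- array(FALSE, dim(tor$data))
  ctr <- dim(tor$data) %/% 2
  half <- round(500 / 8)
  roi1mm[(ctr[1] - half):(ctr[1] + half - 1),
         (ctr[2] - half):(ctr[2] + half - 1),
         (ctr[3] - half):(ctr[3] + half - 1)] <- TRUE
  cd1 <- connectivity_density(binary_volume(
    tor$data & roi1mm, tor$spacing), roi1mm)
  expect_equal(cd1$connectivity / (sum(roi1mm) * (8 / 1000)^3),
               cd1$conn_d)

  lat <- rasterize_phantom(make_phantom(phantom_spec(
    "rod_lattice", extent = 800, diameter = 40, spacing = 150,
    n_x = 4, n_y = 4)), 4.35)
  expect_equal(connectivity_density(lat)$connectivity, 9)
})

test_that("purification fills cavities before the Euler count", {
  hollow <- ball_mask(10, pad = 3)
  hollow[10:16, 10:16, 10:16] <- FALSE  # internal cavity
  cd <- connectivity_density(binary_volume(hollow, 5))
  expect_equal(cd$euler, 1)
  expect_equal(cd$connectivity, 0)
})

test_that("thickness is translation invariant and scale equivariant", {
  base <- slab_volume(10, nx = 30, spacing = 4.35, pad = 5)
  shifted <- binary_volume(base$data[, , c(3:20, 1:2)], 4.35)
  expect_equal(local_thickness(base)$mean_um,
               local_thickness(shifted)$mean_um, tolerance = 1e-9)
  # doubling the voxel size doubles reported thickness of the same grid
  expect_equal(local_thickness(binary_volume(base$data, 8.7))$mean_um,
               2 * local_thickness(base)$mean_um, tolerance = 1e-9)
})

test_that("cortical thickness measures a uniform plate and closes pores", {
  plate <- slab_volume(16, nx = 60, spacing = 10, pad = 8)
  roi <- array(TRUE, dim(plate$data))
  expect_lt(abs(cortical_thickness(plate, roi) - 160), 10 / 2)

  # plate with sub-kernel pores matches the pore-free value within 2%
  pored <- plate$data
  g <- expand.grid(x = 1:60, y = 1:60)
  for (ctr in list(c(15, 15), c(40, 30), c(25, 48))) {
    hole <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 <= 6^2
    for (s in which(apply(pored, 3, any))) pored[, , s][hole] <- FALSE
  }
  ct_pored <- cortical_thickness(binary_volume(pored, 10), roi)
  expect_lt(abs(ct_pored / cortical_thickness(plate, roi) - 1), 0.02)

  # in-plane translation invariance on a uniform plate
  roi2 <- array(FALSE, dim(plate$data))
  roi2[10:40, 10:40, ] <- TRUE
  roi3 <- array(FALSE, dim(plate$data))
  roi3[20:50, 15:45, ] <- TRUE
  expect_equal(cortical_thickness(plate, roi2),
               cortical_thickness(plate, roi3), tolerance = 1e-9)
})

test_that("measure_all populates every parameter with medial/lateral additivity", {
  spec <- animal_phantom_spec(77, extent = 850)
  ph <- make_phantom(spec)
  vol <- simulate_acquisition(ph, acq_in_vivo(seed = 78))
  bin <- segment_volume(vol)
  rois <- bonemorph:::animal_rois(vol, spec)
  rois <- split_medial_lateral(rois)
  res <- measure_all(bin, rois, specimen = "a77", modality = "in_vivo",
                     n_directions = 128L)
  pars <- c("BV/TV", "BS/BV", "Tb.Th", "Tb.Sp", "Tb.N", "DA", "SMI", "Conn.D")
  whole <- res[res$roi == "trabecular-whole", ]
  expect_setequal(whole$parameter, pars)
  expect_true(all(is.finite(whole$value)))
  expect_true(any(res$parameter == "Ct.Th.Med") &&
                any(res$parameter == "Ct.Th.Lat"))

  # bone-count additivity: whole BV equals medial BV + lateral BV
  get_bv <- function(lab) {
    roi <- roi_select(rois, lab)
    bvtv <- res$value[res$roi == lab & res$parameter == "BV/TV"] / 100
    bvtv * sum(roi)
  }
  expect_equal(get_bv("trabecular-whole"),
               get_bv("trabecular-medial") + get_bv("trabecular-lateral"),
               tolerance = 1e-9)

  # invariants of the result record
  expect_true(all(res$value[res$parameter == "BV/TV"] >= 0 &
                    res$value[res$parameter == "BV/TV"] <= 100))
  expect_true(all(res$value[res$parameter == "DA"] >= 1))
  expect_true(all(res$value[res$parameter %in%
                              c("Tb.Th", "Tb.Sp", "Ct.Th.Med",
                                "Ct.Th.Lat")] > 0))
})
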