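#' Acquisition specification
#'
#' Describes one simulated microCT acquisition: grid resolution, point-spread
#' blur, noise and grey calibration. The two modality presets reproduce the
#' study conditions: 4.35 um voxels for the high-resolution ex vivo scan and
#' 10.4 um voxels for the in vivo scan, with the in vivo point-spread and
#' noise set worse than ex vivo (PSF sigma 1.0 vs 0.6 voxel, noise 10% vs 5%
#' of the bone-background contrast).
#'
#' @param voxel_size Voxel size in um (> 0).
#' @param psf_sigma Gaussian point-spread standard deviation in um (>= 0).
#' @param noise_sd Additive Gaussian noise standard deviation in grey units
#'   (>= 0).
#' @param background,bone Grey levels of the two pure classes
#'   (`bone > background`).
#' @param supersample Integer >= 1; each voxel's bone fraction is averaged
#'   over a `supersample`^3 subgrid of the implicit solid.
#' @param seed Integer seed for the noise.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(voxel_size, psf_sigma = 0.6 * voxel_size,
                             noise_sd = 9, background = 40, bone = 220,
                             supersample = 2L, seed = 1L) {
  if (voxel_size <= 0) stop("voxel size must be positive")
  if (bone <= background) stop("bone grey must exceed background grey")
  if (noise_sd < 0) stop("noise SD must be non-negative")
  if (supersample < 1) stop("supersampling factor must be >= 1")
  structure(list(voxel_size = voxel_size, psf_sigma = psf_sigma,
                 noise_sd = noise_sd, background = background, bone = bone,
                 supersample = as.integer(supersample), seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @export
acq_ex_vivo <- function(seed = 1L) {
  acquisition_spec(4.35, psf_sigma = 0.6 * 4.35, noise_sd = 0.05 * 180,
                   supersample = 2L, seed = seed)
}

#' @rdname acquisition_spec
#' @export
acq_in_vivo <- function(seed = 1L) {
  acquisition_spec(10.4, psf_sigma = 1.0 * 10.4, noise_sd = 0.10 * 180,
                   supersample = 2L, seed = seed)
}

#' Simulate a microCT acquisition of a phantom
#'
#' Per-voxel bone fraction is obtained by supersampling the continuous solid;
#' grey values are `background + fraction * (bone - background)`, blurred by
#' the Gaussian point-spread function and corrupted by seeded additive
#' Gaussian noise. Sampling the same phantom at two voxel sizes yields
#' spatially aligned volumes because both grids are anchored at the phantom
#' domain origin.
#'
#' @param phantom A [make_phantom()] result.
#' @param acq An [acquisition_spec()].
#' @param max_voxels Guard against accidental huge grids.
#' @return A [grey_volume()].
#' @export
simulate_acquisition <- function(phantom, acq, max_voxels = 4e8) {
  dom <- phantom$domain
  h <- acq$voxel_size
  dims <- pmax(1L, as.integer(floor((dom$max - dom$min) / h)))
  if (prod(dims) > max_voxels)
    stop("requested grid exceeds the voxel-count cap (", max_voxels, ")")
  origin <- dom$min + h / 2
  ss <- acq$supersample

  if (!is.null(phantom$raster)) {
    frac <- array(phantom$raster(dims, origin, h, ss), dims)
  } else {
    offs <- ((seq_len(ss) - 0.5) / ss - 0.5) * h
    frac <- array(0, dims)
    xs <- origin[1] + (seq_len(dims[1]) - 1) * h
    ys <- origin[2] + (seq_len(dims[2]) - 1) * h
    zs <- origin[3] + (seq_len(dims[3]) - 1) * h
    base <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    for (oz in offs) for (oy in offs) for (ox in offs) {
      p <- base
      p[, 1] <- p[, 1] + ox; p[, 2] <- p[, 2] + oy; p[, 3] <- p[, 3] + oz
      frac <- frac + phantom$membership(p)
    }
    frac <- frac / ss^3
  }

  grey <- acq$background + frac * (acq$bone - acq$background)
  if (acq$psf_sigma > 0)
    grey <- gauss3d(grey, acq$psf_sigma / h)
  if (acq$noise_sd > 0)
    grey <- grey + array(with_seed(acq$seed, rnorm(prod(dims), 0, acq$noise_sd)),
                         dims)
  grey_volume(grey, h, origin)
}

#' Default phantom geometry of one synthetic animal
#'
#' The subchondral compartment is emulated by a composite phantom: an 850 um
#' cubic domain holding trabecular foam (target BV/TV 0.35, correlation
#' length 33 um) capped by a 160 um cortical plate under a 60 um air gap.
#' Between-animal biological variation perturbs the volume fraction, strut
#' scale and plate thickness.
#'
#' @param seed Per-animal integer seed.
#' @param effects Optional named list perturbing the generating parameters
#'   (`vf_scale`, `corr_scale`, `stretch`, `plate_scale`), used to give one
#'   group a DMM-like microstructural contrast.
#' @param extent Domain edge length in um.
#' @return A `phantom_spec`.
#' @export
animal_phantom_spec <- function(seed, effects = NULL, extent = 850) {
  jit <- with_seed(seed, rnorm(3, 0, c(0.03, 2.5, 10)))
  vf <- min(0.6, max(0.15, 0.35 + jit[1]))
  cl <- max(18, 33 + jit[2])
  pt <- min(200, max(100, 160 + jit[3]))
  stretch <- c(1, 1, 1)
  if (!is.null(effects)) {
    vf <- vf * (effects$vf_scale %||% 1)
    cl <- cl * (effects$corr_scale %||% 1)
    pt <- pt * (effects$plate_scale %||% 1)
    stretch <- stretch * (effects$stretch %||% c(1, 1, 1))
  }
  phantom_spec("composite_epiphysis", extent = extent, seed = seed,
               vf = vf, corr_length = cl, plate_thickness = pt,
               stretch = stretch)
}

#' Programmatic ROIs for a composite-epiphysis phantom
#'
#' Builds the analysis regions on a given grid: a trabecular box inset from
#' the lateral faces and below the plate, and two 500 um cortical boxes
#' centered on the "condyles" at fixed world positions (identical across
#' registered specimens).
#'
#' @param vol A volume supplying the target grid.
#' @param spec The `phantom_spec` of the composite phantom.
#' @param margin Inset of the trabecular box from the domain faces (um).
#' @param box_side Cortical box side (um).
#' @return An [roi_mask()] with `trabecular-whole`, `cortical-medial` and
#'   `cortical-lateral`.
#' @export
animal_rois <- function(vol, spec, margin = 100, box_side = 500) {
  dom <- spec$domain
  ctr <- (dom$min + dom$max) / 2
  ext <- dom$max - dom$min
  slope <- spec$plate_slope %||% c(0.25, 0.08)
  tilt_span <- (abs(slope[1]) * ext[1] + abs(slope[2]) * ext[2]) / 2
  plate_hi <- dom$max[3] - (spec$air_gap %||% 60) - tilt_span
  plate_lo <- plate_hi - spec$plate_thickness
  foam_top <- plate_lo - tilt_span - 10
  trab <- box_mask(vol, lo = dom$min + margin,
                   hi = c(dom$max[1] - margin, dom$max[2] - margin,
                          foam_top - margin / 2))
  ctr_y <- ctr[2]
  qx <- dom$min[1] + ext[1] * c(0.32, 0.68)
  # per-box z-window bracketing the tilted plate over the box footprint
  box_z <- function(cx, cy) {
    w <- outer(slope[1] * (cx + c(-1, 1) * box_side / 2 - ctr[1]),
               slope[2] * (cy + c(-1, 1) * box_side / 2 - ctr[2]), "+")
    c(plate_lo + min(w), plate_hi + max(w))
  }
  med <- cortical_box_roi(vol, center = c(qx[1], ctr_y), side = box_side,
                          z_range = box_z(qx[1], ctr_y),
                          label = "cortical-medial")
  lat <- cortical_box_roi(vol, center = c(qx[2], ctr_y), side = box_side,
                          z_range = box_z(qx[2], ctr_y),
                          label = "cortical-lateral")
  roi_mask(c(list(`trabecular-whole` = trab), med$masks, lat$masks),
           vol$spacing, vol$origin)
}

box_mask <- function(vol, lo, hi) {
  d <- dim(vol$data)
  xin <- axis_coords(vol, 1) >= lo[1] & axis_coords(vol, 1) <= hi[1]
  yin <- axis_coords(vol, 2) >= lo[2] & axis_coords(vol, 2) <= hi[2]
  zin <- axis_coords(vol, 3) >= lo[3] & axis_coords(vol, 3) <= hi[3]
  array(outer(outer(xin, yin, "&"), zin, "&"), d)
}

#' Generate a paired dual-resolution cohort
#'
#' For each synthetic animal: one random composite phantom (per-animal
#' geometry), one ex vivo and one in vivo grey volume of the same phantom,
#' programmatic ROI masks on each grid, and the generating ground truth.
#' `group_effects` perturbs the generating parameters of group 2 to emulate a
#' DMM-like contrast; with `NULL` both groups share the same generator.
#'
#' @param n_per_group Animals per group (>= 2); groups are labeled SHAM and
#'   DMM.
#' @param group_effects Optional effects list passed to
#'   [animal_phantom_spec()] for the DMM group.
#' @param seed Cohort seed; all per-animal seeds derive from it.
#' @param extent Domain edge length (um).
#' @param keep_volumes Simulate and keep the grey volumes (`TRUE`, default);
#'   with `FALSE` only specs, ROI masks and ground truth are produced (the
#'   acquisition step is skipped), which is fast and sufficient for
#'   manifest-level work.
#' @return A list with `specimens` (list of per-animal records) and
#'   `manifest` (data frame).
#' @export
generate_paired_cohort <- function(n_per_group = 8L, group_effects = NULL,
                                   seed = 1L, extent = 850,
                                   keep_volumes = TRUE) {
  if (n_per_group < 2) stop("need at least 2 animals per group")
  n <- 2L * n_per_group
  animal_seeds <- with_seed(seed, sample.int(1e6, n))
  specimens <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    group <- if (i <= n_per_group) "SHAM" else "DMM"
    eff <- if (group == "DMM") group_effects else NULL
    spec <- animal_phantom_spec(animal_seeds[i], effects = eff,
                                extent = extent)
    ph <- make_phantom(spec)
    if (keep_volumes) {
      ex <- simulate_acquisition(ph, acq_ex_vivo(seed = animal_seeds[i] + 1L))
      iv <- simulate_acquisition(ph, acq_in_vivo(seed = animal_seeds[i] + 2L))
    } else {
      grid_only <- function(h) {
        dims <- pmax(1L, as.integer(floor((spec$domain$max -
                                             spec$domain$min) / h)))
        grey_volume(array(0, dims), h, spec$domain$min + h / 2)
      }
      ex <- grid_only(4.35)
      iv <- grid_only(10.4)
    }
    specimens[[i]] <- list(
      id = sprintf("%s%02d", tolower(group), ((i - 1) %% n_per_group) + 1),
      group = group, seed = animal_seeds[i], spec = spec,
      ground_truth = ph$ground_truth,
      ex_vivo = if (keep_volumes) ex else NULL,
      in_vivo = if (keep_volumes) iv else NULL,
      rois_ex = animal_rois(ex, spec), rois_in = animal_rois(iv, spec))
    rows[[i]] <- data.frame(
      id = specimens[[i]]$id, group = group, seed = animal_seeds[i],
      vf = spec$vf, corr_length = spec$corr_length,
      plate_thickness = spec$plate_thickness,
      stretch_z = spec$stretch[3], stringsAsFactors = FALSE)
  }
  list(specimens = specimens, manifest = do.call(rbind, rows))
}
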