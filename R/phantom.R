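#' Specify an implicit-geometry bone phantom
#'
#' Phantoms are continuous solids defined by a point-membership function over
#' world coordinates (um), so they can be sampled onto any acquisition grid
#' without resampling artifacts. Available kinds:
#'
#' * `"slab"`: plate of given `thickness` normal to z, spanning the domain
#'   laterally, centered at mid-depth.
#' * `"cylinder"`: solid cylinder of `diameter` along z, spanning the domain.
#' * `"sphere"`: solid ball of `diameter` at the domain center.
#' * `"torus"`: solid torus (`major_radius`, `minor_radius`) in the central
#'   xy-plane.
#' * `"plate_stack"`: parallel plates of `thickness` separated by `gap`,
#'   normal to z.
#' * `"rod_lattice"`: planar grid of rods (`diameter`, `spacing`,
#'   `n_x` x `n_y` rods) in the central z-plane; its first Betti number is
#'   `(n_x - 1) * (n_y - 1)`.
#' * `"foam"`: trabecular-like random solid, a stationary Gaussian random
#'   field thresholded at the quantile matching `vf`; `corr_length` (um) sets
#'   the strut scale, `stretch` (length-3) elongates the microstructure per
#'   axis to create anisotropy.
#' * `"cortical_plate"`: plate of `thickness` normal to z with `n_pores`
#'   random transverse cylindrical pores of radius `pore_radius`.
#' * `"composite_epiphysis"`: foam below a solid cortical plate of
#'   `plate_thickness` at the top of the domain, emulating subchondral
#'   trabecular bone under its cortical plate.
#'
#' @param kind Phantom kind, see Details.
#' @param extent Cubic domain edge length (um) used when `domain` is not
#'   given.
#' @param domain List with `min` and `max` (length-3, um) bounding the solid.
#' @param seed Integer seed for random phantoms.
#' @param ... Kind-specific geometric parameters (um), see Details.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind, extent = 500, domain = NULL, seed = 1L, ...) {
  kinds <- c("slab", "cylinder", "sphere", "torus", "plate_stack",
             "rod_lattice", "foam", "cortical_plate", "composite_epiphysis")
  kind <- match.arg(kind, kinds)
  if (is.null(domain))
    domain <- list(min = c(0, 0, 0), max = rep(extent, 3))
  p <- list(...)
  spec <- structure(c(list(kind = kind, domain = domain, seed = as.integer(seed)), p),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ext <- spec$domain$max - spec$domain$min
  if (any(ext <= 0)) stop("phantom domain must have positive extent")
  lens <- unlist(spec[names(spec) %in%
    c("thickness", "diameter", "major_radius", "minor_radius", "gap",
      "spacing", "corr_length", "pore_radius", "plate_thickness")])
  if (any(lens <= 0)) stop("all phantom lengths must be positive")
  feature <- switch(spec$kind,
    slab = spec$thickness,
    cylinder = spec$diameter,
    sphere = spec$diameter,
    torus = 2 * (spec$major_radius + spec$minor_radius),
    plate_stack = spec$thickness + spec$gap,
    rod_lattice = spec$spacing,
    foam = spec$corr_length,
    cortical_plate = spec$thickness,
    composite_epiphysis = spec$plate_thickness)
  if (!is.null(feature) && min(ext) < 4 * feature)
    stop("phantom domain must be at least 4x the largest feature size")
  if (spec$kind %in% c("foam", "composite_epiphysis")) {
    if (is.null(spec$vf) || spec$vf <= 0 || spec$vf >= 1)
      stop("foam target volume fraction must lie in (0, 1)")
    if (min(ext) < 4 * spec$corr_length)
      stop("foam domain must be at least 4 correlation lengths wide")
  }
  if (spec$kind == "cortical_plate" && !is.null(spec$pore_radius) &&
      spec$pore_radius >= spec$thickness)
    stop("pore radius must be smaller than the plate thickness")
  invisible(spec)
}

# spectral representation of a squared-exponential Gaussian field: the exact
# spectral measure is k ~ N(0, I / corr_length^2). To keep the finite
# expansion statistically isotropic at modest K, frequency directions are a
# quasi-uniform Fibonacci lattice (randomly rotated in assignment) and the
# magnitudes are stratified chi(3 df) quantiles with random within-stratum
# jitter; phases are uniform. Axis stretches divide the corresponding
# frequency component, elongating the microstructure along that axis.
foam_field <- function(corr_length, stretch = c(1, 1, 1), seed, n_terms = 64L) {
  with_seed(seed, {
    dirs <- fibonacci_directions(n_terms)
    flip <- sample(c(-1, 1), n_terms, replace = TRUE)
    dirs <- dirs * flip
    jit <- runif(n_terms)
    mags <- sqrt(stats::qchisq((sample(n_terms) - jit) / n_terms, df = 3)) /
      corr_length
    freqs <- dirs * mags
    freqs <- sweep(freqs, 2, stretch, "/")
    phases <- runif(n_terms, 0, 2 * pi)
  })
  list(freqs = freqs, phases = phases)
}

# empirical level-set threshold so the covered fraction matches the target
foam_threshold <- function(field, domain, vf, seed, n_sample = 200000L) {
  pts <- with_seed(seed + 1L, {
    matrix(runif(3 * n_sample), ncol = 3)
  })
  pts <- sweep(sweep(pts, 2, domain$max - domain$min, "*"), 2, domain$min, "+")
  vals <- grf_points_cpp(pts, field$freqs, field$phases)
  unname(quantile(vals, 1 - vf, names = FALSE))
}

#' Build a phantom from its specification
#'
#' Returns the continuous solid as a point-membership function together with
#' its ground-truth morphometry (closed forms where they exist). Random
#' phantoms are deterministic given the seed in the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` object with elements `membership` (function taking an
#'   n x 3 matrix of world points in um, returning logical), `ground_truth`
#'   (named list), `domain`, `spec`, and for foam-based phantoms a fast
#'   rasterization path used by [simulate_acquisition()].
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dom <- spec$domain
  ctr <- (dom$min + dom$max) / 2
  ext <- dom$max - dom$min
  gt <- list()
  raster <- NULL

  membership <- switch(spec$kind,
    slab = {
      t2 <- spec$thickness / 2
      gt <- list(thickness = spec$thickness, smi = 0,
                 volume = prod(ext[1:2]) * spec$thickness)
      function(p) abs(p[, 3] - ctr[3]) <= t2
    },
    cylinder = {
      r <- spec$diameter / 2
      gt <- list(thickness = spec$diameter, smi = 3)
      function(p) (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 <= r^2
    },
    sphere = {
      r <- spec$diameter / 2
      gt <- list(thickness = spec$diameter, smi = 4, surface = 4 * pi * r^2,
                 volume = 4 / 3 * pi * r^3, euler = 1, connectivity = 0)
      function(p) {
        (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2 <= r^2
      }
    },
    torus = {
      R <- spec$major_radius; r <- spec$minor_radius
      gt <- list(euler = 0, connectivity = 1, surface = 4 * pi^2 * R * r,
                 volume = 2 * pi^2 * R * r^2, thickness = 2 * r)
      function(p) {
        q <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) - R
        q^2 + (p[, 3] - ctr[3])^2 <= r^2
      }
    },
    plate_stack = {
      period <- spec$thickness + spec$gap
      t2 <- spec$thickness / 2
      gt <- list(thickness = spec$thickness, separation = spec$gap,
                 vf = spec$thickness / period, axis = c(0, 0, 1))
      function(p) {
        z <- (p[, 3] - dom$min[3]) %% period
        z <= t2 | z >= period - t2
      }
    },
    rod_lattice = {
      r <- spec$diameter / 2
      nxr <- spec$n_x; nyr <- spec$n_y
      x0 <- ctr[1] - (nxr - 1) * spec$spacing / 2
      y0 <- ctr[2] - (nyr - 1) * spec$spacing / 2
      xs <- x0 + (seq_len(nxr) - 1) * spec$spacing
      ys <- y0 + (seq_len(nyr) - 1) * spec$spacing
      gt <- list(connectivity = (nxr - 1) * (nyr - 1), thickness = spec$diameter)
      function(p) {
        inside <- rep(FALSE, nrow(p))
        zd2 <- (p[, 3] - ctr[3])^2
        xin <- p[, 1] >= xs[1] - r & p[, 1] <= xs[nxr] + r
        yin <- p[, 2] >= ys[1] - r & p[, 2] <= ys[nyr] + r
        for (x in xs) # rods along y
          inside <- inside | ((p[, 1] - x)^2 + zd2 <= r^2 & yin)
        for (y in ys) # rods along x
          inside <- inside | ((p[, 2] - y)^2 + zd2 <= r^2 & xin)
        inside
      }
    },
    foam = {
      field <- foam_field(spec$corr_length, spec$stretch %||% c(1, 1, 1),
                          spec$seed, spec$n_terms %||% 64L)
      tau <- foam_threshold(field, dom, spec$vf, spec$seed)
      gt <- list(vf = spec$vf, corr_length = spec$corr_length,
                 stretch = spec$stretch %||% c(1, 1, 1))
      raster <- function(dims, origin, spacing, supersample) {
        grf_fraction_cpp(as.integer(dims), origin, spacing,
                         as.integer(supersample), field$freqs, field$phases,
                         tau, -Inf, Inf)
      }
      local({
        f <- field; tt <- tau
        function(p) grf_points_cpp(p, f$freqs, f$phases) > tt
      })
    },
    cortical_plate = {
      t2 <- spec$thickness / 2
      npores <- spec$n_pores %||% 0L
      pores <- if (npores > 0) {
        with_seed(spec$seed, {
          cbind(runif(npores, dom$min[1] + spec$pore_radius,
                      dom$max[1] - spec$pore_radius),
                runif(npores, dom$min[2] + spec$pore_radius,
                      dom$max[2] - spec$pore_radius))
        })
      } else matrix(numeric(0), ncol = 2)
      gt <- list(thickness = spec$thickness)
      function(p) {
        inside <- abs(p[, 3] - ctr[3]) <= t2
        if (nrow(pores) > 0) {
          for (q in seq_len(nrow(pores))) {
            inside <- inside &
              ((p[, 1] - pores[q, 1])^2 + (p[, 2] - pores[q, 2])^2 >
                 spec$pore_radius^2)
          }
        }
        inside
      }
    },
    composite_epiphysis = {
      air_gap <- spec$air_gap %||% 60
      # the plate is tilted like a condyle surface: constant thickness
      # measured along z, boundaries z = plate_lo/hi + s . (xy - center).
      # The tilt sweeps the boundary through every subvoxel phase, removing
      # the degenerate grid alignment of a perfectly flat plate.
      slope <- spec$plate_slope %||% c(0.25, 0.08)
      tilt <- function(x, y) slope[1] * (x - ctr[1]) + slope[2] * (y - ctr[2])
      tilt_span <- (abs(slope[1]) * ext[1] + abs(slope[2]) * ext[2]) / 2
      plate_hi <- dom$max[3] - air_gap - tilt_span
      plate_lo <- plate_hi - spec$plate_thickness
      foam_top <- plate_lo - tilt_span - 10
      if (foam_top - dom$min[3] < 4 * spec$corr_length)
        stop("composite domain too shallow for foam below the tilted plate")
      field <- foam_field(spec$corr_length, spec$stretch %||% c(1, 1, 1),
                          spec$seed, spec$n_terms %||% 64L)
      foam_dom <- list(min = dom$min, max = c(dom$max[1], dom$max[2], foam_top))
      tau <- foam_threshold(field, foam_dom, spec$vf, spec$seed)
      gt <- list(vf = spec$vf, corr_length = spec$corr_length,
                 stretch = spec$stretch %||% c(1, 1, 1),
                 plate_thickness = spec$plate_thickness,
                 plate_zlo = plate_lo, plate_zhi = plate_hi,
                 plate_slope = slope, foam_top = foam_top)
      raster <- function(dims, origin, spacing, supersample) {
        fr <- grf_fraction_cpp(as.integer(dims), origin, spacing,
                               as.integer(supersample), field$freqs,
                               field$phases, tau, -Inf, foam_top)
        # plate fraction: same subsample offsets, z-interval test against
        # the tilted plate boundaries
        offs <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * spacing
        xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing
        ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing
        zc <- origin[3] + (seq_len(dims[3]) - 1) * spacing
        pf <- array(0, dims)
        kaff <- which(zc + spacing / 2 >= plate_lo - tilt_span &
                        zc - spacing / 2 <= plate_hi + tilt_span)
        inv <- 1 / supersample^3
        for (ox in offs) for (oy in offs) {
          w <- outer(xs + ox, ys + oy, tilt)
          for (oz in offs) for (k in kaff) {
            z <- zc[k] + oz
            pf[, , k] <- pf[, , k] + inv * ((z >= plate_lo + w) &
                                              (z <= plate_hi + w))
          }
        }
        pmin(1, fr + as.vector(pf))
      }
      local({
        f <- field; tt <- tau
        function(p) {
          w <- tilt(p[, 1], p[, 2])
          (p[, 3] >= plate_lo + w & p[, 3] <= plate_hi + w) |
            (p[, 3] < foam_top & grf_points_cpp(p, f$freqs, f$phases) > tt)
        }
      })
    })

  structure(list(kind = spec$kind, spec = spec, domain = dom,
                 membership = membership, ground_truth = gt, raster = raster),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind '%s', domain [%g, %g] x [%g, %g] x [%g, %g] um\n",
              x$kind, x$domain$min[1], x$domain$max[1], x$domain$min[2],
              x$domain$max[2], x$domain$min[3], x$domain$max[3]))
  if (length(x$ground_truth)) {
    gt <- vapply(x$ground_truth, function(v) paste(signif(unlist(v), 4),
                                                   collapse = ","), "")
    cat("  ground truth:", paste(names(gt), gt, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Rasterize a phantom to a binary reference volume
#'
#' Samples the continuous solid at voxel centers of a grid covering its
#' domain. A 2 um rasterization is the package's gold-standard oracle for
#' morphometric quantities without closed forms.
#'
#' @param phantom A [make_phantom()] result.
#' @param spacing Voxel size in um.
#' @return A [binary_volume()].
#' @export
rasterize_phantom <- function(phantom, spacing = 2) {
  dom <- phantom$domain
  dims <- pmax(1L, floor((dom$max - dom$min) / spacing))
  origin <- dom$min + spacing / 2
  if (!is.null(phantom$raster)) {
    fr <- phantom$raster(dims, origin, spacing, 1L)
    arr <- array(fr >= 0.5, dims)
  } else {
    # evaluate slab-by-slab to bound memory on large grids
    arr <- array(FALSE, dims)
    xy <- as.matrix(expand.grid(
      x = origin[1] + (seq_len(dims[1]) - 1) * spacing,
      y = origin[2] + (seq_len(dims[2]) - 1) * spacing))
    for (k in seq_len(dims[3])) {
      pts <- cbind(xy, origin[3] + (k - 1) * spacing)
      arr[, , k] <- phantom$membership(pts)
    }
  }
  binary_volume(arr, spacing, origin)
}
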