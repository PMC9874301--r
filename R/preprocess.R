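#' Gaussian noise filtering
#'
#' Convolution with the discrete 3x3x3 Gaussian kernel of standard deviation
#' 0.65 voxels, renormalized to sum 1 after truncation; image borders are
#' handled by edge replication. These are the standard denoising settings of
#' the processing chain.
#'
#' @param vol A [grey_volume()].
#' @param sigma Kernel standard deviation in voxels.
#' @return A smoothed [grey_volume()].
#' @export
gaussian_smooth <- function(vol, sigma = 0.65) {
  out <- gauss3d(vol$data, sigma, radius = 1L)
  grey_volume(out, vol$spacing, vol$origin)
}

#' Automatic global threshold from histogram peaks
#'
#' Builds a 256-bin histogram of the (optionally masked) grey values,
#' smooths it with a 5-bin moving average, finds the two highest local
#' maxima separated by at least `min_separation` bins whose intervening
#' valley drops below half the smaller peak, and returns the arithmetic mean
#' of the two peak grey levels. A candidate second peak must also reach
#' `min_peak_frac` of the primary peak height, so isolated tail-noise bins
#' do not masquerade as a bone peak. Fails loudly on non-bimodal input.
#'
#' @param vol A [grey_volume()].
#' @param mask Optional logical array restricting the histogram.
#' @param bins Number of histogram bins.
#' @param smooth_bins Moving-average window (odd).
#' @param min_separation Minimum peak separation in bins.
#' @param min_peak_frac Minimum smoothed height of the secondary peak,
#'   relative to the primary peak.
#' @return Threshold in grey units, with attributes `peaks` (the two peak
#'   grey levels).
#' @export
histogram_peak_threshold <- function(vol, mask = NULL, bins = 256L,
                                     smooth_bins = 5L, min_separation = 25L,
                                     min_peak_frac = 0.05) {
  g <- if (is.null(mask)) as.vector(vol$data) else vol$data[mask]
  if (length(g) < bins) stop("too few voxels for histogram thresholding")
  rng <- range(g)
  if (diff(rng) <= 0) stop("constant image: histogram is not bimodal")
  centers <- rng[1] + (seq_len(bins) - 0.5) * diff(rng) / bins
  idx <- pmin(bins, pmax(1L, 1L + floor((g - rng[1]) / diff(rng) * bins)))
  counts <- tabulate(idx, nbins = bins)
  # moving average smoothing (edge-shrunk window)
  half <- smooth_bins %/% 2
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(bins) - half, 1L)
  hi <- pmin(seq_len(bins) + half, bins)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)

  left <- c(-Inf, sm[-bins])
  right <- c(sm[-1], -Inf)
  is_peak <- sm >= left & sm >= right & (sm > left | sm > right)
  peaks <- which(is_peak)
  if (length(peaks) < 2) stop("histogram is not bimodal: fewer than two peaks")
  p1 <- peaks[which.max(sm[peaks])]
  far <- peaks[abs(peaks - p1) >= min_separation &
                 sm[peaks] >= min_peak_frac * sm[p1]]
  valley_ok <- vapply(far, function(p) {
    rng2 <- sort(c(p, p1))
    min(sm[rng2[1]:rng2[2]]) < 0.5 * min(sm[p], sm[p1])
  }, logical(1))
  far <- far[valley_ok]
  if (length(far) == 0)
    stop("histogram is not bimodal: no second peak at sufficient separation")
  p2 <- far[which.max(sm[far])]
  thr <- mean(centers[c(p1, p2)])
  attr(thr, "peaks") <- sort(centers[c(p1, p2)])
  thr
}

#' Global threshold segmentation
#'
#' A voxel is classified as bone iff its grey value is greater than or equal
#' to the threshold.
#'
#' @param vol A [grey_volume()].
#' @param threshold Grey-level threshold.
#' @return A [binary_volume()].
#' @export
apply_threshold <- function(vol, threshold) {
  binary_volume(array(vol$data >= threshold, dim(vol$data)), vol$spacing,
                vol$origin)
}

#' Connected-component filtering
#'
#' Labels the foreground with 6-connectivity and keeps either the largest
#' component (used to strip femur, fibula and menisci from the field of
#' view) or all components of at least `min_volume` voxels.
#'
#' @param bin A [binary_volume()].
#' @param policy `"largest"` or `"min_volume"`.
#' @param min_volume Components with voxel count strictly below this are
#'   removed.
#' @param connectivity 6 or 26.
#' @return A filtered [binary_volume()].
#' @export
filter_components <- function(bin, policy = c("largest", "min_volume"),
                              min_volume = 10L, connectivity = 6L) {
  policy <- match.arg(policy)
  if (!any(bin$data)) {
    warning("empty foreground")
    return(bin)
  }
  lab <- label3d_cpp(bin$data, dim(bin$data), as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- if (policy == "largest") which.max(sizes) else which(sizes >= min_volume)
  out <- array(lab %in% keep & bin$data, dim(bin$data))
  binary_volume(out, bin$spacing, bin$origin)
}

#' Despeckling
#'
#' Removes isolated bone regions with volume lower than 10 voxels
#' (6-connectivity); a 10-voxel island is kept.
#'
#' @param bin A [binary_volume()].
#' @param min_volume Strict lower volume bound in voxels.
#' @return A [binary_volume()].
#' @export
despeckle <- function(bin, min_volume = 10L) {
  if (!any(bin$data)) return(bin)
  filter_components(bin, "min_volume", min_volume = min_volume)
}

#' Rigid transform
#'
#' Intrinsic Z-Y-X rotation (degrees) about the given center followed by a
#' translation: a fixed-frame point `x` maps to
#' `R %*% (x - center) + center + translation`. [resample()] samples the
#' moving image at the mapped positions, so this is the resampling transform
#' from the fixed frame into the moving frame.
#'
#' @param angles_deg Rotations about z, y, x in degrees (applied in that
#'   intrinsic order).
#' @param translation_um Translation vector in um.
#' @param center_um Rotation center in world um.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_um = c(0, 0, 0),
                            center_um = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles_deg),
                 translation = as.numeric(translation_um),
                 center = as.numeric(center_um)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (z,y,x) = (%.3f, %.3f, %.3f) deg, t = (%.2f, %.2f, %.2f) um\n",
              x$angles[1], x$angles[2], x$angles[3], x$translation[1],
              x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

angles_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[2, 1], R[1, 1])
  g <- atan2(R[3, 2], R[3, 3])
  c(a, b, g) * 180 / pi
}

#' Invert or compose rigid transforms
#'
#' @param t,t1,t2 `rigid_transform` objects (sharing one center for
#'   composition).
#' @return A `rigid_transform`.
#' @export
invert_transform <- function(t) {
  R <- rotation_matrix(t$angles)
  rigid_transform(angles_from_matrix(t(R)),
                  as.numeric(-t(R) %*% t$translation), t$center)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(t1, t2) {
  # x -> t1 -> t2 when used for resampling: y = R2 (R1 (x-c) + t1) + c + t2
  R1 <- rotation_matrix(t1$angles)
  R2 <- rotation_matrix(t2$angles)
  rigid_transform(angles_from_matrix(R2 %*% R1),
                  as.numeric(R2 %*% t1$translation + t2$translation),
                  t1$center)
}

#' Resample a volume under a rigid transform
#'
#' Lanczos-3 windowed-sinc interpolation (the registration chain's
#' resampling kernel) of the moving volume onto a fixed grid; trilinear and
#' nearest-neighbor interpolation are available for metric evaluation and
#' masks. Out-of-domain voxels take the background value.
#'
#' @param vol Moving [grey_volume()].
#' @param t A [rigid_transform()].
#' @param grid Optional [grey_volume()] supplying the output grid (defaults
#'   to the input grid).
#' @param method `"lanczos"`, `"trilinear"` or `"nearest"`.
#' @param background Fill value outside the moving volume.
#' @return A [grey_volume()] on the target grid.
#' @export
resample <- function(vol, t = rigid_transform(), grid = vol,
                     method = c("lanczos", "trilinear", "nearest"),
                     background = 0) {
  method <- match.arg(method)
  mcode <- c(nearest = 0L, trilinear = 1L, lanczos = 2L)[[method]]
  out <- rigid_resample_cpp(vol$data, dim(vol$data), vol$spacing, vol$origin,
                            rotation_matrix(t$angles), t$center,
                            t$translation, dim(grid$data), grid$spacing,
                            grid$origin, mcode, background)
  grey_volume(array(out, dim(grid$data)), grid$spacing, grid$origin)
}

# normalized mutual information (H(A)+H(B))/H(A,B) from a 2D histogram;
# NaN-filled out-of-overlap voxels are excluded
nmi_metric <- function(a, b, nbins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 100) return(0)
  ia <- pmin(nbins, 1L + floor((a - min(a)) / (diff(range(a)) + 1e-12) * nbins))
  ib <- pmin(nbins, 1L + floor((b - min(b)) / (diff(range(b)) + 1e-12) * nbins))
  joint <- tabulate(ia + nbins * (ib - 1L), nbins = nbins * nbins)
  p <- joint / sum(joint)
  pa <- tabulate(ia, nbins = nbins) / length(a)
  pb <- tabulate(ib, nbins = nbins) / length(b)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hab <- -sum(p[p > 0] * log(p[p > 0]))
  (ha + hb) / hab
}

# block-average downsampling by an integer factor
downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol$data)
  nd <- d %/% f
  arr <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
                  drop = FALSE]
  a <- array(arr, c(f, nd[1], f, nd[2], f, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  grey_volume(out, vol$spacing * f, vol$origin + (f - 1) * vol$spacing / 2)
}

#' Rigid registration by normalized mutual information
#'
#' Finds the rigid transform maximizing normalized mutual information
#' between the fixed image and the resampled moving image, over a
#' multi-resolution pyramid with a derivative-free (Nelder-Mead) optimizer
#' started at the identity. Rotation center is the physical center of the
#' fixed volume. Deterministic for fixed inputs.
#'
#' @param moving,fixed [grey_volume()] objects with overlapping fields of
#'   view.
#' @param levels Number of pyramid levels (downsampling factors
#'   `2^(levels-1), ..., 1`).
#' @param maxit Optimizer iteration cap per level.
#' @return A [rigid_transform()] mapping fixed-frame points into the moving
#'   frame (i.e. `resample(moving, t, fixed)` aligns moving onto fixed),
#'   with attribute `nmi` (final metric).
#' @export
rigid_register <- function(moving, fixed, levels = 3L, maxit = 1000L,
                           max_metric_voxels = 1e5) {
  center <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing / 2
  par <- c(0, 0, 0, 0, 0, 0)
  opt <- NULL
  # deterministic lattice search at the coarsest level seeds the optimizer
  # inside the capture range of the NMI basin
  {
    f0 <- 2^(levels - 1)
    fx0 <- downsample_volume(fixed, f0)
    mv0 <- downsample_volume(moving, f0)
    best <- -Inf
    steps_a <- c(-6, 0, 6)
    steps_t <- c(-6, 0, 6) * fixed$spacing
    for (a1 in steps_a) for (a2 in steps_a) for (a3 in steps_a)
      for (t1 in steps_t) for (t2 in steps_t) for (t3 in steps_t) {
        t <- rigid_transform(c(a1, a2, a3), c(t1, t2, t3), center)
        v <- nmi_metric(resample(mv0, t, grid = fx0, method = "trilinear",
                                 background = NaN)$data, fx0$data)
        if (v > best) {
          best <- v
          par <- c(a1, a2, a3, t1, t2, t3)
        }
      }
  }
  for (lev in seq(levels, 1)) {
    if (lev > 1) {
      f <- 2^(lev - 1)
      fx <- downsample_volume(fixed, f)
      mv <- downsample_volume(moving, f)
    } else {
      fx <- fixed
      mv <- moving
    }
    # cap the metric cost: evaluate on a strided subgrid of the fixed image
    # (interpolation of the moving image keeps subvoxel sensitivity)
    s <- max(1L, ceiling((prod(dim(fx$data)) / max_metric_voxels)^(1 / 3)))
    fx <- stride_volume(fx, s)
    objective <- function(p) {
      t <- rigid_transform(p[1:3], p[4:6], center)
      res <- resample(mv, t, grid = fx, method = "trilinear",
                      background = NaN)
      -nmi_metric(res$data, fx$data)
    }
    sc <- if (lev == 1) 0.25 else 1
    opt <- optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8,
                                parscale = c(sc, sc, sc,
                                             rep(sc * fixed$spacing, 3))))
    par <- opt$par
    if (!is.finite(opt$value) || -opt$value <= 1)
      stop("registration did not converge; final NMI = ", -opt$value)
  }
  t <- rigid_transform(opt$par[1:3], opt$par[4:6], center)
  attr(t, "nmi") <- -opt$value
  attr(t, "convergence") <- opt$convergence
  t
}

# every s-th voxel along each axis, keeping native grey values
stride_volume <- function(vol, s) {
  if (s == 1) return(vol)
  d <- dim(vol$data)
  grey_volume(vol$data[seq(1, d[1], s), seq(1, d[2], s), seq(1, d[3], s),
                       drop = FALSE],
              vol$spacing * s, vol$origin)
}
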