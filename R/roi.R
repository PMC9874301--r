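# signed distance (um) from grid points to a closed polygon: positive inside
polygon_signed_distance <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  npt <- length(px)
  d2 <- rep(Inf, npt)
  inside <- rep(FALSE, npt)
  for (e in seq_len(n)) {
    ex <- x2[e] - x1[e]; ey <- y2[e] - y1[e]
    len2 <- ex^2 + ey^2
    if (len2 < 1e-24) next
    t <- pmin(1, pmax(0, ((px - x1[e]) * ex + (py - y1[e]) * ey) / len2))
    dx <- px - (x1[e] + t * ex); dy <- py - (y1[e] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
    # even-odd crossing test
    cross <- ((y1[e] > py) != (y2[e] > py)) &
      (px < x1[e] + (py - y1[e]) * ex / ey)
    inside <- xor(inside, cross & is.finite(ex / ey))
  }
  ifelse(inside, 1, -1) * sqrt(d2)
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Shape-based interpolation of sparse planar contours
#'
#' Rasterizes each closed contour to a signed distance field on its slice
#' and linearly interpolates the distance fields between contoured slices;
#' the zero level set defines the mask on intermediate slices. Slices
#' outside the contoured range are empty. This reproduces the trabecular
#' ROI drawn every few slices and filled in between.
#'
#' @param contours Either a data frame with columns `slice`, `x`, `y`
#'   (vertices in order, um) or a list of `list(slice =, xy = matrix)`.
#' @param grid A [grey_volume()] or [binary_volume()] supplying the target
#'   grid.
#' @param label ROI label for the result.
#' @return An [roi_mask()] with one label.
#' @export
interpolate_contours <- function(contours, grid,
                                 label = "trabecular-whole") {
  if (is.data.frame(contours)) {
    contours <- lapply(split(contours, contours$slice), function(df) {
      list(slice = df$slice[1], xy = cbind(df$x, df$y))
    })
  }
  slices <- vapply(contours, function(c) c$slice, numeric(1))
  if (is.unsorted(slices, strictly = TRUE))
    stop("contour slice indices must be strictly increasing")
  if (length(contours) < 2) stop("need at least two contours to interpolate")
  for (c in contours)
    if (polygon_area(c$xy) <= 0) stop("degenerate (zero-area) contour polygon")

  d <- dim(grid$data)
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  g <- expand.grid(x = xs, y = ys)
  sdf <- vapply(contours, function(c) {
    polygon_signed_distance(g$x, g$y, c$xy)
  }, numeric(nrow(g)))

  mask <- array(FALSE, d)
  for (s in seq_len(d[3])) {
    if (s < slices[1] || s > slices[length(slices)]) next
    i <- findInterval(s, slices)
    if (i == length(slices)) {
      sl <- sdf[, i]
    } else {
      w <- (s - slices[i]) / (slices[i + 1] - slices[i])
      sl <- (1 - w) * sdf[, i] + w * sdf[, i + 1]
    }
    mask[, , s] <- matrix(sl >= 0, d[1], d[2])
  }
  roi_mask(stats::setNames(list(mask), label), grid$spacing, grid$origin)
}

#' Split a trabecular ROI into medial and lateral compartments
#'
#' Partitions the whole trabecular region by a sagittal plane, by default
#' through the region centroid with its normal along the medial-lateral
#' axis. Voxels exactly on the plane go to the medial side.
#'
#' @param roi An [roi_mask()] containing `trabecular-whole`.
#' @param plane_x World coordinate (um) of the dividing plane along the
#'   medial-lateral axis; default is the ROI centroid.
#' @param axis Medial-lateral grid axis (1 = x).
#' @return The [roi_mask()] with `trabecular-medial` and
#'   `trabecular-lateral` added.
#' @export
split_medial_lateral <- function(roi, plane_x = NULL, axis = 1L) {
  whole <- roi_select(roi, "trabecular-whole")
  coords <- roi$origin[axis] +
    (slice.index(whole, axis) - 1) * roi$spacing
  if (is.null(plane_x)) {
    if (!any(whole)) stop("empty trabecular ROI")
    plane_x <- mean(coords[whole])
  }
  med <- whole & coords <= plane_x
  lat <- whole & coords > plane_x
  if (!any(med) || !any(lat))
    warning("dividing plane misses the ROI: one compartment is empty")
  roi$masks[["trabecular-medial"]] <- med
  roi$masks[["trabecular-lateral"]] <- lat
  roi
}

#' Fixed-size cortical plate box ROI
#'
#' Axis-aligned square box in the transverse plane (side given in um,
#' converted to `round(side / voxel)` voxels with ties away from zero),
#' centered at the given condyle position, spanning the full available depth
#' or a given world z-range. Because boxes are placed in world coordinates,
#' registered specimens receive boxes at identical spatial positions.
#'
#' @param grid A volume supplying the target grid.
#' @param center World (x, y) center in um.
#' @param side Box side in um.
#' @param z_range Optional world z-interval; default full depth.
#' @param label ROI label.
#' @return An [roi_mask()] with one label. Boxes exceeding the volume are
#'   clipped with a warning.
#' @export
cortical_box_roi <- function(grid, center, side = 500, z_range = NULL,
                             label = "cortical-medial") {
  h <- grid$spacing
  d <- dim(grid$data)
  nside <- floor(side / h + 0.5) # round half away from zero
  ci <- round((center[1] - grid$origin[1]) / h) + 1
  cj <- round((center[2] - grid$origin[2]) / h) + 1
  ilo <- ci - (nside - 1) %/% 2; ihi <- ilo + nside - 1
  jlo <- cj - (nside - 1) %/% 2; jhi <- jlo + nside - 1
  if (ilo < 1 || jlo < 1 || ihi > d[1] || jhi > d[2]) {
    warning("cortical box exceeds the volume: clipping")
    ilo <- max(1, ilo); jlo <- max(1, jlo)
    ihi <- min(d[1], ihi); jhi <- min(d[2], jhi)
  }
  zin <- if (is.null(z_range)) rep(TRUE, d[3]) else {
    zc <- axis_coords(grid, 3)
    zc >= z_range[1] & zc <= z_range[2]
  }
  mask <- array(FALSE, d)
  mask[ilo:ihi, jlo:jhi, zin] <- TRUE
  roi_mask(stats::setNames(list(mask), label), h, grid$origin)
}

# 2D morphological operation on one slice via the Euclidean distance
# transform: a disc of the given radius (pixel included iff its center is
# within `radius` of the disc center)
close_slice <- function(slice, radius) {
  d <- c(dim(slice), 1L)
  r2 <- radius^2 + 1e-9
  dil <- array(edt_sq_cpp(!slice, d) <= r2, dim(slice))
  array(edt_sq_cpp(dil, d) > r2, dim(slice))
}

#' 2D pore closing within a cortical ROI
#'
#' Slice-by-slice morphological closing with a discrete Euclidean disc of
#' the given pixel radius, applied within the cortical ROI only (voxels
#' outside the ROI are passed through unchanged). Closing fills plate pores
#' smaller than the structuring element.
#'
#' @param bin A [binary_volume()].
#' @param roi Optional logical array or [roi_mask()] label restricting where
#'   closed values replace the input.
#' @param radius Disc radius in pixels.
#' @param label Label used when `roi` is an [roi_mask()].
#' @return A [binary_volume()].
#' @export
close_pores_2d <- function(bin, roi = NULL, radius = 10,
                           label = "cortical-medial") {
  if (inherits(roi, "roi_mask")) roi <- roi_select(roi, label)
  d <- dim(bin$data)
  out <- bin$data
  for (s in seq_len(d[3])) {
    cl <- close_slice(bin$data[, , s], radius)
    if (is.null(roi)) {
      out[, , s] <- cl
    } else {
      rs <- roi[, , s]
      sl <- out[, , s]
      sl[rs] <- cl[rs]
      out[, , s] <- sl
    }
  }
  binary_volume(out, bin$spacing, bin$origin)
}
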