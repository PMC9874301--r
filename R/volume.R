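#' Grey-level image volume
#'
#' A 3D scalar image on an isotropic grid. World coordinates are
#' `origin + (index - 1) * spacing`, i.e. `origin` is the world position of
#' the center of voxel (1,1,1), in micrometres.
#'
#' @param data 3D numeric array of grey values.
#' @param spacing Isotropic voxel size in micrometres (> 0).
#' @param origin World position (um) of the first voxel center, length 3.
#' @return An object of class `grey_volume`.
#' @export
grey_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("voxel spacing must be a single positive number (um)")
  stopifnot(length(origin) == 3)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "grey_volume")
}

#' Binary (segmented) volume
#'
#' A boolean grid sharing the geometry of the grey volume it was segmented
#' from; `TRUE` marks bone.
#'
#' @param data 3D logical array.
#' @inheritParams grey_volume
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.logical(data))
  if (spacing <= 0) stop("voxel spacing must be positive")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_volume")
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grey_volume> %d x %d x %d voxels @ %.4g um, origin (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  grey range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.4g um, %.1f%% foreground\n",
              d[1], d[2], d[3], x$spacing, 100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.grey_volume <- function(x) dim(x$data)

#' @export
dim.binary_volume <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    abs(a$spacing - b$spacing) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

# world coordinates of voxel centers along each axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing
}

#' Region-of-interest mask
#'
#' A set of named label masks on a common grid. Standard label vocabulary:
#' `trabecular-whole`, `trabecular-medial`, `trabecular-lateral`,
#' `cortical-medial`, `cortical-lateral`. The whole trabecular region is the
#' disjoint union of the medial and lateral compartments once a split has
#' been applied.
#'
#' @param masks Named list of 3D logical arrays sharing one grid.
#' @inheritParams grey_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(masks, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (m in masks) stopifnot(is.logical(m), identical(dim(m), d))
  structure(list(masks = masks, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<roi_mask> %d x %d x %d voxels @ %.4g um\n", d[1], d[2], d[3],
              x$spacing))
  for (nm in names(x$masks))
    cat(sprintf("  %-20s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Extract one labeled region from an `roi_mask`
#'
#' `trabecular-whole` is synthesized as the union of the medial and lateral
#' compartments when not stored explicitly.
#'
#' @param roi An `roi_mask`.
#' @param label Label name.
#' @return Logical array.
#' @export
roi_select <- function(roi, label) {
  if (!is.null(roi$masks[[label]])) return(roi$masks[[label]])
  if (label == "trabecular-whole" &&
      !is.null(roi$masks[["trabecular-medial"]]) &&
      !is.null(roi$masks[["trabecular-lateral"]]))
    return(roi$masks[["trabecular-medial"]] | roi$masks[["trabecular-lateral"]])
  stop("no such ROI label: ", label)
}
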