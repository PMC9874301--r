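#' Read and write volumes
#'
#' Two on-disk formats are supported, both carrying the grid geometry:
#'
#' * MetaImage (`.mhd` header + `.raw` little-endian data), element spacing
#'   in um; grey data as `MET_DOUBLE`/`MET_FLOAT`/`MET_SHORT`/`MET_USHORT`/
#'   `MET_UCHAR`, binary data written as `MET_UCHAR`.
#' * Multi-page TIFF stack (16-bit) with a YAML sidecar (`<file>.yml`)
#'   carrying voxel size, origin and the integer grey scale; integer data in
#'   `[0, 65535]` round-trips bit-exactly.
#'
#' A TIFF without its sidecar, or an MHD without `ElementSpacing`, is
#' refused rather than silently assuming a voxel size.
#'
#' @param path File path (`.mhd` or `.tif`/`.tiff`).
#' @param vol A [grey_volume()] or [binary_volume()].
#' @param type Element type for MHD grey output.
#' @return `read_volume()` returns a [grey_volume()] (or [binary_volume()]
#'   if the MHD was written from one, detected via a header comment).
#' @export
read_volume <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) read_mhd(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) read_tiff_stack(path)
  else stop("unsupported volume format: ", path)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, type = "MET_DOUBLE") {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) write_mhd(vol, path, type)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    write_tiff_stack(vol, path)
  else stop("unsupported volume format: ", path)
  invisible(path)
}

mhd_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT = list(what = "double", size = 4L),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE))

write_mhd <- function(vol, path, type = "MET_DOUBLE") {
  binary <- inherits(vol, "binary_volume")
  if (binary) type <- "MET_UCHAR"
  tp <- mhd_types[[type]]
  if (is.null(tp)) stop("unsupported element type: ", type)
  d <- dim(vol$data)
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol$spacing, vol$spacing,
            vol$spacing),
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2],
            vol$origin[3]),
    sprintf("ElementType = %s", type),
    sprintf("AnatomicalOrientation = ???"),
    sprintf("ElementDataFile = %s", basename(raw_path)),
    if (binary) "Comment = bonemorph-binary")
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  v <- if (binary) as.integer(vol$data) else
    if (tp$what == "integer") as.integer(round(vol$data)) else
      as.vector(vol$data)
  writeBin(v, con, size = tp$size, endian = "little")
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- get("ElementSpacing")
  if (is.na(sp)) stop("MHD header missing ElementSpacing; refusing to assume a voxel size")
  spacing <- as.numeric(strsplit(sp, "\\s+")[[1]])
  if (max(spacing) - min(spacing) > 1e-9 * spacing[1])
    stop("anisotropic spacing not supported")
  off <- get("Offset")
  origin <- if (is.na(off)) c(0, 0, 0) else
    as.numeric(strsplit(off, "\\s+")[[1]])
  type <- get("ElementType")
  tp <- mhd_types[[type]]
  if (is.null(tp)) stop("unsupported element type: ", type)
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, tp$what, n = n, size = tp$size, endian = "little",
               signed = if (tp$size < 4) isTRUE(tp$signed) else TRUE)
  binary <- identical(get("Comment"), "bonemorph-binary")
  if (binary)
    binary_volume(array(v != 0, d), spacing[1], origin)
  else
    grey_volume(array(as.numeric(v), d), spacing[1], origin)
}

tiff_sidecar <- function(path) paste0(path, ".yml")

write_tiff_stack <- function(vol, path, scale = 65535) {
  d <- dim(vol$data)
  data <- vol$data
  if (inherits(vol, "binary_volume")) data <- data * scale
  if (min(data) < 0 || max(data) > scale)
    stop("TIFF output expects grey values in [0, ", scale, "]")
  pages <- lapply(seq_len(d[3]), function(k) data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(voxel_size_um = vol$spacing,
                        origin_um = as.numeric(vol$origin),
                        scale = scale,
                        binary = inherits(vol, "binary_volume")), tiff_sidecar(path))
  invisible(path)
}

read_tiff_stack <- function(path) {
  sc <- tiff_sidecar(path)
  if (!file.exists(sc))
    stop("TIFF stack has no metadata sidecar (", sc,
         "); refusing to assume a voxel size")
  meta <- yaml::read_yaml(sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  arr <- array(0, d)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- round(arr * meta$scale)
  if (isTRUE(meta$binary))
    binary_volume(array(arr != 0, d), meta$voxel_size_um, meta$origin_um)
  else
    grey_volume(arr, meta$voxel_size_um, meta$origin_um)
}

#' Serialize rigid transforms as plain text
#'
#' Key-value files with angles in degrees and translations in um.
#'
#' @param t A [rigid_transform()].
#' @param path File path.
#' @return `read_transform()` returns a [rigid_transform()].
#' @export
write_transform <- function(t, path) {
  writeLines(c(
    sprintf("angles_deg = %.12g %.12g %.12g", t$angles[1], t$angles[2],
            t$angles[3]),
    sprintf("translation_um = %.12g %.12g %.12g", t$translation[1],
            t$translation[2], t$translation[3]),
    sprintf("center_um = %.12g %.12g %.12g", t$center[1], t$center[2],
            t$center[3])), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  get <- function(k) {
    i <- match(k, vapply(kv, `[`, "", 1))
    as.numeric(strsplit(kv[[i]][2], "\\s+")[[1]])
  }
  rigid_transform(get("angles_deg"), get("translation_um"), get("center_um"))
}

#' Pipeline configuration
#'
#' Flat YAML configuration whose defaults are the protocol's stated values:
#' Gaussian kernel sigma 0.65 voxels, despeckle threshold 10 voxels,
#' cortical box side 500 um, closing radius 10 px, contour spacing 5
#' slices, voxel sizes 10.4 um (in vivo) and 4.35 um (ex vivo).
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @param overrides Named list overriding file values (CLI flags map here).
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    ex_vivo_voxel_um = 4.35, in_vivo_voxel_um = 10.4,
    ex_vivo_psf_voxels = 0.6, in_vivo_psf_voxels = 1.0,
    ex_vivo_noise_frac = 0.05, in_vivo_noise_frac = 0.10,
    background_grey = 40, bone_grey = 220, supersample = 2L,
    smooth_sigma_voxels = 0.65,
    despeckle_min_voxels = 10L,
    histogram_bins = 256L, histogram_min_separation = 25L,
    cortical_box_um = 500, closing_radius_px = 10L,
    contour_spacing_slices = 5L,
    mil_directions = 512L, smi_epsilon_voxels = 0.5,
    group_test_var_equal = TRUE, mc_replicates = 10000L,
    seed = 1L, output_dir = "bonemorph-out")
}

#' @rdname default_config
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

# machine-readable provenance record for a pipeline run
write_provenance <- function(cfg, dir, command) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- list(command = command, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = cfg,
              config_hash = sum(utf8ToInt(paste(names(cfg),
                                                unlist(cfg), collapse = ";"))))
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Write a cohort manifest CSV
#'
#' One row per specimen with group label, seed, file paths and the
#' generating ground-truth values.
#'
#' @param cohort A [generate_paired_cohort()] result.
#' @param dir Output directory; volumes are written as MetaImage when
#'   `write_volumes` is `TRUE`.
#' @param write_volumes Also write the grey volumes.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_volumes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$ex_vivo_path <- file.path(dir, paste0(man$id, "_ex.mhd"))
  man$in_vivo_path <- file.path(dir, paste0(man$id, "_in.mhd"))
  if (write_volumes) {
    for (i in seq_along(cohort$specimens)) {
      sp <- cohort$specimens[[i]]
      if (!is.null(sp$ex_vivo)) {
        write_volume(sp$ex_vivo, man$ex_vivo_path[i], type = "MET_FLOAT")
        write_volume(sp$in_vivo, man$in_vivo_path[i], type = "MET_FLOAT")
      }
    }
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
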