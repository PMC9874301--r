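#' Segment a grey volume into a bone mask
#'
#' The standard preprocessing chain applied to an already-aligned image:
#' 3x3x3 Gaussian smoothing (sigma 0.65 voxels), automatic two-peak global
#' threshold, and despeckling of isolated regions below 10 voxels.
#'
#' @param vol A [grey_volume()].
#' @param config Configuration list, see [default_config()].
#' @param mask Optional histogram mask.
#' @return A [binary_volume()] with attribute `threshold`.
#' @export
segment_volume <- function(vol, config = default_config(), mask = NULL) {
  sm <- gaussian_smooth(vol, config$smooth_sigma_voxels)
  thr <- histogram_peak_threshold(sm, mask = mask,
                                  bins = config$histogram_bins,
                                  min_separation = config$histogram_min_separation)
  bin <- apply_threshold(sm, thr)
  bin <- despeckle(bin, config$despeckle_min_voxels)
  attr(bin, "threshold") <- as.numeric(thr)
  bin
}

#' Measure one cohort specimen at both resolutions
#'
#' Segments the ex vivo and in vivo volumes and runs the morphometry suite
#' on each with its own ROI masks.
#'
#' @param specimen One element of `generate_paired_cohort()$specimens`.
#' @param config Configuration list.
#' @param trabecular_rois,cortical_rois Passed to [measure_all()].
#' @return Tidy data frame of both modalities with a `group` column.
#' @export
measure_specimen <- function(specimen, config = default_config(),
                             trabecular_rois = NULL, cortical_rois = NULL) {
  out <- list()
  for (mod in c("ex_vivo", "in_vivo")) {
    vol <- specimen[[mod]]
    rois <- specimen[[if (mod == "ex_vivo") "rois_ex" else "rois_in"]]
    bin <- segment_volume(vol, config)
    res <- measure_all(bin, rois, specimen = specimen$id, modality = mod,
                       trabecular_rois = trabecular_rois,
                       cortical_rois = cortical_rois,
                       n_directions = config$mil_directions)
    res$group <- specimen$group
    out[[mod]] <- res
  }
  do.call(rbind, out)
}

#' Run the full dual-resolution analysis on a synthetic cohort
#'
#' Generates (or takes) a paired cohort, measures every specimen at both
#' resolutions, and builds the accuracy report.
#'
#' @param cohort A [generate_paired_cohort()] result.
#' @param config Configuration list.
#' @param trabecular_rois,cortical_rois ROI label subsets (defaults measure
#'   all available).
#' @return List with `results` (tidy measurements) and `report`
#'   (accuracy_report).
#' @export
run_cohort_analysis <- function(cohort, config = default_config(),
                                trabecular_rois = NULL,
                                cortical_rois = NULL) {
  results <- do.call(rbind, lapply(cohort$specimens, measure_specimen,
                                   config = config,
                                   trabecular_rois = trabecular_rois,
                                   cortical_rois = cortical_rois))
  report <- build_report(results, seed = config$seed,
                         var_equal = config$group_test_var_equal)
  list(results = results, report = report)
}

#' Phantom oracle validation suite
#'
#' Runs the morphometry suite on phantoms with closed-form ground truth and
#' tabulates measured versus expected values: sphere surface area and
#' thickness, slab and cylinder thickness, ball and torus topology, and
#' plate/rod/sphere structure model index.
#'
#' @param spacing Rasterization voxel size (um).
#' @return Data frame with columns `check`, `measured`, `expected`,
#'   `rel_error`.
#' @export
validate_phantoms <- function(spacing = 4.35) {
  rows <- list()
  add <- function(check, measured, expected) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, measured = measured, expected = expected,
      rel_error = if (expected != 0) abs(measured - expected) / abs(expected)
      else abs(measured), stringsAsFactors = FALSE)
  }
  sph <- rasterize_phantom(make_phantom(
    phantom_spec("sphere", extent = odd_extent(4 * 174, spacing),
                 diameter = 174)), spacing)
  gt <- 4 * pi * 87^2
  add("sphere surface area (um^2)", bone_surface(sph)$area_um2, gt)
  add("sphere thickness (um)", local_thickness(sph)$mean_um, 174)
  add("sphere SMI", structure_model_index(sph), 4)
  add("ball Euler characteristic", connectivity_density(sph)$euler, 1)

  slab <- rasterize_phantom(make_phantom(
    phantom_spec("slab", extent = odd_extent(4 * 14 * spacing, spacing),
                 thickness = 14 * spacing)), spacing)
  add("slab thickness (um)", local_thickness(slab)$mean_um, 14 * spacing)
  add("slab SMI", structure_model_index(slab), 0)

  cyl <- rasterize_phantom(make_phantom(
    phantom_spec("cylinder", extent = odd_extent(4 * 104.4, spacing),
                 diameter = 104.4)), spacing)
  add("cylinder thickness (um)", local_thickness(cyl)$mean_um, 104.4)
  add("cylinder SMI", structure_model_index(cyl), 3)

  tor <- rasterize_phantom(make_phantom(
    phantom_spec("torus", extent = odd_extent(4 * 280, 2 * spacing),
                 major_radius = 100, minor_radius = 40)), 2 * spacing)
  add("torus Euler characteristic", connectivity_density(tor)$euler, 0)
  add("torus connectivity", connectivity_density(tor)$connectivity, 1)

  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (paired cohort generation), `preprocess`
#' (segment one volume), `measure` (morphometry of a simulated cohort
#' directory), `compare` (accuracy report from tidy results CSV),
#' `validate` (phantom oracle suite). Every run writes a provenance record
#' (configuration, seeds) beside its outputs.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
bm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bonemorph <simulate|preprocess|measure|compare|validate> [options]",
    "  simulate   --out DIR [--seed N] [--n N] [--extent UM] [--config FILE]",
    "  preprocess --in VOL --out VOL [--config FILE]",
    "  measure    --dir DIR --out CSV [--config FILE]",
    "  compare    --results CSV --out DIR [--config FILE]",
    "  validate   [--spacing UM]", sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    1L
  }
  if (length(args) < 1) return(fail("no subcommand given"))
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    if (!grepl("^--", rest[i])) return(fail(paste("unexpected argument:", rest[i])))
    key <- sub("^--", "", rest[i])
    if (i + 1 > length(rest)) return(fail(paste("missing value for --", key)))
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  known <- c("out", "seed", "n", "extent", "config", "in", "dir", "results",
             "spacing")
  if (length(setdiff(names(opts), known)))
    return(fail(paste("unknown option(s):",
                      paste(setdiff(names(opts), known), collapse = ", "))))
  cfg <- tryCatch(read_config(opts$config,
                              overrides = if (!is.null(opts$seed))
                                list(seed = as.integer(opts$seed)) else list()),
                  error = function(e) e)
  if (inherits(cfg, "error")) return(fail(conditionMessage(cfg)))

  status <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) stop("simulate requires --out")
        cohort <- generate_paired_cohort(
          n_per_group = as.integer(opts$n %||% 2L),
          seed = cfg$seed,
          extent = as.numeric(opts$extent %||% 850))
        write_cohort(cohort, opts$out)
        write_provenance(cfg, opts$out, paste("simulate", opts$out))
        0L
      },
      preprocess = {
        if (is.null(opts$`in`) || is.null(opts$out))
          stop("preprocess requires --in and --out")
        vol <- read_volume(opts$`in`)
        bin <- segment_volume(vol, cfg)
        write_volume(bin, opts$out)
        write_provenance(cfg, dirname(opts$out),
                         paste("preprocess", opts$`in`))
        message("threshold: ", signif(attr(bin, "threshold"), 6))
        0L
      },
      measure = {
        if (is.null(opts$dir) || is.null(opts$out))
          stop("measure requires --dir and --out")
        man <- read.csv(file.path(opts$dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
        res <- list()
        for (r in seq_len(nrow(man))) {
          for (mod in c("ex_vivo", "in_vivo")) {
            vol <- read_volume(man[[paste0(sub("_vivo", "", mod), "_vivo_path")]][r])
            spec <- animal_phantom_spec(man$seed[r],
                                        extent = max(vol$origin +
                                                       dim(vol$data) * vol$spacing))
            rois <- animal_rois(vol, spec)
            bin <- segment_volume(vol, cfg)
            m <- measure_all(bin, rois, specimen = man$id[r], modality = mod,
                             n_directions = cfg$mil_directions)
            m$group <- man$group[r]
            res[[length(res) + 1]] <- m
          }
        }
        out <- do.call(rbind, res)
        write.csv(out, opts$out, row.names = FALSE)
        write_provenance(cfg, dirname(opts$out), paste("measure", opts$dir))
        0L
      },
      compare = {
        if (is.null(opts$results) || is.null(opts$out))
          stop("compare requires --results and --out")
        res <- read.csv(opts$results, stringsAsFactors = FALSE)
        rep <- build_report(res, seed = cfg$seed,
                            var_equal = cfg$group_test_var_equal)
        write_report(rep, opts$out)
        write_provenance(cfg, opts$out, paste("compare", opts$results))
        0L
      },
      validate = {
        tab <- validate_phantoms(as.numeric(opts$spacing %||% 4.35))
        print(format(tab, digits = 4), row.names = FALSE)
        0L
      },
      return(fail(paste("unknown subcommand:", cmd))))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
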