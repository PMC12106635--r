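#' Subject- and population-level pipeline orchestration
#'
#' `run_subject()` composes the stages in acquisition-processing order:
#' SWI contrast (skipped when a precomputed SWI volume is supplied) ->
#' vesselness + segmentation + orientation pooling -> FOD peak extraction
#' -> dominant/nearest angle maps, histogram and region summary ->
#' along-tract profiles. `run_population()` reorients per-subject vessel
#' fields into a common space and averages them.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' All tunable pipeline parameters in one serializable list; values not
#' supplied fall back to the documented defaults.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    window_fraction = 0.25,   # Hanning low-pass fraction for phase HP
    mask_power = 4L,          # phase-mask exponent
    mask_polarity = "negative",
    slicewise = TRUE,
    frangi_scales = c(0.2, 0.4, 0.8, 1.2),  # mm
    frangi_alpha = 0.5,
    frangi_beta = 0.5,
    frangi_c = NULL,
    vessel_threshold = 0.5,
    vessel_polarity = "both",
    dilation_voxels = 3L,
    target_voxel_mm = 2,
    pool_weighting = "vesselness",
    n_seed_directions = 100L,
    max_peaks = 3L,
    rel_threshold = 0.1,
    min_separation_deg = 15,
    n_segments = 100L,
    bin_width_deg = 2,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (lossless JSON round trip)
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the subject-level pipeline
#'
#' @param inputs list of in-memory inputs: either `swi` (precomputed SWI
#'   volume, with `affine`/`voxel_mm` attributes) or `magnitude` + `phase`
#'   (lists of repetitions or single arrays); `wm_mask`; optional
#'   `gm_mask`, `csf_mask`; `sh` (an [sh_field()] on the coarse grid);
#'   optional `atlas` (coarse-grid label array), `label_names`, `bundles`
#'   (named list of `streamline_bundle`s); `fine_voxel_mm`.
#' @param config a [run_config()].
#' @return list of class `subject_result` with `swi`, `vesselness`,
#'   `vessel_mask`, `vessels` (coarse `axial_field`), `peaks`,
#'   `dominant`, `nearest` (angle maps), `histograms`, `regions`
#'   (tibble or NULL), `profiles` (named list of tract profiles) and
#'   `manifest` (config hash, stage voxel counts, timings).
#' @export
run_subject <- function(inputs, config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   stages = list())
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - ts)
    val
  }
  voxel_mm <- inputs$fine_voxel_mm %||% attr(inputs$swi, "voxel_mm") %||% 1

  swi <- if (!is.null(inputs$swi)) {
    manifest$stages$swi_contrast <- list(skipped = "precomputed SWI supplied")
    inputs$swi
  } else {
    stage("swi_contrast", {
      mags <- if (is.list(inputs$magnitude)) inputs$magnitude else
        list(inputs$magnitude)
      phs <- if (is.list(inputs$phase)) inputs$phase else list(inputs$phase)
      reps <- mapply(function(m, p) {
        swi_contrast(m, p, config$window_fraction, config$mask_power,
                     config$mask_polarity, config$slicewise)
      }, mags, phs, SIMPLIFY = FALSE)
      average_repetitions(reps)
    })
  }

  fparams <- frangi_params(config$frangi_scales, config$frangi_alpha,
                           config$frangi_beta, config$frangi_c,
                           config$vessel_threshold)
  vres <- stage("vesselness", {
    frangi_vesselness(swi, fparams, voxel_mm, config$vessel_polarity)
  })
  vmask <- stage("segmentation", {
    segment_vessels(vres, fparams, inputs$wm_mask, inputs$gm_mask,
                    inputs$csf_mask, config$dilation_voxels)
  })
  manifest$stages$segmentation$n_vessel_voxels <- sum(vmask)
  vessels <- stage("orientation_pooling", {
    downsample_orientations(vres, vmask, config$target_voxel_mm,
                            config$pool_weighting)
  })
  manifest$stages$orientation_pooling$n_coarse_voxels <- sum(vessels$mask)

  peaks <- dominant <- nearest <- histograms <- regions <- NULL
  if (!is.null(inputs$sh)) {
    peaks <- stage("fod_peaks", {
      extract_peaks(inputs$sh,
                    seeds = sphere_fibonacci(config$n_seed_directions),
                    max_peaks = config$max_peaks,
                    rel_threshold = config$rel_threshold,
                    min_separation_deg = config$min_separation_deg)
    })
    manifest$stages$fod_peaks$n_peak_voxels <- sum(peaks$n_peaks > 0)
    dominant <- stage("angle_maps", dominant_angle_map(vessels, peaks))
    nearest <- nearest_angle_map(vessels, peaks)
    histograms <- list(dominant = angle_histogram(dominant,
                                                  config$bin_width_deg),
                       nearest = angle_histogram(nearest,
                                                 config$bin_width_deg))
    if (!is.null(inputs$atlas)) {
      regions <- stage("region_summary", {
        region_summary(dominant, nearest, inputs$atlas, inputs$label_names)
      })
    }
  }

  profiles <- NULL
  if (!is.null(inputs$bundles)) {
    profiles <- stage("tract_profiles", {
      lapply(inputs$bundles, along_tract_profile, vessels = vessels,
             n_segments = config$n_segments)
    })
  }
  manifest$total_seconds <- proc.time()[["elapsed"]] - t0
  structure(list(swi = swi, vesselness = vres, vessel_mask = vmask,
                 vessels = vessels, peaks = peaks, dominant = dominant,
                 nearest = nearest, histograms = histograms,
                 regions = regions, profiles = profiles,
                 manifest = manifest),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result>", sum(x$vessel_mask), "vessel voxels ->",
      sum(x$vessels$mask), "pooled orientations\n")
  if (!is.null(x$dominant)) {
    g <- dplyr::bind_rows(glance(x$dominant), glance(x$nearest))
    print(g)
  }
  invisible(x)
}

#' Run the population-level pipeline
#'
#' Reorients each subject's vessel orientation field into the common space
#' with the preservation-of-principal-direction rule, then averages.
#'
#' @param fields list of >= 2 subject `axial_field`s already resampled to
#'   one common grid.
#' @param jacobians list of per-subject Jacobians (3 x 3 matrix or
#'   per-voxel array), or NULL for identity (already reoriented inputs).
#' @param dispersion passed to [population_mean()].
#' @return list with `mean` (`axial_field`), `deviation` (array, deg) and
#'   `n_subjects`.
#' @export
run_population <- function(fields, jacobians = NULL,
                           dispersion = "about-mean") {
  if (length(fields) < 2) stop("need at least two subjects", call. = FALSE)
  if (!is.null(jacobians)) {
    stopifnot(length(jacobians) == length(fields))
    fields <- mapply(ppd_reorient, fields, jacobians, SIMPLIFY = FALSE)
  }
  population_mean(fields, dispersion = dispersion)
}

#' Write a region summary as TSV
#'
#' @param regions tibble from [region_summary()].
#' @param path file path.
#' @export
write_region_summary <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
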