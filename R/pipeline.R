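#' Demo pipeline configuration
#'
#' Collects every stage's settings for [run_pipeline()] with defaults sized
#' for a laptop-scale demonstration: a synthetic cohort whose per-subject
#' WMH volumes drive phantom lesion sizes, segmentation of every phantom, a
#' frequency map, the correlation table, the six-model mediation suite, and
#' the combined-sample path model.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_subjects cohort / phantom count (default 24).
#' @param phantom_shape phantom grid (default 64^3 at 1 mm).
#' @param lesion_volume_scale factor mapping a subject's cohort WMH volume
#'   (cc) to the phantom lesion volume, keeping lesions inside the phantom's
#'   WM compartment without saturating the radius clamp (default 0.12).
#' @param noise_free use zero-variance compartment intensities (exact
#'   segmentation; default `FALSE`).
#' @param n_sims mediation Monte-Carlo draws (default 500 for the demo).
#' @param bootstrap_n path-model bootstrap resamples (default 500).
#' @param write_volumes also write per-subject NIfTI masks (default
#'   `FALSE`; the frequency map is always written).
#' @param cohort_csv optional existing cohort CSV to use instead of
#'   simulating one.
#' @param force overwrite an existing run in `out_dir` (default `FALSE`;
#'   without it a completed run is never silently overwritten).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_subjects = 24,
                            phantom_shape = c(64, 64, 64),
                            lesion_volume_scale = 0.12, noise_free = FALSE,
                            n_sims = 500, bootstrap_n = 500,
                            write_volumes = FALSE, cohort_csv = NULL,
                            force = FALSE) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_subjects = as.integer(n_subjects),
         phantom_shape = as.integer(phantom_shape),
         lesion_volume_scale = lesion_volume_scale,
         noise_free = isTRUE(noise_free),
         n_sims = as.integer(n_sims), bootstrap_n = as.integer(bootstrap_n),
         write_volumes = isTRUE(write_volumes), cohort_csv = cohort_csv,
         force = isTRUE(force)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path a `.json` or `.yaml`/`.yml` file whose keys match
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# sphere radius (mm) of a given volume in cc, clamped to the phantom's WM
lesion_radius_mm <- function(volume_cc, r_min = 2, r_max = 7) {
  r <- (3 * pmax(volume_cc, 0) * 1000 / (4 * pi))^(1 / 3)
  pmin(pmax(r, r_min), r_max)
}

#' Run the full demonstration pipeline
#'
#' Executes simulate -> segment (per subject) -> table assembly -> stats ->
#' mediate -> path, writing every stage's outputs and a JSON run manifest
#' (inputs, config, seeds, package version, per-file checksums) into
#' `config$out_dir`. The run is deterministic: identical config and seed
#' reproduce bitwise-identical outputs and manifest.
#'
#' The assembled cohort table carries each subject's *segmented* phantom
#' WMH volume in `wmh_cc` (the generative volume is kept in
#' `wmh_cc_generated`), so downstream statistics exercise the imaging arm
#' end to end; in a noise-free run the segmented volume equals the
#' phantom's ground truth exactly.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path) && !config$force) {
    stop(sprintf(
      "output directory '%s' already holds a completed run; use force = TRUE",
      out), call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)

  # -- stage: simulate cohort ------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$cohort_csv)) {
      read_biomarker_table(config$cohort_csv)
    } else {
      make_cohort(cohort_spec(n = config$n_subjects, seed = config$seed))
    }
  })

  # -- stage: segment phantoms ----------------------------------------------
  seg <- run_stage("segment", {
    ip <- if (config$noise_free) {
      list(background = c(30, 0), wm = c(100, 0), lesion = c(170, 0))
    } else {
      list(background = c(30, 10), wm = c(100, 5), lesion = c(170, 5))
    }
    masks <- vector("list", nrow(cohort))
    true_cc <- seg_cc <- numeric(nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      r <- lesion_radius_mm(config$lesion_volume_scale * cohort$wmh_cc[i])
      sp <- phantom_spec(
        shape = config$phantom_shape, intensity_params = ip,
        lesions = NULL, seed = config$seed + i
      )
      # mid-WM placement on the ventricular side: keeps the lesion clear of
      # the WM boundary shell so contour cleanup never clips true lesion
      geo <- phantom_geometry(sp)
      sp$lesions <- list(list(
        centre = c((geo$cav_ax[1] + geo$wm_ax[1]) / 2, 0, 0), radius_mm = r
      ))
      ph <- make_phantom(sp)
      res <- segment_wmh(ph$flair, ph$wm_mask)
      masks[[i]] <- res$mask
      true_cc[i] <- ph$true_volume_cc
      seg_cc[i] <- res$volume_cc
      if (config$write_volumes) {
        p <- file.path(out, sprintf("wmh_mask_%03d.nii.gz", i))
        write_volume(res$mask, p); add_file(p)
      }
    }
    list(masks = masks, true_cc = true_cc, seg_cc = seg_cc)
  })

  # -- stage: frequency map --------------------------------------------------
  run_stage("freqmap", {
    fmap <- build_frequency_map(seg$masks)
    p <- file.path(out, "wmh_frequency_map.nii.gz")
    write_volume(fmap, p); add_file(p)
  })

  # -- stage: table assembly -------------------------------------------------
  cohort <- run_stage("assemble", {
    cohort$wmh_cc_generated <- cohort$wmh_cc
    cohort$wmh_cc_true_phantom <- seg$true_cc
    cohort$wmh_cc <- seg$seg_cc
    cohort <- residualize_age(cohort)
    p <- file.path(out, "cohort.csv")
    utils::write.csv(cohort, p, row.names = FALSE); add_file(p)
    cohort
  })

  # -- stage: stats ----------------------------------------------------------
  run_stage("stats", {
    ct <- correlation_table(cohort)
    p <- file.path(out, "correlation_table.tsv")
    utils::write.table(ct, p, sep = "\t", row.names = FALSE, quote = FALSE)
    add_file(p)
    im <- fit_interaction_model(cohort)
    p2 <- file.path(out, "interaction_model.json")
    jsonlite::write_json(
      list(coefficients = as.list(im$coefficients),
           conditional_slopes = im$conditional_slopes, n = im$n),
      p2, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    add_file(p2)
  })

  # -- stage: mediate --------------------------------------------------------
  run_stage("mediate", {
    suite <- run_mediation_suite(cohort, n_sims = config$n_sims,
                                 seed = config$seed)
    p <- file.path(out, "mediation_suite.tsv")
    utils::write.table(mediation_summary(suite), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    add_file(p)
  })

  # -- stage: path -----------------------------------------------------------
  run_stage("path", {
    sp <- path_spec(default_cascade_edges(),
                    bootstrap_n = config$bootstrap_n, seed = config$seed)
    fit <- fit_path_model(cohort, sp)
    p <- file.path(out, "path_model.json")
    jsonlite::write_json(
      list(stratum = fit$stratum, n = fit$n,
           coefficients = as.list(fit$coefficients),
           std_errors = as.list(fit$std_errors),
           coefficients_std = as.list(fit$coefficients_std),
           indirect_effects = fit$indirect_effects,
           total_effects = fit$total_effects),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    add_file(p)
    p2 <- file.path(out, "path_model.dot")
    export_path_dot(fit, p2); add_file(p2)
  })

  # -- manifest --------------------------------------------------------------
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # keep manifests location-independent
  manifest <- list(
    package = "dswmh",
    version = as.character(utils::packageVersion("dswmh")),
    seed = config$seed,
    config = cfg,
    stages = c("simulate", "segment", "freqmap", "assemble", "stats",
               "mediate", "path"),
    n_subjects = nrow(cohort),
    outputs = lapply(sort(files), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
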