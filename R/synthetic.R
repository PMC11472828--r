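#' Specification of a synthetic FLAIR phantom
#'
#' Describes a FLAIR-like test volume: a centred white-matter ellipsoid with
#' a ventricle-like central cavity, spherical hyperintense lesions (by
#' default placed against the cavity wall, emulating the periventricular
#' distribution of WMH), per-compartment Gaussian intensities, optional
#' additional global noise and an optional low-order multiplicative bias
#' field.
#'
#' @param shape integer triple of voxel counts (default 64^3).
#' @param voxel_dims_mm voxel edge lengths in mm (default 1 mm isotropic).
#' @param wm_semiaxes_frac semi-axes of the WM ellipsoid as fractions of the
#'   half-extent per axis.
#' @param cavity_semiaxes_frac semi-axes of the central cavity, same units.
#' @param intensity_params list of `c(mean, sd)` per compartment:
#'   `background` (also fills the cavity, as CSF is suppressed on FLAIR),
#'   `wm`, `lesion`. Defaults 30/10, 100/5, 170/5.
#' @param lesions list of `list(centre = c(x, y, z), radius_mm = r)` spheres
#'   in mm relative to the volume centre, or `NULL` for two default
#'   periventricular spheres.
#' @param noise_sd additional global Gaussian noise SD (default 0; the
#'   per-compartment SDs are the primary noise source).
#' @param bias_amplitude amplitude of a multiplicative first-order polynomial
#'   bias field `1 + a * g(x)` with `g` in `[-1, 1]` (default 0).
#' @param seed RNG seed; phantoms are bitwise reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_dims_mm = c(1, 1, 1),
                         wm_semiaxes_frac = c(0.80, 0.84, 0.76),
                         cavity_semiaxes_frac = c(0.22, 0.32, 0.22),
                         intensity_params = list(background = c(30, 10),
                                                 wm = c(100, 5),
                                                 lesion = c(170, 5)),
                         lesions = NULL, noise_sd = 0, bias_amplitude = 0,
                         seed = 1) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("phantom shape must be at least 8 per axis", call. = FALSE)
  ip <- intensity_params
  if (!(ip$background[1] < ip$wm[1] && ip$wm[1] < ip$lesion[1])) {
    stop("intensity means must be ordered background < wm < lesion", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_dims_mm = as.numeric(voxel_dims_mm),
         wm_semiaxes_frac = wm_semiaxes_frac,
         cavity_semiaxes_frac = cavity_semiaxes_frac,
         intensity_params = ip, lesions = lesions,
         noise_sd = noise_sd, bias_amplitude = bias_amplitude,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# physical (mm) coordinates of voxel centres relative to the volume centre
phantom_coords <- function(shape, vox) {
  half <- shape * vox / 2
  list(
    x = (seq_len(shape[1]) - 0.5) * vox[1] - half[1],
    y = (seq_len(shape[2]) - 0.5) * vox[2] - half[2],
    z = (seq_len(shape[3]) - 0.5) * vox[3] - half[3],
    half = half
  )
}

# semi-axes in mm
phantom_geometry <- function(spec) {
  co <- phantom_coords(spec$shape, spec$voxel_dims_mm)
  list(
    coords = co,
    wm_ax = spec$wm_semiaxes_frac * co$half,
    cav_ax = spec$cavity_semiaxes_frac * co$half
  )
}

#' Generate a synthetic FLAIR phantom with known lesion ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List with `flair` ([volume_grid()]), `wm_mask`, `lesion_truth`
#'   (both [binary_mask()]), `true_volume_cc` (exact rasterised lesion
#'   volume) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), seed = 7))
#' ph$true_volume_cc
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  co <- geo$coords
  d <- spec$shape

  ell <- function(ax) {
    outer(outer((co$x / ax[1])^2, (co$y / ax[2])^2, "+"), (co$z / ax[3])^2, "+")
  }
  wm_region <- ell(geo$wm_ax) <= 1 & ell(geo$cav_ax) > 1

  lesions <- spec$lesions
  if (is.null(lesions)) {
    # two periventricular spheres against the cavity wall, +/- x
    r <- 0.09 * min(d * spec$voxel_dims_mm)
    lesions <- list(
      list(centre = c(geo$cav_ax[1] + r, 0, 0), radius_mm = r),
      list(centre = c(-(geo$cav_ax[1] + r), 0, 0), radius_mm = r)
    )
  }

  lesion <- array(FALSE, d)
  for (ls in lesions) {
    cc <- ls$centre
    d2 <- outer(outer((co$x - cc[1])^2, (co$y - cc[2])^2, "+"),
                (co$z - cc[3])^2, "+")
    sph <- d2 <= ls$radius_mm^2
    inside <- sph & wm_region
    if (!any(inside)) {
      stop("invalid phantom spec: lesion sphere lies outside the WM region",
           call. = FALSE)
    }
    lesion <- lesion | inside
  }

  base <- array(spec$intensity_params$background[1], d)
  base[wm_region] <- spec$intensity_params$wm[1]
  base[lesion] <- spec$intensity_params$lesion[1]
  sds <- array(spec$intensity_params$background[2], d)
  sds[wm_region] <- spec$intensity_params$wm[2]
  sds[lesion] <- spec$intensity_params$lesion[2]

  if (spec$bias_amplitude > 0) {
    g <- outer(outer(co$x / co$half[1], 0.6 * co$y / co$half[2], "+"),
               0.3 * co$z / co$half[3], "+") / 1.9
    base <- base * (1 + spec$bias_amplitude * g)
  }

  set.seed(spec$seed)
  vals <- base + stats::rnorm(prod(d), 0, 1) * sds
  if (spec$noise_sd > 0) vals <- vals + stats::rnorm(prod(d), 0, spec$noise_sd)
  flair <- volume_grid(array(vals, d), spec$voxel_dims_mm)

  n_lesion <- sum(lesion)
  list(
    flair = flair,
    wm_mask = binary_mask(wm_region, spec$voxel_dims_mm),
    lesion_truth = binary_mask(lesion, spec$voxel_dims_mm),
    true_volume_cc = n_lesion * prod(spec$voxel_dims_mm) / 1000,
    spec = spec
  )
}

#' Specification of a synthetic biomarker cohort
#'
#' Generates per-subject tables from a linear Gaussian structural cascade
#' age -> WMH -> GFAP -> p-tau217 -> NfL (with the configurable direct edges
#' WMH -> p-tau217, WMH -> NfL and GFAP -> NfL), additive per-site shifts
#' shared across a subject's markers, and diagnosis strata with optional
#' per-stratum coefficient overrides. The plasma amyloid ratio is generated
#' as an independent near-constant channel: its dynamic range plateaus in
#' adults with Down syndrome, so it carries essentially no association with
#' the cascade.
#'
#' Default effect sizes put whole-sample correlations of cascade neighbours
#' in the 0.3-0.6 band; default stratum proportions are 137/24/16/8 of 185
#' (cognitively stable / MCI / DS-AD / undetermined).
#'
#' @param n number of subjects (default 185).
#' @param seed RNG seed.
#' @param coefficients named vector of structural coefficients on the raw
#'   measurement scales: `age_wmh` (cc per year), `wmh_gfap`, `wmh_ptau`,
#'   `gfap_ptau`, `ptau_nfl`, `wmh_nfl`, `gfap_nfl`.
#' @param noise_sds named vector of per-equation residual SDs
#'   (`wmh`, `gfap`, `ptau`, `nfl`).
#' @param base_levels named vector of intercept levels at the mean age
#'   (`wmh` cc, `gfap`, `ptau`, `nfl` in assay units).
#' @param age_dist `c(mean, sd)` of age in years (default 45.2, 9.3).
#' @param n_sites number of research sites.
#' @param site_effects list of per-variable shift vectors of length
#'   `n_sites` (`wmh`, `gfap`, `ptau`, `nfl`), or `NULL` for small defaults.
#' @param strata list with `proportions` (named, summing to 1 over the four
#'   diagnosis levels) and optional `overrides`: a named list mapping a
#'   diagnosis level to a named coefficient vector replacing entries of
#'   `coefficients` within that stratum.
#' @param abeta_ratio `c(mean, sd)` of the independent amyloid 42/40 ratio.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 185, seed = 1,
                        coefficients = c(age_wmh = 0.15, wmh_gfap = 12,
                                         wmh_ptau = 0.015, gfap_ptau = 0.001,
                                         ptau_nfl = 18, wmh_nfl = 1.2,
                                         gfap_nfl = 0.04),
                        noise_sds = c(wmh = 2, gfap = 45, ptau = 0.1, nfl = 6),
                        base_levels = c(wmh = 6, gfap = 180, ptau = 0.6,
                                        nfl = 30),
                        age_dist = c(45.2, 9.3),
                        n_sites = 4, site_effects = NULL,
                        strata = list(proportions = c(
                          cognitively_stable = 137, MCI = 24, DS_AD = 16,
                          undetermined = 8) / 185),
                        abeta_ratio = c(0.065, 0.008)) {
  if (n < 1) stop("invalid cohort spec: n must be >= 1", call. = FALSE)
  if (any(noise_sds <= 0)) {
    stop("invalid cohort spec: noise_sds must be positive", call. = FALSE)
  }
  pr <- strata$proportions
  if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
    stop("invalid cohort spec: stratum proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!all(names(pr) %in% diagnosis_levels())) {
    stop("invalid cohort spec: unknown diagnosis level in proportions",
         call. = FALSE)
  }
  if (is.null(site_effects)) {
    site_effects <- list(
      wmh = c(0, 0.3, -0.2, 0.1), gfap = c(0, 8, -5, 3),
      ptau = c(0, 0.02, -0.01, 0.01), nfl = c(0, 1.5, -1, 0.5)
    )
    site_effects <- lapply(site_effects, function(v) {
      rep_len(v, n_sites)
    })
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         coefficients = coefficients, noise_sds = noise_sds,
         base_levels = base_levels, age_dist = age_dist,
         n_sites = as.integer(n_sites), site_effects = site_effects,
         strata = strata, abeta_ratio = abeta_ratio),
    class = "cohort_spec"
  )
}

#' The four clinical diagnosis levels
#'
#' @return Character vector: cognitively stable, MCI, Down syndrome
#'   Alzheimer's disease, and undetermined.
#' @export
diagnosis_levels <- function() {
  c("cognitively_stable", "MCI", "DS_AD", "undetermined")
}

#' Generate a synthetic biomarker cohort table
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` in the shared cohort schema: `subject_id`, `age`,
#'   `sex`, `site`, `diagnosis`, `wmh_cc`, `abeta42`, `abeta40`,
#'   `abeta42_40`, `ptau217`, `gfap`, `nfl`.
#' @examples
#' head(make_cohort(cohort_spec(n = 20, seed = 3)))
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  cf0 <- spec$coefficients
  ns <- spec$noise_sds
  b0 <- spec$base_levels

  age <- stats::rnorm(n, spec$age_dist[1], spec$age_dist[2])
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.44, 0.56))
  site <- sample(paste0("site", seq_len(spec$n_sites)), n, replace = TRUE)
  site_i <- as.integer(sub("site", "", site))
  pr <- spec$strata$proportions
  diagnosis <- sample(names(pr), n, replace = TRUE, prob = pr)

  # per-subject coefficient matrix honouring stratum overrides
  cf <- matrix(cf0, nrow = n, ncol = length(cf0), byrow = TRUE,
               dimnames = list(NULL, names(cf0)))
  ov <- spec$strata$overrides
  if (!is.null(ov)) {
    for (dg in names(ov)) {
      rows <- diagnosis == dg
      for (cn in names(ov[[dg]])) cf[rows, cn] <- ov[[dg]][[cn]]
    }
  }

  se <- spec$site_effects
  age_c <- age - spec$age_dist[1]
  wmh <- b0["wmh"] + cf[, "age_wmh"] * age_c + se$wmh[site_i] +
    stats::rnorm(n, 0, ns["wmh"])
  gfap <- b0["gfap"] + cf[, "wmh_gfap"] * (wmh - b0["wmh"]) +
    se$gfap[site_i] + stats::rnorm(n, 0, ns["gfap"])
  ptau <- b0["ptau"] + cf[, "wmh_ptau"] * (wmh - b0["wmh"]) +
    cf[, "gfap_ptau"] * (gfap - b0["gfap"]) + se$ptau[site_i] +
    stats::rnorm(n, 0, ns["ptau"])
  nfl <- b0["nfl"] + cf[, "ptau_nfl"] * (ptau - b0["ptau"]) +
    cf[, "wmh_nfl"] * (wmh - b0["wmh"]) +
    cf[, "gfap_nfl"] * (gfap - b0["gfap"]) + se$nfl[site_i] +
    stats::rnorm(n, 0, ns["nfl"])

  ratio <- stats::rnorm(n, spec$abeta_ratio[1], spec$abeta_ratio[2])
  abeta40 <- stats::rnorm(n, 250, 30)
  abeta42 <- ratio * abeta40

  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, site = site,
    diagnosis = factor(diagnosis, levels = diagnosis_levels()),
    wmh_cc = unname(wmh), abeta42 = abeta42, abeta40 = abeta40,
    abeta42_40 = ratio, ptau217 = unname(ptau), gfap = unname(gfap),
    nfl = unname(nfl),
    stringsAsFactors = FALSE
  )
}
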