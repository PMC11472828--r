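# shared fixtures: everything is generated in code, no stored data

dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# zero-variance compartments: perfectly separated intensity supports
noise_free_params <- function() {
  list(background = c(30, 0), wm = c(100, 0), lesion = c(170, 0))
}

# 64^3 phantom with a lattice-aligned interior sphere (radius 5 mm, 515
# voxels), at least 2 voxels clear of the WM boundary everywhere
interior_phantom_spec <- function(seed = 1, noise_free = TRUE) {
  phantom_spec(
    intensity_params = if (noise_free) noise_free_params() else
      list(background = c(30, 10), wm = c(100, 5), lesion = c(170, 5)),
    lesions = list(list(centre = c(17.5, 0.5, 0.5), radius_mm = 5)),
    seed = seed
  )
}

# simple mediation triple T -> M -> Y with configurable coefficients
make_mediation_data <- function(n, a, b, d, seed, noise = 1) {
  set.seed(seed)
  tr <- stats::rnorm(n)
  m <- a * tr + stats::rnorm(n, 0, noise)
  y <- d * tr + b * m + stats::rnorm(n, 0, noise)
  data.frame(T = tr, M = m, Y = y)
}

# noisy 3-node chain A -> B -> C for the path engine
make_chain_data <- function(n, b_ab, b_bc, seed, noise = 1) {
  set.seed(seed)
  a <- stats::rnorm(n)
  b <- b_ab * a + stats::rnorm(n, 0, noise)
  c_ <- b_bc * b + stats::rnorm(n, 0, noise)
  data.frame(A = a, B = b, C = c_)
}

# cohort generated by the pure hypothesised chain wmh -> gfap -> ptau -> nfl
chain_cohort_spec <- function(n, seed) {
  cohort_spec(
    n = n, seed = seed,
    coefficients = c(age_wmh = 0, wmh_gfap = 12, wmh_ptau = 0,
                     gfap_ptau = 0.001, ptau_nfl = 18, wmh_nfl = 0,
                     gfap_nfl = 0)
  )
}

# default cascade but age-free, so generating coefficients survive the
# age-residualisation of the outcome unchanged
ageless_cascade_spec <- function(n, seed) {
  cohort_spec(
    n = n, seed = seed,
    coefficients = c(age_wmh = 0, wmh_gfap = 12, wmh_ptau = 0.015,
                     gfap_ptau = 0.001, ptau_nfl = 18, wmh_nfl = 1.2,
                     gfap_nfl = 0.04)
  )
}
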