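test_that("percentile thresholds follow the linear-rank convention and the IPR relaxation formula", {
  v <- volume_grid(array(c(0:100, rep(0, 24)), c(5, 5, 5)))
  m <- binary_mask(array(c(rep(TRUE, 101), rep(FALSE, 24)), c(5, 5, 5)))
  thr <- compute_histogram_thresholds(v, m, p_bright = 95, p_brightest = 99,
                                      relaxation_factor = 10)
  expect_equal(thr$t_bright, 95)
  expect_equal(thr$t_brightest, 99)
  expect_equal(thr$ipr, 4)
  expect_equal(thr$t_relaxed, 94.6)

  # degenerate constant histogram
  vc <- volume_grid(array(5, c(3, 3, 3)))
  mc <- binary_mask(array(TRUE, c(3, 3, 3)))
  thc <- compute_histogram_thresholds(vc, mc)
  expect_equal(thc$ipr, 0)
  expect_equal(thc$t_relaxed, thc$t_bright)

  # sort-and-rank oracle on a mixture sample
  set.seed(11)
  x <- c(rnorm(9500, 100, 10), rnorm(500, 170, 12))
  s <- sort(x)
  rank_quantile <- function(p) {
    h <- (length(s) - 1) * p / 100 + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  th <- dswmh:::percentile_thresholds(x, 95, 99.5, 10)
  expect_equal(th$t_bright, rank_quantile(95), tolerance = 1e-9)
  expect_equal(th$t_brightest, rank_quantile(99.5), tolerance = 1e-9)

  expect_error(compute_histogram_thresholds(v, binary_mask(array(FALSE, c(5, 5, 5)))),
               "empty")
  expect_error(dswmh:::percentile_thresholds(x, 99, 95), "percentiles")
})

test_that("EM separates point-mass clusters exactly and labels the brighter component hyperintense", {
  fit <- fit_gmm_em(c(0, 0, 0, 10, 10, 10), init = 5)
  expect_equal(fit$means, c(0, 10), tolerance = 1e-9)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(fit$posterior, c(0, 0, 0, 1, 1, 1), tolerance = 1e-9)
  expect_false(fit$fallback)

  # init outside the data range forces the documented median fallback
  expect_message(
    fit2 <- fit_gmm_em(c(1, 1, 1, 2, 2), init = -5),
    "fell back"
  )
  expect_true(fit2$fallback)
  expect_equal(fit2$means, c(1, 2), tolerance = 1e-6)

  expect_error(fit_gmm_em(rep(3, 10), init = 3), "distinct")
  expect_error(fit_gmm_em(c(1, 2), init = 1.5, max_iter = 0), "max_iter")
  expect_error(fit_gmm_em(c(1, 2), init = 1.5, tol = 0), "tol")
})

test_that("EM log-likelihood is non-decreasing on randomly generated mixtures", {
  for (s in 1:20) {
    set.seed(s)
    w2 <- runif(1, 0.02, 0.4)
    x <- c(rnorm(round(2000 * (1 - w2)), 100, runif(1, 3, 15)),
           rnorm(round(2000 * w2), 150 + runif(1, 0, 40), runif(1, 3, 15)))
    fit <- suppressMessages(fit_gmm_em(x, init = quantile(x, 0.9)))
    expect_true(all(diff(fit$log_likelihood_trace) >= -1e-8))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(fit$variances > 0))
    expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  }
})

test_that("EM recovers generating parameters at n = 20000 and agrees with an independent mixture fitter", {
  set.seed(2024)
  n <- 20000
  n2 <- rbinom(1, n, 0.03)
  x <- c(rnorm(n - n2, 100, 10), rnorm(n2, 170, 12))
  thr <- dswmh:::percentile_thresholds(x, 95, 99.5, 10)
  fit <- fit_gmm_em(x, thr)
  expect_lt(abs(fit$means[1] - 100), 2)
  expect_lt(abs(fit$means[2] - 170), 2)
  expect_lt(abs(fit$weights[2] - 0.03), 0.01)

  # independent EM implementation as cross-check
  library(mclust, quietly = TRUE, warn.conflicts = FALSE)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.5)
})

test_that("labelling applies the >= cutoff inside the WM mask only", {
  wm <- binary_mask(array(c(rep(TRUE, 3), FALSE), c(2, 2, 1)))
  pm <- volume_grid(array(c(0.2, 0.5, 0.9, 1.0), c(2, 2, 1)))
  lab <- label_wmh(pm, wm, 0.5)
  expect_identical(as.vector(lab$data), c(FALSE, TRUE, TRUE, FALSE))

  zeros <- volume_grid(array(0, c(2, 2, 1)))
  expect_equal(sum(label_wmh(zeros, wm)$data), 0)
  ones <- volume_grid(array(1, c(2, 2, 1)))
  expect_identical(label_wmh(ones, wm)$data, wm$data)

  expect_error(label_wmh(pm, wm, 0), "prob_cutoff")
  wm_bad <- binary_mask(array(TRUE, c(2, 2, 2)))
  expect_error(label_wmh(pm, wm_bad), "mismatch")
})

test_that("edge cleanup removes exactly the detected contour voxels on the WM shell", {
  d <- c(16, 16, 16)
  wm <- array(FALSE, d); wm[4:12, 4:12, 4:12] <- TRUE

  # interior lesion (>= 2 voxels from the WM boundary): untouched
  les <- array(FALSE, d); les[7:9, 7:9, 7:9] <- TRUE
  pm <- volume_grid(array(as.numeric(les), d))
  out <- edge_cleanup(binary_mask(les), pm, binary_mask(wm))
  expect_identical(out$data, les)

  # scattered labelled voxels on the WM shell: all removed
  shell_pts <- array(FALSE, d)
  shell_pts[4, 6, 6] <- TRUE; shell_pts[12, 8, 9] <- TRUE
  shell_pts[8, 4, 10] <- TRUE; shell_pts[10, 12, 5] <- TRUE
  pm2 <- volume_grid(array(as.numeric(shell_pts), d))
  out2 <- edge_cleanup(binary_mask(shell_pts), pm2, binary_mask(wm))
  expect_equal(sum(out2$data), 0)

  # cube lesion touching one WM face: removed voxels are exactly the
  # brute-force (lesion AND WM-boundary) set
  cube <- array(FALSE, d); cube[4:6, 7:9, 7:9] <- TRUE
  pm3 <- volume_grid(array(as.numeric(cube), d))
  out3 <- edge_cleanup(binary_mask(cube), pm3, binary_mask(wm))
  boundary <- array(FALSE, d)
  for (i in 4:12) for (j in 4:12) for (k in 4:12) {
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_b <- FALSE
    for (q in 1:6) {
      p <- nb[q, ]
      if (any(p < 1) || any(p > d) || !wm[p[1], p[2], p[3]]) on_b <- TRUE
    }
    boundary[i, j, k] <- wm[i, j, k] && on_b
  }
  expect_identical(out3$data, cube & !(cube & boundary))
  expect_true(all(out3$data <= cube))
})

test_that("volume computation is exact voxel bookkeeping", {
  m1 <- binary_mask(array(c(rep(TRUE, 1000), rep(FALSE, 728)), c(12, 12, 12)))
  expect_equal(compute_wmh_volume(m1),
               list(n_voxels = 1000L, volume_cc = 1))
  m0 <- binary_mask(array(FALSE, c(4, 4, 4)))
  expect_equal(compute_wmh_volume(m0)$volume_cc, 0)
  m2 <- binary_mask(array(c(rep(TRUE, 250), rep(FALSE, 750)), c(10, 10, 10)),
                    c(2, 2, 1))
  expect_identical(compute_wmh_volume(m2)$volume_cc, 1)
})

test_that("noise-free segmentation recovers an interior lesion exactly", {
  ph <- make_phantom(interior_phantom_spec(seed = 3))
  expect_equal(sum(ph$lesion_truth$data), 515)
  # point-mass intensities force the documented median-split fallback
  res <- suppressMessages(segment_wmh(ph$flair, ph$wm_mask))
  expect_identical(res$mask$data, ph$lesion_truth$data)
  expect_identical(res$volume_cc, ph$true_volume_cc)
  expect_identical(res$volume_cc, 0.515)
})

test_that("a lesion-free noise-free phantom yields zero volume", {
  sp <- phantom_spec(intensity_params = noise_free_params(),
                     lesions = list(), seed = 5)
  ph <- make_phantom(sp)
  expect_equal(sum(ph$lesion_truth$data), 0)
  res <- segment_wmh(ph$flair, ph$wm_mask)
  expect_equal(res$volume_cc, 0)
  expect_equal(res$n_voxels, 0L)
})

test_that("noisy segmentation is accurate, deterministic, affine-invariant and respects the WM mask", {
  ph <- make_phantom(phantom_spec(seed = 17))
  res <- segment_wmh(ph$flair, ph$wm_mask)

  expect_gte(dice(res$mask$data, ph$lesion_truth$data), 0.90)
  expect_lt(abs(res$volume_cc - ph$true_volume_cc) / ph$true_volume_cc, 0.10)

  # mask subset of WM; exact volume identity
  expect_true(all(!res$mask$data | ph$wm_mask$data))
  expect_identical(res$volume_cc,
                   res$n_voxels * prod(res$mask$voxel_dims_mm) / 1000)

  # determinism
  res2 <- segment_wmh(ph$flair, ph$wm_mask)
  expect_identical(res$mask$data, res2$mask$data)

  # invariance under a strictly monotone affine intensity rescale
  fl_aff <- volume_grid(2.5 * ph$flair$data - 40, ph$flair$voxel_dims_mm)
  res3 <- segment_wmh(fl_aff, ph$wm_mask)
  expect_identical(res$mask$data, res3$mask$data)
})

test_that("segmentation records full provenance", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), seed = 2))
  cfg <- wmh_config(p_bright = 94, prob_cutoff = 0.6)
  res <- segment_wmh(ph$flair, ph$wm_mask, cfg)
  expect_s3_class(res$thresholds, "histogram_thresholds")
  expect_s3_class(res$gmm, "gmm_fit")
  expect_equal(res$config$p_bright, 94)
  expect_gte(res$gmm$n_iter, 1)
})
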