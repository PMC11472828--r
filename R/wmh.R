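#' Percentile thresholds of the white-matter intensity histogram
#'
#' Two percentile thresholds are extracted from the FLAIR intensity histogram
#' inside the white-matter segment: one for the dark-to-bright transition and
#' one for the bright-to-brightest transition. Their difference is the
#' inter-percentile range (IPR). To tolerate scan-quality variation, a relaxed
#' threshold is derived by subtracting a multiplicative fraction of the IPR
#' from the bright threshold:
#' `t_relaxed = t_bright - ipr * relaxation_factor / 100`.
#'
#' Percentiles use the linear-interpolation-between-closest-ranks convention
#' (`stats::quantile(type = 7)`).
#'
#' @param volume FLAIR [volume_grid()].
#' @param wm_mask white-matter [binary_mask()] on the same grid.
#' @param p_bright percentile (0-100) of the dark/bright transition.
#' @param p_brightest percentile (0-100) of the bright/brightest transition;
#'   must exceed `p_bright`.
#' @param relaxation_factor relaxation expressed as a percentage of the IPR
#'   (default 10).
#' @return A `histogram_thresholds` object with fields `t_bright`,
#'   `t_brightest`, `ipr`, `relaxation_factor`, `t_relaxed`.
#' @examples
#' v <- volume_grid(array(0:124, c(5, 5, 5)))
#' m <- binary_mask(array(TRUE, c(5, 5, 5)))
#' compute_histogram_thresholds(v, m)
#' @export
compute_histogram_thresholds <- function(volume, wm_mask, p_bright = 95,
                                         p_brightest = 99.5,
                                         relaxation_factor = 10) {
  check_aligned(volume, wm_mask, "volume and WM mask")
  vals <- volume$data[wm_mask$data]
  if (length(vals) == 0L) {
    stop("empty white-matter mask: no intensities to threshold", call. = FALSE)
  }
  percentile_thresholds(vals, p_bright, p_brightest, relaxation_factor)
}

# vector-level worker shared with fit_gmm_em initialisation
percentile_thresholds <- function(values, p_bright = 95, p_brightest = 99.5,
                                  relaxation_factor = 10) {
  if (!(p_bright > 0 && p_bright < p_brightest && p_brightest < 100)) {
    stop("percentiles must satisfy 0 < p_bright < p_brightest < 100",
         call. = FALSE)
  }
  qs <- unname(stats::quantile(values, c(p_bright, p_brightest) / 100,
                               names = FALSE, type = 7))
  ipr <- qs[2] - qs[1]
  structure(
    list(
      t_bright = qs[1], t_brightest = qs[2], ipr = ipr,
      relaxation_factor = relaxation_factor,
      t_relaxed = qs[1] - ipr * relaxation_factor / 100,
      p_bright = p_bright, p_brightest = p_brightest
    ),
    class = "histogram_thresholds"
  )
}

#' @export
print.histogram_thresholds <- function(x, ...) {
  cat(sprintf(
    "<histogram_thresholds> t_bright(p%g)=%.6g  t_brightest(p%g)=%.6g  IPR=%.6g  t_relaxed=%.6g\n",
    x$p_bright, x$t_bright, x$p_brightest, x$t_brightest, x$ipr, x$t_relaxed
  ))
  invisible(x)
}

# first split of the intensities whose two sides are both non-empty; the
# primary split is at t_relaxed, the documented fallback at the median
init_partition <- function(x, split) {
  candidates <- list(
    list(lo = x < split, at = "t_relaxed"),
    list(lo = x <= split, at = "t_relaxed"),
    list(lo = x < stats::median(x), at = "median"),
    list(lo = x <= stats::median(x), at = "median")
  )
  for (i in seq_along(candidates)) {
    lo <- candidates[[i]]$lo
    if (any(lo) && any(!lo)) {
      return(list(lo = lo, fallback = i > 2L, at = candidates[[i]]$at))
    }
  }
  stop("degenerate data: cannot form a two-group initial partition",
       call. = FALSE)
}

#' Two-component Gaussian mixture by expectation-maximisation
#'
#' Fits a univariate two-component Gaussian mixture to white-matter
#' intensities, representing non-hyperintense and hyperintense voxels. The EM
#' is initialised from the relaxed histogram threshold: initial component
#' means and weights come from the below/at-or-above partition of the
#' intensities at `t_relaxed` (falling back to a median split, with a
#' `fallback` flag and message, if one side is empty). Variances are floored
#' at `1e-6` times the overall intensity variance so point-mass clusters
#' remain well-defined. Iteration stops when the log-likelihood improves by
#' less than `tol` or after `max_iter` iterations; the log-likelihood is
#' non-decreasing by construction of EM.
#'
#' The component with the larger mean is labelled hyperintense, and
#' `posterior` holds each input value's posterior probability of membership
#' in it.
#'
#' @param intensities numeric vector with at least two distinct values.
#' @param init a `histogram_thresholds` object or a single numeric split
#'   value (used as `t_relaxed`).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @return A `gmm_fit` object: `means`, `variances`, `weights` (each ordered
#'   non-hyperintense then hyperintense), `log_likelihood_trace`,
#'   `posterior`, `n_iter`, `converged`, `fallback`.
#' @examples
#' fit <- fit_gmm_em(c(rnorm(300, 100, 5), rnorm(30, 170, 5)), init = 140)
#' fit$means
#' @export
fit_gmm_em <- function(intensities, init, max_iter = 200, tol = 1e-6) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("intensities must be finite", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate data: need at least 2 distinct intensity values",
         call. = FALSE)
  }
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  split <- if (inherits(init, "histogram_thresholds")) init$t_relaxed else as.numeric(init)

  part <- init_partition(x, split)
  if (part$fallback) {
    message("fit_gmm_em: empty partition at t_relaxed; fell back to ",
            part$at, " split")
  }
  var_floor <- 1e-6 * stats::var(x)

  n <- length(x)
  mu <- c(mean(x[part$lo]), mean(x[!part$lo]))
  w <- c(mean(part$lo), mean(!part$lo))
  sg2 <- pmax(c(stats::var(x[part$lo]), stats::var(x[!part$lo])), var_floor)
  sg2[is.na(sg2)] <- var_floor  # single-point partition has NA variance

  loglik <- function(mu, sg2, w) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(sg2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(sg2[2]))
    sum(log(d1 + d2))
  }

  trace <- numeric(0)
  resp <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities of component 2
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(sg2[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(sg2[2]), log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    trace <- c(trace, ll)
    resp <- 1 / (1 + exp(l1 - l2))
    if (iter > 1L && abs(trace[iter] - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    # M-step
    n2 <- sum(resp); n1 <- n - n2
    if (n1 < .Machine$double.eps || n2 < .Machine$double.eps) break
    mu <- c(sum((1 - resp) * x) / n1, sum(resp * x) / n2)
    sg2 <- pmax(
      c(sum((1 - resp) * (x - mu[1])^2) / n1,
        sum(resp * (x - mu[2])^2) / n2),
      var_floor
    )
    w <- c(n1, n2) / n
  }

  # hyperintense = larger mean; reorder so component 2 is hyperintense
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg2 <- rev(sg2); w <- rev(w); resp <- 1 - resp
  }
  structure(
    list(
      means = mu, variances = sg2, weights = w,
      log_likelihood_trace = trace, posterior = resp,
      n_iter = length(trace), converged = converged,
      fallback = part$fallback, var_floor = var_floor
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> means (%.4g, %.4g)  sds (%.4g, %.4g)  weights (%.4g, %.4g)  %d iter%s\n",
    x$means[1], x$means[2], sqrt(x$variances[1]), sqrt(x$variances[2]),
    x$weights[1], x$weights[2], x$n_iter,
    if (x$converged) " (converged)" else ""
  ))
  invisible(x)
}

#' Posterior hyperintensity probability map
#'
#' Spreads the per-voxel posterior probabilities of the hyperintense mixture
#' component back into the volume: probability inside the white-matter mask,
#' zero elsewhere.
#'
#' @param gmm a [fit_gmm_em()] result fitted on the WM-interior intensities
#'   of `wm_mask` (in array order).
#' @param wm_mask white-matter [binary_mask()].
#' @return A [volume_grid()] probability map in `[0, 1]`.
#' @export
probability_map <- function(gmm, wm_mask) {
  if (length(gmm$posterior) != sum(wm_mask$data)) {
    stop("shape mismatch: GMM was not fitted on this WM mask's intensities",
         call. = FALSE)
  }
  p <- array(0, dim = wm_mask$shape)
  p[wm_mask$data] <- gmm$posterior
  volume_grid(p, wm_mask$voxel_dims_mm)
}

#' Label hyperintense voxels
#'
#' A voxel is labelled WMH iff it lies inside the white-matter mask and its
#' posterior hyperintensity probability is at or above `prob_cutoff` (ties
#' labelled).
#'
#' @param prob_map posterior probability [volume_grid()].
#' @param wm_mask white-matter [binary_mask()] on the same grid.
#' @param prob_cutoff probability cutoff in (0, 1), default 0.5.
#' @return A [binary_mask()], guaranteed a subset of `wm_mask`.
#' @export
label_wmh <- function(prob_map, wm_mask, prob_cutoff = 0.5) {
  if (!(prob_cutoff > 0 && prob_cutoff < 1)) {
    stop("`prob_cutoff` must be in (0, 1)", call. = FALSE)
  }
  check_aligned(prob_map, wm_mask, "probability map and WM mask")
  binary_mask(wm_mask$data & (prob_map$data >= prob_cutoff),
              wm_mask$voxel_dims_mm)
}

# 3D binary erosion with the 6-connected cross element; voxels outside the
# volume count as background, so WM touching the volume border is boundary
erode6 <- function(m) {
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  m & shift(m, 1, 1) & shift(m, 1, -1) &
    shift(m, 2, 1) & shift(m, 2, -1) &
    shift(m, 3, 1) & shift(m, 3, -1)
}

# Otsu threshold on a numeric vector (256-bin histogram, maximal
# between-class variance); returns -Inf when there is nothing to split
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || max(v) == min(v)) return(-Inf)
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = n_bins + 1L),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (tot_mu * w0[valid] - mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])
  h$breaks[which.max(between) + 1L]
}

# Roberts-cross edge voxels of a 3D map, detected per axial slice.
# Each 2x2 block (i..i+1, j..j+1) carries one gradient magnitude
# sqrt((p11-p22)^2 + (p21-p12)^2); blocks above an Otsu threshold over all
# block magnitudes mark all four participating voxels as edge, so both sides
# of a contour are flagged.
roberts_edges <- function(p) {
  d <- dim(p)
  if (d[1] < 2L || d[2] < 2L) return(array(FALSE, d))
  i <- 1:(d[1] - 1L); j <- 1:(d[2] - 1L)
  gx <- p[i, j, , drop = FALSE] - p[i + 1L, j + 1L, , drop = FALSE]
  gy <- p[i + 1L, j, , drop = FALSE] - p[i, j + 1L, , drop = FALSE]
  gmag <- sqrt(gx^2 + gy^2)
  thr <- otsu_threshold(as.numeric(gmag))
  hit <- gmag > thr   # (d1-1) x (d2-1) x d3 block indicator
  edge <- array(FALSE, d)
  edge[i, j, ] <- hit
  edge[i + 1L, j, ] <- edge[i + 1L, j, , drop = FALSE] | hit
  edge[i, j + 1L, ] <- edge[i, j + 1L, , drop = FALSE] | hit
  edge[i + 1L, j + 1L, ] <- edge[i + 1L, j + 1L, , drop = FALSE] | hit
  edge
}

#' Remove brain-contour voxels from a WMH mask (Roberts edge cleanup)
#'
#' Applies the Roberts cross operator slice-wise (axial, third axis) to the
#' probability map; 2x2 blocks whose gradient magnitude exceeds an Otsu
#' threshold over the magnitude distribution mark their voxels as edges.
#' Labelled voxels that are both edges and on the outermost white-matter
#' shell (the 1-voxel difference between the WM mask and its 6-connected
#' erosion) are removed, ensuring no non-white-matter contour voxels survive.
#' Lesions at least two voxels interior to the WM boundary are never touched.
#'
#' @param mask candidate WMH [binary_mask()].
#' @param prob_map posterior probability [volume_grid()].
#' @param wm_mask white-matter [binary_mask()].
#' @return A cleaned [binary_mask()], a subset of `mask`.
#' @export
edge_cleanup <- function(mask, prob_map, wm_mask) {
  check_aligned(mask, prob_map, "mask and probability map")
  check_aligned(mask, wm_mask, "mask and WM mask")
  edge <- roberts_edges(prob_map$data)
  shell <- wm_mask$data & !erode6(wm_mask$data)
  keep <- mask$data & !(edge & shell)
  binary_mask(keep, mask$voxel_dims_mm)
}

#' WMH voxel count and volume
#'
#' @param mask a [binary_mask()].
#' @return List with `n_voxels` and `volume_cc`
#'   (`n_voxels * prod(voxel_dims_mm) / 1000`, exact).
#' @examples
#' m <- binary_mask(array(c(rep(TRUE, 250), rep(FALSE, 750)), c(10, 10, 10)),
#'                  c(2, 2, 1))
#' compute_wmh_volume(m)  # 250 voxels x 4 mm^3 = 1 cc
#' @export
compute_wmh_volume <- function(mask) {
  n <- sum(mask$data)
  list(n_voxels = as.integer(n),
       volume_cc = n * prod(mask$voxel_dims_mm) / 1000)
}

#' Segmentation configuration
#'
#' Collects every tunable of [segment_wmh()] with the pipeline defaults.
#'
#' @param p_bright,p_brightest histogram percentiles (defaults 95 and 99.5).
#' @param relaxation_factor IPR relaxation percentage (default 10).
#' @param prob_cutoff posterior labelling cutoff (default 0.5).
#' @param max_iter,tol EM settings (defaults 200 and 1e-6).
#' @param target_shape optional integer triple; when given, FLAIR and mask
#'   are first resampled to this grid (e.g. `c(256, 256, 256)`).
#' @param target_voxel_mm voxel dims of the target grid (default 1 mm iso).
#' @param edge_cleanup logical; apply the Roberts contour cleanup (default
#'   `TRUE`).
#' @return A `wmh_config` list.
#' @export
wmh_config <- function(p_bright = 95, p_brightest = 99.5,
                       relaxation_factor = 10, prob_cutoff = 0.5,
                       max_iter = 200, tol = 1e-6,
                       target_shape = NULL, target_voxel_mm = c(1, 1, 1),
                       edge_cleanup = TRUE) {
  structure(
    list(
      p_bright = p_bright, p_brightest = p_brightest,
      relaxation_factor = relaxation_factor, prob_cutoff = prob_cutoff,
      max_iter = max_iter, tol = tol,
      target_shape = target_shape, target_voxel_mm = target_voxel_mm,
      edge_cleanup = edge_cleanup
    ),
    class = "wmh_config"
  )
}

#' Segment white matter hyperintensities from a FLAIR volume
#'
#' End-to-end WMH quantification: optional resampling to a uniform grid,
#' percentile thresholds of the WM intensity histogram, threshold-initialised
#' two-component Gaussian mixture EM on WM-interior intensities, posterior
#' probability map, cutoff labelling, Roberts-edge contour cleanup, and
#' volumetry in cubic centimetres. Deterministic given inputs and config.
#'
#' @param flair FLAIR [volume_grid()].
#' @param wm_mask white-matter [binary_mask()] on the same grid.
#' @param config a [wmh_config()].
#' @return A `wmh_result`: `mask`, `prob_map`, `n_voxels`, `volume_cc`,
#'   `thresholds`, `gmm`, `config`, `n_removed_edge` (voxels removed by the
#'   contour cleanup).
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), seed = 1))
#' res <- segment_wmh(ph$flair, ph$wm_mask)
#' res$volume_cc
#' @export
segment_wmh <- function(flair, wm_mask, config = wmh_config()) {
  check_aligned(flair, wm_mask, "FLAIR and WM mask")
  if (!is.null(config$target_shape)) {
    flair <- resample_to_grid(flair, config$target_shape,
                              config$target_voxel_mm, is_mask = FALSE)
    wm_mask <- resample_to_grid(wm_mask, config$target_shape,
                                config$target_voxel_mm, is_mask = TRUE)
  }
  thr <- compute_histogram_thresholds(
    flair, wm_mask,
    p_bright = config$p_bright, p_brightest = config$p_brightest,
    relaxation_factor = config$relaxation_factor
  )
  wm_vals <- flair$data[wm_mask$data]
  if (length(unique(wm_vals)) < 2L) {
    # constant WM histogram: no bright tail, hence no hyperintensities
    empty <- binary_mask(array(FALSE, flair$shape), flair$voxel_dims_mm)
    return(structure(
      list(mask = empty,
           prob_map = volume_grid(array(0, flair$shape), flair$voxel_dims_mm),
           n_voxels = 0L, volume_cc = 0, thresholds = thr, gmm = NULL,
           config = config, n_removed_edge = 0L),
      class = "wmh_result"
    ))
  }
  gmm <- fit_gmm_em(wm_vals, thr, max_iter = config$max_iter,
                    tol = config$tol)
  pmap <- probability_map(gmm, wm_mask)
  raw <- label_wmh(pmap, wm_mask, config$prob_cutoff)
  final <- if (isTRUE(config$edge_cleanup)) {
    edge_cleanup(raw, pmap, wm_mask)
  } else {
    raw
  }
  vol <- compute_wmh_volume(final)
  structure(
    list(
      mask = final, prob_map = pmap,
      n_voxels = vol$n_voxels, volume_cc = vol$volume_cc,
      thresholds = thr, gmm = gmm, config = config,
      n_removed_edge = sum(raw$data) - vol$n_voxels
    ),
    class = "wmh_result"
  )
}

#' @export
print.wmh_result <- function(x, ...) {
  cat(sprintf(
    "<wmh_result> %d WMH voxels = %.3f cc  (EM %d iter, %d contour voxels removed)\n",
    x$n_voxels, x$volume_cc, x$gmm$n_iter, x$n_removed_edge
  ))
  invisible(x)
}
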