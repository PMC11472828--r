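#' 3D image volume with voxel dimensions
#'
#' A `volume_grid` is the carrier for FLAIR intensities, probability maps and
#' frequency maps: a 3D numeric array plus the physical voxel edge lengths in
#' millimetres. All pipeline stages operate on this container; NIfTI files are
#' converted to and from it at the I/O boundary.
#'
#' @param data 3D numeric array of finite values.
#' @param voxel_dims_mm numeric triple of positive voxel edge lengths (mm).
#' @return An object of class `volume_grid` with elements `data`,
#'   `voxel_dims_mm` and `shape`.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
#' v$shape
#' @export
volume_grid <- function(data, voxel_dims_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  voxel_dims_mm <- as.numeric(voxel_dims_mm)
  if (length(voxel_dims_mm) != 3L || any(!is.finite(voxel_dims_mm)) ||
      any(voxel_dims_mm <= 0)) {
    stop("`voxel_dims_mm` must be three positive finite numbers", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume intensities must be finite everywhere", call. = FALSE)
  }
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_dims_mm = voxel_dims_mm, shape = dim(data)),
    class = "volume_grid"
  )
}

#' Binary mask aligned with a volume
#'
#' @param data 3D logical (or 0/1) array.
#' @param voxel_dims_mm numeric triple of positive voxel edge lengths (mm).
#' @return An object of class `binary_mask` with elements `data` (logical),
#'   `voxel_dims_mm` and `shape`.
#' @examples
#' m <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
#' sum(m$data)
#' @export
binary_mask <- function(data, voxel_dims_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("mask values must be 0/1 or logical", call. = FALSE)
    }
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask values must be 0/1 or logical", call. = FALSE)
  voxel_dims_mm <- as.numeric(voxel_dims_mm)
  if (length(voxel_dims_mm) != 3L || any(voxel_dims_mm <= 0)) {
    stop("`voxel_dims_mm` must be three positive numbers", call. = FALSE)
  }
  structure(
    list(data = data, voxel_dims_mm = voxel_dims_mm, shape = dim(data)),
    class = c("binary_mask", "volume_grid")
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<%s> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
    class(x)[1], x$shape[1], x$shape[2], x$shape[3],
    x$voxel_dims_mm[1], x$voxel_dims_mm[2], x$voxel_dims_mm[3]
  ))
  rng <- range(x$data)
  cat(sprintf("  range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

# shape/voxel-dim agreement between two grids; used as a precondition everywhere
check_aligned <- function(a, b, what = "volumes") {
  if (!identical(as.integer(a$shape), as.integer(b$shape)) ||
      max(abs(a$voxel_dims_mm - b$voxel_dims_mm)) > 1e-9) {
    stop(sprintf("shape mismatch: %s are not on the same grid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Resample a volume onto a target grid
#'
#' Resamples by mapping each output voxel centre to a continuous input
#' coordinate under the physical (mm) correspondence of the two grids, then
#' interpolating: trilinear for intensity volumes, nearest-neighbour for
#' masks. The physical field of view is preserved (voxel-centre convention,
#' clamped at the borders), and interpolated intensities never leave the
#' input's min/max range — trilinear weights are convex.
#'
#' @param volume a [volume_grid()] or [binary_mask()].
#' @param target_shape integer triple, e.g. `c(256, 256, 256)`.
#' @param target_voxel_mm numeric triple of output voxel dims (mm).
#' @param is_mask logical; force nearest-neighbour interpolation. Defaults to
#'   `TRUE` for `binary_mask` input.
#' @return A resampled `volume_grid` (or `binary_mask` if `is_mask`).
#' @examples
#' v <- volume_grid(array(rnorm(8^3), c(8, 8, 8)))
#' r <- resample_to_grid(v, c(16, 16, 16), c(0.5, 0.5, 0.5))
#' r$shape
#' @export
resample_to_grid <- function(volume, target_shape, target_voxel_mm,
                             is_mask = inherits(volume, "binary_mask")) {
  target_shape <- as.integer(target_shape)
  target_voxel_mm <- as.numeric(target_voxel_mm)
  if (length(target_shape) != 3L || any(is.na(target_shape)) ||
      any(target_shape <= 0L)) {
    stop("`target_shape` must be three positive integers", call. = FALSE)
  }
  if (length(target_voxel_mm) != 3L || any(!is.finite(target_voxel_mm)) ||
      any(target_voxel_mm <= 0)) {
    stop("`target_voxel_mm` must be three positive numbers", call. = FALSE)
  }

  src <- if (is_mask) array(as.double(volume$data), dim = volume$shape) else volume$data
  in_shape <- volume$shape
  in_vox <- volume$voxel_dims_mm

  # identity fast-path keeps bitwise equality
  if (identical(as.integer(in_shape), target_shape) &&
      max(abs(in_vox - target_voxel_mm)) == 0) {
    return(volume)
  }

  # continuous input index of each output voxel centre, per axis (1-based)
  axis_coord <- function(n_out, d_out, d_in) {
    ((seq_len(n_out) - 0.5) * d_out) / d_in + 0.5
  }
  cx <- axis_coord(target_shape[1], target_voxel_mm[1], in_vox[1])
  cy <- axis_coord(target_shape[2], target_voxel_mm[2], in_vox[2])
  cz <- axis_coord(target_shape[3], target_voxel_mm[3], in_vox[3])

  out <- array(0, dim = target_shape)

  if (is_mask) {
    ix <- pmin(pmax(round(cx), 1L), in_shape[1])
    iy <- pmin(pmax(round(cy), 1L), in_shape[2])
    iz <- pmin(pmax(round(cz), 1L), in_shape[3])
    out[] <- src[ix, iy, iz]
    return(binary_mask(array(out != 0, dim = target_shape), target_voxel_mm))
  }

  clamp <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- clamp(floor(cx), in_shape[1]); x1 <- clamp(x0 + 1, in_shape[1])
  y0 <- clamp(floor(cy), in_shape[2]); y1 <- clamp(y0 + 1, in_shape[2])
  z0 <- clamp(floor(cz), in_shape[3]); z1 <- clamp(z0 + 1, in_shape[3])
  fx <- pmin(pmax(cx - floor(cx), 0), 1); fx[floor(cx) < 1] <- 0; fx[floor(cx) >= in_shape[1]] <- 1
  fy <- pmin(pmax(cy - floor(cy), 0), 1); fy[floor(cy) < 1] <- 0; fy[floor(cy) >= in_shape[2]] <- 1
  fz <- pmin(pmax(cz - floor(cz), 0), 1); fz[floor(cz) < 1] <- 0; fz[floor(cz) >= in_shape[3]] <- 1

  # slab-wise over output z to bound memory; the incremental form
  # a + f * (b - a) keeps constant fields exactly constant
  FX <- matrix(fx, nrow = target_shape[1], ncol = target_shape[2])
  FY <- matrix(fy, nrow = target_shape[1], ncol = target_shape[2], byrow = TRUE)
  bilerp <- function(zi) {
    s00 <- src[x0, y0, zi]; s10 <- src[x1, y0, zi]
    s01 <- src[x0, y1, zi]; s11 <- src[x1, y1, zi]
    e0 <- s00 + (s10 - s00) * FX
    e1 <- s01 + (s11 - s01) * FX
    e0 + (e1 - e0) * FY
  }
  for (k in seq_len(target_shape[3])) {
    lo <- bilerp(z0[k])
    if (fz[k] > 0) {
      hi <- bilerp(z1[k])
      out[, , k] <- lo + (hi - lo) * fz[k]
    } else {
      out[, , k] <- lo
    }
  }
  volume_grid(out, target_voxel_mm)
}

#' Read a NIfTI volume into a `volume_grid`
#'
#' Only the voxel dimensions are taken from the header; orientation handling
#' beyond axis order is out of scope (inputs are assumed preprocessed and
#' co-registered).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_mask logical; binarise (`!= 0`) and return a [binary_mask()].
#' @return A `volume_grid` or `binary_mask`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as_mask) binary_mask(arr != 0, vox) else volume_grid(arr, vox)
}

#' Write a `volume_grid` or `binary_mask` to NIfTI
#'
#' @param volume object to write; masks are written as 0/1 integers.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- if (inherits(volume, "binary_mask")) {
    array(as.integer(volume$data), dim = volume$shape)
  } else {
    volume$data
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
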