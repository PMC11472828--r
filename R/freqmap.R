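#' Voxel-wise WMH frequency map across subjects
#'
#' Sums the binary WMH masks of all subjects voxel-by-voxel and divides by
#' the number of subjects, so each voxel holds the proportion of subjects in
#' whom it was labelled WMH. Masks must already be on a common grid
#' (registration is a precondition, not performed here).
#'
#' @param masks list of [binary_mask()] objects with identical shape and
#'   voxel dims.
#' @return A `frequency_map` (a [volume_grid()] subclass) with an
#'   `n_subjects` field; values lie in `{0, 1/N, ..., 1}`.
#' @examples
#' m <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)))
#' build_frequency_map(list(m, m))$data[1]
#' @export
build_frequency_map <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("`masks` must be a non-empty list of binary masks", call. = FALSE)
  }
  ref <- masks[[1]]
  counts <- array(0, dim = ref$shape)
  for (m in masks) {
    if (!inherits(m, "binary_mask")) {
      stop("`masks` must be a non-empty list of binary masks", call. = FALSE)
    }
    check_aligned(ref, m, "frequency-map masks")
    counts <- counts + m$data
  }
  out <- volume_grid(counts / length(masks), ref$voxel_dims_mm)
  out$n_subjects <- length(masks)
  class(out) <- c("frequency_map", class(out))
  out
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf(
    "<frequency_map> %d x %d x %d over %d subjects, max frequency %.3f\n",
    x$shape[1], x$shape[2], x$shape[3], x$n_subjects, max(x$data)
  ))
  invisible(x)
}

#' Build a frequency map from NIfTI mask files
#'
#' @param paths character vector of NIfTI mask paths, or the path of a
#'   manifest CSV with a `path` column.
#' @return A `frequency_map`.
#' @export
frequency_map_from_files <- function(paths) {
  if (length(paths) == 1L && grepl("\\.csv$", paths)) {
    paths <- utils::read.csv(paths, stringsAsFactors = FALSE)$path
  }
  build_frequency_map(lapply(paths, read_volume, as_mask = TRUE))
}
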