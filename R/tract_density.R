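#' Raw tract-density counts
#'
#' For each streamline, the set of distinct voxels its polyline traverses is
#' found by exact Amanatides-Woo 3D voxel walking of every segment (robust to
#' step lengths exceeding the voxel size); each visited voxel's count is
#' incremented by exactly one per streamline, however many of that
#' streamline's points fall inside it. This makes TD independent of the
#' integration step length.
#'
#' @param tractogram a `tractogram` (see [track()]).
#' @param grid target grid (any object carrying one); defaults to the
#'   tractogram's own grid.
#' @return 3D numeric array of raw counts.
#' @export
td_counts <- function(tractogram, grid = tractogram$grid) {
  grid <- as_vox_grid(grid)
  .cpp_td_counts(grid$dim, grid$voxel_size, grid$origin,
                 tractogram$points, tractogram$n_points)
}

#' Normalized tract-density map
#'
#' Raw counts from [td_counts()] are normalized by the mean count over a
#' reference region so that muscle tissue sits near TD = 1. The reference
#' region should be the anatomical foreground (e.g. voxels with nonzero b = 0
#' signal, or labelled voxels) rather than the full rectangular FOV, since
#' air voxels would deflate the mean.
#'
#' @param tractogram a `tractogram` from whole-volume seeding, or a 3D array
#'   of pre-accumulated raw counts (as produced by chunked [td_counts()]
#'   accumulation).
#' @param grid the target grid (required when passing raw counts).
#' @param reference_mask logical/integer 3D array defining the normalization
#'   region; default: all voxels.
#' @return An object of class `td_map`: `map` (a TD [scalar_map()]),
#'   `counts` (raw), `normalization` (mean raw count over the reference),
#'   `reference_mask`.
#' @export
compute_td <- function(tractogram, grid = NULL, reference_mask = NULL) {
  if (inherits(tractogram, "tractogram")) {
    if (n_streamlines(tractogram) == 0L)
      stop("empty tractogram: tract density normalization is undefined")
    grid <- as_vox_grid(grid %||% tractogram$grid)
    counts <- td_counts(tractogram, grid)
  } else {
    counts <- tractogram
    if (is.null(grid)) stop("grid is required when passing raw counts")
    grid <- as_vox_grid(grid)
    stopifnot(all(dim(counts) == grid$dim))
    if (all(counts == 0))
      stop("all-zero counts: tract density normalization is undefined")
  }
  if (is.null(reference_mask)) {
    reference_mask <- array(TRUE, dim = grid$dim)
  } else {
    if (inherits(reference_mask, "label_volume"))
      reference_mask <- reference_mask$labels
    reference_mask <- reference_mask > 0
    stopifnot(all(dim(reference_mask) == grid$dim))
  }
  norm <- mean(counts[reference_mask])
  if (!is.finite(norm) || norm <= 0)
    stop("mean raw TD over the reference region is zero: cannot normalize")
  structure(list(map = scalar_map(counts / norm, "TD", grid$voxel_size,
                                  grid$origin),
                 counts = counts, normalization = norm,
                 reference_mask = reference_mask),
            class = "td_map")
}

#' @export
print.td_map <- function(x, ...) {
  cat(sprintf("<td_map> normalization %.3g tracts/voxel, %d voxels > 1.5\n",
              x$normalization, sum(x$map$values > 1.5)))
  invisible(x)
}

#' Tendinous-tissue mask from a TD map
#'
#' Voxels whose normalized tract density exceeds the threshold are segmented
#' as tendinous (tendon, aponeurosis, fascia, or artifact).
#'
#' @param td a `td_map` (from [compute_td()]) or a TD [scalar_map()].
#' @param threshold unit-less normalized TD threshold (default 1.5).
#' @return Logical 3D array.
#' @export
tendon_mask <- function(td, threshold = 1.5) {
  vals <- if (inherits(td, "td_map")) td$map$values else td$values
  vals > threshold
}
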