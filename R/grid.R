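#' Voxel grid geometry
#'
#' A light container for the geometry shared by all volumes in this package:
#' integer grid dimensions, voxel size in mm, and the world coordinate (mm) of
#' the centre of voxel (0,0,0). The world position of 0-based voxel index
#' `i` is `origin + i * voxel_size`; axes are assumed axis-aligned (no
#' rotation), which holds for all phantom data and for scanner data resampled
#' to a canonical orientation.
#'
#' @param dim integer vector of length 3, voxel counts per axis.
#' @param voxel_size numeric length 3, mm per voxel along each axis.
#' @param origin numeric length 3, world mm of the first voxel centre.
#'   Defaults to `voxel_size / 2` so the physical volume spans
#'   `[0, dim * voxel_size]`.
#' @return An object of class `vox_grid`.
#' @export
vox_grid <- function(dim, voxel_size, origin = voxel_size / 2) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(dim = dim, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @rdname vox_grid
#' @param x an object carrying a grid (`dwi_stack`, `scalar_map`,
#'   `tensor_volume`, or a `vox_grid` itself).
#' @export
as_vox_grid <- function(x) {
  if (inherits(x, "vox_grid")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "vox_grid")) return(x$grid)
  stop("cannot extract a vox_grid from object of class ",
       paste(class(x), collapse = "/"))
}

# world extent: lower/upper corners of the physical volume (mm)
grid_extent <- function(grid) {
  lower <- grid$origin - grid$voxel_size / 2
  upper <- grid$origin + (grid$dim - 1) * grid$voxel_size + grid$voxel_size / 2
  list(lower = lower, upper = upper, size = upper - lower)
}

# world mm (n x 3) -> continuous 0-based index coordinates (n x 3)
world_to_index <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3L)
  sweep(sweep(pts, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
}

# 0-based voxel indices (n x 3) -> world mm of voxel centres
index_to_world <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx, 2L, grid$voxel_size, "*"), 2L, grid$origin, "+")
}

# voxel-centre world coordinates along one axis
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$voxel_size[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  a <- as_vox_grid(a); b <- as_vox_grid(b)
  identical(a$dim, b$dim) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
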