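#' Diffusion-weighted image stack
#'
#' A 4D array of acquired volumes (x, y, z, volume) plus voxel geometry. The
#' number of volumes must match the accompanying [gradient_table()] when the
#' two are used together.
#'
#' @param data 4D numeric array (x, y, z, volume); 3D input is promoted to a
#'   single volume.
#' @param voxel_size,origin grid geometry, see [vox_grid()].
#' @return An object of class `dwi_stack` with elements `data` and `grid`.
#' @export
dwi_stack <- function(data, voxel_size, origin = voxel_size / 2) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3D or 4D array")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  grid <- vox_grid(dim(data)[1:3], voxel_size, origin)
  structure(list(data = data, grid = grid), class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_stack> %d x %d x %d voxels, %d volume(s), voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$grid$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Scalar map (FA, MD, TD, SNR, ...)
#'
#' @param values 3D numeric array.
#' @param quantity one of `"FA"`, `"MD"`, `"TD"`, `"SNR"`, `"other"`.
#' @param voxel_size,origin grid geometry, see [vox_grid()].
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, quantity = c("other", "FA", "MD", "TD", "SNR"),
                       voxel_size, origin = voxel_size / 2) {
  quantity <- match.arg(quantity)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  fin <- values[is.finite(values)]
  if (quantity == "FA" && (any(fin < -1e-9) || any(fin > 1 + 1e-9)))
    stop("FA values must lie in [0, 1]")
  if (quantity %in% c("TD", "SNR") && any(fin < 0))
    stop(quantity, " values must be nonnegative")
  grid <- vox_grid(dim(values), voxel_size, origin)
  structure(list(values = values, quantity = quantity, grid = grid),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map:%s> %d x %d x %d, range [%.4g, %.4g]\n",
              x$quantity, x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Integer muscle-label volume
#'
#' @param labels 3D integer array; 0 = background, k > 0 = muscle k.
#' @param voxel_size,origin grid geometry.
#' @param names optional named character vector mapping label -> muscle name.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, origin = voxel_size / 2,
                         names = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be nonnegative integers")
  grid <- vox_grid(dim(labels), voxel_size, origin)
  structure(list(labels = labels, grid = grid, names = names),
            class = "label_volume")
}

# ---- NIfTI I/O ------------------------------------------------------------

nifti_affine <- function(grid) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(grid$voxel_size)
  m[1:3, 4] <- grid$origin
  m
}

write_nifti_grid <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  pd <- grid$voxel_size
  if (length(dim(arr)) == 4L) pd <- c(pd, 1)
  RNifti::`pixdim<-`(img, pd) -> img
  RNifti::`qform<-`(img, structure(nifti_affine(grid), code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  if (all(aff == 0)) stop("NIfTI file ", path, " carries no affine")
  if (max(abs(aff[1:3, 1:3] - diag(diag(aff[1:3, 1:3])))) > 1e-4)
    stop("only axis-aligned NIfTI volumes are supported (", path, ")")
  sgn <- sign(diag(aff[1:3, 1:3]))
  vox <- abs(diag(aff[1:3, 1:3]))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop niftiImage attributes
  origin <- aff[1:3, 4]
  # flip axes with negative spacing to keep a positive-step convention
  for (a in which(sgn < 0)) {
    idx <- rev(seq_len(dim(arr)[a]))
    arr <- switch(a, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    origin[a] <- origin[a] + (dim(arr)[a] - 1) * aff[a, a]
  }
  list(data = arr, grid = vox_grid(dim(arr)[1:3], vox, origin))
}

#' Read a DWI dataset (NIfTI + FSL bvec/bval)
#'
#' @param path 4D NIfTI file.
#' @param bvec_path,bval_path FSL-style gradient files.
#' @return list with elements `stack` ([dwi_stack()]) and `table`
#'   ([gradient_table()]).
#' @export
read_dwi <- function(path, bvec_path, bval_path) {
  raw <- read_nifti_grid(path)
  arr <- raw$data
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  table <- read_gradient_table(bvec_path, bval_path)
  if (dim(arr)[4] != length(table$bvalues))
    stop("image has ", dim(arr)[4], " volumes but gradient table has ",
         length(table$bvalues), " entries")
  stack <- dwi_stack(arr, raw$grid$voxel_size, raw$grid$origin)
  list(stack = stack, table = table)
}

#' @rdname read_dwi
#' @param stack a [dwi_stack()].
#' @param table a [gradient_table()].
#' @export
write_dwi <- function(stack, table, path, bvec_path, bval_path) {
  write_nifti_grid(stack$data, stack$grid, path)
  write_gradient_table(table, bvec_path, bval_path)
  invisible(path)
}

#' Read/write scalar and label volumes as NIfTI
#' @param map a [scalar_map()] (or [label_volume()] for `write_labels`).
#' @param path NIfTI file path.
#' @param quantity quantity tag to attach on read.
#' @export
write_scalar_map <- function(map, path)
  write_nifti_grid(map$values, map$grid, path)

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path, quantity = "other") {
  raw <- read_nifti_grid(path)
  scalar_map(raw$data, quantity, raw$grid$voxel_size, raw$grid$origin)
}

#' @rdname write_scalar_map
#' @export
write_labels <- function(map, path)
  write_nifti_grid(map$labels, map$grid, path)

#' @rdname write_scalar_map
#' @export
read_labels <- function(path) {
  raw <- read_nifti_grid(path)
  label_volume(raw$data, raw$grid$voxel_size, raw$grid$origin)
}

# ---- Resampling -----------------------------------------------------------

# trilinear sample of a 3D array at continuous 0-based index coords (n x 3),
# clamped to the grid (nearest-edge extension)
trilinear_sample <- function(arr, ci) {
  d <- dim(arr)
  ci[, 1] <- pmin(pmax(ci[, 1], 0), d[1] - 1)
  ci[, 2] <- pmin(pmax(ci[, 2], 0), d[2] - 1)
  ci[, 3] <- pmin(pmax(ci[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(ci[, 1]), d[1] - 2L); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(ci[, 2]), d[2] - 2L); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(ci[, 3]), d[3] - 2L); k0 <- pmax(k0, 0)
  if (d[1] == 1L) i0 <- rep(0, nrow(ci))
  if (d[2] == 1L) j0 <- rep(0, nrow(ci))
  if (d[3] == 1L) k0 <- rep(0, nrow(ci))
  fx <- ci[, 1] - i0; fy <- ci[, 2] - j0; fz <- ci[, 3] - k0
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, d[1] - 1L); jj <- pmin(j0 + dj, d[2] - 1L)
    kk <- pmin(k0 + dk, d[3] - 1L)
    arr[1L + ii + d[1] * (jj + d[2] * kk)]
  }
  at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
}

#' Resample a DWI stack to a new voxel size
#'
#' Trilinear interpolation of each volume onto a new grid with the requested
#' voxel size. The new grid spans the same physical extent (to within one
#' voxel): the voxel count per axis is `round(extent / target)` and the origin
#' is placed half a voxel inside the lower physical corner.
#'
#' @param stack a [dwi_stack()].
#' @param target_voxel_size numeric length 3, mm.
#' @return A resampled [dwi_stack()].
#' @export
resample <- function(stack, target_voxel_size) {
  stopifnot(inherits(stack, "dwi_stack"), length(target_voxel_size) == 3L,
            all(target_voxel_size > 0))
  ext <- grid_extent(stack$grid)
  new_dim <- pmax(1L, as.integer(round(ext$size / target_voxel_size)))
  new_grid <- vox_grid(new_dim, target_voxel_size,
                       ext$lower + target_voxel_size / 2)
  centers <- as.matrix(expand.grid(axis_centers(new_grid, 1),
                                   axis_centers(new_grid, 2),
                                   axis_centers(new_grid, 3)))
  ci <- world_to_index(stack$grid, centers)
  nvol <- dim(stack$data)[4]
  out <- array(0, dim = c(new_dim, nvol))
  for (v in seq_len(nvol)) {
    out[, , , v] <- array(trilinear_sample(stack$data[, , , v], ci), dim = new_dim)
  }
  dwi_stack(out, target_voxel_size, new_grid$origin)
}

# ---- SNR ------------------------------------------------------------------

#' SNR map and summary from a noise scan
#'
#' SNR is the ratio of the mean b = 0 muscle signal to the Gaussian noise
#' standard deviation. The noise scan is a pure-noise magnitude (Rician)
#' image, whose underlying Gaussian standard deviation is recovered from the
#' second moment: `sigma = sqrt(mean(noise^2) / 2)`.
#'
#' @param stack a [dwi_stack()].
#' @param table the matching [gradient_table()] (identifies b = 0 volumes).
#' @param noise a [scalar_map()] or 3D array: the noise scan, same grid.
#' @param mask logical 3D array: muscle voxels over which the summary SNR is
#'   computed.
#' @return list with `map` (a `scalar_map` of voxelwise b0/sigma), `snr`
#'   (summary scalar), and `sigma` (estimated Gaussian noise SD).
#' @export
snr_map <- function(stack, table, noise, mask) {
  noise_vals <- if (inherits(noise, "scalar_map")) noise$values else noise
  if (!all(dim(noise_vals) == stack$grid$dim))
    stop("noise volume grid does not match the DWI stack")
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("empty mask: SNR undefined")
  b0 <- stack$data[, , , which(table$b0)[1], drop = TRUE]
  if (sum(table$b0) > 1L) {
    b0 <- apply(stack$data[, , , table$b0, drop = FALSE], 1:3, mean)
  }
  sigma <- sqrt(mean(noise_vals^2) / 2)
  vals <- if (sigma > 0) b0 / sigma else array(0, dim = dim(b0))
  snr <- if (sigma > 0) mean(b0[mask]) / sigma else 0
  list(map = scalar_map(vals, "SNR", stack$grid$voxel_size, stack$grid$origin),
       snr = snr, sigma = sigma)
}
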