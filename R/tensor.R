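#' Diffusion tensor volume
#'
#' Per-voxel symmetric diffusion tensor stored as a 4D array with the six
#' unique components in the order `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz` (mm^2/s).
#'
#' @param tensors 4D array (x, y, z, 6).
#' @param voxel_size,origin grid geometry.
#' @param mask logical 3D validity mask (voxels with a usable fit).
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(tensors, voxel_size, origin = voxel_size / 2,
                          mask = NULL) {
  d <- dim(tensors)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensors must be an (x, y, z, 6) array")
  grid <- vox_grid(d[1:3], voxel_size, origin)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  structure(list(tensors = tensors, mask = mask, grid = grid),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %d x %d x %d voxels, %d valid\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3], sum(x$mask)))
  invisible(x)
}

# WLLS design matrix: ln S = X [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]'
wlls_design <- function(table) {
  g <- table$directions; b <- table$bvalues
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Weighted linear least-squares tensor fit
#'
#' Fits the log-linear tensor model `ln S = ln S0 - b g' D g` per voxel:
#' first an ordinary least-squares pass, then one re-weighted pass with
#' weights equal to the squared model-predicted signals (the standard WLLS
#' scheme, accounting for the log transform making noise heteroscedastic).
#' Voxels with any nonpositive signal are excluded from the validity mask.
#'
#' @param stack a [dwi_stack()].
#' @param table the matching [gradient_table()].
#' @param mask optional logical 3D array restricting the fit.
#' @return A [tensor_volume()] whose attribute `s0` holds the fitted baseline
#'   signal map.
#' @export
fit_wlls <- function(stack, table, mask = NULL) {
  stopifnot(inherits(stack, "dwi_stack"), inherits(table, "gradient_table"))
  d <- stack$grid$dim
  if (dim(stack$data)[4] != length(table$bvalues))
    stop("stack and gradient table disagree in volume count")
  ndir <- nrow(unique(round(table$directions[!table$b0, , drop = FALSE], 6)))
  if (ndir < 6L) stop("need at least 6 distinct diffusion-weighted directions")
  X <- wlls_design(table)
  if (qr(X)$rank < 7L)
    stop("rank-deficient gradient design (directions coplanar?): cannot fit")
  nvox <- prod(d)
  S <- matrix(stack$data, nrow = nvox)           # voxels x volumes
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  valid <- as.vector(mask) & apply(S > 0, 1L, all)
  beta <- matrix(0, nvox, 7L)
  if (any(valid)) {
    y <- log(S[valid, , drop = FALSE])
    # OLS pass, shared pseudo-inverse across voxels
    beta0 <- y %*% t(solve(crossprod(X), t(X)))
    # one reweighted pass, per voxel (weights = squared predicted signals)
    pred <- beta0 %*% t(X)
    idx <- which(valid)
    bloc <- matrix(0, length(idx), 7L)
    for (r in seq_along(idx)) {
      w <- exp(2 * pred[r, ])
      Xw <- X * w
      bloc[r, ] <- solve(crossprod(X, Xw), crossprod(Xw, y[r, ]))
    }
    beta[idx, ] <- bloc
  }
  tens <- array(beta[, 2:7], dim = c(d, 6L))
  out <- tensor_volume(tens, stack$grid$voxel_size, stack$grid$origin,
                       mask = array(valid, dim = d))
  attr(out, "s0") <- array(exp(beta[, 1]) * valid, dim = d)
  out
}

# sorted (descending) eigenvalues of all voxel tensors, vectorized Cardano
tensor_eigenvalues <- function(tensors) {
  tv <- matrix(tensors$tensors, ncol = 6L)
  a11 <- tv[, 1]; a22 <- tv[, 2]; a33 <- tv[, 3]
  a12 <- tv[, 4]; a13 <- tv[, 5]; a23 <- tv[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3)
}

#' Eigen-decomposition of a tensor volume
#'
#' @param tensors a [tensor_volume()].
#' @return list with `values` (x,y,z,3 array, eigenvalues sorted descending)
#'   and `vectors` (x,y,z,3 array, unit principal eigenvector; sign is
#'   arbitrary as fibre orientations are antipodally symmetric).
#' @export
eigensystem <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  d <- tensors$grid$dim
  ev <- tensor_eigenvalues(tensors)
  tv <- matrix(tensors$tensors, ncol = 6L)
  n <- nrow(tv)
  vec <- matrix(0, n, 3L)
  for (r in seq_len(n)) {
    D <- matrix(c(tv[r, 1], tv[r, 4], tv[r, 5],
                  tv[r, 4], tv[r, 2], tv[r, 6],
                  tv[r, 5], tv[r, 6], tv[r, 3]), 3L, 3L)
    vec[r, ] <- eigen(D, symmetric = TRUE)$vectors[, 1]
  }
  list(values = array(ev, dim = c(d, 3L)), vectors = array(vec, dim = c(d, 3L)))
}

#' Fractional anisotropy and mean diffusivity maps
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clipped to
#' [0, 1] and defined as 0 for a zero tensor; `MD = mean(lambda)`. Both are
#' computed from tensor invariants (no per-voxel eigendecomposition needed).
#' Voxels outside the validity mask get FA = 0 / MD = 0, so they fail any
#' FA-window tracking criterion.
#'
#' @param tensors a [tensor_volume()].
#' @return A [scalar_map()].
#' @export
fa_map <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  tv <- matrix(tensors$tensors, ncol = 6L)
  md <- (tv[, 1] + tv[, 2] + tv[, 3]) / 3
  frob2 <- tv[, 1]^2 + tv[, 2]^2 + tv[, 3]^2 + 2 * (tv[, 4]^2 + tv[, 5]^2 + tv[, 6]^2)
  num <- pmax(frob2 - 3 * md^2, 0)
  fa <- ifelse(frob2 > 0, sqrt(1.5 * num / frob2), 0)
  fa <- pmin(pmax(fa, 0), 1) * as.vector(tensors$mask)
  scalar_map(array(fa, dim = tensors$grid$dim), "FA",
             tensors$grid$voxel_size, tensors$grid$origin)
}

#' @rdname fa_map
#' @export
md_map <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  tv <- matrix(tensors$tensors, ncol = 6L)
  md <- (tv[, 1] + tv[, 2] + tv[, 3]) / 3 * as.vector(tensors$mask)
  scalar_map(array(md, dim = tensors$grid$dim), "MD",
             tensors$grid$voxel_size, tensors$grid$origin)
}
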