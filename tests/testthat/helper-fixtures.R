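# Shared fixtures, all generated in code.

# a uniform tensor field with principal axis `axis` (unit 3-vector)
uniform_tensor_volume <- function(dim3, voxel_size, axis = c(0, 0, 1),
                                  eigs = c(1.7, 1.0, 1.0) * 1e-3) {
  axis <- axis / sqrt(sum(axis^2))
  # build D = l1 v v' + l2 (I - v v') when l2 == l3 (axisymmetric)
  stopifnot(abs(eigs[2] - eigs[3]) < 1e-15)
  D <- eigs[1] * tcrossprod(axis) + eigs[2] * (diag(3) - tcrossprod(axis))
  comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tens <- array(0, dim = c(dim3, 6L))
  for (c6 in 1:6) tens[, , , c6] <- comp[c6]
  tensor_volume(tens, voxel_size)
}

# tensor field whose principal axis rotates in the x-z plane by
# `deg_per_mm` degrees per mm of z
rotating_tensor_volume <- function(dim3, voxel_size, deg_per_mm, z0,
                                   eigs = c(1.7, 1.0, 1.0) * 1e-3) {
  tens <- array(0, dim = c(dim3, 6L))
  zc <- voxel_size[3] / 2 + (seq_len(dim3[3]) - 1) * voxel_size[3]
  for (k in seq_len(dim3[3])) {
    phi <- deg_per_mm * (zc[k] - z0) * pi / 180
    v <- c(sin(phi), 0, cos(phi))
    D <- eigs[1] * tcrossprod(v) + eigs[2] * (diag(3) - tcrossprod(v))
    comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    for (c6 in 1:6) tens[, , k, c6] <- comp[c6]
  }
  tensor_volume(tens, voxel_size)
}

# small phantom (fits the full 55 mm slab; short in y and z) for fast tests
small_phantom_spec <- function(seed = 42L, ...) {
  phantom_spec(grid_shape = c(40L, 12L, 30L), seed = seed, ...)
}

# heavy shared state for the acceptance checks: the default phantom at the
# default fixed seed, its tensor fit, first-pass TD map and the three-method
# comparison. Computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_state <- function() {
  if (!is.null(.acceptance_cache$state)) return(.acceptance_cache$state)
  cfg <- run_config(seed = 42L)
  ph <- generate_phantom(phantom_spec(seed = 42L))
  tens <- fit_wlls(ph$stack, ph$table)
  fa <- fa_map(tens)
  p1 <- td_first_pass(tens, fa, ph$truth$foreground, cfg)
  cm <- compare_methods(tens, fa, p1$td, ph$truth$labels, 1L, cfg)
  .acceptance_cache$state <- list(cfg = cfg, ph = ph, tens = tens, fa = fa,
                                  p1 = p1, td = p1$td, cm = cm)
  .acceptance_cache$state
}

# erode a logical mask n times (test-side convenience)
erode_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- tdtract:::erode_once6(mask)
  mask
}
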