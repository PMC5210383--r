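#' Specification of the synthetic unipennate-muscle phantom
#'
#' The phantom emulates a DT-MRI acquisition of a unipennate muscle: a planar
#' internal aponeurosis (normal along x, tendon fibres along z) flanked by two
#' muscle compartments whose fascicles lie in the x-z plane at
#' `+/- pennation_angle` to z, attaching to the aponeurosis on one side and to
#' a bounding fascia on the other. Ground-truth fascicle length is
#' `L = muscle_half_width / sin(pennation_angle)`.
#'
#' Defaults mirror a typical lower-leg muscle protocol: working voxel size
#' 1.5 x 1.5 x 3.0 mm, b = 400 s/mm^2, 12 gradient directions, SNR 40.
#' Tendinous tissue is simulated hypointense (`tendon_s0_fraction`, default
#' 0.1) because its T2 is far below typical echo times; without this the
#' phantom would carry implausibly coherent signal inside tendon.
#'
#' @param grid_shape integer length 3, voxel counts.
#' @param voxel_size numeric length 3, mm.
#' @param pennation_angle degrees between fibre axis and the aponeurosis
#'   plane, in (0, 90].
#' @param muscle_half_width mm from the aponeurosis surface to the fascia.
#' @param aponeurosis_thickness mm, full thickness of the central aponeurosis.
#' @param fascia_thickness mm, thickness of each bounding fascia sheet.
#' @param muscle_eigenvalues,tendon_eigenvalues three diffusivities each,
#'   mm^2/s, strictly positive and non-increasing.
#' @param s0 baseline (b = 0) muscle signal, arbitrary units.
#' @param tendon_s0_fraction baseline signal of pure tendinous tissue as a
#'   fraction of `s0` (short-T2 hypointensity).
#' @param snr ratio of `s0` to the Gaussian noise standard deviation.
#' @param b_value s/mm^2 for the diffusion-weighted volumes.
#' @param n_directions number of diffusion-weighted gradient directions.
#' @param seed integer RNG seed controlling noise and the direction scheme.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 60L),
                         voxel_size = c(1.5, 1.5, 3.0),
                         pennation_angle = 30,
                         muscle_half_width = 25,
                         aponeurosis_thickness = 2,
                         fascia_thickness = 1.5,
                         muscle_eigenvalues = c(2.1, 1.6, 1.4) * 1e-3,
                         tendon_eigenvalues = c(1.8, 0.5, 0.5) * 1e-3,
                         s0 = 100,
                         tendon_s0_fraction = 0.1,
                         snr = 40,
                         b_value = 400,
                         n_directions = 12L,
                         seed = 42L) {
  chk_eigs <- function(e, what) {
    if (length(e) != 3L || any(e <= 0) || any(diff(e) > 0))
      stop(what, " eigenvalues must be 3 strictly positive non-increasing values")
  }
  chk_eigs(muscle_eigenvalues, "muscle")
  chk_eigs(tendon_eigenvalues, "tendon")
  if (!(pennation_angle > 0 && pennation_angle <= 90))
    stop("pennation_angle must lie in (0, 90] degrees")
  if (snr <= 0) stop("snr must be positive")
  if (muscle_half_width <= 0 || aponeurosis_thickness <= 0 ||
      fascia_thickness <= 0)
    stop("geometry thicknesses must be positive")
  if (tendon_s0_fraction < 0 || tendon_s0_fraction > 1)
    stop("tendon_s0_fraction must lie in [0, 1]")
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
    pennation_angle = pennation_angle, muscle_half_width = muscle_half_width,
    aponeurosis_thickness = aponeurosis_thickness,
    fascia_thickness = fascia_thickness,
    muscle_eigenvalues = muscle_eigenvalues,
    tendon_eigenvalues = tendon_eigenvalues,
    s0 = s0, tendon_s0_fraction = tendon_s0_fraction, snr = snr,
    b_value = b_value, n_directions = as.integer(n_directions),
    seed = as.integer(seed)), class = "phantom_spec")
  L <- true_fascicle_length(spec)
  if (!is.finite(L) || L <= 0) stop("ground-truth fascicle length must be positive")
  spec
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
true_fascicle_length <- function(spec) {
  spec$muscle_half_width / sin(spec$pennation_angle * pi / 180)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d x %d voxels (%.1f x %.1f x %.1f mm), ",
                     "pennation %.0f deg, true fascicle length %.1f mm, SNR %.0f\n"),
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$pennation_angle, true_fascicle_length(x), x$snr))
  invisible(x)
}

# 1D overlap of voxel [a,b] with interval [lo,hi], as fraction of (b-a)
interval_overlap_fraction <- function(a, b, lo, hi) {
  pmax(0, pmin(b, hi) - pmax(a, lo)) / (b - a)
}

#' Build the phantom geometry (ground truth)
#'
#' Lays out the aponeurosis, muscle compartments and fasciae, computes the
#' per-voxel tendinous tissue fraction analytically (all interfaces are planes
#' normal to x, so the fraction is an exact 1D interval overlap), the fibre
#' orientation field, the muscle label volume and the foreground mask.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: `orientation` (x,y,z,3 array of
#'   unit fibre directions), `tissue_fraction` (tendinous fraction in [0,1]),
#'   `foreground_fraction`, `foreground` (logical), `aponeurosis` and
#'   `fascia` (logical masks of tendinous-majority voxels of the central
#'   sheet and the bounding sheets respectively), `labels`
#'   ([label_volume()], 1 = +x compartment, 2 = -x compartment),
#'   `true_fascicle_length` (mm), and `grid`.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- vox_grid(spec$grid_shape, spec$voxel_size)
  ext <- grid_extent(grid)
  W <- spec$muscle_half_width
  t2 <- spec$aponeurosis_thickness / 2
  tf <- spec$fascia_thickness
  theta <- spec$pennation_angle * pi / 180
  L <- true_fascicle_length(spec)
  xc <- (ext$lower[1] + ext$upper[1]) / 2
  slab_half <- t2 + W + tf
  if (2 * slab_half > ext$size[1])
    stop("grid too small: aponeurosis + muscle + fascia span ",
         format(2 * slab_half), " mm but the x extent is only ",
         format(ext$size[1]), " mm")
  if (L * cos(theta) > ext$size[3])
    stop("grid too small: one full fascicle spans ", format(L * cos(theta)),
         " mm along z but the z extent is only ", format(ext$size[3]), " mm")

  xs <- axis_centers(grid, 1)
  xa <- xs - grid$voxel_size[1] / 2
  xb <- xs + grid$voxel_size[1] / 2
  # tendinous fraction per x column: aponeurosis + two fascia sheets
  f_x <- interval_overlap_fraction(xa, xb, xc - t2, xc + t2) +
    interval_overlap_fraction(xa, xb, xc + t2 + W, xc + slab_half) +
    interval_overlap_fraction(xa, xb, xc - slab_half, xc - t2 - W)
  fg_x <- interval_overlap_fraction(xa, xb, xc - slab_half, xc + slab_half)
  musc_x <- pmax(0, fg_x - f_x)

  d <- grid$dim
  tissue_fraction <- array(rep(f_x, times = d[2] * d[3]), dim = d)
  foreground_fraction <- array(rep(fg_x, times = d[2] * d[3]), dim = d)
  muscle_fraction <- array(rep(musc_x, times = d[2] * d[3]), dim = d)
  foreground <- foreground_fraction >= 0.5

  side_x <- ifelse(xs >= xc, 1, -1)
  orientation <- array(0, dim = c(d, 3L))
  dir_x <- outer(side_x * sin(theta), rep(1, d[2] * d[3]))
  orientation[, , , 1] <- array(dir_x, dim = d)
  orientation[, , , 3] <- cos(theta)

  lab_x <- integer(d[1])
  lab_x[musc_x > 0.5 & xs > xc] <- 1L
  lab_x[musc_x > 0.5 & xs < xc] <- 2L
  labels <- array(rep(lab_x, times = d[2] * d[3]), dim = d)

  # tendinous-majority voxels split by structure: the central aponeurosis
  # sheet vs the two bounding fasciae
  apo_x <- f_x > 0.5 & abs(xs - xc) <= t2 + grid$voxel_size[1]
  fas_x <- f_x > 0.5 & !apo_x
  aponeurosis <- array(rep(apo_x, times = d[2] * d[3]), dim = d)
  fascia <- array(rep(fas_x, times = d[2] * d[3]), dim = d)

  structure(list(orientation = orientation,
                 tissue_fraction = tissue_fraction,
                 foreground_fraction = foreground_fraction,
                 muscle_fraction = muscle_fraction,
                 foreground = foreground,
                 aponeurosis = aponeurosis,
                 fascia = fascia,
                 labels = label_volume(labels, grid$voxel_size, grid$origin,
                                       names = c("1" = "compartment_posx",
                                                 "2" = "compartment_negx")),
                 true_fascicle_length = L,
                 aponeurosis_center = xc,
                 grid = grid),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d x %d, true fascicle length %.2f mm, %d tendinous voxels (f > 0.5)\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              x$true_fascicle_length, sum(x$tissue_fraction > 0.5)))
  invisible(x)
}

# rank-1 outer products for a rotated diffusion tensor with principal axis v1,
# secondary axis y, tertiary in-plane perpendicular
rotated_tensor6 <- function(v1, eigs) {
  v2 <- c(0, 1, 0)
  v3 <- c(v1[3], 0, -v1[1])       # perpendicular to v1 within the x-z plane
  n3 <- sqrt(sum(v3^2))
  if (n3 < 1e-12) v3 <- c(1, 0, 0) else v3 <- v3 / n3
  D <- eigs[1] * tcrossprod(v1) + eigs[2] * tcrossprod(v2) +
    eigs[3] * tcrossprod(v3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Per-voxel diffusion tensor field of the phantom
#'
#' Mixing is done at the tensor level: `D = (1 - f) D_muscle + f D_tendon`
#' with `f` the tendinous tissue fraction, muscle principal axis along the
#' fibre orientation field and tendon principal axis along z. This reproduces
#' the partial-volume mechanism by which the voxel-average principal
#' diffusion direction at a muscle/tendon interface rotates toward the tendon.
#'
#' @param truth a [phantom_truth] from [build_geometry()].
#' @param spec the matching [phantom_spec()].
#' @return A [tensor_volume] (see [fit_wlls()] for the component layout).
#' @export
tensor_field <- function(truth, spec) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "phantom_spec"))
  d <- truth$grid$dim
  theta <- spec$pennation_angle * pi / 180
  Dt <- rotated_tensor6(c(0, 0, 1), spec$tendon_eigenvalues)
  Dm_pos <- rotated_tensor6(c(sin(theta), 0, cos(theta)), spec$muscle_eigenvalues)
  Dm_neg <- rotated_tensor6(c(-sin(theta), 0, cos(theta)), spec$muscle_eigenvalues)
  xs <- axis_centers(truth$grid, 1)
  side_pos <- xs >= truth$aponeurosis_center
  tens <- array(0, dim = c(d, 6L))
  f <- truth$tissue_fraction
  for (c6 in 1:6) {
    Dm_x <- ifelse(side_pos, Dm_pos[c6], Dm_neg[c6])
    Dm <- array(rep(Dm_x, times = d[2] * d[3]), dim = d)
    tens[, , , c6] <- (1 - f) * Dm + f * Dt[c6]
  }
  tensor_volume(tens, truth$grid$voxel_size, truth$grid$origin,
                mask = array(TRUE, dim = d))
}

#' Simulate the diffusion-weighted acquisition
#'
#' Noise-free signals follow the mono-exponential Stejskal-Tanner model
#' `S = S0 * exp(-b g' D g)`; Rician noise is added as the magnitude of
#' `(S + n1, n2)` with `n1, n2 ~ N(0, (s0/snr)^2)`. A pure-noise magnitude
#' volume with the same noise level is returned alongside. Deterministic for
#' a given `spec$seed`.
#'
#' @param tensors a [tensor_volume], e.g. from [tensor_field()].
#' @param spec a [phantom_spec()].
#' @param s0_map optional 3D array of per-voxel baseline signal; defaults to
#'   uniform `spec$s0` (the phantom pipeline passes the hypointensity-weighted
#'   map).
#' @param noise_free if `TRUE`, skip noise (useful for tensor-fit oracles).
#' @return list with `stack` ([dwi_stack()]), `table` ([gradient_table()]),
#'   and `noise` (a [scalar_map()] pure-noise volume; zeros if `noise_free`).
#' @export
simulate_dwi <- function(tensors, spec, s0_map = NULL, noise_free = FALSE) {
  stopifnot(inherits(tensors, "tensor_volume"), inherits(spec, "phantom_spec"))
  if (spec$snr <= 0) stop("snr must be positive")
  d <- tensors$grid$dim
  if (is.null(s0_map)) s0_map <- array(spec$s0, dim = d)
  dirs <- repulsion_directions(spec$n_directions, seed = spec$seed)
  table <- gradient_table(rbind(c(0, 0, 0), dirs),
                          c(0, rep(spec$b_value, spec$n_directions)))
  nvol <- length(table$bvalues)
  signal <- array(0, dim = c(d, nvol))
  tv <- tensors$tensors
  for (v in seq_len(nvol)) {
    if (table$b0[v]) {
      signal[, , , v] <- s0_map
    } else {
      g <- table$directions[v, ]
      quad <- tv[, , , 1] * g[1]^2 + tv[, , , 2] * g[2]^2 +
        tv[, , , 3] * g[3]^2 + 2 * (tv[, , , 4] * g[1] * g[2] +
                                      tv[, , , 5] * g[1] * g[3] +
                                      tv[, , , 6] * g[2] * g[3])
      signal[, , , v] <- s0_map * exp(-table$bvalues[v] * quad)
    }
  }
  sigma <- spec$s0 / spec$snr
  if (noise_free) {
    noise <- array(0, dim = d)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    n <- length(signal)
    signal <- sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
    dim(signal) <- c(d, nvol)
    nv <- prod(d)
    noise <- sqrt(rnorm(nv, sd = sigma)^2 + rnorm(nv, sd = sigma)^2)
    dim(noise) <- d
  }
  list(stack = dwi_stack(signal, tensors$grid$voxel_size, tensors$grid$origin),
       table = table,
       noise = scalar_map(noise, "other", tensors$grid$voxel_size,
                          tensors$grid$origin))
}

#' Generate a complete phantom dataset
#'
#' Convenience wrapper: geometry, tensor field, baseline-signal map with
#' tendon hypointensity, and the simulated noisy acquisition.
#'
#' @param spec a [phantom_spec()].
#' @param noise_free simulate without noise.
#' @return list with `spec`, `truth`, `tensors`, `s0_map`, `stack`, `table`,
#'   `noise`.
#' @export
generate_phantom <- function(spec = phantom_spec(), noise_free = FALSE) {
  truth <- build_geometry(spec)
  tensors <- tensor_field(truth, spec)
  s0_map <- spec$s0 * (truth$muscle_fraction +
                         spec$tendon_s0_fraction * truth$tissue_fraction)
  sim <- simulate_dwi(tensors, spec, s0_map = s0_map, noise_free = noise_free)
  list(spec = spec, truth = truth, tensors = tensors, s0_map = s0_map,
       stack = sim$stack, table = sim$table, noise = sim$noise)
}

#' Write a phantom dataset to disk
#'
#' Writes the 4D DWI NIfTI, FSL bvec/bval, noise scan, label volume, truth
#' volumes (tendinous fraction, foreground) and a JSON sidecar holding the
#' spec and the ground-truth fascicle length.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_dwi(phantom$stack, phantom$table, p("dwi.nii.gz"),
            p("dwi.bvec"), p("dwi.bval"))
  write_scalar_map(phantom$noise, p("noise.nii.gz"))
  write_labels(phantom$truth$labels, p("labels.nii.gz"))
  g <- phantom$truth$grid
  write_nifti_grid(phantom$truth$tissue_fraction, g, p("tissue_fraction.nii.gz"))
  write_nifti_grid(phantom$truth$foreground + 0, g, p("foreground.nii.gz"))
  side <- list(spec = unclass(phantom$spec),
               true_fascicle_length = phantom$truth$true_fascicle_length)
  jsonlite::write_json(side, p("phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(dwi = p("dwi.nii.gz"), bvec = p("dwi.bvec"), bval = p("dwi.bval"),
              noise = p("noise.nii.gz"), labels = p("labels.nii.gz"),
              tissue_fraction = p("tissue_fraction.nii.gz"),
              foreground = p("foreground.nii.gz"), json = p("phantom.json")))
}
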