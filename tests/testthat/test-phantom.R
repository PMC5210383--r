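test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(pennation_angle = 0), "pennation")
  expect_error(phantom_spec(pennation_angle = 91), "pennation")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(muscle_eigenvalues = c(1, 2, 3) * 1e-3),
               "non-increasing")
  expect_error(phantom_spec(tendon_eigenvalues = c(1.8, -0.5, 0.5) * 1e-3),
               "positive")
})

test_that("ground-truth fascicle length follows L = W / sin(theta)", {
  s1 <- phantom_spec(pennation_angle = 90, muscle_half_width = 30,
                     grid_shape = c(48L, 10L, 20L))
  expect_equal(true_fascicle_length(s1), 30)
  s2 <- phantom_spec(pennation_angle = 30, muscle_half_width = 25)
  expect_equal(true_fascicle_length(s2), 50)
  expect_equal(build_geometry(s2)$true_fascicle_length, 50)
})

test_that("geometry rejects grids too small for one fascicle", {
  expect_error(phantom_spec(grid_shape = c(20L, 10L, 20L)) |> build_geometry(),
               "grid too small")
  # z extent shorter than the fascicle's z span
  expect_error(build_geometry(phantom_spec(grid_shape = c(40L, 10L, 10L),
                                           pennation_angle = 20)),
               "grid too small")
})

test_that("tissue fractions match a supersampled voxelization of the planes", {
  spec <- phantom_spec(grid_shape = c(40L, 6L, 16L))
  truth <- build_geometry(spec)
  g <- truth$grid
  # independent oracle: 10x10x10 supersampling of each voxel against the
  # analytic slab intervals
  xc <- (g$dim[1] * g$voxel_size[1]) / 2
  t2 <- spec$aponeurosis_thickness / 2
  W <- spec$muscle_half_width
  tf <- spec$fascia_thickness
  sub <- (seq_len(10) - 0.5) / 10
  f_col <- vapply(seq_len(g$dim[1]), function(i) {
    x0 <- (i - 1) * g$voxel_size[1]
    xs <- x0 + sub * g$voxel_size[1]
    tendin <- (abs(xs - xc) <= t2) |
      (xs >= xc + t2 + W & xs <= xc + t2 + W + tf) |
      (xs <= xc - t2 - W & xs >= xc - t2 - W - tf)
    mean(tendin)  # y/z subdivision adds nothing: the planes are normal to x
  }, numeric(1))
  f_super <- array(rep(f_col, times = g$dim[2] * g$dim[3]), dim = g$dim)
  expect_equal(sum(truth$tissue_fraction > 0 & truth$tissue_fraction < 1),
               sum(f_super > 0.005 & f_super < 0.995))
  expect_true(all(abs(truth$tissue_fraction - f_super) <= 0.05 + 1e-12))
  expect_true(all(truth$tissue_fraction >= 0 & truth$tissue_fraction <= 1))
  # orientation field is unit norm wherever it matters
  nrm <- sqrt(apply(truth$orientation^2, 1:3, sum))
  expect_true(all(abs(nrm[truth$tissue_fraction < 1] - 1) < 1e-12))
})

test_that("tensor mixing reproduces pure tissues and interface tilt", {
  spec <- phantom_spec(grid_shape = c(40L, 6L, 16L))
  truth <- build_geometry(spec)
  tens <- tensor_field(truth, spec)
  # f = 0 voxel: eigenvalues equal the muscle diffusivities exactly
  i0 <- which(truth$tissue_fraction == 0 & truth$labels$labels == 1L,
              arr.ind = TRUE)[1, ]
  D <- matrix(0, 3, 3)
  cmp <- tens$tensors[i0[1], i0[2], i0[3], ]
  D[1, 1] <- cmp[1]; D[2, 2] <- cmp[2]; D[3, 3] <- cmp[3]
  D[1, 2] <- D[2, 1] <- cmp[4]; D[1, 3] <- D[3, 1] <- cmp[5]
  D[2, 3] <- D[3, 2] <- cmp[6]
  expect_equal(sort(eigen(D, symmetric = TRUE)$values, decreasing = TRUE),
               spec$muscle_eigenvalues, tolerance = 1e-12)

  # interface voxel with f = 0.5 at 20 degrees pennation: principal
  # eigenvector closer to z than the muscle fibre direction is
  spec2 <- phantom_spec(grid_shape = c(40L, 6L, 26L), pennation_angle = 20,
                        aponeurosis_thickness = 1.5)
  truth2 <- build_geometry(spec2)
  tens2 <- tensor_field(truth2, spec2)
  iv <- which(abs(truth2$tissue_fraction - 0.5) < 1e-9, arr.ind = TRUE)[1, ]
  cmp <- tens2$tensors[iv[1], iv[2], iv[3], ]
  D <- matrix(c(cmp[1], cmp[4], cmp[5], cmp[4], cmp[2], cmp[6],
                cmp[5], cmp[6], cmp[3]), 3, 3)
  v <- eigen(D, symmetric = TRUE)$vectors[, 1]
  ang_to_z <- acos(abs(v[3])) * 180 / pi
  expect_lt(ang_to_z, 20)

  # a pure-tendon (f = 1) voxel has principal axis z; build one explicitly
  spec3 <- phantom_spec(grid_shape = c(44L, 6L, 16L),
                        aponeurosis_thickness = 4.5)
  truth3 <- build_geometry(spec3)
  tens3 <- tensor_field(truth3, spec3)
  i1 <- which(truth3$tissue_fraction == 1, arr.ind = TRUE)[1, ]
  cmp <- tens3$tensors[i1[1], i1[2], i1[3], ]
  D <- matrix(c(cmp[1], cmp[4], cmp[5], cmp[4], cmp[2], cmp[6],
                cmp[5], cmp[6], cmp[3]), 3, 3)
  v <- eigen(D, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(v[3]), 1 - 1e-9)
})

test_that("forward signals follow the Stejskal-Tanner model exactly", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec, noise_free = TRUE)
  # independent recomputation of S = S0 exp(-b g' D g) at a few voxels
  set.seed(1)
  vox <- cbind(sample(40, 6), sample(12, 6), sample(30, 6))
  for (r in seq_len(nrow(vox))) {
    i <- vox[r, 1]; j <- vox[r, 2]; k <- vox[r, 3]
    cmp <- ph$tensors$tensors[i, j, k, ]
    D <- matrix(c(cmp[1], cmp[4], cmp[5], cmp[4], cmp[2], cmp[6],
                  cmp[5], cmp[6], cmp[3]), 3, 3)
    s0 <- ph$s0_map[i, j, k]
    for (v in seq_along(ph$table$bvalues)) {
      g <- ph$table$directions[v, ]
      expected <- s0 * exp(-ph$table$bvalues[v] * drop(t(g) %*% D %*% g))
      expect_equal(ph$stack$data[i, j, k, v], expected, tolerance = 1e-12)
    }
  }
  # isotropic tensor: identical attenuation in every direction
  iso <- uniform_tensor_volume(c(4L, 4L, 4L), c(1, 1, 1), eigs = rep(1e-3, 3))
  sim <- simulate_dwi(iso, phantom_spec(grid_shape = c(4L, 4L, 4L),
                                        voxel_size = c(1, 1, 1)),
                      noise_free = TRUE)
  dw <- sim$stack$data[1, 1, 1, !sim$table$b0]
  expect_equal(max(dw) - min(dw), 0, tolerance = 1e-12)
  expect_equal(sim$stack$data[1, 1, 1, sim$table$b0], 100)
})

test_that("simulated noise level matches the requested SNR", {
  spec <- phantom_spec(seed = 11L)
  ph <- generate_phantom(spec)
  est <- snr_map(ph$stack, ph$table, ph$noise, ph$truth$labels$labels > 0)
  expect_lt(abs(est$snr - spec$snr) / spec$snr, 0.05)
  # sigma estimated from the Rician noise scan second moment
  expect_lt(abs(est$sigma - spec$s0 / spec$snr) / (spec$s0 / spec$snr), 0.05)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(small_phantom_spec(seed = 5L))
  b <- generate_phantom(small_phantom_spec(seed = 5L))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$noise$values, b$noise$values)
  expect_identical(a$table$directions, b$table$directions)
  c <- generate_phantom(small_phantom_spec(seed = 6L))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("repulsion direction schemes are unit-norm and well spread", {
  dirs <- repulsion_directions(12, seed = 3L)
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, 12), tolerance = 1e-9)
  ang <- acos(pmin(abs(tcrossprod(dirs)), 1)) * 180 / pi
  diag(ang) <- Inf
  expect_gt(min(ang), 25)
  expect_identical(dirs, repulsion_directions(12, seed = 3L))
})

test_that("phantom files round-trip through disk", {
  ph <- generate_phantom(small_phantom_spec(seed = 9L))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  back <- read_dwi(paths["dwi"], paths["bvec"], paths["bval"])
  expect_identical(back$stack$data, ph$stack$data)
  expect_equal(back$stack$grid$voxel_size, ph$stack$grid$voxel_size,
               tolerance = 1e-6)
  expect_equal(back$table$directions, ph$table$directions, tolerance = 1e-9)
  expect_identical(back$table$bvalues, ph$table$bvalues)
  labs <- read_labels(paths["labels"])
  expect_identical(labs$labels, ph$truth$labels$labels)
  side <- jsonlite::read_json(paths["json"])
  expect_equal(side$true_fascicle_length, ph$truth$true_fascicle_length)
})
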