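test_that("stopping configuration enforces its invariants", {
  expect_error(stopping_config(fa_range = c(0.7, 0.1)), "fa_range")
  expect_error(stopping_config(step_length = 0), "step_length")
  expect_error(stopping_config(td_threshold = 0.9,
                               td_map = scalar_map(array(1, c(2, 2, 2)), "TD",
                                                   c(1, 1, 1))),
               "td_threshold")
  expect_error(stopping_config(td_threshold = 1.5), "td_map")
})

test_that("seed lattices have the expected geometry", {
  g <- vox_grid(c(10L, 10L, 10L), c(1, 1, 1))
  s <- seed_grid(g, 1)
  expect_equal(nrow(s), 1000L)
  # anchored at corner + half spacing
  expect_equal(min(s[, 1]), 0.5)
  expect_equal(max(s[, 3]), 9.5)
  # spacing larger than the volume still yields a central seed
  s2 <- seed_grid(g, 50)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2[1, ], c(5, 5, 5))
  # clipping to a mask matches the mask volume to within a lattice shell
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[3:8, 3:8, 3:8] <- TRUE
  s3 <- seed_grid(g, 1, mask)
  expect_equal(nrow(s3), sum(mask))  # 1 mm lattice on a 1 mm grid: one per voxel
  expect_warning(s4 <- seed_grid(g, 1, array(FALSE, dim = c(10, 10, 10))),
                 "empty")
  expect_equal(nrow(s4), 0L)
})

test_that("erosion stops at the first crossing of the target fraction", {
  cube <- array(FALSE, dim = c(34, 34, 34))
  cube[3:32, 3:32, 3:32] <- TRUE   # 30^3
  e <- erode_to_fraction(cube, 0.9)
  expect_identical(e, erode_n(cube, 1))
  expect_equal(sum(e) / sum(cube), (28 / 30)^3, tolerance = 1e-12)
  # tiny mask whose erosion would vanish: original returned with warning
  tiny <- array(FALSE, dim = c(4, 4, 4))
  tiny[2, 2, 2:3] <- TRUE
  expect_warning(kept <- erode_to_fraction(tiny, 0.9), "empty")
  expect_identical(kept, tiny)
  # large digital ball: result lands in [0.8, 0.9] of the original volume
  idx <- expand.grid(x = 1:31, y = 1:31, z = 1:31)
  ball <- array((idx$x - 16)^2 + (idx$y - 16)^2 + (idx$z - 16)^2 <= 13^2,
                dim = c(31, 31, 31))
  eb <- erode_to_fraction(ball, 0.9)
  expect_gte(sum(eb) / sum(ball), 0.8 - 1e-12)
  expect_lte(sum(eb) / sum(ball), 0.9)
})

test_that("a straight uniform field is tracked end to end", {
  tv <- uniform_tensor_volume(c(20L, 20L, 60L), c(1, 1, 1))
  fa <- fa_map(tv)
  tg <- track(matrix(c(10, 10, 30), 1), tv, fa,
              stopping_config(step_length = 1, min_length = 0))
  expect_equal(n_streamlines(tg), 1L)
  expect_equal(tg$length, 60)                      # the full FA-valid extent
  expect_equal(as.character(tg$term_first), "left_volume")
  expect_equal(as.character(tg$term_last), "left_volume")
  pts <- streamline_points(tg, 1)
  # consecutive points exactly one step apart; no lateral drift
  expect_equal(range(sqrt(rowSums(diff(pts)^2))), c(1, 1), tolerance = 1e-9)
  expect_equal(range(pts[, 1]), c(10, 10))
  # seed sits at the midpoint (bidirectional symmetry)
  expect_equal(pts[which(pts[, 3] == 30), ], c(10, 10, 30))
  expect_equal(sum(pts[, 3] < 30), sum(pts[, 3] > 30))
  # reported length consistent with point count
  expect_equal(tg$length, (nrow(pts) - 1) * 1)
})

test_that("a field rotating 25 degrees per step halts on the angle criterion", {
  tv <- rotating_tensor_volume(c(20L, 20L, 40L), c(1, 1, 1), deg_per_mm = 25,
                               z0 = 20)
  fa <- fa_map(tv)
  tg <- track(matrix(c(10, 10, 20), 1), tv, fa,
              stopping_config(step_length = 1, max_angle_per_step = 20,
                              min_length = 0))
  expect_equal(n_streamlines(tg), 1L)
  expect_equal(as.character(tg$term_first), "angle_exceeded")
  expect_equal(as.character(tg$term_last), "angle_exceeded")
  expect_lte(tg$length, 2)  # halts at the first rotation
  # the same field is followed happily when the limit is generous
  tg2 <- track(matrix(c(10, 10, 20), 1), tv, fa,
               stopping_config(step_length = 1, max_angle_per_step = 40,
                               min_length = 0))
  expect_gt(tg2$length, 10)
})

test_that("FA outside the window yields no streamlines", {
  # uniform FA ~0.05: below the 0.1 lower bound
  tv <- uniform_tensor_volume(c(10L, 10L, 10L), c(1, 1, 1),
                              eigs = c(1.1, 1.0, 1.0) * 1e-3)
  fa <- fa_map(tv)
  expect_lt(fa$values[1, 1, 1], 0.1)
  tg <- track(seed_grid(tv, 3), tv, fa, stopping_config(min_length = 0))
  expect_equal(n_streamlines(tg), 0L)
  expect_equal(tg$diagnostics$n_seed_invalid, tg$diagnostics$n_seeds)
})

test_that("tensor antipodal symmetry leaves tracking unchanged", {
  # the tensor of an axis v equals that of -v, so tracks cannot depend on the
  # eigenvector sign convention
  d <- c(12L, 12L, 24L)
  ax <- c(0.3, 0.1, 0.95); ax <- ax / sqrt(sum(ax^2))
  a <- uniform_tensor_volume(d, c(1, 1, 1), axis = ax)
  b <- uniform_tensor_volume(d, c(1, 1, 1), axis = -ax)
  expect_identical(a$tensors, b$tensors)
  fa <- fa_map(a)
  seeds <- seed_grid(a, 4)
  ta <- track(seeds, a, fa, stopping_config(min_length = 0))
  tb <- track(seeds, b, fa, stopping_config(min_length = 0))
  expect_identical(ta$points, tb$points)
})

test_that("tracking is deterministic", {
  ph <- generate_phantom(small_phantom_spec(seed = 12L))
  tens <- fit_wlls(ph$stack, ph$table)
  fa <- fa_map(tens)
  seeds <- seed_grid(tens, 3, ph$truth$foreground)
  a <- track(seeds, tens, fa)
  b <- track(seeds, tens, fa)
  expect_identical(a$points, b$points)
  expect_identical(a$length, b$length)
  expect_identical(a$term_first, b$term_first)
})

test_that("boundary and TD criteria stop propagation where they should", {
  ph <- generate_phantom(small_phantom_spec(seed = 13L))
  tens <- fit_wlls(ph$stack, ph$table)
  fa <- fa_map(tens)
  labs <- ph$truth$labels$labels
  seeds <- seed_grid(tens, 3, labs == 1L)
  # mask = whole volume: identical to unmasked tracking
  whole <- array(TRUE, dim = tens$grid$dim)
  t_plain <- track(seeds, tens, fa, stopping_config(min_length = 0))
  t_whole <- boundary_track(seeds, tens, fa, whole, min_length = 0)
  expect_identical(t_plain$points, t_whole$points)
  # mask excluding all seeds: empty tractogram
  t_none <- boundary_track(seeds, tens, fa, labs == 99L, min_length = 0)
  expect_equal(n_streamlines(t_none), 0L)
  # real muscle mask: left_mask terminations, lengths below truth
  t_b <- boundary_track(seeds, tens, fa, labs == 1L, min_length = 0)
  expect_gt(mean(t_b$term_first == "left_mask" | t_b$term_last == "left_mask"),
            0.5)
  expect_lt(median(t_b$length), ph$truth$true_fascicle_length)
  # uniform TD = 1 map stops nothing; TD > threshold stops everything
  td1 <- scalar_map(array(1, tens$grid$dim), "TD", tens$grid$voxel_size)
  t_td <- track(seeds, tens, fa,
                stopping_config(td_threshold = 1.5, td_map = td1,
                                min_length = 0))
  expect_identical(t_td$points, t_plain$points)
  td_hot <- scalar_map(array(2, tens$grid$dim), "TD", tens$grid$voxel_size)
  t_hot <- track(seeds, tens, fa,
                 stopping_config(td_threshold = 1.5, td_map = td_hot,
                                 min_length = 0))
  expect_equal(n_streamlines(t_hot), 0L)
})

test_that("FA-only tracking equals plain tracking when no tendon exists", {
  # tendon-free phantom: tissue fraction identically zero
  spec <- small_phantom_spec(seed = 14L)
  truth <- build_geometry(spec)
  truth$tissue_fraction[] <- 0
  tens <- tensor_field(truth, spec)
  sim <- simulate_dwi(tens, spec, noise_free = TRUE)
  fit <- fit_wlls(sim$stack, sim$table)
  fa <- fa_map(fit)
  seeds <- seed_grid(fit, 4, truth$labels$labels > 0)
  a <- fa_only_track(seeds, fit, fa, fa_range = c(0.15, 0.65), min_length = 0)
  b <- track(seeds, fit, fa,
             stopping_config(fa_range = c(0.15, 0.65), min_length = 0))
  expect_identical(a$points, b$points)
})

test_that("streamlines shorter than min_length are discarded", {
  tv <- uniform_tensor_volume(c(20L, 20L, 10L), c(1, 1, 1))
  fa <- fa_map(tv)
  seeds <- matrix(c(10, 10, 5), 1)
  short <- track(seeds, tv, fa, stopping_config(min_length = 20))
  expect_equal(n_streamlines(short), 0L)
  expect_equal(short$diagnostics$n_short, 1L)
  kept <- track(seeds, tv, fa, stopping_config(min_length = 5))
  expect_equal(n_streamlines(kept), 1L)
})
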