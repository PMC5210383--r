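#' Stopping configuration for deterministic tractography
#'
#' Bundles the criteria that halt streamline propagation: the FA window, the
#' maximum angle change per step, length bounds, and optionally a tract
#' density threshold (with its TD map) or a binary boundary mask.
#'
#' @param fa_range numeric length 2, allowed FA window `[low, high]`.
#' @param max_angle_per_step degrees.
#' @param step_length mm per integration step.
#' @param min_length mm; shorter streamlines are discarded.
#' @param td_threshold optional unit-less normalized TD stopping threshold
#'   (> 1); requires `td_map`.
#' @param td_map optional [scalar_map()] of normalized tract density.
#' @param boundary_mask optional logical/integer 3D array (or
#'   [label_volume()]): propagation halts on leaving the nonzero region.
#' @param max_length mm, safety cap on total streamline length.
#' @return An object of class `stopping_config`.
#' @export
stopping_config <- function(fa_range = c(0.1, 0.7), max_angle_per_step = 20,
                            step_length = 1, min_length = 2,
                            td_threshold = NULL, td_map = NULL,
                            boundary_mask = NULL, max_length = 500) {
  stopifnot(length(fa_range) == 2L)
  if (!(fa_range[1] >= 0 && fa_range[1] < fa_range[2] && fa_range[2] <= 1))
    stop("fa_range must satisfy 0 <= low < high <= 1")
  if (step_length <= 0) stop("step_length must be positive")
  if (min_length < 0) stop("min_length must be nonnegative")
  if (max_length <= 0) stop("max_length must be positive")
  if (max_angle_per_step <= 0 || max_angle_per_step >= 90)
    stop("max_angle_per_step must lie in (0, 90) degrees")
  if (!is.null(td_threshold)) {
    if (td_threshold <= 1)
      stop("td_threshold must exceed 1 (normalized muscle TD is ~1)")
    if (is.null(td_map)) stop("td_threshold requires a td_map")
  }
  structure(list(fa_range = as.numeric(fa_range),
                 max_angle_per_step = max_angle_per_step,
                 step_length = step_length, min_length = min_length,
                 td_threshold = td_threshold, td_map = td_map,
                 boundary_mask = boundary_mask, max_length = max_length),
            class = "stopping_config")
}

#' @export
print.stopping_config <- function(x, ...) {
  cat(sprintf("<stopping_config> FA [%.2f, %.2f], %g deg/step, step %g mm, length [%g, %g] mm%s%s\n",
              x$fa_range[1], x$fa_range[2], x$max_angle_per_step,
              x$step_length, x$min_length, x$max_length,
              if (!is.null(x$td_threshold))
                sprintf(", TD stop > %g", x$td_threshold) else "",
              if (!is.null(x$boundary_mask)) ", boundary mask" else ""))
  invisible(x)
}

#' Regular seed lattice clipped to a mask
#'
#' World-space lattice with the requested spacing, anchored at the lower
#' physical corner of the volume plus half a spacing, retained where the
#' nearest voxel of `mask` is nonzero. Ordering is deterministic
#' (lexicographic in x, then y, then z).
#'
#' @param x an object carrying a grid ([dwi_stack()], [scalar_map()],
#'   [label_volume()], [vox_grid()]).
#' @param spacing numeric length 1 or 3, mm.
#' @param mask optional logical/integer 3D array; default: everywhere.
#' @return n x 3 matrix of world-mm seed points.
#' @export
seed_grid <- function(x, spacing, mask = NULL) {
  grid <- as_vox_grid(x)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(spacing > 0))
  ext <- grid_extent(grid)
  ax <- lapply(1:3, function(a) {
    first <- ext$lower[a] + spacing[a] / 2
    if (first > ext$upper[a]) return((ext$lower[a] + ext$upper[a]) / 2)
    s <- seq(first, ext$upper[a], by = spacing[a])
    s[s < ext$upper[a] + 1e-12]
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- NULL
  if (!is.null(mask)) {
    if (inherits(mask, "label_volume")) mask <- mask$labels
    mask <- mask > 0
    ci <- round(world_to_index(grid, pts))
    ci[, 1] <- pmin(pmax(ci[, 1], 0), grid$dim[1] - 1)
    ci[, 2] <- pmin(pmax(ci[, 2], 0), grid$dim[2] - 1)
    ci[, 3] <- pmin(pmax(ci[, 3], 0), grid$dim[3] - 1)
    lin <- 1 + ci[, 1] + grid$dim[1] * (ci[, 2] + grid$dim[2] * ci[, 3])
    keep <- mask[lin]
    if (!any(keep)) {
      warning("seed mask is empty: no seeds generated")
      return(pts[integer(0), , drop = FALSE])
    }
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

#' Erode a mask to (about) a target volume fraction
#'
#' Repeated one-voxel binary erosion with the 6-connected structuring element
#' until the voxel count first drops to at most `fraction` times the original
#' count. Voxels on the volume border erode (out-of-volume neighbours count
#' as background). Never returns an empty mask: if the next erosion would
#' empty it, the last nonempty mask is returned with a warning.
#'
#' @param mask logical/integer 3D array or a [label_volume()] (nonzero =
#'   foreground).
#' @param fraction target fraction in (0, 1).
#' @return Logical 3D array.
#' @export
erode_to_fraction <- function(mask, fraction = 0.9) {
  if (inherits(mask, "label_volume")) mask <- mask$labels
  mask <- mask > 0
  stopifnot(length(dim(mask)) == 3L)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  n0 <- sum(mask)
  if (n0 == 0L) stop("cannot erode an empty mask")
  cur <- mask
  repeat {
    if (sum(cur) <= fraction * n0) return(cur)
    nxt <- erode_once6(cur)
    if (!any(nxt)) {
      warning("erosion would empty the mask; returning the previous mask")
      return(cur)
    }
    cur <- nxt
  }
}

# one 6-connected binary erosion via array shifts
erode_once6 <- function(m) {
  d <- dim(m)
  out <- m
  pad_shift <- function(m, axis, by) {
    r <- array(FALSE, dim = d)
    n <- d[axis]
    if (by == 1) {
      src <- 2:n; dst <- 1:(n - 1)
    } else {
      src <- 1:(n - 1); dst <- 2:n
    }
    if (axis == 1) r[dst, , ] <- m[src, , ]
    if (axis == 2) r[, dst, ] <- m[, src, ]
    if (axis == 3) r[, , dst] <- m[, , src]
    r
  }
  for (axis in 1:3) {
    if (d[axis] == 1L) { out[] <- FALSE; next }
    out <- out & pad_shift(m, axis, 1) & pad_shift(m, axis, -1)
  }
  out
}

.term_levels <- c("fa_out_of_range", "angle_exceeded", "td_exceeded",
                  "left_mask", "left_volume", "max_length")

#' Deterministic streamline tractography
#'
#' Propagates bidirectionally from each seed by fixed-step Euler integration
#' along the principal diffusion direction. At each step the six tensor
#' components are trilinearly interpolated at the current point and the
#' principal eigenvector is computed there, sign-aligned with the previous
#' direction. A step is accepted only if (a) the interpolated FA at the new
#' point lies inside `fa_range`, (b) the angle to the previous direction does
#' not exceed `max_angle_per_step`, (c) the normalized TD at the new point
#' (nearest-voxel lookup) does not exceed `td_threshold` when a TD criterion
#' is active, (d) the new point lies inside the boundary mask (when active)
#' and inside the volume, and (e) the total length stays below `max_length`.
#' The two half-tracks are concatenated with the seed in the interior;
#' streamlines shorter than `min_length` are discarded (counted in
#' `diagnostics`). Output is deterministic given the seed order.
#'
#' @param seeds n x 3 matrix of world-mm seed points (see [seed_grid()]).
#' @param tensors a [tensor_volume()].
#' @param fa the matching FA [scalar_map()].
#' @param config a [stopping_config()].
#' @return An object of class `tractogram`: `points` (m x 3), `n_points`
#'   (points per streamline), `length` (mm), `term_first`/`term_last`
#'   (factor: termination reason of each end), `seed_index`, `config`,
#'   `grid`, `diagnostics`.
#' @export
track <- function(seeds, tensors, fa, config = stopping_config()) {
  stopifnot(inherits(tensors, "tensor_volume"), inherits(fa, "scalar_map"),
            inherits(config, "stopping_config"))
  if (!same_grid(tensors, fa)) stop("tensor volume and FA map grids differ")
  seeds <- matrix(as.numeric(seeds), ncol = 3L)
  g <- tensors$grid
  td_vals <- NULL
  if (!is.null(config$td_threshold)) {
    if (!same_grid(config$td_map, tensors)) stop("TD map grid differs")
    td_vals <- as.numeric(config$td_map$values)
  }
  mask_vals <- NULL
  if (!is.null(config$boundary_mask)) {
    bm <- config$boundary_mask
    if (inherits(bm, "label_volume")) bm <- bm$labels
    if (!all(dim(bm) == g$dim)) stop("boundary mask grid differs")
    mask_vals <- as.integer(bm > 0)
  }
  res <- .cpp_track(g$dim, g$voxel_size, g$origin,
                    as.numeric(tensors$tensors), as.numeric(fa$values),
                    seeds, config$step_length, config$max_angle_per_step,
                    config$fa_range[1], config$fa_range[2],
                    config$min_length, config$max_length,
                    td_vals, config$td_threshold %||% Inf, mask_vals)
  structure(list(points = res$points, n_points = res$n_points,
                 length = res$length,
                 term_first = factor(.term_levels[res$term_first],
                                     levels = .term_levels),
                 term_last = factor(.term_levels[res$term_last],
                                    levels = .term_levels),
                 seed_index = res$seed_index, config = config, grid = g,
                 diagnostics = list(n_seeds = nrow(seeds),
                                    n_seed_invalid = res$n_seed_invalid,
                                    n_short = res$n_short)),
            class = "tractogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$n_points)
  cat(sprintf("<tractogram> %d streamlines, %d points, length %.1f-%.1f mm (median %.1f)\n",
              n, nrow(x$points),
              if (n) min(x$length) else NA, if (n) max(x$length) else NA,
              if (n) median(x$length) else NA))
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param tractogram a `tractogram`.
#' @export
n_streamlines <- function(tractogram) length(tractogram$n_points)

#' Extract one streamline's point matrix
#' @param tractogram a `tractogram`.
#' @param i streamline index.
#' @return k x 3 matrix of world-mm points.
#' @export
streamline_points <- function(tractogram, i) {
  ends <- cumsum(tractogram$n_points)
  starts <- ends - tractogram$n_points + 1L
  tractogram$points[starts[i]:ends[i], , drop = FALSE]
}

# subset a tractogram by streamline index (logical or integer)
subset_tractogram <- function(tg, keep) {
  idx <- if (is.logical(keep)) which(keep) else keep
  ends <- cumsum(tg$n_points)
  starts <- ends - tg$n_points + 1L
  rows <- unlist(lapply(idx, function(i) starts[i]:ends[i]), use.names = FALSE)
  tg$points <- tg$points[rows, , drop = FALSE]
  tg$n_points <- tg$n_points[idx]
  tg$length <- tg$length[idx]
  tg$term_first <- tg$term_first[idx]
  tg$term_last <- tg$term_last[idx]
  tg$seed_index <- tg$seed_index[idx]
  tg
}

#' FA-window-only tractography (comparison method 1)
#'
#' Conventional fascicle tracking that relies on the FA window alone
#' (default 0.15-0.65) with no TD criterion and no boundary mask. Used as the
#' first conventional comparator for the TD method.
#'
#' @inheritParams track
#' @param fa_range the FA stopping window.
#' @param ... further arguments passed to [stopping_config()].
#' @export
fa_only_track <- function(seeds, tensors, fa, fa_range = c(0.15, 0.65), ...) {
  track(seeds, tensors, fa,
        stopping_config(fa_range = fa_range, td_threshold = NULL,
                        td_map = NULL, boundary_mask = NULL, ...))
}

#' Muscle-boundary tractography (comparison method 2)
#'
#' Conventional fascicle tracking halted at the segmented muscle boundary:
#' propagation stops when the next point falls outside `muscle_mask`. No TD
#' criterion.
#'
#' @inheritParams track
#' @param muscle_mask logical/integer 3D array or [label_volume()].
#' @param ... further arguments passed to [stopping_config()].
#' @export
boundary_track <- function(seeds, tensors, fa, muscle_mask, ...) {
  track(seeds, tensors, fa,
        stopping_config(boundary_mask = muscle_mask, td_threshold = NULL,
                        td_map = NULL, ...))
}
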