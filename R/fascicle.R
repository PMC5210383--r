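#' Exclude streamlines terminating at the field-of-view edges
#'
#' Streamlines whose proximal or distal endpoint lies within `margin` of the
#' inferior or superior (z) face of the volume do not represent a full
#' fascicle (the fascicle continues outside the FOV) and are removed before
#' length analysis.
#'
#' @param tractogram a `tractogram` (see [track()]).
#' @param grid grid defining the volume extent; defaults to the tractogram's.
#' @param margin mm; default one slice thickness (the z voxel size).
#' @return list with `tractogram` (retained streamlines), `n_excluded`, and
#'   `all_excluded` flag.
#' @export
exclude_fov_edges <- function(tractogram, grid = tractogram$grid,
                              margin = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  if (n_streamlines(tractogram) == 0L)
    stop("empty tractogram: nothing to filter")
  grid <- as_vox_grid(grid)
  if (is.null(margin)) margin <- grid$voxel_size[3]
  ext <- grid_extent(grid)
  ends <- cumsum(tractogram$n_points)
  starts <- ends - tractogram$n_points + 1L
  z_first <- tractogram$points[starts, 3]
  z_last <- tractogram$points[ends, 3]
  near_edge <- function(z) z <= ext$lower[3] + margin | z >= ext$upper[3] - margin
  excluded <- near_edge(z_first) | near_edge(z_last)
  out <- subset_tractogram(tractogram, !excluded)
  list(tractogram = out, n_excluded = sum(excluded),
       all_excluded = !any(!excluded))
}

# skew-normal density: location xi, scale omega > 0, shape alpha
dsn <- function(x, xi, omega, alpha, log = FALSE) {
  z <- (x - xi) / omega
  lg <- log(2) - log(omega) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) lg else exp(lg)
}

# skew-normal sampler (for tests/simulations): Z = delta|U0| + sqrt(1-d^2) U1
rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

# analytic mean of the skew-normal distribution
sn_mean <- function(xi, omega, alpha) {
  xi + omega * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

#' Fit a skew-normal ("skewed Gaussian") distribution to a length sample
#'
#' Maximum-likelihood fit of the three-parameter skew-normal family
#' (location xi, scale omega, shape alpha) to the raw per-streamline length
#' sample, initialized by method of moments. The headline mean fascicle
#' length is the mean of the fitted distribution,
#' `xi + omega * delta * sqrt(2/pi)` with `delta = alpha / sqrt(1 + alpha^2)`.
#' If the optimizer fails, the fit falls back to the Gaussian sub-model
#' (alpha = 0, mean = sample mean) with `converged = FALSE`.
#'
#' @param lengths numeric sample of streamline lengths, mm, all positive.
#' @param min_sample minimum sample size for a fit to be reported.
#' @param muscle optional muscle id carried through to the result.
#' @return An object of class `fascicle_length_result` with fields `muscle`,
#'   `lengths`, `n`, `n_excluded_fov`, `xi`, `omega`, `alpha`,
#'   `mean_fascicle_length` (mm), `mode_fascicle_length`, `sample_mean`,
#'   `loglik`, `converged`, `degenerate`.
#' @export
fit_skew_gaussian <- function(lengths, min_sample = 50L, muscle = NA) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be finite and positive")
  n <- length(lengths)
  if (n < min_sample)
    stop("sample size ", n, " below the minimum of ", min_sample,
         " for a distribution fit")
  m <- mean(lengths); s <- sd(lengths)
  if (s < 1e-10 * max(m, 1)) {
    return(new_flr(muscle, lengths, xi = m, omega = 1e-10 * max(m, 1),
                   alpha = 0, loglik = NA_real_, converged = FALSE,
                   degenerate = TRUE))
  }
  # method-of-moments start: sample skewness -> delta
  g1 <- mean((lengths - m)^3) / s^3
  g1 <- sign(g1) * min(abs(g1), 0.95)
  b <- sqrt(2 / pi)
  r <- abs(g1)^(2 / 3)
  delta <- sign(g1) * sqrt(pi / 2 * r / (r + ((4 - pi) / 2)^(2 / 3)))
  delta <- max(min(delta, 0.995), -0.995)
  alpha0 <- delta / sqrt(1 - delta^2)
  omega0 <- s / sqrt(max(1 - b^2 * delta^2, 1e-6))
  xi0 <- m - omega0 * b * delta
  nll <- function(par) {
    xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
    v <- -sum(dsn(lengths, xi, omega, alpha, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- tryCatch(
    optim(c(xi0, log(omega0), alpha0), nll, method = "Nelder-Mead",
          control = list(maxit = 2000L, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fit2 <- tryCatch(
      optim(fit$par, nll, method = "BFGS", control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit2) && fit2$value <= fit$value) fit <- fit2
  }
  if (is.null(fit) || !all(is.finite(fit$par))) {
    return(new_flr(muscle, lengths, xi = m, omega = s, alpha = 0,
                   loglik = sum(dnorm(lengths, m, s, log = TRUE)),
                   converged = FALSE, degenerate = FALSE))
  }
  new_flr(muscle, lengths, xi = fit$par[1], omega = exp(fit$par[2]),
          alpha = fit$par[3], loglik = -fit$value, converged = TRUE,
          degenerate = FALSE)
}

new_flr <- function(muscle, lengths, xi, omega, alpha, loglik, converged,
                    degenerate, n_excluded_fov = NA_integer_) {
  delta <- alpha / sqrt(1 + alpha^2)
  structure(list(muscle = muscle, lengths = lengths, n = length(lengths),
                 n_excluded_fov = n_excluded_fov,
                 xi = xi, omega = omega, alpha = alpha,
                 mean_fascicle_length = sn_mean(xi, omega, alpha),
                 mode_fascicle_length = sn_mode(xi, omega, alpha),
                 sample_mean = mean(lengths), loglik = loglik,
                 converged = converged, degenerate = degenerate),
            class = "fascicle_length_result")
}

# numeric mode of the skew-normal (no closed form); good approximation + polish
sn_mode <- function(xi, omega, alpha) {
  if (abs(alpha) < 1e-12) return(xi)
  delta <- alpha / sqrt(1 + alpha^2)
  muz <- sqrt(2 / pi) * delta
  sz <- sqrt(max(1 - muz^2, 1e-12))
  g1 <- (4 - pi) / 2 * muz^3 / sz^3
  m0 <- muz - g1 * sz / 2 - sign(alpha) / 2 * exp(-2 * pi / abs(alpha))
  opt <- optim(m0, function(z) -dsn(z, 0, 1, alpha, log = TRUE),
               method = "Brent", lower = m0 - 1, upper = m0 + 1)
  xi + omega * opt$par
}

#' @export
print.fascicle_length_result <- function(x, ...) {
  cat(sprintf(paste0("<fascicle_length_result>%s n = %d tracts",
                     " (%s FOV-excluded)\n",
                     "  skew-normal fit: xi = %.2f mm, omega = %.2f mm, ",
                     "alpha = %.2f%s\n",
                     "  mean fascicle length = %.2f mm (%.2f cm)\n"),
              if (is.na(x$muscle)) "" else paste0(" muscle ", x$muscle),
              x$n,
              if (is.na(x$n_excluded_fov)) "?" else x$n_excluded_fov,
              x$xi, x$omega, x$alpha,
              if (!x$converged) " [fallback: not converged]" else "",
              x$mean_fascicle_length, x$mean_fascicle_length / 10))
  invisible(x)
}

#' Per-muscle fascicle lengths via TD-stopped tractography
#'
#' The per-muscle second tracking pass: seeds on a regular lattice inside the
#' muscle mask eroded to ~90% of its volume, TD-threshold stopping using the
#' whole-volume TD map, FOV-edge exclusion, and the skew-normal length fit.
#'
#' @param tensors a [tensor_volume()].
#' @param fa the matching FA [scalar_map()].
#' @param td a `td_map` from the whole-volume first pass ([compute_td()]).
#' @param labels a [label_volume()].
#' @param muscle integer label of the muscle to analyse.
#' @param config a [run_config()] (pass-2 parameters are taken from it).
#' @return A `fascicle_length_result` (see [fit_skew_gaussian()]); the
#'   retained tractogram is attached as attribute `"tractogram"`.
#' @export
muscle_fascicle_pipeline <- function(tensors, fa, td, labels, muscle,
                                     config = run_config()) {
  stopifnot(inherits(td, "td_map"), inherits(labels, "label_volume"))
  mask <- labels$labels == muscle
  if (!any(mask)) stop("label ", muscle, " is empty")
  seeds_mask <- erode_to_fraction(mask, config$erosion_fraction)
  seeds <- seed_grid(labels, config$pass2$seed_spacing, seeds_mask)
  sc <- stopping_config(fa_range = config$pass2$fa_range,
                        max_angle_per_step = config$pass2$max_angle_per_step,
                        step_length = config$pass2$step_length,
                        min_length = config$pass2$min_length,
                        td_threshold = config$td_threshold, td_map = td$map,
                        max_length = config$pass2$max_length)
  tg <- track(seeds, tensors, fa, sc)
  finalize_length_result(tg, muscle, config)
}

finalize_length_result <- function(tg, muscle, config) {
  if (n_streamlines(tg) == 0L)
    stop("no streamlines reconstructed for muscle ", muscle)
  fov <- exclude_fov_edges(tg, margin = config$fov_margin)
  if (fov$all_excluded)
    stop("all streamlines of muscle ", muscle,
         " terminate at the FOV edges; no length sample")
  res <- fit_skew_gaussian(fov$tractogram$length,
                           min_sample = config$min_tract_sample,
                           muscle = muscle)
  res$n_excluded_fov <- fov$n_excluded
  attr(res, "tractogram") <- fov$tractogram
  res
}

#' Compare TD, FA-window and muscle-boundary stopping criteria
#'
#' Runs the three fascicle-tracking variants on identical seeds (the eroded
#' muscle lattice): TD-threshold stopping, the FA-window-only comparator
#' (default 0.15-0.65), and muscle-boundary stopping. Emits, per method, the
#' fitted length result and a normalized length histogram (total area 1).
#'
#' @inheritParams muscle_fascicle_pipeline
#' @param binwidth histogram bin width, mm.
#' @return list with `results` (named list of `fascicle_length_result`),
#'   `histograms` (data.frame: method, mid, density), `seeds`.
#' @export
compare_methods <- function(tensors, fa, td, labels, muscle,
                            config = run_config(), binwidth = 2) {
  mask <- labels$labels == muscle
  if (!any(mask)) stop("label ", muscle, " is empty")
  seeds_mask <- erode_to_fraction(mask, config$erosion_fraction)
  seeds <- seed_grid(labels, config$pass2$seed_spacing, seeds_mask)
  p2 <- config$pass2
  run <- list(
    td = function() track(seeds, tensors, fa, stopping_config(
      fa_range = p2$fa_range, max_angle_per_step = p2$max_angle_per_step,
      step_length = p2$step_length, min_length = p2$min_length,
      td_threshold = config$td_threshold, td_map = td$map,
      max_length = p2$max_length)),
    fa = function() fa_only_track(seeds, tensors, fa,
      fa_range = config$fa_compare_range,
      max_angle_per_step = p2$max_angle_per_step,
      step_length = p2$step_length, min_length = p2$min_length,
      max_length = p2$max_length),
    boundary = function() boundary_track(seeds, tensors, fa, mask,
      fa_range = p2$fa_range, max_angle_per_step = p2$max_angle_per_step,
      step_length = p2$step_length, min_length = p2$min_length,
      max_length = p2$max_length))
  results <- lapply(run, function(f) finalize_length_result(f(), muscle, config))
  all_len <- unlist(lapply(results, function(r) r$lengths))
  breaks <- seq(floor(min(all_len)) - binwidth, ceiling(max(all_len)) + binwidth,
                by = binwidth)
  histograms <- do.call(rbind, lapply(names(results), function(mth) {
    h <- graphics::hist(results[[mth]]$lengths, breaks = breaks, plot = FALSE)
    data.frame(method = mth, mid = h$mids, density = h$density)
  }))
  list(results = results, histograms = histograms, seeds = seeds)
}
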