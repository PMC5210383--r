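#' Diffusion gradient table
#'
#' Holds the diffusion sensitization scheme: one unit direction and one
#' b-value (s/mm^2) per acquired volume. Entries with b below `b0_threshold`
#' are treated as non-diffusion-weighted (b = 0). Directions on b > 0 rows are
#' re-normalized to unit length.
#'
#' @param directions numeric N x 3 matrix of gradient directions (image frame).
#' @param bvalues numeric vector of N b-values, s/mm^2.
#' @param b0_threshold b-values below this are treated as 0 (default 50).
#' @return An object of class `gradient_table` with elements `directions`
#'   (N x 3), `bvalues` (length N) and logical `b0` marking b = 0 rows.
#' @export
gradient_table <- function(directions, bvalues, b0_threshold = 50) {
  directions <- unname(as.matrix(directions))
  if (ncol(directions) != 3L) stop("directions must be an N x 3 matrix")
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("directions (", nrow(directions), " rows) and bvalues (",
         length(bvalues), ") disagree in length")
  b0 <- bvalues < b0_threshold
  bvalues[b0] <- 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(!b0 & nrm < 1e-8))
    stop("zero gradient direction on a diffusion-weighted (b > 0) row")
  directions[!b0, ] <- directions[!b0, , drop = FALSE] / nrm[!b0]
  directions[b0, ] <- 0
  if (sum(b0) < 1L) stop("gradient table needs at least one b = 0 entry")
  if (sum(!b0) < 6L)
    stop("gradient table needs at least 6 diffusion-weighted directions")
  structure(list(directions = directions, bvalues = bvalues, b0 = b0),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d volumes (%d b=0, %d weighted), b = %s s/mm^2\n",
              length(x$bvalues), sum(x$b0), sum(!x$b0),
              paste(unique(x$bvalues[!x$b0]), collapse = ", ")))
  invisible(x)
}

#' Read / write FSL-style bvec and bval files
#'
#' FSL dialect: `bvec` holds 3 whitespace-separated rows (x, y, z) of N
#' columns; `bval` holds one row of N b-values.
#'
#' @param bvec_path,bval_path file paths.
#' @return `read_gradient_table()` returns a [gradient_table()].
#' @export
read_gradient_table <- function(bvec_path, bval_path) {
  bvec <- as.matrix(utils::read.table(bvec_path))
  bval <- scan(bval_path, quiet = TRUE)
  if (nrow(bvec) != 3L)
    stop("bvec file must have exactly 3 rows (FSL convention), got ", nrow(bvec))
  if (ncol(bvec) != length(bval))
    stop("bvec has ", ncol(bvec), " columns but bval has ", length(bval),
         " entries")
  gradient_table(t(bvec), bval)
}

#' @rdname read_gradient_table
#' @param table a [gradient_table()].
#' @export
write_gradient_table <- function(table, bvec_path, bval_path) {
  m <- t(table$directions)
  writeLines(apply(format(m, digits = 17, scientific = FALSE), 1L, paste,
                   collapse = " "), bvec_path)
  writeLines(paste(format(table$bvalues, scientific = FALSE), collapse = " "),
             bval_path)
  invisible(c(bvec = bvec_path, bval = bval_path))
}

#' Evenly spread gradient directions by electrostatic repulsion
#'
#' Generates `n` unit directions whose antipodally-symmetrized set minimizes a
#' Coulomb-type energy, the standard way to design a diffusion scheme when the
#' scanner's direction table is unknown. Deterministic given `seed`.
#'
#' @param n number of directions.
#' @param seed integer RNG seed for the random initialization.
#' @param n_iter gradient-descent iterations.
#' @return n x 3 matrix of unit row vectors.
#' @export
repulsion_directions <- function(n, seed = 1L, n_iter = 2000L) {
  stopifnot(n >= 6L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- matrix(rnorm(3L * n), ncol = 3L)
  v <- v / sqrt(rowSums(v^2))
  step <- 0.05
  energy <- function(v) {
    d2a <- as.matrix(stats::dist(v))^2
    d2b <- (as.matrix(stats::dist(rbind(v, -v)))^2)[seq_len(n), n + seq_len(n)]
    diag(d2b) <- Inf
    d2a[d2a == 0] <- Inf
    sum(1 / d2a[upper.tri(d2a)]) + sum(1 / d2b[upper.tri(d2b, diag = TRUE)])
  }
  e_old <- energy(v)
  for (it in seq_len(n_iter)) {
    g <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      dif1 <- sweep(v[-i, , drop = FALSE], 2L, v[i, ], "-")   # v_j - v_i
      dif2 <- sweep(-v[-i, , drop = FALSE], 2L, v[i, ], "-")  # -v_j - v_i
      w1 <- (rowSums(dif1^2))^-2
      w2 <- (rowSums(dif2^2))^-2
      # force on i pushes away from both v_j and -v_j
      g[i, ] <- -2 * (colSums(dif1 * w1) + colSums(dif2 * w2))
    }
    vn <- v + step * g
    vn <- vn / sqrt(rowSums(vn^2))
    e_new <- energy(vn)
    if (e_new < e_old) {
      v <- vn; e_old <- e_new; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  unname(v)
}

# preserve caller RNG state around internal seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
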