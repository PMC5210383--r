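#' Write / read tractograms in TrackVis .trk format
#'
#' Minimal TrackVis interchange: the 1000-byte version-2 header plus one
#' (n, xyz...) record per streamline. Points are stored in TrackVis
#' "voxmm" convention (world mm of this package's axis-aligned grids, shifted
#' so the volume's lower corner is at 0). A JSON sidecar with the stopping
#' configuration and diagnostics is written alongside.
#'
#' @param tractogram a `tractogram` (see [track()]).
#' @param path output `.trk` path; the sidecar gets extension `.json`.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(tractogram, path) {
  g <- tractogram$grid
  ext <- grid_extent(g)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(g$dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(g$voxel_size), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")        # origin field (unused by readers)
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  writeBin(raw(200), con)                                       # scalar names
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  writeBin(raw(200), con)                                       # property names
  vox2ras <- diag(4); vox2ras[cbind(1:3, 1:3)] <- g$voxel_size
  vox2ras[1:3, 4] <- g$origin
  writeBin(as.numeric(t(vox2ras)), con, size = 4L, endian = "little")
  writeBin(raw(444), con)                                       # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)                # voxel_order
  writeBin(raw(4), con)                                         # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2), con)                                         # pad1
  writeBin(as.raw(c(0, 0)), con)                                # invert/swap flags
  writeBin(raw(4), con)
  writeBin(length(tractogram$n_points), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")                # version
  writeBin(1000L, con, size = 4L, endian = "little")             # hdr_size
  shift <- ext$lower
  ends <- cumsum(tractogram$n_points)
  starts <- ends - tractogram$n_points + 1L
  for (s in seq_along(tractogram$n_points)) {
    pts <- tractogram$points[starts[s]:ends[s], , drop = FALSE]
    pts <- sweep(pts, 2L, shift, "-")
    writeBin(tractogram$n_points[s], con, size = 4L, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  }
  sidecar <- list(
    n_streamlines = length(tractogram$n_points),
    step_length = tractogram$config$step_length %||% NA,
    fa_range = tractogram$config$fa_range %||% NA,
    max_angle_per_step = tractogram$config$max_angle_per_step %||% NA,
    min_length = tractogram$config$min_length %||% NA,
    td_threshold = tractogram$config$td_threshold,
    diagnostics = tractogram$diagnostics)
  jsonlite::write_json(sidecar, sub("\\.trk$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trk
#' @return `read_trk()` returns a `tractogram` (world-mm points; `config` and
#'   termination reasons are not stored in .trk and come back empty).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop(path, " is not a TrackVis .trk file")
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vox <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  vox2ras <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                    4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 2L + 4L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 2L, size = 4L, endian = "little")
  origin <- vox2ras[1:3, 4]
  if (all(vox2ras == 0)) origin <- vox / 2
  grid <- vox_grid(dim3, vox, origin)
  shift <- grid_extent(grid)$lower
  pts_list <- list()
  npts <- integer(0)
  repeat {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) == 0L) break
    rec <- readBin(con, "numeric", n * (3L + n_scalars), size = 4L,
                   endian = "little")
    m <- matrix(rec, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L,
                              endian = "little")
    pts_list[[length(pts_list) + 1L]] <- sweep(m, 2L, shift, "+")
    npts <- c(npts, n)
  }
  if (n_count > 0L && length(npts) != n_count)
    warning("trk header announced ", n_count, " streamlines, found ",
            length(npts))
  pts <- do.call(rbind, pts_list)
  if (is.null(pts)) pts <- matrix(numeric(0), 0L, 3L)
  lens <- vapply(pts_list, function(m) {
    if (nrow(m) < 2L) return(0)
    sum(sqrt(rowSums(diff(m)^2)))
  }, numeric(1))
  structure(list(points = pts, n_points = npts, length = lens,
                 term_first = factor(rep(NA_character_, length(npts)),
                                     levels = .term_levels),
                 term_last = factor(rep(NA_character_, length(npts)),
                                    levels = .term_levels),
                 seed_index = rep(NA_integer_, length(npts)),
                 config = NULL, grid = grid,
                 diagnostics = list()),
            class = "tractogram")
}
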