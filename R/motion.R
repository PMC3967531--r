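#' Framewise displacement from six rigid-body motion parameters
#'
#' FD at volume i is the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations converted to arc length on a
#' sphere of radius `rotation_radius_mm`. The first volume has no
#' predecessor and gets FD = 0 by convention.
#'
#' @param trace numeric T x 6 matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations; T >= 2
#' @param rotation_radius_mm sphere radius for the rotation-to-displacement
#'   conversion; 50 mm is the standard head-radius convention
#' @param rotation_units `"radians"` (default) or `"degrees"`
#' @return numeric vector of length T, FD in mm
#' @export
framewise_displacement <- function(trace, rotation_radius_mm = 50,
                                   rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  trace <- as.matrix(trace)
  stopifnot(ncol(trace) == 6L, nrow(trace) >= 2L)
  bad <- which(!is.finite(trace), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite motion parameter at volume ", bad[1L, 1L])
  }
  rot <- trace[, 4:6, drop = FALSE]
  if (rotation_units == "degrees") rot <- rot * pi / 180
  d_tr <- abs(diff(trace[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot)) * rotation_radius_mm
  c(0, rowSums(d_tr) + rowSums(d_rot))
}

#' Percent-signal RMSD between consecutive volumes
#'
#' An intensity-based motion proxy: for each volume i >= 1, the root mean
#' square over brain voxels of the difference to the previous volume,
#' expressed as percent of each voxel's temporal mean. Computed on
#' motion-corrected, unfiltered data. The first volume gets RMSD = 0.
#'
#' @param bold a [bold_series()] or a voxel x time numeric matrix
#' @param brain_mask logical/0-1 3D array (for a `bold_series`) or logical
#'   vector over voxel rows (for a matrix)
#' @return numeric vector of length T, RMSD in percent
#' @export
rmsd_percent <- function(bold, brain_mask) {
  if (inherits(bold, "bold_series")) {
    d <- dim(bold$data)
    if (!all(dim(brain_mask) == d[1:3])) stop("mask geometry mismatch")
    vox <- matrix(bold$data, prod(d[1:3]), d[4L])
    mask <- as.vector(brain_mask) != 0
  } else {
    vox <- as.matrix(bold)
    mask <- as.vector(brain_mask) != 0
    if (length(mask) != nrow(vox)) stop("mask length mismatch")
  }
  if (!any(mask)) stop("brain mask is empty")
  v <- vox[mask, , drop = FALSE]
  mu <- rowMeans(v)
  zero_mu <- mu == 0
  if (any(zero_mu)) {
    message(sum(zero_mu), " voxel(s) with zero temporal mean excluded from RMSD")
    v <- v[!zero_mu, , drop = FALSE]
    mu <- mu[!zero_mu]
    if (nrow(v) == 0L) stop("no usable voxels for RMSD")
  }
  pct <- 100 * v / mu
  d <- pct[, -1L, drop = FALSE] - pct[, -ncol(pct), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Flag motion/intensity contaminated volumes
#'
#' A volume is contaminated when FD strictly exceeds `fd_threshold_mm` or
#' RMSD strictly exceeds `rmsd_threshold_pct`.
#'
#' @param fd framewise displacement series (mm)
#' @param rmsd percent-signal RMSD series
#' @param fd_threshold_mm FD threshold, default 0.5 mm
#' @param rmsd_threshold_pct RMSD threshold, default 0.3 percent
#' @return logical vector of flags
#' @export
flag_contaminated <- function(fd, rmsd, fd_threshold_mm = 0.5,
                              rmsd_threshold_pct = 0.3) {
  if (length(fd) != length(rmsd)) {
    stop(sprintf("length mismatch: fd has %d volumes, rmsd %d",
                 length(fd), length(rmsd)))
  }
  fd > fd_threshold_mm | rmsd > rmsd_threshold_pct
}

# flagged runs -> list of (start, end, left unflagged index or NA, right or NA)
flagged_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) {
    list(start = starts[k], end = ends[k],
         left = if (starts[k] > 1L) starts[k] - 1L else NA_integer_,
         right = if (ends[k] < length(flags)) ends[k] + 1L else NA_integer_)
  })
}

#' Replace contaminated volumes by linear interpolation
#'
#' Each maximal run of flagged volumes is replaced by linear interpolation
#' between the nearest unflagged volumes on either side; runs touching the
#' start or end of the series take the nearest unflagged volume (constant
#' extrapolation). Unflagged volumes are untouched. Applied before
#' band-pass filtering.
#'
#' @param series a [bold_series()], [region_signals()] matrix, plain
#'   time x channel matrix, or vector
#' @param flags logical vector, one per volume
#' @return same type as `series` with flagged volumes replaced
#' @export
replace_volumes <- function(series, flags) {
  if (inherits(series, "bold_series")) {
    d <- dim(series$data)
    mat <- t(matrix(series$data, prod(d[1:3]), d[4L]))
    out <- replace_volumes(mat, flags)
    return(bold_series(array(t(out), d), series$affine, series$tr_seconds))
  }
  vec_in <- is.null(dim(series))
  x <- if (vec_in) matrix(series, ncol = 1L) else as.matrix(series)
  if (length(flags) != nrow(x)) {
    stop(sprintf("length mismatch: %d volumes, %d flags", nrow(x), length(flags)))
  }
  if (all(flags)) stop("all volumes are flagged; nothing to interpolate from")
  for (run in flagged_runs(flags)) {
    if (is.na(run$left) && is.na(run$right)) next  # unreachable: not all flagged
    if (is.na(run$left)) {
      x[run$start:run$end, ] <- x[rep(run$right, run$end - run$start + 1L), ,
                                  drop = FALSE]
    } else if (is.na(run$right)) {
      x[run$start:run$end, ] <- x[rep(run$left, run$end - run$start + 1L), ,
                                  drop = FALSE]
    } else {
      span <- run$right - run$left
      for (i in run$start:run$end) {
        w <- (i - run$left) / span
        x[i, ] <- (1 - w) * x[run$left, ] + w * x[run$right, ]
      }
    }
  }
  if (inherits(series, "region_signals")) return(restore_signals(x, series))
  if (vec_in) drop(x) else x
}

#' Compute the full quality-control series for one subject
#'
#' Convenience wrapper producing FD, RMSD and the contamination flags in a
#' single table.
#'
#' @inheritParams framewise_displacement
#' @inheritParams rmsd_percent
#' @inheritParams flag_contaminated
#' @return data.frame with columns `frame`, `fd_mm`, `rmsd_pct`, `flagged`
#' @export
qc_series <- function(trace, bold, brain_mask, rotation_radius_mm = 50,
                      fd_threshold_mm = 0.5, rmsd_threshold_pct = 0.3) {
  fd <- framewise_displacement(trace, rotation_radius_mm)
  rmsd <- rmsd_percent(bold, brain_mask)
  data.frame(frame = seq_along(fd),
             fd_mm = fd,
             rmsd_pct = rmsd,
             flagged = flag_contaminated(fd, rmsd, fd_threshold_mm,
                                         rmsd_threshold_pct))
}

#' Read a six-column motion trace from whitespace-delimited text
#'
#' @param path file with six numeric columns, one row per volume
#' @param order `"trans_first"` (default; columns are x,y,z translations
#'   then rotations) or `"rot_first"`
#' @param rotation_units units of the rotation columns as stored
#' @return T x 6 matrix in package order (translations mm, rotations
#'   radians)
#' @export
read_motion_trace <- function(path, order = c("trans_first", "rot_first"),
                              rotation_units = c("radians", "degrees")) {
  order <- match.arg(order)
  rotation_units <- match.arg(rotation_units)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns, got ", ncol(m))
  if (order == "rot_first") m <- m[, c(4:6, 1:3), drop = FALSE]
  if (rotation_units == "degrees") {
    m[, 4:6] <- m[, 4:6] * pi / 180
  }
  colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  m
}

#' Write a motion trace as whitespace-delimited text
#' @param trace T x 6 matrix, translations (mm) then rotations (radians)
#' @param path output file
#' @export
write_motion_trace <- function(trace, path) {
  utils::write.table(format(trace, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a QC series to TSV
#' @param qc data.frame from [qc_series()]
#' @param path output file
#' @export
write_qc_series <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
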