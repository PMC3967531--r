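## Zero-phase band-pass filtering and nuisance residualization.
##
## The filter is a 4th-order digital Butterworth band-pass (two poles per
## band edge, signal::butter) applied forward and backward. Zero-phase
## application matters here: a causal filter would impose frequency-
## dependent phase shifts that differ with each region's spectral content
## and bias pairwise correlations. The forward-backward pass squares the
## magnitude response, giving ~24 dB attenuation one octave outside the
## band. Edge transients are controlled as in common scientific-computing
## practice: odd-reflection padding plus steady-state initial conditions.

# steady-state initial state of a direct-form-II-transposed filter for a
# unit-step input (removes startup transients when scaled by the first
# sample)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  comp <- rbind(-a[2:n] / a[1L],
                cbind(diag(1, n - 2L), rep(0, n - 2L)))
  i_minus_a <- diag(n - 1L) - t(comp)
  bb <- b[2:n] - a[2:n] * b[1L]
  solve(i_minus_a, bb)
}

# causal IIR filtering of every column of x (T x K), direct form II
# transposed, vectorized across columns; zi is the per-unit state init
lfilter_mat <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1L]; a <- a / a[1L]
  nt <- nrow(x); k <- ncol(x)
  y <- matrix(0, nt, k)
  z <- if (is.null(zi)) matrix(0, n - 1L, k) else zi
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (n > 2L) {
      z[1:(n - 2L), ] <- z[2:(n - 1L), , drop = FALSE] +
        outer(b[2:(n - 1L)], xt) - outer(a[2:(n - 1L)], yt)
    }
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# forward-backward (zero-phase) filtering of every column of a T x K matrix
filtfilt_mat <- function(b, a, x) {
  n <- max(length(a), length(b))
  npad <- 3L * (n - 1L)
  nt <- nrow(x)
  if (nt <= npad) {
    stop("series too short for zero-phase filtering (need > ", npad, " points)")
  }
  # odd reflection about the end samples
  pre <- 2 * x[rep(1L, npad), , drop = FALSE] - x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(nt, npad), , drop = FALSE] -
    x[(nt - 1L):(nt - npad), , drop = FALSE]
  ext <- rbind(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- lfilter_mat(b, a, ext, zi = outer(zi, ext[1L, ]))
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- lfilter_mat(b, a, y, zi = outer(zi, y[1L, ]))
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(npad + 1L):(npad + nt), , drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Filters each column of a time x channel matrix (or each voxel series of
#' a [bold_series()]) with a zero-phase Butterworth band-pass. Defaults are
#' the resting-state connectivity band 0.01-0.08 Hz, which suppresses
#' scanner drift and 1/f noise below the band and respiratory/cardiac
#' fluctuation above it.
#'
#' @param signals a [region_signals()] matrix, plain numeric matrix/vector,
#'   or [bold_series()]
#' @param tr_seconds sampling interval in seconds; taken from the object if
#'   it carries one
#' @param low_hz,high_hz pass-band cut-off frequencies (Hz)
#' @param order Butterworth design order per pass (default 2 per band edge,
#'   i.e. a 4th-order band-pass transfer function)
#' @return filtered object of the same type and shape
#' @export
bandpass <- function(signals, tr_seconds = NULL, low_hz = 0.01,
                     high_hz = 0.08, order = 2L) {
  if (inherits(signals, "bold_series")) {
    d <- dim(signals$data)
    mat <- t(matrix(signals$data, prod(d[1:3]), d[4L]))
    out <- bandpass(mat, signals$tr_seconds, low_hz, high_hz, order)
    return(bold_series(array(t(out), d), signals$affine, signals$tr_seconds))
  }
  if (is.null(tr_seconds)) tr_seconds <- attr(signals, "tr_seconds")
  if (is.null(tr_seconds)) stop("tr_seconds is required")
  nyq <- 1 / (2 * tr_seconds)
  if (high_hz >= nyq) {
    stop(sprintf("high cut-off %.4g Hz must be below the Nyquist frequency %.4g Hz",
                 high_hz, nyq))
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  vec_in <- is.null(dim(signals))
  x <- if (vec_in) matrix(signals, ncol = 1L) else as.matrix(signals)
  y <- filtfilt_mat(bf$b, bf$a, x)
  if (inherits(signals, "region_signals")) return(restore_signals(y, signals))
  if (vec_in) drop(y) else y
}

#' Discard initial filter-lag volumes
#'
#' Drops the first `n_discard` time points from a set of aligned series
#' (signal matrices, QC vectors, nuisance designs), keeping them aligned.
#' Digital filters need a settling run-in and the discarded leading volumes
#' absorb it.
#'
#' @param signals a [region_signals()] matrix, plain matrix or vector
#' @param n_discard number of leading time points to drop (< length)
#' @return the shortened object, same type
#' @export
discard_lag_volumes <- function(signals, n_discard) {
  n_discard <- as.integer(n_discard)
  nt <- if (is.null(dim(signals))) length(signals) else nrow(signals)
  if (n_discard < 0L) stop("n_discard must be >= 0")
  if (n_discard >= nt) {
    stop(sprintf("cannot discard %d of %d time points", n_discard, nt))
  }
  if (n_discard == 0L) return(signals)
  keep <- (n_discard + 1L):nt
  if (is.null(dim(signals))) return(signals[keep])
  out <- signals[keep, , drop = FALSE]
  if (inherits(signals, "region_signals")) out <- restore_signals(out, signals)
  out
}

#' Residualize regional signals against a nuisance design
#'
#' Replaces every regional signal by its ordinary-least-squares residual
#' against an intercept plus the nuisance columns (motion summaries and
#' white-matter / ventricular signals). Zero-variance or collinear nuisance
#' columns are dropped with a warning; residuals are exactly orthogonal to
#' every retained column.
#'
#' @param signals time x region matrix ([region_signals()] or plain)
#' @param nuisance named time x k matrix/data.frame of nuisance regressors
#' @return residualized signals, same type and shape as `signals`
#' @export
residualize <- function(signals, nuisance) {
  x <- as.matrix(signals)
  nz <- as.matrix(nuisance)
  if (nrow(nz) != nrow(x)) {
    stop(sprintf("length mismatch: signals have %d time points, nuisance %d",
                 nrow(x), nrow(nz)))
  }
  if (any(!is.finite(nz))) stop("nuisance regressors must be finite")
  design <- cbind(intercept = 1, nz)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning("dropping collinear/constant nuisance columns: ",
            paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
    qrd <- qr(design)
  }
  res <- qr.resid(qrd, x)
  if (inherits(signals, "region_signals")) res <- restore_signals(res, signals)
  res
}

#' Assemble the nuisance design for residualization
#'
#' Combines the motion quality series (FD, RMSD) with band-passed
#' white-matter and ventricular compartment signals into the ordered
#' nuisance design used by [residualize()].
#'
#' @param fd framewise displacement series (mm)
#' @param rmsd intensity RMSD series (percent)
#' @param wm_left,wm_right,ventricles compartment mean signals (already
#'   filtered to the analysis band)
#' @param columns subset of nuisance names to keep, in this canonical
#'   order: `fd`, `rmsd`, `wm_left`, `wm_right`, `ventricles`
#' @return numeric matrix with the selected named columns
#' @export
nuisance_set <- function(fd, rmsd, wm_left, wm_right, ventricles,
                         columns = c("fd", "rmsd", "wm_left", "wm_right",
                                     "ventricles")) {
  all_cols <- list(fd = fd, rmsd = rmsd, wm_left = wm_left,
                   wm_right = wm_right, ventricles = ventricles)
  columns <- match.arg(columns, names(all_cols), several.ok = TRUE)
  m <- do.call(cbind, all_cols[columns])
  colnames(m) <- columns
  if (length(unique(vapply(all_cols[columns], length, 1L))) != 1L) {
    stop("nuisance columns must share one length")
  }
  m
}
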