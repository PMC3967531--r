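## Subject-specific regional signal extraction and the overlay-map
## quantification of cross-subject mask alignment.
##
## Geometry convention: voxel indices are 0-based in affine arithmetic
## (world = affine %*% c(i, j, k, 1)); R arrays are addressed 1-based, the
## +-1 shifts are confined to this file. Affines are compared within 1e-6.

#' Resample a label volume under a single composed rigid transform
#'
#' Nearest-neighbour resampling of an integer label map onto a target grid.
#' `rigid_transform` maps source world coordinates to target world
#' coordinates; when several alignment steps are involved their matrices
#' must be multiplied into a single transform first so the labels are
#' interpolated exactly once, which preserves more boundary voxels than
#' chaining resampling steps.
#'
#' @param labels a [label_volume()]
#' @param rigid_transform 4x4 matrix, source world -> target world
#' @param target_dim target grid dimensions (default: source dims)
#' @param target_affine target voxel-to-world affine (default: source)
#' @return resampled [label_volume()] on the target grid
#' @export
resample_labels <- function(labels, rigid_transform = diag(4),
                            target_dim = dim(labels$grid),
                            target_affine = labels$affine) {
  if (abs(det(rigid_transform)) < .Machine$double.eps) {
    stop("transform is singular")
  }
  # target voxel -> target world -> source world -> source voxel
  m <- solve(labels$affine) %*% solve(rigid_transform) %*% target_affine
  idx <- as.matrix(expand.grid(i = 0:(target_dim[1L] - 1L),
                               j = 0:(target_dim[2L] - 1L),
                               k = 0:(target_dim[3L] - 1L)))
  src <- cbind(idx, 1) %*% t(m)
  src_i <- round(src[, 1L]); src_j <- round(src[, 2L]); src_k <- round(src[, 3L])
  d <- dim(labels$grid)
  inside <- src_i >= 0 & src_i < d[1L] & src_j >= 0 & src_j < d[2L] &
    src_k >= 0 & src_k < d[3L]
  out <- integer(nrow(idx))
  lin <- src_i[inside] + d[1L] * (src_j[inside] + d[2L] * src_k[inside]) + 1L
  out[inside] <- labels$grid[lin]
  label_volume(array(out, target_dim), target_affine, labels$label_table)
}

#' Extract regional mean time series from a BOLD run
#'
#' For each requested label id, the unweighted mean intensity over that
#' label's voxels at every time point. The BOLD and label grids must share
#' geometry (no further interpolation happens here). Output columns follow
#' the canonical DMN order (region-major, left before right); labels not in
#' the canonical list keep their label-table order after the DMN columns.
#' Empty regions are excluded with a warning.
#'
#' @param bold a [bold_series()]
#' @param labels a [label_volume()] aligned with `bold`
#' @param region_ids label ids to extract (default: all gray-matter labels)
#' @return a [region_signals()] matrix, time x region
#' @export
extract_regional_means <- function(bold, labels, region_ids = NULL) {
  if (!same_geometry(bold$affine, labels$affine,
                     dim(bold$data)[1:3], dim(labels$grid))) {
    stop("BOLD and label volume geometry mismatch")
  }
  lt <- labels$label_table
  if (is.null(region_ids)) region_ids <- lt$id[lt$tissue == "gray"]
  lt <- lt[match(region_ids, lt$id), , drop = FALSE]
  if (anyNA(lt$id)) stop("region id absent from label table")
  # canonical ordering: DMN list region-major with L before R, then any
  # other labels by id (permutation-invariant in the request order)
  key <- match(paste(lt$region, lt$hemisphere, sep = "_"), dmn_region_labels())
  ord <- order(is.na(key), key, lt$id)
  lt <- lt[ord, , drop = FALSE]

  d <- dim(bold$data)
  vox <- matrix(bold$data, prod(d[1:3]), d[4L])
  lab_vec <- as.vector(labels$grid)
  counts <- tabulate(lab_vec, nbins = max(lt$id))
  empty <- counts[lt$id] == 0L
  if (any(empty)) {
    warning("excluding empty region(s): ",
            paste(lt$region[empty], lt$hemisphere[empty], sep = "_",
                  collapse = ", "))
    lt <- lt[!empty, , drop = FALSE]
  }
  if (nrow(lt) == 0L) stop("no non-empty regions to extract")
  sums <- vapply(lt$id, function(id) colSums(vox[lab_vec == id, , drop = FALSE]),
                 numeric(d[4L]))
  means <- sweep(sums, 2L, counts[lt$id], "/")
  region_signals(means, lt$region, lt$hemisphere, bold$tr_seconds)
}

#' Overlay map of a set of binary masks
#'
#' Sums binary masks voxel-wise on a common grid: each voxel's value counts
#' how many subjects' masks contain it. With perfect cross-subject
#' alignment of a region, every in-region voxel equals the number of
#' subjects; misalignment spreads counts beyond the region border.
#'
#' @param masks non-empty list of 3D arrays (0/1 or logical) sharing
#'   dimensions
#' @return integer 3D array of counts
#' @export
overlay_map <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  d <- dim(masks[[1L]])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("mask geometry mismatch")
  }
  out <- array(0L, d)
  for (m in masks) out <- out + (m != 0)
  out
}

#' Fraction of overlay mass inside a reference region
#'
#' Sum of overlay counts inside the reference mask divided by the total
#' overlay count; 1 means every subject's mask lies entirely within the
#' reference, lower values quantify spill-over from misalignment.
#'
#' @param overlay count array from [overlay_map()]
#' @param reference binary 3D array, same grid
#' @return fraction in `[0, 1]`
#' @export
containment_fraction <- function(overlay, reference) {
  if (!all(dim(overlay) == dim(reference))) stop("geometry mismatch")
  total <- sum(overlay)
  if (total == 0) stop("overlay map is empty")
  sum(overlay[reference != 0]) / total
}

# separable Gaussian smoothing of a 3D array, kernel truncated at 4 SD
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(v, axis) {
    d <- dim(v)
    n <- d[axis]
    # banded convolution matrix with edge renormalization (kernel mass
    # falling off the grid is redistributed, keeping flat regions flat)
    km <- matrix(0, n, n)
    for (off in (-half):half) {
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1L & src <= n
      km[cbind(idx[ok], src[ok])] <- km[cbind(idx[ok], src[ok])] + k[off + half + 1L]
    }
    km <- km / rowSums(km)
    perm <- c(axis, setdiff(1:3, axis))
    vp <- aperm(v, perm)
    mp <- matrix(vp, n, prod(d[perm[2:3]]))
    out <- array(km %*% mp, d[perm])
    aperm(out, order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

# smooth every volume of a 4D BOLD array
gaussian_smooth_bold <- function(bold, fwhm_mm, voxel_size_mm) {
  d <- dim(bold$data)
  out <- bold$data
  for (t in seq_len(d[4L])) {
    out[, , , t] <- gaussian_smooth_3d(bold$data[, , , t], fwhm_mm,
                                       voxel_size_mm)
  }
  bold_series(out, bold$affine, bold$tr_seconds)
}

# random small rigid perturbation: translations ~ N(0, jitter_mm) per axis
# and rotations ~ N(0, jitter_mm / 50) radians about the grid centre
random_rigid_jitter <- function(jitter_mm, affine, grid_dim) {
  tr <- stats::rnorm(3L, 0, jitter_mm)
  ang <- stats::rnorm(3L, 0, jitter_mm / 50)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]),
                 cos(ang[1])), 3L, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0,
                 cos(ang[2])), 3L, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3L, byrow = TRUE)
  r <- rx %*% ry %*% rz
  centre <- (affine %*% c((grid_dim - 1) / 2, 1))[1:3]
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4L] <- tr + centre - r %*% centre
  m
}

#' Emulate spatial-normalization error on a synthetic subject
#'
#' Applies a random small rigid perturbation to the subject's label volume
#' (mimicking residual template-registration error) and Gaussian smoothing
#' to the BOLD data, the two ingredients that degrade atlas-space analyses
#' relative to native-space extraction: masks drift off their regions and
#' smoothing blends signal across region borders.
#'
#' @param bundle a subject bundle from [render_subject()]
#' @param jitter_mm SD of the random rigid translation (mm); rotation SD is
#'   `jitter_mm / 50` radians
#' @param smooth_fwhm_mm Gaussian FWHM applied to the BOLD volumes (mm)
#' @param seed integer seed for the perturbation
#' @return the bundle with perturbed `label_volume` and smoothed `bold`
#' @export
emulate_normalization <- function(bundle, jitter_mm, smooth_fwhm_mm, seed) {
  stopifnot(jitter_mm >= 0, smooth_fwhm_mm >= 0)
  if (jitter_mm == 0 && smooth_fwhm_mm == 0) return(bundle)
  out <- bundle
  if (jitter_mm > 0) {
    out$label_volume <- with_rng_seed(seed, {
      m <- random_rigid_jitter(jitter_mm, bundle$label_volume$affine,
                               dim(bundle$label_volume$grid))
      resample_labels(bundle$label_volume, m)
    })
  }
  if (smooth_fwhm_mm > 0) {
    vx <- abs(bundle$bold$affine[1L, 1L])
    out$bold <- gaussian_smooth_bold(bundle$bold, smooth_fwhm_mm, vx)
  }
  out
}

#' Read/write label tables and volumes
#'
#' Label tables are TSV files with columns `id`, `region`, `hemisphere`,
#' `tissue`; volumes go through NIfTI.
#'
#' @param labels a [label_volume()]
#' @param nifti_path path for the integer label NIfTI
#' @param table_path path for the label-table TSV
#' @return `write_label_volume` the paths, `read_label_volume` a
#'   [label_volume()]
#' @export
write_label_volume <- function(labels, nifti_path, table_path) {
  img <- RNifti::asNifti(labels$grid, datatype = "int32")
  RNifti::sform(img) <- structure(labels$affine, code = 2L)
  RNifti::writeNifti(img, nifti_path)
  utils::write.table(labels$label_table, table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nifti_path, table_path))
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(nifti_path, table_path) {
  img <- RNifti::readNifti(nifti_path)
  lt <- utils::read.table(table_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  label_volume(array(as.integer(img), dim(img)[1:3]),
               matrix(RNifti::xform(img), 4L, 4L), lt)
}

#' Read/write a 4D BOLD series as NIfTI
#' @param bold a [bold_series()]
#' @param path NIfTI path
#' @param tr_seconds repetition time to attach when reading
#' @return `write_bold` the path; `read_bold` a [bold_series()]
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(abs(diag(bold$affine)[1:3]), bold$tr_seconds)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(tr_seconds)) tr_seconds <- RNifti::pixdim(img)[4L]
  bold_series(array(as.numeric(img), dim(img)),
              matrix(RNifti::xform(img), 4L, 4L), tr_seconds)
}
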