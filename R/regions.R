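#' Canonical default-mode-network region abbreviations
#'
#' The ten DMN regions used throughout the package, in the canonical order
#' that fixes column ordering of region-signal matrices and pair ordering of
#' connectivity records: hippocampus (Hi), entorhinal cortex (En), inferior
#' parietal lobule (IP), isthmus of the cingulate (IC), medial orbitofrontal
#' cortex (MOF), parahippocampal gyrus (PHi), posterior cingulate (PoC),
#' precuneus (PCu), superior-frontal gyrus (SF), supramarginal gyrus (SM).
#'
#' @return Character vector of length 10.
#' @export
dmn_regions <- function() {
  c("Hi", "En", "IP", "IC", "MOF", "PHi", "PoC", "PCu", "SF", "SM")
}

#' Canonical hemisphere-resolved region labels
#'
#' Region-major ordering: for each region in [dmn_regions()], the left
#' column precedes the right (`Hi_L, Hi_R, En_L, ...`). This is the column
#' order of every 20-column [region_signals()] matrix and the row/column
#' order of the 20x20 population correlation matrices in a cohort spec.
#'
#' @return Character vector of length 20.
#' @export
dmn_region_labels <- function() {
  as.vector(t(outer(dmn_regions(), c("L", "R"), paste, sep = "_")))
}

#' Index of a (region, hemisphere) column in the canonical 20-label order
#' @param region region abbreviation, e.g. `"SM"`
#' @param hemisphere `"L"` or `"R"`
#' @return integer index in 1..20
#' @export
region_index <- function(region, hemisphere) {
  lab <- paste(region, hemisphere, sep = "_")
  idx <- match(lab, dmn_region_labels())
  if (anyNA(idx)) {
    stop("unknown region/hemisphere: ", paste(lab[is.na(idx)], collapse = ", "))
  }
  idx
}

#' The 45 unordered region pairs in canonical (lexicographic-in-list) order
#'
#' @return data.frame with columns `region_a`, `region_b`, `pair`
#'   (e.g. `"Hi-En"`), 45 rows.
#' @export
dmn_region_pairs <- function() {
  regs <- dmn_regions()
  idx <- utils::combn(10L, 2L)
  data.frame(
    region_a = regs[idx[1L, ]],
    region_b = regs[idx[2L, ]],
    pair = paste(regs[idx[1L, ]], regs[idx[2L, ]], sep = "-"),
    stringsAsFactors = FALSE
  )
}

#' Construct a region-signal matrix
#'
#' The pipeline's central container: a numeric time x region matrix with a
#' region table (name, hemisphere) attached and the sampling interval in
#' seconds. Columns are named `<region>_<hemisphere>` (or just the region
#' name for hemisphere `"avg"`).
#'
#' @param values numeric matrix, time points in rows
#' @param regions character vector of region names, one per column
#' @param hemispheres character vector, one of `"L"`, `"R"`, `"avg"` per column
#' @param tr_seconds repetition time (sampling interval), seconds
#' @return object of class `region_signals` (a matrix with attributes
#'   `region_table` and `tr_seconds`)
#' @export
region_signals <- function(values, regions, hemispheres, tr_seconds) {
  values <- as.matrix(values)
  stopifnot(length(regions) == ncol(values),
            length(hemispheres) == ncol(values),
            is.numeric(tr_seconds), tr_seconds > 0)
  if (!all(hemispheres %in% c("L", "R", "avg"))) {
    stop("hemispheres must be 'L', 'R' or 'avg'")
  }
  colnames(values) <- ifelse(hemispheres == "avg", regions,
                             paste(regions, hemispheres, sep = "_"))
  structure(values,
            region_table = data.frame(region = regions,
                                      hemisphere = hemispheres,
                                      stringsAsFactors = FALSE),
            tr_seconds = tr_seconds,
            class = c("region_signals", "matrix", "array"))
}

#' @export
print.region_signals <- function(x, ...) {
  rt <- attr(x, "region_table")
  cat("<region_signals> ", nrow(x), " time points x ", ncol(x),
      " regions (TR = ", attr(x, "tr_seconds"), " s)\n", sep = "")
  cat("columns:", paste(colnames(x), collapse = " "), "\n")
  invisible(x)
}

# rebuild the region_signals wrapper after an operation that returns a bare
# matrix, keeping the region table and TR of the template
restore_signals <- function(values, template, rows = NULL) {
  rt <- attr(template, "region_table")
  region_signals(values, rt$region, rt$hemisphere, attr(template, "tr_seconds"))
}

#' Construct a label volume
#'
#' An integer-coded 3D region map with a voxel-to-world affine and a label
#' table mapping each nonzero id to (region name, hemisphere, tissue class).
#' Value 0 is reserved for background.
#'
#' @param grid 3D integer array of label ids
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices)
#' @param label_table data.frame with columns `id`, `region`, `hemisphere`
#'   (`"L"`, `"R"` or `"none"`), `tissue` (`"gray"`, `"white"`, `"csf"`)
#' @return object of class `label_volume`
#' @export
label_volume <- function(grid, affine, label_table) {
  stopifnot(length(dim(grid)) == 3L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  ids <- sort(unique(as.integer(grid[grid != 0])))
  missing_ids <- setdiff(ids, label_table$id)
  if (length(missing_ids)) {
    stop("grid contains ids absent from label table: ",
         paste(missing_ids, collapse = ", "))
  }
  if (!all(label_table$hemisphere %in% c("L", "R", "none"))) {
    stop("hemisphere must be 'L', 'R' or 'none'")
  }
  if (!all(label_table$tissue %in% c("gray", "white", "csf"))) {
    stop("tissue must be 'gray', 'white' or 'csf'")
  }
  structure(list(grid = grid, affine = affine, label_table = label_table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, ", nrow(x$label_table), " labels\n", sep = "")
  invisible(x)
}

#' Construct a 4D BOLD series
#'
#' @param data 4D numeric array indexed (x, y, z, t)
#' @param affine 4x4 voxel-to-world affine
#' @param tr_seconds repetition time, seconds
#' @return object of class `bold_series`
#' @export
bold_series <- function(data, affine, tr_seconds) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4L] >= 2L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)),
            tr_seconds > 0)
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_series> ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4L], " volumes (TR = ", x$tr_seconds, " s)\n", sep = "")
  invisible(x)
}

# affine equality within tolerance; geometry checks across the package
same_geometry <- function(affine_a, affine_b, dim_a, dim_b, tol = 1e-6) {
  all(dim_a == dim_b) && all(abs(affine_a - affine_b) < tol)
}
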