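#' Fisher Z transform of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform used for inference on correlations. Values with `|r|` within
#' 1e-12 of 1 indicate degenerate (duplicated) signals upstream and raise
#' an error rather than being clipped.
#'
#' @param r correlation value(s), `|r| < 1`
#' @return Fisher Z value(s)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1 - 1e-12)) {
    stop("correlation magnitude >= 1: degenerate (duplicated?) signals")
  }
  atanh(r)
}

#' Inverse Fisher Z transform
#' @param z Fisher Z value(s)
#' @return correlation value(s), `tanh(z)`
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Hemisphere-resolved pairwise Fisher-Z connectivity
#'
#' Pearson correlation of every unordered pair of same-hemisphere regional
#' signals among the 10 canonical DMN regions, Fisher-Z transformed:
#' 45 pairs per hemisphere, 90 values per subject, no cross-hemisphere
#' pairs. When the matrix carries averaged-hemisphere columns
#' (hemisphere `"avg"`), the 45 averaged pairs are produced instead.
#'
#' @param signals a [region_signals()] matrix containing the 10 canonical
#'   regions for each hemisphere present
#' @param subject_id,group optional metadata carried into the record
#' @return a `connectivity_record`: list with `subject_id`, `group`,
#'   `pairs` (the 45 canonical pairs), and per-hemisphere named numeric
#'   vectors `z_left`, `z_right` and/or `z_avg`
#' @export
pairwise_connectivity <- function(signals, subject_id = NA_character_,
                                  group = NA_character_) {
  rt <- attr(signals, "region_table")
  if (is.null(rt)) stop("signals must be a region_signals matrix")
  pairs <- dmn_region_pairs()
  rec <- list(subject_id = subject_id, group = group, pairs = pairs)
  hemi_key <- c(L = "z_left", R = "z_right", avg = "z_avg")
  for (h in intersect(c("L", "R", "avg"), unique(rt$hemisphere))) {
    want <- if (h == "avg") dmn_regions() else paste(dmn_regions(), h, sep = "_")
    idx <- match(want, colnames(signals))
    if (anyNA(idx)) {
      stop("missing region column(s): ", paste(want[is.na(idx)], collapse = ", "))
    }
    cm <- stats::cor(signals[, idx, drop = FALSE])
    ia <- match(pairs$region_a, dmn_regions())
    ib <- match(pairs$region_b, dmn_regions())
    z <- fisher_z(cm[cbind(ia, ib)])
    names(z) <- pairs$pair
    rec[[hemi_key[[h]]]] <- z
  }
  if (is.null(rec$z_left) && is.null(rec$z_right) && is.null(rec$z_avg)) {
    stop("signals contain no hemisphere-labelled columns")
  }
  structure(rec, class = "connectivity_record")
}

#' @export
print.connectivity_record <- function(x, ...) {
  fams <- intersect(c("z_left", "z_right", "z_avg"), names(x))
  cat("<connectivity_record>", x$subject_id, "(", x$group, "):",
      paste(fams, collapse = " "), "\n")
  invisible(x)
}

#' Average homologous left/right regional signals
#'
#' Column-wise mean of each region's left and right signals at every time
#' point, the interhemispheric-averaging variant. Requires both hemisphere
#' columns for all 10 regions. Note that averaging changes the effective
#' correlation structure: for homologous coupling `h` and non-homologous
#' cross-hemisphere correlation `c`, two averaged regions with
#' within-hemisphere correlations `rl`, `rr` have population correlation
#' `(rl + rr + 2 c) / (2 (1 + h))` — inflating weak pairs and diluting
#' strongly lateralized ones (see [averaged_pair_correlation()]).
#'
#' @param signals [region_signals()] with 20 hemisphere-resolved columns
#' @return [region_signals()] with 10 averaged columns (hemisphere `"avg"`)
#' @export
average_hemispheres <- function(signals) {
  regs <- dmn_regions()
  li <- match(paste(regs, "L", sep = "_"), colnames(signals))
  ri <- match(paste(regs, "R", sep = "_"), colnames(signals))
  if (anyNA(li) || anyNA(ri)) {
    miss <- c(paste(regs, "L", sep = "_")[is.na(li)],
              paste(regs, "R", sep = "_")[is.na(ri)])
    stop("missing hemisphere partner(s): ", paste(miss, collapse = ", "))
  }
  avg <- (signals[, li, drop = FALSE] + signals[, ri, drop = FALSE]) / 2
  region_signals(avg, regs, rep("avg", length(regs)),
                 attr(signals, "tr_seconds"))
}

#' Population correlation of interhemispherically averaged signals
#'
#' Closed form for the correlation between `(L1+R1)/2` and `(L2+R2)/2`
#' under unit-variance signals: left/right within-hemisphere pair
#' correlations `rho_left`, `rho_right`, homologous cross-hemisphere
#' correlation `h` (region with its own contralateral partner), and
#' non-homologous cross-hemisphere correlation `cross`.
#'
#' @param rho_left,rho_right within-hemisphere pair correlations
#' @param h homologous cross-hemisphere correlation
#' @param cross non-homologous cross-hemisphere correlation
#' @return population correlation of the averaged pair
#' @export
averaged_pair_correlation <- function(rho_left, rho_right, h = 0, cross = 0) {
  (rho_left + rho_right + 2 * cross) / (2 * (1 + h))
}

#' Connectivity records for a full cohort of signal matrices
#'
#' @param records list of `connectivity_record`
#' @return long-format data.frame: `subject_id`, `group`, `hemisphere`
#'   (`left`/`right`/`avg`), `pair`, `z`, `r`
#' @export
connectivity_table <- function(records) {
  rows <- lapply(records, function(rec) {
    fams <- c(left = "z_left", right = "z_right", avg = "z_avg")
    fams <- fams[fams %in% names(rec)]
    do.call(rbind, lapply(names(fams), function(f) {
      z <- rec[[fams[[f]]]]
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 hemisphere = f, pair = names(z), z = unname(z),
                 r = fisher_z_inv(unname(z)), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
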