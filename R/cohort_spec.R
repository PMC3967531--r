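#' Repair a matrix to the nearest positive semi-definite correlation matrix
#'
#' Symmetrizes, clips eigenvalues below `eps` up to `eps`, reconstructs, and
#' rescales to unit diagonal. A message reports when a repair actually
#' changed the input, so silently altered user-supplied structure is visible.
#'
#' @param m square numeric matrix
#' @param eps eigenvalue floor (default 1e-6)
#' @return repaired correlation matrix (symmetric, unit diagonal, PSD)
#' @export
repair_correlation <- function(m, eps = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  sym <- (m + t(m)) / 2
  diag(sym) <- 1
  e <- eigen(sym, symmetric = TRUE)
  if (min(e$values) < eps) {
    v <- pmax(e$values, eps)
    rep_m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(rep_m))
    rep_m <- rep_m / outer(d, d)
    rep_m <- (rep_m + t(rep_m)) / 2
    diag(rep_m) <- 1
    message(sprintf(
      "correlation matrix repaired to PSD (min eigenvalue %.3g clipped to %.1g)",
      min(e$values), eps))
    dimnames(rep_m) <- dimnames(m)
    return(rep_m)
  }
  if (max(abs(sym - m)) > 1e-12) {
    message("correlation matrix symmetrized")
  }
  sym
}

# background 20x20 population correlation: `within` off-diagonal within a
# hemisphere, `between` across hemispheres, unit diagonal; canonical
# region-major label order
background_pop_corr <- function(within = 0.2, between = 0.1) {
  labs <- dmn_region_labels()
  hemi <- rep(c("L", "R"), 10L)
  m <- ifelse(outer(hemi, hemi, "=="), within, between)
  diag(m) <- 1
  dimnames(m) <- list(labs, labs)
  m
}

#' Default synthetic cohort specification
#'
#' Returns the study-design defaults the generator emulates: 25 young and
#' 26 elder subjects, 285 time points at TR 2 s, 10 DMN regions per
#' hemisphere, pass band 0.01-0.08 Hz, and group population correlation
#' structure in which every pair shares a moderate positive background
#' (0.2 within hemisphere, 0.1 between hemispheres) except the right
#' supramarginal-superior-frontal (SM-SF) pair, set to 0.5 in the young
#' group and 0.04 in the elder group. Both matrices are repaired to the
#' nearest positive semi-definite correlation matrix (a no-op for these
#' defaults).
#'
#' The cognition model ties four factor scores (memory, speed of
#' processing, general fluid ability, vocabulary) linearly to each
#' subject's realized right SM-SF Fisher-Z: in elders the memory and
#' general-fluid slopes are positive, in the young the speed slope is
#' positive, all other slopes zero.
#'
#' @param n_young,n_elder group sizes (>= 4)
#' @param n_timepoints volumes per run (>= 64)
#' @param tr_seconds repetition time, seconds
#' @param band pass band `c(low, high)` in Hz
#' @param background_within,background_between background off-diagonal
#'   correlation levels used to build the group matrices
#' @param smsf_right_young,smsf_right_elder right SM-SF population
#'   correlation per group
#' @param noise_sd voxelwise white-noise SD, scanner intensity units
#' @param drift_amplitude amplitude of the shared low-frequency (< 0.01 Hz)
#'   scanner drift, intensity units
#' @param resp_band_amplitude amplitude of the shared respiratory-band
#'   (> 0.1 Hz) component, intensity units
#' @param spike_rate probability per volume of a motion spike
#' @param spike_translation_mm translation jump at a spike frame, mm
#' @param spike_intensity_pct global intensity perturbation at a spike
#'   frame, percent of baseline
#' @param motion_drift_mm amplitude of the smooth motion baseline drift, mm
#' @param bold_baseline,bold_amplitude mean scanner intensity and the
#'   intensity scale of one standard deviation of regional signal
#' @param seed cohort-level RNG seed (integer)
#' @return object of class `cohort_spec` (a named list)
#' @export
default_dmn_spec <- function(n_young = 25L, n_elder = 26L,
                             n_timepoints = 285L, tr_seconds = 2,
                             band = c(0.01, 0.08),
                             background_within = 0.2,
                             background_between = 0.1,
                             smsf_right_young = 0.5,
                             smsf_right_elder = 0.04,
                             noise_sd = 1,
                             drift_amplitude = 2,
                             resp_band_amplitude = 0.5,
                             spike_rate = 0.02,
                             spike_translation_mm = 0.6,
                             spike_intensity_pct = 1.0,
                             motion_drift_mm = 0.05,
                             bold_baseline = 1000,
                             bold_amplitude = 5,
                             seed = 1L) {
  i_sm <- region_index("SM", "R")
  i_sf <- region_index("SF", "R")
  young <- background_pop_corr(background_within, background_between)
  young[i_sm, i_sf] <- young[i_sf, i_sm] <- smsf_right_young
  elder <- background_pop_corr(background_within, background_between)
  elder[i_sm, i_sf] <- elder[i_sf, i_sm] <- smsf_right_elder

  cog <- list(
    young = list(
      memory  = c(intercept = 0, slope = 0, noise_sd = 0.5),
      speed   = c(intercept = 0, slope = 1, noise_sd = 0.5),
      gf      = c(intercept = 0, slope = 0, noise_sd = 0.5),
      vocab   = c(intercept = 0, slope = 0, noise_sd = 0.5)
    ),
    elder = list(
      memory  = c(intercept = 0, slope = 1, noise_sd = 0.5),
      speed   = c(intercept = 0, slope = 0, noise_sd = 0.5),
      gf      = c(intercept = 0, slope = 1, noise_sd = 0.5),
      vocab   = c(intercept = 0, slope = 0, noise_sd = 0.5)
    )
  )
  # group age distributions (years): mean and SD
  age_model <- list(young = c(mean = 25.36, sd = 2.74),
                    elder = c(mean = 65.11, sd = 2.98))

  spec <- list(
    n_young = as.integer(n_young), n_elder = as.integer(n_elder),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    region_names = dmn_regions(),
    pop_corr_young = repair_correlation(young),
    pop_corr_elder = repair_correlation(elder),
    band = band,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    resp_band_amplitude = resp_band_amplitude,
    spike_rate = spike_rate,
    spike_translation_mm = spike_translation_mm,
    spike_intensity_pct = spike_intensity_pct,
    motion_drift_mm = motion_drift_mm,
    bold_baseline = bold_baseline,
    bold_amplitude = bold_amplitude,
    cognition_model = cog,
    age_model = age_model,
    grid_dim = c(24L, 24L, 18L),
    voxel_size_mm = 3,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks group sizes, run length, pass band against the Nyquist frequency,
#' and that both population matrices are symmetric unit-diagonal PSD
#' correlation matrices.
#'
#' @param spec a `cohort_spec`
#' @return the spec, invisibly; errors on violation
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n_young < 4L || spec$n_elder < 4L) {
    stop("group sizes must be >= 4")
  }
  if (spec$n_timepoints < 64L) stop("n_timepoints must be >= 64")
  nyq <- 1 / (2 * spec$tr_seconds)
  if (!(0 < spec$band[1L] && spec$band[1L] < spec$band[2L] &&
        spec$band[2L] < nyq)) {
    stop(sprintf("band must satisfy 0 < low < high < Nyquist (%.4g Hz)", nyq))
  }
  for (nm in c("pop_corr_young", "pop_corr_elder")) {
    m <- spec[[nm]]
    if (!all(dim(m) == c(20L, 20L))) stop(nm, " must be 20x20")
    if (max(abs(m - t(m))) > 1e-10) stop(nm, " must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-10) stop(nm, " must have unit diagonal")
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop(sprintf("%s is not positive semi-definite (eigenvalue %.3g)", nm, ev))
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n_young =", x$n_young, ", n_elder =", x$n_elder,
      ", T =", x$n_timepoints, ", TR =", x$tr_seconds, "s, band =",
      paste(x$band, collapse = "-"), "Hz\n")
  invisible(x)
}

# deterministic per-subject seed derived from the cohort seed; kept within
# 32-bit integer range
subject_seed <- function(cohort_seed, group, index) {
  offset <- if (group == "young") 0 else 1e5
  (as.numeric(cohort_seed) * 2654435 + offset + as.numeric(index)) %% 2147483647
}
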