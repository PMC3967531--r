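## Synthetic cohort generator.
##
## Generates complete subjects (label volume, 4D BOLD, motion trace,
## cognition scores) whose statistical structure matches the young/elder
## resting-state study design: 20 hemisphere-resolved DMN regional signals
## with a group-specific population correlation matrix, band-limited to the
## analysis band; voxelwise white noise, shared scanner drift and a
## respiratory-band component; motion spikes paired with global intensity
## perturbations; and cognition factor scores linearly tied to the
## subject's realized right SM-SF connectivity.

derive_seed <- function(seed, k) {
  (as.numeric(seed) + k * 97561) %% 2147483647
}

#' Simulate band-limited regional signals with a target correlation
#'
#' Draws multivariate white Gaussian noise with the group's population
#' correlation matrix, band-limits it exactly to the spec's analysis band
#' (brick-wall spectral mask, so essentially no power falls outside the
#' band), and standardizes columns. Linear filtering applied identically to
#' every channel preserves the zero-lag correlation structure exactly, so
#' sample correlations converge to the population matrix as T grows; the
#' band-limiting reduces the effective number of independent samples to
#' roughly `2 * (high - low) * TR * T` and therefore sets the sampling
#' variability of subject-level correlations.
#'
#' @param spec a [default_dmn_spec()] cohort spec
#' @param group `"young"` or `"elder"`
#' @param subject_seed integer seed for this subject
#' @param n_timepoints override for the run length (default `spec$n_timepoints`)
#' @return [region_signals()] matrix, `n_timepoints` x 20
#' @export
simulate_regional_signals <- function(spec, group = c("young", "elder"),
                                      subject_seed,
                                      n_timepoints = spec$n_timepoints) {
  group <- match.arg(group)
  corr <- if (group == "young") spec$pop_corr_young else spec$pop_corr_elder
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop(sprintf("population correlation matrix is not PSD (eigenvalue %.3g)", ev))
  }
  raw <- with_rng_seed(subject_seed, correlated_noise(n_timepoints, corr))
  filt <- spectral_bandlimit(raw, spec$tr_seconds, spec$band[1L], spec$band[2L])
  filt <- scale(filt)
  hemi <- rep(c("L", "R"), length(spec$region_names))
  region_signals(filt, rep(spec$region_names, each = 2L), hemi,
                 spec$tr_seconds)
}

#' Simulate a six-parameter motion trace with spikes
#'
#' Smooth low-amplitude sinusoidal drift in all six rigid-body parameters
#' (amplitude `spec$motion_drift_mm`, rotations scaled by 1/50 so their arc
#' length matches) plus step translation jumps of
#' `spec$spike_translation_mm` at the spike frames, which makes framewise
#' displacement exceed the 0.5 mm threshold exactly at those frames for the
#' default magnitudes.
#'
#' @param spec cohort spec
#' @param spike_frames integer frames (1-based) with a motion spike; each
#'   must be >= 2 since the first volume has no predecessor to displace from
#' @param subject_seed integer seed
#' @param n_timepoints run length (default `spec$n_timepoints`)
#' @return T x 6 matrix: translations (mm) then rotations (radians)
#' @export
simulate_motion_trace <- function(spec, spike_frames = integer(),
                                  subject_seed,
                                  n_timepoints = spec$n_timepoints) {
  tt <- n_timepoints
  if (length(spike_frames) &&
      (min(spike_frames) < 2L || max(spike_frames) > tt)) {
    stop("spike frames must lie in [2, n_timepoints]: the first volume has no predecessor")
  }
  trace <- with_rng_seed(subject_seed, {
    tsec <- (seq_len(tt) - 1L) * spec$tr_seconds
    m <- matrix(0, tt, 6L)
    if (spec$motion_drift_mm > 0) {
      for (p in 1:6) {
        f <- stats::runif(1L, 0.005, 0.02)
        phase <- stats::runif(1L, 0, 2 * pi)
        amp <- spec$motion_drift_mm * if (p <= 3L) 1 else 1 / 50
        m[, p] <- amp * sin(2 * pi * f * tsec + phase)
      }
    }
    m
  })
  # alternating-sign step changes: displacement registers at the spike
  # frame only, and the head does not walk away over many spikes
  if (length(spike_frames)) {
    sgn <- rep_len(c(1, -1), length(spike_frames))
    for (i in seq_along(spike_frames)) {
      k <- spike_frames[i]
      trace[k:tt, 1L] <- trace[k:tt, 1L] + sgn[i] * spec$spike_translation_mm
    }
  }
  colnames(trace) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  trace
}

# deterministic block layout: 12 compartments per hemisphere (10 gray DMN
# regions, white matter, ventricle), 4x4x4-voxel blocks with >= 1 voxel
# gaps; left hemisphere occupies the lower x half
build_label_grid <- function(spec) {
  d <- spec$grid_dim
  grid <- array(0L, d)
  x_starts <- list(L = c(2L, 7L), R = c(14L, 19L))
  y_starts <- c(2L, 8L, 14L, 20L)
  z_starts <- c(4L, 12L)
  slot_table <- expand.grid(x = 1:2, y = 1:4, z = 1:2)
  slot_table <- slot_table[order(slot_table$z, slot_table$y, slot_table$x), ]
  compartments <- c(spec$region_names, "WhiteMatter", "Ventricle")
  tissue <- c(rep("gray", 10L), "white", "csf")
  rows <- list()
  for (h in c("L", "R")) {
    for (ci in seq_along(compartments)) {
      s <- slot_table[ci, ]
      x0 <- x_starts[[h]][s$x]; y0 <- y_starts[s$y]; z0 <- z_starts[s$z]
      id <- if (ci <= 10L) {
        2L * ci - (h == "L")  # region-major: Hi_L=1, Hi_R=2, ...
      } else {
        20L + 2L * (ci - 10L) - (h == "L")  # WM 21/22, ventricle 23/24
      }
      grid[x0:(x0 + 3L), y0:(y0 + 3L), z0:(z0 + 3L)] <- id
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, region = compartments[ci], hemisphere = h,
        tissue = tissue[ci], stringsAsFactors = FALSE)
    }
  }
  lt <- do.call(rbind, rows)
  lt <- lt[order(lt$id), ]
  rownames(lt) <- NULL
  vx <- spec$voxel_size_mm
  affine <- diag(c(vx, vx, vx, 1))
  affine[1:3, 4L] <- -vx * (d - 1) / 2
  label_volume(grid, affine, lt)
}

#' Render a complete synthetic subject
#'
#' Builds the subject's label volume, paints each region's band-limited
#' signal into its voxels on a scanner-intensity baseline, adds voxelwise
#' white noise, a shared low-frequency drift (< 0.01 Hz), a shared
#' respiratory-band component (> 0.1 Hz), and a global intensity
#' perturbation at motion-spike frames; generates the matching motion
#' trace, nuisance compartment signals, and cognition scores drawn from the
#' spec's cognition model using the subject's realized right SM-SF
#' Fisher-Z.
#'
#' @param spec cohort spec
#' @param group `"young"` or `"elder"`
#' @param subject_seed integer seed; identical (spec, seed) give
#'   bit-identical bundles
#' @param subject_id optional id string
#' @return a `subject_bundle`: list with `subject_id`, `group`,
#'   `label_volume`, `bold`, `motion`, `true_regional_signals`,
#'   `spike_frames`, `cognition`
#' @export
render_subject <- function(spec, group = c("young", "elder"), subject_seed,
                           subject_id = NULL) {
  group <- match.arg(group)
  tt <- spec$n_timepoints
  labels <- build_label_grid(spec)
  signals <- simulate_regional_signals(spec, group, derive_seed(subject_seed, 1L))

  # spike frames: Bernoulli per volume, keeping 3 clean frames at each end
  # so interpolation replacement always has unflagged neighbours
  spike_frames <- with_rng_seed(derive_seed(subject_seed, 2L), {
    eligible <- 4:(tt - 3L)
    eligible[stats::runif(length(eligible)) < spec$spike_rate]
  })
  motion <- simulate_motion_trace(spec, spike_frames,
                                  derive_seed(subject_seed, 3L))

  # nuisance compartment signals: band-limited noise independent of the
  # gray-matter structure (WM left/right, ventricle left/right)
  nuis <- with_rng_seed(derive_seed(subject_seed, 4L),
                        matrix(stats::rnorm(tt * 4L), tt, 4L))
  nuis <- scale(spectral_bandlimit(nuis, spec$tr_seconds, spec$band[1L],
                                   spec$band[2L]))

  d <- spec$grid_dim
  nvox <- prod(d)
  bold_mat <- with_rng_seed(derive_seed(subject_seed, 5L),
                            matrix(stats::rnorm(nvox * tt, 0, spec$noise_sd),
                                   nvox, tt))
  bold_mat <- bold_mat + spec$bold_baseline

  shared <- with_rng_seed(derive_seed(subject_seed, 6L), {
    tsec <- (seq_len(tt) - 1L) * spec$tr_seconds
    drift <- resp <- numeric(tt)
    if (spec$drift_amplitude > 0) {
      f <- stats::runif(1L, 0.002, 0.008)
      drift <- spec$drift_amplitude * sin(2 * pi * f * tsec +
                                            stats::runif(1L, 0, 2 * pi))
    }
    nyq <- 1 / (2 * spec$tr_seconds)
    if (spec$resp_band_amplitude > 0) {
      f <- stats::runif(1L, 0.12, min(0.95 * nyq, 0.3))
      resp <- spec$resp_band_amplitude * sin(2 * pi * f * tsec +
                                               stats::runif(1L, 0, 2 * pi))
    }
    drift + resp
  })
  bold_mat <- bold_mat + rep(shared, each = nvox)

  lab_vec <- as.vector(labels$grid)
  paint <- function(id, series) {
    vox <- which(lab_vec == id)
    bold_mat[vox, ] <<- bold_mat[vox, ] +
      rep(series, each = length(vox)) * spec$bold_amplitude
  }
  for (r in seq_along(spec$region_names)) {
    paint(2L * r - 1L, signals[, 2L * r - 1L])  # left
    paint(2L * r, signals[, 2L * r])            # right
  }
  paint(21L, nuis[, 1L]); paint(22L, nuis[, 2L])  # white matter L/R
  paint(23L, nuis[, 3L]); paint(24L, nuis[, 4L])  # ventricles L/R

  if (length(spike_frames) && spec$spike_intensity_pct > 0) {
    bold_mat[, spike_frames] <- bold_mat[, spike_frames] *
      (1 + spec$spike_intensity_pct / 100)
  }
  bold <- bold_series(array(bold_mat, c(d, tt)), labels$affine,
                      spec$tr_seconds)

  # cognition from the realized (painted) right SM-SF Fisher-Z
  r_smsf <- stats::cor(signals[, region_index("SM", "R")],
                       signals[, region_index("SF", "R")])
  z_smsf <- atanh(r_smsf)
  cog_model <- spec$cognition_model[[group]]
  age_model <- spec$age_model[[group]]
  cognition <- with_rng_seed(derive_seed(subject_seed, 7L), {
    scores <- vapply(cog_model, function(p) {
      p[["intercept"]] + p[["slope"]] * z_smsf +
        stats::rnorm(1L, 0, p[["noise_sd"]])
    }, numeric(1L))
    c(scores, age = round(stats::rnorm(1L, age_model[["mean"]],
                                       age_model[["sd"]]), 1))
  })

  structure(list(
    subject_id = if (is.null(subject_id)) sprintf("%s_%d", group, subject_seed)
                 else subject_id,
    group = group,
    label_volume = labels,
    bold = bold,
    motion = motion,
    true_regional_signals = signals,
    spike_frames = spike_frames,
    cognition = cognition
  ), class = "subject_bundle")
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat("<subject_bundle>", x$subject_id, "(", x$group, "),",
      nrow(x$true_regional_signals), "volumes,",
      length(x$spike_frames), "spike frame(s)\n")
  invisible(x)
}

#' Write one synthetic subject to disk
#'
#' Emits the subject's BOLD and label NIfTI volumes, the motion trace as
#' 6-column whitespace-delimited text (translations mm then rotations
#' radians), and cognition as TSV.
#'
#' @param bundle a `subject_bundle`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_subject <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bold(bundle$bold, file.path(dir, "bold.nii.gz"))
  write_label_volume(bundle$label_volume, file.path(dir, "labels.nii.gz"),
                     file.path(dir, "labels.tsv"))
  write_motion_trace(bundle$motion, file.path(dir, "motion.txt"))
  cog <- data.frame(subject_id = bundle$subject_id, group = bundle$group,
                    t(bundle$cognition))
  utils::write.table(cog, file.path(dir, "cognition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a whole cohort to disk
#'
#' Renders every subject of the spec and writes a cohort manifest JSON
#' listing subjects, groups, seeds and spec scalars.
#'
#' @param spec cohort spec
#' @param dir output directory
#' @return manifest as a list, invisibly
#' @export
simulate_cohort <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- cohort_subject_table(spec)
  for (i in seq_len(nrow(subjects))) {
    bundle <- render_subject(spec, subjects$group[i], subjects$seed[i],
                             subjects$subject_id[i])
    write_subject(bundle, file.path(dir, subjects$subject_id[i]))
  }
  manifest <- list(
    n_subjects = nrow(subjects),
    n_young = spec$n_young, n_elder = spec$n_elder,
    n_timepoints = spec$n_timepoints, tr_seconds = spec$tr_seconds,
    band = spec$band, seed = spec$seed,
    subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

# subject id / group / per-subject seed table for a spec
cohort_subject_table <- function(spec) {
  data.frame(
    subject_id = c(sprintf("young%02d", seq_len(spec$n_young)),
                   sprintf("elder%02d", seq_len(spec$n_elder))),
    group = c(rep("young", spec$n_young), rep("elder", spec$n_elder)),
    seed = c(vapply(seq_len(spec$n_young),
                    function(i) subject_seed(spec$seed, "young", i), 1),
             vapply(seq_len(spec$n_elder),
                    function(i) subject_seed(spec$seed, "elder", i), 1)),
    stringsAsFactors = FALSE
  )
}
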