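## Pipeline orchestration: simulate -> scrub -> filter -> discard ->
## residualize -> extract -> connectivity -> group statistics, as one
## configured, logged, reproducible run.

#' Default preprocessing parameters
#'
#' @param fd_threshold_mm FD scrubbing threshold (mm)
#' @param rmsd_threshold_pct RMSD scrubbing threshold (percent)
#' @param rotation_radius_mm rotation-to-displacement radius (mm)
#' @param low_hz,high_hz analysis pass band (Hz)
#' @param filter_order Butterworth design order per band edge
#' @param n_discard leading filter-lag volumes to drop
#' @param nuisance_columns nuisance regressors to keep, subset of
#'   `c("fd", "rmsd", "wm_left", "wm_right", "ventricles")`
#' @return named list of parameters
#' @export
preprocess_params <- function(fd_threshold_mm = 0.5, rmsd_threshold_pct = 0.3,
                              rotation_radius_mm = 50,
                              low_hz = 0.01, high_hz = 0.08,
                              filter_order = 2L, n_discard = 5L,
                              nuisance_columns = c("fd", "rmsd", "wm_left",
                                                   "wm_right", "ventricles")) {
  list(fd_threshold_mm = fd_threshold_mm,
       rmsd_threshold_pct = rmsd_threshold_pct,
       rotation_radius_mm = rotation_radius_mm,
       low_hz = low_hz, high_hz = high_hz,
       filter_order = as.integer(filter_order),
       n_discard = as.integer(n_discard),
       nuisance_columns = nuisance_columns)
}

#' Preprocess one subject from volumes to analysis-ready regional signals
#'
#' Runs the full per-subject chain in the contract order: QC (FD + RMSD on
#' unfiltered volumes) -> flag -> replace contaminated volumes by linear
#' interpolation -> regional extraction (gray-matter DMN regions and the
#' white-matter/ventricular nuisance compartments) -> zero-phase band-pass
#' -> discard filter-lag volumes -> nuisance residualization. Volume
#' replacement and extraction commute because both are linear, so scrubbing
#' is applied to the extracted regional signals.
#'
#' @param bundle a `subject_bundle` (or any list with `bold`,
#'   `label_volume`, `motion`)
#' @param params list from [preprocess_params()]
#' @param brain_mask logical 3D array for the RMSD computation; defaults to
#'   the whole field of view, which for rendered synthetic subjects is
#'   entirely tissue. Pass an explicit mask for data with non-brain voxels.
#' @return list with `signals` (residualized [region_signals()]), `qc` (the
#'   QC data.frame), and `n_replaced` (count of interpolated volumes)
#' @export
preprocess_subject <- function(bundle, params = preprocess_params(),
                               brain_mask = NULL) {
  labels <- bundle$label_volume
  mask <- if (is.null(brain_mask)) {
    array(TRUE, dim(bundle$bold$data)[1:3])
  } else brain_mask
  qc <- qc_series(bundle$motion, bundle$bold, mask,
                  rotation_radius_mm = params$rotation_radius_mm,
                  fd_threshold_mm = params$fd_threshold_mm,
                  rmsd_threshold_pct = params$rmsd_threshold_pct)

  lt <- labels$label_table
  gray_ids <- lt$id[lt$tissue == "gray"]
  signals <- extract_regional_means(bundle$bold, labels, gray_ids)
  comp <- function(tissue, hemi) {
    id <- lt$id[lt$tissue == tissue & lt$hemisphere == hemi]
    if (!length(id)) return(NULL)
    extract_regional_means(bundle$bold, labels, id)
  }
  wm_l <- comp("white", "L"); wm_r <- comp("white", "R")
  vent <- extract_regional_means(bundle$bold, labels,
                                 lt$id[lt$tissue == "csf"])
  vent <- rowMeans(as.matrix(vent))

  flags <- qc$flagged
  tr <- bundle$bold$tr_seconds
  bp <- function(x) bandpass(x, tr, params$low_hz, params$high_hz,
                             params$filter_order)
  # scrub -> filter -> discard -> residualize
  signals <- replace_volumes(signals, flags)
  wm_l <- replace_volumes(as.vector(wm_l), flags)
  wm_r <- replace_volumes(as.vector(wm_r), flags)
  vent <- replace_volumes(vent, flags)

  signals <- bp(signals)
  wm_l <- bp(wm_l); wm_r <- bp(wm_r); vent <- bp(vent)

  nd <- params$n_discard
  signals <- discard_lag_volumes(signals, nd)
  nz <- nuisance_set(fd = discard_lag_volumes(qc$fd_mm, nd),
                     rmsd = discard_lag_volumes(qc$rmsd_pct, nd),
                     wm_left = discard_lag_volumes(wm_l, nd),
                     wm_right = discard_lag_volumes(wm_r, nd),
                     ventricles = discard_lag_volumes(vent, nd),
                     columns = params$nuisance_columns)
  signals <- residualize(signals, nz)
  list(signals = signals, qc = qc, n_replaced = sum(flags))
}

#' Connectivity records for a simulated cohort
#'
#' Generates every subject of the spec and returns their hemisphere-
#' resolved (and optionally averaged) connectivity records. With
#' `render_volumes = TRUE` each subject goes through volume rendering and
#' the full preprocessing chain; with `FALSE` the regional signals are
#' simulated directly (band-limited, standardized), the fast path for
#' statistical calibration studies where the voxel stage is not under
#' test.
#'
#' @param spec cohort spec
#' @param render_volumes render and preprocess full 4D volumes
#' @param families which families to compute: subset of
#'   `c("left", "right", "avg")` (left/right always come together)
#' @param params preprocessing parameters (render path)
#' @return list of `connectivity_record`
#' @export
cohort_records <- function(spec, render_volumes = FALSE,
                           families = c("left", "right"),
                           params = preprocess_params(
                             low_hz = spec$band[1L], high_hz = spec$band[2L])) {
  subjects <- cohort_subject_table(spec)
  lapply(seq_len(nrow(subjects)), function(i) {
    if (render_volumes) {
      bundle <- render_subject(spec, subjects$group[i], subjects$seed[i],
                               subjects$subject_id[i])
      signals <- preprocess_subject(bundle, params)$signals
    } else {
      signals <- simulate_regional_signals(spec, subjects$group[i],
                                           subjects$seed[i])
    }
    if ("avg" %in% families) {
      avg <- average_hemispheres(signals)
      if (!any(c("left", "right") %in% families)) {
        signals <- avg
      } else {
        signals <- region_signals(
          cbind(as.matrix(signals), as.matrix(avg)),
          c(attr(signals, "region_table")$region,
            attr(avg, "region_table")$region),
          c(attr(signals, "region_table")$hemisphere,
            attr(avg, "region_table")$hemisphere),
          attr(signals, "tr_seconds"))
      }
    }
    pairwise_connectivity(signals, subjects$subject_id[i], subjects$group[i])
  })
}

#' Five-number boxplot summary with 1.5 IQR whiskers
#'
#' Lower/upper quartiles (type-7 linear interpolation between order
#' statistics), median, whiskers at the most extreme values within
#' 1.5 x IQR of the quartiles, outliers beyond the whiskers, and the mean.
#'
#' @param values numeric vector, length >= 1
#' @return list: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `mean`, `outliers`
#' @export
summarize_boxplot <- function(values) {
  if (!length(values)) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_lim <- q[1L] - 1.5 * iqr
  hi_lim <- q[3L] + 1.5 * iqr
  inside <- values >= lo_lim & values <= hi_lim
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       mean = mean(values),
       outliers = sort(values[!inside]))
}

#' Assemble a run configuration
#'
#' @param spec cohort spec (or arguments for [default_dmn_spec()] as a
#'   named list)
#' @param families analysis families: subset of
#'   `c("left", "right", "avg")`
#' @param out_dir run output directory
#' @param seed run seed (overrides `spec$seed` when given)
#' @param render_volumes full volume rendering + preprocessing (TRUE) or
#'   direct signal simulation (FALSE)
#' @param params preprocessing parameters
#' @param log_level `"info"` or `"quiet"`
#' @return named list of class `run_config`
#' @export
run_config <- function(spec = default_dmn_spec(), families = c("left", "right"),
                       out_dir = tempfile("nativefc_run_"), seed = NULL,
                       render_volumes = FALSE,
                       params = preprocess_params(low_hz = spec$band[1L],
                                                  high_hz = spec$band[2L]),
                       log_level = c("info", "quiet")) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(default_dmn_spec, spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  structure(list(spec = spec, families = families, out_dir = out_dir,
                 render_volumes = render_volumes, params = params,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

tsv_write <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline and write a results directory
#'
#' Executes the staged analysis for the configured cohort and writes:
#' the serialized config (`config.yaml`), per-subject QC tables (volume
#' path), the cohort connectivity long table, a group-statistics table per
#' family, cross-correlogram CSVs (both-hemisphere runs), a boxplot summary
#' table of the Fisher-Z values per pair/hemisphere/group, and a JSON
#' manifest with package version, seed and subject list. Identical config
#' and seed reproduce byte-identical tables.
#'
#' @param config a [run_config()]
#' @return the output directory, invisibly; the manifest is attached as
#'   attribute `"manifest"`
#' @export
run_pipeline <- function(config) {
  spec <- config$spec
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  yaml::write_yaml(serialize_config(config),
                   file.path(config$out_dir, "config.yaml"))

  subjects <- cohort_subject_table(spec)
  say("stage simulate+preprocess: %d subjects (render_volumes=%s)",
      nrow(subjects), config$render_volumes)
  records <- vector("list", nrow(subjects))
  qc_dir <- file.path(config$out_dir, "qc")
  if (config$render_volumes) dir.create(qc_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    res <- tryCatch({
      if (config$render_volumes) {
        bundle <- render_subject(spec, subjects$group[i], subjects$seed[i], sid)
        pp <- preprocess_subject(bundle, config$params)
        write_qc_series(pp$qc, file.path(qc_dir, paste0(sid, "_qc.tsv")))
        say("subject %s: %d volume(s) flagged and replaced", sid,
            pp$n_replaced)
        pp$signals
      } else {
        simulate_regional_signals(spec, subjects$group[i], subjects$seed[i])
      }
    }, error = function(e) {
      stop(sprintf("stage preprocess failed for subject %s: %s", sid,
                   conditionMessage(e)), call. = FALSE)
    })
    if ("avg" %in% config$families) {
      avg <- average_hemispheres(res)
      res <- if (!any(c("left", "right") %in% config$families)) avg else {
        region_signals(cbind(as.matrix(res), as.matrix(avg)),
                       c(attr(res, "region_table")$region,
                         attr(avg, "region_table")$region),
                       c(attr(res, "region_table")$hemisphere,
                         attr(avg, "region_table")$hemisphere),
                       attr(res, "tr_seconds"))
      }
    }
    records[[i]] <- tryCatch(
      pairwise_connectivity(res, sid, subjects$group[i]),
      error = function(e) {
        stop(sprintf("stage connectivity failed for subject %s: %s", sid,
                     conditionMessage(e)), call. = FALSE)
      })
  }

  conn <- connectivity_table(records)
  tsv_write(round_df(conn), file.path(config$out_dir, "connectivity.tsv"))

  say("stage stats: families %s", paste(config$families, collapse = ","))
  both <- all(c("left", "right") %in% config$families)
  stat_fams <- c(if (both) "both",
                 if (!both && "left" %in% config$families) "left",
                 if (!both && "right" %in% config$families) "right",
                 if ("avg" %in% config$families) "avg")
  for (f in stat_fams) {
    gs <- group_compare(records, family = f)
    tsv_write(round_df(as.data.frame(gs)),
              file.path(config$out_dir, sprintf("group_stats_%s.tsv", f)))
    if (f == "both") {
      cc <- cross_correlogram(gs)
      utils::write.csv(round(cc$young, 10),
                       file.path(config$out_dir, "correlogram_young.csv"))
      utils::write.csv(round(cc$elder, 10),
                       file.path(config$out_dir, "correlogram_elder.csv"))
      utils::write.csv(cc$significance,
                       file.path(config$out_dir, "correlogram_significance.csv"))
    }
  }

  box <- boxplot_table(conn)
  tsv_write(round_df(box), file.path(config$out_dir, "boxplot_summary.tsv"))

  manifest <- list(
    package = "nativefc",
    version = as.character(utils::packageVersion("nativefc")),
    seed = spec$seed,
    n_subjects = nrow(subjects),
    families = config$families,
    render_volumes = config$render_volumes,
    subjects = subjects[, c("subject_id", "group")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  attr(out, "records") <- records
  invisible(out)
}

# fixed-precision rounding for byte-stable table output
round_df <- function(df, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, digits))
  df
}

# per pair x hemisphere x group boxplot summary of Fisher-Z values
boxplot_table <- function(conn) {
  keys <- unique(conn[, c("hemisphere", "pair", "group")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    v <- conn$z[conn$hemisphere == k$hemisphere & conn$pair == k$pair &
                  conn$group == k$group]
    s <- summarize_boxplot(v)
    data.frame(hemisphere = k$hemisphere, pair = k$pair, group = k$group,
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               mean = s$mean, n_outliers = length(s$outliers),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# YAML-serializable view of a run config (spec matrices reduced to their
# defining scalars; full matrices round-trip through the seeded spec)
serialize_config <- function(config) {
  spec <- config$spec
  list(
    spec = list(
      n_young = spec$n_young, n_elder = spec$n_elder,
      n_timepoints = spec$n_timepoints, tr_seconds = spec$tr_seconds,
      band = spec$band, noise_sd = spec$noise_sd,
      drift_amplitude = spec$drift_amplitude,
      resp_band_amplitude = spec$resp_band_amplitude,
      spike_rate = spec$spike_rate,
      spike_translation_mm = spec$spike_translation_mm,
      spike_intensity_pct = spec$spike_intensity_pct,
      motion_drift_mm = spec$motion_drift_mm,
      bold_baseline = spec$bold_baseline,
      bold_amplitude = spec$bold_amplitude,
      seed = spec$seed
    ),
    families = config$families,
    render_volumes = config$render_volumes,
    params = config$params,
    out_dir = config$out_dir
  )
}
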