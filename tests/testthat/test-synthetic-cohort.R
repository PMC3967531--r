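# The synthetic cohort generator: spec defaults, signal simulation,
# motion traces, full subject rendering and cognition coupling.

test_that("default spec encodes the study design", {
  spec <- default_dmn_spec()
  expect_equal(spec$n_young, 25L)
  expect_equal(spec$n_elder, 26L)
  expect_equal(spec$n_timepoints, 285L)
  expect_equal(spec$tr_seconds, 2)
  expect_equal(spec$band, c(0.01, 0.08))
  expect_equal(spec$region_names, dmn_regions())

  i_sm <- region_index("SM", "R"); i_sf <- region_index("SF", "R")
  expect_equal(spec$pop_corr_young[i_sm, i_sf], 0.5)
  expect_equal(spec$pop_corr_elder[i_sm, i_sf], 0.04)
  for (m in list(spec$pop_corr_young, spec$pop_corr_elder)) {
    expect_equal(m, t(m))
    expect_equal(diag(m), setNames(rep(1, 20), dmn_region_labels()))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("spec validation rejects degenerate designs", {
  expect_error(default_dmn_spec(n_young = 3), ">= 4")
  expect_error(default_dmn_spec(n_timepoints = 32), ">= 64")
  expect_error(default_dmn_spec(band = c(0.01, 0.4)), "Nyquist")
})

test_that("non-PSD user matrices are repaired with a report", {
  m <- diag(20)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9  # infeasible triangle -> negative eigenvalue
  expect_message(rep_m <- repair_correlation(m), "repaired")
  expect_equal(diag(rep_m), rep(1, 20))
  expect_gte(min(eigen(rep_m, symmetric = TRUE, only.values = TRUE)$values),
             1e-8)
})

test_that("simulated signals reproduce the population correlations", {
  spec <- default_dmn_spec()
  # identity population matrix -> near-zero off-diagonal at large T
  spec_id <- spec
  spec_id$pop_corr_young <- diag(20)
  dimnames(spec_id$pop_corr_young) <- dimnames(spec$pop_corr_young)
  s <- simulate_regional_signals(spec_id, "young", 31, n_timepoints = 16384)
  cm <- cor(s)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.08)

  # a pair at 0.5: the mean sample correlation over replicates converges
  rs <- vapply(1:60, function(i) {
    si <- simulate_regional_signals(spec, "young", 7000 + i,
                                    n_timepoints = 4096)
    cor(si[, "SM_R"], si[, "SF_R"])
  }, numeric(1))
  expect_equal(mean(rs), 0.5, tolerance = 0.03)

  # determinism under a fixed seed
  expect_identical(simulate_regional_signals(spec, "elder", 5),
                   simulate_regional_signals(spec, "elder", 5))
})

test_that("generated signals are exactly band-limited", {
  spec <- default_dmn_spec()
  s <- simulate_regional_signals(spec, "young", 9, n_timepoints = 1024)
  nt <- nrow(s)
  f <- (seq_len(nt) - 1) / (nt * spec$tr_seconds)
  f <- pmin(f, 1 / spec$tr_seconds - f)
  inside <- f >= spec$band[1] & f <= spec$band[2]
  for (j in c(1, 10, 20)) {
    p <- Mod(fft(s[, j]))^2
    expect_lt(sum(p[!inside]) / sum(p), 0.01)
  }
})

test_that("motion traces drift smoothly and spike where asked", {
  spec <- default_dmn_spec(motion_drift_mm = 0)
  tr <- simulate_motion_trace(spec, integer(), 1)
  expect_equal(framewise_displacement(tr), rep(0, spec$n_timepoints))

  tr1 <- simulate_motion_trace(spec, 50L, 1)
  fd <- framewise_displacement(tr1)
  expect_gte(fd[50], 0.6)
  expect_equal(which(fd > 0.5), 50L)

  spec_d <- default_dmn_spec()
  trd <- simulate_motion_trace(spec_d, c(40L, 90L), 2)
  fdd <- framewise_displacement(trd)
  expect_setequal(which(fdd > 0.5), c(40L, 90L))
  expect_true(all(fdd[-c(40, 90)] < 0.2))  # drift stays far below threshold

  expect_error(simulate_motion_trace(spec, 1L, 1), "predecessor")
  expect_error(simulate_motion_trace(spec, 300L, 1), "predecessor|n_timepoints")
})

test_that("noise-free rendering reproduces the painted signals exactly", {
  spec <- small_spec(noise_sd = 0, drift_amplitude = 0,
                     resp_band_amplitude = 0, spike_rate = 0)
  b <- render_subject(spec, "young", 13)
  expect_length(b$spike_frames, 0)
  got <- extract_regional_means(b$bold, b$label_volume)
  recovered <- (as.matrix(got) - spec$bold_baseline) / spec$bold_amplitude
  expect_equal(recovered, as.matrix(b$true_regional_signals),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("intensity spikes push RMSD over the scrubbing threshold", {
  spec <- small_spec(spike_rate = 0.05)
  b <- render_subject(spec, "elder", 17)
  expect_gt(length(b$spike_frames), 0)
  rmsd <- rmsd_percent(b$bold, array(TRUE, dim(b$bold$data)[1:3]))
  # a perturbed volume differs from its (unperturbed) predecessor; when two
  # spikes land on consecutive frames the second pair of volumes are both
  # perturbed, so only spikes with a clean predecessor must exceed 0.3%
  isolated <- setdiff(b$spike_frames, b$spike_frames + 1L)
  expect_gt(length(isolated), 0)
  expect_true(all(rmsd[isolated] > 0.3))
  # clean interior frames stay clear of the threshold
  clean <- setdiff(5:(spec$n_timepoints - 5),
                   c(b$spike_frames, b$spike_frames + 1L))
  expect_true(all(rmsd[clean] < 0.3))
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- small_spec()
  b1 <- render_subject(spec, "young", 23)
  b2 <- render_subject(spec, "young", 23)
  expect_identical(b1$bold$data, b2$bold$data)
  expect_identical(b1$motion, b2$motion)
  expect_identical(b1$cognition, b2$cognition)
})

test_that("young and elder right SM-SF connectivity differ in sign of the gap", {
  spec <- small_spec()
  zs <- vapply(1:10, function(i) {
    vapply(c("young", "elder"), function(g) {
      b <- render_subject(spec, g, 3000 + i)
      s <- b$true_regional_signals
      atanh(cor(s[, "SM_R"], s[, "SF_R"]))
    }, numeric(1))
  }, numeric(2))
  expect_gt(mean(zs["young", ]) - mean(zs["elder", ]), 0)
})

test_that("cognition scores recover the generating slope", {
  # elder memory is generated as slope 1 on the realized right SM-SF
  # Fisher-Z plus N(0, 0.5) noise; regression across subjects must recover
  # the slope within two standard errors
  spec <- small_spec()
  dat <- t(vapply(1:60, function(i) {
    b <- render_subject(spec, "elder", 8000 + i)
    s <- b$true_regional_signals
    c(z = atanh(cor(s[, "SM_R"], s[, "SF_R"])),
      memory = b$cognition[["memory"]],
      vocab = b$cognition[["vocab"]])
  }, numeric(3)))
  fit <- summary(lm(memory ~ z, data = as.data.frame(dat)))$coefficients
  expect_lt(abs(fit["z", 1] - 1), 2 * fit["z", 2])
  # vocabulary has zero slope in the model
  fit0 <- summary(lm(vocab ~ z, data = as.data.frame(dat)))$coefficients
  expect_lt(abs(fit0["z", 1]), 2.5 * fit0["z", 2])
})

test_that("a cohort writes complete subject directories and a manifest", {
  spec <- small_spec()
  dir <- withr::local_tempdir()
  manifest <- simulate_cohort(spec, dir)
  expect_equal(manifest$n_subjects, 8)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  sub1 <- file.path(dir, "young01")
  expect_true(all(file.exists(file.path(sub1, c("bold.nii.gz",
                                                "labels.nii.gz", "labels.tsv",
                                                "motion.txt",
                                                "cognition.tsv")))))
  # round-trip one subject and re-extract
  labels <- read_label_volume(file.path(sub1, "labels.nii.gz"),
                              file.path(sub1, "labels.tsv"))
  bold <- read_bold(file.path(sub1, "bold.nii.gz"))
  sig <- extract_regional_means(bold, labels)
  expect_equal(ncol(sig), 20)
})
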