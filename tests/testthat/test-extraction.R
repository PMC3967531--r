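# Label resampling, regional averaging, overlay maps and the
# normalization-error emulation.

test_that("label resampling is exact for identity and voxel-aligned shifts", {
  labels <- toy_labels()
  expect_equal(resample_labels(labels)$grid, labels$grid)

  # translation by exactly one voxel (3 mm) shifts indices by one
  shift <- diag(4); shift[1, 4] <- 3
  out <- resample_labels(labels, shift)
  expect_equal(out$grid[3:4, 2:3, 2:3], labels$grid[2:3, 2:3, 2:3])
  expect_equal(sum(out$grid != 0), sum(labels$grid != 0))

  expect_error(resample_labels(labels, matrix(0, 4, 4)), "singular")
})

test_that("one composed resampling beats two chained resamplings", {
  # a rotation followed by its inverse: the composed transform is identity,
  # so single-pass resampling is lossless; chaining two nearest-neighbour
  # resamplings erodes boundary voxels
  labels <- toy_labels(n = 12)
  ang <- 0.3
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  centre <- diag(4); centre[1:3, 4] <- -16.5  # rotate about the grid centre
  a <- solve(centre) %*% rot %*% centre
  b <- solve(a)

  single <- resample_labels(labels, a %*% b)
  double <- resample_labels(resample_labels(labels, b), a)
  expect_equal(single$grid, labels$grid)  # lossless: zero voxels disturbed
  expect_false(identical(double$grid, labels$grid))
  expect_gt(sum(double$grid != labels$grid), 0)
})

test_that("regional means agree exactly with a per-voxel loop oracle", {
  fx <- random_labelled_bold()
  got <- extract_regional_means(fx$bold, fx$labels)

  lt <- fx$labels$label_table
  for (j in seq_len(nrow(lt))) {
    id <- lt$id[j]
    col <- paste(lt$region[j], lt$hemisphere[j], sep = "_")
    # brute force: loop voxels, accumulate
    expected <- rep(0, dim(fx$bold$data)[4])
    count <- 0
    for (x in 1:8) for (y in 1:8) for (z in 1:8) {
      if (fx$labels$grid[x, y, z] == id) {
        expected <- expected + fx$bold$data[x, y, z, ]
        count <- count + 1
      }
    }
    expect_equal(unname(got[, col]), expected / count)
  }

  # permutation-equivariance in region ids
  ids <- rev(lt$id)
  got_rev <- extract_regional_means(fx$bold, fx$labels, ids)
  expect_equal(as.matrix(got_rev), as.matrix(got), ignore_attr = TRUE)
})

test_that("regional extraction validates geometry and empty regions", {
  fx <- random_labelled_bold()
  bad <- bold_series(fx$bold$data, diag(c(2, 2, 2, 1)), 2)
  expect_error(extract_regional_means(bad, fx$labels), "geometry")

  labels2 <- fx$labels
  labels2$label_table <- rbind(labels2$label_table,
                               data.frame(id = 99L, region = "Empty",
                                          hemisphere = "L", tissue = "gray"))
  expect_warning(out <- extract_regional_means(fx$bold, labels2,
                                               c(1L, 99L)),
                 "Empty")
  expect_equal(ncol(out), 1L)

  # single-voxel region equals that voxel's series
  grid <- array(0L, c(4, 4, 4)); grid[2, 3, 1] <- 1L
  lv <- label_volume(grid, diag(4),
                     data.frame(id = 1L, region = "A", hemisphere = "L",
                                tissue = "gray"))
  bs <- bold_series(array(rnorm(4^3 * 5), c(4, 4, 4, 5)), diag(4), 2)
  expect_equal(unname(extract_regional_means(bs, lv)[, 1]), bs$data[2, 3, 1, ])
})

test_that("overlay map counts masks and conserves total mass", {
  m <- toy_labels()$grid != 0
  ov <- overlay_map(rep(list(m), 51))
  expect_equal(max(ov), 51L)
  expect_equal(sum(ov), 51 * sum(m))

  disjoint <- list(array(c(1, rep(0, 7)), c(2, 2, 2)),
                   array(c(0, 1, rep(0, 6)), c(2, 2, 2)))
  expect_equal(max(overlay_map(disjoint)), 1L)
  expect_error(overlay_map(list()), "at least one")
  expect_error(overlay_map(list(m, m[1:4, 1:4, 1:4])), "mismatch")
})

test_that("containment fraction measures overlay mass inside the reference", {
  ref <- array(0, c(4, 4, 4)); ref[1:2, , ] <- 1
  inside <- array(0L, c(4, 4, 4)); inside[1, 1, 1] <- 3L
  expect_equal(containment_fraction(inside, ref), 1)
  outside <- array(0L, c(4, 4, 4)); outside[4, 4, 4] <- 2L
  expect_equal(containment_fraction(outside, ref), 0)
  half <- inside + outside; half[4, 4, 4] <- 3L
  expect_equal(containment_fraction(half, ref), 0.5)
  expect_error(containment_fraction(array(0L, c(4, 4, 4)), ref), "empty")
})

test_that("gaussian smoothing keeps a delta's mass near its source", {
  vol <- array(0, c(24, 24, 24)); vol[12, 12, 12] <- 1
  sm <- nativefc:::gaussian_smooth_3d(vol, fwhm_mm = 6, voxel_size_mm = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # mass conservation
  # >= 90% of mass within 2 FWHM (12 mm = 4 voxels) of the source
  idx <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  d <- sqrt(rowSums((sweep(idx, 2, c(12, 12, 12)))^2)) * 3
  expect_gte(sum(sm[idx[d <= 12, ]]), 0.90)
})

test_that("native labels give perfect containment; jitter degrades it", {
  spec <- small_spec()
  labels <- nativefc:::build_label_grid(spec)
  gray <- labels$label_table[labels$label_table$tissue == "gray", ]
  for (id in gray$id[c(1, 10, 20)]) {
    masks <- rep(list(labels$grid == id), 10)
    expect_equal(containment_fraction(overlay_map(masks), labels$grid == id), 1)
  }

  b <- render_subject(spec, "young", 3)
  pert <- emulate_normalization(b, jitter_mm = 2, smooth_fwhm_mm = 0, seed = 5)
  expect_false(identical(pert$label_volume$grid, b$label_volume$grid))
  # zero perturbation is the identity
  same <- emulate_normalization(b, 0, 0, seed = 5)
  expect_identical(same$label_volume$grid, b$label_volume$grid)
  expect_identical(same$bold$data, b$bold$data)
})

test_that("label volumes and BOLD round-trip through NIfTI", {
  spec <- small_spec()
  labels <- nativefc:::build_label_grid(spec)
  dir <- withr::local_tempdir()
  write_label_volume(labels, file.path(dir, "lab.nii.gz"),
                     file.path(dir, "lab.tsv"))
  back <- read_label_volume(file.path(dir, "lab.nii.gz"),
                            file.path(dir, "lab.tsv"))
  expect_equal(back$grid, labels$grid)
  expect_equal(back$affine, labels$affine, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$label_table, labels$label_table)

  bs <- bold_series(array(rnorm(4^3 * 3, 100), c(4, 4, 4, 3)),
                    diag(c(3, 3, 3, 1)), 2)
  write_bold(bs, file.path(dir, "bold.nii.gz"))
  back2 <- read_bold(file.path(dir, "bold.nii.gz"))
  expect_equal(back2$data, bs$data, tolerance = 1e-5)
  expect_equal(back2$tr_seconds, 2)
})
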