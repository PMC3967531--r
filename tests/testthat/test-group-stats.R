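# Group comparison, hemisphere-interaction regression, cognition
# regressions and effect sizes.

# build connectivity records directly from per-subject z matrices
mock_records <- function(z_left, z_right, groups) {
  pairs <- dmn_region_pairs()$pair
  lapply(seq_along(groups), function(i) {
    structure(list(subject_id = paste0("s", i), group = groups[i],
                   pairs = dmn_region_pairs(),
                   z_left = setNames(z_left[i, ], pairs),
                   z_right = setNames(z_right[i, ], pairs)),
              class = "connectivity_record")
  })
}

test_that("identical groups give t = 0, p = 1 and no flags", {
  set.seed(11)
  z <- matrix(rnorm(8 * 45, 0.2, 0.1), 8, 45)
  recs <- mock_records(rbind(z, z), rbind(z, z),
                       c(rep("young", 8), rep("elder", 8)))
  gs <- group_compare(recs, "both")
  expect_equal(gs$t_statistic, rep(0, 90))
  expect_equal(gs$p_value, rep(1, 90))
  expect_false(any(gs$sig_uncorrected))
  expect_false(any(gs$sig_bonferroni))
})

test_that("the Bonferroni family size follows the analysis family", {
  set.seed(12)
  mk <- function() matrix(rnorm(10 * 45, 0.2, 0.1), 10, 45)
  recs <- mock_records(mk(), mk(), rep(c("young", "elder"), each = 5))
  both <- group_compare(recs, "both")
  expect_equal(attr(both, "m"), 90)
  expect_equal(attr(both, "bonferroni_threshold"), 0.05 / 90)
  expect_equal(signif(attr(both, "bonferroni_threshold"), 2), 0.00056)
  left <- group_compare(recs, "left")
  expect_equal(attr(left, "m"), 45)
  expect_true(all(both$sig_uncorrected[both$sig_bonferroni]))
})

test_that("group comparison is invariant to subject order", {
  set.seed(13)
  mk <- function() matrix(rnorm(12 * 45, 0.2, 0.15), 12, 45)
  recs <- mock_records(mk(), mk(), rep(c("young", "elder"), 6))
  gs1 <- group_compare(recs, "both")
  gs2 <- group_compare(recs[sample(12)], "both")
  expect_equal(as.data.frame(gs1), as.data.frame(gs2))
})

test_that("group comparison requires two subjects per group", {
  set.seed(14)
  mk <- function() matrix(rnorm(3 * 45), 3, 45)
  recs <- mock_records(mk(), mk(), c("young", "young", "elder"))
  expect_error(group_compare(recs), "2 subjects")
})

test_that("hemisphere interaction regression behaves under recoding", {
  set.seed(15)
  n <- 30
  groups <- rep(c("young", "elder"), each = n / 2)

  # right-only group difference: z_left flat, z_right shifted in elders
  z_left <- rnorm(n, 0.2, 0.05)
  z_right <- rnorm(n, 0.2, 0.05) + ifelse(groups == "elder", -0.15, 0)
  fit <- hemisphere_interaction(z_left, z_right, groups)
  expect_named(fit$coefficients,
               c("intercept", "group", "hemisphere", "interaction"))

  # identical hemispheres: hemisphere and interaction terms vanish
  fit0 <- hemisphere_interaction(z_left, z_left, groups)
  expect_equal(unname(fit0$coefficients[c("hemisphere", "interaction")]),
               c(0, 0), tolerance = 1e-12)

  # swapping the hemisphere coding flips the hemisphere coefficient sign
  fit_sw <- hemisphere_interaction(z_right, z_left, groups)
  expect_equal(unname(fit_sw$coefficients["hemisphere"] +
                        fit_sw$coefficients["interaction"]),
               -unname(fit$coefficients["hemisphere"] +
                         fit$coefficients["interaction"]),
               tolerance = 1e-10)
})

test_that("a right-lateralized group effect is detected as interaction", {
  # power check at roughly study-sized groups and subject-level z noise
  set.seed(16)
  hits <- replicate(100, {
    groups <- c(rep("young", 25), rep("elder", 26))
    z_left <- rnorm(51, 0.2, 0.11)
    z_right <- ifelse(groups == "young", rnorm(51, 0.55, 0.11),
                      rnorm(51, 0.05, 0.11))
    hemisphere_interaction(z_left, z_right, groups)$p_values["interaction"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cognition regression recovers slopes and controls type I error", {
  set.seed(17)
  n <- 26
  z <- rnorm(n, 0.1, 0.2)
  age <- rnorm(n, 65, 3)

  # near-deterministic factor: slope recovered
  factor_det <- 2 * z + rnorm(n, 0, 1e-8)
  fit <- cognition_regression(z, factor_det, age)
  expect_equal(fit$slope, 2, tolerance = 1e-5)

  # covariate shift invariance
  fit_shift <- cognition_regression(z, factor_det, age + 100)
  expect_equal(fit_shift$slope, fit$slope, tolerance = 1e-8)

  # null slope: p approximately uniform -> ~5% rejections at alpha 0.05
  pvals <- replicate(1000, {
    cognition_regression(z, rnorm(n), age)$p_value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)

  expect_error(cognition_regression(rep(0.3, n), rnorm(n), age), "constant")
  expect_error(cognition_regression(z[1:3], rnorm(3), age[1:3]), "4 subjects")
})

test_that("effect size is the pooled-SD standardized mean difference", {
  set.seed(18)
  mkz <- function(mu) matrix(rnorm(6 * 45, mu, 0.1), 6, 45)
  zy <- mkz(0.5)
  recs <- mock_records(rbind(zy, zy), rbind(zy, zy),
                       rep(c("young", "elder"), each = 6))
  expect_equal(effect_size(recs, "SF-SM", "right"), 0, tolerance = 1e-12)

  # shift elders down by exactly one pooled SD on one pair
  zm <- rbind(mkz(0.4), mkz(0.4))
  j <- which(dmn_region_pairs()$pair == "SF-SM")
  sp <- sqrt((var(zm[1:6, j]) * 5 + var(zm[7:12, j]) * 5) / 10)
  zm[7:12, j] <- zm[7:12, j] - sp +
    (mean(zm[1:6, j]) - mean(zm[7:12, j]))
  recs2 <- mock_records(zm, zm, rep(c("young", "elder"), each = 6))
  expect_equal(effect_size(recs2, "SF-SM", "right"), 1, tolerance = 1e-10)

  const <- matrix(0.3, 4, 45)
  recs3 <- mock_records(const, const, rep(c("young", "elder"), each = 2))
  expect_error(effect_size(recs3, "SF-SM", "right"), "pooled")
})

test_that("cohort-level effect size matches an independent Monte-Carlo", {
  # oracle: mean and SD of subject-level z computed directly from many
  # independently simulated subjects; the packaged effect_size on a large
  # cohort must agree with (mean_y - mean_e) / pooled SD from that sample
  spec <- default_dmn_spec(n_young = 150L, n_elder = 150L, seed = 33L)
  recs <- cohort_records(spec)
  d_pkg <- effect_size(recs, "SF-SM", "right")

  groups <- nativefc:::record_groups(recs)
  z <- vapply(recs, function(r) r$z_right[["SF-SM"]], numeric(1))
  zy <- z[groups == "young"]; ze <- z[groups == "elder"]
  sp <- sqrt(((length(zy) - 1) * var(zy) + (length(ze) - 1) * var(ze)) /
               (length(zy) + length(ze) - 2))
  expect_equal(d_pkg, (mean(zy) - mean(ze)) / sp, tolerance = 1e-12)
  # and against the analytic z-gap over the empirical z dispersion
  expect_equal(d_pkg, (atanh(0.5) - atanh(0.04)) / sp, tolerance = 0.05 * d_pkg)
})
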