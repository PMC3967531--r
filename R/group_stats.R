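## Group statistics on Fisher-Z connectivity: two-sample comparisons with
## Bonferroni control, the group x hemisphere interaction regression, and
## per-group cognition regressions with age as a covariate.

# subjects x pairs matrix of z values for one family from a record list
family_z_matrix <- function(records, family = c("left", "right", "avg")) {
  family <- match.arg(family)
  key <- c(left = "z_left", right = "z_right", avg = "z_avg")[[family]]
  rows <- lapply(records, function(rec) {
    if (is.null(rec[[key]])) {
      stop("record ", rec$subject_id, " has no ", family, " family")
    }
    rec[[key]]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, function(r) r$subject_id, "")
  m
}

record_groups <- function(records) {
  vapply(records, function(r) r$group, "")
}

#' Group comparison of pairwise connectivity
#'
#' Per region pair, a two-sample t-test (pooled variance by default) on the
#' Fisher-Z values between the young and elder groups, with uncorrected and
#' Bonferroni-corrected significance flags. The Bonferroni family size `m`
#' is the number of tests actually run: 90 for `family = "both"`
#' (hemisphere-resolved), 45 for a single hemisphere or the averaged
#' variant.
#'
#' @param records list of `connectivity_record` for the whole cohort
#' @param family `"left"`, `"right"`, `"both"` (both hemispheres, one
#'   90-test family) or `"avg"`
#' @param alpha family-wise significance level (default 0.05)
#' @param var_equal pooled-variance t-test (default TRUE); FALSE for Welch
#' @return data.frame of class `group_stats_table`, one row per pair x
#'   hemisphere: `pair`, `hemisphere`, `mean_young`, `mean_elder` (Fisher
#'   Z), `mean_r_young`, `mean_r_elder` (back-transformed), `t_statistic`,
#'   `p_value`, `sig_uncorrected`, `sig_bonferroni`, `direction`
#'   (`increase`/`decrease` in elders), `effect_size` (Cohen's d), plus
#'   attributes `m` (family size) and `bonferroni_threshold`
#' @export
group_compare <- function(records, family = c("both", "left", "right", "avg"),
                          alpha = 0.05, var_equal = TRUE) {
  family <- match.arg(family)
  groups <- record_groups(records)
  if (sum(groups == "young") < 2L || sum(groups == "elder") < 2L) {
    stop("need at least 2 subjects per group")
  }
  fams <- if (family == "both") c("left", "right") else family
  tabs <- lapply(fams, function(f) {
    zm <- family_z_matrix(records, f)
    young <- zm[groups == "young", , drop = FALSE]
    elder <- zm[groups == "elder", , drop = FALSE]
    res <- lapply(colnames(zm), function(p) {
      tt <- stats::t.test(young[, p], elder[, p], var.equal = var_equal)
      d <- cohens_d(young[, p], elder[, p])
      data.frame(pair = p, hemisphere = f,
                 mean_young = mean(young[, p]),
                 mean_elder = mean(elder[, p]),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 effect_size = d,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, tabs)
  m <- nrow(out)
  out$mean_r_young <- fisher_z_inv(out$mean_young)
  out$mean_r_elder <- fisher_z_inv(out$mean_elder)
  out$sig_uncorrected <- out$p_value < alpha
  out$sig_bonferroni <- out$p_value < alpha / m
  out$direction <- ifelse(out$mean_elder > out$mean_young,
                          "increase", "decrease")
  rownames(out) <- NULL
  structure(out, m = m, alpha = alpha,
            bonferroni_threshold = alpha / m,
            class = c("group_stats_table", "data.frame"))
}

# Cohen's d with pooled SD, young minus elder
cohens_d <- function(young, elder) {
  n1 <- length(young); n2 <- length(elder)
  sp <- sqrt(((n1 - 1) * stats::var(young) + (n2 - 1) * stats::var(elder)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(young) - mean(elder)) / sp
}

#' Effect size (Cohen's d) for one pair
#'
#' `(mean_young_z - mean_elder_z) / pooled SD`, the standardized group
#' difference on the Fisher-Z scale.
#'
#' @param records cohort record list
#' @param pair pair label, e.g. `"SF-SM"`
#' @param hemisphere `"left"`, `"right"` or `"avg"`
#' @return Cohen's d
#' @export
effect_size <- function(records, pair, hemisphere = c("right", "left", "avg")) {
  hemisphere <- match.arg(hemisphere)
  zm <- family_z_matrix(records, hemisphere)
  if (!pair %in% colnames(zm)) stop("unknown pair: ", pair)
  groups <- record_groups(records)
  cohens_d(zm[groups == "young", pair], zm[groups == "elder", pair])
}

#' Group x hemisphere interaction regression for one pair
#'
#' Stacks two observations per subject (left and right Fisher-Z) and fits
#' ordinary least squares `z ~ group + hemisphere + group:hemisphere`, with
#' the age group coded 0 (young) / 1 (elder) and hemisphere 0 (left) /
#' 1 (right). A significant interaction term indicates a hemisphere-
#' specific (unilateral) group difference. Subject pairing is ignored, so
#' the two rows per subject are treated as independent observations.
#'
#' @param z_left,z_right per-subject Fisher-Z values for the pair
#' @param groups per-subject group labels (`"young"`/`"elder"`)
#' @return list with `coefficients`, `p_values` (both named: intercept,
#'   group, hemisphere, interaction) and the `lm` fit
#' @export
hemisphere_interaction <- function(z_left, z_right, groups) {
  n <- length(groups)
  if (length(z_left) != n || length(z_right) != n) {
    stop("z_left, z_right and groups must share one length per subject")
  }
  if (anyNA(z_left) || anyNA(z_right)) stop("missing hemisphere observation")
  g <- as.integer(groups == "elder")
  df <- data.frame(z = c(z_left, z_right),
                   group = rep(g, 2L),
                   hemisphere = rep(c(0L, 1L), each = n))
  fit <- stats::lm(z ~ group * hemisphere, data = df)
  cf <- summary(fit)$coefficients
  out_names <- c("intercept", "group", "hemisphere", "interaction")
  list(coefficients = stats::setNames(cf[, 1L], out_names),
       p_values = stats::setNames(cf[, 4L], out_names),
       fit = fit)
}

#' Cognition-connectivity regression within one group
#'
#' Ordinary least squares of a cognitive factor score on the pair's
#' Fisher-Z connectivity with age (years) as a covariate, fitted within a
#' single age group: `factor ~ z + age`.
#'
#' @param z per-subject Fisher-Z values for the pair (one group only)
#' @param factor_scores matching factor scores
#' @param age matching ages in years
#' @return list with `slope` (on z), `p_value` (two-sided), and the `lm`
#'   fit
#' @export
cognition_regression <- function(z, factor_scores, age) {
  if (length(z) < 4L) stop("need at least 4 subjects")
  if (stats::sd(z) == 0) stop("connectivity is constant within the group")
  fit <- stats::lm(factor_scores ~ z + age)
  cf <- summary(fit)$coefficients
  list(slope = cf["z", 1L], p_value = cf["z", 4L], fit = fit)
}

#' Cross-correlogram of group-mean correlations
#'
#' A 10 x 10 matrix per group summarizing the pairwise group means:
#' the upper triangle holds the right-hemisphere mean correlations, the
#' lower triangle the left (back-transformed from the mean Fisher-Z), with
#' a significance annotation matrix from the group comparison
#' (`"none"`, `"uncorrected"`, `"bonferroni"`).
#'
#' @param stats_table a `group_stats_table` from
#'   `group_compare(..., family = "both")`
#' @return list with `young`, `elder` (10 x 10 mean-correlation matrices)
#'   and `significance` (10 x 10 character matrix)
#' @export
cross_correlogram <- function(stats_table) {
  if (!all(c("left", "right") %in% stats_table$hemisphere)) {
    stop("cross-correlogram needs both hemispheres (family = 'both')")
  }
  regs <- dmn_regions()
  mk <- function() matrix(NA_real_, 10L, 10L, dimnames = list(regs, regs))
  young <- elder <- mk()
  sig <- matrix("none", 10L, 10L, dimnames = list(regs, regs))
  pairs <- dmn_region_pairs()
  for (i in seq_len(nrow(stats_table))) {
    row <- stats_table[i, ]
    pr <- pairs[pairs$pair == row$pair, ]
    a <- match(pr$region_a, regs); b <- match(pr$region_b, regs)
    # upper triangle (row < col) right hemisphere, lower triangle left
    at <- if (row$hemisphere == "right") cbind(min(a, b), max(a, b))
          else cbind(max(a, b), min(a, b))
    young[at] <- row$mean_r_young
    elder[at] <- row$mean_r_elder
    sig[at] <- if (row$sig_bonferroni) "bonferroni"
               else if (row$sig_uncorrected) "uncorrected" else "none"
  }
  list(young = young, elder = elder, significance = sig)
}
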