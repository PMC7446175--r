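#' Published reference cohort: marginal stage counts
#'
#' Marginal PEDIS stage counts reported for a published German single-centre
#' wound-care cohort of 237 patients with a diabetic foot ulcer, broken down
#' by six-month amputation status. These counts are the default calibration
#' of the synthetic-cohort generator (see [generator_config()]) and the input
#' of the descriptive cross-checks in [expected_pedis_sum()].
#'
#' Groups: `overall` (n = 237), `any_non` / `any_amp` (non-amputees and
#' amputees for the any-amputation outcome, n = 162 / 75), `major_non` /
#' `major_amp` (major-amputation outcome, n = 208 / 29). Subgroup counts per
#' factor sum to the subgroup size.
#'
#' @return A data.frame with columns `factor`, `stage` and one count column
#'   per group.
#' @seealso [dfu_reference_sample()], [dfu_reference_models()]
#' @export
dfu_reference_marginals <- function() {
  out <- data.frame(
    factor = c(rep("perfusion", 3), rep("extent", 3), rep("depth", 3),
               rep("infection", 4), rep("sensation", 2)),
    stage  = c(1:3, 1:3, 1:3, 1:4, 1:2),
    overall   = c(114L, 77L, 46L,  8L, 74L, 155L,  14L, 78L, 145L,  86L, 84L, 61L, 6L,  17L, 220L),
    any_non   = c( 97L, 48L, 17L,  8L, 67L,  87L,  12L, 67L,  83L,  62L, 54L, 43L, 3L,  13L, 149L),
    any_amp   = c( 17L, 29L, 29L,  0L,  7L,  68L,   2L, 11L,  62L,  24L, 30L, 18L, 3L,   4L,  71L),
    major_non = c(108L, 66L, 34L,  8L, 72L, 128L,  14L, 75L, 119L,  80L, 70L, 54L, 4L,  16L, 192L),
    major_amp = c(  6L, 11L, 12L,  0L,  2L,  27L,   0L,  3L,  26L,   6L, 14L,  7L, 2L,   1L,  28L),
    stringsAsFactors = FALSE
  )
  out
}

#' Published reference cohort: sample-level summaries
#'
#' Headline descriptive values reported for the reference cohort: enrolment
#' and follow-up bookkeeping, outcome counts, gender split, and the mean/SD
#' of age and of the PEDIS sum score per outcome group.
#'
#' @return A list with components `n_enrolled`, `n_lost`, `n_total`,
#'   `n_any_amp`, `n_major_amp`, `n_male`, `n_female`, `age` (data.frame of
#'   group/mean/sd) and `pedis_sum` (data.frame of group/mean/sd).
#' @export
dfu_reference_sample <- function() {
  list(
    n_enrolled  = 254L,
    n_lost      = 16L,
    n_total     = 237L,
    n_any_amp   = 75L,
    n_major_amp = 29L,
    n_male      = 198L,
    n_female    = 39L,
    age = data.frame(
      group = c("overall", "any_non", "any_amp", "major_non", "major_amp"),
      mean  = c(65.91, 64.59, 68.76, 65.55, 68.52),
      sd    = c(12.3, 12.8, 10.5, 12.5, 12.4),
      stringsAsFactors = FALSE
    ),
    pedis_sum = data.frame(
      group = c("overall", "any_non", "any_amp", "major_non", "major_amp"),
      mean  = c(10.76, 10.27, 11.81, 10.56, 12.17),
      sd    = c(1.9, 1.9, 1.4, 1.9, 1.4),
      stringsAsFactors = FALSE
    )
  )
}

#' Published reference models: posterior coefficient and AUC summaries
#'
#' Posterior summaries of the four fitted risk models reported for the
#' reference cohort (any- and major-amputation, each with weakly-informative
#' and with informative priors): per risk factor the posterior median of the
#' coefficient with its 95% HDI, the corresponding odds ratio (exponentiated
#' median) with its endpoint-exponentiated HDI, and the posterior AUC median
#' with its 95% HDI.
#'
#' These are structural fixtures (the odds-ratio columns must equal the
#' exponentiated coefficient columns) and supply the coefficient magnitudes
#' used as synthetic-truth defaults; the underlying patient-level data are
#' not redistributed, so the values are not refit targets.
#'
#' @return A list with `coefficients` (data.frame: outcome, prior_mode,
#'   factor, beta_median, beta_lo, beta_hi, or_median, or_lo, or_hi) and
#'   `auc` (data.frame: outcome, prior_mode, median, hdi_lo, hdi_hi).
#' @export
dfu_reference_models <- function() {
  co <- rbind(
    data.frame(outcome = "any", prior_mode = "uninformed",
               factor = c("perfusion", "extent", "depth", "infection", "sensation"),
               beta_median = c(0.688, 1.484, 0.665, -0.112, 0.037),
               beta_lo = c(0.264, 0.617, 0.050, -0.483, -0.726),
               beta_hi = c(1.152, 2.376, 1.418, 0.266, 1.077),
               or_median = c(1.990, 4.411, 1.945, 0.894, 1.037),
               or_lo = c(1.302, 1.853, 1.051, 0.617, 0.484),
               or_hi = c(3.164, 10.762, 4.128, 1.305, 2.937)),
    data.frame(outcome = "any", prior_mode = "informed",
               factor = c("perfusion", "extent", "depth", "infection", "sensation"),
               beta_median = c(0.703, 1.283, 0.656, -0.021, 0.516),
               beta_lo = c(0.352, 0.562, 0.168, -0.439, -0.303),
               beta_hi = c(1.116, 2.233, 1.302, 0.368, 1.223),
               or_median = c(2.020, 3.609, 1.927, 0.979, 1.675),
               or_lo = c(1.422, 1.754, 1.183, 0.644, 0.738),
               or_hi = c(3.052, 9.326, 3.677, 1.446, 3.397)),
    data.frame(outcome = "major", prior_mode = "uninformed",
               factor = c("perfusion", "extent", "depth", "infection", "sensation"),
               beta_median = c(0.471, 0.985, 0.932, 0.155, 0.076),
               beta_lo = c(-0.017, -0.079, -0.088, -0.296, -0.861),
               beta_hi = c(1.069, 2.665, 2.275, 0.635, 1.782),
               or_median = c(1.601, 2.678, 2.540, 1.167, 1.079),
               or_lo = c(0.983, 0.924, 0.916, 0.744, 0.423),
               or_hi = c(2.913, 14.364, 9.726, 1.888, 5.943)),
    data.frame(outcome = "major", prior_mode = "informed",
               factor = c("perfusion", "extent", "depth", "infection", "sensation"),
               beta_median = c(0.586, 0.799, 0.694, 0.368, 0.553),
               beta_lo = c(0.170, 0.061, 0.069, -0.108, -0.404),
               beta_hi = c(1.070, 2.272, 1.893, 0.757, 1.639),
               or_median = c(1.798, 2.222, 2.001, 1.445, 1.738),
               or_lo = c(1.185, 1.063, 1.071, 0.898, 0.668),
               or_hi = c(2.914, 9.702, 6.642, 2.131, 5.149))
  )
  auc <- data.frame(
    outcome    = c("any", "any", "major", "major"),
    prior_mode = c("uninformed", "informed", "uninformed", "informed"),
    median     = c(0.793, 0.790, 0.765, 0.790),
    hdi_lo     = c(0.778, 0.774, 0.725, 0.774),
    hdi_hi     = c(0.801, 0.802, 0.779, 0.802),
    stringsAsFactors = FALSE
  )
  list(coefficients = co, auc = auc)
}

#' Illustrative published effect set for prior elicitation (synthetic)
#'
#' A synthetic set of published odds ratios with 95% confidence intervals for
#' the five PEDIS risk factors, with the magnitude and precision typical of a
#' large multicentre DFU amputation study. It is *not* the estimate table of
#' any specific study; it exists so that the informative-prior workflow
#' (pool, conservative adjustment, log transform) can be exercised and tested
#' end to end without redistributing third-party data.
#'
#' @return A data.frame of [published_effect()] rows: `coefficient_name`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `ci_level`.
#' @export
default_published_effects <- function() {
  data.frame(
    coefficient_name = c("perfusion", "extent", "depth", "infection", "sensation"),
    odds_ratio = c(2.5, 2.2, 2.3, 2.0, 1.9),
    ci_low     = c(1.9, 1.6, 1.7, 1.5, 1.4),
    ci_high    = c(3.3, 3.0, 3.1, 2.7, 2.6),
    ci_level   = 0.95,
    stringsAsFactors = FALSE
  )
}
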