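# Everything computed from posterior draws: highest density intervals,
# coefficient and odds-ratio summaries, null-exclusion decisions, tail
# probabilities, posterior AUC distributions, model comparison, and
# per-patient posterior risk prediction.

#' Highest density interval of a sample
#'
#' Shortest interval containing at least `mass` of the sample, found by an
#' exhaustive scan over sorted-sample windows of length `ceiling(mass * n)`
#' (assumes a unimodal posterior, the usual case for regression
#' coefficients). Width ties are broken by the lowest window.
#'
#' @param samples Numeric vector (>= 2 finite values).
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return List of class `"hdi_interval"` with `lower`, `upper`, `mass`.
#' @examples
#' hdi(c(1, 2, 3, 4, 100), mass = 0.8)  # [1, 4]
#' @export
hdi <- function(samples, mass = 0.95) {
  if (any(is.na(samples))) stop("samples contain NA")
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 finite samples")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) {
    out <- list(lower = x[1], upper = x[n], mass = mass)
  } else {
    width <- x[m:n] - x[1:(n - m + 1L)]
    i <- which.min(width)  # first index on ties
    out <- list(lower = x[i], upper = x[i + m - 1L], mass = mass)
  }
  structure(out, class = "hdi_interval")
}

#' @export
print.hdi_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%.0f%% HDI [%.*f, %.*f]\n", 100 * x$mass, digits, x$lower,
              digits, x$upper))
  invisible(x)
}

#' Does an HDI exclude the null value?
#'
#' A coefficient is considered associated with the outcome when its HDI
#' excludes the null value. A null value lying exactly on an endpoint counts
#' as covered (not excluded).
#'
#' @param interval An `"hdi_interval"` (or list with `lower`/`upper`).
#' @param null_value The null (default 0, i.e. odds ratio 1).
#' @return Logical.
#' @export
null_exclusion <- function(interval, null_value = 0) {
  null_value < interval$lower || null_value > interval$upper
}

#' Posterior tail probability
#'
#' Fraction of draws strictly below a threshold — e.g. the share of posterior
#' coefficient mass below zero.
#'
#' @param draws Numeric vector of posterior draws.
#' @param threshold Threshold (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
tail_probability <- function(draws, threshold = 0) {
  if (length(draws) == 0L) stop("empty draws")
  mean(draws < threshold)
}

#' Posterior summary of one coefficient
#'
#' Posterior median and 95% HDI on the log-odds scale, the odds ratio
#' (exponentiated median), the endpoint-exponentiated odds-ratio interval,
#' the fraction of draws below zero, and the null-exclusion verdict.
#' Endpoint exponentiation matches the reporting convention of the reference
#' analysis (HDIs are not transform-invariant in general; for the monotone
#' exp transform the endpoints of the log-odds HDI are simply carried over).
#'
#' @param fit A `"posterior_draws"` object.
#' @param name Coefficient name.
#' @param mass HDI mass (default 0.95).
#' @return List of class `"coefficient_summary"`.
#' @export
coefficient_summary <- function(fit, name, mass = 0.95) {
  if (!name %in% colnames(fit$draws)) stop("unknown coefficient: ", name)
  x <- fit$draws[, name]
  beta_hdi <- hdi(x, mass)
  med <- stats::median(x)
  structure(list(
    name = name, median_beta = med, beta_hdi = beta_hdi,
    odds_ratio = exp(med),
    or_hdi = structure(list(lower = exp(beta_hdi$lower),
                            upper = exp(beta_hdi$upper), mass = mass),
                       class = "hdi_interval"),
    prob_below_null = tail_probability(x, 0),
    associated = null_exclusion(beta_hdi, 0)),
    class = "coefficient_summary")
}

#' Posterior summary table of a fit
#'
#' One row per coefficient, in the reporting layout of the reference
#' analysis: posterior median and 95% HDI of the coefficient, odds ratio and
#' endpoint-exponentiated odds-ratio interval, tail probability below zero,
#' and the null-exclusion verdict.
#'
#' @param fit A `"posterior_draws"` object.
#' @param mass HDI mass.
#' @return data.frame with one row per coefficient.
#' @export
summarize_fit <- function(fit, mass = 0.95) {
  rows <- lapply(colnames(fit$draws), function(nm) {
    s <- coefficient_summary(fit, nm, mass)
    data.frame(name = nm, median_beta = s$median_beta,
               beta_lo = s$beta_hdi$lower, beta_hi = s$beta_hdi$upper,
               odds_ratio = s$odds_ratio, or_lo = s$or_hdi$lower,
               or_hi = s$or_hdi$upper, prob_below_null = s$prob_below_null,
               associated = s$associated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve via the rank statistic; tied score pairs count
#' one half, so all-tied scores give exactly 0.5.
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior AUC distribution of a fit
#'
#' For each retained posterior draw, the in-sample (apparent) AUC of the
#' draw's predicted probabilities against the observed outcomes, summarised
#' by the posterior median and 95% HDI. Only the ordering of predictions
#' matters, so the AUC is computed on the linear predictor.
#'
#' @param fit A `"posterior_draws"` object.
#' @param cohort The cohort the AUC is evaluated on (fit-eligible records).
#' @param thin Evaluate every `thin`-th draw (default 1 = all draws).
#' @param mass HDI mass.
#' @return List of class `"auc_posterior"`: `auc_draws`, `median`, `hdi`.
#' @export
posterior_auc <- function(fit, cohort, thin = 1L, mass = 0.95) {
  eligible <- fit_eligible(cohort)
  y <- eligible[[paste0("outcome_", fit$outcome)]]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  X <- cbind(intercept = 1,
             code_predictors(eligible, fit$age_center, fit$age_scale))
  if (!all(fit$predictor_names %in% colnames(X))) {
    stop("cohort lacks columns for the fitted predictors")
  }
  X <- X[, fit$predictor_names, drop = FALSE]
  idx <- seq(1L, nrow(fit$draws), by = as.integer(thin))
  eta <- X %*% t(fit$draws[idx, , drop = FALSE])
  pos <- y == 1L
  auc_draws <- vapply(seq_along(idx), function(k) auc(eta[, k], y), numeric(1))
  structure(list(auc_draws = auc_draws, median = stats::median(auc_draws),
                 hdi = hdi(auc_draws, mass), outcome = fit$outcome),
            class = "auc_posterior")
}

#' @export
print.auc_posterior <- function(x, ...) {
  cat(sprintf("Posterior AUC (outcome_%s): median %.3f, %.0f%% HDI [%.3f, %.3f] (%d draws)\n",
              x$outcome, x$median, 100 * x$hdi$mass, x$hdi$lower, x$hdi$upper,
              length(x$auc_draws)))
  invisible(x)
}

#' Compare two posterior AUC distributions
#'
#' `delta_auc` is the difference of posterior medians (second minus first)
#' and `cohens_d` the standardised mean difference with the pooled-SD
#' convention `sqrt((sd_a^2 + sd_b^2) / 2)`. Antisymmetric under swapping the
#' models. A zero pooled SD leaves `cohens_d` undefined (`NA`).
#'
#' @param auc_a,auc_b `"auc_posterior"` objects (e.g. uninformed and
#'   informed model).
#' @return List of class `"model_comparison"` with `delta_auc`, `cohens_d`,
#'   and the two medians.
#' @export
compare_models <- function(auc_a, auc_b) {
  sd_a <- stats::sd(auc_a$auc_draws)
  sd_b <- stats::sd(auc_b$auc_draws)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  structure(list(
    delta_auc = auc_b$median - auc_a$median,
    cohens_d = if (pooled == 0) NA_real_ else
      (mean(auc_b$auc_draws) - mean(auc_a$auc_draws)) / pooled,
    median_a = auc_a$median, median_b = auc_b$median),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f: delta = %.3f, Cohen's d = %.3f\n",
              x$median_a, x$median_b, x$delta_auc, x$cohens_d))
  invisible(x)
}

#' Posterior amputation-risk prediction for a patient profile
#'
#' Pushes every posterior coefficient draw through the inverse-logit of the
#' profile's linear predictor, yielding a full posterior risk distribution
#' summarised by its median and 95% HDI. The profile must state age and
#' gender explicitly (no silent defaults), and is coded exactly as at fit
#' time (the fit's age centring is reused).
#'
#' @param fit A `"posterior_draws"` object.
#' @param profile Named list with the predictors the fit used: the PEDIS
#'   grades plus `age` (years) and `gender` (`"female"`/`"male"`).
#' @param mass HDI mass.
#' @return List of class `"risk_prediction"`: `risk_draws`, `median_risk`,
#'   `hdi`, `profile`.
#' @export
predict_risk <- function(fit, profile, mass = 0.95) {
  profile <- as.list(profile)
  x <- vapply(fit$predictor_names, function(nm) {
    if (nm == "intercept") return(1)
    if (nm == "age_z") {
      if (is.null(profile$age)) stop("profile must state age explicitly")
      return((profile$age - fit$age_center) / fit$age_scale)
    }
    if (nm == "gender") {
      if (is.null(profile$gender)) stop("profile must state gender explicitly")
      if (!profile$gender %in% c("female", "male")) stop("invalid gender")
      return(as.numeric(profile$gender == "male"))
    }
    g <- profile[[nm]]
    rng <- GRADE_RANGE[[nm]]
    if (is.null(g) || g < rng[1] || g > rng[2]) {
      stop("profile grade missing or out of range for ", nm)
    }
    as.numeric(g)
  }, numeric(1))
  risks <- stats::plogis(drop(fit$draws %*% x))
  structure(list(risk_draws = risks, median_risk = stats::median(risks),
                 hdi = if (length(risks) >= 2L) hdi(risks, mass) else NULL,
                 profile = profile),
            class = "risk_prediction")
}

#' @export
print.risk_prediction <- function(x, ...) {
  cat(sprintf("Posterior amputation risk: median %.1f%%", 100 * x$median_risk))
  if (!is.null(x$hdi)) {
    cat(sprintf(", %.0f%% HDI [%.1f%%, %.1f%%]", 100 * x$hdi$mass,
                100 * x$hdi$lower, 100 * x$hdi$upper))
  }
  cat("\n")
  invisible(x)
}
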