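# Cauchy priors for the logistic coefficients.
#
# Two provenances: weakly-informative Cauchy(0, 1) defaults, and informative
# priors elicited from published odds ratios — inverse-variance pooled on the
# log-OR scale, conservatively adjusted by subtracting twice the standard
# error on the OR scale, then log-transformed into the Cauchy location.

#' Construct a prior specification
#'
#' @param coefficient_name Coefficient the prior applies to.
#' @param location Cauchy location on the log-odds scale.
#' @param scale Cauchy scale (> 0).
#' @param provenance `"weakly_informative"` or `"elicited"`.
#' @param source_note Free-text provenance note.
#' @return One-row data.frame of class `"prior_spec"`.
#' @export
prior_spec <- function(coefficient_name, location, scale,
                       provenance = c("weakly_informative", "elicited"),
                       source_note = "") {
  provenance <- match.arg(provenance)
  if (!is.numeric(scale) || scale <= 0) stop("prior scale must be > 0")
  if (provenance == "weakly_informative" && location != 0) {
    stop("weakly-informative priors are zero-centred by definition")
  }
  structure(data.frame(coefficient_name = coefficient_name,
                       distribution = "cauchy", location = location,
                       scale = scale, provenance = provenance,
                       source_note = source_note, stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Weakly-informative default prior
#'
#' The zero-centred Cauchy with scale 1 used for every coefficient when no
#' external knowledge is incorporated, broad enough to span all plausible
#' log-odds effects.
#'
#' @param coefficient_name Coefficient name.
#' @return A [prior_spec()] with location 0, scale 1.
#' @export
weakly_informative_prior <- function(coefficient_name) {
  prior_spec(coefficient_name, location = 0, scale = 1,
             provenance = "weakly_informative", source_note = "default Cauchy(0, 1)")
}

#' A published effect (odds ratio with confidence interval)
#'
#' @param coefficient_name Coefficient the effect informs.
#' @param odds_ratio Published odds ratio (> 0).
#' @param ci_low,ci_high Confidence bounds (> 0, `ci_low <= odds_ratio <=
#'   ci_high`).
#' @param ci_level Confidence level of the interval (default 0.95).
#' @return One-row data.frame of class `"published_effect"`.
#' @export
published_effect <- function(coefficient_name, odds_ratio, ci_low, ci_high,
                             ci_level = 0.95) {
  if (any(c(odds_ratio, ci_low, ci_high) <= 0)) {
    stop("odds ratios and confidence bounds must be positive")
  }
  if (ci_low > odds_ratio || odds_ratio > ci_high) {
    stop("require ci_low <= odds_ratio <= ci_high")
  }
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(data.frame(coefficient_name = coefficient_name,
                       odds_ratio = odds_ratio, ci_low = ci_low,
                       ci_high = ci_high, ci_level = ci_level,
                       stringsAsFactors = FALSE),
            class = c("published_effect", "data.frame"))
}

#' Standard error recovered from a confidence interval
#'
#' Symmetric-width convention on the odds-ratio scale:
#' `SE = (ci_high - ci_low) / (2 z)` with `z` the normal quantile of the
#' interval's level (1.96 at 95%). With `scale = "log_or"` the same formula
#' is applied to the log-transformed bounds instead.
#'
#' @param effect A [published_effect()] (or data.frame row with its fields).
#' @param scale `"or"` (default) or `"log_or"`.
#' @return Standard error (scalar).
#' @export
se_from_ci <- function(effect, scale = c("or", "log_or")) {
  scale <- match.arg(scale)
  if (effect$ci_high < effect$ci_low) stop("ci_high must be >= ci_low")
  z <- stats::qnorm(1 - (1 - effect$ci_level) / 2)
  if (scale == "or") {
    (effect$ci_high - effect$ci_low) / (2 * z)
  } else {
    (log(effect$ci_high) - log(effect$ci_low)) / (2 * z)
  }
}

#' Pool several published effects for one coefficient
#'
#' Inverse-variance fixed-effect pooling on the log-odds-ratio scale; the
#' pooled standard error is carried back to the odds-ratio scale by the delta
#' method (`SE_OR ~= OR * SE_logOR`). A single effect is returned unchanged.
#'
#' @param effects data.frame of [published_effect()] rows for one coefficient.
#' @return List with `odds_ratio` (pooled), `se_or`, `se_log_or`, `log_or`.
#' @export
pool_effects <- function(effects) {
  effects <- as.data.frame(effects)
  if (nrow(effects) == 0L) stop("no effects to pool")
  if (length(unique(effects$coefficient_name)) > 1L) {
    stop("pool_effects expects effects for a single coefficient")
  }
  log_or <- log(effects$odds_ratio)
  se_log <- vapply(seq_len(nrow(effects)), function(i) {
    se_from_ci(effects[i, , drop = FALSE], scale = "log_or")
  }, numeric(1))
  if (any(se_log <= 0)) {
    # degenerate (point) intervals: fall back to an unweighted mean
    pooled_log <- mean(log_or)
    pooled_se_log <- 0
  } else {
    w <- 1 / se_log^2
    pooled_log <- sum(w * log_or) / sum(w)
    pooled_se_log <- sqrt(1 / sum(w))
  }
  or <- exp(pooled_log)
  list(odds_ratio = or, se_or = or * pooled_se_log,
       se_log_or = pooled_se_log, log_or = pooled_log)
}

#' Conservative adjustment of a pooled odds ratio
#'
#' Shrinks the pooled odds ratio toward the null by subtracting twice its
#' standard error (on the odds-ratio scale), flooring the result at a small
#' positive value so the subsequent log transform stays defined.
#'
#' @param pooled_or Pooled odds ratio (> 0).
#' @param se_or Standard error on the odds-ratio scale (>= 0).
#' @param floor Lower bound for the adjusted odds ratio (default 0.05).
#' @return Adjusted odds ratio.
#' @export
conservative_adjust <- function(pooled_or, se_or, floor = 0.05) {
  stopifnot(pooled_or > 0, se_or >= 0, floor > 0)
  max(pooled_or - 2 * se_or, floor)
}

#' Informative prior from an adjusted odds ratio
#'
#' The log of the conservatively adjusted odds ratio becomes the location of
#' an informative Cauchy prior. The scale defaults to 1 — the same as the
#' weakly-informative prior — so informed and uninformed priors differ only
#' in location.
#'
#' @param adjusted_or Adjusted odds ratio (> 0).
#' @param scale Cauchy scale (default 1).
#' @param coefficient_name Coefficient name.
#' @param source_note Free-text provenance note.
#' @return A [prior_spec()] with provenance `"elicited"`.
#' @export
informed_prior <- function(adjusted_or, scale = 1, coefficient_name,
                           source_note = "") {
  stopifnot(adjusted_or > 0)
  prior_spec(coefficient_name, location = log(adjusted_or), scale = scale,
             provenance = "elicited", source_note = source_note)
}

#' Elicit informative priors from published effects
#'
#' Full elicitation chain per coefficient: pool the published effects
#' (inverse-variance, log-OR scale), subtract twice the pooled standard error
#' on the odds-ratio scale, floor, log-transform, and wrap in a Cauchy prior.
#'
#' @param effects data.frame of [published_effect()] rows (any number of
#'   coefficients).
#' @param scale Cauchy scale of the elicited priors (default 1).
#' @param floor Floor of [conservative_adjust()].
#' @return A `prior_spec` data.frame, one row per coefficient.
#' @export
elicit_priors <- function(effects, scale = 1, floor = 0.05) {
  effects <- as.data.frame(effects)
  rows <- lapply(split(effects, effects$coefficient_name), function(d) {
    pooled <- pool_effects(d)
    adj <- conservative_adjust(pooled$odds_ratio, pooled$se_or, floor = floor)
    informed_prior(adj, scale = scale, coefficient_name = d$coefficient_name[1],
                   source_note = sprintf(
                     "pooled OR %.4f (SE %.4f), adjusted to %.4f from %d effect(s)",
                     pooled$odds_ratio, pooled$se_or, adj, nrow(d)))
  })
  out <- do.call(rbind, rows)[, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prior_spec", "data.frame")
  # keep the canonical factor order where applicable
  ord <- order(match(out$coefficient_name, PEDIS_FACTORS))
  out[ord, , drop = FALSE]
}

#' Full prior set for a risk model
#'
#' One prior per model coefficient in the fitting order (intercept,
#' perfusion, extent, depth, infection, sensation, age_z, gender). The
#' intercept always gets a broad Cauchy(0, 10); age and gender always get the
#' weakly-informative Cauchy(0, 1) — external knowledge is elicited for the
#' five risk factors only.
#'
#' @param mode `"uninformed"` (Cauchy(0, 1) for all risk factors) or
#'   `"informed"` (elicited from `effects`).
#' @param effects Published effects for the risk factors (required for
#'   `"informed"`); see [default_published_effects()] for an illustrative set.
#' @param scale Cauchy scale of elicited priors.
#' @return A `prior_spec` data.frame with eight rows.
#' @export
default_priors <- function(mode = c("uninformed", "informed"), effects = NULL,
                           scale = 1) {
  mode <- match.arg(mode)
  intercept <- prior_spec("intercept", 0, 10, "weakly_informative",
                          "broad intercept prior")
  covars <- rbind(weakly_informative_prior("age_z"),
                  weakly_informative_prior("gender"))
  if (mode == "uninformed") {
    factors <- do.call(rbind, lapply(PEDIS_FACTORS, weakly_informative_prior))
  } else {
    if (is.null(effects)) stop("informed priors require a published-effects table")
    factors <- elicit_priors(effects, scale = scale)
    if (!setequal(factors$coefficient_name, PEDIS_FACTORS)) {
      stop("informed effects must cover exactly the five PEDIS factors")
    }
  }
  out <- rbind(intercept, factors, covars)
  rownames(out) <- NULL
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Complete a partial prior set with the model defaults
#'
#' Elicited prior files typically cover only the five risk factors; this
#' fills in every missing model coefficient with its default (broad
#' Cauchy(0, 10) for the intercept, weakly-informative Cauchy(0, 1)
#' otherwise), yielding a full prior set usable by
#' [fit_amputation_model()].
#'
#' @param priors A `prior_spec` data.frame (any subset of the model
#'   coefficients).
#' @return A `prior_spec` data.frame covering all eight coefficients.
#' @export
complete_priors <- function(priors) {
  priors <- as.data.frame(priors)
  full <- default_priors("uninformed")
  keep <- full[!full$coefficient_name %in% priors$coefficient_name, ]
  out <- rbind(priors[, names(full)], keep)
  out <- out[order(match(out$coefficient_name, full$coefficient_name)), ]
  rownames(out) <- NULL
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Cauchy log density
#'
#' `log(1 / (pi * scale * (1 + ((x - location)/scale)^2)))`, the prior term
#' the sampler adds per coefficient.
#'
#' @param x Evaluation point(s).
#' @param location,scale Cauchy parameters (`scale > 0`).
#' @return Log density value(s).
#' @export
cauchy_log_density <- function(x, location = 0, scale = 1) {
  stopifnot(scale > 0)
  -log(pi * scale) - log1p(((x - location) / scale)^2)
}

#' Read / write prior specifications as JSON
#'
#' @param priors A `prior_spec` data.frame.
#' @param path File path.
#' @return `read_priors()` returns a `prior_spec` data.frame;
#'   `write_priors()` invisibly returns `path`.
#' @export
write_priors <- function(priors, path) {
  jsonlite::write_json(as.data.frame(priors), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  out <- jsonlite::fromJSON(path)
  stopifnot(all(c("coefficient_name", "location", "scale") %in% names(out)))
  if (is.null(out$provenance)) out$provenance <- "elicited"
  if (is.null(out$source_note)) out$source_note <- ""
  if (is.null(out$distribution)) out$distribution <- "cauchy"
  class(out) <- c("prior_spec", "data.frame")
  out
}
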