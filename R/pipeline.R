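# End-to-end orchestration of the twofold modelling strategy: for each
# requested outcome, fit the model with weakly-informative priors and with
# informative priors elicited from published effects, run diagnostics,
# summarise, compute the posterior AUC distribution, and compare the two.

# tiny deterministic content hash (31-polynomial over the JSON encoding,
# modulo a Mersenne prime to stay in exact double arithmetic)
content_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full risk-modelling pipeline
#'
#' For every combination of requested outcome and prior mode: build the
#' priors, fit the Bayesian logistic model, compute convergence diagnostics,
#' a coefficient summary table and the posterior AUC distribution, and
#' persist all artifacts. When both prior modes run, the informed and
#' uninformed posterior AUC distributions are compared per outcome.
#' Diagnostic threshold violations warn but do not abort. The run is
#' deterministic for a given config; the manifest records inputs, config and
#' a config hash.
#'
#' Output layout: `<out_dir>/<outcome>/<mode>/{draws.csv, diagnostics.json,
#' summary.csv}`, `<out_dir>/<outcome>/comparison.json`, and
#' `<out_dir>/manifest.json`.
#'
#' @param cohort A `pedis_cohort` or path to a cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param outcomes Subset of `c("any", "major")`.
#' @param prior_mode `"both"`, `"uninformed"` or `"informed"`.
#' @param effects Published-effects table for informed priors (default:
#'   [default_published_effects()]).
#' @param config A [chain_config()]; its seed governs all fits (each
#'   outcome/mode fit gets a distinct deterministic offset).
#' @param thin_auc Thinning for the posterior AUC evaluation.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cohort, out_dir, outcomes = c("any", "major"),
                         prior_mode = c("both", "uninformed", "informed"),
                         effects = default_published_effects(),
                         config = chain_config(), thin_auc = 1L) {
  prior_mode <- match.arg(prior_mode)
  outcomes <- match.arg(outcomes, c("any", "major"), several.ok = TRUE)
  modes <- if (prior_mode == "both") c("uninformed", "informed") else prior_mode
  cohort_path <- if (is.character(cohort)) cohort else NA_character_
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "dfurisk",
    version = as.character(utils::packageVersion("dfurisk")),
    cohort = list(path = cohort_path, n = nrow(cohort),
                  n_fit_eligible = nrow(fit_eligible(cohort)),
                  provenance = attr(cohort, "provenance")),
    config = unclass(config), outcomes = outcomes, prior_modes = modes,
    defaults = list(prior_scale_elicited = 1, intercept_prior_scale = 10,
                    hdi_mass = 0.95, retention = "all post-burn-in draws"),
    artifacts = list()
  )
  manifest$config_hash <- content_hash(jsonlite::toJSON(
    manifest[c("config", "outcomes", "prior_modes")], auto_unbox = TRUE))

  fit_idx <- 0L
  for (oc in outcomes) {
    oc_dir <- file.path(out_dir, oc)
    aucs <- list()
    for (mode in modes) {
      fit_idx <- fit_idx + 1L
      stage <- sprintf("%s/%s", oc, mode)
      res <- tryCatch({
        priors <- if (mode == "uninformed") default_priors("uninformed")
                  else default_priors("informed", effects = effects)
        cfg <- config
        cfg$seed <- config$seed + 1000L * fit_idx
        fit <- fit_amputation_model(cohort, outcome = oc, priors = priors,
                                    config = cfg)
        diag <- diagnostics_report(fit, cohort = cohort)
        if (!isTRUE(diag$verdict$converged)) {
          warning("diagnostics: R-hat threshold exceeded in ", stage)
        }
        ap <- posterior_auc(fit, cohort, thin = thin_auc)
        mode_dir <- file.path(oc_dir, mode)
        dir.create(mode_dir, recursive = TRUE, showWarnings = FALSE)
        write_draws(fit, file.path(mode_dir, "draws.csv"))
        write_diagnostics(diag, file.path(mode_dir, "diagnostics.json"))
        smry <- summarize_fit(fit)
        smry$auc_median <- ap$median
        smry$auc_hdi_lo <- ap$hdi$lower
        smry$auc_hdi_hi <- ap$hdi$upper
        utils::write.csv(smry, file.path(mode_dir, "summary.csv"),
                         row.names = FALSE)
        list(ap = ap, files = file.path(oc, mode,
                                        c("draws.csv", "diagnostics.json", "summary.csv")))
      }, error = function(e) {
        stop("pipeline stage ", stage, " failed: ", conditionMessage(e),
             call. = FALSE)
      })
      aucs[[mode]] <- res$ap
      manifest$artifacts[[stage]] <- res$files
    }
    if (all(c("uninformed", "informed") %in% names(aucs))) {
      cmp <- compare_models(aucs$uninformed, aucs$informed)
      cmp_path <- file.path(oc_dir, "comparison.json")
      jsonlite::write_json(
        list(outcome = oc, auc_uninformed = cmp$median_a,
             auc_informed = cmp$median_b, delta_auc = cmp$delta_auc,
             cohens_d = cmp$cohens_d),
        cmp_path, auto_unbox = TRUE, digits = NA)
      manifest$artifacts[[paste0(oc, "/comparison")]] <- file.path(oc, "comparison.json")
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
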