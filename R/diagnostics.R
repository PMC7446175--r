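# Convergence and adequacy diagnostics: split R-hat, effective sample size
# (Geyer initial-monotone truncation), autocorrelation, and predictor
# collinearity.

as_draws_matrix <- function(draws) {
  if (inherits(draws, "posterior_draws")) {
    return(list(draws = draws$draws, chain_id = draws$chain_id))
  }
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  list(draws = as.matrix(draws), chain_id = NULL)
}

split_chains <- function(x, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    n <- length(v)
    if (n %% 2L == 1L) v <- v[-n]  # drop last element of odd chains
    h <- length(v) / 2L
    halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  halves
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the classical potential-scale-reduction
#' factor is computed over the half-sequences:
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-half
#' variance and `B` the between-half-mean variance times `n`. Values near 1
#' indicate the chains sample the same distribution; the conventional pass
#' threshold is 1.01. Zero-variance draws return exactly 1.
#'
#' @param draws Retained draws: vector, matrix (draws x coefficients) or a
#'   `"posterior_draws"` object.
#' @param chain_id Integer chain label per draw (not needed for
#'   `"posterior_draws"`).
#' @return Named numeric vector, one value per coefficient.
#' @export
split_rhat <- function(draws, chain_id = NULL) {
  dm <- as_draws_matrix(draws)
  if (is.null(chain_id)) chain_id <- dm$chain_id
  if (is.null(chain_id) || length(unique(chain_id)) < 2L) {
    stop("split R-hat needs at least two chains")
  }
  apply(dm$draws, 2, function(x) {
    if (stats::var(x) == 0) return(1)
    halves <- split_chains(x, chain_id)
    n <- length(halves[[1]])
    if (n < 2L) stop("chains too short to split")
    W <- mean(vapply(halves, stats::var, numeric(1)))
    B <- n * stats::var(vapply(halves, mean, numeric(1)))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Autocorrelation function of a single chain
#'
#' Biased autocovariance estimates normalised by lag 0 (so lag 0 is exactly
#' 1), the convention under which the effective-sample-size sum is stable.
#'
#' @param x Numeric chain.
#' @param max_lag Largest lag (< `length(x)`).
#' @return Numeric vector of autocorrelations at lags `0:max_lag`.
#' @export
autocorrelation <- function(x, max_lag) {
  stopifnot(max_lag < length(x))
  rho <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  rho[1] <- 1  # lag 0 is 1 by definition; acf() leaves rounding noise
  rho
}

#' Effective sample size
#'
#' `ESS = N / (1 + 2 * sum_t rho_t)` with `rho_t` the chain-averaged
#' autocorrelations, truncated by Geyer's initial-monotone-positive-pair
#' rule: consecutive lag pairs `rho_{2k} + rho_{2k+1}` are summed while
#' positive and non-increasing. Antithetic chains can legitimately yield
#' ESS above `N`. Zero-variance draws are reported as `ESS = N` and flagged
#' in the `"degenerate"` attribute.
#'
#' @inheritParams split_rhat
#' @param max_lag Cap on autocorrelation lags per chain (default: half the
#'   chain length, at most 1000).
#' @return Named numeric vector with attribute `"degenerate"` (logical per
#'   coefficient).
#' @export
effective_sample_size <- function(draws, chain_id = NULL, max_lag = NULL) {
  dm <- as_draws_matrix(draws)
  if (is.null(chain_id)) chain_id <- dm$chain_id
  if (is.null(chain_id)) chain_id <- rep(1L, nrow(dm$draws))
  chains <- unique(chain_id)
  chain_len <- min(table(chain_id))
  if (is.null(max_lag)) max_lag <- min(floor(chain_len / 2), 1000L)
  n_total <- nrow(dm$draws)

  ess <- numeric(ncol(dm$draws))
  degenerate <- logical(ncol(dm$draws))
  for (j in seq_len(ncol(dm$draws))) {
    x <- dm$draws[, j]
    if (stats::var(x) == 0) {
      ess[j] <- n_total
      degenerate[j] <- TRUE
      next
    }
    rho <- rowMeans(vapply(chains, function(ch) {
      autocorrelation(x[chain_id == ch][seq_len(chain_len)], max_lag)
    }, numeric(max_lag + 1L)))
    # Geyer initial monotone positive sequence over lag pairs
    n_pairs <- floor((max_lag + 1L) / 2L)
    gamma <- rho[2 * seq_len(n_pairs) - 1L] + rho[2 * seq_len(n_pairs)]
    tau <- -rho[1]
    prev <- Inf
    for (k in seq_len(n_pairs)) {
      if (gamma[k] <= 0) break
      g <- min(gamma[k], prev)  # enforce monotone decrease
      tau <- tau + 2 * g
      prev <- g
    }
    tau <- max(tau, 1e-8)
    ess[j] <- n_total / tau
  }
  names(ess) <- colnames(dm$draws)
  names(degenerate) <- colnames(dm$draws)
  attr(ess, "degenerate") <- degenerate
  ess
}

#' Predictor collinearity matrix
#'
#' Pairwise correlations of the numeric predictor columns (grades as numeric,
#' age, gender male = 1). Any absolute off-diagonal correlation at or above
#' the threshold raises the collinearity flag. Zero-variance columns have
#' undefined correlations, reported as `NA`.
#'
#' @param cohort A `pedis_cohort` or a predictor data.frame/matrix.
#' @param threshold Flagging threshold on `|r|` (default 0.8).
#' @param method `"pearson"` (default) or `"spearman"` (rank-based option for
#'   ordinal grades).
#' @return List of class `"collinearity_report"`: `correlation` matrix,
#'   `flag`, and the flagged `pairs`.
#' @export
collinearity_matrix <- function(cohort, threshold = 0.8,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(cohort) && all(PEDIS_FACTORS %in% names(cohort)) &&
      "age" %in% names(cohort)) {
    X <- code_predictors(as.data.frame(cohort),
                         age_center = mean(cohort$age),
                         age_scale = stats::sd(cohort$age))
  } else {
    X <- as.matrix(cohort)
  }
  if (nrow(X) < 3L) stop("need at least 3 records")
  zero_var <- apply(X, 2, stats::var) == 0
  cm <- suppressWarnings(stats::cor(X, method = method))
  cm[zero_var, ] <- NA
  cm[, zero_var] <- NA
  diag(cm)[!zero_var] <- 1
  off <- abs(cm)
  diag(off) <- 0
  hits <- which(off >= threshold & upper.tri(off), arr.ind = TRUE)
  pairs <- if (nrow(hits) > 0L) {
    data.frame(var1 = rownames(cm)[hits[, 1]], var2 = colnames(cm)[hits[, 2]],
               r = cm[hits], stringsAsFactors = FALSE)
  } else {
    data.frame(var1 = character(), var2 = character(), r = numeric())
  }
  structure(list(correlation = cm, flag = nrow(pairs) > 0L, pairs = pairs,
                 threshold = threshold, method = method),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("Collinearity check (|r| >= %.2f, %s): %s\n", x$threshold,
              x$method, if (x$flag) "FLAGGED" else "no collinearity"))
  if (x$flag) print(x$pairs)
  invisible(x)
}

#' Full diagnostics report for a fit
#'
#' Per-coefficient split R-hat, effective sample size and autocorrelations at
#' selected lags, plus (when a cohort is supplied) the predictor collinearity
#' check, with pass/fail verdicts at the conventional thresholds (R-hat <
#' 1.01, ESS > `ess_threshold`).
#'
#' @param fit A `"posterior_draws"` object.
#' @param cohort Optional `pedis_cohort` for the collinearity check.
#' @param lags Lags reported in the autocorrelation table.
#' @param ess_threshold ESS pass threshold (default 10,000, the reported
#'   adequacy level).
#' @return List of class `"diagnostics_report"`.
#' @export
diagnostics_report <- function(fit, cohort = NULL, lags = c(1L, 5L, 10L, 50L),
                               ess_threshold = 10000) {
  rhat <- split_rhat(fit)
  ess <- effective_sample_size(fit)
  chains <- unique(fit$chain_id)
  chain_len <- min(table(fit$chain_id))
  max_lag <- min(max(lags), chain_len - 1L)
  lags <- lags[lags <= max_lag]
  ac <- vapply(seq_len(ncol(fit$draws)), function(j) {
    rho <- rowMeans(vapply(chains, function(ch) {
      autocorrelation(fit$draws[fit$chain_id == ch, j][seq_len(chain_len)], max_lag)
    }, numeric(max_lag + 1L)))
    rho[lags + 1L]
  }, numeric(length(lags)))
  ac <- matrix(ac, nrow = length(lags),
               dimnames = list(paste0("lag", lags), colnames(fit$draws)))
  coll <- if (!is.null(cohort)) collinearity_matrix(fit_eligible(cohort)) else NULL
  structure(list(
    rhat = rhat, ess = ess, autocorr = ac, collinearity = coll,
    verdict = list(converged = all(rhat < 1.01),
                   ess_adequate = all(ess > ess_threshold),
                   no_collinearity = if (is.null(coll)) NA else !coll$flag),
    thresholds = list(rhat = 1.01, ess = ess_threshold)),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("MCMC diagnostics\n")
  tab <- data.frame(rhat = round(x$rhat, 4), ess = round(x$ess))
  print(tab)
  cat(sprintf("converged (R-hat < %.2f): %s;  ESS > %d: %s\n",
              x$thresholds$rhat, x$verdict$converged,
              x$thresholds$ess, x$verdict$ess_adequate))
  if (!is.null(x$collinearity)) print(x$collinearity)
  invisible(x)
}

#' Write a diagnostics report to JSON
#'
#' @param report A `"diagnostics_report"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diagnostics <- function(report, path) {
  out <- list(rhat = as.list(report$rhat),
              ess = as.list(unclass(report$ess)),
              autocorr = as.data.frame(report$autocorr),
              verdict = report$verdict, thresholds = report$thresholds)
  if (!is.null(report$collinearity)) {
    out$collinearity <- list(flag = report$collinearity$flag,
                             pairs = report$collinearity$pairs)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
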