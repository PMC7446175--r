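# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities by the most literal method
# available so they stay independent of the package's code paths.

# Exhaustive window search for the shortest interval holding >= mass of the
# sample (explicit loop, first-index tie-break).
hdi_oracle <- function(samples, mass = 0.95) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  best_i <- 1L
  best_w <- x[m] - x[1]
  if (m < n) {
    for (i in 2:(n - m + 1L)) {
      w <- x[i + m - 1L] - x[i]
      if (w < best_w) {
        best_w <- w
        best_i <- i
      }
    }
  }
  c(x[best_i], x[best_i + m - 1L])
}

# Pairwise-counting AUC: every positive-negative pair contributes 1, 0.5 on
# ties, 0 otherwise.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Deterministic 1-D quadrature of the intercept-only logistic posterior with
# a Cauchy prior: returns grid, normalised density, CDF, and posterior mean.
intercept_posterior_quadrature <- function(n_success, n_fail, prior_scale,
                                           lo = -8, hi = 8, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  loglik <- n_success * grid - (n_success + n_fail) * log1p(exp(grid))
  logpost <- loglik + stats::dcauchy(grid, 0, prior_scale, log = TRUE)
  dens <- exp(logpost - max(logpost))
  z <- sum(dens) * step
  dens <- dens / z
  cdf <- cumsum(dens) * step
  list(grid = grid, density = dens, cdf = cdf,
       mean = sum(grid * dens) * step)
}

ks_distance_to_cdf <- function(draws, grid, cdf) {
  x <- sort(draws)
  n <- length(x)
  F_at <- stats::approx(grid, cdf, xout = x, rule = 2)$y
  max(abs(seq_len(n) / n - F_at), abs((seq_len(n) - 1L) / n - F_at))
}

# Overlapping batch means estimate of the effective sample size.
obm_ess <- function(x, b) {
  n <- length(x)
  cs <- cumsum(x)
  means <- (cs[b:n] - c(0, cs[seq_len(n - b)])) / b
  sigma2 <- n * b / ((n - b + 1) * (n - b)) * sum((means - mean(x))^2)
  n / (sigma2 / stats::var(x))
}

# Minimal valid patient row for record-level tests.
raw_row <- function(...) {
  base <- list(patient_id = "p1", age = 66, gender = "male", perfusion = 2,
               extent = 2, depth = 1, infection = 1, sensation = 1,
               outcome_any = 0, outcome_major = 0, lost_to_followup = FALSE)
  utils::modifyList(base, list(...))
}

# Small deterministic cohort for I/O and fitting tests.
small_cohort <- function(n = 60, seed = 101, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}

# A stub posterior_draws object around a given draws matrix.
fake_fit <- function(draws, chain_id = NULL, outcome = "any",
                     age_center = 65.9, age_scale = 12.3) {
  draws <- as.matrix(draws)
  if (is.null(chain_id)) {
    chain_id <- rep(1:2, length.out = nrow(draws))
    chain_id <- sort(chain_id)
  }
  structure(list(draws = draws, chain_id = chain_id,
                 predictor_names = colnames(draws), outcome = outcome,
                 age_center = age_center, age_scale = age_scale),
            class = "posterior_draws")
}

# Reduced chain settings used where a full-length run adds nothing.
quick_config <- function(seed, n_chains = 4, n_steps = 1500, burn_in = 250,
                         ...) {
  chain_config(n_chains = n_chains, n_steps = n_steps, burn_in = burn_in,
               seed = seed, ...)
}
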