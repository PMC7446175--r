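test_that("inverse logit and linear predictor are stable and exact", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(log(3)), 0.75, tolerance = 1e-12)
  expect_equal(inverse_logit(-745), 0)
  expect_equal(inverse_logit(745), 1)

  x <- c(1, 2, 0.5)
  beta <- c(-1, 0.3, 2)
  expect_equal(linear_predictor(beta, x), sum(beta * x), tolerance = 1e-12)
  expect_error(linear_predictor(c(1, 2), x), "dimension mismatch")
})

test_that("log posterior matches closed forms and a brute-force oracle", {
  # one record, y = 1, intercept only, beta = 0, Cauchy(0, 1):
  # log(0.5) + log(1/pi)
  X <- matrix(1, 1, 1)
  expect_equal(log_posterior(0, X, 1, 0, 1), log(0.5) + log(1 / pi),
               tolerance = 1e-12)
  expect_error(log_posterior(NaN, X, 1, 0, 1), "non-finite")

  # doubling the data doubles exactly the likelihood part
  set.seed(1)
  Xr <- cbind(1, matrix(rnorm(20), 10, 2))
  yr <- rbinom(10, 1, 0.5)
  beta <- c(0.2, -0.5, 1)
  loc <- c(0, 0, 0); scl <- c(10, 1, 1)
  prior_part <- sum(dcauchy(beta, loc, scl, log = TRUE))
  single <- log_posterior(beta, Xr, yr, loc, scl)
  double <- log_posterior(beta, rbind(Xr, Xr), c(yr, yr), loc, scl)
  expect_equal(double - prior_part, 2 * (single - prior_part),
               tolerance = 1e-10)

  # brute-force oracle: per-record Bernoulli log-mass + reference Cauchy density
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:40, 1); p <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    beta <- rnorm(p, sd = 1.5)
    loc <- rnorm(p, sd = 0.3); scl <- runif(p, 0.5, 3)
    probs <- 1 / (1 + exp(-drop(X %*% beta)))
    oracle <- sum(dbinom(y, 1, probs, log = TRUE)) +
      sum(dcauchy(beta, loc, scl, log = TRUE))
    expect_equal(log_posterior(beta, X, y, loc, scl), oracle,
                 tolerance = 1e-8)
  }
})

test_that("fits are deterministic given the seed and refuse constant outcomes", {
  coh <- small_cohort(n = 150, seed = 21)
  cfg <- quick_config(seed = 5, n_steps = 600, burn_in = 100)
  # chains this short may warn on R-hat; determinism is the point here
  f1 <- suppressWarnings(fit_amputation_model(coh, "any", config = cfg))
  f2 <- suppressWarnings(fit_amputation_model(coh, "any", config = cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(colnames(f1$draws),
                   c("intercept", "perfusion", "extent", "depth", "infection",
                     "sensation", "age_z", "gender"))

  const <- coh
  const$outcome_any <- 1L
  const$outcome_major[is.na(const$outcome_major)] <- 0L
  const$outcome_any[const$lost_to_followup] <- NA
  expect_error(fit_amputation_model(const, "any"), "constant")
})

test_that("intercept-only posterior matches 1-D quadrature for both proposals", {
  # 10 successes / 10 failures under a Cauchy(0, 2.5) prior
  df <- data.frame(patient_id = sprintf("p%02d", 1:20), age = 60,
                   gender = "male", perfusion = 1, extent = 1, depth = 1,
                   infection = 1, sensation = 1,
                   outcome_any = rep(0:1, each = 10),
                   outcome_major = 0, lost_to_followup = FALSE)
  coh <- as_cohort(df)
  quad <- intercept_posterior_quadrature(10, 10, 2.5)
  priors <- prior_spec("intercept", 0, 2.5, "weakly_informative")

  for (prop in c("laplace", "random_walk")) {
    fit <- fit_amputation_model(
      coh, "any", priors = priors, predictors = character(0),
      config = chain_config(n_chains = 4, n_steps = 2500, burn_in = 500,
                            seed = 11, proposal = prop))
    draws <- fit$draws[, "intercept"]
    mcse <- sd(draws) / sqrt(effective_sample_size(fit)[["intercept"]])
    expect_lt(abs(mean(draws) - quad$mean), 3 * mcse)
  }
})

test_that("posterior medians approach ML estimates in the flat-prior large-n limit", {
  coh <- generate_cohort(generator_config(n = 5000, seed = 41, loss_prob = 0))
  flat <- default_priors("uninformed")
  flat$scale <- 10  # effectively flat relative to the likelihood at n = 5000
  fit <- fit_amputation_model(coh, "any", priors = flat,
                              config = quick_config(seed = 6))
  med <- apply(fit$draws, 2, median)

  el <- fit_eligible(coh)
  X <- data.frame(dfurisk:::code_predictors(el, fit$age_center, fit$age_scale))
  ml <- coef(glm(el$outcome_any ~ ., data = X, family = binomial))
  expect_equal(unname(med), unname(ml), tolerance = 0.05)
})

test_that("known coefficients are recovered from a large synthetic cohort", {
  cfg <- generator_config(n = 2000, seed = 7)
  coh <- generate_cohort(cfg)
  fit <- fit_amputation_model(coh, "any", config = quick_config(seed = 3))
  truth <- c(intercept = unname(attr(coh, "true_intercept")["any"]),
             cfg$true_beta)
  med <- apply(fit$draws, 2, median)
  sds <- apply(fit$draws, 2, sd)
  # every coefficient's truth lies within 3 posterior SDs of its median
  expect_true(all(abs(med - truth) < 3 * sds))
  # and the grade coefficients are recovered to +/-0.15 on average
  grade <- c("perfusion", "extent", "depth", "infection", "sensation")
  expect_lt(mean(abs(med[grade] - truth[grade])), 0.15)
})

test_that("univariate fits detect strong effects and match multivariate fits", {
  beta <- setNames(c(1, 0, 0, 0, 0, 0, 0),
                   c("perfusion", "extent", "depth", "infection", "sensation",
                     "age_z", "gender"))
  coh <- generate_cohort(generator_config(n = 1500, seed = 51, true_beta = beta,
                                          target_prevalence = 0.3, loss_prob = 0))
  uni <- fit_univariate(coh, "perfusion", "any", config = quick_config(seed = 8))
  s_uni <- coefficient_summary(uni, "perfusion")
  expect_true(s_uni$associated)
  expect_equal(s_uni$median_beta, 1, tolerance = 0.2)

  multi <- fit_amputation_model(coh, "any", config = quick_config(seed = 9))
  s_multi <- coefficient_summary(multi, "perfusion")
  expect_lt(abs(s_uni$median_beta - s_multi$median_beta), 0.1)
})

test_that("null univariate effects are covered by the HDI in most replicates", {
  beta <- setNames(rep(0, 7), c("perfusion", "extent", "depth", "infection",
                                "sensation", "age_z", "gender"))
  covered <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(generator_config(n = 800, seed = 600 + r,
                                            true_beta = beta,
                                            target_prevalence = 0.3,
                                            loss_prob = 0))
    uni <- fit_univariate(coh, "depth", "any",
                          config = quick_config(seed = 700 + r,
                                                n_chains = 2, n_steps = 1200))
    s <- coefficient_summary(uni, "depth")
    covered <- covered + !s$associated
  }
  expect_gte(covered, round(0.9 * n_rep) - 1L)
})

test_that("chains are exchangeable: reseeding shifts draws, not summaries", {
  coh <- small_cohort(n = 400, seed = 61, loss_prob = 0)
  f1 <- fit_amputation_model(coh, "any", config = quick_config(seed = 100))
  f2 <- fit_amputation_model(coh, "any", config = quick_config(seed = 200))
  expect_false(identical(f1$draws, f2$draws))
  m1 <- apply(f1$draws, 2, median)
  m2 <- apply(f2$draws, 2, median)
  mcse <- apply(f1$draws, 2, sd) / sqrt(effective_sample_size(f1))
  expect_true(all(abs(m1 - m2) < 6 * mcse))
})

test_that("draws round-trip through CSV with their coding metadata", {
  coh <- small_cohort(n = 120, seed = 71)
  fit <- suppressWarnings(
    fit_amputation_model(coh, "any",
                         config = quick_config(seed = 2, n_chains = 2,
                                               n_steps = 500, burn_in = 100)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_identical(back$chain_id, fit$chain_id)
  expect_equal(back$age_center, fit$age_center, tolerance = 1e-12)
  expect_identical(back$outcome, fit$outcome)
})

test_that("retention subsampling honours the requested draw count", {
  coh <- small_cohort(n = 120, seed = 81)
  fit <- suppressWarnings(fit_amputation_model(
    coh, "any", config = chain_config(n_chains = 4, n_steps = 800,
                                      burn_in = 300, seed = 3, retain = 1000)))
  expect_equal(nrow(fit$draws), 1000)
  expect_equal(length(fit$chain_id), 1000)
})
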