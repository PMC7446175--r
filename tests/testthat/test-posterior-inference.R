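test_that("hdi finds the narrowest window, with the stated edge behaviour", {
  expect_equal(unlist(hdi(c(1, 2, 3, 4, 100), 0.8)[c("lower", "upper")]),
               c(lower = 1, upper = 4))
  expect_equal(unlist(hdi(c(1, 2, 3, 4, 100), 0.95)[c("lower", "upper")]),
               c(lower = 1, upper = 100))
  cst <- hdi(rep(2.5, 10))
  expect_equal(c(cst$lower, cst$upper), c(2.5, 2.5))
  expect_error(hdi(c(1, NA, 3)), "NA")
  expect_error(hdi(1), "2 finite")
  expect_error(hdi(1:10, mass = 1.2), "mass")
})

test_that("hdi equals the exhaustive window-search oracle", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(5:400, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), round(rnorm(n), 1))  # include ties
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    got <- hdi(x, mass)
    want <- hdi_oracle(x, mass)
    expect_identical(c(got$lower, got$upper), want)
  }
})

test_that("null exclusion treats endpoints as covered", {
  iv <- function(lo, hi) structure(list(lower = lo, upper = hi, mass = 0.95),
                                   class = "hdi_interval")
  expect_true(null_exclusion(iv(0.264, 1.152)))
  expect_false(null_exclusion(iv(-0.483, 0.266)))
  expect_false(null_exclusion(iv(0, 1)))
  expect_true(null_exclusion(iv(-2, -1)))
})

test_that("tail probability is the strict below-threshold fraction", {
  expect_equal(tail_probability(c(-1, 1, 2, 3)), 0.25)
  expect_equal(tail_probability(c(1, 2, 3)), 0)
  set.seed(21)
  expect_lt(abs(tail_probability(rnorm(30000, 2, 1)) - pnorm(-2)), 0.003)
})

test_that("rank-based AUC handles ties and matches pairwise counting", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 8), rep(0:1, 4)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both outcome classes")

  set.seed(22)
  for (i in 1:40) {
    n <- sample(4:120, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(rnorm(n), 1)  # coarse grid forces ties
    expect_equal(auc(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("coefficient summaries exponentiate medians and endpoints", {
  set.seed(23)
  draws <- cbind(perfusion = rnorm(4000, 0.7, 0.2),
                 extent = rnorm(4000, 1.3, 0.4))
  fit <- fake_fit(draws)
  s <- coefficient_summary(fit, "perfusion")
  expect_equal(s$odds_ratio, exp(s$median_beta), tolerance = 1e-12)
  expect_equal(s$or_hdi$lower, exp(s$beta_hdi$lower), tolerance = 1e-12)
  expect_equal(s$or_hdi$upper, exp(s$beta_hdi$upper), tolerance = 1e-12)
  # brute-force recomputation with independent code
  x <- draws[, "perfusion"]
  expect_equal(s$median_beta, median(x), tolerance = 1e-12)
  expect_equal(c(s$beta_hdi$lower, s$beta_hdi$upper), hdi_oracle(x, 0.95))
  expect_equal(s$prob_below_null, mean(x < 0), tolerance = 1e-12)
  expect_error(coefficient_summary(fit, "nope"), "unknown coefficient")

  zero <- fake_fit(cbind(b = rep(0, 100)))
  s0 <- coefficient_summary(zero, "b")
  expect_equal(s0$odds_ratio, 1)
  expect_equal(c(s0$or_hdi$lower, s0$or_hdi$upper), c(1, 1))
  expect_false(s0$associated)

  tab <- summarize_fit(fit)
  expect_identical(tab$name, c("perfusion", "extent"))
  expect_true(all(tab$associated))
})

test_that("published summary table is internally consistent under exp()", {
  co <- dfu_reference_models()$coefficients
  tol <- function(or) 0.002 + 0.0005 * or
  expect_true(all(abs(exp(co$beta_median) - co$or_median) <= tol(co$or_median)))
  expect_true(all(abs(exp(co$beta_lo) - co$or_lo) <= tol(co$or_lo)))
  expect_true(all(abs(exp(co$beta_hi) - co$or_hi) <= tol(co$or_hi)))
})

test_that("posterior AUC collapses correctly for degenerate draws", {
  coh <- small_cohort(n = 150, seed = 24, loss_prob = 0)
  nm <- c("intercept", "perfusion", "extent", "depth", "infection",
          "sensation", "age_z", "gender")

  zero <- matrix(0, 50, 8, dimnames = list(NULL, nm))
  ap0 <- posterior_auc(fake_fit(zero), coh)
  expect_true(all(ap0$auc_draws == 0.5))

  one_vec <- matrix(rep(c(-1, 0.7, 1.3, 0.6, 0, 0.5, 0.2, 0.1), each = 50),
                    50, 8, dimnames = list(NULL, nm))
  ap1 <- posterior_auc(fake_fit(one_vec), coh)
  expect_equal(ap1$hdi$upper - ap1$hdi$lower, 0)
  expect_equal(length(unique(ap1$auc_draws)), 1L)

  # thinning evaluates every k-th draw
  ap_thin <- posterior_auc(fake_fit(one_vec), coh, thin = 10)
  expect_equal(length(ap_thin$auc_draws), 5L)
  expect_equal(ap_thin$median, ap1$median, tolerance = 1e-12)
})

test_that("posterior AUC approximates the true-process AUC on simulation", {
  cfg <- generator_config(n = 2000, seed = 25, loss_prob = 0)
  coh <- generate_cohort(cfg)
  el <- fit_eligible(coh)
  truth_eta <- drop(dfurisk:::code_predictors(el) %*% cfg$true_beta)
  truth_auc <- auc(truth_eta, el$outcome_any)

  fit <- fit_amputation_model(coh, "any", config = quick_config(seed = 26))
  ap <- posterior_auc(fit, coh, thin = 10)
  expect_equal(ap$median, truth_auc, tolerance = 0.03)
})

test_that("model comparison follows the pooled-SD convention", {
  set.seed(27)
  a <- rnorm(1000)
  a <- (a - mean(a)) / sd(a) * 0.1 + 0.7  # sd exactly 0.1
  b <- a + 0.1
  ap_a <- structure(list(auc_draws = a, median = median(a), hdi = hdi(a)),
                    class = "auc_posterior")
  ap_b <- structure(list(auc_draws = b, median = median(b), hdi = hdi(b)),
                    class = "auc_posterior")
  cmp <- compare_models(ap_a, ap_b)
  expect_equal(cmp$delta_auc, 0.1, tolerance = 1e-10)
  expect_equal(cmp$cohens_d, 1.0, tolerance = 1e-10)

  # antisymmetry and the identical-input degenerate case
  rev <- compare_models(ap_b, ap_a)
  expect_equal(rev$delta_auc, -cmp$delta_auc, tolerance = 1e-12)
  expect_equal(rev$cohens_d, -cmp$cohens_d, tolerance = 1e-12)
  self <- compare_models(ap_a, ap_a)
  expect_equal(c(self$delta_auc, self$cohens_d), c(0, 0))

  const <- structure(list(auc_draws = rep(0.8, 100), median = 0.8,
                          hdi = NULL), class = "auc_posterior")
  expect_true(is.na(compare_models(const, const)$cohens_d))
})

test_that("risk prediction pushes draws through the inverse logit", {
  one <- fake_fit(matrix(c(-log(3), log(3)), 2, 1,
                         dimnames = list(NULL, "intercept")),
                  chain_id = c(1, 2))
  pr <- predict_risk(one, list())
  expect_equal(sort(pr$risk_draws), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(pr$median_risk, 0.5, tolerance = 1e-12)

  nm <- c("intercept", "perfusion", "extent", "depth", "infection",
          "sensation", "age_z", "gender")
  zero <- fake_fit(matrix(0, 10, 8, dimnames = list(NULL, nm)))
  prof <- list(perfusion = 2, extent = 2, depth = 1, infection = 1,
               sensation = 1, age = 66, gender = "male")
  pr0 <- predict_risk(zero, prof)
  expect_equal(pr0$median_risk, 0.5)
  expect_equal(pr0$hdi$upper - pr0$hdi$lower, 0)

  expect_error(predict_risk(zero, prof[-6]), "age")
  expect_error(predict_risk(zero, modifyList(prof, list(gender = NULL))),
               "gender")
  expect_error(predict_risk(zero, modifyList(prof, list(depth = 9))), "depth")
})

test_that("a severe profile dominates a moderate one under a positive fit", {
  coh <- small_cohort(n = 500, seed = 28, loss_prob = 0)
  fit <- fit_amputation_model(coh, "any",
                              config = quick_config(seed = 29, n_chains = 2))
  moderate <- list(perfusion = 2, extent = 2, depth = 1, infection = 1,
                   sensation = 1, age = 66, gender = "male")
  severe <- modifyList(moderate, list(perfusion = 3, extent = 3, depth = 3))
  pr_mod <- predict_risk(fit, moderate)
  pr_sev <- predict_risk(fit, severe)
  expect_gt(pr_sev$median_risk, pr_mod$median_risk)
  # stochastic dominance across draws
  expect_gt(mean(pr_sev$risk_draws > pr_mod$risk_draws), 0.95)
})
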