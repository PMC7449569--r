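test_that("difference in means matches the Neyman formulas", {
  d <- data.frame(Y = c(2, 4, 1, 3), Z = c(1, 1, 0, 0))
  row <- difference_in_means(d, "Y", "Z")
  expect_equal(row$estimate, 1)
  expect_equal(row$std_error, sqrt(2))

  exact <- difference_in_means(data.frame(Y = c(3, 3, 1, 1),
                                          Z = c(1, 1, 0, 0)), "Y", "Z")
  expect_equal(exact$estimate, 2)
  expect_equal(exact$std_error, 0)

  same <- difference_in_means(data.frame(Y = c(1, 2, 1, 2),
                                         Z = c(1, 1, 0, 0)), "Y", "Z")
  expect_equal(same$estimate, 0)

  # single-unit arm: estimate returned, uncertainty unavailable
  tiny <- difference_in_means(data.frame(Y = c(5, 1, 2), Z = c(1, 0, 0)),
                              "Y", "Z")
  expect_equal(tiny$estimate, 3.5)
  expect_true(is.na(tiny$std_error))
  expect_error(difference_in_means(data.frame(Y = 1, Z = 1), "Y", "Z"),
               "empty")
})

test_that("difference in means is the OLS coefficient on the treatment", {
  set.seed(8)
  d <- data.frame(Z = rbern(40, 0.5), u = rnorm(40))
  d$Y <- 0.7 * d$Z + d$u
  dim_row <- difference_in_means(d, "Y", "Z")
  ols_row <- ols_estimate(d, Y ~ Z, target = "Z")
  expect_equal(dim_row$estimate, ols_row$estimate, tolerance = 1e-10)
})

test_that("weighted least squares honours weights and records failures", {
  set.seed(9)
  d <- data.frame(x = rnorm(30), w = runif(30, 0.5, 2))
  d$y <- 1 + 2 * d$x + rnorm(30)
  unweighted <- ols_estimate(d, y ~ x, target = "x")
  all_ones <- ols_estimate(d, y ~ x, target = "x", weights = rep(1, 30))
  expect_equal(unweighted$estimate, all_ones$estimate, tolerance = 1e-12)
  expect_equal(unweighted$std_error, all_ones$std_error, tolerance = 1e-12)
  # rank deficiency is an estimator failure, not a crash of the run
  d$x2 <- d$x
  expect_error(ols_estimate(d, y ~ x + x2, target = "x2"), "not estimable")
})

test_that("inverse-probability weights follow the Horvitz-Thompson form", {
  expect_equal(ipw_weights(c(1, 0), c(0.5, 0.5)), c(2, 2))
  expect_equal(ipw_weights(1, 0.25), 4)
  expect_equal(ipw_weights(0, 0.25), 1 / 0.75)
  expect_error(ipw_weights(1, 1), "strictly inside")
})

test_that("beta-binomial prior moment matching reproduces the printed priors", {
  flat <- beta_binomial_posterior(0, 0, 0.5, 0.29)
  expect_lt(abs(flat$prior_a - 1), 0.05)       # ~ Beta(1, 1), the flat prior
  expect_equal(flat$estimate, 0.5)             # zero trials: posterior = prior
  expect_equal(flat$posterior_sd, 0.29, tolerance = 1e-12)

  tight <- beta_binomial_posterior(0, 0, 0.5, 0.11)
  expect_equal(tight$prior_a, 9.8, tolerance = 0.05)
  expect_equal(tight$prior_a, tight$prior_b, tolerance = 1e-9)

  post <- beta_binomial_posterior(7, 10, 0.5, 0.29)
  # posterior mean strictly between prior mean and sample proportion
  expect_gt(post$estimate, 0.5)
  expect_lt(post$estimate, 0.7)
  expect_true(post$ci_low <= post$estimate && post$estimate <= post$ci_high)
  expect_error(beta_binomial_posterior(1, 2, 0.5, 0.6), "valid Beta")
})

test_that("informative priors give tighter but potentially more biased answers", {
  set.seed(14)
  true_p <- 0.85   # far from the prior mean of 0.5
  n <- 20
  runs <- t(vapply(seq_len(500), function(i) {
    k <- rbinom(1, n, true_p)
    c(flat = beta_binomial_posterior(k, n, 0.5, 0.29)$estimate,
      flat_sd = beta_binomial_posterior(k, n, 0.5, 0.29)$posterior_sd,
      tight = beta_binomial_posterior(k, n, 0.5, 0.11)$estimate,
      tight_sd = beta_binomial_posterior(k, n, 0.5, 0.11)$posterior_sd)
  }, numeric(4)))
  expect_lt(mean(runs[, "tight_sd"]), mean(runs[, "flat_sd"]))
  expect_gt(abs(mean(runs[, "tight"]) - true_p),
            abs(mean(runs[, "flat"]) - true_p))
})

test_that("nearest-neighbor matching agrees with brute-force search", {
  set.seed(21)
  n <- 50
  d <- data.frame(X1 = rnorm(n), X2 = rnorm(n), Z = rbern(n, 0.4))
  if (sum(d$Z) == 0) d$Z[1] <- 1
  d$Y <- d$X1 + 2 * d$X2 + 0.5 * d$Z + rnorm(n)
  covs <- c("X1", "X2")
  row <- matching_att(d, "Y", "Z", covs)
  # brute-force oracle with the same Mahalanobis metric
  S_inv <- solve(cov(d[covs]))
  tr <- which(d$Z == 1); co <- which(d$Z == 0)
  att_oracle <- mean(vapply(tr, function(i) {
    d2 <- vapply(co, function(j) {
      v <- as.numeric(d[i, covs] - d[j, covs])
      drop(t(v) %*% S_inv %*% v)
    }, numeric(1))
    d$Y[i] - d$Y[co[which.min(d2)]]
  }, numeric(1)))
  expect_equal(row$estimate, att_oracle, tolerance = 1e-12)

  # exact twins: ATT is the mean within-pair difference
  # collinear covariates: singular covariance falls back to Euclidean, which
  # still pairs each treated unit with its exact twin
  twins <- data.frame(X1 = c(1, 2, 1, 2), X2 = c(0, 1, 0, 1),
                      Z = c(1, 1, 0, 0), Y = c(5, 7, 3, 4))
  expect_warning(att_twins <- matching_att(twins, "Y", "Z", c("X1", "X2")),
                 "Euclidean")
  expect_equal(att_twins$estimate, mean(c(5 - 3, 7 - 4)))
  # one treated, one control: their difference
  pair <- data.frame(X1 = c(0, 1), Z = c(1, 0), Y = c(4, 1))
  expect_equal(matching_att(pair, "Y", "Z", "X1")$estimate, 3)
  # zero-variance covariate triggers the Euclidean fallback
  flat <- data.frame(X1 = c(1, 1, 1, 1), X2 = c(0, 1, 0.1, 2),
                     Z = c(1, 1, 0, 0), Y = c(4, 6, 1, 2))
  expect_warning(fb <- matching_att(flat, "Y", "Z", c("X1", "X2")),
                 "Euclidean")
  # both treated units sit closest to the first control (X2 = 0.1)
  expect_equal(fb$estimate, mean(c(4 - 1, 6 - 1)))
})

test_that("split-sample discovery controls the stage-one false-discovery rate", {
  set.seed(33)
  n <- 200
  alpha <- 0.05
  res <- t(vapply(seq_len(300), function(i) {
    d <- data.frame(Z = rbern(n, 0.5), M1 = rbern(n, 0.5))
    d$Y <- 0.2 * d$Z + rnorm(n)   # no true heterogeneity
    rows <- split_sample_answer(d, "Y", "Z", "M1", 0.5, alpha)
    c(disc = rows$discovered[rows$estimator_label == "principled"],
      produced = rows$result_produced[rows$estimator_label == "principled"])
  }, numeric(2)))
  disc_rate <- mean(res[, "disc"])
  se <- sqrt(alpha * (1 - alpha) / 300)
  expect_lt(abs(disc_rate - alpha), 4 * se)
  # a produced result additionally needs holdout significance
  expect_lte(mean(res[, "produced"]), disc_rate)
  expect_error(split_sample_answer(data.frame(Y = 1, Z = 1), "Y", "Z",
                                   character(0)), "moderators")
})

test_that("the balance statistic matches its definition", {
  d <- data.frame(Z = c(1, 1, 0, 0), X = c(1.5, 0.5, 0.5, -0.5))
  # means 1 vs 0 over the pooled within-arm sd sqrt((0.5 + 0.5) / 2)
  expect_equal(balance_statistic(d, "X", "Z"), 1 / sqrt(0.5))
  # arm means 1 vs 0 with pooled sd 1 give exactly 1
  d2 <- data.frame(Z = rep(c(1, 0), each = 4),
                   X = c(1 + c(-1, 1, -1, 1) * sqrt(3) / 2,
                         0 + c(-1, 1, -1, 1) * sqrt(3) / 2))
  expect_equal(balance_statistic(d2, "X", "Z"), 1)
  same <- data.frame(Z = c(1, 0), X = c(1, 1))
  expect_warning(v <- balance_statistic(same, "X", "Z"), "zero variance")
  expect_true(is.nan(v))
})
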