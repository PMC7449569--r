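fixture_sims <- function(estimate, estimand = 1, p_value = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_) {
  n <- length(estimate)
  data.frame(design = "fix", sim = seq_len(n), estimator_label = "E",
             estimand_label = "I", estimand = rep_len(estimand, n),
             estimate = estimate, std_error = NA_real_,
             p_value = rep_len(p_value, n), ci_low = rep_len(ci_low, n),
             ci_high = rep_len(ci_high, n), df = NA_real_)
}

test_that("point diagnosands match their definitions on fixtures", {
  s <- fixture_sims(c(1.2, 0.8))
  expect_equal(as.numeric(bias(s)), 0)
  expect_equal(as.numeric(rmse(s)), 0.2)
  expect_equal(as.numeric(bias(fixture_sims(c(1, 1)))), 0)
  expect_equal(as.numeric(rmse(fixture_sims(c(1, 1)))), 0)

  p <- fixture_sims(c(1, 1, 1), p_value = c(0.01, 0.20, 0.04))
  expect_equal(as.numeric(power(p)), 2 / 3)
  expect_equal(as.numeric(power(fixture_sims(1, p_value = 1))), 0)

  cv <- fixture_sims(c(1, 2.5), ci_low = c(0, 2), ci_high = c(2, 3))
  expect_equal(as.numeric(coverage(cv)), 0.5)

  expect_equal(sd_estimates(fixture_sims(c(2, 2, 2))), 0)
  expect_equal(sd_estimands(fixture_sims(c(1, 2), estimand = c(1, 1))), 0)
})

test_that("significance-conditioned diagnosands count their undefined runs", {
  s <- fixture_sims(c(2, -1), p_value = c(0.01, 0.01))
  expect_equal(as.numeric(type_s_rate(s)), 0.5)
  expect_equal(as.numeric(exaggeration_ratio(s)), 1.5)

  none <- fixture_sims(c(2, -1), p_value = c(0.5, 0.9))
  ts <- type_s_rate(none)
  expect_true(is.nan(as.numeric(ts)))
  expect_equal(attr(ts, "n_undefined"), 2)

  # a significant run with a zero estimand is undefined for the ratio
  zero <- fixture_sims(c(2, 3), estimand = c(0, 1), p_value = 0.01)
  ex <- exaggeration_ratio(zero)
  expect_equal(as.numeric(ex), 3)
  expect_equal(attr(ex, "n_undefined"), 1)
})

test_that("the error decomposition identity holds on every simulation table", {
  set.seed(44)
  for (i in 1:5) {
    est <- rnorm(50, mean = runif(1), sd = runif(1, 0.1, 2))
    s <- fixture_sims(est, estimand = runif(1))
    m <- nrow(s)
    lhs <- as.numeric(rmse(s))^2
    rhs <- as.numeric(bias(s))^2 + sd_estimates(s)^2 * (m - 1) / m
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # probability-type diagnosands stay in [0, 1]; power is monotone in alpha
  s <- fixture_sims(rnorm(40), p_value = runif(40),
                    ci_low = rnorm(40, -2), ci_high = rnorm(40, 2))
  for (v in c(power(s), coverage(s), type_s_rate(s))) {
    v <- as.numeric(v)
    if (!is.nan(v)) expect_true(v >= 0 && v <= 1)
  }
  expect_lte(as.numeric(power(s, alpha = 0.01)),
             as.numeric(power(s, alpha = 0.05)))
})

test_that("robustness is joint rejection across the test set", {
  two <- rbind(
    transform(fixture_sims(1, p_value = c(0.01)), estimator_label = "A"),
    transform(fixture_sims(1, p_value = c(0.20)), estimator_label = "B"))
  expect_equal(as.numeric(robustness(two, c("A", "B"))), 0)
  expect_equal(as.numeric(robustness(two, "A")), as.numeric(power(two[1, ])))
  expect_error(robustness(two, "C"), "unknown estimator")

  # two independent tests with power ~0.5 each reject jointly ~25%
  set.seed(55)
  m <- 2000
  pa <- runif(m) * ifelse(rbern(m, 0.5), 0.04, 1)
  pb <- runif(m) * ifelse(rbern(m, 0.5), 0.04, 1)
  joint <- rbind(
    data.frame(design = "x", sim = 1:m, estimator_label = "A",
               estimand_label = "I", estimand = 1, estimate = 1,
               std_error = NA, p_value = pa, ci_low = NA, ci_high = NA,
               df = NA),
    data.frame(design = "x", sim = 1:m, estimator_label = "B",
               estimand_label = "I", estimand = 1, estimate = 1,
               std_error = NA, p_value = pb, ci_low = NA, ci_high = NA,
               df = NA))
  p_a <- as.numeric(power(joint[joint$estimator_label == "A", ]))
  p_b <- as.numeric(power(joint[joint$estimator_label == "B", ]))
  expect_equal(as.numeric(robustness(joint, c("A", "B"))), p_a * p_b,
               tolerance = 0.05)
})

test_that("decision-based and posterior diagnosands follow their conventions", {
  s <- fixture_sims(c(0.5, 1, 2), estimand = 1)
  rule <- function(e) e > 0
  benefit <- function(a) a
  expect_equal(as.numeric(value_for_money(s, rule, benefit)), 1)
  # zero benefit counts as correct by convention
  s0 <- fixture_sims(1, estimand = 0)
  expect_equal(as.numeric(value_for_money(s0, rule, benefit)), 1)
  # thresholded rule recomputed by hand on a 10-row fixture
  est <- c(-2, -1, -0.5, 0, 0.2, 0.4, 0.6, 1, 1.5, 3)
  sh <- fixture_sims(est, estimand = 1)
  rule_c <- function(e) e > 0.5
  expect_equal(as.numeric(value_for_money(sh, rule_c, benefit)),
               mean(est > 0.5))

  post <- fixture_sims(c(0.5, 0.5), estimand = 0.5)
  post$posterior_sd <- c(0.29, 0.29)
  post$prior_mean <- 0.5
  post$prior_sd <- 0.29
  ps <- posterior_shift(post)
  expect_equal(unname(ps["location_shift"]), 0)   # no data: posterior = prior
  expect_equal(unname(ps["scale_ratio"]), 1)
  post$prior_sd <- 0
  expect_error(posterior_shift(post), "degenerate")
})

test_that("sampling bias contrasts population- and sample-level estimands", {
  # heterogeneous effects, random sampling: mean(PATE - SATE) centered on 0
  d <- compose_design(list(
    declare_population(N = 60, tau = ~ rnorm(N, 0.5, 1), u = ~ rnorm(N)),
    declare_potential_outcomes("Y", ~ tau * Z + u, conditions = list(Z = c(0, 1))),
    declare_inquiry("PATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
    declare_sampling(n = 20),
    declare_inquiry("SATE", expr = ~ mean(Y_Z_1 - Y_Z_0))
  ), name = "two_level")
  diag <- diagnose_design(d, "sampling_bias", m = 500, n_bootstrap = 100,
                          seed = 77,
                          options = list(population_label = "PATE",
                                         sample_label = "SATE"))
  expect_lt(abs(diag$estimate), 3 * diag$bootstrap_se)
  # homogeneous effects: PATE == SATE identically
  dh <- compose_design(list(
    declare_population(N = 60, u = ~ rnorm(N)),
    declare_potential_outcomes("Y", ~ 0.5 * Z + u, conditions = list(Z = c(0, 1))),
    declare_inquiry("PATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
    declare_sampling(n = 20),
    declare_inquiry("SATE", expr = ~ mean(Y_Z_1 - Y_Z_0))
  ), name = "homog")
  sims <- simulate_design(dh, 20, seed = 1)
  expect_equal(sampling_bias(sims, "PATE", "SATE"), 0)
  expect_equal(sd_estimands(sims[sims$estimand_label == "PATE", ]), 0)
  expect_error(sampling_bias(sims, "PATE", "missing"), "not found")
})

test_that("imbalance under complete randomization matches enumeration at n = 8", {
  # fixed covariate values; average absolute standardized mean difference
  # over all C(8,4) assignments versus the Monte Carlo design estimate
  x <- c(-1.2, -0.6, -0.2, 0.1, 0.3, 0.7, 1.1, 1.6)
  combos <- utils::combn(8, 4, simplify = FALSE)
  exact <- mean(vapply(combos, function(tr) {
    z <- as.integer(seq_len(8) %in% tr)
    balance_statistic(data.frame(X = x, Z = z), "X", "Z")
  }, numeric(1)))
  d <- compose_design(list(
    declare_population(N = 8, X = x),
    declare_inquiry("null", expr = ~ 0 * mean(X)),
    declare_assignment("complete", m = 4),
    declare_estimator("balance", function(data)
      data.frame(estimate = balance_statistic(data, "X", "Z")),
      inquiry = "null")
  ), name = "balance_design")
  diag <- diagnose_design(d, "imbalance", m = 2000, n_bootstrap = 100, seed = 13)
  expect_lt(abs(diag$estimate - exact), 3 * diag$bootstrap_se)
  # identical arms have zero imbalance
  ident <- data.frame(X = c(1, 2, 1, 2), Z = c(1, 1, 0, 0))
  expect_equal(balance_statistic(ident, "X", "Z"), 0)
})
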