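test_that("design composition validates its steps", {
  steps <- make_design("table3_canonical")$steps
  d <- compose_design(steps, name = "canonical")
  expect_s3_class(d, "dd_design")
  expect_equal(vapply(d$steps, `[[`, character(1), "stage"),
               c("population", "potential_outcomes", "inquiry", "sampling",
                 "assignment", "reveal", "estimator"))
  expect_error(compose_design(list()), "at least one step")
  expect_error(compose_design(c(steps, steps[1])), "duplicate step labels")
  # degenerate single-step designs compose (and simply yield no estimates)
  single <- compose_design(declare_population(N = 5, u = ~ rnorm(N)))
  expect_s3_class(single, "dd_design")
  # steps chain with `+`
  chained <- steps[[1]] + steps[[2]] + steps[[3]]
  expect_equal(length(chained$steps), 3)
})

test_that("a single run computes the estimand before the data strategy", {
  d <- make_design("table3_canonical")
  r <- run_once(d, seed = 7)
  # unit treatment effect: the estimand is identically 1
  expect_equal(r$estimands$estimand, 1)
  expect_equal(nrow(r$estimates), 1)
  expect_equal(r$estimates$estimator_label, "DIM")
  expect_true(r$estimates$ci_low <= r$estimates$estimate)
  expect_true(r$estimates$estimate <= r$estimates$ci_high)
  expect_true(r$estimates$p_value >= 0 && r$estimates$p_value <= 1)

  # determinism: same seed, same result
  expect_identical(run_once(d, seed = 7), r)

  # deleting the data-strategy steps never changes the estimand
  stages <- vapply(d$steps, `[[`, character(1), "stage")
  no_data_strategy <- compose_design(
    d$steps[!stages %in% c("sampling", "assignment", "reveal", "estimator")],
    name = "model_only")
  r2 <- run_once(no_data_strategy, seed = 7)
  expect_equal(r2$estimands$estimand, r$estimands$estimand)
  expect_equal(nrow(r2$estimates), 0)
})

test_that("run errors name the offending column and estimator failures are recorded", {
  bad_inquiry <- compose_design(list(
    declare_population(N = 10, u = ~ rnorm(N)),
    declare_inquiry("broken", expr = ~ mean(nonexistent_column))),
    name = "bad")
  expect_error(run_once(bad_inquiry, 1), "nonexistent_column")

  failing <- compose_design(list(
    declare_population(N = 10, u = ~ rnorm(N), x = ~ u),
    declare_inquiry("mean_u", expr = ~ mean(u)),
    declare_estimator_ols("collinear", u ~ x + I(x * 1), target = "I(x * 1)")),
    name = "failing")
  r <- run_once(failing, 1)
  expect_true(is.na(r$estimates$estimate))
  expect_match(r$estimates$failed, "not estimable")
})

test_that("simulation tables stack m runs with reproducible substreams", {
  d <- make_design("table3_canonical")
  s <- simulate_design(d, 3, seed = 5)
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$estimand), 1)
  expect_error(simulate_design(d, 0, seed = 1), "positive count")

  # byte-identical reruns
  expect_identical(simulate_design(d, 3, seed = 5), s)
  # run 2 of m = 3 equals run 2 of m = 2: substreams are counter-derived
  s2 <- simulate_design(d, 2, seed = 5)
  expect_equal(s$estimate[2], s2$estimate[2])

  # inquiry-only designs produce estimand rows with empty estimate fields
  stages <- vapply(d$steps, `[[`, character(1), "stage")
  no_est <- compose_design(d$steps[stages != "estimator"], name = "no_est")
  s3 <- simulate_design(no_est, 2, seed = 1)
  expect_true(all(is.na(s3$estimate)))
  expect_equal(s3$estimand, c(1, 1))
})

test_that("the Monte Carlo mean matches exhaustive assignment enumeration", {
  # N = 6, 3 treated: 20 possible assignments; freeze one population and
  # compare the simulated expectation of the estimate with the exact mean
  set.seed(123)
  u <- rnorm(6)
  y0 <- u
  y1 <- u + 1
  exact <- enumerate_dim_expectation(y1, y0, 3)
  d <- compose_design(list(
    declare_population(N = 6, u = u),
    declare_potential_outcomes("Y", ~ Z + u, conditions = list(Z = c(0, 1))),
    declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
    declare_assignment("complete", m = 3),
    declare_reveal("Y", "Z"),
    declare_estimator_dim("DIM", "Y", "Z", inquiry = "ATE")
  ), name = "fixed_pop")
  s <- simulate_design(d, 4000, seed = 9)
  mc_se <- sd(s$estimate) / sqrt(nrow(s))
  expect_lt(abs(mean(s$estimate) - exact), 3 * mc_se)
  # with constant effects the estimator is unbiased for the ATE of 1
  expect_equal(exact, 1, tolerance = 1e-12)
})

test_that("diagnosis reports bootstrap uncertainty from whole-run resampling", {
  d <- make_design("table3_canonical")
  diag <- diagnose_design(d, c("bias", "power", "sd_estimands"), m = 60,
                          n_bootstrap = 80, seed = 3)
  expect_setequal(diag$diagnosand, c("bias", "power", "sd_estimands"))
  expect_true(all(diag$n_sims == 60))
  expect_identical(
    diagnose_design(d, c("bias", "power", "sd_estimands"), m = 60,
                    n_bootstrap = 80, seed = 3), diag)
  # constant diagnostic statistic: zero bootstrap SE
  expect_equal(diag$bootstrap_se[diag$diagnosand == "sd_estimands"], 0)
  # no bootstrap: SE unavailable, estimates still reported
  diag0 <- diagnose_design(d, "bias", m = 20, n_bootstrap = 0, seed = 3)
  expect_true(is.na(diag0$bootstrap_se))
  expect_true(is.finite(diag0$estimate))
  # diagnosands that need an estimand fail on designs without one
  stages <- vapply(d$steps, `[[`, character(1), "stage")
  no_inq <- compose_design(d$steps[stages != "inquiry"], name = "no_inq")
  expect_error(diagnose_design(no_inq, "bias", m = 5, n_bootstrap = 0, seed = 1),
               "estimand")
})

test_that("bootstrap standard errors shrink like one over root m", {
  d <- make_design("table3_canonical")
  ratios <- vapply(1:10, function(i) {
    se_small <- diagnose_design(d, "bias", m = 100, n_bootstrap = 60,
                                seed = 100 + i)$bootstrap_se
    se_big <- diagnose_design(d, "bias", m = 400, n_bootstrap = 60,
                              seed = 200 + i)$bootstrap_se
    se_small / se_big
  }, numeric(1))
  expect_gt(mean(ratios), 1.6)
  expect_lt(mean(ratios), 2.5)
})

test_that("design comparison across rival models yields the documented verdicts", {
  # constant vs heterogeneous block effects; BFE vs IPW-BFE answers
  base <- function(estimator) {
    sz <- c(60, 20)
    make_blocked <- compose_design(c(list(
      declare_population(N = 80, block = rep(1:2, sz), u = ~ rnorm(N),
                         tau = rep(c(0.5, 0.5), sz)),
      declare_potential_outcomes("Y", ~ tau * Z + u,
                                 conditions = list(Z = c(0, 1))),
      declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
      declare_assignment("blocked", block_var = "block",
                         block_probs = c(0.2, 0.5)),
      declare_reveal("Y", "Z")),
      list(estimator)), name = paste0("blocked_", estimator$label))
  }
  bfe <- base(declare_estimator_ols("BFE", Y ~ Z + factor(block), target = "Z",
                                    inquiry = "ATE"))
  ipw <- base(declare_estimator_ols(
    "BFE_IPW", Y ~ Z + factor(block), target = "Z", inquiry = "ATE",
    weights = function(d) ipw_weights(d$Z, d$Z_prob)))
  models <- list(
    constant = list(
      declare_population(N = 80, block = rep(1:2, c(60, 20)), u = ~ rnorm(N),
                         tau = 0.5),
      declare_potential_outcomes("Y", ~ tau * Z + u,
                                 conditions = list(Z = c(0, 1)))),
    heterogeneous = list(
      declare_population(N = 80, block = rep(1:2, c(60, 20)), u = ~ rnorm(N),
                         tau = rep(c(0.1, 1.7), c(60, 20))),
      declare_potential_outcomes("Y", ~ tau * Z + u,
                                 conditions = list(Z = c(0, 1)))))
  res <- compare_designs(list(BFE = bfe, BFE_IPW = ipw), models = models,
                         diagnosand = "bias", m = 600, seed = 12,
                         n_bootstrap = 60)
  expect_equal(nrow(res$table), 4)
  # the weighted answer ties under constant effects and wins under
  # heterogeneous effects: the robustness argument
  expect_equal(res$verdict, "robustness")

  # identical designs: all cells equal within error, no dominance verdict
  same <- compare_designs(list(a = bfe, b = bfe), models = models,
                          diagnosand = "bias", m = 300, seed = 12,
                          n_bootstrap = 50)
  expect_equal(same$verdict, "none")

  # one design: sensitivity table only
  sens <- compare_designs(list(only = bfe), models = models,
                          diagnosand = "bias", m = 50, seed = 12,
                          n_bootstrap = 20)
  expect_null(sens$verdict)
  expect_equal(nrow(sens$table), 2)
})
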