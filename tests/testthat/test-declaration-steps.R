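run_steps <- function(...) {
  # apply data-stage steps in order to an empty table
  data <- data.frame()
  for (s in list(...)) data <- s$handler(data)
  data
}

test_that("population generators run in order and support distribution specs", {
  set.seed(1)
  pop <- declare_population(N = 200, u = ~ rnorm(N), v = ~ u + 1)
  d <- run_steps(pop)
  expect_equal(nrow(d), 200)
  expect_equal(d$v, d$u + 1)
  expect_lt(abs(mean(d$u)), 3 / sqrt(200))

  one <- run_steps(declare_population(N = 1, x = ~ rnorm(N)))
  expect_equal(nrow(one), 1)

  ones <- run_steps(declare_population(
    N = 50, b = list(dist = "bernoulli", p = 1)))
  expect_true(all(ones$b == 1))

  expect_error(declare_population(N = 0), "positive count")
  expect_error(run_steps(declare_population(N = 10, a = ~ b + 1, b = ~ 1)),
               "b")
})

test_that("potential outcomes add one named column per condition", {
  set.seed(2)
  d <- run_steps(
    declare_population(N = 20, u = ~ rnorm(N)),
    declare_potential_outcomes("Y", ~ Z + u, conditions = list(Z = c(0, 1))))
  expect_equal(d$Y_Z_0, d$u)
  expect_equal(d$Y_Z_1, d$u + 1)

  fact <- run_steps(
    declare_population(N = 10, u = ~ rnorm(N)),
    declare_potential_outcomes("Y", ~ 0.1 * Z1 + 0.2 * Z2 + 0.05 * Z1 * Z2 + u,
                               conditions = list(Z1 = c(0, 1), Z2 = c(0, 1))))
  expect_true(all(c("Y_Z1_0_Z2_0", "Y_Z1_1_Z2_0", "Y_Z1_0_Z2_1",
                    "Y_Z1_1_Z2_1") %in% names(fact)))
  expect_equal(fact$Y_Z1_1_Z2_1 - fact$Y_Z1_0_Z2_0, rep(0.35, 10))

  const <- run_steps(
    declare_population(N = 5, u = ~ rnorm(N)),
    declare_potential_outcomes("W", ~ 2 + 0 * Z, conditions = list(Z = c(0, 1))))
  expect_equal(const$W_Z_0, const$W_Z_1)
})

test_that("sampling respects sizes and strata", {
  set.seed(3)
  pop <- declare_population(N = 200, g = rep(1:4, each = 50))
  d <- run_steps(pop, declare_sampling(n = 100))
  expect_equal(nrow(d), 100)
  expect_true(all(d$S == 1))

  strat <- run_steps(pop, declare_sampling(strata = "g", n_per_stratum = 10))
  expect_equal(as.vector(table(strat$g)), rep(10L, 4))

  all_rows <- run_steps(pop, declare_sampling(n = 200))
  expect_equal(nrow(all_rows), 200)
  expect_error(run_steps(pop, declare_sampling(n = 300)), "exceeds")
})

test_that("assignment allocates exact arm counts", {
  set.seed(4)
  pop <- declare_population(N = 100, u = ~ rnorm(N))
  d <- run_steps(pop, declare_assignment("complete", m = 50))
  expect_equal(sum(d$Z), 50)
  expect_equal(unique(d$Z_prob), 0.5)

  arms <- run_steps(declare_population(N = 99),
                    declare_assignment("multi_arm", var = "arm",
                                       arms = c("control", "T1", "T2"),
                                       probs = rep(1 / 3, 3)))
  expect_equal(as.vector(table(arms$arm)), rep(33L, 3))

  fact <- run_steps(pop, declare_assignment("factorial"))
  expect_equal(as.vector(table(fact$Z1, fact$Z2)), rep(25L, 4))

  blocked <- run_steps(
    declare_population(N = 120, block = rep(1:2, c(80, 40))),
    declare_assignment("blocked", block_var = "block",
                       block_probs = c(0.25, 0.5)))
  expect_equal(sum(blocked$Z[blocked$block == 1]), 20)
  expect_equal(sum(blocked$Z[blocked$block == 2]), 20)
  expect_equal(unique(blocked$Z_prob[blocked$block == 1]), 0.25)

  clustered <- run_steps(
    declare_population(N = 40, cl = rep(1:8, each = 5)),
    declare_assignment("clustered", cluster_var = "cl", m_clusters = 4))
  by_cl <- tapply(clustered$Z, clustered$cl, unique)
  expect_true(all(lengths(by_cl) == 1))   # whole clusters move together
  expect_equal(sum(unlist(by_cl)), 4)

  expect_error(run_steps(pop, declare_assignment("complete", m = 101)),
               "exceeds")
  expect_error(declare_assignment("complete", prob = 1.2), "\\[0, 1\\]")
})

test_that("blocked assignment respects the declared probabilities on average", {
  set.seed(5)
  steps <- list(
    declare_population(N = 60, block = rep(1:2, c(40, 20))),
    declare_assignment("blocked", block_var = "block",
                       block_probs = c(0.3, 0.7)))
  shares <- t(vapply(seq_len(500), function(i) {
    d <- run_steps(steps[[1]], steps[[2]])
    c(mean(d$Z[d$block == 1]), mean(d$Z[d$block == 2]))
  }, numeric(2)))
  # exact integer allocation: 12 of 40 and 14 of 20 every single run
  expect_lt(abs(mean(shares[, 1]) - 0.3), 3 * sd(shares[, 1]) / sqrt(500) + 1e-12)
  expect_lt(abs(mean(shares[, 2]) - 0.7), 3 * sd(shares[, 2]) / sqrt(500) + 1e-12)
})

test_that("measurement maps latent into observed columns without overwriting", {
  set.seed(6)
  pop <- declare_population(N = 400, y = list(dist = "bernoulli", p = 0.5))
  id <- run_steps(pop, declare_measurement("y", "binary_flip", rate = 0))
  expect_equal(id$y_obs, id$y)

  flip <- run_steps(pop, declare_measurement("y", "binary_flip", rate = 1))
  expect_equal(flip$y_obs, 1L - flip$y)

  # overreporting: latent rate p, non-voters overreport at rate r ->
  # expected observed rate p + (1 - p) * r
  over_rates <- vapply(seq_len(300), function(i) {
    d <- run_steps(
      declare_population(N = 200, v = list(dist = "bernoulli", p = 0.4)),
      declare_measurement("v", "overreport", rate = 0.3))
    mean(d$v_obs)
  }, numeric(1))
  expect_lt(abs(mean(over_rates) - 0.58), 3 * sd(over_rates) / sqrt(300))
  expect_error(declare_measurement("y", "binary_flip", rate = 1.5),
               "\\[0, 1\\]")
})

test_that("reveal deterministically selects the assigned potential outcome", {
  d <- data.frame(Z = c(1, 0), Y_Z_0 = c(0, 7), Y_Z_1 = c(5, 9))
  step <- declare_reveal("Y", "Z")
  expect_equal(step$handler(d)$Y, c(5, 7))
  # all units in one arm: realized outcome equals that arm's column
  d2 <- data.frame(Z = c(1, 1), Y_Z_0 = c(0, 7), Y_Z_1 = c(5, 9))
  expect_equal(step$handler(d2)$Y, d2$Y_Z_1)
  # permuting declaration order of the PO columns changes nothing
  expect_equal(step$handler(d[c("Y_Z_1", "Y_Z_0", "Z")])$Y, c(5, 7))
  expect_error(step$handler(data.frame(Z = 2, Y_Z_0 = 1, Y_Z_1 = 2)),
               "missing potential-outcome")
})

test_that("the canonical design realizes Y = Z + u row-wise", {
  d <- make_design("table3_canonical")
  set.seed(11)
  data <- data.frame()
  for (s in d$steps) if (!s$stage %in% c("inquiry", "estimator"))
    data <- s$handler(data)
  expect_equal(data$Y, data$Z + data$u)
})

test_that("linear projections recover slopes of nonlinear response surfaces", {
  grid <- seq(0, 1, length.out = 11)
  # quadratic response: projection slope equals cov(x, x^2)/var(x) = 1 on [0,1]
  beta_quad <- linear_projection_estimand(matrix(grid^2, 1), grid)[["beta"]]
  oracle <- stats::cov(grid, grid^2) / stats::var(grid)
  expect_equal(beta_quad, oracle, tolerance = 1e-10)
  expect_equal(linear_projection_estimand(matrix(2 * grid, 1), grid)[["beta"]], 2)
  expect_equal(linear_projection_estimand(matrix(5, 1, 11), grid)[["beta"]], 0)
  expect_error(linear_projection_estimand(matrix(1, 1, 3), rep(1, 3)),
               "degenerate")
})
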