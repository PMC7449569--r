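# Catalogue of parameterized designs. Each entry couples a parameter schema
# with a builder returning a dd_design; magnitudes that matter only as
# illustrations (noise scales, baseline rates) are exposed parameters with
# documented defaults.

catalog_entry <- function(description, params, builder) {
  list(description = description, params = params, builder = builder)
}

prm <- function(default, type = "numeric", choices = NULL, lower = NULL,
                upper = NULL) {
  list(default = default, type = type, choices = choices,
       lower = lower, upper = upper)
}

design_registry <- function() {
  list(
  table3_canonical = catalog_entry(
    "Two-arm experiment: N units with standard-normal noise, unit treatment effect, a simple random sample and complete assignment; difference-in-means answer.",
    list(N = prm(200, lower = 2), n = prm(100, lower = 2), m_treated = prm(50, lower = 1)),
    function(N = 200, n = 100, m_treated = 50) {
      compose_design(list(
        declare_population(N = N, u = ~ rnorm(N)),
        declare_potential_outcomes("Y", ~ Z + u, conditions = list(Z = c(0, 1))),
        declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
        declare_sampling(n = n),
        declare_assignment("complete", m = m_treated),
        declare_reveal("Y", "Z"),
        declare_estimator_dim("DIM", "Y", "Z", inquiry = "ATE")
      ), name = "table3_canonical",
      params = list(N = N, n = n, m_treated = m_treated))
    }),

  confounded_regression = catalog_entry(
    "Observational regression with a common cause: Y = b*X + Z + e_Y and X = Z + e_X; answers regress Y on X alone (omits the confounder) and on X and Z.",
    list(b = prm(0), n = prm(1000, lower = 10)),
    function(b = 0, n = 1000) {
      compose_design(list(
        declare_population(N = n, Z = ~ rnorm(N), e_X = ~ rnorm(N),
                           e_Y = ~ rnorm(N), X = ~ Z + e_X,
                           Y = ~ b * X + Z + e_Y),
        declare_inquiry("effect_of_X", expr = ~ b + 0 * mean(X)),
        declare_estimator_ols("OLS_X", Y ~ X, target = "X",
                              inquiry = "effect_of_X"),
        declare_estimator_ols("OLS_X_Z", Y ~ X + Z, target = "X",
                              inquiry = "effect_of_X")
      ), name = "confounded_regression", params = list(b = b, n = n))
    }),

  blocked_hetero = catalog_entry(
    "Blocked experiment with assignment probabilities heterogeneous by block and treatment effects correlated with block size; difference-in-means, block-fixed-effects, and inverse-probability-weighted block-fixed-effects answers.",
    list(block_sizes = prm(c(10, 14, 20, 28, 40, 56, 80, 112),
                           type = "numeric_vector"),
         block_probs = prm(seq(0.03, 0.97, length.out = 8),
                           type = "numeric_vector"),
         block_effects = prm(0.55 * (c(10, 14, 20, 28, 40, 56, 80, 112) / 112)^1.2,
                             type = "numeric_vector"),
         noise_sd = prm(1, lower = 0)),
    function(block_sizes = c(10, 14, 20, 28, 40, 56, 80, 112),
             block_probs = seq(0.03, 0.97, length.out = 8),
             block_effects = 0.55 * (c(10, 14, 20, 28, 40, 56, 80, 112) / 112)^1.2,
             noise_sd = 1) {
      K <- length(block_sizes)
      stopifnot(length(block_probs) == K, length(block_effects) == K)
      N <- sum(block_sizes)
      blocks <- rep(seq_len(K), block_sizes)
      taus <- block_effects[blocks]
      compose_design(list(
        declare_population(N = N, block = blocks, tau = taus,
                           u = ~ rnorm(N, sd = noise_sd)),
        declare_potential_outcomes("Y", ~ tau * Z + u,
                                   conditions = list(Z = c(0, 1))),
        declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
        declare_assignment("blocked", block_var = "block",
                           block_probs = block_probs),
        declare_reveal("Y", "Z"),
        declare_estimator_dim("DIM", "Y", "Z", inquiry = "ATE"),
        declare_estimator_ols("BFE", Y ~ Z + factor(block), target = "Z",
                              inquiry = "ATE"),
        declare_estimator_ols("BFE_IPW", Y ~ Z + factor(block), target = "Z",
                              inquiry = "ATE",
                              weights = function(d) ipw_weights(d$Z, d$Z_prob))
      ), name = "blocked_hetero",
      params = list(block_sizes = block_sizes, block_probs = block_probs,
                    block_effects = block_effects, noise_sd = noise_sd))
    }),

  factorial_vs_three_arm = catalog_entry(
    "Two treatments; the inquiry is the effect of treatment 1 with treatment 2 at control. The factorial variant crosses both treatments (each cell probability 1/4); the three-arm variant assigns control/T1/T2 with probability 1/3 each and omits the both-treated cell. The answer regresses the outcome on both indicators without an interaction.",
    list(interaction = prm(0, lower = -0.2, upper = 0.2),
         assignment = prm("factorial", type = "character",
                          choices = c("factorial", "three_arm")),
         N = prm(400, lower = 12), b1 = prm(0.3), b2 = prm(0.3),
         noise_sd = prm(1, lower = 0)),
    function(interaction = 0, assignment = "factorial", N = 400,
             b1 = 0.3, b2 = 0.3, noise_sd = 1) {
      po <- declare_potential_outcomes(
        "Y", ~ b1 * Z1 + b2 * Z2 + interaction * Z1 * Z2 + u,
        conditions = list(Z1 = c(0, 1), Z2 = c(0, 1)))
      steps <- list(
        declare_population(N = N, u = ~ rnorm(N, sd = noise_sd)),
        po,
        declare_inquiry("ATE1_Z2at0", expr = ~ mean(Y_Z1_1_Z2_0 - Y_Z1_0_Z2_0)),
        if (assignment == "factorial") {
          declare_assignment("factorial", vars = c("Z1", "Z2"))
        } else {
          declare_assignment("multi_arm", var = "arm",
                             arms = c("control", "Z1", "Z2"),
                             probs = rep(1 / 3, 3))
        },
        declare_reveal("Y", c("Z1", "Z2")),
        declare_estimator_ols("OLS_main", Y ~ Z1 + Z2, target = "Z1",
                              inquiry = "ATE1_Z2at0")
      )
      compose_design(steps, name = paste0("factorial_vs_three_arm_", assignment),
                     params = list(interaction = interaction,
                                   assignment = assignment, N = N,
                                   b1 = b1, b2 = b2, noise_sd = noise_sd))
    }),

  process_tracing = catalog_entry(
    "Single-case Bayesian process tracing: a case with both cause and outcome present is selected, the causal hypothesis holds with the prior probability, and one or two causal process observations (with likelihoods under each hypothesis, possibly correlated) are sought. The answer is the Bayesian posterior; the estimand the truth of the hypothesis.",
    list(prior = prm(0.5, lower = 0, upper = 1),
         p1_h = prm(0.75), p1_nh = prm(0.25),
         p2_h = prm(0.30), p2_nh = prm(0.05),
         rho = prm(0, lower = -1, upper = 1),
         strategy = prm("cpo1_only", type = "character",
                        choices = c("cpo1_only", "cpo2_only", "both"))),
    function(prior = 0.5, p1_h = 0.75, p1_nh = 0.25, p2_h = 0.30,
             p2_nh = 0.05, rho = 0, strategy = "cpo1_only") {
      table <- likelihood_table(c(p1_h, p2_h), c(p1_nh, p2_nh), rho = rho)
      draw_cpos <- new_step("draw_cpos", "measurement", function(data) {
        h <- data$H[1] == 1
        joint <- if (h) binary_joint(p1_h, p2_h, rho, warn = FALSE)
                 else binary_joint(p1_nh, p2_nh, rho, warn = FALSE)
        cell <- sample.int(4, 1, prob = joint)  # p11, p10, p01, p00
        data$E1 <- as.integer(cell %in% c(1L, 2L))
        data$E2 <- as.integer(cell %in% c(1L, 3L))
        data
      })
      answer <- declare_estimator("posterior", function(data) {
        observed <- switch(strategy,
          cpo1_only = c(data$E1[1] == 1, NA),
          cpo2_only = c(NA, data$E2[1] == 1),
          both = c(data$E1[1] == 1, data$E2[1] == 1))
        estimate_row(estimate = pt_posterior(prior, table, observed))
      }, inquiry = "H_true")
      compose_design(list(
        declare_population(N = 1, H = list(dist = "bernoulli", p = prior)),
        declare_inquiry("H_true", expr = ~ mean(H)),
        draw_cpos,
        answer
      ), name = "process_tracing",
      params = list(prior = prior, p1_h = p1_h, p1_nh = p1_nh, p2_h = p2_h,
                    p2_nh = p2_nh, rho = rho, strategy = strategy))
    }),

  qca_crisp = catalog_entry(
    "Crisp-set QCA: binary causes drawn uniformly, outcome generated by a sum-of-products expression, optional outcome measurement error; the answer builds the truth table and minimizes it (Quine-McCluskey) or runs the saturated-regression route, and is scored 1 when the recovered expression is semantically identical to the generating one.",
    list(truth = prm("aB", type = "character"),
         causes = prm(c("A", "B"), type = "character_vector"),
         n = prm(100, lower = 4), error_rate = prm(0, lower = 0, upper = 1),
         answer = prm("qmc", type = "character",
                      choices = c("qmc", "regression")),
         remainder_policy = prm("exclude", type = "character",
                                choices = c("exclude", "dont_care"))),
    function(truth = "aB", causes = c("A", "B"), n = 100, error_rate = 0,
             answer = "qmc", remainder_policy = "exclude") {
      truth_dnf <- if (inherits(truth, "dd_dnf")) truth
                   else parse_dnf(truth, causes)
      gens <- stats::setNames(
        rep(list(list(dist = "bernoulli", p = 0.5)), length(causes)), causes)
      pop <- do.call(declare_population, c(list(N = n), gens))
      outcome_step <- new_step("latent_outcome", "potential_outcomes",
        function(data) {
          data$Y <- eval_dnf(truth_dnf, data)
          data
        })
      answer_step <- declare_estimator("qca_answer", function(data) {
        found <- if (answer == "qmc") {
          tt <- build_truth_table(data, causes, "Y_obs")
          qmc_minimize(tt, remainder_policy)
        } else {
          regression_qca(data, causes, "Y_obs", remainder_policy)
        }
        estimate_row(estimate = as.numeric(expression_equal(found, truth_dnf)),
                     expression = render_dnf(found))
      }, inquiry = "sufficient_configurations")
      compose_design(list(
        pop, outcome_step,
        declare_inquiry("sufficient_configurations", kind = "qca_configuration",
                        truth = truth_dnf),
        declare_measurement("Y", "binary_flip", rate = error_rate),
        answer_step
      ), name = "qca_crisp",
      params = list(truth = render_dnf(truth_dnf), n = n,
                    error_rate = error_rate, answer = answer,
                    remainder_policy = remainder_policy))
    }),

  likely_voter_survey = catalog_entry(
    "Descriptive survey inference on candidate support among voters when respondents overstate their propensity to vote: latent turnout and support, a random sample, misreported turnout, and a sample-mean answer among self-reported likely voters.",
    list(N = prm(10000, lower = 100), n = prm(1000, lower = 10),
         turnout = prm(0.5, lower = 0, upper = 1),
         support_voters = prm(0.55, lower = 0, upper = 1),
         support_nonvoters = prm(0.45, lower = 0, upper = 1),
         overreport_rate = prm(0.3, lower = 0, upper = 1)),
    function(N = 10000, n = 1000, turnout = 0.5, support_voters = 0.55,
             support_nonvoters = 0.45, overreport_rate = 0.3) {
      compose_design(list(
        declare_population(
          N = N,
          voter = list(dist = "bernoulli", p = turnout),
          support = ~ rbern(N, ifelse(voter == 1, support_voters,
                                      support_nonvoters))),
        declare_inquiry("support_among_voters",
                        expr = ~ mean(support[voter == 1])),
        declare_sampling(n = n),
        declare_measurement("voter", "overreport", rate = overreport_rate),
        declare_estimator("mean_among_likely", function(data) {
          sel <- data$voter_obs == 1
          if (!any(sel)) stop_run("no self-reported likely voters in sample")
          x <- data$support[sel]
          se <- stats::sd(x) / sqrt(length(x))
          estimate_row(estimate = mean(x), std_error = se,
                       ci_low = mean(x) - 1.96 * se,
                       ci_high = mean(x) + 1.96 * se)
        }, inquiry = "support_among_voters")
      ), name = "likely_voter_survey",
      params = list(N = N, n = n, turnout = turnout,
                    support_voters = support_voters,
                    support_nonvoters = support_nonvoters,
                    overreport_rate = overreport_rate))
    }),

  bayes_descriptive = catalog_entry(
    "Bayesian descriptive inference on a latent success probability from a handful of binomial draws, contrasting a flat prior (mean 0.50, sd 0.29) with a more concentrated one (sd 0.11); the estimand is the latent probability drawn fresh each run.",
    list(n = prm(20, lower = 1),
         prior_mean = prm(0.5, lower = 0, upper = 1),
         prior_sd = prm(0.29, lower = 0, upper = 0.5),
         prior_mean_2 = prm(0.5, lower = 0, upper = 1),
         prior_sd_2 = prm(0.11, lower = 0, upper = 0.5)),
    function(n = 20, prior_mean = 0.5, prior_sd = 0.29,
             prior_mean_2 = 0.5, prior_sd_2 = 0.11) {
      draw_truth <- new_step("draw_latent_probability", "population", function(data) {
        p <- stats::runif(1)
        data.frame(ID = seq_len(n), p = p,
                   success = rbern(n, p))
      })
      post <- function(label, pm, ps) declare_estimator(label, function(data)
        beta_binomial_posterior(sum(data$success), nrow(data), pm, ps),
        inquiry = "latent_probability")
      compose_design(list(
        draw_truth,
        declare_inquiry("latent_probability", expr = ~ mean(p)),
        post("uniform_prior", prior_mean, prior_sd),
        post("informative_prior", prior_mean_2, prior_sd_2)
      ), name = "bayes_descriptive",
      params = list(n = n, prior_mean = prior_mean, prior_sd = prior_sd,
                    prior_mean_2 = prior_mean_2, prior_sd_2 = prior_sd_2))
    }),

  nonlinear_regression = catalog_entry(
    "Observational regression when the true response is nonlinear in the treatment: the estimand is the slope of the linear projection of the unit response functions under a reference (uniform) density over the treatment grid; the data strategy assigns treatment values with possibly non-uniform probabilities and the answer is OLS of the outcome on the treatment.",
    list(n = prm(500, lower = 10),
         assignment_weights = prm(NULL, type = "numeric_vector"),
         noise_sd = prm(0.1, lower = 0)),
    function(n = 500, assignment_weights = NULL, noise_sd = 0.1,
             po_fun = function(x, data) x^2 + data$u,
             grid = seq(0, 1, length.out = 11)) {
      w <- assignment_weights %||% rep(1, length(grid))
      assign_x <- new_step("assign_x", "assignment", function(data) {
        data$x <- sample(grid, nrow(data), replace = TRUE, prob = w)
        data
      })
      reveal_y <- new_step("reveal_y", "reveal", function(data) {
        data$Y <- po_fun(data$x, data)
        data
      })
      compose_design(list(
        declare_population(N = n, u = ~ rnorm(N, sd = noise_sd)),
        declare_inquiry("linear_projection", kind = "linear_projection",
                        po_fun = po_fun, grid = grid),
        assign_x,
        reveal_y,
        declare_estimator_ols("OLS", Y ~ x, target = "x",
                              inquiry = "linear_projection")
      ), name = "nonlinear_regression",
      params = list(n = n, assignment_weights = assignment_weights,
                    noise_sd = noise_sd))
    }),

  matching_probit = catalog_entry(
    "Matching on observables: three covariates drive assignment through a probit process and also the outcome; the inquiry is the treatment effect on the treated. Answers: nearest-neighbor Mahalanobis matching on a (possibly incomplete) covariate set versus a naive difference in means.",
    list(n = prm(400, lower = 20), tau = prm(0.5),
         withhold_covariate = prm(TRUE, type = "logical")),
    function(n = 400, tau = 0.5, withhold_covariate = TRUE) {
      match_covs <- if (withhold_covariate) c("X1", "X2") else c("X1", "X2", "X3")
      compose_design(list(
        declare_population(N = n, X1 = ~ rnorm(N), X2 = ~ rnorm(N),
                           X3 = ~ rnorm(N), e = ~ rnorm(N),
                           Z = ~ as.integer(0.5 * (X1 + X2 + X3) + e > 0),
                           u = ~ rnorm(N)),
        declare_potential_outcomes("Y", ~ tau * Z + X1 + X2 + X3 + u,
                                   conditions = list(Z = c(0, 1))),
        declare_inquiry("ATT", expr = ~ mean(Y_Z_1[Z == 1] - Y_Z_0[Z == 1])),
        declare_reveal("Y", "Z"),
        declare_estimator("matching", function(data)
          matching_att(data, "Y", "Z", match_covs), inquiry = "ATT"),
        declare_estimator_dim("naive_DIM", "Y", "Z", inquiry = "ATT")
      ), name = "matching_probit",
      params = list(n = n, tau = tau, withhold_covariate = withhold_covariate))
    }),

  rd_polynomial = catalog_entry(
    "Sharp regression discontinuity: potential-outcome functions of a running variable, treatment assigned at the cutoff, and an answer regressing the outcome on treatment interacted with a fourth-order polynomial of the centered running variable. The estimand is the gap between the two conditional-expectation functions at the cutoff.",
    list(n = prm(1000, lower = 50), cutoff = prm(0), tau = prm(0.25),
         noise_sd = prm(0.2, lower = 0)),
    function(n = 1000, cutoff = 0, tau = 0.25, noise_sd = 0.2,
             control_fun = function(x) 0.5 * x + 0.4 * x^2,
             treat_fun = function(x) tau + 0.5 * x - 0.4 * x^2) {
      reveal_rd <- new_step("reveal_rd", "reveal", function(data) {
        data$Z <- as.integer(data$x >= cutoff)
        data$Y <- ifelse(data$Z == 1, treat_fun(data$x), control_fun(data$x)) +
          data$u
        data$xc <- data$x - cutoff
        data
      })
      compose_design(list(
        declare_population(N = n, x = ~ runif(N, -1, 1),
                           u = ~ rnorm(N, sd = noise_sd)),
        declare_inquiry("rd_gap", kind = "rd_limit", cutoff = cutoff,
                        control_fun = control_fun, treat_fun = treat_fun),
        reveal_rd,
        declare_estimator_ols("OLS_poly4",
                              Y ~ Z * poly(xc, 4, raw = TRUE), target = "Z",
                              inquiry = "rd_gap")
      ), name = "rd_polynomial",
      params = list(n = n, cutoff = cutoff, tau = tau, noise_sd = noise_sd))
    }),

  split_sample_discovery = catalog_entry(
    "Split-sample discovery of heterogeneous effects: a main treatment effect plus candidate moderators; the principled strategy selects the most promising interaction on a training split and estimates it on the holdout, versus the unprincipled full-data analogue.",
    list(n = prm(500, lower = 40), tau = prm(0.3),
         moderator_effects = prm(c(0, 0, 0), type = "numeric_vector"),
         split_fraction = prm(0.5, lower = 0, upper = 1),
         alpha = prm(0.05, lower = 0, upper = 1)),
    function(n = 500, tau = 0.3, moderator_effects = c(0, 0, 0),
             split_fraction = 0.5, alpha = 0.05) {
      k <- length(moderator_effects)
      mods <- paste0("M", seq_len(k))
      gens <- stats::setNames(
        rep(list(list(dist = "bernoulli", p = 0.5)), k), mods)
      pop <- do.call(declare_population,
                     c(list(N = n), gens, list(u = ~ rnorm(N))))
      mod_sum <- paste(sprintf("moderator_effects[%d] * Z * %s", seq_len(k), mods),
                       collapse = " + ")
      po_formula <- stats::as.formula(paste("~ tau * Z +", mod_sum, "+ u"))
      environment(po_formula) <- environment()
      inquiries <- lapply(seq_len(k), function(j) {
        f <- stats::as.formula(
          sprintf("~ moderator_effects[%d] + 0 * mean(u)", j))
        environment(f) <- environment()
        declare_inquiry(paste0("interaction_", mods[j]), expr = f)
      })
      split_step <- declare_estimator("split_sample", function(data) {
        rows <- split_sample_answer(data, "Y", "Z", mods,
                                    split_fraction = split_fraction,
                                    alpha = alpha)
        rows$estimand_label <- ifelse(is.na(rows$selected), NA_character_,
                                      paste0("interaction_", rows$selected))
        rows
      })
      compose_design(c(list(
        pop,
        declare_potential_outcomes("Y", po_formula,
                                   conditions = list(Z = c(0, 1))),
        declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0))),
        inquiries,
        list(
          declare_assignment("complete", prob = 0.5),
          declare_reveal("Y", "Z"),
          declare_estimator_dim("DIM", "Y", "Z", inquiry = "ATE"),
          split_step
        )), name = "split_sample_discovery",
      params = list(n = n, tau = tau, moderator_effects = moderator_effects,
                    split_fraction = split_fraction, alpha = alpha))
    }),

  truncation_replication = catalog_entry(
    "Cluster-randomized community-health intervention with truncation by death: latent family and community health drive both infant survival and weight; the treatment saves low-health infants (concentrated among the young), sampling is stratified by catchment area, and half of the clusters are assigned. Estimands: the survival effect (cluster level) and the weight effect among always-survivors. Answers: naive survivor comparison, an always-survivor proxy subset, and four replicator strategies for conditioning on community-based-organization (CBO) presence.",
    list(n_clusters = prm(50, lower = 4),
         n_per_cluster = prm(10, lower = 2),
         survival_effect = prm(0.14, lower = 0, upper = 1),
         weight_effect = prm(0.2),
         baseline_survival = prm(0.85, lower = 0, upper = 1),
         health_weight_corr = prm(1, lower = 0),
         cbo_correlated = prm(FALSE, type = "logical"),
         cbo_effect = prm(0.35),
         answers = prm(c("naive_survivors", "always_survivor_subset"),
                       type = "character_vector")),
    truncation_replication_design)
  )
}

#' List the design catalogue
#'
#' @return data frame with one row per catalogue entry: name, description,
#'   and the comma-separated parameter names.
#' @export
design_catalog <- function() {
  reg <- design_registry()
  data.frame(
    name = names(reg),
    parameters = vapply(reg, function(e)
      paste(names(e$params), collapse = ", "), character(1)),
    description = vapply(reg, `[[`, character(1), "description"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Parameter schema of a catalogue design
#'
#' @param name catalogue entry name.
#' @return named list of parameter descriptors (default, type, choices,
#'   range), serializable to JSON for configuration authoring.
#' @export
design_schema <- function(name) {
  reg <- design_registry()
  if (!name %in% names(reg))
    stop_config("unknown design '", name, "'; available: ",
                paste(names(reg), collapse = ", "))
  reg[[name]]$params
}

#' Build a catalogue design
#'
#' Dispatches over the design catalogue; see [design_catalog()] for the
#' available entries and [design_schema()] for each entry's parameters.
#'
#' @param design catalogue entry name.
#' @param ... design parameters overriding the schema defaults.
#' @return a `dd_design`.
#' @examples
#' d <- make_design("table3_canonical", N = 20, n = 10, m_treated = 5)
#' run_once(d, seed = 2)
#' @export
make_design <- function(design, ...) {
  reg <- design_registry()
  if (!design %in% names(reg))
    stop_config("unknown design '", design, "'; available: ",
                paste(names(reg), collapse = ", "))
  entry <- reg[[design]]
  args <- list(...)
  known <- names(formals(entry$builder))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop_config("unknown parameter(s) for design '", design, "': ",
                paste(unknown, collapse = ", "))
  for (pn in intersect(names(args), names(entry$params))) {
    sch <- entry$params[[pn]]
    v <- args[[pn]]
    if (!is.null(sch$choices) && !v %in% sch$choices)
      stop_config("parameter '", pn, "' must be one of ",
                  paste(sch$choices, collapse = ", "))
    if (!is.null(sch$lower) && is.numeric(v) && any(v < sch$lower))
      stop_config("parameter '", pn, "' below its lower bound ", sch$lower)
    if (!is.null(sch$upper) && is.numeric(v) && any(v > sch$upper))
      stop_config("parameter '", pn, "' above its upper bound ", sch$upper)
  }
  do.call(entry$builder, args)
}

#' Truncation-by-death replication design
#'
#' Builds the cluster-randomized design in which an intervention affects
#' both survival and an anthropometric outcome, so that the weight effect is
#' only well-defined on the always-survivor stratum. Unobserved family and
#' community health drive both survival and weight; the treatment's survival
#' effect is concentrated among young, low-health infants, which is exactly
#' what biases a naive comparison of surviving infants downward. An
#' age-based proxy stratum whose survival is treatment-independent supports
#' the always-survivor subset answer. CBO (community-based organization)
#' presence per cluster is optionally correlated with community health and
#' supports four replicator answer strategies: ignore it, always include it
#' as a regressor, include it only when significantly imbalanced across arms
#' at the 5 percent level, or include it with a treatment interaction.
#'
#' @param n_clusters number of catchment areas (even; half are treated).
#' @param n_per_cluster infants per cluster.
#' @param survival_effect increase in survival probability among young
#'   infants under treatment (the overall survival effect is about half of
#'   this, since half the infants are young).
#' @param weight_effect treatment effect on weight-for-age among survivors.
#' @param baseline_survival control-condition survival probability.
#' @param health_weight_corr loading of latent health on weight; positive
#'   values create the survival-weight correlation that biases the naive
#'   answer.
#' @param cbo_correlated whether CBO presence is correlated with community
#'   health (the replicators' claim) or independent of it (the original
#'   authors' claim).
#' @param cbo_effect additional weight shift in CBO clusters when
#'   `cbo_correlated` is `TRUE`.
#' @param answers which weight answer strategies to include:
#'   `"naive_survivors"`, `"always_survivor_subset"`, `"cbo_ignore"`,
#'   `"cbo_include"`, `"cbo_include_if_imbalanced"`,
#'   `"cbo_include_interaction"`.
#' @return a `dd_design` with a cluster-level survival estimator
#'   (`mortality_OLS`, targeting the `survival_effect` estimand) plus the
#'   selected weight estimators (targeting `weight_always_survivors`).
#' @export
truncation_replication_design <- function(
    n_clusters = 50, n_per_cluster = 10, survival_effect = 0.14,
    weight_effect = 0.2, baseline_survival = 0.85, health_weight_corr = 1,
    cbo_correlated = FALSE, cbo_effect = 0.35,
    answers = c("naive_survivors", "always_survivor_subset")) {
  if (!is_count(n_clusters) || n_clusters < 4)
    stop_declaration("n_clusters must be a count >= 4")
  assert_prob(baseline_survival, "baseline_survival")
  assert_prob(survival_effect, "survival_effect")
  valid <- c("naive_survivors", "always_survivor_subset", "cbo_ignore",
             "cbo_include", "cbo_include_if_imbalanced",
             "cbo_include_interaction")
  if (length(setdiff(answers, valid)))
    stop_declaration("unknown answer strategy: ",
                     paste(setdiff(answers, valid), collapse = ", "))
  # each catchment area holds a larger household pool; sampling is
  # stratified by area so every cluster is represented
  pool_per_cluster <- 2 * n_per_cluster
  N <- n_clusters * pool_per_cluster
  cluster_of <- rep(seq_len(n_clusters), each = pool_per_cluster)

  pop <- new_step("population", "population", function(data) {
    community <- stats::rnorm(n_clusters, sd = 0.5)
    cbo <- if (cbo_correlated) rbern(n_clusters, stats::pnorm(2 * community))
           else rbern(n_clusters, 0.5)
    data.frame(
      ID = seq_len(N),
      cluster = cluster_of,
      community_health = community[cluster_of],
      cbo = cbo[cluster_of],
      family_health = stats::rnorm(N, sd = 0.5),
      young = rbern(N, 0.5),
      e_surv = stats::rnorm(N, sd = 0.6),
      e_weight = stats::rnorm(N, sd = 0.5))
  })

  po <- new_step("potential_outcomes", "potential_outcomes", function(data) {
    health <- data$community_health + data$family_health
    s_latent <- 0.8 * health + data$e_surv
    s_sd <- sqrt(0.8^2 * 0.5 + 0.36)
    thr <- stats::qnorm(1 - baseline_survival, sd = s_sd)
    # treatment shifts the survival latent for young infants by the amount
    # that raises their survival probability by survival_effect on average
    delta <- s_sd * (stats::qnorm(
      pmin(baseline_survival + survival_effect, 1 - 1e-9)) -
        stats::qnorm(baseline_survival))
    data$Alive_Z_0 <- as.integer(s_latent > thr)
    data$Alive_Z_1 <- as.integer(s_latent + delta * data$young > thr)
    cbo_term <- if (cbo_correlated) cbo_effect * data$cbo else 0
    base_w <- health_weight_corr * health + cbo_term + data$e_weight
    data$Weight_Z_0 <- base_w
    data$Weight_Z_1 <- base_w + weight_effect
    data
  })

  inquiry_surv <- declare_inquiry("survival_effect",
                                  expr = ~ mean(Alive_Z_1 - Alive_Z_0))
  inquiry_weight <- declare_inquiry(
    "weight_always_survivors",
    expr = ~ mean(Weight_Z_1[Alive_Z_0 == 1 & Alive_Z_1 == 1] -
                    Weight_Z_0[Alive_Z_0 == 1 & Alive_Z_1 == 1]))

  sampling <- declare_sampling(strata = "cluster",
                               n_per_stratum = n_per_cluster)
  assignment <- declare_assignment("clustered", cluster_var = "cluster",
                                   m_clusters = floor(n_clusters / 2))
  reveal_alive <- declare_reveal("Alive", "Z")
  reveal_weight <- declare_reveal("Weight", "Z")

  mortality <- declare_estimator("mortality_OLS", function(data) {
    counts <- rowsum(cbind(alive = data$Alive, one = 1), data$cluster)
    agg <- fast_df(list(Alive = counts[, "alive"] / counts[, "one"],
                        Z = data$Z[match(rownames(counts), data$cluster)]))
    ols_estimate(agg, Alive ~ Z, target = "Z")
  }, inquiry = "survival_effect")

  weight_est <- function(strategy) {
    switch(strategy,
      naive_survivors = declare_estimator("naive_survivors", function(data) {
        ols_estimate(data[data$Alive == 1, ], Weight ~ Z, target = "Z",
                     cluster = "cluster")
      }, inquiry = "weight_always_survivors"),
      always_survivor_subset = declare_estimator("always_survivor_subset",
        function(data) {
          sel <- data$Alive == 1 & data$young == 0
          ols_estimate(data[sel, ], Weight ~ Z, target = "Z",
                       cluster = "cluster")
        }, inquiry = "weight_always_survivors"),
      cbo_ignore = declare_estimator("cbo_ignore", function(data) {
        ols_estimate(data[data$Alive == 1, ], Weight ~ Z, target = "Z",
                     cluster = "cluster")
      }, inquiry = "weight_always_survivors"),
      cbo_include = declare_estimator("cbo_include", function(data) {
        ols_estimate(data[data$Alive == 1, ], Weight ~ Z + cbo, target = "Z",
                     cluster = "cluster")
      }, inquiry = "weight_always_survivors"),
      cbo_include_if_imbalanced = declare_estimator("cbo_include_if_imbalanced",
        function(data) {
          cl <- data[!duplicated(data$cluster), c("cluster", "Z", "cbo")]
          bal <- tryCatch(ols_estimate(cl, cbo ~ Z, target = "Z"),
                          error = function(e) NULL)
          include <- !is.null(bal) && !is.na(bal$p_value) && bal$p_value <= 0.05
          f <- if (include) Weight ~ Z + cbo else Weight ~ Z
          row <- ols_estimate(data[data$Alive == 1, ], f, target = "Z",
                              cluster = "cluster")
          row$cbo_included <- as.integer(include)
          row
        }, inquiry = "weight_always_survivors"),
      cbo_include_interaction = declare_estimator("cbo_include_interaction",
        function(data) {
          ols_estimate(data[data$Alive == 1, ], Weight ~ Z * cbo, target = "Z",
                       cluster = "cluster")
        }, inquiry = "weight_always_survivors"))
  }

  steps <- c(list(pop, po, inquiry_surv, inquiry_weight, sampling,
                  assignment, reveal_alive, reveal_weight, mortality),
             lapply(answers, weight_est))
  compose_design(steps, name = "truncation_replication",
                 params = list(n_clusters = n_clusters,
                               n_per_cluster = n_per_cluster,
                               survival_effect = survival_effect,
                               weight_effect = weight_effect,
                               baseline_survival = baseline_survival,
                               cbo_correlated = cbo_correlated,
                               cbo_effect = cbo_effect,
                               answers = answers))
}
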