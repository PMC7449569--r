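# Answer-strategy primitives. Every estimator returns a one-row (or few-row)
# data frame with the standard estimate fields so results from different
# strategies stack into one simulation table.

fast_df <- function(lst) {
  n <- length(lst[[1]])
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

estimate_row <- function(estimate = NA_real_, std_error = NA_real_,
                         p_value = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, df = NA_real_, ...) {
  fast_df(c(list(estimate = estimate, std_error = std_error,
                 p_value = p_value, ci_low = ci_low, ci_high = ci_high,
                 df = df), list(...)))
}

#' Difference-in-means estimator
#'
#' Mean outcome difference between two arms with the Neyman variance
#' estimator, a Welch-style two-sided t test and 95 percent t confidence
#' interval. With fewer than two units in an arm the estimate is returned
#' but its uncertainty statistics are unavailable.
#'
#' @param data data frame containing the outcome and assignment columns.
#' @param outcome outcome column name.
#' @param assignment binary assignment column name.
#' @param treat,control values of the assignment column defining the arms.
#' @param alpha two-sided test level used for the confidence interval.
#' @return one-row data frame of estimate fields.
#' @export
difference_in_means <- function(data, outcome, assignment,
                                treat = 1, control = 0, alpha = 0.05) {
  y1 <- data[[outcome]][data[[assignment]] == treat]
  y0 <- data[[outcome]][data[[assignment]] == control]
  if (length(y1) == 0 || length(y0) == 0)
    stop_run("difference_in_means: an arm is empty")
  est <- mean(y1) - mean(y0)
  if (length(y1) < 2 || length(y0) < 2) return(estimate_row(estimate = est))
  v1 <- stats::var(y1) / length(y1)
  v0 <- stats::var(y0) / length(y0)
  se <- sqrt(v1 + v0)
  if (se == 0) {
    return(estimate_row(estimate = est, std_error = 0,
                        p_value = if (est == 0) 1 else 0,
                        ci_low = est, ci_high = est,
                        df = length(y1) + length(y0) - 2))
  }
  df <- (v1 + v0)^2 / (v1^2 / (length(y1) - 1) + v0^2 / (length(y0) - 1))
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  crit <- stats::qt(1 - alpha / 2, df)
  estimate_row(estimate = est, std_error = se, p_value = p,
               ci_low = est - crit * se, ci_high = est + crit * se, df = df)
}

#' (Weighted) least squares with heteroskedasticity-robust uncertainty
#'
#' Fits the model by (weighted) least squares and reports the target
#' coefficient with an HC2 heteroskedasticity-robust standard error
#' (cluster-robust when a cluster column is given), t-based p-value and
#' confidence interval. Block fixed effects enter as factor terms in the
#' formula; polynomial answer strategies (e.g. a treatment interacted with a
#' fourth-order polynomial of a running variable) are expressed the same
#' way.
#'
#' @param data data frame.
#' @param formula model formula.
#' @param target name of the coefficient reported (exact match against
#'   `coef()` names).
#' @param weights optional: a column name or a numeric vector of weights.
#' @param cluster optional column name for cluster-robust standard errors.
#' @param alpha two-sided level for the confidence interval.
#' @return one-row data frame of estimate fields.
#' @export
ols_estimate <- function(data, formula, target, weights = NULL,
                         cluster = NULL, alpha = 0.05) {
  rownames(data) <- NULL
  w <- NULL
  if (!is.null(weights)) {
    w <- if (is.character(weights)) data[[weights]] else weights
    if (is.null(w)) stop_run("ols_estimate: weights column not found")
  }
  data$`(w)` <- if (is.null(w)) rep(1, nrow(data)) else w
  fit <- stats::lm(formula, data = data, weights = `(w)`)
  cf <- stats::coef(fit)
  if (anyNA(cf[target]) || !target %in% names(cf))
    stop_run("ols_estimate: target coefficient '", target,
             "' not estimable (rank deficiency?)")
  vc <- if (is.null(cluster)) {
    sandwich::vcovHC(fit, type = "HC2")
  } else {
    # CR1 (Stata-style) cluster-robust covariance; the per-cluster leverage
    # adjustments of CR2 are prohibitive inside Monte Carlo loops
    cl <- data[[cluster]][as.integer(rownames(stats::model.frame(fit)))]
    sandwich::vcovCL(fit, cluster = cl, type = "HC1")
  }
  se <- sqrt(vc[target, target])
  df <- if (is.null(cluster)) fit$df.residual else {
    cl <- data[[cluster]][as.integer(rownames(stats::model.frame(fit)))]
    length(unique(cl)) - 1
  }
  est <- unname(cf[target])
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  crit <- stats::qt(1 - alpha / 2, df)
  estimate_row(estimate = est, std_error = se, p_value = p,
               ci_low = est - crit * se, ci_high = est + crit * se, df = df)
}

#' Inverse-probability-of-assignment weights
#'
#' Horvitz-Thompson style weights for a binary assignment with known,
#' possibly heterogeneous, assignment probabilities: treated units receive
#' `1/p`, control units `1/(1-p)`.
#'
#' @param z binary assignment vector (0/1).
#' @param p per-unit probability of assignment to treatment, strictly
#'   inside (0, 1).
#' @return numeric weight vector.
#' @export
ipw_weights <- function(z, p) {
  if (any(p <= 0 | p >= 1))
    stop_run("ipw_weights: assignment probabilities must be strictly inside (0, 1)")
  z / p + (1 - z) / (1 - p)
}

#' Conjugate beta-binomial posterior for a proportion
#'
#' Matches a Beta prior to the supplied prior mean and standard deviation by
#' the method of moments, updates it with the observed successes, and
#' reports the posterior mean with a central 95 percent credible interval in
#' the confidence-interval fields. The posterior standard deviation and the
#' prior moments are carried as auxiliary columns so that posterior-shift
#' diagnosands can be computed downstream.
#'
#' @param successes,trials observed binomial data; zero trials returns the
#'   prior itself.
#' @param prior_mean,prior_sd prior moments; must admit a valid Beta
#'   distribution (mean strictly inside (0,1) and sd^2 < mean(1-mean)).
#' @param alpha credible-interval tail mass (default central 95 percent).
#' @return one-row data frame of estimate fields plus `posterior_sd`,
#'   `prior_mean`, `prior_sd`.
#' @export
beta_binomial_posterior <- function(successes, trials, prior_mean, prior_sd,
                                    alpha = 0.05) {
  if (!(prior_mean > 0 && prior_mean < 1))
    stop_declaration("prior mean must be strictly inside (0, 1)")
  if (prior_sd <= 0 || prior_sd^2 >= prior_mean * (1 - prior_mean))
    stop_declaration("prior sd does not admit a valid Beta distribution")
  if (successes < 0 || trials < 0 || successes > trials)
    stop_run("invalid binomial data")
  nu <- prior_mean * (1 - prior_mean) / prior_sd^2 - 1
  a <- prior_mean * nu
  b <- (1 - prior_mean) * nu
  a_post <- a + successes
  b_post <- b + trials - successes
  mean_post <- a_post / (a_post + b_post)
  sd_post <- sqrt(a_post * b_post /
                    ((a_post + b_post)^2 * (a_post + b_post + 1)))
  estimate_row(estimate = mean_post, std_error = sd_post,
               ci_low = stats::qbeta(alpha / 2, a_post, b_post),
               ci_high = stats::qbeta(1 - alpha / 2, a_post, b_post),
               posterior_sd = sd_post, prior_mean = prior_mean,
               prior_sd = prior_sd,
               prior_a = a, prior_b = b)
}

#' Nearest-neighbor matching estimator of the ATT
#'
#' One-to-one nearest-neighbor matching with replacement on the Mahalanobis
#' distance over the supplied covariates; each treated unit is paired with
#' its closest control (ties broken by the lowest unit index, for
#' determinism). The ATT is the mean within-pair outcome difference. The
#' standard error is a matched-pair approximation (the standard deviation of
#' pair differences over the square root of the number of treated units); it
#' ignores the reuse of controls and is documented as an approximation. With
#' a zero-variance covariate the distance falls back to Euclidean on the raw
#' scale, with a warning.
#'
#' @param data data frame.
#' @param outcome,treatment column names (treatment binary 0/1).
#' @param covariates character vector of covariate column names.
#' @param alpha two-sided level for the confidence interval.
#' @return one-row data frame of estimate fields plus `n_treated` and
#'   `n_matched_controls` (distinct controls used).
#' @export
matching_att <- function(data, outcome, treatment, covariates, alpha = 0.05) {
  tr <- which(data[[treatment]] == 1)
  co <- which(data[[treatment]] == 0)
  if (length(tr) == 0 || length(co) == 0)
    stop_run("matching_att: need at least one treated and one control unit")
  X <- as.matrix(data[covariates])
  S <- stats::cov(X)
  if (any(diag(S) == 0) || inherits(try(solve(S), silent = TRUE), "try-error")) {
    warning("zero-variance covariate: falling back to Euclidean distance",
            call. = FALSE)
    S <- diag(ncol(X))
  }
  Sinv <- solve(S)
  match_of <- integer(length(tr))
  for (i in seq_along(tr)) {
    d <- X[co, , drop = FALSE] -
      matrix(X[tr[i], ], nrow = length(co), ncol = ncol(X), byrow = TRUE)
    dist2 <- rowSums((d %*% Sinv) * d)
    match_of[i] <- co[which.min(dist2)]  # which.min takes the lowest index on ties
  }
  diffs <- data[[outcome]][tr] - data[[outcome]][match_of]
  est <- mean(diffs)
  if (length(diffs) < 2) {
    return(estimate_row(estimate = est, n_treated = length(tr),
                        n_matched_controls = length(unique(match_of))))
  }
  se <- stats::sd(diffs) / sqrt(length(diffs))
  df <- length(diffs) - 1
  tstat <- if (se > 0) est / se else NA_real_
  p <- if (se > 0) 2 * stats::pt(-abs(tstat), df) else if (est == 0) 1 else 0
  crit <- stats::qt(1 - alpha / 2, df)
  estimate_row(estimate = est, std_error = se, p_value = p,
               ci_low = est - crit * se, ci_high = est + crit * se, df = df,
               n_treated = length(tr),
               n_matched_controls = length(unique(match_of)))
}

#' Split-sample discovery of heterogeneous effects
#'
#' Two-stage "principled" discovery: a random training split is used to fit
#' one treatment-by-moderator interaction model per candidate moderator; the
#' moderator with the smallest interaction p-value is selected if that
#' p-value is below `alpha`, and the selected interaction is then estimated
#' on the held-out data only. The "unprincipled" analogue applies the same
#' selection rule and estimation to the full data. Rows are labelled
#' `principled` and `unprincipled`; auxiliary columns record whether a
#' discovery was made (`discovered`), which moderator was selected
#' (`selected`), and whether a result was produced (discovery and a
#' significant holdout estimate).
#'
#' @param data data frame.
#' @param outcome,treatment column names.
#' @param moderators character vector of candidate moderator columns.
#' @param split_fraction share of units in the training split, in (0, 1).
#' @param alpha selection and testing level.
#' @return data frame with one row per strategy.
#' @export
split_sample_answer <- function(data, outcome, treatment, moderators,
                                split_fraction = 0.5, alpha = 0.05) {
  if (length(moderators) == 0) stop_declaration("no candidate moderators supplied")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_declaration("split_fraction must be strictly inside (0, 1)")
  n <- nrow(data)
  n_train <- floor(split_fraction * n)
  if (n_train < 1 || n_train >= n) stop_run("split leaves an empty stage")
  train_idx <- sample.int(n, n_train)
  train <- data[train_idx, , drop = FALSE]
  holdout <- data[-train_idx, , drop = FALSE]

  interaction_fit <- function(d, mod) {
    f <- stats::as.formula(paste(outcome, "~", treatment, "*", mod))
    ols_estimate(d, f, target = paste0(treatment, ":", mod), alpha = alpha)
  }
  select_on <- function(d) {
    ps <- vapply(moderators, function(mod) {
      row <- tryCatch(interaction_fit(d, mod), error = function(e) NULL)
      if (is.null(row)) NA_real_ else row$p_value
    }, numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) > alpha) NA_character_
    else moderators[which.min(ps)]
  }

  sel <- select_on(train)
  if (is.na(sel)) {
    principled <- estimate_row(discovered = 0L, selected = NA_character_,
                               result_produced = 0L)
  } else {
    row <- tryCatch(interaction_fit(holdout, sel), error = function(e)
      estimate_row())
    row$discovered <- 1L
    row$selected <- sel
    row$result_produced <- as.integer(!is.na(row$p_value) && row$p_value <= alpha)
    principled <- row
  }
  sel_full <- select_on(data)
  if (is.na(sel_full)) {
    unprincipled <- estimate_row(discovered = 0L, selected = NA_character_,
                                 result_produced = 0L)
  } else {
    row <- interaction_fit(data, sel_full)
    row$discovered <- 1L
    row$selected <- sel_full
    row$result_produced <- as.integer(!is.na(row$p_value) && row$p_value <= alpha)
    unprincipled <- row
  }
  principled$estimator_label <- "principled"
  unprincipled$estimator_label <- "unprincipled"
  rbind_fill(list(principled, unprincipled))
}

#' Mean absolute standardized covariate difference between arms
#'
#' The per-dataset balance statistic behind the imbalance diagnosand: for
#' each covariate, the absolute difference in arm means divided by the
#' pooled standard deviation; averaged over covariates. Zero-variance
#' covariates are skipped with a warning.
#'
#' @param data data frame.
#' @param covariates covariate column names.
#' @param assignment binary assignment column name.
#' @return numeric scalar.
#' @export
balance_statistic <- function(data, covariates, assignment) {
  z <- data[[assignment]]
  vals <- vapply(covariates, function(cv) {
    x <- data[[cv]]
    s <- sqrt((stats::var(x[z == 1]) + stats::var(x[z == 0])) / 2)
    if (is.na(s) || s == 0) {
      warning("covariate '", cv, "' has zero variance; skipped", call. = FALSE)
      return(NA_real_)
    }
    abs(mean(x[z == 1]) - mean(x[z == 0])) / s
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
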