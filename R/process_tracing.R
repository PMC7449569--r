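#' Likelihood table for causal process observations
#'
#' Collects, for each causal process observation (CPO), the probability of
#' observing its confirmatory evidence when the causal hypothesis H is true
#' and when it is false. An optional correlation `rho` between the first two
#' evidence indicators (conditional on the hypothesis) supports jointly
#' distributed clues; it is clipped to the feasible Frechet bounds implied
#' by the marginals, with a warning.
#'
#' @param p_h numeric vector, Pr(E_k | H) per CPO.
#' @param p_nh numeric vector, Pr(E_k | not H) per CPO.
#' @param rho optional correlation between the first two evidence
#'   indicators, in \[-1, 1\].
#' @param labels optional CPO labels.
#' @return an object of class `dd_likelihood_table`.
#' @export
likelihood_table <- function(p_h, p_nh, rho = NULL, labels = NULL) {
  if (length(p_h) != length(p_nh))
    stop_declaration("p_h and p_nh must have the same length")
  assert_prob(p_h, "Pr(E|H)")
  assert_prob(p_nh, "Pr(E|not H)")
  if (!is.null(rho) && (rho < -1 || rho > 1))
    stop_declaration("rho must lie in [-1, 1]")
  structure(list(p_h = p_h, p_nh = p_nh, rho = rho,
                 labels = labels %||% paste0("E", seq_along(p_h))),
            class = "dd_likelihood_table")
}

# Joint distribution of two correlated binary indicators with marginals
# (p1, p2): returns c(p11, p10, p01, p00). rho is clipped to the Frechet
# bounds so all four cells are non-negative.
binary_joint <- function(p1, p2, rho, warn = TRUE) {
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- p1 * p2 + rho * s
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    if (warn) warning("rho outside feasible Frechet bounds; clipped",
                      call. = FALSE)
    p11 <- min(max(p11, lo), hi)
  }
  c(p11 = p11, p10 = p1 - p11, p01 = p2 - p11, p00 = 1 - p1 - p2 + p11)
}

#' Joint distribution of two CPO evidence patterns
#'
#' Given the likelihoods of the first two CPOs and a correlation between
#' their evidence indicators (the same correlation under both hypotheses),
#' returns the probabilities of the four see/not-see patterns under H and
#' under not-H, with marginals preserved.
#'
#' @param table a [likelihood_table()] with at least two CPOs.
#' @param rho correlation between the two evidence indicators; defaults to
#'   the table's own `rho`, or 0.
#' @return list with numeric vectors `h` and `nh`, each with elements
#'   `p11`, `p10`, `p01`, `p00` (seen/seen, seen/not, not/seen, not/not).
#' @export
joint_cpo_distribution <- function(table, rho = NULL) {
  stopifnot(inherits(table, "dd_likelihood_table"))
  if (length(table$p_h) < 2) stop_declaration("need at least two CPOs")
  rho <- rho %||% table$rho %||% 0
  list(h = binary_joint(table$p_h[1], table$p_h[2], rho),
       nh = binary_joint(table$p_nh[1], table$p_nh[2], rho))
}

pattern_likelihood <- function(table, observed, hypothesis) {
  p <- if (hypothesis) table$p_h else table$p_nh
  sought <- which(!is.na(observed))
  rho <- table$rho %||% 0
  if (length(sought) >= 2 && all(c(1, 2) %in% sought) && rho != 0) {
    joint <- binary_joint(p[1], p[2], rho, warn = FALSE)
    cell <- paste0("p", as.integer(observed[1]), as.integer(observed[2]))
    lik <- joint[[cell]]
    rest <- setdiff(sought, c(1, 2))
  } else {
    lik <- 1
    rest <- sought
  }
  for (k in rest) lik <- lik * if (observed[k]) p[k] else 1 - p[k]
  lik
}

#' Posterior probability of a hypothesis after process tracing
#'
#' Applies Bayes' rule to a pattern of sought causal process observations.
#' Evidence indicators are independent given the hypothesis unless the
#' likelihood table carries a correlation for the first two CPOs.
#'
#' @param prior prior probability of the hypothesis, in \[0, 1\].
#' @param table a [likelihood_table()].
#' @param observed logical vector, one entry per CPO: `TRUE` if the evidence
#'   was sought and seen, `FALSE` if sought and not seen, `NA` if not
#'   sought. A pattern with no sought evidence returns the prior.
#' @return posterior probability Pr(H | pattern).
#' @export
pt_posterior <- function(prior, table, observed) {
  stopifnot(inherits(table, "dd_likelihood_table"))
  assert_prob(prior, "prior")
  if (length(observed) != length(table$p_h))
    stop_declaration("observed pattern length must match the number of CPOs")
  lh <- pattern_likelihood(table, observed, TRUE)
  lnh <- pattern_likelihood(table, observed, FALSE)
  denom <- prior * lh + (1 - prior) * lnh
  if (denom <= 0) stop_run("observed evidence pattern has zero probability")
  prior * lh / denom
}

strategy_pattern_sets <- function(strategy, k) {
  base <- rep(NA, k)
  switch(strategy,
    cpo1_only = lapply(c(TRUE, FALSE), function(e) { p <- base; p[1] <- e; p }),
    cpo2_only = lapply(c(TRUE, FALSE), function(e) { p <- base; p[2] <- e; p }),
    both = {
      grid <- expand.grid(e1 = c(TRUE, FALSE), e2 = c(TRUE, FALSE))
      lapply(seq_len(4), function(i) {
        p <- base; p[1] <- grid$e1[i]; p[2] <- grid$e2[i]; p
      })
    },
    stop_declaration("unknown strategy '", strategy, "'"))
}

#' Expected inferential error of a process-tracing strategy
#'
#' Enumerates the truth of the hypothesis (true with the prior probability)
#' and every evidence pattern the strategy can observe, and returns the
#' expected absolute difference between the truth indicator and the
#' posterior the strategy reports. Lower is better; a doubly-decisive clue
#' drives the error to zero.
#'
#' @inheritParams pt_posterior
#' @param strategy which clues are sought: `"cpo1_only"`, `"cpo2_only"`, or
#'   `"both"`.
#' @return expected absolute posterior error (numeric scalar).
#' @export
pt_strategy_diagnosis <- function(prior, table, strategy = c("cpo1_only", "cpo2_only", "both")) {
  strategy <- match.arg(strategy)
  patterns <- strategy_pattern_sets(strategy, length(table$p_h))
  err <- 0
  for (h in c(TRUE, FALSE)) {
    ph <- if (h) prior else 1 - prior
    if (ph == 0) next
    for (pat in patterns) {
      lik <- pattern_likelihood(table, pat, h)
      if (lik <= 0) next
      post <- pt_posterior(prior, table, pat)
      err <- err + ph * lik * abs(as.numeric(h) - post)
    }
  }
  err
}

#' Classify a process-tracing test by its likelihoods
#'
#' Uses threshold heuristics on the two likelihoods: evidence nearly certain
#' under H (>= 0.9) makes a hoop test; evidence very unlikely under not-H
#' (<= 0.1) makes a smoking gun; both at once are doubly decisive; anything
#' else is a straw in the wind.
#'
#' @param pr_e_h probability of the evidence when the hypothesis is true.
#' @param pr_e_nh probability of the evidence when it is false.
#' @return one of `"hoop"`, `"smoking_gun"`, `"doubly_decisive"`,
#'   `"straw_in_the_wind"`.
#' @export
classify_test <- function(pr_e_h, pr_e_nh) {
  assert_prob(pr_e_h, "Pr(E|H)")
  assert_prob(pr_e_nh, "Pr(E|not H)")
  hoop <- pr_e_h >= 0.9
  gun <- pr_e_nh <= 0.1
  if (hoop && gun) "doubly_decisive"
  else if (hoop) "hoop"
  else if (gun) "smoking_gun"
  else "straw_in_the_wind"
}
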