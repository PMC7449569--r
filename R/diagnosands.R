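# Diagnosands: summaries of the distribution of per-run diagnostic
# statistics over a simulation table, with nonparametric bootstrap standard
# errors obtained by resampling whole simulation runs.

with_undefined <- function(value, n_undefined) {
  attr(value, "n_undefined") <- n_undefined
  value
}

#' Diagnosands
#'
#' Each diagnosand maps (a slice of) a simulation table to a scalar. The
#' conditioning conventions follow the definitions: power is the share of
#' runs rejecting the null at `alpha`; bias and RMSE compare estimates to
#' the estimand of the targeted inquiry; coverage is the share of
#' confidence intervals containing the estimand; the Type-S rate and the
#' exaggeration ratio condition on statistical significance and return
#' `NaN` (with the excluded count attached as the `n_undefined` attribute)
#' when no run qualifies. Standard deviations use the (m - 1) denominator.
#'
#' @param sims a simulation table (or subset) from [simulate_design()].
#' @param alpha significance level for significance-conditioned
#'   diagnosands.
#' @return numeric scalar (possibly with an `n_undefined` attribute).
#' @name diagnosands
NULL

#' @rdname diagnosands
#' @export
power <- function(sims, alpha = 0.05) {
  p <- sims$p_value
  if (all(is.na(p))) stop_config("power: no p-values for estimator '",
                                 paste(unique(sims$estimator_label), collapse = ","), "'")
  with_undefined(mean(p <= alpha, na.rm = TRUE), sum(is.na(p)))
}

#' @rdname diagnosands
#' @export
bias <- function(sims) {
  if (all(is.na(sims$estimand))) stop_config("bias: estimand missing")
  e <- sims$estimate - sims$estimand
  with_undefined(mean(e, na.rm = TRUE), sum(is.na(e)))
}

#' @rdname diagnosands
#' @export
rmse <- function(sims) {
  if (all(is.na(sims$estimand))) stop_config("rmse: estimand missing")
  e <- sims$estimate - sims$estimand
  with_undefined(sqrt(mean(e^2, na.rm = TRUE)), sum(is.na(e)))
}

#' @rdname diagnosands
#' @export
coverage <- function(sims) {
  if (all(is.na(sims$ci_low))) stop_config("coverage: no confidence intervals")
  hit <- sims$ci_low <= sims$estimand & sims$estimand <= sims$ci_high
  with_undefined(mean(hit, na.rm = TRUE), sum(is.na(hit)))
}

#' @rdname diagnosands
#' @export
sd_estimates <- function(sims) stats::sd(sims$estimate, na.rm = TRUE)

#' @rdname diagnosands
#' @export
sd_estimands <- function(sims) stats::sd(sims$estimand, na.rm = TRUE)

#' @rdname diagnosands
#' @export
mean_estimate <- function(sims) mean(sims$estimate, na.rm = TRUE)

#' @rdname diagnosands
#' @export
mean_estimand <- function(sims) mean(sims$estimand, na.rm = TRUE)

#' @rdname diagnosands
#' @export
mean_absolute_error <- function(sims) {
  mean(abs(sims$estimate - sims$estimand), na.rm = TRUE)
}

#' @rdname diagnosands
#' @param population_label,sample_label estimand labels of the population-
#'   and sample-level versions of the same inquiry.
#' @export
sampling_bias <- function(sims, population_label, sample_label) {
  by_run <- function(lab) {
    rows <- sims[sims$estimand_label == lab, , drop = FALSE]
    if (nrow(rows) == 0)
      stop_config("sampling_bias: estimand '", lab, "' not found; ",
                  "declare both population- and sample-level inquiries")
    rows$estimand[!duplicated(rows$sim)][order(unique(rows$sim))]
  }
  pop <- by_run(population_label)
  sam <- by_run(sample_label)
  mean(pop - sam)
}

#' @rdname diagnosands
#' @export
type_s_rate <- function(sims, alpha = 0.05) {
  sig <- !is.na(sims$p_value) & sims$p_value <= alpha &
    !is.na(sims$estimate) & !is.na(sims$estimand)
  if (!any(sig)) return(with_undefined(NaN, nrow(sims)))
  wrong <- sign(sims$estimate[sig]) != sign(sims$estimand[sig])
  with_undefined(mean(wrong), sum(!sig))
}

#' @rdname diagnosands
#' @export
exaggeration_ratio <- function(sims, alpha = 0.05) {
  sig <- !is.na(sims$p_value) & sims$p_value <= alpha &
    !is.na(sims$estimate) & !is.na(sims$estimand)
  zero_and <- sig & sims$estimand == 0
  use <- sig & !zero_and
  if (!any(use)) return(with_undefined(NaN, nrow(sims)))
  with_undefined(mean(abs(sims$estimate[use]) / abs(sims$estimand[use])),
                 sum(!use))
}

#' @rdname diagnosands
#' @export
imbalance <- function(sims) mean(sims$estimate, na.rm = TRUE)

#' @rdname diagnosands
#' @param test_set estimator labels whose tests must all reject.
#' @export
robustness <- function(sims, test_set, alpha = 0.05) {
  missing_lab <- setdiff(test_set, unique(sims$estimator_label))
  if (length(missing_lab))
    stop_config("robustness: unknown estimator label(s) ",
                paste(missing_lab, collapse = ", "))
  rows <- sims[sims$estimator_label %in% test_set, , drop = FALSE]
  joint <- tapply(rows$p_value <= alpha, rows$sim, all)
  with_undefined(mean(joint, na.rm = TRUE), sum(is.na(joint)))
}

#' @rdname diagnosands
#' @param decision_rule function of the estimate returning `TRUE` to fund.
#' @param benefit_fn function of the estimand returning the net benefit.
#'   A benefit of exactly zero is counted as a correct decision either way
#'   (documented convention).
#' @export
value_for_money <- function(sims, decision_rule, benefit_fn) {
  if (missing(decision_rule) || missing(benefit_fn))
    stop_config("value_for_money: decision_rule and benefit_fn are required")
  fund <- vapply(sims$estimate, function(e) isTRUE(decision_rule(e)), logical(1))
  ben <- vapply(sims$estimand, benefit_fn, numeric(1))
  correct <- ifelse(ben == 0, TRUE, fund == (ben > 0))
  with_undefined(mean(correct, na.rm = TRUE), sum(is.na(correct)))
}

#' @rdname diagnosands
#' @export
posterior_shift <- function(sims) {
  if (is.null(sims$posterior_sd) || is.null(sims$prior_mean) ||
      is.null(sims$prior_sd) || all(is.na(sims$posterior_sd)))
    stop_config("posterior_shift: auxiliary posterior/prior columns missing")
  if (any(sims$prior_sd == 0, na.rm = TRUE))
    stop_config("posterior_shift: degenerate prior sd of 0")
  c(location_shift = mean(abs(sims$estimate - sims$prior_mean), na.rm = TRUE),
    scale_ratio = mean(sims$posterior_sd / sims$prior_sd, na.rm = TRUE))
}

# ---------------------------------------------------------------------------

#' Built-in diagnosand registry
#'
#' Returns the named list of diagnosand specifications selectable by name in
#' [diagnose_design()] and in run configurations. Each specification has a
#' summary function, a scope (`estimate`: per estimator-and-estimand group;
#' `estimand`: per estimand; `design`: across the whole table) and the
#' option names it accepts.
#'
#' @return named list of diagnosand specs.
#' @export
diagnosand_registry <- function() {
  spec <- function(fn, scope, opts = character(0))
    list(fn = fn, scope = scope, opts = opts)
  list(
    power = spec(power, "estimate", "alpha"),
    bias = spec(bias, "estimate"),
    rmse = spec(rmse, "estimate"),
    coverage = spec(coverage, "estimate"),
    sd_estimates = spec(sd_estimates, "estimate"),
    sd_estimands = spec(sd_estimands, "estimand"),
    mean_estimate = spec(mean_estimate, "estimate"),
    mean_estimand = spec(mean_estimand, "estimand"),
    mean_absolute_error = spec(mean_absolute_error, "estimate"),
    sampling_bias = spec(sampling_bias, "design",
                         c("population_label", "sample_label")),
    type_s_rate = spec(type_s_rate, "estimate", "alpha"),
    exaggeration_ratio = spec(exaggeration_ratio, "estimate", "alpha"),
    imbalance = spec(imbalance, "estimate"),
    robustness = spec(robustness, "design", c("test_set", "alpha")),
    value_for_money = spec(value_for_money, "estimate",
                           c("decision_rule", "benefit_fn")),
    posterior_location_shift = spec(function(sims, ...)
      posterior_shift(sims)[["location_shift"]], "estimate"),
    posterior_scale_ratio = spec(function(sims, ...)
      posterior_shift(sims)[["scale_ratio"]], "estimate")
  )
}

resolve_diagnosands <- function(diagnosands) {
  reg <- diagnosand_registry()
  out <- list()
  for (d in diagnosands) {
    if (is.character(d)) {
      if (!d %in% names(reg)) {
        near <- agrep(d, names(reg), max.distance = 2, value = TRUE)
        stop_config("unknown diagnosand '", d, "'",
                    if (length(near)) paste0("; did you mean '", near[1], "'?"))
      }
      out[[d]] <- reg[[d]]
    } else if (is.list(d) && !is.null(d$name) && is.function(d$fn)) {
      out[[d$name]] <- list(fn = d$fn, scope = d$scope %||% "estimate",
                            opts = d$opts %||% character(0))
    } else stop_config("diagnosands must be registry names or custom specs")
  }
  out
}

apply_diagnosand <- function(spec, sims, options) {
  args <- c(list(sims), options[intersect(names(options), spec$opts)])
  do.call(spec$fn, args)
}

group_slices <- function(sims, scope) {
  if (scope == "design") return(list(list(est = NA, and = NA, rows = sims)))
  if (scope == "estimand") {
    labs <- unique(sims$estimand_label[!is.na(sims$estimand_label)])
    return(lapply(labs, function(l) {
      rows <- sims[!is.na(sims$estimand_label) & sims$estimand_label == l, ,
                   drop = FALSE]
      rows <- rows[!duplicated(rows$sim), , drop = FALSE]
      list(est = NA, and = l, rows = rows)
    }))
  }
  keys <- unique(sims[!is.na(sims$estimator_label),
                      c("estimator_label", "estimand_label"), drop = FALSE])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- !is.na(sims$estimator_label) &
      sims$estimator_label == keys$estimator_label[i] &
      (is.na(keys$estimand_label[i]) & is.na(sims$estimand_label) |
         (!is.na(sims$estimand_label) &
            !is.na(keys$estimand_label[i]) &
            sims$estimand_label == keys$estimand_label[i]))
    list(est = keys$estimator_label[i], and = keys$estimand_label[i],
         rows = sims[sel, , drop = FALSE])
  })
}

#' Diagnose an existing simulation table
#'
#' Applies each requested diagnosand to its groups of the simulation table
#' and attaches bootstrap standard errors computed by resampling whole
#' simulation runs (the run, not the row, is the resampling unit) with
#' replacement `n_bootstrap` times. With `n_bootstrap = 0` the standard
#' error is reported as unavailable (`NA`).
#'
#' @param sims a simulation table from [simulate_design()].
#' @param diagnosands character vector of registry names (see
#'   [diagnosand_registry()]) or custom specs.
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed seed for the bootstrap resampling.
#' @param options named list of diagnosand options (e.g. `alpha`,
#'   `test_set`, `population_label`).
#' @return a `dd_diagnosis` data frame with columns `design`,
#'   `estimator_label`, `estimand_label`, `diagnosand`, `estimate`,
#'   `bootstrap_se`, `n_sims`, `n_bootstrap`, `n_undefined`.
#' @export
diagnose_simulations <- function(sims, diagnosands, n_bootstrap = 100,
                                 seed = 1L, options = list()) {
  specs <- resolve_diagnosands(diagnosands)
  sim_ids <- sort(unique(sims$sim))
  m <- length(sim_ids)

  boot_indices <- NULL
  if (n_bootstrap > 0) {
    set.seed(derive_seed(seed, 777001L))
    boot_indices <- lapply(seq_len(n_bootstrap), function(b)
      sample.int(m, m, replace = TRUE))
  }

  out <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    for (slice in group_slices(sims, spec$scope)) {
      value <- apply_diagnosand(spec, slice$rows, options)
      n_undef <- attr(value, "n_undefined") %||% 0L
      se <- NA_real_
      if (n_bootstrap > 0) {
        idx_map <- split(seq_len(nrow(slice$rows)),
                         factor(slice$rows$sim, levels = sim_ids))
        reps <- vapply(boot_indices, function(pos) {
          chosen <- idx_map[pos]
          take <- unlist(chosen, use.names = FALSE)
          boot_rows <- slice$rows[take, , drop = FALSE]
          # relabel runs so a run drawn twice counts twice in run-level
          # summaries
          boot_rows$sim <- rep(seq_along(pos), lengths(chosen))
          tryCatch(
            as.numeric(apply_diagnosand(spec, boot_rows, options))[1],
            error = function(e) NA_real_)
        }, numeric(1))
        se <- stats::sd(reps[is.finite(reps)])
      }
      out[[length(out) + 1]] <- data.frame(
        design = sims$design[1] %||% NA_character_,
        estimator_label = slice$est, estimand_label = slice$and,
        diagnosand = nm, estimate = as.numeric(value), bootstrap_se = se,
        n_sims = m, n_bootstrap = n_bootstrap,
        n_undefined = as.integer(n_undef), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("dd_diagnosis", "data.frame")
  res
}

#' Declare, simulate and diagnose in one call
#'
#' Simulates the design `m` times and summarizes the simulation table with
#' the requested diagnosands; see [diagnose_simulations()] for the
#' bootstrap.
#'
#' @inheritParams diagnose_simulations
#' @param design a `dd_design`.
#' @param m number of simulation runs (>= 2 for bootstrap standard errors).
#' @param seed master seed governing both the simulations and the
#'   bootstrap.
#' @return a `dd_diagnosis` data frame.
#' @examples
#' d <- make_design("table3_canonical")
#' diagnose_design(d, c("bias", "power"), m = 20, n_bootstrap = 20, seed = 4)
#' @export
diagnose_design <- function(design, diagnosands, m = 500, n_bootstrap = 100,
                            seed = 1L, options = list()) {
  if (n_bootstrap > 0 && m < 2)
    stop_declaration("m must be >= 2 for bootstrap standard errors")
  sims <- simulate_design(design, m, seed)
  diagnose_simulations(sims, diagnosands, n_bootstrap = n_bootstrap,
                       seed = seed, options = options)
}

# ---------------------------------------------------------------------------

swap_model <- function(design, model_steps, model_name) {
  is_model <- vapply(design$steps, function(s)
    s$stage %in% c("population", "potential_outcomes"), logical(1))
  steps <- c(model_steps, design$steps[!is_model])
  compose_design(steps, name = paste0(design$name, "@", model_name),
                 params = design$params)
}

#' Compare answer strategies across rival models
#'
#' Diagnoses each design under each claimed model (a bundle of population
#' and potential-outcome steps substituted for the design's own model
#' stages) and, for the two-design/two-model case, adjudicates between the
#' original (first) and alternative (second) answer strategy: "home ground
#' dominance" when the alternative beats the original under the original's
#' own model; "robustness" when the two tie under the original model but the
#' alternative wins under the alternative model; "model plausibility" when
#' each wins on its home ground (the verdict then rests on which model is
#' more credible); otherwise "none". Ties and wins are judged at three
#' combined bootstrap standard errors.
#'
#' @param designs named list of `dd_design` objects (the first is treated
#'   as the original answer strategy).
#' @param models named list of model bundles (lists of population /
#'   potential-outcome steps); `NULL` keeps each design's own model.
#' @param diagnosand single registry name used for the comparison.
#' @param m,seed,n_bootstrap,options as in [diagnose_design()].
#' @param better how values are ranked: `"smaller_abs"` (default; right for
#'   bias-like diagnosands), `"smaller"`, or `"larger"`.
#' @return list with `table` (one row per design-model cell) and `verdict`
#'   (`NULL` unless two designs and two models are supplied).
#' @export
compare_designs <- function(designs, models = NULL, diagnosand = "bias",
                            m = 500, seed = 1L, n_bootstrap = 100,
                            options = list(),
                            better = c("smaller_abs", "smaller", "larger")) {
  better <- match.arg(better)
  if (is.null(names(designs))) names(designs) <- vapply(designs, `[[`, character(1), "name")
  if (!is.null(models) && is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  cells <- list()
  for (dn in names(designs)) {
    model_set <- models %||% list(own = NULL)
    for (mn in names(model_set)) {
      d <- designs[[dn]]
      if (!is.null(model_set[[mn]])) d <- swap_model(d, model_set[[mn]], mn)
      diag <- diagnose_design(d, diagnosand, m = m, seed = seed,
                              n_bootstrap = n_bootstrap, options = options)
      diag$design <- dn
      diag$model <- mn
      cells[[length(cells) + 1]] <- diag
    }
  }
  table <- do.call(rbind, cells)
  verdict <- NULL
  if (length(designs) == 2 && !is.null(models) && length(models) == 2) {
    score <- function(dn, mn) {
      row <- table[table$design == dn & table$model == mn, , drop = FALSE][1, ]
      v <- switch(better, smaller_abs = abs(row$estimate),
                  smaller = row$estimate, larger = -row$estimate)
      list(v = v, se = row$bootstrap_se)
    }
    dns <- names(designs); mns <- names(models)
    s11 <- score(dns[1], mns[1]); s21 <- score(dns[2], mns[1])
    s12 <- score(dns[1], mns[2]); s22 <- score(dns[2], mns[2])
    tol1 <- 3 * sqrt(s11$se^2 + s21$se^2)
    tol2 <- 3 * sqrt(s12$se^2 + s22$se^2)
    verdict <- if (s21$v < s11$v - tol1) {
      "home_ground_dominance"
    } else if (abs(s21$v - s11$v) <= tol1 && s22$v < s12$v - tol2) {
      "robustness"
    } else if (s11$v < s21$v - tol1 && s22$v < s12$v - tol2) {
      "model_plausibility"
    } else "none"
  }
  list(table = table, verdict = verdict)
}
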