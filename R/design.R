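# The simulation engine: compose steps into a design, execute one run,
# simulate m runs into a simulation table.

#' Compose steps into a design
#'
#' A design is an ordered sequence of steps covering the model (population
#' and potential outcomes), the inquiry, the data strategy (sampling,
#' assignment, measurement, revelation) and the answer strategy
#' (estimators). Steps can also be chained with `+`. Column dependencies
#' between steps are checked at the first run.
#'
#' @param steps list of `dd_step` objects (or a single step).
#' @param name design name.
#' @param params optional named list of the parameters used to build the
#'   design (carried along for reporting).
#' @return an object of class `dd_design`.
#' @examples
#' d <- compose_design(list(
#'   declare_population(N = 10, u = ~ rnorm(N)),
#'   declare_inquiry("mean_u", expr = ~ mean(u))), name = "tiny")
#' @export
compose_design <- function(steps, name = "design", params = list()) {
  if (inherits(steps, "dd_step")) steps <- list(steps)
  if (length(steps) == 0) stop_declaration("a design needs at least one step")
  if (!all(vapply(steps, inherits, logical(1), "dd_step")))
    stop_declaration("all elements must be dd_step objects")
  labels <- vapply(steps, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop_declaration("duplicate step labels: ",
                     paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(steps = steps, name = name, params = params),
            class = "dd_design")
}

#' @export
`+.dd_step` <- function(e1, e2) {
  steps1 <- if (inherits(e1, "dd_design")) e1$steps else list(e1)
  steps2 <- if (inherits(e2, "dd_design")) e2$steps else list(e2)
  compose_design(c(steps1, steps2))
}

#' @export
`+.dd_design` <- `+.dd_step`

#' @export
print.dd_design <- function(x, ...) {
  cat("<design '", x$name, "' with ", length(x$steps), " steps>\n", sep = "")
  for (s in x$steps) cat("  - ", s$label, " [", s$stage, "]\n", sep = "")
  invisible(x)
}

#' Execute one simulation run of a design
#'
#' Runs the steps in declared order: data stages transform the prevailing
#' data table (population-level inquiries therefore see the full
#' potential-outcome table when declared before sampling and assignment),
#' inquiry steps append estimand rows, and estimator steps append estimate
#' rows computed on the revealed data visible at their position. The run is
#' deterministic given the design and seed. Estimator failures (e.g. a
#' singular regression) are recorded as rows with missing estimates and a
#' `failed` flag rather than aborting the run, so failure-rate diagnosands
#' remain computable.
#'
#' @param design a `dd_design`.
#' @param seed integer seed for the run.
#' @return a `dd_run_result`: list with data frames `estimands`
#'   (`inquiry_label`, `estimand`, `estimand_chr`) and `estimates`
#'   (estimator label, targeted estimand label, estimate, standard error,
#'   p-value, confidence bounds, and any auxiliary columns).
#' @export
run_once <- function(design, seed = 1L) {
  stopifnot(inherits(design, "dd_design"))
  set.seed(as.integer(seed))
  data <- data.frame()
  estimands <- list()
  estimates <- list()
  for (step in design$steps) {
    if (step$stage == "inquiry") {
      estimands[[length(estimands) + 1]] <- step$handler(data)
    } else if (step$stage == "estimator") {
      rows <- tryCatch(step$handler(data), error = function(e) {
        r <- estimate_row()
        r$estimator_label <- step$label
        r$estimand_label <- NA_character_
        r$failed <- conditionMessage(e)
        r
      })
      if (is.null(rows$failed)) rows$failed <- NA_character_
      estimates[[length(estimates) + 1]] <- rows
    } else {
      new_data <- step$handler(data)
      dropped <- setdiff(names(data), names(new_data))
      if (length(dropped))
        stop_run("step '", step$label, "' deleted column(s): ",
                 paste(dropped, collapse = ", "))
      data <- new_data
    }
  }
  structure(list(
    estimands = rbind_fill(estimands) %||% inquiry_row(character(0), numeric(0))[0, ],
    estimates = rbind_fill(estimates) %||% estimate_row()[0, ]),
    class = "dd_run_result")
}

#' Simulate a design m times
#'
#' Runs the design `m` times under per-run seeds derived from the master
#' seed by a counter, so any single run can be reproduced independently of
#' `m`. Estimate rows are joined with the estimand of the inquiry they
#' target; inquiries no estimator targets are appended as estimand-only
#' rows.
#'
#' @param design a `dd_design`.
#' @param m number of simulation runs (>= 1).
#' @param seed master seed.
#' @return a `dd_simulations` data frame with columns `design`, `sim`,
#'   `run_seed`, `estimator_label`, `estimand_label`, `estimand`,
#'   `estimate`, `std_error`, `p_value`, `ci_low`, `ci_high`, `df`, plus
#'   any auxiliary estimator columns.
#' @export
simulate_design <- function(design, m, seed = 1L) {
  if (!is_count(m) || m < 1) stop_declaration("m must be a positive count")
  runs <- vector("list", m)
  for (i in seq_len(m)) {
    run_seed <- derive_seed(seed, i)
    rr <- run_once(design, run_seed)
    est <- rr$estimates
    ands <- rr$estimands
    if (nrow(est) > 0) {
      idx <- match(est$estimand_label, ands$inquiry_label)
      est$estimand <- ands$estimand[idx]
      est$estimand_chr <- ands$estimand_chr[idx]
      untargeted <- ands[!ands$inquiry_label %in% est$estimand_label, , drop = FALSE]
    } else {
      untargeted <- ands
    }
    extra <- NULL
    if (nrow(untargeted) > 0) {
      extra <- estimate_row()[rep(1, nrow(untargeted)), , drop = FALSE]
      extra$estimator_label <- NA_character_
      extra$estimand_label <- untargeted$inquiry_label
      extra$estimand <- untargeted$estimand
      extra$estimand_chr <- untargeted$estimand_chr
      extra$failed <- NA_character_
    }
    out <- rbind_fill(list(est, extra))
    if (is.null(out)) next
    out$sim <- i
    out$run_seed <- run_seed
    runs[[i]] <- out
  }
  sims <- rbind_fill(runs)
  if (is.null(sims)) stop_run("design produced no estimands or estimates")
  sims$design <- design$name
  front <- c("design", "sim", "run_seed", "estimator_label", "estimand_label",
             "estimand", "estimate", "std_error", "p_value", "ci_low",
             "ci_high", "df")
  sims <- sims[c(intersect(front, names(sims)),
                 setdiff(names(sims), front))]
  class(sims) <- c("dd_simulations", "data.frame")
  sims
}
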