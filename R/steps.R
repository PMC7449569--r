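# Step primitives. A step couples a label, a stage, and a transform. Data
# stages (population, potential_outcomes, sampling, assignment, measurement,
# reveal) map a data table to a data table and may add columns (never delete
# any); inquiry and estimator stages emit result rows and leave the data
# untouched.

DD_STAGES <- c("population", "potential_outcomes", "inquiry", "sampling",
               "assignment", "measurement", "reveal", "estimator")

#' Construct a design step
#'
#' Low-level constructor behind the `declare_*` factories; useful for custom
#' steps. Data-stage handlers receive and return a data frame; inquiry
#' handlers return rows with `inquiry_label` and `estimand`; estimator
#' handlers return rows of estimate fields.
#'
#' @param label short unique step name.
#' @param stage one of `r paste(DD_STAGES, collapse = ", ")`.
#' @param handler the transform function (signature depends on the stage).
#' @return an object of class `dd_step`.
#' @export
new_step <- function(label, stage, handler) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label))
    stop_declaration("step label must be a non-empty string")
  if (!stage %in% DD_STAGES)
    stop_declaration("unknown stage '", stage, "'")
  stopifnot(is.function(handler))
  structure(list(label = label, stage = stage, handler = handler),
            class = "dd_step")
}

#' @export
print.dd_step <- function(x, ...) {
  cat("<step ", x$label, " [", x$stage, "]>\n", sep = "")
  invisible(x)
}

eval_generator <- function(spec, env, n) {
  if (inherits(spec, "formula")) {
    # lexical scope of the formula supplies functions and free parameters
    parent.env(env) <- environment(spec)
    val <- eval(spec[[length(spec)]], env)
  } else if (is.list(spec) && !is.null(spec$dist)) {
    parent.env(env) <- asNamespace("designdiag")
    val <- switch(spec$dist,
      normal = stats::rnorm(n, spec$mean %||% 0, spec$sd %||% 1),
      uniform = stats::runif(n, spec$lo %||% 0, spec$hi %||% 1),
      bernoulli = rbern(n, assert_prob(spec$p %||% 0.5, "bernoulli p")),
      expression = eval(parse(text = spec$expr), env),
      stop_declaration("unknown distribution '", spec$dist, "'"))
  } else if (is.numeric(spec) || is.character(spec)) {
    val <- spec
  } else {
    stop_declaration("unsupported generator specification")
  }
  if (length(val) == 1) val <- rep(val, n)
  if (length(val) != n)
    stop_declaration("generator produced ", length(val), " values for ", n, " units")
  val
}

#' Declare the background population of units
#'
#' Creates the model's units and exogenous variables. Generators run in
#' declared order, each seeing `N` and all previously generated columns, and
#' may be one-sided formulas (`u = ~ rnorm(N)`), distribution-specification
#' lists (`list(dist = "normal", mean = 0, sd = 1)`, also `uniform`,
#' `bernoulli`, and `expression`), or constants.
#'
#' @param N number of units (>= 1).
#' @param ... named generators, evaluated in order.
#' @param label step label.
#' @return a `dd_step` of stage `population`.
#' @examples
#' declare_population(N = 200, u = ~ rnorm(N))
#' @export
declare_population <- function(N, ..., label = "population") {
  if (!is_count(N) || N < 1) stop_declaration("N must be a positive count")
  gens <- list(...)
  if (length(gens) && (is.null(names(gens)) || any(!nzchar(names(gens)))))
    stop_declaration("population generators must be named")
  force(N)
  new_step(label, "population", function(data) {
    env <- new.env(parent = emptyenv())
    assign("N", N, envir = env)
    out <- data.frame(ID = seq_len(N))
    for (nm in names(gens)) {
      # each generator sees N and all earlier columns
      for (col in names(out)) assign(col, out[[col]], envir = env)
      out[[nm]] <- eval_generator(gens[[nm]], env, N)
    }
    out
  })
}

po_col_name <- function(outcome, vars, levels) {
  paste(c(outcome, as.vector(rbind(vars, as.character(levels)))), collapse = "_")
}

#' Declare potential outcomes
#'
#' Adds one potential-outcome column per condition, named
#' `outcome_variable_level` (for example `Y_Z_1`), or with every
#' variable-level pair concatenated for factorial condition sets
#' (`Y_Z1_0_Z2_1`). The supplied formula is evaluated once per condition
#' with the condition variable(s) set to that level for every unit.
#'
#' @param outcome outcome name.
#' @param formula one-sided formula over existing columns and the condition
#'   variable(s), e.g. `~ Z + u`.
#' @param conditions named list mapping each condition variable to its
#'   levels, e.g. `list(Z = c(0, 1))`.
#' @param label step label.
#' @return a `dd_step` of stage `potential_outcomes`.
#' @examples
#' declare_potential_outcomes("Y", ~ Z + u, conditions = list(Z = c(0, 1)))
#' @export
declare_potential_outcomes <- function(outcome, formula, conditions,
                                       label = paste0("po_", outcome)) {
  if (!is.list(conditions) || is.null(names(conditions)))
    stop_declaration("conditions must be a named list of level vectors")
  for (lv in conditions) if (length(lv) < 2 || anyDuplicated(lv))
    stop_declaration("each condition set needs >= 2 unique levels")
  grid <- expand.grid(conditions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  vars <- names(conditions)
  new_step(label, "potential_outcomes", function(data) {
    n <- nrow(data)
    for (r in seq_len(nrow(grid))) {
      col <- po_col_name(outcome, vars, unlist(grid[r, , drop = FALSE]))
      if (col %in% names(data))
        stop_declaration("potential-outcome column '", col, "' already exists")
      env <- list2env(as.list(data), parent = environment(formula))
      for (v in vars) assign(v, rep(grid[[v]][r], n), envir = env)
      val <- eval(formula[[length(formula)]], env, environment(formula))
      data[[col]] <- if (length(val) == 1) rep(val, n) else val
    }
    data
  })
}

inquiry_row <- function(label, value, value_chr = NA_character_) {
  fast_df(list(inquiry_label = label, estimand = as.numeric(value),
               estimand_chr = rep(value_chr, length.out = length(label))))
}

#' Declare an inquiry
#'
#' An inquiry summarizes the (potential-outcome) data available at its
#' position in the design into the estimand, the quantity the answer
#' strategy targets. Kinds:
#' \describe{
#'   \item{summary}{`expr` is a one-sided formula evaluated over the data
#'     (e.g. `~ mean(Y_Z_1 - Y_Z_0)` for the average treatment effect).}
#'   \item{cause_of_effects}{probability that the outcome would not have
#'     occurred absent the cause, among cases where the cause occurred and
#'     the outcome would occur under it:
#'     Pr(Y(0) = 0 | X = 1, Y(1) = 1). Needs `outcome`, `cause`.}
#'   \item{linear_projection}{slope of the weighted least-squares projection
#'     of the unit potential-outcome functions on the treatment grid; needs
#'     `po_fun(x, data)`, `grid`, and optional `density` weights.}
#'   \item{qca_configuration}{the generating sum-of-products expression
#'     (`truth`, a `dd_dnf`); stored in the `estimand_chr` field.}
#'   \item{rd_limit}{difference of the two conditional-expectation functions
#'     at the cutoff; needs `control_fun`, `treat_fun`, `cutoff`.}
#' }
#'
#' @param label inquiry label (becomes `estimand_label` in results).
#' @param kind one of the kinds above.
#' @param expr one-sided formula (for `kind = "summary"`).
#' @param ... kind-specific fields, see Details.
#' @return a `dd_step` of stage `inquiry`.
#' @export
declare_inquiry <- function(label, kind = "summary", expr = NULL, ...) {
  opts <- list(...)
  handler <- switch(kind,
    summary = {
      if (!inherits(expr, "formula")) stop_declaration("summary inquiry needs a formula")
      function(data) {
        env <- list2env(as.list(data), parent = environment(expr))
        val <- tryCatch(eval(expr[[length(expr)]], env),
                        error = function(e) stop_run(
                          "inquiry '", label, "': ", conditionMessage(e)))
        inquiry_row(label, val)
      }
    },
    cause_of_effects = {
      outcome <- opts$outcome; cause <- opts$cause
      function(data) {
        y1 <- data[[po_col_name(outcome, cause, 1)]]
        y0 <- data[[po_col_name(outcome, cause, 0)]]
        x <- data[[cause]]
        if (is.null(y1) || is.null(y0) || is.null(x))
          stop_run("inquiry '", label, "': required potential-outcome or cause column missing")
        sel <- x == 1 & y1 == 1
        inquiry_row(label, mean(y0[sel] == 0))
      }
    },
    linear_projection = {
      po_fun <- opts$po_fun; grid <- opts$grid
      density <- opts$density %||% rep(1 / length(grid), length(grid))
      function(data) {
        po <- vapply(grid, function(x) po_fun(x, data), numeric(nrow(data)))
        ab <- linear_projection_estimand(po, grid, density)
        inquiry_row(label, ab[["beta"]])
      }
    },
    qca_configuration = {
      truth <- opts$truth
      stopifnot(inherits(truth, "dd_dnf"))
      function(data) inquiry_row(label, NA_real_, render_dnf(truth))
    },
    rd_limit = {
      cutoff <- opts$cutoff; f0 <- opts$control_fun; f1 <- opts$treat_fun
      function(data) inquiry_row(label, f1(cutoff) - f0(cutoff))
    },
    stop_declaration("unknown inquiry kind '", kind, "'"))
  new_step(label, "inquiry", handler)
}

#' Linear-projection estimand
#'
#' The intercept and slope that minimize the density-weighted squared
#' deviation between the pooled unit potential outcomes and a line in the
#' treatment variable: the coefficient a least-squares regression would
#' target if every unit were observed at every treatment level with the
#' given frequency.
#'
#' @param po matrix of potential outcomes, units in rows, one column per
#'   grid point (or a vector for a single unit).
#' @param grid treatment levels (>= 3 points, more than one distinct value).
#' @param density non-negative weights over the grid; normalized internally.
#' @return named numeric vector `c(alpha, beta)`.
#' @export
linear_projection_estimand <- function(po, grid, density = NULL) {
  if (is.null(dim(po))) po <- matrix(po, nrow = 1)
  if (length(grid) < 3) stop_declaration("grid needs at least 3 points")
  if (length(unique(grid)) < 2) stop_declaration("degenerate grid: slope undefined")
  density <- density %||% rep(1, length(grid))
  if (any(density < 0) || sum(density) <= 0)
    stop_declaration("density must be non-negative with positive mass")
  w <- density / sum(density)
  xbar <- sum(w * grid)
  ybar_g <- colMeans(po)              # mean over units at each grid point
  ybar <- sum(w * ybar_g)
  beta <- sum(w * (grid - xbar) * (ybar_g - ybar)) / sum(w * (grid - xbar)^2)
  c(alpha = ybar - beta * xbar, beta = beta)
}

#' Declare a sampling step
#'
#' Draws the study sample. Simple random sampling keeps `n` of the rows;
#' stratified sampling keeps `n_per_stratum` within each level of the
#' stratifying column (every stratum is represented). A sampling indicator
#' column `S` is set to 1 on the retained rows; downstream steps see sampled
#' rows only.
#'
#' @param n sample size (simple sampling).
#' @param strata stratifying column name (stratified sampling).
#' @param n_per_stratum per-stratum sample size, recycled across strata.
#' @param label step label.
#' @return a `dd_step` of stage `sampling`.
#' @export
declare_sampling <- function(n = NULL, strata = NULL, n_per_stratum = NULL,
                             label = "sampling") {
  if (is.null(strata)) {
    if (!is_count(n) || n < 1) stop_declaration("n must be a positive count")
    new_step(label, "sampling", function(data) {
      if (n > nrow(data))
        stop_run("sampling: n = ", n, " exceeds the ", nrow(data), " available rows")
      keep <- sort(sample.int(nrow(data), n))
      out <- data[keep, , drop = FALSE]
      out$S <- 1L
      rownames(out) <- NULL
      out
    })
  } else {
    new_step(label, "sampling", function(data) {
      groups <- split(seq_len(nrow(data)), data[[strata]])
      sizes <- rep(n_per_stratum, length.out = length(groups))
      keep <- sort(unlist(Map(function(idx, k) {
        if (k > length(idx))
          stop_run("sampling: stratum smaller than requested n")
        idx[sample.int(length(idx), k)]
      }, groups, sizes), use.names = FALSE))
      out <- data[keep, , drop = FALSE]
      out$S <- 1L
      rownames(out) <- NULL
      out
    })
  }
}

# Complete allocation of n units across arms with target probabilities:
# floor(p * n) per arm, the remaining units assigned by a draw weighted by
# the fractional parts, then a random permutation over units.
complete_allocation <- function(n, probs) {
  base <- floor(probs * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- probs * n - base
    extra <- sample.int(length(probs), rem,
                        prob = if (sum(frac) > 0) frac else NULL)
    for (a in extra) base[a] <- base[a] + 1
  }
  sample(rep(seq_along(probs), base))
}

#' Declare a random-assignment step
#'
#' Adds the assignment column(s). Realized arm counts are the deterministic
#' floor allocation of probability times size, with remainders assigned by
#' draw, so "complete" randomization semantics hold for every scheme:
#' \describe{
#'   \item{complete}{`m` treated of the current rows (or `prob`); adds a
#'     binary column and a `<var>_prob` column of assignment probabilities.}
#'   \item{blocked}{per-block treatment probabilities `block_probs` (named
#'     by block level or in level order); complete assignment within block.}
#'   \item{clustered}{complete assignment of whole clusters; `m_clusters`
#'     or `prob` of the clusters treated.}
#'   \item{factorial}{two binary factors crossed, each of the four cells
#'     with probability 1/4 (or `cell_probs`).}
#'   \item{multi_arm}{one arm label per unit from `arms` with probabilities
#'     `probs` (summing to 1); also adds an indicator column per non-control
#'     arm when `indicators = TRUE`.}
#' }
#'
#' @param scheme assignment scheme, see above.
#' @param var assignment variable name (default `"Z"`).
#' @param m,prob,block_var,block_probs,cluster_var,m_clusters,vars,cell_probs,arms,probs,indicators
#'   scheme-specific parameters.
#' @param label step label.
#' @return a `dd_step` of stage `assignment`.
#' @export
declare_assignment <- function(scheme = c("complete", "blocked", "clustered",
                                          "factorial", "multi_arm"),
                               var = "Z", m = NULL, prob = NULL,
                               block_var = NULL, block_probs = NULL,
                               cluster_var = NULL, m_clusters = NULL,
                               vars = c("Z1", "Z2"), cell_probs = rep(0.25, 4),
                               arms = NULL, probs = NULL, indicators = TRUE,
                               label = "assignment") {
  scheme <- match.arg(scheme)
  if (!is.null(prob)) {
    assert_prob(prob, "assignment probability")
    if (prob <= 0 || prob >= 1)
      stop_declaration("assignment probability must be strictly inside (0, 1)")
  }
  if (!is.null(block_probs) && any(block_probs <= 0 | block_probs >= 1))
    stop_declaration("block probabilities must be strictly inside (0, 1)")
  handler <- switch(scheme,
    complete = function(data) {
      n <- nrow(data)
      p <- if (!is.null(m)) {
        if (m > n) stop_run("assignment: m exceeds sample size")
        m / n
      } else {
        assert_prob(prob, "assignment probability")
        if (prob <= 0 || prob >= 1) stop_declaration("probability must be inside (0, 1)")
        prob
      }
      z <- complete_allocation(n, c(1 - p, p)) - 1L
      data[[var]] <- z
      data[[paste0(var, "_prob")]] <- p
      data
    },
    blocked = function(data) {
      blocks <- data[[block_var]]
      if (is.null(blocks)) stop_run("assignment: block column '", block_var, "' missing")
      levels_b <- sort(unique(blocks))
      pb <- if (!is.null(names(block_probs))) block_probs[as.character(levels_b)]
            else rep(block_probs, length.out = length(levels_b))
      if (any(pb <= 0 | pb >= 1))
        stop_declaration("block probabilities must be inside (0, 1)")
      z <- integer(nrow(data))
      pcol <- numeric(nrow(data))
      for (i in seq_along(levels_b)) {
        idx <- which(blocks == levels_b[i])
        z[idx] <- complete_allocation(length(idx), c(1 - pb[i], pb[i])) - 1L
        pcol[idx] <- pb[i]
      }
      data[[var]] <- z
      data[[paste0(var, "_prob")]] <- pcol
      data
    },
    clustered = function(data) {
      cl <- data[[cluster_var]]
      if (is.null(cl)) stop_run("assignment: cluster column '", cluster_var, "' missing")
      ucl <- sort(unique(cl))
      p <- if (!is.null(m_clusters)) m_clusters / length(ucl) else prob %||% 0.5
      zc <- complete_allocation(length(ucl), c(1 - p, p)) - 1L
      data[[var]] <- zc[match(cl, ucl)]
      data[[paste0(var, "_prob")]] <- p
      data
    },
    factorial = function(data) {
      n <- nrow(data)
      cell <- complete_allocation(n, cell_probs)  # 1..4 = (00, 10, 01, 11)
      data[[vars[1]]] <- as.integer(cell %in% c(2L, 4L))
      data[[vars[2]]] <- as.integer(cell %in% c(3L, 4L))
      data
    },
    multi_arm = function(data) {
      if (abs(sum(probs) - 1) > 1e-9)
        stop_declaration("arm probabilities must sum to 1")
      n <- nrow(data)
      a <- complete_allocation(n, probs)
      data[[var]] <- arms[a]
      if (indicators) {
        for (k in seq_along(arms)[-1])
          data[[arms[k]]] <- as.integer(a == k)
      }
      data
    })
  new_step(label, "assignment", handler)
}

#' Declare a measurement step
#'
#' Maps a latent column into an observed one (suffix `_obs`), possibly with
#' error; the latent column is retained so estimands can still be computed
#' from it. `binary_flip` flips the latent binary value with probability
#' `rate`; `overreport` lets units with latent value 0 report 1 with
#' probability `rate`; `none` copies the column. If `dependence` names a
#' binary column, the error applies only where it equals 1.
#'
#' @param target latent column name.
#' @param kind one of `"binary_flip"`, `"overreport"`, `"none"`.
#' @param rate error probability in \[0, 1\].
#' @param dependence optional binary column gating the error.
#' @param label step label.
#' @return a `dd_step` of stage `measurement`.
#' @export
declare_measurement <- function(target, kind = c("binary_flip", "overreport", "none"),
                                rate = 0, dependence = NULL,
                                label = paste0("measure_", target)) {
  kind <- match.arg(kind)
  assert_prob(rate, "measurement error rate")
  new_step(label, "measurement", function(data) {
    latent <- data[[target]]
    if (is.null(latent)) stop_run("measurement: column '", target, "' missing")
    gate <- if (is.null(dependence)) rep(1L, nrow(data)) else data[[dependence]]
    obs <- switch(kind,
      none = latent,
      binary_flip = {
        flip <- rbern(nrow(data), rate) * gate
        as.integer(abs(latent - flip))
      },
      overreport = {
        up <- rbern(nrow(data), rate) * gate * (latent == 0)
        as.integer(pmax(latent, up))
      })
    data[[paste0(target, "_obs")]] <- obs
    data
  })
}

#' Declare outcome revelation
#'
#' Deterministically selects, for each unit, the potential-outcome column
#' matching its realized assignment, writing it to the outcome column. With
#' several assignment variables the full combination selects the column.
#'
#' @param outcome outcome name (potential-outcome columns must exist for
#'   every assigned condition).
#' @param assignment assignment variable name(s).
#' @param label step label.
#' @return a `dd_step` of stage `reveal`.
#' @export
declare_reveal <- function(outcome, assignment, label = paste0("reveal_", outcome)) {
  new_step(label, "reveal", function(data) {
    n <- nrow(data)
    cols <- rep(outcome, n)
    for (v in assignment)
      cols <- paste(cols, v, as.character(data[[v]]), sep = "_")
    missing_cols <- setdiff(unique(cols), names(data))
    if (length(missing_cols))
      stop_run("reveal: missing potential-outcome column(s) ",
               paste(missing_cols, collapse = ", "))
    out <- numeric(n)
    for (col in unique(cols)) {
      sel <- cols == col
      out[sel] <- data[[col]][sel]
    }
    data[[outcome]] <- out
    data
  })
}

#' Declare an estimator step
#'
#' Wraps an estimating function into a design step. The handler receives
#' the revealed data visible at the estimator's position and must return a
#' data frame of estimate fields (see [difference_in_means()] and friends);
#' the step attaches the estimator label and the targeted inquiry label.
#'
#' @param label estimator label.
#' @param handler function(data) returning estimate row(s).
#' @param inquiry label of the inquiry this estimator targets (optional).
#' @param subset optional one-sided formula; rows where it evaluates `TRUE`
#'   are kept before estimation.
#' @return a `dd_step` of stage `estimator`.
#' @export
declare_estimator <- function(label, handler, inquiry = NA_character_,
                              subset = NULL) {
  new_step(label, "estimator", function(data) {
    if (!is.null(subset)) {
      env <- list2env(as.list(data), parent = environment(subset))
      keep <- eval(subset[[length(subset)]], env)
      data <- data[keep, , drop = FALSE]
    }
    if (nrow(data) == 0) stop_run("estimator '", label, "': empty sample")
    rows <- handler(data)
    if (is.null(rows$estimator_label)) rows$estimator_label <- label
    if (is.null(rows$estimand_label)) rows$estimand_label <- inquiry
    rows
  })
}

#' @rdname declare_estimator
#' @param outcome,assignment,treat,control passed to [difference_in_means()].
#' @param alpha test level.
#' @export
declare_estimator_dim <- function(label, outcome, assignment, inquiry = NA_character_,
                                  treat = 1, control = 0, alpha = 0.05,
                                  subset = NULL) {
  declare_estimator(label, function(data)
    difference_in_means(data, outcome, assignment, treat, control, alpha),
    inquiry = inquiry, subset = subset)
}

#' @rdname declare_estimator
#' @param formula,target,weights,cluster passed to [ols_estimate()];
#'   `weights` may also be a function of the data returning a weight vector.
#' @export
declare_estimator_ols <- function(label, formula, target, inquiry = NA_character_,
                                  weights = NULL, cluster = NULL, alpha = 0.05,
                                  subset = NULL) {
  declare_estimator(label, function(data) {
    w <- if (is.function(weights)) weights(data) else weights
    ols_estimate(data, formula, target, weights = w, cluster = cluster,
                 alpha = alpha)
  }, inquiry = inquiry, subset = subset)
}
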