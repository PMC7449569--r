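#' Build a crisp-set truth table from case data
#'
#' Groups binary cases by their configuration of causes and computes, per
#' configuration, the number of cases, the number with the outcome present,
#' and the consistency (share of positive cases). A configuration is coded
#' positive when its consistency exceeds the threshold, negative otherwise;
#' configurations with no observed cases are coded as remainders (`NA`).
#'
#' @param data data frame with binary cause columns and a binary outcome.
#' @param causes character vector of cause column names.
#' @param outcome outcome column name.
#' @param threshold consistency above which a row is coded positive
#'   (default 0.5, mirroring a majority-vote inclusion rule).
#' @return a `dd_truth_table`: a data frame with one row per configuration
#'   (2^k rows), columns for each cause, `n_cases`, `n_positive`,
#'   `consistency` and `outcome_coded` (1, 0, or NA for remainder).
#' @export
build_truth_table <- function(data, causes, outcome, threshold = 0.5) {
  for (col in c(causes, outcome)) {
    v <- data[[col]]
    if (is.null(v)) stop_declaration("column '", col, "' not found in case data")
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% c(0L, 1L))) stop_declaration("column '", col, "' is not binary")
    data[[col]] <- as.integer(v)
  }
  grid <- all_configurations(causes)
  key <- function(d) do.call(paste, c(d[causes], sep = "."))
  data_key <- key(data)
  grid_key <- key(grid)
  grid$n_cases <- as.integer(table(factor(data_key, levels = grid_key)))
  pos <- tapply(data[[outcome]], factor(data_key, levels = grid_key), sum)
  grid$n_positive <- as.integer(ifelse(is.na(pos), 0L, pos))
  grid$consistency <- ifelse(grid$n_cases > 0, grid$n_positive / grid$n_cases, NA_real_)
  grid$outcome_coded <- ifelse(grid$n_cases == 0, NA_integer_,
                               as.integer(grid$consistency > threshold))
  structure(grid, class = c("dd_truth_table", "data.frame"), causes = causes)
}

#' Quine-McCluskey minimization of a truth table
#'
#' Computes the minimal sum-of-products expression covering the
#' positive-coded configurations. Prime implicants are found by iterative
#' pairwise merging of terms differing in a single literal; a minimal cover
#' of the positive configurations is then chosen exactly (smallest number of
#' implicants, ties broken by fewest literals, then lexicographically) by
#' exhaustive search over prime-implicant subsets, falling back to a greedy
#' set cover when the prime-implicant chart is very large.
#'
#' @param tt a `dd_truth_table` from [build_truth_table()], or a data frame
#'   with cause columns and an `outcome_coded` column.
#' @param remainder_policy how to treat configurations with no observed
#'   cases: `"exclude"` treats them as negative; `"dont_care"` lets them be
#'   absorbed into larger implicants without requiring coverage.
#' @return a `dd_dnf` expression; empty when no configuration is positive.
#' @export
qmc_minimize <- function(tt, remainder_policy = c("exclude", "dont_care")) {
  remainder_policy <- match.arg(remainder_policy)
  causes <- attr(tt, "causes")
  if (is.null(causes)) causes <- setdiff(
    names(tt), c("n_cases", "n_positive", "consistency", "outcome_coded"))
  conf <- as.matrix(tt[causes])
  storage.mode(conf) <- "integer"
  coded <- tt$outcome_coded
  pos <- which(!is.na(coded) & coded == 1L)
  if (length(pos) == 0) return(dnf(list(), causes))
  dc <- if (remainder_policy == "dont_care") which(is.na(coded)) else integer(0)

  terms <- lapply(c(pos, dc), function(i) conf[i, ])
  term_key <- function(t) paste(ifelse(is.na(t), "-", t), collapse = "")
  primes <- list()
  seen_prime <- character(0)
  while (length(terms) > 0) {
    keys <- vapply(terms, term_key, character(1))
    keep <- !duplicated(keys)
    terms <- terms[keep]; keys <- keys[keep]
    merged_flag <- logical(length(terms))
    nxt <- list()
    if (length(terms) > 1) {
      for (i in seq_len(length(terms) - 1)) {
        for (j in seq(i + 1, length(terms))) {
          a <- terms[[i]]; b <- terms[[j]]
          if (!identical(is.na(a), is.na(b))) next
          diff <- which(!is.na(a) & a != b)
          if (length(diff) == 1) {
            m <- a; m[diff] <- NA_integer_
            nxt[[length(nxt) + 1]] <- m
            merged_flag[i] <- TRUE; merged_flag[j] <- TRUE
          }
        }
      }
    }
    for (i in which(!merged_flag)) {
      if (!keys[i] %in% seen_prime) {
        primes[[length(primes) + 1]] <- terms[[i]]
        seen_prime <- c(seen_prime, keys[i])
      }
    }
    terms <- nxt
  }

  # coverage chart over positive configurations only
  covers <- function(imp, row) {
    fixed <- !is.na(imp)
    all(imp[fixed] == row[fixed])
  }
  chart <- vapply(primes, function(imp)
    vapply(pos, function(i) covers(imp, conf[i, ]), logical(1)),
    logical(length(pos)))
  chart <- matrix(chart, nrow = length(pos))

  n_lit <- vapply(primes, function(p) sum(!is.na(p)), integer(1))
  pick <- select_cover(chart, n_lit)
  out <- dnf(lapply(primes[pick], function(p) {
    v <- p[!is.na(p)]
    stats::setNames(v, causes[!is.na(p)])
  }), causes)
  out
}

# Exact minimal set cover for small charts, greedy otherwise. Columns are
# candidate implicants, rows the positive configurations to cover.
select_cover <- function(chart, n_lit) {
  np <- ncol(chart)
  if (np == 0) return(integer(0))
  # essential primes: sole coverers of some row
  essential <- integer(0)
  for (r in seq_len(nrow(chart))) {
    cv <- which(chart[r, ])
    if (length(cv) == 1) essential <- union(essential, cv)
  }
  covered <- if (length(essential))
    apply(chart[, essential, drop = FALSE], 1, any) else rep(FALSE, nrow(chart))
  remaining_rows <- which(!covered)
  if (length(remaining_rows) == 0) return(sort(essential))
  cand <- setdiff(seq_len(np), essential)
  sub <- chart[remaining_rows, cand, drop = FALSE]
  if (length(cand) <= 20) {
    for (k in seq_len(length(cand))) {
      combos <- utils::combn(seq_along(cand), k, simplify = FALSE)
      ok <- Filter(function(cs) all(apply(sub[, cs, drop = FALSE], 1, any)), combos)
      if (length(ok)) {
        lits <- vapply(ok, function(cs) sum(n_lit[cand[cs]]), numeric(1))
        best <- ok[[which.min(lits)]]
        return(sort(c(essential, cand[best])))
      }
    }
    return(sort(essential))
  }
  # greedy fallback for very large charts
  chosen <- integer(0)
  rows_left <- seq_len(nrow(sub))
  while (length(rows_left) > 0) {
    gain <- vapply(seq_along(cand), function(ci)
      sum(sub[rows_left, ci]), numeric(1))
    best <- which.max(gain)
    if (gain[best] == 0) break
    chosen <- c(chosen, cand[best])
    rows_left <- rows_left[!sub[rows_left, best]]
  }
  sort(c(essential, chosen))
}

#' QCA by saturated regression
#'
#' Fits a saturated least-squares model of the outcome on indicators for
#' every observed configuration of the causes (equivalently, the per-
#' configuration mean outcome), includes configurations whose predicted
#' probability of the outcome exceeds 0.5 in the positive set, and minimizes
#' that set with [qmc_minimize()]. Unobserved configurations are remainders.
#'
#' @inheritParams build_truth_table
#' @param remainder_policy passed to [qmc_minimize()].
#' @return a `dd_dnf` expression.
#' @export
regression_qca <- function(data, causes, outcome,
                           remainder_policy = c("exclude", "dont_care")) {
  remainder_policy <- match.arg(remainder_policy)
  for (col in c(causes, outcome)) {
    if (is.null(data[[col]])) stop_declaration("column '", col, "' not found")
    if (!all(data[[col]] %in% c(0, 1))) stop_declaration("column '", col, "' is not binary")
  }
  cfg <- factor(do.call(paste, c(data[causes], sep = ".")))
  fit <- stats::lm(data[[outcome]] ~ 0 + cfg)
  pred <- stats::coef(fit)
  names(pred) <- sub("^cfg", "", names(pred))
  grid <- all_configurations(causes)
  grid_key <- do.call(paste, c(grid[causes], sep = "."))
  grid$outcome_coded <- ifelse(grid_key %in% names(pred),
                               as.integer(pred[grid_key] > 0.5), NA_integer_)
  tt <- structure(grid, class = c("dd_truth_table", "data.frame"), causes = causes)
  qmc_minimize(tt, remainder_policy)
}
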