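#' Sum-of-products expressions over binary causes
#'
#' A DNF (disjunctive normal form) expression is a set of implicants over a
#' fixed universe of binary causes. Each implicant fixes some causes to 1
#' ("must be present"), some to 0 ("must be absent") and leaves the rest
#' free. The expression is true for a case when at least one implicant is
#' satisfied. These objects carry crisp-set QCA estimands and answers.
#'
#' Implicants are stored as named integer vectors with values `1`, `0` or
#' `NA` (free). Construction canonicalizes: duplicate implicants are merged,
#' implicants subsumed by a more general one are dropped, and implicants are
#' sorted by their rendered form, so two semantically-identical construction
#' orders yield identical objects.
#'
#' @param implicants list of named vectors with values 0, 1 or NA, named by
#'   cause. Partial naming is allowed; unnamed causes are free.
#' @param causes character vector naming the cause universe.
#' @return an object of class `dd_dnf`.
#' @examples
#' dnf(list(c(A = 1, B = 1), c(C = 1)), causes = c("A", "B", "C"))
#' @export
dnf <- function(implicants, causes) {
  if (length(causes) < 1) stop_declaration("DNF needs at least one cause")
  imps <- lapply(implicants, function(imp) {
    full <- rep(NA_integer_, length(causes))
    names(full) <- causes
    if (length(imp)) {
      if (is.null(names(imp)) || any(!names(imp) %in% causes))
        stop_declaration("implicant names must be a subset of the causes")
      full[names(imp)] <- as.integer(imp)
    }
    full
  })
  out <- structure(list(implicants = imps, causes = causes), class = "dd_dnf")
  canonicalize_dnf(out)
}

canonicalize_dnf <- function(x) {
  imps <- x$implicants
  if (length(imps) > 1) {
    # drop implicants subsumed by a more general one (general = fewer fixed
    # literals, agreeing on every literal it fixes)
    subsumed <- vapply(seq_along(imps), function(i) {
      any(vapply(seq_along(imps), function(j) {
        if (i == j) return(FALSE)
        a <- imps[[i]]; b <- imps[[j]]
        fixed_b <- !is.na(b)
        all(!is.na(a[fixed_b]) & a[fixed_b] == b[fixed_b]) &&
          (sum(fixed_b) < sum(!is.na(a)) || j < i)
      }, logical(1)))
    }, logical(1))
    imps <- imps[!subsumed]
  }
  keys <- vapply(imps, function(imp) paste(ifelse(is.na(imp), "-", imp), collapse = ""),
                 character(1))
  imps <- imps[order(keys)]
  x$implicants <- imps
  x
}

#' @export
format.dd_dnf <- function(x, ...) render_dnf(x)

#' @export
print.dd_dnf <- function(x, ...) {
  cat("<DNF over ", paste(x$causes, collapse = ", "), ">: ",
      render_dnf(x), "\n", sep = "")
  invisible(x)
}

#' Render a DNF expression as text
#'
#' Single-letter causes use case to encode presence/absence (`A` present,
#' `a` absent); multi-letter causes use `name` / `~name` joined by `*`.
#' Implicants are joined by `" + "`. The empty expression renders as `"0"`
#' and the tautology (one all-free implicant) as `"1"`.
#'
#' @param x a `dd_dnf` object.
#' @return character scalar.
#' @export
render_dnf <- function(x) {
  stopifnot(inherits(x, "dd_dnf"))
  if (length(x$implicants) == 0) return("0")
  single <- all(nchar(x$causes) == 1)
  terms <- vapply(x$implicants, function(imp) {
    fixed <- which(!is.na(imp))
    if (length(fixed) == 0) return("1")
    lits <- vapply(fixed, function(i) {
      nm <- names(imp)[i]
      if (single) {
        if (imp[i] == 1) toupper(nm) else tolower(nm)
      } else {
        if (imp[i] == 1) nm else paste0("~", nm)
      }
    }, character(1))
    paste(lits, collapse = if (single) "" else "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

#' Parse a DNF expression from text
#'
#' Inverse of [render_dnf()]: terms separated by `+`, literals either
#' case-coded single letters (`aB` means A absent and B present) or
#' `name`/`~name` separated by `*`.
#'
#' @param text character scalar.
#' @param causes cause universe (upper-case names for case-coded input).
#' @return a `dd_dnf` object.
#' @export
parse_dnf <- function(text, causes) {
  text <- gsub("[[:space:]]", "", text)
  if (text == "" || text == "0") return(dnf(list(), causes))
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  single <- all(nchar(causes) == 1)
  imps <- lapply(terms, function(term) {
    if (term == "1") return(integer(0))
    term <- gsub("·", "*", term)
    vals <- integer(0)
    if (single && !grepl("*", term, fixed = TRUE) && !grepl("~", term, fixed = TRUE)) {
      chars <- strsplit(term, "")[[1]]
      for (ch in chars) {
        nm <- toupper(ch)
        if (!nm %in% causes) stop_declaration("unknown cause '", ch, "' in '", text, "'")
        vals[nm] <- if (ch == nm) 1L else 0L
      }
    } else {
      for (lit in strsplit(term, "*", fixed = TRUE)[[1]]) {
        neg <- grepl("^~", lit)
        nm <- sub("^~", "", lit)
        if (!nm %in% causes) {
          if (toupper(nm) %in% causes) { neg <- TRUE; nm <- toupper(nm) }
          else stop_declaration("unknown cause '", nm, "' in '", text, "'")
        }
        vals[nm] <- if (neg) 0L else 1L
      }
    }
    vals
  })
  dnf(imps, causes)
}

#' Evaluate a DNF expression on case data
#'
#' @param x a `dd_dnf` object.
#' @param data data frame or named list with one binary column per cause.
#' @return integer vector of 0/1 outcomes, one per row.
#' @export
eval_dnf <- function(x, data) {
  stopifnot(inherits(x, "dd_dnf"))
  n <- length(data[[x$causes[1]]])
  if (length(x$implicants) == 0) return(rep(0L, n))
  hit <- rep(FALSE, n)
  for (imp in x$implicants) {
    ok <- rep(TRUE, n)
    for (nm in names(imp)[!is.na(imp)]) {
      ok <- ok & (data[[nm]] == imp[[nm]])
    }
    hit <- hit | ok
  }
  as.integer(hit)
}

all_configurations <- function(causes) {
  grid <- expand.grid(rep(list(c(0L, 1L)), length(causes)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- causes
  grid[do.call(order, grid), , drop = FALSE]
}

#' Semantic equality of two DNF expressions
#'
#' Compares the full truth-table expansions over the shared cause universe,
#' so syntactically different but logically equivalent expressions compare
#' equal.
#'
#' @param e1,e2 `dd_dnf` objects over the same causes.
#' @return logical scalar.
#' @export
expression_equal <- function(e1, e2) {
  stopifnot(inherits(e1, "dd_dnf"), inherits(e2, "dd_dnf"))
  if (!identical(sort(e1$causes), sort(e2$causes)))
    stop_declaration("expressions are defined over different cause sets")
  grid <- all_configurations(e1$causes)
  identical(eval_dnf(e1, grid), eval_dnf(e2, grid))
}

#' Expected marginal effect of one cause in a Boolean outcome function
#'
#' For an outcome generated by a sum-of-products expression, the marginal
#' effect of a target cause in a given context of the other causes is the
#' difference in outcomes with the target switched on versus off. The
#' expectation is taken over the distribution of contexts; for example with
#' `Y = AB + C` the effect of `A` is the probability that `B` is present and
#' `C` absent, the only context where `A` is difference-making (an INUS
#' condition).
#'
#' @param x a `dd_dnf` object.
#' @param target cause whose effect is computed.
#' @param context_probs optional named vector of marginal probabilities for
#'   the other causes (independent); defaults to 1/2 each.
#' @return numeric scalar expected effect.
#' @export
inus_marginal_effect <- function(x, target, context_probs = NULL) {
  stopifnot(inherits(x, "dd_dnf"))
  if (!target %in% x$causes) stop_declaration("unknown target cause '", target, "'")
  others <- setdiff(x$causes, target)
  if (length(others) == 0) {
    d1 <- eval_dnf(x, stats::setNames(data.frame(1L), target))
    d0 <- eval_dnf(x, stats::setNames(data.frame(0L), target))
    return(as.numeric(d1 - d0))
  }
  grid <- all_configurations(others)
  p <- rep(1, nrow(grid))
  for (nm in others) {
    pn <- if (!is.null(context_probs) && nm %in% names(context_probs))
      context_probs[[nm]] else 0.5
    p <- p * ifelse(grid[[nm]] == 1L, pn, 1 - pn)
  }
  g1 <- grid; g1[[target]] <- 1L
  g0 <- grid; g0[[target]] <- 0L
  sum(p * (eval_dnf(x, g1) - eval_dnf(x, g0)))
}
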