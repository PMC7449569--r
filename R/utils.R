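# Internal helpers shared across modules.

# rbind data frames with differing columns; missing columns filled with NA.
rbind_fill <- function(dfs) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, dfs)
  if (length(dfs) == 0) return(NULL)
  if (length(dfs) == 1) return(dfs[[1]])
  all_cols <- unique(unlist(lapply(dfs, names)))
  out <- lapply(dfs, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
    d[all_cols]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Deterministic substream seed derivation: master seed plus counter, folded
# into the 31-bit range accepted by set.seed(). Runs are reproducible
# individually, independent of how many runs precede them.
derive_seed <- function(master, counter) {
  m <- 2147483629
  s <- (as.double(master) %% m) * 48271 + as.double(counter) * 10007
  as.integer(s %% m) + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_declaration <- function(...) {
  stop(structure(class = c("dd_declaration_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_run <- function(...) {
  stop(structure(class = c("dd_run_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("dd_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Bernoulli draws.
rbern <- function(n, prob) stats::rbinom(n, 1L, prob)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_declaration(what, " must lie in [0, 1]")
  invisible(x)
}
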