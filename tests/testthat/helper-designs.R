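# Shared fixtures, generated in code.

# Tiny two-arm experiment with deterministic unit effect; N units, n treated.
tiny_experiment <- function(N = 6, m_treated = 3, tau = 1) {
  compose_design(list(
    declare_population(N = N, u = ~ rnorm(N)),
    declare_potential_outcomes("Y", ~ tau * Z + u, conditions = list(Z = c(0, 1))),
    declare_inquiry("ATE", expr = ~ mean(Y_Z_1 - Y_Z_0)),
    declare_assignment("complete", m = m_treated),
    declare_reveal("Y", "Z"),
    declare_estimator_dim("DIM", "Y", "Z", inquiry = "ATE")
  ), name = "tiny")
}

# Exact expectation of the difference-in-means over all complete assignments
# of m treated among the rows of `data` (enumeration oracle).
enumerate_dim_expectation <- function(y1, y0, m_treated) {
  n <- length(y1)
  combos <- utils::combn(n, m_treated, simplify = FALSE)
  mean(vapply(combos, function(tr) {
    mean(y1[tr]) - mean(y0[setdiff(seq_len(n), tr)])
  }, numeric(1)))
}

# All 2^(2^k) outcome labelings of a k-cause truth table as a matrix of 0/1
# rows (k = 2 only; larger k sampled by callers).
all_labelings <- function(k) {
  n_conf <- 2^k
  labs <- expand.grid(rep(list(0:1), n_conf), KEEP.OUT.ATTRS = FALSE)
  as.matrix(labs)
}

# Truth table object from an explicit labeling of all configurations.
tt_from_labeling <- function(labeling, causes) {
  grid <- expand.grid(rep(list(c(0L, 1L)), length(causes)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- causes
  grid <- grid[do.call(order, grid), , drop = FALSE]
  grid$n_cases <- 1L
  grid$n_positive <- as.integer(labeling)
  grid$consistency <- as.numeric(labeling)
  grid$outcome_coded <- as.integer(labeling)
  structure(grid, class = c("dd_truth_table", "data.frame"), causes = causes)
}
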