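# Independent oracles used across the suite. Each is a deliberately naive
# brute-force or closed-form computation, kept independent of the package
# code paths it checks.

# Optimal 1-D k-clustering by exhaustive enumeration of all contiguous
# partitions of the sorted values. Returns the minimal total within-cluster
# sum of squares. Feasible for n <= ~15.
oracle_kmeans_1d_wss <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  best <- Inf
  # boundaries: choose k-1 cut points among the n-1 gaps
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ss(xs[(b[i] + 1):b[i + 1]])
    if (tot < best) best <- tot
  }
  best
}

# Spearman correlation by explicit rank-then-Pearson computation
# (tie-corrected through midranks), complete pairs only.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Box-Cox profile log-likelihood scanned on a dense lambda grid,
# written from the closed form for an intercept-only model.
oracle_boxcox_lambda <- function(x, grid = seq(-2, 2, by = 0.001)) {
  n <- length(x)
  ll <- vapply(grid, function(l) {
    y <- if (l == 0) log(x) else (x^l - 1) / l
    -n / 2 * log(sum((y - mean(y))^2) / n) + (l - 1) * sum(log(x))
  }, 0)
  grid[which.max(ll)]
}

# Small helper: a parameter table built directly from a matrix.
make_table <- function(values, group = NULL, model = NULL) {
  n <- nrow(values)
  parameter_table(values,
                  animal_id = sprintf("R%02d", seq_len(n)),
                  group = group %||% rep("naive", n),
                  model = model %||% rep("kindling", n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
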