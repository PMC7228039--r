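#' Clustering configuration for severity-level estimation
#'
#' @param k Number of severity clusters (default 3: three levels are
#'   sufficient for a meaningful severity scale; more elaborate gradings
#'   simply use a larger `k`).
#' @param n_runs Number of resampled clustering runs (default 100).
#' @param train_fraction Training fraction per run (default 0.80). Set
#'   `use_full_data = TRUE` to cluster the full population every run
#'   instead.
#' @param seed Integer master seed.
#' @param n_init k-means++ restarts per run (default 10).
#' @param use_full_data Fit each run on all animals rather than an 80%
#'   subsample (off by default).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(k = 3L, n_runs = 100L, train_fraction = 0.80,
                           seed = 1L, n_init = 10L, use_full_data = FALSE) {
  if (k < 2L) cms_stop("k must be >= 2")
  if (n_runs < 1L) cms_stop("n_runs must be >= 1")
  if (!(train_fraction > 0 && train_fraction <= 1))
    cms_stop("train_fraction must be in (0, 1]")
  structure(list(k = as.integer(k), n_runs = as.integer(n_runs),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 n_init = as.integer(n_init),
                 use_full_data = isTRUE(use_full_data)),
            class = "cluster_config")
}

# Lloyd iterations from given centers; x is the data vector.
lloyd_1d <- function(x, centers, max_iter = 100L) {
  k <- length(centers)
  assign_old <- integer(length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    assignment <- max.col(-d, ties.method = "first")
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (j in seq_len(k)) {
      pts <- x[assignment == j]
      if (length(pts)) {
        centers[j] <- mean(pts)
      } else {
        # re-seed an empty cluster at the point farthest from its center
        far <- which.max(d[cbind(seq_along(x), assignment)])
        centers[j] <- x[far]
        assignment[far] <- j
        assign_old <- integer(length(x))
      }
    }
  }
  wss <- sum((x - centers[assignment])^2)
  list(centers = centers, assignment = assignment, wss = wss)
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding).
kmeanspp_init <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(outer(x, centers[seq_len(j - 1L)], "-")^2, 1, min)
    if (sum(d2) == 0) {
      centers[j] <- x[sample.int(length(x), 1L)]
    } else {
      centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
    }
  }
  centers
}

# Exact optimal contiguous k-partition of 1-D data by dynamic programming
# (O(k n^2) with prefix sums). Returns assignment in sorted order.
dp_optimal_1d <- function(xs, k) {
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  ss <- function(i, j) {   # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- ss(1, j)
  if (k > 1) for (m in 2:k) {
    for (j in m:n) {
      costs <- vapply(m:j, function(i) D[m - 1, i - 1] + ss(i, j), 0)
      best <- which.min(costs)
      D[m, j] <- costs[best]
      B[m, j] <- (m:j)[best]
    }
  }
  assignment <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    assignment[i:j] <- m
    j <- i - 1L
  }
  list(assignment = assignment, wss = D[k, n])
}

#' One-dimensional k-means clustering
#'
#' Lloyd iterations with k-means++ seeding, best of `n_init` restarts by
#' within-cluster sum of squares, followed by an exact dynamic-programming
#' pass over contiguous partitions of the sorted scores — for 1-D data the
#' optimal k-means partition is contiguous, so the DP certifies (and, on
#' the rare restart that stalls in a local optimum, restores) the global
#' within-cluster sum-of-squares optimum. Clusters are relabeled so
#' centroids are in ascending order. Uses the current RNG state; seed the
#' generator before calling for reproducibility.
#'
#' @param scores Numeric vector with at least `k` distinct values.
#' @param k Number of clusters.
#' @param n_init Number of restarts (default 10).
#' @return A list with `centers` (ascending), `cluster` (index into the
#'   ascending centers, per point) and `wss` (total within-cluster sum of
#'   squares of the best restart).
#' @export
kmeans_1d <- function(scores, k, n_init = 10L) {
  if (anyNA(scores)) cms_stop("scores must be finite and non-missing")
  if (length(unique(scores)) < k)
    cms_stop("fewer distinct score values (", length(unique(scores)),
             ") than clusters (", k, ")")
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd_1d(scores, kmeanspp_init(scores, k))
    if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
  }
  ord <- order(best$centers)
  relabel <- match(seq_along(ord), ord)
  cluster <- relabel[best$assignment]
  wss <- best$wss
  # certify global optimality against the exact contiguous-partition DP
  sort_ord <- order(scores)
  dp <- dp_optimal_1d(scores[sort_ord], k)
  if (dp$wss < wss - 1e-9 * max(1, wss)) {
    cluster <- integer(length(scores))
    cluster[sort_ord] <- dp$assignment
    wss <- dp$wss
  }
  centers <- vapply(seq_len(k), function(j) mean(scores[cluster == j]), 0)
  list(centers = centers, cluster = cluster, wss = wss)
}

#' Severity thresholds from a 1-D clustering
#'
#' The threshold between two adjacent clusters is the midpoint of the two
#' "outer values" flanking the boundary: the maximum score of the lower
#' cluster and the minimum score of the upper cluster.
#'
#' @param scores Numeric vector.
#' @param cluster Cluster indices ordered by ascending centroid (as
#'   returned by [kmeans_1d()]).
#' @return Numeric vector of `k - 1` strictly non-decreasing thresholds,
#'   ascending on the composite-score scale (worst-severity boundary
#'   first).
#' @export
extract_thresholds <- function(scores, cluster) {
  k <- max(cluster)
  vapply(seq_len(k - 1L), function(j) {
    (max(scores[cluster == j]) + min(scores[cluster == j + 1L])) / 2
  }, 0)
}

#' Aggregate per-run thresholds into means and confidence borders
#'
#' Per boundary: the mean across runs and distribution-free percentile
#' (2.5th, 97.5th) 95% confidence borders. Wide borders flag variance
#' instability of the clustering under random subsampling. Per-run values
#' are retained for audit.
#'
#' @param run_thresholds Matrix (runs x boundaries) of per-run thresholds.
#' @param k Number of clusters the thresholds separate (default: number of
#'   boundaries + 1).
#' @return An object of class `threshold_set`: data frame `thresholds`
#'   with columns `boundary` (labeled worst-to-best, e.g. `"3_to_2"`),
#'   `mean`, `ci_low`, `ci_high`, plus `per_run` (the input matrix) and
#'   `k`.
#' @export
aggregate_thresholds <- function(run_thresholds, k = ncol(run_thresholds) + 1L) {
  run_thresholds <- as.matrix(run_thresholds)
  if (nrow(run_thresholds) < 1L) cms_stop("no runs to aggregate")
  m <- colMeans(run_thresholds)
  ci <- apply(run_thresholds, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  lab <- paste0(seq(k, 2L), "_to_", seq(k - 1L, 1L))
  df <- data.frame(boundary = lab, mean = m, ci_low = ci[1, ], ci_high = ci[2, ],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(thresholds = df, per_run = run_thresholds, k = k),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Severity thresholds (composite-score scale, worst to best):\n")
  for (i in seq_len(nrow(x$thresholds)))
    cat(sprintf("  threshold %s: %.2f (95%% CI: %.2f to %.2f)\n",
                sub("_to_", " to ", x$thresholds$boundary[i]),
                x$thresholds$mean[i], x$thresholds$ci_low[i],
                x$thresholds$ci_high[i]))
  invisible(x)
}

#' Assign severity levels from thresholds
#'
#' Level `k` (worst) is the cluster with the lowest composite scores (a
#' low composite denotes high severity); level 1 is the best. A score
#' below the lowest threshold maps to level `k`; a score at or above the
#' highest threshold maps to level 1; a score exactly on a boundary is
#' assigned to the LESS severe side (conservative against over-reporting
#' severity).
#'
#' @param scores A `composite_scores` data frame or a bare numeric vector.
#' @param thresholds A `threshold_set`, or a strictly increasing numeric
#'   vector of boundary values (ascending, worst boundary first).
#' @param membership Optional per-run membership matrix (animals x runs)
#'   from [run_severity_clustering()], used to report the stability of
#'   each assignment.
#' @return A data frame with `animal_id` (when available),
#'   `severity_level` (integer, 1 = best, k = worst) and
#'   `membership_stability` (fraction of runs agreeing with the modal
#'   per-run level; `NA` without membership history).
#' @export
assign_severity <- function(scores, thresholds, membership = NULL) {
  thr <- if (inherits(thresholds, "threshold_set"))
    thresholds$thresholds$mean else as.numeric(thresholds)
  if (is.unsorted(thr, strictly = TRUE))
    cms_stop("thresholds must be strictly increasing")
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  k <- length(thr) + 1L
  level <- k - findInterval(s, thr)   # score >= boundary -> less severe side
  stab <- rep(NA_real_, length(s))
  if (!is.null(membership)) {
    stab <- apply(membership, 1, function(row) {
      tab <- table(row)
      max(tab) / length(row)
    })
  }
  out <- data.frame(animal_id = if (is.data.frame(scores)) scores$animal_id
                    else paste0("obs", seq_along(s)),
                    score = s, severity_level = as.integer(level),
                    membership_stability = stab, stringsAsFactors = FALSE)
  class(out) <- c("severity_assignment", "data.frame")
  out
}

#' Repeated resampled k-means severity clustering
#'
#' Per run: draw a training subsample of the composite scores (same RNG
#' contract as the selection stage), fit a seeded 1-D k-means on the
#' training scores, extract the boundary thresholds, and assign ALL
#' animals (training and held-out) to severity levels by those
#' thresholds — so every animal has a membership in every run. Thresholds
#' are aggregated into means with 95% percentile confidence borders.
#'
#' @param scores A `composite_scores` data frame (or numeric vector).
#' @param config A [cluster_config()].
#' @return An object of class `severity_model`: `thresholds` (a
#'   `threshold_set`), `membership` (animals x runs matrix of levels),
#'   `assignments` (per-animal modal level with stability, via
#'   [assign_severity()] on the mean thresholds), and `runs` (per-run
#'   training indices, centers, thresholds and training memberships).
#' @export
run_severity_clustering <- function(scores, config = cluster_config()) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (anyNA(s) || any(!is.finite(s))) cms_stop("composite scores must be finite")
  n <- length(s)
  rc <- resample_config(n_runs = config$n_runs,
                        train_fraction = min(config$train_fraction, 0.999999),
                        seed = config$seed)
  thr_runs <- matrix(NA_real_, config$n_runs, config$k - 1L)
  membership <- matrix(NA_integer_, n, config$n_runs)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    train <- if (config$use_full_data) seq_len(n)
             else draw_subsample(n, rc, r)$train
    set.seed(derive_seed(config$seed, "cluster", r))
    km <- kmeans_1d(s[train], config$k, n_init = config$n_init)
    thr <- extract_thresholds(s[train], km$cluster)
    thr_runs[r, ] <- thr
    membership[, r] <- config$k - findInterval(s, thr)
    runs[[r]] <- list(train = train, centers = km$centers, thresholds = thr,
                      train_cluster = km$cluster, wss = km$wss)
  }
  ts <- aggregate_thresholds(thr_runs, k = config$k)
  assignments <- assign_severity(scores, ts, membership = membership)
  structure(list(thresholds = ts, membership = membership,
                 assignments = assignments, runs = runs, config = config),
            class = "severity_model")
}

#' @export
print.severity_model <- function(x, ...) {
  cat("Severity model: k =", x$config$k, "clusters,", x$config$n_runs,
      "resampled runs\n")
  print(x$thresholds)
  tab <- table(factor(x$assignments$severity_level, levels = seq_len(x$config$k)))
  cat("  animals per level (1 = best ...", x$config$k, "= worst):",
      paste(sprintf("L%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Per-group severity-level distributions across runs
#'
#' For every (model, group, level) combination: the mean percentage of
#' that group's animals assigned that level across runs, and the SD of
#' that percentage — the run-to-run spread that quantifies how stable the
#' per-group severity picture is under resampling.
#'
#' @param membership Animals x runs matrix of severity levels (from
#'   [run_severity_clustering()]).
#' @param model,group Per-animal labels.
#' @param k Number of levels (default: maximum observed level).
#' @return A data frame with columns `model`, `group`, `severity_level`,
#'   `mean_pct`, `sd_pct`; within each (model, group) the mean percentages
#'   sum to 100.
#' @export
group_distribution <- function(membership, model, group,
                               k = max(membership)) {
  membership <- as.matrix(membership)
  stopifnot(nrow(membership) == length(model), length(model) == length(group))
  cells <- unique(data.frame(model = model, group = group,
                             stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- model == cells$model[i] & group == cells$group[i]
    sub <- membership[sel, , drop = FALSE]
    for (lev in seq_len(k)) {
      pct <- 100 * colMeans(sub == lev)   # per-run percentage at this level
      out[[length(out) + 1L]] <- data.frame(
        model = cells$model[i], group = cells$group[i], severity_level = lev,
        mean_pct = mean(pct),
        sd_pct = if (length(pct) > 1L) stats::sd(pct) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
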