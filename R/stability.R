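#' Resampling configuration
#'
#' Controls the repeated 80/20 subdivision used both for the resampled PCA
#' parameter selection and for the repeated k-means threshold estimation.
#' The split exists to probe robustness against sampling variation, not for
#' supervised validation.
#'
#' @param n_runs Number of resampling runs, default 100.
#' @param train_fraction Training fraction, default 0.80.
#' @param seed Integer master seed.
#' @param stratify_by_group Preserve group proportions within rounding,
#'   default off (simple random subsampling).
#' @return A list of class `resample_config`.
#' @export
resample_config <- function(n_runs = 100L, train_fraction = 0.80, seed = 1L,
                            stratify_by_group = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    cms_stop("train_fraction must be in (0, 1)")
  if (n_runs < 1L) cms_stop("n_runs must be >= 1")
  structure(list(n_runs = as.integer(n_runs), train_fraction = train_fraction,
                 seed = as.integer(seed),
                 stratify_by_group = isTRUE(stratify_by_group)),
            class = "resample_config")
}

#' Parameter-selection configuration
#'
#' @param top_k Number of parameters tallied per PCA run (default 4).
#' @param component `"auto"` (pick the group-separating component by
#'   one-way F statistic among the first 3) or a fixed component index.
#' @param n_selected Size of the final parameter set (default 4).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(top_k = 4L, component = "auto", n_selected = 4L) {
  if (top_k < 1L) cms_stop("top_k must be >= 1")
  if (!identical(component, "auto")) {
    component <- as.integer(component)
    if (is.na(component) || component < 1L)
      cms_stop("component must be 'auto' or a positive index")
  }
  structure(list(top_k = as.integer(top_k), component = component,
                 n_selected = as.integer(n_selected)),
            class = "selection_config")
}

#' Draw one training/test split
#'
#' The training set has `round(train_fraction * n_animals)` animals sampled
#' without replacement; the test set is the complement. The draw is fully
#' determined by `(config$seed, run_index)` so runs are reproducible and
#' independent of each other.
#'
#' @param n_animals Number of animals (>= 5).
#' @param config A [resample_config()].
#' @param run_index Run number (1-based).
#' @param groups Optional per-animal group labels, required when
#'   `config$stratify_by_group` is on.
#' @return A list with sorted integer vectors `train` and `test`.
#' @export
draw_subsample <- function(n_animals, config, run_index, groups = NULL) {
  if (n_animals < 5L) cms_stop("need at least 5 animals to subsample")
  set.seed(derive_seed(config$seed, "subsample", run_index))
  if (config$stratify_by_group) {
    if (is.null(groups) || length(groups) != n_animals)
      cms_stop("stratified subsampling requires per-animal group labels")
    train <- integer()
    for (g in unique(groups)) {
      idx <- which(groups == g)
      train <- c(train, sample(idx, round(config$train_fraction * length(idx))))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n_animals, round(config$train_fraction * n_animals)))
  }
  list(train = train, test = setdiff(seq_len(n_animals), train))
}

#' Principal component decomposition of a scaled matrix
#'
#' Eigendecomposition of the covariance matrix of the (already z-scaled,
#' imputed) training data. Components are ordered by decreasing eigenvalue.
#' Loading signs follow the convention that each component's
#' largest-magnitude loading is positive, which removes the arbitrary sign
#' flips of eigen-solvers and makes runs comparable.
#'
#' @param x Numeric matrix (animals x parameters), no missing cells,
#'   >= 3 animals and >= 2 parameters.
#' @return A list with `explained` (variance fractions, non-increasing),
#'   `loadings` (parameters x components, unit-norm columns) and `scores`
#'   (centered data projected on the loadings).
#' @export
pca_decompose <- function(x) {
  if (anyNA(x)) cms_stop("PCA input must have no missing cells (impute first)")
  if (nrow(x) < 3L || ncol(x) < 2L)
    cms_stop("PCA needs >= 3 animals and >= 2 parameters")
  e <- eigen(stats::cov(x), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  centered <- sweep(x, 2, colMeans(x))
  list(explained = vals / sum(vals), loadings = load,
       scores = centered %*% load)
}

# One-way between-group F statistic of y over labels g.
oneway_f <- function(y, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) return(NA_real_)
  gm <- tapply(y, g, mean)
  ng <- tapply(y, g, length)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  dfb <- nlevels(g) - 1L
  dfw <- length(y) - nlevels(g)
  if (ssw == 0 || dfw <= 0) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}

#' Choose the severity-relevant principal component
#'
#' In fixed mode returns the configured index. In auto mode returns the
#' component, among the first three, whose training scores maximize the
#' one-way between-group F statistic — the component along which the
#' treatment groups separate. The first component often tracks disease
#' phenotype rather than burden, which is why the choice is made on group
#' separation and all per-component F statistics are surfaced for audit.
#'
#' @param scores Score matrix (training animals x components).
#' @param groups Per-animal group labels for the training animals
#'   (required in auto mode).
#' @param config A [selection_config()].
#' @return A list with `component` (index), `f_statistics` (per audited
#'   component) and `ambiguous` (TRUE when even the best component does not
#'   separate the groups at the 0.05 level, i.e. all F statistics are at
#'   chance level and the choice is unstable).
#' @export
choose_component <- function(scores, groups = NULL, config = selection_config()) {
  if (!identical(config$component, "auto")) {
    return(list(component = config$component, f_statistics = NULL,
                ambiguous = FALSE))
  }
  if (is.null(groups))
    cms_stop("component = 'auto' requires group labels; ",
             "use a fixed component index otherwise")
  n_audit <- min(3L, ncol(scores))
  f <- vapply(seq_len(n_audit), function(j) oneway_f(scores[, j], groups), 0)
  names(f) <- colnames(scores)[seq_len(n_audit)]
  ord <- order(f, decreasing = TRUE)
  df1 <- length(unique(groups)) - 1L
  df2 <- nrow(scores) - df1 - 1L
  crit <- stats::qf(0.95, df1, max(df2, 1L))
  ambiguous <- is.finite(f[ord[1]]) && f[ord[1]] < crit
  list(component = ord[1], f_statistics = f, ambiguous = unname(ambiguous))
}

#' Resampled-PCA stability selection of informative parameters
#'
#' The selection engine: for each run an 80% training subsample is drawn,
#' a PCA is computed on it, the group-separating component is identified,
#' parameters are ranked by absolute loading on that component, and the
#' `top_k` parameters are recorded. Frequencies over all runs are tallied
#' and the `n_selected` most frequent parameters form the selected set —
#' the parameters whose importance is stable under resampling. Ties at the
#' selection boundary are broken by higher mean absolute loading across
#' runs, then by input column order (deterministic and auditable).
#'
#' @param scaled A `scaled_matrix` (imputed; no missing cells).
#' @param rconf A [resample_config()].
#' @param sconf A [selection_config()].
#' @return An object of class `stability_selection`: `frequency` (named
#'   count per parameter), `selected`, `mean_explained` /
#'   `sd_explained` (per component across runs), `runs` (per-run records
#'   with chosen component, F statistics, top parameters, loadings on the
#'   chosen component, training indices) and the configs.
#' @export
run_stability_selection <- function(scaled, rconf = resample_config(),
                                    sconf = selection_config()) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  x <- scaled$values
  if (anyNA(x)) cms_stop("scaled matrix has missing cells; impute first")
  params <- colnames(x)
  if (sconf$top_k > length(params))
    cms_stop("top_k exceeds the number of parameters")
  if (sconf$n_selected > length(params))
    cms_stop("n_selected exceeds the number of parameters")
  n <- nrow(x)
  freq <- stats::setNames(integer(length(params)), params)
  absload_sum <- stats::setNames(numeric(length(params)), params)
  expl <- NULL
  runs <- vector("list", rconf$n_runs)
  for (r in seq_len(rconf$n_runs)) {
    split <- draw_subsample(n, rconf, r,
                            groups = if (rconf$stratify_by_group) scaled$group)
    pca <- pca_decompose(x[split$train, , drop = FALSE])
    ch <- choose_component(pca$scores, scaled$group[split$train], sconf)
    lo <- pca$loadings[, ch$component]
    top <- names(sort(abs(lo), decreasing = TRUE))[seq_len(sconf$top_k)]
    freq[top] <- freq[top] + 1L
    absload_sum <- absload_sum + abs(lo)[params]
    expl <- rbind(expl, pca$explained)
    runs[[r]] <- list(run_index = r, chosen_component = ch$component,
                      f_statistics = ch$f_statistics, ambiguous = ch$ambiguous,
                      explained = pca$explained, top_parameters = top,
                      loadings = lo, train = split$train, test = split$test)
  }
  # selection order: frequency desc, mean |loading| desc, input column order
  ord <- order(-freq, -absload_sum / rconf$n_runs, seq_along(params))
  selected <- params[ord][seq_len(sconf$n_selected)]
  colnames(expl) <- paste0("PC", seq_len(ncol(expl)))
  structure(list(frequency = freq, selected = selected,
                 mean_explained = colMeans(expl),
                 sd_explained = apply(expl, 2, stats::sd),
                 runs = runs, resample_config = rconf,
                 selection_config = sconf),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  n_runs <- x$resample_config$n_runs
  cat("Stability selection over", n_runs, "resampled PCA runs\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat("  top-", x$selection_config$top_k, " frequencies:\n", sep = "")
  f <- sort(x$frequency, decreasing = TRUE)
  f <- f[f > 0]
  for (nm in names(f))
    cat(sprintf("    %-28s %3d / %d\n", nm, f[[nm]], n_runs))
  cat(sprintf("  explained variance: PC1 %.2f%% (SD %.2f%%), PC2 %.2f%% (SD %.2f%%)\n",
              100 * x$mean_explained[1], 100 * x$sd_explained[1],
              100 * x$mean_explained[2], 100 * x$sd_explained[2]))
  invisible(x)
}

#' Spearman correlation matrix with pairwise-complete observations
#'
#' Exploratory rank-correlation structure of the candidate parameters
#' (tie-corrected ranks). Pairs with fewer than 3 complete observations
#' get a missing entry and a warning.
#'
#' @param table A [parameter_table()] (raw values; ranks are unaffected by
#'   the monotone preprocessing).
#' @return Symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
spearman_correlation_matrix <- function(table) {
  stopifnot(inherits(table, "parameter_table"))
  vals <- table$values
  rho <- suppressWarnings(
    stats::cor(vals, method = "spearman", use = "pairwise.complete.obs"))
  obs <- !is.na(vals)
  n_complete <- crossprod(obs)
  thin <- n_complete < 3 & upper.tri(n_complete)
  if (any(thin)) {
    rho[n_complete < 3] <- NA_real_
    diag(rho) <- 1
    cms_warn("parameter pairs with < 3 complete observations set to NA: ",
             sum(thin))
  }
  rho
}
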