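# Box-Cox profile log-likelihood for an intercept-only model.
# x must be strictly positive and non-constant.
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  if (any(!is.finite(y))) return(-1e300)
  s2 <- sum((y - mean(y))^2) / n
  # extreme lambdas can compress the column to numerically constant values
  if (!is.finite(s2) || s2 <= 1e-300) return(-1e300)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Transforms a parameter toward normality before standardization. If the
#' column minimum is <= 0 an offset of `1 - min` is added first so every
#' value is strictly positive. When `lambda` is not supplied it is fitted
#' by profile maximum likelihood: a coarse scan over the bounded grid
#' \[-5, 5\] followed by [stats::optimize()] refinement (tolerance 1e-4).
#' The transform is `(x^lambda - 1) / lambda` for `lambda != 0` and
#' `log(x)` for `lambda = 0`.
#'
#' @param column Numeric vector (missing values allowed; they stay missing).
#' @param lambda Optional fixed exponent; fitted when `NULL`.
#' @return A list with `values` (transformed vector, same length and
#'   missingness as the input), `lambda` (applied exponent) and `offset`
#'   (additive shift applied before transforming), so the transform can be
#'   replayed exactly on new animals.
#' @export
boxcox_transform <- function(column, lambda = NULL) {
  obs <- column[!is.na(column)]
  if (length(obs) < 3L)
    cms_stop("Box-Cox needs at least 3 non-missing values")
  if (stats::sd(obs) == 0)
    cms_stop("zero variance, cannot transform")
  offset <- if (min(obs) <= 0) 1 - min(obs) else 0
  shifted <- column + offset
  if (is.null(lambda)) {
    pos <- shifted[!is.na(shifted)]
    grid <- seq(-5, 5, by = 0.25)
    ll <- vapply(grid, function(l) boxcox_loglik(pos, l), 0)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    lambda <- if (lo == hi) lo else
      stats::optimize(function(l) boxcox_loglik(pos, l),
                      interval = c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  }
  values <- if (abs(lambda) < 1e-12) log(shifted) else (shifted^lambda - 1) / lambda
  list(values = values, lambda = lambda, offset = offset)
}

#' Center and scale to zero mean and unit standard deviation
#'
#' Non-missing values get mean 0 and SD 1 (n-1 denominator); missing cells
#' stay missing.
#'
#' @param column Numeric vector with at least 2 non-missing values.
#' @param name Optional parameter name used in error messages.
#' @return The scaled vector with attributes `center` and `scale`.
#' @export
zscale <- function(column, name = "column") {
  obs <- column[!is.na(column)]
  if (length(obs) < 2L)
    cms_stop("zscale needs at least 2 non-missing values in ", name)
  m <- mean(obs)
  s <- stats::sd(obs)
  if (s == 0)
    cms_stop("zero standard deviation in parameter '", name, "'")
  out <- (column - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Preprocess a parameter table to the analysis scale
#'
#' Fixed pipeline order: optional Box-Cox on the raw (offset-shifted)
#' values, then centering/scaling to zero mean and unit SD, then optional
#' column-mean imputation of missing cells (the column mean on the scaled
#' scale is 0, which is neutral under both PCA covariance and the
#' composite-score summation). All fitted constants (lambda, offset, mean,
#' SD per parameter) are stored so the identical transform can be replayed
#' on new animals via [apply_preprocessing()].
#'
#' @param table A [parameter_table()].
#' @param boxcox Logical, apply Box-Cox before scaling (default `TRUE`).
#' @param impute `"column_mean"` (default) or `"none"`.
#' @return An object of class `scaled_matrix`: `values` (dimensionless
#'   matrix), `animal_id`, `group`, `model`, `column_means`, `column_sds`,
#'   `boxcox_lambdas`, `boxcox_offsets`, `imputation_mask` (logical matrix
#'   flagging imputed cells), `boxcox`, `impute`.
#' @export
preprocess_table <- function(table, boxcox = TRUE,
                             impute = c("column_mean", "none")) {
  stopifnot(inherits(table, "parameter_table"))
  impute <- match.arg(impute)
  vals <- table$values
  p <- ncol(vals)
  lambdas <- offsets <- rep(NA_real_, p)
  means <- sds <- rep(NA_real_, p)
  out <- vals
  for (j in seq_len(p)) {
    col <- vals[, j]
    if (boxcox) {
      bc <- boxcox_transform(col)
      col <- bc$values
      lambdas[j] <- bc$lambda
      offsets[j] <- bc$offset
    }
    z <- zscale(col, name = colnames(vals)[j])
    means[j] <- attr(z, "center")
    sds[j] <- attr(z, "scale")
    out[, j] <- as.numeric(z)
  }
  mask <- is.na(out) & impute == "column_mean"
  if (impute == "column_mean") out[is.na(out)] <- 0
  names(means) <- names(sds) <- colnames(vals)
  if (boxcox) names(lambdas) <- names(offsets) <- colnames(vals)
  structure(list(values = out, animal_id = table$animal_id,
                 group = table$group, model = table$model,
                 column_means = means, column_sds = sds,
                 boxcox_lambdas = if (boxcox) lambdas else NULL,
                 boxcox_offsets = if (boxcox) offsets else NULL,
                 imputation_mask = mask, boxcox = boxcox, impute = impute),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat("Scaled matrix:", nrow(x$values), "animals x", ncol(x$values),
      "parameters (Box-Cox", if (x$boxcox) "on" else "off",
      "| imputation", x$impute, ")\n")
  cat("  imputed cells:", sum(x$imputation_mask), "\n")
  invisible(x)
}

#' Impute missing cells of a scaled matrix with the column mean
#'
#' On the scaled scale the column mean over observed cells is 0, so
#' imputation replaces missing cells by 0 and records them in the
#' imputation mask. Provided separately for pipelines that preprocess with
#' `impute = "none"`.
#'
#' @param scaled A `scaled_matrix`.
#' @param strategy Only `"column_mean"` is implemented.
#' @return The `scaled_matrix` with no missing cells and an updated mask.
#' @export
impute_missing <- function(scaled, strategy = "column_mean") {
  stopifnot(inherits(scaled, "scaled_matrix"))
  strategy <- match.arg(strategy, "column_mean")
  bad <- colSums(!is.na(scaled$values)) == 0
  if (any(bad))
    cms_stop("columns with no observed values: ",
             paste(colnames(scaled$values)[bad], collapse = ", "))
  add <- is.na(scaled$values)
  scaled$values[add] <- 0
  scaled$imputation_mask <- scaled$imputation_mask | add
  scaled$impute <- "column_mean"
  scaled
}

#' Extract the preprocessing manifest
#'
#' The manifest carries every fitted constant needed to reproduce a scaled
#' value bit-for-bit on new animals: per-parameter Box-Cox lambda and
#' offset, mean and SD, plus the pipeline flags.
#'
#' @param scaled A `scaled_matrix`.
#' @return A list of class `preprocess_manifest`.
#' @export
preprocessing_manifest <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  structure(list(parameters = colnames(scaled$values),
                 boxcox = scaled$boxcox, impute = scaled$impute,
                 boxcox_lambdas = scaled$boxcox_lambdas,
                 boxcox_offsets = scaled$boxcox_offsets,
                 column_means = scaled$column_means,
                 column_sds = scaled$column_sds),
            class = "preprocess_manifest")
}

#' Apply a frozen preprocessing manifest to new animals
#'
#' Replays the stored Box-Cox (fixed lambda and offset) and the stored
#' center/scale constants; nothing is refitted. This is what allows a
#' frozen composite measure scheme to score animals from a new study on
#' the original scale.
#'
#' @param table A [parameter_table()] containing at least the manifest's
#'   parameters.
#' @param manifest A `preprocess_manifest` (or the equivalent list read
#'   back from JSON).
#' @return A `scaled_matrix` for the new animals.
#' @export
apply_preprocessing <- function(table, manifest) {
  stopifnot(inherits(table, "parameter_table"))
  params <- unlist(manifest$parameters)
  missing_cols <- setdiff(params, colnames(table$values))
  if (length(missing_cols))
    cms_stop("table lacks required parameter columns: ",
             paste(missing_cols, collapse = ", "))
  vals <- table$values[, params, drop = FALSE]
  out <- vals
  for (j in seq_along(params)) {
    col <- vals[, j]
    if (isTRUE(manifest$boxcox)) {
      lam <- manifest$boxcox_lambdas[[params[j]]]
      off <- manifest$boxcox_offsets[[params[j]]]
      shifted <- col + off
      col <- if (abs(lam) < 1e-12) log(shifted) else (shifted^lam - 1) / lam
    }
    out[, j] <- (col - manifest$column_means[[params[j]]]) /
      manifest$column_sds[[params[j]]]
  }
  mask <- is.na(out) & identical(manifest$impute, "column_mean")
  if (identical(manifest$impute, "column_mean")) out[is.na(out)] <- 0
  structure(list(values = out, animal_id = table$animal_id,
                 group = table$group, model = table$model,
                 column_means = unlist(manifest$column_means)[params],
                 column_sds = unlist(manifest$column_sds)[params],
                 boxcox_lambdas = if (isTRUE(manifest$boxcox))
                   unlist(manifest$boxcox_lambdas)[params] else NULL,
                 boxcox_offsets = if (isTRUE(manifest$boxcox))
                   unlist(manifest$boxcox_offsets)[params] else NULL,
                 imputation_mask = mask, boxcox = isTRUE(manifest$boxcox),
                 impute = manifest$impute %||% "none"),
            class = "scaled_matrix")
}

#' Write a preprocessing manifest as structured text
#'
#' @param manifest A `preprocess_manifest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_preprocessing_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  # keep names of per-parameter constants through JSON (objects, not arrays)
  for (f in c("boxcox_lambdas", "boxcox_offsets", "column_means", "column_sds"))
    if (!is.null(m[[f]])) m[[f]] <- as.list(m[[f]])
  write_report_json(m, path)
}

#' Read a preprocessing manifest
#'
#' @param path JSON path written by [write_preprocessing_manifest()].
#' @return A `preprocess_manifest`.
#' @export
read_preprocessing_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "preprocess_manifest")
}
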