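#' Build the composite severity score
#'
#' Sums the selected, scaled parameters per animal after aligning their
#' directionality so that a LOW composite value always denotes HIGHER
#' severity: a parameter whose spec direction is `+1` (low raw value =
#' higher severity) enters the sum as its z-value, a parameter with
#' direction `-1` enters negated. Weights are equal (unit weight per
#' parameter); an optional loading-weighted variant is available for
#' exploration but off by default because the scheme is defined as a plain
#' sum.
#'
#' Imputed cells contribute their neutral imputed value (0) to the sum but
#' are not counted in `n_contributing`; animals with more than half of the
#' selected parameters imputed are flagged unreliable rather than dropped.
#'
#' @param scaled A `scaled_matrix` containing the selected parameters.
#' @param selected Character vector of selected parameter names.
#' @param specs A [parameter_spec()] providing a direction for every
#'   selected parameter.
#' @param weights Optional numeric weights per selected parameter
#'   (default: equal unit weights).
#' @return A data frame of class `composite_scores` with columns
#'   `animal_id`, `group`, `model`, `score`, `n_contributing`, `flag`
#'   and attributes `parameters_used` and `directions`.
#' @export
build_composite <- function(scaled, selected, specs, weights = NULL) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  missing_cols <- setdiff(selected, colnames(scaled$values))
  if (length(missing_cols))
    cms_stop("selected parameters absent from scaled matrix: ",
             paste(missing_cols, collapse = ", "))
  no_spec <- setdiff(selected, specs$name)
  if (length(no_spec))
    cms_stop("selected parameters lack a directionality spec: ",
             paste(no_spec, collapse = ", "))
  dir <- specs$direction[match(selected, specs$name)]
  if (is.null(weights)) weights <- rep(1, length(selected))
  if (length(weights) != length(selected))
    cms_stop("weights must match the selected parameters")
  z <- scaled$values[, selected, drop = FALSE]
  if (anyNA(z)) cms_stop("scaled values contain missing cells; impute first")
  score <- as.numeric(z %*% (dir * weights))
  imput <- scaled$imputation_mask[, selected, drop = FALSE]
  n_contrib <- as.integer(rowSums(!imput))
  flag <- ifelse(n_contrib < length(selected) / 2, "unreliable", "ok")
  out <- data.frame(animal_id = scaled$animal_id, group = scaled$group,
                    model = scaled$model, score = score,
                    n_contributing = n_contrib, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "parameters_used") <- selected
  attr(out, "directions") <- dir
  class(out) <- c("composite_scores", "data.frame")
  out
}

#' Score new animals with a frozen composite measure scheme
#'
#' Applies a stored preprocessing manifest (means, SDs, Box-Cox constants)
#' and a stored parameter selection to a new table; nothing is refitted,
#' so scores from different studies live on the same frozen scale.
#'
#' @param table A [parameter_table()] for the new animals.
#' @param manifest A `preprocess_manifest` restricted to (or containing)
#'   the selected parameters.
#' @param selected Character vector of the frozen selected parameters.
#' @param specs A [parameter_spec()] with directions for the selection.
#' @return A `composite_scores` data frame.
#' @export
score_new_animals <- function(table, manifest, selected, specs) {
  missing_cols <- setdiff(selected, colnames(table$values))
  if (length(missing_cols))
    cms_stop("new table lacks selected parameter columns: ",
             paste(missing_cols, collapse = ", "))
  scaled <- apply_preprocessing(table, manifest)
  build_composite(scaled, selected, specs)
}

#' Write composite scores to CSV
#'
#' @param scores A `composite_scores` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_composite_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
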