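#' Construct a parameter table
#'
#' The central input container: one row per animal, one numeric column per
#' behavioral or biochemical parameter, plus a treatment-group label and a
#' model label. Missing cells are permitted in the parameter columns; group
#' and model must be complete. Group/model labels are free strings so the
#' container is reusable beyond any particular disease-model vocabulary.
#'
#' @param values Numeric matrix (animals x parameters) with column names;
#'   missing cells as `NA`.
#' @param animal_id Character vector of unique animal identifiers.
#' @param group Character vector of treatment-group labels (e.g. naive,
#'   sham, treated).
#' @param model Character vector of model labels.
#' @param parse_report Optional list describing non-numeric cells coerced to
#'   `NA` during file parsing.
#' @return An object of class `parameter_table` with fields `animal_id`,
#'   `group`, `model`, `values`, `parse_report`.
#' @export
parameter_table <- function(values, animal_id, group, model,
                            parse_report = list(n_coerced = 0L, cells = list())) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  animal_id <- as.character(animal_id)
  group <- as.character(group)
  model <- as.character(model)
  n <- length(animal_id)
  if (nrow(values) != n || length(group) != n || length(model) != n)
    cms_stop("animal_id, group, model and rows of values must have equal length")
  dup <- unique(animal_id[duplicated(animal_id)])
  if (length(dup))
    cms_stop("duplicate animal_id values: ", paste(dup, collapse = ", "))
  if (anyNA(group) || any(group == ""))
    cms_stop("every animal must have a non-missing group label")
  if (anyNA(model) || any(model == ""))
    cms_stop("every animal must have a non-missing model label")
  if (n < 2L)
    cms_stop("a parameter table needs at least 2 animals")
  if (ncol(values) < 1L)
    cms_stop("a parameter table needs at least 1 parameter column")
  if (is.null(colnames(values)) || anyNA(colnames(values)) || any(colnames(values) == ""))
    cms_stop("all parameter columns must be named")
  rownames(values) <- animal_id
  structure(list(animal_id = animal_id, group = group, model = model,
                 values = values, parse_report = parse_report),
            class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat("Parameter table:", length(x$animal_id), "animals x",
      ncol(x$values), "parameters\n")
  cat("  models:", paste(unique(x$model), collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$group), collapse = ", "), "\n")
  miss <- sum(is.na(x$values))
  cat("  missing cells:", miss,
      sprintf("(%.1f%%)", 100 * miss / length(x$values)), "\n")
  invisible(x)
}

#' @export
dim.parameter_table <- function(x) dim(x$values)

#' Read an animal-parameter table from delimited text
#'
#' Reads a CSV (or other delimited file) with a mandatory header row, one
#' row per animal. The identifier, group and model columns are taken by
#' name; every remaining column is treated as a numeric parameter. Empty
#' cells, `"NA"` and `"NaN"` are missing values; any other non-numeric cell
#' is coerced to missing and counted in the parse report.
#'
#' @param path Path to the delimited file.
#' @param id_column,group_column,model_column Names of the mandatory
#'   columns (defaults `"id"`, `"group"`, `"model"`).
#' @param delimiter Field delimiter, default comma.
#' @return A [parameter_table()].
#' @export
read_parameter_table <- function(path, id_column = "id", group_column = "group",
                                 model_column = "model", delimiter = ",") {
  if (!file.exists(path)) cms_stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          na.strings = MISSING_TOKENS, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          strip.white = TRUE)
  for (col in c(id_column, group_column, model_column))
    if (!col %in% names(df))
      cms_stop("mandatory column '", col, "' not found in ", path)
  param_cols <- setdiff(names(df), c(id_column, group_column, model_column))
  if (!length(param_cols))
    cms_stop("no parameter columns found in ", path)
  coerced <- list()
  n_coerced <- 0L
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(param_cols),
                 dimnames = list(NULL, param_cols))
  for (p in param_cols) {
    raw <- df[[p]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      coerced[[p]] <- bad
      n_coerced <- n_coerced + length(bad)
    }
    vals[, p] <- num
  }
  parameter_table(vals, df[[id_column]], df[[group_column]], df[[model_column]],
                  parse_report = list(n_coerced = n_coerced, cells = coerced))
}

#' Per-parameter severity directionality and exclusion specification
#'
#' The directionality convention follows the composite-score definition:
#' `direction = +1` means a LOW raw value indicates HIGHER severity (e.g.
#' reduced burrowing), `direction = -1` means a HIGH raw value indicates
#' higher severity (e.g. increased immobility). `excluded` marks a manual,
#' domain-based exclusion from the candidate set; the tool itself makes no
#' domain judgement.
#'
#' @param name Parameter names (matching table columns).
#' @param direction Integer vector of +1 / -1, recycled if length 1.
#' @param excluded Logical exclusion flags, recycled if length 1.
#' @param note Free-text rationale, recycled if length 1.
#' @return A data frame of class `parameter_spec`.
#' @export
parameter_spec <- function(name, direction = 1L, excluded = FALSE, note = "") {
  name <- as.character(name)
  direction <- as.integer(rep_len(direction, length(name)))
  excluded <- as.logical(rep_len(excluded, length(name)))
  note <- as.character(rep_len(note, length(name)))
  if (!all(direction %in% c(-1L, 1L)))
    cms_stop("direction must be exactly +1 or -1 for every parameter")
  if (anyDuplicated(name))
    cms_stop("duplicate parameter names in spec")
  structure(data.frame(name = name, direction = direction, excluded = excluded,
                       note = note, stringsAsFactors = FALSE),
            class = c("parameter_spec", "data.frame"))
}

#' Read a parameter specification file
#'
#' Flat YAML config with one block per parameter:
#' ```
#' burrowing:
#'   direction: 1
#'   excluded: false
#'   note: g gravel displaced in 2 h; reduced by distress
#' ```
#'
#' @param path Path to the YAML spec.
#' @return A [parameter_spec()] data frame.
#' @export
read_parameter_spec <- function(path) {
  if (!file.exists(path)) cms_stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) cms_stop("empty parameter spec: ", path)
  parameter_spec(names(raw),
                 direction = vapply(raw, function(b) as.integer(b$direction %||% 1L), 1L),
                 excluded = vapply(raw, function(b) isTRUE(b$excluded), TRUE),
                 note = vapply(raw, function(b) as.character(b$note %||% ""), ""))
}

#' Write a parameter specification file
#'
#' @param spec A [parameter_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_parameter_spec <- function(spec, path) {
  blocks <- lapply(seq_len(nrow(spec)), function(i)
    list(direction = spec$direction[i], excluded = spec$excluded[i],
         note = spec$note[i]))
  names(blocks) <- spec$name
  yaml::write_yaml(blocks, path)
  invisible(path)
}

new_filter_report <- function(input, miss_frac, removed_missing = character(),
                              removed_excluded = character()) {
  retained <- setdiff(input, c(removed_missing, removed_excluded))
  structure(list(n_input_parameters = length(input),
                 missingness_per_parameter = miss_frac,
                 removed_by_missingness = removed_missing,
                 removed_by_exclusion = removed_excluded,
                 retained = retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Parameter filter report\n")
  cat("  input parameters:      ", x$n_input_parameters, "\n")
  cat("  removed (missingness): ", length(x$removed_by_missingness),
      if (length(x$removed_by_missingness))
        paste0(" [", paste(x$removed_by_missingness, collapse = ", "), "]")
      else "", "\n", sep = "")
  cat("  removed (exclusion):   ", length(x$removed_by_exclusion),
      if (length(x$removed_by_exclusion))
        paste0(" [", paste(x$removed_by_exclusion, collapse = ", "), "]")
      else "", "\n", sep = "")
  cat("  retained:              ", length(x$retained), "\n", sep = "")
  invisible(x)
}

#' Remove parameters by missingness
#'
#' A parameter is removed if and only if its fraction of missing cells,
#' computed over all animals in the combined table, is strictly greater
#' than `max_missing_fraction` ("more than 20% missing" under the default).
#' A parameter missing exactly the threshold fraction survives. Animals are
#' never removed at this stage, and remaining missing cells in retained
#' parameters are left untouched (their handling is a preprocessing
#' decision).
#'
#' @param table A [parameter_table()].
#' @param max_missing_fraction Fraction in `[0, 1)`, default `0.20`.
#' @return A list with elements `table` (filtered) and `report`
#'   (a `filter_report`). Column order of retained parameters preserves
#'   input order.
#' @export
filter_by_missingness <- function(table, max_missing_fraction = 0.20) {
  stopifnot(inherits(table, "parameter_table"))
  if (!(max_missing_fraction >= 0 && max_missing_fraction < 1))
    cms_stop("max_missing_fraction must be in [0, 1)")
  miss <- colMeans(is.na(table$values))
  removed <- names(miss)[miss > max_missing_fraction]
  keep <- setdiff(colnames(table$values), removed)
  if (!length(keep))
    cms_stop("all parameters exceed the missingness threshold (",
             max_missing_fraction, "); review the threshold or the data")
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  list(table = out,
       report = new_filter_report(colnames(table$values), miss,
                                  removed_missing = removed))
}

#' Drop manually excluded parameters
#'
#' Applies the user-declared exclusions from a [parameter_spec()] (for the
#' original battery: change in body weight and seizure frequency, judged
#' unsuitable for a severity composite). Exclusion is purely declarative;
#' an exclusion naming an absent column (e.g. one already removed by the
#' missingness filter) yields a warning, not an error.
#'
#' @param table A [parameter_table()].
#' @param specs A [parameter_spec()].
#' @param report Optional `filter_report` from [filter_by_missingness()] to
#'   extend, so the final report partitions the original input set.
#' @return A list with elements `table` and `report`.
#' @export
apply_exclusions <- function(table, specs, report = NULL) {
  stopifnot(inherits(table, "parameter_table"))
  excl <- specs$name[specs$excluded]
  absent <- setdiff(excl, colnames(table$values))
  if (length(absent))
    cms_warn("excluded parameters not present (already removed or unknown): ",
             paste(absent, collapse = ", "))
  drop <- intersect(excl, colnames(table$values))
  keep <- setdiff(colnames(table$values), drop)
  if (!length(keep))
    cms_stop("exclusions would remove every parameter")
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  if (is.null(report)) {
    report <- new_filter_report(colnames(table$values),
                                colMeans(is.na(table$values)),
                                removed_excluded = drop)
  } else {
    report <- new_filter_report(
      c(report$removed_by_missingness, report$removed_by_exclusion, report$retained),
      report$missingness_per_parameter,
      removed_missing = report$removed_by_missingness,
      removed_excluded = union(report$removed_by_exclusion, drop))
  }
  list(table = out, report = report)
}

#' Filter the candidate parameter set
#'
#' Convenience wrapper chaining [filter_by_missingness()] and
#' [apply_exclusions()] with a single report that partitions the input
#' parameter set into retained / removed-by-missingness /
#' removed-by-exclusion.
#'
#' @inheritParams filter_by_missingness
#' @inheritParams apply_exclusions
#' @return A list with elements `table` and `report`.
#' @export
filter_parameters <- function(table, specs = NULL, max_missing_fraction = 0.20) {
  st1 <- filter_by_missingness(table, max_missing_fraction)
  if (is.null(specs)) return(st1)
  apply_exclusions(st1$table, specs, report = st1$report)
}

#' Write a parameter table to CSV
#'
#' @param table A [parameter_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  df <- data.frame(id = table$animal_id, group = table$group,
                   model = table$model, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a filter report as structured text
#'
#' @param report A `filter_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_report_json(unclass(report), path)
}
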