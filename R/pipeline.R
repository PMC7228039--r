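#' Run the full composite-measure-scheme pipeline
#'
#' Orchestrates filter -> preprocess -> select -> score -> cluster ->
#' report. Every stage writes its artifact to `out_dir` and the run
#' manifest records resolved configuration, seeds and MD5 digests of all
#' inputs and outputs, so a run can be replayed and verified bit-for-bit.
#'
#' Artifacts written: `filtered.csv`, `filter_report.json`,
#' `preprocess_manifest.json`, `correlation.csv`, `selection.json`,
#' `scores.csv`, `severity.json`, `levels.csv`, `group_distribution.csv`,
#' `summary.txt`, `manifest.json`.
#'
#' @param table A [parameter_table()] or a path to a battery CSV.
#' @param specs A [parameter_spec()] or a path to a spec YAML.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; fanned out to independent per-stage streams.
#' @param max_missing_fraction Missingness filter threshold (default 0.20).
#' @param boxcox Apply Box-Cox before scaling (default `TRUE`).
#' @param n_runs Resampling runs for both selection and clustering
#'   (default 100).
#' @param train_fraction Training fraction (default 0.80).
#' @param top_k Parameters tallied per PCA run (default 4).
#' @param n_selected Size of the selected set (default 4).
#' @param component `"auto"` or a fixed component index.
#' @param k Number of severity clusters (default 3).
#' @return Invisibly, a list with all stage results (`filter`, `scaled`,
#'   `selection`, `scores`, `severity`, `distribution`, `manifest`) and
#'   `paths` to the written artifacts.
#' @export
run_pipeline <- function(table, specs, out_dir, seed = 1L,
                         max_missing_fraction = 0.20, boxcox = TRUE,
                         n_runs = 100L, train_fraction = 0.80,
                         top_k = 4L, n_selected = 4L, component = "auto",
                         k = 3L) {
  if (is.character(table)) table <- read_parameter_table(table)
  if (is.character(specs)) specs <- read_parameter_spec(specs)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  flt <- filter_parameters(table, specs, max_missing_fraction)
  write_parameter_table(flt$table, pth("filtered.csv"))
  write_filter_report(flt$report, pth("filter_report.json"))

  scaled <- preprocess_table(flt$table, boxcox = boxcox, impute = "column_mean")
  manifest_pp <- preprocessing_manifest(scaled)
  write_preprocessing_manifest(manifest_pp, pth("preprocess_manifest.json"))

  rho <- spearman_correlation_matrix(flt$table)
  utils::write.csv(round(rho, 6), pth("correlation.csv"))

  rconf <- resample_config(n_runs = n_runs, train_fraction = train_fraction,
                           seed = derive_seed(seed, "selection"))
  sconf <- selection_config(top_k = top_k, component = component,
                            n_selected = n_selected)
  sel <- run_stability_selection(scaled, rconf, sconf)
  write_report_json(list(selected = sel$selected,
                         frequency = as.list(sel$frequency),
                         mean_explained = as.list(sel$mean_explained),
                         sd_explained = as.list(sel$sd_explained),
                         n_runs = n_runs, top_k = top_k), pth("selection.json"))

  scores <- build_composite(scaled, sel$selected, specs)
  write_composite_scores(scores, pth("scores.csv"))

  cconf <- cluster_config(k = k, n_runs = n_runs,
                          train_fraction = train_fraction,
                          seed = derive_seed(seed, "clustering"))
  sev <- run_severity_clustering(scores, cconf)
  write_report_json(list(k = k, thresholds = sev$thresholds$thresholds,
                         per_run = apply(sev$thresholds$per_run, 1, as.list)),
                    pth("severity.json"))
  utils::write.csv(as.data.frame(sev$assignments), pth("levels.csv"),
                   row.names = FALSE, quote = FALSE)

  dist <- group_distribution(sev$membership, scores$model, scores$group, k = k)
  utils::write.csv(dist, pth("group_distribution.csv"),
                   row.names = FALSE, quote = FALSE)

  summary_lines <- c(
    "Composite measure scheme pipeline summary",
    sprintf("animals: %d", length(table$animal_id)),
    sprintf("parameter funnel: %d input -> %d after missingness filter -> %d retained",
            flt$report$n_input_parameters,
            flt$report$n_input_parameters - length(flt$report$removed_by_missingness),
            length(flt$report$retained)),
    sprintf("selected parameters (%d): %s", n_selected,
            paste(sel$selected, collapse = ", ")),
    sprintf("top-%d frequencies: %s", top_k,
            paste(sprintf("%s=%d", names(sort(sel$frequency, decreasing = TRUE))[1:n_selected],
                          sort(sel$frequency, decreasing = TRUE)[1:n_selected]),
                  collapse = ", ")),
    sprintf("explained variance: PC1 %.2f%% (SD %.2f%%), PC2 %.2f%% (SD %.2f%%)",
            100 * sel$mean_explained[1], 100 * sel$sd_explained[1],
            100 * sel$mean_explained[2], 100 * sel$sd_explained[2]),
    vapply(seq_len(k - 1L), function(i)
      sprintf("threshold %s: %.4f (95%% CI %.4f to %.4f)",
              sub("_to_", " to ", sev$thresholds$thresholds$boundary[i]),
              sev$thresholds$thresholds$mean[i],
              sev$thresholds$thresholds$ci_low[i],
              sev$thresholds$thresholds$ci_high[i]), ""),
    sprintf("group-distribution rows: %d (model x group cells: %d)",
            nrow(dist), nrow(unique(data.frame(scores$model, scores$group)))))
  writeLines(summary_lines, pth("summary.txt"))

  artifact_files <- c("filtered.csv", "filter_report.json",
                      "preprocess_manifest.json", "correlation.csv",
                      "selection.json", "scores.csv", "severity.json",
                      "levels.csv", "group_distribution.csv", "summary.txt")
  manifest <- list(
    tool = paste0("cmskit ", as.character(utils::packageVersion("cmskit"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(max_missing_fraction = max_missing_fraction,
                  boxcox = boxcox, impute = "column_mean", n_runs = n_runs,
                  train_fraction = train_fraction, top_k = top_k,
                  n_selected = n_selected, component = component, k = k,
                  n_init = cconf$n_init),
    selected = sel$selected,
    artifact_digests = as.list(tools::md5sum(pth(artifact_files))))
  names(manifest$artifact_digests) <- artifact_files
  write_report_json(manifest, pth("manifest.json"))

  invisible(list(filter = flt, scaled = scaled, selection = sel,
                 scores = scores, severity = sev, distribution = dist,
                 manifest = manifest,
                 paths = stats::setNames(as.list(pth(c(artifact_files, "manifest.json"))),
                                         c(artifact_files, "manifest.json"))))
}

#' Apply a frozen composite measure scheme to new animals
#'
#' Scores a new table with the stored preprocessing manifest and selected
#' parameter set, then assigns severity levels with the stored thresholds.
#' Nothing is refitted anywhere: the same raw value always yields the
#' same score and level, which is what makes a published scheme directly
#' applicable to other studies.
#'
#' @param table A [parameter_table()] or path to a battery CSV.
#' @param manifest A `preprocess_manifest` or path to
#'   `preprocess_manifest.json`.
#' @param selected Character vector of frozen selected parameters.
#' @param specs A [parameter_spec()] or path to a spec YAML.
#' @param thresholds A `threshold_set` or ascending numeric vector of
#'   frozen boundary values.
#' @param out Optional CSV path for the per-animal levels.
#' @return A data frame with `animal_id`, `group`, `model`, `score`,
#'   `severity_level`, `flag`.
#' @export
apply_frozen_cms <- function(table, manifest, selected, specs, thresholds,
                             out = NULL) {
  if (is.character(table)) table <- read_parameter_table(table)
  if (is.character(manifest)) manifest <- read_preprocessing_manifest(manifest)
  if (is.character(specs)) specs <- read_parameter_spec(specs)
  scores <- score_new_animals(table, manifest, selected, specs)
  lv <- assign_severity(scores, thresholds)
  res <- data.frame(animal_id = scores$animal_id, group = scores$group,
                    model = scores$model, score = scores$score,
                    severity_level = lv$severity_level, flag = scores$flag,
                    stringsAsFactors = FALSE)
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}
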