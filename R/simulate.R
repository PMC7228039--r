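#' Simulation design for a synthetic behavioral battery
#'
#' Describes a multi-model, multi-group study whose derived per-animal
#' parameters have planted structure: standardized group effects (Cohen's
#' d) on a chosen subset of parameters, a target Spearman correlation
#' structure imposed through a Gaussian copula, and per-parameter
#' missingness injected completely at random. Effects are expressed as
#' severity magnitudes: the generator shifts each affected parameter in
#' its severity direction (down for low-is-worse parameters, up for
#' high-is-worse ones).
#'
#' @param models Named list: per model, a named integer vector of animal
#'   counts per group, e.g. `list(kindling = c(naive = 20, sham = 20,
#'   treated = 25))`.
#' @param parameters Data frame with columns `name`, `direction` (+1 low
#'   raw = worse, -1 high raw = worse), `mean`, `sd` (raw units),
#'   `missingness` (fraction in \[0, 0.5\]).
#' @param effects Data frame with columns `parameter`, `model`, `group`,
#'   `d` (standardized severity shift, >= 0); absent combinations have no
#'   effect.
#' @param spearman Target Spearman correlation matrix between parameters
#'   (default identity). Converted internally to the latent Pearson
#'   correlation `2 sin(pi rho / 6)` of the Gaussian copula.
#' @param seed Integer seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(models, parameters, effects = NULL,
                              spearman = NULL, seed = 1L) {
  stopifnot(is.list(models), length(models) >= 1L)
  req <- c("name", "direction", "mean", "sd", "missingness")
  if (!all(req %in% names(parameters)))
    cms_stop("parameters needs columns: ", paste(req, collapse = ", "))
  if (any(parameters$sd <= 0)) cms_stop("parameter SDs must be > 0")
  if (any(parameters$missingness < 0 | parameters$missingness > 0.5))
    cms_stop("missingness fractions must be in [0, 0.5]")
  if (!all(parameters$direction %in% c(-1, 1)))
    cms_stop("direction must be +1 or -1")
  p <- nrow(parameters)
  if (is.null(spearman)) spearman <- diag(p)
  spearman <- as.matrix(spearman)
  if (!isSymmetric(unname(spearman)) || nrow(spearman) != p)
    cms_stop("spearman must be a symmetric ", p, " x ", p, " matrix")
  latent <- 2 * sin(pi * spearman / 6)
  diag(latent) <- 1
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    cms_stop("latent correlation matrix is not positive definite ",
             "(smallest eigenvalue ", format(min(ev)), ")")
  if (any(vapply(models, function(m) any(m < 1), TRUE)))
    cms_stop("all group counts must be >= 1")
  structure(list(models = models, parameters = parameters,
                 effects = effects, spearman = spearman,
                 latent = latent, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a behavioral battery with planted structure
#'
#' Draws one latent multivariate normal vector per animal under the
#' design's Gaussian-copula correlation, adds the planted standardized
#' group effects (signed by each parameter's severity direction), maps to
#' raw units through the marginal means/SDs, and injects missingness
#' completely at random. Fully reproducible from the design seed.
#'
#' @param design A [simulation_design()].
#' @return A list with `table` (a [parameter_table()]) and `truth`
#'   (informative parameter set, the effects table, and per-animal labels)
#'   for oracle-based validation.
#' @export
simulate_battery <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(derive_seed(design$seed, "battery"))
  par <- design$parameters
  p <- nrow(par)
  labs <- do.call(rbind, lapply(names(design$models), function(m) {
    counts <- design$models[[m]]
    data.frame(model = m, group = rep(names(counts), counts),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(labs)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(design$latent)
  colnames(z) <- par$name
  if (!is.null(design$effects)) {
    for (i in seq_len(nrow(design$effects))) {
      e <- design$effects[i, ]
      j <- match(e$parameter, par$name)
      if (is.na(j)) cms_stop("effect on unknown parameter: ", e$parameter)
      rows <- labs$model == e$model & labs$group == e$group
      # severity shift: low-is-worse parameters move down, high-is-worse up
      z[rows, j] <- z[rows, j] - par$direction[j] * e$d
    }
  }
  vals <- sweep(sweep(z, 2, par$sd, "*"), 2, par$mean, "+")
  for (j in seq_len(p)) {
    f <- par$missingness[j]
    if (f > 0) vals[stats::runif(n) < f, j] <- NA_real_
  }
  informative <- if (is.null(design$effects)) character() else
    unique(design$effects$parameter[design$effects$d > 0])
  tab <- parameter_table(vals, sprintf("A%03d", seq_len(n)),
                         labs$group, labs$model)
  list(table = tab,
       truth = list(informative = informative, effects = design$effects,
                    model = labs$model, group = labs$group,
                    seed = design$seed))
}

#' Default planted-battery design
#'
#' The validation workhorse: 13 behavioral/biochemical parameters across
#' 3 models x 3 groups, with 4 informative parameters (burrowing,
#' open-field distance, social interaction, saccharin preference) carrying
#' a standardized severity shift of `d` in the treated groups. Correlation
#' targets: Spearman 0.5 between burrowing and social interaction and
#' -0.65 between the two locomotion parameters (distance moved and time
#' immobile); these are simulation settings chosen to resemble a
#' realistic battery, not reproductions of any dataset.
#'
#' @param n_per_group Animals per (model, group) cell; the default 9
#'   cells of 22-23 give ~200 animals.
#' @param d Standardized effect size on the informative parameters in
#'   treated groups (default 1.5).
#' @param affected_models Models whose treated group carries the effect
#'   (default all three).
#' @param missingness Baseline per-parameter missingness fraction
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A [simulation_design()].
#' @export
design_planted_battery <- function(n_per_group = c(22, 22, 23), d = 1.5,
                                   affected_models = c("kindling",
                                                       "chemical_post_se",
                                                       "electrical_post_se"),
                                   missingness = 0.05, seed = 1L) {
  n_per_group <- rep_len(n_per_group, 3)
  models <- list(
    kindling = c(naive = n_per_group[1], sham = n_per_group[1],
                 treated = n_per_group[1]),
    chemical_post_se = c(naive = n_per_group[2], sham = n_per_group[2],
                         treated = n_per_group[2]),
    electrical_post_se = c(naive = n_per_group[3], sham = n_per_group[3],
                           treated = n_per_group[3]))
  parameters <- data.frame(
    name = c("burrowing", "of_distance", "social_interaction",
             "saccharin_preference", "of_immobility", "of_rearing",
             "of_center_time", "nest_building", "bwb_latency",
             "bwb_time_white", "bdnf", "creatine_kinase", "corticosterone"),
    direction = c(1, 1, 1, 1, -1, 1, 1, 1, -1, 1, 1, -1, -1),
    mean = c(1500, 4200, 55, 85, 110, 28, 40, 4.2, 35, 120, 18, 220, 310),
    sd = c(420, 900, 16, 9, 38, 8, 14, 0.9, 14, 35, 4.5, 60, 80),
    missingness = missingness, stringsAsFactors = FALSE)
  informative <- c("burrowing", "of_distance", "social_interaction",
                   "saccharin_preference")
  effects <- expand.grid(parameter = informative, model = affected_models,
                         stringsAsFactors = FALSE)
  effects$group <- "treated"
  effects$d <- d
  sp <- diag(13)
  rownames(sp) <- colnames(sp) <- parameters$name
  sp["burrowing", "social_interaction"] <-
    sp["social_interaction", "burrowing"] <- 0.5
  sp["of_distance", "of_immobility"] <-
    sp["of_immobility", "of_distance"] <- -0.65
  simulation_design(models, parameters, effects, spearman = sp, seed = seed)
}

#' Simulate composite scores with planted severity strata
#'
#' Direct simulation on the composite-score scale: each stratum draws its
#' scores from a normal with the given mean and SD. Stratum order follows
#' severity (first stratum = lowest mean = worst = level `k`). Used to
#' validate threshold recovery of the clustering stage against known
#' boundaries (the midpoints of adjacent stratum means).
#'
#' @param n_per_stratum Animals per stratum (default 60).
#' @param means Stratum means on the composite scale, ascending
#'   (default `c(-4, 0, 2)`).
#' @param sd Within-stratum SD (default 0.8).
#' @param seed Integer seed.
#' @return A list with `scores` (a `composite_scores`-shaped data frame),
#'   `true_level` (planted severity level per animal, k = worst) and
#'   `true_boundaries` (midpoints between adjacent stratum means,
#'   ascending).
#' @export
simulate_severity_strata <- function(n_per_stratum = 60L, means = c(-4, 0, 2),
                                     sd = 0.8, seed = 1L) {
  stopifnot(!is.unsorted(means, strictly = TRUE), sd > 0)
  k <- length(means)
  set.seed(derive_seed(seed, "strata"))
  n_per_stratum <- rep_len(n_per_stratum, k)
  score <- unlist(lapply(seq_len(k), function(i)
    stats::rnorm(n_per_stratum[i], means[i], sd)))
  true_level <- rep(seq(k, 1L), n_per_stratum)   # lowest mean = worst level
  n <- length(score)
  out <- data.frame(animal_id = sprintf("S%03d", seq_len(n)),
                    group = "simulated", model = "strata",
                    score = score, n_contributing = k, flag = "ok",
                    stringsAsFactors = FALSE)
  class(out) <- c("composite_scores", "data.frame")
  list(scores = out, true_level = true_level,
       true_boundaries = (means[-k] + means[-1]) / 2)
}

#' Write the packaged tutorial battery
#'
#' Generates the reference synthetic study — 3 models x 3 groups, 205
#' animals, 13 core parameters plus 2 sparsely measured columns (afterdischarge
#' threshold, PET uptake; > 20% missing, measured in single subprojects
#' only) and 2 columns excluded by domain judgement (body-weight change
#' and seizure frequency) — and writes the battery CSV, the parameter
#' spec YAML and the ground-truth JSON. The effect pattern mirrors a
#' post-status-epilepticus-dominated severity profile: both post-SE-like
#' models carry effects on the 4 informative parameters, the kindling-like
#' model on none.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces the files
#'   byte-identically.
#' @param d Standardized effect size in the affected treated groups
#'   (default 2.5, strong enough that treated post-SE-like animals form a
#'   distinct severity stratum).
#' @return Invisibly, a list with paths `battery`, `spec`, `truth`.
#' @export
simulate_reference_fixture <- function(dir, seed = 1L, d = 2.5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  des <- design_planted_battery(
    n_per_group = c(21, 23, 24), d = d,
    affected_models = c("chemical_post_se", "electrical_post_se"),
    missingness = 0.05, seed = seed)
  # counts 3x(21,23,24) = 204; add one extra naive kindling animal -> 205
  des$models$kindling["naive"] <- des$models$kindling["naive"] + 1L
  sim <- simulate_battery(des)
  tab <- sim$table
  n <- length(tab$animal_id)
  set.seed(derive_seed(seed, "fixture_extras"))
  # sparse single-subproject columns (> 20% missing, removed by the filter)
  adt <- stats::rnorm(n, 180, 45)
  adt[tab$model != "kindling"] <- NA_real_
  pet <- stats::rnorm(n, 1.4, 0.3)
  pet[stats::runif(n) < 0.70] <- NA_real_
  # columns excluded by domain judgement, not by missingness
  epileptic <- tab$group == "treated" & tab$model != "kindling"
  weight_change <- stats::rnorm(n, 12, 6) + ifelse(epileptic, 25, 0)
  seizure_freq <- ifelse(epileptic, stats::rpois(n, 10), 0)
  vals <- cbind(tab$values, adt_threshold = adt, pet_uptake = pet,
                body_weight_change = weight_change,
                seizure_frequency = seizure_freq)
  full <- parameter_table(vals, tab$animal_id, tab$group, tab$model)
  par <- des$parameters
  spec <- parameter_spec(
    c(par$name, "adt_threshold", "pet_uptake", "body_weight_change",
      "seizure_frequency"),
    direction = c(par$direction, -1, -1, -1, -1),
    excluded = c(rep(FALSE, nrow(par)), FALSE, FALSE, TRUE, TRUE),
    note = c(rep("", nrow(par)), "kindling subproject only",
             "imaging subproject only",
             "confounded by seizure-associated hyperphagia",
             "disease phenotype measure, present only in epileptic animals"))
  paths <- list(battery = file.path(dir, "battery.csv"),
                spec = file.path(dir, "parameter_spec.yaml"),
                truth = file.path(dir, "truth.json"))
  write_parameter_table(full, paths$battery)
  write_parameter_spec(spec, paths$spec)
  write_report_json(list(informative = sim$truth$informative,
                         effect_size = d, seed = seed,
                         affected_models = c("chemical_post_se",
                                             "electrical_post_se")),
                    paths$truth)
  invisible(paths)
}
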