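test_that("subsample draws partition the animals and are run-reproducible", {
  rc <- resample_config(n_runs = 10, train_fraction = 0.8, seed = 42)
  sp <- draw_subsample(10, rc, 1)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:10)

  # same (seed, run_index) twice -> identical sets
  expect_identical(draw_subsample(10, rc, 3), draw_subsample(10, rc, 3))
  # different run_index -> a different draw (with overwhelming probability)
  expect_false(identical(draw_subsample(100, rc, 1)$train,
                         draw_subsample(100, rc, 2)$train))

  # 100 runs at n = 205: every training set has round(0.8 * 205) = 164 animals
  sizes <- vapply(1:100, function(r) length(draw_subsample(205, rc, r)$train), 0L)
  expect_true(all(sizes == 164L))
})

test_that("stratified subsampling preserves group proportions within rounding", {
  rc <- resample_config(seed = 1, stratify_by_group = TRUE)
  groups <- rep(c("naive", "sham", "treated"), c(10, 20, 30))
  sp <- draw_subsample(60, rc, 1, groups = groups)
  expect_equal(as.numeric(table(groups[sp$train])), c(8, 16, 24))
  expect_error(draw_subsample(60, rc, 1), "requires per-animal group labels")
})

test_that("PCA matches an independent eigen-solver and fixes loading signs", {
  set.seed(14)
  x <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("p", 1:5)))
  pc <- pca_decompose(x)
  ref <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(pc$explained, as.numeric(ref$sdev^2 / sum(ref$sdev^2)),
               tolerance = 1e-8)
  for (j in 1:5) {
    # same axis up to sign; our convention pins the sign
    expect_equal(abs(pc$loadings[, j]), abs(ref$rotation[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  # explained fractions are non-increasing and sum to 1
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1)
})

test_that("two perfectly correlated columns put all variance on one component", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  # equalize variances so loadings are symmetric
  x <- scale(x)
  pc <- pca_decompose(x)
  expect_equal(pc$explained[1], 1)
  expect_equal(as.numeric(abs(pc$loadings[, 1])), c(1, 1) * sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("component choice is a pass-through in fixed mode and F-driven in auto", {
  set.seed(2)
  scores <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  groups <- rep(c("ctrl", "trt"), 15)
  fixed <- choose_component(scores, groups, selection_config(component = 2))
  expect_equal(fixed$component, 2L)

  # plant separation on component 2
  scores[groups == "trt", 2] <- scores[groups == "trt", 2] + 5
  auto <- choose_component(scores, groups, selection_config())
  expect_equal(as.integer(auto$component), 2L)
  expect_equal(unname(which.max(auto$f_statistics)), 2L)
  expect_error(choose_component(scores, NULL, selection_config()),
               "requires group labels")
})

test_that("indistinguishable groups flag ambiguous component choice under the null", {
  set.seed(77)
  hits <- 0
  for (r in 1:20) {
    scores <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, paste0("PC", 1:3)))
    ch <- choose_component(scores, rep(c("a", "b"), 20), selection_config())
    if (ch$ambiguous) hits <- hits + 1
  }
  # with no group effect, even the best component's F is usually at chance
  # level, so most null runs carry the instability flag
  expect_gt(hits, 10)
})

test_that("one exhaustive run gives every parameter frequency one", {
  set.seed(6)
  tab <- make_table(matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))),
                    group = rep(c("ctrl", "trt"), 10))
  scaled <- preprocess_table(tab, boxcox = FALSE)
  res <- run_stability_selection(scaled,
                                 resample_config(n_runs = 1, seed = 9),
                                 selection_config(top_k = 3, n_selected = 3))
  expect_true(all(res$frequency == 1L))
})

test_that("frequencies conserve n_runs * top_k and results are deterministic", {
  set.seed(10)
  sim <- simulate_battery(design_planted_battery(n_per_group = 8, d = 1.5,
                                                 missingness = 0, seed = 3))
  scaled <- preprocess_table(sim$table, boxcox = FALSE)
  rc <- resample_config(n_runs = 25, seed = 5)
  sc <- selection_config(top_k = 4)
  res1 <- run_stability_selection(scaled, rc, sc)
  expect_equal(sum(res1$frequency), 25L * 4L)
  expect_true(all(res1$frequency <= 25L))
  # identical inputs and configs reproduce the result bit-for-bit
  res2 <- run_stability_selection(scaled, rc, sc)
  expect_identical(res1$frequency, res2$frequency)
  expect_identical(res1$selected, res2$selected)
  expect_identical(res1$mean_explained, res2$mean_explained)
})

test_that("planted informative parameters are recovered by the selection", {
  sim <- simulate_battery(design_planted_battery(d = 1.5, missingness = 0.05,
                                                 seed = 101))
  scaled <- preprocess_table(sim$table, boxcox = TRUE)
  res <- run_stability_selection(scaled,
                                 resample_config(n_runs = 100, seed = 101),
                                 selection_config())
  expect_setequal(res$selected, sim$truth$informative)
  expect_true(all(res$frequency[sim$truth$informative] >= 95L))
})

test_that("null data keeps every frequency below the binomial bound", {
  # one run on each of 100 independent null datasets: top-4 membership is
  # then exchangeable across the 13 parameters and binomial per parameter
  freq <- NULL
  for (s in 1:100) {
    des <- design_planted_battery(n_per_group = 5, d = 0, missingness = 0,
                                  seed = 1000 + s)
    des$spearman <- diag(13)
    des$latent <- diag(13)
    sim <- simulate_battery(des)
    scaled <- preprocess_table(sim$table, boxcox = FALSE)
    res <- run_stability_selection(scaled,
                                   resample_config(n_runs = 1, seed = s),
                                   selection_config())
    f <- res$frequency
    freq <- if (is.null(freq)) f else freq + f
  }
  bound <- qbinom(0.999, 100, 4 / 13)   # Bonferroni-ish across 13 parameters
  expect_true(all(freq <= bound))
})

test_that("Spearman matrix matches a rank-then-Pearson oracle, ties included", {
  x <- c(1, 2, 2, 4)
  y <- c(2, 3, 3, 5)
  tab <- make_table(cbind(x = x, y = y))
  rho <- spearman_correlation_matrix(tab)
  expect_equal(rho["x", "y"], oracle_spearman(x, y), tolerance = 1e-12)

  mono <- make_table(cbind(up = 1:6, up2 = c(2, 5, 9, 14, 20, 27),
                           down = c(30, 25, 19, 12, 4, 1)))
  r2 <- spearman_correlation_matrix(mono)
  expect_equal(r2["up", "up2"], 1)
  expect_equal(r2["up", "down"], -1)
  expect_equal(diag(r2), c(up = 1, up2 = 1, down = 1))
  expect_true(all(abs(r2) <= 1 + 1e-12))
  expect_identical(r2, t(r2))
})

test_that("pairwise-complete handling uses available pairs and warns when too few", {
  vals <- cbind(a = c(1, 2, 3, 4, 5, NA), b = c(2, 4, 6, 8, NA, 12),
                c = c(9, NA, 1, 2, 5, 6))
  tab <- make_table(vals)
  rho <- spearman_correlation_matrix(tab)
  expect_equal(rho["a", "b"], oracle_spearman(vals[, "a"], vals[, "b"]),
               tolerance = 1e-12)

  # a pair sharing < 3 complete observations becomes NA with a warning
  sparse <- cbind(p = c(1, 2, NA, NA, 7, 8), q = c(NA, NA, 3, 4, 5, NA),
                  r = 1:6)
  expect_warning(rho2 <- spearman_correlation_matrix(make_table(sparse)),
                 "< 3 complete")
  expect_true(is.na(rho2["p", "q"]))
  expect_equal(diag(rho2), c(p = 1, q = 1, r = 1))
})
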