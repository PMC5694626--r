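test_that("linear-kernel row-space reduction leaves SVM predictions unchanged", {
  set.seed(55)
  X <- matrix(rnorm(40 * 300), 40, 300)
  X[1:20, 1:15] <- X[1:20, 1:15] + 0.8
  y <- factor(rep(c("a", "b"), each = 20))
  tr <- c(1:14, 21:34); te <- setdiff(1:40, tr)
  red <- eigensynth:::reduce_linear(X[tr, ], X[te, ])
  for (cost in c(0.01, 1, 100)) {
    raw <- e1071::svm(x = X[tr, ], y = y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    rot <- e1071::svm(x = red$train, y = y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    expect_identical(as.character(predict(raw, X[te, ])),
                     as.character(predict(rot, red$test)))
  }
})

test_that("sensitivity and specificity follow the positive-class convention", {
  truth <- factor(c("d", "d", "d", "n", "n"))
  pred <- factor(c("d", "n", "d", "n", "d"), levels = c("d", "n"))
  m <- eigensynth:::binary_metrics(truth, pred, "d")
  expect_equal(unname(m), c(3 / 5, 2 / 3, 1 / 2))
})

test_that("VAF accuracy is at chance for identical populations and perfect when separable", {
  # two labels drawn from one population
  ph <- one_class_population(n = 60, seed = 404)
  ds <- ph$dataset
  ds$labels <- factor(rep(c("P", "Q"), 30))
  r <- vaf_cross_validate(ds, "P", "Q", folds = 5, seed = 3)
  g <- glance(r)
  expect_lt(abs(g$accuracy - 0.5), 3 * max(g$accuracy_sd, 0.05))
  # separable phantom: every fold perfect
  sep <- separable_two_class()
  rs <- vaf_cross_validate(sep$dataset, "DIS", "CON", folds = 5, seed = 3)
  expect_true(all(tidy(rs)$accuracy == 1))
  # permuting the labels of the separable problem collapses it to chance
  perm <- sep$dataset
  withr::with_seed(8, perm$labels <- sample(perm$labels))
  rp <- vaf_cross_validate(perm, "DIS", "CON", folds = 5, seed = 3)
  expect_lt(glance(rp)$accuracy, 0.75)
  expect_error(vaf_cross_validate(sep$dataset, "DIS", "CON", folds = 25),
               class = "eigensynth_configuration_error")
})

test_that("synthetic-trained classifiers generalize to held-out real data", {
  sep <- separable_two_class()
  r <- experiment_generalization(sep$dataset, "DIS", "CON",
                                 estimator = "mvn", n_per_class = 60,
                                 folds = 5, seed = 11)
  expect_gte(glance(r)$accuracy, 0.95)
})

test_that("truncation below the signal component destroys generalization", {
  # class signal injected on ground-truth mode 3 only: with L = 1 the
  # synthesis cannot carry it
  spec <- phantom_spec(shape = c(12, 12, 12),
                       n_per_class = c(DIS = 16, CON = 16),
                       latent_dim = 3, latent_sd = c(2.5, 1.2, 0.3),
                       noise_sd = 0.05, smoothing_fwhm = 1.5, seed = 77)
  ph <- generate_phantom(spec)
  ds <- ph$dataset
  shift <- ph$truth$modes[, 3] * 1.2
  dis <- ds$labels == "DIS"
  ds$data[dis, ] <- sweep(ds$data[dis, ], 2, shift, `+`)
  full <- experiment_generalization(ds, "DIS", "CON", estimator = "mvn",
                                    folds = 4, n_per_class = 40, seed = 5)
  trunc <- experiment_generalization(ds, "DIS", "CON", estimator = "mvn",
                                     L = 1, folds = 4, n_per_class = 40,
                                     seed = 5)
  expect_gte(glance(full)$accuracy, 0.9)
  expect_lt(glance(trunc)$accuracy, 0.75)
})

test_that("no training statistic leaks from the held-out fold", {
  sep <- separable_two_class()
  base <- experiment_generalization(sep$dataset, "DIS", "CON",
                                    estimator = "mvn", n_per_class = 30,
                                    folds = 4, seed = 21)
  # corrupt one subject; in the fold where it is held out the training
  # portion (hence chosen cost and trained model) must be unchanged
  corrupted <- sep$dataset
  corrupted$data[1, ] <- corrupted$data[1, ] * 10
  alt <- experiment_generalization(corrupted, "DIS", "CON",
                                   estimator = "mvn", n_per_class = 30,
                                   folds = 4, seed = 21)
  fold_of_1 <- withr::with_seed(21, {
    eigensynth:::stratified_folds(sep$dataset$labels, 4)
  })[1]
  expect_identical(tidy(base)$cost[fold_of_1], tidy(alt)$cost[fold_of_1])
})

test_that("optimal-L selection returns the highest in-band candidate or warns", {
  sep <- separable_two_class()
  sel <- select_optimal_L(sep$dataset, "DIS", "CON", estimator = "mvn",
                          L_grid = c(2), folds = 4, n_per_class = 30,
                          seed = 31)
  expect_s3_class(sel, "optimal_L_selection")
  expect_equal(sel$L, 2L)
  # impossible band: fall back to the closest candidate with a warning
  fake <- sel$baseline
  fake$summary$mean[1] <- 0.2
  fake$summary$sd[1] <- 1e-6
  expect_warning(
    sel2 <- select_optimal_L(sep$dataset, "DIS", "CON", estimator = "mvn",
                             L_grid = c(2), folds = 4, n_per_class = 30,
                             seed = 31, baseline = fake),
    "closest")
  expect_equal(sel2$L, 2L)
})

test_that("two-sample t statistics agree with t.test and handle zero variance", {
  set.seed(61)
  A <- matrix(rnorm(8 * 5), 8, 5)
  B <- matrix(rnorm(10 * 5, mean = 0.5), 10, 5)
  res <- tmap_two_sample(A, B, correction = "bonferroni")
  oracle <- stats::t.test(A[, 3], B[, 3], var.equal = TRUE)$statistic
  expect_equal(res$t_values[3], unname(oracle), tolerance = 1e-12)
  expect_equal(res$df, 16L)
  expect_equal(res$threshold, qt(1 - 0.05 / (2 * 5), 16))
  # identical constant groups: t = 0 by convention, nothing significant
  C <- matrix(1, 2, 4)
  rz <- tmap_two_sample(C, C, correction = "bonferroni")
  expect_true(all(rz$t_values == 0))
  expect_false(any(rz$significant_mask))
  expect_error(tmap_two_sample(A[1, , drop = FALSE], B),
               class = "eigensynth_configuration_error")
  expect_error(tmap_two_sample(A, B[, 1:3]),
               class = "eigensynth_dimension_error")
})

test_that("t-maps are null on shuffled populations and localize a planted effect", {
  ph <- one_class_population(n = 100, seed = 505)
  X <- ph$dataset$data
  withr::with_seed(9, idx <- sample(100, 50))
  null_res <- tmap_two_sample(X[idx, ], X[-idx, ],
                              correction = "permutation", n_perm = 200,
                              seed = 13)
  expect_equal(sum(null_res$significant_mask), 0)
  # planted effect: 2-SD offset inside a known sphere
  sd_vox <- mean(apply(X, 2, sd))
  region <- which(eigensynth:::sphere_mask(c(14, 14, 14), c(7, 7, 7),
                                           2.5)[ph$dataset$mask])
  Xe <- X
  Xe[1:50, region] <- Xe[1:50, region] + 2 * sd_vox
  eff <- tmap_two_sample(Xe[1:50, ], Xe[51:100, ],
                         correction = "permutation", n_perm = 200, seed = 13)
  hits <- which(eff$significant_mask)
  expect_gt(length(hits), 0)
  expect_gte(mean(hits %in% region), 0.9)
  # original-vs-original and effect maps agree where it matters (Dice)
  bon <- tmap_two_sample(Xe[1:50, ], Xe[51:100, ], correction = "bonferroni")
  dice <- 2 * sum(bon$significant_mask & eff$significant_mask) /
    (sum(bon$significant_mask) + sum(eff$significant_mask))
  expect_gte(dice, 0.5)
})

test_that("permutation maxT controls the family-wise error under the global null", {
  fwe <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    sp <- phantom_spec(shape = c(8, 8, 8), n_per_class = c(A = 16),
                       latent_dim = 2, latent_sd = c(0.4, 0.2),
                       seed = 9000 + r)
    d <- generate_phantom(sp)$dataset
    tm <- tmap_two_sample(d$data[1:8, ], d$data[9:16, ],
                          correction = "permutation", n_perm = 100,
                          seed = 9500 + r)
    if (any(tm$significant_mask)) fwe <- fwe + 1
  }
  expect_lte(fwe / reps, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("report objects tidy, glance and plot cleanly", {
  sep <- separable_two_class()
  r <- vaf_cross_validate(sep$dataset, "DIS", "CON", folds = 4, seed = 3)
  expect_named(glance(r),
               c("accuracy", "accuracy_sd", "sensitivity", "sensitivity_sd",
                 "specificity", "specificity_sd", "folds"))
  expect_equal(nrow(tidy(r)), 4)
  expect_s3_class(autoplot(r), "ggplot")
  tm <- tmap_two_sample(sep$dataset$data[1:10, ], sep$dataset$data[21:30, ],
                        correction = "bonferroni")
  expect_s3_class(plot_tmap_slice(tm, sep$dataset$mask,
                                  sep$dataset$geometry), "ggplot")
  eb <- fit_eigenbrains(sep$dataset)
  expect_s3_class(autoplot(eb), "ggplot")
  expect_equal(sum(tidy(eb)$variance_explained), 1)
})
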