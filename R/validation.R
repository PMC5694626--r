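#' @name validation
#' @title Validation battery for synthetic neuroimage datasets
#' @description Voxels-as-features (VAF) linear SVM classification with
#'   nested cross-validation, the synthetic-training generalization
#'   experiment, the resubstitution/dependence experiment, the optimal-L
#'   selection rule, and mass-univariate two-sample t-maps with
#'   family-wise error control.
NULL

# stratified fold assignment; deterministic given the RNG state
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Lossless dimensionality reduction for the linear kernel: the SVM weight
# vector lives in the span of the training rows, so expressing training
# rows in an orthonormal basis of their own row space (and projecting test
# rows onto it) leaves every inner product with training vectors, and hence
# every prediction, unchanged.
reduce_linear <- function(train, test) {
  if (ncol(train) <= nrow(train)) {
    return(list(train = train, test = test))
  }
  sv <- svd(train)
  r <- sum(sv$d > max(sv$d, 1e-300) * 1e-12)
  r <- max(r, 1L)
  V <- sv$v[, seq_len(r), drop = FALSE]
  list(train = sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)],
                                                         r, r),
       test = test %*% V)
}

svm_fit <- function(x, y, cost) {
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

binary_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# inner-CV choice of the SVM cost on the training portion only
choose_cost <- function(x, y, inner_folds, c_grid) {
  if (length(c_grid) == 1L) return(c_grid)
  fold <- stratified_folds(y, inner_folds)
  acc <- vapply(c_grid, function(cc) {
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr], cc)
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  c_grid[which.max(acc)]  # ties -> smallest cost (grid is ascending)
}

classifier_report <- function(fold_tbl, positive_class, config) {
  summary <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    mean = c(mean(fold_tbl$accuracy), mean(fold_tbl$sensitivity, na.rm = TRUE),
             mean(fold_tbl$specificity, na.rm = TRUE)),
    sd = c(sd(fold_tbl$accuracy), sd(fold_tbl$sensitivity, na.rm = TRUE),
           sd(fold_tbl$specificity, na.rm = TRUE)))
  if (nrow(fold_tbl) == 1L) summary$sd <- 0
  structure(list(summary = summary, folds = fold_tbl,
                 positive_class = positive_class, config = config),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<classifier_report> positive class '%s', %d fold(s)\n",
              x$positive_class, nrow(x$folds)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f [%.3f]\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) x$folds

#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(accuracy = s$mean[1], accuracy_sd = s$sd[1],
                 sensitivity = s$mean[2], sensitivity_sd = s$sd[2],
                 specificity = s$mean[3], specificity_sd = s$sd[3],
                 folds = nrow(x$folds))
}

#' Fold-metric plot of a classifier report
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot of per-fold accuracy/sensitivity/specificity.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- object$folds |>
    tidyr_longer()
  ggplot2::ggplot(df, ggplot2::aes(.data$fold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "rate") +
    ggplot2::theme_minimal()
}

tidyr_longer <- function(folds) {
  purrr::map_dfr(c("accuracy", "sensitivity", "specificity"), function(m)
    tibble::tibble(fold = folds$fold, metric = m, value = folds[[m]]))
}

#' Voxels-as-features cross-validated linear SVM
#'
#' The baseline classification analysis: a linear-kernel SVM on raw voxel
#' intensities, stratified 10-fold outer cross-validation, with the
#' regularization constant `C` chosen per fold by grid search in an inner
#' 5-fold loop on the training portion only. `class_a` is the positive
#' class for sensitivity/specificity (list the disease class first).
#'
#' @param dataset A [voxel_dataset()].
#' @param class_a,class_b The two classes to discriminate; each must have
#'   at least `folds` subjects.
#' @param folds Outer folds (default 10).
#' @param inner_folds Inner folds for the C grid search (default 5).
#' @param c_grid Ascending candidate costs (default
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param seed Seed controlling fold assignment (and inner splits).
#' @return A `classifier_report`: `summary` tibble (metric, mean, sd),
#'   per-fold tibble `folds` (including the chosen cost), the positive
#'   class and the configuration.
#' @export
vaf_cross_validate <- function(dataset, class_a, class_b, folds = 10,
                               inner_folds = 5,
                               c_grid = c(0.01, 0.1, 1, 10, 100),
                               seed = 1L) {
  keep <- dataset$labels %in% c(class_a, class_b)
  X <- dataset$data[keep, , drop = FALSE]
  y <- factor(as.character(dataset$labels[keep]),
              levels = c(class_a, class_b))
  if (any(table(y) < folds)) {
    abort("each class needs at least `folds` subjects.",
          class = "eigensynth_configuration_error")
  }
  withr::with_seed(seed, {
    fold <- stratified_folds(y, folds)
    fold_rows <- lapply(seq_len(folds), function(f) {
      tr <- fold != f
      red <- reduce_linear(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      cost <- choose_cost(red$train, y[tr], inner_folds, c_grid)
      fit <- svm_fit(red$train, y[tr], cost)
      pred <- predict(fit, red$test)
      m <- binary_metrics(y[!tr], pred, class_a)
      tibble::tibble(fold = f, accuracy = m[1], sensitivity = m[2],
                     specificity = m[3], cost = cost)
    })
  })
  classifier_report(dplyr::bind_rows(fold_rows), class_a,
                    list(folds = folds, inner_folds = inner_folds,
                         c_grid = c_grid, seed = seed))
}

#' Generalization experiment: train on synthetic, test on real
#'
#' Within each outer cross-validation fold, the eigenbrain basis and the
#' per-class latent densities are fitted on the real training portion
#' ONLY; a synthetic set (`n_per_class` images per class) is drawn from
#' them; the SVM is trained on the synthetic images and tested on the
#' held-out real fold. No held-out subject influences the basis, the
#' densities, or any training statistic.
#'
#' @inheritParams vaf_cross_validate
#' @param estimator `"mvn"` or `"kde"`.
#' @param L Truncation level for the fold models (capped at each fold's
#'   rank); `NULL` = full rank.
#' @param n_per_class Synthetic subjects drawn per class each fold
#'   (default 200).
#' @return A `classifier_report` on the real held-out folds.
#' @export
experiment_generalization <- function(dataset, class_a, class_b,
                                      estimator = c("mvn", "kde"),
                                      L = NULL, n_per_class = 200,
                                      folds = 10, inner_folds = 5,
                                      c_grid = c(0.01, 0.1, 1, 10, 100),
                                      seed = 1L) {
  estimator <- match.arg(estimator)
  keep <- which(dataset$labels %in% c(class_a, class_b))
  sub <- subset_subjects(dataset, keep)
  y <- factor(as.character(sub$labels), levels = c(class_a, class_b))
  sub$labels <- y
  if (any(table(y) < folds)) {
    abort("each class needs at least `folds` subjects.",
          class = "eigensynth_configuration_error")
  }
  withr::with_seed(seed, {
    fold <- stratified_folds(y, folds)
    synth_seeds <- sample.int(.Machine$integer.max %/% 2, folds)
    fold_rows <- lapply(seq_len(folds), function(f) {
      tr <- fold != f
      train_ds <- subset_subjects(sub, which(tr))
      model <- fit_synthesis_model(train_ds, estimator = estimator,
                                   L = if (is.null(L)) NULL else
                                     min(L, nrow(train_ds$data) - 1L))
      syn <- synthesize_dataset(model, n_per_class, seed = synth_seeds[f])
      ys <- factor(as.character(syn$labels), levels = levels(y))
      red <- reduce_linear(syn$data, sub$data[!tr, , drop = FALSE])
      cost <- choose_cost(red$train, ys, inner_folds, c_grid)
      fit <- svm_fit(red$train, ys, cost)
      pred <- predict(fit, red$test)
      m <- binary_metrics(y[!tr], pred, class_a)
      tibble::tibble(fold = f, accuracy = m[1], sensitivity = m[2],
                     specificity = m[3], cost = cost)
    })
  })
  classifier_report(dplyr::bind_rows(fold_rows), class_a,
                    list(folds = folds, inner_folds = inner_folds,
                         c_grid = c_grid, seed = seed, estimator = estimator,
                         L = L, n_per_class = n_per_class))
}

#' Resubstitution experiment: dependence of synthetic images on their source
#'
#' Trains the SVM on ALL real data (cost chosen by inner CV) and reports
#' (A) resubstitution accuracy — testing on the training data itself —
#' and (B) accuracy on synthetic test sets generated from that same data.
#' The gap A - B measures how independent the synthetic images are from
#' their source: near-zero gap means the synthesis reproduces the training
#' set (overfitting); a gap comparable to the real generalization loss
#' means genuinely new images.
#'
#' @inheritParams experiment_generalization
#' @param n_repeats Number of independent synthetic test sets; their
#'   spread gives the SD of report B.
#' @return List with `resubstitution` and `synthetic_test`, both
#'   `classifier_report`s (the synthetic report has one "fold" per
#'   repeat).
#' @export
experiment_resubstitution <- function(dataset, class_a, class_b,
                                      estimator = c("mvn", "kde"),
                                      L = NULL, n_per_class = 200,
                                      n_repeats = 5, inner_folds = 5,
                                      c_grid = c(0.01, 0.1, 1, 10, 100),
                                      seed = 1L) {
  estimator <- match.arg(estimator)
  keep <- which(dataset$labels %in% c(class_a, class_b))
  sub <- subset_subjects(dataset, keep)
  y <- factor(as.character(sub$labels), levels = c(class_a, class_b))
  sub$labels <- y
  withr::with_seed(seed, {
    model <- fit_synthesis_model(sub, estimator = estimator,
                                 L = if (is.null(L)) NULL else
                                   min(L, nrow(sub$data) - 1L))
    synth_seeds <- sample.int(.Machine$integer.max %/% 2, n_repeats)
    syn_sets <- lapply(synth_seeds, function(s)
      synthesize_dataset(model, n_per_class, seed = s))
    all_test <- do.call(rbind, lapply(syn_sets, function(s) s$data))
    red <- reduce_linear(sub$data, all_test)
    cost <- choose_cost(red$train, y, inner_folds, c_grid)
    fit <- svm_fit(red$train, y, cost)
    m_res <- binary_metrics(y, predict(fit, red$train), class_a)
    resub <- classifier_report(
      tibble::tibble(fold = 1L, accuracy = m_res[1], sensitivity = m_res[2],
                     specificity = m_res[3], cost = cost),
      class_a, list(seed = seed, estimator = estimator, L = L))
    offsets <- c(0L, cumsum(vapply(syn_sets, function(s) nrow(s$data),
                                   integer(1))))
    rep_rows <- lapply(seq_along(syn_sets), function(r) {
      rows <- (offsets[r] + 1L):offsets[r + 1L]
      ys <- factor(as.character(syn_sets[[r]]$labels), levels = levels(y))
      m <- binary_metrics(ys, predict(fit, red$test[rows, , drop = FALSE]),
                          class_a)
      tibble::tibble(fold = r, accuracy = m[1], sensitivity = m[2],
                     specificity = m[3], cost = cost)
    })
  })
  syn_rep <- classifier_report(dplyr::bind_rows(rep_rows), class_a,
                               list(seed = seed, estimator = estimator,
                                    L = L, n_per_class = n_per_class,
                                    n_repeats = n_repeats))
  list(resubstitution = resub, synthetic_test = syn_rep)
}

#' Optimal-L selection by the one-standard-deviation rule
#'
#' Sweeps the truncation level over `L_grid`, running the generalization
#' experiment at each L, and returns the HIGHEST L whose mean accuracy
#' lies within one baseline standard deviation of the baseline (real-data)
#' accuracy. A higher-performing synthetic model is treated as suspect
#' (overfitting), not better. If no candidate falls in the band, the L
#' with accuracy closest to baseline is returned with a warning.
#'
#' @inheritParams experiment_generalization
#' @param L_grid Integer candidate truncation levels.
#' @param baseline Optional precomputed [vaf_cross_validate()] report on
#'   the real data; computed here when `NULL`.
#' @return List of class `optimal_L_selection`: `L` (the chosen integer),
#'   `sweep` (tibble: L, accuracy, accuracy_sd, in_band), `baseline`.
#' @export
select_optimal_L <- function(dataset, class_a, class_b,
                             estimator = c("mvn", "kde"), L_grid,
                             n_per_class = 200, folds = 10, inner_folds = 5,
                             c_grid = c(0.01, 0.1, 1, 10, 100),
                             seed = 1L, baseline = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(baseline)) {
    baseline <- vaf_cross_validate(dataset, class_a, class_b, folds = folds,
                                   inner_folds = inner_folds,
                                   c_grid = c_grid, seed = seed)
  }
  base <- glance(baseline)
  sweep_tbl <- purrr::map_dfr(sort(unique(as.integer(L_grid))), function(l) {
    rep <- experiment_generalization(dataset, class_a, class_b,
                                     estimator = estimator, L = l,
                                     n_per_class = n_per_class, folds = folds,
                                     inner_folds = inner_folds,
                                     c_grid = c_grid, seed = seed)
    g <- glance(rep)
    tibble::tibble(L = l, accuracy = g$accuracy, accuracy_sd = g$accuracy_sd)
  })
  band <- c(base$accuracy - base$accuracy_sd, base$accuracy + base$accuracy_sd)
  sweep_tbl$in_band <- sweep_tbl$accuracy >= band[1] &
    sweep_tbl$accuracy <= band[2]
  if (any(sweep_tbl$in_band)) {
    L_opt <- max(sweep_tbl$L[sweep_tbl$in_band])
  } else {
    L_opt <- sweep_tbl$L[which.min(abs(sweep_tbl$accuracy - base$accuracy))]
    warn(sprintf(
      "no candidate L within 1 SD of baseline accuracy %.3f; returning closest (L = %d).",
      base$accuracy, L_opt))
  }
  structure(list(L = as.integer(L_opt), sweep = sweep_tbl,
                 baseline = baseline, band = band),
            class = "optimal_L_selection")
}

#' @export
print.optimal_L_selection <- function(x, ...) {
  cat(sprintf("<optimal_L_selection> L = %d (baseline band [%.3f, %.3f])\n",
              x$L, x$band[1], x$band[2]))
  print(x$sweep)
  invisible(x)
}

#' Sweep plot of the optimal-L selection
#'
#' @param object An `optimal_L_selection`.
#' @param ... Unused.
#' @return A ggplot of accuracy vs L with the baseline one-SD band.
#' @method autoplot optimal_L_selection
#' @export
autoplot.optimal_L_selection <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(.data$L, .data$accuracy)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$band[1], ymax = object$band[2],
                      alpha = 0.2, fill = "grey40") +
    ggplot2::geom_hline(yintercept = glance(object$baseline)$accuracy,
                        linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$L, colour = "firebrick") +
    ggplot2::labs(y = "synthetic-trained accuracy") +
    ggplot2::theme_minimal()
}

pooled_t <- function(A, B) {
  Ka <- nrow(A); Kb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums(sweep(A, 2L, ma)^2)
  vb <- colSums(sweep(B, 2L, mb)^2)
  sp2 <- (va + vb) / (Ka + Kb - 2)
  se <- sqrt(sp2 * (1 / Ka + 1 / Kb))
  t <- (ma - mb) / se
  t[se == 0] <- 0  # zero-variance voxels by convention
  t
}

#' Mass-univariate two-sample t-map with family-wise error control
#'
#' Computes a pooled-variance two-sample t statistic per voxel
#' (`df = K_a + K_b - 2`; zero-variance voxels yield t = 0) and a
#' two-sided FWE-corrected threshold: either Bonferroni
#' (`qt(1 - alpha/(2N), df)`) or permutation maxT — the `(1 - alpha)`
#' quantile of the maximum |t| over label permutations, with the observed
#' labelling included in the null set so the test is exact-conservative.
#' A voxel is significant iff `|t| > threshold`.
#'
#' @param group_a,group_b Numeric matrices (subjects x voxels), equal
#'   voxel counts, at least 2 rows each.
#' @param correction `"bonferroni"` or `"permutation"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @return Object of class `tmap_result`: `t_values`, `threshold`,
#'   `significant_mask` (logical), `correction`, `alpha`, `df`.
#' @export
tmap_two_sample <- function(group_a, group_b,
                            correction = c("bonferroni", "permutation"),
                            alpha = 0.05, n_perm = 1000, seed = 1L) {
  correction <- match.arg(correction)
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) {
    abort("groups must have equal voxel counts.",
          class = "eigensynth_dimension_error")
  }
  if (nrow(A) < 2L || nrow(B) < 2L) {
    abort("each group needs at least 2 subjects.",
          class = "eigensynth_configuration_error")
  }
  t_obs <- pooled_t(A, B)
  N <- ncol(A)
  df <- nrow(A) + nrow(B) - 2L
  if (correction == "bonferroni") {
    threshold <- qt(1 - alpha / (2 * N), df)
  } else {
    X <- rbind(A, B)
    Ka <- nrow(A)
    maxT <- withr::with_seed(seed, {
      c(max(abs(t_obs)),
        vapply(seq_len(n_perm - 1L), function(b) {
          idx <- sample.int(nrow(X), Ka)
          max(abs(pooled_t(X[idx, , drop = FALSE],
                           X[-idx, , drop = FALSE])))
        }, numeric(1)))
    })
    sorted <- sort(maxT)
    threshold <- sorted[ceiling((1 - alpha) * n_perm)]
  }
  structure(list(t_values = t_obs, threshold = threshold,
                 significant_mask = abs(t_obs) > threshold,
                 correction = correction, alpha = alpha, df = df,
                 n_perm = if (correction == "permutation") n_perm else NA_integer_),
            class = "tmap_result")
}

#' @export
print.tmap_result <- function(x, ...) {
  cat(sprintf(
    "<tmap_result> %s FWE at alpha = %.2f: threshold |t| > %.3f (df = %d), %d / %d voxels significant\n",
    x$correction, x$alpha, x$threshold, x$df,
    sum(x$significant_mask), length(x$t_values)))
  invisible(x)
}

#' @method tidy tmap_result
#' @export
tidy.tmap_result <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$t_values), t = x$t_values,
                 significant = x$significant_mask)
}

#' @method glance tmap_result
#' @export
glance.tmap_result <- function(x, ...) {
  tibble::tibble(correction = x$correction, alpha = x$alpha,
                 threshold = x$threshold, df = x$df,
                 n_significant = sum(x$significant_mask),
                 n_voxels = length(x$t_values))
}

#' Axial-slice plot of a t-map
#'
#' @param object A `tmap_result`.
#' @param mask Logical 3D array used to unflatten the map.
#' @param geometry The matching [volume_geometry()].
#' @param slice Axial (third-axis) slice index; default middle.
#' @param ... Unused.
#' @return A ggplot heat map of the t values on one slice, outlining
#'   significant voxels.
#' @export
plot_tmap_slice <- function(object, mask, geometry, slice = NULL, ...) {
  vol <- unflatten(object$t_values, mask, geometry)
  sig <- unflatten(as.numeric(object$significant_mask), mask, geometry)
  if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
  df <- expand.grid(x = seq_len(dim(vol)[1]), y = seq_len(dim(vol)[2]))
  df$t <- as.vector(vol[, , slice])
  df$significant <- as.vector(sig[, , slice]) > 0
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 4, size = 0.8, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("t-map, axial slice %d (%s FWE %.2f)",
                                  slice, object$correction, object$alpha)) +
    ggplot2::theme_minimal()
}
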