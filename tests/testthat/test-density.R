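lw_mid_fixture <- function() {
  set.seed(314)
  matrix(round(rnorm(200) * rep(c(1, 1.5, 2, 3), each = 50), 4), 50, 4)
}

test_that("Ledoit-Wolf shrinkage matches the frozen reference values", {
  # expected values computed once with sklearn.covariance.ledoit_wolf on
  # the identical fixture matrices and frozen here
  m <- fit_mvn(scores_of(lw_mid_fixture(), rep("c", 50)), "c")
  expect_equal(m$alpha, 0.2042264068586266, tolerance = 1e-10)
  expect_equal(unname(m$sigma[1, ]),
               c(1.445148932437, 0.296306991006, 0.441228172296,
                 0.599153317705), tolerance = 1e-9)
  expect_equal(unname(diag(m$sigma)),
               c(1.445148932437, 2.355506109194, 3.419183685312,
                 5.848629081728), tolerance = 1e-9)
  set.seed(7)
  X2 <- matrix(rnorm(40 * 119), 40, 119)
  m2 <- fit_mvn(scores_of(X2, rep("c", 40)), "c")
  expect_equal(m2$alpha, 0.9648781534394982, tolerance = 1e-10)
  expect_equal(m2$sigma[1, 1], 0.9700926506676072, tolerance = 1e-9)
  expect_equal(m2$sigma[1, 2], 0.009940675889400211, tolerance = 1e-9)
})

test_that("forced shrinkage endpoints give the target and the empirical covariance", {
  set.seed(21)
  X <- matrix(rnorm(30 * 3), 30, 3)
  sc <- scores_of(X, rep("c", 30))
  m1 <- fit_mvn(sc, "c", alpha = 1)
  emp_trace <- sum(diag(crossprod(sweep(X, 2, colMeans(X))) / 30))
  expect_equal(m1$sigma, diag(emp_trace / 3, 3), tolerance = 1e-12)
  m0 <- fit_mvn(sc, "c", alpha = 0)
  # brute-force double-loop empirical covariance oracle
  mu <- colMeans(X)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    oracle[i, j] <- mean((X[, i] - mu[i]) * (X[, j] - mu[j]))
  }
  expect_equal(m0$sigma, oracle, tolerance = 1e-10)
})

test_that("estimated shrinkage is small for an informative anisotropic covariance", {
  set.seed(99)
  X <- sweep(matrix(rnorm(5000 * 3), 5000, 3), 2, sqrt(c(1, 2, 3)), `*`)
  m <- fit_mvn(scores_of(X, rep("c", 5000)), "c")
  expect_lte(m$alpha, 0.05)
  expect_lt(max(abs(m$sigma - diag(c(1, 2, 3)))), 0.15)
})

test_that("shrinkage makes the covariance better conditioned monotonically", {
  set.seed(31)
  X <- matrix(rnorm(10 * 8), 10, 8)
  sc <- scores_of(X, rep("c", 10))
  conds <- vapply(c(0.05, 0.2, 0.5, 0.8, 1), function(a) {
    ev <- eigen(fit_mvn(sc, "c", alpha = a)$sigma, symmetric = TRUE,
                only.values = TRUE)$values
    max(ev) / min(ev)
  }, numeric(1))
  expect_true(all(diff(conds) <= 1e-8))
})

test_that("MVN density matches closed forms and integrates to one", {
  sc1 <- scores_of(matrix(c(-1, 1, 0.5, -0.5), 4, 1), rep("c", 4))
  m1 <- fit_mvn(sc1, "c", alpha = 0)
  # rebuild as exact standard normal for the analytic check
  m1$mu <- 0; m1$sigma <- matrix(1); m1$chol <- matrix(1)
  expect_equal(mvn_pdf(m1, 0), 0.3989423, tolerance = 1e-6)
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  m2 <- fit_mvn(scores_of(X, rep("c", 20)), "c")
  expect_equal(mvn_pdf(m2, m2$mu),
               (2 * pi)^(-1) * det(m2$sigma)^(-0.5), tolerance = 1e-10)
  # diagonal covariance: joint density is the product of 1-D normals
  md <- m2
  md$mu <- c(0, 0); md$sigma <- diag(c(1, 4)); md$chol <- chol(diag(c(1, 4)))
  expect_equal(mvn_pdf(md, c(1, 2)),
               dnorm(1, 0, 1) * dnorm(2, 0, 2), tolerance = 1e-12)
  # quadrature: density integrates to 1 (L = 2)
  g <- seq(-6, 6, length.out = 201)
  vals <- mvn_pdf(md, as.matrix(expand.grid(g, 2 * g)))
  expect_equal(sum(vals) * diff(g)[1]^2 * 2, 1, tolerance = 1e-3)
  expect_error(mvn_pdf(m2, c(1, 2, 3)), class = "eigensynth_dimension_error")
})

test_that("diffusion bandwidth tracks Silverman on normal data and undersmooths on bimodal", {
  set.seed(101)
  x <- rnorm(5000)
  expect_lt(abs(bw_diffusion(x) - bw_silverman(x)) / bw_silverman(x), 0.25)
  # two points: positive and finite (fallback is acceptable)
  expect_gt(quiet_bw(bw_diffusion(c(-1, 1))), 0)
  set.seed(202)
  xb <- c(rnorm(1000, -5), rnorm(1000, 5))
  expect_lt(bw_diffusion(xb), bw_silverman(xb))
})

test_that("KDE density matches hand-computed kernels and integrates to one", {
  single <- fit_kde_component(scores_of(matrix(c(0, 0.5), 2, 1),
                                        rep("c", 2)), "c", 1, bandwidth = 1)
  single$points <- 0  # one kernel at the origin
  expect_equal(kde_pdf(single, 0), 0.3989423, tolerance = 1e-6)
  two <- fit_kde_component(scores_of(matrix(c(-1, 1), 2, 1), rep("c", 2)),
                           "c", 1, bandwidth = 1)
  expect_equal(kde_pdf(two, 0), mean(dnorm(c(-1, 1))), tolerance = 1e-10)
  expect_equal(kde_pdf(two, 0), 0.2420, tolerance = 2e-4)
  # normalization on an adaptive grid
  set.seed(12)
  k <- quiet_bw(fit_kde_component(scores_of(matrix(rnorm(80)), rep("c", 80)),
                                  "c", 1))
  g <- seq(min(k$points) - 10 * k$bandwidth, max(k$points) + 10 * k$bandwidth,
           length.out = 4001)
  f <- kde_pdf(k, g)
  expect_equal(sum((f[-1] + f[-length(f)]) / 2 * diff(g)), 1,
               tolerance = 1e-3)
})

test_that("degenerate classes and components are rejected with informative errors", {
  sc <- scores_of(matrix(c(1, 1, 1, 2, 3, 4), 3, 2), rep("c", 3))
  expect_error(fit_kde_component(sc, "c", 1),
               class = "eigensynth_degenerate_error")
  expect_error(fit_kde_component(sc, "c", 3), class = "eigensynth_value_error")
  one <- scores_of(matrix(1, 1, 2), "c")
  expect_error(fit_mvn(one, "c"),
               class = "eigensynth_insufficient_class_data_error")
  same <- scores_of(matrix(2, 4, 2), rep("c", 4))
  expect_error(fit_mvn(same, "c"), class = "eigensynth_degenerate_error")
})

test_that("fitted class models assign higher likelihood to their own class", {
  ph <- tiny_two_class()
  eb <- fit_eigenbrains(ph$dataset)
  sc <- project(ph$dataset, eb, L = 5)
  m_dis <- fit_mvn(sc, "DIS")
  m_con <- fit_mvn(sc, "CON")
  dis_rows <- sc$scores[sc$labels == "DIS", , drop = FALSE]
  con_rows <- sc$scores[sc$labels == "CON", , drop = FALSE]
  expect_gt(sum(mvn_pdf(m_dis, dis_rows, log = TRUE)),
            sum(mvn_pdf(m_con, dis_rows, log = TRUE)))
  expect_gt(sum(mvn_pdf(m_con, con_rows, log = TRUE)),
            sum(mvn_pdf(m_dis, con_rows, log = TRUE)))
})
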