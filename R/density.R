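#' Fit a shrinkage-regularized multivariate normal to one class's scores
#'
#' Models the latent coordinates of class `c` as multivariate normal with
#' the class sample mean and a shrunk covariance
#' `Sigma = (1 - alpha) * S + alpha * (tr(S)/L) * I`,
#' where `S` is the empirical (maximum-likelihood, `1/K_c`) class
#' covariance and the intensity `alpha` in `[0, 1]` is the Ledoit–Wolf
#' minimum-MSE estimate for the well-conditioned scaled-identity target.
#' Shrinkage reduces the spread between the smallest and largest
#' eigenvalues, so the result is positive definite even when the class has
#' fewer subjects than latent dimensions.
#'
#' @param scores An [eb_scores()] object.
#' @param class_id Which class to fit (must have at least 2 subjects).
#' @param alpha Optional forced shrinkage intensity in `[0, 1]`; default
#'   `NULL` estimates it from the data.
#' @return An object of class `mvn_class_model` with fields `class_id`,
#'   `mu`, `sigma`, `alpha`, `K_c`.
#' @export
fit_mvn <- function(scores, class_id, alpha = NULL) {
  stopifnot(inherits(scores, "eb_scores"))
  S <- scores$scores[scores$labels == class_id, , drop = FALSE]
  K_c <- nrow(S)
  if (K_c < 2L) {
    abort(sprintf("class '%s' has %d subject(s); at least 2 required.",
                  class_id, K_c),
          class = "eigensynth_insufficient_class_data_error")
  }
  p <- ncol(S)
  mu <- colMeans(S)
  Xc <- sweep(S, 2L, mu)
  emp <- crossprod(Xc) / K_c
  m <- sum(diag(emp)) / p
  if (m <= 0) {
    abort(sprintf("class '%s' scores are degenerate (zero variance).",
                  class_id),
          class = "eigensynth_degenerate_error")
  }
  if (is.null(alpha)) {
    # Ledoit-Wolf (2004) intensity for target (tr/L) I, using the
    # normalized Frobenius inner product <A,B> = tr(AB')/p
    d2 <- sum((emp - diag(m, p))^2) / p
    # sum_k ||x_k x_k' - emp||^2_F = sum_k ||x_k||^4 - K_c ||emp||^2_F
    bbar2 <- (sum(rowSums(Xc^2)^2) - K_c * sum(emp^2)) / (K_c^2 * p)
    b2 <- min(bbar2, d2)
    alpha <- if (d2 > 0) b2 / d2 else 0
  }
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "eigensynth_value_error")
  }
  sigma <- (1 - alpha) * emp + diag(alpha * m, p)
  sigma <- (sigma + t(sigma)) / 2
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    abort(sprintf("shrunk covariance for class '%s' is not positive definite.",
                  class_id),
          class = "eigensynth_degenerate_error")
  }
  structure(list(class_id = as.character(class_id), mu = mu, sigma = sigma,
                 alpha = alpha, K_c = K_c, chol = ch),
            class = "mvn_class_model")
}

#' @export
print.mvn_class_model <- function(x, ...) {
  cat(sprintf("<mvn_class_model> class '%s': L = %d, K_c = %d, alpha = %.4f\n",
              x$class_id, length(x$mu), x$K_c, x$alpha))
  invisible(x)
}

#' @method glance mvn_class_model
#' @export
glance.mvn_class_model <- function(x, ...) {
  ev <- eigen(x$sigma, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(class_id = x$class_id, L = length(x$mu), K_c = x$K_c,
                 alpha = x$alpha, condition_number = max(ev) / min(ev))
}

#' Multivariate normal density of a fitted class model
#'
#' Evaluated through the Cholesky factor in log space (latent dimensions can
#' reach several hundred, where the direct product underflows), then
#' exponentiated. The dimension entering the `(2*pi)^(d/2)` normalizer is
#' the latent dimension `L`, not the sample count.
#'
#' @param model An `mvn_class_model`.
#' @param x Length-L numeric vector or a matrix with L columns.
#' @param log Return log-density?
#' @return Density value(s), one per row of `x`.
#' @export
mvn_pdf <- function(model, x, log = FALSE) {
  stopifnot(inherits(model, "mvn_class_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  L <- length(model$mu)
  if (ncol(X) != L) {
    abort(sprintf("x has %d columns; model dimension is %d.", ncol(X), L),
          class = "eigensynth_dimension_error")
  }
  if (any(!is.finite(X))) {
    abort("x must be finite.", class = "eigensynth_value_error")
  }
  R <- model$chol
  logdet <- 2 * sum(log(diag(R)))
  z <- backsolve(R, t(sweep(X, 2L, model$mu)), transpose = TRUE)
  logf <- -0.5 * (L * log(2 * pi) + logdet + colSums(z^2))
  if (log) logf else exp(logf)
}

# --- diffusion (improved Sheather-Jones) bandwidth -------------------------

dct1d <- function(x) {
  n <- length(x)
  w <- c(1, 2 * exp(-1i * (seq_len(n - 1)) * pi / (2 * n)))
  reordered <- c(x[seq(1, n, by = 2)], x[seq(2 * (n %/% 2), 2, by = -2)])
  Re(w * fft(reordered))
}

#' Silverman's normal-reference bandwidth
#'
#' `1.06 * sd(x) * n^(-1/5)`; used as the fallback when the diffusion
#' fixed point cannot be bracketed, and as an asymptotic cross-check.
#'
#' @param x Numeric sample.
#' @return Positive bandwidth.
#' @export
bw_silverman <- function(x) 1.06 * stats::sd(x) * length(x)^(-1 / 5)

#' Diffusion (improved Sheather-Jones) KDE bandwidth
#'
#' Plug-in bandwidth selected by solving the fixed point of the smoothing
#' (diffusion) equation `t = xi * gamma^[l](t)` on a discrete cosine
#' transform of the binned data, rather than a normal-reference rule. The
#' sample is binned on a `2^14`-point grid spanning the data range padded
#' by 10% on each side; the fixed point is solved to `1e-9`. When no root
#' can be bracketed (tiny or pathological samples) the function falls back
#' to [bw_silverman()] with a warning.
#'
#' @param x Numeric sample (at least 2 distinct values).
#' @param grid_size Number of DCT bins (default `2^14`).
#' @param pad Fractional range padding on each side (default 0.1).
#' @param tol Fixed-point tolerance (default 1e-9).
#' @return Positive bandwidth on the scale of `x`.
#' @export
bw_diffusion <- function(x, grid_size = 2^14, pad = 0.1, tol = 1e-9) {
  x <- as.numeric(x)
  n <- length(unique(x))
  if (n < 2L) {
    abort("bandwidth selection needs at least 2 distinct points.",
          class = "eigensynth_degenerate_error")
  }
  rng <- range(x)
  width <- diff(rng) * (1 + 2 * pad)
  lo <- rng[1] - pad * diff(rng)
  breaks <- seq(lo, lo + width, length.out = grid_size + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = grid_size)
  initial <- counts / length(x)
  a <- dct1d(initial / sum(initial))
  I2 <- (seq_len(grid_size - 1))^2
  a2 <- (a[-1] / 2)^2
  fixed_point <- function(t) {
    l <- 7
    f <- 2 * pi^(2 * l) * sum(I2^l * a2 * exp(-I2 * pi^2 * t))
    for (s in seq(l - 1, 2)) {
      K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
      cnst <- (1 + (1 / 2)^(s + 1 / 2)) / 3
      tt <- (2 * cnst * K0 / (n * f))^(2 / (3 + 2 * s))
      f <- 2 * pi^(2 * s) * sum(I2^s * a2 * exp(-I2 * pi^2 * tt))
    }
    t - (2 * n * sqrt(pi) * f)^(-2 / 5)
  }
  t_star <- NULL
  upper <- 0.1
  repeat {
    res <- tryCatch(
      stats::uniroot(fixed_point, c(.Machine$double.eps, upper), tol = tol),
      error = function(e) NULL)
    if (!is.null(res)) {
      t_star <- res$root
      break
    }
    upper <- upper * 2
    if (upper > 10) break
  }
  if (is.null(t_star) || !is.finite(t_star) || t_star <= 0) {
    warn("diffusion bandwidth fixed point not bracketed; falling back to Silverman's rule.")
    return(bw_silverman(x))
  }
  sqrt(t_star) * width
}

#' Fit a per-component kernel density estimate for one class
#'
#' The latent distribution of class `c` along eigenbrain `l` is modeled by
#' a Gaussian-kernel KDE over the observed class scores, with bandwidth
#' selected by the diffusion fixed point ([bw_diffusion()]). Components are
#' modeled independently: PCA scores are uncorrelated by construction and
#' the per-component estimate is robust to heavy tails.
#'
#' @param scores An [eb_scores()] object.
#' @param class_id Class to fit.
#' @param component Component index (1-based).
#' @param bandwidth Optional forced bandwidth (> 0).
#' @return Object of class `kde_component_model` with `class_id`,
#'   `component`, `points`, `bandwidth`.
#' @export
fit_kde_component <- function(scores, class_id, component, bandwidth = NULL) {
  stopifnot(inherits(scores, "eb_scores"))
  component <- as.integer(component)
  if (component < 1L || component > ncol(scores$scores)) {
    abort("component index out of range.", class = "eigensynth_value_error")
  }
  pts <- scores$scores[scores$labels == class_id, component]
  if (length(pts) < 2L) {
    abort(sprintf("class '%s' has fewer than 2 subjects.", class_id),
          class = "eigensynth_insufficient_class_data_error")
  }
  if (diff(range(pts)) == 0) {
    abort(sprintf("class '%s', component %d: all scores identical.",
                  class_id, component),
          class = "eigensynth_degenerate_error")
  }
  if (is.null(bandwidth)) bandwidth <- bw_diffusion(pts)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    abort("bandwidth must be a positive finite number.",
          class = "eigensynth_value_error")
  }
  structure(list(class_id = as.character(class_id), component = component,
                 points = as.numeric(pts), bandwidth = bandwidth),
            class = "kde_component_model")
}

#' @export
print.kde_component_model <- function(x, ...) {
  cat(sprintf("<kde_component_model> class '%s', component %d: K_c = %d, h = %.4g\n",
              x$class_id, x$component, length(x$points), x$bandwidth))
  invisible(x)
}

#' Gaussian-kernel KDE density
#'
#' `f(x) = 1/(K_c h) * sum_i G((x - s_i)/h)` with the standard normal
#' kernel `G` (zero mean, unit second moment).
#'
#' @param model A `kde_component_model`.
#' @param x Numeric vector of evaluation points.
#' @return Nonnegative densities, same length as `x`.
#' @export
kde_pdf <- function(model, x) {
  stopifnot(inherits(model, "kde_component_model"))
  if (any(!is.finite(x))) {
    abort("x must be finite.", class = "eigensynth_value_error")
  }
  h <- model$bandwidth
  Kd <- dnorm(outer(x, model$points, `-`) / h)
  as.numeric(rowMeans(Kd) / h)
}

#' Fit the latent density of one class
#'
#' Dispatches to the chosen estimator: a single joint [fit_mvn()] model, or
#' one [fit_kde_component()] per retained component.
#'
#' @param scores An [eb_scores()] object.
#' @param class_id Class to fit.
#' @param estimator `"mvn"` or `"kde"`.
#' @return A `class_density` object: list with `estimator`, `class_id` and
#'   either `mvn` or `components` (list of KDE models).
#' @export
fit_class_density <- function(scores, class_id,
                              estimator = c("kde", "mvn")) {
  estimator <- match.arg(estimator)
  fit <- if (estimator == "mvn") {
    list(mvn = fit_mvn(scores, class_id))
  } else {
    list(components = lapply(seq_len(ncol(scores$scores)), function(l)
      fit_kde_component(scores, class_id, l)))
  }
  structure(c(list(estimator = estimator, class_id = as.character(class_id),
                   L = ncol(scores$scores)), fit),
            class = "class_density")
}

#' @export
print.class_density <- function(x, ...) {
  cat(sprintf("<class_density> class '%s', estimator %s, L = %d\n",
              x$class_id, x$estimator, x$L))
  invisible(x)
}
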