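# Shared fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# two moderately overlapping classes on a small grid; fast to decompose
tiny_two_class <- function() {
  fixture("tiny_two_class", function() {
    ctr <- c(7, 7, 7)
    spec <- phantom_spec(
      shape = c(14, 14, 14), n_per_class = c(DIS = 20, CON = 20),
      class_effects = list(
        DIS = list(list(center = ctr + c(-2, 2, 0), radius = 2,
                        amplitude = -0.15)),
        CON = list()),
      latent_dim = 3, latent_sd = c(0.5, 0.3, 0.2),
      noise_sd = 0.5, smoothing_fwhm = 2, seed = 101)
    generate_phantom(spec)
  })
}

# near-separable two-class problem: big effect, low noise
separable_two_class <- function() {
  fixture("separable_two_class", function() {
    ctr <- c(7, 7, 7)
    spec <- phantom_spec(
      shape = c(14, 14, 14), n_per_class = c(DIS = 20, CON = 20),
      class_effects = list(
        DIS = list(list(center = ctr, radius = 3, amplitude = -0.8)),
        CON = list()),
      latent_dim = 2, latent_sd = c(0.2, 0.1),
      noise_sd = 0.1, smoothing_fwhm = 2, seed = 202)
    generate_phantom(spec)
  })
}

# single-class population for null comparisons
one_class_population <- function(n = 50, seed = 303) {
  spec <- phantom_spec(shape = c(14, 14, 14),
                       n_per_class = stats::setNames(n, "A"),
                       latent_dim = 4, seed = seed)
  generate_phantom(spec)
}

# a dataset wrapper around a bare matrix (trivial full mask, one row of
# voxels) for analytic decomposition tests
matrix_dataset <- function(X, labels = rep("a", nrow(X))) {
  N <- ncol(X)
  geom <- volume_geometry(c(N, 1, 1))
  voxel_dataset(X, labels, array(TRUE, dim = c(N, 1, 1)), geom)
}

scores_of <- function(X, labels) eb_scores(as.matrix(X), labels)

quiet_bw <- function(expr) suppressWarnings(expr)
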