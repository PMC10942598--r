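test_that("embed_waveforms is deterministic with a fixed sign convention", {
  set.seed(2)
  W <- matrix(rnorm(200 * 128), 200, 128)
  e1 <- embed_waveforms(W)
  e2 <- embed_waveforms(W)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(200, 2))
  expect_error(embed_waveforms(W[1:5, ]), "too few")
})

test_that("fit_cluster_gaussian is robust to stray points", {
  set.seed(4)
  P <- matrix(rnorm(400), 200, 2)
  out <- rbind(P, matrix(50, 10, 2))  # 5% gross outliers
  f_clean <- fit_cluster_gaussian(P)
  f_dirty <- fit_cluster_gaussian(out)
  expect_lt(sqrt(sum((f_dirty$mu - f_clean$mu)^2)), 0.5)
  expect_lt(max(abs(f_dirty$sigma - f_clean$sigma)), 0.5)
  expect_error(fit_cluster_gaussian(P[1:10, ]), ">= 50")
})

test_that("misclassification distance: identity, symmetry, bounds", {
  set.seed(6)
  A <- matrix(rnorm(300), 150, 2)
  B <- sweep(matrix(rnorm(300), 150, 2), 2, c(3, 0), `+`)
  fa <- fit_cluster_gaussian(A)
  fb <- fit_cluster_gaussian(B)
  expect_equal(misclassification_distance(fa, fa, A, A)$d, 0)
  dab <- misclassification_distance(fa, fb, A, B)
  dba <- misclassification_distance(fb, fa, B, A)
  expect_equal(dab$d, dba$d)
  expect_true(dab$d >= 0 && dab$d <= 1)
  # far-apart clouds approach the maximum distance
  C <- sweep(A, 2, c(100, 0), `+`)
  fc <- fit_cluster_gaussian(C)
  expect_gt(misclassification_distance(fa, fc, A, C)$d, 0.99)
})

test_that("gaussian divergences match their closed forms", {
  I2 <- diag(2)
  f0 <- list(mu = c(0, 0), sigma = I2)
  expect_equal(gaussian_divergences(f0, f0)$H2, 0)
  expect_equal(gaussian_divergences(f0, f0)$KL, 0)
  f1 <- list(mu = c(1, 0), sigma = I2)
  expect_equal(gaussian_divergences(f0, f1)$KL, 0.5)
  f2 <- list(mu = c(2, 0), sigma = I2)
  expect_equal(gaussian_divergences(f0, f2)$H2, 1 - exp(-0.5),
               tolerance = 1e-12)
  expect_equal(1 - exp(-0.5), 0.3935, tolerance = 1e-4)
  # oracle: KL for unequal covariances vs direct Monte-Carlo estimate
  f3 <- list(mu = c(0.5, -0.5), sigma = matrix(c(2, 0.5, 0.5, 1), 2))
  set.seed(8)
  X <- MASS::mvrnorm(200000, f3$mu, f3$sigma)
  lr <- function(x, f) {
    si <- solve(f$sigma)
    dx <- sweep(x, 2, f$mu)
    -0.5 * rowSums((dx %*% si) * dx) - 0.5 * log(det(f$sigma))
  }
  kl_mc <- mean(lr(X, f3) - lr(X, f0))
  expect_equal(gaussian_divergences(f3, f0)$KL, kl_mc, tolerance = 0.02)
  expect_error(gaussian_divergences(
    list(mu = c(0, 0), sigma = matrix(0, 2, 2)), f0), "singular")
})

test_that("match_units recovers identity on a small benchmark", {
  ws <- simulate_waveform_sets(4, n_sessions = 2, separation = 2,
                               n_spikes = 400, seed = 9)
  m <- match_units(ws$sessions, seed = 1)
  expect_equal(nrow(m$assignment), 4)
  expect_equal(sub("s1_", "", m$assignment$unit_a),
               sub("s2_", "", m$assignment$unit_b))
  # the one-to-one assignment never reuses a unit
  expect_false(any(duplicated(c(m$assignment$unit_a,
                                m$assignment$unit_b))))
  # pair table: symmetric-by-construction distance columns within bounds
  expect_true(all(m$pairs$d >= 0 & m$pairs$d <= 1, na.rm = TRUE))
  expect_true(all(m$pairs$H2 >= 0 & m$pairs$H2 <= 1, na.rm = TRUE))
})

test_that("the three cluster metrics order pairs concordantly", {
  # sweep a Gaussian cloud away from a reference in the unsaturated
  # regime (d well below its clip at 1) and compare the orderings
  set.seed(12)
  A <- matrix(rnorm(1600), 800, 2)
  fa <- fit_cluster_gaussian(A)
  offs <- seq(0.25, 3, by = 0.25)
  d <- h2 <- kl <- numeric(length(offs))
  for (i in seq_along(offs)) {
    B <- sweep(matrix(rnorm(1600), 800, 2), 2, c(offs[i], 0), `+`)
    fb <- fit_cluster_gaussian(B)
    d[i] <- misclassification_distance(fa, fb, A, B)$d
    dv <- gaussian_divergences(fa, fb)
    h2[i] <- dv$H2; kl[i] <- dv$KL
  }
  expect_gt(kendall_tau(d, h2), 0.8)
  expect_gt(kendall_tau(d, kl), 0.8)
  expect_gt(kendall_tau(h2, kl), 0.8)
})

test_that("match_units is embedding-agnostic on the benchmark", {
  skip_if_not_installed("kernlab")
  ws <- simulate_waveform_sets(4, n_sessions = 2, separation = 2,
                               n_spikes = 300, seed = 10)
  m <- match_units(ws$sessions, seed = 1, method = "kpca")
  expect_equal(sub("s1_", "", m$assignment$unit_a),
               sub("s2_", "", m$assignment$unit_b))
})

test_that("units on different tetrodes or depths are never candidates", {
  ws <- simulate_waveform_sets(2, n_sessions = 2, n_spikes = 200, seed = 11)
  ws$sessions[[2]]$index$depth <- 40  # advanced between sessions
  m <- match_units(ws$sessions)
  expect_equal(m$n_candidates, 0)
  expect_equal(nrow(m$assignment), 0)
})
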