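test_that("kendall_tau matches brute-force pair counting", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    # heavy ties on purpose: zone rates tie at zero often
    x <- sample(0:3, n, replace = TRUE) + rnorm(n, 0, 0.01 * (i %% 2))
    y <- sample(0:3, n, replace = TRUE)
    expect_equal(kendall_tau(x, y), kendall_brute(x, y), tolerance = 1e-12)
  }
  # NA masking: only jointly unmasked pairs enter
  x <- c(1, 2, 3, NA, 5); y <- c(NA, 1, 4, 2, 2)
  expect_equal(kendall_tau(x, y), kendall_brute(x, y))
  expect_true(is.na(kendall_tau(c(1, 2), c(2, 1))))
  expect_true(is.na(kendall_tau(c(1, 1, 1), c(1, 2, 3))))
})

test_that("tau_to_z is the Fisher transform of sin(pi tau / 2)", {
  expect_equal(tau_to_z(0), 0)
  expect_equal(tau_to_z(0.5), atanh(sin(pi * 0.25)))
  expect_equal(tau_to_z(-0.5), -tau_to_z(0.5))
  # perfect correlation is large but finite
  expect_true(is.finite(tau_to_z(1)))
  expect_gt(tau_to_z(1), 10)
})

test_that("z_delta closed forms", {
  expect_equal(z_delta(0.7, 39, 0.7, 39), 0)
  expect_equal(z_delta(0.8814, 39, 0, 39), 3.739, tolerance = 1e-3)
  # symmetric in sign
  expect_equal(z_delta(0, 39, 0.8814, 39), -3.739, tolerance = 1e-3)
  expect_true(is.na(z_delta(1, 3, 0, 39)))
  # smaller n widens the denominator
  expect_lt(abs(z_delta(0.5, 10, 0, 10)), abs(z_delta(0.5, 100, 0, 100)))
})

test_that("mann_whitney_uz agrees with wilcox.test and rank oracle", {
  set.seed(7)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:5, n1, replace = TRUE)
    b <- sample(1:5, n2, replace = TRUE)
    res <- mann_whitney_uz(a, b)
    expect_equal(res$U, u_brute(a, b))
    w <- suppressWarnings(wilcox.test(a, b))
    expect_equal(res$U, unname(w$statistic))
  }
  # large-sample rank route equals the exhaustive definition
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(mann_whitney_uz(a, b)$U, u_brute(a, b))
  # all tied -> UZ = 0 with flag
  res <- mann_whitney_uz(rep(1, 5), rep(1, 6))
  expect_true(res$tied)
  expect_equal(res$UZ, 0)
  expect_error(mann_whitney_uz(numeric(0), 1), "empty")
})

test_that("uz_segment matches a hand-computed segment-rate comparison", {
  fx <- tm_fixture()
  r <- tm_rates("rate")
  res <- uz_segment(r, fx$trials, "cue", "stem")
  expect_equal(res$segment, "stem")
  # oracle: stem rates as total counts / total occupancy over stem zones
  stem_cols <- which(treemaze_zones()$zones$segment3 == "stem")
  seg <- rowSums(r$counts[, stem_cols]) / rowSums(r$occupancy[, stem_cols])
  a <- seg[r$trials$cue == "RC"]
  b <- seg[r$trials$cue == "LC"]
  orc <- mann_whitney_uz(a, b)
  expect_equal(res$U, orc$U)
  expect_equal(res$UZ, orc$UZ)
  expect_equal(res$n1, sum(!is.na(a)))
  # every trial traverses the stem outbound
  expect_equal(res$n1 + res$n2, nrow(r$trials))
})

test_that("remap_score separates remapping from stable units", {
  fx <- tm_fixture()
  plan_t <- resample_plan("cue", n_boot = 50, seed = 2)
  plan_n <- resample_plan("parity", n_boot = 50, seed = 3)
  sc_flat <- remap_score(tm_rates("flat"), fx$trials, plan_t, plan_n)
  sc_glob <- remap_score(tm_rates("glob"), fx$trials, plan_t, plan_n)
  expect_s3_class(sc_flat, "remap_score")
  expect_false(sc_flat$excluded)
  # a flat unit's cue maps look like parity halves
  expect_lt(abs(sc_flat$zbar), 1)
  # a globally remapped unit scores strongly negative
  expect_lt(sc_glob$zbar, -2)
  expect_lt(sc_glob$zbar, sc_flat$zbar)
  expect_equal(sc_glob$n_boot_used, 50)
  expect_output(print(sc_glob), "zbar")
})

test_that("population_remap concatenates units into one score", {
  fx <- tm_fixture()
  plan_t <- resample_plan("cue", n_boot = 30, seed = 2)
  plan_n <- resample_plan("parity", n_boot = 30, seed = 3)
  rl <- list(tm_rates("glob"), tm_rates("rate"))
  pop <- population_remap(rl, fx$trials, plan_t, plan_n)
  expect_false(pop$excluded)
  expect_equal(pop$unit_id, "population")
  # concatenated zone counts: about twice a single unit's
  single <- remap_score(tm_rates("glob"), fx$trials, plan_t, plan_n)
  expect_gt(mean(pop$n_test), 1.8 * mean(single$n_test))
  expect_lt(pop$zbar, -2)
})

test_that("behavior_correlation fits LMEM with multi-subject data", {
  set.seed(9)
  n <- 40
  subject <- rep(c("a", "b", "c", "d"), each = 10)
  score <- rnorm(n)
  p_se <- 0.7 - 0.1 * score + rnorm(n, 0, 0.03) +
    rep(rnorm(4, 0, 0.02), each = 10)
  res <- behavior_correlation(data.frame(score, p_se, subject))
  expect_equal(res$method, "lmem")
  expect_lt(res$slope, 0)
  expect_lt(res$p_value, 0.01)
  expect_true(res$slope_ci[1] < res$slope && res$slope < res$slope_ci[2])
  expect_lt(res$tau, 0)
  # single subject falls back to OLS with a warning
  expect_warning(
    res1 <- behavior_correlation(
      data.frame(score = score[1:10], p_se = p_se[1:10],
                 subject = "a")),
    "single subject")
  expect_equal(res1$method, "ols")
  expect_error(behavior_correlation(
    data.frame(score = 1:3, p_se = 1:3, subject = "a")), "fewer than 5")
})
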