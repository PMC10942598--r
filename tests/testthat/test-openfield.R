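# Shared small open-field fixture: 5 min, 3 units (place / HD / speed)
of_fixture <- function() {
  if (is.null(.fixtures$of)) {
    units <- list(
      of_tuning(base_rate = 4, place_center = c(40, 100), place_width = 12,
                place_amp = 6),
      of_tuning(base_rate = 4, hd_mu = 1, hd_kappa = 2),
      of_tuning(base_rate = 4, speed_slope = 0.5))
    sim <- simulate_openfield(of_config(duration_s = 420, units = units,
                                        seed = 13))
    .fixtures$of <- list(sim = sim, ofb = of_binned(sim$session))
  }
  .fixtures$of
}

test_that("of_binned digitizes tracking and spikes consistently", {
  fx <- of_fixture()
  ofb <- fx$ofb
  n <- length(ofb$t)
  expect_equal(dim(ofb$rates), c(n, 3))
  # rates integrate back to the spike counts
  expect_equal(sum(ofb$rates[, 1]) * ofb$dt,
               length(fx$sim$session$spike_trains$u001), tolerance = 1)
  expect_true(all(ofb$speed_bin >= 1 &
                    ofb$speed_bin <= length(ofb$bins$speed_breaks) - 1))
  expect_true(all(ofb$hd_bin >= 1 & ofb$hd_bin <= 36))
  expect_true(all(ofb$pos_bin >= 1 & ofb$pos_bin <= ofb$bins$nx * ofb$bins$ny))
  expect_equal(ofb$immobile, ofb$speed < 2)
})

test_that("of_rate_map peaks at the planted place field", {
  fx <- of_fixture()
  m <- of_rate_map(fx$ofb, 1)
  expect_equal(dim(m), c(fx$ofb$bins$ny, fx$ofb$bins$nx))
  peak <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  # field center (40, 100) cm -> bin col 40/5 = 8, row 100/5 = 20
  expect_lt(abs(peak["col"] - 8.5), 3)
  expect_lt(abs(peak["row"] - 20.5), 3)
  # dual route: the unsmoothed map bin equals the mean sample rate there
  raw <- of_rate_map(fx$ofb, 1, smooth_sd = 0)
  bin <- fx$ofb$pos_bin[1]
  col <- (bin - 1) %% fx$ofb$bins$nx + 1
  row <- (bin - 1) %/% fx$ofb$bins$nx + 1
  expect_equal(raw[row, col],
               mean(fx$ofb$rates[fx$ofb$pos_bin == bin, 1]),
               tolerance = 1e-8)
})

test_that("hd_score of an exact von Mises response equals the Bessel ratio", {
  for (kappa in c(0.5, 2, 4)) {
    ofb <- toy_of_binned(kappa = kappa)
    met <- of_tuning_metrics(ofb, 1)
    expect_equal(met$hd_score, besselI(kappa, 1) / besselI(kappa, 0),
                 tolerance = 1e-3)
    expect_equal(met$pref_hd, 0, tolerance = 1e-6)
  }
  # kappa = 2 reference value
  expect_equal(besselI(2, 1) / besselI(2, 0), 0.6978, tolerance = 1e-4)
})

test_that("tuning metrics separate the three planted unit types", {
  fx <- of_fixture()
  mets <- lapply(1:3, function(u) of_tuning_metrics(fx$ofb, u))
  # the HD unit has the highest hd_score, the speed unit the highest
  # speed score, the place unit the highest split-half map stability
  expect_equal(which.max(vapply(mets, `[[`, 1, "hd_score")), 2L)
  expect_equal(which.max(vapply(mets, `[[`, 1, "speed_score")), 3L)
  expect_equal(which.max(vapply(mets, `[[`, 1, "pos_score")), 1L)
  expect_gt(mets[[3]]$speed_score, 0.8)
  # a silent unit yields NAs, not errors
  ofb0 <- fx$ofb
  ofb0$rates[, 1] <- 0
  expect_true(is.na(of_tuning_metrics(ofb0, 1)$hd_score))
})

test_that("blocked folds never split a 20 s block across folds", {
  fx <- of_fixture()
  fold <- mazeremap:::.blocked_folds(fx$ofb$t, 20, 5)
  block <- floor((fx$ofb$t - fx$ofb$t[1]) / 20)
  expect_true(all(tapply(fold, block, function(x) length(unique(x))) == 1))
  expect_equal(sort(unique(fold)), 1:5)
  expect_error(mazeremap:::.blocked_folds(1:10, 20, 5), "fewer blocks")
})

test_that("single-variable encoders rank the generating variable first", {
  fx <- of_fixture()
  fits <- list(speed = fit_of_encoder(fx$ofb, "speed"),
               hd = fit_of_encoder(fx$ofb, "hd"),
               position = fit_of_encoder(fx$ofb, "position"))
  r2 <- vapply(fits, function(f) colMeans(f$r2), numeric(3))
  expect_equal(unname(apply(r2, 1, which.max)), c(3L, 2L, 1L))
  # the aggregate model beats or ties each single model on its own unit
  agg <- fit_aggregate_model(fits$speed, fits$hd, fits$position, fx$ofb)
  expect_equal(dim(agg$coef), c(3, 3))
  # contribution structure: each variable's largest contribution across
  # units belongs to the unit generated from it
  expect_equal(unname(apply(agg$coef, 2, which.max)), c(3L, 2L, 1L))
})

test_that("cluster_functional_types partitions clear coefficient classes", {
  set.seed(5)
  coef <- rbind(
    matrix(rnorm(12 * 3, rep(c(5, 0, 0), each = 12), 0.3), 12, 3),
    matrix(rnorm(12 * 3, rep(c(0, 5, 0), each = 12), 0.3), 12, 3),
    matrix(rnorm(12 * 3, rep(c(0, 0, 5), each = 12), 0.3), 12, 3))
  colnames(coef) <- c("beta_s", "beta_h", "beta_P")
  rownames(coef) <- sprintf("u%02d", 1:36)
  cl <- cluster_functional_types(coef, seed = 2)
  truth <- rep(1:3, each = 12)
  expect_equal(ari_oracle(cl$cluster, truth), 1)
  # labels are deterministic under the seed
  cl2 <- cluster_functional_types(coef, seed = 2)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("of_tm_transfer joins clusters to scores with bootstrap CIs", {
  clusters <- setNames(rep(0:2, each = 5), sprintf("u%02d", 1:15))
  scores <- data.frame(unit_id = c(sprintf("u%02d", 1:15), "zz"),
                       value = c(rep(c(-1, 0, 1), each = 5), 99))
  out <- of_tm_transfer(clusters, scores, n_boot = 200, seed = 1)
  expect_equal(out$cluster, 0:2)
  expect_equal(out$mean, c(-1, 0, 1))
  expect_equal(attr(out, "n_unmatched"), 1)
  expect_true(all(out$ci_lo <= out$mean & out$mean <= out$ci_hi))
})
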