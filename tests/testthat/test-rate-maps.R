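test_that("trial_zone_rates masks unvisited zones and normalizes by time", {
  fx <- tm_fixture()
  r <- tm_rates("flat")
  expect_s3_class(r, "trial_zone_rates")
  expect_equal(dim(r$rate), c(sum(!fx$trials$excluded), 39))
  # a zone with zero occupancy on a trial is NA, never 0
  expect_true(all(is.na(r$rate[r$occupancy == 0])))
  expect_true(all(is.finite(r$rate[r$occupancy > 0])))
  # rate * occupancy recovers integer spike counts
  cnt <- r$rate * r$occupancy
  expect_equal(cnt[r$occupancy > 0], round(cnt[r$occupancy > 0]),
               tolerance = 1e-6)
  # on outbound runs only one branch is visited
  right_zones <- as.character(25:38)
  rc <- r$rate[r$trials$decision == "L", right_zones]
  expect_true(all(is.na(rc)))
  # occupancy roughly accounts for the outbound window durations
  win <- r$trials$t_out1 - r$trials$t_out0
  expect_equal(unname(rowSums(r$occupancy)), win, tolerance = 0.2)
})

test_that("dual route: zone rates agree with direct spike counting", {
  fx <- tm_fixture()
  r <- tm_rates("rate")
  st <- fx$sim$session$spike_trains$rate
  tk <- fx$sim$session$tracking
  dt <- median(diff(tk$t))
  # oracle: per trial/zone, count spikes whose nearest earlier tracking
  # sample sits in that zone, and occupancy as dt * samples
  for (ti in c(1, 7, 20)) {
    w0 <- r$trials$t_out0[ti]; w1 <- r$trials$t_out1[ti]
    in_win <- tk$t >= w0 & tk$t < w1
    for (z in c(0, 5, 10)) {
      sel <- in_win & !is.na(fx$zone_seq) & fx$zone_seq == z
      occ_o <- sum(sel) * dt
      expect_equal(unname(r$occupancy[ti, z + 1]), occ_o,
                   tolerance = 1e-8)
      sp <- st[st >= w0 & st < w1]
      if (length(sp)) {
        zi <- fx$zone_seq[pmax(findInterval(sp, tk$t), 1)]
        cnt_o <- sum(zi == z, na.rm = TRUE)
        if (occ_o > 0) {
          expect_equal(unname(r$rate[ti, z + 1]), cnt_o / occ_o,
                       tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("resample_plan validates condition/balancing combinations", {
  p <- resample_plan("cue")
  expect_equal(p$balancing, "correct_incorrect")
  expect_equal(resample_plan("reward")$balancing, "cue")
  expect_equal(resample_plan("parity")$balancing, "cue")
  expect_error(resample_plan("cue", balancing = "cue"), "must differ")
  expect_error(resample_plan("cue", n_boot = 0))
})

test_that("balanced_resample draws equal numbers per balancing cell", {
  fx <- tm_fixture()
  plan <- resample_plan("cue", n_boot = 20, seed = 4)
  rs <- balanced_resample(fx$trials, plan)
  expect_false(rs$excluded)
  expect_equal(rs$levels, c("LC", "RC"))
  tr <- fx$trials[!fx$trials$excluded, ]
  for (b in c(1, 20)) {
    for (lv in rs$levels) {
      ids <- rs$draws[[b]][[lv]]
      drawn <- tr[match(ids, tr$trial_id), ]
      expect_true(all(drawn$cue == lv))
      # equal draws from correct and incorrect trials (the minority count)
      expect_equal(sum(drawn$correct), sum(!drawn$correct))
      expect_equal(sum(drawn$correct), unname(rs$m[lv]))
    }
  }
  # reproducible under the same seed
  rs2 <- balanced_resample(fx$trials, plan)
  expect_identical(rs$draws, rs2$draws)
})

test_that("sparse cells give a structured exclusion, not an error", {
  fx <- tm_fixture()
  tr <- fx$trials
  # drop incorrect LC trials below the threshold
  bad <- which(tr$cue == "LC" & !tr$correct)
  tr2 <- tr[-bad[-(1:2)], ]
  rs <- balanced_resample(tr2, resample_plan("cue", min_per_cell = 5))
  expect_true(rs$excluded)
  expect_match(rs$reason, "below 5")
  sc <- remap_score(tm_rates("flat"), tr2, resample_plan("cue"),
                    resample_plan("parity"))
  expect_true(sc$excluded)
  expect_true(is.na(sc$zbar))
})

test_that("noise matching equalizes draw counts against the test plan", {
  fx <- tm_fixture()
  rs_test <- balanced_resample(fx$trials, resample_plan("cue", n_boot = 5))
  rs_null <- balanced_resample(fx$trials,
                               resample_plan("parity", n_boot = 5),
                               match_noise = rs_test)
  # every null cell draws the test plan's per-level minority count
  for (lv in rs_null$levels) {
    expect_equal(length(rs_null$draws[[1]][[lv]]), sum(rs_test$m))
  }
})

test_that("condition_maps averages over drawn trials with masking", {
  fx <- tm_fixture()
  r <- tm_rates("flat")
  rs <- balanced_resample(fx$trials, resample_plan("cue", n_boot = 10))
  maps <- condition_maps(r, rs)
  expect_equal(dim(maps), c(10, 2, 39))
  # oracle: recompute map for one bootstrap and level by hand
  ids <- rs$draws[[3]][["RC"]]
  rows <- match(ids, r$trial_id)
  mu <- colMeans(r$rate[rows, ], na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  expect_equal(unname(maps[3, "RC", ]), unname(mu))
  # exclusion result cannot be mapped
  rs_x <- list(excluded = TRUE)
  expect_error(condition_maps(r, rs_x), "exclusion")
})
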