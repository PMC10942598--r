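#' Trial-wise zone firing rates
#'
#' The substrate of every remapping statistic: for each (non-excluded)
#' trial and each of the 39 maze zones, the unit's firing rate during that
#' trial's outbound or inbound window, i.e. spike count in the zone divided
#' by the time spent there. Zones the subject never visited on a trial have
#' zero occupancy and are masked (`NA`), never silently zero.
#'
#' @param spikes numeric vector of spike times (s)
#' @param zone_seq integer vector of zone ids per tracking sample (from
#'   [assign_zones()]; `NA` = out of bounds, excluded)
#' @param tracking data.frame with column `t` (uniform sampling)
#' @param trials trial table from [parse_trials()]
#' @param direction "outbound" or "inbound"
#' @param unit_id identifier stored in the result
#' @return object of class `trial_zone_rates`: list(rate, occupancy
#'   (trials x 39 matrices), trial_id, direction, unit_id)
#' @export
trial_zone_rates <- function(spikes, zone_seq, tracking, trials,
                             direction = c("outbound", "inbound"),
                             unit_id = "unit") {
  direction <- match.arg(direction)
  use <- trials[!trials$excluded & !is.na(trials$t_out0), , drop = FALSE]
  if (nrow(use) == 0) stop("trial_zone_rates: no usable trials")
  if (direction == "outbound") {
    w0 <- use$t_out0; w1 <- use$t_out1
  } else {
    w0 <- use$t_in0; w1 <- use$t_in1
  }
  dt <- stats::median(diff(tracking$t))
  nt <- nrow(use)
  occ <- matrix(0, nt, 39)
  cnt <- matrix(0, nt, 39)
  # sample -> trial assignment via half-open windows [w0, w1)
  samp_trial <- .window_index(tracking$t, w0, w1)
  ok <- !is.na(samp_trial) & !is.na(zone_seq)
  if (any(ok)) {
    occ_tab <- table(factor(samp_trial[ok], levels = seq_len(nt)),
                     factor(zone_seq[ok], levels = 0:38))
    occ <- unclass(occ_tab) * dt
  }
  if (length(spikes)) {
    sp_trial <- .window_index(spikes, w0, w1)
    sp_sample <- findInterval(spikes, tracking$t)
    sp_sample[sp_sample == 0] <- 1L
    sp_zone <- zone_seq[sp_sample]
    ok <- !is.na(sp_trial) & !is.na(sp_zone)
    if (any(ok)) {
      cnt_tab <- table(factor(sp_trial[ok], levels = seq_len(nt)),
                       factor(sp_zone[ok], levels = 0:38))
      cnt <- unclass(cnt_tab)
    }
  }
  rate <- cnt / occ
  rate[occ == 0] <- NA_real_
  dimnames(rate) <- dimnames(occ) <- list(use$trial_id, 0:38)
  structure(list(rate = rate, occupancy = occ, counts = cnt,
                 trial_id = use$trial_id, direction = direction,
                 unit_id = unit_id,
                 trials = use),
            class = "trial_zone_rates")
}

# index of the window [w0_i, w1_i) containing each time, NA if none
.window_index <- function(t, w0, w1) {
  idx <- findInterval(t, w0)
  idx[idx == 0] <- NA_integer_
  inside <- !is.na(idx) & t < w1[idx]
  idx[!inside] <- NA_integer_
  idx
}

#' A balanced trial-resampling plan
#'
#' Condition maps must not be confounded by performance (correct trials
#' dominate) or by cue frequency, so trials entering a condition-level map
#' are drawn with replacement in equal numbers per balancing level. For the
#' cue condition (LC vs RC) the balancing variable is correct/incorrect;
#' for the reward condition (RW vs NRW inbound trajectories) and for the
#' even/odd parity null it is the cue. `m`, the per-cell draw count, is the
#' minority-cell count across the balancing levels within each condition
#' level. Sessions with any nested cell below `min_per_cell` trials are
#' excluded from the analysis (a structured result, not an error).
#'
#' @param condition "cue", "reward" or "parity"
#' @param balancing balancing variable; defaults to "correct_incorrect" for
#'   the cue condition and "cue" otherwise
#' @param n_boot bootstrap repetitions (100 for statistics, 50 acceptable
#'   for plots)
#' @param min_per_cell minimum trials per nested cell
#' @param seed integer
#' @export
resample_plan <- function(condition = c("cue", "reward", "parity"),
                          balancing = NULL, n_boot = 100, min_per_cell = 5,
                          seed = 1) {
  condition <- match.arg(condition)
  if (is.null(balancing)) {
    balancing <- if (condition == "cue") "correct_incorrect" else "cue"
  }
  balancing <- match.arg(balancing, c("correct_incorrect", "cue"))
  if (condition == "cue" && balancing == "cue") {
    stop("resample_plan: condition and balancing variable must differ")
  }
  stopifnot(n_boot >= 1)
  list(condition = condition, balancing = balancing, n_boot = n_boot,
       min_per_cell = min_per_cell, seed = seed)
}

.trial_levels <- function(trials, variable) {
  switch(variable,
         cue = factor(trials$cue, levels = c("LC", "RC")),
         reward = factor(ifelse(trials$rewarded, "RW", "NRW"),
                         levels = c("RW", "NRW")),
         parity = factor(ifelse(seq_len(nrow(trials)) %% 2 == 0,
                                "even", "odd"),
                         levels = c("even", "odd")),
         correct_incorrect = factor(ifelse(trials$correct, "correct",
                                           "incorrect"),
                                    levels = c("correct", "incorrect")),
         stop("unknown variable ", variable))
}

#' Draw balanced trial resamples
#'
#' @param trials trial table; excluded trials are dropped first (parity is
#'   defined on the chronological index among the non-excluded trials)
#' @param plan a [resample_plan()]
#' @param match_noise optional result of a previous [balanced_resample()]
#'   (the test plan's); the null's draws are then noise-matched to the test
#'   maps: per nested cell the draw count is the test plan's `m` and, per
#'   bootstrap, draws come from a without-replacement subsample of the cell
#'   whose size is the harmonic mean of the test plan's balancing-cell
#'   sizes (map noise scales as 1/m + 1/pool, so matching both terms gives
#'   the null maps the test maps' sampling noise). Balancing levels are
#'   matched to the test condition levels by name when possible (the cue
#'   condition), otherwise the aggregate over all test cells is used.
#' @return list with `excluded` (logical), `reason`, `levels` and, when not
#'   excluded, `draws`: a list of `n_boot` elements, each a named list
#'   mapping condition level -> drawn trial ids (a multiset)
#' @export
balanced_resample <- function(trials, plan, match_noise = NULL) {
  use <- trials[!trials$excluded & !is.na(trials$correct), , drop = FALSE]
  cond <- .trial_levels(use, plan$condition)
  bal <- .trial_levels(use, plan$balancing)
  cells <- table(cond, bal)
  if (any(cells < plan$min_per_cell)) {
    return(list(excluded = TRUE,
                reason = sprintf("cell below %d trials (min = %d)",
                                 plan$min_per_cell, min(cells)),
                cells = cells, levels = levels(cond)))
  }
  set.seed(plan$seed)
  lev <- levels(cond)
  blev <- levels(bal)
  # per condition level: ids by balancing cell and the balanced draw count m
  cell_ids <- lapply(lev, function(cl) {
    lapply(blev, function(bl) use$trial_id[cond == cl & bal == bl])
  })
  m <- vapply(cell_ids, function(cells) min(lengths(cells)), 1L)
  # per (condition level, balancing cell) draw counts and pool sizes:
  # minority rule with full pools by default; noise-matched to another
  # plan's cells when match_noise is given
  n_draw <- matrix(m, length(lev), length(blev))
  pool <- matrix(Inf, length(lev), length(blev))
  if (!is.null(match_noise)) {
    hmean <- function(x) length(x) / sum(1 / x)
    tcells <- match_noise$cells
    tm <- match_noise$m
    for (bi in seq_along(blev)) {
      if (blev[bi] %in% names(tm)) {
        n_draw[, bi] <- max(1L, as.integer(round(tm[blev[bi]])))
        pool[, bi] <- hmean(tcells[blev[bi], ])
      } else {
        n_draw[, bi] <- max(1L, as.integer(round(mean(tm))))
        pool[, bi] <- hmean(as.vector(tcells))
      }
    }
  }
  draws <- lapply(seq_len(plan$n_boot), function(b) {
    d <- lapply(seq_along(lev), function(ci) {
      unlist(lapply(seq_along(blev), function(bi) {
        ids <- cell_ids[[ci]][[bi]]
        p <- min(length(ids), round(pool[ci, bi]))
        if (p < length(ids)) ids <- ids[sample.int(length(ids), p)]
        ids[sample.int(length(ids), n_draw[ci, bi], replace = TRUE)]
      }), use.names = FALSE)
    })
    names(d) <- lev
    d
  })
  list(excluded = FALSE, reason = NA_character_, draws = draws,
       levels = lev, m = stats::setNames(m, lev), cells = cells,
       n_draw = n_draw)
}

#' Mean zone rate maps per bootstrap and condition level
#'
#' Zone-wise mean over the sampled trials' rates, taken over the trials
#' that occupied each zone; a zone occupied by none of a draw's trials is
#' masked for that (bootstrap, level) map.
#'
#' @param rates a `trial_zone_rates`
#' @param resample result of [balanced_resample()] (not excluded)
#' @return 3-d array `n_boot x n_levels x 39` of mean maps (NA = masked)
#' @export
condition_maps <- function(rates, resample) {
  if (isTRUE(resample$excluded)) {
    stop("condition_maps: resample is an exclusion result")
  }
  lev <- resample$levels
  nb <- length(resample$draws)
  out <- array(NA_real_, c(nb, length(lev), 39),
               dimnames = list(NULL, lev, 0:38))
  for (b in seq_len(nb)) {
    for (ci in seq_along(lev)) {
      ids <- resample$draws[[b]][[ci]]
      rows <- match(ids, rates$trial_id)
      if (anyNA(rows)) stop("condition_maps: draw references unknown trial")
      m <- rates$rate[rows, , drop = FALSE]
      mu <- colMeans(m, na.rm = TRUE)
      mu[!is.finite(mu)] <- NA_real_
      out[b, ci, ] <- mu
    }
  }
  if (all(is.na(out))) stop("condition_maps: all zones masked")
  out
}
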