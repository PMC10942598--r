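#' Tuning specification for a simulated Tree-Maze unit
#'
#' Rates are inhomogeneous Poisson with a piecewise-constant intensity:
#' base_rate x zone_gain(zone), modulated by the cue and by errors. On
#' Right-Cue trials the zone gains become zone_gains x g_C^gain_weights
#' (rate remapping: a zone-heterogeneous rate change; with the default
#' uniform weights this is a pure rescaling, which leaves the map's rank
#' order -- and hence any rank-correlation score -- untouched). With
#' `remap_mode = "global"` the zone-gain vector is instead replaced by a
#' permutation of itself on Right-Cue trials, modeling a reorganized
#' (rather than rescaled) spatial map. Incorrect trials multiply the rate
#' by g_E. The Left Cue is always the reference condition.
#'
#' @param base_rate Hz
#' @param zone_gains multiplicative gain per zone (length 39, >= 0)
#' @param g_C cue gain applied on RC trials (rate remapping when != 1)
#' @param g_E error gain applied on incorrect trials
#' @param remap_mode "none", "rate" or "global"
#' @param gain_weights per-zone exponents in [0, 1] applied to g_C
#'   (heterogeneous rate remapping); default uniform 1
#' @param a_C additive rate offset (Hz) on Right-Cue trials -- the
#'   generative counterpart of the additive condition term in the Z+C
#'   encoding design; may be negative, rates are clipped at 0
#' @param global_perm permutation of 1..39 applied to `zone_gains` on RC
#'   trials when `remap_mode = "global"`
#' @return list of class `unit_tuning`
#' @export
unit_tuning <- function(base_rate = 5, zone_gains = rep(1, 39), g_C = 1,
                        g_E = 1, remap_mode = c("none", "rate", "global"),
                        gain_weights = rep(1, 39), a_C = 0,
                        global_perm = NULL) {
  remap_mode <- match.arg(remap_mode)
  stopifnot(length(zone_gains) == 39, all(zone_gains >= 0),
            base_rate >= 0, g_C >= 0, g_E >= 0, length(a_C) == 1,
            length(gain_weights) == 39, all(gain_weights >= 0),
            all(gain_weights <= 1))
  if (remap_mode == "global") {
    if (is.null(global_perm)) stop("global remap_mode needs global_perm")
    stopifnot(length(global_perm) == 39,
              all(sort(global_perm) == 1:39))
  }
  structure(list(base_rate = base_rate, zone_gains = zone_gains,
                 g_C = g_C, g_E = g_E, remap_mode = remap_mode,
                 gain_weights = gain_weights, a_C = a_C,
                 global_perm = global_perm),
            class = "unit_tuning")
}

#' Random heterogeneous zone tuning
#'
#' Draws lognormal zone gains (median 1), giving each simulated unit a
#' distinct spatial profile, plus uniform per-zone cue-gain exponents so a
#' cue gain g_C != 1 perturbs the map's shape (not just its scale); uses
#' the current RNG stream.
#'
#' @param base_rate Hz
#' @param sdlog spread of the lognormal zone gains
#' @param ... passed to [unit_tuning()]
#' @export
random_unit_tuning <- function(base_rate = 5, sdlog = 0.8, ...) {
  unit_tuning(base_rate = base_rate,
              zone_gains = stats::rlnorm(39, 0, sdlog),
              gain_weights = stats::runif(39), ...)
}

#' Simulation configuration for Tree-Maze sessions
#'
#' Defaults mirror the behavioral regime of trained animals: ~110 trials per
#' session at ~75% accuracy with random (50/50) cues, ~0.3 s dwell per maze
#' zone and 1 s reward-consumption pauses at wells (which also supply the
#' immobility epochs used by exclusion logic downstream).
#'
#' @param n_trials number of complete trials
#' @param p_correct probability of a correct decision, independent of cue
#' @param cue_prob probability of a Left Cue
#' @param dwell_mean mean zone dwell (s)
#' @param dwell_jitter lognormal sd of the dwell multiplier
#' @param well_pause pause at Home/Goal wells (s)
#' @param tracking_rate Hz
#' @param units list of `unit_tuning`
#' @param p_change_of_mind probability a trial triggers a goal on the wrong
#'   branch before the decided goal (parsed as excluded downstream)
#' @param seed integer; fixes all randomness
#' @export
sim_config <- function(n_trials = 110, p_correct = 0.75, cue_prob = 0.5,
                       dwell_mean = 0.3, dwell_jitter = 0.25,
                       well_pause = 1.0, tracking_rate = 50,
                       units = list(unit_tuning()),
                       p_change_of_mind = 0, seed = 1) {
  stopifnot(p_correct > 0, p_correct < 1, n_trials >= 1, dwell_mean > 0)
  list(n_trials = n_trials, p_correct = p_correct, cue_prob = cue_prob,
       dwell_mean = dwell_mean, dwell_jitter = dwell_jitter,
       well_pause = well_pause, tracking_rate = tracking_rate,
       units = units, p_change_of_mind = p_change_of_mind, seed = seed)
}

# branch zones from (after) the decision well to a goal well
.tm_branch <- function(goal) {
  switch(goal,
         G4 = c(11:16, 17:20),
         G3 = c(11:16, 21:24),
         G1 = c(25:30, 31:34),
         G2 = c(25:30, 35:38))
}

# outbound zone path from home to a goal well
.tm_path_out <- function(goal) c(0:10, .tm_branch(goal))

#' Expected zone-rate vector of a simulated unit for one condition
#'
#' The analytic counterpart of the generator: rates implied by the tuning
#' algebra for a given cue and correctness, used as ground truth in tests.
#'
#' @param tuning a `unit_tuning`
#' @param cue "LC" or "RC"
#' @param correct logical
#' @return numeric(39) expected rate (Hz) per zone
#' @export
expected_zone_rates <- function(tuning, cue, correct) {
  gains <- tuning$zone_gains
  if (cue == "RC") {
    gains <- if (tuning$remap_mode == "global") {
      gains[tuning$global_perm]
    } else {
      gains * tuning$g_C^tuning$gain_weights
    }
  }
  r <- tuning$base_rate * gains
  if (cue == "RC") r <- pmax(r + tuning$a_C, 0)
  if (!correct) r <- r * tuning$g_E
  r
}

#' Simulate a Tree-Maze session with known ground truth
#'
#' Behavior is a zone-level semi-Markov walk over the canonical 39-zone
#' geometry: each trial runs Home -> stem -> Decision -> branch -> Goal and
#' back, with lognormal zone dwells and reward pauses at wells. The decision
#' is correct with probability `p_correct` independent of cue; the goal
#' within the chosen branch is uniform. Tracking (position, heading, speed)
#' is interpolated along zone centroids; spikes are inhomogeneous Poisson
#' with the piecewise-constant intensity of [unit_tuning()].
#'
#' @param cfg a [sim_config()]
#' @return list(session = `session_data`, truth = list(cfg, trials,
#'   intervals, expected_rates))
#' @export
simulate_treemaze <- function(cfg) {
  set.seed(cfg$seed)
  zones <- treemaze_zones()
  zdf <- zones$zones

  cue <- ifelse(stats::runif(cfg$n_trials) < cfg$cue_prob, "LC", "RC")
  correct <- stats::runif(cfg$n_trials) < cfg$p_correct
  dec <- ifelse(correct, ifelse(cue == "LC", "L", "R"),
                ifelse(cue == "LC", "R", "L"))
  goal <- ifelse(dec == "L",
                 ifelse(stats::runif(cfg$n_trials) < 0.5, "G3", "G4"),
                 ifelse(stats::runif(cfg$n_trials) < 0.5, "G1", "G2"))
  com <- stats::runif(cfg$n_trials) < cfg$p_change_of_mind

  # build the interval table (zone occupancy) and event log trial by trial
  iv_t0 <- iv_t1 <- numeric(0)
  iv_zone <- iv_trial <- integer(0)
  ev_t <- numeric(0); ev_kind <- ev_payload <- character(0)
  t <- 0
  push_ev <- function(tt, kind, payload) {
    ev_t <<- c(ev_t, tt); ev_kind <<- c(ev_kind, kind)
    ev_payload <<- c(ev_payload, payload)
  }
  wellz <- well_zones(zones)
  for (i in seq_len(cfg$n_trials)) {
    push_ev(t, "well_trigger", "H")
    push_ev(t, "reward", "H")
    push_ev(t, "cue_on", cue[i])
    wrong_goal <- NA_character_
    if (com[i]) {
      # detour: trigger a goal on the non-decided branch, return to the
      # decision well, then run out to the decided goal
      wrong_goal <- if (dec[i] == "L") "G1" else "G3"
      bw <- .tm_branch(wrong_goal)
      path <- c(0:10, bw, rev(bw)[-1], 10, .tm_branch(goal[i]))
    } else {
      path <- .tm_path_out(goal[i])
    }
    full <- c(path, rev(path)[-1])  # outbound + inbound back to H
    ndw <- length(full)
    dw <- cfg$dwell_mean * stats::rlnorm(ndw, 0, cfg$dwell_jitter)
    # pauses: at trial-start Home and at the decided goal
    dw[1] <- dw[1] + cfg$well_pause
    gpos <- which(full == wellz[goal[i]])[1]
    dw[gpos] <- dw[gpos] + cfg$well_pause
    enter <- t + cumsum(c(0, dw[-ndw]))
    dpos <- which(full == wellz[["D"]])[1]  # first outbound pass through D
    push_ev(enter[dpos], "well_trigger", "D")
    if (com[i]) {
      wpos <- which(full == wellz[wrong_goal])[1]
      push_ev(enter[wpos], "well_trigger", wrong_goal)
    }
    tg <- enter[gpos]
    push_ev(tg, "well_trigger", goal[i])
    push_ev(tg, "cue_off", cue[i])
    if (correct[i]) push_ev(tg, "reward", goal[i])
    iv_t0 <- c(iv_t0, enter)
    iv_t1 <- c(iv_t1, enter + dw)
    iv_zone <- c(iv_zone, full)
    iv_trial <- c(iv_trial, rep(i, ndw))
    t <- enter[ndw] + dw[ndw]
  }
  push_ev(t, "well_trigger", "H")  # terminates the last trial
  events <- data.frame(t = ev_t, kind = ev_kind, payload = ev_payload,
                       stringsAsFactors = FALSE)
  events <- events[order(events$t), ]
  rownames(events) <- NULL

  intervals <- data.frame(t0 = iv_t0, t1 = iv_t1, zone = iv_zone,
                          trial = iv_trial, cue = cue[iv_trial],
                          correct = correct[iv_trial])

  tracking <- .tm_tracking(intervals, zdf, cfg$tracking_rate, t)

  # spikes: piecewise-constant Poisson per occupancy interval
  dur <- intervals$t1 - intervals$t0
  unit_names <- names(cfg$units)
  if (is.null(unit_names) || any(!nzchar(unit_names))) {
    unit_names <- sprintf("u%03d", seq_along(cfg$units))
  }
  spike_trains <- list()
  exp_rates <- list()
  for (u in seq_along(cfg$units)) {
    tun <- cfg$units[[u]]
    lam <- .tm_rate_matrix(tun)[
      cbind(intervals$zone + 1L,
            1L + (intervals$cue == "RC") + 2L * (!intervals$correct))]
    counts <- stats::rpois(length(lam), lam * dur)
    st <- rep(intervals$t0, counts) + stats::runif(sum(counts)) *
      rep(dur, counts)
    spike_trains[[unit_names[u]]] <- sort(st)
    exp_rates[[unit_names[u]]] <- list(
      LC_correct = expected_zone_rates(tun, "LC", TRUE),
      LC_incorrect = expected_zone_rates(tun, "LC", FALSE),
      RC_correct = expected_zone_rates(tun, "RC", TRUE),
      RC_incorrect = expected_zone_rates(tun, "RC", FALSE))
  }

  session <- session_data(
    subject_id = "sim", session_id = sprintf("tm_seed%d", cfg$seed),
    task = "treemaze", spike_trains = spike_trains, tracking = tracking,
    events = events, tetrode_depths = c(tt1 = 0), zones = zones)

  truth_trials <- data.frame(trial_id = seq_len(cfg$n_trials), cue = cue,
                             decision = dec, correct = correct,
                             rewarded = correct,
                             switch = c(FALSE, cue[-1] != cue[-cfg$n_trials]),
                             goal_well = goal, change_of_mind = com,
                             stringsAsFactors = FALSE)
  list(session = session,
       truth = list(cfg = cfg, trials = truth_trials, intervals = intervals,
                    expected_rates = exp_rates))
}

# 39 x 4 matrix of firing rates by condition (LC/RC x correct/incorrect)
.tm_rate_matrix <- function(tun) {
  r_lc <- tun$base_rate * tun$zone_gains
  r_rc <- if (tun$remap_mode == "global") {
    tun$base_rate * tun$zone_gains[tun$global_perm]
  } else {
    tun$base_rate * tun$zone_gains * tun$g_C^tun$gain_weights
  }
  r_rc <- pmax(r_rc + tun$a_C, 0)
  cbind(r_lc, r_rc, r_lc * tun$g_E, r_rc * tun$g_E)
}

# interpolate tracking along zone-centroid waypoints; long dwells (well
# pauses) get two waypoints at the same centroid so the subject is truly
# stationary there (speed ~ 0, the immobility epochs)
.tm_tracking <- function(intervals, zdf, rate, t_end) {
  dur <- intervals$t1 - intervals$t0
  long <- dur > 0.8
  cx <- zdf$x[intervals$zone + 1L]
  cy <- zdf$y[intervals$zone + 1L]
  wp_t <- c((intervals$t0[!long] + intervals$t1[!long]) / 2,
            intervals$t0[long] + 0.25 * dur[long],
            intervals$t1[long] - 0.25 * dur[long])
  wp_x <- c(cx[!long], cx[long], cx[long])
  wp_y <- c(cy[!long], cy[long], cy[long])
  o <- order(wp_t)
  wp_t <- wp_t[o]; wp_x <- wp_x[o]; wp_y <- wp_y[o]
  tt <- seq(0, ceiling(t_end * rate) / rate, by = 1 / rate)
  x <- stats::approx(wp_t, wp_x, xout = tt, rule = 2)$y
  y <- stats::approx(wp_t, wp_y, xout = tt, rule = 2)$y
  dx <- c(diff(x), 0); dy <- c(diff(y), 0)
  theta <- atan2(dy, dx)
  still <- abs(dx) < 1e-9 & abs(dy) < 1e-9
  # hold heading through pauses
  if (any(still) && !all(still)) {
    idx <- seq_along(theta)
    idx[still] <- NA
    filled <- stats::approx(idx[!still], theta[!still], xout = seq_along(theta),
                            method = "constant", rule = 2)$y
    theta[still] <- filled[still]
  }
  speed <- sqrt(dx^2 + dy^2) * rate
  data.frame(t = tt, x = x, y = y,
             theta = ((theta + pi) %% (2 * pi)) - pi, speed = speed)
}
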