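# Shared simulated fixtures, built once per test run (they are the slow
# part of the suite). Everything is seeded, so reuse is deterministic.
.fixtures <- new.env(parent = emptyenv())

# A Tree-Maze session with one flat, one rate-remapping and one
# global-remapping unit, plus parsed trials and the tracked zone sequence.
tm_fixture <- function() {
  if (is.null(.fixtures$tm)) {
    set.seed(11)
    units <- list(
      flat = unit_tuning(base_rate = 6),
      rate = random_unit_tuning(base_rate = 6, g_C = 3, remap_mode = "rate"),
      glob = random_unit_tuning(base_rate = 6, remap_mode = "global",
                                global_perm = sample(39)))
    sim <- simulate_treemaze(sim_config(n_trials = 80, units = units,
                                        seed = 21))
    trials <- parse_trials(sim$session$events)
    zone_seq <- assign_zones(sim$session$tracking, sim$session$zones)
    .fixtures$tm <- list(sim = sim, trials = trials, zone_seq = zone_seq)
  }
  .fixtures$tm
}

# trial_zone_rates for one unit of the Tree-Maze fixture
tm_rates <- function(unit = "flat", direction = "outbound") {
  fx <- tm_fixture()
  key <- paste0("rates_", unit, "_", direction)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- trial_zone_rates(
      fx$sim$session$spike_trains[[unit]], fx$zone_seq,
      fx$sim$session$tracking, fx$trials, direction = direction,
      unit_id = unit)
  }
  .fixtures[[key]]
}

# A hand-written minimal event log: n complete trials with the given cues
# and decisions, fixed timing (outbound 5 s, inbound 5 s).
toy_events <- function(cues, decisions) {
  stopifnot(length(cues) == length(decisions))
  ev <- NULL
  t <- 0
  add <- function(t, kind, payload) {
    rbind(ev, data.frame(t = t, kind = kind, payload = payload,
                         stringsAsFactors = FALSE))
  }
  for (i in seq_along(cues)) {
    ev <- add(t, "well_trigger", "H")
    ev <- add(t, "reward", "H")
    ev <- add(t, "cue_on", cues[i])
    ev <- add(t + 2.5, "well_trigger", "D")
    goal <- if (decisions[i] == "L") "G3" else "G1"
    correct <- (cues[i] == "LC") == (decisions[i] == "L")
    ev <- add(t + 5, "well_trigger", goal)
    ev <- add(t + 5, "cue_off", cues[i])
    if (correct) ev <- add(t + 5, "reward", goal)
    t <- t + 10
  }
  ev <- add(t, "well_trigger", "H")
  ev
}

# A minimal open-field binned object with analytically known tuning: the
# animal sweeps headings uniformly on a grid at constant speed, visiting
# position bins round-robin, and the unit's "rate" is an exact von Mises
# function of heading (no sampling noise).
toy_of_binned <- function(kappa = 2, n = 7200) {
  theta <- seq(-pi, pi, length.out = n + 1)[-1]
  rate <- exp(kappa * cos(theta)) / besselI(kappa, 0)
  nx <- 4L; ny <- 4L
  list(t = seq_len(n) * 0.02,
       rates = matrix(rate, n, 1, dimnames = list(NULL, "u1")),
       speed = rep(10, n), theta = theta,
       x = rep(1, n), y = rep(1, n),
       speed_bin = rep(5L, n),
       hd_bin = findInterval(theta, seq(-pi, pi, by = pi / 18),
                             rightmost.closed = TRUE),
       pos_bin = rep_len(seq_len(nx * ny), n),
       immobile = rep(FALSE, n), dt = 0.02,
       bins = list(pos_bin = 5, speed_breaks = seq(2, 40, by = 2),
                   hd_bin_deg = 10, arena = c(20, 20), nx = nx, ny = ny))
}
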