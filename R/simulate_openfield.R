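#' Tuning specification for a simulated open-field unit
#'
#' Intensity model: rate = base_rate x place x hd x speed, clipped at 0,
#' with
#' \itemize{
#'   \item place = 1 + place_amp * exp(-d^2 / (2 place_width^2)), d the
#'     distance to the field center;
#'   \item hd = exp(kappa * cos(theta - hd_mu)) / I0(kappa), normalized so a
#'     uniform-heading average is 1; under uniform heading occupancy the
#'     rate-weighted resultant length of a pure HD unit is the Bessel ratio
#'     I1(kappa) / I0(kappa);
#'   \item speed = 1 + speed_slope * speed / base_rate (the slope is in Hz
#'     per cm/s for an otherwise untuned unit).
#' }
#'
#' @param base_rate Hz
#' @param place_center (x, y) cm, or NULL for no place tuning
#' @param place_width cm (Gaussian sd)
#' @param place_amp peak place gain above baseline (0 = flat)
#' @param hd_mu preferred heading (rad)
#' @param hd_kappa von Mises concentration (0 = no HD tuning)
#' @param speed_slope Hz per cm/s
#' @return list of class `of_tuning`
#' @export
of_tuning <- function(base_rate = 5, place_center = NULL, place_width = 15,
                      place_amp = 0, hd_mu = 0, hd_kappa = 0,
                      speed_slope = 0) {
  stopifnot(base_rate >= 0, hd_kappa >= 0, place_amp >= 0, place_width > 0)
  structure(list(base_rate = base_rate, place_center = place_center,
                 place_width = place_width, place_amp = place_amp,
                 hd_mu = hd_mu, hd_kappa = hd_kappa,
                 speed_slope = speed_slope),
            class = "of_tuning")
}

#' Configuration for an open-field foraging simulation
#'
#' The arena is 1.3 m x 1.5 m. The trajectory is a bounded
#' Ornstein-Uhlenbeck random walk on velocity with reflection at the walls,
#' interleaved with immobility bouts (speed < 2 cm/s) so that the
#' immobility-exclusion logic downstream is exercised.
#'
#' @param duration_s session length (default 30 min)
#' @param tracking_rate Hz
#' @param units list of `of_tuning`
#' @param mean_mobile_s,mean_still_s mean mobile / immobile bout lengths
#' @param speed_sd cm/s scale of the velocity process
#' @param seed integer
#' @export
of_config <- function(duration_s = 1800, tracking_rate = 50,
                      units = list(of_tuning()), mean_mobile_s = 10,
                      mean_still_s = 2, speed_sd = 14, seed = 1) {
  stopifnot(duration_s > 0)
  list(duration_s = duration_s, tracking_rate = tracking_rate,
       units = units, mean_mobile_s = mean_mobile_s,
       mean_still_s = mean_still_s, speed_sd = speed_sd, seed = seed,
       arena = c(130, 150))
}

#' Simulate an open-field foraging session
#'
#' @param cfg an [of_config()]
#' @return list(session = `session_data`, truth = list(cfg, mobile))
#' @export
simulate_openfield <- function(cfg) {
  set.seed(cfg$seed)
  dt <- 1 / cfg$tracking_rate
  n <- floor(cfg$duration_s / dt) + 1L
  W <- cfg$arena[1]; H <- cfg$arena[2]

  # mobile / immobile bout sequence
  state <- logical(0)
  while (length(state) < n) {
    state <- c(state,
               rep(TRUE, max(1, round(stats::rexp(1, 1 / cfg$mean_mobile_s) / dt))),
               rep(FALSE, max(1, round(stats::rexp(1, 1 / cfg$mean_still_s) / dt))))
  }
  state <- state[seq_len(n)]

  tau <- 1.0
  x <- numeric(n); y <- numeric(n); vx <- numeric(n); vy <- numeric(n)
  x[1] <- W / 2; y[1] <- H / 2
  sig <- cfg$speed_sd * sqrt(2 * dt / tau)
  a <- exp(-dt / tau)
  ex <- stats::rnorm(n) * sig
  ey <- stats::rnorm(n) * sig
  for (i in 2:n) {
    if (state[i]) {
      vx[i] <- vx[i - 1] * a + ex[i]
      vy[i] <- vy[i - 1] * a + ey[i]
    } else {
      vx[i] <- 0
      vy[i] <- 0
    }
    x[i] <- x[i - 1] + vx[i] * dt
    y[i] <- y[i - 1] + vy[i] * dt
    if (x[i] < 2) { x[i] <- 4 - x[i]; vx[i] <- -vx[i] }
    if (x[i] > W - 2) { x[i] <- 2 * (W - 2) - x[i]; vx[i] <- -vx[i] }
    if (y[i] < 2) { y[i] <- 4 - y[i]; vy[i] <- -vy[i] }
    if (y[i] > H - 2) { y[i] <- 2 * (H - 2) - y[i]; vy[i] <- -vy[i] }
  }
  speed <- sqrt(vx^2 + vy^2)
  theta <- atan2(vy, vx)
  # hold heading through immobility
  still <- speed < 1e-9
  if (any(still) && !all(still)) {
    idx <- seq_len(n)
    filled <- stats::approx(idx[!still], theta[!still], xout = idx,
                            method = "constant", rule = 2)$y
    theta[still] <- filled[still]
  }
  tt <- (seq_len(n) - 1) * dt
  tracking <- data.frame(t = tt, x = x, y = y,
                         theta = ((theta + pi) %% (2 * pi)) - pi,
                         speed = speed)

  spike_trains <- list()
  for (u in seq_along(cfg$units)) {
    lam <- of_rate(cfg$units[[u]], tracking)
    counts <- stats::rpois(n, lam * dt)
    st <- rep(tt, counts) + stats::runif(sum(counts)) * dt
    st <- sort(pmin(st, tt[n]))
    spike_trains[[sprintf("u%03d", u)]] <- st
  }
  session <- session_data(
    subject_id = "sim", session_id = sprintf("of_seed%d", cfg$seed),
    task = "openfield", spike_trains = spike_trains, tracking = tracking,
    events = NULL, tetrode_depths = c(tt1 = 0))
  list(session = session, truth = list(cfg = cfg, mobile = state))
}

#' Instantaneous intensity of an open-field tuning spec along a trajectory
#' @param tuning an [of_tuning()]
#' @param tracking data.frame with x, y, theta, speed
#' @return numeric vector of rates (Hz), clipped at 0
#' @export
of_rate <- function(tuning, tracking) {
  r <- rep(tuning$base_rate, nrow(tracking))
  if (!is.null(tuning$place_center) && tuning$place_amp > 0) {
    d2 <- (tracking$x - tuning$place_center[1])^2 +
      (tracking$y - tuning$place_center[2])^2
    r <- r * (1 + tuning$place_amp * exp(-d2 / (2 * tuning$place_width^2)))
  }
  if (tuning$hd_kappa > 0) {
    r <- r * exp(tuning$hd_kappa * cos(tracking$theta - tuning$hd_mu)) /
      besselI(tuning$hd_kappa, 0)
  }
  if (tuning$speed_slope != 0) {
    r <- r * (1 + tuning$speed_slope * tracking$speed / tuning$base_rate)
  }
  pmax(r, 0)
}

#' Simulate spike-waveform sets across sessions with known identity
#'
#' Each unit is a 128-feature template (4 channels x 32 samples built from
#' smooth spike-like shapes). Per session the template drifts by a small
#' multiplicative gain plus a small additive offset, and each of `n_spikes`
#' spikes is the drifted template plus i.i.d. Gaussian noise. All sessions
#' share one tetrode at one depth, the regime in which across-session
#' matching operates.
#'
#' @param n_units number of units (>= 1)
#' @param n_sessions number of sessions
#' @param drift scale of the per-session template drift (multiplicative
#'   gain sd, plus an additive feature offset with sd `5 * drift` on the
#'   fixed feature scale). The drift is deliberately independent of
#'   `separation`: separation controls how far *different* units sit from
#'   each other relative to the fixed spike noise, not how much the *same*
#'   unit moves across sessions
#' @param separation template amplitude scale; larger separates clouds more
#' @param noise per-feature additive spike noise sd
#' @param amp_jitter per-spike multiplicative amplitude jitter sd. Spike
#'   amplitudes fluctuate around the template (bursting, adaptation), so
#'   the cloud's spread along the template direction scales with the
#'   template norm; the session gain drift then displaces a unit by a
#'   fixed fraction (`drift / amp_jitter`) of its own cloud width at any
#'   separation
#' @param n_spikes spikes sampled per unit per session
#' @param seed integer
#' @return list(sessions = list of list(W spikes x 128 matrix, index
#'   data.frame(unit_id, tetrode, depth, row0, row1)), truth =
#'   data.frame(session, unit_id, template))
#' @export
simulate_waveform_sets <- function(n_units, n_sessions = 2, drift = 0.02,
                                   separation = 4, noise = 1,
                                   amp_jitter = 0.05,
                                   n_spikes = 1000, seed = 1) {
  stopifnot(n_units >= 1, n_sessions >= 1)
  set.seed(seed)
  tgrid <- seq(0, 1, length.out = 32)
  shape <- function() {
    w <- stats::runif(1, 0.05, 0.12)
    c0 <- stats::runif(1, 0.25, 0.45)
    -exp(-(tgrid - c0)^2 / (2 * w^2)) +
      0.4 * exp(-(tgrid - c0 - 0.25)^2 / (2 * (2 * w)^2))
  }
  templates <- lapply(seq_len(n_units), function(k) {
    amps <- stats::rnorm(4, 0, 1)
    as.vector(outer(shape(), amps)) * separation * 5
  })
  sessions <- vector("list", n_sessions)
  truth <- NULL
  for (s in seq_len(n_sessions)) {
    W <- matrix(0, n_units * n_spikes, 128)
    index <- data.frame(unit_id = sprintf("s%d_u%d", s, seq_len(n_units)),
                        tetrode = 1L, depth = 0,
                        row0 = (seq_len(n_units) - 1) * n_spikes + 1L,
                        row1 = seq_len(n_units) * n_spikes,
                        stringsAsFactors = FALSE)
    for (k in seq_len(n_units)) {
      tpl <- templates[[k]] * (1 + drift * stats::rnorm(1)) +
        drift * 5 * stats::rnorm(128)
      rows <- index$row0[k]:index$row1[k]
      gains <- 1 + amp_jitter * stats::rnorm(n_spikes)
      W[rows, ] <- outer(gains, tpl) +
        matrix(stats::rnorm(n_spikes * 128, 0, noise), n_spikes, 128)
    }
    sessions[[s]] <- list(W = W, index = index)
    truth <- rbind(truth, data.frame(session = s, unit_id = index$unit_id,
                                     template = seq_len(n_units),
                                     stringsAsFactors = FALSE))
  }
  list(sessions = sessions, truth = truth)
}
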