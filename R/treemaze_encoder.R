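#' Bin a Tree-Maze session into 20 ms samples
#'
#' Builds the sample-level substrate of the encoding and decoding models:
#' within each non-excluded trial's outbound (or inbound) window, time is
#' cut into half-open 20 ms bins; each sample carries the occupied zone
#' (from the tracked zone sequence at the bin center), the trial id and its
#' covariates (cue, correctness, reward), and per-unit firing rates (spike
#' count in the bin / bin width). A spike exactly on a bin edge belongs to
#' the later bin.
#'
#' @param session a `session_data`
#' @param trials trial table
#' @param zone_seq zone id per tracking sample (from [assign_zones()])
#' @param direction "outbound" or "inbound"
#' @param bin bin width (s)
#' @return object of class `binned_session`: list(t, zone, trial, cue,
#'   correct, rewarded, rates (samples x units matrix), bin, unit_ids)
#' @export
bin_session <- function(session, trials, zone_seq,
                        direction = c("outbound", "inbound"), bin = 0.02) {
  direction <- match.arg(direction)
  use <- trials[!trials$excluded & !is.na(trials$t_out0), , drop = FALSE]
  if (nrow(use) == 0) stop("bin_session: no usable trials")
  w0 <- if (direction == "outbound") use$t_out0 else use$t_in0
  w1 <- if (direction == "outbound") use$t_out1 else use$t_in1
  centers <- trial <- NULL
  for (i in seq_len(nrow(use))) {
    edges <- seq(w0[i], w1[i], by = bin)
    if (length(edges) < 2) next
    ct <- edges[-length(edges)] + bin / 2
    centers <- c(centers, ct)
    trial <- c(trial, rep(use$trial_id[i], length(ct)))
  }
  if (is.null(centers)) stop("bin_session: no samples")
  samp <- findInterval(centers, session$tracking$t)
  samp[samp == 0] <- 1L
  zone <- zone_seq[samp]
  units <- names(session$spike_trains)
  rates <- matrix(0, length(centers), length(units),
                  dimnames = list(NULL, units))
  left <- centers - bin / 2
  for (u in seq_along(units)) {
    st <- session$spike_trains[[units[u]]]
    if (!length(st)) next
    # half-open [left, left + bin): count spikes per sample bin
    idx <- .window_index(st, left, left + bin)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = length(centers))
      rates[, u] <- tab / bin
    }
  }
  ti <- match(trial, use$trial_id)
  ok <- !is.na(zone)
  structure(list(t = centers[ok], zone = zone[ok], trial = trial[ok],
                 cue = use$cue[ti][ok], correct = use$correct[ti][ok],
                 rewarded = use$rewarded[ti][ok],
                 rates = rates[ok, , drop = FALSE],
                 direction = direction, bin = bin, unit_ids = units),
            class = "binned_session")
}

#' Feature specification for the zone encoding models
#'
#' Schemes: `Z0` one-hot current zone (39 features); `Z+lag` / `Z-lag` add
#' the zones up to `lag_horizon` samples ahead / behind with inverse-lag
#' weights 1/lag, accumulated within trial only; `Z+C` the lagged zone
#' features plus two binary condition indicators (41 features; the additive
#' rate-remapping model); `ZxC` the lagged zone block duplicated per
#' condition level, only the active level's block nonzero (78 features; the
#' interactive global-remapping model). `condition` is "cue" for outbound
#' models (Z+C, ZxC) and "reward" for the inbound variants (Zi+R, ZixR).
#'
#' @param scheme one of "Z0", "Z+lag", "Z-lag", "Z+C", "ZxC"
#' @param lag_horizon samples (50 = 1 s at 20 ms bins)
#' @param condition "cue" or "reward"
#' @export
feature_spec <- function(scheme = c("Z+C", "Z0", "Z+lag", "Z-lag", "ZxC"),
                         lag_horizon = 50, condition = c("cue", "reward")) {
  scheme <- match.arg(scheme)
  condition <- match.arg(condition)
  n_features <- switch(scheme, Z0 = 39L, `Z+lag` = 39L, `Z-lag` = 39L,
                       `Z+C` = 41L, ZxC = 78L)
  list(scheme = scheme, lag_horizon = lag_horizon, condition = condition,
       n_features = n_features)
}

# lagged one-hot zone design: weight 1 on the current zone plus 1/lag on
# the zone `lag` samples ahead (sign +1) or behind (-1), within trial
.zone_lag_design <- function(zone, trial, horizon, sign) {
  n <- length(zone)
  X <- matrix(0, n, 39)
  X[cbind(seq_len(n), zone + 1L)] <- 1
  if (horizon > 0) {
    for (l in seq_len(horizon)) {
      src <- seq_len(n) + sign * l
      ok <- src >= 1 & src <= n
      ok[ok] <- trial[src[ok]] == trial[which(ok)]
      idx <- which(ok)
      X[cbind(idx, zone[src[idx]] + 1L)] <-
        X[cbind(idx, zone[src[idx]] + 1L)] + 1 / l
    }
  }
  X
}

#' Build the design matrix for an encoding scheme
#'
#' @param binned a `binned_session`
#' @param spec a [feature_spec()]
#' @return numeric matrix samples x n_features
#' @export
build_features <- function(binned, spec) {
  cond_flag <- switch(spec$condition,
                      cue = binned$cue == "RC",
                      reward = !binned$rewarded)
  base <- switch(spec$scheme,
                 Z0 = .zone_lag_design(binned$zone, binned$trial, 0, 1L),
                 `Z+lag` = ,
                 `Z+C` = ,
                 ZxC = .zone_lag_design(binned$zone, binned$trial,
                                        spec$lag_horizon, 1L),
                 `Z-lag` = .zone_lag_design(binned$zone, binned$trial,
                                            spec$lag_horizon, -1L))
  if (spec$scheme == "Z+C") {
    cbind(base, lev1 = as.numeric(!cond_flag), lev2 = as.numeric(cond_flag))
  } else if (spec$scheme == "ZxC") {
    cbind(base * as.numeric(!cond_flag), base * as.numeric(cond_flag))
  } else {
    base
  }
}

# cue-balanced trial folds: each condition level's trials are split into
# `folds` random parts; fold f tests on part f of every level, and the
# training trials are subsampled so both levels contribute equally
.balanced_trial_folds <- function(trial_ids, level, folds, seed) {
  set.seed(seed)
  lev <- unique(level)
  assign <- stats::setNames(rep(NA_integer_, length(trial_ids)),
                            trial_ids)
  for (l in lev) {
    ids <- sample(trial_ids[level == l])
    assign[as.character(ids)] <- rep_len(seq_len(folds), length(ids))
  }
  lapply(seq_len(folds), function(f) {
    test <- trial_ids[assign[as.character(trial_ids)] == f]
    train <- trial_ids[assign[as.character(trial_ids)] != f]
    tl <- level[match(train, trial_ids)]
    m <- min(table(tl))
    train_bal <- unlist(lapply(lev, function(l) {
      tr <- train[tl == l]
      sample(tr, m)
    }), use.names = FALSE)
    list(train = train_bal, test = test)
  })
}

# weighted least squares with multiple responses; ridge fallback on rank
# deficiency
.wls_fit <- function(X, Y, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  Yw <- Y * sw
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(X)) {
    XtX <- crossprod(Xw)
    lambda <- 1e-6 * mean(diag(XtX))
    B <- solve(XtX + diag(lambda, ncol(X)), crossprod(Xw, Yw))
    attr(B, "ridge") <- lambda
    return(B)
  }
  qr.coef(qr_x, Yw)
}

#' Fit a zone encoding model with balanced cross-validated least squares
#'
#' Trial-level 5-fold cross validation: trials (never samples) are the
#' cross-validation unit, each training set holds an equal number of trials
#' per condition level, and each training sample is weighted inversely to
#' the frequency of its trial type (correct/incorrect) within its condition
#' level, so that error trials are not swamped. Firing rates of all units
#' are fit jointly (shared design, one least-squares solve per fold). The
#' per-fold test R^2 = 1 - SS_res / SS_tot uses the test-fold mean rate;
#' a unit with any fold R^2 < -1 is flagged `excluded` (convergence
#' pathology by convention).
#'
#' @param binned a `binned_session`
#' @param spec a [feature_spec()]
#' @param folds number of folds
#' @param seed integer (fold assignment and balancing subsample)
#' @return object of class `encoder_result`: list(spec, r2 (folds x units),
#'   weights (features x units, mean over folds), excluded (per unit),
#'   folds, unit_ids)
#' @export
fit_encoder <- function(binned, spec, folds = 5, seed = 1) {
  X <- build_features(binned, spec)
  Y <- binned$rates
  trial_ids <- unique(binned$trial)
  lev_trial <- switch(spec$condition,
                      cue = binned$cue[match(trial_ids, binned$trial)],
                      reward = ifelse(
                        binned$rewarded[match(trial_ids, binned$trial)],
                        "RW", "NRW"))
  if (min(table(lev_trial)) < folds) {
    stop("fit_encoder: fewer trials than folds in a condition level")
  }
  corr_trial <- binned$correct[match(trial_ids, binned$trial)]
  fold_sets <- .balanced_trial_folds(trial_ids, lev_trial, folds, seed)
  nu <- ncol(Y)
  r2 <- matrix(NA_real_, folds, nu, dimnames = list(NULL, colnames(Y)))
  Wsum <- matrix(0, ncol(X), nu)
  for (f in seq_len(folds)) {
    tr <- binned$trial %in% fold_sets[[f]]$train
    te <- binned$trial %in% fold_sets[[f]]$test
    # inverse-frequency weights for correct/incorrect within each level
    w <- rep(1, sum(tr))
    lev_s <- switch(spec$condition, cue = binned$cue[tr],
                    reward = ifelse(binned$rewarded[tr], "RW", "NRW"))
    corr_s <- binned$correct[tr]
    for (l in unique(lev_s)) {
      sel <- lev_s == l
      p_c <- mean(corr_s[sel])
      if (p_c > 0 && p_c < 1) {
        w[sel][corr_s[sel]] <- 1 / p_c
        w[sel][!corr_s[sel]] <- 1 / (1 - p_c)
      }
    }
    w <- w / mean(w)
    B <- .wls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], w)
    Wsum <- Wsum + B
    pred <- X[te, , drop = FALSE] %*% B
    truth <- Y[te, , drop = FALSE]
    mu <- colMeans(truth)
    ss_res <- colSums((truth - pred)^2)
    ss_tot <- colSums(sweep(truth, 2, mu)^2)
    r2[f, ] <- 1 - ss_res / ss_tot
  }
  structure(list(spec = spec, r2 = r2, weights = Wsum / folds,
                 excluded = apply(r2 < -1, 2, any),
                 folds = folds, unit_ids = colnames(Y)),
            class = "encoder_result")
}

#' Compare two encoding models over test folds
#'
#' For each unit, the Mann-Whitney Z statistic over the two models' test-
#' fold R^2 samples (positive = model A better), plus the median R^2
#' difference. Units excluded in either fit are skipped (NA).
#'
#' @param a,b `encoder_result`s fit on the same folds
#' @return data.frame(unit_id, uz, median_dr2, excluded)
#' @export
compare_encoders <- function(a, b) {
  stopifnot(identical(a$unit_ids, b$unit_ids), a$folds == b$folds)
  out <- data.frame(unit_id = a$unit_ids, uz = NA_real_,
                    median_dr2 = NA_real_,
                    excluded = a$excluded | b$excluded,
                    stringsAsFactors = FALSE)
  for (u in seq_along(a$unit_ids)) {
    if (out$excluded[u]) next
    res <- mann_whitney_uz(a$r2[, u], b$r2[, u])
    out$uz[u] <- res$UZ
    out$median_dr2[u] <- stats::median(a$r2[, u] - b$r2[, u])
  }
  out
}
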