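#' Multinomial position decoder
#'
#' Ridge-penalized multinomial logistic regression (softmax link) from the
#' population rate vector (optionally augmented with the two cue
#' indicators) to the 39 maze zones, cross-validated over cue-balanced
#' trial folds. Per test sample the decoder outputs a normalized zone
#' posterior; the predicted zone is the argmax and the decoding error is
#' the distance in cm between the predicted and true zone centroids. Zones
#' absent from a training fold simply get zero posterior (the penalized fit
#' only models observed classes). Errors are summarized per true zone and
#' per linearized maze position (Home -> stem -> Decision -> branch ->
#' Goal, left/right equivalents averaged).
#'
#' @param binned a `binned_session`
#' @param with_cue append the two cue indicator features
#' @param folds number of folds
#' @param seed integer
#' @param lambda ridge penalty of the multinomial fit
#' @param zones a `zone_map`
#' @return list(posterior (samples x 39), predicted, error_cm (per sample),
#'   zone_error (39), linear_error (by linear_pos), balanced folds, lambda)
#' @export
fit_position_decoder <- function(binned, with_cue = FALSE, folds = 5,
                                 seed = 1, lambda = 0.01,
                                 zones = treemaze_zones()) {
  if (ncol(binned$rates) < 2) stop("fit_position_decoder: need >= 2 units")
  X <- binned$rates
  if (with_cue) {
    X <- cbind(X, cueL = as.numeric(binned$cue == "LC"),
               cueR = as.numeric(binned$cue == "RC"))
  }
  y <- binned$zone
  trial_ids <- unique(binned$trial)
  lev_trial <- binned$cue[match(trial_ids, binned$trial)]
  fold_sets <- .balanced_trial_folds(trial_ids, lev_trial, folds, seed)
  n <- nrow(X)
  posterior <- matrix(0, n, 39, dimnames = list(NULL, 0:38))
  for (f in seq_len(folds)) {
    tr <- binned$trial %in% fold_sets[[f]]$train
    te <- binned$trial %in% fold_sets[[f]]$test
    ytr <- factor(y[tr])
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], ytr,
                          family = "multinomial", alpha = 0,
                          lambda = c(10 * lambda, lambda))
    pr <- stats::predict(fit, X[te, , drop = FALSE], s = lambda,
                         type = "response")[, , 1]
    posterior[te, levels(ytr)] <- pr
  }
  predicted <- as.integer(colnames(posterior)[max.col(posterior,
                                                      ties.method = "first")])
  zx <- zones$zones$x; zy <- zones$zones$y
  err <- sqrt((zx[predicted + 1] - zx[y + 1])^2 +
                (zy[predicted + 1] - zy[y + 1])^2)
  zone_error <- vapply(0:38, function(z) {
    if (any(y == z)) mean(err[y == z]) else NA_real_
  }, 1.0)
  lin <- zones$zones$linear_pos
  linear_error <- vapply(sort(unique(lin)), function(lp) {
    mean(zone_error[lin == lp], na.rm = TRUE)
  }, 1.0)
  names(linear_error) <- sort(unique(lin))
  list(posterior = posterior, predicted = predicted, error_cm = err,
       zone_error = zone_error, linear_error = linear_error,
       with_cue = with_cue, lambda = lambda)
}

#' Logit with probability clipping
#' @param p probabilities; clipped to [1e-6, 1 - 1e-6]
#' @return log(p / (1 - p))
#' @export
clip_logit <- function(p) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  log(p / (1 - p))
}

#' Binary decision decoder with per-zone trial evaluation
#'
#' Ridge-penalized logistic regression from population rates to the
#' subject's decision (Left vs Right), cross-validated over cue-balanced
#' trial folds. The per-sample P(Left) outputs are averaged by zone within
#' each trial (trials x zones matrix), converted to logits (clipped) and
#' integrated cumulatively along the linearized maze. Per zone, the
#' decision read out from the mean probability (threshold 0.5) is scored
#' against the subject's decision with balanced accuracy (mean of the
#' per-class accuracies); trials that never visited a zone are excluded
#' from that zone's score.
#'
#' @param binned a `binned_session`
#' @param folds,seed,lambda as in [fit_position_decoder()]
#' @param zones a `zone_map`
#' @return list(p_left (per sample), trial_zone_p (trials x 39),
#'   trial_zone_logit, integrated_logit (trials x linear positions),
#'   zone_bac (39), lin_p (trials x linear positions), lin_bac,
#'   trial_ids, decisions)
#' @export
fit_decision_decoder <- function(binned, folds = 5, seed = 1, lambda = 0.01,
                                 zones = treemaze_zones()) {
  if (ncol(binned$rates) < 2) stop("fit_decision_decoder: need >= 2 units")
  trial_ids <- unique(binned$trial)
  first <- match(trial_ids, binned$trial)
  decision <- ifelse(binned$cue[first] == "LC", binned$correct[first],
                     !binned$correct[first])  # TRUE = Left
  if (length(unique(decision)) < 2) {
    stop("fit_decision_decoder: both decisions must be present")
  }
  lev_trial <- binned$cue[first]
  fold_sets <- .balanced_trial_folds(trial_ids, lev_trial, folds, seed)
  y <- decision[match(binned$trial, trial_ids)]
  p_left <- rep(NA_real_, nrow(binned$rates))
  for (f in seq_len(folds)) {
    tr <- binned$trial %in% fold_sets[[f]]$train
    te <- binned$trial %in% fold_sets[[f]]$test
    fit <- glmnet::glmnet(binned$rates[tr, , drop = FALSE],
                          factor(y[tr], levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 0,
                          lambda = c(10 * lambda, lambda))
    p_left[te] <- as.numeric(
      stats::predict(fit, binned$rates[te, , drop = FALSE], s = lambda,
                     type = "response"))
  }
  nt <- length(trial_ids)
  tz_p <- matrix(NA_real_, nt, 39, dimnames = list(trial_ids, 0:38))
  ti <- match(binned$trial, trial_ids)
  for (z in 0:38) {
    sel <- binned$zone == z
    if (!any(sel)) next
    s <- tapply(p_left[sel], ti[sel], mean)
    tz_p[as.integer(names(s)), z + 1] <- s
  }
  tz_logit <- clip_logit(tz_p)
  lin <- zones$zones$linear_pos
  lps <- sort(unique(lin))
  integrated <- matrix(NA_real_, nt, length(lps),
                       dimnames = list(trial_ids, lps))
  for (i in seq_len(nt)) {
    by_lp <- vapply(lps, function(lp) {
      v <- tz_logit[i, lin == lp]
      if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }, 1.0)
    integrated[i, ] <- cumsum(by_lp)
  }
  zone_bac <- rep(NA_real_, 39)
  for (z in 0:38) {
    p <- tz_p[, z + 1]
    ok <- !is.na(p)
    if (sum(ok) < 4 || length(unique(decision[ok])) < 2) next
    pred_left <- p[ok] > 0.5
    d <- decision[ok]
    zone_bac[z + 1] <- mean(c(mean(pred_left[d]), mean(!pred_left[!d])))
  }
  # branch zones see a single decision class, so the balanced accuracy is
  # evaluated per linearized position, pooling mirrored left/right zones
  lin_p <- matrix(NA_real_, nt, length(lps), dimnames = list(trial_ids, lps))
  for (j in seq_along(lps)) {
    v <- tz_p[, lin == lps[j], drop = FALSE]
    lin_p[, j] <- rowMeans(v, na.rm = TRUE)
  }
  lin_p[is.nan(lin_p)] <- NA_real_
  lin_bac <- rep(NA_real_, length(lps))
  names(lin_bac) <- lps
  for (j in seq_along(lps)) {
    p <- lin_p[, j]
    ok <- !is.na(p)
    if (sum(ok) < 4 || length(unique(decision[ok])) < 2) next
    pred_left <- p[ok] > 0.5
    d <- decision[ok]
    lin_bac[j] <- mean(c(mean(pred_left[d]), mean(!pred_left[!d])))
  }
  list(p_left = p_left, trial_zone_p = tz_p, trial_zone_logit = tz_logit,
       integrated_logit = integrated, zone_bac = zone_bac,
       lin_p = lin_p, lin_bac = lin_bac,
       trial_ids = trial_ids, decisions = decision, lambda = lambda)
}

#' Decoder-vs-behavior performance by zone
#'
#' The model analogue of session performance: per zone, the fraction of
#' trials on which the decoder's decision (mean P(Left) > 0.5) matches the
#' side designated correct by that trial's cue. Returned with the subject's
#' own p_se for comparison.
#'
#' @param decoder result of [fit_decision_decoder()]
#' @param trials trial table
#' @return list(zone_performance (39), p_se)
#' @export
decoder_behavior_performance <- function(decoder, trials) {
  use <- trials[match(decoder$trial_ids, trials$trial_id), , drop = FALSE]
  correct_side_left <- use$cue == "LC"
  perf <- rep(NA_real_, 39)
  for (z in 0:38) {
    p <- decoder$trial_zone_p[, z + 1]
    ok <- !is.na(p)
    if (sum(ok) < 4) next
    perf[z + 1] <- mean((p[ok] > 0.5) == correct_side_left[ok])
  }
  list(zone_performance = perf, p_se = mean(use$correct, na.rm = TRUE))
}
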