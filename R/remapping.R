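#' Kendall rank correlation over jointly unmasked entries
#'
#' Tie-corrected (tau-b) Kendall correlation between two zone maps,
#' restricted to entries unmasked in both (zone rates tie often at zero, so
#' the tie-corrected variant is used throughout). Fewer than 3 usable pairs,
#' or a constant vector (tau undefined), yield `NA`.
#'
#' @param x,y numeric vectors of equal length (NA = masked)
#' @return tau in [-1, 1], or NA
#' @export
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "kendall"))
}

#' Fisher z of a Kendall correlation
#'
#' tau is first converted to its Pearson equivalent r = sin(pi tau / 2),
#' then Fisher-transformed z = artanh(r); |r| is clipped to 1 - 1e-12 so
#' perfect correlations give a large finite z rather than overflowing.
#'
#' @param tau Kendall correlation(s) in [-1, 1]
#' @return Fisher z value(s)
#' @export
tau_to_z <- function(tau) {
  r <- sin(pi * tau / 2)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  atanh(r)
}

#' Difference of Fisher-transformed correlations
#'
#' z_delta = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3)), the standard comparison
#' of two Fisher-transformed correlations computed from n1 and n2 pairs.
#' Undefined (NA) when either n <= 3.
#'
#' @param z1,z2 Fisher z values
#' @param n1,n2 number of pairs entering each correlation
#' @return standardized difference(s)
#' @export
z_delta <- function(z1, n1, z2, n2) {
  out <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  out[n1 <= 3 | n2 <= 3] <- NA_real_
  out
}

#' Condition remapping score of one unit
#'
#' Per bootstrap b, the Kendall correlation between the two condition-level
#' mean maps (tau_test) and between the even/odd parity maps (tau_null) is
#' computed over jointly unmasked zones; both are taken to Fisher z and
#' compared with [z_delta()] using the per-bootstrap zone counts. The mean
#' over bootstraps is the remapping score zbar: negative values mean the
#' condition maps resemble each other less than two arbitrary halves of the
#' same trials do, i.e. the unit remaps with the condition.
#'
#' Test and null bootstraps are paired by index; the unpaired variant
#' (z_delta of the mean Fisher z's) is also reported.
#'
#' The parity-null maps are noise-matched to the test plan (see
#' `match_noise` in [balanced_resample()]): a null built from more trials,
#' or from larger trial pools, than the test maps would be systematically
#' less noisy, biasing the score negative even without any condition
#' dependence.
#'
#' @param rates a [trial_zone_rates()] result
#' @param trials trial table
#' @param plan_test [resample_plan()] for the condition of interest
#' @param plan_null [resample_plan()] for the parity null
#' @return object of class `remap_score`: list(zbar, z_delta (per
#'   bootstrap), tau_test, tau_null, n_test, n_null, n_boot_used,
#'   zbar_unpaired, excluded, reason, unit_id)
#' @export
remap_score <- function(rates, trials, plan_test, plan_null) {
  rs_test <- balanced_resample(trials, plan_test)
  rs_null <- if (rs_test$excluded) {
    balanced_resample(trials, plan_null)
  } else {
    balanced_resample(trials, plan_null, match_noise = rs_test)
  }
  if (rs_test$excluded || rs_null$excluded) {
    return(structure(list(zbar = NA_real_, excluded = TRUE,
                          reason = c(rs_test$reason, rs_null$reason),
                          unit_id = rates$unit_id),
                     class = "remap_score"))
  }
  maps_test <- condition_maps(rates, rs_test)
  maps_null <- condition_maps(rates, rs_null)
  .remap_from_maps(maps_test, maps_null, rates$unit_id)
}

.remap_from_maps <- function(maps_test, maps_null, unit_id) {
  nb <- min(dim(maps_test)[1], dim(maps_null)[1])
  tau_t <- tau_n <- n_t <- n_n <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    x1 <- maps_test[b, 1, ]; x2 <- maps_test[b, 2, ]
    y1 <- maps_null[b, 1, ]; y2 <- maps_null[b, 2, ]
    tau_t[b] <- kendall_tau(x1, x2)
    n_t[b] <- sum(!is.na(x1) & !is.na(x2))
    tau_n[b] <- kendall_tau(y1, y2)
    n_n[b] <- sum(!is.na(y1) & !is.na(y2))
  }
  zd <- z_delta(tau_to_z(tau_t), n_t, tau_to_z(tau_n), n_n)
  used <- is.finite(zd)
  zbar_unpaired <- z_delta(mean(tau_to_z(tau_t[used])), mean(n_t[used]),
                           mean(tau_to_z(tau_n[used])), mean(n_n[used]))
  structure(list(zbar = mean(zd[used]), z_delta = zd,
                 tau_test = tau_t, tau_null = tau_n,
                 n_test = n_t, n_null = n_n,
                 n_boot_used = sum(used),
                 zbar_unpaired = zbar_unpaired,
                 excluded = FALSE, reason = NA_character_,
                 unit_id = unit_id),
            class = "remap_score")
}

#' @export
print.remap_score <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<remap_score> %s: excluded (%s)\n", x$unit_id,
                paste(stats::na.omit(x$reason), collapse = "; ")))
  } else {
    cat(sprintf("<remap_score> %s: zbar = %.3f (%d bootstraps)\n",
                x$unit_id, x$zbar, x$n_boot_used))
  }
  invisible(x)
}

#' Mann-Whitney U and its Z transform
#'
#' U counts, over all cross-condition trial pairs, how often the first
#' sample exceeds the second (ties count 1/2); UZ is the tie-corrected
#' normal approximation (U - n1 n2 / 2) / sigma_U. Positive UZ means the
#' first sample tends to be larger. For small problems (n1 * n2 <= 64) U is
#' obtained by exhaustive pair counting; the rank-based computation is
#' identical and used for larger samples. If every value ties, UZ = 0 with
#' `tied = TRUE`.
#'
#' @param a,b numeric samples (first and second condition level)
#' @return list(U, UZ, n1, n2, tied)
#' @export
mann_whitney_uz <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("mann_whitney_uz: empty sample")
  if (n1 * n2 <= 64) {
    cmp <- outer(a, b, FUN = function(x, y) (x > y) + 0.5 * (x == y))
    U <- sum(cmp)
  } else {
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  }
  n <- n1 + n2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (s2 <= 0) {
    return(list(U = U, UZ = 0, n1 = n1, n2 = n2, tied = TRUE))
  }
  list(U = U, UZ = (U - n1 * n2 / 2) / sqrt(s2), n1 = n1, n2 = n2,
       tied = FALSE)
}

#' Segment-wise condition statistic UZ for one unit
#'
#' Per-trial segment firing rates (occupancy-time-weighted mean over the
#' segment's zones) are compared between the two condition levels with the
#' Mann-Whitney UZ statistic. The sign convention follows the first level
#' of the condition pair: for the cue condition levels are (RC, LC), so
#' positive UZ means higher rates on Right-Cue trials; for reward the
#' levels are (NRW, RW).
#'
#' @param rates a `trial_zone_rates`
#' @param trials trial table
#' @param condition "cue" or "reward"
#' @param segment "left", "stem" or "right" (the three-way maze partition)
#' @param zones a `zone_map`
#' @return list(unit_id, segment, direction, U, UZ, n1, n2, tied)
#' @export
uz_segment <- function(rates, trials, condition = c("cue", "reward"),
                       segment = c("left", "stem", "right"),
                       zones = treemaze_zones()) {
  condition <- match.arg(condition)
  segment <- match.arg(segment)
  zcols <- which(zones$zones$segment3 == segment)
  occ <- rates$occupancy[, zcols, drop = FALSE]
  num <- rates$counts[, zcols, drop = FALSE]
  seg_rate <- rowSums(num) / rowSums(occ)
  seg_rate[rowSums(occ) == 0] <- NA_real_
  tr <- rates$trials
  lev <- if (condition == "cue") {
    list(first = tr$cue == "RC", second = tr$cue == "LC")
  } else {
    list(first = !tr$rewarded, second = tr$rewarded)
  }
  a <- seg_rate[lev$first]
  b <- seg_rate[lev$second]
  if (all(is.na(a)) || all(is.na(b))) {
    stop("uz_segment: a condition level has no occupancy in the segment")
  }
  res <- mann_whitney_uz(a, b)
  c(list(unit_id = rates$unit_id, segment = segment,
         direction = rates$direction), res)
}

#' Population-level remapping score for a session
#'
#' Per bootstrap, the units' condition-level maps are concatenated into one
#' population vector per level (masks intersected across levels within each
#' unit), correlated, Fisher-transformed and compared against the
#' concatenated parity-null maps exactly as in [remap_score()], with n the
#' concatenated vector length.
#'
#' @param rates_list list of `trial_zone_rates`, one per unit (shared
#'   trials)
#' @param trials trial table
#' @param plan_test,plan_null resampling plans (draws are shared across
#'   units since they depend only on the trial table)
#' @return a `remap_score` for the population vector
#' @export
population_remap <- function(rates_list, trials, plan_test, plan_null) {
  stopifnot(length(rates_list) >= 1)
  rs_test <- balanced_resample(trials, plan_test)
  rs_null <- if (rs_test$excluded) {
    balanced_resample(trials, plan_null)
  } else {
    balanced_resample(trials, plan_null, match_noise = rs_test)
  }
  if (rs_test$excluded || rs_null$excluded) {
    return(structure(list(zbar = NA_real_, excluded = TRUE,
                          reason = c(rs_test$reason, rs_null$reason),
                          unit_id = "population"),
                     class = "remap_score"))
  }
  maps_t <- lapply(rates_list, condition_maps, resample = rs_test)
  maps_n <- lapply(rates_list, condition_maps, resample = rs_null)
  cat_maps <- function(maps) {
    nb <- dim(maps[[1]])[1]
    out <- array(NA_real_, c(nb, 2, 39 * length(maps)))
    for (u in seq_along(maps)) {
      cols <- (u - 1) * 39 + 1:39
      out[, , cols] <- maps[[u]][, 1:2, , drop = FALSE]
    }
    out
  }
  .remap_from_maps(cat_maps(maps_t), cat_maps(maps_n), "population")
}

#' Correlate remapping scores with session performance
#'
#' Kendall correlation between session performance p_se and remapping
#' scores, plus the slope of a linear mixed-effects model
#' p_se ~ score + (1 | subject) with a likelihood-ratio test against the
#' null model without the score term. With a single subject (random effect
#' inestimable) an ordinary least-squares fit is used with a warning.
#'
#' @param df data.frame with columns `score`, `p_se`, `subject`
#' @return list(tau, slope, slope_ci, chisq, p_value, n, method)
#' @export
behavior_correlation <- function(df) {
  stopifnot(all(c("score", "p_se", "subject") %in% names(df)))
  df <- df[is.finite(df$score) & is.finite(df$p_se), , drop = FALSE]
  if (nrow(df) < 5) stop("behavior_correlation: fewer than 5 pairs")
  tau <- suppressWarnings(stats::cor(df$p_se, df$score, method = "kendall"))
  if (length(unique(df$subject)) < 2) {
    warning("behavior_correlation: single subject; falling back to OLS")
    fit <- stats::lm(p_se ~ score, data = df)
    null <- stats::lm(p_se ~ 1, data = df)
    lrt <- stats::anova(null, fit)
    ci <- stats::confint(fit)["score", ]
    dev <- 2 * (stats::logLik(fit) - stats::logLik(null))
    return(list(tau = tau, slope = stats::coef(fit)[["score"]],
                slope_ci = unname(ci), chisq = as.numeric(dev),
                p_value = stats::pchisq(as.numeric(dev), 1,
                                        lower.tail = FALSE),
                n = nrow(df), method = "ols"))
  }
  fit <- lme4::lmer(p_se ~ score + (1 | subject), data = df, REML = FALSE)
  null <- lme4::lmer(p_se ~ 1 + (1 | subject), data = df, REML = FALSE)
  lrt <- stats::anova(null, fit)
  ci <- tryCatch(stats::confint(fit, parm = "score", method = "Wald"),
                 error = function(e) matrix(NA_real_, 1, 2))
  list(tau = tau, slope = unname(lme4::fixef(fit)["score"]),
       slope_ci = as.numeric(ci[1, ]),
       chisq = lrt$Chisq[2], p_value = lrt$`Pr(>Chisq)`[2],
       n = nrow(df), method = "lmem")
}
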