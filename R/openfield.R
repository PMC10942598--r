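#' Bin an open-field session
#'
#' Sample-level substrate of the open-field tuning metrics and encoding
#' models: per tracking sample, instantaneous firing rates (spike count per
#' sample / sampling step) for all units, binned speed, head direction and
#' position, and the immobility flag (speed < 2 cm/s).
#'
#' @param session a `session_data` (task "openfield")
#' @param pos_bin position bin size (cm)
#' @param speed_breaks speed bin edges (cm/s); values are clamped into the
#'   range before binning
#' @param hd_bin_deg head-direction bin width (degrees)
#' @param arena c(width, height) cm
#' @return list(t, rates (samples x units), speed, theta, speed_bin,
#'   hd_bin, pos_bin, immobile, dt, bins = list(...))
#' @export
of_binned <- function(session, pos_bin = 5,
                      speed_breaks = seq(2, 40, by = 2), hd_bin_deg = 10,
                      arena = c(130, 150)) {
  tk <- session$tracking
  dt <- stats::median(diff(tk$t))
  n <- nrow(tk)
  units <- names(session$spike_trains)
  rates <- matrix(0, n, length(units), dimnames = list(NULL, units))
  for (u in seq_along(units)) {
    st <- session$spike_trains[[units[u]]]
    if (!length(st)) next
    idx <- findInterval(st, tk$t)
    idx[idx == 0] <- 1L
    rates[, u] <- tabulate(idx, nbins = n) / dt
  }
  sp <- pmin(pmax(tk$speed, min(speed_breaks)), max(speed_breaks) - 1e-9)
  speed_bin <- findInterval(sp, speed_breaks)
  hd_edges <- seq(-pi, pi, by = hd_bin_deg * pi / 180)
  hd_bin <- findInterval(tk$theta, hd_edges, rightmost.closed = TRUE)
  px <- pmin(floor(tk$x / pos_bin), ceiling(arena[1] / pos_bin) - 1)
  py <- pmin(floor(tk$y / pos_bin), ceiling(arena[2] / pos_bin) - 1)
  nx <- ceiling(arena[1] / pos_bin)
  pos_idx <- pmax(px, 0) + nx * pmax(py, 0) + 1L
  list(t = tk$t, rates = rates, speed = tk$speed, theta = tk$theta,
       x = tk$x, y = tk$y,
       speed_bin = speed_bin, hd_bin = hd_bin, pos_bin = pos_idx,
       immobile = tk$speed < 2, dt = dt,
       bins = list(pos_bin = pos_bin, speed_breaks = speed_breaks,
                   hd_bin_deg = hd_bin_deg, arena = arena, nx = nx,
                   ny = ceiling(arena[2] / pos_bin)))
}

# separable Gaussian smoothing of a matrix; NAs treated as empty (handled
# by smoothing numerator and denominator maps separately)
.smooth2d <- function(M, sd_bins = 2) {
  if (sd_bins <= 0) return(M)
  half <- ceiling(3 * sd_bins)
  k <- stats::dnorm(-half:half, 0, sd_bins)
  k <- k / sum(k)
  M[is.na(M)] <- 0
  sm_rows <- function(A) {
    out <- matrix(0, nrow(A), ncol(A))
    for (i in seq_along(k)) {
      off <- i - half - 1
      src <- seq_len(nrow(A)) + off
      okk <- src >= 1 & src <= nrow(A)
      out[okk, ] <- out[okk, ] + k[i] * A[src[okk], , drop = FALSE]
    }
    out
  }
  t(sm_rows(t(sm_rows(M))))
}

#' Occupancy-normalized, smoothed firing-rate map
#'
#' @param ofb an [of_binned()] result
#' @param unit unit column (index or name)
#' @param sel optional logical sample selector
#' @param smooth_sd Gaussian smoothing sd in bins (0 = raw)
#' @return matrix ny x nx of rates (Hz), NA where unvisited
#' @export
of_rate_map <- function(ofb, unit, sel = NULL, smooth_sd = 2) {
  if (is.null(sel)) sel <- rep(TRUE, length(ofb$t))
  nx <- ofb$bins$nx; ny <- ofb$bins$ny
  occ <- matrix(0, ny, nx)
  spk <- matrix(0, ny, nx)
  idx <- ofb$pos_bin[sel]
  occ_tab <- tabulate(idx, nbins = nx * ny) * ofb$dt
  spk_tab <- rep(0, nx * ny)
  r <- ofb$rates[sel, unit]
  s <- tapply(r * ofb$dt, idx, sum)  # spike counts per bin
  spk_tab[as.integer(names(s))] <- s
  occ[] <- matrix(occ_tab, ny, nx, byrow = TRUE)
  spk[] <- matrix(spk_tab, ny, nx, byrow = TRUE)
  socc <- .smooth2d(occ, smooth_sd)
  sspk <- .smooth2d(spk, smooth_sd)
  out <- sspk / socc
  out[socc < 1e-9] <- NA_real_
  out
}

#' Open-field tuning metrics of one unit
#'
#' Speed score: Pearson correlation between speed-bin centers and the mean
#' firing rate per bin. Head-direction score: magnitude of the
#' rate-weighted circular resultant |sum(fr e^{i theta})| / sum(fr) over
#' mobile samples (in [0, 1]); the unnormalized per-sample variant
#' (division by N instead of sum fr) is reported alongside as
#' `hd_score_raw`. Position score: Pearson correlation between smoothed
#' rate maps from the first and second halves of the session. A silent
#' unit yields NAs.
#'
#' @param ofb an [of_binned()] result
#' @param unit unit column (index or name)
#' @return list(speed_score, hd_score, hd_score_raw, pref_hd, pos_score)
#' @export
of_tuning_metrics <- function(ofb, unit) {
  fr <- ofb$rates[, unit]
  if (sum(fr) == 0) {
    return(list(speed_score = NA_real_, hd_score = NA_real_,
                hd_score_raw = NA_real_, pref_hd = NA_real_,
                pos_score = NA_real_))
  }
  sb <- ofb$bins$speed_breaks
  centers <- sb[-length(sb)] + diff(sb) / 2
  mobile <- !ofb$immobile
  mu <- tapply(fr[mobile], ofb$speed_bin[mobile], mean)
  got <- as.integer(names(mu))
  speed_score <- if (length(mu) >= 3) {
    stats::cor(centers[got], as.numeric(mu))
  } else NA_real_
  w <- fr[mobile]
  th <- ofb$theta[mobile]
  R <- sum(w * exp(1i * th))
  hd_score <- Mod(R) / sum(w)
  hd_score_raw <- Mod(R) / length(w)
  pref_hd <- Arg(R)
  half <- ofb$t <= stats::median(ofb$t)
  m1 <- of_rate_map(ofb, unit, half)
  m2 <- of_rate_map(ofb, unit, !half)
  ok <- !is.na(m1) & !is.na(m2)
  pos_score <- if (sum(ok) >= 10) stats::cor(m1[ok], m2[ok]) else NA_real_
  list(speed_score = speed_score, hd_score = hd_score,
       hd_score_raw = hd_score_raw, pref_hd = pref_hd,
       pos_score = pos_score)
}

# blocked fold assignment: contiguous `block_s` blocks dealt cyclically to
# folds, so no block straddles a train/test boundary
.blocked_folds <- function(t, block_s, folds) {
  block <- floor((t - t[1]) / block_s)
  if (length(unique(block)) < folds) {
    stop("blocked CV: fewer blocks than folds")
  }
  (block %% folds) + 1L
}

#' Per-variable open-field encoding model, blocked cross-validation
#'
#' Linear regression of instantaneous firing rate on a binned behavioral
#' design: speed bins, head-direction bins (immobility excluded for the
#' head-direction model), or position bins projected onto the principal
#' components explaining 95% of the training-design variance. Cross
#' validation is blocked: the session is cut into contiguous 20 s blocks,
#' dealt cyclically to 5 folds. All units are fit jointly against a shared
#' design. Test performance is reported as R^2 and as the correlation
#' (`rp`) between the smoothed rate maps of the true and predicted test
#' rates.
#'
#' @param ofb an [of_binned()] result
#' @param variable "speed", "hd" or "position"
#' @param block_s block length (s)
#' @param folds number of folds
#' @param var_explained PCA variance target for the position design
#' @return object of class `of_encoder`: list(variable, r2, rp (folds x
#'   units), fold (per sample; NA = sample excluded for this variable),
#'   pred (samples x units cross-validated predictions; training
#'   predictions for the aggregate model are refit per fold), npc)
#' @export
fit_of_encoder <- function(ofb, variable = c("speed", "hd", "position"),
                           block_s = 20, folds = 5, var_explained = 0.95) {
  variable <- match.arg(variable)
  fold <- .blocked_folds(ofb$t, block_s, folds)
  keep <- if (variable == "hd") !ofb$immobile else rep(TRUE, length(ofb$t))
  idx <- switch(variable, speed = ofb$speed_bin, hd = ofb$hd_bin,
                position = ofb$pos_bin)
  nlev <- switch(variable,
                 speed = length(ofb$bins$speed_breaks) - 1,
                 hd = round(360 / ofb$bins$hd_bin_deg),
                 position = ofb$bins$nx * ofb$bins$ny)
  Y <- ofb$rates
  nu <- ncol(Y)
  r2 <- rp <- matrix(NA_real_, folds, nu, dimnames = list(NULL, colnames(Y)))
  pred_cv <- matrix(NA_real_, length(ofb$t), nu)
  pred_train <- vector("list", folds)
  npc <- rep(NA_integer_, folds)
  for (f in seq_len(folds)) {
    tr <- keep & fold != f
    te <- keep & fold == f
    occ_lev <- sort(unique(idx[tr]))
    hit <- match(idx, occ_lev)
    okk <- !is.na(hit)
    if (variable == "position") {
      # the one-hot position design is too wide to hold densely; keep it
      # sparse and only densify the PC scores
      X <- Matrix::sparseMatrix(i = which(okk), j = hit[okk], x = 1,
                                dims = c(length(ofb$t), length(occ_lev)))
      ntr <- sum(tr)
      mu <- Matrix::colSums(X[tr, , drop = FALSE]) / ntr
      # covariance of the centered training design without densifying it
      cv <- (as.matrix(Matrix::crossprod(X[tr, , drop = FALSE])) -
               ntr * tcrossprod(mu)) / (ntr - 1)
      eg <- eigen(cv, symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      k <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
      npc[f] <- k
      V <- eg$vectors[, seq_len(k), drop = FALSE]
      S <- as.matrix(X %*% V)
      S <- sweep(S, 2, as.numeric(crossprod(mu, V)))
      D <- cbind(1, S)
    } else {
      X <- matrix(0, length(ofb$t), length(occ_lev))
      X[cbind(which(okk), hit[okk])] <- 1
      D <- cbind(1, X)
    }
    B <- .wls_fit(D[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                  rep(1, sum(tr)))
    ptr <- D[tr, , drop = FALSE] %*% B
    pte <- D[te, , drop = FALSE] %*% B
    pred_train[[f]] <- list(rows = which(tr), pred = ptr)
    pred_cv[te, ] <- pte
    truth <- Y[te, , drop = FALSE]
    mu_y <- colMeans(truth)
    r2[f, ] <- 1 - colSums((truth - pte)^2) /
      colSums(sweep(truth, 2, mu_y)^2)
    # map correlation on the held-out samples
    sel_te <- which(te)
    for (u in seq_len(nu)) {
      m_true <- .of_map_from(ofb, Y[sel_te, u], sel_te)
      m_pred <- .of_map_from(ofb, pte[, u], sel_te)
      ok <- !is.na(m_true) & !is.na(m_pred)
      rp[f, u] <- if (sum(ok) >= 10 && stats::sd(m_pred[ok]) > 0) {
        stats::cor(m_true[ok], m_pred[ok])
      } else NA_real_
    }
  }
  structure(list(variable = variable, r2 = r2, rp = rp, fold = fold,
                 keep = keep, pred = pred_cv, pred_train = pred_train,
                 npc = npc, folds = folds),
            class = "of_encoder")
}

# rate map from explicit per-sample rate values at given sample rows
.of_map_from <- function(ofb, values, rows, smooth_sd = 2) {
  nx <- ofb$bins$nx; ny <- ofb$bins$ny
  idx <- ofb$pos_bin[rows]
  occ <- tabulate(idx, nbins = nx * ny)
  sums <- rep(0, nx * ny)
  s <- tapply(values, idx, sum)
  sums[as.integer(names(s))] <- s
  occ_m <- matrix(occ, ny, nx, byrow = TRUE)
  sum_m <- matrix(sums, ny, nx, byrow = TRUE)
  socc <- .smooth2d(occ_m, smooth_sd)
  ssum <- .smooth2d(sum_m, smooth_sd)
  out <- ssum / socc
  out[socc < 1e-9] <- NA_real_
  out
}

#' Aggregate open-field model from the three per-variable models
#'
#' Per fold and unit, regresses the training firing rate on the three
#' variable models' training-set predicted rates (3 features plus
#' intercept), then scores on the held-out fold using the test-set
#' predictions. The exported per-variable coefficients (beta_s, beta_h,
#' beta_P) are signed contributions: the regression slope times the
#' training sd of that model's predicted rate (Hz). Each single-variable
#' prediction carries the unit's mean rate, so raw slopes are dominated by
#' that shared component; a variable the unit does not code for produces a
#' near-flat prediction, and its contribution — unlike its slope — is near
#' zero. Contributions are averaged across folds for functional
#' clustering. Collinear prediction features fall back to a tiny ridge.
#'
#' @param fit_speed,fit_hd,fit_pos `of_encoder` results on shared folds
#' @param ofb the [of_binned()] used for the fits
#' @return list(coef (units x 3: beta_s, beta_h, beta_P), r2, rp (folds x
#'   units))
#' @export
fit_aggregate_model <- function(fit_speed, fit_hd, fit_pos, ofb) {
  folds <- fit_speed$folds
  Y <- ofb$rates
  nu <- ncol(Y)
  r2 <- rp <- matrix(NA_real_, folds, nu, dimnames = list(NULL, colnames(Y)))
  coefs <- array(NA_real_, c(folds, nu, 3))
  fits <- list(fit_speed, fit_hd, fit_pos)
  fold <- fit_speed$fold
  for (f in seq_len(folds)) {
    keep_all <- fit_speed$keep & fit_hd$keep & fit_pos$keep
    tr <- which(keep_all & fold != f)
    te <- which(keep_all & fold == f)
    Ftr <- matrix(NA_real_, length(tr), 3)
    Fte <- matrix(NA_real_, length(te), 3)
    for (u in seq_len(nu)) {
      for (m in 1:3) {
        pt <- fits[[m]]$pred_train[[f]]
        Ftr[, m] <- pt$pred[match(tr, pt$rows), u]
        Fte[, m] <- fits[[m]]$pred[te, u]
      }
      D <- cbind(1, Ftr)
      B <- .wls_fit(D, Y[tr, u, drop = FALSE], rep(1, length(tr)))
      coefs[f, u, ] <- B[-1, 1] * apply(Ftr, 2, stats::sd)
      pte <- cbind(1, Fte) %*% B
      truth <- Y[te, u]
      r2[f, u] <- 1 - sum((truth - pte)^2) / sum((truth - mean(truth))^2)
      m_true <- .of_map_from(ofb, truth, te)
      m_pred <- .of_map_from(ofb, as.numeric(pte), te)
      ok <- !is.na(m_true) & !is.na(m_pred)
      rp[f, u] <- if (sum(ok) >= 10 && stats::sd(m_pred[ok]) > 0) {
        stats::cor(m_true[ok], m_pred[ok])
      } else NA_real_
    }
  }
  coef_mean <- apply(coefs, c(2, 3), mean, na.rm = TRUE)
  dimnames(coef_mean) <- list(colnames(Y), c("beta_s", "beta_h", "beta_P"))
  list(coef = coef_mean, r2 = r2, rp = rp)
}

#' Cluster units into functional coding types
#'
#' Standardizes the aggregate-model coefficients (beta_s, beta_h, beta_P),
#' embeds them in 2-D (seeded PCA) and partitions the embedding with
#' k-means (k = 3, 50 restarts). With fewer than 3k units the raw
#' standardized coefficients are clustered directly.
#'
#' @param coef units x 3 coefficient matrix (rownames = unit ids)
#' @param k number of clusters
#' @param seed integer
#' @return list(cluster (named), embedding (units x 2), centers, summary
#'   (per-cluster mean coefficients))
#' @export
cluster_functional_types <- function(coef, k = 3, seed = 1) {
  stopifnot(ncol(coef) == 3)
  Z <- scale(coef)
  set.seed(seed)
  if (nrow(coef) >= 3 * k) {
    pc <- stats::prcomp(Z, rank. = 2)
    emb <- pc$x[, 1:2, drop = FALSE]
  } else {
    emb <- Z
  }
  km <- stats::kmeans(emb, centers = k, nstart = 50, iter.max = 100)
  # stable labeling: order clusters by decreasing beta_h mean
  mh <- tapply(coef[, "beta_h"], km$cluster, mean)
  relab <- match(km$cluster, as.integer(names(sort(mh, decreasing = TRUE))))
  cl <- stats::setNames(relab - 1L, rownames(coef))
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    colMeans(coef[cl == g, , drop = FALSE])
  }))
  rownames(summ) <- sort(unique(cl))
  list(cluster = cl, embedding = emb, centers = km$centers, summary = summ)
}

#' Join open-field clusters to Tree-Maze remapping and model scores
#'
#' For units matched across tasks, summarizes Tree-Maze remapping scores
#' and encoder comparison statistics per open-field functional cluster,
#' with seeded bootstrap confidence intervals on the cluster means.
#'
#' @param clusters named vector (unit -> cluster) from
#'   [cluster_functional_types()]
#' @param scores data.frame(unit_id, value): any per-unit Tree-Maze score
#'   (e.g. remap zbar or encoder-comparison UZ)
#' @param n_boot bootstrap draws for the CI
#' @param seed integer
#' @return data.frame(cluster, n, mean, ci_lo, ci_hi, n_unmatched attr)
#' @export
of_tm_transfer <- function(clusters, scores, n_boot = 500, seed = 1) {
  m <- match(scores$unit_id, names(clusters))
  unmatched <- sum(is.na(m))
  df <- data.frame(cluster = clusters[m[!is.na(m)]],
                   value = scores$value[!is.na(m)])
  set.seed(seed)
  out <- do.call(rbind, lapply(sort(unique(df$cluster)), function(g) {
    v <- df$value[df$cluster == g]
    v <- v[is.finite(v)]
    bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
    data.frame(cluster = g, n = length(v), mean = mean(v),
               ci_lo = stats::quantile(bs, 0.025),
               ci_hi = stats::quantile(bs, 0.975))
  }))
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- unmatched
  out
}
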