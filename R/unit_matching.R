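#' Embed pooled spike waveforms in two dimensions
#'
#' Seeded 2-D embedding of the pooled spikes-by-128-features waveform
#' matrix. The matching algorithm only requires that spikes of the same
#' unit stay locally contiguous in the embedding; the default is principal
#' components (deterministic, with a fixed sign convention), and a
#' nonlinear RBF kernel PCA alternative (`method = "kpca"`, via kernlab) is
#' provided to verify that the pipeline is embedding-agnostic.
#'
#' @param W spikes x 128 matrix
#' @param method "pca" or "kpca"
#' @param seed integer (kernel PCA subsampling)
#' @return spikes x 2 coordinate matrix
#' @export
embed_waveforms <- function(W, method = c("pca", "kpca"), seed = 1) {
  method <- match.arg(method)
  if (nrow(W) < 10) stop("embed_waveforms: too few spikes")
  if (method == "pca") {
    pc <- stats::prcomp(W, rank. = 2, center = TRUE, scale. = FALSE)
    X <- pc$x[, 1:2, drop = FALSE]
    # sign convention: largest-magnitude loading positive
    for (j in 1:2) {
      l <- pc$rotation[, j]
      if (l[which.max(abs(l))] < 0) X[, j] <- -X[, j]
    }
    return(X)
  }
  if (!requireNamespace("kernlab", quietly = TRUE)) {
    stop("embed_waveforms: method 'kpca' needs the kernlab package")
  }
  set.seed(seed)
  # kernel PCA on a subsample, projected to all spikes
  sub <- sample.int(nrow(W), min(2000, nrow(W)))
  kp <- kernlab::kpca(W[sub, ], kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * stats::median(
                        stats::dist(W[sample.int(nrow(W), min(200, nrow(W))), ])^2))),
                      features = 2)
  kernlab::predict(kp, W)[, 1:2, drop = FALSE]
}

#' Robust 2-D Gaussian summary of a unit's embedded waveform cloud
#'
#' Location and scatter via the Minimum Covariance Determinant (MCD)
#' estimator with 75% support, so stray spikes do not inflate the cluster.
#' The covariance is floored to positive definiteness (eigenvalues below
#' 1e-8 x trace are raised, with a warning).
#'
#' @param points n x 2 matrix (n >= 50)
#' @return list(mu, sigma, support_frac)
#' @export
fit_cluster_gaussian <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 50) stop("fit_cluster_gaussian: need >= 50 points")
  fit <- MASS::cov.rob(points, method = "mcd",
                       quantile.used = floor(0.75 * nrow(points)))
  sigma <- fit$cov
  eg <- eigen(sigma, symmetric = TRUE)
  floor_ev <- 1e-8 * sum(diag(sigma))
  if (any(eg$values < floor_ev)) {
    warning("fit_cluster_gaussian: covariance regularized")
    ev <- pmax(eg$values, floor_ev)
    sigma <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
  }
  list(mu = fit$center, sigma = sigma, support_frac = 0.75)
}

# 2-d Gaussian density at rows of x
.dmvn2 <- function(x, mu, sigma) {
  si <- solve(sigma)
  dx <- sweep(x, 2, mu)
  q <- rowSums((dx %*% si) * dx)
  exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

#' Misclassification-error distance between two waveform clouds
#'
#' E_kk is the mean of unit k's fitted Gaussian density over unit k's own
#' embedded spikes (a normalizer); E_kp the mean of that density over unit
#' p's spikes. The normalized error ne_kp = 1 - E_kp / E_kk and the
#' symmetric distance d_kp = (ne_kp + ne_pk) / 2, clipped to [0, 1]:
#' d = 0 for perfectly overlapping clouds, 1 for disjoint ones, 0.5 when
#' the clusters are equally likely.
#'
#' @param fk,fp Gaussian fits from [fit_cluster_gaussian()]
#' @param points_k,points_p the two units' embedded spike coordinates
#' @return list(d, ne_kp, ne_pk, E_kk, E_kp, E_pk, E_pp)
#' @export
misclassification_distance <- function(fk, fp, points_k, points_p) {
  E_kk <- mean(.dmvn2(points_k, fk$mu, fk$sigma))
  E_pp <- mean(.dmvn2(points_p, fp$mu, fp$sigma))
  if (E_kk < .Machine$double.xmin || E_pp < .Machine$double.xmin) {
    return(list(d = NA_real_, ne_kp = NA_real_, ne_pk = NA_real_,
                E_kk = E_kk, E_kp = NA_real_, E_pk = NA_real_, E_pp = E_pp))
  }
  E_kp <- mean(.dmvn2(points_p, fk$mu, fk$sigma))
  E_pk <- mean(.dmvn2(points_k, fp$mu, fp$sigma))
  ne_kp <- 1 - E_kp / E_kk
  ne_pk <- 1 - E_pk / E_pp
  d <- min(max((ne_kp + ne_pk) / 2, 0), 1)
  list(d = d, ne_kp = ne_kp, ne_pk = ne_pk,
       E_kk = E_kk, E_kp = E_kp, E_pk = E_pk, E_pp = E_pp)
}

#' Closed-form Hellinger and Kullback-Leibler divergences of two Gaussians
#'
#' Squared Hellinger distance
#' H2 = 1 - (|Sk|^(1/4) |Sp|^(1/4) / |(Sk+Sp)/2|^(1/2)) exp(-(1/8) dmu'
#' ((Sk+Sp)/2)^(-1) dmu), and D_KL(fk || fp) = (tr(Sp^-1 Sk) + dmu' Sp^-1
#' dmu - 2 + ln(|Sp|/|Sk|)) / 2 (the -2 is the dimension term for 2-D).
#'
#' @param fk,fp Gaussian fits
#' @return list(H2, KL)
#' @export
gaussian_divergences <- function(fk, fp) {
  Sk <- fk$sigma; Sp <- fp$sigma
  if (det(Sk) <= 0 || det(Sp) <= 0) {
    stop("gaussian_divergences: singular covariance")
  }
  Sm <- (Sk + Sp) / 2
  dmu <- fk$mu - fp$mu
  bc <- (det(Sk)^0.25 * det(Sp)^0.25 / sqrt(det(Sm))) *
    exp(-crossprod(dmu, solve(Sm, dmu)) / 8)
  H2 <- 1 - as.numeric(bc)
  spi <- solve(Sp)
  KL <- 0.5 * (sum(diag(spi %*% Sk)) +
                 as.numeric(crossprod(dmu, spi %*% dmu)) - 2 +
                 log(det(Sp) / det(Sk)))
  list(H2 = H2, KL = KL)
}

#' Match units across sessions from their waveform clouds
#'
#' Restricted to tetrodes recorded at the same depth across sessions (the
#' only regime where identity is plausible): all spikes of the candidate
#' units are pooled, embedded in 2-D, summarized as robust Gaussians, and
#' every unit pair gets the misclassification-error distance `d` plus the
#' Hellinger and KL comparators. Cross-session pairs with d <= `threshold`
#' are candidate matches; a greedy one-to-one assignment (ascending d, ties
#' by unit id) resolves conflicts. Match groups are built transitively
#' across more than two sessions.
#'
#' @param wsets list of per-session waveform sets, each
#'   list(W, index = data.frame(unit_id, tetrode, depth, row0, row1))
#'   (see [simulate_waveform_sets()])
#' @param threshold maximal d for a match
#' @param seed integer (embedding)
#' @param method embedding method, see [embed_waveforms()]
#' @param depth_tol depth tolerance (um; default exact equality)
#' @return list(pairs = data.frame(unit_a, unit_b, session_a, session_b,
#'   d, H2, KL, matched), assignment = matched subset after one-to-one
#'   resolution, n_candidates)
#' @export
match_units <- function(wsets, threshold = 0.5, seed = 1,
                        method = "pca", depth_tol = 0) {
  if (length(wsets) < 2) stop("match_units: need >= 2 sessions")
  units <- do.call(rbind, lapply(seq_along(wsets), function(s) {
    idx <- wsets[[s]]$index
    idx$session <- s
    idx
  }))
  pairs <- NULL
  # candidate tetrode groups: same tetrode id, depths within tolerance
  for (tet in unique(units$tetrode)) {
    sub <- units[units$tetrode == tet, , drop = FALSE]
    for (dep in unique(sub$depth)) {
      grp <- sub[abs(sub$depth - dep) <= depth_tol, , drop = FALSE]
      grp <- grp[!duplicated(grp$unit_id), , drop = FALSE]
      if (length(unique(grp$session)) < 2 || nrow(grp) < 2) next
      W <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
        wsets[[grp$session[i]]]$W[grp$row0[i]:grp$row1[i], , drop = FALSE]
      }))
      set.seed(seed)  # fixes the MCD subsampling as well as the embedding
      emb <- embed_waveforms(W, method = method, seed = seed)
      n_spk <- grp$row1 - grp$row0 + 1L
      stop_at <- cumsum(n_spk)
      start_at <- stop_at - n_spk + 1L
      fits <- lapply(seq_len(nrow(grp)), function(i) {
        fit_cluster_gaussian(emb[start_at[i]:stop_at[i], , drop = FALSE])
      })
      for (i in seq_len(nrow(grp) - 1)) {
        for (j in (i + 1):nrow(grp)) {
          pi_ <- emb[start_at[i]:stop_at[i], , drop = FALSE]
          pj <- emb[start_at[j]:stop_at[j], , drop = FALSE]
          md <- misclassification_distance(fits[[i]], fits[[j]], pi_, pj)
          dv <- gaussian_divergences(fits[[i]], fits[[j]])
          pairs <- rbind(pairs, data.frame(
            unit_a = grp$unit_id[i], unit_b = grp$unit_id[j],
            session_a = grp$session[i], session_b = grp$session[j],
            d = md$d, H2 = dv$H2, KL = dv$KL,
            stringsAsFactors = FALSE))
        }
      }
      # ensure duplicates within one embedding give d ~ 0: nothing to do,
      # handled by construction
    }
  }
  if (is.null(pairs)) {
    return(list(pairs = empty_pairs(), assignment = empty_pairs(),
                n_candidates = 0L))
  }
  cross <- pairs$session_a != pairs$session_b
  pairs$matched <- cross & !is.na(pairs$d) & pairs$d <= threshold
  cand <- pairs[pairs$matched, , drop = FALSE]
  cand <- cand[order(cand$d, cand$unit_a, cand$unit_b), , drop = FALSE]
  taken <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$unit_a[i] %in% taken) && !(cand$unit_b[i] %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, cand$unit_a[i], cand$unit_b[i])
    }
  }
  list(pairs = pairs, assignment = cand[keep, , drop = FALSE],
       n_candidates = sum(cross))
}

empty_pairs <- function() {
  data.frame(unit_a = character(0), unit_b = character(0),
             session_a = integer(0), session_b = integer(0),
             d = numeric(0), H2 = numeric(0), KL = numeric(0),
             matched = logical(0), stringsAsFactors = FALSE)
}
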