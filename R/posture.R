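#' Canonical gravity directions of the four labor postures
#'
#' Unit gravity vectors, in the chest-mounted sensor frame, that each merged
#' cluster is mapped to: supine (flat on the back, gravity along -z),
#' lateral (side-lying, gravity along +-x), hands-knees (prone-like, +z) and
#' high Fowler's (sitting upright at >= 45 degrees, gravity between -z and
#' -y). Remappable for other mounting conventions.
#'
#' @export
posture_gravity_targets <- list(
  supine = c(0, 0, -1),
  lateral_left = c(1, 0, 0),
  lateral_right = c(-1, 0, 0),
  hands_knees = c(0, 0, 1),
  high_fowlers = c(0, -sqrt(2) / 2, -sqrt(2) / 2)
)

# merge the two lateral targets into one reported posture
target_posture_name <- function(nm) sub("^lateral_.*$", "lateral", nm)

# ---- Gaussian mixture via EM (full covariances, k-means++ init) ----

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(X)))
  Z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(Z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_em <- function(X, k, tol = 1e-6, max_iter = 300, reg = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = kmeanspp_centers(X, k),
                                   iter.max = 50, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km))
    km <- suppressWarnings(stats::kmeans(X, centers = k, iter.max = 50,
                                         algorithm = "Lloyd"))
  mu <- km$centers
  w <- pmax(tabulate(km$cluster, k), 1) / n
  Sg <- lapply(seq_len(k), function(j) {
    Xi <- X[km$cluster == j, , drop = FALSE]
    if (nrow(Xi) < d + 1) return(stats::cov(X) + reg * diag(d))
    stats::cov(Xi) + reg * diag(d)
  })
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(k), function(j) log(w[j]) + log_dmvnorm(X, mu[j, ], Sg[[j]]),
                 numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    R <- exp(lp - lse)
    nk <- colSums(R)
    # revive collapsed components at a random data point
    dead <- which(nk < 1e-6)
    for (j in dead) {
      mu[j, ] <- X[sample.int(n, 1), ]
      Sg[[j]] <- stats::cov(X) + reg * diag(d)
      w[j] <- 1 / n
      nk[j] <- 1
    }
    w <- nk / sum(nk)
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(R[, j] * X) / nk[j]
      Xc <- X - matrix(mu[j, ], n, d, byrow = TRUE)
      Sg[[j]] <- crossprod(Xc * sqrt(R[, j])) / nk[j] + reg * diag(d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = Sg, loglik = ll_trace)
}

gmm_posterior <- function(model, X) {
  k <- length(model$weights); n <- nrow(X)
  lp <- vapply(seq_len(k), function(j)
    log(model$weights[j]) + log_dmvnorm(X, model$means[j, ], model$covs[[j]]),
    numeric(n))
  if (n == 1) lp <- matrix(lp, nrow = 1)
  m <- apply(lp, 1, max)
  lse <- m + log(rowSums(exp(lp - m)))
  list(post = exp(lp - lse), logdens = lse)
}

# windowed variance of the acceleration magnitude, used as the motion gate
motion_variance <- function(accel, window_s = 2) {
  mag <- sqrt(rowSums(accel$samples[, c("x", "y", "z"), drop = FALSE]^2))
  w <- max(2L, round(window_s * accel$rate_hz))
  mu <- moving_mean(mag, w)
  v <- moving_mean(mag^2, w) - mu^2
  v[!is.finite(v)] <- Inf
  pmax(v, 0)
}

#' Fit the Gaussian-mixture body-posture model
#'
#' Fits a full-covariance Gaussian mixture (8 components by default) on up
#' to `sample_budget` randomly sampled low-motion accelerometer triples
#' (k-means++ initialization, several restarts keeping the best
#' log-likelihood, EM tolerance 1e-6; deterministic given the seed).
#' Samples are first normalized to unit gravity, so classification is
#' invariant to uniform accelerometer gain. Each fitted cluster mean is then
#' merged onto the nearest canonical gravity direction, translating the
#' clusters into the four labor postures: supine, lateral, hands-knees and
#' high Fowler's.
#'
#' @param accel chest accelerometer [sensor_stream()] with `x`,`y`,`z`
#'   columns.
#' @param n_clusters mixture components (default 8).
#' @param sample_budget maximum points used for fitting (default 50000).
#' @param seed RNG seed; the fit is bit-reproducible given it.
#' @param restarts number of EM restarts (best log-likelihood kept).
#' @param motion_var_threshold motion gate: 2-s windowed variance of the
#'   acceleration magnitude must stay below this (g^2).
#' @param targets canonical gravity directions (see
#'   [posture_gravity_targets]).
#' @return an object of class `posture_model`.
#' @export
fit_posture_model <- function(accel, n_clusters = 8, sample_budget = 50000,
                              seed = 1L, restarts = 10,
                              motion_var_threshold = 0.02,
                              targets = posture_gravity_targets) {
  if (!is.matrix(accel$samples) || !all(c("x", "y", "z") %in% colnames(accel$samples)))
    stop("accel stream must have x, y and z columns")
  X <- accel$samples[, c("x", "y", "z")]
  g <- stats::median(sqrt(rowSums(X^2)))
  if (!is.finite(g) || g <= 0) stop("cannot normalize accelerometer gravity")
  X <- X / g
  low <- motion_variance(accel) / g^2 < motion_var_threshold
  X <- X[low & stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < n_clusters * 50)
    stop("insufficient low-motion data: need at least ", n_clusters * 50,
         " samples, have ", nrow(X))
  set.seed(seed)
  if (nrow(X) > sample_budget) X <- X[sample.int(nrow(X), sample_budget), , drop = FALSE]
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- gmm_em(X, n_clusters)
    if (is.null(best) || utils::tail(fit$loglik, 1) > utils::tail(best$loglik, 1))
      best <- fit
  }
  tgt <- do.call(rbind, targets)
  map <- apply(best$means, 1, function(mu) {
    u <- mu / sqrt(sum(mu^2))
    names(targets)[which.max(tgt %*% u / sqrt(rowSums(tgt^2)))]
  })
  posture <- target_posture_name(map)
  if (length(unique(posture)) == 1L)
    warning("all clusters merge to a single posture (", unique(posture),
            "): data span one orientation only")
  pd <- gmm_posterior(best, X)
  model <- list(n_clusters = n_clusters, weights = best$weights,
                means = best$means, covs = best$covs,
                cluster_to_posture = posture, loglik = best$loglik,
                gravity_scale = g, sample_budget = sample_budget,
                seed = seed, targets = targets,
                logdens_floor = stats::quantile(pd$logdens, 0.005, names = FALSE))
  class(model) <- "posture_model"
  model
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model> %d clusters -> %s; loglik %.1f (%d EM iters)\n",
              x$n_clusters, paste(unique(x$cluster_to_posture), collapse = "/"),
              utils::tail(x$loglik, 1), length(x$loglik)))
  invisible(x)
}

#' Classify body posture per accelerometer sample
#'
#' Maximum-posterior cluster assignment mapped through the cluster-to-posture
#' merge, with two guards: samples whose assigned-cluster posterior falls
#' below the confidence threshold, or whose mixture density falls below the
#' training floor (high-motion, off-manifold points), are labeled
#' `unknown`. A 5-s majority filter smooths the label stream.
#'
#' @param accel chest accelerometer [sensor_stream()] with `x`,`y`,`z`.
#' @param model a [fit_posture_model()] result.
#' @param conf_threshold minimum assigned-cluster posterior (default 0.6).
#' @param smooth_window_s majority-filter window (s).
#' @return data.frame of class `posture_series`: `time_ms`, `posture`,
#'   `confidence`.
#' @export
classify_posture <- function(accel, model, conf_threshold = 0.6,
                             smooth_window_s = 5) {
  stopifnot(inherits(model, "posture_model"))
  X <- accel$samples[, c("x", "y", "z")]
  g <- stats::median(sqrt(rowSums(X^2)))
  X <- X / g
  X[!is.finite(X)] <- 0
  pd <- gmm_posterior(model, X)
  # posture-level posterior: clusters merged to one posture pool their mass,
  # so a posture split across several components is not penalized
  postures <- unique(model$cluster_to_posture)
  pp <- vapply(postures, function(p)
    rowSums(pd$post[, model$cluster_to_posture == p, drop = FALSE]),
    numeric(nrow(X)))
  if (nrow(X) == 1) pp <- matrix(pp, nrow = 1, dimnames = list(NULL, postures))
  best <- max.col(pp)
  conf <- pp[cbind(seq_len(nrow(X)), best)]
  lab <- postures[best]
  lab[conf < conf_threshold | pd$logdens < model$logdens_floor] <- "unknown"
  w <- max(1L, round(smooth_window_s * accel$rate_hz))
  if (w %% 2 == 0) w <- w + 1L
  if (w >= 3 && length(lab) >= w) {
    lv <- sort(unique(lab))
    half <- (w - 1L) %/% 2L
    counts <- vapply(lv, function(l) {
      cs <- cumsum(c(0, lab == l))
      n <- length(lab)
      lo <- pmax(0L, seq_len(n) - half - 1L)
      hi <- pmin(n, seq_len(n) + half)
      cs[hi + 1L] - cs[lo + 1L]
    }, numeric(length(lab)))
    lab <- lv[max.col(counts, ties.method = "first")]
  }
  out <- data.frame(time_ms = stream_times_ms(accel), posture = lab,
                    confidence = conf, stringsAsFactors = FALSE)
  class(out) <- c("posture_series", "data.frame")
  out
}

#' Per-posture vital-sign summary
#'
#' Cross-tabulates derived vitals by concurrent body posture: each vital
#' sample is matched to the posture label nearest in time, and per
#' posture x vital the count, mean, SD and a histogram are reported.
#' Postures carrying less than `min_posture_s` of data are excluded.
#'
#' @param postures a `posture_series` from [classify_posture()].
#' @param vitals list of [vital_series()].
#' @param min_posture_s minimum dwell time to report a posture.
#' @return data.frame with columns `posture`, `vital`, `n`, `mean`, `sd`,
#'   plus a `histogram` list-column of `hist()` objects.
#' @export
posture_vital_summary <- function(postures, vitals, min_posture_s = 60) {
  stopifnot(inherits(postures, "posture_series"))
  if (inherits(vitals, "vital_series")) vitals <- list(vitals)
  dt <- stats::median(diff(postures$time_ms)) / 1000
  dwell <- table(postures$posture) * dt
  keep_post <- setdiff(names(dwell)[dwell >= min_posture_s], "unknown")
  rows <- list()
  for (v in vitals) {
    ok <- !is.na(v$values)
    if (!any(ok)) next
    idx <- findInterval(v$times_ms[ok], postures$time_ms)
    idx[idx < 1L] <- 1L
    lab <- postures$posture[idx]
    for (p in keep_post) {
      x <- v$values[ok][lab == p]
      if (!length(x)) next
      rows[[length(rows) + 1L]] <- data.frame(
        posture = p, vital = v$vital, n = length(x), mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else 0)
    }
  }
  if (!length(rows))
    return(data.frame(posture = character(0), vital = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0)))
  out <- do.call(rbind, rows)
  out$histogram <- I(lapply(seq_len(nrow(out)), function(i) {
    v <- vitals[[which(vapply(vitals, `[[`, character(1), "vital") == out$vital[i])[1]]]
    ok <- !is.na(v$values)
    idx <- findInterval(v$times_ms[ok], postures$time_ms)
    idx[idx < 1L] <- 1L
    graphics::hist(v$values[ok][postures$posture[idx] == out$posture[i]],
                   plot = FALSE)
  }))
  out
}
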