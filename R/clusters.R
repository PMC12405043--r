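# Ramp-phase EMG activity analysis: smoothed RMS envelopes, participant
# averages, shape-based distance, k-shape clustering and cluster-count
# selection by WCSS elbow + silhouette.

#' Smoothed RMS activity envelope of an EMG channel
#'
#' Z-normalizes the channel, full-wave rectifies it, smooths with a sliding
#' root-mean-square window (`rms_s` seconds, one-sample step, shrinking at
#' the edges), and clips to the first `clip_s` seconds of the trial, which
#' contain the ramp phase where activity-pattern differences appear.
#'
#' @param emg numeric raw EMG series (one channel, full trial).
#' @param fs sampling rate, Hz.
#' @param rms_s RMS window, seconds.
#' @param clip_s analyzed duration from trial start, seconds.
#' @return An object of class `activity_envelope` with nonnegative `samples`
#'   and `fs`.
#' @export
smoothed_power <- function(emg, fs, rms_s = 0.5, clip_s = 15) {
  if (length(emg) / fs < clip_s) {
    stop_invalid("trial shorter than ", clip_s, " s")
  }
  z <- (emg - mean(emg)) / stats::sd(emg)
  r2 <- abs(z)^2
  n <- length(r2)
  half <- round_half_up(rms_s * fs / 2)
  cs <- cumsum(c(0, r2))
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  env <- sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  keep <- seq_len(round_half_up(clip_s * fs))
  structure(list(samples = env[keep], fs = fs),
            class = "activity_envelope")
}

#' Pointwise average of activity envelopes
#'
#' Averages a participant's per-trial envelopes (typically the three repeats
#' of one force level) into one representative activation pattern.
#'
#' @param envelopes list of `activity_envelope` objects (or numeric vectors)
#'   of equal length.
#' @return an `activity_envelope` (numeric mean when inputs are bare
#'   vectors).
#' @export
participant_average <- function(envelopes) {
  xs <- lapply(envelopes, function(e) {
    if (inherits(e, "activity_envelope")) e$samples else e
  })
  if (length(unique(lengths(xs))) != 1L) {
    stop_invalid("envelope lengths differ")
  }
  m <- Reduce(`+`, xs) / length(xs)
  if (inherits(envelopes[[1]], "activity_envelope")) {
    structure(list(samples = m, fs = envelopes[[1]]$fs),
              class = "activity_envelope")
  } else {
    m
  }
}

#' Resample an activity envelope onto a coarser grid
#'
#' The 500-ms RMS smoothing leaves almost no content above a few Hz, so
#' envelopes are resampled (by linear interpolation) to a modest rate before
#' clustering; this keeps the shape-extraction eigenproblem small without
#' losing shape information.
#'
#' @param env an `activity_envelope` (or numeric vector with `fs` supplied).
#' @param to_fs target rate, Hz.
#' @param fs original rate when `env` is a bare vector.
#' @return numeric envelope sampled at `to_fs`.
#' @export
decimate_envelope <- function(env, to_fs = 20, fs = NULL) {
  if (inherits(env, "activity_envelope")) { fs <- env$fs; env <- env$samples }
  if (is.null(fs)) stop_invalid("`fs` required for bare numeric input")
  t_old <- (seq_along(env) - 1) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / to_fs)
  stats::approx(t_old, env, xout = t_new)$y
}

znorm <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop_invalid("zero-variance series")
  (x - mean(x)) / s
}

# Full normalized cross-correlation sequence of two z-normalized series
# (lag 0 at index length(y)).
ncc_sequence <- function(x, y) {
  cc <- stats::convolve(x, y, conj = TRUE, type = "open")
  cc / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

#' Shape-based distance between two series
#'
#' `1 - max` over all shifts of the coefficient-normalized cross-correlation
#' of the z-normalized series: 0 for identical shapes (up to scale, offset
#' and shift), 2 for perfectly anticorrelated ones.
#'
#' @param a,b numeric series of equal length.
#' @return distance in `[0, 2]`.
#' @export
sbd_distance <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("series lengths differ")
  max(0, 1 - max(ncc_sequence(znorm(a), znorm(b))))
}

# Align y to reference by the shift maximizing normalized cross-correlation;
# out-of-range samples are zero-padded.
sbd_align <- function(y, ref) {
  cc <- ncc_sequence(znorm(ref), znorm(y))
  shift <- which.max(cc) - length(y)
  n <- length(y)
  out <- numeric(n)
  if (shift >= 0) {
    out[(1 + shift):n] <- y[1:(n - shift)]
  } else {
    out[1:(n + shift)] <- y[(1 - shift):n]
  }
  out
}

# k-shape centroid (shape extraction): members are aligned to the current
# centroid, and the new centroid is the leading eigenvector of the centered
# Gram matrix, z-normalized, with its sign chosen to correlate positively
# with the members. Degenerate (flat) members or centroids fall back to the
# first member's shape.
shape_extract <- function(X, centroid) {
  if (nrow(X) == 1L) return(znorm(X[1, ]))
  has_ref <- !is.null(centroid) && stats::sd(centroid) > 0
  A <- t(apply(X, 1, function(row) {
    row <- znorm(row)
    if (has_ref) sbd_align(row, centroid) else row
  }))
  A <- A[apply(A, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(A) == 0L) return(znorm(X[1, ]))
  if (nrow(A) == 1L) return(znorm(A[1, ]))
  m <- ncol(A)
  S <- crossprod(A)
  Q <- diag(m) - matrix(1 / m, m, m)
  M <- Q %*% S %*% Q
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (stats::sd(v) == 0) return(znorm(A[1, ]))
  if (sum(A %*% v) < 0) v <- -v
  znorm(v)
}

#' k-shape clustering of activity envelopes
#'
#' Iterates assignment by minimum shape-based distance and centroid update
#' by shape extraction, from a seeded random initial assignment, until the
#' assignments stabilize or `max_iter` is reached. Iterations that would
#' increase the objective (the sum of within-cluster shape-based distances)
#' are rejected, so the objective is non-increasing.
#'
#' @param envelopes numeric matrix (rows = participants) or list of equal-
#'   length series.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed; the model is deterministic per seed.
#' @param max_iter iteration cap.
#' @return An object of class `cluster_model`: `k`, `assignments`,
#'   z-normalized `centroids` (k x m matrix), `objective` and `seed`.
#' @export
kshape <- function(envelopes, k, seed = 1L, max_iter = 100) {
  X <- if (is.matrix(envelopes)) envelopes else do.call(rbind, lapply(
    envelopes, function(e) if (inherits(e, "activity_envelope")) e$samples else e))
  n <- nrow(X)
  if (k < 1 || k > n) stop_invalid("`k` must be between 1 and n")
  with_seed(seed, {
    lab <- if (k == n) seq_len(n) else {
      l <- sample(rep_len(seq_len(k), n))
      l
    }
    cent <- matrix(0, k, ncol(X))
    for (j in seq_len(k)) cent[j, ] <- shape_extract(X[lab == j, , drop = FALSE], NULL)
    obj <- sum(vapply(seq_len(n), function(i) sbd_distance(X[i, ], cent[lab[i], ]),
                      numeric(1)))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      D <- vapply(seq_len(k), function(j) {
        vapply(seq_len(n), function(i) sbd_distance(X[i, ], cent[j, ]), numeric(1))
      }, numeric(n))
      D <- matrix(D, nrow = n)
      new_lab <- max.col(-D, ties.method = "first")
      # re-seed empty clusters with the worst-fitting member
      for (j in seq_len(k)) {
        if (!any(new_lab == j)) {
          worst <- which.max(D[cbind(seq_len(n), new_lab)])
          new_lab[worst] <- j
        }
      }
      new_cent <- cent
      for (j in seq_len(k)) {
        new_cent[j, ] <- shape_extract(X[new_lab == j, , drop = FALSE], cent[j, ])
      }
      new_obj <- sum(vapply(seq_len(n), function(i) {
        sbd_distance(X[i, ], new_cent[new_lab[i], ])
      }, numeric(1)))
      if (new_obj > obj + 1e-12) break      # reject non-improving move
      converged <- all(new_lab == lab) && abs(new_obj - obj) < 1e-12
      lab <- new_lab; cent <- new_cent; obj <- new_obj
      if (converged || iter >= max_iter) break
    }
    nm <- rownames(X)
    structure(list(k = k,
                   assignments = stats::setNames(lab, nm),
                   centroids = cent, objective = obj,
                   iterations = iter, seed = seed),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-shape model: k = %d, sizes %s, objective %.4f (%d iterations)\n",
              x$k, paste(tabulate(x$assignments, x$k), collapse = "/"),
              x$objective, x$iterations))
  invisible(x)
}

# Within-cluster sum of squared shape-based distances to the centroids.
kshape_wcss <- function(model, X) {
  sum(vapply(seq_len(nrow(X)), function(i) {
    sbd_distance(X[i, ], model$centroids[model$assignments[i], ])^2
  }, numeric(1)))
}

# Pairwise SBD distance matrix as a `dist` object.
sbd_dist_matrix <- function(X) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sbd_distance(X[i, ], X[j, ])
    }
  }
  stats::as.dist(d)
}

#' Cluster-count diagnostics: WCSS elbow and silhouette selection
#'
#' Computes the within-cluster sum of squares (WCSS, on the shape-based
#' distance) for k = 1..`k_max` for elbow inspection, and average silhouette
#' widths for k = 2..`k_max`; the k with the largest silhouette is selected.
#' Each k is fitted from `n_init` seeded restarts, keeping the best
#' objective. A maximum silhouette below `support_min` marks the data as not
#' supporting clustering.
#'
#' @param envelopes matrix or list of equal-length series, `n >= 6`.
#' @param seed integer seed.
#' @param k_max largest cluster count considered.
#' @param n_init random restarts per k.
#' @param support_min silhouette level below which clustering is flagged
#'   unsupported.
#' @return An object of class `cluster_diagnostics`: `wcss` (k = 1..k_max),
#'   `silhouette` (k = 2..k_max), `chosen_k`, `supported`, and the fitted
#'   `models`.
#' @export
choose_k <- function(envelopes, seed = 1L, k_max = 5, n_init = 8,
                     support_min = 0.25) {
  X <- if (is.matrix(envelopes)) envelopes else do.call(rbind, lapply(
    envelopes, function(e) if (inherits(e, "activity_envelope")) e$samples else e))
  n <- nrow(X)
  if (n < 6L) stop_invalid("need at least 6 series")
  k_max <- min(k_max, n)
  best <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fits <- lapply(seq_len(n_init), function(r) {
      kshape(X, k, seed = derive_seed(seed, k, r))
    })
    best[[k]] <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  }
  wcss <- vapply(best, function(m) kshape_wcss(m, X), numeric(1))
  dmat <- sbd_dist_matrix(X)
  sil <- vapply(2:k_max, function(k) {
    mean(cluster::silhouette(best[[k]]$assignments, dmat)[, "sil_width"])
  }, numeric(1))
  names(sil) <- 2:k_max
  chosen <- as.integer(names(sil)[which.max(sil)])
  structure(list(wcss = stats::setNames(wcss, seq_len(k_max)),
                 silhouette = sil, chosen_k = chosen,
                 supported = max(sil) >= support_min,
                 models = best, seed = seed),
            class = "cluster_diagnostics")
}

#' Plot a k-shape clustering of activity envelopes
#'
#' One panel per cluster: member envelopes as thin lines, the (rescaled)
#' centroid as a bold line, and optionally the target force profile overlaid
#' as a dashed line, rescaled to the panel.
#'
#' @param model a [kshape()] result.
#' @param envelopes the matrix (rows = participants) the model was fitted to.
#' @param target optional numeric target/force profile to overlay.
#' @param fs sampling rate of the envelope rows, Hz (for the time axis).
#' @export
plot_clusters <- function(model, envelopes, target = NULL, fs = 1) {
  X <- if (is.matrix(envelopes)) envelopes else do.call(rbind, envelopes)
  old <- graphics::par(mfrow = c(1, model$k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tt <- (seq_len(ncol(X)) - 1) / fs
  rescale <- function(v, lo, hi) {
    lo + (hi - lo) * (v - min(v)) / max(1e-12, diff(range(v)))
  }
  for (j in seq_len(model$k)) {
    members <- X[model$assignments == j, , drop = FALSE]
    ylim <- range(members)
    graphics::matplot(tt, t(members), type = "l", lty = 1,
                      col = grDevices::adjustcolor("steelblue", 0.5),
                      xlab = "time (s)", ylab = "envelope (a.u.)",
                      main = sprintf("cluster %d (n = %d)", j,
                                     nrow(members)))
    graphics::lines(tt, rescale(model$centroids[j, ], ylim[1], ylim[2]),
                    lwd = 3)
    if (!is.null(target)) {
      graphics::lines(tt, rescale(target, ylim[1], ylim[2]), lty = 2,
                      col = "grey40")
    }
  }
  invisible(NULL)
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat("Cluster-count diagnostics\n")
  cat("  WCSS:", paste(sprintf("k=%s %.3f", names(x$wcss), x$wcss),
                       collapse = ", "), "\n")
  cat("  silhouette:", paste(sprintf("k=%s %.3f", names(x$silhouette),
                                     x$silhouette), collapse = ", "), "\n")
  cat(sprintf("  chosen k = %d (%s)\n", x$chosen_k,
              if (x$supported) "clustering supported"
              else "clustering not supported"))
  invisible(x)
}
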