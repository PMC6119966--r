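#' One subject's component time-courses with motion bookkeeping
#'
#' @param values Numeric timepoints x r matrix of component time-courses.
#' @param fd Optional framewise-displacement series (length = timepoints,
#'   non-negative).
#' @param motion Optional timepoints x 24 motion-regressor matrix (6
#'   rigid-body estimates, their derivatives and the squares of both).
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(values, fd = NULL, motion = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("time-course values must be finite")
  if (!is.null(fd)) {
    stopifnot(length(fd) == nrow(values))
    if (any(fd < 0)) stop("framewise displacement must be non-negative")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(values))
      stop("motion table length mismatch")
  }
  structure(list(values = values, fd = fd, motion = motion),
            class = "timecourse")
}

#' Detect motion spikes in a framewise-displacement series
#'
#' Flags timepoints whose FD strictly exceeds `mean(fd) + 2.5 * sd(fd)`.
#' A constant series yields no spikes.
#'
#' @param fd Numeric FD series, length >= 3.
#' @return Integer vector of spike indices (possibly empty).
#' @export
detect_spikes <- function(fd) {
  stopifnot(length(fd) >= 3L)
  which(fd > mean(fd) + 2.5 * stats::sd(fd))
}

#' Interpolate spike timepoints with cubic splines
#'
#' Replaces each flagged timepoint, per component, by the value of a cubic
#' spline fitted through the good (non-spike) timepoints; good points are
#' left untouched.
#'
#' @param tc A [timecourse()] or plain timepoints x r matrix.
#' @param spikes Integer indices of spike timepoints.
#' @return Same type as the input, with spike rows interpolated.
#' @export
despike <- function(tc, spikes) {
  vals <- if (inherits(tc, "timecourse")) tc$values else as.matrix(tc)
  spikes <- sort(unique(as.integer(spikes)))
  if (length(spikes) == 0L) return(tc)
  good <- setdiff(seq_len(nrow(vals)), spikes)
  if (length(good) < 4L)
    stop("too few good points for cubic spline interpolation")
  for (cc in seq_len(ncol(vals))) {
    f <- stats::splinefun(good, vals[good, cc], method = "fmm")
    vals[spikes, cc] <- f(spikes)
  }
  if (inherits(tc, "timecourse")) { tc$values <- vals; tc } else vals
}

#' Post-process a subject time-course for dynamic connectivity
#'
#' Applies the standard cleaning sequence: drop the first `drop_initial`
#' timepoints, project the motion regressors (with an intercept) out of
#' every component by least squares, then spline-interpolate motion spikes
#' flagged by [detect_spikes()] on the FD series.
#'
#' @param tc A [timecourse()] carrying `motion` and (optionally) `fd`.
#' @param drop_initial Leading timepoints to discard (default 2).
#' @return A cleaned [timecourse()] (trimmed values, fd and motion).
#' @export
clean_timecourse <- function(tc, drop_initial = 2L) {
  stopifnot(inherits(tc, "timecourse"))
  T0 <- nrow(tc$values)
  if (T0 <= drop_initial + 24L)
    stop("time-course too short to clean")
  keep <- (drop_initial + 1L):T0
  vals <- tc$values[keep, , drop = FALSE]
  fd <- if (!is.null(tc$fd)) tc$fd[keep]
  mot <- if (!is.null(tc$motion)) tc$motion[keep, , drop = FALSE]
  if (!is.null(mot)) {
    X <- cbind(1, mot)
    vals <- stats::lm.fit(X, vals)$residuals
  }
  out <- timecourse(vals, fd = fd, motion = mot)
  if (!is.null(fd)) {
    spikes <- detect_spikes(fd)
    if (length(spikes)) out <- despike(out, spikes)
  }
  out
}

#' Sliding-window covariance features
#'
#' Slides a rectangular (boxcar) window of length `w` with stride 1 over the
#' time-course, producing `T - w` windows; each window yields the r x r
#' sample covariance of its `w` timepoints, vectorized as the strict upper
#' triangle in row-wise order (r(r-1)/2 features per window).
#'
#' @param tc A [timecourse()] or timepoints x r matrix.
#' @param w Window length (timepoints must exceed it).
#' @return Object of class `windowed_fnc` with `windows` (list of r x r
#'   symmetric matrices), `vectorized` ((T-w) x r(r-1)/2 matrix) and `w`.
#' @export
sliding_windows <- function(tc, w) {
  vals <- if (inherits(tc, "timecourse")) tc$values else as.matrix(tc)
  T_len <- nrow(vals); r <- ncol(vals)
  if (T_len <= w) stop("time-course length must exceed the window length")
  nwin <- T_len - w
  ut <- lower.tri(matrix(0, r, r))   # applied to t(cov): row-wise upper triangle
  windows <- vector("list", nwin)
  vectorized <- matrix(0, nwin, r * (r - 1) / 2)
  for (i in seq_len(nwin)) {
    C <- stats::cov(vals[i:(i + w - 1L), , drop = FALSE])
    windows[[i]] <- C
    vectorized[i, ] <- t(C)[ut]
  }
  structure(list(windows = windows, vectorized = vectorized, w = w, r = r),
            class = "windowed_fnc")
}

#' Select exemplar windows of maximal connectivity variability
#'
#' Computes, per window, the variance of the dynamic connectivity values
#' across all component pairs, and returns the windows at strict interior
#' local maxima of that variance series. When no interior local maximum
#' exists (monotone or constant series), falls back to the single
#' global-maximum window.
#'
#' @param fnc A `windowed_fnc` from [sliding_windows()] (>= 3 windows).
#' @return Integer vector of exemplar window indices.
#' @export
select_exemplars <- function(fnc) {
  stopifnot(inherits(fnc, "windowed_fnc"))
  v <- apply(fnc$vectorized, 1L, stats::var)
  n <- length(v)
  if (n < 3L) stop("need at least 3 windows to select exemplars")
  interior <- 2:(n - 1L)
  hits <- interior[v[interior] > v[interior - 1L] & v[interior] > v[interior + 1L]]
  if (length(hits) == 0L) hits <- which.max(v)
  hits
}

#' Correlation distance between connectivity feature vectors
#'
#' `1 - cor(a, b)`, in [0, 2]; 0 for identical patterns, 2 for exactly
#' opposite ones.
#'
#' @param a,b Non-constant numeric feature vectors.
#' @return The correlation distance.
#' @export
correlation_distance <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation distance undefined for a constant vector")
  1 - stats::cor(a, b)
}

# rows x centroids distance matrix under the chosen metric
dist_to_centroids <- function(X, C, distance) {
  if (distance == "correlation") {
    if (any(apply(X, 1L, stats::sd) == 0) || any(apply(C, 1L, stats::sd) == 0))
      stop("correlation distance undefined for a constant vector")
    1 - stats::cor(t(X), t(C))
  } else {
    xx <- rowSums(X^2)
    cc <- rowSums(C^2)
    outer(xx, cc, `+`) - 2 * tcrossprod(X, C)
  }
}

#' Decentralized K-Means by weighted centroid averaging
#'
#' Each iteration: the aggregator broadcasts the current centroids; every
#' site assigns its rows to the nearest centroid under the chosen distance
#' and returns its per-centroid local means and counts; the aggregator merges
#' them by count-weighted averaging and rebroadcasts. The run stops when the
#' assignments are unchanged for a full round (or after `max_iter`
#' iterations). With a single site this reduces exactly to Lloyd's
#' algorithm. A cluster that ends a round empty is reseeded from the
#' globally farthest point (largest distance to its assigned centroid),
#' costing one logged extra upload.
#'
#' @param sites List of per-site feature matrices (windows x features).
#' @param k Number of clusters (<= total rows).
#' @param init k x features matrix of initial centroids.
#' @param distance "correlation" (default, the connectivity-state metric) or
#'   "euclidean".
#' @param max_iter Iteration cap.
#' @param log Optional [message_log()]; per iteration logs the centroid
#'   broadcast to each site and each site's centroid upload (k x features
#'   real scalars each way; integer counts ride along untallied).
#' @param round0 Starting round index for logging.
#' @return Object of class `cluster_model` with `centroids`, `assignments`
#'   (per-site integer vectors), `counts`, `iterations`, `distance` and
#'   `converged`.
#' @export
dkmeans <- function(sites, k, init, distance = c("correlation", "euclidean"),
                    max_iter = 1000L, log = NULL, round0 = 0L) {
  distance <- match.arg(distance)
  sites <- lapply(sites, as.matrix)
  stopifnot(all(vapply(sites, nrow, 0L) >= 1L))
  total <- sum(vapply(sites, nrow, 0L))
  if (k > total) stop("k exceeds the total number of rows")
  C <- as.matrix(init)
  stopifnot(nrow(C) == k)
  Fdim <- ncol(C)
  ids <- names(sites)
  if (is.null(ids)) ids <- paste0("site", seq_along(sites))
  prev <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rnd <- round0 + iter
    sums <- matrix(0, k, Fdim)
    counts <- integer(k)
    assignments <- vector("list", length(sites))
    far_dist <- -Inf; far_point <- NULL
    for (j in seq_along(sites)) {
      if (!is.null(log)) log_message(log, rnd, "AGG", ids[j], k * Fdim)
      D <- dist_to_centroids(sites[[j]], C, distance)
      a <- max.col(-D, ties.method = "first")
      assignments[[j]] <- a
      for (cc in seq_len(k)) {
        rows <- which(a == cc)
        counts[cc] <- counts[cc] + length(rows)
        if (length(rows))
          sums[cc, ] <- sums[cc, ] + colSums(sites[[j]][rows, , drop = FALSE])
      }
      dj <- D[cbind(seq_len(nrow(D)), a)]
      if (max(dj) > far_dist) {
        far_dist <- max(dj)
        far_point <- sites[[j]][which.max(dj), ]
      }
      if (!is.null(log)) log_message(log, rnd, ids[j], "AGG", k * Fdim)
    }
    newC <- C
    for (cc in seq_len(k)) {
      if (counts[cc] > 0L) newC[cc, ] <- sums[cc, ] / counts[cc]
      else {
        newC[cc, ] <- far_point
        if (!is.null(log)) log_message(log, rnd, ids[1L], "AGG", Fdim)
      }
    }
    flat <- unlist(assignments)
    if (!is.null(prev) && identical(flat, prev)) { converged <- TRUE; break }
    prev <- flat
    C <- newC
  }
  structure(list(centroids = C, k = k, assignments = assignments,
                 counts = counts, distance = distance,
                 iterations = iter, converged = converged),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k=%d, %s distance, %d iterations%s, counts: %s>\n",
              x$k, x$distance, x$iterations,
              if (x$converged) "" else " (NOT converged)",
              paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Settings for the decentralized dynamic-connectivity pipeline
#'
#' Full-scale defaults follow the standard analysis: window length 22,
#' k = 5 states, 200 random initializations for the exemplar stage.
#'
#' @param w Sliding-window length in timepoints.
#' @param k Number of connectivity states.
#' @param n_init Random initializations for the exemplar clustering stage.
#' @param seed Master seed; run index i uses the i-th child seed drawn from
#'   it.
#' @param max_iter Iteration cap per K-Means run.
#' @param drop_initial Leading timepoints to discard during cleaning.
#' @param clean Apply [clean_timecourse()] to every subject first (TRUE) or
#'   take the inputs as already cleaned (FALSE).
#' @return An object of class `ddfnc_config`.
#' @export
ddfnc_config <- function(w = 22L, k = 5L, n_init = 200L, seed = 1L,
                         max_iter = 1000L, drop_initial = 2L, clean = TRUE) {
  structure(list(w = as.integer(w), k = as.integer(k),
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 max_iter = as.integer(max_iter),
                 drop_initial = as.integer(drop_initial), clean = clean),
            class = "ddfnc_config")
}

#' Decentralized dynamic functional network connectivity
#'
#' Runs the two-stage decentralized clustering pipeline over multi-site
#' subject time-courses: optional cleaning per subject, sliding-window
#' covariance features, per-subject exemplar selection (windows of locally
#' maximal connectivity variance), `n_init` seeded [dkmeans()] runs on the
#' exemplars with centroids drawn uniformly at random from the exemplar
#' windows, selection of the run with the highest mean silhouette (computed
#' on the exemplars with the same correlation distance), and a final
#' [dkmeans()] over all windows initialized from the winning centroids.
#'
#' @param sites List (one element per site) of lists of [timecourse()]
#'   objects.
#' @param cfg A [ddfnc_config()].
#' @param log Optional [message_log()].
#' @return List of class `ddfnc_result` with the final `model`
#'   (cluster_model), `labels` (per site, per subject, per window state
#'   assignments), `exemplar_model`, `silhouette` of the winning init,
#'   `exemplars` (per site/subject indices) and `log`.
#' @export
run_ddfnc <- function(sites, cfg = ddfnc_config(), log = NULL) {
  stopifnot(inherits(cfg, "ddfnc_config"), length(sites) >= 1L)
  ids <- names(sites)
  if (is.null(ids)) { ids <- paste0("site", seq_along(sites)); names(sites) <- ids }
  cleaned <- lapply(sites, function(subjects)
    lapply(subjects, function(tc)
      if (cfg$clean) clean_timecourse(tc, cfg$drop_initial) else tc))
  fncs <- lapply(cleaned, function(subjects)
    lapply(subjects, sliding_windows, w = cfg$w))
  exemplar_idx <- lapply(fncs, function(subjects)
    lapply(subjects, select_exemplars))
  exemplar_feats <- lapply(seq_along(fncs), function(j)
    do.call(rbind, lapply(seq_along(fncs[[j]]), function(i)
      fncs[[j]][[i]]$vectorized[exemplar_idx[[j]][[i]], , drop = FALSE])))
  names(exemplar_feats) <- ids
  all_feats <- lapply(fncs, function(subjects)
    do.call(rbind, lapply(subjects, `[[`, "vectorized")))
  E <- do.call(rbind, exemplar_feats)
  if (nrow(E) < cfg$k) stop("fewer exemplar windows than clusters")

  set.seed(cfg$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_init)
  Edist <- 1 - stats::cor(t(E))
  best <- NULL; best_sil <- -Inf; best_run <- NA_integer_
  for (i in seq_len(cfg$n_init)) {
    set.seed(child_seeds[i])
    init <- E[sample.int(nrow(E), cfg$k), , drop = FALSE]
    fit <- dkmeans(exemplar_feats, cfg$k, init, distance = "correlation",
                   max_iter = cfg$max_iter)
    labs <- unlist(fit$assignments)
    sil <- if (length(unique(labs)) < 2L) -Inf else
      mean(cluster::silhouette(labs, dmatrix = Edist)[, "sil_width"])
    if (is.null(best) || sil > best_sil) {
      best_sil <- sil; best <- fit; best_run <- i
    }
  }
  # exemplar-stage traffic is logged once, for the winning run
  if (!is.null(log)) {
    set.seed(child_seeds[best_run])
    init <- E[sample.int(nrow(E), cfg$k), , drop = FALSE]
    best <- dkmeans(exemplar_feats, cfg$k, init, distance = "correlation",
                    max_iter = cfg$max_iter, log = log)
  }
  round0 <- if (!is.null(log)) best$iterations else 0L
  final <- dkmeans(all_feats, cfg$k, best$centroids, distance = "correlation",
                   max_iter = cfg$max_iter, log = log, round0 = round0)
  # split flat per-site assignments back into per-subject label sequences
  labels <- lapply(seq_along(fncs), function(j) {
    lens <- vapply(fncs[[j]], function(f) nrow(f$vectorized), 0L)
    split(final$assignments[[j]], rep(seq_along(lens), lens))
  })
  names(labels) <- ids
  structure(list(model = final, labels = labels, exemplar_model = best,
                 silhouette = best_sil, best_run = best_run,
                 exemplars = exemplar_idx, log = log),
            class = "ddfnc_result")
}

#' @export
print.ddfnc_result <- function(x, ...) {
  cat(sprintf("<ddfnc_result: k=%d, best init %d (silhouette %.3f), %d final iterations>\n",
              x$model$k, x$best_run, x$silhouette, x$model$iterations))
  invisible(x)
}
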