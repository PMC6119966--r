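#' Configuration for decentralized group spatial ICA
#'
#' @param k1 Subject-level principal components retained by the temporal
#'   LocalPCA stage (120 in a full-scale analysis; desk-scale runs use less).
#' @param r Number of global spatial components.
#' @param ica_max_steps,ica_learning_rate,ica_seed Infomax settings passed to
#'   [infomax_ica()].
#' @return An object of class `gica_config`.
#' @export
gica_config <- function(k1 = 120L, r = 100L, ica_max_steps = 512L,
                        ica_learning_rate = NULL, ica_seed = 1L) {
  stopifnot(k1 >= 1, r >= 1)
  structure(list(k1 = as.integer(k1), r = as.integer(r),
                 ica = list(max_steps = as.integer(ica_max_steps),
                            learning_rate = ica_learning_rate,
                            seed = as.integer(ica_seed))),
            class = "gica_config")
}

#' Subject-level temporal PCA with whitening
#'
#' Reduces one subject's voxels x timepoints block to its top `k1` whitened
#' principal directions in the temporal dimension: timepoint columns are
#' centered over voxels, and the returned d x k1 scores have unit variance
#' and zero pairwise covariance.
#'
#' @param subject A [subject_data()] (or plain voxels x timepoints matrix).
#' @param k1 Number of components to keep; must not exceed the data rank.
#' @return A d x k1 matrix of whitened temporal principal directions, with
#'   attribute `retained_variance` (share of total variance kept).
#' @export
local_pca <- function(subject, k1) {
  X <- if (inherits(subject, "subject_data")) subject$data else as.matrix(subject)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0L)
  rank <- sum(sv$d > sv$d[1L] * 1e-10)
  if (k1 > rank)
    stop("k1 (", k1, ") exceeds the data rank (", rank, ")")
  out <- sv$u[, seq_len(k1), drop = FALSE] * sqrt(nrow(X) - 1)
  attr(out, "retained_variance") <- sum(sv$d[seq_len(k1)]^2) / sum(sv$d^2)
  out
}

#' Peer-to-peer global spatial PCA
#'
#' Computes the global top-`r` spatial eigenvectors of the column-stacked
#' site blocks without pooling them: the first site reduces its own block to
#' a rank-r spectrum-weighted basis (`U_r diag(d_r)` of its truncated SVD)
#' and passes the d x r result to the next peer, which stacks it with its
#' own block in the column dimension, reduces again, and passes on. The last
#' site in the chain is the aggregator and returns the final orthonormalized
#' basis.
#'
#' @param site_blocks Ordered list of d x (columns) site matrices (the order
#'   fixes the chain).
#' @param r Number of global components; must not exceed the stacked rank.
#' @param log Optional [message_log()]; every hop logs a d x r message.
#' @param site_ids Optional site labels (defaults to site1..siteS, the last
#'   one acting as aggregator).
#' @param round Round index used when logging.
#' @return An r x d matrix V with orthonormal rows spanning (approximately,
#'   for multi-site chains) the pooled top-r spatial subspace.
#' @export
global_pca <- function(site_blocks, r, log = NULL, site_ids = NULL,
                       round = 0L) {
  S <- length(site_blocks)
  stopifnot(S >= 1L)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(S))
  d <- nrow(site_blocks[[1L]])
  running <- NULL
  for (j in seq_len(S)) {
    stacked <- cbind(running, site_blocks[[j]])
    sv <- svd(stacked, nu = min(dim(stacked)), nv = 0L)
    rank <- sum(sv$d > sv$d[1L] * 1e-10)
    if (r > rank)
      stop("r (", r, ") exceeds the stacked rank (", rank, ") at site ",
           site_ids[j])
    running <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
    if (j < S && !is.null(log))
      log_message(log, round, site_ids[j], site_ids[j + 1L], d * r)
  }
  sv <- svd(running, nu = r, nv = 0L)
  t(sv$u)
}

# Row-whitening for the ICA input: center each row, then sphere with the
# inverse square root of the row covariance.
whiten_rows <- function(X) {
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values))
    stop("whitening input is rank deficient")
  K <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  list(x = K %*% Xc, K = K)
}

#' Infomax independent component analysis
#'
#' Natural-gradient infomax with the logistic nonlinearity, suited to the
#' super-Gaussian (sparse) spatial sources typical of brain maps. Updates run
#' over randomly permuted column blocks of size `max(8, floor(sqrt(d)))`; the
#' learning rate is annealed whenever the angle between successive weight
#' updates exceeds 60 degrees, and the run stops when the per-pass weight
#' change drops below 1e-7 (or `max_steps` passes). Deterministic for a fixed
#' seed.
#'
#' @param whitened r x d matrix with whitened rows (see the row-whitening
#'   performed by [dgica()]).
#' @param max_steps Maximum number of passes over the data.
#' @param learning_rate Initial step size; default `0.01 / log(r + 1)`.
#' @param seed Integer seed for the weight init and block permutations.
#' @return List with `W` (r x r unmixing matrix; rows of `W %*% whitened`
#'   are the estimated independent spatial maps), `A_hat` (their d x r
#'   transpose), `steps` (passes used).
#' @export
infomax_ica <- function(whitened, max_steps = 512L, learning_rate = NULL,
                        seed = 1L) {
  X <- as.matrix(whitened)
  r <- nrow(X); d <- ncol(X)
  if (is.null(learning_rate)) learning_rate <- 0.01 / log(r + 1)
  lr <- learning_rate
  set.seed(seed)
  W <- diag(r) + matrix(stats::rnorm(r * r, 0, 0.01), r, r)
  block <- max(8L, floor(sqrt(d)))
  oldW <- W
  olddelta <- NULL
  steps <- 0L
  for (step in seq_len(max_steps)) {
    steps <- step
    perm <- sample.int(d)
    for (b0 in seq(1L, d, by = block)) {
      idx <- perm[b0:min(b0 + block - 1L, d)]
      u <- W %*% X[, idx, drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lr * (diag(length(idx), r) + (1 - 2 * y) %*% t(u)) %*% W
      if (max(abs(W)) > 1e8)
        stop("infomax learning diverged at pass ", step,
             " (weight norm blow-up); lower the learning rate")
    }
    delta <- W - oldW
    change <- sqrt(sum(delta^2))
    if (!is.null(olddelta)) {
      denom <- sqrt(sum(delta^2) * sum(olddelta^2))
      angle <- if (denom > 0) acos(pmin(1, pmax(-1,
        sum(delta * olddelta) / denom))) * 180 / pi else 0
      if (angle > 60) lr <- lr * 0.9
    }
    olddelta <- delta
    oldW <- W
    if (change < 1e-7) break
  }
  list(W = W, A_hat = t(W %*% X), steps = steps)
}

#' Spatio-temporal regression back-reconstruction
#'
#' Recovers one subject's component time-courses and subject-specific spatial
#' maps from the group spatial maps: the time-courses are the least-squares
#' projection of the subject data onto the group maps, and the subject maps
#' come from a second regression of the data on those time-courses.
#'
#' @param subject A [subject_data()] (or d x N matrix).
#' @param A_hat d x r group spatial maps, full column rank.
#' @return List with `timecourses` (N x r) and `maps` (d x r).
#' @export
back_reconstruct <- function(subject, A_hat) {
  X <- if (inherits(subject, "subject_data")) subject$data else as.matrix(subject)
  A_hat <- as.matrix(A_hat)
  qa <- qr(A_hat)
  if (qa$rank < ncol(A_hat)) stop("A_hat is rank deficient")
  tc <- t(qr.coef(qa, X))                       # N x r
  qt <- qr(tc)
  maps <- t(qr.coef(qt, t(X)))                  # d x r
  list(timecourses = tc, maps = maps)
}

#' Decentralized group spatial ICA
#'
#' End-to-end pipeline over multi-site subject data: per-subject temporal
#' [local_pca()], temporal concatenation of the reduced subjects within each
#' site, peer-to-peer [global_pca()] chaining the sites into the aggregator
#' (the last site), row-whitening of the global eigenvectors, [infomax_ica()]
#' at the aggregator, broadcast of the r x r unmixing matrix to the other
#' sites, and per-subject [back_reconstruct()].
#'
#' With the chain and broadcast logged, the chain-head site's total traffic
#' is exactly `d*r + r^2` scalars (cf. [predicted_dgica_bandwidth()]).
#'
#' @param sites List (one element per site) of lists of [subject_data()].
#' @param cfg A [gica_config()].
#' @param log Optional [message_log()].
#' @return List of class `spatial_decomposition` with `V` (r x d global
#'   eigenvectors), `W` (r x r unmixing), `A_hat` (d x r group spatial maps),
#'   `maps` (r x d independent spatial maps, = t(A_hat)), per-subject
#'   `timecourses` and `subject_maps`, `aggregator` label and `log`.
#' @export
dgica <- function(sites, cfg, log = NULL) {
  stopifnot(inherits(cfg, "gica_config"), length(sites) >= 1L)
  site_ids <- names(sites)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_along(sites))
  blocks <- lapply(sites, function(subjects)
    do.call(cbind, lapply(subjects, local_pca, k1 = cfg$k1)))
  V <- global_pca(blocks, cfg$r, log = log, site_ids = site_ids)
  wh <- whiten_rows(V)
  fit <- infomax_ica(wh$x, max_steps = cfg$ica$max_steps,
                     learning_rate = cfg$ica$learning_rate,
                     seed = cfg$ica$seed)
  agg <- site_ids[length(site_ids)]
  if (!is.null(log))
    for (sid in setdiff(site_ids, agg))
      log_message(log, 1L, agg, sid, cfg$r^2)
  A_hat <- fit$A_hat
  recon <- lapply(sites, function(subjects)
    lapply(subjects, back_reconstruct, A_hat = A_hat))
  structure(list(V = V, whitening = wh$K, W = fit$W, A_hat = A_hat,
                 maps = t(A_hat),
                 timecourses = lapply(recon, lapply, `[[`, "timecourses"),
                 subject_maps = lapply(recon, lapply, `[[`, "maps"),
                 ica_steps = fit$steps, aggregator = agg, log = log),
            class = "spatial_decomposition")
}

#' @export
print.spatial_decomposition <- function(x, ...) {
  cat(sprintf("<spatial_decomposition: %d components x %d voxels, aggregator '%s'>\n",
              nrow(x$V), ncol(x$V), x$aggregator))
  invisible(x)
}

# Minimum-cost rectangular assignment (rows <= columns) via the standard
# O(n^2 m) shortest augmenting path algorithm with dual potentials.
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol")
  stopifnot(all(is.finite(cost)))
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)   # slot j+1 holds column j; column 0 is virtual
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      js <- which(!used[-1L])
      cur <- cost[i0, js] - u[i0 + 1L] - v[js + 1L]
      upd <- cur < minv[js + 1L]
      minv[js[upd] + 1L] <- cur[upd]
      way[js[upd] + 1L] <- j0
      j1 <- js[which.min(minv[js + 1L])]
      delta <- minv[j1 + 1L]
      usedIdx <- which(used)
      u[p[usedIdx] + 1L] <- u[p[usedIdx] + 1L] + delta
      v[usedIdx] <- v[usedIdx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assigned <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assigned[p[j + 1L]] <- j
  assigned
}

#' Match estimated components to a reference set
#'
#' Resolves the permutation and sign indeterminacy of ICA (and of cluster
#' centroids) by Hungarian assignment under the correlation distance
#' `1 - |cor|`: each reference row is matched to a distinct estimated row so
#' that the total absolute correlation is maximal. Estimated sets may hold
#' more components than the reference (used to select a subset against a
#' reference set).
#'
#' @param estimated Matrix with components in rows.
#' @param reference Matrix with components in rows (same column dimension;
#'   at most as many rows as `estimated`).
#' @return List with `permutation` (for each reference row, the matched
#'   estimated row index), `signs` (+1/-1 flips making the matched
#'   correlations positive), `correlations` (matched absolute correlations)
#'   and `aligned` (estimated rows reordered and sign-flipped to line up with
#'   the reference).
#' @export
match_components <- function(estimated, reference) {
  estimated <- as.matrix(estimated)
  reference <- as.matrix(reference)
  if (ncol(estimated) != ncol(reference))
    stop("estimated and reference must share the feature dimension")
  if (nrow(reference) > nrow(estimated))
    stop("reference has more components than estimated")
  if (any(apply(estimated, 1L, stats::sd) == 0) ||
      any(apply(reference, 1L, stats::sd) == 0))
    stop("zero-variance component")
  R <- stats::cor(t(reference), t(estimated))   # n_ref x n_est
  assigned <- hungarian_assignment(1 - abs(R))
  corr <- R[cbind(seq_len(nrow(reference)), assigned)]
  signs <- ifelse(corr >= 0, 1, -1)
  aligned <- estimated[assigned, , drop = FALSE] * signs
  list(permutation = assigned, signs = signs, correlations = abs(corr),
       aligned = aligned)
}
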