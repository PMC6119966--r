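#' Ground truth for a synthetic multi-site voxelwise regression problem
#'
#' Describes a multi-site linear-model dataset with known coefficients:
#' per-subject covariates (age, diagnosis, gender) plus additive site offsets,
#' and V voxel responses generated as `design %*% true_weights + offset +
#' noise`. Desk-scale defaults: 3 sites of 50 subjects and 200 voxels.
#'
#' @param n_per_site Integer vector of per-site sample counts (its length sets
#'   the site count).
#' @param V Number of voxel targets.
#' @param noise_sd Gaussian noise standard deviation on each response.
#' @param site_offsets Per-site additive offsets (length = site count);
#'   defaults to an evenly spaced spread around 0.
#' @param true_weights Optional 4 x V matrix of true coefficients in row order
#'   age, diagnosis, gender, intercept; drawn from the seed when NULL.
#' @param seed Integer seed; the generated dataset is a pure function of it.
#' @return An object of class `regression_truth`.
#' @export
regression_truth <- function(n_per_site = c(50L, 50L, 50L), V = 200L,
                             noise_sd = 1, site_offsets = NULL,
                             true_weights = NULL, seed = 1L) {
  S <- length(n_per_site)
  if (is.null(site_offsets))
    site_offsets <- if (S == 1L) 0 else seq(-0.5, 0.5, length.out = S)
  stopifnot(length(site_offsets) == S, all(n_per_site >= 1), V >= 1)
  structure(list(n_per_site = as.integer(n_per_site), V = as.integer(V),
                 noise_sd = noise_sd, site_offsets = site_offsets,
                 true_weights = true_weights, seed = as.integer(seed)),
            class = "regression_truth")
}

#' Generate multi-site regression data with known coefficients
#'
#' Draws per-site covariates (age uniform on 18-65, diagnosis and gender
#' Bernoulli(0.5)), builds responses as the true linear model plus the site's
#' offset plus Gaussian noise, and returns per-site covariate tables and
#' response matrices together with the realized truth. Deterministic given
#' the truth's seed.
#'
#' @param truth A [regression_truth()].
#' @return List with elements `covariates` (per-site data frames with columns
#'   id, age, diagnosis, gender, site), `response` (per-site n_j x V
#'   matrices) and `truth` (input truth with `true_weights` filled in).
#' @seealso [as_site_datasets()] to turn the output into design matrices.
#' @export
gen_multisite_regression <- function(truth) {
  stopifnot(inherits(truth, "regression_truth"))
  set.seed(truth$seed)
  S <- length(truth$n_per_site)
  V <- truth$V
  if (is.null(truth$true_weights)) {
    truth$true_weights <- rbind(
      age = stats::rnorm(V, 0, 0.02),
      diagnosis = stats::rnorm(V, 0, 0.5),
      gender = stats::rnorm(V, 0, 0.5),
      intercept = stats::rnorm(V, 1, 0.25))
  }
  stopifnot(nrow(truth$true_weights) == 4L, ncol(truth$true_weights) == V)
  covariates <- vector("list", S)
  response <- vector("list", S)
  id0 <- 0L
  for (j in seq_len(S)) {
    n <- truth$n_per_site[j]
    tab <- data.frame(
      id = sprintf("sub-%04d", id0 + seq_len(n)),
      age = stats::runif(n, 18, 65),
      diagnosis = stats::rbinom(n, 1L, 0.5),
      gender = stats::rbinom(n, 1L, 0.5),
      site = paste0("site", j),
      stringsAsFactors = FALSE)
    id0 <- id0 + n
    X <- cbind(tab$age, tab$diagnosis, tab$gender, 1)
    response[[j]] <- X %*% truth$true_weights + truth$site_offsets[j] +
      matrix(stats::rnorm(n * V, 0, truth$noise_sd), n, V)
    covariates[[j]] <- tab
  }
  names(covariates) <- names(response) <- paste0("site", seq_len(S))
  list(covariates = covariates, response = response, truth = truth)
}

#' Build per-site design matrices from covariate tables
#'
#' Converts the output of [gen_multisite_regression()] (or covariate tables of
#' the same layout) into a list of [site_dataset()] objects. The design
#' columns are age, diagnosis, gender, optionally S-1 site indicator columns
#' (the first site is the dropped reference), and the constant intercept
#' appended last. Site indicators are what single-shot regression cannot
#' carry, since they are locally constant and hence collinear with the
#' intercept.
#'
#' @param sim Output of [gen_multisite_regression()], or a list with
#'   `covariates` and `response` elements of the same shape.
#' @param site_dummies If TRUE (default), include the S-1 site indicator
#'   columns.
#' @return A list of [site_dataset()] objects.
#' @export
as_site_datasets <- function(sim, site_dummies = TRUE) {
  covs <- sim$covariates
  S <- length(covs)
  site_levels <- names(covs)
  lapply(seq_len(S), function(j) {
    tab <- covs[[j]]
    X <- cbind(age = tab$age, diagnosis = tab$diagnosis, gender = tab$gender)
    if (site_dummies && S > 1L) {
      for (lev in site_levels[-1L]) {
        col <- as.numeric(tab$site == lev)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- lev
      }
    }
    X <- cbind(X, intercept = 1)
    site_dataset(site_levels[j], X, sim$response[[j]])
  })
}

#' Ground truth for synthetic multi-site fMRI-like data
#'
#' Describes an ICA-mixture dataset with latent connectivity states: `r`
#' spatial source maps (Gaussian blobs on a 3-D grid, super-Gaussian across
#' voxels), per-subject component time-courses drawn segment-wise from `k`
#' well-separated covariance templates (dwell length at least the sliding
#' window), voxel data `A_true %*% S + noise`, plus per-subject motion
#' regressors and a framewise-displacement series with planted spikes.
#' Desk-scale defaults: 2 sites x 10 subjects, 500 voxels (10 x 10 x 5 grid),
#' 5 components, 3 states, 162 timepoints.
#'
#' @param grid_dim 3-D grid dimensions; their product is the voxel count d.
#' @param r Number of spatial components.
#' @param k Number of latent covariance states.
#' @param n_subjects Total subjects, split as evenly as possible across sites.
#' @param n_sites Number of sites.
#' @param T_len Timepoints per subject.
#' @param w Sliding-window length (dwell segments are at least this long).
#' @param noise_sd Voxel-level Gaussian noise standard deviation.
#' @param n_spikes Motion spikes planted per subject.
#' @param seed Integer seed.
#' @return An object of class `fmri_truth`.
#' @export
fmri_truth <- function(grid_dim = c(10L, 10L, 5L), r = 5L, k = 3L,
                       n_subjects = 20L, n_sites = 2L, T_len = 162L,
                       w = 22L, noise_sd = 0.1, n_spikes = 3L, seed = 1L) {
  d <- prod(grid_dim)
  stopifnot(r <= d, k >= 1, T_len > w, n_sites >= 1, n_subjects >= n_sites)
  structure(list(grid_dim = as.integer(grid_dim), d = as.integer(d),
                 r = as.integer(r), k = as.integer(k),
                 n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites), T_len = as.integer(T_len),
                 w = as.integer(w), noise_sd = noise_sd,
                 n_spikes = as.integer(n_spikes), seed = as.integer(seed)),
            class = "fmri_truth")
}

#' One subject's voxel-by-time data block
#'
#' @param data Numeric voxels x timepoints matrix.
#' @param subject_id,site_id Labels.
#' @return An object of class `subject_data`.
#' @export
subject_data <- function(data, subject_id, site_id) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("subject data must be finite")
  if (any(apply(data, 1L, function(v) all(v == 0))))
    stop("subject data must carry no constant-zero voxel rows")
  structure(list(data = data, subject_id = as.character(subject_id),
                 site_id = as.character(site_id)),
            class = "subject_data")
}

# k well-separated r x r SPD covariance templates (pairwise correlation
# distance of their vectorized forms >= 0.5); deterministic under the caller's
# RNG state.
make_state_templates <- function(r, k, min_sep = 0.5, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    templates <- lapply(seq_len(k), function(cc) {
      B <- matrix(stats::rnorm(r * 2L), r, 2L)
      S <- tcrossprod(B) + diag(r)
      Dinv <- diag(1 / sqrt(diag(S)))
      Dinv %*% S %*% Dinv   # correlation-scaled SPD template
    })
    vecs <- vapply(templates, function(S) S[upper.tri(S)],
                   numeric(r * (r - 1) / 2))
    seps <- stats::cor(vecs)
    if (all(1 - seps[upper.tri(seps)] >= min_sep)) return(templates)
  }
  stop("could not draw sufficiently separated state templates")
}

# Gaussian blob spatial source maps: d x r, blob centers spread over the grid.
make_blob_maps <- function(grid_dim, r, sigma = 1.3) {
  coords <- as.matrix(expand.grid(x = seq_len(grid_dim[1L]),
                                  y = seq_len(grid_dim[2L]),
                                  z = seq_len(grid_dim[3L])))
  centers <- coords[sample.int(nrow(coords), r), , drop = FALSE]
  A <- vapply(seq_len(r), function(cc) {
    d2 <- rowSums(sweep(coords, 2L, centers[cc, ])^2)
    exp(-d2 / (2 * sigma^2))
  }, numeric(nrow(coords)))
  A
}

#' Generate multi-site fMRI-like subjects with planted states
#'
#' For each subject, draws a sequence of latent states with dwell lengths of
#' at least one window, samples component time-courses from the corresponding
#' covariance template, projects them through the spatial maps and adds
#' voxel-level noise. Also emits 6 rigid-body motion parameters (random
#' walks), their 24-regressor expansion, and a framewise-displacement series
#' with spikes planted at known indices (magnitude 10x the baseline).
#'
#' @param truth An [fmri_truth()].
#' @return A list with `sites` (per-site lists of [subject_data()]),
#'   `timecourses` (per-subject r x T component time-courses),
#'   `states` (per-subject length-T state labels), `motion` (per-subject
#'   T x 24 regressor matrices), `fd` (per-subject length-T series),
#'   `spike_idx` (per-subject planted spike indices), and `truth` augmented
#'   with `A_true` (d x r spatial maps) and `templates` (k covariance
#'   templates).
#' @export
gen_fmri_subjects <- function(truth) {
  stopifnot(inherits(truth, "fmri_truth"))
  set.seed(truth$seed)
  r <- truth$r; k <- truth$k; T_len <- truth$T_len; w <- truth$w
  A_true <- make_blob_maps(truth$grid_dim, r)
  templates <- make_state_templates(r, k)
  chol_t <- lapply(templates, chol)
  site_of <- rep(seq_len(truth$n_sites), length.out = truth$n_subjects)
  site_of <- sort(site_of)
  sites <- rep(list(list()), truth$n_sites)
  timecourses <- states <- motion <- fd <- spike_idx <- vector("list", truth$n_subjects)
  for (i in seq_len(truth$n_subjects)) {
    # latent state sequence: dwell segments of length >= w
    lab <- integer(0)
    cur <- sample.int(k, 1L)
    while (length(lab) < T_len) {
      dwell <- sample(w:(2L * w), 1L)
      lab <- c(lab, rep(cur, dwell))
      nxt <- if (k == 1L) 1L else sample(setdiff(seq_len(k), cur), 1L)
      cur <- nxt
    }
    lab <- lab[seq_len(T_len)]
    S <- matrix(0, r, T_len)
    for (t in seq_len(T_len))
      S[, t] <- drop(crossprod(chol_t[[lab[t]]], stats::rnorm(r)))
    X <- A_true %*% S +
      matrix(stats::rnorm(truth$d * T_len, 0, truth$noise_sd), truth$d, T_len)
    # 6 rigid-body parameters as smooth random walks; 24-regressor expansion
    p6 <- apply(matrix(stats::rnorm(T_len * 6L, 0, 0.02), T_len, 6L), 2L, cumsum)
    dp6 <- rbind(0, diff(p6))
    mot <- cbind(p6, dp6, p6^2, dp6^2)
    base_fd <- abs(stats::rnorm(T_len, 0.1, 0.02))
    spikes <- sort(sample(3:(T_len - 2L), truth$n_spikes))
    base_fd[spikes] <- base_fd[spikes] + 10 * 0.1
    sid <- sprintf("sub-%03d", i)
    sites[[site_of[i]]] <- c(sites[[site_of[i]]],
                             list(subject_data(X, sid, paste0("site", site_of[i]))))
    timecourses[[i]] <- S
    states[[i]] <- lab
    motion[[i]] <- mot
    fd[[i]] <- base_fd
    spike_idx[[i]] <- spikes
  }
  names(sites) <- paste0("site", seq_len(truth$n_sites))
  truth$A_true <- A_true
  truth$templates <- templates
  list(sites = sites, timecourses = timecourses, states = states,
       motion = motion, fd = fd, spike_idx = spike_idx,
       subject_site = site_of, truth = truth)
}

#' Per-site timecourse objects from generated fMRI truth
#'
#' Packages the generator's planted component time-courses, FD series and
#' motion regressors as per-site lists of [timecourse()] objects, the input
#' layout [run_ddfnc()] expects.
#'
#' @param gen Output of [gen_fmri_subjects()].
#' @return Named list (one element per site) of lists of [timecourse()].
#' @export
as_site_timecourses <- function(gen) {
  tr <- gen$truth
  out <- lapply(seq_len(tr$n_sites), function(j) {
    idx <- which(gen$subject_site == j)
    lapply(idx, function(i)
      timecourse(t(gen$timecourses[[i]]), fd = gen$fd[[i]],
                 motion = gen$motion[[i]]))
  })
  names(out) <- paste0("site", seq_len(tr$n_sites))
  out
}

#' Score a ddFNC run against the planted states
#'
#' Hungarian-matches the fitted centroids to the generator's covariance
#' templates under the correlation distance, then scores the state labels
#' over pure windows only: windows fully contained in one dwell segment.
#' (A window straddling a state transition mixes two covariance templates
#' and has no well-defined true label.)
#'
#' @param result A `ddfnc_result` from [run_ddfnc()] fitted on
#'   [as_site_timecourses()] output.
#' @param gen The matching [gen_fmri_subjects()] output.
#' @param drop_initial Leading timepoints the cleaning stage discarded.
#' @return List with `accuracy` (pure-window label accuracy),
#'   `centroid_correlations` (matched absolute correlations between centroids
#'   and templates) and `n_pure` (pure windows scored).
#' @export
ddfnc_state_accuracy <- function(result, gen, drop_initial = 2L) {
  tr <- gen$truth
  vecf <- function(S) t(S)[lower.tri(S)]
  templates <- t(vapply(tr$templates, vecf, numeric(tr$r * (tr$r - 1) / 2)))
  mm <- match_components(result$model$centroids, templates)
  state_map <- integer(tr$k)
  state_map[mm$permutation] <- seq_len(tr$k)
  hits <- 0L; n_pure <- 0L
  for (j in seq_len(tr$n_sites)) {
    idx <- which(gen$subject_site == j)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      lab <- gen$states[[i]]
      est <- state_map[result$labels[[j]][[ii]]]
      for (t0 in seq_along(est)) {
        seg <- lab[(t0 + drop_initial):(t0 + drop_initial + tr$w - 1L)]
        if (length(unique(seg)) == 1L) {
          n_pure <- n_pure + 1L
          hits <- hits + (est[t0] == seg[1L])
        }
      }
    }
  }
  list(accuracy = hits / n_pure, centroid_correlations = mm$correlations,
       n_pure = n_pure)
}
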