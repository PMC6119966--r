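#' Optimizer settings for multi-shot regression
#'
#' Multi-shot decentralized regression performs full-batch gradient descent at
#' the aggregator using the Adam update on the summed per-site gradients.
#' Defaults: learning rate 0.01, beta1 0.9, beta2 0.999, epsilon 1e-8; the run
#' stops when the infinity norm of the aggregated gradient drops to
#' `tolerance` or the largest weight change in a round drops to
#' `weight_tolerance`, whichever comes first.
#'
#' @param scheme Optimization scheme; only "adam" is implemented.
#' @param learning_rate Positive step size.
#' @param beta1,beta2 Exponential decay rates for the first and second moment
#'   estimates, in (0, 1).
#' @param epsilon Small positive constant stabilizing the Adam denominator.
#' Constant-rate Adam orbits the optimum of a deterministic quadratic at a
#' radius proportional to the learning rate, so the rate is annealed on
#' plateaus: whenever the aggregated gradient norm fails to improve for
#' `anneal_patience` consecutive rounds, the rate is multiplied by
#' `anneal_factor`. This preserves Adam's per-coordinate scaling (which
#' handles the poor conditioning of raw covariates such as age) while making
#' the stated tolerances reachable.
#'
#' @param tolerance Gradient infinity-norm stopping threshold (> 0).
#' @param weight_tolerance Weight-change stopping threshold (> 0).
#' @param max_iterations Iteration cap (>= 1).
#' @param anneal_patience Rounds without gradient-norm improvement before the
#'   learning rate is reduced.
#' @param anneal_factor Multiplier applied to the learning rate on a plateau.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(scheme = "adam", learning_rate = 0.01,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                             tolerance = 1e-6, weight_tolerance = 1e-9,
                             max_iterations = 10000L,
                             anneal_patience = 50L, anneal_factor = 0.5) {
  scheme <- match.arg(scheme, "adam")
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, tolerance > 0, weight_tolerance > 0,
            max_iterations >= 1, anneal_patience >= 1,
            anneal_factor > 0, anneal_factor < 1)
  structure(list(scheme = scheme, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 tolerance = tolerance, weight_tolerance = weight_tolerance,
                 max_iterations = as.integer(max_iterations),
                 anneal_patience = as.integer(anneal_patience),
                 anneal_factor = anneal_factor),
            class = "optimizer_config")
}

as_weight_matrix <- function(w, d1, V) {
  if (is.null(dim(w))) w <- matrix(w, ncol = 1L)
  if (nrow(w) != d1)
    stop("weight length does not match the design column count")
  if (ncol(w) == 1L && V > 1L) w <- w[, rep(1L, V), drop = FALSE]
  if (ncol(w) != V)
    stop("weight column count does not match the response target count")
  w
}

#' Local sum-of-squares objective at one site
#'
#' Evaluates the site's contribution to the global least-squares objective,
#' `sum_i (y_i - w'x_i)^2`, for each response target.
#'
#' @param site A [site_dataset()].
#' @param w Weight vector of length d+1 (intercept last), or a (d+1) x V
#'   matrix with one column per response target.
#' @return Numeric vector of per-target objective values (a scalar for a
#'   single-target site).
#' @export
local_objective <- function(site, w) {
  stopifnot(inherits(site, "site_dataset"))
  w <- as_weight_matrix(w, ncol(site$design), ncol(site$response))
  resid <- site$response - site$design %*% w
  drop(colSums(resid^2))
}

#' Local gradient of the sum-of-squares objective
#'
#' Returns the exact gradient `2 X_j' (X_j w - y_j)` of the site's local
#' objective. Because the global objective is the plain sum of the local ones,
#' the aggregated gradient is the elementwise sum of these per-site gradients.
#'
#' @inheritParams local_objective
#' @return A (d+1) x V gradient matrix (dropped to a vector for a
#'   single-target site).
#' @export
local_gradient <- function(site, w) {
  stopifnot(inherits(site, "site_dataset"))
  w <- as_weight_matrix(w, ncol(site$design), ncol(site$response))
  g <- 2 * crossprod(site$design, site$design %*% w - site$response)
  if (ncol(g) == 1L) drop(g) else g
}

# Per-site sufficient statistics shared by DRNE, multi-shot and inference:
# Gram matrix X'X, moment matrix X'Y, response column sums and sums of squares.
site_moments <- function(site) {
  list(gram = crossprod(site$design),
       moment = crossprod(site$design, site$response),
       ysum = colSums(site$response),
       yss = colSums(site$response^2),
       n = site$n_j)
}

check_dims <- function(sites) {
  stopifnot(length(sites) >= 1L,
            all(vapply(sites, inherits, TRUE, "site_dataset")))
  d1 <- ncol(sites[[1L]]$design)
  V <- ncol(sites[[1L]]$response)
  for (s in sites)
    if (ncol(s$design) != d1 || ncol(s$response) != V)
      stop("all sites must share design and response dimensions")
  list(d1 = d1, V = V, n = sum(vapply(sites, function(s) s$n_j, 0L)))
}

new_regression_result <- function(method, weights, sse, sst, r_squared,
                                  t_values, p_values, dof, iterations = 0L,
                                  converged = TRUE) {
  structure(list(method = method, weights = weights, sse = sse, sst = sst,
                 r_squared = r_squared, t_values = t_values,
                 p_values = p_values, dof = dof,
                 iterations = as.integer(iterations), converged = converged),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  V <- if (is.null(dim(x$weights))) 1L else ncol(x$weights)
  cat(sprintf("<regression_result [%s]: %d coefficient(s), %d target(s), dof %d%s>\n",
              x$method, NROW(x$weights), V, x$dof,
              if (x$iterations > 0)
                sprintf(", %d iterations%s", x$iterations,
                        if (x$converged) "" else " (NOT converged)") else ""))
  invisible(x)
}

# Attach decentralized R^2 and t/p inference to a fitted weight matrix.
# Inference is skipped (NA) when the fit leaves no residual degrees of
# freedom, e.g. an exactly determined toy problem.
finish_result <- function(method, sites, w, iterations = 0L,
                          converged = TRUE, log = NULL, round = 0L) {
  r2 <- decentralized_r2(sites, w)
  dims <- check_dims(sites)
  tv <- if (dims$n - dims$d1 > 0)
    decentralized_tvalues(sites, w, log = log, round = round)
  else
    list(t_values = matrix(NA_real_, dims$d1, dims$V),
         p_values = matrix(NA_real_, dims$d1, dims$V),
         dof = dims$n - dims$d1)
  squeeze <- function(m) if (!is.null(dim(m)) && ncol(m) == 1L) drop(m) else m
  new_regression_result(method, squeeze(w), r2$sse, r2$sst, r2$r_squared,
                        squeeze(tv$t_values), squeeze(tv$p_values), tv$dof,
                        iterations, converged)
}

#' Pooled least-squares reference fit
#'
#' The centralized oracle: concatenates all site rows and solves the ordinary
#' least-squares problem directly. Used as the ground-truth comparator for the
#' decentralized fits; no decentralized routine shares raw rows this way.
#'
#' @param sites List of [site_dataset()] objects.
#' @return A `regression_result` with pooled weights, SSE, SST, R-squared and
#'   t/p values.
#' @export
pooled_fit <- function(sites) {
  dims <- check_dims(sites)
  X <- do.call(rbind, lapply(sites, `[[`, "design"))
  Y <- do.call(rbind, lapply(sites, `[[`, "response"))
  qrX <- qr(X)
  if (qrX$rank < dims$d1) stop("pooled design is rank deficient")
  w <- qr.coef(qrX, Y)
  finish_result("pooled", sites, w)
}

#' Single-shot decentralized regression
#'
#' Each site solves its local least-squares problem once and uploads only its
#' local weight vector and sample count; the aggregator forms the
#' sample-size-weighted average `sum_j s_j w_j / sum_j s_j`. This is the
#' meta-analysis-like variant: it needs a single round of communication but is
#' generally suboptimal relative to the pooled solution, and site indicator
#' covariates cannot be included locally (they are constant within a site,
#' hence collinear with the intercept).
#'
#' @param sites List of [site_dataset()] objects (designs without site
#'   indicator columns).
#' @param log Optional [message_log()] recording the site uploads.
#' @return A `regression_result` with decentralized R-squared and t/p
#'   inference evaluated at the averaged weights.
#' @export
single_shot_fit <- function(sites, log = NULL) {
  dims <- check_dims(sites)
  wsum <- matrix(0, dims$d1, dims$V)
  n <- 0L
  for (s in sites) {
    if (s$n_j <= dims$d1)
      stop("site ", s$site_id, " has too few samples for a local fit")
    qrX <- qr(s$design)
    if (qrX$rank < dims$d1)
      stop("collinearity: local design at site ", s$site_id,
           " is rank deficient")
    wj <- qr.coef(qrX, s$response)
    wsum <- wsum + s$n_j * wj
    n <- n + s$n_j
    if (!is.null(log))
      log_message(log, 0L, s$site_id, "AGG", length(wj) + 1L)
  }
  finish_result("single_shot", sites, wsum / n, log = log, round = 1L)
}

#' Decentralized regression with normal equation (DRNE)
#'
#' Each site uploads its Gram matrix `X_j'X_j` and moment matrix `X_j'y_j`;
#' the aggregator sums them and solves the pooled normal equations
#' `w = (sum_j X_j'X_j)^-1 (sum_j X_j'y_j)`. The result is algebraically
#' identical to the pooled least-squares solution regardless of how rows are
#' partitioned across sites, and site covariates can be included.
#'
#' @param sites List of [site_dataset()] objects.
#' @param log Optional [message_log()] recording the per-site uploads
#'   ((d+1)^2 Gram scalars plus (d+1) x V moment scalars plus the sample
#'   count).
#' @return A `regression_result`.
#' @export
drne_fit <- function(sites, log = NULL) {
  dims <- check_dims(sites)
  G <- matrix(0, dims$d1, dims$d1)
  C <- matrix(0, dims$d1, dims$V)
  for (s in sites) {
    m <- site_moments(s)
    G <- G + m$gram
    C <- C + m$moment
    if (!is.null(log))
      log_message(log, 0L, s$site_id, "AGG",
                  dims$d1^2 + dims$d1 * dims$V + 1L)
  }
  w <- tryCatch(solve(G, C),
                error = function(e) stop("global collinearity: aggregate Gram matrix is singular"))
  finish_result("drne", sites, w, log = log, round = 1L)
}

#' Multi-shot decentralized regression
#'
#' Iterative decentralized gradient descent: each round the aggregator
#' broadcasts the current weights, every site returns the gradient of its
#' local sum-of-squares objective, and the aggregator applies an Adam update
#' to the plain sum of the local gradients. On convergence the weights agree
#' with the pooled (and DRNE) solution, because the global objective is convex
#' and exactly separable across sites.
#'
#' Sites evaluate their gradients through cached local moments
#' (`2 (X_j'X_j w - X_j'y_j)`), which is algebraically identical to touching
#' the raw rows each round.
#'
#' @param sites List of [site_dataset()] objects.
#' @param cfg An [optimizer_config()].
#' @param log Optional [message_log()]; each round logs the (d+1) x V
#'   broadcast to every site and the (d+1) x V gradient upload from every
#'   site.
#' @param w0 Optional initial weights; defaults to the zero vector.
#' @return A `regression_result` with `iterations` set and `converged`
#'   flagging whether a stopping tolerance was reached before
#'   `max_iterations`.
#' @export
multi_shot_fit <- function(sites, cfg = optimizer_config(), log = NULL,
                           w0 = NULL) {
  stopifnot(inherits(cfg, "optimizer_config"))
  dims <- check_dims(sites)
  moments <- lapply(sites, site_moments)
  ids <- vapply(sites, `[[`, "", "site_id")
  w <- if (is.null(w0)) matrix(0, dims$d1, dims$V)
       else as_weight_matrix(w0, dims$d1, dims$V)
  m <- v <- matrix(0, dims$d1, dims$V)
  payload <- dims$d1 * dims$V
  lr <- cfg$learning_rate
  best_norm <- Inf
  stalled <- 0L
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$max_iterations)) {
    grad <- matrix(0, dims$d1, dims$V)
    for (j in seq_along(moments)) {
      if (!is.null(log)) {
        log_message(log, iter, "AGG", ids[j], payload)
        log_message(log, iter, ids[j], "AGG", payload)
      }
      grad <- grad + 2 * (moments[[j]]$gram %*% w - moments[[j]]$moment)
    }
    gnorm <- max(abs(grad))
    if (gnorm <= cfg$tolerance) { converged <- TRUE; break }
    if (gnorm < best_norm * 0.999) { best_norm <- gnorm; stalled <- 0L }
    else stalled <- stalled + 1L
    if (stalled >= cfg$anneal_patience) {
      lr <- lr * cfg$anneal_factor
      stalled <- 0L
      best_norm <- gnorm
    }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * grad
    v <- cfg$beta2 * v + (1 - cfg$beta2) * grad^2
    mhat <- m / (1 - cfg$beta1^iter)
    vhat <- v / (1 - cfg$beta2^iter)
    step <- lr * mhat / (sqrt(vhat) + cfg$epsilon)
    w <- w - step
    if (max(abs(step)) <= cfg$weight_tolerance) { converged <- TRUE; break }
  }
  finish_result("multi_shot", sites, w, iterations = iter,
                converged = converged, log = log, round = iter + 1L)
}

#' Decentralized coefficient of determination
#'
#' Computes the global R-squared without pooling rows: the aggregator first
#' forms the global response mean as the sample-size-weighted average of the
#' local means, then each site returns its local sum of squared residuals
#' (SSE) and total sum of squares about the global mean (SST);
#' `R^2 = 1 - SSE/SST`. Identical to the pooled R-squared at the same
#' weights.
#'
#' @param sites List of [site_dataset()] objects.
#' @param w Weight vector or (d+1) x V matrix.
#' @return List with per-target `sse`, `sst` and `r_squared`.
#' @export
decentralized_r2 <- function(sites, w) {
  dims <- check_dims(sites)
  w <- as_weight_matrix(w, dims$d1, dims$V)
  ybar <- rep(0, dims$V)
  for (s in sites) ybar <- ybar + colSums(s$response)
  ybar <- ybar / dims$n
  sse <- sst <- rep(0, dims$V)
  for (s in sites) {
    resid <- s$response - s$design %*% w
    sse <- sse + colSums(resid^2)
    sst <- sst + colSums(sweep(s$response, 2L, ybar)^2)
  }
  if (any(sst <= 0))
    stop("undefined R^2: the global response is constant (SST = 0)")
  list(sse = sse, sst = sst, r_squared = 1 - sse / sst)
}

#' Decentralized t- and p-values for regression coefficients
#'
#' Given global weights from any fit, every site uploads its local Gram
#' matrix and residual sum of squares; the aggregator forms the usual OLS
#' sampling variance `sigma^2 = SSE / (n - d - 1)` and
#' `t_m = w_m / sqrt(sigma^2 [ (sum_j X_j'X_j)^-1 ]_mm)`, with two-tailed
#' p-values from the Student-t distribution on `n - d - 1` degrees of
#' freedom.
#'
#' @param sites List of [site_dataset()] objects.
#' @param w Weight vector or (d+1) x V matrix.
#' @param log Optional [message_log()]; logs each site's Gram + SSE + count
#'   upload.
#' @param round Round index used when logging.
#' @return List with `t_values`, `p_values` ((d+1) x V matrices) and `dof`.
#' @export
decentralized_tvalues <- function(sites, w, log = NULL, round = 0L) {
  dims <- check_dims(sites)
  w <- as_weight_matrix(w, dims$d1, dims$V)
  dof <- dims$n - dims$d1
  if (dof <= 0) stop("non-positive degrees of freedom")
  G <- matrix(0, dims$d1, dims$d1)
  sse <- rep(0, dims$V)
  for (s in sites) {
    G <- G + crossprod(s$design)
    sse <- sse + colSums((s$response - s$design %*% w)^2)
    if (!is.null(log))
      log_message(log, round, s$site_id, "AGG",
                  dims$d1^2 + dims$V + 1L)
  }
  Ginv_diag <- diag(solve(G))
  sigma2 <- sse / dof
  se <- sqrt(outer(Ginv_diag, sigma2))
  tv <- w / se
  tv[se == 0] <- 0
  pv <- 2 * stats::pt(-abs(tv), df = dof)
  list(t_values = tv, p_values = pv, dof = dof)
}
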