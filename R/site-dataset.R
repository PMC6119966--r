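#' One site's share of a multi-site regression problem
#'
#' A `site_dataset` holds the design matrix and response block that a single
#' site contributes to a decentralized analysis. The design is augmented: its
#' last column is the constant-1 intercept column. The response may hold many
#' targets (one column per voxel), so a whole voxelwise analysis can be fitted
#' in one pass with a shared design.
#'
#' Raw rows of a `site_dataset` are never concatenated across sites by any
#' decentralized routine; only aggregate statistics (Gram matrices, gradients,
#' sums of squares) travel between sites.
#'
#' @param site_id Opaque site label (character scalar).
#' @param design Numeric matrix, `n_j` rows by `d + 1` columns, whose last
#'   column is the constant-1 intercept column.
#' @param response Numeric matrix (or vector, treated as one column) with
#'   `n_j` rows; each column is one regression target.
#' @return An object of class `site_dataset` with fields `site_id`, `design`,
#'   `response` and `n_j`.
#' @examples
#' X <- cbind(age = c(21, 34, 55), intercept = 1)
#' site_dataset("siteA", X, c(0.4, 0.5, 0.3))
#' @export
site_dataset <- function(site_id, design, response) {
  design <- as.matrix(design)
  if (is.null(dim(response))) response <- matrix(response, ncol = 1L)
  response <- as.matrix(response)
  if (nrow(design) != nrow(response))
    stop("design and response must have the same number of rows")
  if (nrow(design) < 1L)
    stop("a site must hold at least one sample")
  # the intercept column is appended last; site indicator columns may also be
  # locally constant (a site's own indicator is all-1 at that site)
  if (!all(design[, ncol(design)] == 1))
    stop("design must end with the constant-1 intercept column")
  structure(
    list(site_id = as.character(site_id), design = design,
         response = response, n_j = nrow(design)),
    class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset '%s': %d samples, %d covariates (+intercept), %d target(s)>\n",
              x$site_id, x$n_j, ncol(x$design) - 1L, ncol(x$response)))
  invisible(x)
}

#' Split a pooled dataset across simulated sites
#'
#' Randomly partitions the rows of a pooled `site_dataset` into disjoint
#' per-site datasets. Concatenating the outputs row-wise recovers the pooled
#' rows up to a seed-determined permutation, so pooled-vs-decentralized
#' comparisons can be run on identical data.
#'
#' @param pooled A [site_dataset()] holding all rows.
#' @param proportions Numeric vector of per-site fractions summing to 1.
#' @param seed Integer seed making the assignment deterministic.
#' @return A list of [site_dataset()] objects named `site1`, `site2`, ...
#' @export
partition_dataset <- function(pooled, proportions, seed) {
  stopifnot(inherits(pooled, "site_dataset"))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  n <- pooled$n_j
  d1 <- ncol(pooled$design)
  sizes <- floor(proportions * n)
  # distribute the rounding remainder to the largest fractional parts
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- proportions * n - sizes
    sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  if (any(sizes < d1 + 1L))
    stop("under-determined site: every site needs more rows than design columns")
  set.seed(seed)
  perm <- sample.int(n)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_along(sizes), function(j) {
    idx <- perm[starts[j]:stops[j]]
    site_dataset(paste0("site", j),
                 pooled$design[idx, , drop = FALSE],
                 pooled$response[idx, , drop = FALSE])
  })
}
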