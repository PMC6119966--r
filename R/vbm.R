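#' Masked voxel data for one site
#'
#' Holds a subjects x masked-voxels matrix of gray-matter concentration
#' values together with the boolean 3-D mask, the spatial transform and the
#' mapping from masked column to 3-D grid coordinate, so per-voxel statistics
#' can be mapped back onto the brain grid.
#'
#' @param values Numeric subjects x masked-voxels matrix.
#' @param mask Logical 3-D array; its TRUE count must equal `ncol(values)`.
#' @param affine 4 x 4 spatial transform (defaults to identity).
#' @param template Optional NIfTI image to copy header geometry from when
#'   writing maps.
#' @return An object of class `voxel_matrix`.
#' @export
voxel_matrix <- function(values, mask, affine = diag(4), template = NULL) {
  values <- as.matrix(values)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  nvox <- sum(mask)
  if (nvox == 0L) stop("empty mask")
  if (ncol(values) != nvox)
    stop("values column count must equal the mask's TRUE count")
  if (any(!is.finite(values))) stop("voxel values must be finite")
  structure(list(values = values, mask = mask, affine = affine,
                 voxel_index = which(mask), template = template),
            class = "voxel_matrix")
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("<voxel_matrix: %d subjects x %d masked voxels on a %s grid>\n",
              nrow(x$values), ncol(x$values),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Load 3-D NIfTI volumes into a masked voxel matrix
#'
#' Reads a list of per-subject volumes plus a brain mask, checks that all
#' volumes share the mask's grid shape and affine, and flattens each volume's
#' masked voxels into one row.
#'
#' @param paths Character vector of NIfTI volume paths, one per subject; row
#'   order follows this order.
#' @param mask_path Path to the NIfTI brain mask (nonzero = in-brain).
#' @return A [voxel_matrix()].
#' @export
load_volumes <- function(paths, mask_path) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.logical(mask_img != 0), dim = dim(mask_img))
  aff <- RNifti::xform(mask_img)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  rows <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    if (!identical(dim(img), dim(mask)))
      stop("volume ", p, " does not share the mask's grid shape")
    if (max(abs(RNifti::xform(img) - aff)) > 1e-4)
      stop("volume ", p, " does not share the mask's affine")
    as.numeric(img)[idx]
  })
  voxel_matrix(do.call(rbind, rows), mask, aff, template = mask_img)
}

#' Map a per-voxel statistic back onto the 3-D grid
#'
#' @param vm A [voxel_matrix()] (or anything carrying `mask` and
#'   `voxel_index`).
#' @param values Numeric vector with one entry per masked voxel.
#' @return A 3-D array with the statistic at masked voxels and NaN (the
#'   unmasked sentinel) elsewhere.
#' @export
unflatten <- function(vm, values) {
  if (length(values) != length(vm$voxel_index))
    stop("values length must equal the masked voxel count")
  grid <- array(NaN, dim = dim(vm$mask))
  grid[vm$voxel_index] <- values
  grid
}

#' Signed log-significance
#'
#' The display statistic used for significance maps:
#' `-log10(p) * sign(t)`, with sign(0) = 0.
#'
#' @param t t-statistic (vectorized).
#' @param p Two-tailed p-value in (0, 1].
#' @return `-log10(p) * sign(t)`.
#' @export
signed_log_p <- function(t, p) {
  if (any(p <= 0, na.rm = TRUE)) stop("p-values must be strictly positive")
  if (any(p > 1, na.rm = TRUE)) stop("p-values must not exceed 1")
  -log10(p) * sign(t)
}

#' Voxelwise decentralized regression over multi-site volumes
#'
#' Runs one regression variant independently at every masked voxel. All
#' voxels at a site share one design matrix, so the per-site Gram matrix is
#' computed once and reused across voxels; the whole voxel dimension is fitted
#' as a multi-target regression in one pass. The `pooled` method is the
#' centralized oracle path that concatenates sites; `single_shot` drops the
#' site indicator columns from the designs (they are locally collinear with
#' the intercept), while `drne` and `multi_shot` include them.
#'
#' Voxels whose global response is constant (zero total sum of squares) are
#' flagged with NaN in every output map rather than aborting the run.
#'
#' @param site_volumes List with one element per site, each a list with
#'   `volumes` (a [voxel_matrix()] or plain subjects x voxels matrix) and
#'   `covariates` (data frame with columns age, diagnosis, gender, site; row
#'   order matching the volume rows).
#' @param method One of "pooled", "single_shot", "drne", "multi_shot".
#' @param cfg An [optimizer_config()] (multi-shot only).
#' @param log Optional [message_log()].
#' @return An object of class `stat_maps` carrying per-covariate `t`, `p` and
#'   `signed_log_p` matrices, per-voxel `sse`, `sst` and `r_squared` vectors,
#'   the fitted `weights`, and the mask geometry when the input volumes carry
#'   one.
#' @export
run_voxelwise <- function(site_volumes,
                          method = c("pooled", "single_shot", "drne", "multi_shot"),
                          cfg = optimizer_config(), log = NULL) {
  method <- match.arg(method)
  S <- length(site_volumes)
  vm0 <- site_volumes[[1L]]$volumes
  geom <- if (inherits(vm0, "voxel_matrix")) vm0 else NULL
  if (!is.null(geom)) {
    for (sv in site_volumes) {
      v <- sv$volumes
      if (!inherits(v, "voxel_matrix") || !identical(v$mask, geom$mask))
        stop("all sites must share one mask")
    }
  }
  covariates <- lapply(site_volumes, `[[`, "covariates")
  response <- lapply(site_volumes, function(sv) {
    v <- sv$volumes
    if (inherits(v, "voxel_matrix")) v$values else as.matrix(v)
  })
  for (j in seq_len(S))
    if (nrow(response[[j]]) != nrow(covariates[[j]]))
      stop("covariate rows must align with volume rows at site ", j)
  names(covariates) <- names(response) <- paste0("site", seq_len(S))
  sim <- list(covariates = covariates, response = response)
  sites <- as_site_datasets(sim, site_dummies = (method != "single_shot"))
  V <- ncol(response[[1L]])

  # flag degenerate voxels (constant global response) instead of aborting
  n <- sum(vapply(sites, function(s) s$n_j, 0L))
  ysum <- Reduce(`+`, lapply(sites, function(s) colSums(s$response)))
  sst <- Reduce(`+`, lapply(sites, function(s)
    colSums(sweep(s$response, 2L, ysum / n)^2)))
  good <- sst > 0
  fit_sites <- if (all(good)) sites else
    lapply(sites, function(s)
      site_dataset(s$site_id, s$design, s$response[, good, drop = FALSE]))

  fit <- switch(method,
    pooled = pooled_fit(fit_sites),
    single_shot = single_shot_fit(fit_sites, log = log),
    drne = drne_fit(fit_sites, log = log),
    multi_shot = multi_shot_fit(fit_sites, cfg = cfg, log = log))

  d1 <- ncol(sites[[1L]]$design)
  covnames <- colnames(sites[[1L]]$design)
  expand <- function(x, nr = NULL) {
    if (is.null(nr)) { out <- rep(NaN, V); out[good] <- x; out }
    else { out <- matrix(NaN, nr, V, dimnames = list(covnames, NULL))
           out[, good] <- x; out }
  }
  tmat <- expand(as_weight_matrix(fit$t_values, d1, sum(good)), d1)
  pmat <- expand(as_weight_matrix(fit$p_values, d1, sum(good)), d1)
  structure(list(
    method = method, covariates = covnames,
    weights = expand(as_weight_matrix(fit$weights, d1, sum(good)), d1),
    t = tmat, p = pmat,
    signed_log_p = ifelse(is.nan(pmat), NaN, signed_log_p(tmat, pmat)),
    sse = expand(fit$sse), sst = expand(fit$sst),
    r_squared = expand(fit$r_squared),
    dof = fit$dof, iterations = fit$iterations, converged = fit$converged,
    geometry = geom), class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf("<stat_maps [%s]: %d voxels, covariates: %s>\n",
              x$method, length(x$sse),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' Extract one statistic from fitted maps as a 3-D grid
#'
#' @param maps A `stat_maps` object from [run_voxelwise()] whose input
#'   volumes carried mask geometry.
#' @param statistic One of "t", "p", "signed_log_p", "weights", "sse",
#'   "r_squared".
#' @param covariate Covariate name (required for per-covariate statistics).
#' @return A 3-D array with NaN at unmasked voxels.
#' @export
stat_grid <- function(maps, statistic, covariate = NULL) {
  stopifnot(inherits(maps, "stat_maps"))
  if (is.null(maps$geometry))
    stop("these maps were fitted from plain matrices and carry no grid")
  x <- maps[[statistic]]
  if (!is.null(dim(x))) {
    if (is.null(covariate)) stop("covariate required for ", statistic)
    x <- x[covariate, ]
  }
  unflatten(maps$geometry, x)
}

#' Write fitted statistic maps as NIfTI volumes
#'
#' Writes one volume per covariate for t, p and signed log-p, plus the SSE
#' and R-squared maps, in the input grid's affine.
#'
#' @param maps A `stat_maps` with grid geometry.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_stat_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "stat_maps"), !is.null(maps$geometry))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- maps$geometry$template
  paths <- character(0)
  emit <- function(grid, name) {
    p <- file.path(dir, paste0(maps$method, "_", name, ".nii.gz"))
    img <- if (is.null(ref)) RNifti::asNifti(grid)
           else RNifti::asNifti(grid, reference = ref)
    RNifti::writeNifti(img, p)
    paths[[length(paths) + 1L]] <<- p
  }
  for (cov in setdiff(maps$covariates, "intercept")) {
    emit(stat_grid(maps, "t", cov), paste0("t_", cov))
    emit(stat_grid(maps, "signed_log_p", cov), paste0("slogp_", cov))
  }
  emit(stat_grid(maps, "sse"), "sse")
  emit(stat_grid(maps, "r_squared"), "r2")
  invisible(paths)
}

#' Cross-method correlation table for a per-voxel statistic
#'
#' Computes the matrix of Pearson correlations, across voxels, of one
#' per-voxel statistic (SSE or R-squared) between fitted methods.
#'
#' @param maps Named list of `stat_maps` objects sharing a mask/voxel set.
#' @param statistic "sse" or "r_squared".
#' @return A symmetric correlation matrix with unit diagonal, one row/column
#'   per method.
#' @export
method_comparison_table <- function(maps, statistic = c("sse", "r_squared")) {
  statistic <- match.arg(statistic)
  stopifnot(length(maps) >= 1L)
  vals <- vapply(maps, function(m) m[[statistic]],
                 numeric(length(maps[[1L]][[statistic]])))
  keep <- rowSums(!is.finite(vals)) == 0
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 2L) stop("need at least 2 voxels to correlate")
  if (any(apply(vals, 2L, stats::sd) == 0))
    stop("undefined correlation: constant ", statistic, " vector")
  out <- stats::cor(vals)
  dimnames(out) <- list(names(maps), names(maps))
  out
}
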