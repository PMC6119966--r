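#' Read a covariate table from CSV
#'
#' Expects the header `id,age,diagnosis,gender,site` with diagnosis and
#' gender coded 0/1.
#'
#' @param path CSV path.
#' @return A data frame with those columns, types checked.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "diagnosis", "gender", "site")
  if (!all(need %in% names(tab)))
    stop("covariate CSV must carry columns ", paste(need, collapse = ","))
  if (!all(tab$diagnosis %in% c(0, 1)) || !all(tab$gender %in% c(0, 1)))
    stop("diagnosis and gender must be coded 0/1")
  tab[need]
}

#' Write fitted voxelwise results as CSV, one file per covariate
#'
#' Each covariate file holds one row per voxel with the fitted weight, t, p
#' and signed log-p; a `model.csv` holds the per-voxel SSE, SST and
#' R-squared.
#'
#' @param maps A `stat_maps` object from [run_voxelwise()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_fit_csv <- function(maps, dir) {
  stopifnot(inherits(maps, "stat_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cov in maps$covariates) {
    p <- file.path(dir, paste0(maps$method, "_", cov, ".csv"))
    utils::write.csv(data.frame(voxel = seq_along(maps$sse),
                                weight = maps$weights[cov, ],
                                t = maps$t[cov, ], p = maps$p[cov, ],
                                signed_log_p = maps$signed_log_p[cov, ]),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(maps$method, "_model.csv"))
  utils::write.csv(data.frame(voxel = seq_along(maps$sse), sse = maps$sse,
                              sst = maps$sst, r_squared = maps$r_squared),
                   p, row.names = FALSE)
  invisible(c(paths, p))
}

#' Read a site/aggregator topology from a YAML config
#'
#' The YAML file lists `sites` (labels, in chain order) and optionally
#' `aggregator` (defaults to the last site, which is itself an ordinary site
#' rather than a privileged master).
#'
#' @param path YAML path.
#' @return List with `sites` (character vector) and `aggregator` (scalar).
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites) || length(cfg$sites) < 1L)
    stop("network config must list at least one site")
  sites <- as.character(unlist(cfg$sites))
  agg <- if (!is.null(cfg$aggregator)) as.character(cfg$aggregator)
         else sites[length(sites)]
  if (!agg %in% sites) stop("aggregator must be one of the sites")
  list(sites = sites, aggregator = agg)
}

#' Write cluster centroids and window labels as CSV
#'
#' @param result A `ddfnc_result` from [run_ddfnc()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_ddfnc_csv <- function(result, dir) {
  stopifnot(inherits(result, "ddfnc_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cpath <- file.path(dir, "centroids.csv")
  utils::write.csv(result$model$centroids, cpath, row.names = FALSE)
  rows <- do.call(rbind, lapply(names(result$labels), function(site)
    do.call(rbind, lapply(seq_along(result$labels[[site]]), function(i)
      data.frame(site = site, subject = i,
                 window = seq_along(result$labels[[site]][[i]]),
                 state = result$labels[[site]][[i]])))))
  lpath <- file.path(dir, "labels.csv")
  utils::write.csv(rows, lpath, row.names = FALSE)
  invisible(c(cpath, lpath))
}
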