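#' Message log for simulated site/aggregator communication
#'
#' Every decentralized routine in the package threads a `message_log` through
#' its simulated rounds of communication. Each record stores the round number,
#' sender, receiver and the exact number of real scalars in the payload, so
#' that the communication cost of a completed run can be audited against the
#' closed-form bandwidth predictions ([predicted_dgica_bandwidth()],
#' [predicted_dkmeans_bandwidth()]).
#'
#' The log has reference semantics (it is an environment), so a single log can
#' be filled in by nested protocol stages.
#'
#' @return An empty object of class `message_log`.
#' @seealso [log_message()], [audit_log()], [write_message_log()]
#' @export
message_log <- function() {
  e <- new.env(parent = emptyenv())
  e$round <- integer()
  e$sender <- character()
  e$receiver <- character()
  e$scalar_count <- integer()
  class(e) <- "message_log"
  e
}

#' Record one simulated message
#'
#' @param log A [message_log()].
#' @param round Non-negative integer round index; rounds must be non-decreasing.
#' @param sender,receiver Site labels.
#' @param scalar_count Exact number of real scalars in the payload.
#' @return The log, invisibly.
#' @export
log_message <- function(log, round, sender, receiver, scalar_count) {
  stopifnot(inherits(log, "message_log"), round >= 0, scalar_count >= 0)
  n <- length(log$round)
  if (n > 0L && round < log$round[n])
    stop("rounds must be non-decreasing")
  log$round[n + 1L] <- as.integer(round)
  log$sender[n + 1L] <- as.character(sender)
  log$receiver[n + 1L] <- as.character(receiver)
  log$scalar_count[n + 1L] <- as.integer(scalar_count)
  invisible(log)
}

#' @export
print.message_log <- function(x, ...) {
  cat(sprintf("<message_log: %d messages, %d scalars total>\n",
              length(x$round), sum(x$scalar_count)))
  invisible(x)
}

#' Message log as a data frame
#'
#' @param x A [message_log()].
#' @param ... Unused.
#' @return A data frame with columns round, sender, receiver, scalar_count.
#' @export
as.data.frame.message_log <- function(x, ...) {
  data.frame(round = x$round, sender = x$sender, receiver = x$receiver,
             scalar_count = x$scalar_count, stringsAsFactors = FALSE)
}

#' Serialize a message log to CSV
#'
#' @param log A [message_log()].
#' @param path Output CSV path (columns round,sender,receiver,scalar_count).
#' @export
write_message_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Problem dimensions entering the bandwidth formulas
#'
#' Collects the integer dimensions that determine the communication cost of
#' the decentralized pipelines: feature/voxel dimension `d`, component count
#' `r`, site count `s`, cluster count `k`, iteration count `J`, per-site
#' instance counts `M_i`, per-site exemplar counts `E_i` and window length `w`.
#' Only the fields a given formula needs have to be supplied.
#'
#' @param d,r,s,k,J,M_i,E_i,w Positive integers (J may be 0 for a run with no
#'   iterations).
#' @return An object of class `bandwidth_model`.
#' @export
bandwidth_model <- function(d = 1L, r = 1L, s = 1L, k = 1L, J = 1L,
                            M_i = 1L, E_i = 1L, w = 1L) {
  m <- list(d = d, r = r, s = s, k = k, J = J, M_i = M_i, E_i = E_i, w = w)
  if (any(vapply(m[c("d", "r", "s", "k", "M_i", "E_i", "w")], min, 0) < 1) ||
      J < 0 || any(vapply(m, function(v) any(v != round(v)), FALSE)))
    stop("bandwidth_model fields must be positive integers (J >= 0)")
  structure(m, class = "bandwidth_model")
}

#' Predicted communication cost of decentralized group ICA
#'
#' A non-aggregator site passes one `d x r` eigenvector matrix along the
#' peer-to-peer chain and receives the `r x r` unmixing matrix, for a total of
#' `d*r + r^2` scalars. The aggregator receives one `d x r` matrix and
#' broadcasts the unmixing matrix to each of the `s` sites, for
#' `d*r + r^2*s` scalars.
#'
#' @param model A [bandwidth_model()] with fields `d`, `r` (and `s` for the
#'   aggregator).
#' @param is_aggregator Logical flag.
#' @return Predicted total scalar count.
#' @export
predicted_dgica_bandwidth <- function(model, is_aggregator = FALSE) {
  stopifnot(inherits(model, "bandwidth_model"))
  if (is_aggregator) model$d * model$r + model$r^2 * model$s
  else model$d * model$r + model$r^2
}

#' Predicted communication cost of decentralized K-Means
#'
#' Per iteration every site uploads `k` centroids, each a full `r x r`
#' connectivity matrix (`r^2` scalars), so a site's total upload over `J`
#' iterations is `r^2*k*J`; the aggregator's rebroadcast to `s` sites totals
#' `r^2*k*J*s`. When centroids are stored as strict upper-triangle vectors the
#' per-centroid payload is `r*(r-1)/2` instead of `r^2`; [audit_log()] checks
#' logged runs against that vectorized figure.
#'
#' @param model A [bandwidth_model()] with fields `r`, `k`, `J` (and `s` for
#'   the aggregator).
#' @param is_aggregator Logical flag.
#' @return Predicted total scalar count.
#' @export
predicted_dkmeans_bandwidth <- function(model, is_aggregator = FALSE) {
  stopifnot(inherits(model, "bandwidth_model"))
  base <- model$r^2 * model$k * model$J
  if (is_aggregator) base * model$s else base
}

#' Audit a logged protocol run against a bandwidth prediction
#'
#' Sums the scalar counts of the messages a given site took part in and
#' compares the total with a closed-form prediction. `direction` selects
#' whether messages sent by the site, received by it, or both are counted
#' (the per-site totals quoted by the bandwidth formulas count both
#' directions).
#'
#' @param log A populated [message_log()].
#' @param predicted Predicted scalar count.
#' @param role_filter Site label whose traffic is audited.
#' @param direction One of "both", "sent", "received".
#' @return TRUE iff the summed scalar count equals `predicted` exactly.
#' @export
audit_log <- function(log, predicted, role_filter,
                      direction = c("both", "sent", "received")) {
  stopifnot(inherits(log, "message_log"))
  direction <- match.arg(direction)
  if (length(log$round) == 0L)
    stop("empty message log: no protocol run to audit")
  keep <- switch(direction,
    sent = log$sender == role_filter,
    received = log$receiver == role_filter,
    both = log$sender == role_filter | log$receiver == role_filter)
  sum(log$scalar_count[keep]) == predicted
}
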