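# Longitudinal container: one culture or simulation followed over sessions.

#' Bundle one culture's sessions for longitudinal analysis
#'
#' Collects, in session order, each day's functional network and
#' (optionally) burst annotation and per-node burst-local TE totals, and
#' validates that all sessions share one node universe and strictly
#' increasing day labels.
#'
#' @param days Integer vector of day labels (days in vitro or window
#'   indices), strictly increasing.
#' @param networks List of `functional_network` objects, one per day.
#' @param bursts Optional list of `burst_annotation` objects per day.
#' @param burst_local_in,burst_local_out Optional lists of named per-node
#'   burst-local TE totals (nats/spike) per day.
#' @param culture_id Label for the culture or simulation.
#' @return An object of class `longitudinal_set`.
#' @export
longitudinal_set <- function(days, networks, bursts = NULL,
                             burst_local_in = NULL, burst_local_out = NULL,
                             culture_id = "culture") {
  days <- as.integer(days)
  if (length(days) != length(networks)) {
    stop("one network per day is required")
  }
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  ids <- networks[[1]]$node_ids
  for (net in networks) {
    if (!identical(net$node_ids, ids)) {
      stop("all sessions must share an identical node universe")
    }
  }
  structure(
    list(culture_id = as.character(culture_id), days = days,
         networks = networks, bursts = bursts,
         burst_local_in = burst_local_in,
         burst_local_out = burst_local_out),
    class = "longitudinal_set"
  )
}

#' @export
print.longitudinal_set <- function(x, ...) {
  cat(sprintf("<longitudinal_set> %s: %d sessions (days %s), %d nodes\n",
              x$culture_id, length(x$days),
              paste(x$days, collapse = ", "),
              length(x$networks[[1]]$node_ids)))
  invisible(x)
}

#' Lock-in correlations over all session pairs of a culture
#'
#' For every earlier/later pair of sessions, computes the Spearman lock-in
#' correlation of the chosen statistic: `"edge"` (TE per ordered node
#' pair), `"out"`/`"in"` (per-node mean outgoing/incoming TE), or
#' `"role_ratio"` (outgoing share of burst-local TE, which requires the
#' burst-local totals). Session pairs failing the 10-significant-value
#' gate are reported with `NA` and flagged.
#'
#' @param lset A [longitudinal_set()].
#' @param statistic One of `"edge"`, `"out"`, `"in"`, `"role_ratio"`.
#' @param min_edges Significance-count gate per session (default 10).
#' @return A data.frame with columns `day_early`, `day_late`, `rho`, `p`,
#'   `n`, `gated` (TRUE where the pair was excluded by the gate).
#' @export
lockin_table <- function(lset, statistic = c("edge", "out", "in",
                                             "role_ratio"),
                         min_edges = 10L) {
  statistic <- match.arg(statistic)
  k <- length(lset$days)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      res <- tryCatch({
        if (statistic == "edge") {
          edge_lockin(lset$networks[[i]], lset$networks[[j]], min_edges)
        } else if (statistic %in% c("out", "in")) {
          node_flow_lockin(lset$networks[[i]], lset$networks[[j]],
                           direction = statistic, min_edges = min_edges)
        } else {
          if (is.null(lset$burst_local_in) || is.null(lset$burst_local_out)) {
            stop("role_ratio lock-in requires burst-local totals")
          }
          rr_i <- role_ratio(lset$burst_local_out[[i]],
                             lset$burst_local_in[[i]])
          rr_j <- role_ratio(lset$burst_local_out[[j]],
                             lset$burst_local_in[[j]])
          check_gate(lset$networks[[i]], min_edges)
          check_gate(lset$networks[[j]], min_edges)
          spearman_test(rr_i, rr_j)
        }
      }, infoflow_gated = function(e) NULL)
      gated <- is.null(res)
      rows[[length(rows) + 1]] <- data.frame(
        day_early = lset$days[i], day_late = lset$days[j],
        rho = if (gated) NA_real_ else res$rho,
        p = if (gated) NA_real_ else res$p,
        n = if (gated) NA_integer_ else res$n,
        gated = gated
      )
    }
  }
  do.call(rbind, rows)
}
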