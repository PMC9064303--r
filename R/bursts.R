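# Per-node and population burst detection on interspike-interval criteria,
# mean burst positions, and burst-local TE.

#' Burst detection parameters
#'
#' A node is deemed to enter a burst when the span from a spike back to its
#' k-th most recent predecessor drops below `alpha` seconds; the burst runs
#' until an interspike interval exceeding `a * alpha` is met. A population
#' burst opens when the number of simultaneously bursting nodes exceeds
#' `beta` and closes when it drops below `gamma` (`gamma < beta`).
#'
#' @param k Spike span count for burst onset.
#' @param alpha Onset span threshold in seconds, or `NULL` to derive it per
#'   node as half the node's mean interspike interval (`1 / (2 * rate)`),
#'   see [default_burst_params()].
#' @param a Burst-continuation multiplier (burst ends at an ISI > `a*alpha`).
#' @param beta Population burst opening threshold (bursting-node count).
#' @param gamma Population burst closing threshold.
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(k = 2L, alpha = NULL, a = 3, beta = 15L,
                         gamma = 10L) {
  stopifnot(k >= 1, a >= 1, is.null(alpha) || alpha > 0)
  if (gamma >= beta) stop("gamma must be smaller than beta")
  structure(list(k = as.integer(k), alpha = alpha, a = a,
                 beta = as.integer(beta), gamma = as.integer(gamma)),
            class = "burst_params")
}

#' Default burst parameters for culture or model recordings
#'
#' Two presets: `"culture"` (k = 2, a = 3, beta = 15, gamma = 10), suited to
#' the irregular population bursts of multi-electrode array recordings, and
#' `"model"` (k = 1, a = 1.5, beta = 2, gamma = 1) for the far more
#' stereotyped bursts of the simulated networks. In both, `alpha` is left
#' `NULL` and resolved per node as half the node's mean interspike interval;
#' pass `per_node_alpha = FALSE` to use the recording-wide mean rate
#' instead.
#'
#' @param rec A [recording] (used only when `per_node_alpha = FALSE`).
#' @param preset `"culture"` or `"model"`.
#' @param per_node_alpha Resolve `alpha` per node (default) or globally.
#' @return A `burst_params` object; when `per_node_alpha = FALSE` its
#'   `alpha` is the global value, otherwise `alpha` stays `NULL`.
#' @export
default_burst_params <- function(rec, preset = c("culture", "model"),
                                 per_node_alpha = TRUE) {
  preset <- match.arg(preset)
  p <- switch(preset,
    culture = burst_params(k = 2L, a = 3, beta = 15L, gamma = 10L),
    model = burst_params(k = 1L, a = 1.5, beta = 2L, gamma = 1L)
  )
  if (!per_node_alpha) {
    rate <- mean(spike_counts(rec)) / (rec$t_end - rec$t_start)
    if (rate <= 0) stop("zero mean spike rate")
    p$alpha <- 1 / (2 * rate)
  }
  p
}

resolve_alpha <- function(train, p) {
  if (!is.null(p$alpha)) return(p$alpha)
  rate <- length(train$times) / (train$t_end - train$t_start)
  if (rate <= 0) return(NA_real_)  # silent node: skipped for burst detection
  1 / (2 * rate)
}

#' Detect bursts of a single node
#'
#' Sequential scan over the spikes of one train: at spike `s_i`, if
#' `s_i - s_(i-k) < alpha` and no burst is open, a burst starts at
#' `s_(i-k)`. An open burst continues until an interspike interval greater
#' than `a * alpha` is met, at which point it ends at the earlier spike of
#' that interval; a burst still open at the end of the train closes at the
#' last spike.
#'
#' @param train A [spike_train].
#' @param p A [burst_params]; a `NULL` `alpha` is resolved from the train's
#'   mean rate.
#' @return Two-column matrix of burst `[start, end]` times (zero rows when
#'   the node never bursts).
#' @export
detect_node_bursts <- function(train, p = burst_params()) {
  s <- train$times
  alpha <- resolve_alpha(train, p)
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (is.na(alpha) || length(s) <= p$k) return(empty)
  k <- p$k
  starts <- numeric(0)
  ends <- numeric(0)
  in_burst <- FALSE
  cur_start <- NA_real_
  for (i in seq.int(2L, length(s))) {
    if (in_burst && s[i] - s[i - 1L] > p$a * alpha) {
      starts <- c(starts, cur_start)
      ends <- c(ends, s[i - 1L])
      in_burst <- FALSE
    }
    if (!in_burst && i > k && s[i] - s[i - k] < alpha) {
      in_burst <- TRUE
      cur_start <- s[i - k]
    }
  }
  if (in_burst) {
    starts <- c(starts, cur_start)
    ends <- c(ends, s[length(s)])
  }
  cbind(start = starts, end = ends)
}

#' Detect population bursts from per-node burst intervals
#'
#' Event-driven sweep over the count of simultaneously bursting nodes: a
#' population burst opens at the event where the count first exceeds
#' `beta` while closed, and closes at the event where the count drops below
#' `gamma`. A burst still open at the end of the sweep closes at the last
#' interval endpoint.
#'
#' @param node_bursts Named list of per-node burst interval matrices, as
#'   returned by [detect_node_bursts()].
#' @param p A [burst_params] (`gamma < beta` enforced).
#' @return Two-column matrix of population burst `[start, end]` times.
#' @export
detect_population_bursts <- function(node_bursts, p = burst_params()) {
  if (p$gamma >= p$beta) stop("gamma must be smaller than beta")
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  all_iv <- do.call(rbind, node_bursts)
  if (is.null(all_iv) || nrow(all_iv) == 0) return(empty)
  ev_t <- c(all_iv[, 1], all_iv[, 2])
  ev_d <- c(rep(1L, nrow(all_iv)), rep(-1L, nrow(all_iv)))
  o <- order(ev_t, -ev_d)  # starts before ends at identical times
  ev_t <- ev_t[o]
  ev_d <- ev_d[o]
  count <- 0L
  open <- FALSE
  starts <- numeric(0)
  ends <- numeric(0)
  for (i in seq_along(ev_t)) {
    count <- count + ev_d[i]
    if (!open && count > p$beta) {
      open <- TRUE
      starts <- c(starts, ev_t[i])
    } else if (open && count < p$gamma) {
      open <- FALSE
      ends <- c(ends, ev_t[i])
    }
  }
  if (open) ends <- c(ends, ev_t[length(ev_t)])
  cbind(start = starts, end = ends)
}

#' Mean burst position of each node
#'
#' Within each population burst, participating nodes (those spiking inside
#' the burst interval) are ranked by the time of their first in-burst spike
#' (1 = earliest; ties broken by node label). A node's mean position
#' averages its ranks over the bursts it participates in; nodes absent from
#' every burst get `NA`.
#'
#' @param rec A [recording].
#' @param population_bursts Two-column interval matrix from
#'   [detect_population_bursts()].
#' @return Named numeric vector of mean positions (NA where undefined).
#' @export
mean_burst_positions <- function(rec, population_bursts) {
  if (is.null(population_bursts) || nrow(population_bursts) == 0) {
    stop("need at least one population burst")
  }
  ids <- names(rec$trains)
  acc <- stats::setNames(numeric(length(ids)), ids)
  cnt <- stats::setNames(integer(length(ids)), ids)
  for (b in seq_len(nrow(population_bursts))) {
    t0 <- population_bursts[b, 1]
    t1 <- population_bursts[b, 2]
    first <- vapply(rec$trains, function(tr) {
      i <- findInterval(t0, tr$times, left.open = TRUE) + 1L
      if (i <= length(tr$times) && tr$times[i] <= t1) tr$times[i]
      else NA_real_
    }, numeric(1))
    part <- which(!is.na(first))
    if (length(part) == 0) next
    ord <- part[order(first[part], ids[part])]
    acc[ord] <- acc[ord] + seq_along(ord)
    cnt[ord] <- cnt[ord] + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Full burst annotation of a recording
#'
#' Runs per-node burst detection, population burst detection, and mean
#' burst positions in one call.
#'
#' @param rec A [recording].
#' @param p A [burst_params], e.g. from [default_burst_params()].
#' @return An object of class `burst_annotation`: `node_bursts` (named
#'   list), `population_bursts` (interval matrix), `mean_position` (named
#'   vector, all `NA` when there are no population bursts), `params`.
#' @export
detect_bursts <- function(rec, p = default_burst_params(rec)) {
  node_bursts <- lapply(rec$trains, detect_node_bursts, p = p)
  pop <- detect_population_bursts(node_bursts, p)
  mp <- if (nrow(pop) > 0) mean_burst_positions(rec, pop) else
    stats::setNames(rep(NA_real_, length(rec$trains)), names(rec$trains))
  structure(list(node_bursts = node_bursts, population_bursts = pop,
                 mean_position = mp, params = p),
            class = "burst_annotation")
}

#' @export
print.burst_annotation <- function(x, ...) {
  nb <- sum(vapply(x$node_bursts, nrow, integer(1)))
  cat(sprintf("<burst_annotation> %d node bursts, %d population bursts\n",
              nb, nrow(x$population_bursts)))
  invisible(x)
}

#' Burst-local transfer entropy
#'
#' Averages the per-target-spike local TE contributions over the target
#' spikes that fall inside population bursts, giving a burst-local TE in
#' nats per spike. When the bursts cover the whole window this reduces to
#' `te_rate * tau / N_X`.
#'
#' @param te_result A `te_result` from [estimate_te()] (local contributions
#'   aligned to its usable target spikes).
#' @param population_bursts Interval matrix from
#'   [detect_population_bursts()], or a `burst_annotation`.
#' @return List with `te_per_spike` (nats/spike, `NA` when no target spike
#'   falls in a burst) and `n_burst_spikes`.
#' @export
burst_local_te <- function(te_result, population_bursts) {
  if (inherits(population_bursts, "burst_annotation")) {
    population_bursts <- population_bursts$population_bursts
  }
  inb <- in_intervals(te_result$spike_times, population_bursts)
  n <- sum(inb)
  if (n == 0) {
    return(list(te_per_spike = NA_real_, n_burst_spikes = 0L))
  }
  list(te_per_spike = sum(te_result$local_contributions[inb]) / n,
       n_burst_spikes = n)
}

#' Surrogate significance of a burst-local TE value
#'
#' Re-uses the surrogate machinery of [te_significance()]: each surrogate's
#' per-spike local contributions are averaged over the same in-burst target
#' spikes, and the observed burst-local TE is compared against the Gaussian
#' fit of the surrogate burst-local values ([te_p_value()]).
#'
#' @param te_result A `te_result` from
#'   `te_significance(..., keep_surrogate_locals = TRUE)`.
#' @param population_bursts Interval matrix or `burst_annotation`.
#' @return List with `te_per_spike`, `n_burst_spikes`, `surrogates`,
#'   `p_value` (all `NA`/empty when no target spike falls inside a burst).
#' @export
burst_local_significance <- function(te_result, population_bursts) {
  if (is.null(te_result$surrogate_locals)) {
    stop("te_result lacks surrogate locals; rerun te_significance() with ",
         "keep_surrogate_locals = TRUE")
  }
  if (inherits(population_bursts, "burst_annotation")) {
    population_bursts <- population_bursts$population_bursts
  }
  obs <- burst_local_te(te_result, population_bursts)
  if (obs$n_burst_spikes == 0) {
    return(c(obs, list(surrogates = numeric(0), p_value = NA_real_)))
  }
  inb <- in_intervals(te_result$spike_times, population_bursts)
  surr <- vapply(te_result$surrogate_locals,
                 function(l) mean(l[inb]), numeric(1))
  c(obs, list(surrogates = surr,
              p_value = te_p_value(obs$te_per_spike, surr)))
}

# TRUE for times lying inside any [start, end] interval.
in_intervals <- function(times, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(times)))
  }
  out <- rep(FALSE, length(times))
  for (b in seq_len(nrow(intervals))) {
    out <- out | (times >= intervals[b, 1] & times <= intervals[b, 2])
  }
  out
}
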