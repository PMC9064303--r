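# Consensus embedding-length selection.
#
# One embedding length is chosen for all nodes (and all sessions) so that
# estimator bias is matched across targets: the target length l_X maximises
# the average bias-corrected AIS across nodes, and the source length l_Y
# then maximises the average surrogate-mean-subtracted TE across ordered
# pairs. Candidate lengths are increased by one for as long as each step
# yields a statistically significant increase in the mean statistic
# (paired two-sided t-test across units at level `alpha`; Welch's unpaired
# test available as a fallback).

step_test <- function(curr, prev, paired, alpha) {
  ok <- is.finite(curr) & is.finite(prev)
  tt <- if (paired) {
    stats::t.test(curr[ok], prev[ok], paired = TRUE)
  } else {
    stats::t.test(curr[ok], prev[ok])
  }
  list(p = tt$p.value,
       accept = mean(curr[ok]) > mean(prev[ok]) && tt$p.value < alpha)
}

selection_loop <- function(stat_at, l_max, alpha, paired, label) {
  prev <- stat_at(1L)
  trace <- data.frame(l = 1L, mean = mean(prev, na.rm = TRUE),
                      sd = stats::sd(prev, na.rm = TRUE),
                      p_vs_previous = NA_real_, accepted = TRUE)
  chosen <- 1L
  if (l_max < 2L) {
    warning(label, ": l_max reached before the first increase was tested")
    return(list(l = chosen, trace = trace))
  }
  for (l in seq.int(2L, l_max)) {
    curr <- stat_at(l)
    st <- step_test(curr, prev, paired, alpha)
    trace <- rbind(trace, data.frame(l = l, mean = mean(curr, na.rm = TRUE),
                                     sd = stats::sd(curr, na.rm = TRUE),
                                     p_vs_previous = st$p,
                                     accepted = st$accept))
    if (!st$accept) {
      return(list(l = chosen, trace = trace))
    }
    chosen <- l
    prev <- curr
    if (l == l_max) {
      warning(label, ": still significant at l_max = ", l_max)
    }
  }
  list(l = chosen, trace = trace)
}

#' Select the consensus target embedding length
#'
#' Increases the target history length from 1, keeping each step for which
#' the mean bias-corrected AIS across all nodes increases significantly
#' (paired two-sided t-test at level `alpha`), and returns the last accepted
#' length together with a trace (candidate length, mean, SD, p-value,
#' accepted flag).
#'
#' @param rec A jittered [recording] with at least two nodes.
#' @param params An [estimator_params].
#' @param l_max Largest candidate length.
#' @param alpha Step-acceptance significance level.
#' @param paired Use a paired t-test across nodes (default) or Welch's
#'   unpaired test.
#' @param n_surrogates AIS bias-correction surrogates per node and length.
#' @return List with `l_x` and `trace`.
#' @export
select_target_embedding <- function(rec, params = estimator_params(),
                                    l_max = 8L, alpha = 0.05,
                                    paired = TRUE, n_surrogates = 20L) {
  if (length(rec$trains) < 2) stop("need at least two nodes")
  stat_at <- function(l) {
    vapply(rec$trains, function(tr) {
      tryCatch(estimate_ais(tr, l_x = l, params = params,
                            n_surrogates = n_surrogates)$ais_rate,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out <- selection_loop(stat_at, l_max, alpha, paired, "select_target_embedding")
  list(l_x = out$l, trace = out$trace)
}

#' Select the consensus source embedding length
#'
#' With the target length fixed, increases the source history length from 1
#' for as long as the mean surrogate-mean-subtracted TE across all ordered
#' node pairs increases significantly (same stopping rule as
#' [select_target_embedding()]).
#'
#' @inheritParams select_target_embedding
#' @param l_x The (already selected) target embedding length.
#' @param n_surrogates Surrogates per pair used for the bias subtraction.
#' @return List with `l_y` and `trace`.
#' @export
select_source_embedding <- function(rec, l_x = 4L,
                                    params = estimator_params(),
                                    l_max = 8L, alpha = 0.05,
                                    paired = TRUE, n_surrogates = 20L) {
  ids <- names(rec$trains)
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  stat_at <- function(l) {
    p2 <- params
    p2$l_x <- as.integer(l_x)
    p2$l_y <- as.integer(l)
    p2$n_surrogates <- as.integer(n_surrogates)
    vapply(seq_len(nrow(pairs)), function(i) {
      tryCatch({
        r <- te_significance(rec$trains[[pairs$source[i]]],
                             rec$trains[[pairs$target[i]]], p2)
        r$te_rate - r$surrogate_mean
      }, error = function(e) NA_real_)
    }, numeric(1))
  }
  out <- selection_loop(stat_at, l_max, alpha, paired, "select_source_embedding")
  list(l_y = out$l, trace = out$trace)
}
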