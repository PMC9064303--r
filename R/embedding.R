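#' History embedding at one observation time
#'
#' Represents the past of a point process at time `t` by its `l` most recent
#' inter-event intervals: the first component is the time back from `t` to
#' the most recent spike strictly before `t`, and components `j >= 2` are the
#' successive preceding interspike intervals. The components sum to the span
#' from `t` back to the `l`-th most recent spike.
#'
#' @param times Sorted spike times of the process (seconds), or a
#'   [spike_train].
#' @param t Observation time in seconds.
#' @param l Number of interval components.
#' @return Numeric vector of length `l`, or an error of class
#'   `infoflow_insufficient_history` when fewer than `l` spikes precede `t`.
#' @export
build_embedding <- function(times, t, l) {
  if (inherits(times, "spike_train")) times <- times$times
  if (l < 1) stop("embedding length l must be >= 1")
  i0 <- findInterval(t, times, left.open = TRUE)
  if (i0 < l) {
    stop(structure(
      class = c("infoflow_insufficient_history", "error", "condition"),
      list(message = sprintf("insufficient history: %d spike(s) before t, need %d",
                             i0, l),
           call = sys.call(-1))
    ))
  }
  idx <- seq.int(i0, i0 - l + 1L)
  c(t, times[idx[-l]]) - times[idx]
}

# Vectorised embedding construction: one row per observation time.
# `obs` must each have at least l prior spikes (checked).
embedding_matrix <- function(times, obs, l) {
  i0 <- findInterval(obs, times, left.open = TRUE)
  if (any(i0 < l)) stop("insufficient history at some observation points")
  cols <- lapply(seq_len(l), function(j) {
    prev <- if (j == 1) obs else times[i0 - j + 2L]
    prev - times[i0 - j + 1L]
  })
  do.call(cbind, cols)
}

#' Estimator parameters
#'
#' Bundles the tunable parameters of the continuous-time transfer entropy /
#' active information storage estimator. The defaults are the consensus
#' values used throughout the package: target history of 4 interspike
#' intervals, source history of 2, k = 10 neighbours for both the divergence
#' estimates and the surrogate resampling, 50 random history samples per
#' target spike, a 10x spike-anchored pool for surrogate generation, and 100
#' surrogates per pair.
#'
#' @param l_x Target embedding length (interspike intervals).
#' @param l_y Source embedding length.
#' @param k_global Nearest-neighbour count for the divergence estimates.
#' @param k_perm Neighbour count used when resampling source histories for
#'   surrogates.
#' @param n_u_factor Random history samples per usable target spike
#'   (`N_U = n_u_factor * N_X`).
#' @param n_u_surr_factor Spike-anchored history samples per usable target
#'   spike in the surrogate pool.
#' @param n_surrogates Number of surrogate estimates per pair.
#' @param anchor_noise Half-width (seconds) of the uniform noise added to
#'   spike-anchored sample points (default 0.24 s).
#' @param seed Optional integer master seed; sub-seeds are derived per
#'   (source, target, purpose) tuple so results are order-independent.
#' @return An object of class `estimator_params`.
#' @export
estimator_params <- function(l_x = 4L, l_y = 2L, k_global = 10L,
                             k_perm = 10L, n_u_factor = 50,
                             n_u_surr_factor = 10, n_surrogates = 100L,
                             anchor_noise = 0.24, seed = NULL) {
  stopifnot(l_x >= 1, l_y >= 1, k_global >= 1, k_perm >= 1,
            n_u_factor >= 1, n_u_surr_factor >= 1, n_surrogates >= 1,
            anchor_noise >= 0)
  structure(
    list(l_x = as.integer(l_x), l_y = as.integer(l_y),
         k_global = as.integer(k_global), k_perm = as.integer(k_perm),
         n_u_factor = n_u_factor, n_u_surr_factor = n_u_surr_factor,
         n_surrogates = as.integer(n_surrogates),
         anchor_noise = anchor_noise, seed = seed),
    class = "estimator_params"
  )
}

#' Sample observation points with full histories
#'
#' Draws observation times at which history embeddings can be evaluated,
#' i.e. times preceded by at least `l_x` target spikes and (when a source is
#' supplied) `l_y` source spikes. In `"uniform"` mode times are i.i.d.
#' uniform over the observation window, redrawn until they have full
#' histories. In `"spike_anchored"` mode times are placed at existing target
#' spikes, cycled as often as needed, plus Uniform(-`anchor_noise`,
#' +`anchor_noise`) offsets; this concentrates samples in dense bursting
#' regions that uniform placement would under-sample.
#'
#' @param target A [spike_train] (the target process).
#' @param n Number of points to return.
#' @param mode `"uniform"` or `"spike_anchored"`.
#' @param anchor_noise Half-width in seconds of the anchoring noise.
#' @param source Optional [spike_train]; when given, returned times also have
#'   `l_y` prior source spikes.
#' @param l_x,l_y History length requirements.
#' @param seed Optional seed.
#' @return Numeric vector of `n` observation times.
#' @export
sample_observation_points <- function(target, n,
                                      mode = c("uniform", "spike_anchored"),
                                      anchor_noise = 0.24, source = NULL,
                                      l_x = 4L, l_y = 2L, seed = NULL) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  xs <- target$times
  lo <- if (length(xs) >= l_x) xs[l_x] else Inf
  if (!is.null(source)) {
    ys <- source$times
    lo <- max(lo, if (length(ys) >= l_y) ys[l_y] else Inf)
  }
  if (!is.finite(lo) || lo >= target$t_end) {
    stop("train(s) too short to satisfy the history requirement")
  }
  with_seed(seed, {
    if (mode == "uniform") {
      # uniform on the window, conditioned on having full histories ==
      # uniform on the feasible sub-interval
      stats::runif(n, lo, target$t_end)
    } else {
      out <- numeric(0)
      anchors <- xs[xs > lo - anchor_noise]
      if (length(anchors) == 0) stop("no feasible anchor spikes")
      guard <- 0L
      while (length(out) < n) {
        m <- n - length(out)
        anc <- rep_len(anchors, m)
        cand <- anc + stats::runif(m, -anchor_noise, anchor_noise)
        cand <- cand[cand > lo & cand < target$t_end]
        out <- c(out, cand)
        guard <- guard + 1L
        if (guard > 1000L) stop("failed to place spike-anchored samples")
      }
      out[seq_len(n)]
    }
  })
}
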