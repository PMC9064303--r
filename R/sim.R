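# Synthetic developing-network generator: Izhikevich neurons with all-to-all
# excitatory pulse coupling under additive STDP. With small initial weights
# each neuron fires tonically and near-independently; spike-timing
# correlations induced by the coupling let STDP potentiate causal synapses,
# and the network develops into periodic network-wide population bursts.

#' Simulation configuration
#'
#' Parameters of the developing Izhikevich/STDP network. Defaults define the
#' reference developmental protocol used throughout the package: 59
#' all-excitatory neurons (no inhibitory population, no conduction delays),
#' weights bounded by `g_max = 10`, additive STDP magnitudes
#' `A+ = A- = 4e-4` with 20 ms exponential windows, and a 550 s run over
#' which the network passes from tonic firing to periodic population
#' bursting. The tonic drive current is calibrated so that an uncoupled
#' neuron fires at roughly 100 Hz, i.e. about 5e3 spikes per 50 s
#' analysis window; per-neuron drives are spread uniformly around that value
#' so tonic rates differ across the population, and a small white-noise
#' current desynchronises the tonic phase.
#'
#' @param n_neurons Number of neurons.
#' @param duration Simulated time in seconds.
#' @param dt Integration step in seconds (forward integration with the
#'   classic two-half-step membrane update).
#' @param drive_current Mean tonic input current.
#' @param drive_spread Half-width of the uniform per-neuron spread of the
#'   drive current.
#' @param noise_sd Standard deviation of the per-step white-noise current.
#' @param g_max Upper weight bound (weights clipped to `[0, g_max]`).
#' @param a_plus,a_minus STDP potentiation/depression magnitudes.
#' @param stdp_tau_plus,stdp_tau_minus STDP window time constants (s).
#' @param synaptic_tau Exponential synaptic-current time constant in
#'   seconds. With the default `0`, a presynaptic spike kicks every
#'   target's membrane potential by the synaptic weight instantaneously;
#'   positive values spread the same total depolarisation over this
#'   timescale. The default keeps the causal pre/post timing sharp enough
#'   for the STDP feedback to complete the developmental transition within
#'   the 550 s protocol at the small plasticity magnitudes used.
#' @param izh_a,izh_b,izh_c,izh_d Izhikevich membrane constants (tonic
#'   regular-spiking values by default).
#' @param w_init_max Initial weights are i.i.d. Uniform(0, `w_init_max`).
#' @param inhibitory_fraction Proportion of inhibitory neurons; only 0 is
#'   supported (the developmental protocol is all-excitatory).
#' @param synaptic_delay Conduction delay in seconds; only 0 is supported.
#' @param snapshot_times Times (s) at which to record the weight matrix.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 59L, duration = 550, dt = 5e-4,
                       drive_current = 37.5, drive_spread = 0.7,
                       noise_sd = 1.5, g_max = 10,
                       a_plus = 4e-4, a_minus = 4e-4,
                       stdp_tau_plus = 0.02, stdp_tau_minus = 0.02,
                       synaptic_tau = 0,
                       izh_a = 0.02, izh_b = 0.2, izh_c = -65, izh_d = 6,
                       w_init_max = 0.6, inhibitory_fraction = 0,
                       synaptic_delay = 0,
                       snapshot_times = numeric(0), seed = 1L) {
  if (inhibitory_fraction != 0) {
    stop("only an all-excitatory population (inhibitory_fraction = 0) is supported")
  }
  if (synaptic_delay != 0) stop("only zero synaptic delay is supported")
  stopifnot(n_neurons >= 2, duration > 0, dt > 0, g_max >= 0,
            a_plus >= 0, a_minus >= 0, w_init_max >= 0)
  structure(
    list(n_neurons = as.integer(n_neurons), duration = duration, dt = dt,
         drive_current = drive_current, drive_spread = drive_spread,
         noise_sd = noise_sd, g_max = g_max,
         a_plus = a_plus, a_minus = a_minus,
         stdp_tau_plus = stdp_tau_plus, stdp_tau_minus = stdp_tau_minus,
         synaptic_tau = synaptic_tau,
         izh_a = izh_a, izh_b = izh_b, izh_c = izh_c, izh_d = izh_d,
         w_init_max = w_init_max, snapshot_times = snapshot_times,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a developing Izhikevich/STDP network
#'
#' Integrates the network defined by a [sim_config()]: Izhikevich membrane
#' dynamics per neuron, all-to-all excitatory coupling without
#' self-connections (a presynaptic spike kicks every other neuron's
#' membrane potential by the synaptic weight), and additive
#' exponential-window STDP with weights clipped to `[0, g_max]` at every
#' update. Deterministic given the seed.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_output`: `recording` (a [recording]
#'   spanning the full duration, nodes `"1" ... "n"`), `snapshots` (list of
#'   weight matrices at `config$snapshot_times`, `[j, i]` = weight j -> i),
#'   and `config`.
#' @export
simulate_network <- function(config = sim_config()) {
  n <- config$n_neurons
  drives <- with_seed(derive_seed(config$seed, "drives"), {
    stats::runif(n, config$drive_current - config$drive_spread,
                 config$drive_current + config$drive_spread)
  })
  w0 <- with_seed(derive_seed(config$seed, "weights"), {
    m <- matrix(stats::runif(n * n, 0, config$w_init_max), n, n)
    diag(m) <- 0
    m
  })
  raw <- cpp_simulate_izhikevich(
    n, config$duration, config$dt, drives, config$noise_sd, w0,
    config$g_max, config$a_plus, config$a_minus,
    config$stdp_tau_plus, config$stdp_tau_minus, config$synaptic_tau,
    config$izh_a, config$izh_b, config$izh_c, config$izh_d,
    as.numeric(config$snapshot_times),
    derive_seed(config$seed, "dynamics")
  )
  ids <- as.character(seq_len(n))
  trains <- lapply(ids, function(id) {
    keep <- raw$ids == as.integer(id)
    tms <- raw$times[keep]
    tms <- tms[tms < config$duration]
    spike_train(tms, 0, config$duration, node_id = id)
  })
  rec <- recording(trains, culture_id = "stdp-model", day = 0L)
  structure(list(recording = rec, snapshots = raw$snapshots,
                 snapshot_times = config$snapshot_times, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d neurons over %g s, %d spikes\n",
              x$config$n_neurons, x$config$duration,
              sum(spike_counts(x$recording))))
  invisible(x)
}

#' Extract developmental analysis windows from a simulation
#'
#' Cuts the full-duration recording into per-window recordings with
#' window-local observation bounds. The default windows (200-250 s,
#' 400-450 s, 500-550 s) sample the early near-tonic stage, the emergence
#' of population bursting, and the late strongly bursting stage of the
#' developmental protocol. Jitter is applied downstream exactly as for
#' measured recordings.
#'
#' @param sim_out A `sim_output` (or a full-duration [recording]).
#' @param windows Named list of `c(start, end)` windows in seconds.
#' @return Named list of [recording] objects; each carries its window index
#'   (1-based, in list order) as `day` so longitudinal helpers can order
#'   them.
#' @export
extract_windows <- function(sim_out,
                            windows = list(early = c(200, 250),
                                           mid = c(400, 450),
                                           late = c(500, 550))) {
  rec <- if (inherits(sim_out, "sim_output")) sim_out$recording else sim_out
  out <- vector("list", length(windows))
  names(out) <- names(windows)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[1] < rec$t_start || w[2] > rec$t_end) {
      stop("window outside the simulated duration")
    }
    r <- crop_recording(rec, w[1], w[2])
    r$day <- i
    out[[i]] <- r
  }
  out
}
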