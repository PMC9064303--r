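# Fixture builders and independent brute-force oracles used across tests.

mk_poisson <- function(rate, tau, id = "p", seed = 1) {
  set.seed(seed)
  n <- stats::rpois(1, rate * tau)
  spike_train(sort(stats::runif(n, 0, tau)), 0, tau, node_id = id)
}

mk_gamma_renewal <- function(rate, shape, tau, id = "g", seed = 1) {
  set.seed(seed)
  isi <- stats::rgamma(ceiling(rate * tau * 2) + 50,
                       shape = shape, rate = shape * rate)
  t <- cumsum(isi)
  spike_train(t[t < tau], 0, tau, node_id = id)
}

# deterministic relay: target repeats the source delayed by `delay`
mk_relay_pair <- function(rate, tau, delay = 0.005, seed = 1) {
  src <- mk_poisson(rate, tau, "src", seed)
  src <- spike_train(src$times[src$times + delay < tau], 0, tau, "src")
  tgt <- spike_train(src$times + delay, 0, tau, "tgt")
  jitter_spike_times(recording(list(src, tgt)), seed = seed + 7919)
}

# ISIs alternating short/long: spiking with two-interval history structure
mk_alternating <- function(n_isi, short = 0.1, long = 0.5, id = "a",
                           seed = 1) {
  set.seed(seed)
  isi <- rep(c(short, long), length.out = n_isi) *
    exp(stats::rnorm(n_isi, 0, 0.05))
  t <- cumsum(isi)
  spike_train(t, 0, max(t) + short, node_id = id)
}

poisson_recording <- function(n_nodes, rate, tau, seed = 1,
                              culture_id = "pois", day = 1L) {
  trains <- lapply(seq_len(n_nodes), function(i) {
    mk_poisson(rate, tau, id = as.character(i), seed = seed * 1000 + i)
  })
  recording(trains, culture_id = culture_id, day = day)
}

# brute-force kth-NN max-norm distance (no spatial index)
brute_kth_dist <- function(Q, R, k, self = FALSE) {
  vapply(seq_len(nrow(Q)), function(i) {
    d <- apply(abs(sweep(R, 2, Q[i, ], "-")), 1, max)
    if (self) d <- d[-i]
    sort(d)[k]
  }, numeric(1))
}

# brute-force divergence matching the documented formula
brute_knn_divergence <- function(P, Q, k) {
  d <- ncol(P)
  rho <- brute_kth_dist(P, P, k, self = TRUE)
  nu <- brute_kth_dist(P, Q, k, self = FALSE)
  mean(d * (log(nu) - log(rho))) + log(nrow(Q) / (nrow(P) - 1))
}

# brute-force Spearman rho via explicit average ranks and the Pearson sum
# formula, independent of the package implementation
brute_spearman_rho <- function(x, y) {
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  a <- rk(x)
  b <- rk(y)
  num <- sum((a - mean(a)) * (b - mean(b)))
  num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# exhaustive permutation list by a different algorithm than the package's
brute_permutations <- function(n) {
  if (n == 1) return(list(1L))
  unlist(lapply(brute_permutations(n - 1L), function(p) {
    lapply(seq_len(n), function(k) append(p, n, after = k - 1L))
  }), recursive = FALSE)
}

make_te_table <- function(ids, te, p) {
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$te_rate <- te
  pairs$p_value <- p
  pairs
}
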