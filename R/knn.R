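#' k-nearest-neighbour divergence estimate
#'
#' Kozachenko-Leonenko-style estimate of the Kullback-Leibler divergence
#' D(P || Q) from samples, using k-th nearest-neighbour distances under the
#' maximum norm:
#' \deqn{\hat D(P\|Q) = \frac{d}{N_P}\sum_i \ln\frac{\nu_i}{\rho_i}
#'       + \ln\frac{N_Q}{N_P - 1},}
#' where \eqn{\rho_i} is the distance from sample `i` of P to its k-th
#' nearest neighbour within P (excluding itself) and \eqn{\nu_i} its distance
#' to the k-th nearest neighbour within Q. This is the building block behind
#' the transfer entropy and active information storage rate estimators,
#' where P collects history embeddings observed at target spikes and Q
#' history embeddings at randomly placed times.
#'
#' @param samples_p,samples_q Numeric matrices with one sample per row and a
#'   common number of columns.
#' @param k Neighbour count; must satisfy `k < nrow(samples_p)` and
#'   `k <= nrow(samples_q)`.
#' @param details If `TRUE`, also return the per-sample log ratios.
#' @return The divergence estimate in nats, or (with `details = TRUE`) a list
#'   with elements `divergence` and `log_ratios`.
#' @export
knn_divergence <- function(samples_p, samples_q, k = 10L, details = FALSE) {
  samples_p <- as.matrix(samples_p)
  samples_q <- as.matrix(samples_q)
  d <- ncol(samples_p)
  if (ncol(samples_q) != d) stop("sample sets must share a dimension")
  n_p <- nrow(samples_p)
  n_q <- nrow(samples_q)
  if (n_p <= k) stop("need more than k samples in samples_p")
  if (n_q < k) stop("need at least k samples in samples_q")
  rho <- cpp_kth_nn_dist(samples_p, samples_p, as.integer(k), TRUE)
  nu <- cpp_kth_nn_dist(samples_p, samples_q, as.integer(k), FALSE)
  if (any(rho == 0) || any(nu == 0)) {
    stop("exact neighbour ties (zero distances); jitter the spike times first")
  }
  log_ratios <- d * (log(nu) - log(rho))
  est <- mean(log_ratios) + log(n_q / (n_p - 1))
  if (!details) return(est)
  list(divergence = est, log_ratios = log_ratios, n_p = n_p, n_q = n_q, d = d)
}
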