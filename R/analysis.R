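# Longitudinal statistics: lock-in correlations, computational-role
# analyses, mean-TE comparisons, and significance-count summary tests.

#' Spearman rank correlation with two-sided p-value
#'
#' Spearman's rho computed as the Pearson correlation of average ranks
#' (ties get the mean rank). The two-sided p-value is exact (full
#' permutation enumeration) for n <= 7 and otherwise uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @return List with `rho`, `p`, `n`. `rho` is `NA` when either input is
#'   constant.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho_of <- function(a, b) {
    am <- a - mean(a)
    bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  rho <- rho_of(rx, ry)
  if (n <= 7) {
    perms <- permutations_of(n)
    stats_perm <- apply(perms, 1, function(idx) rho_of(rx, ry[idx]))
    p <- mean(abs(stats_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    left <- if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos < n) sub[, pos:(n - 1L), drop = FALSE]
    cbind(left, matrix(n, nrow(sub), 1L), right)
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  out
}

off_diagonal <- function(m) m[row(m) != col(m)]

check_gate <- function(net, min_edges) {
  nz <- sum(off_diagonal(net$te) > 0, na.rm = TRUE)
  if (nz < min_edges) {
    stop(structure(
      class = c("infoflow_gated", "error", "condition"),
      list(message = sprintf(
        "network has %d significant TE values, below the %d-value gate",
        nz, min_edges), call = sys.call(-1))
    ))
  }
  invisible(nz)
}

#' Edge-level lock-in correlation between two functional networks
#'
#' Spearman correlation, over all ordered node pairs, between the TE values
#' of an earlier and a later functional network of the same culture
#' (non-significant entries count as zero). Networks with fewer than
#' `min_edges` significant values are gated out with an error of class
#' `infoflow_gated`, since correlations over nearly all-zero matrices carry
#' no information.
#'
#' @param early,late `functional_network` objects over the same node set.
#' @param min_edges Significance-count gate (default 10).
#' @return List with `rho`, `p`, `n`.
#' @export
edge_lockin <- function(early, late, min_edges = 10L) {
  if (!identical(early$node_ids, late$node_ids)) {
    stop("networks must share an identical node universe")
  }
  check_gate(early, min_edges)
  check_gate(late, min_edges)
  spearman_test(off_diagonal(early$te), off_diagonal(late$te))
}

#' Node-level flow lock-in correlation
#'
#' Per node, averages the outgoing (or incoming) TE over all counterpart
#' nodes (zeros included for non-significant pairs), then correlates the
#' node values of an earlier and a later network (Spearman). Same gating as
#' [edge_lockin()].
#'
#' @inheritParams edge_lockin
#' @param direction `"out"` (mean TE from each node) or `"in"` (mean TE
#'   into each node).
#' @return List with `rho`, `p`, `n`.
#' @export
node_flow_lockin <- function(early, late, direction = c("out", "in"),
                             min_edges = 10L) {
  direction <- match.arg(direction)
  if (!identical(early$node_ids, late$node_ids)) {
    stop("networks must share an identical node universe")
  }
  check_gate(early, min_edges)
  check_gate(late, min_edges)
  spearman_test(node_mean_flow(early, direction),
                node_mean_flow(late, direction))
}

#' Mean outgoing or incoming TE per node
#'
#' @param net A `functional_network`.
#' @param direction `"out"` or `"in"`.
#' @return Named vector of per-node means over the `n - 1` counterparts.
#' @export
node_mean_flow <- function(net, direction = c("out", "in")) {
  direction <- match.arg(direction)
  m <- net$te
  if (direction == "out") {
    rowMeans(m, na.rm = TRUE)
  } else {
    colMeans(m, na.rm = TRUE)
  }
}

#' Outgoing share of a node's burst-local information flow
#'
#' `out / (in + out)` per node: 1 for a pure transmitter, 0 for a pure
#' receiver, 0.5 for a balanced mediator. Undefined (`NA`) when a node has
#' no burst-local flow at all.
#'
#' @param burst_local_out,burst_local_in Named per-node totals (nats/spike,
#'   non-significant values zeroed).
#' @return Named vector of proportions in `[0, 1]` (NA where undefined).
#' @export
role_ratio <- function(burst_local_out, burst_local_in) {
  tot <- burst_local_out + burst_local_in
  out <- burst_local_out / tot
  out[!is.finite(out)] <- NA_real_
  out
}

#' Correlation between burst position and burst-local flow
#'
#' Spearman correlation across nodes between mean burst position (1 =
#' earliest) and a per-node burst-local TE total (inward or outward).
#' Nodes with undefined positions or totals are dropped; an optional
#' position filter restricts to late-bursting nodes (e.g.
#' `position_min = 20`).
#'
#' @param mean_position Named per-node mean burst positions
#'   ([mean_burst_positions()]).
#' @param burst_local_total Named per-node totals (nats/spike).
#' @param position_min Optional: keep only nodes with position strictly
#'   greater than this.
#' @return List with `rho`, `p`, `n`.
#' @export
position_role_correlation <- function(mean_position, burst_local_total,
                                      position_min = NULL) {
  ids <- intersect(names(mean_position), names(burst_local_total))
  pos <- mean_position[ids]
  tot <- burst_local_total[ids]
  if (!is.null(position_min)) {
    keep <- !is.na(pos) & pos > position_min
    pos <- pos[keep]
    tot <- tot[keep]
  }
  spearman_test(pos, tot)
}

#' Two-sided Student's t-test for a difference in mean TE
#'
#' Compares the full TE vectors (zeros included for non-significant pairs)
#' of two recordings with a pooled-variance two-sample t-test. Bonferroni
#' correction over recording pairs is the caller's responsibility.
#'
#' @param te_a,te_b Numeric TE vectors.
#' @return List with `t`, `p`, `df`.
#' @export
mean_te_comparison <- function(te_a, te_b) {
  te_a <- te_a[is.finite(te_a)]
  te_b <- te_b[is.finite(te_b)]
  if (stats::sd(te_a) == 0 && stats::sd(te_b) == 0) {
    if (mean(te_a) == mean(te_b)) {
      return(list(t = 0, p = 1, df = length(te_a) + length(te_b) - 2))
    }
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(te_a, te_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Binomial test on a count of significant results
#'
#' Given a family of p-values, counts how many fall below `alpha` and
#' reports the upper-tail probability of that count under the null that the
#' p-values are Uniform(0, 1): `P(Binomial(n, alpha) >= k)`. The star
#' annotation follows the summary-table convention: `*` when the (caller-
#' Bonferroni-corrected) tail probability is below 0.05, `**` below 0.001.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Per-test significance level (default 0.05).
#' @param bonferroni Multiplicative correction factor applied to the tail
#'   probability before annotation (default 1).
#' @return List with `k_significant`, `n`, `tail_probability`, `star`.
#' @export
significance_count_test <- function(p_values, alpha = 0.05,
                                    bonferroni = 1) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  n <- length(p_values)
  k <- sum(p_values < alpha)
  tail <- stats::pbinom(k - 1, n, alpha, lower.tail = FALSE)
  adj <- min(1, tail * bonferroni)
  star <- if (adj < 0.001) "**" else if (adj < 0.05) "*" else ""
  list(k_significant = k, n = n, tail_probability = tail, star = star)
}

#' Summary statistics of a recording's TE values
#'
#' Mean TE over all pairs (zeros included), significant-edge count,
#' quartiles of the significant values after excluding points more than 10
#' standard deviations above the mean (a plotting-only exclusion: the mean
#' TE itself keeps every value), and, when at least `min_nonzero`
#' significant values exist, a Gaussian-kernel density of the significant
#' values with bandwidth equal to 10% of their range.
#'
#' @param net A `functional_network`, or a numeric vector of TE values with
#'   zeros for non-significant pairs.
#' @param min_nonzero Minimum significant values for the density estimate.
#' @return List with `mean_te`, `n_significant`, `quartiles`, `density`
#'   (a `stats::density` object or `NULL`).
#' @export
summarize_te <- function(net, min_nonzero = 10L) {
  vals <- if (inherits(net, "functional_network")) {
    off_diagonal(net$te)
  } else {
    as.numeric(net)
  }
  vals <- vals[is.finite(vals)]
  nz <- vals[vals > 0]
  quartiles <- if (length(nz) > 0) {
    keep <- nz <= mean(nz) + 10 * stats::sd(nz) | length(nz) < 2
    stats::quantile(nz[keep], c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  dens <- NULL
  if (length(nz) >= min_nonzero) {
    bw <- 0.1 * diff(range(nz))
    if (bw > 0) dens <- stats::density(nz, bw = bw)
  }
  list(mean_te = mean(vals), n_significant = length(nz),
       quartiles = quartiles, density = dens)
}
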