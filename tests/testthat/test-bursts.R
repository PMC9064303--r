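test_that("single-node burst detection matches hand-traced scans", {
  p <- burst_params(k = 2, alpha = 0.05, a = 3, beta = 15, gamma = 10)
  tr <- spike_train(c(0.001, 0.011, 0.021, 0.031, 1.0), 0, 2, "a")
  b <- detect_node_bursts(tr, p)
  expect_equal(nrow(b), 1)
  expect_equal(unname(b[1, ]), c(0.001, 0.031))

  tr2 <- spike_train(c(0.001, 0.011, 0.021, 0.201, 0.211, 0.221), 0, 1, "a")
  b2 <- detect_node_bursts(tr2, p)
  expect_equal(nrow(b2), 2)
  expect_equal(unname(b2[1, ]), c(0.001, 0.021))
  expect_equal(unname(b2[2, ]), c(0.201, 0.221))

  # all ISIs above alpha: no bursts
  slow <- spike_train(seq(0.1, 1.9, by = 0.2), 0, 2, "a")
  expect_equal(nrow(detect_node_bursts(slow, p)), 0)
})

test_that("every node burst spans at least k+1 spikes", {
  p <- burst_params(k = 2, alpha = NULL, a = 3, beta = 3, gamma = 2)
  for (s in 1:5) {
    tr <- mk_gamma_renewal(20, 0.4, 30, seed = s)  # bursty irregular train
    b <- detect_node_bursts(tr, p)
    if (nrow(b) == 0) next
    for (i in seq_len(nrow(b))) {
      n_in <- sum(tr$times >= b[i, 1] & tr$times <= b[i, 2])
      expect_gte(n_in, p$k + 1)
    }
  }
})

test_that("population bursts follow the event-sweep oracle", {
  p <- burst_params(k = 2, alpha = 0.05, a = 3, beta = 15, gamma = 10)
  # 20 nodes with staggered bursts: count crosses 15 going up at t = 1.0
  # (16th interval opens) and drops below 10 at t = 2.0
  starts <- seq(0.25, 1.2, length.out = 20)
  ends <- c(seq(1.5, 2.0, length.out = 11), seq(2.6, 3, length.out = 9))
  nb <- lapply(seq_len(20), function(i) {
    cbind(start = starts[i], end = ends[i])
  })
  pb <- detect_population_bursts(nb, p)
  expect_equal(nrow(pb), 1)
  expect_equal(unname(pb[1, 1]), starts[16])
  expect_equal(unname(pb[1, 2]), ends[11])  # 11th end drops the count to 9
})

test_that("a sub-gamma dip splits population bursts in two", {
  p <- burst_params(k = 1, alpha = 0.05, a = 3, beta = 2, gamma = 1)
  nb <- list(
    a = cbind(start = c(0, 10), end = c(4, 14)),
    b = cbind(start = c(0.5, 10.5), end = c(4.5, 14.5)),
    c = cbind(start = c(1, 11), end = c(5, 15))
  )
  pb <- detect_population_bursts(nb, p)
  expect_equal(nrow(pb), 2)
  expect_error(detect_population_bursts(nb, burst_params(k = 1, alpha = 1,
                                                         beta = 2,
                                                         gamma = 2)),
               "gamma")
})

test_that("population bursts are invariant to node relabelling", {
  set.seed(8)
  nb <- lapply(1:12, function(i) {
    s <- sort(runif(3, 0, 20))
    cbind(start = s, end = s + 0.8)
  })
  names(nb) <- as.character(1:12)
  p <- burst_params(k = 1, alpha = 0.1, a = 2, beta = 5, gamma = 3)
  pb1 <- detect_population_bursts(nb, p)
  pb2 <- detect_population_bursts(rev(nb), p)
  expect_equal(pb1, pb2)
})

test_that("burst parameter presets match their documented values", {
  rec <- poisson_recording(3, 10, 10, seed = 2)
  cult <- default_burst_params(rec, "culture")
  expect_equal(c(cult$k, cult$a, cult$beta, cult$gamma), c(2, 3, 15, 10))
  mod <- default_burst_params(rec, "model")
  expect_equal(c(mod$k, mod$a, mod$beta, mod$gamma), c(1, 1.5, 2, 1))
  # per-node alpha: half the mean interspike interval at 10 Hz is 0.05 s
  tr <- spike_train(seq(0.05, 9.95, length.out = 100), 0, 10, "r")
  expect_equal(infoflow:::resolve_alpha(tr, mod), 1 / (2 * 10))
})

test_that("mean burst positions rank first in-burst spikes", {
  trains <- list(
    spike_train(c(1.0, 10.2), 0, 20, "A"),
    spike_train(c(1.1, 10.1), 0, 20, "B"),
    spike_train(c(1.2, 10.0), 0, 20, "C")
  )
  rec <- recording(trains)
  pb <- cbind(start = c(0.9, 9.9), end = c(1.5, 10.5))
  mp <- mean_burst_positions(rec, pb)
  expect_equal(unname(mp[c("A", "B", "C")]), c(2, 2, 2))
  mp1 <- mean_burst_positions(rec, pb[1, , drop = FALSE])
  expect_equal(unname(mp1[c("A", "B", "C")]), c(1, 2, 3))
  # node absent from one burst averages over the other only
  rec2 <- recording(list(trains[[1]], trains[[2]],
                         spike_train(c(1.2), 0, 20, "C")))
  mp2 <- mean_burst_positions(rec2, pb)
  expect_equal(unname(mp2["C"]), 3)
  expect_equal(unname(mp2["A"]), (1 + 2) / 2)
})

test_that("burst-local TE averages in-burst local contributions", {
  fake <- structure(
    list(local_contributions = c(2, 0, 0, 4),
         spike_times = c(1, 2, 3, 4), te_rate = 6 / 10,
         n_target_spikes = 4L, tau = 10),
    class = "te_result")
  pb <- cbind(start = c(0.5, 3.5), end = c(1.5, 4.5))
  bl <- burst_local_te(fake, pb)
  expect_equal(bl$te_per_spike, 3)
  expect_equal(bl$n_burst_spikes, 2L)
  none <- burst_local_te(fake, pb[0, , drop = FALSE])
  expect_true(is.na(none$te_per_spike))
})

test_that("whole-window bursts recover the TE rate identity", {
  a <- mk_poisson(1, 100, "a", 51)
  b <- mk_poisson(1.5, 100, "b", 52)
  r <- estimate_te(a, b, estimator_params(seed = 5))
  bl <- burst_local_te(r, cbind(start = 0, end = 100))
  expect_equal(bl$te_per_spike * r$n_target_spikes / 100, r$te_rate,
               tolerance = 1e-9)
})

test_that("burst-local surrogate significance reuses surrogate locals", {
  rec <- mk_relay_pair(2, 80, delay = 0.005, seed = 6)
  p <- estimator_params(n_surrogates = 15, seed = 13)
  res <- te_significance(rec$trains[["src"]], rec$trains[["tgt"]], p,
                         keep_surrogate_locals = TRUE)
  pb <- cbind(start = 0, end = 40)
  bls <- burst_local_significance(res, pb)
  expect_length(bls$surrogates, 15)
  expect_lt(bls$p_value, 0.01)
  plain <- te_significance(rec$trains[["src"]], rec$trains[["tgt"]], p)
  expect_error(burst_local_significance(plain, pb), "keep_surrogate_locals")
})
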