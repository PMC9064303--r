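test_that("Gaussian surrogate p-values follow the closed form", {
  surr <- rnorm(100)
  m <- mean(surr)
  s <- sd(surr)
  expect_equal(te_p_value(m, surr), 0.5)
  expect_equal(te_p_value(m + 5 * s, surr), pnorm(-5), tolerance = 1e-12)
  expect_gt(te_p_value(m - s, surr), 0.5)
  expect_error(te_p_value(1, rep(2, 10)), "sd = 0")
})

test_that("surrogates preserve the target and crush a strong coupling", {
  rec <- mk_relay_pair(1, 150, delay = 0.005, seed = 3)
  p <- estimator_params(n_surrogates = 40, seed = 11)
  res <- te_significance(rec$trains[["src"]], rec$trains[["tgt"]], p)
  expect_length(res$surrogates, 40)
  # observed TE exceeds every surrogate for this deterministic relay
  expect_true(all(res$te_rate > res$surrogates))
  expect_lt(res$p_value, 1e-10)
  # the target spike count is untouched by construction
  expect_equal(res$n_target_spikes,
               sum(seq_along(rec$trains[["tgt"]]$times) > p$l_x &
                   findInterval(rec$trains[["tgt"]]$times,
                                rec$trains[["src"]]$times,
                                left.open = TRUE) >= p$l_y))
})

test_that("independent pairs give unremarkable p-values", {
  a <- mk_poisson(1, 150, "a", 41)
  b <- mk_poisson(1, 150, "b", 42)
  res <- te_significance(a, b, estimator_params(n_surrogates = 40, seed = 4))
  expect_gt(res$p_value, 1e-4)
  expect_lt(abs(res$te_rate - res$surrogate_mean), 4 * res$surrogate_sd)
})

test_that("the history-resample surrogate method runs and is conservative", {
  rec <- mk_relay_pair(1, 120, delay = 0.005, seed = 5)
  p <- estimator_params(n_surrogates = 10, seed = 12)
  res <- te_significance(rec$trains[["src"]], rec$trains[["tgt"]], p,
                         method = "history_resample")
  expect_true(all(res$te_rate > res$surrogates))
})

test_that("functional networks apply the Bonferroni threshold exactly", {
  ids <- as.character(1:59)
  n_tests <- 59 * 58
  expect_equal(n_tests, 3422)
  tab <- make_te_table(ids, te = rep(1, n_tests), p = rep(0.5, n_tests))
  # plant two significant pairs, one exactly at threshold (not significant)
  thr <- 0.01 / n_tests
  tab$p_value[1] <- thr / 2
  tab$p_value[2] <- thr
  net <- build_functional_network(tab, alpha_family = 0.01)
  expect_equal(net$n_tests, 3422)
  expect_equal(net$threshold, 0.01 / 3422)
  expect_equal(signif(net$threshold, 2), 2.9e-6)
  expect_equal(net$n_significant, 1L)
  expect_equal(sum(net$te > 0, na.rm = TRUE), 1L)
  expect_true(all(is.na(diag(net$te))))
})

test_that("an all-null recording yields an all-zero, zero-density network", {
  ids <- c("a", "b", "c")
  tab <- make_te_table(ids, te = runif(6), p = runif(6, 0.2, 1))
  net <- build_functional_network(tab, alpha_family = 0.01)
  expect_equal(net$n_significant, 0L)
  expect_equal(net$density, 0)
  expect_true(all(net$te[row(net$te) != col(net$te)] == 0))
})

test_that("missing pairs are rejected", {
  ids <- c("a", "b", "c")
  tab <- make_te_table(ids, te = runif(6), p = runif(6))
  expect_error(build_functional_network(tab[-2, ]), "missing")
})

test_that("network construction is deterministic in its inputs", {
  ids <- c("a", "b", "c", "d")
  set.seed(1)
  tab <- make_te_table(ids, te = runif(12), p = runif(12, 0, 0.2))
  n1 <- build_functional_network(tab, 0.05)
  n2 <- build_functional_network(tab[sample(12), ], 0.05)
  expect_identical(n1$te, n2$te)
  expect_identical(n1$n_significant, n2$n_significant)
})
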