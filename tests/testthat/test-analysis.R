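test_that("Spearman rho equals the brute-force rank formula", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5 * x
    if (rep %% 3 == 0) x[1:3] <- x[4]  # inject ties
    got <- spearman_test(x, y)
    expect_equal(got$rho, brute_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(got$rho, unname(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-values match enumeration for small n", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  got <- spearman_test(x, y)
  perms <- brute_permutations(6)
  ref <- mean(vapply(perms, function(idx) {
    abs(brute_spearman_rho(x, y[idx]))
  }, numeric(1)) >= abs(brute_spearman_rho(x, y)) - 1e-12)
  expect_equal(got$p, ref, tolerance = 1e-12)
  # monotone data is maximally correlated with minimal exact p
  perfect <- spearman_test(1:6, 2 * (1:6))
  expect_equal(perfect$rho, 1)
  expect_equal(perfect$p, 2 / factorial(6), tolerance = 1e-12)
})

test_that("degenerate inputs give NA correlations", {
  expect_true(is.na(spearman_test(rep(1, 10), rnorm(10))$rho))
  expect_true(is.na(spearman_test(1:2, 2:1)$rho))
})

test_that("edge lock-in is 1 for identical and -1 for reversed networks", {
  ids <- letters[1:6]
  set.seed(21)
  te_vals <- c(runif(12), rep(0, 18))[sample(30)]
  p_vals <- ifelse(te_vals > 0, 1e-9, 0.9)
  tab <- make_te_table(ids, te_vals, p_vals)
  net <- build_functional_network(tab, alpha_family = 0.5)
  expect_gte(net$n_significant, 10)
  same <- edge_lockin(net, net)
  expect_equal(same$rho, 1)
  # rank reversal across all off-diagonal entries
  tab2 <- tab
  tab2$te_rate <- max(te_vals) + 1 - tab$te_rate
  tab2$p_value <- 1e-9
  net2 <- build_functional_network(tab2, alpha_family = 0.5)
  expect_equal(edge_lockin(net, net2)$rho,
               brute_spearman_rho(tab$te_rate, tab2$te_rate))
})

test_that("networks below the 10-edge gate are excluded", {
  ids <- letters[1:5]
  tab <- make_te_table(ids, te = c(rep(1, 5), rep(0, 15)),
                       p = c(rep(1e-9, 5), rep(0.9, 15)))
  sparse <- build_functional_network(tab, alpha_family = 0.5)
  expect_error(edge_lockin(sparse, sparse), class = "infoflow_gated")
})

test_that("node flow lock-in averages flows with zeros included", {
  ids <- c("a", "b", "c", "d")
  tab <- make_te_table(ids, te = 0, p = 1)
  tab$te_rate[tab$source == "a"] <- c(3, 6, 9)
  tab$p_value[tab$source == "a"] <- 1e-9
  net <- build_functional_network(tab, alpha_family = 0.5)
  out_means <- node_mean_flow(net, "out")
  expect_equal(unname(out_means["a"]), mean(c(3, 6, 9)))
  expect_equal(unname(out_means["b"]), 0)
  in_means <- node_mean_flow(net, "in")
  expect_equal(sum(in_means > 0), 3)
  # symmetric matrices have equal in and out means
  sym <- net
  m <- matrix(runif(16), 4, 4, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2
  diag(m) <- NA
  sym$te <- m
  expect_equal(node_mean_flow(sym, "out"), node_mean_flow(sym, "in"))
})

test_that("role ratios classify transmitters, receivers, mediators", {
  out <- c(t = 2, r = 0, m = 1, silent = 0)
  inn <- c(t = 0, r = 3, m = 1, silent = 0)
  rr <- role_ratio(out, inn)
  expect_equal(unname(rr[c("t", "r", "m")]), c(1, 0, 0.5))
  expect_true(is.na(rr["silent"]))
})

test_that("position-role correlations respect filters and oracles", {
  pos <- stats::setNames(1:10, letters[1:10])
  tot <- stats::setNames(exp(seq(0.1, 1, length.out = 10)), letters[1:10])
  expect_equal(position_role_correlation(pos, tot)$rho, 1)
  set.seed(22)
  tot2 <- stats::setNames(rnorm(10), letters[1:10])
  got <- position_role_correlation(pos, tot2)
  expect_equal(got$rho, brute_spearman_rho(pos, tot2), tolerance = 1e-12)
  filt <- position_role_correlation(pos, tot2, position_min = 5)
  expect_equal(filt$n, 5)
  expect_equal(filt$rho, brute_spearman_rho(pos[6:10], tot2[6:10]),
               tolerance = 1e-12)
})

test_that("mean TE comparisons reproduce the closed-form t-test", {
  a <- c(1, 2, 3)
  b <- c(2, 4, 6, 8)
  got <- mean_te_comparison(a, b)
  # hand computation: pooled two-sample t
  sp2 <- (2 * var(a) + 3 * var(b)) / 5
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), 5), tolerance = 1e-12)
  expect_equal(mean_te_comparison(a, a)$p, 1)
  set.seed(23)
  big <- mean_te_comparison(rnorm(1000), rnorm(1000, 1))
  expect_lt(big$p, 1e-10)
  expect_error(mean_te_comparison(rep(1, 5), rep(2, 5)), "variance")
})

test_that("significance counts use the binomial upper tail", {
  all7 <- significance_count_test(rep(0.01, 7), alpha = 0.05)
  expect_equal(all7$tail_probability, 0.05^7, tolerance = 1e-12)
  expect_equal(all7$star, "**")
  none <- significance_count_test(rep(0.5, 9))
  expect_equal(none$tail_probability, 1)
  expect_equal(none$star, "")
  one <- significance_count_test(c(0.01, rep(0.5, 8)))
  expect_equal(one$tail_probability, 1 - 0.95^9, tolerance = 1e-12)
  corrected <- significance_count_test(rep(0.01, 3), bonferroni = 100)
  expect_equal(corrected$k_significant, 3)
  expect_error(significance_count_test(numeric(0)), "empty")
  expect_error(significance_count_test(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("longitudinal sets validate sessions and tabulate lock-in", {
  ids <- letters[1:6]
  set.seed(25)
  mk_net <- function(te) {
    build_functional_network(
      make_te_table(ids, te, p = ifelse(te > 0, 1e-9, 0.9)),
      alpha_family = 0.5)
  }
  base <- runif(30)
  nets <- list(mk_net(base), mk_net(base * 2 + runif(30, 0, 0.1)),
               mk_net(rep(0, 30)))
  expect_error(longitudinal_set(c(1, 1, 2), nets), "strictly increasing")
  lset <- longitudinal_set(c(4, 10, 20), nets, culture_id = "demo")
  tab <- lockin_table(lset, "edge")
  expect_equal(nrow(tab), 3)
  first <- tab[tab$day_early == 4 & tab$day_late == 10, ]
  expect_gt(first$rho, 0.9)
  expect_false(first$gated)
  # the all-zero day fails the 10-significant-value gate
  expect_true(all(tab$gated[tab$day_late == 20]))
  out_tab <- lockin_table(lset, "out")
  expect_gt(out_tab$rho[1], 0.5)
})

test_that("TE summaries report means, counts, and outlier-robust quartiles", {
  vals <- c(1, 2, 3, 4, rep(0, 6))
  s <- summarize_te(vals)
  expect_equal(s$mean_te, 1)
  expect_equal(s$n_significant, 4)
  expect_equal(s$quartiles[2], median(1:4))
  # an extreme outlier is excluded from the quartiles but not the mean
  set.seed(24)
  nz <- rnorm(500, 5, 0.5)
  with_out <- c(nz, mean(nz) + 25 * sd(nz))
  s2 <- summarize_te(with_out)
  expect_equal(s2$mean_te, mean(with_out))
  keep <- with_out <= mean(with_out) + 10 * sd(with_out)
  expect_lt(sum(keep), length(with_out))  # the outlier really is dropped
  expect_equal(s2$quartiles,
               unname(quantile(with_out[keep], c(0.25, 0.5, 0.75))))
  # density uses a bandwidth of 10% of the nonzero range
  s3 <- summarize_te(c(runif(30, 1, 5), rep(0, 10)))
  expect_false(is.null(s3$density))
})
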