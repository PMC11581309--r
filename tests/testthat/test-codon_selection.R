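test_that("degeneracy classes match the enumeration oracle on all sense codons", {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  for (cod in sense) {
    expect_equal(classify_site_degeneracy(cod), brute_degeneracy(cod),
                 info = cod)
  }
  expect_equal(classify_site_degeneracy("GGG"), c(0L, 0L, 4L))
  expect_equal(classify_site_degeneracy("TTT")[3], 2L)
  expect_equal(classify_site_degeneracy("ATG"), c(0L, 0L, 0L))
  expect_error(classify_site_degeneracy("TAA"), "sense codon")
})

test_that("pathway averaging matches hand-worked cases", {
  r <- count_pair_differences("TTT", "GTA")
  expect_equal(r$sd, 0.5)
  expect_equal(r$nd, 1.5)
  expect_equal(r$n_pathways, 2L)  # the path through the TAA/TGA side is cut

  same <- count_pair_differences("AAA", "AAA")
  expect_equal(same$sd + same$nd, 0)
  expect_equal(sum(same$ts) + sum(same$tv), 0)
})

test_that("K2P distance reduces to Jukes-Cantor and handles saturation", {
  expect_equal(k2p_distance(0, 0, 100)$d, 0)
  expect_equal(k2p_distance(0, 0, 100)$variance, 0)
  for (p in c(0.03, 0.15, 0.3)) {
    d <- k2p_distance(p / 3, 2 * p / 3, 500)$d
    expect_equal(d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  }
  # closed-form check at P = 0.1, Q = 0.05
  d <- k2p_distance(0.1, 0.05, 100)$d
  expect_equal(d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)
  expect_true(k2p_distance(0.45, 0.2, 100)$saturated)
})

test_that("site counts conserve L0 + L2 + L4 = 3 n_codons on fuzzed pairs", {
  set.seed(31)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    a <- sample(sense, n, replace = TRUE)
    b <- sample(sense, n, replace = TRUE)
    cnt <- tryCatch(codon_pair_counts(a, b), error = function(e) NULL)
    if (is.null(cnt)) next
    expect_equal(cnt$L0 + cnt$L2 + cnt$L4, 3 * cnt$n_codons,
                 tolerance = 1e-9)
    expect_equal(cnt$N + cnt$S, 3 * cnt$n_codons, tolerance = 1e-9)
  }
})

test_that("identical sequences give zero divergence and undefined omega", {
  r <- estimate_dn_ds("ATGAAACCCGGG", "ATGAAACCCGGG")
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true("omega_undefined" %in% r$flags)
  expect_equal(z_test_selection(r, "neutral")$p_value, 1)
  expect_equal(r$fisher_p, 1)
})

test_that("omega recovery is unbiased within Monte Carlo error", {
  for (w in c(0.2, 1.0)) {
    o <- vapply(1:20, function(i) {
      s <- simulate_codon_pair(8000, kappa = 2, omega = w,
                               branch_length = 0.1, seed = 500 + i)
      estimate_dn_ds(s$a, s$b)$omega
    }, 0)
    expect_lt(abs(mean(o) - w), 0.05)
  }
})

test_that("degeneracy-class and modified NG estimates agree on simulations", {
  for (kap in c(1, 4)) {
    s <- simulate_codon_pair(8000, kappa = kap, omega = 0.3,
                             branch_length = 0.1, seed = 900 + kap)
    r <- estimate_dn_ds(s$a, s$b)
    expect_lt(abs(r$omega - r$ng$omega), 0.05)
  }
})

test_that("the Z-test tails behave as one- and two-sided normal tests", {
  fake <- list(dN = 0.1, dS = 0.1, var_dN = 1e-4, var_dS = 1e-4)
  expect_equal(z_test_selection(fake, "negative")$p_value, 0.5)
  expect_equal(z_test_selection(fake, "neutral")$p_value, 1)
  # p_negative strictly decreases as dS - dN grows
  ps <- vapply(seq(0, 0.05, by = 0.01), function(delta) {
    z_test_selection(list(dN = 0.1 - delta, dS = 0.1, var_dN = 1e-4,
                          var_dS = 1e-4), "negative")$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("Fisher exact test matches direct hypergeometric summation", {
  expect_equal(fisher_exact_selection(0, 0, 100, 50)$p_value, 1)
  # table [[1, 9], [3, 7]]: P(X <= 1) under the hypergeometric for the
  # 'greater' alternative on the first cell is P(X >= 1)
  p_pkg <- fisher_exact_selection(1, 3, 10, 10, "positive")$p_value
  p_direct <- sum(dhyper(1:4, 10, 10, 4))
  expect_equal(p_pkg, p_direct, tolerance = 1e-12)
  # symmetric table with equal margins: two-sided p = 1
  expect_equal(fisher_exact_selection(2, 2, 10, 10, "two.sided")$p_value, 1)
})

test_that("selection result prints its key quantities", {
  s <- simulate_codon_pair(500, kappa = 2, omega = 0.3,
                           branch_length = 0.1, seed = 3)
  r <- estimate_dn_ds(s$a, s$b)
  expect_output(print(r), "dN/dS")
  expect_output(print(r), "Z = ")
})
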