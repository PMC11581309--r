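test_that("the codon simulator is deterministic under a seed", {
  a <- simulate_codon_pair(200, kappa = 2, omega = 0.5, seed = 123)
  b <- simulate_codon_pair(200, kappa = 2, omega = 0.5, seed = 123)
  expect_identical(a$a, b$a)
  expect_identical(a$b, b$b)
  expect_identical(a$events_a, b$events_a)
})

test_that("zero branch length leaves descendants identical to the ancestor", {
  s <- simulate_codon_pair(100, branch_length = 0, seed = 1)
  expect_identical(s$a, s$ancestor)
  expect_identical(s$b, s$ancestor)
  expect_equal(nrow(s$events_a), 0)
})

test_that("omega = 0 forbids nonsynonymous events", {
  s <- simulate_codon_pair(2000, kappa = 2, omega = 0,
                           branch_length = 0.2, seed = 2)
  expect_equal(s$realized$nonsyn_a, 0)
  expect_equal(s$realized$nonsyn_b, 0)
  expect_gt(s$realized$syn_a, 0)
  # sequences translate identically to the ancestor
  aa <- function(x) paste(GC_TABLE[substring(x, seq(1, nchar(x), 3),
                                             seq(3, nchar(x), 3))],
                          collapse = "")
  expect_equal(aa(s$a), aa(s$ancestor))
})

test_that("replaying the event log reconstructs the descendant sequences", {
  s <- simulate_codon_pair(500, kappa = 2, omega = 0.5,
                           branch_length = 0.3, seed = 11)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  for (lineage in c("a", "b")) {
    state <- s$ancestor_idx
    ev <- s[[paste0("events_", lineage)]]
    ev <- ev[order(ev$time), ]
    for (i in seq_len(nrow(ev))) {
      expect_equal(state[ev$site[i]], ev$from[i])
      state[ev$site[i]] <- ev$to[i]
    }
    expect_identical(paste(sense[state], collapse = ""), s[[lineage]])
    # syn flags in the log agree with the genetic code
    expect_equal(ev$syn, GC_TABLE[sense[ev$from]] == GC_TABLE[sense[ev$to]],
                 ignore_attr = TRUE)
  }
})

test_that("estimated omega is monotone in the planted omega", {
  means <- vapply(c(0.1, 0.5, 1.0), function(w) {
    mean(vapply(1:5, function(i) {
      s <- simulate_codon_pair(3000, kappa = 2, omega = w,
                               branch_length = 0.1, seed = 7000 + i)
      estimate_dn_ds(s$a, s$b)$omega
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("planted expression targets of +/-1 and 0 behave as specified", {
  metric <- setNames(rnorm(17), paste0("g", 1:17))
  samples <- data.frame(sample = paste0("s", 1:500), class = "X")
  expr1 <- plant_expression_matrix(metric, samples[1, , drop = FALSE],
                                   rho = 1, seed = 1)
  expect_equal(cor(rank(metric), rank(expr1$mat[, 1])), 1)
  expect_true(all(expr1$mat >= 0))
  expr0 <- plant_expression_matrix(metric, samples, rho = 0, seed = 2)
  rhos <- apply(expr0$mat, 2, function(e) cor(rank(metric), rank(e)))
  # null sampling at n = 17 has sd(rho) = 0.25, so |rho| is centred near
  # 0.2; the signed mean must vanish
  expect_lt(abs(mean(rhos)), 0.05)
  expect_lt(abs(sd(rhos) - 0.25), 0.05)
  expect_error(plant_expression_matrix(metric, samples[1, , drop = FALSE],
                                       rho = 1.5), "invalid target")
})

test_that("gene fixtures plant per-domain rate orderings", {
  fx0 <- make_gene_fixture(n_species = 2, per_domain_rates = c(
    EC1 = 0, EC2 = 0, EC3 = 0, EC4 = 0, EC5 = 0, CD = 0), seed = 5)
  expect_true(all(fx0$cds == fx0$cds["human"]))

  rates <- c(EC1 = 0.004, EC2 = 0.004, EC3 = 0.004, EC4 = 0.004,
             EC5 = 0, CD = 0.004)
  for (seed in 1:3) {
    fx <- make_gene_fixture(n_species = 1, per_domain_rates = rates,
                            times = 40, seed = 50 + seed)
    aln <- pairwise_alignment(fx$proteins["human"],
                              fx$proteins["species_1"], "protein")
    d <- vapply(c("EC1", "EC2", "EC3", "EC4", "EC5", "CD"), function(seg) {
      p_distance(slice_domain(aln, fx$domain_map, seg, "a"))$d
    }, 0)
    expect_equal(unname(d["EC5"]), 0)
    expect_true(all(d[c("EC1", "EC2", "EC3", "EC4", "CD")] > 0))
  }
})

test_that("doubling planted rates roughly doubles small p-distances", {
  rate1 <- setNames(rep(0.0015, 6), c(paste0("EC", 1:5), "CD"))
  d1 <- mean(vapply(1:6, function(i) {
    fx <- make_gene_fixture(n_species = 1, per_domain_rates = rate1,
                            times = 30, seed = 600 + i)
    p_distance(pairwise_alignment(fx$proteins[1], fx$proteins[2],
                                  "protein"))$d
  }, 0))
  d2 <- mean(vapply(1:6, function(i) {
    fx <- make_gene_fixture(n_species = 1, per_domain_rates = rate1 * 2,
                            times = 30, seed = 600 + i)
    p_distance(pairwise_alignment(fx$proteins[1], fx$proteins[2],
                                  "protein"))$d
  }, 0))
  expect_equal(d2 / d1, 2, tolerance = 0.35)
})

test_that("the synthetic divergence table reproduces its group mean times", {
  div <- make_divergence_table()
  means <- tapply(div$myr, div$group, mean)
  expect_equal(as.numeric(means[c("apes", "new_world_monkeys",
                                  "owm_tarsiers_strepsirrhines")]),
               c(10.9, 27.5, 48.7))
})

test_that("the study fixture writes every pipeline input", {
  dir <- tempfile("study_")
  fx <- make_study_fixture(dir, n_genes = 2, omegas = c(0.2, 0.8),
                           n_codons_fl = 120, n_cns = 3, n_other = 4,
                           seed = 42)
  expect_true(file.exists(fx$domain_map))
  expect_true(file.exists(fx$divergence_table))
  expect_true(file.exists(fx$expression))
  expect_true(file.exists(fx$phenotypes))
  expect_true(file.exists(fx$loeuf))
  prot <- read_fasta(file.path(dir, "SYNCDH1.protein.fasta"), "protein")
  expect_equal(nrow(prot), 10)  # human + 9 species
  expect_true("human" %in% prot$id)
  dm <- read_domain_map(fx$domain_map)
  expect_true(all(c("FL", "EC1", "CD") %in% dm$segment))
  # determinism
  dir2 <- tempfile("study_")
  fx2 <- make_study_fixture(dir2, n_genes = 2, omegas = c(0.2, 0.8),
                            n_codons_fl = 120, n_cns = 3, n_other = 4,
                            seed = 42)
  expect_identical(readLines(file.path(dir, "SYNCDH1.cds.fasta")),
                   readLines(file.path(dir2, "SYNCDH1.cds.fasta")))
  expect_identical(readLines(fx$expression), readLines(fx2$expression))
})
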