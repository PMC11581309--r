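samples_2class <- function(n_cns = 6, n_other = 10) {
  data.frame(sample = c(paste0("cns", seq_len(n_cns)),
                        paste0("t", seq_len(n_other))),
             class = c(rep("CNS", n_cns), rep("non-CNS", n_other)),
             stringsAsFactors = FALSE)
}

test_that("er_profile reports one Spearman per sample with class labels", {
  metric <- setNames(seq(0.01, 0.17, length.out = 17), paste0("g", 1:17))
  expr <- plant_expression_matrix(metric, samples_2class(),
                                  rho = c(CNS = -1, `non-CNS` = 1),
                                  seed = 21)
  prof <- er_profile(metric, expr, "dN")
  expect_equal(nrow(prof), 16)
  expect_equal(prof$rho[prof$class == "CNS"], rep(-1, 6))
  expect_equal(prof$rho[prof$class == "non-CNS"], rep(1, 10))
  expect_true(all(prof$n == 17))
})

test_that("constant expression within a sample is flagged undefined", {
  metric <- setNames(1:5, paste0("g", 1:5))
  expr <- plant_expression_matrix(metric, samples_2class(2, 2), rho = 0.5,
                                  seed = 3)
  expr$mat[, 1] <- 7
  prof <- er_profile(metric, expr, "omega")
  expect_true(prof$undefined[1])
  expect_false(any(prof$undefined[-1]))
})

test_that("significant fractions count sign and class correctly", {
  prof <- data.frame(
    sample = paste0("s", 1:6),
    class = c(rep("CNS", 4), rep("non-CNS", 2)),
    rho = c(-0.9, -0.8, 0.9, -0.1, 0.5, -0.5),
    p = c(0.01, 0.02, 0.01, 0.8, 0.3, 0.6),
    n = 17, metric = "dN", undefined = FALSE)
  fr <- significant_fraction(prof, "CNS", 0.05, "negative")
  expect_equal(fr$fraction, 0.5)
  expect_equal(fr$n_significant, 2)
  expect_equal(fr$n_total, 4)
  any_fr <- significant_fraction(prof, "CNS", 0.05, "any")
  expect_gte(any_fr$fraction, fr$fraction)
  expect_equal(significant_fraction(prof, "non-CNS", 0.05, "any")$fraction, 0)
  expect_error(significant_fraction(prof, "muscle", 0.05, "any"),
               "no samples")
})

test_that("profiles are invariant to monotone rescaling of expression", {
  metric <- setNames(rnorm(12), paste0("g", 1:12))
  expr <- plant_expression_matrix(metric, samples_2class(3, 3), rho = 0.4,
                                  seed = 17)
  prof1 <- er_profile(metric, expr, "dN")
  expr$mat <- expr$mat^3 * 10
  prof2 <- er_profile(metric, expr, "dN")
  expect_equal(prof1$rho, prof2$rho, tolerance = 1e-12)
  expect_equal(prof1$p, prof2$p, tolerance = 1e-12)
})

test_that("planted class-signed correlations are recovered in sign", {
  metric <- setNames(seq(0.02, 0.18, length.out = 17), paste0("g", 1:17))
  hits <- 0L
  total <- 0L
  for (seed in 1:50) {
    expr <- plant_expression_matrix(metric, samples_2class(4, 8),
                                    rho = c(CNS = -0.6, `non-CNS` = 0.6),
                                    seed = 6000 + seed)
    prof <- er_profile(metric, expr, "dN")
    want <- ifelse(prof$class == "CNS", -1, 1)
    hits <- hits + sum(sign(prof$rho) == want)
    total <- total + nrow(prof)
  }
  expect_gte(hits / total, 0.95)
})

test_that("null-planted per-sample p-values are approximately uniform", {
  metric <- setNames(rnorm(17), paste0("g", 1:17))
  expr <- plant_expression_matrix(metric, samples_2class(100, 400),
                                  rho = 0, seed = 99)
  prof <- er_profile(metric, expr, "dN")
  ks <- suppressWarnings(ks.test(prof$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  fr <- significant_fraction(prof, "non-CNS", 0.05, "any")
  expect_lt(abs(fr$fraction - 0.05), 0.035)
})

test_that("LOEUF correlations run in both metric and expression mode", {
  omega <- setNames(seq(0.05, 0.5, length.out = 10), paste0("g", 1:10))
  loeuf <- omega * 2 + 1  # monotone transform
  names(loeuf) <- names(omega)
  r <- loeuf_correlations(loeuf, metric = omega)
  expect_equal(r$rho, 1)
  expect_equal(r$metric, "LOEUF")
  const <- setNames(rep(1, 10), names(omega))
  expect_true(loeuf_correlations(const, metric = omega)$undefined)
  expr <- plant_expression_matrix(omega, samples_2class(3, 3), rho = -1,
                                  seed = 2)
  prof <- loeuf_correlations(loeuf, expression = expr)
  expect_equal(unique(prof$metric), "LOEUF")
  expect_equal(prof$rho, rep(-1, 6))
})

test_that("expression round-trips through the TSV reader", {
  metric <- setNames(1:6 / 10, paste0("g", 1:6))
  expr <- plant_expression_matrix(metric, samples_2class(2, 2), rho = 0.5,
                                  seed = 5)
  ef <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(expr$mat), expr$mat,
                         check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  af <- tempfile(fileext = ".tsv")
  write.table(expr$annotation, af, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_expression_matrix(ef, af)
  expect_equal(back$mat, expr$mat, tolerance = 1e-8)
  expect_equal(back$annotation$class, expr$annotation$class)
})
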