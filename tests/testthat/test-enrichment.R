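test_that("expected counts multiply rate by trios and lambdas add", {
  expect_equal(expected_count(1e-5, 41165), 0.41165)
  expect_equal(expected_count(1e-5, 0), 0)
  expect_equal(expected_count(0, 100), 0)
  expect_equal(combine_expectations(c(0.1, 0.2)), 0.3)
  expect_equal(combine_expectations(c(0.2, 0.1)),
               combine_expectations(c(0.1, 0.2)))
  expect_equal(combine_expectations(list(0.05, 0.3, 0.01)), 0.36)
})

test_that("Poisson upper tail matches term-by-term summation", {
  expect_equal(poisson_upper_p(0, 0.5), 1)
  expect_equal(poisson_upper_p(0, 0), 1)
  expect_equal(poisson_upper_p(2, 0.1), 1 - exp(-0.1) * (1 + 0.1),
               tolerance = 1e-12)
  # brute-force PMF summation oracle
  brute <- function(obs, lam) sum(exp(-lam) * lam^(obs:(obs + 200)) /
                                    factorial(obs:(obs + 200)))
  expect_equal(poisson_upper_p(5, 1), brute(5, 1), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    obs <- sample(0:12, 1)
    lam <- stats::runif(1, 0, 5)
    expect_equal(poisson_upper_p(obs, lam), brute(obs, lam),
                 tolerance = 1e-10)
  }
})

test_that("gene tests assemble observations, CNV lambdas and MPC routing", {
  rt <- data.frame(gene_id = c("g1", "g2"),
                   d_mis = c(2e-6, NA), lof_snv = c(1e-5, 5e-6),
                   has_mpc = c(TRUE, FALSE))
  dn <- data.frame(
    sample = c("s1", "s2", "s3", "s4"),
    gene = c("g1", "g1", "g2", "g1"),
    consequence = c("nonsense", "missense", "cnv_lof", "missense"),
    mpc = c(NA, 3.0, NA, 1.0), cohort = "c1", aa_pos = c(NA, 10, NA, 11))
  ti <- assemble_gene_tests(list(c1 = rt), c(c1 = 1000), dn,
                            cnv_rates = c(g2 = 1e-6), cnv_n_trios = 500)
  g1 <- ti[ti$gene_id == "g1", ]; g2 <- ti[ti$gene_id == "g2", ]
  expect_equal(g1$obs_lof, 1)       # the nonsense call
  expect_equal(g1$obs_dmis, 1)      # MPC 3.0 only; MPC 1.0 is not d-MIS
  expect_equal(g1$lambda_lof, 1e-5 * 1000)
  expect_equal(g2$obs_lof, 1)       # the CNV call counts as LOF
  expect_equal(g2$lambda_lof_cnv, 1e-6 * 500)
  expect_equal(g2$lambda_lof, 5e-6 * 1000 + 1e-6 * 500)

  res <- run_gene_tests(ti)
  expect_equal(res$n_tests, c(3L, 1L))
  expect_true(is.na(res$p_dmis[res$gene_id == "g2"]))
  # CNV-only observation still yields an informative LOF p-value
  expect_lt(res$p_lof[res$gene_id == "g2"], 1)
  # zero observations in every class give p = 1 throughout
  dn0 <- dn[0, ]
  res0 <- run_gene_tests(assemble_gene_tests(list(c1 = rt),
                                             c(c1 = 1000), dn0))
  expect_equal(res0$p_lof, c(1, 1))

  # exclusion list removes a gene entirely
  ti_ex <- assemble_gene_tests(list(c1 = rt), c(c1 = 1000), dn,
                               exclude = "g1")
  expect_false("g1" %in% ti_ex$gene_id)
})

test_that("a strongly enriched gene attains the smallest combined p", {
  g <- make_genome(n_genes = 100, seed = 41)
  rt <- make_rate_table(g$constraints, seed = 42)
  target <- rt$gene_id[rt$has_mpc][which.max(rt$lof_snv[rt$has_mpc])]
  dn <- make_dnm_cohort(rt, n_trios = 20000,
                        spikes = stats::setNames(10, target), seed = 43)
  res <- run_gene_tests(assemble_gene_tests(list(c1 = rt),
                                            c(c1 = 20000), dn))
  expect_equal(res$gene_id[which.min(res$p_combined)], target)
})

test_that("two-step adjustment: gene Bonferroni then exome-wide BH", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    obs_lof = c(3L, 0L, 1L), obs_dmis = c(2L, 0L, 0L),
                    lambda_lof = c(0.1, 0.2, 0.15),
                    lambda_dmis = c(0.05, 0.1, 0.0),
                    lambda_lof_snv = 0, lambda_lof_cnv = 0,
                    has_mpc = c(TRUE, FALSE, FALSE))
  res <- run_gene_tests(res)
  adj <- two_step_adjust(res)
  p_min <- pmin(res$p_lof, res$p_dmis, res$p_combined, na.rm = TRUE)
  expect_equal(adj$p_gene, pmin(1, res$n_tests * p_min))
  expect_equal(adj$q, brute_bh(adj$p_gene))

  # single gene, single test: p passes through both steps
  one <- run_gene_tests(data.frame(
    gene_id = "solo", obs_lof = 2L, obs_dmis = 0L,
    lambda_lof = 0.193, lambda_dmis = 0, lambda_lof_snv = 0,
    lambda_lof_cnv = 0, has_mpc = FALSE))
  a1 <- two_step_adjust(one)
  expect_equal(a1$p_gene, one$p_lof)
  expect_equal(a1$q, one$p_lof)

  # BH q-values match the step-up definition on a random vector
  set.seed(4)
  p <- stats::runif(5)
  expect_equal(stats::p.adjust(p, "BH"), brute_bh(p))
})

test_that("flat Bonferroni threshold covers an exome of 20,034 genes", {
  thr <- flat_threshold(0.05, 20034)
  expect_equal(thr, 0.05 / (20034 * 3))
  expect_equal(signif(thr, 2), 8.3e-7)
  # flat mode flags by raw p against the threshold
  res <- run_gene_tests(data.frame(
    gene_id = c("hit", "null"), obs_lof = c(8L, 0L), obs_dmis = c(0L, 0L),
    lambda_lof = c(0.1, 0.1), lambda_dmis = 0, lambda_lof_snv = 0,
    lambda_lof_cnv = 0, has_mpc = FALSE))
  flat <- two_step_adjust(res, mode = "flat")
  expect_true(flat$significant[1])
  expect_false(flat$significant[2])
})

test_that("candidate classification follows the constraint/recurrence rules", {
  base <- data.frame(
    gene_id = c("known1", "newLof", "newRec", "newWeak"),
    obs_lof = c(6L, 6L, 0L, 0L), obs_dmis = c(0L, 0L, 5L, 1L),
    lambda_lof = c(0.2, 0.2, 0.1, 0.1),
    lambda_dmis = c(0.1, 0.1, 0.2, 0.2),
    lambda_lof_snv = 0, lambda_lof_cnv = 0,
    has_mpc = c(TRUE, TRUE, TRUE, TRUE))
  res <- two_step_adjust(run_gene_tests(base))
  cons <- data.frame(gene_id = base$gene_id,
                     pLI = c(0.99, 0.99, 0.1, 0.1),
                     loeuf = c(0.2, 0.2, 1.0, 1.0),
                     missense_z = c(0, 1.0, 1.0, 1.0))
  dn <- data.frame(
    sample = paste0("s", 1:10),
    gene = c(rep("newRec", 5), rep("newWeak", 5)),
    consequence = "missense", mpc = 3,
    aa_pos = c(7, 7, 12, 30, 41, 1:5), cohort = "c1")
  calls <- classify_candidates(res, known_genes = "known1", cons, dn)
  expect_equal(calls$status[calls$gene_id == "known1"], "known")
  expect_false(calls$plausible[calls$gene_id == "known1"])
  nl <- calls[calls$gene_id == "newLof", ]
  expect_true(nl$plausible)
  expect_equal(nl$rationale, "lof_constrained")
  nr <- calls[calls$gene_id == "newRec", ]
  expect_true(nr$plausible)                     # two d-MIS at codon 7
  expect_equal(nr$rationale, "recurrent_dmis")
  if ("newWeak" %in% calls$gene_id)
    expect_false(calls$plausible[calls$gene_id == "newWeak"])
})

test_that("expected false positives multiply out", {
  expect_equal(expected_false_positives(380, 0.05), 19)
  expect_equal(expected_false_positives(0, 0.05), 0)
  expect_equal(expected_false_positives(100, 0.10), 10)
  expect_error(expected_false_positives(10, 1.5), "fdr")
})

test_that("null cohorts stay controlled; power grows with enrichment fold", {
  g <- make_genome(n_genes = 400, n_chroms = 2, seed = 61)
  rt <- make_rate_table(g$constraints, seed = 62)
  n_trios <- 41165
  lam <- (rt$lof_snv + ifelse(rt$has_mpc & !is.na(rt$d_mis),
                              rt$d_mis, 0)) * n_trios
  target <- rt$gene_id[rt$has_mpc][order(abs(lam[rt$has_mpc] - 2))][1:3]

  fp <- numeric(5); det <- matrix(NA, 5, 3)
  folds <- c(2, 5, 10)
  for (s in 1:5) {
    dn0 <- make_dnm_cohort(rt, n_trios, seed = 700 + s)
    r0 <- two_step_adjust(run_gene_tests(
      assemble_gene_tests(list(c1 = rt), c(c1 = n_trios), dn0)))
    fp[s] <- mean(r0$q < 0.05)
    for (k in seq_along(folds)) {
      dn1 <- make_dnm_cohort(
        rt, n_trios, spikes = stats::setNames(rep(folds[k], 3), target),
        seed = 800 + 10 * s + k)
      r1 <- two_step_adjust(run_gene_tests(
        assemble_gene_tests(list(c1 = rt), c(c1 = n_trios), dn1)))
      det[s, k] <- mean(r1$significant[match(target, r1$gene_id)])
    }
  }
  expect_lte(mean(fp), 0.05)
  pw <- colMeans(det)
  expect_true(all(diff(pw) >= -0.1))   # nondecreasing up to MC noise
  expect_gt(pw[3], pw[1])
})
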