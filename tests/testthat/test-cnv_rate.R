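test_that("training-gene selection applies LOEUF, flank and autosome rules", {
  gm <- tiny_gm()
  # geneA tolerant, geneB intolerant 0.3 Mb away on the same chromosome,
  # geneX tolerant but on chrX
  cons <- data.frame(gene_id = c("geneA", "geneB", "geneX"),
                     pLI = c(0.1, 0.99, 0.1),
                     loeuf = c(0.50, 0.20, 0.50))
  # flank 1 Mb: geneB (intolerant) lies within geneA's window -> excluded
  expect_equal(select_training_genes(gm, cons), character(0))
  # flank 1 kb: geneB is 1.3 kb away -> geneA passes; geneX still fails
  expect_equal(select_training_genes(gm, cons, flank_bp = 1000), "geneA")
  # below-cutoff gene is never a training gene
  cons2 <- cons; cons2$loeuf <- c(0.20, 2, 2)
  expect_false("geneA" %in% select_training_genes(gm, cons2,
                                                  flank_bp = 1000))
  # missing LOEUF excluded with a message
  withr::local_options(dnburden.verbose = TRUE)
  cons3 <- cons; cons3$loeuf[1] <- NA
  expect_message(
    select_training_genes(gm, cons3, flank_bp = 1000),
    "without LOEUF", all = FALSE)
})

test_that("site counting enforces inclusive size bounds and multi-gene hits", {
  gm <- tiny_gm()
  sites <- sv_sites(data.frame(
    chrom = "chr1",
    start = c(150, 150, 150, 150, 100),
    end = c(190, 200, 150 + 1e6, 150 + 1e6 + 1, 2550),
    sv_type = "DEL"))
  # sizes: 40 (below), 50 (in), 1e6 (in), 1e6+1 (above), 2450 (multi-gene)
  cnt <- count_lof_cnv_sites(sites, gm)
  expect_equal(unname(cnt["geneA"]), 3)  # 50bp, 1Mb, and the multi-gene one
  # the 1 Mb deletion reaches geneB too; the 2450bp one spans both genes
  expect_equal(unname(cnt["geneB"]), 2)
  expect_equal(unname(cnt["geneX"]), 0)
})

test_that("covariates: telomere cap, boundary genes, SD-pair window", {
  genes <- data.frame(
    gene_id = c("mid", "left"), chrom = "chr1", strand = "+",
    tx_start = c(30e6, 0), tx_end = c(30.1e6, 1e4),
    cds_length = 100, canonical = TRUE)
  exons <- data.frame(gene_id = c("mid", "left"),
                      start = c(30e6, 0), end = c(30.1e6, 1e4))
  gm <- gene_model_set(genes, exons, chrom_sizes = c(chr1 = 100e6))
  cov <- compute_covariates(gm)
  expect_equal(cov$telomere_distance_mb[cov$gene_id == "mid"], 25)
  expect_equal(cov$telomere_distance_mb[cov$gene_id == "left"], 0)
  expect_equal(cov$n_sd_pairs, c(0, 0))

  # SD pair < 1 Mb apart overlapping the gene's 1 Mb window counts once;
  # a pair >= 1 Mb apart never counts
  sd <- sd_pairs(data.frame(
    chromA = "chr1", startA = c(30.2e6, 30.2e6), endA = c(30.21e6, 30.21e6),
    chromB = "chr1", startB = c(30.25e6, 31.9e6), endB = c(30.26e6, 31.91e6)))
  cov2 <- compute_covariates(gm, sd)
  expect_equal(cov2$n_sd_pairs[cov2$gene_id == "mid"], 1)

  expect_error(compute_covariates(gm, chrom_sizes = c(chr9 = 1e6)),
               "unknown chromosome")
})

test_that("model enumeration yields 2^k - 1 fits and AIC selection works", {
  set.seed(7)
  n <- 120
  cov <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    gene_length_kb = stats::rlnorm(n, 3, 0.5),
                    n_exons = 1 + stats::rpois(n, 7),
                    transcript_length_kb = stats::rlnorm(n, 0.3, 0.4),
                    n_sd_pairs = stats::rpois(n, 0.5),
                    telomere_distance_mb = stats::runif(n, 0, 25))
  counts <- stats::setNames(stats::rpois(n, 2), cov$gene_id)
  fits <- fit_cnv_models(counts, cov)
  expect_length(fits, 31)
  fits2 <- fit_cnv_models(counts, cov,
                          covariate_names = c("gene_length_kb", "n_exons"))
  expect_length(fits2, 3)

  expect_error(fit_cnv_models(stats::setNames(rep(0L, n), cov$gene_id), cov),
               "all counts zero")

  # lowest AIC wins; ties break toward fewer covariates
  fake <- list(list(covariates = "a", aic = 100, converged = TRUE),
               list(covariates = c("a", "b"), aic = 90, converged = TRUE))
  expect_equal(select_best_model(fake)$aic, 90)
  tie <- list(list(covariates = c("a", "b", "c"), aic = 50,
                   converged = TRUE),
              list(covariates = c("a", "b"), aic = 50, converged = TRUE))
  expect_length(select_best_model(tie)$covariates, 2)
})

test_that("predicted rates preserve the training total and closed forms", {
  set.seed(11)
  n <- 200
  cov <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    gene_length_kb = stats::rlnorm(n, 3, 0.5),
                    n_exons = 1 + stats::rpois(n, 7),
                    transcript_length_kb = stats::rlnorm(n, 0.3, 0.4),
                    n_sd_pairs = stats::rpois(n, 0.5),
                    telomere_distance_mb = stats::runif(n, 0, 25))
  counts <- stats::setNames(stats::rpois(n, 2 + cov$gene_length_kb / 20),
                            cov$gene_id)
  fits <- fit_cnv_models(counts, cov)
  best <- select_best_model(fits)
  rel <- predict_relative_rates(best, cov)
  # GLM mean preservation over the training genes
  expect_equal(sum(rel), sum(counts), tolerance = 1e-6)
  expect_true(all(rel >= 0))

  # identical covariates give identical rates
  cov2 <- cov; cov2[2, -1] <- cov2[1, -1]
  rel2 <- predict_relative_rates(best, cov2)
  expect_equal(unname(rel2[1]), unname(rel2[2]))

  # intercept-only model: every gene gets the mean count
  int_only <- fit_cnv_models(counts, cov,
                             covariate_names = "telomere_distance_mb")
  m <- int_only[[1]]
  m$fit <- stats::glm(cbind(counts, sum(counts) - counts) ~ 1,
                      family = stats::binomial())
  m$covariates <- "telomere_distance_mb"  # column ignored by intercept fit
  rel3 <- predict_relative_rates(m, cov)
  expect_equal(unname(rel3), rep(mean(counts), n), tolerance = 1e-9)
})

test_that("Watterson estimator matches its closed form", {
  expect_equal(watterson_total_rate(0, 10, 1000), 0)
  expect_equal(watterson_total_rate(4, 2, 1), 1.0)
  # harmonic factor for n = 5 alleles is 25/12
  expect_equal(sum(1 / 1:4), 25 / 12)
  expect_equal(watterson_total_rate(25 / 12, 5, 0.25), 1.0)
  expect_error(watterson_total_rate(4, 1, 100), "n_alleles")

  set.seed(5)
  for (i in 1:100) {
    K <- stats::rpois(1, 50)
    n <- sample(2:5000, 1)
    Ne <- sample(10:1e5, 1)
    a <- 0
    for (j in seq_len(n - 1)) a <- a + 1 / j   # direct summation oracle
    expect_equal(watterson_total_rate(K, n, Ne), K / (a * 4 * Ne))
  }
})

test_that("population averaging is an unweighted mean", {
  expect_equal(average_population_rates(c(0.001, 0.002)), 0.0015)
  expect_equal(average_population_rates(0.42), 0.42)
  expect_equal(average_population_rates(rep(3e-4, 5)), 3e-4)
  expect_error(average_population_rates(numeric()), "at least one")
})

test_that("genes_per_cnv equals the brute-force per-site average", {
  gm <- tiny_gm()
  training <- c("geneA", "geneB")
  # two sites: one hits only geneA, one spans both genes
  sites <- sv_sites(data.frame(chrom = "chr1", start = c(150, 100),
                               end = c(250, 2550), sv_type = "DEL"))
  expect_equal(genes_per_cnv(sites, training, gm), 1.5)
  expect_equal(genes_per_cnv(sites, "geneA", gm), 1)

  set.seed(19)
  g <- make_genome(n_genes = 60, n_chroms = 2, seed = 19)
  tr <- select_training_genes(g$gm, g$constraints, flank_bp = 1e5)
  sv <- make_sv_catalog(g, c(gene_length_kb = 0.004), total_sites = 100,
                        seed = 20)
  got <- genes_per_cnv(sv, tr, g$gm)
  per_site <- vapply(seq_len(nrow(sv)), function(i)
    sum(vapply(tr, function(gene)
      brute_overlap(sv$start[i], sv$end[i], sv$chrom[i], gene, g$gm),
      logical(1))), numeric(1))
  expect_equal(got, mean(per_site[per_site > 0]))
})

test_that("rate absolutization applies the multi-gene adjustment formula", {
  rel <- c(target = 1824, other = 912)
  abs_rates <- absolutize_rates(rel, total_abs_rate = 0.00155,
                                genes_per_cnv = 1.2,
                                training_ids = "target")
  expect_equal(unname(abs_rates["target"]), 0.00186)
  expect_equal(unname(abs_rates["other"]), 0.00093)

  # conservation and scale invariance
  rel2 <- c(a = 3, b = 5, c = 2, d = 10)
  tr <- c("a", "b", "c")
  ab <- absolutize_rates(rel2, 0.002, 1.3, tr)
  expect_equal(sum(ab[tr]), 0.002 * 1.3, tolerance = 1e-12)
  ab_scaled <- absolutize_rates(rel2 * 7.3, 0.002, 1.3, tr)
  expect_equal(ab, ab_scaled)
  expect_equal(unname(absolutize_rates(c(a = 0, b = 1), 0.002, 1, "b")["a"]),
               0)
  expect_error(absolutize_rates(c(a = 0, b = 1), 0.002, 1, "a"), "zero")
})

test_that("o/e ratios divide elementwise and drop zero expectations", {
  withr::local_options(dnburden.verbose = TRUE)
  obs <- c(a = 2L, b = 0L, c = 3L)
  exp <- c(a = 4, b = 2, c = 0)
  expect_message(oe <- oe_ratio(obs, exp), "expected 0")
  expect_equal(oe, c(a = 0.5, b = 0))
})

test_that("regression recovers a known rate law and shrinks with data", {
  truth <- c(gene_length_kb = 0.004, n_exons = 0.025)
  g <- make_genome(n_genes = 700, n_chroms = 4, seed = 31)
  tr <- select_training_genes(g$gm, g$constraints)
  cov <- compute_covariates(g$gm, g$sd, g$chrom_sizes)
  err_at <- function(total_sites, seed) {
    sv <- make_sv_catalog(g, truth, total_sites = total_sites, seed = seed)
    cnt <- count_lof_cnv_sites(sv, g$gm)[tr]
    fit <- fit_cnv_models(cnt, cov, covariate_names = names(truth))
    co <- stats::coef(fit[[3]]$fit)[names(truth)]
    max(abs(co - truth) / truth)
  }
  errs_small <- vapply(1:3, function(s) err_at(1500, 100 + s), numeric(1))
  errs_big <- vapply(1:3, function(s) err_at(12000, 200 + s), numeric(1))
  expect_lt(mean(errs_big), mean(errs_small))
  expect_lt(mean(errs_big), 0.15)
})
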