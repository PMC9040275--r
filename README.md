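# dnburden

Unified gene-based burden testing of de novo SNVs **and** CNVs for
trio cohorts.

## What problem this solves

Trio studies of neurodevelopmental disorders find disease genes by
testing whether a gene carries more de novo mutations (DNMs) than its
mutation rate predicts. Absolute per-gene rates have long existed for
SNVs (trinucleotide-context models), but not for de novo copy-number
variants, so exon-deleting deletions could not enter the same test.
`dnburden` closes that gap:

1. **CNV rate model** — for "neutral" training genes (LOF-tolerant,
   autosomal, no LOF-intolerant gene within 1 Mb) the number of
   deletion sites in a population SV catalog is proportional to the
   deletion mutation rate. All 2⁵−1 = 31 covariate subsets of
   {gene length, exon count, transcript length, SD pairs, telomere
   distance} are fitted by binomial regression; the lowest-AIC model
   predicts relative rates for every gene, and the Watterson estimator
   `K / (a·4Nₑ)` plus a multi-gene adjustment anchors them to absolute
   per-generation rates:
   `rate_g = θ_total · genes_per_cnv / Σ_training rel · rel_g`.
2. **Drift simulator** — a forward Wright–Fisher simulation of a gene
   with unlinked biallelic sites verifies the premise: sampled
   segregating-site counts are proportional to the gene mutation rate
   when selection is absent.
3. **SNV rates** — per-gene class rates summed from per-possible-variant
   tables, with depth adjustment (`rate × 0.025 × depth` below 40×) or
   synonymous-o/e cohort calibration, frameshift = 1.1 × nonsense, and
   d-MIS = missense with MPC > 2.
4. **Burden test** — observed per-gene LOF (SNV + CNV) and d-MIS counts
   against Poisson nulls with summed expectations `rate × n_trios`;
   two-step correction (per-gene Bonferroni over 3 or 1 tests, then
   exome-wide BH, q < 0.05) and candidate classification
   (known / new / plausible) by constraint and recurrence rules.
5. **Gene-set statistics** — hypergeometric/Fisher overrepresentation
   with BH, resampling-calibrated enriched-term counts, and the
   Jaccard + overlap combined similarity for term networks.
6. **Prioritizer** — a small feed-forward network (2 × 128 ReLU,
   sigmoid, Adam, batch 5, 5 epochs) scoring similarity to known
   disease genes, converted to true-positive posteriors via
   Gaussian-KDE likelihood ratios and naive Bayes.

A synthetic-data module generates every input with known ground truth,
so the whole pipeline is testable offline.

## Worked example

End to end on synthetic data with a known truth (runs in ~1 min):

```r
library(dnburden)

# 1. synthetic genome + SV catalog with a known rate law
g  <- make_genome(n_genes = 1200, n_chroms = 4, seed = 1)
sv <- make_sv_catalog(g, c(gene_length_kb = 0.004, n_exons = 0.025),
                      total_sites = 8000, seed = 2)

# 2. train the CNV rate model on neutral genes
training <- select_training_genes(g$gm, g$constraints)
covs     <- compute_covariates(g$gm, g$sd, g$chrom_sizes)
counts   <- count_lof_cnv_sites(sv, g$gm)
best     <- select_best_model(fit_cnv_models(counts[training], covs))

# 3. absolute rates via the Watterson anchor
theta <- watterson_total_rate(K = sum(counts[training]),
                              n_alleles = 20000, Ne = 10000)
gpc   <- genes_per_cnv(sv, training, g$gm)
abs_r <- absolutize_rates(predict_relative_rates(best, covs),
                          theta, gpc, training)

# 4. burden test a simulated 41,165-trio cohort with two spiked genes
rt   <- make_rate_table(g$constraints, seed = 3)
lam  <- (rt$lof_snv + ifelse(rt$has_mpc & !is.na(rt$d_mis),
                             rt$d_mis, 0)) * 41165
spiked <- rt$gene_id[rt$has_mpc][order(abs(lam[rt$has_mpc] - 2))][1:2]
dnms <- make_dnm_cohort(rt, n_trios = 41165,
                        spikes = setNames(c(10, 10), spiked),
                        cnv_rates = abs_r, cnv_n_trios = 3675, seed = 4)
tests <- assemble_gene_tests(list(cohort = rt), c(cohort = 41165), dnms,
                             cnv_rates = abs_r, cnv_n_trios = 3675)
res <- two_step_adjust(run_gene_tests(tests))
res[res$significant, c("gene_id", "obs_lof", "obs_dmis", "q")]
```

Output:

```
best model: gene_length_kb + n_exons (AIC 4158.4 of 31 models)
total rate 0.0139, genes/CNV 1.00, median gene rate 1.3e-05
 gene_id obs_lof obs_dmis lambda_lof lambda_dmis        q
   g0404       8        9       1.22        1.11 2.03e-06
   g0731       6       10       1.07        1.21 5.32e-06
spiked genes recovered: g0404, g0731
```

Reading it: AIC selection over the 31 candidate regressions picks
exactly the two covariates the catalog was generated from; the two
genes spiked to 10× their null expectation (~1.2 expected LOF and
~1.1 expected d-MIS events each) are the only exome-wide-significant
genes, with 6–10 observed events per class and q-values far below
0.05, while the other 1,198 null genes stay below threshold.

A thin command-line wrapper over the same functions ships in
`inst/cli/dnburden.R` with subcommands `synth`, `drift-sim`,
`cnv-rate` and `enrich`.

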