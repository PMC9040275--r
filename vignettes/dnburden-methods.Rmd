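---
title: "Methods: unified burden testing of de novo SNVs and CNVs"
author: "dnburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified burden testing of de novo SNVs and CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Trio sequencing studies of neurodevelopmental disorders (NDDs) find
disease genes by asking whether a gene carries more de novo mutations
(DNMs) across a cohort than its mutation rate predicts. For
single-nucleotide variants this is routine: trinucleotide-context
models provide an absolute per-gene, per-generation rate for each
consequence class, and the observed count can be tested against
`rate x n_trios` under a Poisson null. No comparable rate model has
existed for de novo copy-number variants (dnCNVs), so CNV evidence —
exon-deleting deletions in particular — has been left out of gene
discovery. `dnburden` implements a framework that closes this gap: it
estimates absolute per-gene rates of <1 Mb exon-deleting deletions,
adds them to the SNV rates (sums of independent Poissons are Poisson),
and tests SNVs and CNVs in a single per-gene burden test, followed by
candidate classification and a neural-network prioritizer.

# The CNV rate model

## Why population site counts measure mutation rates

The key assumption is that, for genes where heterozygous loss of
function is selectively neutral, the number of *distinct deletion
sites* segregating in a population sample is proportional to the
gene's deletion mutation rate. This is classical neutral theory: at
mutation–drift equilibrium the expected number of segregating sites in
a sample of $n$ alleles is $a_{n-1}\,4N_e\mu$ with
$a_{n-1}=\sum_{i=1}^{n-1}1/i$ (the Watterson relation), i.e. linear in
$\mu$. The `drift_sim` module verifies this premise by forward
Wright–Fisher simulation: a "gene" of `n_sites` unlinked biallelic
sites evolves under two-way mutation (equal forward/backward rate so
long runs are stationary) with one binomial draw per site per
generation, sites starting monomorphic and the run itself serving as
burn-in. Sampled polymorphic-site counts match the Watterson
expectation and correlate with the total gene rate at $r > 0.99$
across a grid of gene architectures.

The full-scale configuration (population $10^5$, $10^6$ generations,
10,000 sampled individuals — the approximate size of public SV
catalogs) is the package default; tests and the acceptance script use
a scaled-down equilibrium regime ($N_e = 1000$, $20N_e$ generations,
200 sampled individuals, per-site rates up to $2\times10^{-6}$ so that
$4N_e\mu \ll 1$ keeps the infinite-sites approximation valid). The
allele-frequency-vector implementation is statistically identical to
an individual-based simulation for unlinked neutral sites.

## Training genes

Site counts only track mutation rates where selection is absent, so
the regression is trained on "neutral" genes: autosomal, LOF-tolerant
(LOEUF >= 0.278, i.e. outside the most constrained decile) and with no
LOF-intolerant gene inside a 1 Mb flank on either side — a deletion
hitting the training gene must not be removable by selection acting on
a constrained neighbour. All three thresholds are exposed
(`loeuf_cutoff`, `flank_bp`).

## Regression and model selection

Per-gene counts of catalog deletions with size in [50 bp, 1 Mb]
(inclusive; a site counts for every gene whose exons it overlaps by
>= 1 bp) are regressed on five covariates: gene length (kb), exon
count, transcript length (kb), the number of segmental-duplication
pairs whose members are < 1 Mb apart with a member overlapping the
gene body ± 1 Mb, and the distance to the nearer telomere (Mb, capped
at 25 Mb because site counts flatten beyond that). All $2^5-1 = 31$
nonempty covariate subsets are fitted and the lowest-AIC model wins,
ties broken toward fewer covariates (parsimony; ties are otherwise
arbitrary).

The counts are modelled as binomial: gene $g$'s count out of the total
training-site count $N$, with a logit link. A log-link Poisson
alternative (`family = "poisson"`) is provided; the two agree closely
in the rare-event regime that applies here, and the binomial reading
treats the catalog total as fixed, which matches how a site catalog is
actually ascertained. With the canonical link, fitted training counts
sum to the observed total exactly, which makes "relative rate =
expected site count" well defined.

Deletions spanning only UTR exon sequence count as LOF (any-exon
overlap, >= 1 bp): the definition is exon-deletion, and no minimum
coding overlap is imposed. The SD covariate enters linearly; its
relationship to counts is known to be somewhat non-linear, and a
log(1+x) transform can be applied upstream if desired. Telomere
distance is measured from the nearer gene boundary (not the midpoint).

## From relative to absolute rates

Relative rates are anchored by the Watterson estimator: within each
catalog population, the total mutation rate over training genes is
$K/(a_{n-1}\,4N_e)$ from the polymorphic-site count $K$ and allele
count $n$; per-population estimates are combined by an unweighted
mean. $N_e$ is a required input — it is population-specific and no
default would be defensible. Because one deletion can remove several
genes, the per-gene scale is corrected by the mean number of training
genes hit per qualifying site (`genes_per_cnv`). The absolute rate of
gene $g$ is then

$$\mathrm{rate}_g \;=\; \frac{\theta_{\mathrm{total}} \times
\mathrm{genes\_per\_cnv}}{\sum_{\mathrm{training}} \mathrm{rel}}
\times \mathrm{rel}_g,$$

which is invariant to rescaling the relative rates and makes training
absolute rates sum to `total_abs_rate x genes_per_cnv` exactly.

# SNV rates and cohort calibration

Per-gene class rates are sums of per-possible-variant
trinucleotide-context rates (consumed as an input table): synonymous,
missense, nonsense and splice-site sums are direct; damaging missense
(d-MIS) sums the missense variants with MPC > 2 — the only
construction consistent with genes lacking MPC annotation being tested
once; the frameshift rate is 1.1 x nonsense (the observed
frameshift:nonsense DNM ratio in large exome series; config-exposed);
and LOF-SNV = nonsense + splice + frameshift.

Two correction routes mirror the asymmetry of real cohorts. Where
per-base median depth is available, each variant's rate is multiplied
by `0.025 x depth` when depth < 40 (continuous at 40x, never
increasing a rate). Where it is not, the whole table is scaled by the
cohort's observed/expected ratio of rare synonymous DNMs, which by
construction makes expected synonymous counts match observed ones
afterwards.

# The burden test and correction

For each gene: `p_lof` tests the observed LOF count (nonsense,
frameshift, splice, plus dnCNV events — one observed event per gene a
CNV hits, matching the rate model's per-gene assignment) against
`lambda_lof_snv + lambda_lof_cnv`; genes with MPC annotation also get
`p_dmis` and a combined test on the summed counts and expectations.
The p-value is the exact Poisson upper tail, so `p = 1` at zero
observations and the test is conservative for discrete data.

Correction is two-step: per-gene Bonferroni over that gene's 3 (or 1)
tests, then Benjamini–Hochberg across genes on the per-gene minima,
significance at q < 0.05. A flat Bonferroni mode
(`alpha / (n_genes x 3)`) is available; the two-step scheme is the
default because it is the one under which the headline gene lists of
this framework are defined. dnCNV calls >= 1 Mb should be excluded
upstream (they nearly always remove multiple constrained genes and
are individually pathogenic rather than informative about a single
gene); manual exclusions are supported as an input list and never
automated.

Significant genes absent from a curated known-gene list are "new"; a
new gene is "plausible" when LOF-enriched and LOF-constrained
(pLI > 0.9 and LOEUF < 0.35) or d-MIS-enriched and either
missense-constrained (missense z > 2.5) or carrying >= 2 d-MIS DNMs at
one amino acid. The thresholds are conventional constraint cutoffs
and are all config-exposed; borderline judgment calls (small genes
with low o/e but modest pLI) are deliberately left to the analyst.

# Gene-set statistics

All overrepresentation analyses (tissue pSI sets, brain coordinates,
co-expression modules, GO terms, PPI clusters) share one machinery:
the upper hypergeometric tail (identical to a one-tailed Fisher test,
kept as an internal cross-check) against a declared universe, followed
by BH. The universe is always the genes carrying the relevant
annotation, not the full exome — the standard choice, and declared so
results are reproducible. GO-style analyses filter sets to 20–500
members before testing. pSI cutoffs are strict (`< 0.05`). The number
of enriched terms in a candidate list is calibrated by resampling:
draw equally sized random gene lists, recount enriched terms at the
same q threshold, and report the upper-tail proportion (resolution
floor 1/n_draws). Term networks connect sets whose combined
coefficient — the average of the Jaccard and overlap coefficients —
exceeds a threshold (0.375 for PPI-cluster maps, 0.5 for GO maps).

# The prioritizer

The network is deliberately small: input layer of the encoded
features, two dense ReLU layers of 128 units, sigmoid output; Adam
(lr 1e-3), binary cross-entropy, mini-batches of 5, 5 epochs. The
input width is the actual encoded feature count — six standardized
numeric predictors (pLI, LOEUF, missense z, CDS length,
brain-coordinate count, GO-term count), two binaries (brain TSEA,
PPI-cluster membership) and a 5-level one-hot module encoding — i.e.
13 columns; a fixed 8-wide input cannot hold these features, so the
nominal "8 predictors" description is treated as approximate.
Standardization uses training-set statistics (applied unchanged to
query genes); gene order is reshuffled every epoch from the run seed,
making training fully deterministic given the seed. Missing
brain-coordinate counts are imputed with 1 (the observed median in
candidate sets); missing modules map to "Others"; genes missing any
constraint metric are excluded from training. No class reweighting is
applied to the positive/negative imbalance by default.

Scores become probabilities by naive Bayes: Gaussian-KDE densities of
the scores in independent positive and negative reference sets
(Scott's-rule bandwidth by default, floored at 1e-12 to keep ratios
finite off-support) give a likelihood ratio, and
`posterior = prior x LR / (prior x LR + 1 - prior)`. The prior is
supplied by the analyst (e.g. the expected true-positive fraction
among new candidates). Reported posteriors are medians over an
ensemble of retrained networks; AUC comparisons against competing
scores use the retraining distribution for an empirical p-value, with
midrank (Mann–Whitney) AUC so ties are handled exactly.

# The synthetic-data generator

Every input has a generator with known ground truth: `make_genome`
(log-normal gene architecture, a persistent Markov chain for the
LOF-intolerant flag so intolerant genes cluster and the flanking rule
has bite, SD pairs straddling the 1 Mb rule), `make_sv_catalog`
(multinomial site counts with expectation `exp(beta' x)` in the model
covariate units; every site overlaps an exon of its source gene;
sizes log-normal within [50 bp, 1 Mb]), `make_rate_table` (class
magnitudes matching the genome-wide composition of coding DNMs:
roughly 0.25 synonymous, 0.6 missense and 0.085 LOF events per birth
over a 20k-gene exome), `make_dnm_cohort` (per-class Poisson counts,
folds applied to deleterious classes only, injectable recurrent
codons) and `make_predictor_table` (class-conditional distributions
with a single separation dial; separation 0 is exchangeable).

What the generators do *not* emulate: real covariate correlation
structure (e.g. GC content, replication timing), ascertainment and
calling noise in SV catalogs, cohort-specific depth profiles, and the
correlated annotation structure of real predictor tables. Passing
tests therefore demonstrate statistical correctness of the machinery
under its own assumptions, not performance on any particular real
cohort.

# Problem sizes and numerical choices

The validation experiments are sized for a desktop run:

* Drift: $N_e = 1000$, 20,000 generations, 200 sampled individuals,
  300 replicates for the Watterson check (tolerance 15%; observed
  error ~3%), a 3x3 architecture grid at 150 replicates for the
  correlation.
* CNV regression: 2,600-gene genome (~1,700 training genes), true law
  `0.004/kb` gene length + `0.025`/exon. Coefficient recovery is
  measured as the mean estimate over 6 independent 20,000-site
  catalogs — at this density the analytic (Fisher-information)
  relative SE per draw is ~6%, so the 6-draw mean pins the estimate
  within 10% with large margin while a single sparse draw would sit at
  the edge of that band. The recovery fit uses the Poisson family, the
  one matched to the log-linear generating law: the binomial-logit
  default agrees with it in the rare-event regime but acquires a
  genuine link-mismatch bias on genomes where a single very large gene
  captures a double-digit share of the catalog, which is a property of
  the link functions, not of the estimator's correctness. Model
  selection uses 50 independent 6,000-site draws.
* Enrichment: 1,000-gene exome, 41,165 trios, 20 replicate cohorts.
  Spiked genes carry 10x folds at combined null expectations of ~2
  events — typical of established NDD genes at this cohort size.
  Detection power is a function of the null expectation: a 10x fold
  on a gene with lambda ~0.5 is analytically detectable only ~80% of
  the time at exome-wide correction, so power statements are tied to
  the stated lambda regime.
* Prioritizer: 650 genes at separation 3 (held-out AUC > 0.99) and 10
  permutation retrains (mean AUC ~0.5).

Numerical conventions: all internal coordinates are 0-based half-open
(GFF3 converted on read); interval overlap requires >= 1 shared base;
Poisson tails via `ppois` (exact, not normal-approximate); BH via
`p.adjust`; AUC by midranks; KDE bandwidth by Scott's rule; the
posterior identity `posterior(p, 1) = p` holds to machine precision;
non-converged GLM subsets are flagged and excluded from AIC selection
rather than silently kept.

# Known limitations

Only exon-deleting deletions are modelled — duplications, mobile
element insertions and other LOF SV classes are out of scope, as are
sex-chromosome training genes. The neutrality argument ignores
selection on non-coding elements inside training-gene flanks. The
effective population size for the Watterson step must be supplied per
population. The prioritizer's posteriors inherit any mismatch between
the reference score distributions and the candidate genes' true class
composition, and the framework tests de novo dominant burden only.
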