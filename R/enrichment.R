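#' Poisson burden tests of de novo mutations per gene
#'
#' Observed per-gene DNM counts are tested against the expectation
#' `(per-individual mutation rate) x (number of trios)` under the null
#' that counts are Poisson with that mean. Expectations from several
#' cohorts and from SNV and CNV classes add, since sums of independent
#' Poisson variables are Poisson with summed means. Three tests are run
#' per gene -- LOF only, d-MIS only, LOF + d-MIS -- for genes with MPC
#' annotation, one (LOF) otherwise. Correction is two-step: a per-gene
#' Bonferroni over that gene's tests, then Benjamini-Hochberg across
#' genes; a flat exome-wide Bonferroni threshold is available as an
#' alternative mode.
#'
#' @name enrichment
NULL

#' Expected DNM count for a gene in a cohort
#' @param rate per-individual per-generation mutation rate.
#' @param n_trios number of sequenced trios.
#' @return expected count `lambda = rate * n_trios`.
#' @export
expected_count <- function(rate, n_trios) {
  stop_if_not(all(rate >= 0), "rate must be >= 0")
  stop_if_not(all(n_trios >= 0), "n_trios must be >= 0")
  rate * n_trios
}

#' Combine Poisson expectations
#' @param lambdas numeric vector (or list) of nonnegative means.
#' @return their sum.
#' @export
combine_expectations <- function(lambdas) {
  lambdas <- unlist(lambdas)
  stop_if_not(all(lambdas >= 0), "negative lambda")
  sum(lambdas)
}

#' Upper-tail Poisson p-value
#'
#' `P(X >= observed)` for `X ~ Poisson(lambda)`; 1 when observed = 0.
#'
#' @param observed nonnegative integer count(s).
#' @param lambda Poisson mean(s).
#' @return p-value(s) in (0, 1].
#' @export
poisson_upper_p <- function(observed, lambda) {
  stop_if_not(all(observed >= 0 & observed == floor(observed)),
              "observed must be nonnegative integers")
  stop_if_not(all(lambda >= 0), "lambda must be >= 0")
  stats::ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' Assemble per-gene test inputs from rates and DNM calls
#'
#' Builds one row per gene with observed LOF and d-MIS counts (merged
#' across cohorts) and combined expectations. A CNV call hitting k
#' genes contributes one observed event to each of the k genes,
#' matching the per-gene assignment of the rate model. dnCNV calls can
#' be pre-filtered by size upstream (calls >= 1 Mb are conventionally
#' discarded).
#'
#' @param rate_tables named list of per-cohort rate tables (columns
#'   gene_id, d_mis, lof_snv, has_mpc and optionally lof_cnv), already
#'   cohort-calibrated.
#' @param n_trios named numeric vector of trio counts per cohort
#'   (SNV-bearing cohorts); names must match `rate_tables`.
#' @param dnms data.frame of DNM records (columns gene, consequence,
#'   sample, mpc, aa_pos) pooled over cohorts.
#' @param cnv_rates optional named vector of absolute per-gene LOF-CNV
#'   rates, with `cnv_n_trios` the number of CNV-analyzed trios.
#' @param cnv_n_trios trios contributing dnCNV calls (default 0).
#' @param mpc_cutoff MPC threshold for counting observed d-MIS
#'   (default 2, strict `>`).
#' @param exclude character vector of gene ids to drop (manual
#'   curation), default none.
#' @return data.frame with gene_id, obs_lof, obs_dmis, lambda_lof_snv,
#'   lambda_lof_cnv, lambda_lof, lambda_dmis, has_mpc.
#' @export
assemble_gene_tests <- function(rate_tables, n_trios, dnms,
                                cnv_rates = NULL, cnv_n_trios = 0,
                                mpc_cutoff = 2, exclude = character()) {
  stop_if_not(all(names(rate_tables) %in% names(n_trios)),
              "every rate table needs a matching n_trios entry")
  genes <- sort(unique(unlist(lapply(rate_tables, `[[`, "gene_id"))))
  genes <- setdiff(genes, exclude)

  lam_snv <- stats::setNames(numeric(length(genes)), genes)
  lam_dmis <- stats::setNames(numeric(length(genes)), genes)
  has_mpc <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (ch in names(rate_tables)) {
    rt <- rate_tables[[ch]]
    idx <- match(rt$gene_id, genes)
    ok <- !is.na(idx)
    lam_snv[idx[ok]] <- lam_snv[idx[ok]] +
      expected_count(rt$lof_snv[ok], n_trios[[ch]])
    dm <- ifelse(is.na(rt$d_mis[ok]), 0, rt$d_mis[ok])
    lam_dmis[idx[ok]] <- lam_dmis[idx[ok]] +
      expected_count(dm, n_trios[[ch]])
    has_mpc[idx[ok]] <- has_mpc[idx[ok]] | rt$has_mpc[ok]
  }
  lam_cnv <- stats::setNames(numeric(length(genes)), genes)
  if (!is.null(cnv_rates)) {
    common <- intersect(names(cnv_rates), genes)
    lam_cnv[common] <- expected_count(cnv_rates[common], cnv_n_trios)
  }

  dnms <- dnms[!dnms$gene %in% exclude, , drop = FALSE]
  lof <- dnms[dnms$consequence %in% lof_consequences(), , drop = FALSE]
  obs_lof <- stats::setNames(integer(length(genes)), genes)
  t1 <- table(lof$gene)
  obs_lof[intersect(names(t1), genes)] <-
    as.integer(t1[intersect(names(t1), genes)])
  dmis <- dnms[dnms$consequence == "missense" & !is.na(dnms$mpc) &
                 dnms$mpc > mpc_cutoff, , drop = FALSE]
  obs_dmis <- stats::setNames(integer(length(genes)), genes)
  t2 <- table(dmis$gene)
  obs_dmis[intersect(names(t2), genes)] <-
    as.integer(t2[intersect(names(t2), genes)])

  data.frame(gene_id = genes,
             obs_lof = as.integer(obs_lof),
             obs_dmis = as.integer(obs_dmis),
             lambda_lof_snv = as.numeric(lam_snv),
             lambda_lof_cnv = as.numeric(lam_cnv),
             lambda_lof = as.numeric(lam_snv + lam_cnv),
             lambda_dmis = as.numeric(lam_dmis),
             has_mpc = as.logical(has_mpc),
             stringsAsFactors = FALSE)
}

#' Run the per-gene Poisson tests
#'
#' For every gene: `p_lof` from (obs LOF, lambda_lof_snv +
#' lambda_lof_cnv); for genes with MPC annotation also `p_dmis` and
#' `p_combined` on the summed counts and expectations. Genes without
#' MPC annotation get only `p_lof` (`p_dmis`/`p_combined` are NA) and
#' are counted as one test.
#'
#' @param inputs data.frame from [assemble_gene_tests()].
#' @return `inputs` with columns p_lof, p_dmis, p_combined, n_tests.
#' @export
run_gene_tests <- function(inputs) {
  p_lof <- poisson_upper_p(inputs$obs_lof, inputs$lambda_lof)
  p_dmis <- ifelse(inputs$has_mpc,
                   poisson_upper_p(inputs$obs_dmis, inputs$lambda_dmis),
                   NA_real_)
  p_comb <- ifelse(inputs$has_mpc,
                   poisson_upper_p(inputs$obs_lof + inputs$obs_dmis,
                                   inputs$lambda_lof + inputs$lambda_dmis),
                   NA_real_)
  inputs$p_lof <- p_lof
  inputs$p_dmis <- p_dmis
  inputs$p_combined <- p_comb
  inputs$n_tests <- ifelse(inputs$has_mpc, 3L, 1L)
  inputs
}

#' Two-step multiple-testing correction
#'
#' Step 1 (gene level): Bonferroni over each gene's tests -- `p_gene =
#' min over tests of min(1, n_tests * p)`. Step 2 (exome level): BH
#' across genes on `p_gene`, giving a q-value; genes with `q < alpha`
#' are significant. With `mode = "flat"` significance is instead the
#' flat Bonferroni rule: any raw p below `alpha / (n_genes * 3)`.
#'
#' @param results data.frame from [run_gene_tests()].
#' @param alpha significance level (default 0.05).
#' @param mode `"two_step"` (default) or `"flat"`.
#' @return `results` with p_gene, q, significant columns.
#' @export
two_step_adjust <- function(results, alpha = 0.05,
                            mode = c("two_step", "flat")) {
  mode <- match.arg(mode)
  pm <- cbind(results$p_lof, results$p_dmis, results$p_combined)
  p_min <- apply(pm, 1, min, na.rm = TRUE)
  results$p_gene <- pmin(1, results$n_tests * p_min)
  results$q <- stats::p.adjust(results$p_gene, method = "BH")
  if (mode == "two_step") {
    results$significant <- results$q < alpha
  } else {
    thr <- flat_threshold(alpha, nrow(results))
    results$significant <- p_min < thr
  }
  results
}

#' Flat exome-wide Bonferroni per-test threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_genes number of tested genes.
#' @param tests_per_gene tests per gene (default 3).
#' @return per-test significance threshold `alpha / (n_genes *
#'   tests_per_gene)`.
#' @export
flat_threshold <- function(alpha = 0.05, n_genes, tests_per_gene = 3) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  alpha / (n_genes * tests_per_gene)
}

#' Classify significant genes as known or new, and flag plausible ones
#'
#' Significant genes already on the supplied known-gene list are
#' `known`. A `new` gene is flagged plausible when (1) it is
#' LOF-enriched and LOF-constrained (`pLI > pli_min` and `LOEUF <
#' loeuf_max`), or (2) it is d-MIS-enriched and either missense-
#' constrained (`missense_z > mis_z_min`) or harbors recurrent d-MIS
#' DNMs (>= 2 at the same amino-acid position). Enrichment direction is
#' read from the component p-values at level `alpha_component` on the
#' gene-Bonferroni scale.
#'
#' @param results data.frame from [two_step_adjust()].
#' @param known_genes character vector of established disease genes
#'   (curated input, not recomputed).
#' @param constraints constraint table (gene_id, pLI, loeuf,
#'   missense_z).
#' @param dnms DNM records (for the recurrent-codon rule; needs gene,
#'   consequence, mpc, aa_pos).
#' @param pli_min,loeuf_max,mis_z_min constraint thresholds (defaults
#'   0.9, 0.35, 2.5).
#' @param mpc_cutoff MPC cutoff for d-MIS recurrence (default 2).
#' @return data.frame of significant genes: gene_id, status
#'   (known/new), plausible, rationale (lof_constrained /
#'   dmis_constrained / recurrent_dmis / excluded).
#' @export
classify_candidates <- function(results, known_genes, constraints, dnms,
                                pli_min = 0.9, loeuf_max = 0.35,
                                mis_z_min = 2.5, mpc_cutoff = 2) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(), status = character(),
                      plausible = logical(), rationale = character(),
                      stringsAsFactors = FALSE))
  ci <- match(sig$gene_id, constraints$gene_id)
  pli <- constraints$pLI[ci]
  loeuf <- constraints$loeuf[ci]
  mis_z <- if ("missense_z" %in% names(constraints))
    constraints$missense_z[ci] else rep(NA_real_, nrow(sig))

  # enrichment direction: which component tests drive the signal
  lof_enriched <- pmin(1, sig$n_tests * sig$p_lof) < 0.05 &
    sig$obs_lof > sig$lambda_lof
  dmis_p <- ifelse(is.na(sig$p_dmis), 1, sig$p_dmis)
  dmis_enriched <- pmin(1, sig$n_tests * dmis_p) < 0.05 &
    sig$obs_dmis > sig$lambda_dmis

  rec <- vapply(sig$gene_id, function(g) {
    d <- dnms[dnms$gene == g & dnms$consequence == "missense" &
                !is.na(dnms$mpc) & dnms$mpc > mpc_cutoff &
                !is.na(dnms$aa_pos), , drop = FALSE]
    any(table(d$aa_pos) >= 2)
  }, logical(1))

  status <- ifelse(sig$gene_id %in% known_genes, "known", "new")
  lof_ok <- lof_enriched & !is.na(pli) & !is.na(loeuf) &
    pli > pli_min & loeuf < loeuf_max
  dmis_z_ok <- dmis_enriched & !is.na(mis_z) & mis_z > mis_z_min
  dmis_rec_ok <- dmis_enriched & rec
  plausible <- status == "new" & (lof_ok | dmis_z_ok | dmis_rec_ok)
  rationale <- ifelse(status == "known", "excluded",
               ifelse(lof_ok, "lof_constrained",
               ifelse(dmis_rec_ok & !dmis_z_ok, "recurrent_dmis",
               ifelse(dmis_z_ok, "dmis_constrained", "excluded"))))
  data.frame(gene_id = sig$gene_id, status = status,
             plausible = plausible, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Expected false positives among significant genes
#' @param n_significant number of significant genes.
#' @param fdr the FDR level used (in (0,1)).
#' @return `n_significant * fdr`.
#' @export
expected_false_positives <- function(n_significant, fdr) {
  stop_if_not(fdr > 0 && fdr < 1, "fdr must be in (0,1)")
  stop_if_not(n_significant >= 0, "n_significant must be >= 0")
  n_significant * fdr
}
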