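#' Per-gene mutation rates of exon-deleting CNVs
#'
#' Relative per-gene rates of <1 Mb exon-deleting deletions are learned
#' by regressing the number of deletion sites per gene in a population
#' SV catalog on genomic covariates, using only "neutral" training
#' genes: LOF-tolerant autosomal genes with no LOF-intolerant gene
#' within a 1 Mb flank, where deletion sites are expected to segregate
#' free of selection so that site counts are proportional to mutation
#' rates (see the drift-simulation module). Relative rates are then
#' anchored to an absolute per-generation scale via the Watterson
#' estimator and a multi-gene adjustment.
#'
#' @name cnv_rate
NULL

#' Select neutral training genes
#'
#' A training gene is autosomal, LOF-tolerant (LOEUF >= `loeuf_cutoff`),
#' and has no LOF-intolerant gene (LOEUF < `loeuf_cutoff`) whose
#' transcript overlaps the window `[tx_start - flank_bp, tx_end +
#' flank_bp]`. Genes without a LOEUF value are excluded (count
#' reported).
#'
#' @param gm a [gene_model_set()].
#' @param constraints data.frame with gene_id and loeuf columns.
#' @param flank_bp flank width in bp (default 1e6).
#' @param loeuf_cutoff LOEUF first-decile cutoff (default 0.278).
#' @return character vector of training gene ids.
#' @export
select_training_genes <- function(gm, constraints, flank_bp = 1e6,
                                  loeuf_cutoff = 0.278) {
  g <- gm$genes
  loeuf <- constraints$loeuf[match(g$gene_id, constraints$gene_id)]
  miss <- is.na(loeuf)
  if (any(miss))
    dn_msg("select_training_genes: ", sum(miss),
           " gene(s) without LOEUF excluded")
  intolerant <- !miss & loeuf < loeuf_cutoff
  tolerant <- !miss & loeuf >= loeuf_cutoff

  cand <- which(tolerant & g$is_autosomal)
  if (length(cand) == 0) return(character())
  intol <- which(intolerant)
  if (length(intol) == 0) return(g$gene_id[cand])

  win <- GenomicRanges::GRanges(
    g$chrom[cand],
    IRanges::IRanges(start = pmax(1, g$tx_start[cand] - flank_bp + 1),
                     end = g$tx_end[cand] + flank_bp))
  bad <- GenomicRanges::GRanges(
    g$chrom[intol],
    IRanges::IRanges(start = g$tx_start[intol] + 1, end = g$tx_end[intol]))
  hit <- GenomicRanges::countOverlaps(win, bad) > 0
  g$gene_id[cand[!hit]]
}

#' Count qualifying deletion sites per gene
#'
#' A deletion site contributes one count to every gene whose exons it
#' overlaps (>= 1 bp). Sites with size outside `[min_bp, max_bp]`
#' (inclusive bounds) are excluded.
#'
#' @param sites SV site data.frame (DEL records).
#' @param gm a [gene_model_set()].
#' @param min_bp,max_bp inclusive size bounds (defaults 50 and 1e6).
#' @return named integer vector over all genes in `gm` (zeros included).
#' @export
count_lof_cnv_sites <- function(sites, gm, min_bp = 50, max_bp = 1e6) {
  keep <- sites$size >= min_bp & sites$size <= max_bp
  hits <- site_gene_hits(sites[keep, , drop = FALSE], gm)
  counts <- stats::setNames(integer(nrow(gm$genes)), gm$genes$gene_id)
  tab <- table(unlist(hits))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Genomic covariates for the CNV-rate regression
#'
#' Five covariates per gene, in model units:
#' \describe{
#'   \item{gene_length_kb}{`(tx_end - tx_start) / 1000`}
#'   \item{n_exons}{exon count}
#'   \item{transcript_length_kb}{summed exon length / 1000}
#'   \item{n_sd_pairs}{segmental-duplication pairs whose members are
#'     < 1 Mb apart and at least one member overlaps the gene body
#'     extended by `sd_flank_bp`}
#'   \item{telomere_distance_mb}{`min(tx_start, chrom_len - tx_end)` in
#'     Mb, capped at 25 (site counts look flat beyond 25 Mb)}
#' }
#'
#' @param gm a [gene_model_set()]; its `chrom_sizes` must be set or
#'   passed via `chrom_sizes`.
#' @param sd data.frame of SD pairs from [read_sd_pairs()] (may be
#'   `NULL` for zero counts).
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param sd_flank_bp window around the gene body in which an SD member
#'   counts as "surrounding" (default 1e6).
#' @param telomere_cap_mb cap on the telomere distance (default 25).
#' @return data.frame, one row per gene, with gene_id and the five
#'   covariates.
#' @export
compute_covariates <- function(gm, sd = NULL,
                               chrom_sizes = gm$chrom_sizes,
                               sd_flank_bp = 1e6, telomere_cap_mb = 25) {
  g <- gm$genes
  stop_if_not(!is.null(chrom_sizes), "chromosome sizes are required")
  unknown <- setdiff(g$chrom, names(chrom_sizes))
  stop_if_not(length(unknown) == 0,
              paste("unknown chromosome(s):", paste(unknown, collapse = ",")))
  clen <- chrom_sizes[g$chrom]
  tel <- pmin(g$tx_start, clen - g$tx_end) / 1e6
  tel <- pmin(tel, telomere_cap_mb)

  n_sd <- integer(nrow(g))
  if (!is.null(sd) && nrow(sd) > 0) {
    sd_close <- sd[sd$separation < 1e6, , drop = FALSE]
    if (nrow(sd_close) > 0) {
      gene_win <- GenomicRanges::GRanges(
        g$chrom,
        IRanges::IRanges(start = pmax(1, g$tx_start - sd_flank_bp + 1),
                         end = g$tx_end + sd_flank_bp))
      memA <- GenomicRanges::GRanges(
        sd_close$chromA,
        IRanges::IRanges(sd_close$startA + 1, sd_close$endA))
      memB <- GenomicRanges::GRanges(
        sd_close$chromB,
        IRanges::IRanges(sd_close$startB + 1, sd_close$endB))
      hitA <- GenomicRanges::findOverlaps(gene_win, memA)
      hitB <- GenomicRanges::findOverlaps(gene_win, memB)
      pair_hits <- unique(rbind(
        cbind(S4Vectors::queryHits(hitA), S4Vectors::subjectHits(hitA)),
        cbind(S4Vectors::queryHits(hitB), S4Vectors::subjectHits(hitB))))
      if (nrow(pair_hits) > 0) {
        tab <- table(pair_hits[, 1])
        n_sd[as.integer(names(tab))] <- as.integer(tab)
      }
    }
  }

  data.frame(gene_id = g$gene_id,
             gene_length_kb = g$gene_length / 1e3,
             n_exons = g$n_exons,
             transcript_length_kb = g$transcript_length / 1e3,
             n_sd_pairs = n_sd,
             telomere_distance_mb = as.numeric(tel),
             stringsAsFactors = FALSE)
}

#' Names of the five regression covariates
#' @return character vector.
#' @export
cnv_covariate_names <- function() {
  c("gene_length_kb", "n_exons", "transcript_length_kb", "n_sd_pairs",
    "telomere_distance_mb")
}

#' Fit all covariate-subset models of per-gene deletion-site counts
#'
#' Enumerates every nonempty subset of the covariates (`2^k - 1` models;
#' 31 for the default five) and fits either a binomial regression of
#' per-gene counts out of the total site count (logit link) or a Poisson
#' log-linear regression. Models that fail to converge are flagged and
#' excluded from selection.
#'
#' @param counts named integer vector of per-gene site counts for the
#'   training genes.
#' @param covariates data.frame from [compute_covariates()] covering at
#'   least the training genes.
#' @param covariate_names covariates to enumerate (default all five).
#' @param family `"binomial"` (default) or `"poisson"`.
#' @return list of models; each element has `covariates`, `fit` (a
#'   `glm`), `aic`, `converged`, `model_index`.
#' @export
fit_cnv_models <- function(counts, covariates,
                           covariate_names = cnv_covariate_names(),
                           family = c("binomial", "poisson")) {
  family <- match.arg(family)
  stop_if_not(sum(counts) > 0, "all counts zero: no signal to fit")
  idx <- match(names(counts), covariates$gene_id)
  stop_if_not(!anyNA(idx), "covariates missing for some training genes")
  X <- covariates[idx, covariate_names, drop = FALSE]
  k <- as.integer(counts)
  N <- sum(k)

  subsets <- unlist(lapply(seq_along(covariate_names), function(m)
    utils::combn(covariate_names, m, simplify = FALSE)), recursive = FALSE)
  models <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    vars <- subsets[[i]]
    dat <- X[, vars, drop = FALSE]
    fit <- tryCatch({
      if (family == "binomial") {
        dat$.y <- cbind(k, N - k)
        stats::glm(.y ~ ., family = stats::binomial(), data = dat)
      } else {
        dat$.y <- k
        stats::glm(.y ~ ., family = stats::poisson(), data = dat)
      }
    }, error = function(e) NULL, warning = function(w) {
      # refit quietly; keep fit but mark non-convergence below
      if (family == "binomial") {
        dat$.y <- cbind(k, N - k)
        suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                    data = dat))
      } else {
        dat$.y <- k
        suppressWarnings(stats::glm(.y ~ ., family = stats::poisson(),
                                    data = dat))
      }
    })
    ok <- !is.null(fit) && fit$converged && all(is.finite(stats::coef(fit)))
    if (!ok)
      dn_msg("fit_cnv_models: model ", i, " (",
             paste(vars, collapse = "+"), ") failed to converge")
    models[[i]] <- list(covariates = vars, fit = fit,
                        aic = if (ok) stats::AIC(fit) else NA_real_,
                        converged = ok, model_index = i,
                        family = family, n_trials = N)
  }
  class(models) <- "cnv_model_list"
  models
}

#' Pick the lowest-AIC model (ties broken toward fewer covariates)
#'
#' @param models list from [fit_cnv_models()].
#' @return the selected model element.
#' @export
select_best_model <- function(models) {
  ok <- vapply(models, function(m) isTRUE(m$converged), logical(1))
  stop_if_not(any(ok), "no successfully fitted model")
  cand <- models[ok]
  aic <- vapply(cand, `[[`, numeric(1), "aic")
  nv <- vapply(cand, function(m) length(m$covariates), integer(1))
  best <- order(aic, nv)[1]
  cand[[best]]
}

#' Predict relative CNV mutation rates for all genes
#'
#' The relative rate of a gene is its model-expected site count. For the
#' binomial fit this is `N * p_g`; for the Poisson fit, `exp(eta_g)`.
#' With the canonical link and an intercept, expected counts over the
#' training genes sum to the observed total (GLM mean preservation).
#' Genes with missing covariates are excluded with a message.
#'
#' @param model a model element from [select_best_model()].
#' @param covariates data.frame from [compute_covariates()].
#' @return named numeric vector of relative rates (model-scale expected
#'   site counts), one per gene in `covariates`.
#' @export
predict_relative_rates <- function(model, covariates) {
  vars <- model$covariates
  keep <- stats::complete.cases(covariates[, vars, drop = FALSE])
  if (any(!keep))
    dn_msg("predict_relative_rates: ", sum(!keep),
           " gene(s) with missing covariates excluded")
  dat <- covariates[keep, vars, drop = FALSE]
  mu <- stats::predict(model$fit, newdata = dat, type = "response")
  rate <- if (model$family == "binomial") model$n_trials * mu else mu
  stats::setNames(pmax(0, as.numeric(rate)), covariates$gene_id[keep])
}

#' Watterson estimator of the total mutation rate
#'
#' Given `K` segregating (polymorphic) sites observed among `n_alleles`
#' sampled alleles from a population of effective size `Ne`, the
#' per-generation total mutation rate is `K / (a * 4 * Ne)` with
#' `a = sum_{i=1}^{n_alleles-1} 1/i`.
#'
#' @param K number of polymorphic sites (>= 0).
#' @param n_alleles number of sampled alleles (>= 2).
#' @param Ne effective population size (> 0).
#' @return total mutation rate per generation.
#' @export
watterson_total_rate <- function(K, n_alleles, Ne) {
  stop_if_not(is_number(K) && K >= 0, "K must be >= 0")
  stop_if_not(is_number(n_alleles) && n_alleles >= 2,
              "n_alleles must be >= 2")
  stop_if_not(is_number(Ne) && Ne > 0, "Ne must be > 0")
  a <- harmonic_number(n_alleles - 1)
  K / (a * 4 * Ne)
}

#' Average per-population rate estimates
#'
#' The total-rate estimate is computed within each population and the
#' estimates are combined by an unweighted arithmetic mean.
#'
#' @param rates numeric vector of per-population estimates.
#' @return mean rate.
#' @export
average_population_rates <- function(rates) {
  stop_if_not(length(rates) >= 1, "need at least one population")
  mean(rates)
}

#' Mean number of training genes hit per deletion site
#'
#' Over qualifying sites that exon-overlap at least one training gene,
#' the average number of training genes overlapped. Used to adjust the
#' total absolute rate for deletions spanning several genes.
#'
#' @param sites SV site data.frame.
#' @param training_ids character vector of training gene ids.
#' @param gm a [gene_model_set()].
#' @param min_bp,max_bp inclusive size bounds (defaults 50, 1e6).
#' @return mean count (>= 1).
#' @export
genes_per_cnv <- function(sites, training_ids, gm, min_bp = 50,
                          max_bp = 1e6) {
  keep <- sites$size >= min_bp & sites$size <= max_bp
  hits <- site_gene_hits(sites[keep, , drop = FALSE], gm)
  n_tr <- vapply(hits, function(g) sum(g %in% training_ids), integer(1))
  n_tr <- n_tr[n_tr > 0]
  stop_if_not(length(n_tr) > 0, "no qualifying site hits a training gene")
  mean(n_tr)
}

#' Convert relative rates to absolute de novo rates
#'
#' `rate_g = total_abs_rate * genes_per_cnv / sum_{training}(relative) *
#' relative_g`. The training-gene absolute rates then sum to
#' `total_abs_rate * genes_per_cnv` exactly; the formula is invariant to
#' rescaling all relative rates by a constant.
#'
#' @param relative named numeric vector of relative rates for all genes.
#' @param total_abs_rate Watterson-derived total absolute rate over the
#'   training genes (per individual per generation).
#' @param genes_per_cnv multi-gene adjustment factor (mean training
#'   genes hit per deletion).
#' @param training_ids character vector of training gene ids.
#' @return named numeric vector of absolute per-gene rates.
#' @export
absolutize_rates <- function(relative, total_abs_rate, genes_per_cnv,
                             training_ids) {
  tr <- relative[names(relative) %in% training_ids]
  tot_rel <- sum(tr)
  stop_if_not(tot_rel > 0, "training-gene relative rates sum to zero")
  relative * (total_abs_rate * genes_per_cnv / tot_rel)
}

#' Observed/expected ratios per gene
#'
#' @param observed named integer vector of observed site counts.
#' @param expected named numeric vector of model-expected counts.
#' @return named numeric vector of o/e over genes with expected > 0;
#'   genes with expected 0 are omitted with a message.
#' @export
oe_ratio <- function(observed, expected) {
  common <- intersect(names(observed), names(expected))
  obs <- observed[common]; exp <- expected[common]
  zero <- exp <= 0
  if (any(zero))
    dn_msg("oe_ratio: ", sum(zero), " gene(s) with expected 0 omitted")
  obs[!zero] / exp[!zero]
}
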