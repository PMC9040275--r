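#' Per-gene SNV/indel mutation rates from trinucleotide-context tables
#'
#' Per-possible-variant rates (from a trinucleotide-context model,
#' consumed as input) are summed within consequence classes per gene.
#' The frameshift rate is derived from the nonsense rate by a fixed
#' ratio, damaging-missense (d-MIS) rates sum over missense variants
#' with MPC above a cutoff, and total LOF-SNV = nonsense + splice +
#' frameshift. Rates can be corrected for sequencing depth per base, or
#' calibrated per cohort so expected synonymous counts match observed.
#'
#' @name snv_rate
NULL

#' Depth-adjust a per-base mutation rate
#'
#' Below a median depth of 40x the callable fraction scales linearly:
#' `rate * 0.025 * depth`; at >= 40x the rate is unchanged (the two
#' branches agree at depth 40 since 0.025 * 40 = 1).
#'
#' @param rate per-variant mutation rate(s).
#' @param depth median sequencing depth at the base (same length or
#'   scalar); `NA` depth leaves the rate unchanged.
#' @return adjusted rate(s).
#' @export
depth_adjust <- function(rate, depth) {
  stop_if_not(all(rate >= 0, na.rm = TRUE), "negative rate")
  stop_if_not(all(depth >= 0, na.rm = TRUE), "negative depth")
  adj <- ifelse(!is.na(depth) & depth < 40, rate * 0.025 * depth, rate)
  adj
}

#' Aggregate possible-variant rates into per-gene class rates
#'
#' @param variants data.frame of possible variants with columns
#'   `gene_id`, `rate`, `consequence` (synonymous / missense / nonsense
#'   / splice_acceptor / splice_donor) and optionally `mpc`, `depth`.
#' @param mpc_cutoff MPC threshold defining d-MIS (default 2; strict
#'   `>`).
#' @param frameshift_ratio frameshift rate as a multiple of the
#'   nonsense rate (default 1.1, the observed frameshift:nonsense DNM
#'   ratio in large exome series).
#' @param use_depth apply [depth_adjust()] per variant when a `depth`
#'   column is present (default TRUE).
#' @return data.frame, one row per gene: synonymous, missense, d_mis,
#'   nonsense, splice, frameshift, lof_snv; `has_mpc` flags genes whose
#'   missense variants carry MPC annotation. Genes with no MPC
#'   annotation get `d_mis = NA`.
#' @export
aggregate_gene_rates <- function(variants, mpc_cutoff = 2,
                                 frameshift_ratio = 1.1,
                                 use_depth = TRUE) {
  stop_if_not(all(c("gene_id", "rate", "consequence") %in% names(variants)),
              "variants need gene_id, rate, consequence columns")
  stop_if_not(all(variants$rate > 0), "per-variant rates must be > 0")
  r <- variants$rate
  if (use_depth && "depth" %in% names(variants))
    r <- depth_adjust(r, variants$depth)

  genes <- unique(variants$gene_id)
  csum <- function(cls, sub = rep(TRUE, nrow(variants))) {
    sel <- variants$consequence %in% cls & sub
    v <- rowsum(r[sel], variants$gene_id[sel])
    out <- stats::setNames(numeric(length(genes)), genes)
    out[rownames(v)] <- v[, 1]
    out
  }
  syn <- csum("synonymous")
  mis <- csum("missense")
  non <- csum("nonsense")
  spl <- csum(c("splice_acceptor", "splice_donor"))

  has_mpc <- if ("mpc" %in% names(variants)) {
    vapply(genes, function(g) {
      sel <- variants$gene_id == g & variants$consequence == "missense"
      any(sel) && any(!is.na(variants$mpc[sel]))
    }, logical(1))
  } else {
    stats::setNames(rep(FALSE, length(genes)), genes)
  }
  dmis <- if ("mpc" %in% names(variants))
    csum("missense", !is.na(variants$mpc) & variants$mpc > mpc_cutoff)
  else stats::setNames(numeric(length(genes)), genes)
  dmis[!has_mpc] <- NA_real_

  fs <- frameshift_ratio * non
  data.frame(gene_id = genes,
             synonymous = as.numeric(syn[genes]),
             missense = as.numeric(mis[genes]),
             d_mis = as.numeric(dmis[genes]),
             nonsense = as.numeric(non[genes]),
             splice = as.numeric(spl[genes]),
             frameshift = as.numeric(fs[genes]),
             lof_snv = as.numeric(non[genes] + spl[genes] + fs[genes]),
             has_mpc = as.logical(has_mpc[genes]),
             stringsAsFactors = FALSE)
}

#' Cohort calibration multiplier from synonymous counts
#'
#' Cohorts without per-base depth are calibrated by the observed /
#' expected ratio of rare synonymous de novo calls, so that after
#' scaling the expected synonymous count equals the observed one.
#'
#' @param syn_observed observed rare synonymous DNM count.
#' @param syn_expected model-expected synonymous DNM count.
#' @param cohort cohort label.
#' @return list of class `cohort_calibration` with the multiplier.
#' @export
cohort_calibration <- function(syn_observed, syn_expected,
                               cohort = "cohort") {
  stop_if_not(syn_expected > 0, "syn_expected must be > 0")
  stop_if_not(syn_observed > 0, "syn_observed must be > 0")
  structure(list(cohort = cohort, syn_observed = syn_observed,
                 syn_expected = syn_expected,
                 multiplier = syn_observed / syn_expected),
            class = "cohort_calibration")
}

#' Scale a per-gene rate table by a cohort calibration
#'
#' Every per-gene per-class rate is multiplied by the calibration
#' multiplier; class relationships (frameshift = ratio * nonsense,
#' lof_snv = nonsense + splice + frameshift) are preserved.
#'
#' @param rates data.frame from [aggregate_gene_rates()] (or any table
#'   with numeric rate columns and a gene_id column).
#' @param calibration a [cohort_calibration()] (or a bare multiplier).
#' @return rescaled copy of `rates`.
#' @export
calibrate_cohort <- function(rates, calibration) {
  m <- if (inherits(calibration, "cohort_calibration"))
    calibration$multiplier else calibration
  stop_if_not(is_number(m) && m > 0, "multiplier must be > 0")
  num <- vapply(rates, is.numeric, logical(1)) & names(rates) != "gene_id"
  rates[num] <- lapply(rates[num], function(x) x * m)
  rates
}
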