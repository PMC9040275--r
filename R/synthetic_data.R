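#' Synthetic inputs with known ground truth
#'
#' Generators for every input the framework consumes: a toy genome
#' (gene models, chromosome sizes, SD pairs, constraint table), an SV
#' site catalog drawn from a known per-gene rate law, per-gene SNV/CNV
#' rate tables, de novo call tables with spiked-in enriched genes, and
#' predictor tables with controllable class separation. All generators
#' are deterministic given their seed and record their parameters in a
#' `manifest` attribute.
#'
#' @name synthetic_data
NULL

#' Generate a toy genome
#'
#' Genes are laid out sequentially per chromosome with log-normal
#' intergenic gaps (median ~200 kb, so the 1 Mb training-gene flanking
#' rule has bite). Exon counts and exon/intron lengths are log-normal.
#' A fraction of genes is marked LOF-intolerant (LOEUF < 0.278); the
#' intolerant flag follows a persistent Markov chain along the gene
#' order, producing the clustered intolerant regions seen in real
#' genomes. SD pairs are placed near a random subset of genes with
#' separations straddling the 1 Mb rule.
#'
#' @param n_genes total genes (>= 10).
#' @param n_chroms autosomes to distribute genes over (chr1..chrN).
#' @param intolerant_frac stationary fraction of LOF-intolerant genes
#'   (default 0.1, the constrained decile).
#' @param n_sd_pairs segmental-duplication pairs to place (default
#'   `n_genes / 5`).
#' @param max_chrom_bp error if a chromosome would exceed this length
#'   (default 2.5e8).
#' @param seed RNG seed.
#' @return list with `gm` (a [gene_model_set()]), `constraints`,
#'   `sd` (SD-pair data.frame), `chrom_sizes`, and a `manifest`.
#' @export
make_genome <- function(n_genes, n_chroms = 2, intolerant_frac = 0.1,
                        n_sd_pairs = ceiling(n_genes / 5),
                        max_chrom_bp = 2.5e8, seed = 1L) {
  stop_if_not(n_genes >= 10, "need at least 10 genes")
  set.seed(seed)
  chrom_of <- rep(paste0("chr", seq_len(n_chroms)), length.out = n_genes)
  chrom_of <- sort(chrom_of)

  genes <- list(); exons <- list()
  pos <- stats::setNames(rep(NA_real_, n_chroms),
                         paste0("chr", seq_len(n_chroms)))
  for (i in seq_len(n_genes)) {
    ch <- chrom_of[i]
    if (is.na(pos[ch])) pos[ch] <- round(stats::rlnorm(1, log(5e5), 0.6))
    gap <- round(stats::rlnorm(1, log(2e5), 1.0))
    start <- pos[ch] + gap
    n_ex <- max(1L, round(stats::rlnorm(1, log(8), 0.7)))
    ex_len <- pmax(30, round(stats::rlnorm(n_ex, log(150), 0.5)))
    in_len <- if (n_ex > 1)
      pmax(50, round(stats::rlnorm(n_ex - 1, log(3000), 1.0))) else integer()
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len
    gid <- sprintf("g%04d", i)
    genes[[i]] <- data.frame(
      gene_id = gid, chrom = ch,
      strand = sample(c("+", "-"), 1),
      tx_start = start, tx_end = ex_end[n_ex],
      cds_length = round(sum(ex_len) * stats::runif(1, 0.6, 0.95)),
      canonical = TRUE, stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, start = ex_start,
                             end = ex_end, stringsAsFactors = FALSE)
    pos[ch] <- ex_end[n_ex]
    stop_if_not(pos[ch] <= max_chrom_bp,
                paste("infeasible packing on", ch))
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  chrom_sizes <- pos + round(stats::rlnorm(n_chroms, log(2e6), 0.5))

  # persistent Markov chain for the intolerant flag -> clustered regions
  p_stay <- 0.6
  intol <- logical(n_genes)
  if (intolerant_frac > 0) {
    p_enter <- (1 - p_stay) * intolerant_frac / (1 - intolerant_frac)
    intol[1] <- stats::runif(1) < intolerant_frac
    for (i in seq_len(n_genes)[-1]) {
      same_chrom <- genes$chrom[i] == genes$chrom[i - 1]
      p <- if (!same_chrom) intolerant_frac
      else if (intol[i - 1]) p_stay else p_enter
      intol[i] <- stats::runif(1) < p
    }
  }
  constraints <- data.frame(
    gene_id = genes$gene_id,
    pLI = ifelse(intol, stats::runif(n_genes, 0.9, 1),
                 stats::runif(n_genes, 0, 0.9)),
    loeuf = ifelse(intol, stats::runif(n_genes, 0.03, 0.277),
                   stats::runif(n_genes, 0.3, 2)),
    missense_z = stats::rnorm(n_genes, ifelse(intol, 2, 0), 1),
    oe_lof = ifelse(intol, stats::runif(n_genes, 0, 0.3),
                    stats::runif(n_genes, 0.3, 1.2)),
    cds_length = genes$cds_length,
    stringsAsFactors = FALSE)

  sd <- NULL
  if (n_sd_pairs > 0) {
    anchor <- sample(seq_len(n_genes), n_sd_pairs, replace = TRUE)
    a_start <- pmax(0, genes$tx_start[anchor] +
                      round(stats::rnorm(n_sd_pairs, 0, 3e5)))
    len <- pmax(1000, round(stats::rlnorm(n_sd_pairs, log(1e4), 0.6)))
    sep <- round(stats::runif(n_sd_pairs, 0, 2e6))
    sd <- data.frame(chromA = genes$chrom[anchor], startA = a_start,
                     endA = a_start + len,
                     chromB = genes$chrom[anchor],
                     startB = a_start + len + sep,
                     endB = a_start + 2 * len + sep,
                     stringsAsFactors = FALSE)
    sd <- sd_pairs(sd)
  }

  gm <- gene_model_set(genes, exons, chrom_sizes)
  out <- list(gm = gm, constraints = constraints, sd = sd,
              chrom_sizes = chrom_sizes)
  attr(out, "manifest") <- list(generator = "make_genome", seed = seed,
                                n_genes = n_genes, n_chroms = n_chroms,
                                intolerant_frac = intolerant_frac,
                                n_sd_pairs = n_sd_pairs)
  out
}

#' Draw an SV site catalog from a known log-linear rate law
#'
#' Per-gene site counts are multinomial with expectation proportional
#' to `exp(sum(coefficients * covariates))` (covariates in the model
#' units of [compute_covariates()]). Each site is an exon-overlapping
#' deletion: a random exon of the gene is chosen, a size is drawn
#' log-normally within `[50, 1e6]` bp, and breakpoints are placed so
#' the deletion covers a point inside that exon. Population labels are
#' assigned uniformly over `populations`.
#'
#' @param genome output of [make_genome()].
#' @param coefficients named numeric vector over (a subset of)
#'   [cnv_covariate_names()]; missing names mean coefficient 0.
#' @param total_sites total number of catalog sites.
#' @param populations population labels (default 5 gnomAD-style).
#' @param size_meanlog,size_sdlog log-normal size parameters (defaults
#'   log(5e3), 1.2).
#' @param seed RNG seed.
#' @return SV site data.frame ([sv_sites()] format) with a `manifest`
#'   attribute recording the true per-gene expectations.
#' @export
make_sv_catalog <- function(genome, coefficients, total_sites,
                            populations = c("AFR", "AMR", "EAS", "EUR",
                                            "OTH"),
                            size_meanlog = log(5e3), size_sdlog = 1.2,
                            seed = 1L) {
  stop_if_not(all(is.finite(coefficients)), "non-finite coefficients")
  set.seed(seed)
  cov <- compute_covariates(genome$gm, genome$sd, genome$chrom_sizes)
  beta <- stats::setNames(numeric(length(cnv_covariate_names())),
                          cnv_covariate_names())
  beta[names(coefficients)] <- coefficients
  eta <- as.matrix(cov[, cnv_covariate_names()]) %*% beta
  w <- exp(eta - max(eta))
  prob <- as.numeric(w / sum(w))
  if (total_sites == 0) {
    out <- sv_sites(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), sv_type = character(),
                               stringsAsFactors = FALSE))
    attr(out, "manifest") <- list(generator = "make_sv_catalog",
                                  seed = seed, coefficients = coefficients,
                                  total_sites = 0, prob = prob)
    return(out)
  }
  counts <- as.integer(stats::rmultinom(1, total_sites, prob))
  gene_idx <- rep(seq_len(nrow(cov)), counts)
  n <- length(gene_idx)

  g <- genome$gm$genes
  # exons are stored grouped in gene order; pick one uniformly per site
  ex <- genome$gm$exons
  ex_of <- match(ex$gene_id, g$gene_id)
  off <- c(0, cumsum(g$n_exons))            # group offsets into ex
  stopifnot(identical(ex_of, rep(seq_len(nrow(g)), g$n_exons)))
  j <- off[gene_idx] + ceiling(stats::runif(n) * g$n_exons[gene_idx])
  point <- ex$start[j] +
    floor(stats::runif(n) * (ex$end[j] - ex$start[j]))
  size <- round(exp(stats::rnorm(n, size_meanlog, size_sdlog)))
  size <- pmin(pmax(size, 50), 1e6)
  start <- pmax(0, point - floor(stats::runif(n) * size))
  out <- sv_sites(data.frame(
    chrom = g$chrom[gene_idx], start = start, end = start + size,
    sv_type = "DEL",
    population = sample(populations, n, replace = TRUE),
    allele_count = 1L + stats::rpois(n, 0.5),
    stringsAsFactors = FALSE))
  attr(out, "manifest") <- list(generator = "make_sv_catalog", seed = seed,
                                coefficients = coefficients,
                                total_sites = total_sites, prob = prob)
  out
}

#' Generate a per-gene SNV mutation-rate table
#'
#' Class rates are log-normal across genes, scaled by CDS length, with
#' realistic per-generation magnitudes (median per-gene LOF-SNV rate a
#' few 1e-6). The internal class relations of
#' [aggregate_gene_rates()] hold by construction.
#'
#' Class magnitudes follow the genome-wide composition of coding DNMs
#' (roughly 0.25 synonymous, 0.6 missense and 0.085 LOF events per
#' individual per generation over a 20k-gene exome).
#'
#' @param constraints constraint table (gene_id, cds_length) from
#'   [make_genome()].
#' @param base_syn median synonymous rate for a 1.5 kb CDS (default
#'   1.2e-5).
#' @param mpc_frac fraction of genes with MPC annotation (default 0.9).
#' @param frameshift_ratio frameshift:nonsense ratio (default 1.1).
#' @param seed RNG seed.
#' @return data.frame in the [aggregate_gene_rates()] output format.
#' @export
make_rate_table <- function(constraints, base_syn = 1.2e-5,
                            mpc_frac = 0.9, frameshift_ratio = 1.1,
                            seed = 1L) {
  set.seed(seed)
  n <- nrow(constraints)
  len_scale <- constraints$cds_length / 1500
  ln <- function(base) base * len_scale *
    stats::rlnorm(n, 0, 0.4)
  syn <- ln(base_syn)
  mis <- ln(base_syn * 2.4)
  non <- ln(base_syn * 0.16)
  spl <- ln(base_syn * 0.06)
  has_mpc <- stats::runif(n) < mpc_frac
  dmis <- ifelse(has_mpc, mis * stats::runif(n, 0.1, 0.35), NA_real_)
  fs <- frameshift_ratio * non
  data.frame(gene_id = constraints$gene_id,
             synonymous = syn, missense = mis, d_mis = dmis,
             nonsense = non, splice = spl, frameshift = fs,
             lof_snv = non + spl + fs, has_mpc = has_mpc,
             stringsAsFactors = FALSE)
}

#' Simulate a de novo call table from a rate table
#'
#' Per-gene class counts are Poisson with mean `fold * rate * n_trios`,
#' where `fold` (default 1) is taken from `spikes` for enriched genes
#' and applies to the deleterious classes (nonsense, frameshift,
#' splice, d-MIS, and CNV when CNV rates are given); synonymous and
#' non-damaging missense counts stay at their null rates. Missense
#' records carry MPC (> 2 for d-MIS draws, < 2 otherwise, NA for genes
#' without MPC annotation) and amino-acid positions; recurrent-codon
#' d-MIS events can be injected.
#'
#' @param rate_table data.frame from [make_rate_table()] /
#'   [aggregate_gene_rates()].
#' @param n_trios number of trios.
#' @param spikes named numeric vector gene_id -> fold (>= 1).
#' @param cnv_rates optional named vector of absolute LOF-CNV rates.
#' @param cnv_n_trios trios with CNV data (default `n_trios`).
#' @param recurrent named integer vector gene_id -> number of extra
#'   d-MIS records injected at one shared codon.
#' @param cohort cohort label.
#' @param seed RNG seed.
#' @return DNM record data.frame (columns sample, gene, consequence,
#'   mpc, cohort, aa_pos).
#' @export
make_dnm_cohort <- function(rate_table, n_trios, spikes = NULL,
                            cnv_rates = NULL, cnv_n_trios = n_trios,
                            recurrent = NULL, cohort = "synthetic",
                            seed = 1L) {
  stop_if_not(all(spikes >= 1), "spike folds must be >= 1")
  set.seed(seed)
  if (n_trios == 0)
    return(data.frame(sample = character(), gene = character(),
                      consequence = character(), mpc = numeric(),
                      cohort = character(), aa_pos = integer(),
                      stringsAsFactors = FALSE))
  fold <- stats::setNames(rep(1, nrow(rate_table)), rate_table$gene_id)
  if (!is.null(spikes)) fold[names(spikes)] <- spikes

  rows <- list()
  add <- function(gene, consequence, k, mpc = NA_real_, aa = NA_integer_) {
    if (k <= 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      sample = sprintf("s%06d", sample.int(n_trios, k, replace = TRUE)),
      gene = gene, consequence = consequence,
      mpc = if (length(mpc) == k) mpc else rep(mpc, k),
      cohort = cohort,
      aa_pos = if (length(aa) == k) aa else rep(aa, k),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rate_table))) {
    g <- rate_table$gene_id[i]
    f <- fold[g]
    n_aa <- max(50L, 400L)
    draw <- function(rate, f0 = 1) stats::rpois(1, f0 * rate * n_trios)
    add(g, "synonymous", draw(rate_table$synonymous[i]))
    dmis_rate <- if (isTRUE(rate_table$has_mpc[i]) &&
                     !is.na(rate_table$d_mis[i]))
      rate_table$d_mis[i] else 0
    k_dmis <- draw(dmis_rate, f)
    if (k_dmis > 0)
      add(g, "missense", k_dmis, mpc = stats::runif(k_dmis, 2.1, 5),
          aa = sample.int(n_aa, k_dmis, replace = TRUE))
    k_mis <- draw(max(rate_table$missense[i] - dmis_rate, 0))
    if (k_mis > 0)
      add(g, "missense", k_mis,
          mpc = if (isTRUE(rate_table$has_mpc[i]))
            stats::runif(k_mis, 0, 1.9) else NA_real_,
          aa = sample.int(n_aa, k_mis, replace = TRUE))
    add(g, "nonsense", draw(rate_table$nonsense[i], f))
    add(g, "frameshift", draw(rate_table$frameshift[i], f))
    k_spl <- draw(rate_table$splice[i], f)
    if (k_spl > 0)
      for (cs in sample(c("splice_acceptor", "splice_donor"), k_spl,
                        replace = TRUE))
        add(g, cs, 1L)
    if (!is.null(cnv_rates) && g %in% names(cnv_rates))
      add(g, "cnv_lof", stats::rpois(1, f * cnv_rates[g] * cnv_n_trios))
  }
  if (!is.null(recurrent)) {
    for (g in names(recurrent)) {
      k <- recurrent[[g]]
      aa <- sample.int(400L, 1)
      add(g, "missense", k, mpc = stats::runif(k, 2.1, 5),
          aa = rep(aa, k))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), gene = character(),
               consequence = character(), mpc = numeric(),
               cohort = character(), aa_pos = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(generator = "make_dnm_cohort", seed = seed,
                                n_trios = n_trios, spikes = spikes,
                                cohort = cohort)
  out
}

#' Generate a predictor table with controllable class separation
#'
#' Numeric predictors are class-conditional Gaussians whose means are
#' shifted by `separation` (in units of the within-class SD, spread
#' over the predictors); binary predictors and the module category get
#' class-dependent probabilities that converge as `separation -> 0`,
#' where the classes are exchangeable.
#'
#' @param n_pos,n_neg class sizes.
#' @param separation mean shift (>= 0).
#' @param seed RNG seed.
#' @return list with `raw` (data.frame for
#'   [preprocess_predictors()]) and `labels` (1 = positive).
#' @export
make_predictor_table <- function(n_pos, n_neg, separation, seed = 1L) {
  stop_if_not(separation >= 0, "separation must be >= 0")
  set.seed(seed)
  n <- n_pos + n_neg
  y <- rep(c(1, 0), c(n_pos, n_neg))
  s <- separation * y
  shift <- function(w) stats::rnorm(n, w * s, 1)
  p_bin <- stats::plogis(stats::qlogis(0.25) + 1.5 * s)
  mod_levels <- c("M1", "M4", "M7", "M13", "Others")
  p_mod <- stats::plogis(stats::qlogis(0.3) + 1.2 * s)  # P(in a listed module)
  module <- ifelse(stats::runif(n) < p_mod,
                   sample(mod_levels[1:4], n, replace = TRUE), "Others")
  raw <- data.frame(
    gene_id = sprintf("p%05d", seq_len(n)),
    pli = stats::plogis(shift(0.6)),
    loeuf = exp(-0.4 * shift(0.6)),
    missense_z = shift(0.6),
    cds_length = round(1500 * exp(0.2 * stats::rnorm(n))),
    tsea_brain = as.integer(stats::runif(n) < p_bin),
    brain_coord_count = stats::rpois(n, exp(0.35 * s)),
    module = module,
    go_term_count = stats::rpois(n, 2 * exp(0.4 * s)),
    string_member = as.integer(stats::runif(n) < p_bin),
    stringsAsFactors = FALSE)
  out <- list(raw = raw, labels = y)
  attr(out, "manifest") <- list(generator = "make_predictor_table",
                                seed = seed, n_pos = n_pos, n_neg = n_neg,
                                separation = separation)
  out
}
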