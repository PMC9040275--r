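#' Neutral Wright-Fisher drift simulation of a gene
#'
#' Forward simulation demonstrating that, absent selection, the mean
#' number of variant sites of a gene segregating in a population sample
#' is proportional to the gene's total mutation rate -- the rationale
#' for reading relative CNV mutation rates off population site counts.
#'
#' Each gene carries `n_sites` unlinked biallelic mutation sites. Per
#' generation, each of the `2 * pop_size` allele copies mutates with
#' probability `site_mu` (two-way, equal forward/backward rate, so long
#' runs are stationary), then the next generation's derived-allele count
#' is a binomial draw from the post-mutation frequency. All sites start
#' monomorphic ancestral; the run itself is the burn-in (use >= 20 *
#' pop_size generations to reach mutation-drift equilibrium). After the
#' final generation, `2 * sample_size` alleles are drawn without
#' replacement and a site counts as observed when it is polymorphic in
#' the sample (0 < derived < all; set `require_polymorphic = FALSE` to
#' count any sampled derived allele).
#'
#' @name drift_sim
NULL

#' Drift-simulation configuration
#'
#' Defaults are the full-scale neutral setting (population 100,000 run
#' for 1,000,000 generations, 10,000 sampled individuals, >= 300
#' replicates, per-site rates <= 1e-7); tests and examples use
#' scaled-down values.
#'
#' @param n_sites number of mutation sites in the gene.
#' @param site_mu per-site per-generation mutation probability.
#' @param pop_size constant diploid population size.
#' @param generations generations to evolve.
#' @param sample_size diploid individuals sampled at the end.
#' @param reps independent replicate simulations.
#' @param selection_coeff,dominance_coeff must be 0: only the neutral
#'   model is implemented.
#' @param require_polymorphic count only sites polymorphic in the
#'   sample (default TRUE).
#' @param seed integer RNG seed.
#' @return list of class `drift_config`.
#' @export
drift_config <- function(n_sites = 320, site_mu = 1e-8, pop_size = 1e5,
                         generations = 1e6, sample_size = 1e4, reps = 300,
                         selection_coeff = 0, dominance_coeff = 0,
                         require_polymorphic = TRUE, seed = 1L) {
  stop_if_not(selection_coeff == 0 && dominance_coeff == 0,
              "only the neutral model (s = h = 0) is implemented")
  stop_if_not(pop_size > sample_size && sample_size > 0,
              "need pop_size > sample_size > 0")
  stop_if_not(reps >= 1, "reps must be >= 1")
  stop_if_not(site_mu >= 0 && site_mu < 1, "site_mu must be in [0, 1)")
  structure(list(n_sites = as.integer(n_sites), site_mu = site_mu,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 sample_size = as.integer(sample_size),
                 reps = as.integer(reps),
                 require_polymorphic = isTRUE(require_polymorphic),
                 seed = as.integer(seed)),
            class = "drift_config")
}

#' Simulate segregating-site counts for a gene
#'
#' @param config a [drift_config()].
#' @return list of class `drift_result`: `config`, `per_rep_counts`
#'   (integer vector, one per replicate), `mean_segregating_sites`, and
#'   `total_gene_rate = n_sites * site_mu`.
#' @export
simulate_gene <- function(config) {
  stop_if_not(inherits(config, "drift_config"), "need a drift_config")
  set.seed(config$seed)
  n2 <- 2L * config$pop_size           # allele copies in the population
  ns <- 2L * config$sample_size        # allele copies in the sample
  mu <- config$site_mu
  m <- config$n_sites * config$reps    # all sites of all reps, unlinked

  cnt <- integer(m)                    # derived-allele copy number
  for (g in seq_len(config$generations)) {
    p <- cnt / n2
    p <- p * (1 - mu) + (1 - p) * mu   # two-way mutation
    cnt <- stats::rbinom(m, n2, p)
  }
  # sample ns alleles without replacement at each site
  samp <- stats::rhyper(m, cnt, n2 - cnt, ns)
  seg <- if (config$require_polymorphic) samp > 0L & samp < ns else samp > 0L
  per_rep <- as.integer(rowsum(as.integer(seg),
                               rep(seq_len(config$reps),
                                   each = config$n_sites)))
  structure(list(config = config, per_rep_counts = per_rep,
                 mean_segregating_sites = mean(per_rep),
                 total_gene_rate = config$n_sites * config$site_mu),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf(paste0("drift_result: %d sites x mu %.2e (total rate %.2e), ",
                     "%d reps -> mean segregating sites %.3f\n"),
              x$config$n_sites, x$config$site_mu, x$total_gene_rate,
              x$config$reps, x$mean_segregating_sites))
  invisible(x)
}

#' Watterson expectation for a drift configuration
#'
#' Infinite-sites neutral expectation of the number of segregating
#' sites in a sample: `a_{n-1} * 4 * Ne * mu_total` with `n` sampled
#' alleles, valid when `4 * Ne * site_mu << 1`.
#'
#' @param config a [drift_config()].
#' @return expected mean segregating-site count.
#' @export
drift_expected_sites <- function(config) {
  a <- harmonic_number(2L * config$sample_size - 1L)
  a * 4 * config$pop_size * config$n_sites * config$site_mu
}

#' Correlation between gene mutation rate and sampled site counts
#'
#' Runs [simulate_gene()] on every combination of `n_sites_grid` and
#' `site_mu_grid` and returns the Pearson correlation between the total
#' gene rate and the replicate-mean segregating-site count.
#'
#' @param n_sites_grid integer vector of site counts.
#' @param site_mu_grid numeric vector of per-site rates.
#' @param ... further arguments passed to [drift_config()] (pop_size,
#'   generations, sample_size, reps, seed, ...).
#' @return list with `grid` (data.frame of n_sites, site_mu, total_rate,
#'   mean_segregating_sites) and `correlation`.
#' @export
rate_site_correlation <- function(n_sites_grid, site_mu_grid, ...) {
  grid <- expand.grid(n_sites = n_sites_grid, site_mu = site_mu_grid)
  stop_if_not(nrow(grid) >= 2, "need at least two grid points")
  total <- grid$n_sites * grid$site_mu
  stop_if_not(length(unique(total)) >= 2,
              "degenerate grid: all total rates equal")
  extra <- list(...)
  base_seed <- extra$seed %||% 1L
  extra$seed <- NULL
  means <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- do.call(drift_config,
                   c(list(n_sites = grid$n_sites[i],
                          site_mu = grid$site_mu[i],
                          seed = base_seed + i), extra))
    simulate_gene(cfg)$mean_segregating_sites
  }, numeric(1))
  grid$total_rate <- total
  grid$mean_segregating_sites <- means
  list(grid = grid, correlation = stats::cor(total, means))
}
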