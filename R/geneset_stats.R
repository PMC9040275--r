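#' Gene-set overrepresentation statistics
#'
#' Shared machinery for tissue-specific expression (pSI-based),
#' brain-coordinate, co-expression-module, GO-term and PPI-cluster
#' enrichment: upper-tail Fisher / hypergeometric tests with BH
#' adjustment, resampling-based empirical p-values for counts of
#' enriched terms, and the Jaccard + overlap combined similarity
#' coefficient used to cluster enriched terms.
#'
#' @name geneset_stats
NULL

#' Upper-tail overrepresentation test of a gene set in a target list
#'
#' Tests whether the overlap between `target` and `members` (both
#' restricted to `universe`) is larger than expected under the
#' hypergeometric null. `method = "fisher_one_tailed"` and
#' `"hypergeometric"` are algebraically identical (a one-tailed Fisher
#' test on a 2x2 table is the hypergeometric tail) and are both kept as
#' an internal cross-check.
#'
#' @param target character vector of genes of interest (must lie in
#'   `universe`).
#' @param members character vector: the gene set.
#' @param universe character vector of all testable genes.
#' @param method `"hypergeometric"` (default) or `"fisher_one_tailed"`.
#' @return list with overlap, p, enrichment_ratio (observed/expected
#'   overlap), set_size, target_size, universe_size.
#' @export
overrep_test <- function(target, members, universe,
                         method = c("hypergeometric",
                                    "fisher_one_tailed")) {
  method <- match.arg(method)
  universe <- unique(universe)
  stop_if_not(length(universe) > 0, "empty universe")
  target <- unique(intersect(target, universe))
  stop_if_not(length(target) > 0, "target has no genes in the universe")
  set <- unique(intersect(members, universe))
  k <- length(intersect(target, set))
  m <- length(set); n <- length(universe) - m; t <- length(target)
  p <- if (method == "hypergeometric") {
    stats::phyper(k - 1, m, n, t, lower.tail = FALSE)
  } else {
    tab <- matrix(c(k, t - k, m - k, n - (t - k)), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  expected <- t * m / length(universe)
  list(overlap = k, p = p,
       enrichment_ratio = if (expected > 0) k / expected else NA_real_,
       set_size = m, target_size = t, universe_size = length(universe))
}

#' Test a collection of gene sets and BH-adjust
#'
#' @param target genes of interest.
#' @param sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe all testable genes.
#' @param method see [overrep_test()].
#' @param min_size,max_size set-size filter applied after restriction
#'   to the universe (defaults 1 and Inf; GO-style analyses use 20-500).
#' @return data.frame: set_id, overlap, set_size, enrichment_ratio, p,
#'   q (BH over the tested sets).
#' @export
overrep_table <- function(target, sets, universe,
                          method = "hypergeometric",
                          min_size = 1, max_size = Inf) {
  sizes <- vapply(sets, function(s)
    length(unique(intersect(s, universe))), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  stop_if_not(length(sets) > 0, "no gene set passes the size filter")
  rows <- lapply(names(sets), function(id) {
    r <- overrep_test(target, sets[[id]], universe, method = method)
    data.frame(set_id = id, overlap = r$overlap, set_size = r$set_size,
               enrichment_ratio = r$enrichment_ratio, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values (monotone in p-rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(p > 0 & p <= 1), "p-values must be in (0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Empirical p-value for the number of enriched terms in a target list
#'
#' Draws `n_draws` random gene lists of `target_size` from the
#' universe, recounts how many of the supplied sets are enriched (BH q
#' below `q_threshold`) in each draw, and returns the proportion of
#' draws with a count >= `observed_n_terms`. The resolution floor
#' `1/n_draws` is reported alongside.
#'
#' @param observed_n_terms enriched-term count observed for the real
#'   target list.
#' @param target_size size of the target list.
#' @param sets named list of gene sets (typically the terms enriched in
#'   the known-gene list).
#' @param universe sampling universe.
#' @param q_threshold BH threshold defining "enriched" per draw
#'   (default 0.1).
#' @param n_draws number of random draws (default 1000).
#' @param method see [overrep_test()].
#' @param seed RNG seed.
#' @return list with p, floor (= 1/n_draws), draws (the per-draw
#'   counts).
#' @export
empirical_term_count_p <- function(observed_n_terms, target_size, sets,
                                   universe, q_threshold = 0.1,
                                   n_draws = 1000,
                                   method = "hypergeometric", seed = 1L) {
  stop_if_not(n_draws >= 1, "n_draws must be >= 1")
  universe <- unique(universe)
  stop_if_not(target_size <= length(universe),
              "target_size exceeds universe size")
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    tgt <- sample(universe, target_size)
    tab <- overrep_table(tgt, sets, universe, method = method)
    sum(tab$q < q_threshold)
  }, integer(1))
  list(p = mean(draws >= observed_n_terms), floor = 1 / n_draws,
       draws = draws)
}

#' Jaccard + overlap combined similarity of two gene sets
#'
#' `0.5 * |A ∩ B| / |A ∪ B| + 0.5 * |A ∩ B| / min(|A|, |B|)`. Term
#' networks draw an edge when this exceeds a threshold (0.375 for
#' PPI-cluster maps, 0.5 for GO-term maps).
#'
#' @param a,b character vectors (nonempty).
#' @return combined coefficient in [0, 1].
#' @export
term_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  stop_if_not(length(a) > 0 && length(b) > 0, "empty gene set")
  i <- length(intersect(a, b))
  0.5 * i / length(union(a, b)) + 0.5 * i / min(length(a), length(b))
}

#' Edges of a term-similarity network
#'
#' @param sets named list of gene sets.
#' @param threshold minimum combined coefficient for an edge (default
#'   0.375).
#' @return data.frame of edges: set_a, set_b, similarity.
#' @export
term_similarity_edges <- function(sets, threshold = 0.375) {
  ids <- names(sets)
  if (length(ids) < 2)
    return(data.frame(set_a = character(), set_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  pairs <- utils::combn(seq_along(ids), 2)
  sim <- apply(pairs, 2, function(ij)
    term_similarity(sets[[ij[1]]], sets[[ij[2]]]))
  keep <- sim > threshold
  data.frame(set_a = ids[pairs[1, keep]], set_b = ids[pairs[2, keep]],
             similarity = sim[keep], stringsAsFactors = FALSE)
}

#' Specifically-expressed gene sets from a pSI matrix
#'
#' One gene set per column (tissue / brain coordinate) containing the
#' genes with pSI strictly below `threshold`. Columns left empty are
#' dropped with a message.
#'
#' @param psi data.frame or matrix of pSI values in (0, 1], rows =
#'   genes (rownames or a gene_id column), columns = coordinates.
#' @param threshold strict pSI cutoff (default 0.05).
#' @return named list of character vectors.
#' @export
psi_select <- function(psi, threshold = 0.05) {
  if (is.data.frame(psi) && "gene_id" %in% names(psi)) {
    rn <- psi$gene_id
    psi <- as.matrix(psi[, setdiff(names(psi), "gene_id"), drop = FALSE])
    rownames(psi) <- rn
  }
  psi <- as.matrix(psi)
  stop_if_not(all(psi > 0 & psi <= 1, na.rm = TRUE),
              "pSI values must be in (0,1]")
  sets <- lapply(seq_len(ncol(psi)), function(j)
    rownames(psi)[!is.na(psi[, j]) & psi[, j] < threshold])
  names(sets) <- colnames(psi)
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty))
    dn_msg("psi_select: ", sum(empty), " empty coordinate set(s) dropped")
  sets[!empty]
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path input path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (defaults to the ids).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
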