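# Shared fixture builders. Everything is generated in code; no files.

options(dnburden.verbose = FALSE)

# Two genes on chr1, one on chrX, hand-picked coordinates (0-based
# half-open). geneA: exons [100,200) [300,450) [600,700); geneB:
# exons [2000,2100) [2500,2600); geneX on chrX.
tiny_gm <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneX"),
    chrom = c("chr1", "chr1", "chrX"),
    strand = c("+", "-", "+"),
    tx_start = c(100, 2000, 50),
    tx_end = c(700, 2600, 500),
    cds_length = c(250, 150, 300),
    canonical = TRUE,
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB", "geneX"),
    start = c(100, 300, 600, 2000, 2500, 50),
    end = c(200, 450, 700, 2100, 2600, 500),
    stringsAsFactors = FALSE)
  gene_model_set(genes, exons,
                 chrom_sizes = c(chr1 = 10000, chrX = 10000))
}

# brute-force per-base exon overlap (independent of the interval code)
brute_overlap <- function(site_start, site_end, chrom, gene_id, gm) {
  ex <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  if (gm$genes$chrom[match(gene_id, gm$genes$gene_id)] != chrom)
    return(FALSE)
  if (site_end <= site_start) return(FALSE)
  site_bases <- seq(site_start, site_end - 1)
  exon_bases <- unlist(Map(function(s, e) seq(s, e - 1), ex$start, ex$end))
  any(site_bases %in% exon_bases)
}

# hand step-up BH, independent of stats::p.adjust
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force pairwise AUC (ties count half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
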