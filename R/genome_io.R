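#' Gene models, SV catalogs and the interval conventions used throughout
#'
#' All coordinates inside the package are 0-based half-open (BED-style):
#' an interval `[start, end)` covers bases `start .. end-1`. GFF3 input
#' (1-based, closed) is converted on read; BED input is taken as-is.
#' Two intervals overlap iff `a_start < b_end && b_start < a_end`.
#'
#' @name genome_io
NULL

#' Construct a validated gene-model set
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_length`, `canonical` (logical), and
#'   optionally `loeuf` and other annotations. Coordinates 0-based
#'   half-open.
#' @param exons data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), one row per exon.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp,
#'   or `NULL` to skip the bounds check.
#' @return An object of class `gene_model_set`: a list with elements
#'   `genes` (with derived columns `n_exons`, `gene_length`,
#'   `transcript_length`, `is_autosomal`) and `exons` (sorted,
#'   non-overlapping per gene).
#' @export
gene_model_set <- function(genes, exons, chrom_sizes = NULL) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  stop_if_not(all(need %in% names(genes)),
              paste("genes must have columns:", paste(need, collapse = ", ")))
  stop_if_not(all(c("gene_id", "start", "end") %in% names(exons)),
              "exons must have columns gene_id, start, end")
  stop_if_not(!anyDuplicated(genes$gene_id), "duplicated gene_id")
  if (any(exons$end <= exons$start))
    stop("exon with end <= start: invalid interval", call. = FALSE)
  if (any(genes$tx_end <= genes$tx_start))
    stop("transcript with tx_end <= tx_start", call. = FALSE)
  if (any(exons$start < 0) || any(genes$tx_start < 0))
    stop("negative coordinates are not allowed", call. = FALSE)

  # sort exons and check per-gene disjointness and transcript bounds
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (g in names(by_gene)) {
    idx <- by_gene[[g]]
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping exons in gene ", g, call. = FALSE)
    gi <- match(g, genes$gene_id)
    if (is.na(gi)) stop("exon references unknown gene ", g, call. = FALSE)
    if (s[1] < genes$tx_start[gi] || e[length(e)] > genes$tx_end[gi])
      stop("exon outside transcript bounds in gene ", g, call. = FALSE)
  }

  n_ex <- vapply(by_gene, length, integer(1))
  tx_len <- vapply(by_gene, function(i) sum(exons$end[i] - exons$start[i]),
                   numeric(1))
  genes$n_exons <- as.integer(n_ex[genes$gene_id])
  genes$transcript_length <- as.numeric(tx_len[genes$gene_id])
  genes$gene_length <- genes$tx_end - genes$tx_start
  stop_if_not(all(genes$transcript_length <= genes$gene_length),
              "transcript length exceeds gene length")
  genes$is_autosomal <- !genes$chrom %in% c("chrX", "chrY", "X", "Y")

  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(genes$chrom, names(chrom_sizes))
    stop_if_not(length(unknown) == 0,
                paste("unknown chromosome(s):", paste(unknown, collapse = ",")))
    if (any(genes$tx_end > chrom_sizes[genes$chrom]))
      stop("transcript extends beyond chromosome end", call. = FALSE)
  }

  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read canonical protein-coding gene models from GFF3
#'
#' Parses gene/transcript/exon features. Transcripts are kept when their
#' `canonical` attribute is truthy (`"1"`, `"true"`, `"yes"`) and their
#' `biotype`/`transcript_biotype` attribute (if present) equals
#' `protein_coding`; canonicality is taken from the annotation, not
#' recomputed. Dropped transcripts are reported via a message.
#' GFF3 1-based closed coordinates become 0-based half-open.
#'
#' @param path path to a GFF3 file.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(path, chrom_sizes = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  ex <- gr[type == "exon"]
  if (length(tx) == 0) return(empty_gene_model_set(chrom_sizes))

  txm <- S4Vectors::mcols(tx)
  canon <- rep(TRUE, length(tx))
  if (!is.null(txm$canonical))
    canon <- tolower(as.character(txm$canonical)) %in% c("1", "true", "yes")
  bt <- txm$transcript_biotype %||% txm$biotype
  coding <- if (is.null(bt)) rep(TRUE, length(tx)) else
    as.character(bt) == "protein_coding"
  keep <- canon & coding
  if (any(!keep))
    dn_msg("read_gene_models: dropped ", sum(!keep),
           " non-canonical/non-coding transcript(s)")
  tx <- tx[keep]
  txm <- S4Vectors::mcols(tx)

  tx_id <- as.character(txm$ID)
  gene_id <- as.character(txm$gene_id %||% txm$Parent %||% txm$ID)
  cds_len <- if (!is.null(txm$cds_length))
    as.numeric(as.character(txm$cds_length)) else rep(NA_real_, length(tx))

  exm <- S4Vectors::mcols(ex)
  parent <- as.character(exm$Parent)
  sel <- parent %in% tx_id
  ex <- ex[sel]; parent <- parent[sel]

  genes <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    tx_start = GenomicRanges::start(tx) - 1L,
    tx_end = GenomicRanges::end(tx),
    cds_length = cds_len,
    canonical = TRUE,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = gene_id[match(parent, tx_id)],
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  gene_model_set(genes, exons, chrom_sizes)
}

empty_gene_model_set <- function(chrom_sizes = NULL) {
  gene_model_set(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), tx_start = numeric(),
               tx_end = numeric(), cds_length = numeric(),
               canonical = logical(), stringsAsFactors = FALSE),
    data.frame(gene_id = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE),
    chrom_sizes)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open coordinates
#' become 1-based closed GFF3 records with `gene_id`, `canonical` and
#' `cds_length` attributes.
#'
#' @param gm a [gene_model_set()].
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    tid <- paste0("tx_", g$gene_id[i])
    writeLines(sprintf(
      "%s\tdnburden\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;canonical=1;transcript_biotype=protein_coding;cds_length=%s",
      g$chrom[i], g$tx_start[i] + 1L, g$tx_end[i], g$strand[i], tid,
      g$gene_id[i],
      ifelse(is.na(g$cds_length[i]), "0", format(g$cds_length[i],
                                                 scientific = FALSE))), con)
    ex <- gm$exons[gm$exons$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tdnburden\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom[i], ex$start[j] + 1L, ex$end[j],
                         g$strand[i], tid), con)
  }
  invisible(path)
}

#' Read a population SV site catalog from BED-like text
#'
#' Expects columns chrom, start, end, sv_type and optionally population
#' and allele_count (tab-separated, no header, `#` comments allowed;
#' BED 0-based half-open). Only deletion (`DEL`) records are retained;
#' the number of filtered non-DEL records is reported.
#'
#' @param path path to the BED-like file.
#' @return data.frame with columns chrom, start, end, sv_type,
#'   population, allele_count, size.
#' @export
read_sv_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 4, "SV BED needs >= 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "sv_type")
  df$population <- if (ncol(df) >= 5) as.character(df[[5]]) else "ALL"
  df$allele_count <- if (ncol(df) >= 6) as.integer(df[[6]]) else 1L
  df <- df[, c("chrom", "start", "end", "sv_type", "population",
               "allele_count")]
  sv_sites(df)
}

#' Validate an SV site table
#'
#' @param df data.frame with at least chrom, start, end, sv_type.
#' @return validated data.frame of DEL records with a `size` column.
#' @export
sv_sites <- function(df) {
  if (!"population" %in% names(df)) df$population <- rep("ALL", nrow(df))
  if (!"allele_count" %in% names(df)) df$allele_count <- rep(1L, nrow(df))
  if (any(df$start < 0)) stop("negative SV coordinates", call. = FALSE)
  if (any(df$end <= df$start))
    stop("SV site with end <= start", call. = FALSE)
  non_del <- df$sv_type != "DEL"
  if (any(non_del))
    dn_msg("read_sv_sites: filtered ", sum(non_del), " non-DEL record(s)")
  df <- df[!non_del, , drop = FALSE]
  df$size <- df$end - df$start
  rownames(df) <- NULL
  df
}

#' Write SV sites as BED-like text
#' @param sites data.frame as returned by [read_sv_sites()].
#' @param path output path.
#' @export
write_sv_sites <- function(sites, path) {
  utils::write.table(
    sites[, c("chrom", "start", "end", "sv_type", "population",
              "allele_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read segmental-duplication pairs (BEDPE-like)
#'
#' Columns: chromA, startA, endA, chromB, startB, endB (0-based
#' half-open). A `separation` column is derived: the gap between the two
#' members on the same chromosome (0 when they touch or overlap; `Inf`
#' across chromosomes).
#'
#' @param path input path.
#' @return data.frame with the six coordinate columns plus `separation`.
#' @export
read_sd_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 6, "SD pair file needs >= 6 columns")
  names(df)[1:6] <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  df <- df[, 1:6]
  sd_pairs(df)
}

#' Validate an SD-pair table and derive separations
#' @param df data.frame with chromA,startA,endA,chromB,startB,endB.
#' @return validated data.frame with a `separation` column.
#' @export
sd_pairs <- function(df) {
  if (any(df$endA <= df$startA) || any(df$endB <= df$startB))
    stop("SD interval with end <= start", call. = FALSE)
  same <- df$chromA == df$chromB
  gap <- pmax(0, pmax(df$startA, df$startB) - pmin(df$endA, df$endB))
  df$separation <- ifelse(same, gap, Inf)
  df
}

#' Read a gene-level constraint table (TSV with header)
#'
#' Expected columns: gene_id, pLI, loeuf, missense_z, oe_lof, cds_length.
#' @param path input path.
#' @return data.frame, validated (0 <= pLI <= 1, loeuf >= 0).
#' @export
read_constraints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stop_if_not(all(c("gene_id", "pLI", "loeuf") %in% names(df)),
              "constraint table needs gene_id, pLI, loeuf columns")
  ok <- is.na(df$pLI) | (df$pLI >= 0 & df$pLI <= 1)
  stop_if_not(all(ok), "pLI outside [0,1]")
  stop_if_not(all(is.na(df$loeuf) | df$loeuf >= 0), "negative LOEUF")
  df
}

#' Read a de novo mutation call table (TSV with header)
#'
#' Expected columns: sample, gene, consequence, mpc, cohort, aa_pos
#' (mpc/aa_pos may be NA). Consequence must be one of synonymous,
#' missense, nonsense, frameshift, splice_acceptor, splice_donor,
#' cnv_lof.
#'
#' @param path input path.
#' @return data.frame of DNM records.
#' @export
read_dnm_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("sample", "gene", "consequence")
  stop_if_not(all(need %in% names(df)),
              "DNM table needs sample, gene, consequence columns")
  if (!"mpc" %in% names(df)) df$mpc <- NA_real_
  if (!"cohort" %in% names(df)) df$cohort <- "cohort1"
  if (!"aa_pos" %in% names(df)) df$aa_pos <- NA_integer_
  bad <- setdiff(unique(df$consequence), dnm_consequences())
  stop_if_not(length(bad) == 0,
              paste("unknown consequence class:", paste(bad, collapse = ",")))
  if (any(!is.na(df$mpc) & df$consequence != "missense"))
    stop("mpc present for non-missense record", call. = FALSE)
  df
}

#' Consequence classes recognized in DNM tables
#' @return character vector of valid consequence labels.
#' @export
dnm_consequences <- function() {
  c("synonymous", "missense", "nonsense", "frameshift",
    "splice_acceptor", "splice_donor", "cnv_lof")
}

#' LOF consequence classes (nonsense, frameshift, splice sites, CNV)
#' @return character vector.
#' @export
lof_consequences <- function() {
  c("nonsense", "frameshift", "splice_acceptor", "splice_donor", "cnv_lof")
}

#' Read a two-column chromosome-size table (chrom, length)
#' @param path input path (TSV, no header).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

exon_granges <- function(gm) {
  GenomicRanges::GRanges(
    seqnames = gm$genes$chrom[match(gm$exons$gene_id, gm$genes$gene_id)],
    ranges = IRanges::IRanges(start = gm$exons$start + 1L,
                              end = gm$exons$end),
    gene_id = gm$exons$gene_id)
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end))
}

#' Does a deletion overlap any exon of a gene?
#'
#' Half-open intersection: a deletion ending exactly at an exon start
#' (or starting at an exon end) does not overlap. Any overlap of >= 1 bp
#' counts.
#'
#' @param site_start,site_end deletion interval, 0-based half-open.
#' @param chrom chromosome of the deletion.
#' @param gene_id gene to test.
#' @param gm a [gene_model_set()].
#' @return logical flag.
#' @export
overlaps_exon <- function(site_start, site_end, chrom, gene_id, gm) {
  ex <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  gi <- match(gene_id, gm$genes$gene_id)
  stop_if_not(!is.na(gi), paste("unknown gene", gene_id))
  if (gm$genes$chrom[gi] != chrom) return(FALSE)
  any(site_start < ex$end & ex$start < site_end)
}

#' Per-site lists of exon-overlapped genes
#'
#' Vectorized exon-overlap assignment: for each SV site, the set of
#' genes with >= 1 bp of exonic overlap (half-open convention).
#'
#' @param sites SV site data.frame.
#' @param gm a [gene_model_set()].
#' @return list (length `nrow(sites)`) of character vectors of gene ids.
#' @export
site_gene_hits <- function(sites, gm) {
  if (nrow(sites) == 0 || nrow(gm$exons) == 0)
    return(rep(list(character()), nrow(sites)))
  exg <- exon_granges(gm)
  sg <- sites_granges(sites)
  hits <- GenomicRanges::findOverlaps(sg, exg)
  out <- rep(list(character()), nrow(sites))
  if (length(hits) > 0) {
    sp <- split(S4Vectors::mcols(exg)$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    idx <- as.integer(names(sp))
    out[idx] <- lapply(sp, function(g) unique(g))
  }
  out
}
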