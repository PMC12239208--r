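# Readers and writers for the standard formats the pipeline touches:
# FASTA (reference), VCF v4.2 with DP/AD (pools and sectors), GFF3 (CDS
# features), BED or two-column TSV (error-prone-site blacklist).
# Coordinates are 1-based inclusive internally; BED is converted on read.

#' Read a reference genome from FASTA
#'
#' Each FASTA record becomes one chromosome; record order is preserved and
#' lowercase bases are normalised to uppercase. Only the alphabet
#' `{A, C, G, T, N}` is accepted: ambiguity codes other than `N` are rejected
#' so that foreign data fails fast.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] named by chromosome
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(genome) == 0) {
    warnf("FASTA '%s' contains no records: empty genome", path)
    return(genome)
  }
  # drop description after first whitespace, as aligners do
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) stopf("duplicate chromosome names in '%s'", path)
  genome <- Biostrings::DNAStringSet(toupper(genome))
  validate_genome(genome)
  genome
}

#' Validate a reference genome
#'
#' @param genome a named [Biostrings::DNAStringSet]
#' @return the genome, invisibly
#' @export
validate_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stopf("genome chromosomes must carry unique names")
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0))
    stopf("chromosome(s) %s contain letters outside {A,C,G,T,N}",
          paste(names(genome)[other > 0], collapse = ", "))
  invisible(genome)
}

#' Write a genome to FASTA
#' @param genome named [Biostrings::DNAStringSet]
#' @param path output file
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Read per-sample SNP calls from a VCF
#'
#' Converts biallelic SNP records of a single-sample VCF v4.x into the
#' package's variant-call table. The allele frequency is always recomputed
#' from the allelic depths (`AD`), never trusted from an INFO field, so the
#' homozygosity threshold has a single definition throughout the pipeline.
#' Indel and multi-allelic records are skipped with one counted warning.
#'
#' @param path VCF file (plain or gzipped)
#' @param role sample role, see [pool_variant_set()]
#' @param genome optional genome used to reject calls on unknown chromosomes
#' @return a [pool_variant_set()]
#' @export
read_vcf <- function(path, role = "mutant_pool", genome = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sample_id <- if (ncol(vcf@gt) >= 2) colnames(vcf@gt)[2] else
    tools::file_path_sans_ext(basename(path))
  if (nrow(vcf@fix) == 0)
    return(pool_variant_set(sample_id, role, empty_calls(), genome))
  fix <- as.data.frame(vcf@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)

  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    warnf("%s: skipped %d non-SNP or multi-allelic record(s)", basename(path), n_skip)

  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dp) || is.null(ad))
    stopf("%s: FORMAT fields DP and AD are required", basename(path))
  dp <- dp[, 1]
  ad <- ad[, 1]
  keep <- which(snp)
  if (length(keep) && any(is.na(dp[keep]) | is.na(ad[keep]))) {
    bad <- keep[which(is.na(dp[keep]) | is.na(ad[keep]))[1]]
    stopf("%s: record %s:%s lacks DP/AD depth fields",
          basename(path), fix$CHROM[bad], fix$POS[bad])
  }
  alt_depth <- vapply(strsplit(ad[keep], ",", fixed = TRUE),
                      function(x) as.integer(x[2]), integer(1))
  calls <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    depth = as.integer(dp[keep]),
    alt_depth = alt_depth,
    stringsAsFactors = FALSE)
  calls$af <- calls$alt_depth / calls$depth
  pool_variant_set(sample_id, role, calls, genome)
}

#' Write a variant sample to a VCF v4.2 file
#'
#' Emits one biallelic SNP data line per call, sorted by (chrom, pos), with
#' `GT:DP:AD` genotype fields. Reading the file back with [read_vcf()]
#' reproduces the call set exactly (a property the test suite enforces).
#'
#' @param pool a [pool_variant_set()]
#' @param path output file
#' @param genome optional genome; when given, `##contig` header lines are written
#' @export
write_vcf <- function(pool, path, genome = NULL) {
  stopifnot(inherits(pool, "pool_variant_set"))
  calls <- validate_calls(pool$calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=emsmapr",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome), Biostrings::width(genome)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth supporting REF or ALT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (REF,ALT)">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", pool$sample_id))
  con <- tryCatch(file(path, "w"), error = function(e) stopf("cannot write '%s'", path))
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(calls)) {
    gt <- ifelse(calls$af >= 0.99, "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t%s:%d:%d,%d",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       gt, calls$depth, calls$depth - calls$alt_depth,
                       calls$alt_depth), con)
  }
  invisible(path)
}

#' Read an error-prone-site blacklist
#'
#' Accepts either BED (0-based half-open; converted to 1-based positions on
#' read) or a two-column TSV of `chrom<TAB>pos` with 1-based positions.
#' The format is chosen by file extension (`.bed` vs anything else).
#'
#' @param path BED or TSV file
#' @return data.frame with columns `chrom`, `pos`, of class `site_blacklist`
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stopf("blacklist file not found: %s", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        pos = GenomicRanges::start(gr),
                        stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "pos"),
                      colClasses = c("character", "integer"))
    sites <- tab
  }
  if (any(sites$pos < 1L)) stopf("blacklist positions must be >= 1")
  sites <- unique(sites[order(sites$chrom, sites$pos), , drop = FALSE])
  rownames(sites) <- NULL
  class(sites) <- c("site_blacklist", "data.frame")
  sites
}

#' Write a blacklist as BED
#' @param blacklist data.frame with `chrom`, `pos` (1-based)
#' @param path output `.bed` file (0-based half-open)
#' @export
write_blacklist <- function(blacklist, path) {
  gr <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$pos, blacklist$pos))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models (CDS features) from GFF3
#'
#' CDS features are grouped by parent transcript and mapped to their gene via
#' intervening mRNA features when present (otherwise the CDS parent itself is
#' taken as the gene id). Segments are sorted in ascending genomic order, must
#' be disjoint, and the total CDS length of each gene must be divisible by 3.
#'
#' @param path GFF3 file
#' @param genome optional genome used to check that segments lie within
#'   chromosome bounds
#' @return data.frame of class `gene_models`, one row per CDS segment, columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end`
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "GFF3")
  is_cds <- as.character(gr$type) == "CDS"
  if (!any(is_cds)) stopf("no CDS features in '%s'", path)
  cds <- gr[is_cds]
  parent <- vapply(as.list(cds$Parent), function(p) if (length(p)) p[1] else NA_character_,
                   character(1))
  if (anyNA(parent)) stopf("CDS feature without Parent attribute in '%s'", path)
  # translate transcript parents to gene ids where mRNA features exist
  is_tx <- as.character(gr$type) %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    tx <- gr[is_tx]
    tx_gene <- vapply(as.list(tx$Parent), function(p) if (length(p)) p[1] else NA_character_,
                      character(1))
    map <- setNames(ifelse(is.na(tx_gene), tx$ID, tx_gene), tx$ID)
    hit <- parent %in% names(map)
    parent[hit] <- unname(map[parent[hit]])
  }
  df <- data.frame(gene_id = parent,
                   chrom = as.character(GenomicRanges::seqnames(cds)),
                   strand = as.character(GenomicRanges::strand(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   stringsAsFactors = FALSE)
  gene_models(df, genome)
}

#' Construct/validate a gene-model table
#'
#' @param df data.frame with one row per CDS segment (`gene_id`, `chrom`,
#'   `strand`, `start`, `end`)
#' @param genome optional genome for bounds checking
#' @return the validated table, class `gene_models`, segments sorted
#' @export
gene_models <- function(df, genome = NULL) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene model table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  df <- df[order(df$gene_id, df$start), need, drop = FALSE]
  for (g in unique(df$gene_id)) {
    seg <- df[df$gene_id == g, ]
    if (length(unique(seg$chrom)) != 1L || length(unique(seg$strand)) != 1L)
      stopf("gene '%s' mixes chromosomes or strands", g)
    if (any(seg$end < seg$start)) stopf("gene '%s' has a segment with end < start", g)
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stopf("gene '%s' has overlapping CDS segments", g)
    len <- sum(seg$end - seg$start + 1L)
    if (len %% 3L != 0L)
      stopf("gene '%s': total CDS length %d is not divisible by 3", g, len)
    if (!is.null(genome)) {
      if (!seg$chrom[1] %in% names(genome))
        stopf("gene '%s' is on a chromosome absent from the genome", g)
      if (max(seg$end) > Biostrings::width(genome[seg$chrom[1]]))
        stopf("gene '%s' extends beyond its chromosome", g)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene) that
#' [read_gff3()] reads back to the same table.
#'
#' @param genes a `gene_models` table
#' @param path output file
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (g in unique(genes$gene_id)) {
    seg <- genes[genes$gene_id == g, ]
    widths <- seg$end - seg$start + 1L
    tx_order <- if (seg$strand[1] == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
    phase <- integer(nrow(seg))
    phase[tx_order] <- (3L - c(0L, cumsum(widths[tx_order]))[seq_len(nrow(seg))] %% 3L) %% 3L
    rows[[g]] <- data.frame(
      chrom = seg$chrom[1], strand = seg$strand[1],
      start = c(min(seg$start), min(seg$start), seg$start),
      end = c(max(seg$end), max(seg$end), seg$end),
      type = c("gene", "mRNA", rep("CDS", nrow(seg))),
      phase = c(NA_integer_, NA_integer_, phase),
      ID = c(g, paste0(g, ".1"), paste0(g, ".1.cds", seq_len(nrow(seg)))),
      parent = c(NA_character_, g, rep(paste0(g, ".1"), nrow(seg))),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$type <- factor(tab$type, levels = c("gene", "mRNA", "CDS"))
  gr$phase <- tab$phase
  gr$ID <- tab$ID
  gr$Parent <- S4Vectors::List(lapply(tab$parent, function(p)
    if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
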