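# Codon-level consequence classification of candidate SNPs within gene
# models: spliced-CDS coordinate mapping (strand-aware), reference/alternate
# codon translation with the standard genetic code, SnpEff-style categories
# and impact classes, and HGVS.p notation.

VARIANT_TYPES <- c("stop_gained", "stop_lost", "missense_variant",
                   "synonymous_variant", "intron_or_utr", "intergenic")

impact_of <- function(type) {
  switch(type,
         stop_gained = "HIGH", stop_lost = "HIGH",
         missense_variant = "MODERATE",
         synonymous_variant = "LOW",
         "MODIFIER")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stopf("cannot translate codon '%s'", codon)
  aa
}

#' Format a protein change in HGVS.p short notation
#'
#' @param ref_aa reference amino acid (single-letter code, `*` for stop)
#' @param codon_index 1-based codon (residue) index
#' @param alt_aa alternate amino acid
#' @return e.g. `"p.Q150*"`
#' @export
format_hgvs_p <- function(ref_aa, codon_index, alt_aa) {
  ok <- function(a) is.character(a) && nchar(a) == 1L &&
    a %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  if (!ok(ref_aa) || !ok(alt_aa)) stopf("invalid amino-acid code")
  if (codon_index < 1L) stopf("codon index must be >= 1")
  sprintf("p.%s%d%s", ref_aa, codon_index, alt_aa)
}

# Annotation of one variant against one gene. Returns a one-row data.frame.
classify_in_gene <- function(chrom, pos, ref, alt, seg, genome) {
  gene_id <- seg$gene_id[1]
  strand <- seg$strand[1]
  in_cds <- any(pos >= seg$start & pos <= seg$end)
  if (!in_cds)
    return(annotation_row(gene_id, "intron_or_utr", "", NA_integer_))
  widths <- seg$end - seg$start + 1L
  before <- c(0L, cumsum(widths))[which(pos >= seg$start & pos <= seg$end)]
  plus_pos <- before + pos - seg$start[pos >= seg$start & pos <= seg$end] + 1L
  total <- sum(widths)
  cds_pos <- if (strand == "+") plus_pos else total - plus_pos + 1L

  cds_seq <- paste(vapply(seq_len(nrow(seg)), function(i)
    as.character(Biostrings::subseq(genome[[chrom]], seg$start[i], seg$end[i])),
    character(1)), collapse = "")
  if (strand == "-")
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))

  codon_index <- (cds_pos + 2L) %/% 3L
  offset <- cds_pos - 3L * (codon_index - 1L)
  ref_codon <- substr(cds_seq, 3L * codon_index - 2L, 3L * codon_index)
  cds_ref <- substr(ref_codon, offset, offset)
  expected_ref <- if (strand == "+") ref else
    as.character(Biostrings::complement(Biostrings::DNAString(ref)))
  if (cds_ref != expected_ref)
    stopf("reference mismatch at %s:%d in gene %s: genome has %s, variant claims %s",
          chrom, pos, gene_id, cds_ref, expected_ref)
  cds_alt <- if (strand == "+") alt else
    as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- cds_alt

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  type <- if (ref_aa == alt_aa) "synonymous_variant"
  else if (alt_aa == "*") "stop_gained"
  else if (ref_aa == "*") "stop_lost"
  else "missense_variant"
  annotation_row(gene_id, type, format_hgvs_p(ref_aa, codon_index, alt_aa),
                 codon_index)
}

annotation_row <- function(gene_id, type, hgvs_p, codon_index) {
  data.frame(gene_id = gene_id, variant_type = type, impact = impact_of(type),
             hgvs_p = hgvs_p, codon_index = codon_index,
             stringsAsFactors = FALSE)
}

#' Classify a SNP by codon-level consequence
#'
#' Maps the position into spliced CDS coordinates (reverse-complementing on
#' minus-strand genes), translates the reference and alternate codons with the
#' standard genetic code and assigns the SnpEff-style category and impact:
#' stop_gained/stop_lost are HIGH, missense MODERATE, synonymous LOW, and
#' non-coding positions MODIFIER. A variant covered by several genes is
#' annotated against all of them and the highest-impact annotation is
#' reported (ties broken by lowest gene id).
#'
#' @param chrom,pos,ref,alt the SNP (ref must match the genome at pos)
#' @param genes a `gene_models` table
#' @param genome the reference genome
#' @return one-row data.frame: `gene_id`, `variant_type`, `impact`, `hgvs_p`,
#'   `codon_index`
#' @export
classify_variant <- function(chrom, pos, ref, alt, genes, genome) {
  gref <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (gref != ref)
    stopf("reference mismatch at %s:%d: genome has %s, variant claims %s",
          chrom, pos, gref, ref)
  cand <- unique(genes$gene_id[genes$chrom == chrom])
  hits <- list()
  for (g in cand) {
    seg <- genes[genes$gene_id == g, , drop = FALSE]
    if (pos >= min(seg$start) && pos <= max(seg$end))
      hits[[g]] <- classify_in_gene(chrom, pos, ref, alt, seg, genome)
  }
  if (!length(hits))
    return(annotation_row("", "intergenic", "", NA_integer_))
  ann <- do.call(rbind, hits)
  ann <- ann[order(match(ann$impact, IMPACT_LEVELS), ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann[1, , drop = FALSE]
}

#' Classify every variant of a table
#'
#' @param set variant table (`chrom`, `pos`, `ref`, `alt`, ...)
#' @inheritParams classify_variant
#' @return `set` with annotation columns appended
#' @export
classify_variants <- function(set, genes, genome) {
  if (nrow(set) == 0)
    return(cbind(set, data.frame(gene_id = character(0),
                                 variant_type = character(0),
                                 impact = character(0), hgvs_p = character(0),
                                 codon_index = integer(0))))
  ann <- do.call(rbind, lapply(seq_len(nrow(set)), function(i)
    classify_variant(set$chrom[i], set$pos[i], set$ref[i], set$alt[i],
                     genes, genome)))
  cbind(set, ann)
}

#' Rank candidate variants by predicted impact
#'
#' Restricts an annotated variant table to protein-altering (MODERATE/HIGH)
#' entries and orders them HIGH first, then by genomic position. The column
#' layout mirrors a candidate-variant report: Chr, Position, Ref, Alt,
#' Variant type, Impact, Effect, Gene ID.
#'
#' @param annotated output of [classify_variants()]
#' @return ordered candidate table
#' @export
rank_candidates <- function(annotated) {
  cols <- c(chrom = "Chr", pos = "Position", ref = "Ref", alt = "Alt",
            variant_type = "Variant_type", impact = "Impact",
            hgvs_p = "Effect", gene_id = "Gene_ID")
  if (nrow(annotated) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  unname(cols)))
    out$Position <- integer(0)
    return(out)
  }
  keep <- annotated[annotated$impact %in% c("HIGH", "MODERATE"), , drop = FALSE]
  keep <- keep[order(match(keep$impact, c("HIGH", "MODERATE")),
                     keep$chrom, keep$pos), , drop = FALSE]
  out <- keep[, names(cols), drop = FALSE]
  names(out) <- unname(cols)
  rownames(out) <- NULL
  out
}
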