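# Independent brute-force oracles. Each re-derives a result by the most
# literal possible route (explicit loops, full-CDS retranslation, direct
# counting) and is kept deliberately separate from the package's code paths.

oracle_bin_counts <- function(set, lens, bin_size) {
  out <- list()
  for (ch in names(lens)) {
    n_bins <- max(1, ceiling(lens[[ch]] / bin_size))
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * bin_size + 1
      hi <- b * bin_size
      cnt <- 0L
      for (i in seq_len(nrow(set)))
        if (set$chrom[i] == ch && set$pos[i] >= lo && set$pos[i] <= hi)
          cnt <- cnt + 1L
      out[[length(out) + 1]] <- data.frame(chrom = ch, bin_start = lo, count = cnt)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

oracle_subtract <- function(mutant_set, sibling_hom) {
  keep <- rep(TRUE, nrow(mutant_set))
  for (i in seq_len(nrow(mutant_set))) {
    for (j in seq_len(nrow(sibling_hom))) {
      if (mutant_set$chrom[i] == sibling_hom$chrom[j] &&
          mutant_set$pos[i] == sibling_hom$pos[j] &&
          mutant_set$alt[i] == sibling_hom$alt[j]) keep[i] <- FALSE
    }
  }
  out <- mutant_set[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# literal re-execution of the interval rule on a bins table
oracle_detect <- function(bins, consecutive_background = 2, min_peak_excess = 3) {
  counts <- bins$count
  bg <- median(counts)
  peak_count <- max(counts)
  if (peak_count <= bg + min_peak_excess) return(NULL)
  peak <- which(counts == peak_count)[1]
  chrom <- bins$chrom[peak]
  idx <- which(bins$chrom == chrom)
  pk <- match(peak, idx)
  cc <- counts[idx]
  expand <- function(step) {
    edge <- pk; run <- 0; i <- pk + step
    while (i >= 1 && i <= length(cc)) {
      if (cc[i] <= bg) {
        run <- run + 1
        if (run >= consecutive_background) break
      } else { run <- 0; edge <- i }
      i <- i + step
    }
    edge
  }
  bs <- attr(bins, "bin_size")
  list(chrom = chrom,
       start = bins$bin_start[idx[expand(-1)]],
       end = bins$bin_start[idx[expand(1)]] + bs - 1,
       peak_count = peak_count, background_level = bg)
}

# full-CDS retranslation oracle for SNP consequences
oracle_classify <- function(chrom, pos, ref, alt, genes, genome) {
  splice <- function(gnm, seg, strand) {
    s <- paste(vapply(seq_len(nrow(seg)), function(i)
      as.character(Biostrings::subseq(gnm[[chrom]], seg$start[i], seg$end[i])),
      character(1)), collapse = "")
    d <- Biostrings::DNAString(s)
    if (strand == "-") d <- Biostrings::reverseComplement(d)
    d
  }
  mutant <- genome
  mutant[[chrom]] <- Biostrings::replaceLetterAt(mutant[[chrom]], pos,
                                                 Biostrings::DNAString(alt))
  best <- NULL
  for (g in unique(genes$gene_id[genes$chrom == chrom])) {
    seg <- genes[genes$gene_id == g, , drop = FALSE]
    if (pos < min(seg$start) || pos > max(seg$end)) next
    if (!any(pos >= seg$start & pos <= seg$end)) {
      ann <- data.frame(gene_id = g, variant_type = "intron_or_utr",
                        impact = "MODIFIER", hgvs_p = "", codon_index = NA_integer_)
    } else {
      strand <- seg$strand[1]
      p_ref <- suppressWarnings(as.character(Biostrings::translate(splice(genome, seg, strand))))
      p_alt <- suppressWarnings(as.character(Biostrings::translate(splice(mutant, seg, strand))))
      if (p_ref == p_alt) {
        cds <- splice(genome, seg, strand)
        # locate the codon anyway for the record
        diffpos <- which(strsplit(as.character(splice(genome, seg, strand)), "")[[1]] !=
                           strsplit(as.character(splice(mutant, seg, strand)), "")[[1]])
        ci <- (diffpos + 2) %/% 3
        ann <- data.frame(gene_id = g, variant_type = "synonymous_variant",
                          impact = "LOW",
                          hgvs_p = sprintf("p.%s%d%s", substr(p_ref, ci, ci), ci,
                                           substr(p_ref, ci, ci)),
                          codon_index = ci)
      } else {
        ci <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
        ra <- substr(p_ref, ci, ci); aa <- substr(p_alt, ci, ci)
        type <- if (aa == "*") "stop_gained" else if (ra == "*") "stop_lost"
        else "missense_variant"
        ann <- data.frame(gene_id = g, variant_type = type,
                          impact = if (type %in% c("stop_gained", "stop_lost")) "HIGH"
                          else "MODERATE",
                          hgvs_p = sprintf("p.%s%d%s", ra, ci, aa), codon_index = ci)
      }
    }
    rank <- match(ann$impact, c("HIGH", "MODERATE", "LOW", "MODIFIER"))
    if (is.null(best) || rank < best$rank ||
        (rank == best$rank && ann$gene_id < best$ann$gene_id))
      best <- list(ann = ann, rank = rank)
  }
  if (is.null(best))
    return(data.frame(gene_id = "", variant_type = "intergenic",
                      impact = "MODIFIER", hgvs_p = "", codon_index = NA_integer_))
  best$ann
}

# count-based re-statement of the phasing decision rule
oracle_phase_verdict <- function(n_both_alt, n_both_ref, n_a_only, n_b_only,
                                 min_informative = 3, max_discord_frac = 0.05) {
  n <- n_both_alt + n_both_ref + n_a_only + n_b_only
  if (n < min_informative) return("ambiguous")
  if ((n_both_alt + n_both_ref) >= (1 - max_discord_frac) * n) return("cis")
  if ((n_a_only + n_b_only) >= (1 - max_discord_frac) * n &&
      n_a_only >= 1 && n_b_only >= 1) return("trans")
  "ambiguous"
}
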