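# Small in-code fixtures shared across test files.

make_calls <- function(chrom, pos, ref, alt, depth, alt_depth) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             depth = as.integer(depth), alt_depth = as.integer(alt_depth),
             af = alt_depth / depth, stringsAsFactors = FALSE)
}

one_site <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# random EMS-style call table on a toy genome
random_ems_calls <- function(n, chroms = c("Chr1", "Chr2"), max_pos = 1e5) {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("G", "C"), n, replace = TRUE)
  depth <- sample(5:40, n, replace = TRUE)
  alt_depth <- vapply(depth, function(d) sample.int(d, 1), integer(1))
  make_calls(sample(chroms, n, replace = TRUE), pos, ref,
             ifelse(ref == "G", "A", "T"), depth, alt_depth)
}

# hand-assembled bin_counts table
make_bins <- function(counts_by_chrom, bin_size = 1e6L) {
  out <- do.call(rbind, lapply(names(counts_by_chrom), function(ch) {
    n <- length(counts_by_chrom[[ch]])
    data.frame(chrom = ch, bin_start = (seq_len(n) - 1L) * bin_size + 1L,
               count = counts_by_chrom[[ch]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("bin_counts", "data.frame")
  out
}

# read-observation table built from per-read allele pairs at two sites
make_pair_reads <- function(siteA, siteB, n_both_alt = 0, n_both_ref = 0,
                            n_a_only = 0, n_b_only = 0, n_a_single = 0) {
  rows <- list(); id <- 0
  add <- function(allele_a, allele_b, k, only_a = FALSE) {
    for (i in seq_len(k)) {
      id <<- id + 1
      rows[[length(rows) + 1]] <<- data.frame(
        read_id = sprintf("r%04d", id),
        chrom = c(siteA$chrom, if (!only_a) siteB$chrom),
        pos = c(siteA$pos, if (!only_a) siteB$pos),
        allele = c(allele_a, if (!only_a) allele_b),
        stringsAsFactors = FALSE)
    }
  }
  add(siteA$alt, siteB$alt, n_both_alt)
  add(siteA$ref, siteB$ref, n_both_ref)
  add(siteA$alt, siteB$ref, n_a_only)
  add(siteA$ref, siteB$alt, n_b_only)
  add(siteA$alt, NULL, n_a_single, only_a = TRUE)
  if (!length(rows))
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), allele = character()))
  do.call(rbind, rows)
}

# small favourable screen configuration for pipeline mechanics tests:
# dense mutations, mild recombination and low error so the signal is sharp
small_screen_config <- function(seed = 5) {
  sim_config(seed = seed, n_chrom = 2, chrom_length = 3e5, genes_per_chrom = 4,
             ems_rate = 2e-3, recomb_rate = 0.05,
             n_shared_background = 15, n_blacklist = 15,
             n_mutant_individuals = c(40, 40), n_wildtype_individuals = c(40, 40),
             mean_depth = 60, seq_error_rate = 0.001,
             n_somatic_shared = 15, n_somatic_unique = 8)
}
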