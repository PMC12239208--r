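# Recovery evaluation on simulated screens: runs the full analysis on
# generated data with known truth and reports per-seed recovery metrics.
# These drive the package's self-validation (see tests and
# scripts/acceptance.R).

#' Study-condition configuration for BSA recovery evaluation
#'
#' The evaluation conditions: 5 x 10-Mbp genome, two F2 families of 40
#' selected homozygotes with 40 wild-type siblings each, 12x mean depth, 1%
#' sequencing error, 0.5 Morgans/Mbp, an expected 200 background EMS
#' mutations, 50 sibling-shared and 50 error-prone sites.
#'
#' @param seed master seed
#' @return a [sim_config()]
#' @export
bsa_eval_config <- function(seed) {
  sim_config(seed = seed, n_mutant_individuals = c(40L, 40L),
             n_wildtype_individuals = c(40L, 40L))
}

#' Evaluate causal-locus recovery on one simulated BSA screen
#'
#' Simulates a two-family screen, runs the filter chain
#' (homozygous calling, sibling subtraction, blacklist removal, spectrum
#' filter), bins and detects per-pool intervals, intersects the pools and
#' ranks candidates, then scores the result against the planted truth.
#'
#' @param seed seed for this replicate
#' @param config a [sim_config()]; defaults to [bsa_eval_config()]
#' @return list of per-replicate metrics: whether the refined interval exists
#'   and contains the causal site, whether the top-ranked candidate is the
#'   causal stop-gain, counts of planted sibling-shared/blacklist sites
#'   surviving each pool's filter chain, and counts of non-EMS survivors
#' @export
evaluate_bsa_screen <- function(seed, config = bsa_eval_config(seed)) {
  scr <- simulate_bsa_screen(config)
  truth <- scr$truth
  key <- function(df) paste(df$chrom, df$pos)
  per_pool <- lapply(scr$families, function(fam) {
    hom <- call_homozygous(fam$mutant)
    sub <- subtract_shared(hom, fam$sibling)
    blk <- apply_blacklist(sub, scr$blacklist)
    ems <- filter_ems_spectrum(blk)
    bins <- bin_variant_counts(ems, scr$genome)
    interval <- suppressMessages(detect_mapping_interval(bins))
    list(filtered = ems, interval = interval,
         n_shared_leaked = sum(key(ems) %in% key(truth$shared_sites)),
         n_blacklist_leaked = sum(key(ems) %in% key(truth$blacklist_sites)),
         n_non_ems = sum(!((ems$ref == "G" & ems$alt == "A") |
                             (ems$ref == "C" & ems$alt == "T"))))
  })
  res <- tryCatch(suppressWarnings(
    intersect_pools(per_pool[[1]]$filtered, per_pool[[2]]$filtered,
                    per_pool[[1]]$interval, per_pool[[2]]$interval)),
    error = function(e) list(shared = per_pool[[1]]$filtered[0, ], interval = NULL))
  causal <- truth$causal_site
  contains <- !is.null(res$interval) && res$interval$chrom == causal$chrom &&
    causal$pos >= res$interval$start && causal$pos <= res$interval$end
  top_is_causal <- FALSE
  if (nrow(res$shared) > 0) {
    ranked <- rank_candidates(classify_variants(res$shared, scr$genes, scr$genome))
    top_is_causal <- nrow(ranked) > 0 && ranked$Impact[1] == "HIGH" &&
      ranked$Chr[1] == causal$chrom && ranked$Position[1] == causal$pos
  }
  list(interval_contains_causal = contains,
       top_is_causal = top_is_causal,
       refined_interval = res$interval,
       causal_in_shared = any(key(res$shared) == paste(causal$chrom, causal$pos)),
       n_shared_leaked = vapply(per_pool, `[[`, numeric(1), "n_shared_leaked"),
       n_blacklist_leaked = vapply(per_pool, `[[`, numeric(1), "n_blacklist_leaked"),
       n_non_ems = vapply(per_pool, `[[`, numeric(1), "n_non_ems"))
}

#' Study-condition configuration for sector recovery evaluation
#'
#' 60x sector depth, 1% sequencing error, a prior heterozygous stop-gain
#' allele and a novel cis pair 39 bp apart (the codon-98/codon-111 geometry),
#' on a compact 2 x 1-Mbp genome.
#'
#' @param seed master seed
#' @return a [sim_config()]
#' @export
sector_eval_config <- function(seed) {
  sim_config(seed = seed, n_chrom = 2L, chrom_length = 1e6, genes_per_chrom = 6L,
             sector_depth = 60, seq_error_rate = 0.01)
}

#' Evaluate novel-allele recovery on one simulated sector pair
#'
#' Simulates a sterile/fertile pair, runs heterozygous calling,
#' sterile-unique differencing within the mapped interval, prior-allele
#' confirmation, annotation, phasing and nomination, and scores the result
#' against the planted truth.
#'
#' @param seed seed for this replicate
#' @param config a [sim_config()]; defaults to [sector_eval_config()]
#' @return list of metrics: nomination correctness, pair membership in the
#'   unique set, cis verdict for the pair, trans verdict against the prior
#'   allele, informative spanning-read count, prior-allele confirmation
#' @export
evaluate_sector_screen <- function(seed, config = sector_eval_config(seed)) {
  pg <- plant_genes(generate_reference(config), config)
  sp <- simulate_sector_pair(pg$genome, config, pg$genes, pg$causal,
                             seed = config$seed + 9L)
  interval <- structure(list(
    chrom = pg$causal$chrom,
    start = max(1L, pg$causal$gene_start - 5e5L),
    end = min(config$chrom_length, pg$causal$gene_end + 5e5L),
    peak_bin = pg$causal$gene_start, peak_count = 1L, background_level = 0),
    class = "mapping_interval")
  het <- call_heterozygous(sp$sterile)
  d <- differential_sterile_unique(het, sp$fertile, interval)
  ann <- classify_variants(d$unique, pg$genes, pg$genome)
  prior <- sp$truth$prior_het_site
  nom <- suppressWarnings(nominate_allele(ann, sp$reads, prior))
  pair <- sp$truth$novel_cis_pair
  pair_in_unique <- all(paste(pair$chrom, pair$pos) %in%
                          paste(d$unique$chrom, d$unique$pos))
  v_pair <- phase_variant_pair(sp$reads, pair[1, ], pair[2, ])
  near <- pair[which.min(abs(pair$pos - prior$pos)), ]  # within read span of prior
  v_prior <- phase_relative_to_prior(sp$reads, near, prior)
  confirmed <- tryCatch(
    confirm_prior_allele(prior, sp$sterile, sp$fertile)$confirmed,
    error = function(e) FALSE)
  list(nominated = nom$nominated,
       nominated_is_truth = identical(nom$nominated, sp$truth$gene_id),
       pair_in_unique = pair_in_unique,
       pair_verdict = v_pair$verdict,
       prior_verdict = v_prior$verdict,
       n_spanning_pair = v_pair$n_informative,
       n_spanning_prior = v_prior$n_informative,
       prior_confirmed = confirmed,
       n_unique_interval = nrow(d$unique),
       n_shared_interval = nrow(d$shared))
}
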