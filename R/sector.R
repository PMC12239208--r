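# Sector analysis: heterozygous EMS-variant calling in sterile/fertile
# chimeric sectors, sterile-unique differencing within the mapped interval,
# confirmation of the prior allele, and read-backed cis/trans phasing.

#' Call heterozygous EMS variants in a sector sample
#'
#' Retains calls with depth at least `min_depth`, alternate-allele frequency
#' inside `freq_window` (operationalising the expected ~50% of a heterozygote)
#' and a canonical EMS change (G>A or C>T).
#'
#' @param sector a [pool_variant_set()] (or variant table)
#' @param min_depth minimum read depth
#' @param freq_window inclusive allele-frequency window
#' @return variant table sorted by (chrom, pos)
#' @export
call_heterozygous <- function(sector, min_depth = 10L, freq_window = c(0.25, 0.75)) {
  calls <- if (inherits(sector, "pool_variant_set")) sector$calls else validate_calls(sector)
  keep <- calls$depth >= min_depth &
    calls$af >= freq_window[1] & calls$af <= freq_window[2] &
    ((calls$ref == "G" & calls$alt == "A") | (calls$ref == "C" & calls$alt == "T"))
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fertile_alt_fraction <- function(chrom, pos, fertile_calls) {
  i <- match(site_key(chrom, pos), site_key(fertile_calls$chrom, fertile_calls$pos))
  ifelse(is.na(i), 0, fertile_calls$alt_depth[i] / fertile_calls$depth[i])
}

#' Partition sterile-sector heterozygous variants into unique and shared
#'
#' Within the mapped interval, a sterile-sector variant is *unique* when the
#' fertile sector shows no alternate-allele evidence above an error floor
#' (`alt_depth / depth <= err_max`, or no call at all), and *shared*
#' otherwise. Genome-wide tallies are also reported.
#'
#' @param sterile_set heterozygous variant table of the sterile sector
#' @param fertile_sector the fertile [pool_variant_set()]
#' @param interval the `mapping_interval` the screen mapped the locus to
#' @param err_max maximum fertile alternate-allele fraction still treated as
#'   sequencing error
#' @return list of class `sector_differential`: `unique` and `shared`
#'   (within-interval variant tables) plus `n_unique_genomewide` /
#'   `n_shared_genomewide`
#' @export
differential_sterile_unique <- function(sterile_set, fertile_sector,
                                        interval, err_max = 0.02) {
  fert <- if (inherits(fertile_sector, "pool_variant_set")) fertile_sector$calls
  else fertile_sector
  frac <- fertile_alt_fraction(sterile_set$chrom, sterile_set$pos, fert)
  is_unique <- frac <= err_max
  inside <- in_interval(sterile_set$chrom, sterile_set$pos, interval)
  res <- list(
    unique = sterile_set[inside & is_unique, , drop = FALSE],
    shared = sterile_set[inside & !is_unique, , drop = FALSE],
    n_unique_genomewide = sum(is_unique),
    n_shared_genomewide = sum(!is_unique))
  rownames(res$unique) <- NULL
  rownames(res$shared) <- NULL
  class(res) <- "sector_differential"
  res
}

#' @export
print.sector_differential <- function(x, ...) {
  cat(sprintf("<sector_differential> interval: %d unique / %d shared; genome-wide: %d / %d\n",
              nrow(x$unique), nrow(x$shared),
              x$n_unique_genomewide, x$n_shared_genomewide))
  invisible(x)
}

#' Confirm the prior mutant allele is heterozygous in both sectors
#'
#' The individual carrying a chimeric sector should be a heterozygote for the
#' pre-existing allele: both sectors must show the known site at roughly 50%
#' allele frequency.
#'
#' @param known_site list or one-row data.frame with `chrom`, `pos`
#' @param sterile,fertile the sector [pool_variant_set()]s
#' @param freq_window inclusive frequency window for "heterozygous"
#' @return list: `freq_sterile`, `freq_fertile`, `confirmed`
#' @export
confirm_prior_allele <- function(known_site, sterile, fertile,
                                 freq_window = c(0.25, 0.75)) {
  fetch <- function(pool) {
    calls <- if (inherits(pool, "pool_variant_set")) pool$calls else pool
    i <- match(site_key(known_site$chrom, known_site$pos),
               site_key(calls$chrom, calls$pos))
    if (is.na(i))
      stopf("cannot confirm prior genotype: no call at %s:%d in sample '%s'",
            known_site$chrom, known_site$pos,
            if (inherits(pool, "pool_variant_set")) pool$sample_id else "?")
    calls$af[i]
  }
  fs <- fetch(sterile)
  ff <- fetch(fertile)
  list(freq_sterile = fs, freq_fertile = ff,
       confirmed = fs >= freq_window[1] && fs <= freq_window[2] &&
         ff >= freq_window[1] && ff <= freq_window[2])
}

read_alleles_at <- function(reads, site) {
  obs <- reads[reads$chrom == site$chrom & reads$pos == site$pos, c("read_id", "allele")]
  setNames(obs$allele, obs$read_id)
}

#' Phase a variant pair from co-observing reads
#'
#' Only reads observing both sites are informative. Each informative read is
#' classified as both-alt, both-ref, or alt-at-exactly-one-site; observations
#' of a base that is neither the site's ref nor its alt are sequencing
#' artifacts and make the read uninformative. With `n` informative reads the
#' verdict is `ambiguous` when `n < min_informative`; `cis` when the
#' concordant reads (both-alt plus both-ref) make up at least
#' `1 - max_discord_frac` of `n`; `trans` when the alt-at-exactly-one reads do,
#' in both orientations; otherwise `ambiguous`.
#'
#' @param reads read-observation table (`read_id`, `chrom`, `pos`, `allele`)
#' @param siteA,siteB one-row variant descriptors (`chrom`, `pos`, `ref`, `alt`)
#' @param min_informative minimum informative reads for a verdict
#' @param max_discord_frac tolerated fraction of rule-discordant reads
#' @return a `phase_verdict`: counts and verdict in {cis, trans, ambiguous}
#' @export
phase_variant_pair <- function(reads, siteA, siteB, min_informative = 3L,
                               max_discord_frac = 0.05) {
  if (siteA$chrom == siteB$chrom && siteA$pos == siteB$pos)
    stopf("cannot phase a site against itself (%s:%d)", siteA$chrom, siteA$pos)
  a <- read_alleles_at(reads, siteA)
  b <- read_alleles_at(reads, siteB)
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  ok <- a %in% c(siteA$ref, siteA$alt) & b %in% c(siteB$ref, siteB$alt)
  a <- a[ok]; b <- b[ok]
  alt_a <- a == siteA$alt
  alt_b <- b == siteB$alt
  n <- length(a)
  n_both_alt <- sum(alt_a & alt_b)
  n_both_ref <- sum(!alt_a & !alt_b)
  n_a_only <- sum(alt_a & !alt_b)
  n_b_only <- sum(!alt_a & alt_b)
  concord <- n_both_alt + n_both_ref
  split_pattern <- n_a_only + n_b_only
  verdict <- if (n < min_informative) "ambiguous"
  else if (concord >= (1 - max_discord_frac) * n) "cis"
  else if (split_pattern >= (1 - max_discord_frac) * n &&
           n_a_only > 0L && n_b_only > 0L) "trans"
  else "ambiguous"
  structure(list(siteA = siteA, siteB = siteB, n_informative = n,
                 n_both_alt = n_both_alt, n_both_ref = n_both_ref,
                 n_alt_a_only = n_a_only, n_alt_b_only = n_b_only,
                 n_discordant = if (verdict == "trans") concord else split_pattern,
                 verdict = verdict),
            class = "phase_verdict")
}

#' @export
print.phase_verdict <- function(x, ...) {
  cat(sprintf("<phase_verdict> %s:%d vs %s:%d -> %s (n=%d: %d both-alt, %d both-ref, %d+%d split)\n",
              x$siteA$chrom, x$siteA$pos, x$siteB$chrom, x$siteB$pos, x$verdict,
              x$n_informative, x$n_both_alt, x$n_both_ref,
              x$n_alt_a_only, x$n_alt_b_only))
  invisible(x)
}

#' Phase a novel variant against the prior allele
#'
#' Same decision rule as [phase_variant_pair()]; a novel lesion on the
#' haplotype opposite the prior allele is expected to come out `trans`.
#'
#' @inheritParams phase_variant_pair
#' @param novel_site,prior_site one-row variant descriptors
#' @return a `phase_verdict`
#' @export
phase_relative_to_prior <- function(reads, novel_site, prior_site,
                                    min_informative = 3L, max_discord_frac = 0.05) {
  phase_variant_pair(reads, novel_site, prior_site,
                     min_informative = min_informative,
                     max_discord_frac = max_discord_frac)
}

#' Nominate the gene carrying a novel noncomplementing allele
#'
#' Lists every gene carrying sterile-unique protein-altering (MODERATE/HIGH)
#' variants, phases each gene's variants among themselves and against the
#' prior allele, and nominates the gene whose novel coding variants are cis
#' with one another and trans to the prior allele (i.e. they hit the
#' remaining functional copy).
#'
#' @param unique_annotated sterile-unique variants annotated by
#'   [classify_variants()]
#' @param reads read-observation table for phasing
#' @param prior_site one-row descriptor of the prior allele
#' @param min_informative,max_discord_frac phasing thresholds
#' @return list of class `allele_nomination`: `genes` (per-gene summary
#'   data.frame), `verdicts` (all phase verdicts), `nominated` (gene ids)
#' @export
nominate_allele <- function(unique_annotated, reads, prior_site,
                            min_informative = 3L, max_discord_frac = 0.05) {
  coding <- unique_annotated[unique_annotated$impact %in% c("HIGH", "MODERATE"), ,
                             drop = FALSE]
  if (nrow(coding) == 0)
    return(structure(list(genes = data.frame(), verdicts = list(),
                          nominated = character(0)),
                     class = "allele_nomination"))
  verdicts <- list()
  summaries <- list()
  for (g in unique(coding$gene_id)) {
    vg <- coding[coding$gene_id == g, , drop = FALSE]
    internal <- character(0)
    if (nrow(vg) >= 2) {
      for (i in seq_len(nrow(vg) - 1)) for (j in seq(i + 1, nrow(vg))) {
        v <- phase_variant_pair(reads, vg[i, ], vg[j, ],
                                min_informative, max_discord_frac)
        verdicts[[length(verdicts) + 1L]] <- v
        internal <- c(internal, v$verdict)
      }
    }
    vs_prior <- vapply(seq_len(nrow(vg)), function(i) {
      v <- phase_relative_to_prior(reads, vg[i, ], prior_site,
                                   min_informative, max_discord_frac)
      verdicts[[length(verdicts) + 1L]] <<- v
      v$verdict
    }, character(1))
    cis_internal <- all(internal == "cis")   # vacuously true for one variant
    trans_support <- any(vs_prior == "trans") && !any(vs_prior == "cis")
    summaries[[g]] <- data.frame(
      gene_id = g, n_coding_variants = nrow(vg),
      internal_cis = cis_internal, trans_to_prior = trans_support,
      nominated = cis_internal && trans_support,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, summaries)
  rownames(genes) <- NULL
  nominated <- genes$gene_id[genes$nominated]
  if (length(nominated) == 0 && nrow(genes) > 0)
    warnf("%d gene(s) carry sterile-unique coding variants but none has phasing support",
          nrow(genes))
  structure(list(genes = genes, verdicts = verdicts, nominated = nominated),
            class = "allele_nomination")
}

#' @export
print.allele_nomination <- function(x, ...) {
  if (nrow(x$genes) == 0) {
    cat("<allele_nomination> no sterile-unique coding variants\n")
  } else {
    cat(sprintf("<allele_nomination> %d candidate gene(s); nominated: %s\n",
                nrow(x$genes),
                if (length(x$nominated)) paste(x$nominated, collapse = ", ") else "none"))
  }
  invisible(x)
}
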