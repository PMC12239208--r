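# Synthetic EMS-screen generator: reference genome, planted gene models,
# EMS mutation spectrum, F2 pool segregation with Haldane linkage, binomial
# read sampling with sequencing error, and chimeric sterile/fertile sector
# pairs with fragment-level read observations for phasing.

#' Configuration for a synthetic EMS screen
#'
#' Defaults describe the desk-scale study conditions the package is tested
#' under: a 5 x 10-Mbp genome, pools of 57/37 selected homozygotes with 40/42
#' wild-type siblings (the two F2 families of the mapping design), 12x mean
#' pool depth with 1% per-base sequencing error, 0.5 Morgans/Mbp recombination,
#' an expected 200 background EMS mutations genome-wide, and 50 planted
#' sibling-shared plus 50 error-prone (blacklist) sites. Sector simulations
#' use 60x depth and fragment spans of 350 bp (2 x 150 bp paired-end reads
#' with a short inner gap; co-observation of two sites on one fragment is what
#' drives phasing).
#'
#' @param seed integer master seed; all randomness flows from it
#' @param n_chrom number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param ems_rate per-G/C-site probability of an EMS background mutation
#' @param causal_site `"auto"` (stop-gain codon of the planted causal gene) or
#'   a list `list(chrom=, pos=)`
#' @param n_mutant_individuals selected homozygous individuals per mutant
#'   pool; length 1 or 2 (one value per F2 family)
#' @param n_wildtype_individuals wild-type sibling individuals per pool
#' @param mean_depth mean sequencing depth per pool site (Poisson)
#' @param seq_error_rate per-base substitution error rate
#' @param recomb_rate genetic map density, Morgans per Mbp (uniform)
#' @param n_shared_background sibling-shared homozygous background sites
#' @param n_blacklist planted error-prone sites
#' @param genes_per_chrom planted gene models per chromosome
#' @param sector_depth mean sector sequencing depth
#' @param read_span fragment span (bp) of sector read observations
#' @param n_somatic_shared somatic heterozygous EMS variants shared by sectors
#' @param n_somatic_unique somatic heterozygous variants unique to each sector
#' @return an object of class `screen_sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L,
                       chrom_length = 1e7,
                       ems_rate = 8e-6,
                       causal_site = "auto",
                       n_mutant_individuals = c(57L, 37L),
                       n_wildtype_individuals = c(40L, 42L),
                       mean_depth = 12,
                       seq_error_rate = 0.01,
                       recomb_rate = 0.5,
                       n_shared_background = 50L,
                       n_blacklist = 50L,
                       genes_per_chrom = 10L,
                       sector_depth = 60,
                       read_span = 350L,
                       n_somatic_shared = 40L,
                       n_somatic_unique = 20L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length), ems_rate = ems_rate,
              causal_site = causal_site,
              n_mutant_individuals = as.integer(n_mutant_individuals),
              n_wildtype_individuals = as.integer(n_wildtype_individuals),
              mean_depth = mean_depth, seq_error_rate = seq_error_rate,
              recomb_rate = recomb_rate,
              n_shared_background = as.integer(n_shared_background),
              n_blacklist = as.integer(n_blacklist),
              genes_per_chrom = as.integer(genes_per_chrom),
              sector_depth = sector_depth, read_span = as.integer(read_span),
              n_somatic_shared = as.integer(n_somatic_shared),
              n_somatic_unique = as.integer(n_somatic_unique))
  with(cfg, {
    stopifnot(n_chrom >= 0, chrom_length >= 0, ems_rate >= 0, ems_rate <= 1,
              seq_error_rate >= 0, seq_error_rate <= 1, mean_depth > 0,
              recomb_rate >= 0, all(n_mutant_individuals >= 1),
              all(n_wildtype_individuals >= 1), n_shared_background >= 0,
              n_blacklist >= 0, sector_depth > 0, read_span >= 1)
  })
  structure(cfg, class = "screen_sim_config")
}

random_dna <- function(n) {
  if (n == 0) return("")
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

#' Generate a random reference genome
#'
#' Uniform base composition; deterministic for a given config seed.
#'
#' @param config a [sim_config()]
#' @return named [Biostrings::DNAStringSet] (`Chr1`, `Chr2`, ...)
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  if (config$n_chrom == 0L) return(Biostrings::DNAStringSet())
  seqs <- vapply(seq_len(config$n_chrom), function(i) random_dna(config$chrom_length),
                 character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("Chr", seq_len(config$n_chrom))
  genome
}

# Sample n distinct G/C positions from one chromosome string (rejection
# sampling; random genomes are ~50% GC so this converges immediately).
sample_gc_positions <- function(chrom_str, n, exclude = integer(0)) {
  L <- nchar(chrom_str)
  out <- integer(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) stopf("could not find %d G/C positions", n)
    cand <- sample.int(L, min(4L * (n - length(out)) + 16L, L), replace = TRUE)
    base <- substring(chrom_str, cand, cand)
    cand <- cand[base %in% c("G", "C")]
    out <- unique(c(out, setdiff(cand, exclude)))
  }
  sort(out[seq_len(n)])
}

#' Map spliced CDS positions to genome coordinates
#'
#' @param segments data.frame of CDS segments (`start`, `end`), ascending
#' @param strand `"+"` or `"-"`
#' @param cds_pos integer vector of 1-based positions in the spliced CDS
#' @return genome positions (1-based)
#' @export
cds_to_genome <- function(segments, strand, cds_pos) {
  widths <- segments$end - segments$start + 1L
  plus_coords <- unlist(mapply(seq, segments$start, segments$end, SIMPLIFY = FALSE))
  if (strand == "-") plus_coords <- rev(plus_coords)
  if (any(cds_pos < 1L | cds_pos > sum(widths))) stopf("CDS position out of range")
  plus_coords[cds_pos]
}

#' Plant gene models in a genome and engineer the causal gene
#'
#' Places `genes_per_chrom` two-exon genes (CDS 480 + 120 bp, 100-bp intron)
#' at regular intervals on alternating strands. The causal gene (middle gene
#' of the middle chromosome, forced to the + strand) has codons 98, 111 and
#' 150 rewritten to CCA, CAA and CAG so that C>T transitions at their first
#' bases produce p.P98S (missense), p.Q111* and p.Q150* (stop gains) --
#' the lesion geometry of the screen being emulated.
#'
#' @param genome reference genome from [generate_reference()]
#' @param config a [sim_config()]
#' @return list with elements `genome` (engineered), `genes` (a `gene_models`
#'   table) and `causal` (gene id, chromosome, causal/novel site positions)
#' @export
plant_genes <- function(genome, config) {
  exon1 <- 480L; exon2 <- 120L; intron <- 100L
  glen <- exon1 + intron + exon2
  gpc <- config$genes_per_chrom
  rows <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- Biostrings::width(genome[ci])
    if (L < (gpc + 1L) * (glen + 10L)) stopf("chromosome %s too short for %d genes", chrom, gpc)
    for (k in seq_len(gpc)) {
      s <- as.integer(round(L * k / (gpc + 1)))
      gid <- sprintf("SYNG_%s_%03d", chrom, k)
      strand <- if (k %% 2L == 1L) "+" else "-"
      rows[[gid]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = c(s, s + exon1 + intron),
        end = c(s + exon1 - 1L, s + exon1 + intron + exon2 - 1L),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)

  causal_chrom_i <- ceiling(length(genome) / 2)
  causal_k <- ceiling(gpc / 2)
  if (causal_k %% 2L == 0L) causal_k <- causal_k + 1L  # keep + strand
  causal_id <- sprintf("SYNG_%s_%03d", names(genome)[causal_chrom_i], causal_k)
  genes$strand[genes$gene_id == causal_id] <- "+"
  seg <- genes[genes$gene_id == causal_id, ]
  # engineer codons 98 (CCA), 111 (CAA), 150 (CAG); all in exon 1
  codon_first <- function(i) cds_to_genome(seg, "+", 3L * i - 2L)
  eng <- list(`98` = "CCA", `111` = "CAA", `150` = "CAG")
  at <- integer(0); letters <- character(0)
  for (i in names(eng)) {
    p <- cds_to_genome(seg, "+", (3L * as.integer(i) - 2L):(3L * as.integer(i)))
    at <- c(at, p); letters <- c(letters, strsplit(eng[[i]], "")[[1]])
  }
  chrom_seq <- genome[[causal_chrom_i]]
  genome[[causal_chrom_i]] <- Biostrings::replaceLetterAt(
    chrom_seq, at, Biostrings::DNAString(paste(letters, collapse = "")))

  causal <- list(gene_id = causal_id,
                 chrom = names(genome)[causal_chrom_i],
                 causal_pos = codon_first(150L),
                 novel_pos = c(codon_first(98L), codon_first(111L)),
                 gene_start = min(seg$start), gene_end = max(seg$end))
  list(genome = genome, genes = gene_models(genes, genome), causal = causal)
}

#' Simulate EMS-induced background mutations
#'
#' Every emitted mutation is a canonical EMS transition (G>A or C>T on the
#' reference strand); sites are drawn uniformly from G/C reference positions,
#' each mutated independently with probability `rate`.
#'
#' @param genome reference genome
#' @param rate per-G/C-site mutation probability
#' @param seed optional seed
#' @param exclude data.frame (`chrom`, `pos`) of positions never to mutate
#' @return data.frame `chrom`, `pos`, `ref`, `alt`
#' @export
simulate_ems_mutations <- function(genome, rate, seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    s <- as.character(genome[[ci]])
    n_gc <- sum(Biostrings::letterFrequency(genome[ci], c("G", "C")))
    if (n_gc == 0 || rate == 0) next
    n_mut <- rbinom(1L, n_gc, rate)
    if (n_mut == 0) next
    excl <- if (!is.null(exclude)) exclude$pos[exclude$chrom == chrom] else integer(0)
    pos <- sample_gc_positions(s, n_mut, exclude = excl)
    ref <- substring(s, pos, pos)
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                               alt = ifelse(ref == "G", "A", "T"),
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Haldane map function
#'
#' Recombination fraction for genetic distance `d` Morgans:
#' `r = (1 - exp(-2 d)) / 2`.
#'
#' @param d genetic distance in Morgans
#' @return recombination fraction in `[0, 0.5]`
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

# Binomial read sampler shared by pool and sector simulation. q is the true
# alternate-allele fraction among pooled chromosomes at each site. Sequencing
# error substitutes a base uniformly among the three others; reads whose
# observed base is neither REF nor ALT are dropped from the biallelic call,
# so DP = ref-supporting + alt-supporting reads.
sim_site_reads <- function(q, mean_depth, err) {
  n <- length(q)
  D <- rpois(n, mean_depth)
  true_alt <- rbinom(n, D, q)
  true_ref <- D - true_alt
  alt_err <- rbinom(n, true_alt, err)           # alt reads mis-sequenced
  alt_to_ref <- rbinom(n, alt_err, 1 / 3)
  ref_err <- rbinom(n, true_ref, err)
  ref_to_alt <- rbinom(n, ref_err, 1 / 3)
  obs_alt <- true_alt - alt_err + ref_to_alt
  obs_ref <- true_ref - ref_err + alt_to_ref
  data.frame(depth = obs_ref + obs_alt, alt_depth = obs_alt)
}

# Caller sensitivity model: a variant record is emitted only when the site has
# >= 2 alt-supporting reads at >= 5% allele fraction (singleton sequencing
# errors do not surface as calls).
emit_calls <- function(sites, reads) {
  keep <- reads$depth >= 1L & reads$alt_depth >= 2L &
    reads$alt_depth / reads$depth >= 0.05
  calls <- cbind(sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                 reads[keep, c("depth", "alt_depth"), drop = FALSE])
  calls$af <- calls$alt_depth / calls$depth
  rownames(calls) <- NULL
  calls
}

#' Simulate one F2 family's mutant and sibling DNA pools
#'
#' Mutant-pool individuals are homozygous for the causal allele; at a linked
#' site at genetic distance `d` Morgans each pooled chromosome carries the
#' causal-parent allele with probability `1 - r`, `r = haldane_r(d)`; unlinked
#' causal-parent mutations segregate at frequency 1/2. The sibling pool is
#' drawn from the fertile genotype classes (1/3 homozygous wild type, 2/3
#' heterozygous; causal-allele frequency 1/3 among chromosomes). Read counts
#' are binomial at Poisson depth with per-base sequencing error; planted
#' sibling-shared sites are homozygous in both pools and planted error-prone
#' sites carry a fully inflated nonreference fraction in every sample.
#'
#' @param genome engineered genome (see [plant_genes()])
#' @param config a [sim_config()]
#' @param causal list with `chrom` and `causal_pos` (from [plant_genes()]);
#'   when `NULL`, resolved from `config$causal_site`
#' @param mutations background EMS mutation table (generated when `NULL`)
#' @param planted optional list with `shared` and `blacklist` site tables
#' @param family which family's pool sizes to use (1 or 2)
#' @param seed seed for the segregation and read sampling
#' @return list with `mutant` and `sibling` [pool_variant_set()]s and `truth`
#'   (causal site, per-site expected mutant-pool frequencies, planted sites)
#' @export
simulate_f2_pools <- function(genome, config, causal = NULL, mutations = NULL,
                              planted = NULL, family = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(causal)) {
    if (identical(config$causal_site, "auto"))
      stopf("causal_site='auto' requires planted genes; call plant_genes() first")
    causal <- list(chrom = config$causal_site$chrom, causal_pos = config$causal_site$pos)
    ref <- as.character(Biostrings::subseq(genome[[causal$chrom]],
                                           causal$causal_pos, causal$causal_pos))
    if (!ref %in% c("G", "C"))
      stopf("causal site %s:%d is not a G/C position", causal$chrom, causal$causal_pos)
  }
  cchrom <- causal$chrom; cpos <- causal$causal_pos
  cref <- as.character(Biostrings::subseq(genome[[cchrom]], cpos, cpos))
  calt <- if (cref == "G") "A" else "T"

  if (is.null(mutations))
    mutations <- simulate_ems_mutations(genome, config$ems_rate,
                                        exclude = data.frame(chrom = cchrom, pos = cpos))
  if (is.null(planted)) {
    used <- rbind(mutations[, c("chrom", "pos")],
                  data.frame(chrom = cchrom, pos = cpos))
    planted <- plant_extra_sites(genome, config, used)
  }

  add_cat <- function(df, cat) {
    df$category <- rep(cat, nrow(df))
    df
  }
  sites <- rbind(
    data.frame(chrom = cchrom, pos = cpos, ref = cref, alt = calt,
               category = "causal", stringsAsFactors = FALSE),
    add_cat(mutations, "background"),
    add_cat(planted$shared, "shared"),
    add_cat(planted$blacklist, "blacklist"))

  d <- ifelse(sites$chrom == cchrom,
              config$recomb_rate * abs(sites$pos - cpos) / 1e6, Inf)
  r <- haldane_r(pmin(d, 1e6))
  r[!is.finite(d)] <- 0.5

  n_mut <- config$n_mutant_individuals[min(family, length(config$n_mutant_individuals))]
  n_wt <- config$n_wildtype_individuals[min(family, length(config$n_wildtype_individuals))]

  p_mut <- ifelse(sites$category == "background", 1 - r, 1)
  p_sib <- ifelse(sites$category == "background", (1 - r) / 3 + 2 * r / 3, 1)
  p_sib[sites$category == "causal"] <- 1 / 3
  # planted shared/error-prone sites: nonreference in every sample
  q_mut <- rbinom(nrow(sites), 2L * n_mut, p_mut) / (2 * n_mut)
  q_sib <- rbinom(nrow(sites), 2L * n_wt, p_sib) / (2 * n_wt)
  fixed <- sites$category %in% c("shared", "blacklist")
  q_mut[fixed] <- 1; q_sib[fixed] <- 1

  mut_reads <- sim_site_reads(q_mut, config$mean_depth, config$seq_error_rate)
  sib_reads <- sim_site_reads(q_sib, config$mean_depth, config$seq_error_rate)

  mutant <- pool_variant_set(sprintf("mutant_pool%d", family), "mutant_pool",
                             emit_calls(sites, mut_reads), genome)
  sibling <- pool_variant_set(sprintf("sibling_pool%d", family), "wildtype_pool",
                              emit_calls(sites, sib_reads), genome)
  linked <- sites$category == "background" & sites$chrom == cchrom
  truth <- list(
    causal_site = data.frame(chrom = cchrom, pos = cpos, ref = cref, alt = calt,
                             stringsAsFactors = FALSE),
    linked_sites = cbind(sites[linked, c("chrom", "pos", "ref", "alt")],
                         expected_freq = 1 - r[linked]),
    background = mutations,
    shared_sites = planted$shared,
    blacklist_sites = planted$blacklist)
  list(mutant = mutant, sibling = sibling, truth = truth)
}

# Draw the planted sibling-shared and error-prone site tables.
plant_extra_sites <- function(genome, config, used) {
  chrom_str <- as.character(genome)
  pick <- function(n) {
    if (n == 0)
      return(data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    per <- table(sample(names(genome), n, replace = TRUE))
    out <- lapply(names(per), function(ch) {
      excl <- used$pos[used$chrom == ch]
      pos <- sample_gc_positions(chrom_str[[ch]], per[[ch]], exclude = excl)
      ref <- substring(chrom_str[[ch]], pos, pos)
      data.frame(chrom = ch, pos = pos, ref = ref,
                 alt = ifelse(ref == "G", "A", "T"), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  }
  shared <- pick(config$n_shared_background)
  used <- rbind(used, shared[, c("chrom", "pos")])
  blacklist <- pick(config$n_blacklist)
  list(shared = shared, blacklist = blacklist)
}

#' Simulate a complete two-family BSA screen
#'
#' Generates the reference, plants gene models, draws one causal-parent EMS
#' mutation set (both F2 families descend from the same mutagenized stock),
#' and simulates both families' mutant and sibling pools plus the planted
#' sibling-shared and error-prone sites.
#'
#' @param config a [sim_config()]
#' @return list with `genome`, `genes`, `causal`, `blacklist` (site table),
#'   `families` (list of two [simulate_f2_pools()] results) and `truth`
#' @export
simulate_bsa_screen <- function(config) {
  planted <- generate_reference(config)
  pg <- plant_genes(planted, config)
  set.seed(config$seed + 1L)
  mutations <- simulate_ems_mutations(
    pg$genome, config$ems_rate,
    exclude = data.frame(chrom = pg$causal$chrom,
                         pos = c(pg$causal$causal_pos, pg$causal$novel_pos)))
  set.seed(config$seed + 2L)
  used <- rbind(mutations[, c("chrom", "pos")],
                data.frame(chrom = pg$causal$chrom, pos = pg$causal$causal_pos))
  extra <- plant_extra_sites(pg$genome, config, used)
  fams <- lapply(1:2, function(f)
    simulate_f2_pools(pg$genome, config, causal = pg$causal, mutations = mutations,
                      planted = extra, family = f, seed = config$seed + 2L + f))
  blk <- extra$blacklist[, c("chrom", "pos")]
  class(blk) <- c("site_blacklist", "data.frame")
  list(genome = pg$genome, genes = pg$genes, causal = pg$causal,
       blacklist = blk, families = fams, truth = fams[[1]]$truth)
}

#' Simulate a sterile/fertile chimeric sector pair
#'
#' Both sectors are heterozygous for the pre-existing (prior) stop-gain allele
#' of the causal gene. The sterile sector additionally carries two novel C>T
#' lesions (p.P98S and p.Q111*) in cis on the haplotype **not** carrying the
#' prior allele; the fertile sector carries neither. Fragment-level read
#' observations spanning the causal gene are emitted so that some fragments
#' co-observe the novel pair and some co-observe a novel site with the prior
#' site. Somatic heterozygous EMS background variants are planted shared
#' between sectors and unique to each.
#'
#' @param genome engineered genome
#' @param config a [sim_config()]
#' @param genes `gene_models` (planted when `NULL`, in which case `genome`
#'   must be the raw [generate_reference()] output)
#' @param causal causal-gene descriptor from [plant_genes()]
#' @param seed seed
#' @return list with `sterile`/`fertile` [pool_variant_set()]s, `reads`
#'   (read-observation table), and `truth` (prior site, novel cis pair,
#'   haplotype assignment, planted somatic sites)
#' @export
simulate_sector_pair <- function(genome, config, genes = NULL, causal = NULL,
                                 seed = NULL) {
  if (is.null(genes) || is.null(causal)) {
    pg <- plant_genes(genome, config)
    genome <- pg$genome; genes <- pg$genes; causal <- pg$causal
  }
  if (!is.null(seed)) set.seed(seed)
  err <- config$seq_error_rate
  chrom <- causal$chrom
  chrom_str <- as.character(genome[[chrom]])

  prior_pos <- causal$causal_pos
  novel_pos <- sort(causal$novel_pos)
  if (diff(range(novel_pos)) >= config$read_span)
    warnf("novel pair separation %d bp exceeds the read span %d bp: phasing will be ambiguous",
          diff(range(novel_pos)), config$read_span)
  base_at <- function(p) substring(chrom_str, p, p)
  gene_sites <- data.frame(chrom = chrom, pos = c(prior_pos, novel_pos),
                           ref = base_at(c(prior_pos, novel_pos)),
                           stringsAsFactors = FALSE)
  gene_sites$alt <- ifelse(gene_sites$ref == "G", "A", "T")

  # somatic heterozygous background variants, away from the causal gene
  used <- data.frame(chrom = gene_sites$chrom, pos = gene_sites$pos)
  gene_span <- seq(causal$gene_start - config$read_span,
                   causal$gene_end + config$read_span)
  used <- rbind(used, data.frame(chrom = chrom, pos = gene_span))
  somatic <- plant_extra_sites(genome, replace_counts(config,
                                                      config$n_somatic_shared,
                                                      2L * config$n_somatic_unique),
                               used)
  shared_som <- somatic$shared
  uniq <- somatic$blacklist
  half <- seq_len(config$n_somatic_unique)
  sterile_uniq <- uniq[half, , drop = FALSE]
  fertile_uniq <- uniq[setdiff(seq_len(nrow(uniq)), half), , drop = FALSE]

  # fragment observations across the causal gene: haplotype A carries the
  # prior allele; haplotype B is the (ex-)wild-type copy, which in the sterile
  # sector carries the novel cis pair
  span <- config$read_span
  p_min <- min(gene_sites$pos); p_max <- max(gene_sites$pos)
  W <- p_max - p_min + span
  n_frag <- round(config$sector_depth * W / span)
  make_reads <- function(prefix, hapB_alt) {
    starts <- p_min - span + sample.int(W, n_frag, replace = TRUE)
    hap <- sample(c("A", "B"), n_frag, replace = TRUE)
    rows <- list()
    for (i in seq_len(nrow(gene_sites))) {
      pos <- gene_sites$pos[i]
      covered <- which(starts <= pos & starts + span - 1L >= pos)
      if (!length(covered)) next
      is_alt_hap <- if (i == 1L) hap[covered] == "A" else (hap[covered] == "B" & hapB_alt)
      allele <- ifelse(is_alt_hap, gene_sites$alt[i], gene_sites$ref[i])
      flip <- runif(length(covered)) < err
      if (any(flip)) {
        allele[flip] <- vapply(allele[flip], function(a)
          sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1))
      }
      rows[[i]] <- data.frame(read_id = sprintf("%s%05d", prefix, covered),
                              chrom = chrom, pos = pos, allele = allele,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  sterile_reads <- make_reads("s", hapB_alt = TRUE)
  fertile_reads <- make_reads("f", hapB_alt = FALSE)

  calls_from_reads <- function(reads) {
    out <- lapply(seq_len(nrow(gene_sites)), function(i) {
      obs <- reads$allele[reads$pos == gene_sites$pos[i]]
      data.frame(chrom = chrom, pos = gene_sites$pos[i],
                 ref = gene_sites$ref[i], alt = gene_sites$alt[i],
                 depth = sum(obs %in% c(gene_sites$ref[i], gene_sites$alt[i])),
                 alt_depth = sum(obs == gene_sites$alt[i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  het_calls <- function(sites) {
    if (nrow(sites) == 0) return(NULL)
    reads <- sim_site_reads(rep(0.5, nrow(sites)), config$sector_depth, err)
    cbind(sites[, c("chrom", "pos", "ref", "alt")], reads)
  }
  assemble <- function(reads, uniq_sites) {
    gene_calls <- calls_from_reads(reads)
    calls <- rbind(gene_calls, het_calls(shared_som), het_calls(uniq_sites))
    calls <- calls[calls$depth >= 1L & calls$alt_depth >= 2L &
                     calls$alt_depth / calls$depth >= 0.05, , drop = FALSE]
    calls$af <- calls$alt_depth / calls$depth
    calls
  }
  sterile <- pool_variant_set("sterile_sector", "sterile_sector",
                              assemble(sterile_reads, sterile_uniq), genome)
  fertile_gene <- calls_from_reads(fertile_reads)
  fertile_gene <- fertile_gene[fertile_gene$pos == prior_pos | fertile_gene$alt_depth > 0, ,
                               drop = FALSE]
  fertile_calls <- rbind(fertile_gene, het_calls(shared_som), het_calls(fertile_uniq))
  fertile_calls <- fertile_calls[fertile_calls$depth >= 1L & fertile_calls$alt_depth >= 2L &
                                   fertile_calls$alt_depth / fertile_calls$depth >= 0.05, ,
                                 drop = FALSE]
  fertile_calls$af <- fertile_calls$alt_depth / fertile_calls$depth
  fertile <- pool_variant_set("fertile_sector", "fertile_sector", fertile_calls, genome)

  truth <- list(
    prior_het_site = gene_sites[1, c("chrom", "pos", "ref", "alt")],
    novel_cis_pair = gene_sites[2:3, c("chrom", "pos", "ref", "alt")],
    haplotype = c(prior = "A", novel = "B"),
    gene_id = causal$gene_id,
    somatic_shared = shared_som,
    sterile_unique = rbind(gene_sites[2:3, c("chrom", "pos", "ref", "alt")],
                           sterile_uniq[, c("chrom", "pos", "ref", "alt")]),
    fertile_unique = fertile_uniq)
  # phasing consumes the sterile sector's reads; the fertile table is kept for
  # control constructions
  list(sterile = sterile, fertile = fertile,
       reads = sterile_reads, reads_fertile = fertile_reads, truth = truth)
}

replace_counts <- function(config, n_shared, n_blacklist) {
  config$n_shared_background <- as.integer(n_shared)
  config$n_blacklist <- as.integer(n_blacklist)
  config
}

#' Build a single-gene fixture genome for annotation tests
#'
#' Constructs a random genome containing one gene whose selected codons are
#' overwritten with given triplets (coding-strand sense), e.g.
#' `list("150" = "CAG")` so a C>T at the codon's first base yields p.Q150*.
#'
#' @param codons named list: codon index -> 3-letter codon (coding strand)
#' @param strand gene strand on the reference
#' @param n_codons CDS length in codons
#' @param seed seed for the random backbone
#' @return list: `genome`, `genes`, and `codon_start` (genome position of each
#'   requested codon's first coding base)
#' @export
synthetic_gene_fixture <- function(codons = list(`150` = "CAG"), strand = "+",
                                   n_codons = 250L, seed = 1L) {
  set.seed(seed)
  cds_len <- 3L * n_codons
  flank <- 500L
  L <- cds_len + 2L * flank
  genome <- Biostrings::DNAStringSet(random_dna(L))
  names(genome) <- "ChrF"
  seg <- data.frame(start = flank + 1L, end = flank + cds_len)
  for (i in names(codons)) {
    idx <- as.integer(i)
    cod <- Biostrings::DNAString(codons[[i]])
    if (strand == "-") cod <- Biostrings::reverseComplement(cod)
    at <- cds_to_genome(seg, strand, (3L * idx - 2L):(3L * idx))
    genome[[1]] <- Biostrings::replaceLetterAt(genome[[1]], sort(at),
                                               if (strand == "-") cod else cod)
  }
  genes <- gene_models(data.frame(gene_id = "FIXG", chrom = "ChrF",
                                  strand = strand, start = seg$start,
                                  end = seg$end, stringsAsFactors = FALSE),
                       genome)
  codon_start <- vapply(names(codons), function(i)
    cds_to_genome(seg, strand, 3L * as.integer(i) - 2L), integer(1))
  list(genome = genome, genes = genes, codon_start = codon_start)
}

#' Write a read-observation table to TSV
#' @param reads data.frame `read_id`, `chrom`, `pos`, `allele`
#' @param path output file
#' @export
write_read_observations <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-observation table from TSV
#' @param path TSV with columns `read_id`, `chrom`, `pos`, `allele`
#' @return data.frame
#' @export
read_read_observations <- function(path) {
  if (!file.exists(path)) stopf("read-observation file not found: %s", path)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer", "character"))
  if (!all(tab$allele %in% c("A", "C", "G", "T")))
    stopf("read observations contain alleles outside {A,C,G,T}")
  tab
}
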