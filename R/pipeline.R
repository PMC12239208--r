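# Pipeline entry points: configuration handling, the BSA workflow, the
# sector workflow, and synthetic-dataset export. All numeric outputs (TSV,
# JSON, VCF) are deterministic for a given configuration and seed.

PIPELINE_KEYS <- c(
  # inputs
  "genome", "gff3", "blacklist", "mutant_vcfs", "sibling_vcfs",
  "sterile_vcf", "fertile_vcf", "reads_tsv", "interval_json", "prior_site",
  # stage thresholds
  "min_depth", "freq_threshold", "bin_size", "consecutive_background",
  "min_peak_excess", "het_min_depth", "freq_window", "err_max",
  "min_informative", "max_discord_frac",
  # run control
  "seed", "outdir", "verbose")

PIPELINE_DEFAULTS <- list(
  min_depth = 2L, freq_threshold = 0.99, bin_size = 1000000L,
  consecutive_background = 2L, min_peak_excess = 3,
  het_min_depth = 10L, freq_window = c(0.25, 0.75), err_max = 0.02,
  min_informative = 3L, max_discord_frac = 0.05,
  seed = 1L, outdir = ".", verbose = TRUE)

#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; `...` overrides individual
#' values. Unknown keys are rejected and every threshold is checked against
#' its documented range.
#'
#' @param x YAML file path or named list (may be `NULL`)
#' @param ... individual overrides, e.g. `outdir = "run1"`
#' @return a validated named list of class `pipeline_config`
#' @export
pipeline_config <- function(x = NULL, ...) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    yaml::read_yaml(x)
  } else x %||% list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) stopf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", "))
  for (k in names(PIPELINE_DEFAULTS))
    if (is.null(cfg[[k]])) cfg[[k]] <- PIPELINE_DEFAULTS[[k]]
  with(cfg, {
    stopifnot(min_depth >= 1, freq_threshold > 0.5, freq_threshold <= 1,
              bin_size >= 1, consecutive_background >= 1, min_peak_excess >= 0,
              het_min_depth >= 1, length(freq_window) == 2,
              freq_window[1] >= 0, freq_window[2] <= 1,
              freq_window[1] < freq_window[2],
              err_max >= 0, err_max < 0.5, min_informative >= 1,
              max_discord_frac >= 0, max_discord_frac < 1)
  })
  structure(cfg, class = "pipeline_config")
}

#' Write a mapping interval to JSON
#' @param interval a `mapping_interval`
#' @param path output file
#' @export
write_interval <- function(interval, path) {
  jsonlite::write_json(unclass(interval), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mapping interval from JSON
#' @param path JSON written by [write_interval()]
#' @return a `mapping_interval`
#' @export
read_interval <- function(path) {
  if (!file.exists(path)) stopf("interval file not found: %s", path)
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "mapping_interval")
}

new_log <- function(verbose) {
  lines <- character(0)
  list(add = function(fmt, ...) {
    line <- sprintf(fmt, ...)
    lines <<- c(lines, line)
    if (verbose) message(line)
  },
  dump = function(path) writeLines(lines, path))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the bulked-segregant mapping workflow
#'
#' Executes, per mutant/sibling pool pair: homozygous calling, sibling-pool
#' subtraction, blacklist removal, EMS-spectrum filtering, per-bin density
#' counting and interval detection; then, with two pools, the shared-variant
#' intersection, interval refinement and candidate ranking. Every filter
#' step's input/output counts are logged, and all stage outputs (filtered
#' VCFs, per-bin TSVs, interval JSON, candidate TSV, a density figure per
#' pool, run log) are written under `config$outdir`.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one)
#' @return list with per-pool results, the refined interval and the candidate
#'   table, invisibly
#' @export
run_bsa <- function(config) {
  cfg <- pipeline_config(config)
  for (k in c("genome", "gff3", "mutant_vcfs", "sibling_vcfs"))
    if (is.null(cfg[[k]])) stopf("run_bsa: config key '%s' is required", k)
  missing <- !vapply(c(cfg$genome, cfg$gff3, cfg$mutant_vcfs, cfg$sibling_vcfs,
                       cfg$blacklist), file.exists, logical(1))
  if (any(missing)) stopf("run_bsa: missing input file(s): %s",
                          paste(c(cfg$genome, cfg$gff3, cfg$mutant_vcfs,
                                  cfg$sibling_vcfs, cfg$blacklist)[missing],
                                collapse = ", "))
  if (length(cfg$mutant_vcfs) != length(cfg$sibling_vcfs))
    stopf("run_bsa: each mutant pool needs a matched sibling pool")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- new_log(cfg$verbose)
  log$add("emsmapr %s | run_bsa", as.character(utils::packageVersion("emsmapr")))

  genome <- read_fasta(cfg$genome)
  genes <- read_gff3(cfg$gff3, genome)
  blacklist <- if (!is.null(cfg$blacklist)) read_blacklist(cfg$blacklist) else NULL
  log$add("genome: %d chromosome(s); %d gene model(s); blacklist: %d site(s)",
          length(genome), length(unique(genes$gene_id)),
          if (is.null(blacklist)) 0L else nrow(blacklist))

  pools <- vector("list", length(cfg$mutant_vcfs))
  for (i in seq_along(cfg$mutant_vcfs)) {
    mut <- read_vcf(cfg$mutant_vcfs[i], role = "mutant_pool", genome = genome)
    sib <- read_vcf(cfg$sibling_vcfs[i], role = "wildtype_pool", genome = genome)
    log$add("pool %d: %d mutant / %d sibling call(s)", i, nrow(mut$calls), nrow(sib$calls))
    hom <- call_homozygous(mut, cfg$min_depth, cfg$freq_threshold)
    log$add("pool %d: homozygous (depth >= %d, freq >= %g): %d -> %d",
            i, cfg$min_depth, cfg$freq_threshold, nrow(mut$calls), nrow(hom))
    sub <- subtract_shared(hom, sib, cfg$min_depth, cfg$freq_threshold)
    log$add("pool %d: sibling-shared subtraction: %d -> %d", i, nrow(hom), nrow(sub))
    blk <- apply_blacklist(sub, blacklist)
    log$add("pool %d: blacklist removal: %d -> %d", i, nrow(sub), nrow(blk))
    ems <- filter_ems_spectrum(blk)
    log$add("pool %d: EMS-spectrum filter: %d -> %d", i, nrow(blk), nrow(ems))
    bins <- bin_variant_counts(ems, genome, cfg$bin_size)
    interval <- detect_mapping_interval(bins, cfg$consecutive_background,
                                        cfg$min_peak_excess)
    log$add("pool %d: interval: %s", i,
            if (is.null(interval)) "none" else
              sprintf("%s:%d-%d (peak %d)", interval$chrom, interval$start,
                      interval$end, interval$peak_count))
    filt_pool <- pool_variant_set(mut$sample_id, "mutant_pool", ems, genome)
    write_vcf(filt_pool, file.path(cfg$outdir, sprintf("pool%d_filtered.vcf", i)), genome)
    write_tsv(as.data.frame(bins), file.path(cfg$outdir, sprintf("pool%d_bins.tsv", i)))
    fig <- plot_variant_density(bins, interval)
    ggplot2::ggsave(file.path(cfg$outdir, sprintf("pool%d_density.pdf", i)), fig,
                    width = 10, height = 2.5)
    if (!is.null(interval))
      write_interval(interval, file.path(cfg$outdir, sprintf("pool%d_interval.json", i)))
    pools[[i]] <- list(filtered = ems, bins = bins, interval = interval)
  }

  shared <- NULL; refined <- NULL
  if (length(pools) >= 2) {
    res <- tryCatch(suppressWarnings(
      intersect_pools(pools[[1]]$filtered, pools[[2]]$filtered,
                      pools[[1]]$interval, pools[[2]]$interval)),
      error = function(e) {
        log$add("intersection failed: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      shared <- res$shared; refined <- res$interval
      log$add("two-pool intersection: %d shared variant(s); refined interval %s",
              nrow(shared),
              if (is.null(refined)) "none" else
                sprintf("%s:%d-%d", refined$chrom, refined$start, refined$end))
      if (!is.null(refined))
        write_interval(refined, file.path(cfg$outdir, "refined_interval.json"))
    }
  } else {
    log$add("single pool: intersection skipped")
    refined <- pools[[1]]$interval
    if (!is.null(refined))
      write_interval(refined, file.path(cfg$outdir, "refined_interval.json"))
  }

  candidate_set <- shared %||% pools[[1]]$filtered
  annotated <- classify_variants(candidate_set, genes, genome)
  candidates <- rank_candidates(annotated)
  log$add("candidates: %d protein-altering variant(s) ranked", nrow(candidates))
  write_tsv(candidates, file.path(cfg$outdir, "candidates.tsv"))
  log$dump(file.path(cfg$outdir, "bsa_run_log.txt"))
  invisible(list(pools = pools, shared = shared, interval = refined,
                 candidates = candidates))
}

#' Run the sterile/fertile sector workflow
#'
#' Executes heterozygous EMS-variant calling on the sterile sector,
#' sterile-unique differencing against the fertile sector within the mapped
#' interval, confirmation of the prior allele in both sectors, consequence
#' annotation of the unique variants, read-backed phasing and gene
#' nomination; writes a JSON report and a TSV of the unique variants.
#'
#' @param config a [pipeline_config()]; requires `genome`, `gff3`,
#'   `sterile_vcf`, `fertile_vcf`, `reads_tsv`, `interval_json` and
#'   `prior_site` (list with `chrom`, `pos`)
#' @return list with the differential partition, prior-allele report and
#'   nomination, invisibly
#' @export
run_sector <- function(config) {
  cfg <- pipeline_config(config)
  for (k in c("genome", "gff3", "sterile_vcf", "fertile_vcf", "reads_tsv", "prior_site"))
    if (is.null(cfg[[k]])) stopf("run_sector: config key '%s' is required", k)
  if (is.null(cfg$interval_json) || !file.exists(cfg$interval_json))
    stopf("run_sector: no mapping interval at '%s'; run run_bsa first",
          cfg$interval_json %||% "<unset>")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- new_log(cfg$verbose)
  log$add("emsmapr %s | run_sector", as.character(utils::packageVersion("emsmapr")))

  genome <- read_fasta(cfg$genome)
  genes <- read_gff3(cfg$gff3, genome)
  interval <- read_interval(cfg$interval_json)
  sterile <- read_vcf(cfg$sterile_vcf, role = "sterile_sector", genome = genome)
  fertile <- read_vcf(cfg$fertile_vcf, role = "fertile_sector", genome = genome)
  reads <- read_read_observations(cfg$reads_tsv)
  log$add("interval %s:%d-%d; %d sterile / %d fertile call(s); %d read observation(s)",
          interval$chrom, interval$start, interval$end,
          nrow(sterile$calls), nrow(fertile$calls), nrow(reads))

  het <- call_heterozygous(sterile, cfg$het_min_depth, cfg$freq_window)
  log$add("sterile heterozygous EMS calls: %d -> %d", nrow(sterile$calls), nrow(het))
  diff <- differential_sterile_unique(het, fertile, interval, cfg$err_max)
  log$add("within interval: %d sterile-unique / %d shared (genome-wide %d / %d)",
          nrow(diff$unique), nrow(diff$shared),
          diff$n_unique_genomewide, diff$n_shared_genomewide)

  prior <- cfg$prior_site
  prior_report <- tryCatch(
    confirm_prior_allele(prior, sterile, fertile, cfg$freq_window),
    error = function(e) { log$add("prior allele: %s", conditionMessage(e)); NULL })
  if (!is.null(prior_report))
    log$add("prior allele %s:%d: sterile %.3f / fertile %.3f -> %s",
            prior$chrom, prior$pos, prior_report$freq_sterile,
            prior_report$freq_fertile,
            if (prior_report$confirmed) "heterozygote confirmed" else "NOT confirmed")

  annotated <- classify_variants(diff$unique, genes, genome)
  prior_full <- sterile$calls[sterile$calls$chrom == prior$chrom &
                                sterile$calls$pos == prior$pos, , drop = FALSE]
  if (nrow(prior_full) == 0)
    prior_full <- data.frame(chrom = prior$chrom, pos = prior$pos,
                             ref = prior$ref %||% NA_character_,
                             alt = prior$alt %||% NA_character_)
  nomination <- nominate_allele(annotated, reads, prior_full[1, ],
                                cfg$min_informative, cfg$max_discord_frac)
  log$add("nominated gene(s): %s",
          if (length(nomination$nominated)) paste(nomination$nominated, collapse = ", ")
          else "none")

  write_tsv(annotated, file.path(cfg$outdir, "sterile_unique_variants.tsv"))
  report <- list(
    interval = unclass(interval),
    n_unique_interval = nrow(diff$unique),
    n_shared_interval = nrow(diff$shared),
    n_unique_genomewide = diff$n_unique_genomewide,
    n_shared_genomewide = diff$n_shared_genomewide,
    prior_allele = prior_report,
    genes = nomination$genes,
    nominated = nomination$nominated)
  jsonlite::write_json(report, file.path(cfg$outdir, "sector_report.json"),
                       auto_unbox = TRUE, digits = NA)
  log$dump(file.path(cfg$outdir, "sector_run_log.txt"))
  invisible(list(differential = diff, prior = prior_report,
                 annotated = annotated, nomination = nomination))
}

#' Write a complete synthetic screen dataset
#'
#' Simulates a two-family BSA screen plus a sterile/fertile sector pair and
#' writes every artifact the pipeline consumes: reference FASTA, gene-model
#' GFF3, pool and sector VCFs, blacklist BED, read-observation TSVs and a
#' ground-truth JSON.
#'
#' @param config a [sim_config()]
#' @param outdir output directory
#' @return the dataset (as from [simulate_bsa_screen()] and
#'   [simulate_sector_pair()]), invisibly
#' @export
simulate_screen <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  screen <- simulate_bsa_screen(config)
  sector <- simulate_sector_pair(screen$genome, config, screen$genes,
                                 screen$causal, seed = config$seed + 9L)
  write_fasta(screen$genome, file.path(outdir, "genome.fasta"))
  write_gff3(screen$genes, file.path(outdir, "genes.gff3"))
  write_blacklist(screen$blacklist, file.path(outdir, "blacklist.bed"))
  for (f in 1:2) {
    write_vcf(screen$families[[f]]$mutant,
              file.path(outdir, sprintf("mutant_pool%d.vcf", f)), screen$genome)
    write_vcf(screen$families[[f]]$sibling,
              file.path(outdir, sprintf("sibling_pool%d.vcf", f)), screen$genome)
  }
  write_vcf(sector$sterile, file.path(outdir, "sterile_sector.vcf"), screen$genome)
  write_vcf(sector$fertile, file.path(outdir, "fertile_sector.vcf"), screen$genome)
  write_read_observations(sector$reads, file.path(outdir, "reads_sterile.tsv"))
  write_read_observations(sector$reads_fertile, file.path(outdir, "reads_fertile.tsv"))
  truth <- list(causal = screen$truth$causal_site,
                linked_sites = screen$truth$linked_sites,
                shared_sites = screen$truth$shared_sites,
                blacklist_sites = screen$truth$blacklist_sites,
                sector = sector$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(screen = screen, sector = sector))
}
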