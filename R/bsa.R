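# Bulked-segregant mapping: homozygosity calling, sibling-pool and
# error-prone-site subtraction, EMS-spectrum filtering, per-bin variant
# density, interval detection and two-pool intersection.

#' Call homozygous nonreference variants in a pool
#'
#' A variant is retained as homozygous when its read depth is at least
#' `min_depth` (default two reads) and its alternate-allele frequency is at
#' least `freq_threshold` (default 0.99).
#'
#' @param pool a [pool_variant_set()] (or a plain variant-call data.frame)
#' @param min_depth minimum read coverage
#' @param freq_threshold minimum alternate-allele frequency
#' @return variant-call data.frame sorted by (chrom, pos)
#' @export
call_homozygous <- function(pool, min_depth = 2L, freq_threshold = 0.99) {
  calls <- if (inherits(pool, "pool_variant_set")) pool$calls else validate_calls(pool)
  keep <- calls$depth >= min_depth & calls$af >= freq_threshold
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract variants shared with the wild-type sibling pool
#'
#' Removes exactly those variants that are homozygous (same thresholds) at the
#' same (chrom, pos, alt) in the sibling pool. Sites merely heterozygous in
#' the sibling are retained.
#'
#' @param mutant_set homozygous variant table of the mutant pool
#' @param sibling_pool the sibling [pool_variant_set()]
#' @inheritParams call_homozygous
#' @return filtered variant table
#' @export
subtract_shared <- function(mutant_set, sibling_pool, min_depth = 2L,
                            freq_threshold = 0.99) {
  sib_hom <- call_homozygous(sibling_pool, min_depth, freq_threshold)
  key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")
  out <- mutant_set[!(key(mutant_set) %in% key(sib_hom)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants at blacklisted error-prone sites
#'
#' @param set variant table
#' @param blacklist a `site_blacklist` (data.frame with `chrom`, `pos`)
#' @return variant table without blacklisted positions
#' @export
apply_blacklist <- function(set, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(set)
  out <- set[!(site_key(set$chrom, set$pos) %in%
                 site_key(blacklist$chrom, blacklist$pos)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only canonical EMS transitions
#'
#' EMS predominantly induces G:C to A:T transitions, observed against the
#' reference as G>A or C>T single-nucleotide changes. All other substitutions
#' are removed.
#'
#' @param set variant table
#' @return variant table restricted to G>A / C>T changes
#' @export
filter_ems_spectrum <- function(set) {
  keep <- (set$ref == "G" & set$alt == "A") | (set$ref == "C" & set$alt == "T")
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count variants per chromosomal bin
#'
#' Bins tile each chromosome from position 1 at `bin_size` spacing; the bin of
#' a variant at `pos` is `floor((pos - 1) / bin_size)`. Per-chromosome counts
#' always conserve the total number of variants.
#'
#' @param set variant table
#' @param genome reference genome ([Biostrings::DNAStringSet]) or a named
#'   numeric vector of chromosome lengths
#' @param bin_size bin width in bp (default 1 Mbp)
#' @return data.frame `chrom`, `bin_start`, `count` (class `bin_counts`, with
#'   a `bin_size` attribute); chromosomes ordered as in the genome
#' @export
bin_variant_counts <- function(set, genome, bin_size = 1000000L) {
  lens <- if (methods::is(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome)) else genome
  if (is.null(names(lens))) stopf("genome lengths must be named by chromosome")
  bad <- setdiff(unique(set$chrom), names(lens))
  if (length(bad)) stopf("variants on chromosome(s) absent from the genome: %s",
                         paste(bad, collapse = ", "))
  out <- lapply(names(lens), function(ch) {
    n_bins <- max(1L, ceiling(lens[[ch]] / bin_size))
    starts <- (seq_len(n_bins) - 1L) * bin_size + 1L
    pos <- set$pos[set$chrom == ch]
    idx <- (pos - 1L) %/% bin_size + 1L
    counts <- tabulate(idx, nbins = n_bins)
    data.frame(chrom = ch, bin_start = starts, count = counts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_size") <- as.integer(bin_size)
  class(res) <- c("bin_counts", "data.frame")
  res
}

#' Detect the mapping interval from binned variant counts
#'
#' The peak bin is the genome-wide maximum count (ties broken by chromosome
#' order, then lowest bin start, and logged). The background level is the
#' median count over all bins. The interval extends from the peak in both
#' directions until `consecutive_background` successive bins fall to or below
#' the background level, i.e. until the variant density returns to background.
#' No interval is declared when the peak does not exceed the background by
#' more than `min_peak_excess` counts.
#'
#' @param bins a `bin_counts` table covering every chromosome
#' @param consecutive_background bins at/below background that terminate the
#'   interval on each side
#' @param min_peak_excess minimum peak prominence above background
#' @return a `mapping_interval` (list with `chrom`, `start`, `end`,
#'   `peak_bin`, `peak_count`, `background_level`) or `NULL`
#' @export
detect_mapping_interval <- function(bins, consecutive_background = 2L,
                                    min_peak_excess = 3) {
  bin_size <- attr(bins, "bin_size") %||% stop("bins lack a bin_size attribute")
  bg <- median(bins$count)
  peak_count <- max(bins$count)
  if (peak_count <= bg + min_peak_excess) {
    message("no mapping interval: peak count ", peak_count,
            " does not exceed background ", bg, " by more than ", min_peak_excess)
    return(NULL)
  }
  hits <- which(bins$count == peak_count)
  if (length(hits) > 1L)
    message("tied peak bins; keeping the first in (chromosome, bin_start) order")
  peak <- hits[1L]  # bins are already ordered by (chromosome order, bin_start)
  chrom <- bins$chrom[peak]
  cb <- bins[bins$chrom == chrom, , drop = FALSE]
  pk <- which(cb$bin_start == bins$bin_start[peak])

  walk <- function(idx_seq) {
    last_above <- pk; run <- 0L
    for (i in idx_seq) {
      if (cb$count[i] <= bg) {
        run <- run + 1L
        if (run >= consecutive_background) break
      } else {
        run <- 0L
        last_above <- i
      }
    }
    last_above
  }
  left <- walk(rev(seq_len(pk - 1L)))
  right <- walk(seq(pk + 1L, length.out = max(0L, nrow(cb) - pk)))
  structure(list(chrom = chrom,
                 start = cb$bin_start[left],
                 end = cb$bin_start[right] + bin_size - 1L,
                 peak_bin = cb$bin_start[pk],
                 peak_count = peak_count,
                 background_level = bg),
            class = "mapping_interval")
}

#' @export
print.mapping_interval <- function(x, ...) {
  cat(sprintf("<mapping_interval> %s:%d-%d (peak bin %d, count %d, background %.1f)\n",
              x$chrom, x$start, x$end, x$peak_bin, x$peak_count, x$background_level))
  invisible(x)
}

in_interval <- function(chrom, pos, interval) {
  !is.null(interval) & chrom == interval$chrom &
    pos >= interval$start & pos <= interval$end
}

#' Intersect two pools' filtered variants and refine the interval
#'
#' The shared set consists of variants with identical (chrom, pos, ref, alt)
#' in both pools. The refined interval is the positional span of the shared
#' variants, intersected with the overlap of the two single-pool intervals.
#'
#' @param setA,setB identically filtered variant tables from the two pools
#' @param intervalA,intervalB the pools' [detect_mapping_interval()] results
#' @return list with `shared` (variant table) and `interval`
#'   (a `mapping_interval`)
#' @export
intersect_pools <- function(setA, setB, intervalA, intervalB) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  shared <- setA[key(setA) %in% key(setB), , drop = FALSE]
  rownames(shared) <- NULL
  if (is.null(intervalA) || is.null(intervalB)) {
    warnf("no consensus region: a pool lacks a detected interval; returning the shared set without refinement")
    return(list(shared = shared, interval = NULL))
  }
  if (intervalA$chrom != intervalB$chrom)
    stopf("no consensus region: intervals lie on different chromosomes (%s vs %s)",
          intervalA$chrom, intervalB$chrom)
  if (nrow(shared) == 0)
    stopf("no consensus region: the pools share no filtered variants")
  chrom <- intervalA$chrom
  span <- range(shared$pos[shared$chrom == chrom])
  lo <- max(span[1], intervalA$start, intervalB$start)
  hi <- min(span[2], intervalA$end, intervalB$end)
  if (!is.finite(lo) || lo > hi)
    stopf("no consensus region: shared variants fall outside the interval overlap")
  refined <- structure(list(chrom = chrom, start = lo, end = hi,
                            peak_bin = intervalA$peak_bin,
                            peak_count = intervalA$peak_count,
                            background_level = intervalA$background_level),
                       class = "mapping_interval")
  list(shared = shared, interval = refined)
}

#' Plot per-bin homozygous-variant density
#'
#' One panel per chromosome; the detected interval, when given, is shaded.
#'
#' @param bins a `bin_counts` table
#' @param interval optional `mapping_interval` to highlight
#' @return a ggplot object
#' @export
plot_variant_density <- function(bins, interval = NULL) {
  df <- as.data.frame(bins)
  df$mbp <- (df$bin_start - 1) / 1e6
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mbp, y = count)) +
    ggplot2::geom_col(width = (attr(bins, "bin_size") %||% 1e6) / 1e6,
                      fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "Position (Mbp)", y = "Homozygous variants per bin") +
    ggplot2::theme_bw()
  if (!is.null(interval)) {
    shade <- data.frame(chrom = interval$chrom,
                        xmin = (interval$start - 1) / 1e6,
                        xmax = interval$end / 1e6)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = xmin, xmax = xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.25, fill = "orange",
      inherit.aes = FALSE)
  }
  p
}

utils::globalVariables(c("mbp", "count", "xmin", "xmax"))
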