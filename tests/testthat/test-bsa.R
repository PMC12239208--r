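test_that("homozygous calling enforces the frequency and coverage thresholds", {
  calls <- make_calls("Chr1", c(10L, 20L, 30L), c("G", "C", "C"), c("A", "T", "T"),
                      c(10L, 100L, 1L), c(10L, 98L, 1L))
  hom <- call_homozygous(pool_variant_set("p", "mutant_pool", calls))
  expect_equal(hom$pos, 10L)            # 0.98 < 0.99 and depth 1 < 2 are removed
  expect_equal(nrow(call_homozygous(calls, freq_threshold = 0.9)), 2L)
})

test_that("sibling subtraction removes exactly the sites homozygous in both", {
  mut <- make_calls("Chr1", c(10L, 20L), c("G", "C"), c("A", "T"),
                    c(20L, 20L), c(20L, 20L))
  sib <- pool_variant_set("sib", "wildtype_pool",
                          make_calls("Chr1", c(10L, 20L), c("G", "C"), c("A", "T"),
                                     c(20L, 20L), c(20L, 10L)))
  out <- subtract_shared(mut, sib)
  expect_equal(out$pos, 20L)  # het (0.5) in sibling -> retained

  for (s in 1:25) {
    set.seed(s)
    m <- validate_calls(random_ems_calls(40, max_pos = 500))
    m$af <- 1; m$alt_depth <- m$depth
    sraw <- random_ems_calls(40, max_pos = 500)
    sib_pool <- pool_variant_set("s", "wildtype_pool", validate_calls(sraw))
    got <- subtract_shared(m, sib_pool)
    want <- oracle_subtract(m, call_homozygous(sib_pool))
    expect_identical(got, want)
  }
})

test_that("blacklist removal is exact set subtraction by position", {
  calls <- validate_calls(random_ems_calls(30))
  expect_identical(apply_blacklist(calls, data.frame(chrom = character(), pos = integer())),
                   calls)
  all_bl <- data.frame(chrom = calls$chrom, pos = calls$pos)
  expect_equal(nrow(apply_blacklist(calls, all_bl)), 0L)
  some <- all_bl[1:10, ]
  out <- apply_blacklist(calls, some)
  expect_equal(nrow(out), nrow(calls) - 10L)
  expect_false(any(paste(out$chrom, out$pos) %in% paste(some$chrom, some$pos)))
})

test_that("the EMS spectrum filter keeps only G>A and C>T changes", {
  calls <- make_calls("Chr4", c(61494009L, 100L, 200L, 300L),
                      c("C", "A", "G", "C"), c("T", "G", "T", "A"),
                      20L, c(20L, 20L, 20L, 20L))
  out <- filter_ems_spectrum(calls)
  expect_equal(out$pos, 61494009L)
})

test_that("filters never grow the set and blacklist/sibling subtraction commute", {
  sib <- pool_variant_set("s", "wildtype_pool", validate_calls(random_ems_calls(50)))
  for (s in 1:10) {
    set.seed(s)
    m <- validate_calls(random_ems_calls(60, max_pos = 300))
    bl <- data.frame(chrom = sample(c("Chr1", "Chr2"), 20, TRUE),
                     pos = sample.int(300, 20))
    a <- filter_ems_spectrum(apply_blacklist(subtract_shared(m, sib), bl))
    b <- filter_ems_spectrum(subtract_shared(apply_blacklist(m, bl), sib))
    expect_identical(a, b)
    expect_lte(nrow(a), nrow(m))
  }
})

test_that("binning respects bin boundaries and conserves totals", {
  lens <- c(Chr1 = 3e6)
  calls <- make_calls("Chr1", c(1L, 1000000L, 1000001L), "C", "T", 10L, 10L)
  bins <- bin_variant_counts(calls, lens)
  expect_equal(bins$count, c(2L, 1L, 0L))
  expect_equal(bins$bin_start, c(1L, 1000001L, 2000001L))

  empty <- bin_variant_counts(emsmapr:::empty_calls(), c(Chr1 = 2.5e6, Chr2 = 1e6))
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 4L)  # bins tile both chromosomes

  for (s in 1:5) {
    set.seed(s)
    lens <- c(Chr1 = 9e5, Chr2 = 4e5)
    calls <- validate_calls(random_ems_calls(200, max_pos = 4e5))
    got <- bin_variant_counts(calls, lens, bin_size = 1e5)
    want <- oracle_bin_counts(calls, lens, 1e5)
    plain <- as.data.frame(got)
    attr(plain, "bin_size") <- NULL
    expect_equal(plain, want)
    expect_equal(sum(got$count), nrow(calls))
  }
})

test_that("interval detection follows the stated background-return rule", {
  bins <- make_bins(list(
    ChrA = c(0, 1, 0, 12, 15, 9, 1, 0, 0, 0),
    ChrB = c(1, 1, 1, 1, 1, 1, 0, 0, 1, 1)))
  iv <- detect_mapping_interval(bins)
  expect_equal(iv$chrom, "ChrA")
  expect_equal(iv$background_level, 1)
  expect_equal(iv$peak_count, 15)
  expect_equal(iv$peak_bin, 4e6 + 1)            # 5th bin
  expect_equal(iv$start, 3e6 + 1)               # bins 4-6 (1-based)
  expect_equal(iv$end, 6e6)

  flat <- make_bins(list(ChrA = rep(0, 6), ChrB = rep(0, 6)))
  expect_message(expect_null(detect_mapping_interval(flat)), "no mapping interval")

  tie <- make_bins(list(ChrA = c(0, 9, 0, 0), ChrB = c(0, 0, 9, 0)))
  expect_message(iv2 <- detect_mapping_interval(tie), "tied peak")
  expect_equal(iv2$chrom, "ChrA")
  expect_equal(iv2$peak_bin, 1e6 + 1)
})

test_that("interval detection matches a literal re-execution on random bins", {
  for (s in 1:40) {
    set.seed(s)
    bins <- make_bins(list(
      ChrA = rpois(12, 0.7) + sample(c(0, 0, 0, 15), 12, TRUE),
      ChrB = rpois(12, 0.7)))
    got <- suppressMessages(detect_mapping_interval(bins))
    want <- oracle_detect(bins)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$peak_count, want$peak_count)
    }
  }
})

test_that("pool intersection keeps identical alleles and refines the interval", {
  iv <- function(chrom, s, e) structure(
    list(chrom = chrom, start = s, end = e, peak_bin = s, peak_count = 10,
         background_level = 0), class = "mapping_interval")
  a <- make_calls("Chr1", c(100L, 5000L, 9000L), "C", "T", 20L, 20L)
  b <- make_calls("Chr1", c(100L, 5000L, 9000L), "C", "T", 25L, 25L)
  res <- intersect_pools(a, b, iv("Chr1", 1L, 8000L), iv("Chr1", 50L, 9500L))
  expect_equal(nrow(res$shared), 3L)
  expect_equal(res$interval$start, 100L)   # span of shared variants
  expect_equal(res$interval$end, 8000L)    # clipped by interval overlap

  disjoint <- make_calls("Chr1", c(1L, 2L), "C", "T", 20L, 20L)
  expect_error(intersect_pools(disjoint, b, iv("Chr1", 1L, 10L), iv("Chr1", 1L, 10L)),
               "share no filtered variants")
  expect_error(intersect_pools(a, b, iv("Chr1", 1L, 10L), iv("Chr2", 1L, 10L)),
               "different chromosomes")
  expect_warning(res2 <- intersect_pools(a, b, NULL, iv("Chr1", 1L, 10L)),
                 "without refinement")
  expect_null(res2$interval)
  expect_equal(nrow(res2$shared), 3L)
})
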