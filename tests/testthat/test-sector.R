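iv_fixture <- function(chrom = "Chr1", s = 1L, e = 1e6L) {
  structure(list(chrom = chrom, start = s, end = e, peak_bin = s,
                 peak_count = 10, background_level = 0),
            class = "mapping_interval")
}

test_that("heterozygous calling applies depth, frequency window and EMS spectrum", {
  calls <- make_calls("Chr1", c(10L, 20L, 30L, 40L),
                      c("C", "C", "A", "C"), c("T", "T", "C", "T"),
                      c(60L, 60L, 60L, 5L), c(31L, 58L, 30L, 3L))
  het <- call_heterozygous(pool_variant_set("st", "sterile_sector", calls))
  expect_equal(het$pos, 10L)  # 0.967 homozygous-like, A>C non-EMS, depth 5 < 10
})

test_that("sterile-unique differencing partitions the interval set exactly", {
  sterile <- make_calls("Chr1", c(100L, 200L, 300L), "C", "T", 60L,
                        c(30L, 29L, 31L))
  fertile <- pool_variant_set("f", "fertile_sector",
                              make_calls("Chr1", 200L, "C", "T", 60L, 30L))
  d <- differential_sterile_unique(sterile, fertile, iv_fixture())
  expect_equal(d$unique$pos, c(100L, 300L))  # no fertile alt evidence
  expect_equal(d$shared$pos, 200L)           # het in fertile too
  # partition property
  expect_setequal(c(d$unique$pos, d$shared$pos), sterile$pos)
  expect_length(intersect(d$unique$pos, d$shared$pos), 0L)

  # a trace of fertile alt reads below the error floor still counts as unique
  fertile2 <- pool_variant_set("f", "fertile_sector",
                               make_calls("Chr1", 100L, "C", "T", 100L, 2L))
  d2 <- differential_sterile_unique(sterile, fertile2, iv_fixture())
  expect_true(100L %in% d2$unique$pos)
  # interval restriction: variants outside are counted genome-wide only
  d3 <- differential_sterile_unique(sterile, fertile, iv_fixture(s = 150L, e = 250L))
  expect_equal(nrow(d3$unique) + nrow(d3$shared), 1L)
  expect_equal(d3$n_unique_genomewide, 2L)
})

test_that("prior-allele confirmation needs a near-50% call in both sectors", {
  st <- pool_variant_set("s", "sterile_sector",
                         make_calls("Chr1", 50L, "C", "T", 100L, 48L))
  fe <- pool_variant_set("f", "fertile_sector",
                         make_calls("Chr1", 50L, "C", "T", 100L, 52L))
  r <- confirm_prior_allele(list(chrom = "Chr1", pos = 50L), st, fe)
  expect_true(r$confirmed)
  expect_equal(r$freq_sterile, 0.48)

  st2 <- pool_variant_set("s", "sterile_sector",
                          make_calls("Chr1", 50L, "C", "T", 100L, 5L))
  r2 <- confirm_prior_allele(list(chrom = "Chr1", pos = 50L), st2, fe)
  expect_false(r2$confirmed)

  fe2 <- pool_variant_set("f", "fertile_sector",
                          make_calls("Chr1", 99L, "C", "T", 100L, 52L))
  expect_error(confirm_prior_allele(list(chrom = "Chr1", pos = 50L), st, fe2),
               "cannot confirm")
})

test_that("phasing verdicts follow the concordance rule", {
  A <- one_site("Chr1", 100L, "C", "T")
  B <- one_site("Chr1", 140L, "C", "T")
  cis_reads <- make_pair_reads(A, B, n_both_alt = 12, n_both_ref = 10)
  v <- phase_variant_pair(cis_reads, A, B)
  expect_equal(v$verdict, "cis")
  expect_equal(v$n_both_alt, 12L)
  expect_equal(v$n_both_ref, 10L)

  trans_reads <- make_pair_reads(A, B, n_a_only = 11, n_b_only = 9)
  expect_equal(phase_variant_pair(trans_reads, A, B)$verdict, "trans")

  # 9 cis-consistent + 1 discordant: 0.1 > 0.05 discordance -> ambiguous
  mixed <- make_pair_reads(A, B, n_both_alt = 5, n_both_ref = 4, n_a_only = 1)
  expect_equal(phase_variant_pair(mixed, A, B)$verdict, "ambiguous")

  # fewer informative reads than required -> ambiguous; single-site reads ignored
  few <- make_pair_reads(A, B, n_both_alt = 2, n_a_single = 10)
  v2 <- phase_variant_pair(few, A, B)
  expect_equal(v2$verdict, "ambiguous")
  expect_equal(v2$n_informative, 2L)

  expect_error(phase_variant_pair(cis_reads, A, A), "itself")
})

test_that("phasing is symmetric in its two sites", {
  A <- one_site("Chr1", 100L, "G", "A")
  B <- one_site("Chr1", 160L, "C", "T")
  for (s in 1:15) {
    set.seed(s)
    k <- sample(0:8, 4, replace = TRUE)
    reads <- make_pair_reads(A, B, k[1], k[2], k[3], k[4])
    v1 <- phase_variant_pair(reads, A, B)
    v2 <- phase_variant_pair(reads, B, A)
    expect_equal(v1$verdict, v2$verdict)
    expect_equal(v1$n_both_alt, v2$n_both_alt)
    expect_equal(v1$n_alt_a_only, v2$n_alt_b_only)
  }
})

test_that("observations of artifact bases make a read uninformative", {
  A <- one_site("Chr1", 100L, "C", "T")
  B <- one_site("Chr1", 140L, "C", "T")
  reads <- make_pair_reads(A, B, n_both_alt = 5)
  reads$allele[reads$read_id == "r0001" & reads$pos == 100L] <- "G"
  v <- phase_variant_pair(reads, A, B)
  expect_equal(v$n_informative, 4L)
  expect_equal(v$verdict, "cis")
})

test_that("a cis control construction against the prior allele is called cis", {
  A <- one_site("Chr1", 100L, "C", "T")
  prior <- one_site("Chr1", 180L, "G", "A")
  reads <- make_pair_reads(A, prior, n_both_alt = 8, n_both_ref = 7)
  expect_equal(phase_relative_to_prior(reads, A, prior)$verdict, "cis")
})

test_that("gene nomination requires internal cis and trans-to-prior support", {
  fx <- synthetic_gene_fixture(list(`150` = "CAG"), strand = "+", seed = 4)
  empty <- classify_variants(emsmapr:::empty_calls(), fx$genes, fx$genome)
  nom0 <- nominate_allele(empty, data.frame(read_id = character(), chrom = character(),
                                            pos = integer(), allele = character()),
                          one_site("ChrF", 1L, "C", "T"))
  expect_length(nom0$nominated, 0L)
  expect_equal(nrow(nom0$genes), 0L)

  # coding variants in two genes but no spanning reads: both listed, none nominated
  genome2 <- Biostrings::DNAStringSet(paste(rep("CAA", 220), collapse = ""))
  names(genome2) <- "ChrQ"
  g2 <- gene_models(data.frame(gene_id = c("gA", "gB"), chrom = "ChrQ", strand = "+",
                               start = c(10L, 202L), end = c(108L, 300L)))
  # every in-frame C>T turns CAA (Q) into TAA (stop)
  vars <- make_calls("ChrQ", c(13L, 205L), "C", "T", 60L, 30L)
  ann <- classify_variants(vars, g2, genome2)
  expect_equal(ann$variant_type, rep("stop_gained", 2))
  expect_warning(
    nom <- nominate_allele(ann, data.frame(read_id = character(), chrom = character(),
                                           pos = integer(), allele = character()),
                           one_site("ChrQ", 500L, "C", "T")),
    "phasing support")
  expect_length(nom$nominated, 0L)
  expect_equal(nrow(nom$genes), 2L)
})
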