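test_that("stop-gain, missense and synonymous consequences carry the expected notation", {
  fx <- synthetic_gene_fixture(list(`150` = "CAG", `98` = "CCA", `10` = "CTG"),
                               strand = "+", seed = 4)
  # C>T at the first base of codon 150 (CAG -> TAG): premature stop
  ann <- classify_variant("ChrF", fx$codon_start[["150"]], "C", "T",
                          fx$genes, fx$genome)
  expect_equal(ann$variant_type, "stop_gained")
  expect_equal(ann$impact, "HIGH")
  expect_equal(ann$hgvs_p, "p.Q150*")
  # C>T at the first base of codon 98 (CCA -> TCA): P98S missense
  ann <- classify_variant("ChrF", fx$codon_start[["98"]], "C", "T",
                          fx$genes, fx$genome)
  expect_equal(ann$variant_type, "missense_variant")
  expect_equal(ann$impact, "MODERATE")
  expect_equal(ann$hgvs_p, "p.P98S")
  # G>A at the third base of codon 10 (CTG -> CTA): both encode Leu
  ann <- classify_variant("ChrF", fx$codon_start[["10"]] + 2L, "G", "A",
                          fx$genes, fx$genome)
  expect_equal(ann$variant_type, "synonymous_variant")
  expect_equal(ann$impact, "LOW")
})

test_that("minus-strand genes are annotated through the reverse complement", {
  fx <- synthetic_gene_fixture(list(`209` = "GAC"), strand = "-", seed = 6)
  # coding GAC -> AAC (D209N); on the reference strand this is a C>T
  pos <- fx$codon_start[["209"]]
  ann <- classify_variant("ChrF", pos, "C", "T", fx$genes, fx$genome)
  expect_equal(ann$variant_type, "missense_variant")
  expect_equal(ann$hgvs_p, "p.D209N")
})

test_that("strand mirror images yield identical annotations", {
  codons <- c("CAA", "CGA", "GGA", "CTG", "GAT")
  for (s in 1:10) {
    set.seed(s)
    idx <- sample(5:200, 1)
    cod <- sample(codons, 1)
    off <- sample(0:2, 1)
    fp <- synthetic_gene_fixture(setNames(list(cod), idx), strand = "+", seed = s)
    fm <- synthetic_gene_fixture(setNames(list(cod), idx), strand = "-", seed = s)
    base_p <- substring(as.character(fp$genome[[1]]),
                        fp$codon_start[[1]] + off, fp$codon_start[[1]] + off)
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), base_p), 1)
    ann_p <- classify_variant("ChrF", fp$codon_start[[1]] + off, base_p, alt_p,
                              fp$genes, fp$genome)
    pos_m <- fm$codon_start[[1]] - off  # minus-strand coordinates run downwards
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    base_m <- substring(as.character(fm$genome[[1]]), pos_m, pos_m)
    expect_equal(base_m, unname(comp[base_p]))
    ann_m <- classify_variant("ChrF", pos_m, base_m, unname(comp[alt_p]),
                              fm$genes, fm$genome)
    expect_equal(ann_m[, -1], ann_p[, -1])  # same consequence, fixture gene ids equal anyway
  }
})

test_that("positions outside genes or CDS get MODIFIER annotations", {
  fx <- synthetic_gene_fixture(list(`5` = "AAA"), strand = "+", seed = 2)
  gseg <- as.data.frame(fx$genes)
  # intergenic: upstream of the gene
  base_at <- function(p) substring(as.character(fx$genome[[1]]), p, p)
  p0 <- 5L
  a0 <- classify_variant("ChrF", p0, base_at(p0),
                         setdiff(c("A", "C"), base_at(p0))[1], fx$genes, fx$genome)
  expect_equal(a0$variant_type, "intergenic")
  expect_equal(a0$impact, "MODIFIER")
  expect_equal(a0$hgvs_p, "")

  # inside the gene span but outside CDS: split the gene into two segments
  genes2 <- gene_models(data.frame(
    gene_id = "gI", chrom = "ChrF", strand = "+",
    start = c(gseg$start, gseg$end + 101L),
    end = c(gseg$end, gseg$end + 220L)))
  p1 <- gseg$end + 50L
  a1 <- classify_variant("ChrF", p1, base_at(p1),
                         setdiff(c("A", "C"), base_at(p1))[1], genes2, fx$genome)
  expect_equal(a1$variant_type, "intron_or_utr")
  expect_equal(a1$impact, "MODIFIER")
})

test_that("a reference mismatch is reported as a data-integrity error", {
  fx <- synthetic_gene_fixture(list(`150` = "CAG"), strand = "+", seed = 4)
  pos <- fx$codon_start[["150"]]
  wrong <- setdiff(c("A", "C", "G", "T"), c("C", "T"))[1]
  expect_error(classify_variant("ChrF", pos, wrong, "T", fx$genes, fx$genome),
               "mismatch")
})

test_that("codon-level classification agrees with full-CDS retranslation", {
  fx <- synthetic_gene_fixture(list(`1` = "ATG"), strand = "+", n_codons = 120, seed = 9)
  fx2 <- synthetic_gene_fixture(list(`1` = "ATG"), strand = "-", n_codons = 120, seed = 10)
  for (trial in 1:120) {
    set.seed(trial)
    f <- if (trial %% 2 == 0) fx else fx2
    pos <- sample.int(Biostrings::width(f$genome)[1], 1)
    ref <- substring(as.character(f$genome[[1]]), pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_variant("ChrF", pos, ref, alt, f$genes, f$genome)
    want <- oracle_classify("ChrF", pos, ref, alt, f$genes, f$genome)
    expect_equal(got$variant_type, want$variant_type, label = sprintf("type @%d", pos))
    expect_equal(got$impact, want$impact)
    if (want$variant_type %in% c("stop_gained", "stop_lost", "missense_variant"))
      expect_equal(got$hgvs_p, want$hgvs_p)
  }
})

test_that("HGVS.p formatting validates its inputs", {
  expect_equal(format_hgvs_p("Q", 150, "*"), "p.Q150*")
  expect_equal(format_hgvs_p("D", 209, "N"), "p.D209N")
  expect_equal(format_hgvs_p("L", 478, "F"), "p.L478F")
  expect_error(format_hgvs_p("B", 5, "A"), "invalid")
  expect_error(format_hgvs_p("Q", 0, "*"), "codon index")
})

test_that("candidate ranking keeps protein-altering variants, HIGH first", {
  fx <- synthetic_gene_fixture(list(`150` = "CAG", `98` = "CCA"), strand = "+", seed = 4)
  set <- make_calls("ChrF",
                    c(fx$codon_start[["150"]], fx$codon_start[["98"]], 3L),
                    "C", "T", 20L, 20L)
  set$ref <- substring(as.character(fx$genome[[1]]), set$pos, set$pos)
  set$alt <- ifelse(set$ref == "G", "A", "T")
  set <- set[set$ref %in% c("C", "G"), ]
  ann <- classify_variants(set, fx$genes, fx$genome)
  rk <- rank_candidates(ann)
  expect_true(all(rk$Impact %in% c("HIGH", "MODERATE")))
  if (nrow(rk) >= 2) {
    expect_equal(rk$Impact[1], "HIGH")
    expect_equal(rk$Effect[1], "p.Q150*")
  }
  empty <- rank_candidates(classify_variants(emsmapr:::empty_calls(), fx$genes, fx$genome))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("Chr", "Position", "Ref", "Alt", "Variant_type",
                        "Impact", "Effect", "Gene_ID"))
})
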