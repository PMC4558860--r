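test_that("closed-form NG86 cases", {
  # identical sequences: everything zero, ratio undefined
  r0 <- nei_gojobori(codon_alignment(c("ATG", "AAA"), c("ATG", "AAA")))
  expect_equal(r0$Sd, 0); expect_equal(r0$Nd, 0)
  expect_equal(r0$Ka, 0); expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  # 10x GGG vs 9x GGG + GGA: S = 10, Sd = 1, pS = 0.1, Ks ~ 0.1073, Ka = 0
  r1 <- nei_gojobori(codon_alignment(rep("GGG", 10),
                                     c(rep("GGG", 9), "GGA")))
  expect_equal(r1$S_sites, 10)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$pS, 0.1)
  expect_lt(abs(r1$Ks - 0.1073), 1e-4)
  expect_equal(r1$Ka, 0)
  expect_equal(r1$ratio, 0)
  # TTTGGG vs TTCGGG: S = 4/3, Sd = 1, pS = 0.75 -> saturated
  r2 <- nei_gojobori(codon_alignment(c("TTT", "GGG"), c("TTC", "GGG")))
  expect_equal(r2$S_sites, 4 / 3)
  expect_equal(r2$pS, 0.75)
  expect_true(r2$saturated)
  expect_true(is.na(r2$Ks))
})

test_that("site fractions sum to three per codon and NG86 is symmetric", {
  set.seed(11)
  for (i in 1:25) {
    pair <- random_codon_pair(8, max_diff = 3L)
    ca <- codon_alignment(pair$parent, pair$retro)
    r <- nei_gojobori(ca)
    expect_equal(r$S_sites + r$N_sites, 3 * r$n_codons)
    r_swap <- nei_gojobori(codon_alignment(pair$retro, pair$parent))
    expect_equal(r$Sd, r_swap$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, r_swap$Nd, tolerance = 1e-12)
    expect_equal(r$S_sites, r_swap$S_sites, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction is monotone and bounded below by p", {
  p <- seq(0, 0.74, by = 0.02)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.8)))
})

test_that("NG86 equals the brute-force pathway oracle, including multi-hit", {
  set.seed(21)
  for (i in 1:40) {
    pair <- random_codon_pair(12, max_diff = sample(1:3, 1))
    r <- nei_gojobori(codon_alignment(pair$parent, pair$retro))
    o <- oracle_ng86(pair$parent, pair$retro)
    expect_equal(r$S_sites, o$S, tolerance = 1e-10)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-10)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-10)
    if (!is.na(r$Ks) && !is.na(o$Ks))
      expect_equal(r$Ks, o$Ks, tolerance = 1e-10)
  }
})

test_that("stop-containing codon columns are dropped and counted", {
  r <- nei_gojobori(codon_alignment(c("ATG", "TAA", "GGG"),
                                    c("ATG", "AAA", "GGG")))
  expect_equal(r$n_codons, 2L)
  expect_equal(r$n_stop_dropped, 1L)
  expect_error(nei_gojobori(codon_alignment(character(0), character(0))),
               "empty")
  expect_error(codon_alignment("ANG", "ATG"), "ACGT")
})

test_that("CDS projection pairs codons through the alignment", {
  # toy gene: one exon, CDS spanning transcript positions 30..90
  gm <- gene_models(data.frame(
    seqname = "chr1", start = c(1000L, 1000L + 30L), end = c(1120L, 1090L),
    strand = "+", feature = c("exon", "CDS"), gene_id = "g1",
    transcript_id = "g1.t1", stringsAsFactors = FALSE))
  set.seed(5)
  chrom <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  tx <- retroscape:::transcript_sequence(gm, "g1.t1", genome)
  # identical retrocopy planted at 50000 (conceptually): alignment is exact
  aln <- chained_alignment("g1.t1", nchar(tx), "chr1", "+",
                           nchar(tx), 0L, 0L, 50000L, nchar(tx))
  # fake the planted copy by aligning transcript to itself via coordinates:
  # here the target bases differ from tx, so compare to the mapped region
  ca <- extract_cds_pair(aln, gm, genome)
  expect_s3_class(ca, "codon_alignment")
  expect_equal(length(ca$parent), (90 - 30) / 3)
  expect_identical(paste(ca$parent, collapse = ""),
                   substr(tx, 31, 90))
  expect_identical(paste(ca$retro, collapse = ""),
                   substr(chrom, 50031, 50090))
  # truncated copy: only the aligned CDS portion survives, codon-rounded
  aln2 <- chained_alignment("g1.t1", nchar(tx), "chr1", "+",
                            70L, 0L, 50L, 50050L, 70L)  # covers tx 50..120
  ca2 <- extract_cds_pair(aln2, gm, genome)
  expect_equal(length(ca2$parent), (90 - 51) %/% 3)
  # a 1-nt hole in the alignment removes the affected codon column
  aln3 <- chained_alignment("g1.t1", nchar(tx), "chr1", "+",
                            119L, 0L, c(0L, 46L), c(50000L, 50046L),
                            c(45L, 74L))
  ca3 <- extract_cds_pair(aln3, gm, genome)
  # codon covering transcript position 45 is dropped
  expect_equal(length(ca3$parent), (90 - 30) / 3 - 1L)
  # no CDS annotated -> NULL
  gm2 <- gene_models(data.frame(
    seqname = "chr1", start = 1000L, end = 1120L, strand = "+",
    feature = "exon", gene_id = "g1", transcript_id = "g1.t1",
    stringsAsFactors = FALSE))
  expect_null(extract_cds_pair(aln, gm2, genome))
})

test_that("random-set comparison separates shifted distributions", {
  set.seed(9)
  pop <- stats::runif(500, 0.4, 1.2)
  # maximal separation: target all 0, population all ~1
  res <- compare_to_random(rep(0, 30), pop, n_sets = 50, seed = 2)
  expect_lt(res$p, 1e-3)
  expect_equal(res$median_target, 0)
  # deterministic under a fixed seed
  r1 <- compare_to_random(pop[1:30], pop, n_sets = 5, seed = 3)
  r2 <- compare_to_random(pop[1:30], pop, n_sets = 5, seed = 3)
  expect_identical(r1, r2)
  expect_error(compare_to_random(pop[1:30], pop[1:10], set_size = 30),
               "set_size")
})
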