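mk_aln <- function(matches, mismatches, qsize, qstarts, tstarts, sizes,
                   qname = "g1.t1", tname = "chr1", strand = "+") {
  chained_alignment(qname, qsize, tname, strand, matches, mismatches,
                    qstarts, tstarts, sizes)
}

test_that("alignment filters implement the identity/coverage/gap rules", {
  th <- detection_thresholds()
  # identity 0.70 -> rejected
  a <- mk_aln(70L, 30L, 120L, 0L, 0L, 100L)
  expect_length(filter_alignments(list(a), th), 0L)
  # identity 0.90, coverage 0.30, aligned 120 nt -> kept (second disjunct)
  b <- mk_aln(108L, 12L, 400L, 0L, 0L, 120L)
  expect_length(filter_alignments(list(b), th), 1L)
  # same but only 119 nt aligned and low coverage -> rejected
  b2 <- mk_aln(108L, 11L, 400L, 0L, 0L, 119L)
  expect_length(filter_alignments(list(b2), th), 0L)
  # one internal target gap of 20,000 nt -> rejected
  g <- mk_aln(190L, 10L, 250L, c(0L, 100L), c(0L, 20100L), c(100L, 100L))
  expect_length(filter_alignments(list(g), th), 0L)
  # gap of exactly 15,000 nt -> kept
  g2 <- mk_aln(190L, 10L, 250L, c(0L, 100L), c(0L, 15100L), c(100L, 100L))
  expect_length(filter_alignments(list(g2), th), 1L)
  # zero query length -> error
  expect_error(filter_alignments(list(mk_aln(90L, 5L, 0L, 0L, 0L, 100L)), th),
               "query_length")
})

test_that("the intronless signature separates retrocopies from gene loci", {
  gm <- toy_gene_models()   # g1: 3 exons of 200 nt at junctions 200, 400
  # contiguous copy of the whole transcript: one block, all junctions bridged
  retro <- mk_aln(590L, 10L, 600L, 0L, 50000L, 600L)
  calls <- call_retrocopies(list(retro), gm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_exons_bridged, 3L)
  expect_equal(calls$parental_gene, "g1")
  # alignment retaining the parental introns (1,800 nt target gaps) -> no call
  genic <- mk_aln(590L, 10L, 600L, c(0L, 200L, 400L),
                  c(50000L, 52000L, 54000L), c(200L, 200L, 200L))
  expect_equal(nrow(call_retrocopies(list(genic), gm)), 0L)
  # junction bridged within tolerance (25 nt slack) still bridges all 3
  near <- mk_aln(590L, 10L, 600L, c(0L, 200L), c(50000L, 50225L),
                 c(200L, 400L))
  nc <- call_retrocopies(list(near), gm)
  expect_equal(nc$n_exons_bridged, 3L)
  # 31 nt slack breaks that junction; the remaining pair still qualifies
  far <- mk_aln(590L, 10L, 600L, c(0L, 200L), c(50000L, 50231L),
                c(200L, 400L))
  fc <- call_retrocopies(list(far), gm)
  expect_equal(fc$n_exons_bridged, 2L)
  # two-exon parent: the junction slack decides the call outright
  ok2 <- mk_aln(595L, 5L, 600L, c(0L, 300L), c(90000L, 90330L),
                c(300L, 300L), qname = "g2.t1")
  expect_equal(nrow(call_retrocopies(list(ok2), gm)), 1L)
  bad2 <- mk_aln(595L, 5L, 600L, c(0L, 300L), c(90000L, 90331L),
                 c(300L, 300L), qname = "g2.t1")
  expect_equal(nrow(call_retrocopies(list(bad2), gm)), 0L)
})

test_that("self-alignments to the parental span are discarded", {
  gm <- toy_gene_models()
  self_hit <- mk_aln(590L, 10L, 600L, 0L, 1100L, 600L)  # inside g1 span
  expect_equal(nrow(call_retrocopies(list(self_hit), gm)), 0L)
})

test_that("overlapping candidates collapse to the best representative", {
  gm <- gene_models(rbind(toy_gene_models(),
    data.frame(seqname = "chr1", start = c(1000L, 3000L, 5000L),
               end = c(1200L, 3200L, 5200L), strand = "+", feature = "exon",
               gene_id = "g1", transcript_id = "g1.t2",
               stringsAsFactors = FALSE)))
  a1 <- mk_aln(590L, 10L, 600L, 0L, 50000L, 600L, qname = "g1.t1")
  a2 <- mk_aln(560L, 40L, 600L, 0L, 50010L, 600L, qname = "g1.t2")
  calls <- call_retrocopies(list(a1, a2), gm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$parental_transcript, "g1.t1")  # higher identity wins
})

test_that("single-exon parents can never yield a call", {
  gm <- gene_models(data.frame(
    seqname = "chr1", start = 1000L, end = 1600L, strand = "+",
    feature = "exon", gene_id = "s1", transcript_id = "s1.t1",
    stringsAsFactors = FALSE))
  aln <- mk_aln(590L, 10L, 600L, 0L, 50000L, 600L, qname = "s1.t1")
  expect_equal(nrow(call_retrocopies(list(aln), gm)), 0L)
})

test_that("unknown transcripts raise a named error", {
  gm <- toy_gene_models()
  aln <- mk_aln(590L, 10L, 600L, 0L, 50000L, 600L, qname = "nope.t1")
  expect_error(call_retrocopies(list(aln), gm), "nope.t1")
})

test_that("planted retrocopies are recovered on synthetic data", {
  sim <- small_sim()
  gt <- sim$ground_truth$retrocopies
  for (sp in c("A", "B")) {
    s <- sim$species[[sp]]
    calls <- detect_retrocopies(s$genome, s$gene_models)
    gts <- gt[gt$species == sp, ]
    expect_gte(mean(truth_found(gts, calls)), 0.9)
    expect_lte(mean(!truth_overlap(calls, gts)), 0.1)
    # no call overlaps its parental gene span
    spans <- retroscape:::gene_spans(s$gene_models)
    for (i in seq_len(nrow(calls))) {
      sp_i <- spans[spans$gene_id == calls$parental_gene[i], ]
      expect_true(all(sp_i$seqname != calls$seqname[i] |
                        sp_i$end <= calls$start[i] |
                        sp_i$start >= calls$end[i]))
    }
  }
})

test_that("raising min_identity never increases the number of calls", {
  sim <- small_sim()
  s <- sim$species$A
  tx <- unique(s$gene_models$transcript_id[s$gene_models$feature == "exon"])
  seqs <- vapply(tx, retroscape:::transcript_sequence, character(1L),
                 gm = s$gene_models, genome = s$genome)
  aln <- align_transcripts(seqs, s$genome)
  n_prev <- Inf
  for (mi in c(0.75, 0.9, 0.97, 0.985)) {
    th <- detection_thresholds(min_identity = mi)
    n <- nrow(call_retrocopies(filter_alignments(aln, th), s$gene_models, th))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("catalog summaries count calls and distinct parental genes", {
  empty <- retroscape:::empty_call_table()
  cs <- catalog_summary(list(sp = empty))
  expect_equal(cs$n_retrocopies, 0L)
  expect_equal(cs$n_parental_genes, 0L)
  five <- empty[0, ]
  five <- do.call(rbind, lapply(1:5, function(i)
    data.frame(seqname = "c", start = i * 1000L, end = i * 1000L + 10L,
               strand = "+", parental_gene = c("a", "a", "b", "c", "c")[i],
               parental_transcript = "t", identity = 1, query_coverage = 1,
               aligned_nt = 10L, n_exons_bridged = 2L, on_x = FALSE,
               parent_on_x = FALSE, stringsAsFactors = FALSE)))
  cs <- catalog_summary(list(sp = five))
  expect_equal(cs$n_retrocopies, 5L)
  expect_equal(cs$n_parental_genes, 3L)
})
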