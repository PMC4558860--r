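# hand-built genome with one plus-strand host gene and one retrocopy locus,
# wired so junction reads can be constructed explicitly
chim_fixture <- function() {
  set.seed(31)
  chrom <- sample(c("A", "C", "G", "T"), 30000, replace = TRUE)
  # host gene: exons [1000,1200) and [9000,9200), intron GT...AG
  chrom[1201:1202] <- c("G", "T")
  chrom[8999:9000] <- c("A", "G")
  # retrocopy at [5000, 6000), acceptor AG just before it
  chrom[4999:5000] <- c("A", "G")
  genome <- c(chr1 = paste(chrom, collapse = ""))
  gm <- gene_models(data.frame(
    seqname = "chr1", start = c(1000L, 9000L), end = c(1200L, 9200L),
    strand = "+", feature = "exon", gene_id = "host1",
    transcript_id = "host1.t1", stringsAsFactors = FALSE))
  calls <- add_call_ids(data.frame(
    seqname = "chr1", start = 5000L, end = 6000L, strand = "+",
    parental_gene = "gsrc", parental_transcript = "gsrc.t1",
    identity = 0.98, query_coverage = 1, aligned_nt = 1000L,
    n_exons_bridged = 2L, on_x = FALSE, parent_on_x = FALSE,
    stringsAsFactors = FALSE), "S")
  list(genome = genome, gm = gm, calls = calls)
}

junction_reads <- function(n, genome, mapq = 60L) {
  # 50 nt from the host exon end (1150..1200) spliced to 50 nt of retrocopy
  seq <- paste0(substring(genome[["chr1"]], 1151, 1200),
                substring(genome[["chr1"]], 5001, 5050))
  data.frame(qname = sprintf("c%02d", seq_len(n)), flag = 0L,
             seqname = "chr1", pos = 1150L, mapq = mapq,
             cigar = "50M3800N50M", seq = seq, stringsAsFactors = FALSE)
}

test_that("chimeric events need five reads, MAPQ > 40 and GT-AG", {
  fx <- chim_fixture()
  th <- expression_thresholds()
  ev5 <- detect_chimeric(junction_reads(5, fx$genome), fx$gm, fx$calls,
                         fx$genome, th)
  expect_equal(nrow(ev5), 1L)
  expect_equal(ev5$host_gene, "host1")
  expect_equal(ev5$n_reads, 5L)
  # four reads: rejected
  ev4 <- detect_chimeric(junction_reads(4, fx$genome), fx$gm, fx$calls,
                         fx$genome, th)
  expect_equal(nrow(ev4), 0L)
  # MAPQ exactly 40 is not "higher than 40"
  ev40 <- detect_chimeric(junction_reads(5, fx$genome, mapq = 40L), fx$gm,
                          fx$calls, fx$genome, th)
  expect_equal(nrow(ev40), 0L)
  # non-canonical donor (GC) is rejected
  fx2 <- fx
  g <- fx2$genome[["chr1"]]
  substr(g, 1202, 1202) <- "C"   # GT -> GC
  fx2$genome <- c(chr1 = g)
  evgc <- detect_chimeric(junction_reads(5, fx2$genome), fx2$gm, fx2$calls,
                          fx2$genome, th)
  expect_equal(nrow(evgc), 0L)
})

test_that("decoy alignment suppresses parent-identical retrocopies", {
  set.seed(33)
  parent <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                  collapse = "")
  flankL <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  flankR <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  decoy <- c("tx:p.t1" = parent, "S:chr1:1000-1800" = paste0(flankL, parent,
                                                             flankR))
  attr(decoy, "retro_region") <- matrix(c(300L, 1100L), nrow = 1,
    dimnames = list("S:chr1:1000-1800", c("start", "end")))
  reads <- data.frame(qname = sprintf("r%02d", 1:10), flag = 0L,
                      seqname = "x", pos = 0L, mapq = 60L, cigar = "100M",
                      seq = vapply(1:10, function(i)
                        substr(parent, i * 50, i * 50 + 99), character(1L)),
                      stringsAsFactors = FALSE)
  hits <- align_reads_to_decoy(reads, decoy)
  # every read maps equally to parent and retrocopy -> multi-mapping MAPQ
  expect_true(all(hits$mapq <= 3L))
  # a diverged retrocopy gives unique, high-MAPQ hits
  retro <- parent
  for (p in seq(10, 790, by = 40))
    substr(retro, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(retro, p, p))[1L]
  decoy2 <- decoy
  decoy2[[2L]] <- paste0(flankL, retro, flankR)
  reads2 <- reads
  reads2$seq <- vapply(1:10, function(i) substr(retro, i * 50, i * 50 + 99),
                       character(1L))
  hits2 <- align_reads_to_decoy(reads2, decoy2)
  best2 <- hits2[hits2$ref == "S:chr1:1000-1800", ]
  expect_true(all(best2$mapq == 60L))
})

test_that("expression calls honor the unique-read threshold and flanks", {
  calls <- data.frame(call_id = "rc1", seqname = "chr1", start = 1000L,
                      end = 2000L, stringsAsFactors = FALSE)
  decoy <- c(rc1 = strrep("A", 1600))
  attr(decoy, "retro_region") <- matrix(c(300L, 1300L), nrow = 1,
    dimnames = list("rc1", c("start", "end")))
  th <- expression_thresholds()
  mk_hits <- function(n, start = 500L, mapq = 60L)
    data.frame(qname = sprintf("r%d", seq_len(max(n, 1))[seq_len(n)]),
               ref = rep("rc1", n), start = start, end = start + 100L,
               mapq = mapq, stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  # 2 reads (default threshold) -> expressed; 1 -> not
  p2 <- call_expressed(list(t1 = mk_hits(2)), calls, decoy, th)
  expect_true(p2$expressed)
  p1 <- call_expressed(list(t1 = mk_hits(1)), calls, decoy, th)
  expect_false(p1$expressed)
  # flank-only alignments never count
  pf <- call_expressed(list(t1 = mk_hits(5, start = 100L)), calls, decoy, th)
  expect_false(pf$expressed)
  expect_equal(pf$n_reads, 0L)
  # low-MAPQ alignments never count
  pm <- call_expressed(list(t1 = mk_hits(5, mapq = 3L)), calls, decoy, th)
  expect_false(pm$expressed)
})

test_that("tau closed forms and scale invariance", {
  expect_equal(tau(c(1, 1, 1, 1)), 0)
  expect_equal(tau(c(0, 0, 7, 0)), 1)
  expect_equal(tau(c(1, 0.5, 0)), 0.75)
  x <- c(0.2, 1.4, 0.9, 0, 2.2)
  expect_equal(tau(x), tau(17.3 * x))
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(c(1)), ">= 2")
  expect_error(tau(c(-1, 2)), "non-negative")
  set.seed(8)
  for (i in 1:20) {
    v <- stats::runif(6)
    expect_gte(tau(v), 0); expect_lte(tau(v), 1)
  }
})

test_that("context classes partition calls with documented precedence", {
  fx <- chim_fixture()
  th <- expression_thresholds()
  # retrocopy inside the host intron, no chimera -> intragenic
  ctx <- classify_context(fx$calls, fx$gm, NULL, th)
  expect_equal(ctx, "intragenic")
  # with an accepted chimeric event on the same strand
  ev <- detect_chimeric(junction_reads(5, fx$genome), fx$gm, fx$calls,
                        fx$genome, th)
  expect_equal(classify_context(fx$calls, fx$gm, ev, th),
               "intragenic_same_chimeric")
  # opposite-strand call
  fx$calls$strand <- "-"
  expect_equal(classify_context(fx$calls, fx$gm, ev, th),
               "intragenic_opposite_chimeric")
  # TSS proximity boundary: 14,999 in, 15,000 out
  gm <- gene_models(data.frame(
    seqname = "chr1", start = c(100000L, 105000L), end = c(100200L, 105200L),
    strand = "+", feature = "exon", gene_id = "far1",
    transcript_id = "far1.t1", stringsAsFactors = FALSE))
  near_call <- data.frame(seqname = "chr1", start = 100000L - 15000L,
                          end = 100000L - 14999L + 1L, strand = "+",
                          call_id = "c1", stringsAsFactors = FALSE)
  # distance from call end-1 (85002-1) to TSS 100000 is 14999
  near_call$start <- 85000L; near_call$end <- 85002L
  expect_equal(classify_context(near_call, gm, NULL, th), "near_TSS_same")
  far_call <- near_call; far_call$start <- 84999L; far_call$end <- 85001L
  expect_equal(classify_context(far_call, gm, NULL, th), "distant")
  opp <- near_call; opp$strand <- "-"
  expect_equal(classify_context(opp, gm, NULL, th), "near_TSS_opposite")
})

test_that("the permutation context test is calibrated at the extremes", {
  # gene-sparse genome (one 2 kb gene in 1 Mb): all-intragenic observed
  # group is essentially unreachable by random placement -> minimal p
  genome <- c(chr1 = strrep("A", 1000000L))
  gm <- gene_models(data.frame(
    seqname = "chr1", start = 500000L, end = 502000L, strand = "+",
    feature = "exon", gene_id = "g", transcript_id = "g.t",
    stringsAsFactors = FALSE))
  calls <- data.frame(seqname = "chr1",
                      start = 500100L + (0:4) * 300L,
                      end = 500100L + (0:4) * 300L + 200L,
                      strand = "+", stringsAsFactors = FALSE)
  th <- expression_thresholds(n_permutations = 99L)
  res <- permutation_context_test(calls, genome, gm, th, seed = 4)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$p, 1 / 100)
  expect_length(res$null_fractions, 99L)
  expect_error(permutation_context_test(calls, genome, gm,
    expression_thresholds(n_permutations = 0L)), "n_permutations")
  expect_error(permutation_context_test(calls[0, ], genome, gm, th),
               "expressed call")
})

test_that("expression correlations hit the rank-correlation extremes", {
  pairs <- data.frame(pair_type = "parental", retro = 1:10, gene = 1:10)
  res <- expression_correlations(pairs)
  expect_equal(res$rho, 1)
  pairs$gene <- 10:1
  expect_equal(expression_correlations(pairs)$rho, -1)
  small <- data.frame(pair_type = "host", retro = 1:2, gene = 2:1)
  res2 <- expression_correlations(small)
  expect_false(res2$defined)
  set.seed(14)
  ind <- data.frame(pair_type = "neighbor", retro = stats::runif(500),
                    gene = stats::runif(500))
  expect_lt(abs(expression_correlations(ind)$rho), 0.1)
})

test_that("synthetic expression ground truth is recovered", {
  sim <- expr_sim()
  gt <- sim$ground_truth$retrocopies
  gtA <- gt[gt$species == "A", ]
  s <- sim$species$A
  calls <- add_call_ids(detect_retrocopies(s$genome, s$gene_models), "A")
  reads <- simulate_reads(sim, "A", depth = 30, seed = 42)
  th <- expression_thresholds()
  decoy <- build_decoy_reference(calls, s$genome, s$gene_models)
  hits <- lapply(reads, function(r) align_reads_to_decoy(r, decoy))
  prof <- call_expressed(hits, calls, decoy, th)
  expr <- sim$ground_truth$expression
  exp_ids <- unique(expr$retro_id[expr$level > 0])
  calls$retro_id <- vapply(calls$call_id, call_to_retro, character(1L),
                           gt = gtA)
  truth_exp <- calls$retro_id %in% exp_ids
  pred_exp <- calls$call_id %in% unique(prof$call_id[prof$expressed])
  expect_gte(sum(truth_exp & pred_exp) / sum(truth_exp), 0.95)
  expect_equal(sum(!truth_exp & pred_exp), 0L)
  # chimeric ground truth recovered
  allrec <- do.call(rbind, reads)
  ev <- detect_chimeric(allrec, s$gene_models, calls, s$genome, th)
  truth_chim <- gtA$retro_id[gtA$chimeric & gtA$retro_id %in% exp_ids]
  found_chim <- unique(na.omit(calls$retro_id[match(ev$call_id,
                                                    calls$call_id)]))
  expect_setequal(intersect(found_chim, truth_chim), truth_chim)
  # chimeric calls are a subset of intragenic calls
  ctx <- classify_context(calls, s$gene_models, ev, th)
  chim_idx <- calls$call_id %in% ev$call_id
  expect_true(all(grepl("^intragenic", ctx[chim_idx])))
})
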