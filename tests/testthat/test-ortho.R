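no_repeats <- data.frame(seqname = character(), start = integer(),
                         end = integer(), strand = character(),
                         subfamily = character(), repeat_class = character(),
                         stringsAsFactors = FALSE)

mk_call <- function(seqname, start, end, gene = "g1", species = "S") {
  add_call_ids(data.frame(
    seqname = seqname, start = as.integer(start), end = as.integer(end),
    strand = "+", parental_gene = gene, parental_transcript = paste0(gene, ".t1"),
    identity = 0.98, query_coverage = 1, aligned_nt = end - start,
    n_exons_bridged = 2L, on_x = seqname == "chrX", parent_on_x = FALSE,
    stringsAsFactors = FALSE), species)
}

test_that("flank blocks honor repeat masking and the per-side budget", {
  set.seed(1)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 40000,
                                  replace = TRUE), collapse = ""))
  call <- mk_call("chr1", 20000, 21000)
  # repeat-free: one 3000-nt block per side
  fs <- extract_flanks(call[1, ], genome, no_repeats)
  expect_equal(nrow(fs$upstream), 1L)
  expect_equal(fs$upstream$start, 17000L)
  expect_equal(fs$upstream$end, 20000L)
  expect_equal(nrow(fs$downstream), 1L)
  expect_equal(fs$downstream$start, 21000L)
  expect_false(any(fs$empty_side))
  # side fully repeat-masked: flagged empty
  mask <- data.frame(seqname = "chr1", start = 0L, end = 20000L,
                     strand = "+", subfamily = "L1PA7",
                     repeat_class = "LINE/L1", stringsAsFactors = FALSE)
  fs2 <- extract_flanks(call[1, ], genome, mask)
  expect_equal(nrow(fs2$upstream), 0L)
  expect_true(fs2$empty_side[["upstream"]])
  expect_false(fs2$empty_side[["downstream"]])
  # alternating 100-nt repeat / 200-nt clean: 15 blocks of 200 = 3000
  pat <- do.call(rbind, lapply(0:59, function(k)
    data.frame(seqname = "chr1", start = 20000L - (k + 1L) * 300L,
               end = 20000L - (k + 1L) * 300L + 100L, strand = "+",
               subfamily = "AluY", repeat_class = "SINE/Alu",
               stringsAsFactors = FALSE)))
  fs3 <- extract_flanks(call[1, ], genome, pat)
  expect_equal(nrow(fs3$upstream), 15L)
  expect_true(all(fs3$upstream$end - fs3$upstream$start == 200L))
  expect_equal(sum(fs3$upstream$end - fs3$upstream$start), 3000L)
})

test_that("the 5000-nt search offset preset skips the adjacent window", {
  set.seed(2)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 40000,
                                  replace = TRUE), collapse = ""))
  call <- mk_call("chr1", 20000, 21000)
  call$query_coverage <- 1; call$aligned_nt <- 1000L
  fs <- extract_flanks(call[1, ], genome, no_repeats, search_offset = 5000L)
  expect_equal(fs$upstream$end, 15000L)
  expect_equal(fs$downstream$start, 26000L)
})

test_that("shared insertions pair; independent or cross-gene loci do not", {
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                collapse = "")
  # species X and Y share the locus context around 20000 (same string)
  gX <- c(chr1 = base)
  gY <- c(chr1 = base)
  callX <- mk_call("chr1", 20000, 21000, species = "X")
  callY_shared <- mk_call("chr1", 20000, 21000, species = "Y")
  callY_indep <- mk_call("chr1", 45000, 46000, species = "Y")
  fl <- function(calls, g) lapply(seq_len(nrow(calls)), function(i)
    extract_flanks(calls[i, ], g, no_repeats))
  m <- match_orthologs(callX, callY_shared, fl(callX, gX), gY)
  expect_equal(nrow(m), 1L)
  # independent insertion of the same gene at a different locus: no pair
  m2 <- match_orthologs(callX, callY_indep, fl(callX, gX), gY)
  expect_equal(nrow(m2), 0L)
  # same locus but different parental genes: no pair
  callY_other <- mk_call("chr1", 20000, 21000, gene = "g2", species = "Y")
  m3 <- match_orthologs(callX, callY_other, fl(callX, gX), gY)
  expect_equal(nrow(m3), 0L)
  # symmetry of the match relation
  m_rev <- match_orthologs(callY_shared, callX, fl(callY_shared, gY), gX)
  expect_equal(nrow(m_rev), 1L)
  expect_equal(m_rev$call_b, m$call_a)
})

test_that("group origin follows the MRCA rule", {
  tree <- retroscape:::label_tree_nodes(
    ape::read.tree(text = "((human:6,chimp:6)hc:2,(gorilla:7,orang:7)go:1):5;"))
  calls <- list(
    human = mk_call("chr1", 100, 200, species = "human"),
    chimp = mk_call("chr1", 100, 200, species = "chimp"),
    gorilla = mk_call("chr1", 100, 200, species = "gorilla"),
    orang = mk_call("chr1", 100, 200, species = "orang"))
  pair <- function(a, b) data.frame(
    call_a = calls[[a]]$call_id, call_b = calls[[b]]$call_id,
    coverage = 1, identity = 1, side = "upstream", stringsAsFactors = FALSE)
  # human + chimp only -> branch above their common ancestor
  res <- build_groups(list(pair("human", "chimp")),
                      calls[c("human", "chimp")], tree)
  expect_equal(res$groups$origin_branch, "hc")
  expect_equal(nrow(res$species_specific), 0L)
  # present in all four species -> root edge
  res2 <- build_groups(list(pair("human", "chimp"), pair("chimp", "gorilla"),
                            pair("gorilla", "orang")), calls, tree)
  expect_equal(res2$groups$origin_branch, "root")
  expect_false(res2$groups$discordant)
  # unmatched call -> species-specific on its terminal branch
  res3 <- build_groups(list(), calls["human"], tree)
  expect_equal(res3$species_specific$origin_branch, "human")
  # discordant pattern (human + gorilla) is kept but flagged
  res4 <- build_groups(list(pair("human", "gorilla")),
                       calls[c("human", "gorilla")], tree)
  expect_equal(res4$groups$origin_branch, "root")
  expect_true(res4$groups$discordant)
})

test_that("every call lands in exactly one group or the specific set", {
  sim <- small_sim()
  gt <- sim$ground_truth$retrocopies
  calls <- lapply(c(A = "A", B = "B"), function(sp) {
    s <- sim$species[[sp]]
    add_call_ids(detect_retrocopies(s$genome, s$gene_models), sp)
  })
  genomes <- lapply(sim$species, `[[`, "genome")
  reps <- lapply(sim$species, `[[`, "repeats")
  orth <- infer_orthology(calls, genomes, reps, sim$tree)
  grouped <- unlist(strsplit(orth$groups$members, ","))
  specific <- orth$species_specific$call_id
  all_ids <- c(calls$A$call_id, calls$B$call_id)
  expect_setequal(c(grouped, specific), all_ids)
  expect_equal(anyDuplicated(c(grouped, specific)), 0L)
  # rate additivity: branch counts sum to total insertion events
  expect_equal(nrow(orth$groups) + nrow(orth$species_specific),
               length(all_ids) - nrow(orth$groups))
})

test_that("branch rates divide counts by durations", {
  expect_equal(round(branch_rate(1707, 12)), 142)
  expect_equal(round(branch_rate(6734, 42)), 160)
  expect_equal(branch_rate(0, 10), 0)
  expect_error(branch_rate(10, 0), "duration")
  expect_error(divergence_table("b", -1), "durations")
})

test_that("X-flux counts and binomial tails behave", {
  # all parents on X, all insertions autosomal -> n_out equals subset size
  calls <- mk_call("chr1", seq(1000, 10000, by = 1000),
                   seq(1000, 10000, by = 1000) + 100)
  calls$parent_on_x <- TRUE
  subset <- rep(c(TRUE, FALSE), 5)
  res <- x_flux_test(calls, subset)
  expect_equal(res$n_out_of_x, sum(subset))
  # background proportion 0.01, n = 63, observed 13 -> p < 0.001
  p <- stats::binom.test(13, 63, 0.01, alternative = "greater")$p.value
  expect_lt(p, 0.001)
  big <- mk_call("chr1", seq(1000, 700000, by = 1000),
                 seq(1000, 700000, by = 1000) + 100)
  n <- nrow(big)
  big$parent_on_x <- FALSE; big$on_x <- FALSE
  subset <- c(rep(TRUE, 63), rep(FALSE, n - 63))
  # plant 13 out-of-X in the subset and ~1% in the background
  big$parent_on_x[1:13] <- TRUE
  bg <- which(!subset)
  big$parent_on_x[bg[seq_len(round(0.01 * length(bg)))]] <- TRUE
  res <- x_flux_test(big, subset)
  expect_equal(res$n_out_of_x, 13L)
  expect_lt(res$p_out, 0.001)
  expect_error(x_flux_test(big, rep(FALSE, n)), "empty")
})

test_that("null x-flux p-values are well calibrated", {
  set.seed(42)
  n <- 400L
  ps <- replicate(300, {
    calls <- mk_call("chr1", seq_len(n) * 1000, seq_len(n) * 1000 + 100)
    calls$parent_on_x <- stats::runif(n) < 0.05
    calls$on_x <- FALSE
    subset <- c(rep(TRUE, 60), rep(FALSE, n - 60))
    x_flux_test(calls, subset)$p_out
  })
  # one-sided binomial p under the null is super-uniform
  expect_gte(mean(ps <= 0.05), 0.0)
  expect_lte(mean(ps <= 0.05), 0.09)
})
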