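# Retrocopy detection from transcript-to-genome chained alignments.
#
# A retrocopy is an intronless genomic copy of a multiexonic gene's mature
# mRNA.  Candidates are mRNA-to-genome alignments that pass identity /
# coverage / gap filters and show the intronless signature: at least two
# consecutive parental exons well aligned with their junction bridged on
# the genome (no intron-sized target gap).

#' Detection thresholds
#'
#' Defaults: identity > 0.75; query coverage > 0.5 *or* at least 120 nt
#' aligned; no internal target gap above 15 kb (putative introns); at least
#' 2 adjacent parental exons each contributing more than 50 aligned nt,
#' with the exon-exon junction bridged within 30 nt of target-side slack.
#'
#' @param min_identity minimum alignment identity (exclusive bound).
#' @param min_query_coverage minimum fraction of the parental transcript
#'   aligned (exclusive bound; disjunctive with `min_aligned_nt`).
#' @param min_aligned_nt minimum aligned nt (inclusive bound).
#' @param max_internal_gap largest tolerated target gap between alignment
#'   blocks, nt.
#' @param min_exon_aligned_nt per-exon aligned nt (exclusive bound).
#' @param min_adjacent_exons minimum run of qualifying adjacent exons.
#' @param junction_gap_tolerance target-side slack, nt, for a junction to
#'   count as bridged (intronless).
#' @return a list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(min_identity = 0.75,
                                 min_query_coverage = 0.50,
                                 min_aligned_nt = 120L,
                                 max_internal_gap = 15000L,
                                 min_exon_aligned_nt = 50L,
                                 min_adjacent_exons = 2L,
                                 junction_gap_tolerance = 30L) {
  th <- list(min_identity = min_identity,
             min_query_coverage = min_query_coverage,
             min_aligned_nt = as.integer(min_aligned_nt),
             max_internal_gap = as.integer(max_internal_gap),
             min_exon_aligned_nt = as.integer(min_exon_aligned_nt),
             min_adjacent_exons = as.integer(min_adjacent_exons),
             junction_gap_tolerance = as.integer(junction_gap_tolerance))
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0")
  if (min_identity > 1 || min_query_coverage > 1)
    stop("min_identity and min_query_coverage must lie in [0, 1]")
  class(th) <- "detection_thresholds"
  th
}

#' Align transcripts to a genome
#'
#' A seed-and-extend chained aligner: exact k-mer seeds (default k = 12),
#' ungapped X-drop extension along diagonals and greedy chaining with
#' bounded target gaps.  Output is equivalent in content to PSL; externally
#' produced PSL may be substituted via [read_psl()].
#'
#' @param transcripts named character vector of query (mRNA) sequences.
#' @param genome named character vector of target sequences.
#' @param k seed length (`-tileSize` analogue).
#' @param maxocc seeds occurring more often than this in the target are
#'   skipped (masks simple repeats such as polyA runs).
#' @param min_chain_matches minimum matched nt for a chain to be reported.
#' @param max_target_gap largest target gap the chainer will bridge, nt
#'   (kept above the detection gap filter so that intron-containing
#'   alignments are produced, then rejected by [filter_alignments()]).
#' @return a list of [chained_alignment()] objects.
#' @export
align_transcripts <- function(transcripts, genome, k = 12L, maxocc = 64L,
                              min_chain_matches = 30L,
                              max_target_gap = 50000L) {
  if (!length(transcripts) || !length(genome))
    stop("transcripts and genome must be non-empty")
  raw <- cpp_align(unname(genome), unname(transcripts), k = k,
                   maxocc = maxocc, min_matches = min_chain_matches,
                   max_tgap = max_target_gap)
  lapply(raw, function(r)
    chained_alignment(query_name = names(transcripts)[r$qid],
                      query_length = r$qsize,
                      target_name = names(genome)[r$tid],
                      strand = r$strand, matches = r$matches,
                      mismatches = r$mismatches, qstarts = r$qstarts,
                      tstarts = r$tstarts, blocksizes = r$blocksizes))
}

#' Filter chained alignments
#'
#' Keeps an alignment iff identity exceeds `min_identity` *and* either
#' query coverage exceeds `min_query_coverage` or at least `min_aligned_nt`
#' nt aligned, *and* no inter-block target gap exceeds `max_internal_gap`.
#' Identity is `matches / (matches + mismatches)`; coverage is aligned nt
#' over query length.
#'
#' @param alignments list of [chained_alignment()].
#' @param thresholds a [detection_thresholds()].
#' @return the surviving subset of `alignments`.
#' @export
filter_alignments <- function(alignments, thresholds = detection_thresholds()) {
  keep <- vapply(alignments, function(a) {
    id <- alignment_identity(a)
    if (is.na(id) || id <= thresholds$min_identity) return(FALSE)
    cov <- alignment_coverage(a)
    nt <- alignment_aligned_nt(a)
    if (!(cov > thresholds$min_query_coverage ||
          nt >= thresholds$min_aligned_nt)) return(FALSE)
    alignment_max_target_gap(a) <= thresholds$max_internal_gap
  }, logical(1L))
  alignments[keep]
}

# per-transcript lookup used during calling
build_tx_index <- function(gm) {
  ex <- gm[gm$feature == "exon", , drop = FALSE]
  spans <- gene_spans(gm)
  idx <- new.env(parent = emptyenv())
  for (tid in unique(ex$transcript_id)) {
    e <- transcript_exons(gm, tid)
    lens <- e$end - e$start
    assign(tid, list(gene = e$gene_id[1L], exon_lens = lens,
                     seqname = e$seqname[1L], strand = e$strand[1L]),
           envir = idx)
  }
  list(idx = idx, spans = spans)
}

#' Call retrocopies from filtered alignments
#'
#' A candidate is called iff a run of at least `min_adjacent_exons`
#' consecutive parental exons each contributes more than
#' `min_exon_aligned_nt` aligned nt and the junctions inside the run are
#' bridged with a target-side gap of at most `junction_gap_tolerance` nt
#' (the intronless signature).  Alignments overlapping the parental gene's
#' own annotated span are discarded, and overlapping candidate loci are
#' merged keeping the representative with the highest identity x coverage
#' (ties: longer alignment, then lexicographically smaller transcript id).
#'
#' @param alignments filtered [chained_alignment()] list.
#' @param gene_models a [gene_models()] table covering every query
#'   transcript.
#' @param thresholds a [detection_thresholds()].
#' @param x_seqnames sequence names carrying the chromosome-X flag.
#' @param exclude_genes optional character vector of parental gene ids to
#'   drop (exclusion list replacing manual curation).
#' @return a data.frame of calls: locus (`seqname`, `start`, `end`,
#'   `strand`; 0-based half-open), `parental_gene`, `parental_transcript`,
#'   `identity`, `query_coverage`, `aligned_nt`, `n_exons_bridged`,
#'   `on_x`, `parent_on_x`.
#' @export
call_retrocopies <- function(alignments, gene_models,
                             thresholds = detection_thresholds(),
                             x_seqnames = "chrX", exclude_genes = NULL) {
  txi <- build_tx_index(gene_models)
  rows <- list()
  for (a in alignments) {
    info <- tryCatch(get(a$query_name, envir = txi$idx),
                     error = function(e)
                       stop("no gene model for transcript ", a$query_name,
                            call. = FALSE))
    if (!is.null(exclude_genes) && info$gene %in% exclude_genes) next
    n_ex <- length(info$exon_lens)
    if (n_ex < 2L) next    # single-exon parents are undetectable by design
    bounds <- cumsum(c(0L, info$exon_lens))   # transcript coords
    # exon intervals in alignment orientation
    or <- orient_query_interval(a, bounds[-length(bounds)], bounds[-1L])
    # aligned nt per exon
    q_lo <- a$qstarts; q_hi <- a$qstarts + a$blocksizes
    ex_nt <- vapply(seq_len(n_ex), function(i)
      sum(interval_overlap(q_lo, q_hi, or[i, 1L], or[i, 2L])), numeric(1L))
    ex_ok <- ex_nt > thresholds$min_exon_aligned_nt
    # junction bridging: junction after exon i (transcript order) sits at
    # transcript coord bounds[i+1]; in alignment orientation:
    jq <- if (a$strand == "+") bounds[2:n_ex] else
      a$query_length - bounds[2:n_ex]
    tl <- query_to_target(a, jq - 1L)
    tr <- query_to_target(a, jq)
    gap <- ifelse(is.na(tl) | is.na(tr), NA_integer_, abs(tr - tl) - 1L)
    bridged <- !is.na(gap) & gap <= thresholds$junction_gap_tolerance
    # longest chain of qualifying exons whose internal junctions are bridged
    best <- 0L; cur <- 0L
    for (i in seq_len(n_ex)) {
      if (!ex_ok[i]) { cur <- 0L; next }
      cur <- if (cur == 0L) 1L
             else if (bridged[i - 1L]) cur + 1L else 1L
      best <- max(best, cur)
    }
    if (best < thresholds$min_adjacent_exons) next
    tr_range <- alignment_target_range(a)
    # parental-locus exclusion: any overlap with the gene's annotated span
    sp <- txi$spans[txi$spans$gene_id == info$gene, , drop = FALSE]
    self_hit <- any(sp$seqname == a$target_name &
                      interval_overlap(sp$start, sp$end,
                                       tr_range[["start"]],
                                       tr_range[["end"]]) > 0L)
    if (self_hit) next
    rows[[length(rows) + 1L]] <- data.frame(
      seqname = a$target_name, start = unname(tr_range[["start"]]),
      end = unname(tr_range[["end"]]), strand = a$strand,
      parental_gene = info$gene, parental_transcript = a$query_name,
      identity = alignment_identity(a),
      query_coverage = alignment_coverage(a),
      aligned_nt = alignment_aligned_nt(a),
      n_exons_bridged = best,
      on_x = a$target_name %in% x_seqnames,
      parent_on_x = info$seqname %in% x_seqnames,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_call_table())
  calls <- do.call(rbind, rows)
  merge_overlapping_calls(calls)
}

empty_call_table <- function() {
  data.frame(seqname = character(), start = integer(), end = integer(),
             strand = character(), parental_gene = character(),
             parental_transcript = character(), identity = numeric(),
             query_coverage = numeric(), aligned_nt = integer(),
             n_exons_bridged = integer(), on_x = logical(),
             parent_on_x = logical(), stringsAsFactors = FALSE)
}

# overlapping candidate loci collapse to one call: the representative with
# highest identity x coverage, ties by longer aligned_nt then transcript id
merge_overlapping_calls <- function(calls) {
  gr <- intervals_to_granges(calls[, c("seqname", "start", "end")])
  cl <- GenomicRanges::findOverlaps(
    gr, GenomicRanges::reduce(gr, ignore.strand = TRUE),
    ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(cl)[order(S4Vectors::queryHits(cl))]
  score <- calls$identity * calls$query_coverage
  o <- order(grp, -score, -calls$aligned_nt, calls$parental_transcript)
  keep <- !duplicated(grp[o])
  out <- calls[o, , drop = FALSE][keep, , drop = FALSE]
  out <- out[order(out$seqname, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-species catalog summary
#'
#' @param calls_by_species named list (species to call table).
#' @return a data.frame with one row per species: `species`,
#'   `n_retrocopies`, `n_parental_genes`.
#' @export
catalog_summary <- function(calls_by_species) {
  out <- data.frame(
    species = names(calls_by_species),
    n_retrocopies = vapply(calls_by_species, nrow, integer(1L)),
    n_parental_genes = vapply(calls_by_species, function(x)
      length(unique(x$parental_gene)), integer(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-stop detection for a single species
#'
#' Convenience wrapper: splice transcripts from the gene models, align them
#' to the genome (or take alignments from a PSL file), filter and call.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gm a [gene_models()] table.
#' @param thresholds a [detection_thresholds()].
#' @param psl optional path to an externally produced PSL file used instead
#'   of the internal aligner.
#' @param ... passed to [align_transcripts()].
#' @return a call table (see [call_retrocopies()]).
#' @export
detect_retrocopies <- function(genome, gm, thresholds = detection_thresholds(),
                               psl = NULL, ...) {
  if (is.null(psl)) {
    tx <- unique(gm$transcript_id[gm$feature == "exon"])
    seqs <- vapply(tx, transcript_sequence, character(1L), gm = gm,
                   genome = genome)
    aln <- align_transcripts(seqs, genome, ...)
  } else {
    aln <- read_psl(psl)
  }
  aln <- filter_alignments(aln, thresholds)
  call_retrocopies(aln, gm, thresholds)
}
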