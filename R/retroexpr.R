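# Expressed-retrocopy calling from read alignments.
#
# Two complementary strategies: (1) chimeric junction reads that splice a
# host-gene exon onto an intragenic retrocopy across a canonical GT-AG
# intron; (2) reads aligning uniquely (high MAPQ) to the retrocopy portion
# of a decoy reference that also carries every parental mature mRNA, so
# that parent-derived reads cannot masquerade as retrocopy expression.

#' Expression thresholds
#'
#' @param min_chimeric_reads reads required to accept a chimeric event.
#' @param min_mapq mapping quality bound (exclusive) for supporting reads.
#' @param context_distance nt bound (exclusive) for TSS/polyA proximity.
#' @param n_permutations permutations for the genomic-context test.
#' @param min_unique_reads unique reads required to call a retrocopy
#'   expressed in a tissue.
#' @param decoy_flank nt of genomic flank kept around each retrocopy in the
#'   decoy reference.
#' @return a list of class `expression_thresholds`.
#' @export
expression_thresholds <- function(min_chimeric_reads = 5L, min_mapq = 40L,
                                  context_distance = 15000L,
                                  n_permutations = 10000L,
                                  min_unique_reads = 2L,
                                  decoy_flank = 300L) {
  th <- list(min_chimeric_reads = as.integer(min_chimeric_reads),
             min_mapq = as.integer(min_mapq),
             context_distance = as.integer(context_distance),
             n_permutations = as.integer(n_permutations),
             min_unique_reads = as.integer(min_unique_reads),
             decoy_flank = as.integer(decoy_flank))
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0")
  class(th) <- "expression_thresholds"
  th
}

# reference-space M-blocks and N-gaps of SAM records
cigar_blocks <- function(records) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    records$cigar, pos = records$pos + 1L, ops = "M")
}
cigar_gaps <- function(records) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    records$cigar, pos = records$pos + 1L, ops = "N")
}

#' Detect host-retrocopy chimeric events
#'
#' An event is a (host gene, retrocopy, junction) triple supported by
#' spliced reads whose junction has one side in a host-gene exon and the
#' other inside the retrocopy locus, with canonical GT-AG intron interior
#' bases in transcription orientation.  Events need at least
#' `min_chimeric_reads` supporting reads, each with MAPQ above `min_mapq`.
#'
#' @param records SAM records (data.frame with `qname`, `seqname`, `pos`,
#'   `mapq`, `cigar`; see [simulate_reads()] / [read_sam()]).
#' @param gm a [gene_models()] table.
#' @param calls a call table with ids ([add_call_ids()]).
#' @param genome named character vector.
#' @param thresholds an [expression_thresholds()].
#' @return a data.frame of accepted events: `host_gene`, `call_id`,
#'   `junction_start`, `junction_end`, `host_strand`, `n_reads`.
#' @export
detect_chimeric <- function(records, gm, calls, genome,
                            thresholds = expression_thresholds()) {
  empty <- data.frame(host_gene = character(), call_id = character(),
                      junction_start = integer(), junction_end = integer(),
                      host_strand = character(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  records <- records[records$mapq > thresholds$min_mapq &
                       grepl("N", records$cigar, fixed = TRUE), , drop = FALSE]
  if (!nrow(records)) return(empty)
  if (any(!records$seqname %in% names(genome)))
    stop("SAM contig absent from genome: ",
         setdiff(records$seqname, names(genome))[1L])
  gaps <- cigar_gaps(records)
  nper <- lengths(gaps)
  flat <- unlist(gaps)
  if (!length(flat)) return(empty)
  # one row per junction: interior interval [gs, ge), 0-based
  jx <- data.frame(seqname = rep(records$seqname, nper),
                   gs = BiocGenerics::start(flat) - 1L,
                   ge = BiocGenerics::end(flat),
                   stringsAsFactors = FALSE)
  ex <- gm[gm$feature == "exon", , drop = FALSE]
  ex_gr <- intervals_to_granges(ex)
  # called loci are aligned cores: pad them so a junction landing on the
  # insertion edge (unaligned polyA / slightly trimmed ends) still counts
  call_gr <- intervals_to_granges(calls[, c("seqname", "start", "end")]) + 100L
  point <- function(p) GenomicRanges::GRanges(
    jx$seqname, IRanges::IRanges(start = p + 1L, width = 1L))
  left_pt <- point(jx$gs - 1L)    # last aligned base before the gap
  right_pt <- point(jx$ge)        # first aligned base after the gap
  first_hit <- function(q, s) {
    h <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE,
                                     select = "first")
    h
  }
  exl <- first_hit(left_pt, ex_gr[GenomicRanges::strand(ex_gr) == "+"])
  exr <- first_hit(right_pt, ex_gr[GenomicRanges::strand(ex_gr) == "-"])
  rcl <- first_hit(left_pt, call_gr)
  rcr <- first_hit(right_pt, call_gr)
  chrom_seq <- genome[jx$seqname]
  donor2 <- substring(chrom_seq, jx$gs + 1L, jx$gs + 2L)
  accept2 <- substring(chrom_seq, jx$ge - 1L, jx$ge)
  ex_plus <- ex[ex$strand == "+", , drop = FALSE]
  ex_minus <- ex[ex$strand == "-", , drop = FALSE]
  plus_ok <- !is.na(exl) & !is.na(rcr) & donor2 == "GT" & accept2 == "AG"
  minus_ok <- !is.na(exr) & !is.na(rcl) & accept2 == "AC" & donor2 == "CT"
  rows <- list()
  if (any(plus_ok)) {
    rows[[1L]] <- data.frame(
      host_gene = ex_plus$gene_id[exl[plus_ok]],
      call_id = calls$call_id[rcr[plus_ok]],
      junction_start = jx$gs[plus_ok], junction_end = jx$ge[plus_ok],
      host_strand = "+", stringsAsFactors = FALSE)
  }
  if (any(minus_ok)) {
    rows[[length(rows) + 1L]] <- data.frame(
      host_gene = ex_minus$gene_id[exr[minus_ok]],
      call_id = calls$call_id[rcl[minus_ok]],
      junction_start = jx$gs[minus_ok], junction_end = jx$ge[minus_ok],
      host_strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  ev <- do.call(rbind, rows)
  key <- paste(ev$host_gene, ev$call_id, ev$junction_start, ev$junction_end)
  cnt <- table(key)
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev$n_reads <- as.integer(cnt[paste(ev$host_gene, ev$call_id,
                                     ev$junction_start, ev$junction_end)])
  ev <- ev[ev$n_reads >= thresholds$min_chimeric_reads, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Build the decoy reference for unique-alignment expression calling
#'
#' The reference holds each retrocopy locus with `decoy_flank` nt of
#' genomic context plus every parental mature mRNA, so reads from a parent
#' align best to the parent transcript and cannot be counted as retrocopy
#' expression; identical-sequence collapse is deliberately not performed.
#'
#' @param calls call table with ids.
#' @param genome named character vector.
#' @param gm a [gene_models()] table (source of the mature mRNAs).
#' @param decoy_flank nt of flank per side.
#' @return named character vector; retrocopy entries are named by
#'   `call_id` and carry the retro portion as attribute `retro_region`
#'   (a matrix of per-entry `start`,`end` within the decoy sequence).
#' @export
build_decoy_reference <- function(calls, genome, gm, decoy_flank = 300L) {
  tx <- unique(gm$transcript_id[gm$feature == "exon"])
  seqs <- vapply(tx, transcript_sequence, character(1L), gm = gm,
                 genome = genome)
  names(seqs) <- paste0("tx:", tx)
  region <- matrix(integer(0), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(calls)) {
    rc <- character(nrow(calls))
    region <- matrix(0L, nrow = nrow(calls), ncol = 2,
                     dimnames = list(calls$call_id, c("start", "end")))
    for (i in seq_len(nrow(calls))) {
      chrom <- genome[[calls$seqname[i]]]
      lo <- max(0L, calls$start[i] - decoy_flank)
      hi <- min(nchar(chrom), calls$end[i] + decoy_flank)
      rc[i] <- substring(chrom, lo + 1L, hi)
      region[i, ] <- c(calls$start[i] - lo, calls$end[i] - lo)
    }
    names(rc) <- calls$call_id
    seqs <- c(seqs, rc)
  }
  attr(seqs, "retro_region") <- region
  seqs
}

#' Align reads to the decoy reference
#'
#' Each read is placed at its best-scoring chain; MAPQ is 60 when the best
#' placement beats every alternative by at least one matched base and 3
#' when tied (multi-mapping, e.g. a retrocopy identical to its parent).
#'
#' @param records SAM records with a `seq` column.
#' @param decoy reference from [build_decoy_reference()].
#' @return data.frame: `qname`, `ref`, `start`, `end`, `mapq`.
#' @export
align_reads_to_decoy <- function(records, decoy) {
  if (!nrow(records))
    return(data.frame(qname = character(), ref = character(),
                      start = integer(), end = integer(), mapq = integer(),
                      stringsAsFactors = FALSE))
  raw <- cpp_align(unname(decoy), records$seq, k = 12L,
                   maxocc = 256L, min_matches = 25L, max_tgap = 10L)
  if (!length(raw))
    return(data.frame(qname = character(), ref = character(),
                      start = integer(), end = integer(), mapq = integer(),
                      stringsAsFactors = FALSE))
  qid <- vapply(raw, function(r) r$qid, integer(1L))
  sc <- vapply(raw, function(r) r$matches, integer(1L))
  ord <- order(qid, -sc)
  q_o <- qid[ord]
  first <- !duplicated(q_o)
  best <- ord[first]
  # second-best score per read (ties mean multi-mapping)
  dup <- !first
  sec_idx <- ord[dup][!duplicated(q_o[dup])]
  second <- rep(-Inf, length(best))
  second[match(qid[sec_idx], qid[best])] <- sc[sec_idx]
  tid <- vapply(raw[best], function(r) r$tid, integer(1L))
  st <- vapply(raw[best], function(r) r$tstarts[1L], integer(1L))
  en <- vapply(raw[best], function(r) {
    nb <- length(r$blocksizes); r$tstarts[nb] + r$blocksizes[nb]
  }, integer(1L))
  out <- data.frame(qname = records$qname[qid[best]],
                    ref = names(decoy)[tid], start = st, end = en,
                    mapq = ifelse(sc[best] - second >= 1L, 60L, 3L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call expressed retrocopies from decoy alignments
#'
#' A read counts for a retrocopy iff its MAPQ exceeds `min_mapq` and the
#' alignment overlaps the retrocopy portion of the decoy entry (flank-only
#' alignments are ignored).  A retrocopy is expressed in a tissue iff at
#' least `min_unique_reads` such reads are found; normalized expression is
#' reads per kilobase of retrocopy per million counted-tissue reads.
#'
#' @param decoy_hits_by_tissue named list (tissue to [align_reads_to_decoy()]
#'   output).
#' @param calls call table with ids.
#' @param decoy the decoy reference (for the retro-region attribute).
#' @param thresholds an [expression_thresholds()].
#' @return data.frame: `call_id`, `tissue`, `n_reads`, `rpkm`, `expressed`.
#' @export
call_expressed <- function(decoy_hits_by_tissue, calls, decoy,
                           thresholds = expression_thresholds()) {
  region <- attr(decoy, "retro_region")
  rows <- list()
  for (tis in names(decoy_hits_by_tissue)) {
    h <- decoy_hits_by_tissue[[tis]]
    total <- nrow(h)
    h <- h[h$mapq > thresholds$min_mapq & h$ref %in% calls$call_id, ,
           drop = FALSE]
    if (nrow(h)) {
      reg <- region[h$ref, , drop = FALSE]
      inside <- h$end > reg[, "start"] & h$start < reg[, "end"]
      h <- h[inside, , drop = FALSE]
    }
    cnt <- table(factor(h$ref, levels = calls$call_id))
    n <- as.integer(cnt)
    len_kb <- (calls$end - calls$start) / 1000
    rpkm <- if (total > 0) n / len_kb / (total / 1e6) else rep(0, length(n))
    rows[[tis]] <- data.frame(call_id = calls$call_id, tissue = tis,
                              n_reads = n, rpkm = rpkm,
                              expressed = n >= thresholds$min_unique_reads,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)`: 0 for uniform expression,
#' 1 for single-tissue expression.  Undefined (`NA`) for all-zero vectors.
#'
#' @param x non-negative expression vector over `N >= 2` tissues.
#' @return tau in `[0, 1]`, or `NA` if undefined.
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs >= 2 tissues")
  if (any(x < 0)) stop("expression values must be non-negative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

#' Classify the genomic context of a retrocopy
#'
#' Precedence: chimeric intragenic (same/opposite strand of the host) >
#' intragenic > near TSS (< `context_distance` nt, same/opposite strand) >
#' near polyA (same/opposite) > distant.  Distances are measured from the
#' retrocopy edges with an exclusive bound.
#'
#' @param calls call table with ids.
#' @param gm a [gene_models()] table.
#' @param chimeric_events accepted events from [detect_chimeric()] (or an
#'   empty data.frame).
#' @param thresholds an [expression_thresholds()].
#' @return character vector of context classes, parallel to `calls` rows.
#' @export
classify_context <- function(calls, gm, chimeric_events = NULL,
                             thresholds = expression_thresholds()) {
  spans <- gene_spans(gm)
  ex <- gm[gm$feature == "exon", , drop = FALSE]
  # per-transcript TSS and polyA points with strands
  tx_tab <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(e) {
    data.frame(seqname = e$seqname[1L], strand = e$strand[1L],
               tss = if (e$strand[1L] == "+") min(e$start) else max(e$end) - 1L,
               polya = if (e$strand[1L] == "+") max(e$end) - 1L else
                 min(e$start),
               stringsAsFactors = FALSE)
  }))
  d <- thresholds$context_distance
  out <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$start[i]; e <- calls$end[i]; chrom <- calls$seqname[i]
    host <- spans$gene_id[spans$seqname == chrom &
                            spans$start < e & spans$end > s]
    chim <- NULL
    if (!is.null(chimeric_events) && nrow(chimeric_events))
      chim <- chimeric_events[chimeric_events$call_id == calls$call_id[i], ,
                              drop = FALSE]
    if (length(host) && !is.null(chim) && nrow(chim)) {
      same <- chim$host_strand[1L] == calls$strand[i]
      out[i] <- if (same) "intragenic_same_chimeric" else
        "intragenic_opposite_chimeric"
      next
    }
    if (length(host)) { out[i] <- "intragenic"; next }
    tt <- tx_tab[tx_tab$seqname == chrom, , drop = FALSE]
    # point-to-edge distance, exclusive bound, 0 for a point inside the locus
    dist_to <- function(p) pmax(0L, pmax(s - p, p - (e - 1L)))
    if (nrow(tt)) {
      dt <- dist_to(tt$tss)
      if (any(dt < d)) {
        j <- which.min(dt)
        out[i] <- if (tt$strand[j] == calls$strand[i]) "near_TSS_same" else
          "near_TSS_opposite"
        next
      }
      dp <- dist_to(tt$polya)
      if (any(dp < d)) {
        j <- which.min(dp)
        out[i] <- if (tt$strand[j] == calls$strand[i]) "near_polyA_same" else
          "near_polyA_opposite"
        next
      }
    }
    out[i] <- "distant"
  }
  out
}

#' Permutation test for genomic-context enrichment
#'
#' Places `n_permutations` random groups of loci, length-matched to the
#' expressed retrocopies, uniformly on the genome; each locus is classified
#' intragenic/near (within `context_distance` of a gene span) versus
#' distant, and the intragenic/near fraction recorded.  The one-sided
#' p-value is `(1 + #{null >= observed}) / (n_permutations + 1)`.
#'
#' @param expressed_calls call table of expressed retrocopies.
#' @param genome named character vector (placement space).
#' @param gm a [gene_models()] table.
#' @param thresholds an [expression_thresholds()].
#' @param seed integer seed.
#' @return list: `observed_fraction`, `null_fractions`, `p`.
#' @export
permutation_context_test <- function(expressed_calls, genome, gm,
                                     thresholds = expression_thresholds(),
                                     seed = 1L) {
  if (!nrow(expressed_calls)) stop("need >= 1 expressed call")
  nperm <- thresholds$n_permutations
  if (nperm <= 0L) stop("n_permutations must be > 0")
  set.seed(seed)
  d <- thresholds$context_distance
  spans <- gene_spans(gm)
  chrom_len <- vapply(genome, nchar, integer(1L))
  # intragenic/near intervals on a single global axis, merged and sorted,
  # so classification is a plain findInterval lookup (no per-permutation
  # object construction)
  off <- c(0, cumsum(as.numeric(chrom_len)))[seq_along(chrom_len)]
  names(off) <- names(chrom_len)
  iv_s <- off[spans$seqname] + pmax(0L, spans$start - (d - 1L))
  iv_e <- off[spans$seqname] + pmin(chrom_len[spans$seqname],
                                    spans$end + (d - 1L))
  o <- order(iv_s)
  iv_s <- iv_s[o]; iv_e <- cummax(iv_e[o])
  keep <- c(TRUE, iv_s[-1L] > iv_e[-length(iv_e)])
  grp <- cumsum(keep)
  iv_start <- as.numeric(tapply(iv_s, grp, min))
  iv_end <- as.numeric(tapply(iv_e, grp, max))
  classify_hits <- function(gstart, gend) {
    k <- findInterval(gend - 0.5, iv_start)
    k >= 1 & ifelse(k >= 1, iv_end[pmax(k, 1L)] > gstart, FALSE)
  }
  obs <- mean(classify_hits(off[expressed_calls$seqname] +
                              expressed_calls$start,
                            off[expressed_calls$seqname] +
                              expressed_calls$end))
  lens <- expressed_calls$end - expressed_calls$start
  m <- length(lens)
  # all permutations placed and classified in one pass
  tot <- nperm * m
  chrom <- sample(names(chrom_len), tot, replace = TRUE,
                  prob = chrom_len / sum(chrom_len))
  lens_all <- rep(lens, nperm)
  maxs <- pmax(1, chrom_len[chrom] - lens_all)
  start <- floor(stats::runif(tot, 0, maxs))
  hit <- classify_hits(off[chrom] + start, off[chrom] + start + lens_all)
  nulls <- as.numeric(rowsum(as.numeric(hit),
                             rep(seq_len(nperm), each = m))) / m
  list(observed_fraction = obs, null_fractions = nulls,
       p = (1 + sum(nulls >= obs)) / (nperm + 1))
}

#' Spearman expression correlations for retrocopy-gene pairings
#'
#' @param pairs data.frame with columns `pair_type`, `retro`, `gene`
#'   (mean expression values of each member of a pair).
#' @return data.frame: `pair_type`, `n`, `rho`, `p` (`NA` and flagged via
#'   `defined` when fewer than 3 pairs).
#' @export
expression_correlations <- function(pairs) {
  out <- lapply(split(pairs, pairs$pair_type), function(pp) {
    if (nrow(pp) < 3L)
      return(data.frame(pair_type = pp$pair_type[1L], n = nrow(pp),
                        rho = NA_real_, p = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(pp$retro, pp$gene,
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(pair_type = pp$pair_type[1L], n = nrow(pp),
               rho = unname(ct$estimate), p = ct$p.value, defined = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
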