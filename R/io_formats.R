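# Readers/writers for on-disk formats.  The internal coordinate convention
# is 0-based half-open on the plus strand everywhere; conversions to and
# from 1-based inclusive formats (GTF, RepeatMasker, SAM) happen only here.

# ---- coordinate conversions -------------------------------------------------

# 1-based inclusive (GTF/RepeatMasker/SAM) -> internal 0-based half-open
coord_to_internal <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}
# internal -> 1-based inclusive
coord_to_external <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# ---- genomic intervals ------------------------------------------------------

#' Create a table of genomic intervals
#'
#' Intervals are 0-based half-open, the package-wide internal convention.
#'
#' @param seqname character vector of sequence (chromosome) names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return a `data.frame` with columns `seqname`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(seqname, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("invalid interval: need 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(seqname = as.character(seqname), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# internal intervals -> GRanges (and back); GRanges is 1-based inclusive
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

granges_to_intervals <- function(gr) {
  data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# ---- chained alignments (PSL) ----------------------------------------------

#' Construct a chained alignment
#'
#' Mirrors a PSL record: an ordered set of ungapped blocks linking a query
#' (transcript) to a target (genome) sequence.  Block query coordinates
#' follow PSL semantics: for minus-strand alignments they refer to the
#' reverse-complemented query; target coordinates are always plus-strand.
#'
#' @param query_name,target_name sequence names.
#' @param query_length query length in nt.
#' @param strand `"+"` or `"-"` (orientation of the query).
#' @param matches,mismatches aligned base counts over all blocks.
#' @param qstarts,tstarts,blocksizes integer vectors, one entry per block,
#'   0-based; blocks must be non-overlapping and increasing on both sides.
#' @return an object of class `chained_alignment`.
#' @export
chained_alignment <- function(query_name, query_length, target_name, strand,
                              matches, mismatches, qstarts, tstarts, blocksizes) {
  qstarts <- as.integer(qstarts); tstarts <- as.integer(tstarts)
  blocksizes <- as.integer(blocksizes)
  n <- length(blocksizes)
  stopifnot(length(qstarts) == n, length(tstarts) == n, n >= 1L)
  if (n > 1L) {
    if (any(diff(qstarts) < blocksizes[-n]) || any(diff(tstarts) < blocksizes[-n]))
      stop("alignment blocks overlap or are out of order")
  }
  if (matches + mismatches > sum(blocksizes))
    stop("matches + mismatches exceed total block length")
  structure(list(query_name = as.character(query_name),
                 query_length = as.integer(query_length),
                 target_name = as.character(target_name),
                 strand = strand,
                 matches = as.integer(matches),
                 mismatches = as.integer(mismatches),
                 qstarts = qstarts, tstarts = tstarts, blocksizes = blocksizes),
            class = "chained_alignment")
}

#' @export
print.chained_alignment <- function(x, ...) {
  cat(sprintf("<chained_alignment> %s -> %s:%d-%d (%s) %d blocks, id %.3f\n",
              x$query_name, x$target_name, min(x$tstarts),
              max(x$tstarts + x$blocksizes), x$strand,
              length(x$blocksizes), alignment_identity(x)))
  invisible(x)
}

#' Alignment summary statistics
#'
#' Identity is `matches / (matches + mismatches)`; aligned length is the sum
#' of block sizes; coverage is aligned length over query length.
#'
#' @param aln a `chained_alignment`.
#' @return a scalar.
#' @export
alignment_identity <- function(aln) {
  d <- aln$matches + aln$mismatches
  if (d == 0) return(NA_real_)
  aln$matches / d
}

#' @rdname alignment_identity
#' @export
alignment_aligned_nt <- function(aln) sum(aln$blocksizes)

#' @rdname alignment_identity
#' @export
alignment_coverage <- function(aln) {
  if (aln$query_length == 0L) stop("query_length is zero")
  alignment_aligned_nt(aln) / aln$query_length
}

# largest target-side gap between consecutive blocks (0 for single-block)
alignment_max_target_gap <- function(aln) {
  n <- length(aln$blocksizes)
  if (n == 1L) return(0L)
  max(aln$tstarts[-1L] - (aln$tstarts[-n] + aln$blocksizes[-n]))
}

alignment_target_range <- function(aln) {
  c(start = aln$tstarts[1L],
    end = aln$tstarts[length(aln$tstarts)] + aln$blocksizes[length(aln$blocksizes)])
}

# map a query position (alignment orientation) to its target position, or NA
query_to_target <- function(aln, qpos) {
  idx <- findInterval(qpos, aln$qstarts)
  res <- rep(NA_integer_, length(qpos))
  ok <- idx >= 1L
  off <- qpos[ok] - aln$qstarts[idx[ok]]
  inside <- off < aln$blocksizes[idx[ok]]
  res[ok][inside] <- aln$tstarts[idx[ok]][inside] + off[inside]
  res
}

# convert an interval on the original query to alignment orientation
orient_query_interval <- function(aln, start, end) {
  if (aln$strand == "+") return(cbind(start = start, end = end))
  cbind(start = aln$query_length - end, end = aln$query_length - start)
}

PSL_NCOL <- 21L

#' Read / write PSL chained-alignment files
#'
#' PSL coordinates (0-based half-open; minus-strand query starts given on
#' the reverse-complemented query) are preserved exactly.  Lines that do not
#' parse are skipped and counted in the `n_malformed` attribute.
#'
#' @param path file path.
#' @return `read_psl`: a list of [chained_alignment()] objects with attribute
#'   `n_malformed`.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # skip the optional psLayout 5-line header and comment/blank lines
  if (length(lines) && startsWith(lines[1L], "psLayout"))
    lines <- lines[-seq_len(min(5L, length(lines)))]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < PSL_NCOL) { bad <- bad + 1L; next }
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(num))
      stop(sprintf("PSL parse error at line %d: non-numeric mandatory field", i))
    split_ints <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1L]])
    out[[i]] <- chained_alignment(
      query_name = f[10L], query_length = as.integer(f[11L]),
      target_name = f[14L], strand = substr(f[9L], 1L, 1L),
      matches = as.integer(f[1L]), mismatches = as.integer(f[2L]),
      qstarts = split_ints(f[20L]), tstarts = split_ints(f[21L]),
      blocksizes = split_ints(f[19L]))
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  attr(out, "n_malformed") <- bad
  out
}

#' @param alignments a list of [chained_alignment()] objects.
#' @rdname read_psl
#' @export
write_psl <- function(alignments, path) {
  lines <- vapply(alignments, function(a) {
    n <- length(a$blocksizes)
    tsize <- max(a$tstarts + a$blocksizes)  # lower bound; PSL requires a value
    qr <- if (a$strand == "+") {
      c(a$qstarts[1L], a$qstarts[n] + a$blocksizes[n])
    } else {
      c(a$query_length - (a$qstarts[n] + a$blocksizes[n]),
        a$query_length - a$qstarts[1L])
    }
    paste(c(a$matches, a$mismatches, 0L, 0L, 0L, 0L,
            max(0L, n - 1L),
            sum(a$tstarts[-1L] - (a$tstarts[-n] + a$blocksizes[-n])),
            a$strand, a$query_name, a$query_length, qr[1L], qr[2L],
            a$target_name, tsize, a$tstarts[1L],
            a$tstarts[n] + a$blocksizes[n], n,
            paste0(paste(a$blocksizes, collapse = ","), ","),
            paste0(paste(a$qstarts, collapse = ","), ","),
            paste0(paste(a$tstarts, collapse = ","), ",")),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- gene models (GTF) ------------------------------------------------------

#' Build a gene-model table
#'
#' @param df a data.frame with columns `seqname`, `start`, `end` (0-based
#'   half-open), `strand`, `feature` (`"exon"` or `"CDS"`), `gene_id`,
#'   `transcript_id`.
#' @return the validated data.frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("seqname", "start", "end", "strand", "feature",
            "gene_id", "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(is.na(df$transcript_id) | df$transcript_id == ""))
    stop("gene model with missing transcript_id")
  ex <- df[df$feature == "exon", , drop = FALSE]
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("transcript has overlapping exons: ", tx)
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from GTF
#'
#' 1-based inclusive GTF is converted to the internal 0-based half-open
#' convention; exon order within transcripts is 5' to 3' in transcript
#' orientation.
#'
#' @param path GTF file.
#' @return a [gene_models()] table.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  tid <- gr$transcript_id
  if (is.null(tid) || any(is.na(tid)))
    stop("GTF record with missing transcript_id")
  df <- data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   feature = as.character(gr$type),
                   gene_id = gr$gene_id,
                   transcript_id = tid,
                   stringsAsFactors = FALSE)
  gene_models(df)
}

#' @param gm a [gene_models()] table.
#' @param source source column for the emitted GTF.
#' @rdname read_gtf
#' @export
write_gtf <- function(gm, path, source = "retroscape") {
  lines <- sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   gm$seqname, source, gm$feature, gm$start + 1L, gm$end,
                   gm$strand, gm$gene_id, gm$transcript_id)
  writeLines(c(writer_header(), lines), path)
  invisible(path)
}

# exon table of one transcript, ordered 5'->3' in transcript orientation
transcript_exons <- function(gm, transcript_id) {
  e <- gm[gm$feature == "exon" & gm$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(e)) stop("no gene model for transcript ", transcript_id)
  e <- e[order(e$start), , drop = FALSE]
  if (e$strand[1L] == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  e
}

transcript_length <- function(gm, transcript_id) {
  e <- transcript_exons(gm, transcript_id)
  sum(e$end - e$start)
}

# spliced transcript sequence (character) from a genome (named character vec)
transcript_sequence <- function(gm, transcript_id, genome) {
  e <- transcript_exons(gm, transcript_id)
  chrom <- genome[[e$seqname[1L]]]
  parts <- substring(chrom, e$start + 1L, e$end)
  if (e$strand[1L] == "-") {
    paste(cpp_revcomp(parts), collapse = "")
  } else {
    paste(parts, collapse = "")
  }
}

# per-gene span table (0-based half-open over all exons of the gene)
gene_spans <- function(gm) {
  ex <- gm[gm$feature == "exon", , drop = FALSE]
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], seqname = e$seqname[1L],
               start = min(e$start), end = max(e$end), strand = e$strand[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

# CDS of a transcript in transcript coordinates: c(start, end), 0-based
cds_transcript_coords <- function(gm, transcript_id) {
  cds <- gm[gm$feature == "CDS" & gm$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  e <- transcript_exons(gm, transcript_id)
  lens <- e$end - e$start
  offs <- cumsum(c(0L, lens[-length(lens)]))
  gstart <- min(cds$start); gend <- max(cds$end)
  # locate genomic CDS bounds within the exon walk
  pos_of <- function(gpos_left) {       # genomic coord -> transcript coord
    for (i in seq_len(nrow(e))) {
      if (gpos_left >= e$start[i] && gpos_left <= e$end[i]) {
        within <- if (e$strand[i] == "+") gpos_left - e$start[i]
                  else e$end[i] - gpos_left
        return(offs[i] + within)
      }
    }
    stop("CDS boundary outside exons for ", transcript_id)
  }
  if (e$strand[1L] == "+") {
    c(start = pos_of(gstart), end = pos_of(gend))
  } else {
    c(start = pos_of(gend), end = pos_of(gstart))
  }
}

# ---- RepeatMasker .out ------------------------------------------------------

RM_HEADER <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
  "")

#' Read / write RepeatMasker .out annotation tables
#'
#' The whitespace-table dialect with its 3-line header; 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @return `read_repeatmasker`: a data.frame with columns `seqname`, `start`,
#'   `end`, `strand`, `subfamily`, `repeat_class`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) >= 2L && grepl("^\\s*SW", lines[1L]))
    lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      subfamily = character(), repeat_class = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(trimws(lines), "\\s+")
  df <- data.frame(
    seqname = vapply(f, `[`, "", 5L),
    start = as.integer(vapply(f, `[`, "", 6L)) - 1L,
    end = as.integer(vapply(f, `[`, "", 7L)),
    strand = ifelse(vapply(f, `[`, "", 9L) == "C", "-", "+"),
    subfamily = vapply(f, `[`, "", 10L),
    repeat_class = vapply(f, `[`, "", 11L),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end)))
    stop("RepeatMasker parse error: non-numeric coordinates")
  df
}

#' @param repeats a repeat-annotation data.frame as returned by
#'   `read_repeatmasker`.
#' @rdname read_repeatmasker
#' @export
write_repeatmasker <- function(repeats, path) {
  rows <- sprintf("  250  1.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  %s  1  %d  (0)  %d",
                  repeats$seqname, repeats$start + 1L, repeats$end,
                  ifelse(repeats$strand == "-", "C", "+"),
                  repeats$subfamily, repeats$repeat_class,
                  repeats$end - repeats$start, seq_len(nrow(repeats)))
  writeLines(c(RM_HEADER, rows), path)
  invisible(path)
}

# ---- FASTA ------------------------------------------------------------------

#' Read / write genome FASTA
#'
#' Genomes are handled as named character vectors (one element per
#' chromosome); [Biostrings::readDNAStringSet()] does the parsing.
#'
#' @param path FASTA file.
#' @return `read_genome_fasta`: a named character vector.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @param genome named character vector of sequences.
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- SAM --------------------------------------------------------------------

#' Read a SAM file of read alignments
#'
#' Converts through BAM in a temporary directory and returns a
#' [GenomicAlignments::GAlignments] with `qname`, `flag`, `mapq` and `seq`
#' metadata columns; MAPQ and CIGAR are retained.  Unknown CIGAR operations
#' are rejected by the underlying parser.
#'
#' @param path SAM file with an `@SQ` header.
#' @return a `GAlignments` object.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq"))
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Write SAM records
#'
#' @param records data.frame with columns `qname`, `flag`, `seqname`, `pos`
#'   (0-based leftmost), `mapq`, `cigar`, `seq`.
#' @param seqlengths named integer vector for the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(records, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)),
           sprintf("@PG\tID:retroscape\tPN:retroscape\tVN:%s",
                   as.character(utils::packageVersion("retroscape"))))
  o <- order(match(records$seqname, names(seqlengths)), records$pos)
  records <- records[o, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$seqname,
                  records$pos + 1L, records$mapq, records$cigar, records$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- newick species tree ----------------------------------------------------

#' Read a species tree with divergence times
#'
#' Branch lengths are taken to be in millions of years.  Unnamed internal
#' nodes are labelled `n<k>` so that every edge can be referred to by the
#' label of its child node (its *branch id*).
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object with node labels filled in.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  label_tree_nodes(tree)
}

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

label_tree_nodes <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("species tree needs >= 2 leaves")
  nn <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nn)
  fill <- is.na(lab) | !nzchar(lab)
  lab[fill] <- paste0("n", seq_len(nn))[fill]   # keep labels already present
  tree$node.label <- lab
  tree
}

# all node labels indexed by node number (tips then internals)
tree_node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

# branch ids = child-node labels of every edge, plus a root edge "root"
tree_branch_ids <- function(tree) {
  labs <- tree_node_labels(tree)
  c(labs[tree$edge[, 2L]], "root")
}

# species below a given branch id (the edge above that node); "root" = all
tree_branch_species <- function(tree, branch_id) {
  if (branch_id == "root") return(tree$tip.label)
  labs <- tree_node_labels(tree)
  node <- match(branch_id, labs)
  if (is.na(node)) stop("unknown branch id: ", branch_id)
  if (node <= length(tree$tip.label)) return(labs[node])
  desc <- phangorn_descendants(tree, node)
  labs[desc[desc <= length(tree$tip.label)]]
}

# tip + internal descendants of a node (including itself), plain recursion
phangorn_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  if (!length(kids)) return(node)
  c(node, unlist(lapply(kids, phangorn_descendants, tree = tree)))
}

# ---- BED export -------------------------------------------------------------

#' Export retrocopy calls as BED6
#'
#' `name` is `parental_gene|parental_transcript`; `score` is
#' `round(1000 * identity)`.
#'
#' @param calls a retrocopy call table (see [call_retrocopies()]).
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t%s",
                   calls$seqname, calls$start, calls$end,
                   calls$parental_gene, calls$parental_transcript,
                   as.integer(round(1000 * calls$identity)), calls$strand)
  writeLines(lines, path)
  invisible(path)
}
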