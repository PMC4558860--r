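# Multi-species genome simulator with planted retrocopies.
#
# An ancestral genome with multi-exon protein-coding genes and annotated
# repeat intervals is evolved along a dated species tree by point
# substitution.  On each branch, retrocopies are planted by splicing the
# parental transcript from the branch-start genome (optionally
# 5'-truncated), appending a polyA tail and inserting the copy at a random
# non-genic (optionally intronic) position; descendant species inherit the
# insertion and keep accumulating substitutions.  Ground truth records every
# insertion per species together with its expression and chimeric status.

# genomes are held as integer vectors (1..4 = A,C,G,T) during simulation
INT2BASE <- c("A", "C", "G", "T")

ints_to_string <- function(x) paste(INT2BASE[x], collapse = "")
string_to_ints <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], INT2BASE)
}
revcomp_ints <- function(x) rev(5L - x)

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic multi-species run.  The
#' defaults describe a two-species scenario: 10 Mb genomes, 300 multi-exon
#' genes, 200 planted retrocopies (100 ancestral, 50 per terminal branch)
#' and a substitution rate giving roughly 2% retrocopy-parent divergence for
#' ancestral insertions.
#'
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param species_tree a `phylo` tree with branch lengths in Myr (a root
#'   edge, if present, is the branch named `"root"`), or a newick string.
#' @param genome_length genome size per species, nt.
#' @param n_genes number of multi-exon genes.
#' @param exons_per_gene,exon_length,intron_length integer ranges
#'   `c(min, max)`.
#' @param n_retrocopies_per_branch named integer vector, branch id (child
#'   node label, or `"root"`) to insertion count.
#' @param substitution_rate substitutions per site per Myr.
#' @param truncation_prob probability that a planted copy is 5'-truncated
#'   (by a uniform fraction of up to half the transcript).
#' @param polyA_length range of appended polyA tail lengths, nt.
#' @param repeat_fraction fraction of the genome covered by annotated
#'   repeat intervals.
#' @param repeat_subfamily_weights named numeric vector of subfamily
#'   sampling weights (`L1*` names are class `LINE/L1`, `Alu*` are
#'   `SINE/Alu`).
#' @param x_chromosome_fraction fraction of the genome assigned to the
#'   X-flagged chromosome (`chrX`).
#' @param intragenic_fraction fraction of insertions placed inside host-gene
#'   introns (to exercise chimeric and context logic).
#' @param chimeric_prob probability that an intragenic insertion is marked
#'   as forming a chimeric transcript with its host.
#' @param expressed_fraction probability that an insertion is expressed in
#'   at least one tissue.
#' @param tissues tissue panel used for expression ground truth.
#' @param multi_isoform if `TRUE`, some genes get a second, exon-skipping
#'   isoform (to exercise per-gene merging in detection).
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              species_tree = "(A:5,B:5):5;",
                              genome_length = 10e6,
                              n_genes = 300L,
                              exons_per_gene = c(4L, 8L),
                              exon_length = c(100L, 300L),
                              intron_length = c(500L, 3000L),
                              n_retrocopies_per_branch = c(root = 100L,
                                                           A = 50L, B = 50L),
                              substitution_rate = 0.001,
                              truncation_prob = 0.25,
                              polyA_length = c(10L, 30L),
                              repeat_fraction = 0.10,
                              repeat_subfamily_weights = c(L1PA7 = 0.25,
                                                           L1PA5 = 0.20,
                                                           L1P3 = 0.05,
                                                           L1PA4 = 0.10,
                                                           AluY = 0.25,
                                                           AluSx = 0.15),
                              x_chromosome_fraction = 0.10,
                              intragenic_fraction = 0,
                              chimeric_prob = 0.5,
                              expressed_fraction = 0.3,
                              tissues = c("brain", "cerebellum", "heart",
                                          "liver", "kidney", "testis"),
                              multi_isoform = FALSE) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  species_tree <- label_tree_nodes(species_tree)
  cfg <- list(seed = as.integer(seed), species_tree = species_tree,
              genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              n_retrocopies_per_branch = n_retrocopies_per_branch,
              substitution_rate = substitution_rate,
              truncation_prob = truncation_prob,
              polyA_length = as.integer(polyA_length),
              repeat_fraction = repeat_fraction,
              repeat_subfamily_weights = repeat_subfamily_weights,
              x_chromosome_fraction = x_chromosome_fraction,
              intragenic_fraction = intragenic_fraction,
              chimeric_prob = chimeric_prob,
              expressed_fraction = expressed_fraction,
              tissues = tissues,
              multi_isoform = isTRUE(multi_isoform))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$truncation_prob, cfg$repeat_fraction,
             cfg$x_chromosome_fraction, cfg$intragenic_fraction,
             cfg$chimeric_prob, cfg$expressed_fraction)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$substitution_rate < 0) stop("substitution_rate must be >= 0")
  for (rng in list(cfg$exons_per_gene, cfg$exon_length, cfg$intron_length,
                   cfg$polyA_length)) {
    if (length(rng) != 2L || rng[1L] > rng[2L] || any(rng < 0L))
      stop("ranges must be c(min, max) with 0 <= min <= max")
  }
  if (cfg$exons_per_gene[1L] < 2L)
    stop("genes must be multiexonic (exons_per_gene min >= 2)")
  if (length(cfg$species_tree$tip.label) < 2L)
    stop("species tree needs >= 2 leaves")
  known <- tree_branch_ids(cfg$species_tree)
  unknown <- setdiff(names(cfg$n_retrocopies_per_branch), known)
  if (length(unknown))
    stop("unknown branch id(s) in n_retrocopies_per_branch: ",
         paste(unknown, collapse = ", "))
  invisible(cfg)
}

sample_range <- function(rng, n = 1L) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n)
  else sample(seq.int(rng[1L], rng[2L]), n, replace = TRUE)
}

# apply point substitutions: expected load = rate * myr per site
mutate_genome <- function(genome, rate, myr) {
  p <- min(1, rate * myr)
  if (p <= 0) return(genome)
  for (chrom in names(genome)) {
    L <- length(genome[[chrom]])
    n <- stats::rbinom(1L, L, p)
    if (n == 0L) next
    pos <- sample.int(L, n)
    shift <- sample.int(3L, n, replace = TRUE)
    genome[[chrom]][pos] <- ((genome[[chrom]][pos] - 1L + shift) %% 4L) + 1L
  }
  genome
}

# insert several sequences into one chromosome in a single pass;
# positions are 0-based insertion points (sequence goes before that offset)
multi_insert <- function(chrom, positions, seqs) {
  o <- order(positions)
  positions <- positions[o]; seqs <- seqs[o]
  pieces <- vector("list", 2L * length(positions) + 1L)
  prev <- 0L
  for (i in seq_along(positions)) {
    pieces[[2L * i - 1L]] <- if (positions[i] > prev)
      chrom[(prev + 1L):positions[i]] else integer(0)
    pieces[[2L * i]] <- seqs[[i]]
    prev <- positions[i]
  }
  pieces[[2L * length(positions) + 1L]] <-
    if (prev < length(chrom)) chrom[(prev + 1L):length(chrom)] else integer(0)
  unlist(pieces, use.names = FALSE)
}

# shift a coordinate vector for insertions at `positions` of lengths `lens`;
# a coordinate moves right by every insertion at or before it
shift_coords <- function(x, positions, lens) {
  if (!length(positions)) return(x)
  o <- order(positions)
  positions <- positions[o]; lens <- as.integer(lens[o])
  idx <- findInterval(x, positions)        # number of insertions at or before x
  x + c(0L, cumsum(lens))[idx + 1L]
}

# ---- ancestral genome -------------------------------------------------------

build_ancestor <- function(cfg) {
  Lx <- as.integer(round(cfg$genome_length * cfg$x_chromosome_fraction))
  La <- cfg$genome_length - Lx
  chrom_lens <- c(chrA = La, chrX = Lx)
  chrom_lens <- chrom_lens[chrom_lens > 0L]
  genome <- lapply(chrom_lens, function(L)
    sample.int(4L, L, replace = TRUE))

  # gene placement: rejection sampling against occupied intervals
  occupied <- lapply(genome, function(g) matrix(numeric(0), ncol = 2))
  exon_rows <- list(); cds_rows <- list()
  margin <- 1000L
  for (gi in seq_len(cfg$n_genes)) {
    n_ex <- sample_range(cfg$exons_per_gene)
    ex_len <- sample_range(cfg$exon_length, n_ex)
    in_len <- if (n_ex > 1L) sample_range(cfg$intron_length, n_ex - 1L)
              else integer(0)
    span <- sum(ex_len) + sum(in_len)
    placed <- FALSE
    for (try in 1:200) {
      chrom <- sample(names(genome), 1L,
                      prob = lengths(genome) / sum(lengths(genome)))
      L <- length(genome[[chrom]])
      if (L < span + 2L * margin) next
      s <- sample.int(L - span - 2L * margin, 1L) + margin
      occ <- occupied[[chrom]]
      if (nrow(occ) && any(pmin(occ[, 2], s + span + margin) >
                           pmax(occ[, 1], s - margin))) next
      occupied[[chrom]] <- rbind(occ, c(s - margin, s + span + margin))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("genome too small to host the requested genes (capacity error)")
    strand <- sample(c("+", "-"), 1L)
    starts <- s + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ends <- starts + ex_len
    gid <- sprintf("gene%04d", gi)
    tid <- paste0(gid, ".t1")
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      seqname = chrom, start = starts, end = ends, strand = strand,
      feature = "exon", gene_id = gid, transcript_id = tid,
      stringsAsFactors = FALSE)
    # canonical GT-AG introns in gene orientation
    for (k in seq_len(n_ex - 1L)) {
      is0 <- ends[k]; ie <- starts[k + 1L]      # intron [is0, ie)
      if (strand == "+") {
        genome[[chrom]][is0 + 1:2] <- c(3L, 4L)        # GT
        genome[[chrom]][(ie - 1L):ie] <- c(1L, 3L)     # AG
      } else {
        genome[[chrom]][is0 + 1:2] <- c(2L, 4L)        # CT = rc(AG)
        genome[[chrom]][(ie - 1L):ie] <- c(1L, 2L)     # AC = rc(GT)
      }
    }
    # CDS: transcript positions [30, 30 + 3k) projected onto exons
    tx_len <- sum(ex_len)
    cds_len <- 3L * ((tx_len - 60L) %/% 3L)
    if (cds_len >= 30L) {
      cds_rows[[length(cds_rows) + 1L]] <-
        project_tx_interval(chrom, strand, starts, ends, 30L, 30L + cds_len,
                            gid, tid, "CDS")
    }
    # optional exon-skipping second isoform
    if (cfg$multi_isoform && n_ex >= 4L && stats::runif(1) < 0.3) {
      skip <- sample(2:(n_ex - 1L), 1L)
      keep <- setdiff(seq_len(n_ex), skip)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        seqname = chrom, start = starts[keep], end = ends[keep],
        strand = strand, feature = "exon", gene_id = gid,
        transcript_id = paste0(gid, ".t2"), stringsAsFactors = FALSE)
    }
  }
  genes <- gene_models(do.call(rbind, c(exon_rows, cds_rows)))

  # repeat annotation in intergenic space
  rep_rows <- list()
  target_nt <- cfg$repeat_fraction * sum(lengths(genome))
  acc <- 0
  guard <- 0L
  while (acc < target_nt && guard < 50L * cfg$n_genes + 5000L) {
    guard <- guard + 1L
    chrom <- sample(names(genome), 1L,
                    prob = lengths(genome) / sum(lengths(genome)))
    L <- length(genome[[chrom]])
    len <- sample(300:3000, 1L)
    if (L < len + 2L) next
    s <- sample.int(L - len, 1L)
    occ <- occupied[[chrom]]
    if (nrow(occ) && any(pmin(occ[, 2], s + len) > pmax(occ[, 1], s))) next
    occupied[[chrom]] <- rbind(occ, c(s, s + len))
    subf <- sample(names(cfg$repeat_subfamily_weights), 1L,
                   prob = cfg$repeat_subfamily_weights)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      seqname = chrom, start = s, end = s + len,
      strand = sample(c("+", "-"), 1L), subfamily = subf,
      repeat_class = if (startsWith(subf, "L1")) "LINE/L1" else "SINE/Alu",
      stringsAsFactors = FALSE)
    acc <- acc + len
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(seqname = character(), start = integer(), end = integer(),
               strand = character(), subfamily = character(),
               repeat_class = character(), stringsAsFactors = FALSE)

  list(genome = genome, genes = genes, repeats = repeats,
       retros = empty_retro_table())
}

# project a transcript-coordinate interval [a, b) onto genomic exon pieces
project_tx_interval <- function(chrom, strand, starts, ends, a, b, gid, tid,
                                feature) {
  ex_len <- ends - starts
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends)
                       ex_len <- rev(ex_len) }
  offs <- cumsum(c(0L, head(ex_len, -1L)))
  out <- list()
  for (i in seq_along(starts)) {
    lo <- max(a, offs[i]); hi <- min(b, offs[i] + ex_len[i])
    if (lo >= hi) next
    if (strand == "+") {
      gs <- starts[i] + (lo - offs[i]); ge <- starts[i] + (hi - offs[i])
    } else {
      ge <- ends[i] - (lo - offs[i]); gs <- ends[i] - (hi - offs[i])
    }
    out[[length(out) + 1L]] <- data.frame(
      seqname = chrom, start = gs, end = ge, strand = strand,
      feature = feature, gene_id = gid, transcript_id = tid,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_retro_table <- function() {
  data.frame(retro_id = character(), seqname = character(),
             start = integer(), end = integer(), strand = character(),
             parental_gene = character(), parental_transcript = character(),
             origin_branch = character(), truncation_nt = integer(),
             intragenic_host = character(), chimeric = logical(),
             stringsAsFactors = FALSE)
}

# ---- planting ---------------------------------------------------------------

# plant `n` retrocopies into `state` at the start of branch `branch_id`;
# returns list(state, new_records, expression_rows)
plant_retrocopies <- function(state, n, branch_id, cfg, id_offset) {
  if (n == 0L)
    return(list(state = state, records = empty_retro_table(),
                expression = NULL))
  spans <- gene_spans(state$genes)
  exon_df <- state$genes[state$genes$feature == "exon", , drop = FALSE]
  recs <- list(); expr <- list()
  per_chrom_ins <- lapply(state$genome, function(x) list(pos = integer(0),
                                                         seqs = list()))
  pending <- list()
  for (i in seq_len(n)) {
    gid <- sample(unique(spans$gene_id), 1L)
    tids <- unique(state$genes$transcript_id[
      state$genes$gene_id == gid & state$genes$feature == "exon"])
    tid <- tids[1L]                          # canonical isoform is copied
    ex <- transcript_exons(state$genes, tid)
    # transcript_exons rows are already 5'->3'; for minus-strand genes each
    # genomic piece is reverse-complemented in place
    parts <- lapply(seq_len(nrow(ex)), function(k)
      state$genome[[ex$seqname[k]]][(ex$start[k] + 1L):ex$end[k]])
    if (ex$strand[1L] == "-") parts <- lapply(parts, revcomp_ints)
    tx <- unlist(parts, use.names = FALSE)
    trunc_nt <- 0L
    if (stats::runif(1) < cfg$truncation_prob) {
      trunc_nt <- as.integer(floor(stats::runif(1, 0, 0.5) * length(tx)))
      if (trunc_nt > 0L) tx <- tx[-seq_len(trunc_nt)]
    }
    polyA <- rep(1L, sample_range(cfg$polyA_length))
    ins_strand <- sample(c("+", "-"), 1L)
    body <- c(tx, polyA)
    ins_seq <- if (ins_strand == "+") body else revcomp_ints(body)
    intragenic <- stats::runif(1) < cfg$intragenic_fraction
    site <- choose_insertion_site(state, per_chrom_ins, length(ins_seq),
                                  intragenic, spans, exon_df)
    if (is.null(site))
      stop("genome too small to host requested insertions (capacity error)")
    chimeric <- intragenic && !is.na(site$host) &&
      stats::runif(1) < cfg$chimeric_prob
    pending[[i]] <- list(chrom = site$chrom, pos = site$pos, seq = ins_seq,
                         host = site$host, chimeric = chimeric)
    per_chrom_ins[[site$chrom]]$pos <-
      c(per_chrom_ins[[site$chrom]]$pos, site$pos)
    per_chrom_ins[[site$chrom]]$seqs <-
      c(per_chrom_ins[[site$chrom]]$seqs, list(ins_seq))
    rid <- sprintf("retro%05d", id_offset + i)
    recs[[i]] <- data.frame(
      retro_id = rid, seqname = site$chrom, start = site$pos,
      end = site$pos + length(ins_seq), strand = ins_strand,
      parental_gene = gid, parental_transcript = tid,
      origin_branch = branch_id, truncation_nt = trunc_nt,
      intragenic_host = ifelse(is.na(site$host), NA_character_, site$host),
      chimeric = chimeric, stringsAsFactors = FALSE)
    # expression ground truth, decided once per insertion event
    expressed <- stats::runif(1) < cfg$expressed_fraction
    lev <- numeric(length(cfg$tissues)); names(lev) <- cfg$tissues
    if (expressed) {
      k <- sample.int(length(cfg$tissues), 1L)
      on <- sample(cfg$tissues, k)
      lev[on] <- stats::runif(length(on), 0.5, 2)
    }
    expr[[i]] <- data.frame(retro_id = rid, tissue = cfg$tissues,
                            level = unname(lev), stringsAsFactors = FALSE)
  }
  # chimeric acceptor enforcement happens on the pre-insertion genome
  for (p in pending) {
    if (!p$chimeric) next
    host_strand <- spans$strand[spans$gene_id == p$host][1L]
    if (host_strand == "+") {
      state$genome[[p$chrom]][(p$pos - 1L):p$pos] <- c(1L, 3L)   # AG before
    }  # minus-strand hosts handled after insertion (bases after the copy)
  }
  # apply all insertions chromosome by chromosome
  new_recs <- do.call(rbind, recs)
  for (chrom in names(per_chrom_ins)) {
    ci <- per_chrom_ins[[chrom]]
    if (!length(ci$pos)) next
    state$genome[[chrom]] <- multi_insert(state$genome[[chrom]], ci$pos,
                                          ci$seqs)
    lens <- lengths(ci$seqs)
    sel <- state$genes$seqname == chrom
    state$genes$start[sel] <- shift_coords(state$genes$start[sel], ci$pos, lens)
    state$genes$end[sel] <- shift_coords(state$genes$end[sel] - 1L, ci$pos,
                                         lens) + 1L
    sel <- state$repeats$seqname == chrom
    if (any(sel)) {
      state$repeats$start[sel] <- shift_coords(state$repeats$start[sel],
                                               ci$pos, lens)
      state$repeats$end[sel] <- shift_coords(state$repeats$end[sel] - 1L,
                                             ci$pos, lens) + 1L
    }
    sel <- state$retros$seqname == chrom
    if (any(sel)) {
      state$retros$start[sel] <- shift_coords(state$retros$start[sel],
                                              ci$pos, lens)
      state$retros$end[sel] <- shift_coords(state$retros$end[sel] - 1L,
                                            ci$pos, lens) + 1L
    }
    # and the new records themselves (earlier insertions shift later ones)
    sel <- new_recs$seqname == chrom
    other <- ci$pos
    for (ri in which(sel)) {
      before <- other < new_recs$start[ri]
      delta <- sum(lens[before])
      new_recs$start[ri] <- new_recs$start[ri] + delta
      new_recs$end[ri] <- new_recs$end[ri] + delta
    }
  }
  # minus-strand chimeric hosts: acceptor (host orientation) sits just
  # 3' of the insertion on the genomic plus strand, i.e. right after it
  for (ri in seq_len(nrow(new_recs))) {
    p <- pending[[ri]]
    if (!p$chimeric) next
    host_strand <- spans$strand[spans$gene_id == p$host][1L]
    if (host_strand == "-") {
      e <- new_recs$end[ri]
      state$genome[[new_recs$seqname[ri]]][(e + 1L):(e + 2L)] <- c(2L, 4L) # CT
    }
  }
  state$retros <- rbind(state$retros, new_recs)
  list(state = state, records = new_recs,
       expression = do.call(rbind, expr))
}

choose_insertion_site <- function(state, per_chrom_ins, ins_len, intragenic,
                                  spans, exon_df) {
  margin <- 200L
  if (intragenic) {
    for (try in 1:200) {
      gid <- sample(spans$gene_id, 1L)
      ex <- exon_df[exon_df$gene_id == gid, , drop = FALSE]
      ex <- ex[ex$transcript_id == ex$transcript_id[1L], , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) < 2L) next
      k <- if (nrow(ex) == 2L) 1L else sample.int(nrow(ex) - 1L, 1L)
      is0 <- ex$end[k]; ie <- ex$start[k + 1L]
      if (ie - is0 < 320L) next
      pos <- sample(seq.int(is0 + 150L, ie - 150L), 1L)
      if (site_clear(state, per_chrom_ins, spans, exon_df, ex$seqname[1L],
                     pos, margin, skip_genes = TRUE)) {
        return(list(chrom = ex$seqname[1L], pos = pos, host = gid))
      }
    }
    return(NULL)
  }
  for (try in 1:500) {
    chrom <- sample(names(state$genome), 1L,
                    prob = lengths(state$genome) / sum(lengths(state$genome)))
    L <- length(state$genome[[chrom]])
    if (L < 2L * margin + 10L) next
    pos <- sample.int(L - 2L * margin, 1L) + margin
    if (site_clear(state, per_chrom_ins, spans, exon_df, chrom, pos, margin)) {
      return(list(chrom = chrom, pos = pos, host = NA_character_))
    }
  }
  NULL
}

site_clear <- function(state, per_chrom_ins, spans, exon_df, chrom, pos,
                       margin, skip_genes = FALSE) {
  if (!skip_genes) {
    sp <- spans[spans$seqname == chrom, , drop = FALSE]
    if (nrow(sp) && any(pos > sp$start - margin & pos < sp$end + margin))
      return(FALSE)
  } else {
    # intragenic: still keep out of exons
    e <- exon_df[exon_df$seqname == chrom, , drop = FALSE]
    if (any(pos > e$start - 50L & pos < e$end + 50L)) return(FALSE)
  }
  r <- state$repeats[state$repeats$seqname == chrom, , drop = FALSE]
  if (nrow(r) && any(pos > r$start - margin & pos < r$end + margin))
    return(FALSE)
  rt <- state$retros[state$retros$seqname == chrom, , drop = FALSE]
  if (nrow(rt) && any(pos > rt$start - margin & pos < rt$end + margin))
    return(FALSE)
  prior <- per_chrom_ins[[chrom]]$pos
  if (length(prior) && any(abs(prior - pos) < margin + 100L)) return(FALSE)
  TRUE
}

# ---- tree walk --------------------------------------------------------------

#' Simulate multi-species genomes with planted retrocopies
#'
#' Evolves an ancestral genome along the configured species tree and plants
#' the configured number of retrocopies on each branch.  See
#' [simulation_config()] for the knobs.
#'
#' @param config a [simulation_config()].
#' @return a list of class `retro_simulation`:
#'   * `species`: per species, `genome` (named character vector),
#'     `gene_models`, `repeats`;
#'   * `ground_truth`: `retrocopies` (per-species planted records),
#'     `expression` (per insertion x tissue levels), `gene_expression`;
#'   * `tree`, `config`.
#' @export
simulate_species <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  tree <- config$species_tree
  anc <- build_ancestor(config)
  nb <- config$n_retrocopies_per_branch
  get_n <- function(b) if (b %in% names(nb)) as.integer(nb[[b]]) else 0L
  counter <- new.env(); counter$id <- 0L
  expr_rows <- list()

  plant_and_mutate <- function(state, branch_id, myr) {
    res <- plant_retrocopies(state, get_n(branch_id), branch_id, config,
                             counter$id)
    counter$id <- counter$id + get_n(branch_id)
    if (!is.null(res$expression))
      expr_rows[[length(expr_rows) + 1L]] <<- res$expression
    st <- res$state
    st$genome <- mutate_genome(st$genome, config$substitution_rate, myr)
    st
  }

  root_len <- config$species_tree$root.edge %||% 0
  state0 <- plant_and_mutate(anc, "root", root_len)

  labs <- tree_node_labels(tree)
  species_states <- list()
  walk <- function(node, state) {
    kids <- which(tree$edge[, 1L] == node)
    if (!length(kids)) {
      species_states[[labs[node]]] <<- state
      return(invisible())
    }
    for (e in kids) {
      child <- tree$edge[e, 2L]
      st <- plant_and_mutate(state, labs[child], tree$edge.length[e])
      walk(child, st)
    }
  }
  root_node <- length(tree$tip.label) + 1L
  walk(root_node, state0)

  # finalize: stringify genomes, attach species column to ground truth
  gt_rows <- list()
  species <- list()
  for (sp in tree$tip.label) {
    st <- species_states[[sp]]
    genome_chr <- vapply(st$genome, ints_to_string, character(1L))
    rt <- st$retros
    if (nrow(rt)) {
      rt$species <- sp
      rt$chimeric <- rt$chimeric & verify_chimeric(st, rt)
    }
    gt_rows[[sp]] <- rt
    species[[sp]] <- list(genome = genome_chr, gene_models = st$genes,
                          repeats = st$repeats)
  }
  gt <- do.call(rbind, gt_rows)
  rownames(gt) <- NULL
  expression <- if (length(expr_rows)) do.call(rbind, expr_rows) else
    data.frame(retro_id = character(), tissue = character(),
               level = numeric(), stringsAsFactors = FALSE)
  rownames(expression) <- NULL
  # host/parental gene expression levels (per species-independent gene id)
  gene_ids <- unique(anc$genes$gene_id)
  gene_expression <- data.frame(
    gene_id = rep(gene_ids, each = length(config$tissues)),
    tissue = rep(config$tissues, length(gene_ids)),
    level = stats::runif(length(gene_ids) * length(config$tissues), 0.25, 4),
    stringsAsFactors = FALSE)
  structure(list(species = species,
                 ground_truth = list(retrocopies = gt,
                                     expression = expression,
                                     gene_expression = gene_expression),
                 tree = tree, config = config),
            class = "retro_simulation")
}

# a chimeric mark survives only if the splice signals are still canonical
# at the tip: donor GT after the host exon and acceptor AG just before the
# retrocopy, both in host orientation
verify_chimeric <- function(state, rt) {
  ok <- logical(nrow(rt))
  spans <- gene_spans(state$genes)
  for (i in seq_len(nrow(rt))) {
    if (!rt$chimeric[i] || is.na(rt$intragenic_host[i])) { ok[i] <- FALSE; next }
    host <- rt$intragenic_host[i]
    hs <- spans$strand[spans$gene_id == host][1L]
    g <- state$genome[[rt$seqname[i]]]
    ex <- state$genes[state$genes$gene_id == host &
                        state$genes$feature == "exon", , drop = FALSE]
    if (hs == "+") {
      don <- max(ex$end[ex$end <= rt$start[i]])
      ok[i] <- all(g[don + 1:2] == c(3L, 4L)) &&
        all(g[(rt$start[i] - 1L):rt$start[i]] == c(1L, 3L))
    } else {
      don <- min(ex$start[ex$start >= rt$end[i]])
      ok[i] <- all(g[(don - 1L):don] == c(1L, 2L)) &&      # AC = rc(GT)
        all(g[(rt$end[i] + 1L):(rt$end[i] + 2L)] == c(2L, 4L))  # CT = rc(AG)
    }
  }
  ok
}

#' @export
print.retro_simulation <- function(x, ...) {
  cat(sprintf("<retro_simulation> %d species, %d planted insertions\n",
              length(x$species),
              length(unique(x$ground_truth$retrocopies$retro_id))))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits, per species, genome FASTA, gene-model GTF and RepeatMasker-style
#' .out, plus the species tree (newick) and the ground-truth tables (TSV).
#'
#' @param sim a [simulate_species()] result.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    s <- sim$species[[sp]]
    write_genome_fasta(s$genome, file.path(dir, paste0(sp, ".fa")))
    write_gtf(s$gene_models, file.path(dir, paste0(sp, ".gtf")))
    write_repeatmasker(s$repeats, file.path(dir, paste0(sp, ".rm.out")))
    tx <- unique(s$gene_models$transcript_id[s$gene_models$feature == "exon"])
    seqs <- vapply(tx, transcript_sequence, character(1L),
                   gm = s$gene_models, genome = s$genome)
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(sp, ".tx.fa")))
  }
  write_newick(sim$tree, file.path(dir, "species.nwk"))
  write_tsv_with_header(sim$ground_truth$retrocopies,
                        file.path(dir, "ground_truth_retrocopies.tsv"),
                        extra = "planted retrocopy records, 0-based half-open")
  write_tsv_with_header(sim$ground_truth$expression,
                        file.path(dir, "ground_truth_expression.tsv"),
                        extra = "per-insertion per-tissue expression levels")
  invisible(dir)
}

# ---- read simulation --------------------------------------------------------

#' Simulate tissue-stratified RNA-seq-like read alignments
#'
#' Generates uniform-coverage, error-free reads over every transcript and
#' retrocopy flagged expressed in the ground truth, including spliced reads
#' (CIGAR `N` over introns) for host genes and host-retrocopy chimeric
#' junction reads with canonical GT-AG intron interiors on the reference.
#' Unexpressed loci receive no dedicated reads.
#'
#' @param sim a [simulate_species()] result.
#' @param species species (tip label) to simulate reads for.
#' @param tissues tissue names; must be a subset of the ground-truth panel.
#' @param depth mean per-base coverage of an expressed locus at level 1.
#' @param seed integer seed (reads are deterministic given the seed).
#' @param read_length read length, nt.
#' @param n_chimeric_reads junction reads generated per chimeric event and
#'   expressed tissue.
#' @return named list, one element per tissue, each a data.frame of SAM
#'   records (see [write_sam()]) with attribute `seqlengths`.
#' @export
simulate_reads <- function(sim, species, tissues = sim$config$tissues,
                           depth = 30, seed = 1L, read_length = 100L,
                           n_chimeric_reads = 8L) {
  if (depth <= 0) stop("depth must be > 0")
  known <- unique(sim$ground_truth$expression$tissue)
  bad <- setdiff(tissues, known)
  if (length(bad)) stop("unknown tissue name(s): ", paste(bad, collapse = ", "))
  if (!species %in% names(sim$species)) stop("unknown species: ", species)
  set.seed(seed)
  s <- sim$species[[species]]
  genome <- s$genome
  gm <- s$gene_models
  seqlengths <- vapply(genome, nchar, integer(1L))
  gt <- sim$ground_truth$retrocopies
  gt <- gt[gt$species == species, , drop = FALSE]
  expr <- sim$ground_truth$expression
  gexpr <- sim$ground_truth$gene_expression
  out <- list()
  for (tis in tissues) {
    recs <- list()
    rid <- 0L
    # gene reads (spliced)
    glev <- gexpr[gexpr$tissue == tis, , drop = FALSE]
    for (gi in seq_len(nrow(glev))) {
      lev <- glev$level[gi]
      if (lev <= 0) next
      tids <- unique(gm$transcript_id[gm$gene_id == glev$gene_id[gi] &
                                        gm$feature == "exon"])
      tid <- tids[1L]
      r <- transcript_reads(gm, tid, genome, lev * depth, read_length)
      if (!is.null(r)) { rid <- rid + 1L
        r$qname <- sprintf("%s_%s_g%05d_%s", species, tis, rid, r$qname)
        recs[[length(recs) + 1L]] <- r }
    }
    # retrocopy reads (contiguous)
    for (ri in seq_len(nrow(gt))) {
      lev <- expr$level[expr$retro_id == gt$retro_id[ri] &
                          expr$tissue == tis]
      if (!length(lev) || lev <= 0) next
      r <- locus_reads(genome, gt$seqname[ri], gt$start[ri], gt$end[ri],
                       lev * depth, read_length)
      if (!is.null(r)) {
        r$qname <- sprintf("%s_%s_%s_%s", species, tis, gt$retro_id[ri],
                           r$qname)
        recs[[length(recs) + 1L]] <- r
      }
      # chimeric junction reads
      if (isTRUE(gt$chimeric[ri])) {
        cr <- chimeric_reads(gm, genome, gt[ri, ], read_length,
                             n_chimeric_reads)
        if (!is.null(cr)) recs[[length(recs) + 1L]] <- cr
      }
    }
    df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(qname = character(), flag = integer(), seqname = character(),
                 pos = integer(), mapq = integer(), cigar = character(),
                 seq = character(), stringsAsFactors = FALSE)
    attr(df, "seqlengths") <- seqlengths
    out[[tis]] <- df
  }
  out
}

# uniform reads over a spliced transcript, mapped back through the introns
transcript_reads <- function(gm, tid, genome, cov, read_length) {
  e <- transcript_exons(gm, tid)
  tx_len <- sum(e$end - e$start)
  if (tx_len < read_length) return(NULL)
  n <- max(1L, as.integer(round(cov * tx_len / read_length)))
  starts <- sample.int(tx_len - read_length + 1L, n, replace = TRUE) - 1L
  strand <- e$strand[1L]
  chrom_name <- e$seqname[1L]
  chrom <- genome[[chrom_name]]
  # exon walk in genomic (plus-strand) order with transcript offsets:
  # tx_lo[i] = transcript coordinate of the genomic-leftmost base of exon i
  eg <- e[order(e$start), , drop = FALSE]
  lens <- eg$end - eg$start
  tx_lo <- if (strand == "+") cumsum(c(0L, head(lens, -1L)))
           else rev(cumsum(c(0L, head(rev(lens), -1L))))
  tx_hi <- tx_lo + lens
  pos <- integer(n); cig <- character(n); seqv <- character(n)
  for (i in seq_len(n)) {
    a <- starts[i]; b <- a + read_length
    js <- which(tx_hi > a & tx_lo < b)
    lo <- pmax(a, tx_lo[js]); hi <- pmin(b, tx_hi[js])
    if (strand == "+") {
      gs <- eg$start[js] + (lo - tx_lo[js]); ge <- eg$start[js] + (hi - tx_lo[js])
    } else {
      ge <- eg$end[js] - (lo - tx_lo[js]); gs <- eg$end[js] - (hi - tx_lo[js])
    }
    o <- order(gs); gs <- gs[o]; ge <- ge[o]
    m <- length(gs)
    parts <- sprintf("%dM", ge - gs)
    if (m > 1L) {
      gapped <- sprintf("%dN%s", gs[-1L] - ge[-m], parts[-1L])
      cig[i] <- paste0(parts[1L], paste(gapped, collapse = ""))
    } else cig[i] <- parts[1L]
    pos[i] <- gs[1L]
    seqv[i] <- paste(substring(chrom, gs + 1L, ge), collapse = "")
  }
  data.frame(qname = sprintf("r%06d", seq_len(n)),
             flag = if (strand == "+") 0L else 16L,
             seqname = chrom_name, pos = pos, mapq = 60L, cigar = cig,
             seq = seqv, stringsAsFactors = FALSE)
}

locus_reads <- function(genome, chrom, start, end, cov, read_length) {
  len <- end - start
  if (len < read_length) return(NULL)
  n <- max(1L, as.integer(round(cov * len / read_length)))
  pos <- start + sample.int(len - read_length + 1L, n, replace = TRUE) - 1L
  data.frame(qname = sprintf("r%06d", seq_len(n)), flag = 0L, seqname = chrom,
             pos = pos, mapq = 60L, cigar = sprintf("%dM", read_length),
             seq = substring(genome[[chrom]], pos + 1L, pos + read_length),
             stringsAsFactors = FALSE)
}

# junction reads spanning host-exon donor -> retrocopy acceptor
chimeric_reads <- function(gm, genome, rt, read_length, n_reads) {
  ex <- gm[gm$gene_id == rt$intragenic_host & gm$feature == "exon", ,
           drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  hs <- ex$strand[1L]
  chrom <- rt$seqname
  rows <- list()
  for (i in seq_len(n_reads)) {
    a <- sample(20:(read_length - 20L), 1L)   # host-side bases
    b <- read_length - a
    if (hs == "+") {
      don <- max(ex$end[ex$end <= rt$start])
      b1 <- c(don - a, don); b2 <- c(rt$start, rt$start + b)
    } else {
      don <- min(ex$start[ex$start >= rt$end])
      b1 <- c(rt$end - b, rt$end); b2 <- c(don, don + a)
    }
    gapn <- b2[1L] - b1[2L]
    if (gapn < 4L) return(NULL)
    seq <- paste0(substring(genome[[chrom]], b1[1L] + 1L, b1[2L]),
                  substring(genome[[chrom]], b2[1L] + 1L, b2[2L]))
    rows[[i]] <- data.frame(
      qname = sprintf("%s_chim%03d", rt$retro_id, i),
      flag = if (hs == "+") 0L else 16L, seqname = chrom, pos = b1[1L],
      mapq = 60L,
      cigar = sprintf("%dM%dN%dM", b1[2L] - b1[1L], gapn, b2[2L] - b2[1L]),
      seq = seq, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
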