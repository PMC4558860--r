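# Cross-species retrocopy orthology from flanking-sequence synteny.
#
# Two insertions in different species descend from one ancestral event iff
# they carry the same parental gene and their non-repetitive flanking
# sequence aligns (shared synteny).  Shared calls are grouped, dated by the
# tree branch above the most recent common ancestor of the presence
# pattern, and per-branch origination/fixation rates computed against a
# divergence-time table.

#' Add stable call ids to a call table
#'
#' @param calls a call table (see [call_retrocopies()]).
#' @param species species name recorded with each id.
#' @return the table with `call_id` and `species` columns.
#' @export
add_call_ids <- function(calls, species) {
  calls$species <- species
  calls$call_id <- sprintf("%s:%s:%d-%d", species, calls$seqname,
                           calls$start, calls$end)
  calls
}

#' Extract a flank signature for one retrocopy call
#'
#' Scanning outward from each edge of the locus (starting `search_offset`
#' nt beyond it, plus a guard band covering the unaligned query remainder),
#' maximal non-repeat runs of at least `min_block` nt are collected until
#' `flank_total` nt per side are accumulated or the chromosome ends.
#'
#' @param call one row of a call table.
#' @param genome named character vector of chromosome sequences.
#' @param repeats repeat annotation (see [read_repeatmasker()]).
#' @param flank_total per-side flank budget, nt (default 3000).
#' @param min_block minimum non-repetitive block length, nt (default 150).
#' @param search_offset nt skipped beyond the retrocopy edge before the
#'   block search begins (0 by default; 5000 available as a conservative
#'   preset against under-annotated retrocopy ends).
#' @return a list of class `flank_signature`: `call_id`, `upstream` and
#'   `downstream` block data.frames (`start`, `end`, `seq`) ordered nearest
#'   first, and `empty_side` flags.
#' @export
extract_flanks <- function(call, genome, repeats, flank_total = 3000L,
                           min_block = 150L, search_offset = 0L) {
  chrom <- call$seqname
  L <- nchar(genome[[chrom]])
  guard <- 0L
  if (!is.null(call$query_coverage) && !is.null(call$aligned_nt) &&
      call$query_coverage > 0) {
    guard <- max(0L, as.integer(round(call$aligned_nt / call$query_coverage)) -
                   as.integer(call$aligned_nt))
  }
  off <- as.integer(search_offset) + guard
  rep_iv <- repeats[repeats$seqname == chrom, c("start", "end"), drop = FALSE]
  up <- collect_flank_blocks(genome[[chrom]], rep_iv,
                             edge = call$start - off, direction = -1L,
                             flank_total, min_block)
  dn <- collect_flank_blocks(genome[[chrom]], rep_iv,
                             edge = call$end + off, direction = 1L,
                             flank_total, min_block, L = L)
  structure(list(call_id = call$call_id %||% NA_character_,
                 upstream = up, downstream = dn,
                 empty_side = c(upstream = nrow(up) == 0L,
                                downstream = nrow(dn) == 0L)),
            class = "flank_signature")
}

# maximal clean (non-repeat) runs on one side of `edge`, nearest first
collect_flank_blocks <- function(chrom_seq, rep_iv, edge, direction,
                                 flank_total, min_block, L = nchar(chrom_seq)) {
  lo <- if (direction < 0L) 0L else min(edge, L)
  hi <- if (direction < 0L) max(edge, 0L) else L
  if (hi <= lo)
    return(data.frame(start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  # clean intervals = [lo, hi) minus repeat intervals
  if (nrow(rep_iv)) {
    iv <- rep_iv[rep_iv$end > lo & rep_iv$start < hi, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    starts <- c(lo, pmin(hi, pmax(lo, iv$end)))
    ends <- c(pmin(hi, pmax(lo, iv$start)), hi)
    clean <- data.frame(start = starts, end = ends)
    clean <- clean[clean$end > clean$start, , drop = FALSE]
    clean <- clean[order(clean$start), , drop = FALSE]
    # merge any touching pieces (overlapping repeats)
    if (nrow(clean) > 1L) {
      keep <- c(TRUE, clean$start[-1L] >= cummax(clean$end[-nrow(clean)]))
      clean <- clean[keep, , drop = FALSE]
    }
  } else {
    clean <- data.frame(start = lo, end = hi)
  }
  if (direction < 0L) clean <- clean[order(-clean$start), , drop = FALSE]
  acc <- 0L
  out <- list()
  for (i in seq_len(nrow(clean))) {
    s <- clean$start[i]; e <- clean$end[i]
    if (e - s < min_block) next
    remaining <- flank_total - acc
    if (remaining <= 0L) break
    if (e - s > remaining) {     # clip on the side nearest the retrocopy
      if (direction < 0L) s <- e - remaining else e <- s + remaining
    }
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e,
      seq = substring(chrom_seq, s + 1L, e), stringsAsFactors = FALSE)
    acc <- acc + (e - s)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Match orthologous retrocopies between two species
#'
#' A pair is orthologous iff both calls share the parental gene and the
#' flank blocks of one align to the region around the other, covering at
#' least `min_flank_fraction` of the collected flank nt at
#' `min_flank_identity` or better, on at least one side.  Pairing is
#' one-to-one per species pair: best flank coverage wins, ties broken by
#' identity.
#'
#' @param calls_a,calls_b call tables with ids (see [add_call_ids()]).
#' @param flanks_a list of [extract_flanks()] signatures for `calls_a`,
#'   parallel to its rows.
#' @param genome_b genome of species B (named character vector).
#' @param min_flank_fraction,min_flank_identity matching thresholds.
#' @param window nt of genome B around each candidate locus searched.
#' @return data.frame of matched pairs: `call_a`, `call_b`, `coverage`,
#'   `identity`, `side`.
#' @export
match_orthologs <- function(calls_a, calls_b, flanks_a, genome_b,
                            min_flank_fraction = 0.5,
                            min_flank_identity = 0.7,
                            window = 15000L) {
  cand <- list()
  for (i in seq_len(nrow(calls_a))) {
    js <- which(calls_b$parental_gene == calls_a$parental_gene[i])
    for (j in js) {
      m <- flank_match_score(flanks_a[[i]], calls_b[j, ], genome_b, window)
      if (is.null(m)) next
      if (m$coverage >= min_flank_fraction &&
          m$identity >= min_flank_identity) {
        cand[[length(cand) + 1L]] <- data.frame(
          call_a = calls_a$call_id[i], call_b = calls_b$call_id[j],
          coverage = m$coverage, identity = m$identity, side = m$side,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(data.frame(call_a = character(), call_b = character(),
                      coverage = numeric(), identity = numeric(),
                      side = character(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  # greedy 1-to-1 assignment by coverage then identity
  cand <- cand[order(-cand$coverage, -cand$identity), , drop = FALSE]
  used_b <- character(0)
  sel <- logical(nrow(cand))
  used_a <- character(0)
  for (r in seq_len(nrow(cand))) {
    if (cand$call_a[r] %in% used_a || cand$call_b[r] %in% used_b) next
    sel[r] <- TRUE
    used_a <- c(used_a, cand$call_a[r])
    used_b <- c(used_b, cand$call_b[r])
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best per-side flank alignment of signature `fa` around call `cb`
flank_match_score <- function(fa, cb, genome_b, window) {
  chrom <- genome_b[[cb$seqname]]
  lo <- max(0L, cb$start - window)
  hi <- min(nchar(chrom), cb$end + window)
  target <- substring(chrom, lo + 1L, hi)
  best <- NULL
  for (side in c("upstream", "downstream")) {
    blocks <- fa[[side]]
    if (!nrow(blocks)) next
    total <- sum(nchar(blocks$seq))
    raw <- cpp_align(target, blocks$seq, k = 12L,
                     maxocc = 256L, min_matches = 30L, max_tgap = 20000L)
    if (!length(raw)) next
    # best chain per block, then pooled coverage/identity
    per_block <- split(raw, vapply(raw, function(r) r$qid, integer(1L)))
    matches <- 0L; mism <- 0L
    for (pb in per_block) {
      sc <- vapply(pb, function(r) r$matches, integer(1L))
      bsti <- which.max(sc)
      matches <- matches + pb[[bsti]]$matches
      mism <- mism + pb[[bsti]]$mismatches
    }
    cov <- (matches + mism) / total
    idn <- if (matches + mism > 0) matches / (matches + mism) else 0
    if (is.null(best) || cov > best$coverage ||
        (cov == best$coverage && idn > best$identity)) {
      best <- list(coverage = cov, identity = idn, side = side)
    }
  }
  best
}

#' Group pairwise matches into orthology groups
#'
#' Groups are the connected components of the pairwise match graph (split
#' if members disagree on the parental gene); the origin branch is the tree
#' edge above the most recent common ancestor of the presence pattern
#' (Dollo-style: losses allowed but not modelled).  Calls matched to no
#' other species are species-specific and dated to their terminal branch.
#'
#' @param matches list of pairwise match tables from [match_orthologs()].
#' @param calls_by_species named list (species to call table with ids).
#' @param tree the species tree (`phylo`; see [read_newick()]).
#' @return a list with `groups` (group_id, parental_gene, origin_branch,
#'   n_species, species, members, discordant) and `species_specific`
#'   (call_id, species, parental_gene, origin_branch).
#' @export
build_groups <- function(matches, calls_by_species, tree) {
  tree <- label_tree_nodes(tree)
  all_calls <- do.call(rbind, lapply(calls_by_species, function(x)
    x[, c("call_id", "species", "parental_gene"), drop = FALSE]))
  rownames(all_calls) <- NULL
  edges <- do.call(rbind, lapply(matches, function(m)
    m[, c("call_a", "call_b"), drop = FALSE]))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(all_calls), name = all_calls$call_id)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  comp <- igraph::components(g)$membership
  all_calls$component <- comp[all_calls$call_id]
  # split components whose members disagree on the parental gene
  all_calls$grp_key <- paste(all_calls$component, all_calls$parental_gene)
  grp_rows <- list(); sp_rows <- list()
  gid <- 0L
  for (key in unique(all_calls$grp_key)) {
    mem <- all_calls[all_calls$grp_key == key, , drop = FALSE]
    sps <- unique(mem$species)
    if (length(sps) == 1L) {
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        call_id = mem$call_id, species = mem$species,
        parental_gene = mem$parental_gene,
        origin_branch = mem$species, stringsAsFactors = FALSE)
      next
    }
    gid <- gid + 1L
    branch <- mrca_branch(tree, sps)
    full <- tree_branch_species(tree, branch)
    grp_rows[[length(grp_rows) + 1L]] <- data.frame(
      group_id = sprintf("og%05d", gid),
      parental_gene = mem$parental_gene[1L],
      origin_branch = branch, n_species = length(sps),
      species = paste(sort(sps), collapse = ","),
      members = paste(sort(mem$call_id), collapse = ","),
      discordant = !setequal(sps, full), stringsAsFactors = FALSE)
  }
  groups <- if (length(grp_rows)) do.call(rbind, grp_rows) else
    data.frame(group_id = character(), parental_gene = character(),
               origin_branch = character(), n_species = integer(),
               species = character(), members = character(),
               discordant = logical(), stringsAsFactors = FALSE)
  species_specific <- if (length(sp_rows)) do.call(rbind, sp_rows) else
    data.frame(call_id = character(), species = character(),
               parental_gene = character(), origin_branch = character(),
               stringsAsFactors = FALSE)
  rownames(groups) <- rownames(species_specific) <- NULL
  list(groups = groups, species_specific = species_specific)
}

# branch id of the edge above the MRCA of a species set
mrca_branch <- function(tree, species) {
  labs <- tree_node_labels(tree)
  if (length(species) == 1L) return(species)
  node <- ape::getMRCA(tree, species)
  root <- length(tree$tip.label) + 1L
  if (node == root) "root" else labs[node]
}

#' Retrocopy origination/fixation rate on a branch
#'
#' @param n_retrocopies insertions dated to the branch.
#' @param duration_myr branch duration, Myr.
#' @return retrocopies per Myr (unrounded; reporting rounds).
#' @export
branch_rate <- function(n_retrocopies, duration_myr) {
  if (any(duration_myr <= 0)) stop("duration_myr must be > 0")
  n_retrocopies / duration_myr
}

#' X-chromosome flux test
#'
#' Counts, within a designated subset of calls, migrations out of the X
#' (parent on X, insertion autosomal) and into the X (parent autosomal,
#' insertion on X).  Expected counts come from the corresponding
#' proportions among all calls outside the subset; p-values are one-sided
#' binomial.
#'
#' @param calls a call table with `on_x` and `parent_on_x` flags.
#' @param subset logical vector (or call_id vector) designating the subset.
#' @return a list: `n_out_of_x`, `n_into_x`, `expected_out`, `expected_into`,
#'   `p_out`, `p_into`.
#' @export
x_flux_test <- function(calls, subset) {
  if (!is.logical(subset)) subset <- calls$call_id %in% subset
  if (!any(subset)) stop("designated subset is empty")
  if (all(subset)) stop("no background calls outside the subset")
  n <- sum(subset)
  out_flag <- calls$parent_on_x & !calls$on_x
  in_flag <- !calls$parent_on_x & calls$on_x
  p_bg_out <- mean(out_flag[!subset])
  p_bg_in <- mean(in_flag[!subset])
  n_out <- sum(out_flag[subset]); n_in <- sum(in_flag[subset])
  p_out <- stats::binom.test(n_out, n, p = max(p_bg_out, 1e-12),
                             alternative = "greater")$p.value
  p_in <- stats::binom.test(n_in, n, p = max(p_bg_in, 1e-12),
                            alternative = "greater")$p.value
  list(n_out_of_x = n_out, n_into_x = n_in,
       expected_out = p_bg_out * n, expected_into = p_bg_in * n,
       p_out = p_out, p_into = p_in)
}

#' Divergence-time table
#'
#' @param branch_id branch identifiers.
#' @param duration_myr branch durations, Myr (> 0).
#' @return a validated data.frame.
#' @export
divergence_table <- function(branch_id, duration_myr) {
  if (any(duration_myr <= 0)) stop("durations must be > 0")
  data.frame(branch_id = as.character(branch_id),
             duration_myr = duration_myr, stringsAsFactors = FALSE)
}

#' The primate divergence-time table
#'
#' Branch durations for the seven-branch anthropoid tree used in the
#' reported rate arithmetic (split ages 6, 8, 18, 30, 42 and 90 Ma; branch
#' 1 is the period after the last human/chimpanzee common ancestor, branch
#' 6 the New World Monkey lineage, branch 7 the pre-split primate stem).
#'
#' @return a [divergence_table()] with branches `"1"`..`"7"`.
#' @export
primate_divergence_table <- function() {
  divergence_table(branch_id = as.character(1:7),
                   duration_myr = c(6, 2, 10, 12, 12, 42, 48))
}

#' Full orthology analysis over a set of species
#'
#' Extracts flank signatures for every call, matches all species pairs
#' symmetrically and builds orthology groups.
#'
#' @param calls_by_species named list of call tables with ids.
#' @param genomes named list of genomes.
#' @param repeats_by_species named list of repeat annotations.
#' @param tree species tree.
#' @param ... passed to [match_orthologs()] / [extract_flanks()].
#' @param search_offset see [extract_flanks()].
#' @return see [build_groups()], plus the pairwise `matches`.
#' @export
infer_orthology <- function(calls_by_species, genomes, repeats_by_species,
                            tree, search_offset = 0L, ...) {
  species <- names(calls_by_species)
  flanks <- lapply(species, function(sp) {
    calls <- calls_by_species[[sp]]
    lapply(seq_len(nrow(calls)), function(i)
      extract_flanks(calls[i, ], genomes[[sp]], repeats_by_species[[sp]],
                     search_offset = search_offset))
  })
  names(flanks) <- species
  matches <- list()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (i >= j) next
      a <- species[i]; b <- species[j]
      m <- match_orthologs(calls_by_species[[a]], calls_by_species[[b]],
                           flanks[[a]], genomes[[b]], ...)
      matches[[paste(a, b, sep = "|")]] <- m
    }
  }
  res <- build_groups(matches, calls_by_species, tree)
  res$matches <- matches
  res
}
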