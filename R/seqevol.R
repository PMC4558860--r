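# Ka/Ks for retrocopy-parent pairs: Nei-Gojobori (1986) site counting with
# unweighted pathway averaging for multi-hit codons and the Jukes-Cantor
# multiple-hit correction d = -(3/4) ln(1 - (4/3) p).

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

codon_aa <- function(codon) GENETIC_CODE_TABLE[[codon]]
is_stop <- function(codon) codon_aa(codon) == "*"

#' Codon alignment of a retrocopy-parent pair
#'
#' @param parent,retro character vectors of codons (3-mers over ACGT),
#'   equal length.
#' @return a list of class `codon_alignment`.
#' @export
codon_alignment <- function(parent, retro) {
  if (length(parent) != length(retro))
    stop("codon vectors must have equal length")
  all_codons <- c(parent, retro)
  if (length(all_codons) && (any(nchar(all_codons) != 3L) ||
                             any(grepl("[^ACGT]", all_codons))))
    stop("codons must be 3-mers over ACGT")
  structure(list(parent = parent, retro = retro), class = "codon_alignment")
}

#' Pair retrocopy bases with the parental CDS via a chained alignment
#'
#' Parent CDS codons are projected through the alignment onto the genome;
#' codon columns with any unaligned position (gaps, truncation) are removed
#' together with their pair, and any trailing partial codon is dropped.
#' Codon columns containing a stop in either sequence are removed later by
#' [nei_gojobori()] and counted in its diagnostics.
#'
#' @param aln the [chained_alignment()] of the parental transcript to the
#'   retrocopy locus.
#' @param gm a [gene_models()] table with `CDS` features for the parent.
#' @param genome named character vector (source of both sequences).
#' @return a [codon_alignment()], or `NULL` (no-CDS result) when the parent
#'   has no annotated CDS or the retrocopy covers no full codon.
#' @export
extract_cds_pair <- function(aln, gm, genome) {
  cds <- cds_transcript_coords(gm, aln$query_name)
  if (is.null(cds)) return(NULL)
  tx <- transcript_sequence(gm, aln$query_name, genome)
  chrom <- genome[[aln$target_name]]
  a <- as.integer(cds[["start"]]); b <- as.integer(cds[["end"]])
  b <- a + 3L * ((b - a) %/% 3L)              # trailing partial codon dropped
  if (b <= a) return(NULL)
  pos <- a:(b - 1L)
  qpos <- if (aln$strand == "+") pos else aln$query_length - 1L - pos
  tpos <- query_to_target(aln, qpos)
  base <- rep(NA_character_, length(pos))
  okp <- !is.na(tpos)
  base[okp] <- substring(chrom, tpos[okp] + 1L, tpos[okp] + 1L)
  if (aln$strand == "-")
    base[okp] <- c(A = "T", C = "G", G = "C", T = "A")[base[okp]]
  parent_nt <- substring(tx, pos + 1L, pos + 1L)
  n_codon <- length(pos) %/% 3L
  cidx <- rep(seq_len(n_codon), each = 3L)
  keep <- tapply(!is.na(base) & parent_nt %in% BASES & base %in% BASES,
                 cidx, all)
  if (!any(keep)) return(NULL)
  pc <- vapply(which(keep), function(k)
    paste(parent_nt[cidx == k], collapse = ""), character(1L))
  rc <- vapply(which(keep), function(k)
    paste(base[cidx == k], collapse = ""), character(1L))
  codon_alignment(unname(pc), unname(rc))
}

# synonymous-site fraction per position of one codon: the share of the 3
# possible substitutions at that position that preserve the amino acid
# (substitutions creating a stop count as nonsynonymous)
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (alt in setdiff(BASES, ref)) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (codon_aa(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged synonymous/nonsynonymous differences between two codons;
# pathways through stop codons are excluded, and if every pathway is
# blocked the raw differences are split by the pair's site proportions
codon_differences <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  if (nd == 1L) {
    syn <- codon_aa(c1) == codon_aa(c2)
    return(c(sd = as.numeric(syn), nd = as.numeric(!syn)))
  }
  perms <- if (nd == 2L) list(dpos, rev(dpos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) dpos[o])
  tot_sd <- 0; tot_nd <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- c1; sd <- 0; ndf <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop(nxt) && nxt != c2) { blocked <- TRUE; break }
      if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    if (!blocked) { tot_sd <- tot_sd + sd; tot_nd <- tot_nd + ndf
                    n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) {
    s_frac <- (codon_syn_sites(c1) + codon_syn_sites(c2)) / 2 / 3
    return(c(sd = nd * s_frac, nd = nd * (1 - s_frac)))
  }
  c(sd = tot_sd / n_ok, nd = tot_nd / n_ok)
}

#' Jukes-Cantor distance
#'
#' `d = -(3/4) ln(1 - (4/3) p)`; undefined (`NA`) for `p >= 3/4`.
#'
#' @param p observed proportion of differences.
#' @return corrected distance.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction
#'
#' Synonymous site counts are averaged between the two sequences;
#' multi-substitution codons average synonymous/nonsynonymous differences
#' over all shortest substitution pathways that avoid stop codons.  Codon
#' columns containing a stop codon in either sequence are dropped and
#' counted in `n_stop_dropped`.
#'
#' @param aln a [codon_alignment()].
#' @return a list of class `kaks_result`: `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio`, `saturated`, `n_codons`,
#'   `n_stop_dropped`.
#' @export
nei_gojobori <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!length(aln$parent)) stop("empty codon alignment")
  drop <- vapply(seq_along(aln$parent), function(i)
    is_stop(aln$parent[i]) || is_stop(aln$retro[i]), logical(1L))
  p <- aln$parent[!drop]; r <- aln$retro[!drop]
  n <- length(p)
  if (n == 0L)
    return(structure(list(S_sites = 0, N_sites = 0, Sd = 0, Nd = 0,
                          pS = NA_real_, pN = NA_real_, Ks = NA_real_,
                          Ka = NA_real_, ratio = NA_real_, saturated = FALSE,
                          n_codons = 0L, n_stop_dropped = sum(drop)),
                     class = "kaks_result"))
  S1 <- sum(vapply(p, codon_syn_sites, numeric(1L)))
  S2 <- sum(vapply(r, codon_syn_sites, numeric(1L)))
  S <- (S1 + S2) / 2
  N <- 3 * n - S
  d <- vapply(seq_len(n), function(i) codon_differences(p[i], r[i]),
              numeric(2L))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- if (!is.na(pS)) jukes_cantor(pS) else NA_real_
  Ka <- if (!is.na(pN)) jukes_cantor(pN) else NA_real_
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS,
                 pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
                 saturated = saturated, n_codons = n,
                 n_stop_dropped = sum(drop)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %d codons: Ka=%.4f Ks=%.4f Ka/Ks=%s%s\n",
              x$n_codons, x$Ka, x$Ks,
              ifelse(is.na(x$ratio), "undef", sprintf("%.3f", x$ratio)),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Compare a target Ka/Ks set against random retrocopy sets
#'
#' Draws `n_sets` random subsets (without replacement within a set) of the
#' full Ka/Ks population, and compares the target ratios against one pooled
#' random draw with a two-sample Mann-Whitney U test (normal approximation
#' with tie correction).  Undefined ratios are excluded from medians.
#'
#' @param target_ratios numeric vector of Ka/Ks ratios for the target set.
#' @param all_ratios population of ratios to sample from.
#' @param n_sets number of random sets.
#' @param set_size size of each random set (defaults to the target size).
#' @param seed integer seed.
#' @return list: `median_target`, `median_random` (median of the random-set
#'   medians), `random_medians`, `p`.
#' @export
compare_to_random <- function(target_ratios, all_ratios, n_sets = 1000L,
                              set_size = length(target_ratios), seed = 1L) {
  if (set_size > length(all_ratios))
    stop("set_size exceeds the population size")
  set.seed(seed)
  meds <- vapply(seq_len(n_sets), function(i)
    stats::median(sample(all_ratios, set_size), na.rm = TRUE), numeric(1L))
  null_draw <- sample(all_ratios, set_size)
  p <- stats::wilcox.test(target_ratios[!is.na(target_ratios)],
                          null_draw[!is.na(null_draw)],
                          exact = FALSE, correct = FALSE)$p.value
  list(median_target = stats::median(target_ratios, na.rm = TRUE),
       median_random = stats::median(meds, na.rm = TRUE),
       random_medians = meds, p = p)
}
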