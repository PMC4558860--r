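# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-species simulation used by several module tests
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- simulation_config(seed = 7, genome_length = 5e5, n_genes = 30,
                             n_retrocopies_per_branch = c(root = 8, A = 4,
                                                          B = 4))
    simulate_species(cfg)
  })
}

# expression-oriented simulation: intragenic insertions, chimeras, reads
expr_sim <- function() {
  cached("expr_sim", function() {
    cfg <- simulation_config(seed = 3, genome_length = 1.5e6, n_genes = 45,
                             n_retrocopies_per_branch = c(root = 20, A = 8,
                                                          B = 8),
                             intragenic_fraction = 0.3,
                             expressed_fraction = 0.5)
    simulate_species(cfg)
  })
}

# overlap of call table rows with ground-truth rows of one species
truth_overlap <- function(calls, gt_species) {
  vapply(seq_len(nrow(calls)), function(i)
    any(gt_species$seqname == calls$seqname[i] &
          pmin(gt_species$end, calls$end[i]) -
            pmax(gt_species$start, calls$start[i]) > 0), logical(1L))
}

truth_found <- function(gt_species, calls) {
  vapply(seq_len(nrow(gt_species)), function(i)
    any(calls$seqname == gt_species$seqname[i] &
          pmin(calls$end, gt_species$end[i]) -
            pmax(calls$start, gt_species$start[i]) > 0), logical(1L))
}

# map a call id back to the planted insertion it covers (or NA)
call_to_retro <- function(call_id, gt) {
  p <- strsplit(call_id, ":")[[1L]]
  se <- as.integer(strsplit(p[3L], "-")[[1L]])
  g <- gt[gt$species == p[1L] & gt$seqname == p[2L] &
            gt$end > se[1L] & gt$start < se[2L], , drop = FALSE]
  if (nrow(g) == 1L) g$retro_id else NA_character_
}

# three-exon toy gene model on the plus strand (exon lengths 200 each,
# introns 1800), plus a minus-strand two-exon gene
toy_gene_models <- function() {
  gene_models(data.frame(
    seqname = "chr1",
    start = c(1000L, 3000L, 5000L, 20000L, 22000L),
    end = c(1200L, 3200L, 5200L, 20300L, 22300L),
    strand = c("+", "+", "+", "-", "-"),
    feature = "exon",
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("g1.t1", "g1.t1", "g1.t1", "g2.t1", "g2.t1"),
    stringsAsFactors = FALSE))
}

# ---- independent Nei-Gojobori oracle -----------------------------------
# Brute-force recursive enumeration over all substitution orderings,
# written independently of the package implementation.

oracle_translate <- function(codon) Biostrings::GENETIC_CODE[[codon]]

oracle_sites_one <- function(codon) {
  s <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (oracle_translate(alt) == oracle_translate(codon)) s <- s + 1 / 3
    }
  }
  s
}

# recursive pathway enumeration; returns matrix of (sd, nd) per valid path
oracle_paths <- function(from, to) {
  dpos <- which(strsplit(from, "")[[1L]] != strsplit(to, "")[[1L]])
  if (!length(dpos)) return(matrix(c(0, 0), ncol = 2))
  res <- NULL
  for (p in dpos) {
    nxt <- from
    substr(nxt, p, p) <- substr(to, p, p)
    if (oracle_translate(nxt) == "*" && nxt != to) next
    step <- as.numeric(oracle_translate(from) == oracle_translate(nxt))
    sub <- oracle_paths(nxt, to)
    if (is.null(sub)) next
    res <- rbind(res, cbind(sub[, 1] + step, sub[, 2] + (1 - step)))
  }
  res
}

oracle_ng86 <- function(parent, retro) {
  keep <- !vapply(seq_along(parent), function(i)
    oracle_translate(parent[i]) == "*" || oracle_translate(retro[i]) == "*",
    logical(1L))
  parent <- parent[keep]; retro <- retro[keep]
  S <- (sum(vapply(parent, oracle_sites_one, numeric(1L))) +
          sum(vapply(retro, oracle_sites_one, numeric(1L)))) / 2
  N <- 3 * length(parent) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(parent)) {
    paths <- oracle_paths(parent[i], retro[i])
    if (is.null(paths)) {
      ndiff <- sum(strsplit(parent[i], "")[[1L]] !=
                     strsplit(retro[i], "")[[1L]])
      sfrac <- (oracle_sites_one(parent[i]) +
                  oracle_sites_one(retro[i])) / 2 / 3
      Sd <- Sd + ndiff * sfrac
      Nd <- Nd + ndiff * (1 - sfrac)
    } else {
      Sd <- Sd + mean(paths[, 1])
      Nd <- Nd + mean(paths[, 2])
    }
  }
  pS <- Sd / S; pN <- Nd / N
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA_real_,
       Ka = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_)
}

# random non-stop codon
random_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    if (oracle_translate(cd) != "*") return(cd)
  }
}

# random codon pair list with at most `max_diff` differences per codon
random_codon_pair <- function(n_codons, max_diff = 1L) {
  parent <- vapply(seq_len(n_codons), function(i) random_codon(),
                   character(1L))
  retro <- parent
  for (i in seq_len(n_codons)) {
    nd <- sample(0:max_diff, 1L)
    if (nd == 0L) next
    pos <- sample(1:3, nd)
    cd <- retro[i]
    for (p in pos) {
      substr(cd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(cd, p, p)), 1L)
    }
    retro[i] <- cd
  }
  list(parent = parent, retro = retro)
}
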