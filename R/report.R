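# Summary arithmetic and pipeline orchestration.

#' Per-species catalog table with totals
#'
#' @param catalogs a [catalog_summary()] data.frame.
#' @return the table with a `total` row appended.
#' @export
table1_report <- function(catalogs) {
  if (!nrow(catalogs)) return(catalogs)
  rbind(catalogs,
        data.frame(species = "total",
                   n_retrocopies = sum(catalogs$n_retrocopies),
                   n_parental_genes = sum(catalogs$n_parental_genes),
                   stringsAsFactors = FALSE))
}

#' Percentage excess of one species group over another
#'
#' `100 * (mean(counts over A) / mean(counts over B) - 1)`, rounded to the
#' nearest integer.
#'
#' @param counts named numeric vector of per-species counts.
#' @param group_a,group_b disjoint, non-empty species sets (names into
#'   `counts`).
#' @return integer percentage.
#' @export
group_excess <- function(counts, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), names(counts))
  if (length(missing)) stop("counts missing for: ",
                            paste(missing, collapse = ", "))
  mb <- mean(counts[group_b])
  if (mb == 0) stop("zero mean in group B")
  as.integer(round(100 * (mean(counts[group_a]) / mb - 1)))
}

#' Rounded percentage of a fraction
#'
#' @param numerator,denominator integers, `numerator <= denominator`,
#'   `denominator > 0`.
#' @return `round(100 * numerator / denominator)` as integer.
#' @export
fraction_report <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator > denominator) stop("numerator exceeds denominator")
  as.integer(round(100 * numerator / denominator))
}

#' Per-branch origination/fixation rate table
#'
#' @param origin_branches character vector of branch ids, one entry per
#'   dated insertion event (orthology groups plus species-specific calls),
#'   or a data.frame with an `origin_branch` column.
#' @param divergence a [divergence_table()]; every branch with events must
#'   have a duration.
#' @return data.frame: `branch_id`, `n_retrocopies`, `duration_myr`,
#'   `rate_per_myr` (unrounded), `rate_rounded`.
#' @export
table2_report <- function(origin_branches, divergence) {
  if (is.data.frame(origin_branches))
    origin_branches <- origin_branches$origin_branch
  cnt <- table(factor(origin_branches, levels = divergence$branch_id))
  missing <- setdiff(unique(origin_branches), divergence$branch_id)
  if (length(missing))
    stop("branch missing from divergence table: ",
         paste(missing, collapse = ", "))
  rate <- branch_rate(as.integer(cnt), divergence$duration_myr)
  data.frame(branch_id = divergence$branch_id,
             n_retrocopies = as.integer(cnt),
             duration_myr = divergence$duration_myr,
             rate_per_myr = rate,
             rate_rounded = as.integer(round(rate)),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param species named list; each element a list with `genome` (FASTA),
#'   `annotation` (GTF), `repeats` (RepeatMasker .out) and optionally
#'   `reads` (named list tissue -> SAM path).
#' @param tree path to the newick species tree.
#' @param divergence path to a divergence TSV (`branch_id`,
#'   `duration_myr`), or `NULL` to derive durations from the tree's branch
#'   lengths.
#' @param out output directory.
#' @param detection a [detection_thresholds()].
#' @param expression a [expression_thresholds()].
#' @param seed integer seed for the stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(species, tree, divergence = NULL, out,
                            detection = detection_thresholds(),
                            expression = expression_thresholds(),
                            seed = 1L) {
  for (sp in names(species)) {
    for (f in c("genome", "annotation", "repeats")) {
      p <- species[[sp]][[f]]
      if (is.null(p) || !file.exists(p))
        stop("missing input for ", sp, ": ", f, " (", p %||% "NULL", ")")
    }
  }
  if (!file.exists(tree)) stop("missing input: tree (", tree, ")")
  structure(list(species = species, tree = tree, divergence = divergence,
                 out = out, detection = detection, expression = expression,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full retrocopy pipeline
#'
#' Stages in dependency order: detection per species, cross-species
#' orthology and branch rates, Ka/Ks per call, expression (when reads are
#' provided), repeat composition, summary reports.  The run directory gets
#' a manifest recording the package version, seed, every threshold and the
#' md5 of every input; a failed stage leaves a `FAILED` marker and
#' re-raises the error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory.
#' @export
run_all <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  write_manifest(config)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(config$out, "FAILED")))

  tree <- read_newick(config$tree)
  genomes <- list(); gms <- list(); reps <- list(); calls <- list()
  aligns <- list()
  for (sp in names(config$species)) {
    genomes[[sp]] <- read_genome_fasta(config$species[[sp]]$genome)
    gms[[sp]] <- read_gtf(config$species[[sp]]$annotation)
    reps[[sp]] <- read_repeatmasker(config$species[[sp]]$repeats)
    tx <- unique(gms[[sp]]$transcript_id[gms[[sp]]$feature == "exon"])
    seqs <- vapply(tx, transcript_sequence, character(1L), gm = gms[[sp]],
                   genome = genomes[[sp]])
    aln <- align_transcripts(seqs, genomes[[sp]])
    aln <- filter_alignments(aln, config$detection)
    aligns[[sp]] <- aln
    cl <- call_retrocopies(aln, gms[[sp]], config$detection)
    calls[[sp]] <- add_call_ids(cl, sp)
    logf("detect %s: %d alignments kept, %d calls", sp, length(aln), nrow(cl))
    write_tsv_with_header(calls[[sp]],
                          file.path(config$out, paste0("calls_", sp, ".tsv")),
                          extra = sprintf("species %s", sp))
    write_calls_bed(cl, file.path(config$out, paste0("calls_", sp, ".bed")))
  }
  cat1 <- catalog_summary(calls)
  write_tsv_with_header(table1_report(cat1),
                        file.path(config$out, "table1_catalog.tsv"))

  orth <- infer_orthology(calls, genomes, reps, tree)
  write_tsv_with_header(orth$groups, file.path(config$out, "groups.tsv"))
  write_tsv_with_header(orth$species_specific,
                        file.path(config$out, "species_specific.tsv"))
  div <- if (!is.null(config$divergence)) {
    d <- read_tsv_table(config$divergence)
    divergence_table(d$branch_id, d$duration_myr)
  } else {
    ids <- tree_branch_ids(tree)
    dur <- c(tree$edge.length, tree$root.edge %||% NA_real_)
    ok_dur <- !is.na(dur) & dur > 0
    divergence_table(ids[ok_dur], dur[ok_dur])
  }
  dated <- c(orth$groups$origin_branch, orth$species_specific$origin_branch)
  dated <- dated[dated %in% div$branch_id]
  write_tsv_with_header(table2_report(dated, div),
                        file.path(config$out, "table2_rates.tsv"))
  logf("orthology: %d groups, %d species-specific",
       nrow(orth$groups), nrow(orth$species_specific))

  # Ka/Ks per species call set
  for (sp in names(calls)) {
    kk <- kaks_for_calls(calls[[sp]], aligns[[sp]], gms[[sp]], genomes[[sp]])
    write_tsv_with_header(kk, file.path(config$out,
                                        paste0("kaks_", sp, ".tsv")))
  }

  # repeat composition
  comp <- l1_composition(reps)
  write_tsv_with_header(comp, file.path(config$out, "l1_composition.tsv"))

  # expression where reads are given
  for (sp in names(config$species)) {
    rd <- config$species[[sp]]$reads
    if (is.null(rd)) next
    decoy <- build_decoy_reference(calls[[sp]], genomes[[sp]], gms[[sp]],
                                   config$expression$decoy_flank)
    hits <- list(); chim <- list()
    for (tis in names(rd)) {
      recs <- sam_records(read_sam(rd[[tis]]))
      hits[[tis]] <- align_reads_to_decoy(recs, decoy)
      chim[[tis]] <- detect_chimeric(recs, gms[[sp]], calls[[sp]],
                                     genomes[[sp]], config$expression)
    }
    prof <- call_expressed(hits, calls[[sp]], decoy, config$expression)
    write_tsv_with_header(prof, file.path(config$out,
                                          paste0("expression_", sp, ".tsv")))
    ev <- do.call(rbind, chim)
    ev <- ev[!duplicated(ev[, c("host_gene", "call_id", "junction_start",
                                "junction_end")]), , drop = FALSE]
    write_tsv_with_header(ev, file.path(config$out,
                                        paste0("chimeric_", sp, ".tsv")))
    ctx <- classify_context(calls[[sp]], gms[[sp]], ev, config$expression)
    write_tsv_with_header(
      data.frame(call_id = calls[[sp]]$call_id, context = ctx,
                 stringsAsFactors = FALSE),
      file.path(config$out, paste0("context_", sp, ".tsv")))
    tau_tab <- tau_table(prof)
    write_tsv_with_header(tau_tab, file.path(config$out,
                                             paste0("tau_", sp, ".tsv")))
  }
  ok <- TRUE
  logf("run complete")
  invisible(config$out)
}

# Ka/Ks for each call using its representative transcript alignment
kaks_for_calls <- function(calls, alignments, gm, genome) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    aln <- find_call_alignment(calls[i, ], alignments)
    if (is.null(aln)) next
    ca <- extract_cds_pair(aln, gm, genome)
    if (is.null(ca)) next
    k <- nei_gojobori(ca)
    rows[[length(rows) + 1L]] <- data.frame(
      call_id = calls$call_id[i], S_sites = k$S_sites, N_sites = k$N_sites,
      Sd = k$Sd, Nd = k$Nd, pS = k$pS, pN = k$pN, Ka = k$Ka, Ks = k$Ks,
      ratio = k$ratio, saturated = k$saturated, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(call_id = character(), S_sites = numeric(),
                      N_sites = numeric(), Sd = numeric(), Nd = numeric(),
                      pS = numeric(), pN = numeric(), Ka = numeric(),
                      Ks = numeric(), ratio = numeric(),
                      saturated = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# locate the alignment behind a call (same transcript, overlapping locus)
find_call_alignment <- function(call, alignments) {
  for (a in alignments) {
    if (a$query_name != call$parental_transcript) next
    if (a$target_name != call$seqname) next
    tr <- alignment_target_range(a)
    if (tr[["start"]] < call$end && tr[["end"]] > call$start) return(a)
  }
  NULL
}

# mean expression per tissue -> tau per retrocopy
tau_table <- function(profiles) {
  out <- lapply(split(profiles, profiles$call_id), function(p) {
    data.frame(call_id = p$call_id[1L],
               tau = if (any(p$expressed)) tau(p$rpkm) else NA_real_,
               n_tissues_expressed = sum(p$expressed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# GAlignments -> plain record data.frame used by the expression callers
sam_records <- function(ga) {
  mc <- S4Vectors::mcols(ga)
  data.frame(qname = mc$qname, flag = mc$flag,
             seqname = as.character(GenomicRanges::seqnames(ga)),
             pos = BiocGenerics::start(ga) - 1L, mapq = mc$mapq,
             cigar = GenomicAlignments::cigar(ga),
             seq = as.character(mc$seq), stringsAsFactors = FALSE)
}

write_manifest <- function(config) {
  files <- unlist(lapply(config$species, function(s)
    c(s$genome, s$annotation, s$repeats, unlist(s$reads))))
  files <- c(files, config$tree, config$divergence)
  files <- files[!vapply(files, is.null, logical(1L))]
  md5 <- tools::md5sum(unlist(files))
  lines <- c(sprintf("version\t%s",
                     as.character(utils::packageVersion("retroscape"))),
             sprintf("seed\t%d", config$seed),
             sprintf("detection.%s\t%s", names(config$detection),
                     unlist(config$detection)),
             sprintf("expression.%s\t%s", names(config$expression),
                     unlist(config$expression)),
             sprintf("input.%s\t%s", names(md5), md5))
  writeLines(lines, file.path(config$out, "manifest.tsv"))
}
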