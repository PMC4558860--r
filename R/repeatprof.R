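# LINE-1 subfamily composition profiles and pairwise enrichment tests.

#' L1 subfamily composition
#'
#' Restricts the annotation to class `LINE/L1`, counts elements per
#' subfamily, drops subfamilies below `min_members` (applied to the pooled
#' count when several species are given) and reports fractions relative to
#' the retained total.
#'
#' @param repeats a repeat annotation data.frame ([read_repeatmasker()]) or
#'   a named list of them (one per species).
#' @param min_members minimum pooled subfamily count retained.  The default
#'   (50) suits desk-scale synthetic genomes; genome-scale annotations use
#'   proportionally larger values.
#' @return data.frame: `species`, `subfamily`, `count`, `fraction` (within
#'   the retained L1 total of that species).
#' @export
l1_composition <- function(repeats, min_members = 50L) {
  if (is.data.frame(repeats)) repeats <- list(all = repeats)
  l1 <- lapply(repeats, function(r)
    r[r$repeat_class == "LINE/L1", , drop = FALSE])
  pooled <- table(unlist(lapply(l1, function(r) r$subfamily)))
  keep <- names(pooled)[pooled > min_members]
  rows <- lapply(names(l1), function(sp) {
    r <- l1[[sp]]
    cnt <- table(factor(r$subfamily[r$subfamily %in% keep], levels = keep))
    if (!length(keep))
      return(data.frame(species = character(), subfamily = character(),
                        count = integer(), fraction = numeric(),
                        stringsAsFactors = FALSE))
    tot <- sum(cnt)
    data.frame(species = sp, subfamily = keep, count = as.integer(cnt),
               fraction = if (tot > 0) as.numeric(cnt) / tot else
                 rep(NA_real_, length(keep)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subfamily enrichment between two compositions
#'
#' Pearson chi-square (1 d.f., no continuity correction) and odds ratio on
#' the 2x2 table subfamily-vs-rest by group A-vs-B.
#'
#' @param comp_a,comp_b [l1_composition()] tables (counts are pooled over
#'   their species).
#' @param subfamily subfamily to test.
#' @return list: `odds_ratio`, `chisq`, `p`, `table`.
#' @export
enrichment_test <- function(comp_a, comp_b, subfamily) {
  cell <- function(comp) {
    hit <- sum(comp$count[comp$subfamily == subfamily])
    rest <- sum(comp$count) - hit
    c(hit = hit, rest = rest)
  }
  a <- cell(comp_a); b <- cell(comp_b)
  tab <- rbind(A = a, B = b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 enrichment table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, chisq = unname(ct$statistic), p = ct$p.value,
       table = tab)
}
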