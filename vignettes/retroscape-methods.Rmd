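---
title: "Models and methods behind retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retroscape)
```

`retroscape` analyses mRNA retrocopies — intronless genomic copies of
multiexonic genes created by LINE-1-mediated retrotransposition — across a
set of related genomes. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices, what the synthetic
data emulate (and what they do not), and the design decisions that were
genuinely open.

## Detection

The unit of detection is a chained transcript-to-genome alignment, the
same record a PSL file stores. The internal aligner is deliberately
simple: exact k-mer seeds (k = 12) on a 2-bit index, seeds grouped by
diagonal and extended without gaps under an X-drop rule (match +1,
mismatch −3, drop 18), and segments chained greedily with an affine join
penalty (12 nt plus 1 nt per 2 kb of target gap). The penalty is what
keeps stray 12-mer matches tens of kilobases away from attaching to a
genuine alignment; segments shorter than 16 nt are treated as seed noise
and dropped. Because the aligner is substitution-aware only, indel-rich
real data should be aligned externally and supplied as PSL — the package
treats the two sources identically.

Filters follow the field's standard recipe for mRNA-based retrocopy
screens, as `detection_thresholds()` defaults:

* identity = matches/(matches+mismatches) must exceed **0.75**. Query
  gaps are ignored in this definition; alignment tools differ in how they
  penalize gaps in their identity formulas, and the plain substitution
  ratio is the simplest definition whose threshold semantics are
  preserved.
* coverage of the parental transcript must exceed **0.5**, *or* at least
  **120 nt** must align — the disjunction keeps heavily 5'-truncated
  copies, which LINE-1's incomplete reverse transcription makes common.
* no internal target gap may exceed **15 kb**: larger gaps are putative
  introns, while smaller ones still allow repeat insertions into the
  retrocopy locus.
* the intronless signature: at least **2** consecutive parental exons
  each contributing more than **50 nt**, with the junction between them
  bridged on the genome within **30 nt** of target-side slack.
  "Adjacently aligned" needs an operational tolerance; 30 nt admits small
  indels and alignment jitter while excluding any realistic intron, whose
  minimum length is roughly 70 nt.

A candidate overlapping its own parental gene span (any overlap, not just
exons) is discarded — conservative, but it prevents self-calls from
partially annotated isoforms. Overlapping candidate loci collapse to a
single call, keeping the representative with the highest identity ×
coverage (ties: longer alignment, then lexicographic transcript id), so
multi-isoform parents yield exactly one call per locus and outputs are
deterministic. Single-exon parents can never satisfy the signature; their
retrocopies are invisible to this method by construction. Manual curation
steps used in genome-scale studies (e.g. removing olfactory-receptor
artifacts) are replaced by an optional exclusion list, which is
reproducible.

## Orthology and dating

Because independent insertions into large genomes essentially never share
an insertion point, a syntenic locus carrying the same parental gene in
two species identifies one ancestral event. The flank signature of a call
collects, per side, maximal non-repeat runs of at least **150 nt** until
**3,000 nt** are accumulated. The published description of where the
search starts is ambiguous ("5,000 nt up- and downstream" of the event);
`extract_flanks()` therefore starts at the locus edge plus a guard band
covering the unaligned query remainder by default, with
`search_offset = 5000` available as a conservative preset — the two
readings are one parameter apart, and on synthetic data they give
identical pairings.

Two calls pair when the parental gene matches and one side's flank blocks
align to the partner's neighbourhood covering ≥ **50%** of the collected
flank nt at ≥ **70%** identity. These two thresholds are configuration,
not biology: the original tooling used score-based cutoffs of a specific
aligner, which do not translate; explicit coverage/identity semantics are
reproducible. Pairing is one-to-one per species pair (best coverage, then
identity). Groups are connected components of the pairwise match graph,
split if members disagree on the parental gene; the origin branch is the
edge above the most recent common ancestor of the presence pattern
(Dollo-style — losses are allowed but not modelled). Discordant presence
patterns are kept and flagged rather than discarded, since species-specific
sets are known to carry false positives. Per-branch rates divide the
insertion count by the branch duration from a divergence-time table;
`primate_divergence_table()` ships the seven-branch anthropoid table
(split ages 6, 8, 18, 30, 42, 90 Ma). Reported rates are rounded to the
nearest integer, matching the precision such tables print.

The X-flux test counts, within a designated subset, insertions whose
parent is on the X but which landed on an autosome (out-of-X) and the
converse (into-X); expected counts come from the corresponding proportions
among all calls outside the subset, and the p-value is a one-sided exact
binomial. The original analysis does not name its test; the binomial
construction is this package's choice and is calibrated in the test suite.

## Ka/Ks

`nei_gojobori()` implements NG86 with the standard genetic code: each
codon position contributes a synonymous-site fraction equal to the share
of its three possible substitutions that preserve the amino acid
(substitutions to stops count as nonsynonymous), so S + N = 3 per codon
exactly; sites are averaged between the two sequences. Codons differing
at 2–3 positions average synonymous/nonsynonymous step counts over all
orderings of the substitutions, excluding pathways through stop codons; if
every pathway is blocked, the codon contributes its raw differences split
by the pair's site proportions. Codon columns containing a stop in either
sequence are dropped and counted in a diagnostics field — retrocopies
accumulate nonsense changes, and dropping matches the "gaps removed"
treatment of the columns without inventing semantics. The Jukes–Cantor
correction d = −(3/4)·ln(1 − (4/3)p) is undefined at p ≥ 3/4; such results
are flagged `saturated`. Ratios with Ks = 0 are reported as undefined and
excluded from medians, avoiding artificial infinities. The retrocopy side
of the codon alignment is the parent CDS projected through the chained
alignment (annotated retrogene CDSs are rarely available), with any codon
touching an unaligned position removed in pairs. Maximum-likelihood dN/dS
and transition/transversion-weighted pathway schemes are out of scope.

`compare_to_random()` draws sets without replacement, independently per
set, and compares the target against one pooled random draw with a
Mann–Whitney U test under the normal approximation with tie correction —
the simplest null consistent with "random sets of equal size".

## Expression

Two strategies complement each other. *Chimeric*: spliced reads joining a
host-gene exon to an intragenic retrocopy across a junction whose interior
reference bases read GT…AG in the host's transcription orientation;
events require ≥ **5** supporting reads with MAPQ > **40**. *Unique
alignment*: reads are aligned to a decoy reference holding every
retrocopy locus with **300 nt** of genomic flank plus every parental
mature mRNA. The flank length is a compromise — long enough to absorb
reads straddling the insertion boundary, short enough not to create
spurious uniqueness; the source description ("extra regions") is
unquantified. Identical sequences are deliberately not collapsed: a
retrocopy indistinguishable from its parent must lose by MAPQ, which is
exactly the decoy's purpose. A read counts only if its MAPQ exceeds 40
and it overlaps the retrocopy portion; a retrocopy is expressed in a
tissue at ≥ **2** unique reads. No published minimum exists for this
count; one read is indistinguishable from noise, and the threshold is
configurable.

τ = Σᵢ(1 − xᵢ/max x)/(N−1) is computed on normalized (not
log-transformed) per-tissue means — the index is defined on relative
levels and the choice of transform is otherwise free; a log2(x+1) variant
is a one-liner for users who want it. Context classes use a precedence
order (chimeric intragenic > intragenic > near-TSS > near-polyA >
distant) with distances measured from the locus edges and an exclusive
**15 kb** bound, so every call gets exactly one class. The permutation
test places length-matched random loci uniformly, classifies them
intragenic/near versus distant, and reports
p = (1 + #{null ≥ observed})/(n + 1) — the add-one form keeps p positive
and exact under exchangeability. Correlation reports are plain per-pair
Spearman; published values for "highly expressed" subsets involve an
aggregation that is not described and are therefore not targeted.

## The synthetic-data module

`simulate_species()` is first-class, tested code, and its defaults are the
package's reference study conditions: two species, 10 Mb genomes (10% on
an X-flagged chromosome), 300 genes of 4–8 exons (exons 100–300 nt,
introns 0.5–3 kb, canonical GT-AG), 200 planted insertions (100 on the
root edge, 50 per terminal branch), substitution rate 0.001/site/Myr on a
tree of 5-Myr branches — so ancestral retrocopy–parent pairs diverge by
about 2% — 25% truncation probability (uniform up to half the
transcript), 10–30 nt polyA tails, and 10% of the genome annotated as
repeats with fixed subfamily weights. Insertions land uniformly outside
genes and repeats; an `intragenic_fraction` option places copies into
introns to exercise chimeric and context logic, enforcing an AG acceptor
ahead of the copy (chimeric ground truth is downgraded if later
substitutions destroy the splice signals). Retrocopies are planted at the
start of their origin edge and then mutate along that edge and all
descendant edges, which realizes "mutation load proportional to branch
age" without a separate ageing pass. Expression ground truth assigns each
insertion a tissue subset and level; `simulate_reads()` generates
error-free uniform-coverage reads (spliced for host genes, contiguous for
retrocopies, junction reads for chimeras) with MAPQ 60.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: realistic base composition and repeat sequence
(repeats are annotation-only), indels and segmental duplications,
assembly gaps, sequencing error, fragment-length effects, and
target-site duplications (never used by any downstream statistic).
Detection and orthology results on real genomes will be correspondingly
noisier than the ≥ 0.95 recovery measured here.

## Problem sizes, tolerances and determinism

The reference scenarios were sized for a single CPU: detection recovery
runs on the 2 × 10 Mb default (seconds per species); orthology recovery on
a 4-leaf tree with 4 Mb genomes and insertions on every edge (about a
minute, dominated by pairwise flank alignment); statistical calibration
uses 1,000 null replicates with 199 permutations each and groups of 80
loci — granular enough for exact p = k/200 quantiles while keeping the
whole suite in minutes. Every stochastic routine takes an explicit seed;
`run_all()` writes a manifest (version, seeds, thresholds, input md5s)
and identical manifests give byte-identical outputs, which the suite
asserts file by file.

Known limitations: the internal aligner does not model indels inside
blocks (external PSL covers that need); orthology assumes insertions are
rare enough per locus that flank sharing implies common descent — dense
insertion clusters would need explicit loss modelling; Ka/Ks saturates at
p ≥ 3/4 and is undefined for Ks = 0 pairs; and species-specific
*expression* (as opposed to species-specific insertion) has no agreed
operational definition and is left to the user's notion of orthologous
expression.
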