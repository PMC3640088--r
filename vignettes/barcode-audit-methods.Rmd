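---
title: "Auditing a DNA barcode reference collection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference collection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeaudit)
```

## The problem

Large herbarium barcoding campaigns generate hundreds to thousands of ITS
(ITS1 + 5.8S + ITS2) sequences anchored to vouchered macrofungal
specimens. At that scale, no curator can eyeball every
sequence-to-specimen assignment. `barcodeaudit` implements a heuristic
audit of such a collection at the whole-dataset level: it quantifies the
barcode gap between within- and among-species divergence, flags the two
classic barcode error types, evaluates ITS1/ITS2 mini-barcodes as
substitutes for the full region, checks clustering and ordination
concordance with the taxonomic determinations, and tests which factors
(specimen age, taxon) predict PCR amplification success. The goal is
triage — pointing taxonomists at the specimens and genera that need
scrutiny — not species delimitation or phylogenetic inference.

## Distances: counting base-pair differences

Every analysis rests on one primitive: the number of base-pair
differences between two barcodes. The package aligns each pair globally
(Needleman–Wunsch with affine gaps, Gotoh recursion; defaults match +1,
mismatch −1, gap opening 5, gap extension 2, a gap of length *k* costing
`5 + 2k`). End gaps are *penalised in the score* but *excluded from the
count*: the difference count is the number of substitution columns plus
internal gap columns, with terminal gap runs (ragged amplicon ends from
different primer trims) ignored. Two design points deserve emphasis:

* **Why not free end gaps?** A maximum-score alignment with free end
  gaps may slide into a shifted, partially overlapping configuration
  whenever a sequence is locally self-similar, reporting near-zero
  differences between genuinely divergent sequences. Because a zero
  difference triggers a false-negative barcode error call, the aligner
  must not be allowed to discard sequence to flatter the score.
  Penalising end gaps keeps both sequences in play; excluding terminal
  runs from the count still forgives honest length raggedness.
* **Ambiguity codes.** Two IUPAC symbols count as a match when their
  base sets intersect (`R` vs `A` matches, `R` vs `C` does not). This is
  deliberately conservative toward intraspecific identity: a sequencing
  ambiguity should not manufacture divergence between conspecific
  collections. A strict exact-string mode is available where identity
  claims must be literal (`find_false_negatives(exact = TRUE)`).

A multi-base indel counts one difference per column by default
(`indel_mode = "per_column"`); `"per_gap"` counts each run once. Whether
the original practice counted one or *k* cannot be settled from a
distance value alone, so both are exposed and the default is documented.

**Retention rule.** Pairwise counts are kept only for pairs differing by
at most `min(70, floor(0.10 × mean pair length))` bp — 70 bp on a
typical ~700 bp amplicon — because beyond roughly 10% divergence the
pairwise alignment itself is no longer trustworthy. Non-retained pairs
are recorded as a count (and, within species, remembered so that a
conspecific pair beyond the cap still counts as a false positive at any
cutoff). This cap applies to the barcode-gap, error-detection and
clustering analyses. The mini-barcode correlation deliberately does
*not* apply it (see below).

## Barcode gap and error detection

`divergence_profile()` bins retained pairs into integer-bp classes by
intra- versus interspecific status (species = binomial after collapsing
infraspecific epithets; configurable). Percent divergence is derived as
bp / mean pair length when needed, keeping the bp axis primary.

* A **false negative** is a pair of distinct morphological species
  joined by at least one zero-difference specimen pair; results are
  deduplicated to unordered species pairs.
* A **false positive** is a species whose collections carry more than
  one sequence: maximum within-species difference above a cutoff, with
  non-retained conspecific pairs counting as above any cutoff.
* Each flagged species pair is graded on a severity ladder keyed to the
  lowest shared rank: congeneric → confamilial → moderate (same order)
  → major (different order), with `unknown` for unresolvable genera.
  The ladder extends the qualitative worked categories (congeners,
  confamilial epigeous–sequestrate pairs, cross-order mix-ups) into a
  total order so that arbitrary inputs classify deterministically.
* `threshold_sweep()` counts, for each candidate similarity cutoff,
  lumping errors (interspecific pairs at or below it) and splitting
  errors (conspecific pairs above it). Lumping is non-decreasing and
  splitting non-increasing in the cutoff by construction; the sweep
  makes the cost of any "one size fits all" cutoff explicit.

## Mini-barcodes

`split_its_regions()` cuts each sequence into ITS1 / 5.8S / ITS2. With
annotated coordinates (0-based half-open internally; only the NCBI
feature table output is 1-based inclusive) the split is exact and
lossless. Otherwise the 5.8S is located by local alignment against a
packaged anchor, accepted at ≥75% identity over ≥80% of the anchor
length; failures are recorded per specimen, never fatal. The packaged
anchor is a fixed synthetic sequence — the same sequence the simulator
uses as its invariant 5.8S — so the anchor path is exactly testable;
for real data, supply a curated fungal 5.8S consensus via `anchor`.

`minibarcode_report()` builds ITS1, ITS2 and full-length distance
matrices and reports pairwise Pearson correlations over the intersection
of pairs present in both matrices, using raw bp differences. By default
these matrices are complete (no retention cap): the cap exists to guard
alignment quality in the gap analysis, and applying its 10% fraction to
a 250 bp spacer (25 bp) would censor precisely the informative
interspecific pairs whose recovery the correlation is meant to measure.
Degenerate cases (all-identical region, fewer than 3 shared pairs) are
reported as `NA` with the reason rather than silently dropped.

## Concordance with taxonomy

`upgma()` implements unweighted average-linkage clustering directly:
cluster distances are means over observed leaf pairs, ties are broken by
the lexicographically smallest member label, and merge heights are half
the merge distance, so trees are exactly ultrametric and runs are
byte-reproducible. Pairs beyond the retention cap are censored at
`threshold + 1` by default — "far, magnitude unknown" — preserving
far-ness without fabricating precision; an `exclude` policy (averages
over observed pairs only) is available. The implementation is checked
against a naive O(n³) re-derivation and against `stats::hclust` on
tie-free matrices.

`nmds_ordination()` wraps `vegan::monoMDS` (global model, Kruskal
stress-1) with 8 seeded random starts, 300 iterations and tolerance
1e-6 per start, returning the best start. Non-retained pairs are
excluded from the stress sum by default (the original software's
handling of censored pairs is unknown; exclusion is the assumption-free
choice, censoring is available). Stress-1 is scale invariant, which the
tests assert directly.

`concordance_flags()` finds, for each taxon with ≥2 accessions, the
smallest clade containing all of them: members of other taxa inside
that clade become `foreign_inclusion` flags (the misidentification
signature), and a clade more than 3× the taxon's accession count
becomes a `split_group` flag (the multiple-clusters symptom). The 3×
dilation factor is an invented, documented heuristic that
operationalises a qualitative judgement; it is a tunable argument.
`ordination_coherence()` scores each taxon by mean within-taxon point
distance over mean distance to all other points (≈1 means no
clustering), ranking taxa for revision priority.

## Amplification statistics

`build_contingency()` tallies decade × outcome or genus × outcome
tables (decade = `floor(year/10)·10`; records missing either variable
are excluded with a count). `chi_square_posthoc()` computes the Pearson
chi-square without continuity correction (the correction is available
as a flag), Haberman standardized adjusted residuals
$r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-n_{i\cdot}/n)(1-n_{\cdot j}/n)}$,
each cell's relative contribution $((O-E)^2/E)/\chi^2$, and
significance against the standard normal at a Bonferroni-corrected
level. The Bonferroni denominator is the number of **cells** (rows ×
columns: a 3×2 table gives 0.05/6 ≈ 0.008), matching the published
worked arithmetic rather than the row count. `stratified_report()`
repeats the genus analysis inside age strata (default 1980s–1990s
versus 2000s) and marks each genus at both the raw and corrected
alpha.

## The synthetic herbarium generator

`simulate_herbarium()` produces datasets with known ground truth so
every stage is testable without downloads. The genealogy is
deliberately star-shaped — root → genus ancestors (`p_genus = 0.20`) →
species ancestors (`p_inter = 0.05`) → accessions (`p_intra = 0.005`),
all per-site substitutions uniform over the three alternative bases —
because the audit's statistics depend only on the intra/interspecific
divergence contrast, not on topology, and the star model admits exact
expectations: a path of steps $p_1..p_k$ gives per-site mismatch
probability $\tfrac34\bigl(1-\prod_i(1-\tfrac{4p_i}{3})\bigr)$
(`expected_pair_divergence()`), verified against Monte-Carlo simulation.
Defaults give a ~660 bp amplicon (250 + 160 + 250), within-species
differences of ~5 bp and congeneric interspecific differences of
~50 bp, reproducing the observed sharp separation at roughly 1–2%
divergence. The 5.8S is invariant by default (a perfect splitting
anchor, mutable to stress the splitter), and `spacer_bias` routes
mutation pressure between ITS1 and ITS2 (0.8 concentrates signal in
ITS1, reproducing the ITS1 > ITS2 discrimination ordering).

Injections define recoverable errors: a false negative duplicates one
accession's sequence under a different congeneric species; a false
positive re-draws one accession of a species at the interspecific rate;
a major misidentification relabels an accession with a genus from a
different family (genera are grouped two per family, families two per
order, so the whole severity ladder is reachable). Collection years are
uniform over the year range — no empirical specimen-age distribution
was available, so uniform is the placeholder and it is configurable —
and PCR success follows a logistic model in specimen age (decades
before the newest decade) with optional per-genus offsets; defaults
(intercept 1.2, −0.9 per decade) give roughly 55–75% success for
recent material declining steeply for older collections, the regime a
herbarium campaign reports. What the generator does *not* emulate:
indels, chimeras, heterozygous rDNA repeats, length variation between
taxa. Passing tests therefore demonstrate correctness of the audit
machinery under substitution-only divergence, not robustness to every
artefact of real Sanger data.

All randomness flows from a single integer seed; a dataset is a pure
function of its `generator_config()`.

## Problem sizes and numerical choices

The test-suite and acceptance runs use small collections (4 genera × 3
species × 2 accessions, 24 specimens, 276 pairs; statistics checks use
up to ~500 metadata-only records), 20-seed replicate loops, and 2000
null simulations for the type-I error check — sizes chosen so a full
audit of the package's claims reruns in minutes on a laptop while
leaving every assertion statistically meaningful (binomial standard
errors are accounted for explicitly where convergence is asserted).
Deterministic tie-breaks (lexicographic pair choice in UPGMA,
fixed preference order in alignment traceback) and derived per-stage
seeds make whole-pipeline reruns byte-identical.

## Known limitations

* The aligner is O(len²) per pair and all pairs are evaluated; beyond a
  few thousand sequences the distance stage dominates and would need
  blocking or parallelism, which the package deliberately leaves out.
* Severity classification is only as good as the taxonomy index;
  unresolved genera degrade to `unknown` rather than guessing.
* The flags are triage, not verdicts: whether a zero-distance pair is
  synonymy, cryptic speciation or incomplete lineage sorting is left to
  the taxonomist.
* NMDS on censored/incomplete dissimilarities can converge to local
  optima; multiple seeded starts mitigate but do not eliminate this.
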