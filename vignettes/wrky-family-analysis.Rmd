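---
title: "Methods: WRKY family identification, classification and comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WRKY family identification, classification and comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyfam)
```

## The biological problem

WRKY proteins are one of the largest plant transcription-factor families.
Their DNA-binding domain is about 60 residues long and has a two-part
architecture: a nearly invariant heptapeptide (canonically `WRKYGQK`, with
rarer variants such as `WRKYGKK`, `WRKYDQK`, `WRKYDHK` and `WKKY`-spelled
forms) followed by a zinc finger whose four metal-coordinating residues are
either C–C–H–H (C2H2) or C–C–H–C (C2HC), separated by characteristic spacer
runs. Family membership and the classical three-group system follow from
this architecture alone:

* **group I** — two WRKY domains, C2H2 fingers;
* **group II** — one domain, C2H2 finger (spacing `C-X4/5-C-X22..24-H-X1-H`);
* **group III** — one domain, C2HC finger (spacing `C-X7-C-X22/23-H-X1-C`).

Group II further splits into subgroups IIa–IIe, which are *not* decidable
from the domain pattern and are conventionally assigned by phylogenetic
placement against labeled references.

`wrkyfam` implements this analysis as a reusable pipeline: domain
detection, group/subgroup classification, physicochemical and gene-structure
characterization, promoter element scanning, homolog-group calling with
typed pair tallies, and expression analytics (RPKM, 2^-ddCt, Pearson
co-expression networks). Two published carrot (*Daucus carota*) tables — a
95-gene family table and a nine-species homolog pair-count table — ship as
transcribed fixtures and serve as worked examples with exact expected
aggregates.

## Domain scanning

Scanning is anchored on the heptapeptide: every occurrence of a variant in
the configured set (`wrky_variants()`) is found first, then the nearest
downstream zinc finger is sought within a maximum gap. A finger is the
left-most quadruple of coordinating residues whose spacer lengths fall in
the configured `wrky_pattern_space()`; when a C2H2 and a C2HC quadruple
start at the same cysteine, C2H2 wins, and within a type the most compact
spacing is taken. Assembly is greedy left-to-right and each finger can be
consumed by only one anchor.

Tunable parameters and their defaults:

| parameter | default | rationale |
|---|---|---|
| heptapeptide variants | `WRKYGQK`, `WRKYGKK`, `WRKYDQK`, `WRKYDHK`, `WKKYDHK`, `WKKYDQK` | the canonical form plus all variant spellings that occur in published family tables; prose and table spellings of the `W(R/K)KYD..` variants disagree in the source material, so both are accepted |
| C2H2 spacings | n1 ∈ {4,5}, n2 ∈ {22,23,24}, n3 = 1 | published family tables themselves contain X22 and X24 group-II entries; the narrower n2 ∈ {22,23} is available as the `"strict"` profile |
| C2HC spacings | n1 = 7, n2 ∈ {22,23}, n3 = 1 | the canonical group III pattern |
| max anchor-to-finger gap | 60 residues | the approximate span of the whole WRKY domain |

The ambiguity code `X` never matches a heptapeptide or coordinating
position (conservative matching). Spacing signatures are rendered
canonically (`C-X7-C-X23-H-X1-C`); `parse_signature()` additionally accepts
the printed dialect with underscores and compact tails (`HXH`, and literal
residues such as `HTC`, each standing for one spacer position), and dual
`(N)/(C)` patterns for two-domain proteins.

## Classification

`classify_by_rule()` is a pure function of domain count and finger types.
Proteins with two or more domains that include a C2HC finger fall outside
the canonical rules and are assigned group I with a conflict flag.

Subgroups are assigned by reference-guided placement: the single-domain
query sequences and the labeled reference domains are merged into a
center-star multiple alignment (anchored on the longest reference, BLOSUM62,
affine gaps open 11 / extend 1 — conventional defaults, since no scoring
scheme is prescribed for this analysis), p-distances are computed over
shared columns, a neighbor-joining tree is built, and the query takes the
label of the nearest reference by patristic distance (ties: majority of the
three nearest, then lexicographic order). Group I proteins are placed by
their C-terminal domain only, following the convention of labeling
two-domain proteins' N- and C-terminal domains separately in family trees,
and receive no subgroup. A group II query nearest to a non-II reference, or
a group III query nearest to a non-III reference, keeps its rule-based group
and is flagged — structural rules and phylogeny are never silently
reconciled, because published family tables themselves contain rows whose
printed finger pattern contradicts their printed group and the data alone
cannot arbitrate.

Neighbor joining is the standard Saitou–Nei agglomeration with two
deterministic policies: ties in the Q-matrix are broken by the lowest index
pair, and negative branch lengths are clamped to zero. Bootstrap support
resamples alignment columns with replacement under a single seeded
generator; support for a bipartition is the fraction of replicate trees
containing it. A degenerate alignment (all pairwise distances zero) yields
an arbitrary topology, so all supports are reported as zero with a warning
rather than pretending precision. In `classify_family()` the reported
per-query `support` is the fraction of bootstrap replicates that reproduce
the original label assignment, which is the quantity a user of the
classification actually relies on.

## Physicochemical descriptors

All descriptors are computed from their closed forms with bundled,
documented constant tables:

* **pI** — bisection on the Henderson–Hasselbalch net charge over the
  Bjellqvist pKa set (termini plus K, R, H and D, E, C, Y), to an interval
  width of 1e-6 pH units. The net charge is strictly decreasing and changes
  sign on [0, 14] for every peptide, so the root is unique.
* **GRAVY** — mean Kyte–Doolittle hydropathy.
* **instability index** — `(10/L) ×` the sum of dipeptide instability
  weights (Guruprasad et al. 1990) over adjacent pairs; `< 40` classifies a
  protein as stable. A reported claim in the source material attaches the
  `< 40` threshold to the *aliphatic* index; that threshold belongs to the
  instability index, and this package applies it there.
* **aliphatic index** — `X(A) + 2.9·X(V) + 3.9·(X(I)+X(L))` in mole
  percent. The separate aliphatic *composition* statistic uses {A, V, I, L}
  by default with G available by option, because the class membership
  behind published composition percentages is unstated.

The family summary reports the computed mean length (rounded to one decimal
alongside the raw value) without asserting equality to any published
rounded mean, whose derivation from the printed ORF column is not exact.

## Promoter elements

Promoters (conventionally the 1500 bp upstream window) are scanned against
a small bundled dictionary of ten IUPAC consensi (W-box `YTGACY`, G-box,
Sp1, CGTCA-motif, ERF, ABRE, Skn-1, TC-rich, MBS, HSE). Both strands are
scanned; minus-strand hits are mapped to plus-strand coordinates and a
palindromic site matched identically on both strands is reported once. `N`
matches nothing. Users can substitute their own dictionary; the bundled one
stands in for database-backed element annotation, which is out of scope.

## Homolog groups and typed pairs

All-vs-all Smith–Waterman scores (BLOSUM62, affine gaps) are normalised by
the larger self-score, giving weights in (0, 1]; exact alignment replaces a
heuristic search stage because family-scale inputs are at most a few
hundred proteins. Edges below the cutoff (default 0.3) are dropped and the
graph is clustered by Markov clustering (inflation default 1.5, matching
the defaults of the orthology pipeline this emulates). Within each cluster,
every unordered pair receives exactly one type:

* same species → **paralog**;
* cross-species reciprocal best hit → **ortholog** (ties admit all tied
  partners, so no hidden ordering);
* remaining cross-species pairs → **coortholog**.

These operational definitions are this package's documented contract; the
original pipeline's exact pair semantics are internal to that software. The
species-by-species tallies form a pair table whose diagonal holds paralog
counts and whose off-diagonal cells hold ortholog/coortholog counts, with
`aggregate_pair_totals()` summing each component once per unordered pair —
an accounting confirmed by the packaged fixture's arithmetic.

## Expression analytics

RPKM is `1e9 · count / (mapped_total · length_bp)`; the heatmap export is
`log2(rpkm + 1)` (avoids log 0). Fold changes use the 2^-ddCt model with
replicate averaging on the dCt scale and an exact fold of 1 for the
calibrator. Pearson correlations over candidate interaction edges (supplied
externally — interaction priors are an input, not a computation) are signed
by their zero crossing, with no significance filter by default since none
is prescribed; profiles with zero variance and candidates absent from the
matrix are reported as not-calculable, with the two causes distinguished
(`zero_variance` vs `missing`).

## The synthetic-data generators

Every stage is testable without downloads because the generators produce
inputs with recorded ground truth; each generator is a pure function of its
seed.

* **Proteins** (`gen_wrky_protein()`): uniform background over the 20-letter
  alphabet; implanted domains draw their linker and spacer residues from an
  alphabet without C and H, so the implanted coordinating residues are the
  only ones visible to the scanner and recovery is exact by construction.
* **Reference set** (`gen_reference_set()`): one labeled template per
  group/subgroup with label-typical spacings; the random non-conserved
  positions provide placement signal. It is a synthetic stand-in for a
  curated labeled reference set and is named as such.
* **Family histories** (`simulate_family_evolution()`): ancestral genes
  duplicate (Poisson per branch), are lost, and substitute per site along a
  given species tree; pair truth is read off the recorded event history.
  Cross-species pairs whose divergence is a pre-speciation duplication are
  counted as coorthologs (out-paralogs are lumped with coorthologs, the
  same bucket the operational caller puts them in). Default rates
  (10 ancestral genes, birth 0.02, loss 0.02 per unit branch) represent a
  family with occasional duplication — about one event per family per tree
  — which is the regime in which one-to-one ortholog inference is
  meaningful; each surviving post-speciation duplication necessarily
  converts one true coortholog pair into a reciprocal-best-hit call, so
  precision of ortholog calling degrades linearly in the duplication rate
  regardless of sequence divergence.
* **Promoters** (`gen_promoters()`): uniform ACGT background scrubbed of
  accidental consensus matches before implanting, and re-drawn if an
  implant boundary creates an extra match, so the recorded truth is the
  complete hit list. Because a uniform 1500 bp background would otherwise
  contain about one accidental W-box match on average, implant-recovery
  tests exercise coordinate and strand bookkeeping, not discrimination from
  background.
* **Counts** (`gen_expression()`): negative-binomial counts whose module
  genes share a latent per-sample factor; the loading sign plants positive
  or negative correlation.
* **Ct tables** (`gen_ct_table()`): constructed by inverting the 2^-ddCt
  model, so zero-noise recovery is exact and noisy recovery can be checked
  for bias.

What the generators do *not* emulate: real amino-acid composition, indels
(substitution-only mutation), codon structure, promoter base composition,
or read-mapping noise. Passing tests therefore demonstrate the correctness
of the algorithms and their bookkeeping, not performance on real genomes.

## Numerical choices and degenerate inputs

* Alignment scoring: BLOSUM62, gap of length L costs 11 + L.
* NJ ties: lowest index pair; negative branch lengths clamped at 0.
* MCL: self-loops of weight 1, pruning threshold 1e-5, idempotence declared
  at max |change| < 1e-6, cluster extraction by connected components of the
  limit matrix; empty graphs give empty cluster lists and singletons are
  legal clusters.
* p-distance pairs with no shared columns are an error in user-facing
  calls; inside the bootstrap they take the maximal distance 1 so a
  replicate cannot crash the run.
* pI bisection tolerance 1e-6 (well below the 1e-3 quoted precision);
  peptides with no ionizable side chains still have a defined pI through
  the termini.
* Identity counts `X` as a mismatch even against `X`.

## Problem sizes used in the checks

The shipped test-suite and acceptance runs use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: 300 proteins
for group recovery, 100 template-derived group II proteins at 10%
substitution noise for subgroup recovery, six replicate three-species family
simulations (about 30 genes each) for ortholog precision/recall, 1000
random instances per physicochemical oracle comparison, and trees of 4–8
taxa (with exhaustive topology enumeration at 4–5) for neighbor joining.

## Known limitations

* The real nine-genome comparison and the original carrot expression data
  are not reproducible here (they require external proteomes and raw
  reads); the packaged tables provide exact worked-example aggregates
  instead, and the printed tables' internal inconsistencies are preserved
  verbatim rather than resolved.
* Profile-HMM search is replaced by anchored pattern scanning; proteins
  with heavily diverged heptapeptides that only an HMM would find are
  missed by design.
* Center-star alignment is a heuristic multiple alignment; for the short,
  highly conserved domain regions used here it is adequate, but it is not a
  substitute for progressive aligners on divergent full-length proteins.
* The subcommand-style interface is provided as R functions
  (`run_identify()`, `run_homology()`, `run_expression()`) rather than a
  shell executable; the functions are the package's operational surface.
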