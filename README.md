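# wrkyfam

Genome-scale analysis of the WRKY transcription-factor family in R.

WRKY proteins are one of the largest plant transcription-factor families.
Their ~60-residue DNA-binding domain consists of a conserved heptapeptide
(canonically `WRKYGQK`) followed by a zinc finger — either C2H2
(`C-X4/5-C-X22..24-H-X1-H`) or C2HC (`C-X7-C-X22/23-H-X1-C`) — and this
architecture defines the family's classification: group I (two domains,
C2H2), group II (one domain, C2H2; subgroups IIa–IIe by phylogeny) and
group III (one domain, C2HC).

`wrkyfam` provides the full analysis pipeline:

* **domain scanning** — heptapeptide-anchored detection of complete WRKY
  domains with canonical spacing signatures (`assemble_domains()`,
  `spacing_signature()`, `parse_signature()`);
* **classification** — rule-based group calls plus reference-guided
  neighbor-joining placement into subgroups with bootstrap support
  (`classify_family()`, `neighbor_joining()`, `bootstrap_support()`);
* **characterization** — isoelectric point, GRAVY, instability and
  aliphatic indices, residue-class composition, exon–intron structure and
  promoter cis-element scanning (`physchem_profile()`,
  `scan_cis_elements()`);
* **homology** — all-vs-all Smith–Waterman similarity, Markov clustering
  into homolog groups, and typed pair calling (paralog / ortholog /
  coortholog via reciprocal best hits) tallied in a species-by-species
  pair table (`mcl()`, `call_pair_types()`, `pair_count_table()`);
* **expression** — RPKM quantification, qPCR fold changes by the
  2^-ddCt method, and signed Pearson co-expression networks over candidate
  interaction edges (`rpkm_matrix()`, `ddct_fold_change()`,
  `coexpression_network()`);
* **synthetic data** — seeded generators for every input, with recorded
  ground truth (`gen_wrky_protein()`, `simulate_family_evolution()`,
  `gen_promoters()`, `gen_expression()`, `gen_ct_table()`).

Transcriptions of a published carrot (*Daucus carota*) WRKY family table
(95 genes) and of a nine-species homolog pair-count table ship as packaged
fixtures and serve as exact worked examples.

## Worked example

```r
library(wrkyfam)

## the packaged 95-gene carrot family table
s <- summarize_family(load_table1())
s$group_counts
#>            I           II          III unclassified
#>           17           67           11            0
s$variant_counts[["WRKYGQK"]]
#> [1] 88
c(s$length_min, s$length_max)
#> [1] 101 865

## nine-species homolog pair totals
aggregate_pair_totals(load_table2())
#>    paralog   ortholog coortholog
#>        543        452        677

## scan and classify a synthetic cohort with known truth
refs <- gen_reference_set()
coh  <- gen_wrky_cohort(5, c("I", "IIc", "III"), seed = 1,
                        reference_set = refs)
fam  <- classify_family(coh$records, refs)
table(fam$group)
#>
#>   I  II III
#>   5   5   5

## expression: a 16-fold induction planted and recovered
ct <- gen_ct_table(data.frame(gene = "g1", condition = "salt", fold = 16),
                   noise_sd = 0, seed = 1)
ddct_fold_change(ct$ct_table)
#>   gene condition      dct ddct fold
#> 1   g1   control  3.0620347    0    1
#> 2   g1      salt -0.9379653   -4   16
```

The group counts are read directly off the packaged table (group II sums
subgroups IIa–IIe); the pair totals sum the table's diagonal (paralogs) and
off-diagonal ortholog/coortholog cells once per unordered species pair. In
the qPCR example, a fold of 16 corresponds to a ddCt of −4 cycles relative
to the control condition.

## Documentation

The methods vignette (`vignettes/wrky-family-analysis.Rmd`) describes the
models, parameter defaults, numerical policies, what the synthetic
generators do and do not emulate, and known limitations.
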