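# ndhaudit

Audit of plastid *ndh* gene degradation across annotated plastome cohorts.

## What it does, and for whom

The eleven plastid *ndh* genes (*ndhA*–*ndhK*) encode subunits of the NDH
(NAD(P)H dehydrogenase-like) complex that mediates cyclic electron flow
around photosystem I. In many plant lineages — orchids prominently —
these genes decay repeatedly and independently: copies shorten through
indels, pick up premature stop codons, and eventually vanish from the
plastome. Anyone comparing dozens of GenBank plastomes faces the same
chores: extract the gene annotations, decide what length each gene
*should* be, classify every copy, and ask how many times each gene was
independently lost on the phylogeny. ndhaudit automates that audit for
plastome comparative studies.

The pipeline:

1. **Parse** annotated plastomes from GenBank flat files
   (`parse_plastome()`): gene/CDS features, `join`/`complement`
   locations, origin-spanning features on circular molecules,
   inverted-repeat duplicates.
2. **Infer reference lengths** per gene from the cohort
   (`determine_reference_lengths()`): an exact-length value shared by
   ≥ 50% of annotated samples wins (consensus); otherwise a two-pass
   mean that drops copies deviating ≥ 30% from the first-pass mean.
3. **Classify** each gene in each sample (`build_status_matrix()`), with
   ratio r = observed/reference length:
   * **lost** — absent, or r < 0.20;
   * **truncated** — internal stop codon in frame 0 (genetic code
     table 11);
   * **pseudogenized** — r < 0.80 or r > 1.20;
   * **functional** — otherwise.
4. **Supermatrix statistics** (`select_genes()`, `concatenate()`,
   `alignment_statistics()`): genes present in ≥ 90% of samples,
   concatenation with gap-padding and a RAxML-style partition table,
   variable-site (SNP) and missing-data percentages.
5. **Loss mapping** (`loss_summary()`, `render_matrix_tree()`): minimum
   independent loss events per gene by parsimony with the root anchored
   to "retained", and the status-matrix-beside-tree figure.
6. **Simulation** (`simulate_tree()`, `simulate_cohort()`,
   `simulate_alignment()`): GenBank-format cohorts with planted states,
   so the whole pipeline is testable offline against a known truth
   table.

## Worked example

Simulate a 12-sample cohort in which *ndhF* is lost in two separate
clades, *ndhB* is truncated in one cherry, and one sample carries a
half-length *ndhJ* pseudogene — then recover all of it from the GenBank
files alone:

```r
library(ndhaudit)

tree <- simulate_tree(12, seed = 7)
scenario <- data.frame(
  gene  = c("ndhF",    "ndhF",    "ndhB",      "ndhJ"),
  tips  = c("s02;s03", "s09;s10", "s04;s05",   "s07"),
  state = c("lost",    "lost",    "truncated", "pseudogenized"))
cfg <- simulation_config(12, tree_seed = 7, mutation_seed = 8,
                         state_scenario = scenario)
cohort <- simulate_cohort(tree, cfg)

records <- lapply(cohort$files, parse_plastome)
refs    <- determine_reference_lengths(records)
subset(refs, gene %in% c("ndhB", "ndhE", "ndhF", "ndhJ"))
#>    gene reference_length_bp    method n_used n_excluded
#> 2  ndhB                2241 consensus     12          0
#> 5  ndhE                 306 consensus     12          0
#> 6  ndhF                2118 consensus      8          0
#> 10 ndhJ                 477 consensus     12          0
```

Every reference comes from the consensus path (all intact copies agree
exactly); *ndhF* is inferred from the 8 samples that still annotate it.

```r
status <- build_status_matrix(records, refs = refs)
summary(status)[c("ndhB", "ndhF", "ndhJ"), ]
#>      gene functional truncated pseudogenized lost
#> ndhB ndhB         10         2             0    0
#> ndhF ndhF          8         0             0    4
#> ndhJ ndhJ         11         0             1    0

losses <- loss_summary(cohort$tree, status)
losses[losses$gene_name %in% c("ndhB", "ndhF", "ndhJ"), 1:3]
#>    gene_name n_min_losses n_tips_lost_state
#> 2       ndhB            0                 0
#> 6       ndhF            2                 4
#> 10      ndhJ            0                 0
```

The four *ndhF*-less samples sit in two disjoint clades, so parsimony
reports **2 independent losses**; truncated and pseudogenized copies
count as retained under the default encoding (use
`encoding = "functional_vs_nonfunctional"` to derive them too). Every
cell matches the generator's truth table exactly
(`cohort$truth`), and
`render_matrix_tree(cohort$tree, status, "fig")` draws the colored
status grid beside the tree (SVG + PNG).

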