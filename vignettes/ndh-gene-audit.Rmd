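---
title: "Auditing plastid ndh gene degradation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing plastid ndh gene degradation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The eleven plastid *ndh* genes (*ndhA*–*ndhK*) encode subunits of the
NDH (NAD(P)H dehydrogenase-like) complex, which supports cyclic electron
flow around photosystem I. Across land plants — and conspicuously in
several orchid lineages — these genes decay repeatedly and independently:
copies shorten or lengthen through indels, acquire premature stop codons,
and eventually disappear from the plastome. Public GenBank plastomes
record that decay in their annotations, but the annotations are
heterogeneous: the "same" gene is annotated at wildly different lengths
across samples, sometimes as a fragment, sometimes not at all.

ndhaudit packages the audit of such a cohort: establish what length each
gene *should* be from the cohort itself, classify every gene in every
sample into one of four degradation states, and count how many times each
gene was independently lost on a phylogeny.

## The classification model

For each gene the pipeline first infers a **reference length** from the
annotated copies across the cohort (only samples that annotate the gene
contribute; where a sample has inverted-repeat duplicates, its longest
copy represents it):

1. **Exact-length consensus.** If one exact bp value is shared by at
   least 50% of contributing samples, it becomes the reference. This is
   the common case for well-conserved genes.
2. **Two-pass mean** (fallback, for strongly varying genes). The
   arithmetic mean $m_1$ of all contributing lengths is computed; copies
   whose relative deviation $|\ell - m_1|/m_1$ is at least 30% are
   excluded; the mean of the remainder, rounded half-up to an integer, is
   the reference.

Each (sample, gene) cell is then assigned a state from the length ratio
$r = \ell_{obs}/\ell_{ref}$ and a reading-frame scan:

| state | rule |
|---|---|
| lost | gene absent, or $r < 0.20$ |
| truncated | an internal stop codon in frame 0 (genetic code table 11) |
| pseudogenized | $r < 0.80$ or $r > 1.20$ |
| functional | otherwise |

All bounds are **strict**: a ratio of exactly 0.20 is pseudogenized, not
lost; exactly 0.80 or 1.20 is functional. The rules are checked in the
order listed, so absence dominates everything and an internal stop
dominates a length violation.

Losses are mapped onto a phylogeny by binarizing each gene's column
(default: `lost` vs everything else; alternatively functional vs
non-functional) and counting the minimum number of state changes by
parsimony, with the root anchored to the "retained" state — the cohort's
common ancestor is assumed to have carried the gene, which is what makes
the count a count of *losses*.

## Tunable parameters

All thresholds live in one object, `audit_thresholds()`:

| parameter | default | meaning |
|---|---|---|
| `consensus_fraction` | 0.50 | exact-length share required for the consensus path |
| `outlier_fraction` | 0.30 | relative deviation at which a copy leaves the second-pass mean (closed bound: exactly 30% is excluded) |
| `pseudo_lower`, `pseudo_upper` | 0.80, 1.20 | functional length window (strict bounds) |
| `lost_fraction` | 0.20 | below this ratio a copy counts as lost (strict) |
| `supermatrix_presence` | 0.90 | minimum cohort presence for a gene to enter the supermatrix (inclusive) |

The defaults are the audit's published operating point; they are exposed
because the same machinery applies to other gene families with other
conventions. Raising `lost_fraction` can only convert cells *to* lost,
never away from it — this monotonicity is enforced by a property test.

## Design choices where the procedure was open

Several details of the audit are not fixed by the procedure's published
description; the package resolves them as follows, and each choice is
testable and configurable where it plausibly matters.

* **Consensus ties.** Two lengths can reach the consensus share only at
  an exact 50/50 split. The tie is treated as *no consensus* and falls
  through to the two-pass mean: the consensus rule presumes a unique
  majority value, and averaging is the safer resolution of ambiguity.
* **Rounding.** The two-pass mean is rounded half-up (`floor(x + 0.5)`).
  Integer references are reported and some rounding convention is
  unavoidable; half-up keeps `[100, 101] -> 101` rather than R's default
  half-to-even.
* **Gene vs CDS annotations.** When both exist for a gene, the CDS wins:
  it carries the reading frame the stop-codon scan needs. The `gene`
  feature is the fallback.
* **Inverted-repeat duplicates.** Both copies are parsed and retained
  (`copy_index` 1, 2, ...); classification and reference inference use
  the longest copy per sample. A sample with one intact and one decayed
  IR copy plausibly retains function, and IR fragments must not drag the
  reference mean down.
* **Stop-scan scope.** By default every non-lost copy is scanned, so an
  internal stop dominates a length violation; this matches figures that
  plot truncated and pseudogenized as sibling states. The alternative —
  scanning only copies already outside the length window, i.e. truncation
  as a refinement of pseudogenization — is available as
  `truncation_scope = "pseudogenized_only"`. `check_stops = FALSE`
  reproduces a purely annotation-driven assessment (appropriate when
  annotations are trusted and frames unexamined, as for outgroup
  samples).
* **Genetic code.** Table 11 (bacterial/plastid). Its stop codons are
  TAA, TAG, TGA; codons containing ambiguity letters never match a stop.
* **Parsimony algorithm.** `fitch_min_transitions()` is a unit-cost
  dynamic program (Sankoff recursion) over the observed state alphabet.
  On bifurcating trees this is exactly Fitch counting; on polytomies the
  plain intersection/union shortcut can overcount, while the DP stays
  exact, which the brute-force oracle test verifies.
* **Root anchoring.** `loss_summary()` fixes the root to "retained".
  Without the anchor, a gene lost in *every* tip would count zero
  changes; with it the count is never zero when any tip is lost. Note
  that a rooted tree has no stem edge: a gene lost in all tips costs one
  change per root-child clade (two on a bifurcating root), which is the
  correct parsimony statement on the sampled tree.
* **SNP definition.** A supermatrix column is variable when it contains
  at least two distinct unambiguous bases (A/C/G/T); gaps, N and IUPAC
  ambiguity letters are ignored in the variability test. Missing cells
  are `-` and `N` only. These are the most common conventions; both are
  deliberately simple and documented rather than configurable knobs.
* **Config echo format.** The simulator echoes its configuration as JSON
  (`config.json`) rather than YAML; no YAML writer is available in the
  package's dependency footprint and the content is identical.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` writes real GenBank flat files (LOCUS / FEATURES /
ORIGIN, circular records, `join`/`complement` locations, optional
origin-spanning genes and IR duplicates) whose gene states are *planted*:

* functional genes are stop-free ORFs of exactly the true length,
  starting ATG and ending in a terminal TAA;
* truncated genes are full-length copies with one stop codon substituted
  at a configurable relative position (default mid-gene);
* pseudogenized genes are stop-free copies at a configurable fraction of
  the true length (default 50%, safely inside the 20–80% band);
* lost genes are either deleted and unannotated, or annotated fragments
  at 10% of the true length (exercising the sub-20% rule);
* states are assigned to whole clades of a simulated tree, and conflicts
  (a tip assigned two states for one gene) are rejected, which enforces
  the irreversible-loss (Dollo) discipline of the scenarios;
* background substitutions are applied on top, but rejection-sampled so
  they can never create a stop codon in a scanned frame nor touch the
  planted start/stop codons.

The generator therefore targets the classifier's decision boundaries,
not biological realism: there is no codon model, no rate heterogeneity,
no annotation error, no partial gene duplication, no IR boundary shift.
A green planted-state recovery test establishes that the pipeline
implements its own rules exactly; it says nothing about how often real
GenBank annotations violate those rules' assumptions — on real cohorts
the manual-curation step the audit describes remains necessary.

Default true lengths are the eleven reference lengths rounded to the
nearest codon multiple (e.g. *ndhA* 2262, *ndhB* 2241, *ndhE* 306,
*ndhJ* 477), so synthetic cohorts resemble the real size spectrum from
~300 bp to ~2.3 kb. Effect sizes are validated against the thresholds at
configuration time: a pseudogene factor inside the functional window, or
a lost fragment above the lost bound, is rejected rather than silently
producing unrecoverable states.

Reference-length recovery has a stated precondition worth repeating:
decayed copies must form a strict minority of *annotated* samples. At an
exact 50/50 split between the true length and one decayed length, the
consensus is ambiguous by design and the two-pass mean of a perfectly
bimodal sample can exclude everything — the pipeline then raises an
error rather than fabricating a reference.

## Numerical and degenerate-input choices

* Consensus counting compares `count >= fraction * n` with a `1e-9`
  slack so that exact boundary counts (e.g. 3 of 6) are not lost to
  floating-point noise; the presence threshold uses the same guard.
* `detect_premature_stop()` requires at least one complete codon,
  ignores a trailing 1–2 nt remainder, and exempts the final complete
  codon (the normal terminator).
* Features whose locations cannot be resolved (e.g. mixed-strand
  trans-spliced joins) are skipped with a warning; a missing ORIGIN
  section is a hard parse error.
* An empty gene list, an all-gap alignment column, a tree/matrix overlap
  of zero — each fails loudly with a named error rather than returning a
  silent default.

## Known limitations

* Alignment computation, tree inference and divergence dating are out of
  scope; alignments arrive as FASTA, trees as Newick, node ages only as
  annotations to draw.
* The GenBank parser resolves single-strand `join`/`complement`
  locations and origin-spanning features, which covers plastome gene
  annotations; trans-spliced mixed-strand genes (*rps12*-style) are
  skipped with a warning.
* Loss counts are parsimony minima on the sampled tree. Denser taxon
  sampling can only increase them, and a stem-lineage loss shared by the
  whole cohort is counted once per root-child clade because a rooted
  tree has no stem edge.
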