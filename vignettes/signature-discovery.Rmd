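---
title: "Discovering clade-specific molecular signatures with cladesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering clade-specific molecular signatures with cladesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladesig)
```

## The problem

Two kinds of rare genomic events make excellent diagnostic markers for a
bacterial clade. A **conserved signature indel (CSI)** is an insertion or
deletion of defined length inside a highly conserved region of a widely
distributed protein, present in every member of a phylogenetically coherent
group and absent from all outgroup homologs; because such an indel arises
once, in the group's common ancestor, its shared presence is strong evidence
of common descent and a near-perfect diagnostic character. A **conserved
signature protein (CSP)** is a protein whose significant homologs occur only
inside one monophyletic group. `cladesig` automates the discovery of both from
a set of predicted proteomes, together with the core-genome supermatrix
phylogeny that supplies the clade hypotheses being tested.

The pipeline has five stages:

1. **Family clustering** (`cluster_proteomes`, `select_core_families`) —
   greedy seeded clustering in the UCLUST style: sequences are visited in
   length-descending order (id ascending as tie-break) and join the first
   seed to which they align with >= 50% identity and >= 50% mutual coverage,
   else found a new seed. Families present in >= 80% of genomes form the core.
2. **Alignment and trimming** (`align_family`, `trim_blocks`,
   `concatenate_alignments`) — progressive profile–profile alignment, a
   relaxed conserved-block filter, and column-wise concatenation into a
   supermatrix with partition bookkeeping.
3. **Phylogeny** (`distance_matrix`, `neighbor_joining`, `midpoint_root`,
   `bootstrap_support`) — Poisson-corrected distances with pairwise deletion,
   neighbor joining, midpoint rooting, column-resampling bootstrap.
4. **CSI scan** (`find_csi_candidates`, `classify_polarity`, `map_region`,
   `format_signature_alignment`) — the analysis core, below.
5. **CSP screen** (`mini_search`, `call_csps`) — a Smith–Waterman search of
   query proteins against all proteomes, then a specificity verdict per query.

`run_pipeline()` chains all five and writes the reports.

## The CSI model and its parameters

A candidate CSI is a maximal alignment-column interval $I$,
$1 \le |I| \le$ `max_indel_size` (default 30), such that either every focal
("ingroup") row carries at least one residue somewhere in $I$ while every
outgroup row is all-gap across $I$ (an **insertion** pattern) or the reverse
(**deletion**), each side tolerating at most `max_ingroup_exceptions` /
`max_outgroup_exceptions` violating rows (defaults 0, mirroring the strict
"all members / no outgroup" reading; published tables allow "an isolated
exception", which is one knob away). A surviving interval must be embedded in
conserved context: at least `min_conserved_per_flank` (default 5) conserved
columns within the `flank_window` (default 20) columns on each side — the
classic "5–6 conserved residues in the neighboring 30–40 amino acids" rule,
read as ~20 columns per side. A column is *conserved* when its modal non-gap
residue (X never counts) is shared by >= 80% of its non-gap rows and its gap
fraction is <= 0.2. All thresholds live in `csi_params()`.

Polarity follows the outgroup: the character-bearing state found in the
focal group with a gapped outgroup is an insertion, the reverse a deletion;
optional external reference rows that contradict the outgroup consensus
downgrade the call to `ambiguous`. `map_region()` reports the span from the
first conserved column of the left flank to the last conserved column of the
right flank in ungapped coordinates of a chosen reference sequence — the
convention of published signature tables, which quote indel *regions* (indel
plus conserved flanks) rather than bare indel positions. Excerpts rendered by
`format_signature_alignment()` use the dash-identity convention (top line in
full; `-` = identical to top line, `.` = gap) and display 60–100 reference
residues.

Because the exception counts make the interval predicate non-monotone,
"maximal" is implemented as *not strictly contained in a larger satisfying
interval of the same pattern*; overlapping same-pattern survivors merge into
the larger one. The test suite checks the whole scanner against an exhaustive
interval-enumeration oracle on hundreds of random gappy alignments.

## The CSP model

From a 12/13-column tabular hit table (or `mini_search()`'s built-in
Smith–Waterman search), a query is **specific** when at most `max_exceptions`
(default 0) of its significant non-self hits (e-value <= 1e-5 by default)
come from outside the focal group; queries with no significant non-self hits
are **orphans**, never specific. Significance is always relative to the taxon
universe actually searched — the reports say so in their headers. The e-value
of `mini_search` is the standard extreme-value transform of the raw
Smith–Waterman score using the gapped BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$), with $m$ the query length and $n$ the total
database residue count; the verdict logic only requires it to be a
documented, deterministic, monotone function of score.

## Numerical and algorithmic choices

- **Alignment engine.** One affine-gap engine (BLOSUM62, gap open 11,
  extend 1; a gap of length $k$ costs $11 + k$) implemented in C++ backs
  pairwise identity, greedy clustering and the local search. Identity is
  identical columns over aligned columns *excluding terminal-gap columns*;
  coverage of each sequence is the fraction of its residues inside that core
  region — so mutual 50% coverage prevents chaining of short fragments.
  Ties in the dynamic program prefer match over gap-in-second over
  gap-in-first, making every result deterministic. Tests cross-check scores
  against `Biostrings::pairwiseAlignment` and a plain-R DP oracle.
- **Progressive alignment** uses shared 3-mer distances, a UPGMA guide tree
  (`hclust`, average linkage), and profile–profile global DP on
  frequency-weighted BLOSUM62 column scores. It is a deterministic stand-in
  for a production aligner; externally computed aligned FASTA can be imported
  with `read_fasta(aligned = TRUE)` + `msa()` at any point.
- **Trimming** instantiates "relaxed" block filtering: conserved = modal
  residue in > 50% of rows and gap fraction <= 0.5; blocks split at runs of
  more than 8 consecutive non-conserved columns, must start and end on
  conserved columns, and must span >= 5 columns. All four knobs are exposed in
  `trim_params()` so stricter dialects can be matched. Trimming is idempotent
  and always a column subset (both tested).
- **Trees.** Maximum-likelihood inference is out of scope; the built-in path
  is NJ on Poisson-corrected distances (exact on additive matrices — the
  module's oracle), with newick import for externally computed trees.
  Negative NJ branch lengths are clamped to zero with a message. Bootstrap
  supports resample columns with replacement under a caller-supplied seed.
- **Degenerate inputs.** Saturated pairs (p >= 1) and pairs with no shared
  non-gap column are errors naming the pair; all-gap columns are rejected at
  `msa()` construction; empty trim results are legal.

## What the simulator emulates — and what it does not

`generate_dataset()` builds a known rooted tree whose focal clade and
outgroup are sister subtrees (leaf counts 12 and 8 by default), scaled to
unit height so `substitution_rate` (default 0.2) is the expected root-to-tip
substitutions per site. Families (100 × 300 aa) evolve by a uniform
20-state replacement process (Poisson event counts per branch, uniform
replacement among the other 19 residues) with no unplanned indels. CSIs are
planted on the focal-clade stem, one per family, sizes 1–7 recycled plus one
20-residue event — the size span of published ordinal-level signature tables;
inserted segments are identical across carriers and the ±20-residue flanks
are locked against substitution, so every planted event is detectable at
default `csi_params()` by construction (`lock_flanks = FALSE` gives an
unlocked hard mode). CSPs are extra genes evolved only on the focal subtree;
noise proteins are uniform random sequences private to each genome.

This gives exact ground truth but idealizes real data: no rate heterogeneity
or realistic substitution model, no unplanned indels or alignment ambiguity,
no paralogy beyond what clustering resolves, no horizontal transfer, and a
search universe limited to the supplied genomes rather than a comprehensive
database. Passing the recovery tests therefore demonstrates that the
*machinery* is correct (the scanner equals its oracle; planted events are
recovered with exact sizes; nothing is found when nothing is planted) — not
that real proteomes would yield any particular number of signatures.

Problem sizes used by the tests and the acceptance script (20 genomes, 100
families, 300 aa, 200 fuzzed alignments, 500 NJ matrices) were chosen as the
defaults of the study design above; the full acceptance run takes a few
minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
library(cladesig)

ds <- generate_dataset(sim_config(seed = 7))
res <- run_pipeline(pipeline_config(), ds$proteomes, ds$groups,
                    out_dir = "run1")

# planted vs detected
nrow(ds$manifest$csi_events)   # 15 planted
nrow(res$csi)                  # 15 detected
sum(res$csp$verdict == "specific")  # 5 planted CSPs, 5 specific calls

cand <- res$csi[1, ]
al <- res$alignments[[match(cand$family_id,
                            vapply(res$core, `[[`, "", "family_id"))]]
cat(format_signature_alignment(al, cand, al$id[1]))
```

## Known limitations

- The internal aligner is adequate for the conserved families this analysis
  targets but is not a replacement for a production MSA tool on divergent or
  heavily gapped families; use the aligned-FASTA import path there.
- Specificity verdicts (CSI and CSP) are relative to the supplied taxa; a
  marker "specific" against 8 outgroup genomes may fail against a larger
  search horizon.
- Greedy identity clustering is not orthology inference: in-paralogs are
  resolved by best score to the seed, and reciprocal-best-hit or tree-aware
  methods are out of scope.
- ML tree inference and branch-support dialects of external tools are out of
  scope; import their newick output instead.
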