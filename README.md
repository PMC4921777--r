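# cladesig

Discovery of clade-specific molecular signatures — conserved signature
indels (CSIs) and conserved signature proteins (CSPs) — from bacterial
proteomes, together with the core-genome supermatrix phylogeny such analyses
rest on.

## What it does

Rare genomic events make the most reliable diagnostic characters for a
bacterial taxon. A **CSI** is an insertion or deletion of defined length,
embedded in a conserved region of a widely distributed protein, that is
present in all members of a phylogenetically coherent group and absent from
outgroup homologs: having arisen once in the group's common ancestor, it is a
near-perfect synapomorphy. A **CSP** is a protein whose significant homologs
are confined to one monophyletic group. `cladesig` automates both screens and
the supporting phylogenomics:

- **Core families** — greedy seeded clustering (UCLUST-style: length-descending
  order, join the first seed at ≥ 50% identity and ≥ 50% mutual coverage under
  global BLOSUM62/11/1 alignment), then selection of families present in
  ≥ 80% of genomes.
- **Supermatrix** — progressive profile–profile alignment per family, relaxed
  conserved-block trimming (Gblocks-style: blocks split at runs of > 8
  non-conserved columns, ends on conserved columns, length ≥ 5, gaps allowed
  in up to half the rows), concatenation with partition bookkeeping.
- **Tree** — Poisson-corrected pairwise-deletion distances, neighbor joining,
  midpoint rooting, column-resampling bootstrap supports, Robinson–Foulds
  comparison; newick import/export for externally computed (e.g. ML) trees.
- **CSI scan** — for a focal group vs outgroup, find maximal column intervals
  (≤ 30 columns) where one side bears residues and the other is all-gap
  (configurable exception counts), require ≥ 5 conserved columns within the
  20 flanking columns on each side, call insertion/deletion polarity from the
  outgroup state, map the signature region onto reference-protein
  coordinates, and render dash-identity alignment excerpts (60–100 residues).
- **CSP screen** — Smith–Waterman search of query proteins against all
  proteomes (or an imported 12/13-column tabular hit table); a query is
  *specific* when no significant hit (e ≤ 1e-5) comes from outside the focal
  group, *orphan* when it has no significant non-self hits at all.
- **Simulator** — proteome sets evolved on a known tree with planted
  clade-specific indels and clade-restricted genes, so every stage can be
  validated against ground truth.

## Worked example

```r
library(cladesig)

ds <- generate_dataset(sim_config(n_ingroup = 4, n_outgroup = 3,
                                  n_families = 8, n_csi = 2, n_csp = 1,
                                  n_noise_proteins = 1, seed = 19))
res <- run_pipeline(pipeline_config(), ds$proteomes, ds$groups,
                    out_dir = "run1")
```

```
[17:39:25] clustering 7 proteomes
[17:39:26] 16 families, 8 core
[17:39:26] aligning and trimming 8 core families
[17:39:28] supermatrix: 2381 columns over 7 genomes
[17:39:28] building tree (poisson distances)
[17:39:29] 2 CSI candidate(s)
[17:39:29] CSP screen: focal genomes' proteins vs all proteomes
[17:39:30] 1 specific protein(s)
```

The two CSI candidates are exactly the two planted events — a 1-residue
insertion and a 20-residue deletion — with exact sizes, and the one specific
protein is the planted clade-restricted gene:

```r
res$csi[, c("family_id", "col_start", "col_end", "polarity", "size_min", "size_max")]
#>   family_id col_start col_end  polarity size_min size_max
#> 1      F004       235     235 insertion        1        1
#> 2      F011       171     190  deletion       20       20
res$csp[res$csp$verdict == "specific", c("query_id", "n_in_hits", "n_out_hits")]
#>       query_id n_in_hits n_out_hits
#> 1 ing_01.CSP01         3          0
```

`run1/` contains the family table, supermatrix FASTA + partition map, the
midpoint-rooted newick tree, the CSI and CSP reports (published-table layout:
`1 aa ins`, `20 aa del`, region, specificity, violators) and a run log.
Signature excerpts use the dash-identity convention (top line printed in
full with its residue coordinate; `-` = identical to the top line,
`.` = gap; `*` marks the indel columns):

```r
cand <- res$csi[1, ]
al <- res$alignments[[match(cand$family_id,
                            vapply(res$core, `[[`, "", "family_id"))]]
cat(format_signature_alignment(al, cand, al$id[1], csi_params(display_window = 60)))
#>                                                  *
#> ing_01.SF005  205  EKHLAWRVTLITFTGHPMGNHMWEFWMDYTKSQRAVILNSFIVQLREDGGCMAKTVGPNC
#> ing_02.SF005       ------T--M--------------------------------------------M-----
#> out_01.SF005       ------------------------------.----------------------------R
#> ...
```

Real data enter the same way: `read_proteomes()` on per-genome FASTA files,
`read_group_map()` for the clade definitions, optionally
`read_fasta(aligned = TRUE)` / `read_newick()` / `read_hit_table()` to slot in
externally computed alignments, trees and homology searches.

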