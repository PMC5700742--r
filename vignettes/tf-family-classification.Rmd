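---
title: "Rule-based TF/TAP family classification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based TF/TAP family classification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrepertoire)
```

## The classification model

Transcription factor (TF) and transcriptionally active protein (TAP)
families are defined here purely by protein-domain presence and absence.
A rule set maps each family $f$ to a pair of domain sets
$(M_f, X_f)$ — mandatory and forbidden — with the invariants that $M_f$
is non-empty and $M_f \cap X_f = \emptyset$. Given the set $D$ of domains
hit on one (sequence, frame) at or below the acceptance E-value cutoff,
family $f$ is *satisfied* iff $M_f \subseteq D$ and $X_f \cap D =
\emptyset$.

Because different databases name the same family differently (NF-YC and
CCAAT-HAP5; the ABI3/VP1 label for B3), a synonym map resolves aliases to
canonical names in a single step, and families satisfied only through
synonymous names count as one family, not as a conflict.

Two assignment modes are implemented:

* **strict** — assign only when exactly one canonical family is
  satisfied. Zero satisfied families yields `no-rule-satisfied`, or
  `forbidden-domain-present` when some family failed *only* because a
  forbidden domain was hit; two or more yields `multi-family-conflict`.
  This deterministic conflict behaviour reproduces how presence/absence
  pipelines historically under-counted families such as CCAAT-HAP3, whose
  members often also carry evidence for the sibling CCAAT-HAP5 rule.
* **best-domain** — resolve conflicts in favour of the satisfied family
  whose mandatory-domain hit has the lowest E-value. "Strongest
  similarity" is deliberately interpreted as lowest E-value with bit
  score as first tie-break; the final tie-break (lexicographically
  smallest family name) exists only to keep the procedure deterministic
  and is recorded in the output's `note` field. Best-domain assignments
  are a strict superset of strict-mode assignments, which a property test
  pins.

Frames of a translated transcript are classified independently; one
nucleotide sequence may legitimately yield assignments on several
reading frames, and the (sequence, frame) pair is the identity unit
everywhere downstream.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `e_threshold` (classification) | `1e-3` | domain hits above this E-value are ignored. Search-stage cutoffs are tool-specific; this is the acceptance cutoff on the per-domain (independent) E-value. Configurable per call. |
| merge priority | `protein > tfcat > itak > rule` | source trust order for consensus merging |
| `lower`, `upper` (representation band) | `0.9`, `1.1` | closed interval for "similar" representation |
| `min_seq_coverage` | `0.30` | curation: rows covering less than 30% of columns are dropped (strict `<`) |
| `max_col_gap_frac` | `0.90` | curation: columns with at least 90% gaps are dropped (inclusive `>=`) |
| `max_pairwise_identity` | `0.95` | curation: later sequence of a pair at 95%+ identity is dropped (inclusive `>=`) |
| `e_threshold` (expression link) | `1e-5` | best-hit links require `evalue <= 1e-5` |
| `e_threshold` (homolog rescue) | `1e-3` | rescue hits require `evalue < 1e-3` (strict) |

The two linkage thresholds differ on purpose in their boundary handling:
links use a non-strict `<=`, rescue a strict `<`, matching the usual
phrasing of each step ("E-value = 1e-5" versus "with an E-value of
1e-3"); both are configurable.

## Consensus merging

Multiple pipelines classify both proteins and translated transcripts, so
their outputs must be reduced to one non-redundant repertoire. The merge
applies a stepwise priority: a protein-level record is always accepted;
a transcript record survives only if no higher-priority source already
claimed the same (sequence, frame, family) key and no accepted protein
record covers the same (sequence, family) pair. Two readings of the
protein-acceptance step were possible — suppression per sequence or per
(sequence, family) — and the per-family reading was chosen: a locus can
genuinely carry domains of two families (which is why repertoires count
more domains than sequences), and a protein record for one family should
not silence transcript evidence for a different family on the same
locus. Every elimination is logged with the surviving record's source, so
accepted + eliminated always equals the input (a tested conservation
invariant), and the three-level counts obey
`domains >= sequences >= genes` by construction.

## Comparative repertoire statistics

Families are compared between a query and a comparator species on three
bases: share of the TF/TAP repertoire, raw counts, and share of all
protein-coding transcripts. Ratios are always query/comparator; a family
is `under`-represented below 0.9, `over` above 1.1, and `similar` inside
the closed band. Reading "between 0.9 and 1.1" as a closed interval (and
"exceeded"/"smaller than" as strict) is a deliberate literal choice and
is configurable. The band is not reciprocal-symmetric ($1/1.1 \approx
0.909$), so swapping the species roles near a bound can change the call —
a targeted test asserts this rather than hiding it, and the query species
is always the numerator.

Families present in exactly one species are flagged (`absent-query` /
`absent-comparator`) instead of producing infinite ratios, and are
excluded from the summary triple. For comparisons against a
paleotetraploid, `halve_counts()` divides the comparator's counts by a
ploidy factor with half-away-from-zero rounding (so a total of 13419
halves to 6710, and a count of 7 to 4) before raw-count ratios are
formed; share bases are scale invariant, so halving would not change
them.

Published tables often list only the largest families; `repertoire_table()`
therefore accepts explicit repertoire totals alongside a partial
per-family table, and shares use those totals. For complete tables the
totals are the column sums, as the printing convention assumes. Display
convention: shares to 2 decimal places, percent differences to 1;
comparisons always run on unrounded values.

## Alignment curation

Family alignments are curated by the cycle *align → drop low-coverage and
duplicate rows → drop gap-dominated columns → drop near-duplicate
sequences → realign*, repeated until the sequence count and column count
are both unchanged between consecutive cycles. All three filters only
remove material, so the (sequences, columns) pair is lexicographically
non-increasing and the loop terminates; `max_cycles` (default 20, with a
warning when hit) is a safety bound only. The filter order is fixed and
pinned by a test: the row and column filters do not commute, since
removing gap columns can lift a sparse row back over the coverage
threshold.

Pairwise "95% similarity" is computed as identity on the current
alignment — matching non-gap positions over columns where at least one
sequence has a residue — rather than from re-aligned pairs or a
similarity matrix; this is the cheapest faithful reading and is applied
greedily in input order (the first member of a near-identical set is the
one kept, and later members are compared against the kept set only).
Motif-based curation rebuilds a sequence by concatenating its discovered
motifs in start order, ties broken by end then motif id, with no overlap
resolution; the conventional discovery settings (E-value at most 0.001,
widths 8–200 residues, any-repeat mode, at most 100 motifs) are recorded
as configuration for the external discovery tool, whose tabular output
`read_motifs()` consumes.

## Clade labeling and root ordering

A tree containing query leaves and reference anchors of known clade
membership labels the queries in one of two ways. The default,
nearest-anchor, gives each query the group of the anchor at minimal
patristic distance; the alternative, smallest-anchored-clade, uses the
smallest clade containing the query and an anchor, requiring all anchors
inside to agree. Both plausible readings are implemented because the
underlying procedure is rarely stated explicitly in comparative studies;
nearest-anchor is the default since it degrades more gracefully on
paraphyletic reference sets. Ties are broken by distance to the MRCA,
then lexicographically, and logged. Unrooted input is an error unless
midpoint rooting is explicitly requested, because root placement changes
`root_order()`; bootstrap supports are carried but never used in
assignment.

`root_order()` ranks groups by the edge-count depth of their MRCA from
the root (branch-length depth as tie-break), reporting exact ties as
shared ranks — the ordering used when comparing family organisation
across studies "from closest to furthest from the root".

## The synthetic study system

`synthetic_spec()` describes a genome whose families are *defined* by
planted domain architectures, emulating exactly the statistical structure
the classifier exploits: families with at least one mandatory domain,
decoys carrying a forbidden domain alongside mandatory ones, genes with
one or more gene models, spurious/dropped domain hits at a stated rate,
discordant pseudo-pipeline outputs, and a reference expression atlas in
which every transcript has exactly one identical best-hit copy.

Key generator choices:

* Planted domains are fixed random 15-residue motifs embedded in random
  background, so a trivial exact-match scanner (`scan_domains()`) serves
  as the domain caller in tests; 15 residues over a 20-letter alphabet
  makes accidental matches vanishingly unlikely.
* Every family's first mandatory domain is a signature used by no other
  family, which guarantees planted members satisfy exactly one family —
  the property that makes 100% recovery the correct expectation rather
  than a tuned one.
* Synthetic E-values are $10^{-\mathrm{len}/2}$ capped at $10^{-300}$:
  monotone in match length, reproducible, spanning realistic magnitudes.
* Transcripts are random reverse-translations (standard code, no internal
  stops) flanked by uniform 0–30 nt UTRs on either strand, which
  exercises all six reading frames without dominating sequence length.
* All generators are seeded; identical seeds give byte-identical FASTA
  and table outputs (tested at the file level).

What the generator does **not** emulate: realistic phylogenetic sequence
evolution, codon usage bias, HMM emission profiles and partial/degraded
domain matches, paralog similarity structure, or annotation artifacts.
Passing end-to-end tests therefore demonstrates correctness of the
*logic* (classification, merging, counting, linkage) under known ground
truth — not robustness to the noise profile of real domain scanners,
which enters only through the abstract hit-noise and disagreement rates.

## Problem sizes and verification

The test suite verifies the classifier against brute-force enumeration
over every hit subset for random rule sets of at most 6 domains (30 rule
sets in the unit tests, 200 in the acceptance suite), runs the full
pipeline on a synthetic genome of about 500 genes / 750 gene models across
25 families, checks merge idempotence and conservation on 100 random
record sets, curation termination on 100 random alignments, and
nearest-anchor assignment against an exhaustive patristic oracle on 50
random 20-leaf trees. These sizes were chosen to exercise every code path
and boundary (the 30% / 90% / 95% thresholds each sit on their stated
side) while keeping the suite fast enough to run habitually.

## Known limitations

* The bundled rule sets are synthetic or illustrative; a real rule file
  (e.g. a Lang-style catalogue of 134 mandatory and 89 forbidden rules
  across 111 families) is swappable YAML configuration, not package data.
* Motif discovery, alignment, tree inference and similarity search are
  external contracts: the package curates, consumes and reconciles their
  standard-format outputs but does not reimplement them.
* `read_motifs()` expects the tabular motif layout; raw motif-discovery
  text reports must be tabulated first.
* Representation calls are fixed ratio bands, not statistical tests; no
  enrichment p-values are produced, by design.
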