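---
title: "Classifying diatom lipoxygenases and predicting their regiospecificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying diatom lipoxygenases and predicting their regiospecificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtype)
```

## The problem

Lipoxygenases (LOX) are non-heme iron dioxygenases that oxygenate
polyunsaturated fatty acids at one specific carbon of the chain. The carbon
attacked defines the enzyme's type in the LOX-N nomenclature: a LOX12
oxidizes C12, with carbons numbered from the carboxyl carbon C1. In diatoms
the resulting oxylipins carry ecological signalling roles, and candidate
LOX sequences recovered from genome and transcriptome surveys are mostly
annotated as hypothetical proteins. Two sequence-level observations make a
desk classification possible:

* the catalytic iron is held by five coordination residues — canonically
  three histidines, one asparagine and a C-terminal isoleucine/leucine —
  arranged along the sequence in a conserved spacing (His, four spacers,
  His ... His, three spacers, Asn ... terminal Ile), and diatom candidates
  vary at these sites in a small number of characteristic ways;
* in a docked enzyme–substrate pose, the substrate carbon nearest the iron
  plus the state of the oxygen-delivery channel determine which carbon is
  oxidized, hence the LOX type.

`loxtype` implements both observations as a tested pipeline: sequence
curation, coordination-pattern scanning and classification, bootstrap-
supported clustering, and geometric regiospecificity calls, plus seeded
generators that produce synthetic inputs with known truth for every stage.

## Locating the coordination sites

`scan_coordination()` does not search for motifs de novo. Each query is
globally aligned (BLOSUM62, affine gaps) to the best-identity reference in
an annotation panel (`coordination_anchors()`), and the reference's five
annotated positions are projected through the alignment onto the query.
Projection alone is not trusted: each projected position must carry the
residue class expected at that role — His for the three His sites,
Asn/His/Gln/Ser at the fourth site, Ile/Leu/Val at the terminal hydrophobic
site — either exactly at the projected position or within a ±2-residue
window that absorbs small alignment jitter around gaps. A site failing
verification is marked not found rather than guessed. Valine is admitted at
the terminal site because equivalent positions in related structures carry
it in place of isoleucine.

Queries whose best alignment identity falls below 10% are treated as
unalignable: every site is reported not found (completeness 0), which
downstream curation interprets as "no detectable LOX domain". When the
third histidine is immediately followed by another histidine the pattern
records a tandem flag and keeps the first of the pair as the coordinating
residue, since sequence alone cannot resolve which histidine ligates the
iron and structural models favour the first.

From the located sites the scanner measures `s1` (residues strictly
between the first histidine pair; canonical 4) and `s2` (residues strictly
between the third histidine and the fourth site; canonical 3).

## The group decision table

`classify_pattern()` maps a measured pattern to one of eight terminal
groups. The table is ordered and total for any pattern with at least three
located sites:

| condition | fourth site | label |
|---|---|---|
| `s2 == 4` (insertion) | Asn | `G4a` |
| `s2 == 4` | Gln | `G4b` |
| `s2 == 4` | Ser | `G5a` |
| `s2 == 4` | His | `G5b` |
| `s2 == 3`, `s1 < 4` | His | `G3` (deletion between the His pair) |
| `s2 == 3`, tandem His | Asn | `G6` |
| `s2 == 3` | Asn | `G1`/`G2` by motif, else `UNRESOLVED_12` |
| anything else | | `UNCLASSIFIED` |

Groups 1 and 2 share the canonical pattern and differ only by a motif
present in one group and absent in the other. Because such motifs are a
property of the dataset rather than of the method, they are configuration
(`motif_config()`, a small PROSITE-like dialect: literals, character
classes, bounded gaps). Without motifs the canonical pattern is labelled
`UNRESOLVED_12` and left to the phylogenetic stage, which resolves it by
clade co-membership with motif-resolved neighbours.

Two deliberate operationalizations: a "deletion between the first two
histidines" is `s1 < 4` (the exact deleted count is not specified by the
pattern descriptions), and an "insertion" before the fourth site is
exactly `s2 == 4`; larger spacings fall to `UNCLASSIFIED` rather than
being force-fitted. Ser is reported at the fourth site in only part of the
sequences of subgroup 5a; patterns from the remainder carry an unknown
identity there and may legitimately land in `G4a` or `UNCLASSIFIED`.

## Curation

`filter_candidates()` keeps a record iff its length reaches `min_length`
(default 200 residues — a convention for "not a fragment"; a complete LOX
domain is several hundred residues) and its pattern preserves at least
`min_sites` of the five coordination sites (default 3). Zero located sites
is reported as the more specific `removed_no_domain`. The filter is
idempotent and monotone in `min_sites`; both properties are tested.

## Trees, supports, and groups

Pairwise distances are Poisson-corrected p-distances over global
alignments, `d = -ln(1 - p)`, with `p` clamped at 0.95 so saturated pairs
get a finite ceiling of `-ln(0.05) ≈ 3.0` substitutions/site. Trees are
standard Saitou–Nei neighbor joining (`ape::nj`), deterministic given the
matrix. Clade support comes from `B = 100` column bootstrap replicates over
a multiple alignment built by a deliberately simple progressive aligner
(NJ guide tree over the pairwise distances, Needleman–Wunsch on profile
frequency columns with BLOSUM62 scores and a linear gap penalty of -8,
implemented in C++). The aligner exists to provide columns for resampling,
not publication-grade alignments; distance-based clustering consumes only
clade membership and support.

Group extraction is bipartition-based. Each internal edge with support
above the threshold (default 95, strict) defines a supported split,
represented by its *smaller* tip side; on a tree these canonical sides are
nested, and the maximal supported sides are the top-level groups, with
uncovered leaves forming a residual group. Representing splits by rooted
clades instead is a trap we document because we fell into it: with any
fixed root, the complement of a tight family adjacent to the root is
itself a fully supported "clade" and swallows most of the tree. A group
whose members carry two or more distinct fourth-site identities is
recursively split along supported internal edges into lettered subgroups
(`4a`, `4b`, ...) until each subgroup is homogeneous, mirroring how the
subgroup pairs are distinguished by full-support edges plus the
fourth-residue mutation.

## The regiochemistry rule

The iron abstracts a hydrogen from the nearest substrate carbon `n`;
oxygen adds two carbons away, at `n - 2` or `n + 2`. The package selects
the side through the oxygen channel rather than through a head-in/head-out
arithmetic convention: the two candidates are labelled by pocket side
(with the head external, `n - 2` lies toward the entrance and `n + 2`
toward the bottom; head internal swaps them), an open gate — glycine at
the channel mouth — delivers O2 to the entrance-side candidate, and a
closed gate (alanine or anything bulkier) drives O2 deeper, selecting the
bottom-side candidate. This channel-side formulation was chosen because
the naive phrasing "oxidation two positions after the nearest carbon when
the head is external" contradicts the best-characterized head-external,
open-channel case (C10 nearest, C8 oxidized); side selection reproduces
every internally consistent worked pose in both categorical
(`call_lox_type_categorical()`) and geometric
(`call_lox_type_geometric()`) form, and the two routes are required by the
test suite to agree on every generated pocket.

Candidates falling off the chain ends fall back to the other side with a
`single_candidate` flag; a chosen carbon that is not an endpoint of a
recorded double bond is flagged `candidate_not_at_double_bond`; two
carbons within 0.05 Å of the iron minimum raise `tie_at_iron`, the lower
index is reported, and both candidates appear in the rationale (composite
labels such as "LOX4/7" arise exactly from such ties). Stereochemistry
(R/S) is out of scope; calls are regiochemical only. A small number of
reported assignments in the literature (a C6-nearest pose assigned
position 9; a deep-head C13 pose assigned LOX15) cannot be produced by any
±2 side selection; the package makes no attempt to reproduce them and its
flags are the honest signal that a pose falls outside the rule.

## Pocket geometry

Structures are parsed from fixed-column PDB (via bio3d). The pocket frame
is configuration, not detection: the gate residue's Cα marks the channel
mouth, the centroid of configured pocket-bottom residues marks the deep
end, and depth is the projection on the mouth→bottom unit axis. The ligand
chain is rebuilt from connectivity: the carboxyl carbon is the unique
carbon bonded (≤ 1.6 Å) to two oxygens, the chain is ordered by a walk
over C–C bonds (≤ 1.9 Å, branching is an error), and bonds ≤ 1.40 Å are
recorded as double bonds — a fixture-oriented threshold; real poses can
override bond orders upstream. The head is internal iff C1 projects deeper
than Cn. All geometric operations are invariant under rigid motion, which
the tests check with random rotations and translations.

## What the generators emulate — and what they do not

`make_group_sequences()` produces, per terminal group, a family of
sequences with the group's coordination skeleton implanted at randomized
but recorded positions (His pair in the first half, His/fourth-site couple
in the second half, terminal Ile near the end), discriminating motifs in
groups 1 and 2, and ≤ 2% point mutations outside implanted positions for
within-family diversity. The eight family backgrounds radiate star-like
from one ancestral background, about 55% divergence per major group, with
subgroup pairs a further ~12% apart on a shared background. The star
radiation is a deliberate numerical choice: fully independent backgrounds
saturate every inter-family distance at the clamp ceiling, and identical
tie-broken joins then collect spurious bootstrap support; radiation keeps
distances unsaturated and deep edges honestly unsupported. Background
composition is uniform over the 20 residues.

`make_pocket_fixture()` builds an idealized pocket on a straight axis:
mouth at the origin, bottom 15 Å deeper, iron midway, the chain laid along
the axis at bond-length steps with small lateral kinks, anchored so the
requested carbon is uniquely nearest the iron with a ≥ 0.4 Å margin, and
double bonds every third bond from C5 (the cis-methylene pattern).

Passing tests on these fixtures show that the scanning, grouping and
calling machinery is correct on inputs satisfying its assumptions. They do
not show robustness to real data: real LOX families share conserved
domains beyond five sites, real alignments are harder than 98%-identical
families, real docked poses have curved chains, thermal noise and
ambiguous bond orders, and real group boundaries need not coincide with
bootstrap-supported clades. Problem sizes in the shipped tests — 32
sequences with B = 100 bootstrap, NJ-recovery checks up to 8 taxa against
the generating topology, 20 scanner seeds — were chosen as the smallest
sizes at which each property is meaningfully exercised.

## Numerical choices, in one place

| quantity | value | where |
|---|---|---|
| site verification window | ±2 residues | `scan_coordination()` |
| degenerate-alignment identity floor | 10% | `scan_coordination()` |
| p-distance clamp | 0.95 (`d ≤ -ln(0.05)`) | distances |
| progressive-aligner gap penalty | -8 per column, linear | `progressive_alignment()` |
| bootstrap replicates | 100 | `bootstrap_supports()` |
| support threshold | > 95 | `extract_groups()` |
| fragment length floor | 200 residues | `curation_config()` |
| completeness floor | 3 of 5 sites | `curation_config()` |
| carboxyl C–O bond | ≤ 1.6 Å | `ligand_chain()` |
| C–C bond | ≤ 1.9 Å | `ligand_chain()` |
| double bond | ≤ 1.40 Å | `ligand_chain()` |
| iron-distance tie margin | 0.05 Å | `nearest_carbon()` |
| contact / H-bond cutoffs | 4.0 / 3.5 Å | `contacts()`, `hbonds()` |

Ties are broken by lowest index everywhere, and every stochastic step
takes an explicit seed, so identical inputs and seeds reproduce every
report byte-identically.

## Known limitations

* Group 1/2 separation is only as good as the supplied motifs; without
  them the label is `UNRESOLVED_12` unless the tree resolves it.
* The gate map is binary (Gly open, everything else closed); residues
  other than Gly/Ala at the gate are treated as closed and surfaced in the
  gate report rather than modelled.
* Trees are unrooted; group indices are deterministic (ordered by first
  member id) but are labels, not a rooted taxonomy.
* The ±2 rule is a first-order geometric model; poses that genuinely
  oxidize elsewhere are flagged, not explained.
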