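---
title: "Methods: geometric annotation, homology summarization and gap-aware merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric annotation, homology summarization and gap-aware merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaforge)
```

rnaforge builds per-nucleotide datasets for RNA 3D chains by joining a
structural record stream (computed from atomic coordinates) with a
homology record stream (computed from family sequence alignments). This
vignette explains the procedures, the parameters that matter, the
numerical decisions, and what the synthetic fixtures do and do not
establish about real data.

## Geometric descriptors

All descriptors derive from one primitive, the torsion angle of four
points, computed with the atan2 formulation on the two plane normals
about the central bond. Angles are reported in degrees on **[0, 360)**
everywhere; signed conventions are converted at output and never mixed.
Undefined values (missing atoms, chain termini, unresolved neighbours,
collinear triples, coincident points) propagate as `NA`, never as
sentinel numbers. Degenerate geometry returns `NA` rather than raising,
so one distorted residue cannot abort a chain annotation.

Per residue, `annotate_chain()` reports:

* backbone torsions α–ζ over the standard atom quadruples, with
  α requiring O3′ of residue i−1 and ε/ζ requiring P (and O5′) of
  residue i+1, so termini and unresolved neighbours produce exactly the
  `NA` pattern implied by the atom dependencies;
* χ over O4′–C1′–N9–C4 for purines and O4′–C1′–N1–C2 for pyrimidines.
  The syn/anti label uses the standard ±90° window about cis:
  χ ∈ [0°, 90°) ∪ [270°, 360°) is syn, anything else anti. The window
  is stated explicitly here because annotators differ and the boundary
  choice is a genuine convention, not a fact;
* the ribose endocyclic torsions ν₀–ν₄ and the Altona–Sundaralingam
  pseudorotation. With ν_j = ν_max·cos(P + 144°·(j−2)), the phase is
  recovered as the quadrant-correct arctangent of
  ((ν₄+ν₁) − (ν₃+ν₀)) versus 2·ν₂·(sin 36° + sin 72°), and the
  amplitude as the Euclidean norm of the two arguments — this handles
  ν₂ ≈ 0 without a division. A planar ring (all ν below 10⁻⁹°) yields
  amplitude 0 with an undefined phase and label. The pucker label is
  the 36°-wide bin of the pseudorotation wheel containing P, ten bins
  with C3′-endo at [0°, 36°); published annotators do not document
  their exact binning, so the contiguous standard wheel is used and
  stated;
* the three pseudotorsion systems: η/θ over P and C4′, η′/θ′ over P
  and C1′, η″/θ″ over P and the base centre. The base centre is the
  centroid of the base ring heavy atoms (N1, C2, N3, C4, C5, C6, plus
  N7, C8, N9 for purines). "Base centre" admits several definitions;
  the centroid is the simplest reproducible one, and results for η″/θ″
  should be compared across tools with that caveat in mind.

Helix form labels (A/B/Z) are **never** computed from coordinates: they
are ingested from an external annotation file when one is supplied and
default to `none` otherwise, as does the base-pairing information
(`paired`, `pair_type`). Interactions that do not fit the 12
Leontis–Westhof families are kept under the catch-all label `other`
rather than discarded.

## Homology summarization

Alignments are read from Stockholm 1.0 or aligned FASTA with the two
gap dialects kept distinct: `-` marks a deletion against the family
consensus, `.` insertion padding. `T` is accepted and folded to `U`
(DNA-alphabet rows occur in rRNA databases); lowercase letters (the
covariance-model insertion convention) survive reading and are folded
to uppercase only during counting. PSSMs are plain per-column counts —
no sequence weighting, no deduplication — because the intended summary
is literally the base composition of the column. The consensus is the
base of maximal frequency with ties broken alphabetically (A < C < G <
U), `-` when gaps outnumber every base, `N` when ambiguity codes do.
The tie-break is arbitrary but deterministic and documented.

Sequence identity between two aligned rows counts identical-base
columns over columns where **at least one** row has a base; columns
gapped in both rows are ignored, and two all-gap rows have undefined
identity. Without gaps this reduces to 1 − normalized Hamming distance.
The denominator convention is a design decision — other tools divide by
the shorter sequence length — and is pinned by tests. Chains cluster by
Ward's method (`hclust`, `ward.D2`) on the dissimilarity 1 − identity;
an independently coded Lance–Williams recurrence in the test suite
confirms merge heights and topology.

## Gap-aware merging

The chain sequence (gaps = unresolved residues) and the chain's aligned
row (gaps = `-`/`.`) describe the same molecule but differ position by
position. The merge is a two-pointer scan applying, in priority order:
(1) equal symbols pair and both pointers advance; (2) an unresolved
residue facing a non-gap looks ahead in the alignment — first for a
`-` before the next base letter, ignoring `.`; failing that for a `.`
— and pairs with the first hit, otherwise the residue keeps *unknown
homology* (all PSSM fields null); (3) an alignment gap facing a
resolved base is skipped; (4) two differing bases abort with a
mismatch error, which can only mean the inputs describe different
molecules. Three mechanics are deliberate choices: the lookahead
consumes the matched gap column (required for strictly increasing
column assignments), the horizon ends at the next base letter, and the
leftmost eligible gap wins. Exhaustive enumeration over all sequence
pairs up to length 6 verifies totality, monotonicity, agreement with an
independent recursive reference, and that the mismatch error fires
exactly when the degapped sequences differ.

Unresolved residues optionally receive the consensus base of their
alignment column in `nt_align_code` (`fill_missing()`); `nt_code`
always keeps the `-`, so resolution status is never lost, and the fill
can be disabled.

## Selection through equivalence classes

Chain selection operates purely on provided tables: a chain list with
resolutions, a partition into redundancy equivalence classes, and
family mappings with residue ranges. The resolution filter keeps chains
at or below the threshold (default 4.0 Å, the conventional cutoff
below which backbone geometry is still interpretable) and drops
unknown-resolution chains. Chains without a direct mapping inherit
every family mapped to a classmate (flagged `inferred`); a chain mapped
to k families is copied and truncated to each mapping's range. Two
under-specified corners are resolved explicitly: inference runs on the
*unfiltered* tables, so a classmate excluded by resolution still
donates its mapping; and when classmates disagree on a family's range
the widest range wins, maximizing retained data, with clipping to the
recipient chain's length applied (and logged) at truncation time.

## The dataset store

The store is a single-file relational database written as an SQL dump
in SQLite dialect (CREATE TABLE + INSERT statements) with tables for
chains, families, alignment columns and nucleotides, and a matching
reader. Rows are emitted in canonical order and numeric values with 17
significant digits, so identical inputs rebuild a byte-identical file
and doubles survive a round-trip exactly. Referential integrity
(nucleotide→chain, column→family) is checked on every build. Per-chain
CSV export uses a fixed documented column order, empty string for null
— nullable numeric fields (the PSSM frequencies, defined only where
homology is known) therefore keep the null-vs-zero distinction through
export and re-import, which matters because `paired = 0` is meaningful
(no intra-chain partner) while a null frequency means "no homology
information at all". Dates are ISO-8601 strings and the release-date
filter is strictly "earlier than".

## Density analysis on the torus

Pseudotorsion couples live on a torus, so the kernel density estimate
wraps both axes: each Gaussian kernel is summed over ±2 full turns,
which makes the truncation error far below the 10⁻⁶ integral tolerance
at any realistic bandwidth. The default bandwidth is Scott's rule per
axis, σ_circ·n^(−1/6), using the circular standard deviation of the
wrapped sample, floored at 1° so near-degenerate samples cannot
produce a singular estimate; a fixed bandwidth can be supplied instead.
The default grid is 256×256 over [0, 360)², resolving 1.4° features at
negligible cost. Contour levels are ρ+σ, ρ+2σ and ρ+4σ with ρ the mean
and σ the standard deviation of the evaluated grid — thresholds tied
to the grid statistics rather than absolute densities, so panels with
different sample sizes remain comparable. Nucleotide strata follow the
published practice for these plots: the C3′-endo panel excludes
nucleotides whose ingested form label is A, B or Z (stem nucleotides
crowd the central peak), while the C2′-endo panel filters on pucker
only; because captions in the literature are ambiguous about the
second point, a flag (`exclude_helical_c2`) exposes both behaviours.
"Unique chains" for these analyses means one record per
(structure, chain) pair, dropping the copies created by multi-family
mapping.

## The synthetic generator

`make_helix_mmcif()` builds a regular single-stranded helix from one
nucleotide template repeated by rise (2.81 Å) and twist (32.7°) —
A-form-like values. The template's ribose is constructed to an *exact*
pseudorotation state: ν₁ and ν₂ are imposed during sequential atom
placement and the remaining degrees of freedom (three ring bond angles
and, necessarily, the bond lengths — a ring with all five lengths
fixed cannot realize the pseudorotation torsion pattern exactly) are
solved by Levenberg–Marquardt until the measured closure torsions match
the forward-generated values to ~10⁻⁷°, with lengths softly anchored
at ideal values (they move by millångströms). Phase and amplitude are
therefore mathematical ground truth, recoverable through the full
file-write/parse/annotate path to better than 10⁻³° (the residual
comes from fixed-precision coordinates in the writer). The 5′-terminal
residue is written without a phosphate, as in real structures, which
deliberately exercises terminal-undefined-angle handling: α *and* β
are undefined at residue 1, and the θ family there too. Gaussian
coordinate noise (`coordinate_noise_sd`, Å) is available for
robustness checks. Bases are planar idealized rings placed at a
requested χ (default 200°, anti).

The generator emulates: periodic backbone geometry with known pucker,
both alignment gap dialects, redundancy-class structure with partially
missing mappings. It does **not** emulate base-pairing geometry,
realistic energetics, sequence-dependent backbone variation,
experimental noise structure, or alignment error. Green tests
therefore establish correctness of the *computations* — torsions,
pseudorotation inversion, merging, counting, clustering, density
estimation — on inputs with known truth; they do not validate
biological conclusions drawn from real structures, where coordinate
error, alternate conformers and annotation disagreements dominate.

`make_toy_alignment()` derives homolog rows from a consensus by
per-position substitution and deletion and per-junction insertion
(defaults 0.1 / 0.05 / 0.02 — within the range seen across curated RNA
family alignments, where per-column conservation is high); the chain's
row carries the chain sequence so remapping is exercised end to end.
`make_selection_tables()` draws resolutions uniformly on (0, 6] Å
(bracketing the 4.0 Å default threshold from both sides) and gives
each chain a direct mapping with probability 0.6, leaving the rest
inferable only through their class.

## Problem sizes and tolerances in the test suite

The suite verifies the torsion primitive against an independent
vector-algebra implementation on 10⁴ random quadruples (max
disagreement below 10⁻⁹°) and rigid-motion invariance of every
descriptor at the same tolerance; pseudorotation recovery on 10³
random (P, ν_max) draws to 10⁻⁶°; the remapper exhaustively on all
~1.4×10⁵ precondition-satisfying sequence pairs up to length 6 plus
error-side enumeration to length 4 and 2×10⁴ sampled longer pairs;
PSSM normalization on 10³ random alignments to 10⁻¹²; and the torus
KDE against a replicate-points oracle to 10⁻⁸ on 128-grids. These
sizes keep the full suite under a few minutes while leaving the
tolerances far tighter than any scientific use requires.

## Known limitations

* Ligand detection is heuristic (component-table membership plus
  non-polymer flags plus C1′/phosphate-linkage checks); exotic
  modified residues absent from the bundled parent table fold to `N`.
* The bundled modified-nucleotide table is a curated subset of common
  wwPDB components, not an exhaustive dictionary; its provenance is
  the table file itself, not any annotator's internal list.
* Only model 1 and the first alternate location of an mmCIF file are
  read; NMR ensembles and altloc populations are out of scope.
* Base-pair classification, stacking and helix-form detection are
  never computed, only ingested.
* The two descriptors of 3′-phosphorus position reported by some
  annotators are omitted: their definition is not published precisely
  enough to reimplement faithfully.
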