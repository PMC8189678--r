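# rnaforge

Construction of multi-scale, per-nucleotide datasets for RNA 3D chains,
joining two complementary information sources position by position:

* **structure** — geometric descriptors computed from atomic coordinates
  in mmCIF files: the six backbone torsions α, β, γ, δ, ε, ζ; the
  glycosidic torsion χ with its syn/anti label; the five ribose
  endocyclic torsions ν₀–ν₄; the pseudotorsion pairs η/θ (over P and C4′
  virtual bonds), η′/θ′ (over P and C1′) and η″/θ″ (over P and the base
  centre); and the Altona–Sundaralingam pseudorotation phase P,
  amplitude ν_max and sugar-pucker conformer label;
* **homology** — per-column base frequencies (PSSMs) summarized from
  multiple sequence alignments of each chain's RNA family, in Stockholm
  or aligned-FASTA format with both covariance-model gap dialects
  (`-` deletion vs `.` insertion padding).

The two per-position streams rarely line up: residues may be unresolved
in 3D, and the aligned chain row contains family gaps. A gap-aware
two-pointer merge reconciles them, pairing unresolved residues with
deletion gaps where possible, falling back to insertion columns, and
marking homology as unknown when the alignment offers no gap at all.
Merged records land in a single-file relational store (tables for
chains, families, alignment columns and nucleotides, written as an
SQLite-dialect SQL dump) with per-chain CSV export and composable
resolution/date/family filters.

Around this core the package provides: chain selection through
redundancy equivalence classes (chains without a direct family mapping
inherit their classmates'; multi-family chains are copied and truncated
per mapping), mmCIF normalization (renumbering from one, ligand/ion
removal, modified-base folding via a bundled parent table, unresolved
residues materialized from `entity_poly_seq`), sequence identity
matrices with Ward clustering, periodic kernel density estimation of
pseudotorsion couples on the angle torus with ρ+{1,2,4}σ contour
levels, and a synthetic-fixture generator (idealized helices with
mathematically exact pseudorotation ground truth, toy alignments,
selection tables) that makes the whole pipeline testable without any
external data.

Key formulas, as used throughout:

* pseudorotation: ν_j = ν_max·cos(P + 144°·(j−2)), inverted
  quadrant-correctly via
  tan P = ((ν₄+ν₁) − (ν₃+ν₀)) / (2·ν₂·(sin 36° + sin 72°));
* pucker label: the 36°-wide wheel bin containing P, with C3′-endo at
  [0°, 36°);
* η_i = torsion(C4′(i−1), P(i), C4′(i), P(i+1)),
  θ_i = torsion(P(i), C4′(i), P(i+1), C4′(i+1)).

## Worked example

```r
library(rnaforge)

spec  <- helix_spec(n_residues = 6, sequence = "ACGUAC")
chain <- make_helix_mmcif(spec, out_path = "helix.cif")
chain
#> <rna_chain 1SYN_A: 6 residues (6 resolved), resolution 2>
#>  sequence: ACGUAC

ann <- annotate_chain(chain)
round(ann[, c("eta", "theta", "phase", "amplitude")], 2)
#>      eta  theta phase amplitude
#> 1     NA     NA    18        40
#> 2 218.04 214.65    18        40
#> 3 218.04 214.65    18        40
#> 4 218.04 214.65    18        40
#> 5 218.04 214.65    18        40
#> 6     NA     NA    18        40
```

Every ribose reports exactly the requested pseudorotation state
(phase 18°, amplitude 40°, so `pucker_label` is `C3'-endo` throughout);
the pseudotorsions are undefined at both termini (η needs residue i−1
and θ residue i+1; the 5′ residue also has no phosphate, as in real
structures) and identical at every interior position, as a periodic
helix demands.

```r
aln <- make_toy_alignment(toy_msa_spec(5, "ACGUAC", seed = 2),
                          chain_sequence = "AC-UAC", chain_name = "1SYN_A")
pssm <- compute_pssm(aln)
pssm$consensus
#> [1] "A" "C" "G" "U" "A" "C"

fill_missing(remap("AC-UAC", aln[["1SYN_A"]]), pssm)
#>   chain_index alignment_column nt_code nt_align_code homology_known
#> 1           1                1       A             A           TRUE
#> 2           2                2       C             C           TRUE
#> 3           3                3       -             G           TRUE
#> 4           4                4       U             U           TRUE
#> 5           5                5       A             A           TRUE
#> 6           6                6       C             C           TRUE
```

Residue 3 is unresolved in 3D: `nt_code` keeps the gap character, while
`nt_align_code` receives the most common base of its alignment column
(G). `build_store()` then assembles chains, descriptors, mappings and
PSSMs into the relational store; `export_csv()` writes one CSV per
chain.

A command-line front end is installed with the package
(`exec/rnaforge`): `extract`, `annotate`, `pssm`, `identity`, `remap`,
`select`, `stats-pseudotorsions` and `stats-lengths` subcommands wrap
the same functions for shell pipelines.

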