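---
title: "Binding-site annotation transfer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site annotation transfer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`msaligmap` annotates unknown protein sequences by transferring
experimentally grounded binding-site information from homologous PDB
structures. The procedure has five stages — structure parsing, contact
detection, multiple sequence alignment, secondary-structure assignment,
and column-wise projection — and its central assumption is the usual one
for homology-based transfer: the sequences share a common fold and
function, so residues occupying the same alignment column occupy
equivalent structural positions. That assumption degrades sharply below
roughly 30 % pairwise identity (the "twilight zone"), which is why the
package computes the full pairwise identity matrix of every run and warns
about — but does not refuse — sub-twilight pairs: the cutoff is a
reliability caveat, not a hard validity boundary, and the user may have
external evidence of homology.

## Structure parsing

Sequences are extracted from the observed ATOM records, not from SEQRES.
This is deliberate: contact detection needs coordinates, so residues
without coordinates could never carry a binding annotation, and silently
filling gaps from SEQRES would fabricate columns with no structural
support. Consequences the rest of the pipeline must honour:

* Author numbering is preserved exactly — gaps (5, 6, 9, 10) and
  insertion codes (52, 52A, 53) included. The residue-number map is a
  bijection between dense 0-based sequence indices and
  (author number, insertion code) pairs, asserted in both directions by
  the tests.
* Multi-model (NMR) entries contribute only their first model; a single
  coordinate set is required for distance computations, and the first
  model is the depositor's representative conformer.
* Alternate locations resolve to the highest-occupancy atom, ties broken
  by file order — the standard convention.
* MODRES records plus a small built-in table (MSE→MET, SEP→SER, …) map
  modified residues to canonical letters; anything unmappable becomes `X`
  so the alignment alphabet stays valid.

mmCIF, assemblies, and hydrogen addition are out of scope.

## Contact detection

Interactions are classified by heavy-atom distance alone, into the two
classes used by LigPlot-style interaction diagrams:

* **hydrogen bond** — one atom can donate and the other accept, and the
  pair distance lies in **2.70–3.35 Å**;
* **non-bonded contact** — any other heavy-atom pair within **3.90 Å**.

Donor/acceptor capability comes from a fixed table for the 20 standard
amino acids (backbone N donates except proline, backbone O accepts;
sidechain O/N per residue chemistry). Ligand chemistry is in general
unknown, so partner atoms are typed by element: N and O count as both
donor and acceptor — a deliberate superset that can only over-call
hydrogen bonds, never miss one on distance grounds. Peptide partners with
standard residues use the protein table instead.

Angles and explicit hydrogens are not used. A distance-only test is the
reproducible core of the two-class scheme: it needs no hydrogen placement
heuristics for sidechains, behaves identically on X-ray and NMR input,
and its failure modes (an occasional mis-typed borderline pair) move a
record between two classes that are both reported. `nonbonded_min`
(2.90 Å) is a reporting floor only: a pair closer than that is
geometrically anomalous but still a contact, so it is kept and flagged
rather than dropped. Per (residue, class) only the minimum-distance atom
pair is recorded; a residue may legitimately appear in both classes, and
the renderers treat the two styles (bold, underline) as orthogonal for
that reason. Waters never mediate and the DNA partner is the union of all
DNA chains, since a duplex contributes both strands to the interface.

The same residue lists a curator would take from PDBsum/LigPlot can be
ingested verbatim (`COMP NUM[ICODE](CHAIN)`, one per line) with distances
unset; the mapping stage treats both sources identically, and listed
residues absent from the coordinates are reported as *unmappable* rather
than dropped, so record counts are conserved.

## Alignment

The default path shells out to MAFFT (Clustal Omega selectable); output
is validated — every input id present, every row ungapping byte-for-byte
to its input — and reordered to input order. The built-in fallback is a
conventional progressive aligner: 3-mer count distances, UPGMA guide tree
(average linkage, ties broken by lexicographic id so runs are fully
deterministic), and profile–profile Needleman–Wunsch under BLOSUM62 with
affine gaps. A gap run of length *L* costs `gap_open + gap_extend·(L−1)`
with defaults −10 / −0.5; terminal gaps are charged, which suits
globally alignable homolog sets (the intended use) better than free end
gaps would. Column-pair scores are the mean substitution score over all
row pairs with gap characters contributing zero. The pairwise special
case is exact: its score equals the optimum found by exhaustive
enumeration of all alignments, which the acceptance suite verifies on
random short pairs.

Percent identity between two rows is
`100 × matches / columns where at least one of the pair is non-gap` —
the conservative denominator choice (mutual gaps excluded, one-sided gaps
count against identity); the formula is stated here because conventions
differ and the twilight warning depends on it.

## Secondary structure

When DSSP files are supplied they win; the classic fixed-column layout is
parsed (chain at column 12, summary code at column 17), chain-break `!`
lines contribute nothing, and codes outside the `{H,E,G,I,S,B,T}`
alphabet — e.g. the newer polyproline `P` — map to coil. Otherwise a
simplified Kabsch–Sander assignment runs on the backbone: amide hydrogens
are reconstructed 1 Å from N opposite the preceding carbonyl, a hydrogen
bond exists when the electrostatic energy
`0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` falls below
−0.5 kcal/mol, two consecutive n-turns make a helix (n = 4 → H, 3 → G,
5 → I), bridge patterns make ladders (E) or isolated bridges (B),
remaining turn spans get T, and a CA-trace direction change above 70°
over (i−2, i, i+2) gets S, with priority H > E/B > G > I > T > S.
Peptide-bond breaks (C–N above 2.5 Å) suppress hydrogen donors, and
residues missing backbone atoms are coded coil and noted. This is not a
bit-exact DSSP: π-helix preference toggles and the 2011+ PPII class are
omitted, and corner rules at helix termini may differ by a residue.
Tracks are rendered with coil as blank internally and `-` in reports,
since the summary-code alphabet defines no coil symbol.

## Mapping and conservation

Projection is a pure index transformation: structure residue → sequence
index (residue-number map) → alignment column (column map) → letter per
sequence. A binding column is **identical** only when every sequence
shows the same residue and none shows a gap; everything else —
mismatch or deletion — is **substituted**, because a deletion at a
binding position is functionally a substitution and "identical across
all sequences" cannot include absence. Summary counts deduplicate by
alignment column within each interaction class (two structures'
equivalent residues occupy one column and are one site), count a residue
once per class even when several atom pairs hit it, and are emitted per
structure and pooled, since published per-complex tallies are ambiguous
about pooling. Graded similarity (substitution-matrix shades) is
deliberately out of scope: the binary classes match the red/blue output
convention; the HTML renderer's `--graded` option only modulates the
substituted shade by the fraction of sequences matching the structure
residue.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage has computable ground truth:

* `make_toy_complex()` builds poly-alanine backbones from standard bond
  geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ω = 180°) with
  preset dihedrals — helix (φ = −57°, ψ = −47°), extended strand
  (φ = −139°, ψ = 135°), or a two-strand antiparallel hairpin whose
  inter-strand displacement (13.25, 8.25, 3.5 Å, frozen in the preset)
  was chosen so the Kabsch–Sander bonds form in antiparallel register.
  Ligand atoms are placed at exact offsets from named protein atoms, so
  expected interaction records follow in closed form from the distance
  criteria; placements whose ground truth would be ambiguous (contact
  range of residues outside the anchor ±1 window, or any pair below
  0.5 Å) are refused.
* `make_homolog_set()` derives targets by seeded point substitutions
  (each forced position replaced by the cyclically next amino acid, never
  itself) and optional short indels, recording every edit so conservation
  statuses are predictable.
* `make_random_complex()` scatters random N/O/C ligand atoms around a
  short chain for oracle-equivalence testing, with no ground truth
  attached — there the reference is a literal O(n²) brute-force
  implementation of the criteria.

These fixtures are *not* realistic proteins: no sidechain packing beyond
Cβ, no solvent, no B-factors, single conformers, and ligands without
covalent structure. Passing tests therefore demonstrate correctness of
the parsing, geometry, alignment, and bookkeeping — not biological
accuracy of any particular contact call on real structures, where
crystallographic noise and unusual chemistry enter. On real complexes the
de-novo contact path approximates, but need not reproduce, curated
interaction lists; the list-ingestion path exists precisely so curated
lists can be used when exact reproduction matters.

## Numerical choices and problem sizes

Distances compare in double precision with no tolerance; criteria bounds
are inclusive. Rigid-body invariance of contacts and secondary structure
is exact up to coordinate round-off (PDB files carry 3 decimals, ~5·10⁻⁴ Å).
Deterministic tie-breaks: alt-locs by file order after occupancy, tree
joins by lexicographic id, equal-score DP moves by a fixed state order
(match, then gap-in-second, then gap-in-first). The verification suite
sizes were chosen to finish in seconds on one core while exercising every
branch: 200 random complexes (≤ 50 atoms) for the contact oracle, 100
seeded homolog sets for mapping closure, 20 random pairs of length 4–8
for alignment optimality (the enumeration oracle is exponential — 8×8
already visits ~2.6·10⁵ alignments), and 12-residue ideal-geometry
fixtures for secondary structure.

## Known limitations

* Distance-only hydrogen bonds over-call relative to angle-aware tools
  (HBPLUS); borderline pairs may land in the wrong class.
* No water-mediated bridges, salt-bridge/π-stacking subtypes, or
  backbone-vs-sidechain discrimination.
* The built-in aligner is quadratic per profile merge and meant for
  moderate sets; large runs should use MAFFT.
* Single-character chain identifiers only (PDB-format scope; mmCIF-style
  multi-character chains are rejected with a message).
* The secondary-structure assignment is a simplified Kabsch–Sander, not
  a DSSP replacement; supplied DSSP files always take precedence.
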