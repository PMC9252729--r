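---
title: "Models, conventions and design choices in omegafeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in omegafeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`omegafeat` turns biological sequences, protein structures and ligands into
named numeric feature vectors and analyses the resulting matrices. This
vignette is the package's own account of the underlying models: what each
descriptor family computes, which parameters matter and why their defaults
were chosen, the numerical conventions that make edge cases well defined,
and what the bundled fixture generator does and does not emulate.

## The descriptor manifest

The registry pins **189 descriptor sets**: 71 protein, 49 DNA, 37 RNA, 14
structure and 18 ligand. The per-kind *totals* are fixed design targets; the
item-by-item roster is a package decision, recorded in `R/registry.R` and
queryable with `list_descriptors()`. Three roster conventions are worth
stating explicitly:

* Several composition families are registered twice, as **type 1**
  (frequency-normalized) and **type 2** (raw count) variants — e.g.
  `CKSAAP type 1/2`, `DPC type 1/2`, `Kmer type 2`. Type 2 columns carry a
  `.t2.` tag so batch runs keep unique names.
* The DNA and RNA rosters share one code path. RNA excludes the
  trinucleotide-property sets (TAC/TCC/TACC, TPCP, PC-/SC-PseTNC), the
  position-specific propensity sets and the count variants, reflecting that
  curated trinucleotide step parameters are a DNA-centric resource; RNA uses
  A-RNA dinucleotide step parameters and A↔U complementation.
* The 14 structure sets are the per-shell/cumulative pairs of four shell
  compositions (residues, five-group residues, 3-state and 8-state secondary
  structure), two half-sphere-exposure variants (true C&beta; and pseudo-C&beta;
  direction), residue depth, per-shell/cumulative atom composition, and the
  contact-network block.

## Sequence descriptors

**Compositions.** Every frequency-type block is non-negative and sums to 1
(per window or per gap block where applicable); this is asserted by
property tests. Ambiguous characters (X/B/Z/U for protein, IUPAC degenerate
codes for nucleic acids) are rejected by default because the formulas are
defined on canonical alphabets; a permissive mode drops them so they never
inflate composition denominators.

**Autocorrelation.** Moran, Geary and normalized Moreau–Broto statistics
are computed over per-residue property signals standardized to mean 0 and
*population* standard deviation 1 across the 20 amino acids (or the 16/64
k-nucleotides). A zero-variance signal on a given sequence (e.g. a
homopolymer) would put 0 in the denominator; the package defines the
descriptor value as 0 in that case — a constant signal carries no
autocorrelation — keeping matrices dense and finite. The default lag count
is 5 (protein) and 2 (nucleotide), small enough for short windows; both are
parameters.

**Property tables.** Eight classical amino-acid scales (hydropathy,
hydrophilicity, side-chain mass, polarity, volume, isoelectric point,
bulkiness, polarizability) are bundled for the autocorrelation and
profile encodings; the pseudo-composition triplet is the standard
hydrophobicity/hydrophilicity/side-chain-mass set. The quasi-sequence-order
block uses two 20×20 distance matrices: the Grantham matrix, reconstructed
from its published composition/polarity/volume component formula and scaled
to a mean off-diagonal distance of 100, and a `physchem` matrix defined as
the normalized Euclidean distance over the standardized pseudo-composition
triplet. The second matrix is this package's own sequence-order metric (a
documented stand-in where a second published matrix is conventionally used);
it is never labelled as anything else. Nucleotide tables are representative
B-DNA and A-RNA base-step parameters; the trinucleotide table is *derived*
(mean of the two constituent dinucleotide steps) and documented as such.

**Pseudo compositions.** PAAC/APAAC and the six pseudo k-nucleotide
compositions augment a composition block with λ sequence-order correlation
terms and normalize the whole vector by (Σf + wΣθ). Defaults: protein
λ = min(30, L−1), w = 0.05; nucleotide λ = 2, w = 0.1 (community
conventions; small λ keeps short fixtures valid). The exact degeneracies
PAAC(λ=0)=AAC, QSOrder(w=0)→AAC and PseDNC(λ=0)=DNC are tested identities.

**Reduced alphabets.** Published reduced-alphabet cluster tables for the 16
scheme families are not bundled verbatim; instead the package pins 16
deterministic families (19 variants — families 3 and 6 carry lettered
sub-variants) generated from the eight bundled property orderings with two
split rules: equal-size contiguous blocks (families 1–8) and largest-gap
splits (families 9–16). Supported cluster counts are
{2, 3, 4, 5, 8, 10, 15, 20}; 20 is the identity reduction for every family,
so k=1 reproduces AAC exactly — the anchor property the tests rely on.
Lambda-correlation mode applies PAAC-style correlation terms to the
standardized group indices.

**Nearest-neighbour descriptor.** Similarity is a global alignment score
(BLOSUM62, gap open 10 / extend 1 for protein; +2/−1 match/mismatch for
nucleic acids) normalized by the longer sequence length; ties are broken by
training-set order so results are deterministic. Neighbourhood sizes are
fractions of the training set, rounded up to at least one sequence.

## Structure descriptors

Structures are read with bio3d (PDB, or mmCIF by extension). Only the first
model is used; alternate locations resolve to the highest occupancy with
ties going to altloc `A`; waters and hetero groups are excluded from the
residue table. Glycine — or any residue missing C&beta; — receives a
pseudo-C&beta; synthesized from backbone geometry and flagged.

**Shells.** The default shell scheme is r₀ = 0, Δ = 2 Å, n = 15 (0–30 Å),
half-open on the outer bound: a point at exactly r₀+sΔ belongs to shell
s+1. Type 1 features are per-shell compositions, type 2 cumulative; an
empty shell contributes a zero block rather than NaN. The target residue is
excluded from its own shells. Because all shell, exposure, depth and
network quantities are functions of inter-atomic distances only, every
structure descriptor is rigid-motion invariant — asserted to 1e-9 (depth to
sampling tolerance) in the tests.

**Secondary structure** is assigned internally (no external binary) with
the classic electrostatic hydrogen-bond model,
E = 0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol with a bond
below −0.5 kcal/mol and the amide hydrogen placed 1 Å from N opposite the
preceding carbonyl. Turn patterns give G/H/I helices, bridge patterns
E/B strands, plus T (turn) and S (bend, C&alpha; direction change > 70°); the
3-state collapse is H,G,I→H; E,B→E; rest→C. This reproduces ideal-geometry
fixtures faithfully; on experimental structures it is an approximation to
full DSSP (no ladder/sheet bookkeeping), which is the documented trade-off
for a self-contained package.

**Half-sphere exposure** counts C&alpha; neighbours within 13 Å above and below
the plane normal to the side-chain direction; the two registered variants
take that direction from the real C&beta; or from the backbone-derived
pseudo-C&beta;. The partition identity up + down = neighbour count holds by
construction and is tested.

**Residue depth** approximates the solvent-accessible surface by
Shrake–Rupley sampling (default 240 points/atom in routine use; the
parameter is exposed and convergence is tested by doubling it), probe
1.4 Å. Per-atom depth is the distance to the nearest accessible sample
point minus (r~vdW~ + probe), clamped at 0, so an isolated atom has depth
exactly 0; residue depth is the mean over its atoms.

**Contact network.** Nodes are residues, edges C&alpha;–C&alpha; distance ≤ 8 Å
(configurable). Degree centrality divides by n−1, betweenness is normalized
by (n−1)(n−2)/2, closeness uses the component-aware improved formula, and
the sixth published metric ("centrality") is implemented as eigenvector
centrality — an interpretation, flagged here.

## Ligand descriptors

Parsing, aromaticity perception, Gasteiger partial charges, SMARTS
matching, MACCS keys and path-based fingerprints are delegated to
ChemmineR/ChemmineOB (OpenBabel); every entry is normalized to an SDF with
explicit hydrogens and generated 2-D coordinates, and unparseable entries
are reported by input index while the run continues. The descriptor blocks
operate on the heavy-atom graph with per-atom element, attached-H count,
aromatic flag and hydrogen-summed partial charge.

Block conventions: autocorrelations use ordered pairs (both directions
counted) at topological distances 1..8 over four atomic properties (mass,
electronegativity, van-der-Waals volume, polarizability); Burden matrices
put the scaled property on the diagonal, 0.1×bond order on bonded pairs and
0.001 elsewhere, reporting the two highest and two lowest eigenvalues per
property; E-state values use the Kier–Hall intrinsic state with 1/(d+1)²
perturbation; the information indices refine atom classes by neighbourhood
up to order 2. Indices whose formula degenerates on single-atom molecules
return 0, never NaN. The surface-area (MOE-type) block bins a per-atom
accessible-surface proxy — sphere area shrunk by a degree-dependent
shielding factor — over partial-charge and E-state ranges; the bin edges
and the proxy are pinned roster choices, stable across toolkit versions.
The circular fingerprint is an in-package Morgan-style iteration (radius 2,
2048 bits) over canonical atom invariants, so it is deterministic and
invariant to input atom order; the E-state fingerprint counts 79 pinned
atom types keyed by element × aromaticity × heavy degree.

## Feature analysis

`zscore` normalization uses the *population* standard deviation, which
makes it exactly idempotent (a second application is a no-op to 1e-9);
`minmax` maps to [0, 1]; constant columns map to zeros under both rather
than dividing by zero. Ten clustering algorithms are registered: k-means,
mini-batch k-means, Gaussian mixtures, Ward agglomerative (cut at k),
spectral (RBF affinity, γ = 1/p), Markov clustering, average-linkage tree
cut (cut at height h), affinity propagation, mean shift and DBSCAN (noise
id −1). k-means/hclust/Ward come from base R, mixtures from mclust,
spectral from kernlab; the remainder are implemented in the package, and
Markov clustering follows the expansion-2 / inflation-2 / prune-1e-5
iteration on a k-nearest-neighbour-sparsified Gaussian affinity so that
well-separated groups decouple. All stochastic algorithms draw from a
locally seeded RNG: the same seed gives identical partitions, and the
caller's RNG stream is never disturbed.

Reductions: PCA (base `prcomp`; orthonormal components, non-increasing
explained variance, matched against an eigendecomposition oracle in the
tests), LDA (MASS; requires labels, components ≤ classes − 1), and an
in-package exact-gradient t-SNE (PCA initialisation plus seeded jitter,
early exaggeration 4× for 100 of 400 iterations, perplexity
min(30, (n−1)/3)) — sized for the hundreds-of-samples matrices this package
produces, not for single-cell-scale data.

## Plots

Nine kinds: histogram (Freedman–Diaconis bins, floor 10), kernel density
(Scott-family `nrd` bandwidth), heatmap, boxplot, line, scatter (for 2-D
embeddings, coloured by label or cluster), circular (samples on a rim,
edges where pairwise Pearson correlation ≥ 0.75 by default; Euclidean and
cosine similarities offered), a static backbone-trace projection for
structures and a 2-D ligand depiction. Histograms and densities overlay by
label when labels exist. Output formats: PNG, JPG, PDF, TIFF. The static
structure/ligand views stand in for interactive viewers so the full set of
nine kinds exists in a command-line artifact.

## Fixtures: what they do and do not emulate

`generate_fixtures()` produces uniform-random equal-length sequence sets
with alternating class labels, an ideal-geometry single-chain backbone
(helix, extended or jittered mixed conformations, 16 varied residue types
including CYS/HIS/ASP/GLU, full backbone + C&beta;) and a small SMILES panel
(methane, benzene, heteroaromatics, small polar molecules). They exercise
every code path deterministically — identical seeds give byte-identical
files — but they are not biological data: uniform sequences have no motif
or compositional structure, the toy backbone has no side chains beyond
C&beta; or packing core, and the ligand panel spans few pharmacophores.
Passing tests therefore demonstrate formula correctness, contracts and
invariants, not predictive value on real datasets.

Routine problem sizes were chosen for interactive turnaround: sequence
fixtures of 6–50 sequences × 15–50 residues, a 14–16-residue structure,
8 ligands; the omnibus acceptance run executes all 189 sets on these sizes
in well under a minute.

## Known limitations

* The secondary-structure assigner approximates DSSP (no sheet topology);
  an externally produced assignment can be substituted upstream.
* The AAindex exposure is a curated 8-scale subset, not the full database.
* The Schneider–Wrede-style second sequence-order matrix is replaced by the
  documented `physchem` metric (see above).
* Ligand blocks requiring 3-D conformers are out of scope; all ligand
  descriptors are 2-D/topological.
* PSTNP descriptors need exactly two classes and equal-length sequences by
  definition; KNN-style descriptors are training-set-relative and should be
  interpreted accordingly.
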