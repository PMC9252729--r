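# omegafeat

Machine-learning studies on biomolecules start with the same step: turning a
protein, DNA or RNA sequence, a 3-D protein structure, or a small-molecule
ligand into a fixed-length numeric feature vector. `omegafeat` is an R
package for that step. It computes **189 named descriptor sets** — 71 for
protein sequences, 49 for DNA, 37 for RNA, 14 for protein structures and 18
for ligands — and couples them to a feature-analysis layer (two
normalizations, ten clustering algorithms, three dimensionality reductions)
and nine plot kinds, with export to CSV, TSV, SVM-light and ARFF.

Everything flows through tibbles: a sequence set is a tibble of
`id`/`seq`/`label`, a feature matrix is a tibble of `id` (+ optional
`label`) and named numeric columns, so results chain directly into
dplyr/ggplot2 workflows. Fitted analysis objects carry broom-style
`tidy()`/`glance()` and ggplot2 `autoplot()` methods.

## The descriptors in brief

* **Sequence composition** — amino-acid/k-mer compositions and their gapped,
  grouped, windowed and count variants (AAC, DPC, CKSAAP, CTDC/T/D, conjoint
  triads, Kmer, reverse-complement Kmer, mismatch and subsequence profiles,
  …). Composition blocks are frequency-normalized: each block sums to 1.
* **Autocorrelation** — Moran, Geary and normalized Moreau–Broto statistics
  plus auto/cross-covariance (AC/CC/ACC, DAC/DCC/DACC, TAC/TCC/TACC) over
  standardized physicochemical property profiles, e.g. for lag *d* and
  property signal *P*:
  `Moran(d) = [Σ (P_i − P̄)(P_{i+d} − P̄)/(N−d)] / [Σ (P_i − P̄)²/N]`.
* **Sequence order and pseudo compositions** — quasi-sequence-order
  descriptors from squared inter-residue physicochemical distances, pseudo
  amino-acid composition (PAAC/APAAC) and six pseudo k-nucleotide
  compositions; all reduce exactly to plain compositions when the
  order-correlation weight or lag is zero.
* **Reduced alphabets** — 16 pseudo K-tuple reduced amino-acid composition
  scheme families (19 registered variants) over pinned cluster tables.
* **Residue-level encodings** — one-hot, physicochemical bit codes, Z-scales,
  BLOSUM62 rows and property-profile encodings for equal-length windows.
* **Structure** — concentric-shell microenvironments (residue, grouped,
  secondary-structure and atom compositions, per-shell and cumulative),
  half-sphere exposure within 13 Å, sampled-surface residue depth, and
  residue contact-network indices (degree, betweenness, clustering,
  closeness, eigenvector centrality). Secondary structure is assigned
  internally with the classic hydrogen-bond electrostatic energy model.
* **Ligands** — 14 descriptor blocks (constitutional counts, topological and
  connectivity indices, shape kappas, E-state, information indices, Burden
  eigenvalues, pharmacophore counts, three topological autocorrelations,
  Gasteiger-charge summaries, bulk properties, surface-area bins) and four
  fingerprint families (MACCS keys, circular/Morgan, E-state types,
  path-based bits). Chemistry perception is delegated to
  ChemmineR/OpenBabel.

## Worked example

```r
library(omegafeat)

# seeded fixture data: 6 labelled DNA sequences of length 24
paths <- generate_fixtures(seed = 1, dir = tempdir(), n_seq = 6, seq_len = 24)
seqs  <- read_fasta(paths$dna, "dna")
kmer  <- calculate_features(seqs, "Kmer", k = 2)
kmer[, 1:6]
#> # A tibble: 6 × 6
#>   id     label Kmer2.AA Kmer2.AC Kmer2.AG Kmer2.AT
#>   <chr>  <chr>    <dbl>    <dbl>    <dbl>    <dbl>
#> 1 seq001 1       0.130    0.0870   0.0870   0.0435
#> 2 seq002 0       0.0870   0.0870   0        0.0870
#> 3 seq003 1       0        0.0435   0.0870   0.0435
#> 4 seq004 0       0        0        0.0870   0.130
#> 5 seq005 1       0.130    0        0.0870   0.0870
#> 6 seq006 0       0        0.0435   0.0435   0.0870
```

Each row is one sequence; the 16 dinucleotide frequencies sum to 1 per row.
The feature tibble pipes straight into the analysis layer:

```r
fit <- kmer |> normalize_features("zscore") |> cluster_features("kmeans", k = 2, seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>   method     n n_clusters n_noise  seed
#>   <chr>  <int>      <int>   <int> <dbl>
#> 1 kmeans     6          2       0     1

emb <- reduce_features(kmer, "pca", n_components = 2, seed = 1)
autoplot(emb)                       # 2-D embedding, coloured by label
write_features(kmer, "kmer.svm", "svm_light")
```

Structures and ligands use the same verbs:

```r
model <- read_structure(paths$structure)
hse   <- calculate_features(model, "HSE_CB")       # per-residue exposure
mols  <- read_molecules(paths$smiles, "smiles")
tops  <- calculate_features(mols, "topology")
tops$Wiener[tops$id == "butane"]
#> [1] 10
```

A thin command-line wrapper (`inst/cli/omegafeat`) dispatches the seven
schemes (`iProtein`, `iDNA`, `iRNA`, `iStructure`, `iLigand`, `iAnalysis`,
`iPlot`) from a JSON configuration:

```sh
omegafeat run -c config.json     # read -> compute -> write (+ run log)
omegafeat list --kind rna
omegafeat fixtures --seed 1 --out fixtures/
```

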