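---
title: "Interpreting HATS descriptors: leverages, lags, weights and fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting HATS descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgetaway)
```

## The model

HATS descriptors combine three independent encodings of a molecular
structure, and interpreting a value requires keeping all three apart:

1. **Geometry → leverages.** The coordinates, centered on the unweighted
   geometric center, form the molecular matrix $M$ ($A \times 3$). The
   molecular influence matrix $H = M(M^\top M)^{-1}M^\top$ is the
   orthogonal projector onto the column space of $M$; its diagonal
   $h_{ii} \in [0,1]$ (the leverage of atom $i$) grows with the atom's
   distance from the molecular center, and $\sum_i h_{ii} = D$, the rank
   of $M$, so the *mean* leverage is $D/A$. Centering makes everything
   invariant to rigid motion.
2. **Topology → the lag.** The molecular graph (atoms = vertices,
   bonds = edges) gives topological distances $d_{ij}$ as shortest-path
   bond counts. The Dirac delta $\delta(k; d_{ij})$ selects the unordered
   pairs exactly $k$ bonds apart. This is 2D information: conformers share
   it exactly.
3. **Chemistry → the weights.** A per-element property scaled by the
   carbon value, $w(\mathrm{C}) = 1$: unweighted (u), atomic mass (m), van
   der Waals volume (v), Sanderson electronegativity (e), polarizability
   (p), first ionization potential (i).

The descriptors are
$\mathrm{HATS}_0(w) = \sum_i (w_i h_{ii})^2$ and
$\mathrm{HATS}_k(w) = \sum_{i<j} (w_i h_{ii})(w_j h_{jj})\,\delta(k; d_{ij})$.
Explicit hydrogens are part of the model: hydrogens carry large leverages
(periphery) but tiny mass weights, and dropping them changes every term.

The package's contribution is bookkeeping, not a new statistic: every
summand is kept as a pair-contribution record $(i, j, w_i h_{ii} w_j
h_{jj})$, so a value can be decomposed exactly.

### Why intuition fails without the lag term

Among three roughly 60-atom molecules, the spherical fullerene C60 has
uniformly *low* leverages (all $h_{ii} = 3/60 = 0.05$ by icosahedral
symmetry) yet by far the *highest* HATS5m — because its graph has 300
pairs at lag 5, each contributing $0.05^2$, giving exactly
$300 \times 0.0025 = 0.75$:

```{r shapes}
sapply(list(C60 = make_fullerene_c60(), C42H18 = make_hexabenzocoronene(),
            icosane = make_n_alkane(20)),
       function(m) c(pairs_lag5 = topological_distances(m)$n_pairs_at[["5"]],
                     HATS5m = round(coef(hats_profile(m, "m", 5))[1L], 4)))
```

The extended n-icosane has fewer lag-5 pairs, most of them involving
low-weight hydrogens, and lands near 0.01 despite its high peripheral
leverages. Leverage intuition alone inverts the ordering.

## Decomposition and substructure cutting

A fragment partition (total assignment of atoms to labels) routes each
pair contribution to an unordered fragment cell; diagonal cells are
intra-fragment, off-diagonal inter-fragment, and the cells sum *exactly*
to the descriptor value (a partition of summands, checked to 1e-12
relative in the tests). Lag-0 self terms sit on the diagonal.

```{r decompose}
mol  <- make_halide_probe("Br")
part <- fragment_partition(
  ifelse(seq_len(n_atoms(mol)) == n_atoms(mol), "R4", "core"), mol)
fragment_decompose(hats_profile(mol, "m", 5), part, lag = 5)
```

`substructure_cut()` implements the companion operation: keep a subset of
atoms *with their original coordinates* — no hydrogen capping and no
geometry relaxation, so the spatial arrangement of the surviving pairs is
preserved — and recompute everything from scratch on the cut structure.
Recomputation is the point: leverages depend on the whole molecule through
the centering and the projector, so they are never sliced from the parent.
Shrinking a molecule raises the mean leverage mechanically
($D/A$ with smaller $A$; for all-anti alkanes exactly $3/(3n+2)$).

## Conformer shape clustering

Conformers of one molecule share the bond topology, hence the lag-$k$ pair
set; only the leverages differ. The per-pair contributions therefore form
aligned fingerprint vectors, and Euclidean distances between them feed
UPGMA (average-linkage) clustering, validated by the cophenetic
correlation coefficient (Pearson correlation between input and
dendrogram-implied distances; exactly 1 on ultrametric input). Raw
(unnormalized) contributions are clustered by default, so fingerprint sums
equal the conformers' descriptor values; `normalize = TRUE` switches to
pure shape comparison.

```{r cluster}
confs <- make_synthetic_conformers(6, 6, 6, seed = 1)
fp <- pair_fingerprints(confs, lag = 5, scheme = "m")
shape_report(fp, n_clusters = 3)
```

## What the synthetic generators emulate — and what they do not

All reference structures are generated programmatically from ideal
geometric parameters:

* `make_fullerene_c60()`: canonical truncated-icosahedron vertices at a
  uniform 1.44 Å bond length. Real C60 has two slightly different bond
  lengths (≈1.40/1.46 Å); the uniform choice is deliberate because every
  quantity the package asserts about C60 (pair counts from pure topology,
  equal leverages and HATS5m = 0.75 from icosahedral symmetry) is
  invariant to it.
* `make_n_alkane(n)`: ideal sp³ chains (C–C 1.54 Å, C–H 1.09 Å,
  tetrahedral angles), all-anti by default or with user dihedrals.
* `make_hexabenzocoronene()`: the graphene-like C42H18 sheet is identified
  as hexa-peri-hexabenzocoronene — the unique planar honeycomb PAH with
  that formula — on an ideal lattice (C–C 1.42 Å), strictly planar so the
  rank-2 case is exercised exactly.
* `make_halide_probe(X)`: a planar styrene-like ring with the substituent
  X para to a vinyl arm, placed at the *same* coordinates for every X.
  Exactly one lag-5 pair involves X, so the halogen series H→F→Cl→Br
  varies the atomic weight at frozen leverages — isolating the weighting
  scheme's effect.
* `make_synthetic_conformers()`: one decane topology in three planted
  dihedral classes — all-anti (linear), one central gauche kink (L-like),
  two gauche kinks (U-like) — with seeded Gaussian coordinate jitter of
  0.02 Å. Defaults (9 linear, 6 U, 5 L = 20 conformers) mirror the size
  and linear/nonlinear balance of a typical force-field conformer
  ensemble.

These are idealized geometries. Passing tests establish that the
*machinery* is exact (oracle equivalence, conservation, symmetry-forced
values) and that shape classes separable by construction are recovered;
they do not certify descriptor values for force-field-optimized real
structures, which depend on the preparation protocol. No geometry
optimization is ever performed by this package — reproducibility of the
input coordinates is treated as the user's contract.

## Numerical and design choices

* **SVD projector, not the literal inverse.** $M^\top M$ is singular for
  planar and collinear molecules, which are legitimate and common inputs
  (benzene derivatives). Singular values below `tol = 1e-8` (relative,
  overridable) are treated as zero; leverages are clamped to $[0,1]$
  against last-bit roundoff. The textbook inverse survives as an
  independent oracle in the tests for full-rank structures.
* **Degenerate input.** All atoms coincident gives $D = 0$, $H = 0$,
  all descriptors 0 — documented, not an error. Disconnected graphs are
  legal: infinite distances simply never match a finite lag.
* **Determinism of reports.** Pair lists are sorted by descending
  contribution with an ascending $(i, j)$ tie-break, so coverage counts
  ("$n$ pairs cover 80%") are reproducible across platforms; the uniform
  C60 case (all 300 contributions equal) yields exactly
  $\lceil 0.8 \times 300\rceil = 240$.
* **Bond perception** (needed only for XYZ input) bonds $i,j$ when their
  distance is ≤ 1.15 × the sum of Cordero single-bond covalent radii; the
  1.15 default is the common tolerance for slightly stretched bonds and is
  exposed as a parameter. SDF bond blocks are always taken as-is.
* **Weight tables.** Raw properties ship as a documented CSV (IUPAC
  masses, Bondi radii → volumes, Sanderson electronegativities, CRC
  polarizabilities and ionization energies), carbon-scaled at load. The
  electronegativity scale is a genuine degree of freedom — descriptor
  systems do not agree on one — and Sanderson is chosen for consistency
  with the dominant convention; values computed under scheme `e` shift
  slightly under other scales.
* **Lag range.** Default 0–8: autocorrelation lags beyond 8 are rarely
  informative and values vanish past the graph diameter anyway.
* **Cutting never caps.** `substructure_cut()` deliberately leaves open
  valences rather than adding hydrogens: capping would introduce atoms
  (and leverage mass) that the parent molecule does not have, breaking the
  size-effect comparison the operation exists for. A cut of $m$ carbons
  from an alkane therefore has $3m + 1$ atoms, not the $3m + 2$ of the
  free alkane.
* **UPGMA** is delegated to `stats::hclust(method = "average")` with
  `stats::cophenetic`; a naive agglomeration oracle in the tests confirms
  the merge heights. Whether to cluster all pair contributions or only a
  top-coverage subset is open in principle; all pairs is the default since
  truncation discards exactly the small contributions that distinguish
  near-linear shapes.

## Problem sizes

The test and reproduction workloads are sized for interactive use: the
largest single structure is 62 atoms (the reference molecules of the
shape comparison), oracle sweeps use 50 random molecules of up to 30
atoms, the MIM invariant suite 100 random structures of up to 40 atoms,
and the clustering demonstrations 9–18 conformers of decane. All scale
polynomially ($A^3$ at worst) and complete in seconds.

## Known limitations

* Element coverage of the weight tables is the organic/medicinal set
  (H, B, C, N, O, F, Si, P, S, Cl, Br, I); other elements error loudly.
* Only HATS indices are computed — not the R-GETAWAY family or the other
  H-GETAWAY aggregate indices — and bond orders, aromaticity and charges
  are ignored, as none enter the HATS equations.
* No conformer generation or geometry optimization; coordinates are
  accepted as given.
* V3000 SDF records are not parsed.
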