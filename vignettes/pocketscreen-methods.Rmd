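---
title: "Binding-site similarity screening and assay quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site similarity screening and assay quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketscreen)
```

## The problem

Structure-based drug repurposing asks whether a ligand crystallized in one
protein might also bind a different target whose binding site "looks the
same" physicochemically, even when the two proteins share no sequence or
fold similarity. The motivating application is the taxane site of
beta-tubulin — the paclitaxel-binding cleft whose occupancy stabilizes
microtubules — and the observation that estrogen-receptor ligand pockets
can resemble it closely enough that selective estrogen receptor modulators
(SERMs) act as microtubule stabilizers. `pocketscreen` implements the full
desk side of that programme: pocket extraction, microenvironment
featurization, similarity scoring and screening, drug-like library
construction, docking-score post-processing, a chemical similarity
network, and quantification of the validation assays (tubulin
polymerization kinetics, microtubule phenotypes, live-cell potency).

## Pocket model

A binding pocket is defined geometrically: every polymer residue with at
least one heavy atom within 6 Å (inclusive) of a heavy atom of the
co-crystal ligand. Distances use heavy atoms on both sides because
hydrogen placement is inconsistent across deposited structures. Multiple
chains may contribute residues — tubulin pockets genuinely span subunit
interfaces — so no chain filter is applied. The first coordinate model is
used for multi-model entries; alternate locations resolve to the
highest-occupancy conformer with a lexicographic tie-break on the altloc
identifier; waters, common ions and a documented list of crystallization
additives are excluded both from ligand enumeration and from pocket
membership. No symmetry-mate expansion is performed: pockets are read in
the as-deposited frame, which under-counts contacts for pockets completed
by crystallographic neighbors.

## Microenvironment descriptors

Each pocket residue is summarized by the protein matter around its
side-chain heavy-atom centroid (the CA position for glycine). Six
concentric shells of width 1 Å partition the 6 Å ball; an atom at distance
$d$ belongs to shell $k$ iff $(k-1) < d \le k$. An atom exactly at the
center (possible only for single-atom side chains, whose centroid is the
atom itself) falls in no shell by this definition. Eighty count-type
descriptors are evaluated per shell, 480 per residue, shell-major:

* element counts C/N/O/S/P/other (6);
* per-residue-type atom counts for the 20 standard amino acids (20);
* residue-class atom counts over a fixed partition into hydrophobic,
  aromatic, polar-uncharged, positive, negative, special (6);
* backbone vs side-chain atom counts (2);
* hydrogen-bond donor and acceptor heavy atoms, by atom-name tables plus
  the backbone N/O (2);
* atoms of formally charged side-chain groups, positive and negative (2);
* aromatic-ring atom count (1);
* total heavy-atom count (1);
* the shell's Kyte–Doolittle hydropathy sum, one-hot binned into five
  signed bins with edges −10, −2, 2, 10 (5; all zero for an empty shell so
  that empty surroundings give an all-zero vector);
* element × class cross counts for C/N/O/S/P against the six residue
  classes plus "backbone" (35).

Only polymer atoms contribute. The pocket's own co-crystal ligand is
excluded so that the same pocket featurizes identically whichever ligand
sits in it; other hetero groups and solvent are excluded for the same
reason. All descriptors are rigid-motion invariant by construction, which
the tests assert directly.

Binarization is presence/absence: a bit is set iff its descriptor value
exceeds a threshold, 0 for every descriptor in the default schema. The
schema carries an identifier (`default-v1`); feature sets from different
schema versions refuse to be compared. The exact composition of the
80-descriptor panel is a design choice of this package: it reproduces the
count-character of residue-microenvironment descriptor sets used in the
field while being fully specified, versioned and testable. Centering on
residue-type-specific functional atoms rather than side-chain centroids is
a known alternative we deliberately did not implement; it would change
absolute similarities but not the architecture.

## Pocket similarity score

Pairwise residue similarity is the Tanimoto coefficient over shared bits,
$T = |A \wedge B| / |A \vee B|$ (0 when both vectors are empty). Two
pockets are aligned by a maximum-weight one-to-one matching on the
bipartite graph whose edges are residue pairs with $T \ge \tau$ (default
$\tau = 0.5$); the PocketFeature-style score is

$$\mathrm{PFS} = -\sum_{(a,b) \in M^\*} T(a,b),$$

so more negative means more similar, $-\min(|A|,|B|) \le \mathrm{PFS} \le 0$,
self-comparison of an $n$-residue pocket gives exactly $-n$, and raising
$\tau$ can only make the score less negative. The matching is solved
exactly with a Hungarian-style shortest-augmenting-path algorithm on the
zero-padded square weight matrix (no greedy approximation); the test suite
checks it against exhaustive enumeration of all matchings on random
instances up to 7×7. Screening ranks database pockets by ascending PFS
with a stable pocket-id tie-break; significance uses the strict cutoff
PFS < −3.5. The published score this mirrors is not numerically
reproducible here — the original 80-descriptor panel and any background
normalization are not public — so absolute parity with published PFS
values for real structures is explicitly not claimed; optional pocket-size
or background normalizations are left to the caller as post-hoc
transforms. With the default schema and tau, random unrelated toy pockets
score mildly negative (a few shared coarse bits are expected by chance),
while jittered copies of a pocket stay near its self-score; the planted
recovery experiment quantifies that separation.

## Compound library and docking post-processing

Drug-likeness is Lipinski's rule of five with "fewer than 2 violations"
(violations counted among MW > 500 Da, logP > 5, H-bond donors > 5,
H-bond acceptors > 10) plus an inclusive 170–1000 Da molecular-weight
window applied in addition to the MW rule. Acceptor counts are taken as
supplied N+O counts; which HBA variant the original screen used is
ambiguous, and supplying the counts keeps the filter testable without a
cheminformatics toolkit. Deduplication keeps the first record per
structure key (InChIKey or equivalent), in input order.

Docking scores convert to predicted inhibition constants by
$K_i = e^{\Delta G / RT}$ with $R = 1.9872036 \times 10^{-3}$
kcal K⁻¹ mol⁻¹ and $T = 300$ K; the conversion is strictly increasing and
log-linear in $\Delta G$. High-confidence binders are those with
$\Delta G$ strictly below −6 kcal/mol. Docking itself (pose search) is out
of scope; only score post-processing is implemented.

## Chemical similarity network

Fingerprints are hashed circular neighborhoods: the radius-0 atom
invariant combines element, heavy-atom degree and bond-order sum; each
iteration concatenates the sorted (bond order, neighbor invariant) list,
and all identifiers up to radius 2 hash into 2048 bits. Sorting neighbor
invariants makes the bits canonical over SMILES atom order. Formal
charges and kekulization differences are not part of the invariant; exact
numeric parity with any particular toolkit's fingerprint is not claimed,
and the network's published counterpart did not specify one. Edges
connect pairs with Tc strictly above 0.75. Node color classes follow the
published bands, which leave [−3, −2] unspecified: PFS < −3 is `high_sim`,
PFS > −2 is `low_sim`, the closed band in between is an explicit
`intermediate` class, and nodes without a PFS are `unscored`.

## Assay quantification

**Polymerization.** Raw fluorescence curves normalize as
$100\,(F(t) - F_{\min}) / (F_{\mathrm{ref}}(t_{\mathrm{end}}) - F_{\min})$,
where the reference is the paclitaxel-like condition and $F_{\min}$ is the
lowest reading across all curves of the run (scoping the minimum per run
rather than per curve is configurable in principle; per-run is the
default because a shared plate shares its optical floor). The reference
final value maps exactly to 100. Vmax is the steepest least-squares slope
over any 3 consecutive points of the normalized curve (%/min) — the
window length is this package's choice, small enough to track the
inflection at 30-s sampling and large enough to damp single-point noise;
MEP is the normalized value at the final time. Fold changes are plain
ratios to the DMSO control with an effect threshold of 1. Vmax is
computed on the normalized scale; whether the published table used
normalized or raw-scale Vmax is not stated, and ratios (the FC columns)
are identical either way for curves sharing a run.

**Phenotypes.** The abnormality score is total counted abnormalities over
cells scored; a cell may contribute several categories, so scores above 1
occur. Polymerized/soluble proportions are simple fractions.

**Potency.** EC50 on proliferation fits a least-squares slope per
concentration, targets half the vehicle slope, and interpolates linearly
in log10 concentration between the bracketing doses; when no bracket
exists, or the vehicle slope is non-positive, the result is an explicit
not-assigned state, never a silent number. EC50 on death fits a
four-parameter logistic in log10 dose by Levenberg–Marquardt least
squares with the floor constrained to be non-negative; non-convergence or
a fitted span below 10% of the admissible response range (0.1 on the
fraction scale) also yields not-assigned.

## Synthetic data: what it emulates and what it does not

The generators stand in for PDB-wide structure sets and wet-lab plates.
Toy complexes place a compact 8-atom hetero ligand near the origin and
build residues from backbone plus side-chain pseudo-atoms with correct
element labels; the construction guarantees the planted minimum
heavy-atom distance exactly (the anchor atom sits at the planted distance
along a direction in which it is provably the closest atom), so pocket
membership at any cutoff is known by construction. Geometry is minimal:
no stereochemistry, no realistic rotamers, no packing. Consequently the
tests demonstrate the pipeline's correctness and discrimination on
controlled inputs, not biological accuracy on real crystal structures.
Perturbed copies add Gaussian coordinate jitter and random residue-type
relabeling with recorded ground truth, enabling planted-recovery screens
(a 0.1 Å-jittered, 10%-relabeled copy of a 10-residue query should beat
20 random decoys). Compound tables plant rule violations record by
record; polymerization runs are logistic curves whose analytic maximum
slope and normalized end-points are recorded exactly; live-cell series
draw growth slopes and death fractions from four-parameter logistic
dose responses with Gaussian noise. Defaults mirror the validated assay
conditions: 30-min polymerization at 30-s sampling, a DMSO control at
20.5% of the paclitaxel end-point, half-log dose ladders spanning
~0.3–1000 µM around a 25 µM proliferation EC50, 2% reading noise for
growth and 5% for death fractions.

## Numerical choices and problem sizes

Pocket distances compare against the cutoff with a 10⁻⁹ Å tolerance so
constructions placed exactly at the boundary are stable. All boundary
rules are strict or inclusive exactly as documented: pocket membership
inclusive at 6.0 Å; PFS significance strict below −3.5; docking
confidence strict below −6 kcal/mol; network edges strict above Tc 0.75.
Assignment ties resolve deterministically through the solver's fixed
iteration order. The test and acceptance workloads are sized for a
single-CPU desk run: property checks loop over 50 seeded replicates,
matching-oracle checks over 100 random ≤ 7×7 instances, recovery screens
over 20 replicates of 21-pocket databases, and potency recovery over 20
simulated plates; the full suite completes in about a minute.

## Known limitations

* Absolute PFS values are schema-dependent; only ordinal behavior and the
  documented invariants transfer to other descriptor panels.
* mmCIF support covers the atom_site records needed here; exotic entries
  (multi-assembly, extensive altloc trees) are untested.
* The fingerprint is a clean-room circular fingerprint, not a clone of
  any specific toolkit's; Tc values near the 0.75 edge may differ from
  published networks.
* Phenotype and challenge-assay inputs are counted events from imaging;
  no image analysis is performed.
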