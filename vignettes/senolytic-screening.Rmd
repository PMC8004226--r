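---
title: "Screening natural products for senolytic candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening natural products for senolytic candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senoscreen)
```

## The screening problem

Senolytics are compounds that selectively kill senescent cells — cells in
stable proliferative arrest whose secretory phenotype (SASP) drives chronic
inflammation and several age-related diseases. Known senolytics are
chemically heterogeneous, so a practical virtual screen does not fit one
pharmacophore; instead it asks, for a library of natural products, which
members (a) look drug-like, (b) are structurally similar to known senolytic
leads, and (c) hit protein targets that sit in senescence-associated
pathways. `senoscreen` implements that screen as four phases, each usable on
its own:

1. **Lead selection.** Cluster known senolytics in molecular-descriptor
   space (K-means and Ward on z-scored descriptors, PCA for visualization)
   and keep the cluster holding the anchor compounds.
2. **Drug-likeness.** Score every library compound with the quantitative
   estimate of drug-likeness (QED) and keep scores strictly above 0.5.
3. **Similarity screen.** For each lead, cluster the lead together with the
   drug-like candidates in fingerprint (Tanimoto) space, validate the
   partition with silhouette and Dunn indices, and keep the candidates
   sharing the lead's cluster; take the deduplicated union across leads.
4. **Network ranking.** Build a bipartite compound–target network joined to
   senescence pathway gene sets, and rank candidates by multitarget
   capacity.

## Models and conventions

### QED

Each of eight descriptors — molecular weight, Crippen-type logP (ALOGP),
hydrogen-bond acceptors and donors, topological polar surface area,
rotatable bonds, an aromaticity count, and a structural-alert count — is
mapped through an asymmetric double sigmoid desirability
$d(x) = \mathrm{ADS}(x)/d_{max}$ peaked at the drug-like optimum, and the
weighted QED is the weighted geometric mean

$$\mathrm{QED} = \exp\!\left(\frac{\sum_i w_i \ln d_i}{\sum_i w_i}\right).$$

The ADS parameters and default weights are the published constants of the
original QED formulation (Bickerton et al., 2012, *Nature Chemistry*
4:90–98), vendored in `qed_parameters()` / `qed_weights()`. Desirabilities
are floored at $10^{-6}$ so the logarithm stays finite; with the vendored
constants the sigmoid tails actually level off at $a/d_{max} > 10^{-6}$, so
the floor is a guard rather than an active constraint. The drug-likeness
threshold is strictly greater than 0.5: a compound scoring exactly 0.5
fails.

One wording trap deserves a note: screening protocols in this area often
describe the aromaticity descriptor as an "aromatic bond count", but the
published ADS constants for the aromaticity term were fit to aromatic
*ring* counts (typical values 0–4, not 0–30). `compute_descriptors()`
returns both (`arom` = aromatic bonds, `n_aromatic_rings`), and
`qed_score(arom_source =)` chooses which one feeds the desirability —
`"rings"` by default, because that is the quantity the constants are valid
for; `"bonds"` is available for literal emulation of bond-count protocols.

The ALERTS term counts matches against a curated structural-alert set
shipped with the package (`default_alert_patterns()`): ~40 SMARTS patterns
covering the standard unwanted-functionality classes used in
screening-library triage (reactive halides, Michael acceptors, azo/diazo
groups, thiols, quinones, …). `compute_descriptors(alerts = FALSE)` sets
the count to zero for protocols that ignore alerts.

### Descriptors and perception

Molecule perception is delegated to OpenBabel through
ChemmineR/ChemmineOB. Conventions pinned by this package (because toolkits
disagree):

* **HBA** = N and O atoms, not positively charged, excluding pyrrole-type
  nitrogens (aromatic N with three substituents counting hydrogens, whose
  lone pair is part of the ring).
* **HBD** = N/O atoms bearing at least one hydrogen, counted per
  heteroatom.
* **ROTB** = acyclic single bonds between two non-terminal heavy atoms, no
  amide exclusion.
* **PSA** is topological (fragment-contribution), not 3-D.
* Implicit hydrogens come from a standard-valence model over the kekulized
  bond orders; aromaticity from smallest-set ring perception.

These are tested against an independent perception of the same structures
with count-level tolerances (exact for HBD, ±2 Å² for PSA, ±0.5 for
ALOGP), documenting the expected backend dependence.

Structure identity, used for de-duplication, is the backend canonical
SMILES of the largest covalent fragment (salts stripped, largest fragment
by heavy-atom count, ties toward the lexicographically smaller string).
Unparseable records are never dropped silently: they stay in the compound
table flagged invalid, with reasons, and are excluded from downstream
phases with counts reported at every stage.

### Fingerprints

The similarity screen uses a fully pinned hashed path fingerprint so that
bits are identical across platforms and sessions:

* features are all simple atom paths of 0–6 bonds (a single atom is the
  0-bond path);
* atom invariant = (element, aromatic flag, in-ring flag, formal charge);
  bond invariant = kekulized order, or `a` for aromatic bonds;
* each path string is the lexicographically smaller of its two traversal
  directions; distinct strings are hashed with 32-bit FNV-1a and set bit
  `hash mod n_bits` (default 1024; 512 and 2048 supported);
* stereochemistry is ignored.

Tanimoto similarity on these bit sets gives the Jaccard distance
`1 − T`, a true metric (the triangle inequality is property-tested).
Two all-zero fingerprints compare as 0, not 1: featureless records should
not cluster together.

### Clustering and validity

Ward clustering on a precomputed distance matrix follows the convention of
squaring the input distances inside the Lance–Williams update
(`stats::hclust(method = "ward.D2")`): plain Euclidean or Jaccard distances
go in unsquared. K-means is Lloyd's algorithm from k-means++ starts, best
of 10 restarts by within-cluster sum of squares, reproducible via an
explicit seed. The silhouette of a singleton cluster is defined as 0. The
Dunn index returns `Inf` when every cluster has zero diameter. The elbow
choice of k maximizes the second difference of the WSS curve, with ties
broken toward smaller k; for distance matrices the WSS of a partition is
the sum over clusters of squared pairwise distances divided by twice the
cluster size, which coincides with the centroid form in Euclidean space
and generalizes it to fingerprint space.

A caveat worth stating: agglomerative Ward is greedy, and on weakly
separated data its k = 2 cut can miss the globally optimal minimum-variance
bipartition. The package's oracle tests compare it against exhaustive
enumeration on small two-blob instances with clear separation — the regime
where the screen actually operates (a lead plus its structural analogs
against decoys) and where the greedy cut is reliably optimal.

### Network ranking

Binding records become a bipartite compound–target graph (igraph);
duplicate rows collapse onto single edges, and gene/protein symbols are
uppercased, whitespace-stripped, and passed through a small alias map for
common typos (e.g. `HDCA4` → `HDAC4`). Targets are annotated with the
pathway codes of the gene sets containing them (two-column CSV or GMT).
"Multitarget capacity" is operationalized as the sort key (number of
pathway-annotated targets, descending; total distinct targets, descending;
compound id, alphabetical) — the underlying counts are all returned, so a
ranking purely by total target count is one `arrange()` away. Exports:
GraphML (round-trip exact), SIF, and node/edge CSVs.

## The synthetic-data generator

Real inputs for phases 1 and 3 of the original screen (the descriptor
matrix of the literature-derived senolytics and the BindingDB-filtered
candidate set) were never published, so the package carries a generator
that emulates their statistical structure and gives every stage a ground
truth:

* **Libraries** come from a fragment grammar — aryl/heteroaryl/cycloalkyl
  scaffold templates with drug-like substituents — so every SMILES is valid
  by construction. Planted analog families share a large (~20 heavy atom),
  deliberately desymmetrized three-ring scaffold and differ from their
  parent by a single small (one heavy atom) substituent edit; this keeps
  parent–analog Tanimoto similarity above ~0.7 while decoys, drawn from
  disjoint scaffolds, average below 0.25. The desymmetrization matters:
  on highly symmetric scaffolds many paths collapse to identical canonical
  strings, which shrinks the shared bit set and makes even single-atom
  edits look disproportionately large.
* **Descriptor tables** are uniform draws inside wide drug-like windows
  (MW 150–800 Da, ALOGP −2–8, HBA 0–12, HBD 0–8, PSA 10–220 Å², ROTB 0–15,
  aromaticity 0–15, alerts 0–3), count columns rounded — matching the
  spread seen in natural-product libraries rather than any particular
  distribution shape.
* **Binding tables** give background compounds 0–2 random targets and one
  planted winner 6 distinct targets, of which 3 belong to senescence
  pathway gene sets, so the multitarget ranking must place it first.

What the generator does **not** emulate: real natural-product chemotypes
(macrocycles, glycosides, fused terpenoid systems), tautomerism,
stereochemistry, correlated descriptor distributions, or the promiscuity
structure of real binding databases. Green recovery tests therefore show
that the machinery is correct and discriminating under the stated
conditions, not that the screen has a particular sensitivity on real
chemical matter.

## Fixtures from the published screen

Three plain-text fixtures transcribe what the original report actually
printed: the nine cluster-one lead compounds with their PubChem CIDs, the
17 drug-like candidates with ZINC IDs, and the interaction lists of the
three top candidates (hinokitiol → 7 HDAC/TYR targets, preussomerin C →
10 chemokine-axis targets, tanshinone I → 6 targets including RAD51),
plus minimal pathway sets (CC = {HDAC4, HDAC5}, OSIS = {JUN},
DDR = {RAD51}) consistent with the reported annotations. Structures and
descriptor values were *not* printed, so the SMILES column of the
candidate fixture and the lead descriptor matrix are local
reconstructions, labelled `synthetic` in their filenames; compound
identity is carried by the database IDs. The fixtures support
self-consistency checks (the lead table clusters back to its own
membership; the candidate table deduplicates to 17; the network degrees
come out 7/10/6), not byte-level reproduction of the original software
outputs — the original 79-compound clustering, the 345/562 QED split
(computed with an undocumented descriptor implementation), the per-lead
silhouettes of an unprinted 53-molecule set, and the full 861-node network
are documented as not desk-reproducible, and the package replaces them
with the property-based tests described above.

## Parameters that matter

| Parameter | Default | Where | Why |
|---|---|---|---|
| QED threshold | 0.5 (strict >) | `filter_druglike()` | published protocol |
| QED weights | published optimal set | `qed_weights()` | the "weighted" in wQED; `"equal"` gives the plain geometric mean |
| Fingerprint length | 1024 bits | `fingerprint_compounds()` | protocol default; 512/2048 supported |
| Max path length | 6 bonds | `fingerprint_compounds()` | standard path-fingerprint depth |
| k (lead selection) | 2 | `select_lead_cluster()` | two broad senolytic chemotype families |
| k (similarity screen) | elbow per lead over k = 2..min(8, n−1) | `screen_against_lead()` | the protocol chose 3 for its data; the elbow reproduces that choice on three-blob data |
| K-means restarts | 10 | `kmeans_cluster()` | stable WSS optimum at screen-sized n |
| Seeds | explicit everywhere | all stochastic functions | no wall-clock seeding; reruns reproduce manifests |

## Problem sizes used in the tests

Unit and property tests run on 3–36-point clustering instances, libraries
of 25–56 generated molecules, 10-seed recovery loops with 50 decoys + 5
analogs, and the 17-compound / 23-edge fixtures; these sizes exercise
every code path while keeping the full suite around a minute and a half of
compute. Degenerate inputs are tested explicitly: empty registries,
all-identical fingerprints (rejected as degenerate geometry), zero-variance
descriptor columns (dropped with a warning), singleton clusters, evenly
split anchors (an error demanding an explicit choice), and non-monotone
elbow curves (warned, still answered).

## Known limitations

* Descriptor values are backend-dependent; only counts are exact across
  toolkits. No attempt is made to byte-match any proprietary descriptor
  software.
* The fingerprint is this package's pinned definition — reproducible
  within the package, but not bit-compatible with any external toolkit's
  "extended" fingerprint.
* Tautomers and protonation states are not normalized; stereoisomers
  collapse in fingerprint space but remain distinct registry records.
* The pathway gene sets shipped are minimal placeholders for the fixture
  checks; real analyses should supply their own GMT.
* Greedy Ward is not globally optimal on weakly separated data (see
  above).
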