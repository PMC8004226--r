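# senoscreen

Virtual screening of natural-product libraries for **senolytic
candidates** — compounds that selectively kill senescent cells. The package
is for computational chemists and aging-biology groups who want a tested,
fully offline implementation of the descriptor/fingerprint/network screen
used to propose natural products as senolytics, with every stage exposed as
an ordinary R function over tibbles.

## The method

The screen runs in four phases:

1. **Lead selection.** Known senolytics are clustered in z-scored
   molecular-descriptor space (K-means with k-means++ starts, and Ward
   `ward.D2` on Euclidean distances, same k; PCA for chemical-space maps).
   The cluster containing the anchor compounds becomes the lead set.
2. **Drug-likeness (QED).** Each library compound's eight descriptors
   (MW, ALOGP, HBA, HBD, TPSA, ROTB, aromaticity, structural alerts) are
   mapped through the published asymmetric-double-sigmoid desirabilities
   d_i and combined as the weighted geometric mean

   QED = exp( Σ w_i ln d_i / Σ w_i ),

   with the published weights; compounds with QED > 0.5 (strict) survive.
3. **Similarity screen.** For each lead, the lead plus the drug-like
   candidates are fingerprinted (1024-bit hashed atom paths with ring and
   atomic properties), the Tanimoto distance matrix `1 − |A∩B|/|A∪B|` is
   clustered with Ward (k from the elbow of the WSS curve), the partition
   is validated by mean silhouette and Dunn index, and the candidates
   sharing the lead's cluster are kept. The union over leads is
   de-duplicated by canonical structure.
4. **Network ranking.** Candidates' protein targets (BindingDB-style
   tables) are joined to senescence pathway gene sets (DD/TSIS, OSIS, DDR,
   SASP, CC, …) in a bipartite compound–target graph, and candidates are
   ranked by multitarget capacity: pathway-annotated target count, then
   total distinct targets.

Molecule perception (SMILES parsing, canonicalization, SDF I/O, SMARTS
matching) runs on OpenBabel via ChemmineR/ChemmineOB; clustering and PCA
use base R; the network uses igraph. The QED desirabilities, the pinned
path fingerprint, the cluster-validity indices, and the synthetic-data
generator are implemented in this package. See the methods vignette
(`vignettes/senolytic-screening.Rmd`) for all pinned conventions.

## Worked example

Network-phase ranking from the interaction lists of the three reported top
candidates, plus QED filtering of the 17-compound candidate table:

```r
library(senoscreen)
fixture <- function(f) system.file("extdata", f, package = "senoscreen")

net <- build_target_network(
  read_bindings(fixture("figure6_bindings.csv")),
  read_pathways(fixture("senescence_pathways.csv"))
)
net
#> <seno_network> 3 compounds, 23 targets, 23 edges

rank_multitarget(net) |> dplyr::select(compound_id, n_targets, n_senescence_targets)
#> # A tibble: 3 × 3
#>   compound_id  n_targets n_senescence_targets
#>   <chr>            <int>                <int>
#> 1 ZINC95911093         7                    2
#> 2 ZINC34383300        10                    1
#> 3 ZINC2558154          6                    1
```

ZINC95911093 (hinokitiol) reaches 7 distinct targets of which 2 (HDAC4,
HDAC5) sit in the cell-cycle pathway set; ZINC34383300 (preussomerin C) has
the largest total degree, 10; ZINC2558154 (tanshinone I) hits 6 targets
including RAD51 (DNA-damage response). Ranked by raw target count,
preussomerin C comes first.

```r
cand <- read_compounds(fixture("table2_candidates_synthetic_smiles.csv"))
nrow(dedup_compounds(cand))
#> [1] 17

scores <- qed_score(compute_descriptors(cand))
head(dplyr::arrange(scores, dplyr::desc(qed)), 3) |> dplyr::select(compound_id, qed)
#> # A tibble: 3 × 2
#>   compound_id     qed
#>   <chr>         <dbl>
#> 1 ZINC3875454   0.827
#> 2 ZINC3871891   0.768
#> 3 ZINC100090140 0.732
```

All 17 reconstructed candidate structures are unique, and their QED scores
put gliotoxin, carnosol and neurolenin B at the drug-like top of this set.

A full synthetic run with planted ground truth:

```r
sp <- synth_spec(seed = 11, n_decoys = 30, n_analog_families = 1,
                 analogs_per_family = 5)
inputs <- generate_pipeline_inputs(sp, tempfile())
res <- run_pipeline(pipeline_config(
  library = inputs$paths$library, leads = "FAM1_PARENT",
  bindings = inputs$paths$bindings, pathways = inputs$paths$pathways,
  seed = 11))
res$ranking$compound_id[1] == inputs$winner$winner_id
#> [1] TRUE
```

The manifest in `res$manifest` records the attrition counts at every stage
(loaded → valid → drug-like → with binding records → co-clustered →
de-duplicated → ranked).

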