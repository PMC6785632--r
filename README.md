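# neighborsep

Gene order in yeast genomes is not random: some neighboring gene pairs keep
their adjacency across large evolutionary distances, which suggests the
neighborhood itself is under selection. `neighborsep` asks what happens
*after* such a conserved neighborhood breaks. Given per-species gene
annotations, an orthology map from a focal species (S. cerevisiae in the
motivating application) to its relatives, expression matrices, gene sets
and interaction networks, the package:

1. **identifies** focal gene pairs whose orthologous counterparts are
   chromosomal neighbors in more than half of their *appeared* species
   (the species where both genes have orthologs) yet are separated in the
   focal genome — on different chromosomes, or flanked by at least 15
   genes;
2. **derives** the two gene groups: **ECNS** genes (evolutionary-conserved
   neighbors separated) and the presence-matched control **NECNS** genes,
   whose ortholog pairs were neighbors in exactly one species before
   separating;
3. **contrasts** the groups by expression divergence (a corrected,
   z-normalized, per-gene summary of 1 − interspecies expression
   correlation) and by Spearman coexpression, with Mann–Whitney *U* tests
   and bootstrap confidence intervals for medians;
4. **tests** whether the *cross pairs* — a group gene's before-separation
   partner paired with its current (after-separation) neighbor — share TF
   binding, GO cellular components, genetic interactions or PPIs more often
   than expected, using a chromosome-matched permutation null: every gene
   is replaced by a random gene from its own chromosome (never itself) and
   the co-feature frequency is recomputed; the empirical *P* is the
   fraction of randomizations with a strictly higher frequency (the
   add-one estimate `(k+1)/(n+1)` is reported alongside).

Key thresholds: per-gene ortholog presence in ≥ 60% of the non-focal
species; conserved means adjacent in ≥ ⌈n/2⌉ of *n* appeared species (3, 4,
4, 5, 5 for n = 6…10); separation means different chromosomes or ≥ 15
intervening genes; permutation default is 100,000 iterations.

Because the real multi-species datasets are external downloads, the
package ships a first-class synthetic data generator (`synth_config()`,
`simulate_dataset()`) that emulates an 11-species design with gene loss,
inversions/translocations, planted conserved-but-separated pairs, planted
coexpression and planted co-feature enrichment — with a machine-readable
ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(neighborsep)

cfg    <- synth_config(seed = 1)          # 11 species, 800 genes, defaults
gen    <- simulate_genomes(cfg)
pairs  <- classify_pairs(gen$annotations[-1], gen$orthomap)
table(pairs$class)
#>      conserved          other single_species
#>            694            744            657

groups <- derive_groups(pairs, gen$annotations[["sp00"]])
groups
#> group_assignment: 60 ECNS, 60 NECNS genes; 34 conserved-separated,
#> 378 single-species-separated pairs; 341 exclusions
mean(gen$truth$ecns_genes %in% groups$ecns)   # planted genes recovered
#> [1] 1

feats <- simulate_features(cfg, gen$truth,
                           gen$annotations[["sp00"]]$gene_index$gene)
cp  <- cross_pairs(groups, "ecns", gen$annotations[["sp00"]],
                   gen$orthomap, gen$annotations[-1])
res <- permutation_test(unique_cross_pairs(cp), feats$cellular_component,
                        "co_component", gen$annotations[["sp00"]],
                        n_iter = 10000, seed = 2)
res
#> permutation_result: co_component — observed 0.5417, empirical P 0
#> (add-one 9.999e-05) over 10000 iterations (seed 2)
```

The observed 0.54 co-component frequency of the before/after cross pairs
never occurs among 10,000 chromosome-matched randomizations — the planted
enrichment is detected. The `table(pairs$class)` line shows the search
space: 694 candidate pairs are conserved (mostly still-adjacent backbone
pairs), 34 of them are also separated in the focal genome, and after
excluding genes that keep another conserved neighbor, 60 ECNS genes remain
— exactly the planted set.

The same analysis runs as a staged pipeline from a YAML config
(`run_pipeline()`, or `inst/scripts/run_pipeline.R` from a shell), writing
a pair table, group memberships, cross pairs, divergence and contrast
tables, a permutation report and a JSON summary, all stamped with the
config hash and seed.

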