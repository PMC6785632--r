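---
title: "Detecting constraints on gene repositioning after conserved neighborhoods separate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting constraints on gene repositioning after conserved neighborhoods separate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighborsep)
```

## The question and the procedure

Neighboring genes in yeast genomes are often coexpressed, and some
neighborhoods are conserved across species — evidence that adjacency can
be selectively maintained. When such a conserved neighborhood *does* break
in one lineage, the genes do not land in arbitrary places: this package
implements the analysis that quantifies those constraints.

The procedure has four parts.

**Identification.** A focal-species gene is *eligible* if it has
orthologous counterparts in at least a fraction (default 60%) of the
non-focal species. For an eligible gene pair, the *appeared species* are
the non-focal species in which both genes have at least one ortholog; the
pair is an *evolutionary-conserved neighboring pair* if its orthologs are
immediately adjacent in more than half of the appeared species — as an
integer count, `conservation_threshold(n) = ceiling(n / 2)`, i.e. 3, 4, 4,
5, 5 species for pairs appearing in 6–10. "Neighbors" means adjacent order
indices on the same chromosome, strand ignored: the source analysis never
defines a wider neighborhood, and simple adjacency is the minimal reading
that makes the printed thresholds meaningful. A pair adjacent in exactly
one species is a *single-species* pair; everything else is `other`.

**Separation and groups.** A pair is *separated* in the focal genome if
its genes sit on different chromosomes or have at least `min_intervening`
(default 15) genes between them. Conserved pairs passing separation are
the conserved-separated pairs; their genes, minus any gene that also
occurs in a conserved pair *failing* separation (it has not left all of
its conserved neighbors), form the **ECNS** group. Genes of separated
single-species pairs, minus any gene occurring in *any* conserved pair,
form the matched control **NECNS** group. Each group gene carries its
*before-separation partners* (the other genes of its separated pairs) and
its *after-separation neighbors* (its current adjacent genes); pairing
them, and dropping any pair that is itself adjacent in the focal genome or
ortholog-adjacent in any species, yields the *cross pairs* on which the
co-feature analysis runs.

**Expression statistics.** Coexpression is Spearman correlation over
shared non-missing conditions (at least 3, otherwise the pair is dropped
and logged). Expression divergence follows a correction/normalization
recipe: per gene and species pair, raw divergence is 1 − Pearson
correlation of matched-condition profiles; it is corrected by subtracting
the mean intraspecies divergence of the two species (1 − correlation
between replicate profiles, averaged over genes); corrected values are
z-normalized over genes within each species pair (mean 0, variance 1,
checked to 1e-9); a gene's final value is the mean of its available
components. The cited upstream divergence measure publishes only these
correction and normalization steps, not its base formula; 1 − Pearson on
log expression is this package's choice of base measure and is validated
by rank-recovery simulations rather than by numeric equality to the
external dataset. Group contrasts use the Mann–Whitney *U* test —
tie-aware exact enumeration when both groups have ≤ 8 values, tie-corrected
normal approximation otherwise — and medians carry bootstrap percentile
confidence intervals (default 1000 resamples, explicit seed).

**Permutation test.** For each co-feature (shared TF-target set, shared
cellular component, negative/positive genetic interaction, PPI) the
observed frequency over cross pairs is compared with a chromosome-matched
null: each *distinct* gene in the pair list is independently replaced by a
uniform draw from its own chromosome excluding itself, one mapping per
iteration, applied to all pairs. Chromosome matching controls for
chromosome-scale biases in features such as TF binding. The empirical *P*
is the fraction of iterations with a *strictly* higher frequency, matching
the source definition; since a strict count can legitimately be zero, the
add-one estimate `(k + 1) / (n_iter + 1)` is always reported next to it.
Replacement collisions (two genes mapped to one, or a pair collapsing to a
self-pair) are kept as drawn: a self-pair can never satisfy an interaction
feature (networks store no self-edges) and trivially satisfies a shared-set
feature when the gene has any set, which the randomization treats as part
of the null.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eligibility_fraction` | 0.6 | minimum fraction of non-focal species with an ortholog, per gene |
| `min_intervening` | 15 genes | separation threshold on one chromosome |
| `n_iter` | 100000 | permutation iterations |
| `n_boot` | 1000 | bootstrap resamples for median CIs |
| `full_enum_limit` | 2000 genes | below this, background coexpression enumerates all pairs; above, it samples `n_pairs` (default 1e5) |

The defaults reproduce the study conditions of the motivating analysis;
tests and examples lower `n_iter` (1e3–1e4), which changes only Monte
Carlo resolution, not the statistic.

## Design decisions on genuinely open points

* **Appeared species = joint presence.** The species count governing the
  threshold is the number of species where *both* genes are present, the
  reading under which the printed 6–10 range of a pair's species counts is
  coherent with per-gene 60% eligibility.
* **One-to-many orthologs.** A species counts as a neighbor species if
  *any* ortholog of one gene is adjacent to *any* ortholog of the other
  (existential rule, the weakest assumption); in divergence, the
  minimum-divergence ortholog is used (`ortholog_mode = "mean"` is
  available). Tandem duplicate orthologs are not collapsed.
* **NECNS eligibility.** The control group also enforces per-gene
  eligibility (`necns_eligibility = TRUE` by default) so that ECNS and
  NECNS are matched on ortholog presence; the toggle exists because the
  source describes the rule only for the conserved group.
* **ECNS exclusion set.** Genes are excluded when they occur in a
  conserved pair failing the *separation criterion* (its negation), not
  merely in a still-adjacent pair; `exclusion_mode = "adjacent"` provides
  the stricter variant.
* **Cross-pair deduplication.** Identical (before, after) pairs arising
  from different source genes are deduplicated for frequency statistics
  (frequencies are over gene pairs) but kept with multiplicity in the
  audit table.
* **Class precedence.** At very small appeared counts a pair could satisfy
  both the conserved and the single-species definition
  (`ceiling(2 / 2) = 1`); `conserved` takes precedence. Under the 60%
  eligibility rule with ten non-focal species this situation cannot arise.
* **Two-sided tests.** Mann–Whitney *P* values are two-sided throughout;
  the directional claims in the motivating analysis never state sidedness,
  and two-sided is the conservative choice.

## What the simulator emulates — and what it does not

`simulate_genomes()` evolves all species from a shared backbone gene order
on a star phylogeny: conservation counting is tree-blind (it only counts
species), so independent lineages suffice for testing; a tree mode is
deliberately out of scope. Noise consists of per-gene Bernoulli loss
(non-focal species) and random inversions and segment translocations with
uniform breakpoints (all species).

Planted structure is inserted *outside* the backbone so its classification
is controlled exactly:

* a conserved-separated unit `[a, b]` is inserted adjacently in every
  non-focal species at insertion slots each shared by 2 (or 3) species, so
  each incidental flank adjacency is seen in 2–3 species — too many to be
  single-species, too few to reach the threshold;
* a single-species unit `[c, d]` is adjacent only in one species (at a
  chromosome tail, whose single flank adjacency is repeated in a second
  species), with both genes inserted separately elsewhere;
* in the focal genome every planted gene gets its own slot, pair members
  on different chromosomes.

This is why the generator requires at least 8 species: with 6 non-focal
species an odd spread forces a 3-species context, and
`ceiling(6 / 2) = 3` would make that context a conserved pair. Planted
genes are exempt from loss, and rearrangement breakpoints that would break
a planted adjacency (or un-separate a planted pair in the focal genome)
are rejected and redrawn, so the emitted truth always passes its
consistency check. With `loss_rate = 0` and `rearrangement_events = 0`
the planted pairs are *provably the only* conserved-separated and
single-species-separated pairs, and the pipeline must recover them with
precision = recall = 1; under noise, loss can thin incidental flank
contexts into spurious single-species pairs, so only recall of the planted
structure is guaranteed — a property real data share, which is exactly why
the control group exists.

Expression is a latent-factor model: each gene has a latent condition
profile shared by its orthologs, planted coexpressed pairs mix in a common
factor with weight `sqrt(rho)` (so the target Pearson correlation is
`rho`, and the expected Spearman is the bivariate-normal mapping
`(6 / pi) * asin(rho / 2)`), species add Gaussian noise
(`interspecies_sd`, default 0.5), and each condition is emitted in two
replicates with noise `noise_sd` (default 0.1) to support the intraspecies
baseline. Features are drawn so a random gene pair shares a set with
probability `cofeature_background` (default 0.05, via per-set membership
`p = sqrt(1 - (1 - bg)^(1/m))`), planted cross pairs gain a shared
set/edge with probability `cofeature_enrichment` (default 0.5), and
essentiality is drawn per group at rates 0.22 (ECNS), 0.07 (NECNS) and
0.16 (other), the fractions reported for the real groups.

What the simulator does **not** emulate: realistic yeast divergence times
or rearrangement rates, whole-genome duplication (the identification
procedure never uses it), duplicated orthologs, condition-set mismatches
between species, and missing expression values. Passing tests therefore
demonstrate correctness of the inference machinery under its stated
assumptions, not robustness to every artifact of real compendia.

## Numerical choices and degenerate inputs

Gene order is the rank of the start coordinate per chromosome (0-based),
ties broken by lexicographic gene ID, so annotation reading is
permutation-invariant. Coordinates are 1-based inclusive; only order
indices are used downstream. Spearman uses average ranks for ties. The
divergence z-normalization refuses zero-variance components (identical
matrices with perfect replicates) with a hard error rather than emitting
NaNs. Empirical *P* values compare integer co-feature *counts*, never
floating-point frequencies, so strict-greater is exact. All stochastic
operations take an explicit seed and restore the caller's RNG state; the
permutation test draws replacements in chunks (2000 iterations) to bound
memory at large `n_iter`.

The type-I behaviour of the strict-greater empirical *P* was analyzed at
design time: with discrete co-feature counts the rejection probability at
the 5% level depends on the null's granularity, and 30 pairs at a 5%
background co-feature rate give an analytic rejection probability of
about 0.06 — the configuration the null-calibration test uses.

## Problem sizes used by the test suite

The default generator configuration (11 species, 800 genes, 16
chromosomes, 30 planted pairs of each kind, 50 duplicated conditions) is
the package's reference scale: large enough that thresholds, eligibility
and chromosome-matched randomization all operate non-trivially, small
enough for interactive use. Property tests run the brute-force candidate
oracle at 60 genes, the exhaustive permutation oracle on chromosomes of
≤ 4 genes, null calibration at 200 permutation-test replicates of 400
iterations, and divergence rank-recovery at 500 genes — each size chosen
so the check's own Monte Carlo error is far below the tolerance it
asserts.

## Known limitations

* The divergence base measure (1 − Pearson) is a reconstruction; absolute
  divergence values are not comparable to the external precomputed
  dataset, only to other values from this package.
* Cross pairs whose genes lack expression data are silently absent from
  coexpression summaries (they are logged, not imputed).
* The permutation null preserves each gene's chromosome but not its local
  gene density or telomere distance; features correlated with position at
  sub-chromosome scale would need a finer-grained null.
* GO biological-process enrichment of the groups is out of scope (the
  motivating analysis used an external web service for it).
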