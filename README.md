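# hostspec

Host-use specificity analysis for armored scale insect (Diaspididae)
communities surveyed on individual canopy trees.

Armored scale insects disperse as wind-blown first instars and settle for
life, so the occurrence of a second instar or adult female on a tree is
direct evidence the tree is a suitable host, and abundance and patch
occupancy are clean proxies for performance.  Given an occurrence table of
insects on individual trees (with a species/genus/family host taxonomy),
multi-locus sequence data, and a time-scaled insect phylogeny, `hostspec`
answers, with permutation-calibrated tests at each host-taxonomic level:

* **Who are the species?**  DNA-based delimitation by genealogical
  concordance: clades shared by at least two of three gene trees and
  contradicted by none are independent lineages; the smallest lineages with
  three or more specimens are provisional species; the minimum
  between-species divergence becomes a threshold that rescues the remaining
  specimens (`delimit()`).
* **Are they diet specialists?**  The mean Simpson's reciprocal diversity
  index (1/D, the effective number of host taxa) of the trees each species
  colonizes, against a degree-preserving randomization of the
  species-by-tree network; negative Z means specialization
  (`specificity_test()`).
* **Is host use phylogenetically conservative?**  A Bayesian threshold
  (liability) model estimates, per host taxon, the proportion of liability
  variance explained by the phylogeny, h² = σ²ₚ/(σ²ₚ+1), tested against
  checkerboard-swap null matrices with BH-FDR control (`fit_signal()`,
  `signal_test()`).
* **Do specialists outperform generalists?**  Poisson abundance-per-tree
  and binomial patch-occupancy GLMs on diet breadth, with significance from
  permuting breadths across species (`tradeoff_test()`).

A synthetic-data module (`simulate_survey()`, `simulate_gene_trees()`)
generates every input with known ground truth — species partitions,
liability heritabilities, diet-breadth effects — so the whole chain is
validated end to end.

## Worked example

```r
library(hostspec)

set.seed(1)
sv <- simulate_survey(n_insect_species = 50, beta_abund = 0, beta_occ = 0.5,
                      h2 = 0.5, regime = "mixed", sites = "site1")$site1

specificity_test(sv$links, "family", n_permutations = 1000, seed = 2)
#> Diet-specificity permutation test (mean Simpson's 1/D of host trees)
#>   site: site1   host-taxon level: family   permutations: 1000
#>   empirical 1/D: 2.687   null 1/D: 3.733 (sd 0.099)
#>   Z = -10.579,  two-sided p = <0.001

tt <- tradeoff_test(sv$links, sv$census, "species", n_perm = 1000, seed = 3)
tt$abundance
#> Permutation GLM test (poisson-log)
#>   slope: 0.010   null: -0.001 (sd 0.009)
#>   Z = 1.258,  two-sided p = 0.208   (1000 permutations)
tt$occupancy
#> Permutation GLM test (binomial-logit)
#>   slope: 0.402   null: -0.004 (sd 0.067)
#>   Z = 6.078,  two-sided p = <0.001   (1000 permutations)
```

The simulated community is specialized (empirical host diversity far below
the null: Z = −10.6), diet breadth does not predict abundance on a tree
(slope ≈ 0, p = .21; the generator's abundance effect is zero), and broader
diets predict occupying more of the potential host trees (positive slope,
p < .001; generated effect 0.5 on the logit scale).

Delimitation on synthetic gene trees with a known partition:

```r
part <- list(A = paste0("a", 1:4), B = paste0("b", 1:4), Z = "z1")
g <- simulate_gene_trees(part, concordance = 1, dropout = 0, seed = 4)
D <- p_distance(trim_alignment(g$supermatrix$alignment))
delimit(g$trees, D)
#> Species assignment (genealogical concordance + divergence threshold)
#>   specimens:           9
#>   species:             3
#>   provisional species: 2
#>   threshold:           0.1606
#>   origins:             provisional=8, threshold_singleton=1
```

The two 4-specimen species are recovered as provisional species and the
deep singleton `z1` is rescued by the divergence threshold.

`run_all()` stratifies a multi-site table by site, runs all three analyses
at the requested host-taxonomic levels, and writes `specificity.tsv`,
`tradeoff.tsv`, `signal.tsv` and a JSON manifest with the seed and settings.

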