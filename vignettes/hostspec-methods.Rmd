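---
title: "Methods: host-use specificity analysis in hostspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-use specificity analysis in hostspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostspec)
```

# The problem

Armored scale insects (Diaspididae) are sessile herbivores with a
pathogen-like life history: first-instar nymphs disperse on the wind, settle
on whatever plant they land on, and never move again.  A second instar or
adult female on a tree is therefore direct evidence that the tree is a
suitable developmental host, and the abundance and patch occupancy of a
scale-insect species across host trees are unusually clean proxies for its
ecological performance on those hosts.  `hostspec` implements the analysis
chain for canopy surveys of this kind: individual trees, nested in a
species/genus/family host taxonomy, carry counts of insect specimens by life
stage; insect species boundaries come from multi-locus sequence data; and
the questions are (i) are species diet-specialized, (ii) is host use
phylogenetically conservative, and (iii) do specialists outperform
generalists on shared hosts?

All statistics use the *establishment view* of the occurrence table: records
of second instars and adult females with positive counts.  First instars
land haphazardly and demonstrate nothing about host suitability.

# Species delimitation by genealogical concordance

`delimit()` consumes three per-locus gene trees and a pairwise divergence
matrix.  Clades (leaf sets of nodes, on the tree as rooted; unrooted input
is midpoint rooted) are *evolutionarily independent lineages* when they are
present in at least two of the three gene trees and contradicted by none.
Because loci fail to amplify for some specimens, a clade's status in a tree
is evaluated on its restriction to the tree's leaves: restrictions of size
one or covering the whole tree are uninformative; otherwise the clade is
present if the restriction is exactly some node's leaf set, and contradicted
if not.  *Provisional species* are the smallest independent lineages with at
least three specimens (nested lineages with fewer than three members do not
disqualify a parent — otherwise any concordant cherry would).  When
independent lineages overlap without nesting (possible under partial
overlap), the lineage present in more trees wins, then the larger, then the
lexicographically smallest; the survivors form a laminar family.

Species represented by fewer than three specimens cannot be delimited this
way.  The *divergence threshold* — the minimum between-provisional-species
distance — becomes the maximum allowed within-species divergence: specimens
farther than the threshold from every other specimen become singleton
species, and the rest join their nearest cluster by single linkage at the
threshold (chains of mutually close leftovers form new multi-member
species).  With a single provisional species the threshold falls back to
that species' maximum internal divergence; with none, `delimit()` stops with
an error rather than invent a threshold.

Divergences default to uncorrected p-distances on the trimmed supermatrix
(`p_distance()` after `trim_alignment()`, which keeps exactly the columns
with unambiguous nucleotides in at least 80% of specimens); patristic
distances on a supplied tree (`patristic_distances()`) are an equivalent
plug-in.  Gaps, `N` and IUPAC ambiguity codes all count as missing, a
conservative convention for divergence.

# Diet specificity

For each insect species, host diversity is Simpson's reciprocal diversity
index (1/D) of the *distinct trees* it colonizes, counted per host taxon at
the chosen level; 1/D is the effective number of equally used host taxa and
equals 1 for a single-tree species (such species are retained).  The test
statistic is the mean 1/D across insect species.

The null model randomizes which trees each species occupies while holding
fixed both every species' number of colonized trees and every tree's number
of species.  `permute_associations()` and `specificity_test()` implement
this with curveball trades on the bipartite species-by-tree incidence,
which sample uniformly from the simple bipartite graphs with the observed
margins.  A plain permutation of the species column across links
(`method = "label"`) is also provided, but note that it samples
*multigraphs* — one species can be dealt the same tree twice — and against
data in which trees are colonized independently it is badly anticonservative
(measured type-I error near 1 at nominal 0.05).  The degree-preserving
randomization conserves the same two quantities the label permutation is
meant to conserve, and is exactly calibrated conditionally on the margins,
so it is the default and the scheme used by `specificity_test()`.
Significance is summarized as `Z = (empirical − null mean)/null sd` with a
two-sided normal p-value; specialization shows up as negative Z.  One
curveball chain supplies the null draws (burn-in of 10 trades per species,
one sample per species-count trades); at these settings the chain decorrelates
faster than the statistic's Monte Carlo noise at 200–1000 draws.

# Phylogenetic signal of host use

The binary use/nonuse of each host taxon is modelled with a threshold
(liability) model on the insect species tree:

$$y_i = \mathbf{1}[\,l_i > 0\,], \qquad
  l = \mu + u + e, \quad u \sim N(0,\ \sigma_p^2 V^\*), \quad
  e \sim N(0, I),$$

where $V^\*$ is the Brownian-motion covariance of the tree
(`phylo_vcv()`) scaled to unit mean diagonal, so estimates are invariant to
branch-length rescaling.  The residual variance is fixed at 1 — a binary
threshold model is otherwise unidentifiable — and the quantity of interest
is the phylogenetic heritability of the liability,
$h^2 = \sigma_p^2 / (\sigma_p^2 + 1)$.

`fit_signal()` samples the posterior by Gibbs: liabilities are one-sided
truncated normals (inverse-CDF sampling, with an exponential-rejection tail
for extreme truncation points); the random effect updates in the eigenbasis
of $V^\*$, where its conditional is independent normals; the intercept has a
flat prior; and $\sigma_p^2$ carries a half-Cauchy(scale 1) prior on
$\sigma_p$, updated by slice sampling on $\log \sigma_p^2$.  Chain defaults
are 13,000 iterations, 3,000 burn-in, thinning 10, matching common practice
for binary phylogenetic mixed models; the reported `ess_h2` (autocorrelation-
based effective sample size) typically lands near 100, and posterior means
across chain seeds agree to about 0.01.  Fits are deterministic given a
seed.

`signal_test()` compares each host taxon's empirical $h^2$ to its
distribution over null host-use matrices produced by checkerboard swaps
(`swap_null()`): 2x2 submatrix exchanges that conserve every row and column
sum exactly, run for 10 times the number of associations per null matrix.
A row-wise shuffle preserving only diet breadths is available as
`null_method = "rowshuffle"`.  Only taxa with at least two using and two
non-using species are testable (the model is undefined for constant
columns); others are reported as skipped.  Per-taxon two-sided Z tests are
corrected by Benjamini–Hochberg FDR at `q = 0.05` within each taxonomic
level, since the three levels are alternative configurations of the same
data.  Null refits default to the same chain settings as the empirical fit;
`null_mcmc` can shorten them when thousands of nulls are needed, at some
cost in null-distribution sharpness.

**What the estimator can and cannot do.**  Parameter-recovery simulations
(single binary trait, 100-tip trees, balanced prevalence) show the posterior
mean of $h^2$ is essentially unbiased and monotone in the truth, with mean
absolute error about 0.13 at $h^2 = 0$ and $h^2 = 0.8$.  At intermediate
signal ($h^2 = 0.4$) the across-dataset scatter is larger (MAE near 0.19):
the per-dataset posterior sd is itself 0.17–0.25, so this is an information
limit of one binary character on 100 tips, not sampler noise — posterior
means recomputed with different chain seeds move by ~0.01.  Single-taxon
$h^2$ estimates should be read with their credible intervals, and the
permutation Z test — which is calibrated at this scale — carries the
inferential weight.

# Diet-breadth trade-offs

Diet breadth is the number of host taxa (at the level under analysis) with
at least one colonized tree.  Two GLMs relate performance to breadth, fitted
by IRLS (`stats::glm.fit`, tolerance 1e-10):

* **Abundance**: one record per colonized (species, tree) pair; the response
  is the establishment count on that tree, Poisson with log link.
* **Occupancy**: one record per observed (species, host taxon) pair; the
  response is trees colonized out of trees surveyed within the taxon,
  binomial with logit link.  Host taxa with fewer than three surveyed trees
  are excluded, which is why the tree census is a required input — the link
  table alone only lists colonized trees.

Breadth enters untransformed on the link scale.  Significance is by
permutation: diet breadths are shuffled *across species* and propagated to
records (the species is the exchangeable unit; shuffling per record would
break within-species predictor constancy, though `permute = "record"` is
available), the model refit 1,000 times, and `Z = (slope − null mean)/null
sd` converted to a two-sided normal p-value.  More than 10% non-converging
null fits abort the test.

# The synthetic-data generator

`simulate_survey()` builds, per site: an ultrametric birth–death insect
tree with depth 1; a hierarchical host taxonomy; a binary host-use matrix
from the same liability model the signal test assumes (`sqrt(h2)` Brownian
plus `sqrt(1-h2)` independent liabilities, thresholded at the quantile
giving a target prevalence, default 0.15 per host taxon); and a link table
in which each usable (species, tree) pair is colonized with probability
`plogis(qlogis(0.5) + beta_occ * centred breadth)` and colonized trees carry
`1 + Poisson(exp(log lambda + beta_abund * centred breadth) − 1)` adult
females.  Defaults encode the study conditions the analyses address:
`beta_abund = 0` (no abundance effect of breadth), `beta_occ = 0.5`
(generalists occupy more of their potential hosts), `h2 = 0.5`, mixed
specialization.  Species that happen to colonize nothing are absent from
the table, as in a real survey.

Two regimes matter for validation.  *Calibration of the specificity test*
uses indiscriminate host use — `prevalence = 1`, so every species can use
every host and trees are colonized independently — which realizes the
test's null hypothesis of random species-by-tree association.  With
`prevalence < 1`, host use is genuinely structured at the host-species
level (a species' trees concentrate in its usable hosts), and the test
should and does reject; that is its power regime, not a calibration
setting.

`simulate_gene_trees()` surrounds a known species partition with three
gene trees and sequences: an ultrametric species tree with splits between
heights 0.03 and 0.1; shallow within-species genealogies (specimen
divergence at most 0.016) grafted onto its tips; Jukes–Cantor-style
sequences (600 bp per locus) evolved along each gene tree, so supermatrix
p-distances mirror the tree depths.  Within-species topologies are
*deliberately discordant* across loci (pectinate resolutions rotated per
locus), emulating incomplete lineage sorting; if the loci agreed on
within-species clades of three or more specimens, the concordance rule
would — correctly — split those species.  Species-level discordance is
injected, with probability `1 − concordance` per locus, as an exchange of
two species' positions (a depth-preserving rearrangement).  Singleton
species attach as deep outgroups (height at least 0.5, an order of
magnitude beyond any plausible threshold) so they exercise the
threshold-rescue path.  Locus dropout removes a specimen from at most one
locus, mirroring the usual "at least two loci" inclusion rule for
multi-locus data sets; with the default 20% dropout, a species can
occasionally lose concordance entirely (three specimens missing three
different loci), which is a real property of the method under missing
data — the recovery benchmarks therefore run with `dropout = 0` and full
concordance, where recovery is exact.

## What passing the synthetic benchmarks does and does not show

The generator matches the analyses' structural assumptions (liability
signal, logistic occupancy, log-linear abundance, independent colonization
given the host-use matrix).  Passing calibration and recovery tests on it
shows the implementation is correct and conditionally calibrated; it does
not show the models fit real survey data, where abundances are
overdispersed, sites are sampled unevenly, and host phylogeny (ignored
here, as in the analyses) structures the host side as well.

# Numerical and design choices

* "At least 80%" column occupancy is implemented as `>=` (boundary kept).
* Threshold comparisons in delimitation are strict: a specimen farther than
  the threshold from everything becomes a new species; ties attach.
* Ties in single-linkage merging resolve by distance, then lexicographic
  cluster key — delimitation is deterministic given inputs.
* Z tests are two-sided everywhere, consistent with reporting conventions
  for permutation nulls; `z_to_p()` is the single transform used.
* All randomized stages take a `seed`; `run_all()` draws per-stage child
  seeds from one root seed and logs them in its manifest.
* Problem sizes in the test suite are chosen for desk-scale runs: 200
  replicates with 200 permutations for calibration of the specificity and
  trade-off tests; 12 replicate communities (24 tips, 8 host taxa, 100
  swap-null refits with 800-iteration chains) for the signal test; 20
  replicates of 100-tip trees with full-length chains for heritability
  recovery; 100 seeds for delimitation recovery.

# Known limitations

* The delimitation threshold rule inherits the method's blind spots: a
  species with fewer than three specimens that is *not* divergent beyond
  the threshold will be absorbed into its nearest neighbour, and heavy
  locus dropout can erase a species' concordance signal.
* The abundance model is plain Poisson; real counts are typically
  overdispersed, which the permutation null absorbs only partially.
* $h^2$ for a single host taxon is weakly identified at moderate signal
  (see above); conclusions should rest on the permutation test and on
  patterns across taxa, not on point estimates.
* No phylogenetic correction on the host side, and no spatial structure
  within sites; sites are strata, never pooled.
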