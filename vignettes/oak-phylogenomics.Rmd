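---
title: "Shared ancestral variation, concordance, and dating in white-oak phylogenomics"
author: "oakdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared ancestral variation, concordance, and dating in white-oak phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakdiv)
library(ape)
```

## The problem

White oaks carry extraordinary standing variation: nucleotide diversity
within *Quercus alba* is on the order of 1%, comparable to the divergence
between oak species. When a clade radiates quickly relative to its
effective population sizes, much of that variation predates speciation and
keeps segregating across species boundaries (incomplete lineage sorting).
Three practical consequences drive everything in this package:

1. a large fraction of the sites variable *within* one species is also
   variable in its relatives — worth measuring directly;
2. gene trees disagree with the species tree, so branch support must be
   reported as concordance (what fraction of windows or sites agree), not
   as bootstrap certainty;
3. ancestral polymorphism inflates measured branch lengths — a pair of
   species that split `T` generations ago differs on average by
   `2*mu*T + 4*N_anc*mu` substitutions per site, not `2*mu*T` — and a
   time calibration applied to uncorrected branch lengths pushes node ages
   too far into the past.

`oakdiv` implements the full analysis path: a multispecies-coalescent
(MSC) simulator that produces diploid resequencing datasets with known
truth; pseudo-reference construction from variant calls; nucleotide
diversity and Reich–Patterson F<sub>ST</sub>; the shared-variation
statistic; neighbor-joining window trees with gene and site concordance
factors; penalized-likelihood dating with a π-based correction; and the
genomic interval accounting used for resistance-gene clusters and
structural variants.

## The coalescent simulator and what it emulates

`species_tree_model()` fixes the study conditions: a rooted, ultrametric
species tree with branch lengths in **generations**, a diploid effective
size `Ne` per branch (a root stem of unbounded duration included), a
per-site per-generation mutation rate `mu`, and a sampling plan of diploid
individuals per species. Windows are unlinked loci: each window draws an
independent gene tree by the censored coalescent — within a branch holding
`k` lineages, waiting times are exponential with rate `k(k-1)/(4*Ne)`, so
a sampled pair coalesces after `2*Ne` generations on average — and
mutations fall on the gene tree as a Poisson process under the
infinite-sites model (each mutation hits a fresh position; `mu*L` must
stay well below 1 per branch-generation or the simulator stops with an
overflow error). Infinite sites is deliberate: the shared-variation
statistic asks whether the *same site* segregates in two groups, and
finite-site homoplasy would blur exactly the signal the statistic
measures.

What the generator does **not** emulate: recombination within windows,
migration and introgression, selection, sequencing error, and missing
data. Passing tests therefore demonstrate estimator correctness under
clean ILS — they do not show robustness to introgression (which the
shared-variation statistic cannot distinguish from ILS) or to call-quality
artifacts.

```{r simulate}
sptree <- read.tree(text = "((alba:4000,montana:4000):4000,rubra:8000);")
model <- species_tree_model(sptree, Ne = 1000, mu = 2e-6,
                            sample_plan = c(alba = 2, montana = 2, rubra = 1),
                            window_length = 2000, n_windows = 10)
ds <- simulate_dataset(model, seed = 7)
ds
```

Reproducibility is structural: every stochastic unit (window, site,
branch, restart) draws from a named substream derived from one master
seed (`substream_seed()`), so results do not depend on evaluation order
and identical configurations are byte-identical.

## Pseudo-references and the site matrix

`build_pseudoreference()` substitutes a sample's called alleles into the
reference, resolves each heterozygous call to one allele with a fair coin
tied to `(seed, chromosome, position, sample)`, and masks repeats,
indels, and calls whose support falls below `quality_threshold`
(default 20). The support metric is the per-sample GQ field, falling back
to site QUAL, and passing when neither is present; the published analyses
this stage mirrors used a dedicated genotype-quality tool whose exact
statistic is not printed, so GQ is the documented stand-in.
`build_site_matrix()` then keeps exactly the columns where **no** sample
is masked; every downstream statistic operates on those complete columns.
One consequence worth remembering: with one pseudo-reference per sample,
each sample contributes a single haplotype drawn at random from its two —
which is also why the singleton definition below is per sequence, not per
individual.

## Diversity, differentiation, and shared variation

Per site with haploid sample size `n` and allele counts `c_k`,
`pi_site = sum_{k<l} 2 c_k c_l / (n(n-1))`; genome-wide π divides by all
retained sites, monomorphic included. The Reich–Patterson
F<sub>ST</sub> estimator accumulates, over biallelic sites,
`N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2` and `D = N + h1 + h2` with
`h_j = a_j(n_j - a_j)/(n_j(n_j - 1))`, and reports the ratio of sums —
unbiased at small, unequal sample sizes, which is why it suits a handful
of trees per provenance. Sites with three or more alleles are skipped
with a logged count for F<sub>ST</sub> (the estimator is defined for two
alleles) but handled natively by π. An optional thinning stride is
exposed for F<sub>ST</sub>; the default uses every biallelic site.

`shared_variable_sites()` asks: of the sites variable within a focal
group, what fraction is also variable in a disjoint comparison group? A
focal singleton — a site whose variation is carried by exactly one focal
sequence (implemented as `n - max(base count) == 1`, which extends the
rule to multi-allelic columns) — can be excluded, since singletons are
disproportionately young variants and sequencing artifacts. The
comparison side deliberately ignores singleton status: the exclusion rule
modifies only the focal tally. Because "variable on both sides" can be
satisfied by different allele pairs, the result also carries a stricter
`n_shared_same_allele` tally requiring at least two of the comparison
group's segregating bases to occur in the focal group.

```{r shared}
sm <- site_matrix_from_sim(ds)
nucleotide_diversity(sm, "alba")
shared_variable_sites(sm, "alba", "montana")
```

## Window trees and concordance factors

`window_trees()` cuts the reference into nonoverlapping windows (5 kb by
default, trailing partial windows dropped), keeps windows with at least
`min_fraction` (default 0.5) of their positions retained and at least
`min_informative` (default 1) parsimony-informative sites, and builds one
neighbor-joining tree per window from JC69 distances
(`d = -(3/4) log(1 - 4p/3)`; a pair at `p >= 0.75` is saturated and the
window is skipped with a logged count). NJ ties are broken by the lowest
(row, column) index pair and negative branch estimates are clamped to
zero, making the output deterministic. Distance-based window trees
replace likelihood tree search deliberately: at 5-kb scale the topology
signal is dominated by a handful of informative sites, the concordance
accounting downstream is agnostic to how window trees were produced, and
`gene_concordance()` accepts externally supplied newick window trees.

For each internal branch of a reference tree, a window tree is *decisive*
when it carries at least one taxon from each of the four taxon blocks
around the branch, *concordant* when the branch's bipartition (restricted
to shared taxa) occurs in it; gCF is the concordant percentage of
decisive windows, and the concordant/conflicting/uninformative counts
always partition the window set. `site_concordance()` samples quartets
around each branch (one taxon per block, seeded per branch) and scores
alignment columns with two-versus-two base patterns; 33.3% is the
random expectation among the three quartet topologies. Under the MSC, the
expected gCF of a branch with `tau = t/(2*Ne)` coalescent units is
`1 - (2/3) exp(-tau)` — the package's tests verify both the gene-tree
frequencies and the NJ-window gCF against this closed form.

## Dating with an ancestral-polymorphism correction

`penalized_likelihood_date()` minimizes a Poisson likelihood on branch
substitution counts (`x_b = branch length x L_effective`) plus a
smoothness penalty `lambda * sum (r_b - r_parent)^2` over node ages and
per-branch rates, with the root-children rates tied through a variance
term so a dominant penalty drives every branch to one clock rate. Node
ordering and the calibration are enforced by construction: nodes below
the calibrated node are parameterized as fractions of their parent's age,
ancestors as positive increments. The optimizer starts from a
root-to-tip-mean clock solution, takes seeded random restarts, and uses
an analytic gradient with a polishing stage — needed because the
likelihood is exactly flat along an age–rate ridge and only the penalty
separates solutions on it. `lambda` defaults to 1; cross-validating it is
out of scope, and results on clocklike input are independent of `lambda`
by construction (the penalty vanishes at the optimum).

The correction: under a uniform ancestral diversity π, every tip lineage
carries an expected π/2 of "extra" substitutions accumulated in the
ancestral population, so `correct_ancestral_polymorphism()` subtracts
π/2 from each terminal branch (clamping at a floor, with clamp events
counted) and leaves internal branches alone — on a near-ultrametric tree
this equals shifting every node height down by π/2, and each tip-to-tip
path shrinks by exactly π. Correction is applied to branch lengths
*before* dating by default; because both orderings are defensible and the
original analyses do not print theirs, the correction is an isolated,
composable operation, so shifting ages after dating is equally available.

```{r dating}
tr <- read.tree(text = "((A:0.030,B:0.030):0.026,C:0.056);")
raw <- penalized_likelihood_date(tr, calibration_age = 56, seed = 1)
cor <- penalized_likelihood_date(correct_ancestral_polymorphism(tr, pi = 0.012),
                                 calibration_age = 56, seed = 1)
age_shift_report(cor, raw)
```

With π = 1.2% the A–B divergence moves from 30.0 to 26.88 Ma — a 3.12 Myr
shift toward the present from the correction alone.

## Interval accounting

`cluster_features()` chains same-category features whose gap to the
running end of the chain is at most 200 kb; chains of two or more are
clusters (a lone gene is not a cluster, matching summaries where the
percentage of clustered genes is below 100). Using the running maximum
end makes chaining equal to the transitive closure of the pairwise
"within 200 kb" relation even for nested intervals, and the tests enforce
that equivalence against a brute-force oracle. `classify_sv_sizes()` bins
structural variants of at least 100 bases into left-closed size classes
(`[100,1kb) ... [1Mb,inf)`) with margin conservation guaranteed;
`density_bins()` counts feature starts in half-open 2-Mb segments;
`gene_sv_overlap()` and `fractional_repeat_overlap()` count gene-body,
exonic, and fractional repeat overlaps on half-open coordinates (adjacency
is not overlap; overlapping repeats are unioned before fractions, and the
10%-of-length threshold is inclusive). All coordinates are 0-based
half-open internally; VCF and GFF3 are converted exactly once at the
file boundary.

```{r svtable}
classify_sv_sizes(sv_records_from_class_counts(oak_sv_class_counts()))
```

## Numerical choices and problem sizes

Defaults that matter: heterozygote resolution and quartet sampling use
per-unit substreams (order-independent); NJ tie-breaks are lexicographic;
JC saturation aborts a window rather than truncating the distance;
`quality_threshold = 20`; `min_fraction = 0.5` and `min_informative = 1`
for window retention (published window counts imply heavier, unspecified
filtering — counts are therefore not comparable across implementations);
dating uses `L_effective = 1e4` by default and three random restarts.
The test-suite simulations use hundreds of windows of 1–5 kb with
`Ne` of 200–5000 and check estimators within three standard errors of
their closed-form expectations; those sizes make the checks sharp for
means while staying desk-sized, and all are stated in the tests
themselves.

## Limitations

The statistic "variable here and variable there" counts ILS and
introgression alike; formal introgression tests are out of scope. The
MSC concordance checks calibrate the accounting, not NJ's power on real
heterogeneous data. The π correction assumes one uniform ancestral
diversity across the tree; lineage-specific ancestral sizes would need a
per-branch correction the data here cannot identify. And the penalized
likelihood ridge means very distant starting points can stall — the
clock initialization makes this a non-issue for near-ultrametric inputs,
which is the intended regime.
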