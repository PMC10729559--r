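---
title: "Methods: haploid IBD, population structure and AIM panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid IBD, population structure and AIM panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aimkit implements, end to end, the analysis workflow used to
characterise a local honey bee population (here: the Algerian
*A. m. intermissa* / *A. m. sahariensis* complex, "ALG") against European
reference lineages (M and C), and to distil that contrast into a 96-SNP
ancestry panel.  This vignette documents the models, their assumptions,
the defaults and the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

## Genotype representation and QC

Drones are haploid — each genome is a single maternal gamete — so calls
are alternate-allele counts in {0, 1}; simulated hybrids are diploid with
counts in {0, 1, 2}.  All classifiers and PCA consume the *dosage
fraction* `calls / ploidy` so that both ploidies live on a common [0, 1]
scale (a design choice: how haploid references and diploid hybrids are
co-encoded is not dictated by the workflow itself, and the dosage
fraction is the natural common scale).

A heterozygous call in a haploid sample is biologically impossible and
flags collapsed repeats or copy-number variation.  Such calls are counted
per site and then stored as missing: the site-level filter (het fraction
> 1% of samples) is the published rule; what to do with the individual
call is not specified anywhere, and treating it as missing is the
conservative choice because the filter already removes sites where the
signal is systematic.  The remaining site filters are missingness > 5%
and observed allele number ≥ 4; samples below 90% call rate are dropped.

LD pruning follows the PLINK `indep-pairwise` scheme: windows of 1749
SNPs (the window that covers ~100 kb at the SNP density of a
whole-genome drone panel; for synthetic data the window stays SNP-count
based since synthetic densities are arbitrary), advancing by
`ceiling(window * 0.9)` so consecutive windows overlap by ~10%, never
spanning chromosomes, with the last partial window still processed.
Within a window, every pair with squared Pearson correlation above 0.30
(pairwise-complete on dosage fractions) loses one member.  Which member
is dropped is unspecified in the original; we drop the lower-MAF member
(tie: the later variant), which keeps the more informative marker.  An
O(n²) within-window oracle in the test suite verifies that no retained
pair in any window exceeds the threshold.

## The IBD hidden Markov model

Kinship between two haploid genomes is estimated with a two-state HMM
(states IBD / DBD) over the sites that are polymorphic and non-missing in
both samples.  With stationary distribution π = (f, 1 − f):

* transitions over an inter-site gap of d bp:
  `a_ij(d) = δ_ij exp(−kρd) + (1 − exp(−kρd)) π_j`, with ρ the
  recombination rate (9.04 × 10⁻⁷ per bp per generation, the honey-bee
  value; bees have one of the highest recombination rates measured in
  animals) and k a generation-scale parameter;
* emissions at a site with alternate-allele frequency p and genotyping
  error ε (default 0.001): DBD emits the two alleles independently,
  `m(a₁) m(a₂)` with `m(a) = Σ_t p_t e(a|t)`; IBD emits a shared true
  allele, `Σ_t p_t e(a₁|t) e(a₂|t)`.

f and k are fitted by scaled forward–backward EM (per-site
normalisation; the package contract, enforced by a test against
exhaustive path enumeration on ≤ 12-site toys, is relative
log-likelihood error < 1e−9).  f updates to the mean posterior IBD
occupancy; k to the expected number of state switches divided by
ρ × (total inter-site gap).  EM is capped at 5 iterations by default
(the behaviour of the published haploid-IBD tool this model follows),
with tolerance 1e−3 on both parameters.  Missing sites are skipped but
their physical gap still accrues; the chain restarts at every chromosome
start (whether the original concatenated chromosomes or reset at
boundaries is unstated; resetting is the assumption here).  The reported
kinship `f_viterbi` is the fraction of used sites assigned to IBD on the
Viterbi path — the "fraction of sites IBD" convention — with the mean
posterior occupancy reported alongside.

At study scale the model is run on a seeded random subsample of 5% of
the polymorphic sites, mirroring the ~168k-of-3.4M subset used at whole
genome scale; tests verify the estimate is stable across subsample
seeds.

**Working regime.**  Detection degrades when IBD tracts span only a
handful of sites: at ~90 sites/Mb (20k sites on a 224 Mb genome) pairs
constructed at 50/25/12.5% sharing are recovered within a point or two,
while at ~4 sites/Mb the Viterbi undercalls IBD substantially.  The
package's scaled-down pipeline demonstrations therefore keep several
thousand sites so the family filter operates where the model works; this
is a property of sparse-marker HMM decoding, not of the implementation.

Families are connected components of the kinship graph above 30% — a
threshold separating full-sib drone pairs (expectation 50%) from the
unrelated background — retaining the best-call-rate member per family;
close-kin reporting uses a conservative 10% cutoff, below the
third-degree expectation of 12.5%.

## Structure and geography

PCA uses smartpca normalisation: centre each variant's dosage fraction,
scale by `sqrt(p(1−p))`, mean-impute missing calls (imputation behaviour
is unstated in the original; mean imputation is what smartpca does), and
take the SVD.  Percent variance uses all nonzero eigenvalues.

The two-PC genetic distance weights the first coordinate by the
eigenvalue ratio: `d_ij = sqrt((w ΔPC1)² + ΔPC2²)`, `w = λ₁/λ₂`.  The
published phrasing admits a second reading in which w multiplies the
*squared* term; both are implemented (`weight_on = "squared"`), the
coordinate reading is the default because it makes w a plain rescaling
of the PC1 axis.  Geographic distances are Haversine on a 6371 km
sphere.  Correlation tables report Pearson r, r² and the two-sided
t-transform p-value over samples (PCs vs latitude/longitude/altitude)
or over all sample pairs (genetic distance or kinship vs geographic
distance; n(n−1)/2 pairs, masks for within-West, within-East and
between-cluster partitioning the pair set exactly).  Pair p-values are
naive Pearson p — pairs sharing a sample are not independent, and no
correction is applied, matching the source analysis's reporting.

The East/West cluster labels come from 2-means on PC1 (50 seeded
restarts), justified because the two-way model-based admixture
clustering is captured by PC1; the cluster with the lower mean longitude
is "W".  Model-based admixture estimation itself is out of scope.

## AIM panel selection

Candidates are variants with zero missing genotypes, LD-pruned at a
strengthened r² of 0.13 (at whole-genome scale this yields ~100k
candidates; synthetic runs keep the two filters and let the count scale
with the simulated SNP total).  For each of two population settings
(ALG vs M, ALG vs C) a random-forest classifier on dosage fractions is
fitted `n_runs = 100` times with distinct seeds, recording impurity
importances.  Two split criteria (gini, entropy) × two ranking methods
give the four configurations: GI1/EN1 rank by how often a SNP enters a
run's top-96 importance list ("highest frequency among top features"),
GI2/EN2 by mean importance over runs ("highest significance in the
average" — read as mean importance, as no formal test is described).
The importance runs are shared between the two ranking methods of one
criterion: ranking is pure post-processing of the stored importance
matrices, so refitting would reproduce the same distribution at twice
the cost.

Gini forests and all probability classification use `ranger`.  No
released R random-forest implementation exposes an entropy split
criterion, so the entropy configurations use an in-package bagged
ensemble of `rpart` trees grown with `split = "information"` on
bootstrap resamples and sqrt(p)-sized random feature subspaces,
importance being the summed impurity improvement of primary splits —
the same impurity-decrease notion, under the entropy impurity.  Tree
count is pinned at 100 per forest (the common library default) and
recorded, since "default parameters" are otherwise unreproducible.

Each panel takes the top 48 per setting (48 + 48 = 96, one microplate).
When a SNP makes both top-48 lists the union falls short; the panel is
completed by advancing alternately down both rankings past rank 48 (M
first) until 96 unique SNPs — the completion rule is unspecified in the
original and alternate advancement keeps the two settings balanced.
Panels are validated on the held-out test split: PCA restricted to the
panel, plain Euclidean distances on the top two PCs, objectives = mean
within-ALG distance (minimise) and mean ALG-vs-European distance
(maximise).  The best panel maximises the between/within ratio — a
formalisation of what was originally a visual call on the two
objectives — with ties broken in configuration order GI1, GI2, EN1,
EN2.  An empirical null re-runs the classification for panels of 96
SNPs sampled uniformly from the candidates (1000 panels × 50 trainings
at full scale; the pipeline default is a reduced 50 × 5 null, with the
full null available by argument), recording mean accuracy, min P(ALG)
over ALG test samples and max P(ALG) over the rest.

## Hybrid simulation

Gametes are simulated with Poisson(ρL) crossovers per chromosome,
uniform breakpoints, Bernoulli(0.5) starting haplotype, no interference
and no mutation.  F1 hybrids pair one European and one ALG drone
haplotype directly (drones *are* gametes, so this is the natural
construction); BC(n+1) pairs a meiotic gamete of a BC(n) individual with
a fresh random ALG haplotype.  Forty matings per cross type per lineage
per split are drawn among all unique parent combinations, giving
4 × 2 × 40 = 320 hybrids per split and 640 total; per-site ancestry
labels ride along through every meiosis, so BC(n) European ancestry has
expectation 2^−(n+1) by construction and is verified by bookkeeping.  No
genotyping error is injected into hybrids.

Three experiments: (A) classifiers trained on originals only, applied to
test-split hybrids — P(ALG) rises monotonically from F1 through BC3 as
backcrossing erodes the European signal; (B) training augmented with the
train-split hybrids labelled non-ALG (mimicking known admixture in the
references) — accuracy and per-class misassignment over repeated runs;
(C) experiment B with all candidate SNPs instead of the panel, isolating
what the 96-SNP reduction costs or buys.

## Synthetic populations

The generator is Balding–Nichols: ancestral frequencies Uniform(0.05,
0.95); ALG, M and C drift from the ancestor at F = 0.12 each; two
Algerian sub-backgrounds (West/East) drift from ALG at F = 0.02; an ALG
sample at longitude x draws genotypes from the mixture
`a p_E + (1−a) p_W` with `a = logistic(s(x − mid))`.  No quantitative
Fst between the real populations is published, so the lineage F was
chosen once such that the four-cluster PCA geometry of the real data is
qualitatively reproduced (distinct ALG/M/C clusters, PC1 separating ALG
from Europe) while the within-ALG cline stays an order of magnitude
weaker — and is not revisited.  Altitude is drawn anti-correlated with
latitude at r = −0.6, emulating the sampling area (southern sites are
high-plateau).  Default sample sizes follow the study layout: 82 ALG +
50 M + 118 C training, 20/13/30 test.  Missingness and
heterozygote-artifact rates default to 0: the analysis-stage conditions
emulate post-QC data (and the AIM candidate filter requires
zero-missingness sites); both rates are exposed to stress the QC stage.
The genome is 16 chromosomes × 14 Mb.

Controlled-IBD pairs come in two modes.  Pedigree mode draws two meiosis
gametes of one simulated queen (expected sharing 50%, exact mask from
the gamete sources).  Tract mode copies exponentially distributed tracts
(mean 2 Mb — long enough that the HMM at the honey-bee ρ sees
multi-segment sharing; configurable) from one independent genome onto
another until exactly 2^−degree of the genome (in bp) is covered, the
last tract trimmed to hit the target exactly.

**What the synthetic data does not show.**  The generator has no
coalescent demography, no mutation model, no selection, independent
sites (no background LD beyond what drift induces), and uniform SNP
density.  Passing tests therefore demonstrate correctness of the
implementations and recoverability of planted structure under the
stated conditions — not performance on real sequencing data, where LD,
batch effects and uneven coverage can all be adversarial.

## Reproducibility and scale choices

Every stochastic function takes a seed; the pipeline derives per-stage
seeds from one master seed through a fixed counter scheme, and writes a
manifest of md5 checksums so that reruns are comparable byte for byte.
The shipped demonstrations use scaled-down sizes chosen to keep the
full suite in the minutes range while staying inside each method's
working regime: 20k sites / 40 pairs per degree for IBD recovery, ~6k
SNPs / 250 + 63 samples for panel selection, a 50-panel × 5-run reduced
null, and a small-cohort hybrid experiment; the full-scale settings
(100 ranking runs, 1000-panel null, 40-mating cohorts) remain the
defaults of the corresponding functions.
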