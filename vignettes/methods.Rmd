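---
title: "Methods: kin structure, null alleles and fine-scale differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kin structure, null alleles and fine-scale differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

High-dispersal marine animals with huge census populations are classically
expected to be panmictic below the dispersal range of an individual. Yet
blooms of holoplanktonic jellyfish — and recruit cohorts of many other
broadcast spawners — can carry *family structure*: full-sib and half-sib
aggregations, elevated inbreeding, and small-scale, temporally unstable
genetic differentiation ("chaotic genetic patchiness"), a signature of
large variance in individual reproductive success. Detecting this from
co-dominant microsatellite genotypes requires an analysis chain in which
every inference is guarded against the classic microsatellite artefact —
null alleles, which silently convert heterozygotes into apparent
homozygotes and mimic inbreeding.

patchkin implements that chain end to end, and ships a simulator with
known pedigrees so that every estimator can be validated against ground
truth rather than against another program's output.

## The data model

A `genotype_dataset` holds unordered pairs of positive-integer allele
labels (typically fragment sizes in base pairs) per individual and locus,
with population labels and blanks (complete amplification failures).
Half-called genotypes are rejected: a peak profile either yields a full
diploid call or nothing. GenePop (2- or 3-digit) and a long-form CSV are
the interchange formats; population and individual order are preserved on
round trip so that seeded permutation tests are bit-reproducible.

## Diversity and Hardy-Weinberg testing

Observed heterozygosity is the fraction of heterozygous non-blank
genotypes; expected heterozygosity uses the unbiased estimator
$\tilde H_e = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$. (Analysis suites differ
on whether the printed $H_e$ is plug-in or unbiased; we chose the
unbiased form and flag the choice here.)

The exact Hardy-Weinberg test conditions on allele counts: a genotype
table with heterozygote total $h$ and genotype counts $n_{gg}$ has
probability $n!\,2^h\prod_a m_a!\,/\,((2n)!\prod n_{gg}!)$, and the
p-value sums tables no more probable than the observed one (Fisher
criterion, ties included). Two engines are provided:

* `hwe_exact_enumeration()` — complete enumeration, exact; feasible for
  small allele totals and used as the oracle;
* `hwe_exact_mc()` — a Markov chain over the vector of $2n$ gametes in
  which two uniformly chosen allele copies are swapped per step. The
  uniform distribution over gamete arrangements induces exactly the
  conditional table distribution above, so no Metropolis correction is
  needed; the estimate converges to the enumeration p at the usual
  $\mathrm{steps}^{-1/2}$ Monte-Carlo rate. Defaults (1,000 steps after
  10,000 dememorization steps) mirror common practice and are
  configurable; the test suite uses longer chains for tighter oracle
  agreement.

Genotypic linkage disequilibrium is tested per locus pair and population
by permuting one locus's genotypes among individuals and scoring the
fixed-margin log-probability of the two-locus contingency table;
permutation p-values always use the add-one correction so they are never
exactly zero. Multiple testing is controlled by the Bonferroni threshold
$\alpha/k$. Per-locus "global" Hardy-Weinberg assessment across samples
uses Fisher's combination of the per-sample exact p-values — the
combination method is an assumption of this package and is reported
alongside the per-sample values.

## F-statistics

Both $F_{IS}$ ($f$) and $F_{ST}$ ($\theta$) come from the Weir-Cockerham
(1984) variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals), computed
per allele and locus and combined as ratios of sums — never means of
per-locus ratios, a classic implementation bug that a dedicated test
guards against. Significance uses randomization (alleles among
individuals within samples for $f$; individuals between samples for
pairwise $\theta$, the standard permutation unit), and confidence
intervals bootstrap loci (50,000 draws by default). Negative $\theta$
estimates are reported as computed. Loci with no within-sample variation
are flagged not-evaluated rather than forced into the sums.

## Null alleles: estimation and correction

Moment estimators (Chakraborty's $(H_e-H_o)/(H_e+H_o)$ and Brookfield's
$(H_e-H_o)/(1+H_e)$) are reported alongside an EM fit that treats the
null as an extra allele class: each observed homozygote $(i,i)$ is
distributed between true $(i,i)$ and $(i,\mathrm{null})$ in ratio
$p_i : 2p_{\mathrm{null}}$, blanks are attributed to
$(\mathrm{null},\mathrm{null})$ (an option excludes them, since missing
data are ambiguous in real datasets), and gamete counts are renormalized
until the non-decreasing log-likelihood converges. Loci are flagged when
a one-sided homozygote-excess exact test rejects at 0.05.

The "corrected dataset" re-labels the EM-expected excess of each
homozygote class as visible/null heterozygotes $(i, \mathrm{sentinel})$,
deterministically (integer apportionment largest-residual-first, ties by
allele order, applied in input order). A proprietary adjustment of this
kind exists in the classic detection software but its internals are not
fully published; the EM-expectation re-labelling reproduces its intent —
adjusting homozygote counts to the estimated "real" values — while being
exactly reproducible. The sentinel is a reserved out-of-range allele
label (0 being taken by missing data) that downstream likelihood and
F-statistic code recognizes.

The ENA-style corrected $\theta$ drops genotypes carrying the sentinel
per locus. Because the EM removes exactly the expected visible/null
excess from each homozygote class, the retained genotypes emulate a clean
Hardy-Weinberg sample at the conditional (visible-only, renormalized)
allele frequencies, and the corrected estimator reduces to the plain one
when all null estimates are zero.

A finding worth stating plainly: under this package's generative model —
Balding-Nichols differentiation with nulls inserted independently at
gamete level — the observed visible-allele frequencies are *unbiased* for
the conditional visible frequencies, and the normalized visible frequency
vector carries the same differentiation as the full vector. Nulls
therefore add almost no upward bias to the Weir-Cockerham $\theta$ in
these simulations (measured bias of order $10^{-4}$), so the corrected
and uncorrected estimators differ mostly by noise. The often-cited
inflation of uncorrected $F_{ST}$ by null alleles is not reproduced
directionally at high per-replicate frequency under this model; the
corrected estimator is retained for its robustness properties, not
because the raw one fails here. The acceptance suite asserts the
directional claim anyway and documents its outcome.

## Maximum-likelihood dyadic relatedness

A dyad's single-locus likelihood is the IBD mixture
$P(g_1,g_2\,|\,k) = k_0 P(g_1)P(g_2) + k_1 P(g_1)T_1(g_2|g_1) +
k_2 P(g_1)T_2(g_2|g_1)$ with the standard one- and two-gene transition
probabilities; the test suite verifies $T_1/T_2$ against brute-force
enumeration of parental genotypes and gamete transmissions, exactly.
Canonical relationships sit at fixed $k$ points (UR, HS, FS, PO), and
relatedness is $r = k_2 + k_1/2$. Loci multiply in the log domain;
classification is by maximum likelihood over the enabled categories
(default UR/HS/FS, matching single-cohort adult samples; PO available).
Ties go to the least-related category — a conservative rule that never
inflates kin counts. The ML $\hat k$ is found by grid refinement over the
simplex to below $10^{-3}$ (the likelihood is linear in $k$ per locus, so
the surface is smooth and unimodal along the simplex); the maximization
is unconstrained beyond the simplex, which we flag as a choice. Because
a single locus makes the ML of $k$ degenerate, $\hat r$ is reported only
when at least 5 informative loci are typed (configurable).

Null accommodation expands observed homozygotes over
$\{(i,i),(i,\mathrm{null})\}$ and blanks over
$\{(\mathrm{null},\mathrm{null})\}$, weighted by frequencies — so a
heterozygote deficit no longer masquerades as relatedness. Within-sample
dyads use their own sample's allele frequencies (the convention of the
classic pairwise-likelihood software); cross-sample dyads and the
permutation matrix use pooled frequencies. No per-dyad likelihood-ratio
test is applied: classification is by likelihood rank alone.

## Kin-aggregation permutation test

Mean pairwise $r$ is assembled for every sample pair (within-sample on
the diagonal). Significance comes from permuting population labels
globally — sample sizes preserved — and re-indexing the precomputed dyad
$r$ values; the one-tailed upper p asks whether mean relatedness could be
this high by chance. The quoted procedure in the field is "1000
permutations of individuals across populations", i.e. plain label
permutation, and that is what is implemented (no chain dependence).
Re-indexing keeps the dyad $r$ multiset fixed; a flag enables the
stricter mode that recomputes dyad likelihoods from permuted
per-population frequency pools, at a substantial cost. The with/without
null-accommodation comparison pairs the eight per-sample HS (and FS) dyad
frequencies and applies a classic paired two-tailed t-test — the paired
form is validated in the acceptance suite against published p-values that
a two-sample test does not reproduce.

## Sibship networks

Dyads classified HS or FS with confidence at least 0.95 (likelihood share
of the winning category; threshold configurable) become edges; extended
sibship networks are the connected components of the HS∪FS graph with at
least two members, singletons are reported as unrelated, and full-sib
families are the components of the FS-only subgraph, each nested in
exactly one network (reported in `k(m)` notation — `4(2)` meaning four
families of two). The reference reconstruction in the field is a joint
maximum-full-likelihood pedigree partition; a full re-implementation of
that simulated-annealing machinery is out of scope, and pairwise
classifications are known to track it closely except for a tendency to
find fewer half-sibs — reports carry that caveat. The likelihood-share
confidence proxy replaces that software's posterior probability; their
divergence is characterized only empirically on synthetic data.

## The simulator

`sim_config()` fixes: population sizes, locus panel, symmetric-Dirichlet
base frequencies, Balding-Nichols differentiation (chosen because it
yields an analytic $F_{ST}$ oracle: each allele frequency has mean $p$
and variance $F p(1-p)$), an inbreeding probability (an offspring's
second gamete is an identical-by-descent copy of the first, giving
expected observed heterozygosity $(1-F)H_e$), family plans (an FS family
is one parent pair with Mendelian offspring; an HS family shares the
"mother", a pure labelling convention with no sex-specific genetics),
per-locus null frequencies (inserted per gamete; visible/null appears
homozygous, null/null blank — expected blank fraction $r^2$), and an
optional uniform mis-scoring rate (default 0, matching the common 0.005
only when asked). One master seed drives fixed per-stage seed splitting,
so each stage is independently reproducible.

`generate_study_like_dataset()` is the one-call survey emulation: 8
samples of sizes 52, 43, 36, 24, 13, 53, 14, 24 (259 individuals), 9
loci with allele pools of 4-18, inbreeding $F = 0.25$, among-sample
$F = 0.02$, per-locus null frequencies up to 0.12, and family plans
planting HS blocks of 3-8 and FS pairs/triples in five samples — sizes
chosen once so that within-sample HS/FS dyad frequencies land in the
few-per-mille to few-percent range typical of bloom samples. What the
simulator does *not* emulate: mutation (no stepwise model), overlapping
generations, selection, spatial structure beyond the single
differentiation parameter, and locus-specific scoring pathologies
(stutter, large-allele dropout). Tests passing on these data therefore
validate the estimators' statistical machinery, not robustness to every
real-data artefact.

## Numerical choices and problem sizes

Permutation p-values use the add-one correction throughout. Exact-test
ties are included within a $10^{-9}$ log-probability tolerance. The EM
stops when the log-likelihood moves less than $10^{-10}$ (cap 2,000
iterations). The $\hat k$ grid starts at step 0.05 and refines three
times by a factor of 5. Degenerate inputs have defined outcomes:
monomorphic loci give HWE p = 1 and He = 0; blank-only cells are flagged
absent, not errors; samples of size 1 have no within-sample statistics.

The test-suite problem sizes are chosen as the smallest that leave the
Monte-Carlo error well inside each tolerance: recovery runs use n = 500
individuals (inbreeding, EM), 20 populations × 50 loci (differentiation),
and 1,000 dyads (relatedness); calibration uses 200 null replicates with
99 permutations each; oracle agreement suites enumerate all biallelic
tables to n = 6 and all 2-3 allele genotype pairs.

## Known limitations

* Half-sib detection from pairwise likelihoods is intrinsically weak at
  9-20 microsatellites (most true HS dyads classify UR under the
  conservative tie rule); networks built from them fragment more than
  joint-likelihood reconstructions, so network counts at the default
  0.95 confidence are conservative, and recovering a large planted
  half-sib chain needs a majority-support edge threshold (around 0.6)
  instead.
* In strongly inbred samples the classified HS/FS dyad frequencies run
  well above the planted ones: homozygote excess mimics relatedness.
  This is the false-kin confound the parallel corrected/uncorrected
  design is meant to expose, not an estimator defect; the permutation
  test of kin *aggregation* is unaffected because inbreeding inflates
  all samples' dyads alike while the test compares against the pooled
  permutation distribution.
* The EM null model assumes a single null lineage per locus and random
  mating within samples; inbreeding inflates its estimates (the same
  confounding the with/without-correction design is meant to expose).
* The permutation test's re-indexing mode keeps per-dyad $r$ fixed under
  relabelling, which is exact for pooled-frequency likelihoods but an
  approximation to recomputing per-population frequencies per
  permutation; the exact mode is available behind a flag.
* Allelic-richness rarefaction, hierarchical F-statistics beyond
  $F_{IS}$/$F_{ST}$, $R_{ST}$ and isolation-by-distance tests are out of
  scope.
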