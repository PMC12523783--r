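---
title: "Models and methods behind panmixsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panmixsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmixsel)
```

panmixsel is a forward-in-time simulator for recurrent genomic selection in
panmictic (random-mating) animal populations. This vignette is the package's
own account of the models it implements, the tunable parameters and their
defaults, the numerical choices, and what the bundled scaled-down experiments
can and cannot show.

## The simulated system

The default design emulates a broiler-chicken style breeding program
improving feed conversion ratio (FCR), a trait where *lower is better*:

* a genome of 10 chromosomes totalling 770 cM, carrying a 38,500-SNP panel
  and 1,000 QTL;
* two reference populations with the same expected allele frequencies but
  contrasting linkage disequilibrium (LD), each founded by crossing two
  parental populations;
* a trait with additive and (partially) recessive-favorable dominance
  effects, optional constrained digenic epistasis, and broad-sense
  heritability held at 0.30 in every generation;
* seven cycles of truncation selection of 400 dams and 80 sires (20% and 4%
  of candidates), five dams per sire, progeny size 10.

## Genome construction

Only the first and last chromosomes' lengths and locus counts are pinned
(199.4 and 25.7 cM; 10,000 and 1,250 SNPs; 260 and 30 QTL), together with
the totals (770 cM, 38,500, 1,000). Intermediate chromosomes are
interpolated with a power law
$v_i = v_{10} + (v_1 - v_{10})\left(\frac{10-i}{9}\right)^\gamma$, solving
$\gamma$ per quantity so the totals are exact. A linear interpolation of the
same endpoints would give a 1,125.5 cM map and 56,250 SNPs, inconsistent
with the design's average SNP spacing of 0.02 cM and gene spacing of
0.77 cM; the power law honours endpoints, totals and densities
simultaneously. Loci are placed uniformly at random per chromosome, with
SNP and QTL position sets kept disjoint.

## Engineered founder LD

Each reference population is created by crossing two parental populations in
linkage equilibrium and then performing one round of random mating, which
restores Hardy-Weinberg proportions while leaving gametic-phase
disequilibrium

$$\Delta_{ab} = \frac{1-2\theta_{ab}}{4}\,(p_{a1}-p_{a2})(p_{b1}-p_{b2}),$$

where $\theta$ is the recombination fraction and $p_{\cdot 1}, p_{\cdot 2}$
are allele frequencies in the two parental populations. Per-locus
frequencies are drawn from Beta$(\mu\nu, (1-\mu)\nu)$ with design means
$\mu$: the *low-LD* design uses equal means in both parents (SNP MAF
0.3/0.3, favorable allele 0.6/0.6), so frequency differences, and hence LD,
are centred at zero; the *high-LD* design uses divergent means (SNP MAF
0.1/0.5, favorable 0.3/0.9), so within-chromosome LD is systematically
positive. Both designs give the same expected generation-0 frequencies.

Two deliberate choices here:

* **Beta concentration** $\nu = 10$ (unstated in the design; a moderate
  spread with negligible mass at 0/1), configurable.
* **No MAF folding.** The beta draw is used directly as the allele-1
  frequency. Folding draws above 0.5 would bias the realized mean at a
  target of 0.5 (Beta(5,5) folds to a mean near 0.38) and, worse, random
  folding would scramble the sign of $(p_{a1}-p_{a2})$ across loci and
  destroy the engineered positive LD. "Mean MAF" is therefore interpreted
  as the mean of the targeted allele's frequency.

Every allele copy in generation 0 receives a unique founder-origin label
(two per individual), with identical-by-state copies distinguished, so
identity by descent can later be counted exactly: the *realized* inbreeding
coefficient of an individual is the fraction of loci at which its two labels
coincide.

## Meiosis and mating

Gametes are formed under the Haldane map function: crossover counts per
chromosome are Poisson(length/100) with uniform positions and no
interference. Allele states and founder labels travel together. Sex is
assigned Bernoulli(1/2) at birth (required for the 20%/4% selected-fraction
arithmetic), generations do not overlap, and there is no mutation.

Generation 1 is created by 1:1 random pairing of the founders (the founder
sexes are balanced, and the design is silent on this cross; the pairing is
configurable). In each selection cycle the selected dams are allocated five
per sire, re-shuffling and repairing by pairwise swaps until no mating
violates the avoidance rule. The default rule forbids **full-sib** matings
only: the design describes allocation as avoiding full-sib crosses, and the
stricter rule (also banning half sibs) pushes the no-selection inbreeding
trajectory *below* the level the reference design reports, so the weaker
reading is the better-supported one. Both rules (and no avoidance) are
available; if no conflict-free allocation is found within the attempt cap
the rule is relaxed stepwise with a warning.

## Trait model

With $n$ QTL and genotypic bounds for homozygotes $g_{\min} = 1.1$,
$g_{\max} = 2.9$ (ignoring epistasis), each QTL receives
$m = (g_{\max}+g_{\min})/2n$ and, by default, equal half-ranges
$a = (g_{\max}-g_{\min})/2n$, so $\sum (m+a) = g_{\max}$ and
$\sum (m-a) = g_{\min}$ exactly (a geometric-series allocation is available;
the equal default keeps the bound sums exact and the architecture
interpretable). Dominance is positive toward the unfavorable (high-FCR)
allele — the favorable allele is partially recessive — with per-QTL degree
of dominance $d/a$ drawn uniformly on $[0, 1.2]$ (mean 0.6). Genotypic
values for favorable-allele dosage 2, 1, 0 are $m-a$, $m+d$, $m+a$.

### Constrained digenic epistasis

A chosen fraction of QTL (50% in the epistatic scenarios) interact in
disjoint pairs. Each pair is assigned one of seven classical two-locus
patterns, named by their F2 phenotypic ratios: complementary (9:7),
duplicate (15:1), dominant (12:3:1), recessive (9:3:4), dominant-and-
recessive (13:3), duplicate-with-cumulative-effects (9:6:1), and a
four-class "non-epistatic gene interaction" in which all four dominance
classes differ. (The printed ratio for the last type, 9:3:3:4, does not sum
to 16 and is treated as the four-distinct-class pattern.) Under an
`all_random` policy each pair draws its type uniformly; with a fixed seed
the pairing is identical across type policies, so single-type scenarios are
paired comparisons.

For a pair, the two-locus genotypic value is
$G_{xy} = m_i + m_j + \alpha_x + \alpha_y + I_{xy}$ with $\alpha$ the
single-locus contribution and $I$ the epistatic effect. The anchor effect
$I_{22}$ is drawn from $N\!\big(0,\,k(\sigma^2_A + \sigma^2_D +
2\sigma_{A,D})\big)$, where the variances are the single-locus additive and
dominance variances of the two genes at their realized generation-0
frequencies and $k = 1.5$ by default. The normal family is assumed from the
design's variance notation; $\sigma_{A,D}$ is identically zero here because
generation 0 is in Hardy-Weinberg proportions, where additive and dominance
deviations are orthogonal (the term is retained in the interface and
becomes relevant only under inbreeding). The remaining eight effects are
solved from the type's class constraints: $G$ must be constant within each
phenotypic class; the class containing the double dominant homozygote takes
the value $m_i+m_j+a_i+a_j+I_{22}$, and every other class is anchored by
zeroing the epistatic effect of its reference genotype (the member with the
lowest dosage code), i.e. it keeps its non-epistatic value. This minimal-
perturbation anchoring is a modelling choice; the resulting table has
exactly as many distinct values as the ratio has classes. Epistatic tables
are solved once at generation 0 and fixed thereafter — effects are
properties of genotypes, not of frequencies.

The package verifies its two-locus machinery against Kempthorne's
orthogonal partition: with HWE weights and linkage equilibrium, the
contrasts $\alpha(x) = x - 2p$ and $\delta(x) = (-2p^2, 2pq, -2q^2)$ and
their products decompose any 3x3 genotype table into additive, dominance,
AxA, AxD, DxA and DxD components whose variances sum exactly to the total;
the test suite checks this against an independent weighted-regression
oracle to $10^{-10}$.

### Phenotypes

Phenotypes add a normal error calibrated to the *realized* genotypic
variance of the cohort, $\sigma^2_e = \sigma^2_G (1-H^2)/H^2$ with
$H^2 = 0.30$, so broad-sense heritability is constant across generations
even as selection erodes $\sigma^2_G$. Phenotypes are clipped into
$[y_{\min}, y_{\max}] = [1.0, 3.5]$ to avoid outliers; under the default
designs truncation touches well under 1% of records (a warning is raised
otherwise). If a cohort's genotypic variance is zero the last nonzero
generation's error SD is reused, with a warning.

## Evaluation and selection

The mixed model is $y = X\beta + \sum_k u_k + \varepsilon$ with independent
kernel effects $u_k \sim N(0, \sigma^2_k K_k)$. Kernels: VanRaden's
method-1 additive matrix $G = WW'/\sum 2p_j(1-p_j)$ ($W$ = dosages minus
$2p_j$), Su's dominance matrix from centred heterozygosity codes, and —
for the epistatic model — Hadamard products $G\#G$, $G\#D$ (housing
AxD + DxA) and $D\#D$, each rescaled to mean diagonal 1 so components are
comparable. Reference frequencies are computed from the currently genotyped
set (training plus candidates) at each evaluation; a flag switches to
generation-0 frequencies. Pedigree BLUP uses the numerator relationship
matrix A from the tabular recursion, with inbreeding by the Meuwissen-Luo
algorithm.

Variance components are estimated by average-information REML with an EM
fallback, a small diagonal ridge ($10^{-6}$) on each kernel, variance
floors at $10^{-8}\,\mathrm{var}(y)$, and convergence when the largest
component change is below $10^{-6}$ relative to the larger of the component
and 0.1% of the phenotypic variance (components smaller than that scale are
scientifically negligible and would otherwise stall the relative-change
criterion). AI steps are halved until no component crosses its floor;
components pinned at the floor with negative gradients for two consecutive
iterations are frozen (boundary estimates). BLUPs for all units, phenotyped
or not, come from $\hat u_k = \hat\sigma^2_k K_k[\cdot, t]\,P y$ — the
joint mixed-model solution, verified in the tests against Henderson's MME
on small instances to $10^{-8}$.

Selection is truncation within sex on the additive (G-kernel) BLUP, lowest
first; ties break on id for reproducibility. The eight schemes differ only
in criterion and training policy: GS (founders + a random 20% of each
generation, cumulative "historical" training), GS1 (founders only, no
updating), GS2 (10% per generation), GS3 (half the parents, double progeny
size: higher intensity at equal candidate numbers), GV (true genotypic
value; the upper reference, since additive values are not separately
reported under selection in the reference design), pbB (pedigree BLUP, all
candidates phenotyped), pbB1 (pedigree BLUP, 20% phenotyped, the rest
predicted through A), and NS (random parents; the drift control). Within a
replicate all schemes share the same genome, founders and architecture.
Whether training members of the current generation are also selection
candidates is not specified in the design; they are retained as candidates
here (they are part of the generation).

## Reported metrics

Per generation and scheme: genotypic mean and variance (from true genotypic
values, independent of the evaluation model), prediction accuracy (Pearson
correlation between candidate BLUPs and true genotypic values — computed on
candidates because selection acts on them), genetic gain (first differences
of genotypic means; totals telescope), mean pedigree F, mean genomic F
($G_{ii}-1$, using the generation's own reference frequencies, so its mean
is near zero by construction — its *spread* is the signal), mean realized F
(label counting; reported for the whole cohort, with the parent subset
available through the selected-id log), the number of distinct full-sib
families among selected parents (the design's "number of progenies with
selected individuals"), and favorable-allele frequency summaries (min,
mean, max, counts fixed and lost).

## Scale presets and what the scaled-down runs show

`preset("full")` is the reference design. `preset("desk")` is the bundled
desktop replication used by the acceptance experiments: it keeps the full
10-chromosome map and **all 1,000 QTL** — per-QTL effects $a = 0.9/1000$
and the QTL linkage map determine both the genetic variance and its LD
inflation, which the replication quantities measure — and thins only the
SNP panel (to 7,700, one in five per chromosome — sparse enough to be fast,
dense enough that genomic prediction still resolves within-family
differences; sparser panels visibly push selection toward whole families
and inflate inbreeding) and the population (200
founders per sex; 200 dams / 40 sires selected; about 16,400 individuals
per replicate). All dimensionless quantities are preserved: 20%/4% selected
fractions, the 5:1 mating ratio, progeny size, $H^2$, $k$, dominance-degree
distribution, trait bounds and founder frequency designs. Five replicates
are the default. At this size a GS replicate runs in seconds on one core.

The desk scale reproduces the reference design's headline quantities well
(total gains by LD level, no-selection variance erosion, accuracies), but
two caveats follow from its halved effective population size (about 133
versus 267):

* the low-LD population is in *exact* linkage equilibrium here (equal
  parental means share one frequency draw per locus), so it has no LD to
  lose: without selection its genotypic variance changes only through
  drift. Empirically the cohort variance even rises slightly over the
  cycles (about one percent per generation at desk scale, present for a
  purely additive trait as well; controlled small-genome experiments with
  the same machinery reproduce the textbook (1-F) decline, so this is a
  dense-linkage/bottleneck cohort effect, not a transmission artifact). A
  reported *decrease* in low-LD genotypic variance under no selection
  therefore cannot be reproduced by this design; it would require the
  reference population to carry net positive LD;
* selection-driven pedigree inbreeding is inflated relative to full scale:
  the desk design selects half as many families at the same co-selection
  proportion, roughly doubling the family-driven inbreeding rate, so
  desk-scale final-generation F under genomic selection (about 0.12 in the
  low-LD design) sits above what the full design reports (about 0.07) even
  though the mechanism and the selected-family proportions match.

More generally, the simulated data are idealized: biallelic loci, no
mutation, no genotyping error, no genotype-by-environment interaction, no
maternal or litter effects, sex ratio exactly 1/2 in expectation, discrete
generations. Passing tests on synthetic data demonstrate internal
consistency with the stated models, not performance on any real livestock
population.

## Numerical choices collected

* Kernel ridge $10^{-6}$; REML floors $10^{-8}\mathrm{var}(y)$; AI step
  halving; boundary freezing; 50-iteration cap with warm starts across
  cycles.
* Ties in truncation selection break on id; mate-allocation repair caps at
  200 reshuffles per rule before relaxing.
* SNP/QTL position ties (probability ~0) are resampled; exact degenerate
  inputs (zero-length chromosomes, fixed loci, zero-variance cohorts) are
  handled explicitly and tested.
* Per-stage seeds are derived from one master seed by a counter scheme, so
  schemes are paired within replicates and adding replicates never perturbs
  earlier ones.

## Session info

```{r}
sessionInfo()
```
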