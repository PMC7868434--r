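---
title: "Methods: bin-map QTL analysis of the multi-element ionome in RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-map QTL analysis of the multi-element ionome in RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionqtl)
```

## The problem

Element concentrations in plant tissues — the ionome — are heritable,
polygenic, and strongly inter-correlated: chemical analogues such as Ca and
Sr move through shared transport systems, and nutrient status couples P, K
and Mg. Mapping quantitative trait loci (QTLs) element by element ignores
this covariance and misses loci whose main effect is on the *joint*
distribution of elements. `ionqtl` implements a complete analysis chain for
a recombinant inbred line (RIL) population genotyped by low-coverage
whole-genome resequencing and phenotyped for a 16-element ionome in several
environments and tissues:

1. SNP filtering and sliding-window genotype calling per RIL (`bingeno`),
2. population-level recombination **bin map** construction,
3. genetic map estimation with the selfing-RIL correction (`linkmap`),
4. Haley–Knott interval mapping with permutation thresholds (`scan`),
5. PCA composite traits within and across environments (`pctraits`),
6. co-localization of elemental, PC- and aPC-QTLs into clusters (`colocal`),
7. a seeded synthetic-data generator with a known truth set (`ionsim`) and a
   one-call pipeline (`run_pipeline`).

## Genotyping model

**Window calling.** At ~2× mean depth a RIL observes each SNP site with
probability $1 - e^{-2} \approx 0.86$, almost always by a single read, so
individual calls are unreliable and sparse. Windows therefore slide over a
RIL's *observed* calls (not genomic sites): each window of $W = 15$ observed
SNPs (step 1) is labelled by a strict majority rule — TQ-type if more than
$T = 11$ calls are TQ, LM-type if more than 11 are LM. A window with at
least 4 calls from *each* parent is labelled heterozygous; anything else is
missing. The two-sided HET rule is a conservative design choice: a
parent-specific rule alone would label sparse, noisy windows as parental.

**Blocks and breakpoints.** Runs of identical window labels become genotype
blocks; the breakpoint between discordant blocks is the midpoint between
the flanking window anchors (each window is anchored at its median observed
SNP). Two post-processing rules matter:

- A missing run between agreeing parental flanks is absorbed.
- A HET run of at most $W$ windows between *opposite* parental flanks is
  interpreted as the sliding window crossing a single crossover — the
  intermediate compositions $(c_{TQ}, c_{LM})$ between $(15, 0)$ and
  $(0, 15)$ necessarily pass through the HET zone — and is split at its
  midpoint. Without this rule every crossover would be flanked by a
  spurious ~8-window HET band, which both inflates heterozygosity and,
  because HET calls are uninformative for linkage, collapses the genetic
  map. Genuine residual heterozygosity at F$_{20}$ (expected fraction
  $(1/2)^{19} \approx 2\times10^{-6}$ per locus) survives as *long* HET
  runs, which are kept.

**Bins.** Population bin boundaries are the union of all per-RIL
breakpoints; bins shorter than 20 kb are merged into the neighbour with
fewer population-level genotype conflicts (ties merge left). Chromosome 4
is exempt by default, mirroring practice in marker-poor chromosomes. The
partition property — bins tile the SNP-covered span, disjoint and ordered —
is enforced and tested.

**SNP filters.** Retained sites must be homozygous-divergent between the
parents, have parental depth ≥ 10×, lie more than 5 bp from any other SNP
or indel, and meet a 4× depth rule. At 2× mean coverage a *per-RIL* 4× rule
would discard everything; the rule is applied at the population level
(summed RIL depth), which we read as the discovery-level intent of such a
filter.

## Genetic map

For adjacent bins the observed recombinant fraction $R$ is the fraction of
discordant parental calls among informative RILs (HET and missing are
uninformative; with HET at 0.3% this loses essentially nothing). In a
selfing RIL panel recombinants accumulate over generations:
$R = 2r/(1+2r)$, inverted as $r = R / (2(1-R))$, with $r$ the per-meiosis
recombination fraction. Distances use Kosambi by default
($d = 25\ln\frac{1+2r}{1-2r}$), with Haldane ($d = -50\ln(1-2r)$)
selectable; Kosambi is the convention in rice linkage mapping. Marker order
is fixed to physical order — the bin map is built on a reference-anchored
coordinate system and collinearity is a tested invariant — so no de novo
ordering is attempted. Map gaps with no informative pair are bridged by
estimating against the last informative bin.

## QTL scanning

Genotype probabilities $P(\text{TQ})$ are computed on a 1-cM grid (plus all
marker positions) by forward–backward smoothing of a two-state Markov chain
whose step transition probability is the RIL-level recombinant fraction
implied by the map distance. Fully observed markers pin the state; missing
and HET markers are uninformative. A floor of $10^{-9}$ on the step
probability keeps the chain irreducible across zero-length intervals, and
conflicting evidence at a coincident position (possible after gap bridging)
is treated as uninformative rather than impossible.

The primary engine is Haley–Knott regression: the trait is regressed on
$E[x] = 2P(\text{TQ}) - 1$ at every grid point and
$\mathrm{LOD} = \frac{n}{2}\log_{10}(RSS_0 / RSS_1)$. HK is deterministic
and testable against a closed-form single-marker oracle, which the test
suite enforces to $10^{-8}$ at every marker. A multiple-imputation scan
(genotype realizations drawn by forward-filter backward-sampling, combined
by the log-mean-likelihood rule) is provided as a cross-check; under full
observation it reproduces HK exactly, and on sparse panels the two agree to
within 0.5 LOD.

Significance uses per-trait permutation thresholds: the trait is permuted
across RILs with genotypes fixed, the genome-wide maximum LOD recorded, and
the empirical $(1-\alpha)$ quantile (type-7) taken, following the
1,000-permutation, $\alpha = 0.05$ convention; no cross-trait multiplicity
correction is applied, matching the per-trait design. Peaks are local
maxima above threshold; maxima closer than 10 cM merge keeping the higher —
we read the scan's "10-cM window" setting as a minimum peak separation,
the only interpretation consistent with a single-QTL scan, and expose it as
a parameter. Support intervals use the conventional 1.5-LOD drop for RIL
panels; PVE uses the identity
$\mathrm{PVE} = 1 - 10^{-2\,\mathrm{LOD}/n}$; the additive effect is the
fitted slope at the peak, signed so that positive means the TQ allele
raises the trait.

LS-mean traits across environment groups are adjusted means from the
additive two-way fixed-effects model (RIL + environment, environments
sum-coded), which reduces to per-RIL means for balanced data.

## PCA composite traits

Within one environment/tissue, elements are z-scored and the correlation
matrix eigendecomposed (`prcomp`, centre and scale), yielding 16 PCs whose
scores become scan traits. Across an environment set (e.g. all flooded
years F; unflooded U; FUGG; grains+roots+shoots GRS) the per-environment
tables are *stacked in long format* — one row per RIL × environment, 16
columns — z-scored over the stacked rows, and decomposed the same way. The
stacking reading is the only one consistent with obtaining exactly 16 aPCs
and per-environment aPC trait vectors (`<set>_<env>_aPC<k>`); it is a
documented interpretation, not an attested implementation detail of any
prior analysis. Eigenvector signs are arbitrary, so each PC is oriented to
make its largest-|loading| element positive; this makes score traits
reproducible across runs and platforms. Rows with missing elements are
dropped listwise per PCA scope with a reported count.

## Co-localization and clusters

All significant peaks become unified records of class elemental, PC or aPC.
Two records co-localize iff their 1.5-LOD support intervals intersect as
*closed* intervals in cM on the same linkage group — the scan's native
coordinate; physical kb intervals are reporting-only. Repeated elemental
QTLs (same element, overlapping intervals, transitively) merge into unique
QTLs keeping the best-LOD representative and full environment provenance.
QTL clusters are connected components of the co-localization graph that
contain all three classes; on a line, components of an interval-overlap
graph are computed by a sort-and-sweep. For every (PC-or-aPC, elemental)
co-localized pair we test whether the elemental QTL's element appears in
the composite record's top-5 |loading| list (ties broken by the fixed
element order).

## The synthetic generator

`ionsim` defines the study conditions used throughout validation:

- **Parents** are opposite homozygotes at every SNP site — the post-filter
  SNP set is parent-divergent by construction.
- **RILs** descend by strict single-seed selfing from the F$_1$ for
  `generation − 1` = 19 rounds of meiosis; crossovers per meiosis per
  chromosome are Poisson with mean equal to the map length in Morgans, with
  no interference (the Haldane model, consistent with the map functions).
  No residual-heterozygosity masking or selection is modelled.
- **Sequencing**: per-RIL per-site depth is Poisson with mean 2 (default);
  zero depth is missing; observed calls flip with probability 0.5%
  (default) — the error rate of low-coverage calling is not attested
  anywhere we could anchor it, so it is an exposed parameter.
- **Phenotypes**: $y = \sum_q a_{qj} x_q + \mu_{ej} + \epsilon$ with
  $x_q \in \{-1, +1\}$, effects in residual-SD units so a lone QTL's
  theoretical PVE is $a^2/(a^2+1)$, environment shifts
  $\mu_{ej} \sim N(0, 0.5^2)$, and residuals multivariate normal with a
  configurable correlation matrix (unit variances). Planted pleiotropy plus
  residual correlation reproduces the qualitative Ca–Sr-type structure of
  real ionome data.

What the generator does *not* emulate: read-level errors and alignment
artefacts, segregation distortion, epistasis, genotype-by-environment
interaction beyond per-environment QTL activity lists, non-normal trait
distributions, and shared soil/batch effects. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every pathology of field data.

## Validation problem sizes and numerical choices

The test suite validates, among others: exhaustive window-rule enumeration
(all compositions with $c_{TQ}+c_{LM} \le 15$); bin-map recovery on 100
RILs × 5,000 SNPs (full-coverage error-free and 2×/0.5%-error regimes) —
every *resolvable* crossover (flanking segments spanning two full windows,
away from span edges) is recovered within 15 observed SNPs and (RIL, bin)
accuracy exceeds 99.9% / 99%; locus-level F$_{20}$ heterozygosity against
$(1/2)^{19}$ over $10^6$ draws; 150-cM map recovery within 10% at $n=250$;
HK-vs-oracle equality on 50 random instances; threshold calibration on 200
null traits at 300 permutations each; detection power for a 15%-PVE QTL
over 100 replicates ($n = 250$, 100 permutations per trait); and the
multivariate gain of PC traits for a 3-element pleiotropic locus at 5%
per-element PVE over 50 replicates. Permutation counts in these studies are
scaled to 100–300 per trait — calibration is tested explicitly, and the
quantile estimator, not its Monte-Carlo resolution, is what the studies
exercise; production runs default to 1,000.

Localization error and interval coverage are scored in the *estimated*
map's coordinates (the true locus mapped through the marker grid), since an
estimated map's small global expansion would otherwise masquerade as
localization error.

## Known limitations

- Marker order is taken from physical coordinates; misassemblies would
  propagate.
- Single-QTL scans only: no composite interval mapping, multi-QTL models or
  epistasis.
- HET genotypes are uninformative in mapping rather than modelled as a
  third state — harmless at F$_{20}$ heterozygosity levels, inappropriate
  for early-generation populations.
- Support-interval overlap is a deliberately liberal co-localization rule;
  with very dense QTL landscapes clusters can chain.
- The imputation scan shares the HK model's additive assumption; neither
  models dominance (absent in RILs by design).
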