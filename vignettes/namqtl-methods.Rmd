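---
title: "Methods: simulating and mapping a backcross NAM panel"
author: "namqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping a backcross NAM panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namqtl)
```

This vignette records the models the package implements, the defaults it
ships, and the design decisions taken where the methodology left choices
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The population simulator

The simulator exists so every analysis stage can be exercised against
planted truth. It reproduces the *structure* of a backcross NAM panel,
not any particular real dataset.

**Meiosis.** Crossovers form a Poisson process along the genetic (cM)
map with no interference (Haldane model). The recombination fraction
between loci $d$ cM apart is therefore $\tfrac12(1-e^{-2d/100})$ in
expectation, which gives closed-form oracles for the tests (e.g. 0.316
at 50 cM). Interference models (Kosambi) would change multi-locus
patterns slightly but have no closed form as convenient; the Haldane
choice is deliberate and documented rather than tunable.

**Maps.** `makeGeneticMap()` spaces markers uniformly in bp and
interpolates cM linearly by default. A per-chromosome monotone profile
(`cmProfile`) can emulate pericentromeric recombination suppression,
which is what produces the very wide QTL peaks seen near centromeres in
real wheat data; the default is linear because none of the package's
numerical checks depend on suppression.

**Crossing scheme.** Each nested population is built as
F1 = recurrent × donor, BC1F1 = F1 pollen onto the recurrent parent,
then eight BC1F2 per each of twelve BC1F1 "streams" (96 initial
genotypes) advanced by single-seed descent to BC1F5 (four selfing
generations). These defaults are the study conditions of the motivating
panel design. Two consequences serve as acceptance oracles: the mean
recurrent-parent genome fraction is 75% and the residual heterozygous
fraction at donor-polymorphic loci is $0.5 \times (1/2)^4 = 3.125\%$.
Attrition from 96 to the target size (default 60, the panel-wide
average; 3241 genotypes over 54 crosses) is uniform random dropout —
no loss mechanism beyond the final average is specified anywhere, so
the simplest one is used.

**Founders.** Donors are fully homozygous; their A/B sub-genome
haplotypes are drawn from a pool of 15 tetraploid parents and D
haplotypes from 47 diploid parents, so donors sharing a parent share
that sub-genome. The per-marker probability that a donor carries the
non-reference allele defaults to 0.6, a deliberately high
polymorphism rate reflecting that array content is pre-selected to
segregate; tests that need denser LD information raise it to 0.8.

**Phenotypes.** A half-plot unit value is
$\mu + \sum_q \beta_q x_q + u_g + b + r + c + d + t + e$ — planted QTL
effects times dosage, a polygenic genotype value, and block, row,
column, scorer, lid and residual draws from configured variances.
Checks carry fixed true values so they inform only the spatial terms.
Planted QTL effects are sized from a variance share relative to
polygenic-plus-residual variance; spatial variance is deliberately
excluded from that denominator so the share describes the genetic
signal, which means realized shares in BLUEs are somewhat smaller when
spatial noise survives adjustment — visible in the pipeline-scale
tests.

**What the simulator does not emulate.** Real marker ascertainment
(cluster-calling artifacts, null alleles), segregation distortion,
selection during inbreeding, spatially correlated field trends beyond
the block/row/column structure, and genotype-by-environment
interaction. Passing tests therefore validate the machinery, not the
behavior of any specific field dataset.

## Genotype QC

The cascade order is fixed: marker filter → genotype filter → duplicate
detection → non-parental check → imputation, with every stage
individually callable and a `QcReport` reconciling counts.

* Marker filter: removed if heterozygote fraction > 0.10 (among
  non-missing calls), missing fraction > 0.10 (among all genotypes), or
  minor-allele homozygotes < 15. The heterozygosity denominator is
  non-missing calls so the two filters stay independent; a count of
  exactly 15 passes.
* Genotype filter: heterozygous fraction > 0.10; missingness alone
  never removes a genotype.
* Duplicates: the "too similar" judgement is codified as a dual rule —
  absolute r ≥ 0.99, or above mean + 6 sd of the within-population pair
  distribution. Both are configurable; the member with more missing
  data is dropped (ties: lexicographically later id).
* Non-parental check: at markers where both parents of a population
  share a homozygous dosage, offspring disagreement above 5% flags a
  genotype. The 5% default tolerates genotyping error while catching
  cross-contamination; it is configurable because the appropriate value
  scales inversely with the number of parent-monomorphic markers.
* Imputation: iterative random-forest classification (200 trees),
  markers swept in order of increasing missingness, stopping when the
  count of changed calls rises between sweeps. Forests are grown on the
  50 markers most correlated with each target (computed once on the
  mode-initialised matrix), which exploits the strong local LD of
  inbred panels and keeps sweeps linear in marker count. Classification
  guarantees outputs in {0, 1, 2}; observed cells are never altered;
  the mean out-of-bag error is reported.

## Marker positioning

Alignment-based placement takes the best hit per marker (bitscore, then
e-value, then alignment length, then chromosome name) and uses the
orientation-independent midpoint `floor((start+stop)/2)`. Correlation
transfer places an unmapped marker only if its best-R² mapped partner
(floor 0.2) has a same-chromosome hit to adopt — there is deliberately
no fallback to other chromosomes. LD-bin repositioning builds bins as
connected components of the R² > 0.5 graph (components are
order-independent and reproducible, which is why they stand in for the
unspecified "bin" construction), computes each marker's guide as the
strict modal chromosome of the *other* bin members (plurality mode
available), falls back to the single highest-LD partner when no strict
mode exists, and runs exactly two passes. Markers monomorphic in the
analysed genotypes carry no LD information and cannot be repaired —
which is consistent with the pipeline order, since the marker filter
removes them before repositioning. Within-chromosome position errors
(right chromosome, wrong bp) are outside the algorithm's mandate.
`adjacentLdSummary()` quantifies map improvement as mean adjacent-marker
R² per chromosome.

## Population structure

Marker skimming is a greedy scan in map order (chromosome, bp) that
keeps the first-seen member of any pair with |r| at or above the
threshold — deterministic given the map. PCoA is classical metric
scaling (via `ape`) on Euclidean dosage distance by default, with a
simple-matching alternative; percent variance uses the positive
eigenvalues as denominator. The D-sub-genome-only view is a chromosome
filter before analysis; lineage labels are user metadata, never
inferred.

## Trial mixed models

`fitBlues()` fits the half-plot model with genotype fixed and block,
row-in-block, column-in-block, scorer (only when more than one scorer
is recorded) and drilling-lid random, then prunes random terms by
backward elimination using REML likelihood-ratio tests at α = 0.10 (the
common default of stepwise mixed-model tools). The LRT uses a 1-df
chi-square, which is conservative at the variance boundary; with α as
loose as 0.10 the practical effect is small. BLUEs are intercept plus
treatment-coded genotype coefficients, reported on the response scale
with the recurrent parent as reference when present. Half-plots are
independent units — no plot random term by default (available as an
option). H² = V_g/(V_g+V_e) comes from refitting the eliminated model
with genotype random. Group contrasts use Welch's t-test.

## Association scanning

The Q+K model treats the nested-population factor as fixed dummies and
the kinship as a centred cross-product relationship matrix
$K = ZZ^\top/m$ on a marker set skimmed at |r| ≤ 0.8 (high-LD blocks
otherwise dominate K). Variance components are estimated once on the
null model by REML on the eigenbasis of K and reused for every marker
(P3D/EMMAX); each marker is then a GLS F-test with residual degrees of
freedom. The F-form (rather than a Wald chi-square) makes the scan
reduce *exactly* to per-marker OLS when K is the identity and there is
one population — the equivalence the tests assert to 0.01 on the
−log₁₀ scale. Markers whose dosage is constant within every population
are confounded with Q and reported `NA`. Thresholds divide α = 0.05 by
the effective marker number, estimated per chromosome from the
eigenvalues of the marker correlation matrix (each eigenvalue
contributes its fractional part, plus one if ≥ 1) and summed; the
estimator choice is recorded in the scan metadata so alternatives
(e.g. permutation) can be swapped in. The genomic inflation factor is
the median association chi-square over 0.4549.

Known behavior worth stating: because K is built from all chromosomes
(no leave-one-chromosome-out), a tested marker's own region contributes
to K and some signal is absorbed — scans lose a little power relative
to an oracle OLS with known structure. This matches the configuration
of the tooling the analysis mirrors.

## QTL calling

The LD-decay window fits a monotone non-increasing curve (isotonic
regression) to 1-Mb-binned mean R² pooled over chromosomes and returns
the first distance at or below R² = 0.2, rounded up to a whole Mb.
Isotonic fitting was chosen over a parametric decay because it cannot
be pushed below the critical value by lack of fit in the tail. Peaks
are called greedily (highest score, suppress ± window, repeat; ties to
the smaller bp), intervals extend through consecutive significant
markers confined to the suppression window (preventing run-away
intervals on dense significant stretches), and cross-trial merging
requires same trait, chromosome and effect sign within 3× the window —
single-linkage along the chromosome. The 3× multiplier accommodates
the documented cross-trial peak shifts of tens of Mb that a 1× window
would split; it is configurable and every merge is logged. Names follow
`Q{trait}.{lab}-{chrom}.{index}` ordered by chromosome then position.
Multi-QTL variance uses the whitened joint model and reports each
peak's drop-one partial R² in percent; collinear peaks are pooled with
a warning.

## Selection summaries

Background summaries are deliberately descriptive (counts and percent
selected per tetraploid donor and diploid lineage) because donor
representation across trials is unbalanced by construction; the only
inference offered is the explicitly defined Welch t-test between
homozygous allele classes. "Carrying" a donor allele defaults to
homozygous dosage 2, with a dominant (dosage ≥ 1) switch, since zygosity
conventions differ between studies.

## Numerical and reproducibility choices

* All stochastic functions take explicit seeds; the pipeline derives
  every stage's randomness from one master seed and stamps each
  artifact with the seed and a hash of the resolved configuration
  (output paths excluded, so identical settings hash identically).
* Coordinates are externally 1-based inclusive throughout.
* Dosages are integers 0/1/2 with `NA` missing ("NA" in CSV, `./.` in
  VCF); scans require a complete (imputed) matrix, mirroring the
  pipeline order.
* REML optimisation profiles the variance ratio on a log grid over
  [e^-10, e^10]; kinship eigenvalues are floored at zero.
* Degenerate inputs fail loudly: all-missing markers, monomorphic
  enrichment loci, non-decaying LD (with advice to raise the critical
  value), and fewer than two group members in t-tests are errors, not
  silent results.

## Problem sizes used in the checks

The test suite and acceptance script run at desk scale, chosen so each
statistical check has adequate power while the whole suite stays quick:
genome-scale pedigree checks use 21 chromosomes × 100 markers and 288
BC1F5 genotypes; association calibration and power use 800 genotypes ×
~1050 markers with 50 phenotype replicates; mixed-model recovery uses
50 replicate trials of 60 genotypes × 2 replicates and a single
500 × 2 heritability trial; the orchestrated pipeline demonstration
uses 6 populations × 60 genotypes over 10 chromosomes. Scaling any of
these up is a configuration change, not a code change.

## Known limitations

* The simulator's LD structure comes purely from the pedigree; it does
  not reproduce ancestral haplotype sharing among donors beyond shared
  sub-genome parents.
* P3D variance components are held fixed across markers; very large
  single-QTL effects can therefore slightly misestimate their own
  standard errors (the standard trade-off of the approximation).
* Backward elimination tests one term at a time with a 1-df LRT;
  correlated random terms can mask each other in small designs.
* The duplicate-detection distribution rule assumes enough
  within-population pairs to estimate a mean and sd; tiny panels fall
  back to the absolute rule alone.
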