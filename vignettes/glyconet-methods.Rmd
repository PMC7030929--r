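---
title: "Models and methods behind glyconet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glyconet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconet)
```

`glyconet` analyzes the genetics of the IgG N-glycome from summary
statistics alone: per-cohort association tables are pooled, mapped to loci,
summarized as glycome-wide effect vectors, assembled into a correlation
network with a permutation reference, and interrogated for pleiotropy with
gene expression and complex traits. This vignette explains each model, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical and design choices that a user or reviewer would want to
know about.

## Meta-analysis of per-cohort summary statistics

Glycan traits are assumed rank-transformed to a standard normal within each
cohort, so effects are in standardized-trait units per effect-allele copy
and the large-sample standard error of a marginal effect is
$1/\sqrt{2pqN}$. Cohorts are pooled per SNP and trait by fixed-effect
inverse-variance weighting,
$$\hat\beta = \frac{\sum_i \beta_i / se_i^2}{\sum_i 1/se_i^2},\qquad
  se = \Big(\sum_i 1/se_i^2\Big)^{-1/2},$$
with p-values taken from $z=\hat\beta/se$ rather than by combining
per-cohort p-values — the two are equivalent only under equal weights, and
inverse-variance pooling is the model actually fitted. A METAL-style
direction string records the per-cohort effect signs.

Before pooling, each cohort-trait scan can be corrected for residual
inflation with the genomic-control factor
$\lambda_{GC} = \mathrm{median}(z^2)/0.4549$ (the denominator is the median
of $\chi^2_1$). Correction rescales $se \to se\sqrt{\lambda}$, which is
equivalent to deflating $\chi^2$ statistics. Two conventions were
genuinely open and are resolved as follows: correction is applied only when
$\lambda > 1$ (deflating already-deflated statistics would manufacture
signal), and the $\lambda$ used is recorded either way so a run is
auditable. `gc_lambda()` refuses fewer than 100 statistics by default: the
median of a handful of tests estimates nothing.

Allele harmonization resolves swapped and strand-flipped records
(swap: $\beta \to -\beta$, $f \to 1-f$; strand: complement both alleles,
then apply the swap rule). Palindromic A/T and C/G SNPs cannot be
strand-resolved from alleles alone; they are flagged and retained by
default, with a strict mode that drops them. Rejected rows are always
counted with a reason, never silently dropped.

## Significance scheme and locus mapping

Genome-wide significance is $5\times10^{-8}/21 = 2.4\times10^{-9}$,
Bonferroni-corrected for 21 independent glycan traits; the suggestive tier
extends one order of magnitude to $2.4\times10^{-8}$. A boundary p-value
falls in the stricter tier. (The printed rendering of the suggestive band
in the source literature inverts the inequality; the implementation follows
the evident intent.)

Loci are built by greedy clumping: in ascending p-value order, each
unclaimed SNP seeds a locus and claims associated SNPs with $r^2 \ge 0.5$
within 1 Mb. Both parameters are configurable — the reference analysis
delegated locus definition to an external tool without printing its
parameters, so these defaults are this package's own choice of standard
clumping values. Overlapping loci are merged transitively; the merged lead
is the member with the smallest p-value, and exact ties break
lexicographically by SNP id so results are order-independent. Replication
requires both $P \le 0.05/n_{loci}$ and sign agreement with discovery. The
per-locus glycan count excludes the lead trait (it counts *other*
associated glycans); a flag includes it.

## The glycome-wide effect network

Each lead SNP's glycome-wide effect is its vector of z-scores across the
retained traits. The 15 derived traits — re-normalizations of directly
measured glycans — are excluded before the network is built: a derived
trait is (noisily) monotone in its parent, so including it would duplicate
rank information and inflate every correlation that its parent
participates in. One of the package's property tests verifies exactly this
inflation on synthetic data, which is the rationale for the exclusion.

Edges are Spearman correlations with average ranks for ties and a
t-approximation p-value on $n-2$ degrees of freedom ($n = 62$ retained
traits makes the approximation comfortable; the implementation is verified
against a rank-then-Pearson oracle at $10^{-12}$). The network is pruned at
the Bonferroni bound over all pairs ($0.05/351 \approx 1.4\times10^{-4}$
for 27 loci). Absolute correlation values are reported: with traits on
arbitrary signed scales, the magnitude of shared architecture is the
quantity of interest.

The permutation reference draws $k$ SNPs (100,000 in the reference
configuration) once, without replacement, from a null pool and reuses the
same draw for every top SNP; per-top-SNP resampling is available by flag.
The pool excludes all SNPs inside associated loci and any SNP with
$\min_t P \le 5\times10^{-5}$, with counts recorded at each stage so the
bookkeeping chain is checkable. The observed edge's quantile is the
*upper-tail* fraction of null values at or above it, so 0 means "no null
SNP reached this correlation". Whether the null is tabulated in $|\rho|$ or
$\rho^2$ is immaterial — the map is monotone and the quantile invariant.

Loci are clustered on the rows of the symmetric absolute-correlation matrix
(unit diagonal) with Euclidean distance and complete linkage; a signed-matrix
mode exists for sensitivity analysis. The dendrogram cut `k` defaults to 3,
matching the module structure the reference analysis observed; on
zero-template-noise simulations the cut at the planted number of clusters
recovers the partition exactly (adjusted Rand index 1).

## Variance explained

For an independently associated SNP with minor-allele frequency $p$
($q = 1-p$) and marginal effect $\beta_u$ on a standardized trait, the
explained variance fraction is $\sigma = 2pq\beta_u^2$; with a joint
(conditional) estimate $\beta_J$ from an external stepwise analysis the
contribution is $2pq\beta_u\beta_J$, which is reported signed — a negative
value flags sign-discordant marginal and joint estimates rather than being
clipped. Frequencies are folded to the minor allele before use; the
stepwise conditional selection itself (GCTA-COJO in the reference analysis)
is consumed as input, not re-implemented.

## TF-binding-site disruption

PWMs are read from JASPAR or MEME text, converted to log2-odds against a
background base distribution with a pseudocount (a zero count with
pseudocount 0 is an error, not a silent $-\infty$). An allele's score is
the maximum over all motif-length windows covering the SNP, on both
strands. The score p-value is the exact background probability that a
random motif-length sequence scores at least as high: computed by full
enumeration for motifs up to length 8 and by a convolution dynamic program
for longer motifs. The DP aggregates identical partial sums exactly and
falls back to a $10^{-4}$ discretization grid only when the value set would
explode (generic real-valued matrices); for count-derived PWMs the exact
path is essentially always taken, and the DP is tested against brute-force
enumeration. A score above the attainable maximum returns the consensus
mass point, never 0.

A SNP *disrupts* a site when the reference allele scores significantly
($P \le 1.8\times10^{-8}$, i.e. 0.05 Bonferroni-corrected for 2,764,712
allele-level tests) and the alternate does not, and *introduces* one in the
mirror case. Alleles whose best scores differ by less than 1 log2-odds unit
are filtered to `no_effect` regardless of significance — the similar-score
filter; the tolerance is configurable since the source analysis leaves
"similar" undefined. Enrichment compares the fraction of associated SNPs
with any disrupts/introduces call against the same fraction among
nonassociated SNPs, flagging ratios of 2 or more. Nonassociated SNPs are
defined as SNPs near a locus with association $P > 5\times10^{-4}$ — the
literal printed inequality ($\le$) contradicts "nonassociated" and is
available by flag, but the default inverts it.

## SMR and the heterogeneity test

At the top SNP, the ratio estimate $b_{xy} = \beta_{out}/\beta_{exp}$
measures outcome change per unit exposure, and
$$T_{SMR} = \frac{z_{exp}^2\, z_{out}^2}{z_{exp}^2 + z_{out}^2}
  \sim \chi^2_1$$
under the null of no shared effect. $T_{SMR} \le \min(z_{exp}^2,
z_{out}^2)$ always; the test is slightly conservative at finite instrument
strength and approaches nominal size as $z_{exp}^2$ grows (type-I error
0.047 at $z_{exp}^2 \approx 200$, measured at $10^4$ replicates in the
acceptance script). Context thresholds follow the reference analysis:
$1.9\times10^{-5}$ for expression outcomes (2622 regions),
$9.1\times10^{-4}$ for complex traits (55 glycan-trait combinations).

The heterogeneity test asks whether $b_{xy}$ is constant across SNPs in LD
with the top SNP, as it must be under one shared causal variant. Eligible
SNPs have exposure $P < 1.6\times10^{-4}$, $r^2$ with the top SNP in
$[0.05, 0.90]$, at most 20 (strongest exposure first) — fewer than 3 makes
the region "not testable", which is distinct from passing. Each deviation
$d_i = b_{xy}(i) - b_{xy}(top)$ is standardized by a first-order
delta-method variance that propagates both traits' sampling error and the
LD-induced covariance with the top SNP, and $\sum_i z_{d_i}^2$ is referred
to $\chi^2_m$ with $m$ the number of eligible SNPs.

This $\chi^2_m$ reference ignores the correlation *among* the $d_i$ and the
heavy tails of ratio estimates at moderate instrument strength, and is
therefore mildly anti-conservative: across the generator's shared-causal
scenarios the measured rejection rate at $\alpha = 0.05$ is roughly
0.09–0.14 rather than 0.05 (refined tail approximations for correlated
quadratic forms are deliberately out of scope). This matters little for the
package's use of the test as a discriminator: linkage scenarios are
rejected essentially always, so shared-vs-linkage verdicts are correct in a
large majority of replicates in both directions, as the acceptance suite
measures. The HLA region (chr6:29570005-33377657, GRCh37) is excluded by
default because its LD structure violates the test's working assumptions.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions everything else is validated under: four cohorts of 849, 802,
1960 and 4479 samples ($N = 8090$), 62 directly modelled traits plus 15
derived ones, 27 loci in 3 latent clusters, and a genome-wide background
pool of null SNPs.

Cluster template effect vectors $w_c$ are drawn once per cluster from
$\mathcal N(0, \text{effect\_scale}^2)$ over traits, and locus $l$ in
cluster $c$ loads as $\beta_{lt} = a_l w_{ct} + \varepsilon$ with
$a_l \sim |\mathcal N(1, 0.2)|$ and
$\varepsilon \sim \mathcal N(0, \text{noise\_sd}^2)$ — the minimal
generative structure under which same-cluster loci have monotone-similar
glycome-wide effects, which is precisely what the network method assumes.
`effect_scale` defaults to 0.1 standardized units, putting lead-SNP effects
in the 0.1–0.3 range typical of the reference association tables;
`noise_sd` defaults to 0.01. Non-lead locus SNPs carry the lead effect
attenuated by their correlation with the lead ($r^2$ drawn in
[0.55, 0.95]); background SNPs are null. Observed effects add sampling
noise with $se = 1/\sqrt{2pqN}$, consistent with rank-normalized traits.
Derived traits are positive noisy affine re-scalings of one parent each —
enough structure to make the exclusion step consequential and testable,
though real derived glycan traits are ratios with more complex error
coupling.

LD panels use an exchangeable within-block haplotype model (each haplotype
copies a block-ancestral allele with probability $\sqrt r$), giving
genotype correlation $r$ for every within-block pair and 0 across blocks;
all SNPs in a block share an allele frequency. eQTL scenarios plant one
shared causal SNP, two distinct causal SNPs in LD, or a null outcome, in
two independent samples, and return marginal summary statistics plus the
reference LD matrix. The motif generator embeds a sharp 14-position
consensus (count 997 vs 1; consensus probability $0.25^{14} \approx
3.7\times10^{-9}$, clearing the $1.8\times10^{-8}$ score threshold) across
the SNP at fold-differentiated rates between classes, with the alternate
allele on the worst-scoring base.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: compositional trait covariance from
total-area normalization (glycan traits sum to a constant), realistic
decaying LD within loci, allele-frequency-dependent effect sizes,
cross-cohort heterogeneity and batch structure, and imputation-quality
variation (`info` is emitted as 1). Regeneration with the same seed is
byte-identical.

## Numerical choices and degenerate inputs

- Spearman edges refuse constant vectors ("degenerate vector") rather than
  returning `NA`; vectors shorter than 4 are rejected.
- $|\rho| = 1$ edges get $p = 0$ directly, avoiding a division by zero in
  the t-transform.
- Score-distribution comparisons use a $10^{-9}$ slack on `>=` so that
  floating-point equality of a score with a mass point lands on the
  inclusive side.
- All tie-breaks (lead-SNP selection, clump seeding) are lexicographic and
  therefore deterministic and input-order invariant.
- The pipeline derives per-stage seeds from the global seed by a fixed
  affine map, so stages can be rerun in isolation; manifests record
  parameter sets and content hashes of every stage output.

## Problem sizes used in validation

The packaged tests and the acceptance script run, by design, at desk scale:
27 planted loci with 62 + 15 traits for the dimensional checks, a
permutation null of $k = 10{,}000$ against 12,000 candidate null SNPs (the
reference configuration's $k = 10^5$ is a parameter, not a different code
path), $10^4$ replicates for SMR calibration, 60 replicates per eQTL
scenario for verdict rates, 500 SNPs per class for motif enrichment, and
$n = 10{,}000$ individuals for the variance-recovery check. These sizes
give Monte-Carlo error well inside the asserted bands while keeping a full
validation run in minutes on one core.

## Known limitations

- The HEIDI-style reference distribution is the unadjusted $\chi^2_m$
  (see above); verdicts near the 0.05 boundary inherit its mild
  anti-conservatism.
- Greedy clumping can split a planted locus when the best-powered SNP in a
  region is not the planted lead — visible occasionally as one extra
  recovered locus; the interval-merge step only repairs splits whose spans
  overlap.
- Palindromic SNPs are retained by default without frequency-based strand
  inference.
- Random-effects meta-analysis, sample-overlap correction, colocalization
  posteriors and multi-SNP SMR extensions are out of scope.
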