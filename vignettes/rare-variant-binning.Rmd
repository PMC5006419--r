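---
title: "Knowledge-guided rare-variant binning: models, weights, and the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided rare-variant binning: models, weights, and the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebin)
```

## The problem

Individually rare variants carry too little information for single-marker
case-control tests: at a site carried by a handful of samples, no test has
power.  Collapsing (binning) methods aggregate all qualifying variants inside
a biological feature — a gene, a pathway, a fixed genomic window — into one
per-sample burden score, trading locus-level resolution for a composite
allele frequency high enough to test.  The scientific leverage comes from
*where* the boundaries are drawn: bins aligned with biological units (genes,
pathways, protein families) concentrate signal, while arbitrary windows
dilute it.

rarebin automates this multi-level binning from plain-text knowledge files
and provides the two burden tests most commonly applied to the resulting
scores, plus a simulation harness for studying the operating characteristics
of its variant-weighting schemes.

## Binning model

For each locus $j$ and sample $i$, let $m_{ij}$ be the number of
*non-major* alleles in sample $i$'s genotype — the major allele being the
most frequent allele at $j$ in the full loaded population, fixed once so
that risk/protective orientation is coherent everywhere.  The disease-model
encoding maps $m_{ij}$ to a contribution $g_{ij}$: additive ($g = m$),
dominant ($g = \mathbf{1}[m \ge 1]$), or recessive ($g = \mathbf{1}[m = 2]$).
The score of sample $i$ in bin $B$ is

$$ s_i(B) = \sum_{j \in B} w_j \, g_{ij}, $$

with locus weights $w_j$ described below.

**Locus selection.**  A locus enters a bin only if its non-major allele
frequency (NMAF, $1 -$ the top allele frequency; the classical MAF at
biallelic sites) falls *strictly below* a threshold $T$ (default $0.05$).
Three modes decide which NMAF is compared: `overall` uses the pooled
frequency; `either` (the default) selects when $\min(\mathrm{NMAF}_{case},
\mathrm{NMAF}_{control}) < T$, admitting variants rare in either stratum so
that both risk and protective variants aggregate; `both` requires
$\max(\cdot) < T$, the conservative option.  The published description of
the selection rule admits more than one reading ("rare in the case or the
control group" versus "the minimum of the two"), so all three modes are
exposed explicitly rather than hard-coding one interpretation.

**Feature assignment.**  Gene-level runs create one bin per region
containing at least one selected locus; group (pathway) runs create one bin
per group, its loci pooled over the group's transitively expanded region
set.  Regions may overlap, and a locus inside two genes contributes to both
bins — the knowledge sources themselves overlap, and silently assigning to
one would make results depend on file order.  Loci covered by no feature
fall into fixed-width intergenic windows (window index
$\lfloor pos / (w \cdot 1000) \rfloor$, default $w = 50$ kb), so every
selected locus is testable somewhere.

Coordinates are 0-based half-open (the BED convention) everywhere
internally; VCF's 1-based positions are converted once on ingest.

## Madsen–Browning weighting and the population schemes

The weighted-sum approach gives rarer variants larger weights:

$$ w_j = \frac{1}{\sqrt{n_j \, q_j (1 - q_j)}}, \qquad
   q_j = \frac{m_j + 1}{2\,n_{pop} + 2}, $$

where $m_j$ is the non-major allele count observed in the *weighting
population*, $n_{pop}$ the number of genotyped individuals in that
population, and $n_j$ the total genotyped individuals at the locus.  The
scheme chooses the weighting population:

| scheme    | population supplying $q$                           |
|-----------|----------------------------------------------------|
| `control` | controls only (the original proposal)              |
| `overall` | all samples                                        |
| `minimum` | the smaller of the control- and case-based weights |
| `maximum` | the larger of the two                              |
| `none`    | no weighting ($w = 1$)                             |
| `custom`  | user table, absent loci default to $w = 1$         |

$n_j$ is held common across schemes (the full genotyped cohort) so the
schemes differ only through $q$; since $w$ is strictly decreasing in $q$ on
$(0, 0.5)$, the minimum/maximum schemes bracket any common-denominator
pooled estimate.  Note the pseudo-count makes stratum and pooled estimates
use different denominators, so the bracketing is exact only in the
common-denominator idealisation — visible at loci monomorphic in the
sample, where the pooled $q$ falls below both stratum estimates.

Control-only weighting is the scientifically interesting pathology: the
selection threshold bounds control frequencies but leaves case frequencies
unbounded, and estimating $q$ from controls alone couples the weight to the
case-control frequency difference.  The simulation harness exists largely
to quantify the resulting type I error inflation and its growth with bin
size.

## Burden tests

*Logistic regression*: case/control status on the bin score (plus optional
covariates); the reported p-value is the Wald test of the score
coefficient.  The Wald form is chosen over the likelihood ratio for speed
across the many thousands of fits a simulation study performs; an
independently coded IRLS oracle in the test suite pins the implementation
to $10^{-6}$.  Constant scores are reported as `degenerate`; non-converged
fits and (quasi-)separation — detected as a standardised slope
$|\hat\beta| \cdot \mathrm{sd}(s) > 10$ — as `nonconverged`, rather than
returning a meaningless p-value.

*Wilcoxon rank-sum*: two-sided, midranks for ties.  The exact null
distribution is used when the smaller group has $\le 10$ samples and the
scores are tie-free; otherwise the normal approximation with tie correction
and a continuity correction.  An exhaustive rank-split enumeration oracle
covers the exact path in the tests.

No multiplicity correction is applied inside the engine — the simulation
studies evaluate per-bin $\alpha = 0.05$ — but the results table carries a
Bonferroni flag at a user-chosen family-wise level for real-data use.

## The simulation generative model

The harness replaces an external sequence simulator and reference panel
with a transparent generative model:

1. **Bin size.**  Gene bins draw $\mathrm{round}(N(50, 5))$ variants,
   XL-gene bins $N(200, 5)$, pathway bins concatenate $U\{2, \dots, 50\}$
   independently drawn gene-sized sub-bins (roughly 100–2500 variants);
   draws are truncated below at $n_{causal} + 1$.  The source design
   reports both "standard deviation = 5" and a "$\pm 10$" shorthand for
   gene bins; the explicit sd = 5 is used.
2. **Site frequency spectrum.**  Allele frequencies are i.i.d. with density
   $\propto 1/q$ on $[5 \times 10^{-4}, 0.5]$ — the rare-skewed, neutral-like
   shape of sequencing panels — sampled by inverse CDF $q = a (b/a)^u$.
   An empirical frequency vector (e.g. parsed from a reference panel) can
   be supplied instead and is resampled with replacement.
3. **Genotypes.**  Hardy–Weinberg: allele counts $\mathrm{Binomial}(2, q)$,
   independent across loci and samples; no missingness.
4. **Disease model.**  $\Pr(\mathrm{case}) =
   \mathrm{logit}^{-1}(\alpha + \log(\mathrm{OR}) \sum_{c} m_{ic})$ over
   the causal loci; $\alpha$ is calibrated so the population prevalence
   equals the target (default 5%) by root-finding to $10^{-10}$ against
   the *exact* burden distribution (a convolution of the causal-locus
   binomials), not a Monte-Carlo estimate.  Cases and controls are
   collected by rejection sampling until exactly $n_{cases}$ and
   $n_{controls}$ accumulate (generation cap $10^7$ individuals per
   replicate).  Under OR $= 1$ status is independent of genotype, so null
   replicates generate the target sample directly — an exact shortcut, not
   an approximation.  Under OR $> 1$ only the causal columns are generated
   for the rejection pool; neutral columns, independent of status, are
   generated for the retained individuals only.  Both shortcuts leave the
   joint distribution of (genotypes, status) unchanged and make the
   1000-replicate studies run in minutes on one core.

Each replicate is then pushed through the same selection, weighting,
scoring, and testing code paths as real data (a dedicated test asserts the
vectorised study engine agrees with the general pipeline to $10^{-10}$).

**What the model does and does not emulate.**  It preserves the features
the weighting-scheme study actually depends on: a rare-skewed spectrum, a
hard frequency threshold interacting with stratum-level sampling noise, and
a prevalence-calibrated case-control design.  It omits linkage
disequilibrium, population structure, missingness, and genotyping error.
Consequences: calibration results (type I error near $\alpha$ for the
symmetric schemes, control-only inflation growing with bin size, the
bin-size bias regression pattern) transfer well, as the acceptance suite
verifies against the published grid; absolute power values are
spectrum-dependent and should be read as orderings, not forecasts for any
particular dataset.

## Defaults and numerical choices

| parameter | default | rationale |
|---|---|---|
| NMAF threshold $T$ | 0.05 | the conventional rare/low-frequency cutoff used throughout the reference study |
| NMAF mode | `either` | aggregates risk and protective variants; the study's selection behaviour |
| disease model | additive | the standard default encoding |
| intergenic width | 50 kb | of the order of a median gene footprint |
| cases / controls | 500 / 500 | study design |
| prevalence | 5% | study design |
| causal variants | 10 | study design |
| replicates | 1000 | study design; binomial SE at $\alpha=0.05$ is $\approx 0.007$ |

Other fixed choices: threshold comparisons are strict (`<`); bins and loci
are emitted in lexicographic id order so outputs are byte-reproducible;
ties in the major-allele choice break toward the REF allele; missing
genotypes contribute 0 to scores and drop out of frequency denominators;
multi-allelic loci pool all non-major alleles in the encoding (the
non-major framing makes this the coherent generalisation, though it is a
documented choice — the reference describes only biallelic behaviour);
phased and unphased genotypes are treated as unordered allele pairs.  All
study randomness flows from the single configured seed, and identical
configurations reproduce identical results bit for bit.

The bin-size bias diagnostic regresses replicate p-values on replicate bin
sizes with a quasi-binomial (fractional response) link, since the outcome
is bounded in $[0, 1]$.

## Problem sizes used by the shipped checks

The packaged test suite runs the three null studies (gene, XL-gene,
pathway) at 1000 replicates each and the power sweep at 400 replicates per
odds ratio; `scripts/acceptance.R` re-runs the null grid at 1000 and the
power sweep at 1000 replicates per odds ratio.  These sizes put the
Monte-Carlo standard error of a rejection rate near 0.007–0.016, small
against the effects under study (e.g. control-only inflation of +0.05 at
gene bins and +0.75 at pathway bins over the nominal 0.05).

## Known limitations

* The power-study causal model applies one shared odds ratio to all causal
  variants; mixed effect directions are not simulated.
* The restriction of causal draws to rare sites (`restrict_causal_rare`)
  is exposed because the reference study reports both behaviours, but the
  main analyses here leave it off.
* Dispersion-style (variance-component) tests, dosages/genotype
  likelihoods, sex-chromosome ploidy, and quantitative traits are out of
  scope.
* The knowledge store is a file-based stand-in for a relational
  biorepository: regions and nested groups from tab-delimited files, with
  cycle detection, not a database build.
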