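---
title: "Inversion genotyping by haplotype-family similarity scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion genotyping by haplotype-family similarity scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invTyper)
```

## The statistical model

A polymorphic inversion suppresses recombination between its two
orientations, so the inverted (I) and non-inverted (NI) chromosomes form
two haplotype families with family-specific SNP allele frequencies inside
the region. invTyper treats the inversion as a biallelic locus whose
genotype must be inferred from region SNPs.

Given a phased, orientation-labelled reference panel, `buildReference()`
tabulates, for each inversion-genotype group $k \in \{NN, NI, II\}$ and
each SNP $i$, the empirical frequency $f_{k,i}(s)$ of diploid genotype
$s \in \{0,1,2\}$, plus a weight $\rho_i^2$: the squared haplotype
correlation between the SNP's alternate allele and the inverted
orientation. A sample with genotype posteriors $P_i(\cdot)$ and certainty
$p_i = \max_s P_i(s)$ receives one similarity score per group,

$$H_k \;=\; \frac{\sum_{i} \sum_{s} P_i(s)\, f_{k,i}(s)\, \rho_i^2}
{\sum_{i} p_i^2},$$

and is called $\arg\max_k H_k$ subject to quality control. The score
rewards genotype patterns that are simultaneously *probable in group k*
and *informative about orientation*; SNPs uncorrelated with the inversion
($\rho_i^2 = 0$) contribute nothing to the numerator.

Assumptions worth keeping in mind: the reference panel and study cohort
must describe the same population (frequencies are taken as known, not
re-estimated); SNPs are treated as conditionally independent given the
inversion genotype; and the posterior vectors are trusted as given — the
package does not re-impute.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minSnps` | 15 | minimum SNPs entering a score; below this the regional SNP coverage cannot support a call |
| `minDiff` | 0.1 | minimum top-minus-runner-up score gap (score units); smaller gaps mean the sample resembles two reference genotypes at once |
| `minR2` | 0.9 | haplotype $r^2$ threshold for a SNP to serve as a tag |
| QC thresholds | 0.10 / 0.05 / 1e-6 / 0.01 | individual missingness, SNP missingness, Hardy–Weinberg p, MAF |
| `relatednessThreshold` | 0.1 | GRM cutoff (closer than ~third cousins) for pruning |
| `alpha`, `gwAlpha` | 0.05, 5e-8 | family-wise and genome-wide significance levels |

Both call-QC failures are values, not errors: a failed sample carries
per-criterion flags and a missing genotype, and `callCohort()` reports the
cohort callability.

## What the synthetic generator emulates — and what it does not

`simConfig()` + `simulateReferencePanel()` / `simulateCohort()` /
`simulatePhenotypes()` generate the structure the analysis assumes:

* two haplotype families at inverted-allele frequency `invFreq`
  (default 0.2, typical of a common European inversion such as the one on
  17q21.31), Hardy–Weinberg diploids, and per-SNP family allele
  frequencies separated by `divergence` around a
  $\mathrm{Uniform}(0.05, 0.95)$ base frequency, clipped to
  $[0.01, 0.99]$;
* imputation-style genotype posteriors: the observed genotype is miscalled
  to an *adjacent* dosage with probability `genotypeErrorRate` (mimicking
  single-allele miscalls), then wrapped in a posterior with mass $p_i$
  (drawn from `certaintyModel`) on the observed genotype and
  $(1-p_i)/2$ on each alternative — the simplest distribution consistent
  with a stated maximum posterior;
* phenotypes with additive inversion effects, age/sex/site/quality
  covariates, a global-size component with loading `globalWeight`, and
  noise matching a target correlation matrix; X-linked male contributions
  follow a configurable generative dosage-compensation mode.

Deliberately **not** modelled: intra-family LD beyond family membership
(the classifier uses only per-SNP frequencies, so richer LD would
complicate oracles without exercising additional code paths),
recombination maps or coalescent history, inter-locus LD between
inversions, breakpoint sequence content, and population stratification.
Consequently, passing tests demonstrate correctness of the *procedures*
under the assumed structure; they do not certify performance on real
cohorts, where intra-family LD makes effective SNP information smaller
than the nominal SNP count and where reference-panel mismatch is the
dominant failure mode.

One generator option bends the frequency model: `plantPerfectTag = TRUE`
fixes the first SNP of each region at frequency 1 on I haplotypes and 0 on
NI haplotypes, outside the usual clipping. The clipped model cannot
produce a SNP in *perfect* LD with the orientation, and a $\rho^2 = 1$ tag
is the reference case against which tag-SNP calling is validated
(tag calls then provably equal score calls on error-free data).

All generator randomness derives from the configuration seed; identical
configurations give bit-identical panels, cohorts and phenotypes.
Sub-stage seeds are derived with fixed offsets so that a panel and a
cohort from the same configuration share the same underlying family
frequencies without sharing draws.

## Numerical and procedural choices

* **Score denominator.** The default normalization is
  $\sum_i p_i^2$, the certainty-only form. Because it ignores the weights,
  scores can exceed 1 when high-$\rho^2$ SNPs dominate the numerator over
  many low-weight SNPs in the denominator — only score *differences*
  matter for calling. `normalization = "weighted"`
  ($\sum_i p_i \rho_i^2$) is available and rescales all three scores by a
  common factor, leaving calls unchanged.
* **No smoothing by default.** Group frequency tables are raw empirical
  frequencies; a genotype unseen in a reference group contributes exactly
  0. A pseudocount `smoothing` option exists for tiny panels.
* **Exact score ties are no-calls.** A tie cannot satisfy any positive
  `minDiff`, and silent argmax tie-breaking would make calls depend on
  group ordering.
* **Missing SNPs** leave both the numerator and the denominator and do not
  count toward `nSnpsUsed`.
* **Inverse normal transformation** uses the Blom offset,
  $\Phi^{-1}((r - 3/8)/(n + 1/4))$, with average ranks for ties.
* **Effective number of tests** uses the eigenvalue integer/fractional
  decomposition (Li–Ji) by default, which reproduces integer-valued
  $t_e$ on equicorrelated matrices; the Nyholt variance-based variant is
  available. Eigenvalues are rounded to 10 decimals before the
  integer/fractional split so numerical noise cannot flip a floor.
* **Relatedness pruning** is greedy on pair counts (ties broken toward the
  larger index), which removes exactly one individual per isolated pair
  and two per mutually related triangle.
* **Conditional adjustment** is forward stepwise selection on
  individual-level data at 5e-8 with an $r^2 > 0.99$ collinearity guard
  and a 20-step cap, followed by refitting the inversion with selected
  SNPs as covariates. Summary-statistic conditional analysis against an
  external LD reference is out of scope.
* **Error-adjusted effect correlation** uses method-of-moments
  disattenuation: the covariance of the paired estimates divided by
  error-corrected standard deviations,
  $\sqrt{(\widehat{var}(\beta_d) - \overline{se_d^2})
  (\widehat{var}(\beta_r) - \overline{se_r^2})}$, clamped to $[-1,1]$ and
  flagged undefined when a corrected variance is non-positive. The
  sign-concordance binomial test is one-sided (greater than 0.5) by
  default, with exactly zero betas conservatively counted discordant.
* **Site** enters association models as fixed-effect indicator contrasts,
  and the diagnosis flag is an ordinary covariate.
* **Coordinates** are 1-based inclusive (VCF convention) throughout;
  multi-allelic and half-missing VCF genotypes are treated as missing.

## Validation problem sizes

The test-suite recovery studies use cohorts of 2,000 individuals with
500-individual reference panels and 30-SNP regions for genotyping checks;
5,000 null simulations at $n = 500$ for the type-I error of the
residualize → INT → joint-regression pipeline; 200 replicates at
$n = 5{,}000$ for effect recovery (planted standardized effect 0.2,
recovered within ±0.02); 20 replicates at $n = 5{,}000$ for conditional
absorption by an $r^2 \approx 0.98$ tag SNP (judged on the median
conditional p, which is robust to single-draw noise in the residual
noncentrality); and 200 replicates of 30 effect pairs for generalization
calibration (true cross-cohort correlation 0.8 recovered within ±0.1).
These sizes give the property checks comfortable statistical margins
while keeping the whole suite quick on a single CPU.

## Known limitations

* The classifier assumes two haplotype families; loci with more than two
  deep haplotype clades (which in practice show chronically small score
  differences) will suffer low callability rather than wrong calls, but
  the package does not model multi-clade references.
* Disattenuation can exceed the $[-1, 1]$ range or become undefined in
  small, noisy effect tables; the flag must be checked.
* The file-based pipeline expects genotype posteriors (or hard calls) in
  the input VCF; it performs no imputation and no strand harmonization —
  reference and study VCFs must agree on REF/ALT.
* `simulateTwoCohorts()` draws true effects anew per run; it calibrates
  the generalization statistics but is not a model of any particular pair
  of real cohorts.
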