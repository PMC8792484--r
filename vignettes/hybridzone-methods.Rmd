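---
title: "Models and methods behind hybridzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybridzone)
```

This vignette is the package's account of its statistical machinery: the
models, the estimators, the thresholds with their units and defaults, the
numerical choices, and what the synthetic-data tests do and do not
establish about real data.

## The setting

Two deer species with broad range overlap hybridize at low frequency;
hybrids backcross into either parental gene pool, so most admixed
individuals look morphologically pure and carry only a thin slice of
donor ancestry. Nuclear evidence comes from thousands of unlinked
biallelic ddRAD SNPs; maternal history comes from an aligned
mitochondrial fragment, where "capture" — one species' matriline fixed in
the other species — records the direction of historical crosses. The
package's job is to turn a filtered genotype matrix, a haplotype
alignment and sample metadata into diversity tables, ancestry and
hybrid-generation calls, introgression tests and demographic-inference
inputs.

## Genotype QC

The filter chain is depth mask, then locus screens, then the individual
screen, in that fixed order; it is idempotent. Boundary semantics follow
the usual wording of the tools that produce such panels: a genotype is
kept at depth >= 20 reads; a locus is kept at call rate >= 0.80, minor
allele frequency >= 0.05 (computed over called genotypes only, so
missingness does not dilute frequencies) and observed heterozygote
fraction <= 0.8 (a catch-all against paralog collapse); an individual is
kept when strictly less than 30% of its genotypes are missing. Each
dropped locus is reported with the first rule it failed, in that order.
Whether the depth mask runs before or after the locus screens is not a
settled convention; the chain documents its order rather than asserting
anyone else's.

## Diversity and differentiation

Per-locus expected heterozygosity uses the unbiased 2n/(2n−1) correction;
at a biallelic SNP this equals the mean pairwise difference, so the
nucleotide-diversity column is per SNP (a per-genomic-site figure would
need invariant-site counts, which a SNP panel does not carry). F_IS is
1 − H_O/H_E averaged over polymorphic loci. F_ST is Weir & Cockerham's
theta with variance components summed across loci before the ratio —
the de facto standard, robust to rare loci. Jost's D uses Nei–Chesser
corrected within- and total-gene-diversities, averaged across loci before
the ratio (the "global" estimator), times k/(k−1) with k = 2.

For mtDNA, haplotype diversity is the unbiased n/(n−1)(1 − Σp²);
columns containing gaps or N are excluded pairwise for nucleotide
diversity and listwise for segregating sites — deterministic and simple,
at the cost of slightly different site sets for the two statistics.
Tajima's D and the Ramos-Onsins & Rozas R2 (computed from minor-allele
singletons, since no outgroup polarizes the data) are tested against a
standard neutral coalescent conditioned on the observed S: exponential
coalescence times, uniform pair merging, exactly S mutations placed
proportionally to branch length. Conditioning on S mirrors the cited
significance machinery of the field's sequence-analysis tools. Both
statistics flag demographic expansion at small values, so p-values are
lower-tail: Pr(sim <= observed). Under fixed-S conditioning the null mean
of D is itself slightly negative (about −0.1 at n = 20, S = 30, a ratio
bias, cross-checked against an independent coalescent simulator) — the
p-values account for this automatically because the null is simulated
under the same conditioning.

## Ancestry and the hybrid index

PCA runs on locus-mean-imputed, centred, unit-variance dosages —
deterministic and adequate at the few-percent missingness these panels
have after QC. The number of gene pools is chosen by lowest BIC over
spherical Gaussian mixtures fitted to the retained PCs (mclust model
EII, the probabilistic counterpart of k-means). We use the mixture
likelihood rather than a pooled within-cluster-sum-of-squares BIC
because the latter is not a likelihood: across penalty scalings it
either always prefers K = 1 or fragments isotropic noise once samples
exceed a few dozen, while the mixture criterion recovers K = 1 on
homogeneous panels and K = 2 on two-species panels across the simulated
regimes we tested.

Ancestry proportions and the hybrid index are the same maximum-likelihood
estimator run on the same code path: with parental allele frequencies
p₁ℓ, p₂ℓ known (estimated from designated parental panels), an
individual's genotypes are Binomial(2, h·p₂ℓ + (1−h)·p₁ℓ) and h is
maximised on a 1001-point grid with local refinement; refinement is kept
only when it strictly improves the likelihood, so analytic anchors (an F1
at exactly 0.5, a pure parental at exactly 0 or 1) are hit exactly.
Frequencies are clamped to [1e−9, 1 − 1e−9] inside the likelihood so
fixed loci stay finite at interior h. The 2-log-likelihood-unit support
interval is read off the grid. Only ancestry-informative loci
(|p₁ − p₂| >= 0.8, fixed differences included) enter; this keeps the
estimator sharp when parental panels are modest.

Designations follow the ancestry bands: Q > 0.98 or < 0.02 parental,
0.05 < Q < 0.95 putative hybrid. The bands leave gaps by construction;
individuals there are reported "unassigned" rather than forced.
Interspecific heterozygosity defaults to fixed-difference loci, where a
heterozygote necessarily carries one allele from each species (an F1 is
exactly 1.0); a delta-relaxed mode serves datasets without fixed
differences, at the cost of upward noise. Generation classes come from
the triangle rules (recent generation: 0.25 < HI < 0.75 and het > 0.5;
later generation: same HI band, het < 0.5; otherwise multi-generation
backcross), with boundary values resolved to the outer class since the
source rules are strict inequalities. Note that a deep backcross whose
genome shows no donor alleles at the informative loci is
indistinguishable from a parental and will designate as one — a property
of the data, not a defect of the estimator.

## Introgression

Site-pattern counts use the allele-frequency formulation: with derived
frequencies p₁..p₄ on (((P1,P2),P3),O), a site adds (1−p₁)p₂p₃(1−p₄) to
ABBA, p₁(1−p₂)p₃(1−p₄) to BABA, p₁p₂(1−p₃)(1−p₄) to BBAA;
D = (ABBA−BABA)/(ABBA+BABA). The outgroup's major allele is treated as
ancestral; sites where the outgroup's minor allele exceeds frequency 0.1
are skipped and counted, a rule made explicit because small outgroup
panels are themselves polymorphic. The admixture fraction divides the D
numerator by its value with P3 substituted for P2 — the
complete-introgression ceiling — rather than a subdivided-P3 f4-ratio,
whose subdivision convention the source material does not pin down.
Significance comes from a delete-one-block jackknife over contiguous
locus blocks (default 1000 SNPs, sized for linkage in real data; the
simulator's loci are unlinked, so tests use smaller blocks to give the
jackknife more degrees of freedom), Z = D/SE, two-tailed normal p.

## Outlier scan and SFS

The scan regresses each standardized locus on the first K = 2 PCs,
stacks the coefficient z-scores, and converts their robust Mahalanobis
distances (MASS::cov.rob) to chi-square(K) p-values after rescaling by
the genomic inflation factor (median distance over the chi-square
median). Benjamini–Hochberg at alpha = 0.05 flags outliers; the
partition step takes the union of up to two flag sets by default
(intersection available) — the second slot accepts an externally produced
flag list, so a second method can be slotted in without re-implementing
it. Downstream clustering, hybrid and introgression stages consume the
neutral partition by default.

The folded SFS drops loci with any missing genotype in the target
population (hypergeometric projection is a documented extension, not
implemented), bins minor-allele counts m = min(c, 2n−c) >= 1, and keeps
monomorphic loci in the denominator L. The blueprint writer emits the
text fields a stairway-style demographic-inference tool expects, with a
cervid mutation rate of 1.1e-8 per site per generation and 5-year
generations as defaults.

## The simulator

The generator emulates the study regime the package targets: ~25k SNPs
across 92 individuals (42 + 42 parentals and 8 multi-generation
backcrosses by default), a few percent of loci fixed between species and
the rest drawn from a Balding–Nichols model at F = 0.4, Hardy–Weinberg
parental genotypes, pedigree crosses with independent gamete draws (no
linkage, matching one-SNP-per-tag panels and making jackknife blocks
exchangeable), negative-binomial read depths with mean 40 so the depth-20
mask has real work, ~3% missingness, and a 1103-bp mtDNA alignment in two
clades separated by 25 diagnostic substitutions where species-1
individuals carry captured clade-2 haplotypes with probability 0.58
(over half of the capture-prone species' matrilines, as in the motivating
system). Hybrid matrilines follow the configured maternal species —
which parent was the dam is exposed as configuration because field data
rarely record it. Identical configurations produce byte-identical files.

What the simulator does not emulate: linkage and LD (so the 1000-SNP
jackknife block defaults are untested against real LD), genotyping error
beyond depth-driven missingness, within-species geographic structure
(populations N/S are labels, not demes), selection, and coalescent
ancestry within the mtDNA clades — private mutations are star-like, which
drives simulated mitochondrial Tajima's D negative. Passing tests
therefore establish estimator correctness and pipeline plumbing, not
robustness to LD, batch effects or reference bias in real ddRAD data.

## Numerical and design notes

* Problem sizes in the test-suite simulations (hundreds to a few thousand
  loci, 20–90 individuals, 200-replicate calibrations, 10,000 coalescent
  replicates) were chosen as the smallest sizes at which the estimators'
  sampling noise is well inside the asserted bands.
* All randomness flows from a single seed per run; reports are written
  with fixed column order and 3-decimal formatting so reruns are
  byte-comparable.
* Jost's D is floored at 0; Weir–Cockerham theta may be slightly negative
  at zero differentiation, which is retained (it is the estimator's
  behaviour).
* The one-SNP-per-tag filter keys on `<tag>_<offset>` locus ids and is a
  no-op otherwise.
* K-selection reports BIC on the lower-is-better scale regardless of the
  fitting engine's sign convention.
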