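---
title: "Methods: characterising isolated population cohorts with isopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising isolated population cohorts with isopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopop)
```

# Scope

`isopop` implements the statistical machinery used to characterise
genetically isolated cohorts from whole-genome sequencing data:
reference-imputation-panel site selection, imputation quality metrics,
population-structure statistics, haplotype-based selection scans with
gene-level aggregation, drifted deleterious-variant enrichment, and
putative human-knockout (HKO) detection. Because cohort WGS data of this
kind are typically access-restricted, the package also ships a synthetic
cohort generator; every analysis stage is exercised end to end on
generated data.

# The synthetic cohort generator

## Model

Haplotypes are built by Li–Stephens-style founder-mosaic copying rather
than a coalescent with recombination. A base pool of `n_founders`
template haplotypes carries alleles whose founder frequencies follow the
neutral 1/k spectrum; each panel haplotype copies one founder at a time,
switching templates across a gap of $g$ bp with probability
$1 - e^{-\rho g}$ and flipping each copied allele with the per-copy
mutation probability. This produces the two features the downstream
statistics actually require — linkage disequilibrium that decays with
physical distance (for EHH/iHS and ROH) and a rare-heavy folded site
frequency spectrum — at a trivial computational cost. Genealogical
exactness is not attempted and not needed.

Isolates are derived by resampling a founder subset (the bottleneck)
without replacement and copying new haplotypes from it. Two rates play
deliberately different roles:

* the base mosaic rate (`recombination_switch_rate_per_bp`, default
  5e-6/bp) compresses many generations of ancestral recombination into
  one copying pass;
* isolate copying uses a per-meiosis rate
  (`recomb_per_generation_bp`, default 1e-8/bp, scaled by
  `n_isolate_generations`), because isolate haplotypes are separated
  from their founders by only a few meioses. This is what gives isolates
  their hallmark long identical-by-descent tracts, and therefore runs of
  homozygosity and elevated inbreeding coefficients; re-using the
  ancestral rate here would shred IBD tracts to tens of kb and no ROH
  would ever form.

Default study conditions are a base panel of 200 haplotypes and three
isolates drawn through bottlenecks of 12, 30 and 60 haplotypes after 10
generations — a severity gradient chosen so that pairwise Fst against
the base spans roughly 0.003–0.04 and ROH burdens differ visibly
between isolates, the qualitative regime reported for small, partly
isolated villages. The defaults are chosen for testability, not
calibrated to any particular human demography.

What the generator does **not** emulate: X chromosomes, multiallelic
sites, sequencing-read error, genotype-calling artefacts, gene
conversion, and realistic gene structure (genes tile the chromosome in
equal-width intervals). Passing tests on generated cohorts therefore
demonstrate correctness of the estimators and rules under a plausible
LD/SFS regime, not performance on real call sets.

Planted truth signals are available for three analyses: `plant_sweep()`
homogenises the flanking haplotype of a chosen carrier set (a hard-sweep
caricature whose extended haplotype homozygosity an iHS scan must
detect), a homozygous tract can be written directly into a genotype
matrix for ROH recovery, and a deleteriousness-score excess can be
planted among drifted variants for the enrichment statistic (below).

`corrupt_to_posteriors()` emulates imputation output: with MAF-dependent
error rate $\varepsilon(\mathrm{maf}) = e_{\min} + (e_{\max} -
e_{\min})\,e^{-\mathrm{maf}/d}$ the genotype is resampled from
Hardy–Weinberg proportions, and the posterior mixes a point mass on the
(possibly corrupted) call with a Hardy–Weinberg prior. Rare sites are
thus imputed worse — the gradient the r² and info-score reports are
meant to display — while zero noise reproduces the truth exactly.

# Panel site selection and imputation metrics

Reference-panel inclusion keeps, per cohort, sites with alternative
allele count AC ≥ 2 and mean called-genotype depth ≥ 5, and rescues
singletons that are polymorphic in another cohort or present in an
external resource (exact chrom/pos/ref/alt match). Two interpretation
points are deliberate: the depth rule uses the site mean over called
genotypes (a common site-level QC reading; per-carrier minima would be
an alternative), and "present in another cohort" requires the site to be
polymorphic there, not merely listed.

The info score is the IMPUTE-type information measure: with expected
dosage $e_i$ and second moment $f_i$ per sample,
$\mathrm{info} = 1 - \sum_i (f_i - e_i^2) / (2N\hat\theta(1-\hat\theta))$,
clamped to [0, 1] and defined as 1 when $\hat\theta \in \{0,1\}$.
Concordance r² is the squared Pearson correlation between true and
expected dosage per site, binned by truth MAF; it is sign-blind by
construction, and zero-variance sites are excluded and counted rather
than silently dropped. Association-study QC keeps common variants
(MAF ≥ 1%) with info > 0.4 and rare variants (0.1–1%) with info ≥ 0.8;
meta-analysis combines cohort z-scores with $\sqrt{n}$ weights and
excludes variants lacking a sign-concordant cohort pair, with Bonferroni
significance.

# Population structure

LD pruning follows the windowed pairwise rule (200-site windows, step
50, r² > 0.4 removes the later site, MAF ≥ 0.02 first). PCA standardises
each site by $\sqrt{2p(1-p)}$, mean-imputes missing genotypes after
centring, and orients each axis so its largest-magnitude coordinate is
positive (a documented, arbitrary sign convention). Pairwise Fst is the
two-population Weir–Cockerham (1984) estimator aggregated genome-wide as
a ratio of summed variance components; small negative genome-wide values
are possible and are reported, not truncated. ROH detection is a
PLINK-style scan — windows of 50 sites with at most one heterozygote
flag homozygous sites, and flagged runs must span ≥ 100 sites, ≥ 1 Mb,
with inter-site gaps ≤ 1 Mb — with all parameters surfaced because the
published analyses of this kind rarely state them. The inbreeding
coefficient is the method-of-moments excess homozygosity
$F = (O_{hom} - E_{hom})/(L - E_{hom})$.

# Selection scans

EHH among the carriers of a core allele is the probability that two
random carriers are identical over the extended interval; iHH integrates
the EHH curve over physical distance (trapezoid rule) in both directions
until EHH first drops below 0.05, and the unstandardised score is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$. Sites whose curve reaches the
chromosome edge or a gap larger than 200 kb before the cutoff are
invalidated outright rather than penalised with a scaled correction —
the simpler of the two conventions in circulation. Scores are
standardised within 50 equal-width derived-allele-frequency bins; bins
with fewer than two valid scores or zero spread are flagged rather than
divided. Gene-level calls count markers with |standardised iHS| over the
threshold (2 or 2.5) inside each gene interval and require at least 20.
The compiled scan keeps EHH by incremental partition refinement, so a
20 000-site, 200-haplotype chromosome scans in about a second; a
brute-force string-comparison oracle in the test suite checks the
integrals to 1e-9.

On neutral panels the standardised scores are close to Gaussian: the
fraction of sites beyond ±2 per tail lands near 2.2–2.3%.

# Drifted deleterious-variant enrichment

A variant is *drifted* in population X relative to Y when its AC in X
falls in the class of interest (1–2, 3–5, 5–10, >10, read as disjoint
intervals) while its frequency in Y is below 0.5% (absence counts as
zero). DVxy is the count ratio of X-drifted to Y-drifted variants
restricted to one deleteriousness bin (0–5, 5–15, 15–20, >20), with a
bootstrap SD from resampling the combined drifted list, and the
enrichment call requires dvxy − sd > 1. The exact formula of the
published statistic lives in a companion paper not reproduced here; this
operationalisation reproduces the qualitative behaviour it is used for
(≈1 at low scores, above 1 + sd at high scores when a high-score excess
exists) and is isolated behind one function so it can be swapped.

Two numerical honesty notes. First, the planted-excess experiment moves
mid-score (5–20) drifted variants of one population into the >20 bin:
this leaves the 0–5 bin untouched as a within-experiment null and keeps
the comparison population's >20 count away from zero, which the ratio
needs to be defined. Second, the variant-level bootstrap assumes
exchangeable variants; in haplotype data rare drifted variants cluster
on shared haplotypes, so the realised replicate-to-replicate spread of
dvxy exceeds the bootstrap SD by a factor of roughly 1.3–1.6. A one-SD
band around 1 therefore covers the null in only ~70–85% of replicates,
not the ~90%+ a Gaussian intuition suggests; the package reports the SD
as defined and leaves the interpretation caveat here.

# Human knockouts

A variant is a putative loss-of-function when its consequence term is
one of the eight high-impact terms (frameshift, splice acceptor/donor,
stop gained/lost, start lost, transcript ablation/amplification) and its
phred-scaled deleteriousness score is ≥ 20; unknown terms are rejected
with a warning rather than guessed. A knockout requires at least one
homozygous-alternative individual in at least one cohort; missing
genotypes are ignored and no additional per-genotype quality filter is
applied. TOTAL means all of the gene's transcripts are affected,
otherwise PARTIAL. Cross-population gene overlaps are computed after
restricting to an injected external catalogue (a false-positive guard;
the package never downloads one). The gene-intolerance comparison is a
Wilcoxon rank-sum with normal approximation and tie correction,
implemented directly so that fully tied input returns the null midpoint
with p = 1 instead of an undefined statistic; it agrees with
`stats::wilcox.test(exact = FALSE, correct = FALSE)` on untied data.

# Problem sizes and reproducibility

All stochastic operations are pure functions of their seed. The bundled
experiments use a 200-haplotype, 20 000–30 000-site chromosome for scan
and enrichment work and smaller panels (≤ 1 500 sites) for estimator
unit checks; `scripts/acceptance.R` regenerates a three-isolate bundle
at 8 000 sites and reruns the whole pipeline from the command line.
These sizes keep each experiment in the seconds-to-minutes range while
leaving every statistical contrast (drift ordering, ROH burden, sweep
recovery, enrichment) comfortably detectable.

# Known limitations

* The simulator's demographic realism is intentionally minimal; absolute
  values of Fst, ROH burden or r² on generated data are not calibrated
  to any real cohort.
* Ancestral alleles for the iHS scan default to the reference allele
  when no truth is supplied — a known source of sign error on real data.
* DVxy's bootstrap SD understates replicate variability on linked data
  (above).
* Indels are carried as ordinary variant keys without left-normalisation;
  inputs are assumed normalised.
* Compound-heterozygote (two-hit) knockouts and phasing-based analyses
  are out of scope.
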