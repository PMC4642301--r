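---
title: "Homozygosity, ROH and inbreeding in case-only survival analysis: methods"
author: "rohsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rohsurv methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rohsurv` analyses a case-only survival design: breast-cancer-style
cohorts dichotomized into short-time (STS) and long-time (LTS) survivors,
genotyped on a SNP array, with the question of whether homozygosity —
per SNP, as runs of homozygosity (ROH), or as genome-wide inbreeding —
differs between the outcome groups.  There is no control group and no
survival-time model: the group label is the outcome, so every test is a
two-group comparison.

The package assumes autosomal diploid genotypes coded 0/1/2 (A1-allele
copies, `NA` missing), samples annotated with a population label (the
stratification covariate) and the two-level outcome, and — for the
selection statistics only — phased, ancestrally polarized haplotypes.

# Per-SNP homozygosity association

Each SNP contributes a 2×2 table of homozygote (codes 0 or 2) versus
heterozygote (code 1) counts by outcome group, excluding missing calls per
SNP, so group totals vary across SNPs.  The statistic is the uncorrected
Pearson chi-square on 1 df; no continuity correction is applied because
the study-scale counts (hundreds per cell) do not need it and the
uncorrected form reproduces published table values exactly.  Multiplicity
is handled by Benjamini–Hochberg step-up q-values; `bhQvalues(p, m_total)`
deliberately takes the *total* test count as a separate argument so that
genome-wide q-values can be recomputed for a printed subset of top SNPs —
ranks come from the subset, the multiplier from the genome.

The overall comparison (`overallHomozygosityTest`) compares per-sample
proportions of homozygous calls with a Student t-test, one-sided by
default with the alternative that the STS mean is lower; the direction is
an argument because the one-sidedness encodes a substantive hypothesis
(higher homozygosity favours survival), not a statistical necessity.

# ROH detection

## Why 75 SNPs

With mean per-SNP heterozygosity $\bar h$, a run of $L$ homozygous calls
arises by chance with probability $(1-\bar h)^L$, giving a genome-wide
expectation $(1-\bar h)^L \, m \, n$ across $m$ SNPs and $n$ individuals.
`minRunLength()` returns the smallest $L$ driving this below a tolerance
$\alpha$.  At the study scale ($\bar h = 0.35$, $m = 232\,478$,
$n = 675$, $\alpha = 0.05$) the answer is $L = 51$ with expectation
$0.045$ (~4%).  Because linkage disequilibrium makes adjacent genotypes
non-independent, 51 *independent* calls are approximated by 75
*consecutive* array SNPs; greedy LD pruning (`ldPrune`, $r^2 > 0.8$
within 250 kb) supplies the tag-group count that justifies the ~30%
redundancy factor.  Pruning is *not* applied before calling — the caller
runs on the full SNP set; a pipeline option can enable it.

## The caller

`callROHs()` slides a `window_snps = 50` SNP window one SNP at a time
within each sample and chromosome.  A window is homozygous iff it has at
most `window_het_max = 0` heterozygous and `window_missing_max = 3`
missing calls.  Each SNP's hit proportion is the fraction of windows
containing it that are homozygous; the SNP is eligible iff that
proportion reaches `window_hit_threshold = 0.05` and the SNP itself is
not heterozygous (the explicit SNP-level exclusion pins down the edge
behaviour that the window rule alone leaves ambiguous).  Maximal runs of
eligible SNPs are candidates; a candidate is emitted iff it has
`min_snps = 75` SNPs, spans `min_kb = 1000` kb, contains no inter-SNP gap
above `max_gap_kb = 1000`, and averages at most
`min_density_kb_per_snp = 50` kb per SNP.  Segment boundaries are the
outermost eligible SNP positions, 1-based inclusive; length in kb is
`(end − start + 1)/1000`.  Chromosomes shorter than the window are
scanned with a single whole-chromosome window.  All parameters are
exposed in `rohParams()`; the missing-calls-per-window value follows the
convention of at most three, and both the 50-SNP window and the 75-SNP
segment minimum are independently configurable because the two roles
(error tolerance vs. final length threshold) are distinct.

A consequence of the hit-proportion rule worth knowing: the first and
last couple of SNPs of a true homozygous tract are covered mostly by
windows that straddle heterozygous background, so calls erode by ~2 SNPs
per edge.  Tracts barely at the 75-SNP minimum can therefore be missed;
recovery is essentially complete from ~80 SNPs upward.

# Pooling and common ROHs

Segments on a chromosome are pooled by transitive physical overlap (for
intervals, components are contiguous once sorted by start, so the sweep
needs no graph machinery).  A pool's consensus is the intersection of its
member intervals.  When the consensus spans fewer than
`min_overlap_snps = 75` SNPs, the member whose removal most enlarges the
consensus SNP count is dropped (ties: first member) until the consensus
is large enough or a single member remains (no pool).  This greedy repair
is our disambiguation of "identical start and end across carriers"; an
exhaustive intersection oracle guards the small cases in the tests, and
the alternative (pairwise-complete overlap pooling) is noted as a design
variant we did not take.

A pool is a *common ROH* when it has at least `min_carriers = 5` carriers
— pinned to ≥5 because the sources phrase the threshold both as "more
than five" and "≥5", and the inclusive reading costs only one integer —
or when its carriers (two or more) all belong to one outcome group
(group-exclusive pools are informative at any size and are flagged).
Carrier association uses the shared chi-square kernel plus a Monte-Carlo
p-value over tables with both margins fixed (hypergeometric construction,
`(1 + k)/(n_{mc} + 1)` estimator, mandatory seed) and the two-sided
Fisher exact test.  Pools spanning a supplied centromere interval are
flagged, since centromeres are SNP deserts that mimic autozygosity.

The FDR non-inferiority comparison computes BH q-values within two
p-value sets over the same region SNPs — the homozygosity test and a
standard allelic (allele-count) association standing in for the
conventional GWAS — and applies a paired one-sided t-test with the
alternative that the ROH-based FDR is smaller.

# Burden and inbreeding

Burden metrics (count, total kb, mean kb per person) are compared by
pooled-variance Student t-tests — Student rather than Welch because the
referenced procedure names the Student test; Welch is an option — overall
and within population strata.  The covariate-adjusted model is
`n_roh ~ group + population` with a Gaussian identity family by default
(the count means are far from zero at study scale, and Gaussian matches
the unnamed family in the source procedure); Poisson-log is exposed.

The permutation-of-regressor-residuals test regresses the group indicator
on the other covariates, permutes the residuals of that regression, and
refits the outcome model with the permuted residuals in place of the
group term; the permutation p is the corrected proportion of permuted
term p-values at or below the observed one.  For the Gaussian family the
term p-value is computed by exact partial-regression algebra (identical
to the `glm` Wald p, verified in tests), which keeps 500-permutation runs
in milliseconds.

Inbreeding estimators follow the GCTA convention with sample allele
frequencies $p_j$ and $h_j = 2p_j(1-p_j)$:
$F_I = \overline{(x-2p)^2/h} - 1$, $F_{II} = \overline{1 - x(2-x)/h}$,
$F_{III} = \overline{(x^2 - (1+2p)x + 2p^2)/h}$, genome-wide and per
chromosome.  All three are unbiased for the Bernoulli-autozygosity
simulation model (shown analytically and by parameter recovery to
±0.01 at m = 20 000).  Frequencies are pooled across the cohort by
default, mirroring common practice; a per-population option exists
because stratification inflates $F$ when frequencies diverge — with the
package's default Fst = 0.01 cohort, pooled-frequency estimates run
~0.01 high, which is why the recovery validation estimates frequencies
within populations.

$F_{ROH} = \sum L_{ROH} / L_{AUTO}$ sums segments at or above 1000 kb;
centromere-overlapping portions are removed when a centromere table is
given.  $L_{AUTO}$ defaults to the human SNP-mappable autosome length
(2.67×10⁹ bp); pipelines on simulated genomes pass the simulated span.
Per-chromosome variants use the span between the first and last SNP of
the chromosome as the mappable length — a desk-scale choice that avoids
requiring an assembly table; an explicit table is accepted.

Consanguinity correlations (n_roh, total kb, F II, F ROH) are Pearson
with two-sided p-values; samples beyond mean + 6·SD of the ROH count are
excluded from this analysis only, mirroring the practice of removing a
single extreme individual whose leverage would otherwise dominate r.

# Selection statistics

From a polarized haplotype panel: the site-frequency spectrum
($\xi_i$ = sites with derived count $i$), Tajima's
$D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
constants, and the *unnormalized* Fay–Wu
$H = \theta_\pi - \theta_H$, $\theta_H = \sum_i \xi_i\, 2i^2/(n(n-1))$
(the original definition; the variance-normalized variant is an option).
$S = 0$ yields an explicit undefined marker, never 0 — undefined and
"no departure from neutrality" are different statements.

EHH from a core allele is the probability that two random carriers are
identical from the core out to distance x; iHS integrates the ancestral
and derived EHH curves by trapezoid over physical distance on both sides,
truncating where EHH < 0.05 and at gaps > 200 kb (standard practice; both
exposed), and takes ln(iHH_A/iHH_D).  Standardization subtracts the mean
and divides by the SD within 20 derived-frequency bins; singleton or
zero-spread bins are flagged and left unstandardized.  Region annotation
reports windowed max D, min H and max |standardized iHS|.  These scores
are computed from user-supplied panels; published per-region values that
were retrieved from external reference-panel browsers are therefore not
comparison targets for this implementation.

# The synthetic cohort: what it emulates, and what it does not

`simulationConfig()` defaults encode the study design: 675 individuals in
four subpopulations with the observed group split (Umea 77/137, Iceland
141/143, Malmo 43/41, German 79/14), Balding–Nichols divergence at
Fst = 0.01 (intra-European scale), ancestral MAF uniform on (0.05, 0.5)
giving ~35–37% mean heterozygosity, baseline inbreeding F = 0.005 (the
observed F II scale), implanted autozygous segments at 10.61/12.05 per
person (STS/LTS) with lengths 1000 kb + Gamma(2) averaging ~2600 kb, and
0.5% missing calls.  The genome is deliberately desk-scale: 22 autosomes
proportional to the human ones but totalling ~334 Mb, so the default
20 000 SNPs give ~1 SNP/17 kb, close to the array density the design
assumes.  Coverage-based quantities (e.g. F_ROH) are therefore larger
than their human-genome counterparts by the genome-scaling factor; tests
compare against the simulated span, never the human constant.

The generator draws sites independently by default (a first-order
linkage option exists but is off): implanted segments supply all the
run structure the caller needs, and independent sites keep the chance-run
null analytic — which is exactly what the calibration tests check.
Consequences: passing tests demonstrate correctness of the algorithms
under the stated generative model, not robustness to real-data LD,
genotyping artefacts, or array ascertainment.  Haplotype panels are
likewise generated directly from a specified SFS rather than by
coalescent simulation; they exercise the statistics' definitions, not
population-genetic realism.

# Numerical and validation choices

Problem sizes: the validation suite simulates 675 × 20 000 cohorts for
parameter recovery (inbreeding recovered to ±0.01; implant recovery
≥95% with ±window breakpoint tolerance; false positives bounded by the
run-length formula), 5 000-SNP null cohorts at the study's 340/335 group
sizes for p-value uniformity (the equal-sized 250/250 variant has fewer
distinct 2×2 tables and its discreteness trips the KS test — a property
of the test, not the statistic), and 200-replicate permutation
calibrations at n_perm = 500.  Brute-force oracles (pairwise-difference
D and H, pairwise-identity EHH, double-loop BH, full-intersection
pooling, closed-form t) agree with the implementations to 1e-10.

Degenerate inputs are explicit: zero-marginal tables are flagged with
p = 1, not dropped silently; all-missing SNPs carry undefined MAF;
samples without segments appear with zero burden; undefined selection
statistics propagate as NA markers.  Ties in greedy pruning keep the
lower-bp variant, and greedy pool repair drops the first of tied members,
so every run is deterministic; all stochastic stages (simulation,
Monte-Carlo tables, permutations) take explicit seeds and reproduce
bit-identically.

# Known limitations

Single-threaded R throughout (adequate at the supported scales); no
binary PED/BED support; no sex chromosomes; no IBD matching between
individuals; no CNV screening; the FDR non-inferiority comparator is an
allelic chi-square rather than a full external GWAS; EHH/iHS use physical
distance unless a genetic map is supplied.
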