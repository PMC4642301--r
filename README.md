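# rohsurv

Case-only analysis of genomic homozygosity and survival outcome from SNP
array genotypes.

## The problem

In a case-only survival design, patients are split into two outcome groups
— short-time survivors (STS) and long-time survivors (LTS) — and the
question is whether genomic homozygosity differs between them: at single
SNPs, as runs of homozygosity (ROH), and as genome-wide inbreeding.
Standard co-dominant GWAS misses recessively acting loci; homozygosity
analysis is the complementary view.  `rohsurv` implements that analysis
end to end for diploid SNP genotypes in the PLINK text PED/MAP dialect,
with a synthetic-cohort generator so every stage can be validated without
access to patient data.

## What it computes

- **Per-SNP homozygosity association.** For each SNP, the 2×2 table of
  homozygote/heterozygote counts by outcome group is tested with the
  uncorrected Pearson chi-square, `χ² = N(ad−bc)²/(r₁r₂c₁c₂)` on 1 df,
  with Benjamini–Hochberg step-up q-values `q(i) = min_{j≥i} p(j)·m/j`
  computed against the full genome-wide test count `m`.
- **ROH detection.** The minimum believable run length is derived from the
  chance-run expectation `(1−h̄)^L · m · n < α` (with the study-scale
  inputs h̄ = 0.35, m = 232 478, n = 675 this gives L = 51, motivating a
  75-SNP minimum under linkage disequilibrium); segments are then called by
  a sliding window (50 SNPs, 0 heterozygous, ≤3 missing per window, 5% hit
  proportion) with emission thresholds of ≥75 SNPs, >1000 kb, ≤1000 kb
  gaps and ≤50 kb/SNP.  Greedy r² > 0.8 LD pruning within 250 kb supplies
  the tag-group count behind the degrees-of-freedom argument.
- **Common ROH regions.** Overlapping segments are pooled transitively;
  each pool's consensus is the intersection of its members, repaired by
  greedy member dropping when it spans fewer than 75 SNPs.  Pools with ≥5
  carriers — or exclusive to one outcome group — are *common ROHs*, tested
  by carrier chi-square with Monte-Carlo (margin-fixed) and Fisher exact
  p-values, a one-tailed region homozygosity t-test, and a paired
  one-sided t-test of BH-FDR non-inferiority against single-SNP allelic
  p-values over the same SNPs.
- **Burden and inbreeding.** Per-person ROH counts and lengths (Student
  t-tests, population-adjusted GLM, permutation of regressor residuals);
  GCTA-convention inbreeding estimators F I (variance of additive values),
  F II (excess homozygosity), F III (uniting-gametes correlation), and
  `F_ROH = ΣL_ROH / L_AUTO` with centromere exclusion; correlations among
  consanguinity measures.
- **Selection statistics.** Tajima's D, Fay–Wu's H, EHH and iHS computed
  from phased haplotype panels, with windowed region annotation
  (max D, min H, max |standardized iHS|).
- **Simulation.** Balding–Nichols population structure
  (`Beta(p(1−Fst)/Fst, (1−p)(1−Fst)/Fst)`), per-individual inbreeding
  (`P(2)=p²+Fpq, P(1)=2pq(1−F), P(0)=q²+Fpq`), implanted autozygous
  segments with group-specific rates, and haplotype panels with a
  controllable site-frequency spectrum and optional partial sweeps.

Genotypes travel as a `GenotypeExperiment` (a `RangedSummarizedExperiment`
with an integer `codes` assay counting A1 copies; `NA` = missing call);
ROH segments and regions are `GRanges`.

## Worked example

```r
library(rohsurv)

cfg <- list(
  simulate = list(n_populations = 2L, pop_sizes_sts = c(40L, 40L),
                  pop_sizes_lts = c(40L, 40L), m_variants = 5000L,
                  chrom_lengths = c("1" = 20000000L, "2" = 20000000L,
                                    "3" = 20000000L, "4" = 20000000L),
                  inbreeding_f = 0.01, roh_rate = c(STS = 4, LTS = 6),
                  pop_names = c("North", "South"), seed = 42),
  stats = list(n_mc = 1000L, n_perm = 500L, seed = 42))
res <- runPipeline(cfg, "demo_out")
cat(readLines("demo_out/report.txt"), sep = "\n")
```

```
rohsurv pipeline report (seed 42)
samples: 160 (STS=80, LTS=80); variants: 5000
overall homozygosity: 0.6838 vs 0.7094 (one-sided p = 5.05e-10)
top SNP: snp4280 chi2 = 16.61 p = 4.6e-05 q = 0.13
ROH segments: 677; mean per person 3.35 vs 5.11 (t p = 3.31e-10)
GLM group p = 3.29e-10; permutation p = 0.002
pools: 4; common ROHs: 3
best common ROH: chr2:17634242-18752168 carriers 3/8 (MC p = 0.229)
mean F_II 0.1216 vs 0.1928 (t p = 1.11e-09); mean F_ROH 0.1147 vs 0.1820
```

This simulated cohort implants 4 (STS) vs 6 (LTS) autozygous segments per
person on a small 4-chromosome genome.  The report shows the expected
signature: LTS carry more ROHs per person (3.35 vs 5.11), the
population-adjusted model and the permutation test both confirm the group
effect, and the inbreeding coefficients are correspondingly higher in LTS.
The implant rates are deliberately large here so the effect is visible at
n = 160; study-scale defaults are in `simulationConfig()`.  Per-stage
tables (per-SNP association, segments, burden, common regions, inbreeding)
are written as TSVs next to the report.

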