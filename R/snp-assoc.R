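#' Per-SNP homozygote/heterozygote counts by survival group
#'
#' For each variant, counts homozygous (codes 0 or 2) and heterozygous
#' (code 1) calls separately in each outcome group.  Missing calls are
#' excluded per SNP, so group totals vary from SNP to SNP.
#'
#' @param x a [GenotypeExperiment-class].
#' @param groups optional two-level factor overriding `survivalGroup(x)`.
#' @param levels group level order, `c(reference, comparison)`; defaults to
#'   `c("STS", "LTS")` when present.
#' @return data frame with `hom_1, het_1, hom_2, het_2` (suffix 1 = first
#'   level) and a `degenerate` flag for SNPs with zero non-missing calls.
#' @export
homHetCounts <- function(x, groups = survivalGroup(x),
                         levels = .groupLevels(groups)) {
  g <- genotypes(x)
  groups <- factor(groups, levels = levels)
  stopifnot(nlevels(groups) == 2L, !anyNA(groups))
  g1 <- g[, groups == levels[1L], drop = FALSE]
  g2 <- g[, groups == levels[2L], drop = FALSE]
  out <- data.frame(
    variant_id = rownames(g),
    hom_1 = rowSums(g1 == 0L | g1 == 2L, na.rm = TRUE),
    het_1 = rowSums(g1 == 1L, na.rm = TRUE),
    hom_2 = rowSums(g2 == 0L | g2 == 2L, na.rm = TRUE),
    het_2 = rowSums(g2 == 1L, na.rm = TRUE))
  out$degenerate <- (out$hom_1 + out$het_1 + out$hom_2 + out$het_2) == 0L
  rownames(out) <- NULL
  out
}

.groupLevels <- function(groups) {
  lv <- levels(factor(groups))
  if (setequal(lv, c("STS", "LTS"))) c("STS", "LTS") else lv
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' The shared association kernel: `chi2 = N(ad - bc)^2 / (r1 r2 c1 c2)` with
#' the upper-tail p-value on 1 df.  Tables with a zero marginal are flagged
#' degenerate and returned with `chi2 = 0`, `p = 1`.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = states; vectors are
#'   accepted (vectorized over tables).
#' @return data frame with `chi2`, `p`, `degenerate`.
#' @examples
#' chi2Test2x2(201, 139, 137, 198)  # chi2 = 22.41, p = 2.2e-6
#' @export
chi2Test2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degen <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  chi2 <- ifelse(degen, 0,
                 N * (a * d - b * c)^2 /
                   pmax(1, r1) / pmax(1, r2) / pmax(1, c1) / pmax(1, c2))
  p <- ifelse(degen, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = p, degenerate = degen)
}

#' Benjamini-Hochberg step-up q-values with an external test count
#'
#' `q_(i) = min_{j >= i} p_(j) * m_total / j`, capped at 1 and mapped back
#' to input order.  `m_total` may exceed the number of supplied p-values,
#' so genome-wide q-values can be recomputed for a printed subset of top
#' SNPs (ranks are still 1..k within the subset, the multiplier uses the
#' full test count).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m_total total number of tests; default `length(p)`.
#' @return q-values in input order.
#' @export
bhQvalues <- function(p, m_total = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (m_total < length(p))
    stop("m_total must be at least the number of p-values")
  k <- length(p)
  if (!k) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m_total / seq_len(k)))))
  q <- numeric(k)
  q[o] <- q_sorted
  q
}

#' Genome-wide SNP-by-SNP homozygosity association
#'
#' Runs [homHetCounts()] and [chi2Test2x2()] over all variants and attaches
#' BH q-values computed against `m_total` tests (degenerate SNPs are
#' excluded from testing and carry `NA` statistics).
#'
#' @inheritParams homHetCounts
#' @param m_total total test count for the FDR; defaults to the number of
#'   non-degenerate SNPs.
#' @return data frame sorted as input: id, chrom, bp, counts, chi2, p, q.
#' @export
snpAssociation <- function(x, groups = survivalGroup(x),
                           levels = .groupLevels(groups), m_total = NULL) {
  cnt <- homHetCounts(x, groups, levels)
  rr <- variantInfo(x)
  res <- chi2Test2x2(cnt$hom_1, cnt$het_1, cnt$hom_2, cnt$het_2)
  res$chi2[cnt$degenerate] <- NA_real_
  res$p[cnt$degenerate] <- NA_real_
  ok <- !cnt$degenerate
  if (is.null(m_total)) m_total <- sum(ok)
  q <- rep(NA_real_, nrow(cnt))
  q[ok] <- bhQvalues(res$p[ok], m_total)
  data.frame(variant_id = cnt$variant_id,
             chrom = as.character(seqnames(rr)), bp = start(rr),
             cnt[, c("hom_1", "het_1", "hom_2", "het_2")],
             chi2 = res$chi2, p = res$p, q = q,
             degenerate = cnt$degenerate)
}

#' Per-SNP allelic association between groups
#'
#' Standard GWAS-style allele-count test: for each variant, the 2x2 table
#' of A1/A2 allele counts by outcome group is tested with the Pearson
#' chi-square kernel.  Used as the single-SNP comparator in the FDR
#' non-inferiority analysis of common ROH regions.
#'
#' @inheritParams homHetCounts
#' @return data frame with allele counts, `chi2`, `p`.
#' @export
allelicAssociation <- function(x, groups = survivalGroup(x),
                               levels = .groupLevels(groups)) {
  g <- genotypes(x)
  groups <- factor(groups, levels = levels)
  g1 <- g[, groups == levels[1L], drop = FALSE]
  g2 <- g[, groups == levels[2L], drop = FALSE]
  a1_1 <- rowSums(g1, na.rm = TRUE)
  n1 <- 2L * rowSums(!is.na(g1))
  a1_2 <- rowSums(g2, na.rm = TRUE)
  n2 <- 2L * rowSums(!is.na(g2))
  res <- chi2Test2x2(a1_1, n1 - a1_1, a1_2, n2 - a1_2)
  data.frame(variant_id = rownames(g), a1_1 = a1_1, a2_1 = n1 - a1_1,
             a1_2 = a1_2, a2_2 = n2 - a1_2, chi2 = res$chi2, p = res$p,
             degenerate = res$degenerate)
}

#' Overall proportion-homozygous comparison between groups
#'
#' Per-sample proportion of homozygous calls among non-missing calls over
#' the whole SNP set, compared between the outcome groups with a Student
#' t-test (one-sided by default, alternative: first group's mean is lower).
#'
#' @inheritParams homHetCounts
#' @param alternative `"less"` (default; first level lower), `"greater"`,
#'   or `"two.sided"`.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return list with `mean_1`, `mean_2`, `p`, `proportions` per sample.
#' @export
overallHomozygosityTest <- function(x, groups = survivalGroup(x),
                                    levels = .groupLevels(groups),
                                    alternative = "less", var_equal = TRUE) {
  g <- genotypes(x)
  groups <- factor(groups, levels = levels)
  hom <- colSums(g == 0L | g == 2L, na.rm = TRUE)
  called <- colSums(!is.na(g))
  prop <- hom / called
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  tt <- t.test(prop[groups == levels[1L]], prop[groups == levels[2L]],
               alternative = alternative, var.equal = var_equal)
  list(mean_1 = mean(prop[groups == levels[1L]]),
       mean_2 = mean(prop[groups == levels[2L]]),
       p = tt$p.value, proportions = prop)
}
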