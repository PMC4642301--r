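.consensus_snp_count <- function(start, end, pos) {
  cs <- max(start); ce <- min(end)
  if (cs > ce) 0L else sum(pos >= cs & pos <= ce)
}

#' Pool overlapping ROH segments into consensus regions
#'
#' Segments on the same chromosome are grouped by transitive physical
#' overlap (for intervals, these components are contiguous once sorted by
#' start).  Each pool's consensus is the intersection of its member
#' intervals.  Pools whose consensus spans fewer than `min_overlap_snps`
#' SNPs are repaired greedily: the member whose removal most enlarges the
#' consensus SNP count is dropped (ties: first member) until the consensus
#' is large enough or only one member remains, in which case the pool is
#' discarded.  Singleton segments never form a pool.
#'
#' @param segments `GRanges` from [callROHs()] (needs `sample_id` mcol).
#' @param x the [GenotypeExperiment-class] supplying variant positions and
#'   sample groups.
#' @param min_overlap_snps minimum SNPs in the consensus region.
#' @param centromeres optional `GRanges` of centromere intervals; pools
#'   whose consensus overlaps one are flagged.
#' @return data frame, one row per pool: `chrom`, `consensus_start_bp`,
#'   `consensus_end_bp`, `consensus_n_snps`, `n_carriers`, `carriers_1`,
#'   `carriers_2` (group-level order as in [homHetCounts()]),
#'   `spans_centromere`, plus a `members` list-column of per-member data
#'   frames.
#' @export
poolROHs <- function(segments, x, min_overlap_snps = 75L,
                     centromeres = NULL) {
  rr <- variantInfo(x)
  vchr <- as.character(seqnames(rr)); vpos <- start(rr)
  groups <- survivalGroup(x)
  lv <- .groupLevels(groups)
  grp_of <- setNames(as.character(groups), colnames(x))

  seg <- data.frame(chrom = as.character(seqnames(segments)),
                    start = start(segments), end = end(segments),
                    sample_id = mcols(segments)$sample_id)
  seg <- seg[order(seg$chrom, seg$start, seg$end, seg$sample_id), ]
  pools <- list()
  for (cc in unique(seg$chrom)) {
    sc <- seg[seg$chrom == cc, , drop = FALSE]
    run_end <- cummax(sc$end)
    comp <- cumsum(c(TRUE, sc$start[-1L] > run_end[-nrow(sc)]))
    pos_c <- vpos[vchr == cc]
    for (k in unique(comp)) {
      mem <- sc[comp == k, , drop = FALSE]
      if (nrow(mem) < 2L) next
      repeat {
        cnt <- .consensus_snp_count(mem$start, mem$end, pos_c)
        if (cnt >= min_overlap_snps || nrow(mem) <= 2L) break
        gains <- vapply(seq_len(nrow(mem)), function(i)
          .consensus_snp_count(mem$start[-i], mem$end[-i], pos_c),
          integer(1))
        mem <- mem[-which.max(gains), , drop = FALSE]
      }
      cnt <- .consensus_snp_count(mem$start, mem$end, pos_c)
      if (cnt < min_overlap_snps || nrow(mem) < 2L) next
      cs <- max(mem$start); ce <- min(mem$end)
      carriers <- unique(mem$sample_id)
      gtab <- table(factor(grp_of[carriers], levels = lv))
      cen <- FALSE
      if (!is.null(centromeres))
        cen <- any(as.character(seqnames(centromeres)) == cc &
                     start(centromeres) <= ce & end(centromeres) >= cs)
      pools[[length(pools) + 1L]] <-
        list(chrom = cc, consensus_start_bp = cs, consensus_end_bp = ce,
             consensus_n_snps = cnt, n_carriers = length(carriers),
             carriers_1 = as.integer(gtab[[1L]]),
             carriers_2 = as.integer(gtab[[2L]]),
             spans_centromere = cen, members = mem)
    }
  }
  if (!length(pools))
    return(data.frame(chrom = character(), consensus_start_bp = integer(),
                      consensus_end_bp = integer(),
                      consensus_n_snps = integer(), n_carriers = integer(),
                      carriers_1 = integer(), carriers_2 = integer(),
                      spans_centromere = logical(),
                      members = I(list())))
  out <- do.call(rbind, lapply(pools, function(p)
    data.frame(chrom = p$chrom, consensus_start_bp = p$consensus_start_bp,
               consensus_end_bp = p$consensus_end_bp,
               consensus_n_snps = p$consensus_n_snps,
               n_carriers = p$n_carriers, carriers_1 = p$carriers_1,
               carriers_2 = p$carriers_2,
               spans_centromere = p$spans_centromere)))
  out$members <- I(lapply(pools, `[[`, "members"))
  attr(out, "group_levels") <- lv
  rownames(out) <- NULL
  out
}

#' Select common ROH regions
#'
#' A pool becomes a common ROH when it has at least `min_carriers` carriers,
#' or when all of its carriers (two or more) belong to one outcome group
#' (group-exclusive pools are kept regardless of size).
#'
#' @param pools output of [poolROHs()].
#' @param min_carriers carrier threshold for non-exclusive pools.
#' @return the selected rows with an `is_group_exclusive` flag.
#' @export
selectCommonROHs <- function(pools, min_carriers = 5L) {
  if (!nrow(pools)) {
    pools$is_group_exclusive <- logical(0)
    return(pools)
  }
  excl <- (pools$carriers_1 == 0L | pools$carriers_2 == 0L) &
    pools$n_carriers >= 2L
  keep <- pools$n_carriers >= min_carriers | excl
  out <- pools[keep, , drop = FALSE]
  out$is_group_exclusive <- excl[keep]
  rownames(out) <- NULL
  out
}

#' Carrier association of a common ROH with the outcome group
#'
#' Tests the 2x2 table carrier/non-carrier x group with the Pearson
#' chi-square kernel (no continuity correction), a Monte-Carlo p-value over
#' tables drawn with both margins fixed (hypergeometric construction), and
#' the two-sided Fisher exact test.
#'
#' @param carriers_1,carriers_2 carrier counts per group.
#' @param n_1,n_2 group sizes.
#' @param n_mc Monte-Carlo table draws.
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return list with `chi2`, `p_mc`, `p_fisher`, `degenerate`.
#' @export
carrierAssociation <- function(carriers_1, carriers_2, n_1, n_2,
                               n_mc = 2000L, seed = 1L) {
  stopifnot(carriers_1 <= n_1, carriers_2 <= n_2)
  a <- carriers_1; b <- n_1 - carriers_1
  cc <- carriers_2; d <- n_2 - carriers_2
  obs <- chi2Test2x2(a, b, cc, d)
  if (a + cc == 0L)
    return(list(chi2 = 0, p_mc = 1, p_fisher = 1, degenerate = TRUE))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  a_star <- rhyper(n_mc, m = n_1, n = n_2, k = a + cc)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  chi2_star <- chi2Test2x2(a_star, n_1 - a_star,
                           (a + cc) - a_star, n_2 - ((a + cc) - a_star))$chi2
  p_mc <- (1 + sum(chi2_star >= obs$chi2 - 1e-12)) / (n_mc + 1)
  p_f <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
  list(chi2 = obs$chi2, p_mc = p_mc, p_fisher = p_f,
       degenerate = obs$degenerate)
}

#' Region-level proportion-homozygous t-test
#'
#' Within the region's SNPs, computes each sample's proportion of
#' homozygous non-missing genotypes and compares the groups with a
#' one-sided Student t-test (alternative: first group's mean is lower).
#'
#' @param x a [GenotypeExperiment-class].
#' @param chrom,start_bp,end_bp region coordinates (1-based inclusive).
#' @inheritParams overallHomozygosityTest
#' @return list with group means and `p`.
#' @export
regionHomozygosityTest <- function(x, chrom, start_bp, end_bp,
                                   groups = survivalGroup(x),
                                   levels = .groupLevels(groups),
                                   alternative = "less", var_equal = TRUE) {
  rr <- variantInfo(x)
  j <- which(as.character(seqnames(rr)) == as.character(chrom) &
               start(rr) >= start_bp & start(rr) <= end_bp)
  if (!length(j)) stop("region contains no SNPs")
  g <- genotypes(x)[j, , drop = FALSE]
  groups <- factor(groups, levels = levels)
  hom <- colSums(g == 0L | g == 2L, na.rm = TRUE)
  called <- colSums(!is.na(g))
  prop <- hom / pmax(called, 1L)
  tt <- t.test(prop[groups == levels[1L]], prop[groups == levels[2L]],
               alternative = alternative, var.equal = var_equal)
  list(mean_1 = mean(prop[groups == levels[1L]]),
       mean_2 = mean(prop[groups == levels[2L]]),
       p = tt$p.value)
}

#' FDR non-inferiority of ROH-based vs GWAS p-values
#'
#' Benjamini-Hochberg q-values are computed within each p-value set over
#' the same SNPs, then compared by a paired one-sided t-test with the
#' alternative that the ROH-based FDR is smaller.
#'
#' @param p_roh,p_gwas p-value vectors over the same SNPs.
#' @return list with `p`, `mean_diff` (ROH minus GWAS), and the two
#'   q-value vectors.
#' @export
fdrNoninferiority <- function(p_roh, p_gwas) {
  if (length(p_roh) != length(p_gwas))
    stop("p-value sets must cover the same SNPs")
  q_roh <- bhQvalues(p_roh)
  q_gwas <- bhQvalues(p_gwas)
  d <- q_roh - q_gwas
  if (all(d == 0))
    return(list(p = 0.5, mean_diff = 0, q_roh = q_roh, q_gwas = q_gwas))
  tt <- t.test(q_roh, q_gwas, paired = TRUE, alternative = "less")
  list(p = tt$p.value, mean_diff = mean(d), q_roh = q_roh, q_gwas = q_gwas)
}
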