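#' Parameters of the sliding-window ROH caller
#'
#' Defaults follow the PLINK homozygosity scan convention: 50-SNP windows
#' with no heterozygous call and at most 3 missing calls allowed per window,
#' SNP hit-proportion threshold 0.05, and final segments of at least 75 SNPs
#' spanning more than 1000 kb, with no inter-SNP gap above 1000 kb and at
#' most 50 kb per SNP.
#'
#' @param window_snps sliding window size in SNPs.
#' @param window_het_max maximum heterozygous calls per homozygous window.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param window_hit_threshold minimum proportion of homozygous windows
#'   covering a SNP for the SNP to be eligible.
#' @param min_snps minimum SNPs per emitted segment.
#' @param min_kb minimum segment length in kb.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment.
#' @param min_density_kb_per_snp maximum kb per SNP inside a segment.
#' @return a validated list of class `ROHParams`.
#' @export
rohParams <- function(window_snps = 50L, window_het_max = 0L,
                      window_missing_max = 3L, window_hit_threshold = 0.05,
                      min_snps = 75L, min_kb = 1000, max_gap_kb = 1000,
                      min_density_kb_per_snp = 50) {
  stopifnot(window_snps >= 1L, window_het_max >= 0L,
            window_missing_max >= 0L,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_snps >= 1L, min_kb >= 0, max_gap_kb >= 0,
            min_density_kb_per_snp > 0)
  structure(list(window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_threshold = window_hit_threshold,
                 min_snps = as.integer(min_snps), min_kb = min_kb,
                 max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp),
            class = "ROHParams")
}

#' Minimum run length against chance homozygosity
#'
#' With mean per-SNP heterozygosity `h`, a run of `L` consecutive homozygous
#' calls arises by chance with probability `(1-h)^L`; across `n_snps` SNPs
#' and `n_samples` individuals the expected number of chance runs is
#' `(1-h)^L * n_snps * n_samples`.  Returns the smallest `L` driving that
#' expectation below `alpha`, plus the expectation at that `L`.  With the
#' study-scale inputs (h = 0.35, 232478 SNPs, 675 samples, alpha = 0.05)
#' this gives `L = 51` with expected count 0.04.
#'
#' @param mean_het mean heterozygosity in `(0, 1)`.
#' @param n_snps,n_samples genome-wide SNP and sample counts.
#' @param alpha tolerated expected number of chance runs.
#' @return list with `L_min` and `expected_count`.
#' @export
minRunLength <- function(mean_het, n_snps, n_samples, alpha = 0.05) {
  if (mean_het <= 0 || mean_het >= 1) stop("mean_het must be in (0, 1)")
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_samples >= 1)
  L <- ceiling((log(alpha) - log(n_snps) - log(n_samples)) /
                 log(1 - mean_het))
  # guard against floating-point boundary effects around the closed form
  while (L > 1 && (1 - mean_het)^(L - 1) * n_snps * n_samples < alpha)
    L <- L - 1
  while ((1 - mean_het)^L * n_snps * n_samples >= alpha) L <- L + 1
  list(L_min = as.integer(L),
       expected_count = (1 - mean_het)^L * n_snps * n_samples)
}

#' Greedy LD pruning into tag groups
#'
#' Scans variants left to right within each chromosome.  A variant joins
#' the tag group of the nearest previously kept variant within `window_bp`
#' whose genotype correlation satisfies `r^2 > r2_max`; otherwise it starts
#' a new group and is kept as the group representative.  `r^2` is computed
#' on pairwise-complete genotype codes.  Monomorphic variants (undefined
#' `r^2`) always start their own group.
#'
#' @param x a [GenotypeExperiment-class] (variants sorted by position).
#' @param r2_max squared-correlation threshold to declare tagging.
#' @param window_bp maximum distance to search for a tagging variant.
#' @return list with `kept` (integer indices of representatives) and
#'   `n_tag_groups`.
#' @export
ldPrune <- function(x, r2_max = 0.8, window_bp = 250000) {
  g <- genotypes(x)
  rr <- variantInfo(x)
  chr <- as.character(seqnames(rr)); pos <- start(rr)
  kept <- integer(0)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    kept_c <- integer(0)
    for (j in idx) {
      cand <- kept_c[pos[j] - pos[kept_c] <= window_bp]
      tagged <- FALSE
      if (length(cand)) {
        for (kk in rev(cand)) {         # nearest kept first
          r <- suppressWarnings(cor(g[j, ], g[kk, ],
                                    use = "pairwise.complete.obs"))
          if (!is.na(r) && r * r > r2_max) { tagged <- TRUE; break }
        }
      }
      if (!tagged) kept_c <- c(kept_c, j)
    }
    kept <- c(kept, kept_c)
  }
  list(kept = kept, n_tag_groups = length(kept))
}

#' Sliding-window ROH caller
#'
#' Scans each sample and chromosome with a window of `window_snps` SNPs
#' advanced one SNP at a time.  A window is homozygous when it contains at
#' most `window_het_max` heterozygous and `window_missing_max` missing
#' calls.  Each SNP's hit proportion is the fraction of windows containing
#' it that are homozygous; a SNP is eligible when that proportion reaches
#' `window_hit_threshold` and the SNP itself is not heterozygous.  Maximal
#' runs of consecutive eligible SNPs become candidate segments, emitted
#' when they span at least `min_snps` SNPs and `min_kb` kb, contain no
#' inter-SNP gap above `max_gap_kb`, and average at most
#' `min_density_kb_per_snp` kb per SNP.  Chromosomes with fewer SNPs than
#' the window are scanned with a single whole-chromosome window.
#'
#' Segment boundaries are the outermost eligible SNP positions; lengths in
#' kb are `(end - start + 1)/1000` on one-based inclusive coordinates.
#'
#' @param x a [GenotypeExperiment-class].
#' @param params a [rohParams()].
#' @return `GRanges` of segments with metadata columns `sample_id`,
#'   `n_snps`, `length_kb`.
#' @export
callROHs <- function(x, params = rohParams()) {
  g <- genotypes(x)
  rr <- variantInfo(x)
  chr <- as.character(seqnames(rr)); pos <- start(rr)
  chroms <- unique(chr)
  W <- params$window_snps
  out <- vector("list", length(chroms) * ncol(g))
  oi <- 0L
  for (cc in chroms) {
    idx <- which(chr == cc)
    nc <- length(idx)
    bp <- pos[idx]
    gap_ok_at <- c(TRUE, diff(bp) <= params$max_gap_kb * 1000)
    for (s in seq_len(ncol(g))) {
      v <- g[idx, s]
      het <- !is.na(v) & v == 1L
      mis <- is.na(v)
      if (nc < W) {
        hom_win <- sum(het) <= params$window_het_max &&
          sum(mis) <= params$window_missing_max
        prop <- rep(as.numeric(hom_win), nc)
      } else {
        ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
        nw <- nc - W + 1L
        k <- seq_len(nw)
        hom_win <- (ch[k + W] - ch[k]) <= params$window_het_max &
          (cm[k + W] - cm[k]) <= params$window_missing_max
        cw <- cumsum(c(0, hom_win))
        i <- seq_len(nc)
        lo <- pmax(1L, i - W + 1L); hi <- pmin(nw, i)
        prop <- (cw[hi + 1L] - cw[lo]) / (hi - lo + 1L)
      }
      elig <- prop >= params$window_hit_threshold & !het
      if (!any(elig)) next
      r <- rle(elig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (b in which(r$values)) {
        a <- starts[b]; e <- ends[b]
        n_snps <- e - a + 1L
        if (n_snps < params$min_snps) next
        len_kb <- (bp[e] - bp[a] + 1) / 1000
        if (len_kb < params$min_kb) next
        if (e > a && !all(gap_ok_at[(a + 1L):e])) next
        if (len_kb / n_snps > params$min_density_kb_per_snp) next
        oi <- oi + 1L
        out[[oi]] <- data.frame(sample_id = colnames(g)[s], chrom = cc,
                                start_bp = bp[a], end_bp = bp[e],
                                n_snps = n_snps, length_kb = len_kb)
      }
    }
  }
  segs <- if (oi) do.call(rbind, out[seq_len(oi)]) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(),
               n_snps = integer(), length_kb = numeric())
  gr <- GRanges(seqnames = segs$chrom,
                ranges = IRanges(start = segs$start_bp, end = segs$end_bp))
  mcols(gr)$sample_id <- segs$sample_id
  mcols(gr)$n_snps <- segs$n_snps
  mcols(gr)$length_kb <- segs$length_kb
  gr
}

#' Per-sample ROH burden
#'
#' Counts, total and mean segment length (kb) per sample; samples with no
#' segments get zeros (mean flagged undefined via `has_roh`).
#'
#' @param segments `GRanges` from [callROHs()].
#' @param sample_ids character vector of all sample ids (so ROH-free
#'   samples appear with zeros).
#' @return data frame: `sample_id`, `n_roh`, `total_kb`, `mean_kb`,
#'   `has_roh`.
#' @export
burdenPerSample <- function(segments, sample_ids) {
  sid <- factor(mcols(segments)$sample_id, levels = sample_ids)
  n <- as.integer(table(sid))
  tot <- as.numeric(tapply(mcols(segments)$length_kb, sid, sum,
                           default = 0))
  tot[is.na(tot)] <- 0
  data.frame(sample_id = sample_ids, n_roh = n, total_kb = tot,
             mean_kb = ifelse(n > 0L, tot / pmax(n, 1L), 0),
             has_roh = n > 0L)
}
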