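# fixtures built in code; no files on disk

# tiny genotype container from a code matrix (variants x samples)
makeGX <- function(codes, chrom = NULL, bp = NULL, group = NULL,
                   population = NULL) {
  codes <- as.matrix(codes)
  m <- nrow(codes); n <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) {
    bp <- integer(m)
    for (cc in unique(chrom)) {
      j <- chrom == cc
      bp[j] <- seq_len(sum(j)) * 1000L
    }
  }
  if (is.null(group)) group <- rep(c("STS", "LTS"), length.out = n)
  if (is.null(population)) population <- rep("pop1", n)
  v <- data.frame(variant_id = sprintf("v%d", seq_len(m)), chrom = chrom,
                  bp = bp, a1 = rep("A", m), a2 = rep("G", m))
  s <- data.frame(sample_id = paste0("s", seq_len(n)),
                  population = population, group = group)
  GenotypeExperiment(codes, v, s)
}

# random genotype matrix with missing calls
randomCodes <- function(m, n, p_missing = 0.05, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:2, m * n, replace = TRUE), m, n)
    g[runif(m * n) < p_missing] <- NA_integer_
    g
  })
}

# brute-force BH step-up (double loop)
bhOracle <- function(p, m_total = length(p)) {
  k <- length(p)
  o <- order(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    best <- Inf
    for (j in i:k) best <- min(best, p[o[j]] * m_total / j)
    q[o[i]] <- min(1, best)
  }
  q
}

# naive Tajima's D / Fay-Wu's H straight from a panel (independent path:
# pi from explicit pairwise differences, not from the SFS)
tajimaOracle <- function(h) {
  n <- nrow(h)
  seg <- which(colSums(h) > 0 & colSums(h) < n)
  S <- length(seg)
  if (S == 0) return(NA_real_)
  pi_sum <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi_sum <- pi_sum + sum(h[i, seg] != h[j, seg])
  pi_hat <- pi_sum / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

fayWuOracle <- function(h) {
  n <- nrow(h)
  dc <- colSums(h)
  seg <- which(dc > 0 & dc < n)
  if (!length(seg)) return(NA_real_)
  pi_sum <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi_sum <- pi_sum + sum(h[i, seg] != h[j, seg])
  pi_hat <- pi_sum / choose(n, 2)
  theta_h <- sum(2 * dc[seg]^2) / (n * (n - 1))
  pi_hat - theta_h
}

# brute-force EHH from pairwise identity over the core..x span
ehhOracle <- function(h, core, allele, x) {
  carriers <- which(h[, core] == allele)
  span <- min(core, x):max(core, x)
  cnt <- 0
  for (i in seq_along(carriers)[-length(carriers)])
    for (j in (i + 1):length(carriers))
      if (all(h[carriers[i], span] == h[carriers[j], span])) cnt <- cnt + 1
  cnt / choose(length(carriers), 2)
}

# pooled-variance two-sample t statistic and p, by hand
studentOracle <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tstat), df),
              less = pt(tstat, df),
              greater = pt(-tstat, df))
  list(t = tstat, p = p)
}

segGR <- function(sample_id, chrom, start, end, n_snps = NA_integer_) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$sample_id <- sample_id
  S4Vectors::mcols(gr)$n_snps <- n_snps
  S4Vectors::mcols(gr)$length_kb <- (end - start + 1) / 1000
  gr
}
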