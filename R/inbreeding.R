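#' Group comparisons of ROH burden
#'
#' Student (pooled-variance) t-tests of the per-sample burden metrics
#' (`n_roh`, `total_kb`, `mean_kb`) between the outcome groups, overall and
#' within each population stratum.  Strata with an empty group are skipped
#' with a message.
#'
#' @param burden data frame from [burdenPerSample()].
#' @param samples sample annotations (`sample_id`, `population`, `group`).
#' @param levels group level order.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return data frame: stratum, metric, group means, `p`.
#' @export
burdenGroupTests <- function(burden, samples,
                             levels = .groupLevels(samples$group),
                             var_equal = TRUE) {
  stopifnot(identical(burden$sample_id, as.character(samples$sample_id)))
  grp <- factor(samples$group, levels = levels)
  pops <- levels(factor(samples$population))
  rows <- list()
  for (st in c("overall", pops)) {
    in_st <- if (st == "overall") rep(TRUE, nrow(burden))
    else samples$population == st
    g1 <- grp == levels[1L] & in_st
    g2 <- grp == levels[2L] & in_st
    if (sum(g1) < 2L || sum(g2) < 2L) {
      message("stratum '", st, "' skipped: fewer than 2 samples in a group")
      next
    }
    for (metric in c("n_roh", "total_kb", "mean_kb")) {
      v <- burden[[metric]]
      p <- if (var(v[g1]) == 0 && var(v[g2]) == 0) {
        if (mean(v[g1]) == mean(v[g2])) 1 else 0
      } else t.test(v[g1], v[g2], var.equal = var_equal)$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = st, metric = metric,
                   mean_1 = mean(v[g1]), mean_2 = mean(v[g2]), p = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted model of ROH count
#'
#' Fits `n_roh ~ group + population` by `glm()` (Gaussian identity by
#' default, Poisson log optional) and reports the Wald p-value for the
#' group term.  With a single population level the covariate is dropped
#' with a message.
#'
#' @param n_roh per-sample ROH counts.
#' @param group two-level factor.
#' @param population population factor covariate.
#' @param family `"gaussian"` or `"poisson"`.
#' @return list with the fitted `model`, `group_coef`, `group_p`, and the
#'   population-term p-values.
#' @export
glmBurden <- function(n_roh, group, population, family = "gaussian") {
  fam <- switch(family, gaussian = gaussian(), poisson = poisson(),
                stop("family must be 'gaussian' or 'poisson'"))
  group <- factor(group)
  population <- factor(population)
  if (nlevels(population) < 2L) {
    message("single population: covariate dropped")
    fit <- glm(n_roh ~ group, family = fam)
  } else {
    fit <- glm(n_roh ~ group + population, family = fam)
  }
  sm <- summary(fit)$coefficients
  gi <- grep("^group", rownames(sm))
  pop_p <- sm[grep("^population", rownames(sm)), 4L]
  list(model = fit,
       group_coef = unname(sm[gi, 1L]),
       group_p = unname(sm[gi, 4L]),
       population_p = pop_p)
}

#' Permutation-of-regressor-residuals test for the group term
#'
#' Conditional permutation test for one regressor in a covariate-adjusted
#' model: the group indicator is regressed on the remaining covariates, the
#' residuals of that regression are permuted, and the outcome model is
#' refit with the permuted residuals standing in for the group term.  The
#' permutation p-value is the proportion of permuted fits whose term
#' p-value is at most the observed one, with the `(1 + k)/(1 + n_perm)`
#' correction.
#'
#' @inheritParams glmBurden
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed.
#' @return list with `p_perm`, `observed_p`, `n_perm`.
#' @export
permutationRegressorResiduals <- function(n_roh, group, population,
                                          family = "gaussian",
                                          n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation p")
  group <- factor(group)
  population <- factor(population)
  z <- as.numeric(group) - 1
  X_cov <- if (nlevels(population) >= 2L)
    model.matrix(~population) else matrix(1, length(z), 1L)
  res_z <- lm.fit(X_cov, z)$residuals
  if (var(res_z) == 0) stop("degenerate regressor residuals (zero variance)")
  fam <- switch(family, gaussian = gaussian(), poisson = poisson())

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  perms <- replicate(n_perm, sample(res_z))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  if (family == "gaussian") {
    # exact Wald p via partial regression: residualize outcome and term on
    # the covariates, then the term t-statistic is the correlation t with
    # df = n - rank(X_cov) - 1 (identical to the glm summary p)
    qrX <- qr(X_cov)
    ry <- qr.resid(qrX, n_roh)
    df <- length(n_roh) - qrX$rank - 1L
    part_p <- function(w) {
      rw <- qr.resid(qrX, w)
      r <- sum(ry * rw) / sqrt(sum(ry^2) * sum(rw^2))
      tstat <- r * sqrt(df) / sqrt(1 - r^2)
      2 * pt(-abs(tstat), df)
    }
    p_obs <- part_p(res_z)
    p_star <- apply(perms, 2L, part_p)
  } else {
    term_p <- function(w) {
      fit <- glm(n_roh ~ w + X_cov - 1, family = fam)
      summary(fit)$coefficients["w", 4L]
    }
    p_obs <- term_p(res_z)
    p_star <- apply(perms, 2L, term_p)
  }
  k <- sum(p_star <= p_obs + 1e-12)
  list(p_perm = (1 + k) / (1 + n_perm), observed_p = p_obs,
       n_perm = n_perm)
}

#' Genomic inbreeding estimators F I, F II, F III
#'
#' Per-sample moment estimators of the inbreeding coefficient from SNP
#' genotypes, in the GCTA convention, with `p_j` the sample A1 frequency
#' and `h_j = 2 p_j (1 - p_j)`:
#' \itemize{
#'   \item F I -- variance of additive genetic values:
#'     `mean_j[(x_ij - 2 p_j)^2 / h_j] - 1`
#'   \item F II -- excess SNP homozygosity:
#'     `mean_j[1 - x_ij (2 - x_ij) / h_j]`
#'   \item F III -- correlation between uniting gametes:
#'     `mean_j[(x_ij^2 - (1 + 2 p_j) x_ij + 2 p_j^2) / h_j]`
#' }
#' Monomorphic SNPs are excluded; missing genotypes are excluded per SNP
#' and sample.  Returns genome-wide values and, optionally, per-chromosome
#' values.
#'
#' @param x a [GenotypeExperiment-class].
#' @param per_chromosome also compute per-chromosome estimates.
#' @param freq_scope `"pooled"` (default, frequencies from the full sample)
#'   or `"population"` (within each population; population structure
#'   otherwise inflates F).
#' @return data frame with `sample_id`, `F_I`, `F_II`, `F_III` (and a
#'   `chrom` column when `per_chromosome`; genome-wide rows have
#'   `chrom = "genome"`).
#' @export
inbreedingCoeffs <- function(x, per_chromosome = FALSE,
                             freq_scope = c("pooled", "population")) {
  freq_scope <- match.arg(freq_scope)
  g <- genotypes(x)
  rr <- variantInfo(x)
  chr <- as.character(seqnames(rr))

  .freqs <- function(gm) {
    called <- rowSums(!is.na(gm))
    rowSums(gm, na.rm = TRUE) / (2 * called)
  }
  p <- if (freq_scope == "pooled") .freqs(g) else {
    pop <- factor(colData(x)$population)
    pv <- matrix(NA_real_, nrow(g), ncol(g))
    for (lv in levels(pop)) {
      sel <- pop == lv
      pv[, sel] <- .freqs(g[, sel, drop = FALSE])
    }
    pv
  }

  .block <- function(rows) {
    gm <- g[rows, , drop = FALSE]
    pj <- if (is.matrix(p)) p[rows, , drop = FALSE] else p[rows]
    poly <- if (is.matrix(pj)) {
      pr <- rowMeans(pj, na.rm = TRUE); pr > 0 & pr < 1
    } else pj > 0 & pj < 1
    poly[is.na(poly)] <- FALSE
    gm <- gm[poly, , drop = FALSE]
    pj <- if (is.matrix(pj)) pj[poly, , drop = FALSE] else pj[poly]
    h <- 2 * pj * (1 - pj)
    use <- !is.na(gm) & h > 0
    n_use <- colSums(use)
    if (any(n_use == 0L))
      stop("sample with zero usable SNPs in inbreeding computation")
    gm0 <- gm; gm0[!use] <- 0
    f1_num <- (gm0 - 2 * pj)^2 / h; f1_num[!use] <- 0
    f2_num <- 1 - gm0 * (2 - gm0) / h; f2_num[!use] <- 0
    f3_num <- (gm0^2 - (1 + 2 * pj) * gm0 + 2 * pj^2) / h
    f3_num[!use] <- 0
    data.frame(sample_id = colnames(g),
               F_I = colSums(f1_num) / n_use - 1,
               F_II = colSums(f2_num) / n_use,
               F_III = colSums(f3_num) / n_use)
  }

  out <- .block(seq_len(nrow(g)))
  out$chrom <- "genome"
  if (per_chromosome) {
    per <- lapply(unique(chr), function(cc) {
      b <- .block(which(chr == cc)); b$chrom <- cc; b
    })
    out <- rbind(out, do.call(rbind, per))
  }
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH content
#'
#' `F_ROH = sum(L_ROH) / L_AUTO` per sample: the summed length of that
#' sample's ROH segments at or above `min_kb`, divided by the mappable
#' autosomal length.  When a centromere table is supplied, the
#' centromere-overlapping portion of each segment is removed before
#' summation (centromeres are SNP deserts that inflate autozygosity
#' estimates).  The human SNP-mappable autosome length is 2.67e9 bp; for
#' simulated genomes pass the simulated total.
#'
#' @param segments `GRanges` from [callROHs()].
#' @param sample_ids all sample ids.
#' @param l_auto mappable autosomal length in bp.
#' @param centromeres optional `GRanges` of centromere intervals.
#' @param min_kb segment inclusion threshold in kb.
#' @return named numeric vector of per-sample F_ROH.
#' @export
fROH <- function(segments, sample_ids, l_auto = 2.67e9,
                 centromeres = NULL, min_kb = 1000) {
  if (l_auto <= 0) stop("l_auto must be positive")
  keep <- mcols(segments)$length_kb >= min_kb
  segments <- segments[keep]
  len <- width(segments)
  if (!is.null(centromeres) && length(segments)) {
    ov <- findOverlaps(segments, centromeres)
    if (length(ov)) {
      cut <- width(pintersect(segments[S4Vectors::queryHits(ov)],
                              centromeres[S4Vectors::subjectHits(ov)]))
      cut_per_seg <- tapply(cut, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(cut_per_seg))
      len[idx] <- pmax(0L, len[idx] - as.integer(cut_per_seg))
    }
  }
  sid <- factor(mcols(segments)$sample_id, levels = sample_ids)
  tot <- tapply(as.numeric(len), sid, sum, default = 0)
  tot[is.na(tot)] <- 0
  setNames(as.numeric(tot) / l_auto, sample_ids)
}

#' Correlations among consanguinity measures
#'
#' Pairwise Pearson correlations (with two-sided p-values) among the
#' per-sample measures `n_roh`, `total_kb`, `F_II` and `F_ROH`.  Samples
#' whose total ROH count exceeds `mean + outlier_sd * SD` are excluded from
#' this analysis only (extreme individuals otherwise dominate r).
#'
#' @param burden data frame from [burdenPerSample()].
#' @param f_ii per-sample F II (same order).
#' @param f_roh per-sample F_ROH (same order).
#' @param outlier_sd SD multiple for the exclusion rule; `Inf` disables it.
#' @return list with matrices `r` and `p`, and `excluded` sample ids.
#' @export
consanguinityCorrelations <- function(burden, f_ii, f_roh,
                                      outlier_sd = 6) {
  m <- data.frame(n_roh = burden$n_roh, total_kb = burden$total_kb,
                  F_II = f_ii, F_ROH = f_roh)
  stopifnot(nrow(m) >= 3L)
  thr <- mean(burden$n_roh) + outlier_sd * sd(burden$n_roh)
  keep <- burden$n_roh <= thr
  excluded <- burden$sample_id[!keep]
  if (length(excluded))
    message(length(excluded), " outlier sample(s) excluded from correlations")
  m <- m[keep, , drop = FALSE]
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(names(m), names(m)))
  pm <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (var(m[[i]]) == 0 || var(m[[j]]) == 0) next
    ct <- cor.test(m[[i]], m[[j]])
    r[i, j] <- unname(ct$estimate); pm[i, j] <- ct$p.value
  }
  list(r = r, p = pm, excluded = excluded)
}

#' Group tests of inbreeding measures
#'
#' For each inbreeding measure, a one-sided Student t-test (alternative:
#' first group's mean lower) and a linear regression of the measure on the
#' 0/1 group indicator (two-sided coefficient p).
#'
#' @param values data frame of per-sample measures (columns tested
#'   separately).
#' @param groups two-level factor.
#' @param levels group level order.
#' @param alternative t-test sidedness.
#' @return data frame: measure, group means, `p_t`, `p_glm`.
#' @export
inbreedingGroupTests <- function(values, groups,
                                 levels = .groupLevels(groups),
                                 alternative = "less") {
  groups <- factor(groups, levels = levels)
  g1 <- groups == levels[1L]; g2 <- groups == levels[2L]
  if (sum(g1) < 2L || sum(g2) < 2L) stop("each group needs >= 2 samples")
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (var(v[g1]) == 0 && var(v[g2]) == 0) {
      p_t <- if (mean(v[g1]) == mean(v[g2])) 0.5 else NA_real_
      p_glm <- 1
    } else {
      p_t <- t.test(v[g1], v[g2], alternative = alternative,
                    var.equal = TRUE)$p.value
      ind <- as.numeric(groups) - 1
      p_glm <- summary(lm(v ~ ind))$coefficients[2L, 4L]
    }
    data.frame(measure = nm, mean_1 = mean(v[g1]), mean_2 = mean(v[g2]),
               p_t = p_t, p_glm = p_glm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
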