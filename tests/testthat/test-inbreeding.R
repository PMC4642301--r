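test_that("a fully homozygous individual has F_II exactly 1", {
  g <- cbind(c(0L, 2L, 2L, 0L, 2L),                 # fully homozygous
             c(1L, 1L, 0L, 1L, 2L),
             c(0L, 1L, 2L, 1L, 0L),
             c(2L, 0L, 1L, 1L, 1L))
  x <- makeGX(g, group = c("STS", "LTS", "STS", "LTS"))
  inb <- inbreedingCoeffs(x)
  expect_equal(inb$F_II[1], 1)
})

test_that("exact Hardy-Weinberg genotype proportions give F near zero", {
  # constructed null: at each SNP the 8 samples hold codes in exact 1:2:1-free
  # HWE proportions for p = 0.5 (2 hom ref, 4 het, 2 hom alt)
  block <- c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L)
  g <- t(vapply(1:200, function(i) sample(block), integer(8)))
  withr::with_seed(3, g <- t(vapply(1:200, function(i) sample(block),
                                    integer(8))))
  x <- makeGX(g, group = rep(c("STS", "LTS"), 4))
  inb <- inbreedingCoeffs(x)
  # h = 0.5, observed het exactly 0.5 per sample in expectation; the exact
  # per-SNP proportions make the averages vanish up to sampling of columns
  expect_lt(abs(mean(inb$F_I)), 0.05)
  expect_lt(abs(mean(inb$F_II)), 0.05)
  expect_lt(abs(mean(inb$F_III)), 0.05)
})

test_that("deterministic two-sample moments reproduce the estimator algebra", {
  # hand-checkable case: one SNP, p = 0.25, genotype 2
  g <- cbind(c(2L), c(0L), c(0L), c(0L))
  x <- makeGX(g, group = c("STS", "LTS", "STS", "LTS"))
  inb <- inbreedingCoeffs(x)
  p <- 0.25; h <- 2 * p * (1 - p)
  expect_equal(inb$F_I[1], (2 - 2 * p)^2 / h - 1)
  expect_equal(inb$F_II[1], 1)             # no hets anywhere
  expect_equal(inb$F_III[1], (4 - (1 + 2 * p) * 2 + 2 * p^2) / h)
})

test_that("F_ROH is the segment-length ratio with thresholds and centromeres", {
  segs <- segGR(c("a", "a", "b"), "1",
                c(1e6, 10e6, 20e6),
                c(1e6 + 26.7e6 - 1, 10e6 + 0.9e6 - 1, 20e6 + 2e6 - 1))
  f <- fROH(segs, c("a", "b", "c"), l_auto = 2.67e9)
  expect_equal(unname(f["a"]), 0.01)       # 26 700 kb / 2.67e9 bp; 900 kb excluded
  expect_equal(unname(f["b"]), 2e6 / 2.67e9)
  expect_equal(unname(f["c"]), 0)
  # centromere exclusion removes the overlapping portion
  cen <- GenomicRanges::GRanges("1", IRanges::IRanges(21e6, 21.5e6 - 1))
  f2 <- fROH(segs, c("a", "b"), l_auto = 2.67e9, centromeres = cen)
  expect_equal(unname(f2["b"]), (2e6 - 0.5e6) / 2.67e9)
  expect_error(fROH(segs, "a", l_auto = 0), "l_auto")
  # monotone in added segments
  more <- suppressWarnings(c(segs, segGR("b", "2", 1e6, 3e6)))
  f3 <- fROH(more, c("a", "b"), l_auto = 2.67e9)
  expect_gte(f3[["b"]], f[["b"]])
})

test_that("burden group tests match the pooled-variance oracle and strata", {
  burden <- data.frame(sample_id = paste0("s", 1:6),
                       n_roh = c(3L, 5L, 4L, 8L, 9L, 10L),
                       total_kb = c(3000, 5000, 4000, 8000, 9000, 10000),
                       mean_kb = rep(1000, 6), has_roh = TRUE)
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        population = "A",
                        group = rep(c("STS", "LTS"), each = 3))
  res <- burdenGroupTests(burden, samples)
  o <- studentOracle(c(3, 5, 4), c(8, 9, 10))
  row <- res[res$stratum == "overall" & res$metric == "n_roh", ]
  expect_equal(row$p, o$p, tolerance = 1e-12)
  expect_equal(c(row$mean_1, row$mean_2), c(4, 9))
  # identical groups: equal means, p = 1
  burden2 <- burden; burden2$n_roh <- rep(c(3L, 5L, 4L), 2)
  burden2$total_kb <- rep(3000, 6); burden2$mean_kb <- rep(1000, 6)
  res2 <- burdenGroupTests(burden2, samples)
  r2 <- res2[res2$metric == "n_roh" & res2$stratum == "overall", ]
  expect_equal(r2$mean_1, r2$mean_2)
  expect_equal(r2$p, 1)
  # stratum with an empty group is skipped
  samples3 <- samples; samples3$population <- c("A", "A", "A", "A", "B", "B")
  expect_message(res3 <- burdenGroupTests(burden, samples3), "skipped")
  expect_false("B" %in% res3$stratum)
})

test_that("population-adjusted GLM separates confounding from group effects", {
  withr::with_seed(91, {
    # population-only effect: marginal t-test confounds, GLM does not
    nonsig <- vapply(1:30, function(i) {
      pop <- factor(rep(c("A", "B"), each = 50))
      # group unbalanced across populations
      grp <- factor(c(sample(rep(c("STS", "LTS"), c(35, 15))),
                      sample(rep(c("STS", "LTS"), c(15, 35)))),
                    levels = c("STS", "LTS"))
      y <- rpois(100, ifelse(pop == "A", 6, 12))
      glmBurden(y, grp, pop)$group_p > 0.05
    }, logical(1))
    expect_gte(mean(nonsig), 0.9)
  })
  # identical response: zero group coefficient
  suppressMessages({
    fit <- glmBurden(rep(5, 40), factor(rep(c("STS", "LTS"), 20)),
                     factor(rep("A", 40)))
  })
  expect_equal(fit$group_coef, 0)
  # single population drops the covariate with a message
  expect_message(glmBurden(rpois(40, 5), factor(rep(c("STS", "LTS"), 20)),
                           factor(rep("A", 40))), "single population")
})

test_that("permutation test is calibrated, seed-stable, and detects effects", {
  set.seed(17)
  n <- 60; pop <- factor(rep(1:3, each = 20))
  grp <- factor(sample(rep(c("STS", "LTS"), n / 2)))
  y <- rpois(n, 8 + as.integer(pop))
  r1 <- permutationRegressorResiduals(y, grp, pop, n_perm = 300, seed = 5)
  r2 <- permutationRegressorResiduals(y, grp, pop, n_perm = 300, seed = 5)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gt(r1$p_perm, 1 / 301)
  # strong injected effect drives p to the ceiling
  y2 <- y + ifelse(grp == "LTS", 25L, 0L)
  r3 <- permutationRegressorResiduals(y2, grp, pop, n_perm = 300, seed = 5)
  expect_equal(r3$p_perm, 1 / 301)
  expect_warning(permutationRegressorResiduals(y, grp, pop, n_perm = 50,
                                               seed = 1), "n_perm")
})

test_that("consanguinity correlations: closed form, nulls, and outliers", {
  # toy n = 5 against hand-computed r
  b <- data.frame(sample_id = paste0("s", 1:5),
                  n_roh = c(1L, 2L, 3L, 4L, 5L),
                  total_kb = c(1100, 1900, 3200, 3800, 5100),
                  mean_kb = 1, has_roh = TRUE)
  f2 <- c(0.01, 0.02, 0.02, 0.05, 0.06)
  fr <- c(0.001, 0.002, 0.003, 0.004, 0.005)
  cc <- consanguinityCorrelations(b, f2, fr, outlier_sd = Inf)
  hand_r <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(cc$r["n_roh", "total_kb"], hand_r(b$n_roh, b$total_kb),
               tolerance = 1e-12)
  expect_equal(cc$r["n_roh", "F_ROH"], 1)   # exactly proportional
  # independent columns stay uncorrelated at n = 500
  withr::with_seed(23, {
    ok <- vapply(1:20, function(i) {
      b2 <- data.frame(sample_id = as.character(1:500),
                       n_roh = rpois(500, 10),
                       total_kb = rgamma(500, 4, 1e-3), mean_kb = 1,
                       has_roh = TRUE)
      cc2 <- consanguinityCorrelations(b2, rnorm(500, 0, .01),
                                       rnorm(500, 0.01, .003),
                                       outlier_sd = Inf)
      abs(cc2$r["n_roh", "F_II"]) < 0.2
    }, logical(1))
    expect_gte(mean(ok), 0.95)
  })
  # outlier exclusion drops extreme samples from the analysis only
  withr::with_seed(27, {
    b3 <- data.frame(sample_id = paste0("s", 1:100),
                     n_roh = c(rpois(99, 10L), 500L),
                     total_kb = rgamma(100, 4, 1e-3), mean_kb = 1,
                     has_roh = TRUE)
    expect_message(cc3 <- consanguinityCorrelations(b3, rnorm(100, 0, .01),
                                                    rnorm(100, .01, .003),
                                                    outlier_sd = 6),
                   "outlier")
    expect_identical(cc3$excluded, "s100")
  })
})

test_that("inbreeding group tests align t-test and regression", {
  withr::with_seed(29, {
    v <- data.frame(F_II = c(rnorm(20, 0.004, 0.002), rnorm(20, 0.006, 0.002)))
    grp <- factor(rep(c("STS", "LTS"), each = 20), levels = c("STS", "LTS"))
    r <- inbreedingGroupTests(v, grp, alternative = "two.sided")
    # two-sided t equals the regression coefficient p for a binary predictor
    expect_equal(r$p_t, r$p_glm, tolerance = 1e-10)
    # identical groups: difference 0
    v0 <- data.frame(F_II = rep(c(.01, .02), 20))
    r0 <- inbreedingGroupTests(v0, grp)
    expect_equal(r0$mean_1, r0$mean_2)
  })
})

test_that("a small mean inbreeding shift is detectable at study scale", {
  # group difference at the study's effect scale (delta F = 0.002)
  hits <- vapply(1:6, function(i) {
    cfg <- simulationConfig(n_populations = 1L, pop_sizes_sts = 340L,
                            pop_sizes_lts = 335L, m_variants = 20000L,
                            fst = 0, missing_rate = 0,
                            roh_rate = c(STS = 0, LTS = 0),
                            inbreeding_f = 0.004, pop_names = "A",
                            seed = 900 + i)
    sim <- simulateCohort(cfg)
    g <- genotypes(sim$data)
    grp <- survivalGroup(sim$data)
    # raise LTS autozygosity by a further 0.002 at the realized frequencies
    withr::with_seed(950 + i, {
      p <- rowSums(g) / (2 * ncol(g))
      for (s in which(grp == "LTS")) {
        auto <- runif(nrow(g)) < 0.002
        g[auto, s] <- 2L * rbinom(sum(auto), 1L, p[auto])
      }
    })
    x <- makeGX(g, group = as.character(grp))
    inb <- inbreedingCoeffs(x)
    r <- inbreedingGroupTests(inb[, c("F_II", "F_III")],
                              factor(as.character(grp),
                                     levels = c("STS", "LTS")))
    r$p_t[r$measure == "F_II"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})
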