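test_that("SFS summaries match hand counts and a per-site loop", {
  # 4 haplotypes, 3 sites, hand-listed
  h <- rbind(c(1L, 0L, 1L),
             c(0L, 0L, 1L),
             c(0L, 1L, 1L),
             c(0L, 0L, 1L))
  p <- HaplotypePanel(h, c(100L, 200L, 300L))
  s <- sfsSummary(p)
  expect_identical(s$n, 4L)
  expect_identical(s$S, 2L)                  # site 3 fixed derived
  expect_identical(s$xi, c(2L, 0L, 0L))      # two singletons
  # identical haplotypes: nothing segregates
  p0 <- HaplotypePanel(matrix(1L, 5, 4), c(1L, 2L, 3L, 4L))
  expect_identical(sfsSummary(p0)$S, 0L)
  # random panels against a naive per-site loop
  withr::with_seed(37, {
    for (i in 1:10) {
      n <- sample(4:9, 1); m <- sample(10:40, 1)
      hm <- matrix(rbinom(n * m, 1L, runif(1, .2, .8)), n, m)
      pp <- HaplotypePanel(hm, sort(sample.int(1e6, m)))
      ss <- sfsSummary(pp)
      xi_loop <- integer(n - 1)
      for (j in seq_len(m)) {
        d <- sum(hm[, j])
        if (d >= 1 && d <= n - 1) xi_loop[d] <- xi_loop[d] + 1L
      }
      expect_identical(ss$xi, xi_loop)
      expect_identical(ss$S, sum(xi_loop))
    }
  })
})

test_that("Tajima's D and Fay-Wu's H match independent pairwise oracles", {
  withr::with_seed(43, {
    for (i in 1:15) {
      n <- sample(4:10, 1); m <- sample(5:50, 1)
      hm <- matrix(rbinom(n * m, 1L, runif(1, .1, .9)), n, m)
      pp <- HaplotypePanel(hm, sort(sample.int(1e7, m)))
      sfs <- sfsSummary(pp)
      d_o <- tajimaOracle(hm); h_o <- fayWuOracle(hm)
      if (is.na(d_o)) {
        expect_true(is.na(tajimasD(sfs)))
      } else {
        expect_equal(tajimasD(sfs), d_o, tolerance = 1e-10)
        expect_equal(fayWuH(sfs), h_o, tolerance = 1e-10)
      }
    }
  })
  # monomorphic: undefined, not zero
  pm <- HaplotypePanel(matrix(0L, 6, 5), (1:5) * 100L)
  expect_true(is.na(tajimasD(sfsSummary(pm))))
  expect_true(is.na(fayWuH(sfsSummary(pm))))
  # all singletons: D < 0; all near-fixed derived: H < 0
  sing <- sfsSummary(HaplotypePanel(diag(6L)[, 1:6], (1:6) * 100L))
  expect_lt(tajimasD(sing), 0)
  expect_gt(fayWuH(sing), 0)
  hi <- matrix(1L, 6, 8); hi[1, ] <- 0L     # derived count n-1 everywhere
  expect_lt(fayWuH(sfsSummary(HaplotypePanel(hi, (1:8) * 100L))), 0)
})

test_that("site order within the panel does not change D or H", {
  withr::with_seed(47, {
    hm <- matrix(rbinom(8 * 30, 1L, 0.4), 8, 30)
    pp <- HaplotypePanel(hm, sort(sample.int(1e6, 30)))
    perm <- sample(30)
    pq <- HaplotypePanel(hm[, perm], sort(sample.int(1e6, 30)))
    expect_equal(tajimasD(sfsSummary(pp)), tajimasD(sfsSummary(pq)))
    expect_equal(fayWuH(sfsSummary(pp)), fayWuH(sfsSummary(pq)))
  })
})

test_that("EHH equals the pairwise-identity oracle and is monotone", {
  withr::with_seed(53, {
    hm <- matrix(rbinom(8 * 25, 1L, 0.5), 8, 25)
    hm[, 13] <- rep(c(0L, 1L), each = 4)          # balanced core
    pp <- HaplotypePanel(hm, sort(sample.int(1e6, 25)))
    for (allele in c(0L, 1L)) {
      curve <- ehh(pp, 13L, allele, "right")
      expect_equal(curve$ehh[1], 1)
      expect_true(all(diff(curve$ehh) <= 1e-12))
      for (t in seq_len(nrow(curve)))
        expect_equal(curve$ehh[t], ehhOracle(hm, 13, allele, curve$site[t]),
                     tolerance = 1e-12)
      curve_l <- ehh(pp, 13L, allele, "left")
      for (t in seq_len(nrow(curve_l)))
        expect_equal(curve_l$ehh[t],
                     ehhOracle(hm, 13, allele, curve_l$site[t]),
                     tolerance = 1e-12)
    }
  })
  # identical carriers: EHH stays 1; fully distinct: drops to 0 immediately
  hid <- rbind(matrix(rep(c(1L, 0L, 1L, 0L, 1L), 3), 3, 5, byrow = TRUE),
               matrix(0L, 3, 5))
  hid[, 3] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  pid <- HaplotypePanel(hid, (1:5) * 1000L)
  expect_true(all(ehh(pid, 3L, 1L, "right")$ehh == 1))
  pdis <- HaplotypePanel(rbind(c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 1L),
                               c(1L, 0L, 0L)), (1:3) * 1000L)
  cr <- ehh(pdis, 2L, 1L, "right")
  expect_equal(cr$ehh[2], 1 / 3)   # one identical pair of three carriers
  # fewer than 2 carriers: undefined
  hone <- matrix(0L, 4, 3); hone[1, 2] <- 1L
  expect_null(ehh(HaplotypePanel(hone, (1:3) * 100L), 2L, 1L))
})

test_that("iHS sign, symmetry, truncation and undefined handling", {
  # panel symmetric under allele swap at the core: iHS = 0
  hs <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  ps <- HaplotypePanel(hs, c(1000L, 2000L, 3000L))
  expect_equal(ihs(ps, 2L, freq_range = c(0.01, 0.99)), 0)
  # constructed sweep: derived carriers share a long flank -> negative iHS
  withr::with_seed(59, {
    p <- simulateHaplotypes(40, 250, region_bp = 2e6, sfs_mode = "neutral",
                            sweep = list(core_frac = 0.5, carrier_frac = 0.6,
                                         flank_bp = 6e5), seed = 61)
    core <- attr(p, "core_site")
    v <- ihs(p, core)
    expect_false(is.na(v))
    expect_lt(v, 0)
  })
  # raising the truncation floor never increases |iHH|
  withr::with_seed(67, {
    hm <- matrix(rbinom(12 * 60, 1L, 0.5), 12, 60)
    hm[, 30] <- rep(c(0L, 1L), 6)
    pp <- HaplotypePanel(hm, sort(sample.int(5e5, 60)))
    curve <- ehh(pp, 30L, 1L, "right")
    i_low <- rohsurv:::.ihh_one_side(curve, 0.05, Inf)
    i_high <- rohsurv:::.ihh_one_side(curve, 0.5, Inf)
    expect_lte(i_high, i_low + 1e-12)
  })
  # out-of-range core frequency is skipped with a message
  hr <- matrix(0L, 20, 5); hr[1, 3] <- 1L
  expect_message(v2 <- ihs(HaplotypePanel(hr, (1:5) * 1000L), 3L),
                 "outside")
  expect_true(is.na(v2))
})

test_that("standardized iHS has zero mean and unit variance within bins", {
  withr::with_seed(71, {
    raw <- rnorm(200); freq <- runif(200, 0.06, 0.94)
    st <- standardizeIhs(raw, freq, n_bins = 5L)
    for (b in unique(st$bin[!st$flagged])) {
      sel <- st$bin == b & !is.na(st$std)
      if (sum(sel) >= 2) {
        expect_lt(abs(mean(st$std[sel])), 1e-10)
        expect_equal(sd(st$std[sel]), 1, tolerance = 1e-10)
      }
    }
    # constant bin is flagged, unstandardized retained
    st2 <- standardizeIhs(c(1, 1, 1), c(0.1, 0.11, 0.12), n_bins = 5L)
    expect_true(all(st2$flagged))
    expect_true(all(is.na(st2$std)))
    expect_identical(st2$raw, c(1, 1, 1))
  })
})

test_that("neutral panels put ~5% of standardized scores beyond 2", {
  withr::with_seed(73, {
    p <- simulateHaplotypes(30, 1500, region_bp = 3e7, sfs_mode = "neutral",
                            seed = 77)
    freq <- colSums(p@haplotypes) / nrow(p@haplotypes)
    eligible <- which(freq > 0.05 & freq < 0.95)
    raw <- vapply(eligible, function(s) suppressMessages(ihs(p, s)),
                  numeric(1))
    st <- standardizeIhs(raw, freq[eligible])
    frac <- mean(abs(st$std) > 2, na.rm = TRUE)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.10)
  })
})

test_that("region annotation flags monomorphic regions and finds sweeps", {
  withr::with_seed(79, {
    p <- simulateHaplotypes(40, 400, region_bp = 4e6, sfs_mode = "neutral",
                            sweep = list(core_frac = 0.25, carrier_frac = 0.6,
                                         flank_bp = 4e5), seed = 83)
    regions <- data.frame(start_bp = c(6e5, 2.6e6), end_bp = c(1.4e6, 3.4e6))
    ann <- annotateRegions(regions, p, window_bp = 4e5)
    # sweep region shows larger |iHS| than the neutral region
    expect_gt(ann$ihs_max[1], ann$ihs_max[2] * 0.99)
    expect_true(all(is.finite(ann$tajima_d_max)))
    # degenerate window covering the whole region equals the plain statistic
    one <- annotateRegions(data.frame(start_bp = 6e5, end_bp = 1.4e6), p,
                           window_bp = 8e5 + 1)
    expect_equal(one$tajima_d_max,
                 tajimasD(sfsSummary(p, c(6e5, 1.4e6))))
    expect_equal(one$fay_wu_h_min, fayWuH(sfsSummary(p, c(6e5, 1.4e6))))
  })
  # region with no polymorphic sites: undefined scores
  pm <- HaplotypePanel(matrix(0L, 10, 6), (1:6) * 1000L)
  annm <- annotateRegions(data.frame(start_bp = 1, end_bp = 10000), pm)
  expect_true(is.na(annm$tajima_d_max))
  expect_true(is.na(annm$ihs_max))
})
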