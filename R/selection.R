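#' Haplotype panel TSV input/output
#'
#' `<prefix>.hap.tsv` holds the 0/1 matrix (haplotypes in rows, no header);
#' `<prefix>.pos.tsv` one base-pair position per line.
#'
#' @param panel a [HaplotypePanel-class].
#' @param prefix file path prefix.
#' @return `readHaplotypePanel` returns a [HaplotypePanel-class].
#' @export
writeHaplotypePanel <- function(panel, prefix) {
  write.table(panel@haplotypes, paste0(prefix, ".hap.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(as.character(panel@positions), paste0(prefix, ".pos.tsv"))
  invisible(prefix)
}

#' @rdname writeHaplotypePanel
#' @export
readHaplotypePanel <- function(prefix) {
  h <- as.matrix(read.table(paste0(prefix, ".hap.tsv"), header = FALSE))
  dimnames(h) <- NULL
  pos <- as.integer(readLines(paste0(prefix, ".pos.tsv")))
  HaplotypePanel(h, pos)
}

#' Site-frequency spectrum summary of a haplotype region
#'
#' Counts, for each derived-allele count `i = 1..n-1`, the number of sites
#' in the region carrying exactly `i` derived alleles.  Sites fixed
#' ancestral (0) or derived (n) in the panel are not segregating and are
#' excluded from `S`.
#'
#' @param panel a [HaplotypePanel-class] (0 = ancestral, 1 = derived).
#' @param region optional `c(start_bp, end_bp)`; default the whole panel.
#' @return list with `n`, `S`, `xi` (length `n - 1`).
#' @export
sfsSummary <- function(panel, region = NULL) {
  h <- panel@haplotypes
  n <- nrow(h)
  sel <- if (is.null(region)) rep(TRUE, ncol(h))
  else panel@positions >= region[1L] & panel@positions <= region[2L]
  dc <- colSums(h[, sel, drop = FALSE])
  dc <- dc[dc > 0L & dc < n]
  xi <- tabulate(dc, nbins = n - 1L)
  list(n = n, S = sum(xi), xi = xi)
}

.theta_pi <- function(sfs) {
  i <- seq_len(sfs$n - 1L)
  sum(sfs$xi * i * (sfs$n - i)) * 2 / (sfs$n * (sfs$n - 1L))
}

#' Tajima's D
#'
#' Contrasts mean pairwise diversity with the scaled number of segregating
#' sites: `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants derived from the haplotype count.  Undefined (NA) when `S = 0`.
#'
#' @param sfs a [sfsSummary()] with `n >= 4`.
#' @return numeric D, or `NA` when undefined.
#' @export
tajimasD <- function(sfs) {
  stopifnot(sfs$n >= 4L)
  S <- sfs$S
  if (S == 0L) return(NA_real_)
  n <- sfs$n
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (.theta_pi(sfs) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay-Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` with
#' `theta_H = sum_i xi_i * 2 i^2 / (n (n - 1))`; strongly negative under an
#' excess of high-frequency derived alleles (the footprint of a completed
#' or partial sweep).  Requires polarized (ancestral-state) data; undefined
#' when `S = 0`.
#'
#' @param sfs a [sfsSummary()] with `n >= 3`.
#' @return numeric H, or `NA` when undefined.
#' @export
fayWuH <- function(sfs) {
  stopifnot(sfs$n >= 3L)
  if (sfs$S == 0L) return(NA_real_)
  i <- seq_len(sfs$n - 1L)
  theta_h <- sum(sfs$xi * 2 * i^2) / (sfs$n * (sfs$n - 1L))
  .theta_pi(sfs) - theta_h
}

#' Extended haplotype homozygosity from a core site
#'
#' Among the carriers of `allele` at the core site, walks outward site by
#' site and computes `EHH(x) = sum_k C(c_k, 2) / C(c, 2)`, where the `c_k`
#' count the distinct extended haplotypes from the core to `x`.  EHH is 1
#' at the core and monotone non-increasing with distance.
#'
#' @param panel a [HaplotypePanel-class].
#' @param core_site column index of the core site.
#' @param allele 0 (ancestral) or 1 (derived) core allele.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @return data frame with `site`, `pos`, `ehh`, starting at the core; or
#'   `NULL` when the allele has fewer than 2 carriers.
#' @export
ehh <- function(panel, core_site, allele, direction = c("right", "left")) {
  direction <- match.arg(direction)
  h <- panel@haplotypes
  carriers <- which(h[, core_site] == allele)
  cN <- length(carriers)
  if (cN < 2L) return(NULL)
  sites <- if (direction == "right")
    seq(core_site, ncol(h)) else seq(core_site, 1L)
  gid <- rep(1L, cN)
  denom <- choose(cN, 2L)
  out_ehh <- numeric(length(sites))
  for (t in seq_along(sites)) {
    s <- sites[t]
    if (t > 1L)
      gid <- as.integer(factor(paste(gid, h[carriers, s])))
    cnts <- tabulate(gid)
    out_ehh[t] <- sum(choose(cnts, 2L)) / denom
  }
  data.frame(site = sites, pos = panel@positions[sites], ehh = out_ehh)
}

# EHH walk that stops once the curve falls below the floor or a gap exceeds
# max_gap_bp -- the integral is truncated there anyway, so the tail of the
# full curve is never needed inside ihs()
.ehh_walk <- function(panel, core_site, allele, direction, ehh_floor,
                      max_gap_bp) {
  h <- panel@haplotypes
  carriers <- which(h[, core_site] == allele)
  cN <- length(carriers)
  if (cN < 2L) return(NULL)
  sites <- if (direction == "right")
    seq(core_site, ncol(h)) else seq(core_site, 1L)
  gid <- rep(1L, cN)
  denom <- choose(cN, 2L)
  pos <- panel@positions
  out_site <- integer(length(sites)); out_ehh <- numeric(length(sites))
  kept <- 0L
  for (t in seq_along(sites)) {
    s <- sites[t]
    if (t > 1L) {
      if (abs(pos[s] - pos[sites[t - 1L]]) > max_gap_bp) break
      gid <- as.integer(factor(paste(gid, h[carriers, s])))
    }
    e <- sum(choose(tabulate(gid), 2L)) / denom
    kept <- kept + 1L
    out_site[kept] <- s; out_ehh[kept] <- e
    if (e < ehh_floor) break
  }
  idx <- seq_len(kept)
  data.frame(site = out_site[idx], pos = pos[out_site[idx]],
             ehh = out_ehh[idx])
}

.ihh_one_side <- function(curve, ehh_floor, max_gap_bp) {
  # trapezoid over |distance from core|, truncated at the floor and at gaps
  if (is.null(curve) || nrow(curve) < 2L) return(0)
  x <- abs(curve$pos - curve$pos[1L])
  y <- curve$ehh
  total <- 0
  for (t in 2L:nrow(curve)) {
    if (x[t] - x[t - 1L] > max_gap_bp) break
    total <- total + (y[t] + y[t - 1L]) / 2 * (x[t] - x[t - 1L])
    if (y[t] < ehh_floor) break
  }
  total
}

#' Unstandardized integrated haplotype score
#'
#' Integrates the ancestral- and derived-allele EHH curves over physical
#' distance on both sides of the core (trapezoid rule, truncated where EHH
#' falls below `ehh_floor` and at inter-site gaps above `max_gap_bp`) and
#' returns `ln(iHH_A / iHH_D)`.  Negative values mean longer haplotypes on
#' the derived background (the partial-sweep signature before
#' standardization).  Undefined (`NA`) when either allele has fewer than 2
#' carriers, when the derived frequency is outside `freq_range`, or when
#' `iHH_D = 0`.
#'
#' @param panel a [HaplotypePanel-class].
#' @param core_site core column index.
#' @param ehh_floor truncation threshold for the EHH curves.
#' @param max_gap_bp integration stops at larger inter-site gaps.
#' @param freq_range admissible derived-allele frequency interval.
#' @return unstandardized iHS, or `NA` when undefined.
#' @export
ihs <- function(panel, core_site, ehh_floor = 0.05, max_gap_bp = 200000,
                freq_range = c(0.05, 0.95)) {
  h <- panel@haplotypes
  n <- nrow(h)
  freq <- sum(h[, core_site]) / n
  if (freq <= freq_range[1L] || freq >= freq_range[2L]) {
    message("core site derived frequency ", signif(freq, 3),
            " outside admissible range; skipped")
    return(NA_real_)
  }
  ihh <- function(allele) {
    right <- .ehh_walk(panel, core_site, allele, "right", ehh_floor,
                       max_gap_bp)
    left <- .ehh_walk(panel, core_site, allele, "left", ehh_floor,
                      max_gap_bp)
    if (is.null(right) || is.null(left)) return(NA_real_)
    .ihh_one_side(right, ehh_floor, max_gap_bp) +
      .ihh_one_side(left, ehh_floor, max_gap_bp)
  }
  ihh_a <- ihh(0L); ihh_d <- ihh(1L)
  if (is.na(ihh_a) || is.na(ihh_d) || ihh_d == 0) return(NA_real_)
  log(ihh_a / ihh_d)
}

#' Standardize iHS within derived-frequency bins
#'
#' Within equal-width derived-frequency bins, centers and scales the
#' unstandardized scores so that genome-wide |iHS| is comparable across
#' frequencies.  Bins with fewer than 2 scores or zero spread are flagged
#' and their scores left unstandardized (`NA` in the standardized column).
#'
#' @param scores unstandardized iHS values.
#' @param frequencies derived-allele frequencies of the core sites.
#' @param n_bins number of frequency bins.
#' @return data frame with `raw`, `freq`, `bin`, `std`, `flagged`.
#' @export
standardizeIhs <- function(scores, frequencies, n_bins = 20L) {
  stopifnot(length(scores) == length(frequencies))
  bin <- pmin(pmax(ceiling(frequencies * n_bins), 1L), n_bins)
  std <- rep(NA_real_, length(scores))
  flagged <- rep(FALSE, length(scores))
  for (b in unique(bin)) {
    sel <- which(bin == b & !is.na(scores))
    if (length(sel) < 2L || sd(scores[sel]) == 0) {
      flagged[bin == b] <- TRUE
      next
    }
    std[sel] <- (scores[sel] - mean(scores[sel])) / sd(scores[sel])
  }
  data.frame(raw = scores, freq = frequencies, bin = bin, std = std,
             flagged = flagged)
}

#' Selection-scan annotation of regions
#'
#' For each region, computes Tajima's D and Fay-Wu's H in sliding windows
#' of `window_bp` (step `window_bp / 2`) and reports the maximum D and
#' minimum H, plus the maximum |standardized iHS| over core sites inside
#' the region (standardization bins span all eligible cores in the panel).
#' Regions without polymorphic sites get `NA` scores.
#'
#' @param regions data frame with `start_bp`, `end_bp` in the panel's
#'   coordinate space.
#' @param panel a [HaplotypePanel-class].
#' @param window_bp window size for the SFS statistics.
#' @return data frame with `tajima_d_max`, `fay_wu_h_min`, `ihs_max` per
#'   region.
#' @export
annotateRegions <- function(regions, panel, window_bp = 200000) {
  pos <- panel@positions
  n_hap <- nrow(panel@haplotypes)
  # genome-wide standardized iHS over all eligible cores
  freq <- colSums(panel@haplotypes) / n_hap
  eligible <- which(freq > 0.05 & freq < 0.95)
  raw <- vapply(eligible, function(s)
    suppressMessages(ihs(panel, s)), numeric(1))
  std <- standardizeIhs(raw, freq[eligible])
  abs_std <- abs(ifelse(is.na(std$std), std$raw, std$std))

  out <- lapply(seq_len(nrow(regions)), function(r) {
    a <- regions$start_bp[r]; b <- regions$end_bp[r]
    starts <- seq(a, max(a, b - window_bp), by = max(1, window_bp / 2))
    if (b - a <= window_bp) starts <- a
    d_vals <- h_vals <- numeric(0)
    for (w in starts) {
      sfs <- sfsSummary(panel, c(w, min(b, w + window_bp)))
      if (sfs$S > 0L) {
        d_vals <- c(d_vals, tajimasD(sfs))
        h_vals <- c(h_vals, fayWuH(sfs))
      }
    }
    in_reg <- which(pos[eligible] >= a & pos[eligible] <= b)
    data.frame(
      tajima_d_max = if (length(d_vals)) max(d_vals) else NA_real_,
      fay_wu_h_min = if (length(h_vals)) min(h_vals) else NA_real_,
      ihs_max = if (length(in_reg) && any(!is.na(abs_std[in_reg])))
        max(abs_std[in_reg], na.rm = TRUE) else NA_real_)
  })
  cbind(regions, do.call(rbind, out))
}
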