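#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses the whitespace-delimited PLINK text dialect: the MAP file carries
#' four columns (chromosome, variant id, genetic position, base-pair
#' position); each PED line carries six leading columns (family id,
#' individual id, paternal id, maternal id, sex, phenotype) followed by two
#' allele columns per variant, with `"0"` denoting a missing allele.  A call
#' with any missing allele becomes `NA`.  Genotype codes count copies of the
#' A1 allele; by default A1 is recomputed from the data as the minor allele
#' (ties and monomorphic variants resolved alphabetically), since PED text
#' does not encode allele order.  Pass `a1` to pin the coded allele per
#' variant instead.
#'
#' Sample annotations come from the optional sidecar TSV (`sample_id`,
#' `population`, `group`); without one, the PED phenotype column is mapped
#' `1 -> STS`, `2 -> LTS` (the PLINK case/control convention) and all samples
#' fall in one population.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param sidecar_path optional path to a sample-annotation TSV.
#' @param a1 optional character vector (one allele per variant) fixing which
#'   allele is counted; default recomputes the minor allele.
#' @return a [GenotypeExperiment-class].
#' @export
readPedMap <- function(ped_path, map_path, sidecar_path = NULL, a1 = NULL) {
  map <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L)
    stop("MAP parse error: expected 4 columns, found ", ncol(map))
  variants <- data.frame(variant_id = map[[2L]], chrom = map[[1L]],
                         bp = as.integer(map[[4L]]),
                         a1 = NA_character_, a2 = NA_character_)
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant id: ",
         variants$variant_id[anyDuplicated(variants$variant_id)])
  bad <- which(variants$chrom[-1L] == variants$chrom[-nrow(variants)] &
                 diff(variants$bp) <= 0L)
  if (length(bad))
    stop("MAP not sorted by bp within chromosome: variants '",
         variants$variant_id[bad[1L]], "' and '",
         variants$variant_id[bad[1L] + 1L], "'")
  m <- nrow(variants)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_len(n))
    if (length(toks[[i]]) != want)
      stop("PED parse error at line ", i, ": expected ", want,
           " fields, found ", length(toks[[i]]))
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  ids <- tok[, 2L, drop = TRUE]
  pheno <- tok[, 6L, drop = TRUE]
  al1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  miss <- al1 == "0" | al2 == "0"

  codes <- matrix(NA_integer_, nrow = m, ncol = n)
  a1_out <- character(m); a2_out <- character(m)
  for (j in seq_len(m)) {
    ok <- !miss[, j]
    als <- c(al1[ok, j], al2[ok, j])
    seen <- sort(unique(als))
    if (length(seen) > 2L)
      stop("variant '", variants$variant_id[j], "' has >2 alleles")
    if (!is.null(a1)) {
      cnt <- a1[j]
      other <- setdiff(seen, cnt)
      oth <- if (length(other)) other[1L] else cnt
    } else if (length(seen) == 0L) {
      cnt <- "0"; oth <- "0"
    } else if (length(seen) == 1L) {
      cnt <- seen; oth <- seen
    } else {
      n1 <- sum(als == seen[1L])
      # minor allele counted; alphabetical on ties
      cnt <- if (n1 <= length(als) - n1) seen[1L] else seen[2L]
      oth <- setdiff(seen, cnt)
    }
    a1_out[j] <- cnt; a2_out[j] <- oth
    codes[j, ok] <- (al1[ok, j] == cnt) + (al2[ok, j] == cnt)
  }
  variants$a1 <- a1_out; variants$a2 <- a2_out

  if (!is.null(sidecar_path)) {
    sc <- read.table(sidecar_path, header = TRUE, sep = "\t",
                     colClasses = "character")
    idx <- match(ids, sc$sample_id)
    if (anyNA(idx))
      stop("sidecar is missing samples: ",
           paste(head(ids[is.na(idx)], 3L), collapse = ", "))
    samples <- data.frame(sample_id = ids,
                          population = sc$population[idx],
                          group = sc$group[idx])
  } else {
    samples <- data.frame(sample_id = ids, population = "pop1",
                          group = ifelse(pheno == "2", "LTS", "STS"))
  }
  GenotypeExperiment(codes, variants, samples)
}

#' Write a GenotypeExperiment to PLINK text PED/MAP
#'
#' Inverse of [readPedMap()]: missing calls become `"0 0"`, code 2 becomes
#' `a1 a1`, code 1 `a1 a2`, code 0 `a2 a2`.  The sample sidecar TSV
#' (`<prefix>.samples.tsv`) preserves population and group labels.  Group
#' `LTS` is written as phenotype 2, anything else as 1.
#'
#' @param x a [GenotypeExperiment-class].
#' @param out_prefix path prefix; writes `<prefix>.ped`, `<prefix>.map` and
#'   `<prefix>.samples.tsv`.
#' @return invisibly, the three file paths.
#' @export
writePedMap <- function(x, out_prefix) {
  rr <- variantInfo(x)
  map <- data.frame(chrom = as.character(seqnames(rr)),
                    id = names(rr), cm = rep(0, length(rr)),
                    bp = start(rr))
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  sc_path <- paste0(out_prefix, ".samples.tsv")
  write.table(map, map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  g <- genotypes(x)
  a1 <- if (nrow(x)) mcols(rr)$a1 else character(0)
  a2 <- if (nrow(x)) mcols(rr)$a2 else character(0)
  cd <- sampleInfo(x)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(ncol(x))) {
    ci <- g[, i]
    f1 <- ifelse(is.na(ci), "0", ifelse(ci >= 1L, a1, a2))
    f2 <- ifelse(is.na(ci), "0", ifelse(ci == 2L, a1, a2))
    pheno <- if (as.character(cd$group[i]) == "LTS") "2" else "1"
    al <- character(2L * length(ci))
    if (length(ci)) {
      al[c(TRUE, FALSE)] <- f1
      al[c(FALSE, TRUE)] <- f2
    }
    writeLines(paste(c(cd$sample_id[i], cd$sample_id[i], "0", "0", "0",
                       pheno, al), collapse = " "), con)
  }
  write.table(as.data.frame(cd[, c("sample_id", "population", "group")]),
              sc_path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, sidecar = sc_path))
}

#' Per-variant and per-sample quality summaries
#'
#' Call rates, minor-allele frequencies and heterozygosity proportions,
#' with flags against user thresholds.  Nothing is removed: filtering is the
#' caller's decision.  Variants with no non-missing calls get call rate 0
#' and an undefined (NA) MAF, and are flagged.
#'
#' @param x a [GenotypeExperiment-class].
#' @param min_variant_call_rate,min_sample_call_rate,min_maf flag thresholds.
#' @return list with `variants` and `samples` data frames.
#' @export
qcSummary <- function(x, min_variant_call_rate = 0.95,
                      min_sample_call_rate = 0.95, min_maf = 0.01) {
  g <- genotypes(x)
  nm <- !is.na(g)
  v_called <- rowSums(nm)
  v_call_rate <- v_called / ncol(g)
  p <- rowSums(g, na.rm = TRUE) / (2 * v_called)   # A1 frequency
  maf <- pmin(p, 1 - p)
  maf[v_called == 0L] <- NA_real_
  v_het <- rowSums(g == 1L, na.rm = TRUE) / v_called
  v_het[v_called == 0L] <- NA_real_
  s_called <- colSums(nm)
  s_call_rate <- s_called / nrow(g)
  s_het <- colSums(g == 1L, na.rm = TRUE) / s_called
  list(
    variants = data.frame(
      variant_id = rownames(g),
      call_rate = v_call_rate, maf = maf, het = v_het,
      flag = v_call_rate < min_variant_call_rate |
        is.na(maf) | maf < min_maf),
    samples = data.frame(
      sample_id = colnames(g),
      call_rate = s_call_rate, mean_het = s_het,
      flag = s_call_rate < min_sample_call_rate))
}

#' Genotype principal components for stratification checks
#'
#' Standardizes each variant by its mean (`2p`) and binomial standard
#' deviation (`sqrt(2p(1-p))`), imputes missing calls to the variant mean,
#' drops monomorphic variants, and returns the first `k` sample scores.
#' Signs are fixed deterministically: within each component the
#' largest-magnitude variant loading is made positive.
#'
#' @param x a [GenotypeExperiment-class].
#' @param k number of components, `k < min(n, m)`.
#' @return matrix of scores, samples x k.
#' @export
pcaGenotypes <- function(x, k = 2L) {
  g <- genotypes(x)
  if (k == 0L)
    return(matrix(numeric(0), nrow = ncol(g), ncol = 0L,
                  dimnames = list(colnames(g), NULL)))
  stopifnot(k < min(dim(g)))
  called <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * called)
  keep <- !is.na(p) & p > 0 & p < 1
  if (any(!keep))
    message(sum(!keep), " monomorphic or all-missing variants excluded from PCA")
  g <- g[keep, , drop = FALSE]; p <- p[keep]
  z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0
  sv <- svd(t(z), nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(g), paste0("PC", seq_len(k)))
  scores
}
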