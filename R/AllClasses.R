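#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` mcols `mcols<-`
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect granges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
#' @importFrom stats pchisq t.test glm lm lm.fit binomial gaussian poisson
#'   coef rbinom rpois runif rbeta rgamma rhyper prcomp cor cor.test
#'   complete.cases var sd setNames fisher.test p.adjust pt qnorm predict
#'   model.matrix qgamma ks.test
#' @importFrom utils read.table write.table head tail
NULL

#' Genotype container for homozygosity analysis
#'
#' `GenotypeExperiment` couples an integer genotype matrix with its variant
#' map and sample annotations, following the SummarizedExperiment layout:
#' rows are variants (carried as a `GRanges` with one-base-pair positions),
#' columns are samples.  The single assay `"codes"` counts copies of the A1
#' allele, so `0` and `2` are the two homozygous states, `1` is heterozygous
#' and `NA` is a missing call.  `NA` is a distinguished sentinel: no counting
#' routine in the package ever treats it as homozygous or heterozygous.
#'
#' Column (sample) metadata must provide `population` (factor with at least
#' one level) and `group`, the two-level survival factor -- conventionally
#' `STS` (short-time survivors) and `LTS` (long-time survivors).
#'
#' @slot .. see \code{\link[SummarizedExperiment]{RangedSummarizedExperiment}}
#' @aliases GenotypeExperiment-class
#' @export
setClass("GenotypeExperiment",
         contains = "RangedSummarizedExperiment")

.validGenotypeExperiment <- function(object) {
  msg <- NULL
  if (!"codes" %in% names(assays(object)))
    msg <- c(msg, "assay 'codes' is required")
  else {
    g <- assay(object, "codes")
    if (!is.integer(g))
      msg <- c(msg, "assay 'codes' must be an integer matrix")
    else {
      bad <- g[!is.na(g)]
      if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
        msg <- c(msg, "genotype codes must be in {0, 1, 2, NA}")
    }
  }
  rr <- rowRanges(object)
  if (any(width(rr) != 1L))
    msg <- c(msg, "variant positions must be single base pairs (width 1)")
  if (anyDuplicated(names(object)))
    msg <- c(msg, "variant ids must be unique")
  pos <- start(rr)
  chr <- as.character(seqnames(rr))
  if (length(pos) > 1L) {
    same <- chr[-1L] == chr[-length(chr)]
    if (any(same & diff(pos) <= 0L))
      msg <- c(msg, "bp must be strictly increasing within each chromosome")
  }
  if (length(pos) && min(pos) < 1L)
    msg <- c(msg, "bp positions must be >= 1")
  cd <- colData(object)
  if (!all(c("population", "group") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'population' and 'group'")
  else if (nlevels(factor(cd$group)) != 2L && ncol(object) > 0L)
    msg <- c(msg, "'group' must have exactly two levels")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param codes integer matrix, variants x samples, values in `{0,1,2,NA}`
#'   counting A1 copies.
#' @param variants `data.frame` or `DataFrame` with columns `variant_id`,
#'   `chrom`, `bp`, `a1`, `a2` (one row per row of `codes`), or a `GRanges`
#'   with those metadata columns.
#' @param samples `data.frame` with columns `sample_id`, `population`,
#'   `group` (one row per column of `codes`).
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2)
#' v <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
#'                 bp = c(100L, 200L), a1 = "A", a2 = "G")
#' s <- data.frame(sample_id = c("s1", "s2"),
#'                 population = "P1", group = c("STS", "LTS"))
#' GenotypeExperiment(g, v, s)
#' @export
GenotypeExperiment <- function(codes, variants, samples) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is(variants, "GRanges")) {
    rr <- variants
  } else {
    variants <- as.data.frame(variants)
    rr <- GRanges(seqnames = as.character(variants$chrom),
                  ranges = IRanges(start = as.integer(variants$bp), width = 1L))
    mcols(rr)$variant_id <- as.character(variants$variant_id)
    mcols(rr)$a1 <- as.character(variants$a1)
    mcols(rr)$a2 <- as.character(variants$a2)
    names(rr) <- mcols(rr)$variant_id
  }
  samples <- as.data.frame(samples)
  cd <- DataFrame(sample_id = as.character(samples$sample_id),
                  population = factor(samples$population),
                  group = factor(samples$group))
  rownames(cd) <- cd$sample_id
  dimnames(codes) <- list(names(rr), cd$sample_id)
  se <- SummarizedExperiment(assays = list(codes = codes),
                             rowRanges = rr, colData = cd)
  new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment show method
#' @param object a `GenotypeExperiment`
#' @export
setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment with", nrow(object), "variants x",
      ncol(object), "samples\n")
  g <- factor(colData(object)$group)
  if (ncol(object))
    cat("  groups:",
        paste(sprintf("%s=%d", levels(g), tabulate(g)), collapse = ", "),
        "| populations:", nlevels(colData(object)$population), "\n")
  chr <- unique(as.character(seqnames(rowRanges(object))))
  cat("  chromosomes:", length(chr), "\n")
})

#' Phased haplotype panel
#'
#' Binary haplotype matrix (rows = haplotypes, columns = segregating sites)
#' with physical positions.  `0` is the ancestral allele, `1` the derived
#' allele, so the site-frequency spectrum and the EHH/iHS statistics can be
#' polarized directly.
#'
#' @slot haplotypes integer matrix of 0/1, `2n x m`.
#' @slot positions integer vector of strictly increasing base-pair positions.
#' @export
setClass("HaplotypePanel",
         representation(haplotypes = "matrix", positions = "integer"))

.validHaplotypePanel <- function(object) {
  msg <- NULL
  h <- object@haplotypes
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "haplotypes must be binary 0/1")
  if (ncol(h) != length(object@positions))
    msg <- c(msg, "positions length must equal number of sites")
  p <- object@positions
  if (length(p) > 1L && any(diff(p) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (is.null(msg)) TRUE else msg
}
setValidity("HaplotypePanel", .validHaplotypePanel)

#' Construct a HaplotypePanel
#' @param haplotypes 0/1 matrix, haplotypes in rows, sites in columns.
#' @param positions base-pair positions, strictly increasing.
#' @return a [HaplotypePanel-class]
#' @export
HaplotypePanel <- function(haplotypes, positions) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", haplotypes = haplotypes,
      positions = as.integer(positions))
}

#' @describeIn HaplotypePanel show method
#' @param object a `HaplotypePanel`
#' @export
setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "sites\n")
})

#' @describeIn HaplotypePanel number of haplotypes and sites
#' @param x a `HaplotypePanel`
#' @export
setMethod("dim", "HaplotypePanel", function(x) dim(x@haplotypes))

#' Accessors for GenotypeExperiment
#'
#' `genotypes()` returns the integer code matrix (variants x samples);
#' `variantInfo()` the variant `GRanges`; `sampleInfo()` the sample
#' `DataFrame`; `survivalGroup()` the two-level outcome factor.
#'
#' @param x a [GenotypeExperiment-class]
#' @return see individual descriptions.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
genotypes <- function(x) assay(x, "codes")

#' @rdname genotype-accessors
#' @export
variantInfo <- function(x) rowRanges(x)

#' @rdname genotype-accessors
#' @export
sampleInfo <- function(x) colData(x)

#' @rdname genotype-accessors
#' @export
survivalGroup <- function(x) factor(colData(x)$group)
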