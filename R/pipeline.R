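#' Read or write a pipeline configuration
#'
#' The configuration is a plain list, round-tripped losslessly through
#' YAML.  Every stochastic stage carries an explicit seed.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `readPipelineConfig` returns the list.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full homozygosity-survival analysis pipeline
#'
#' Orchestrates the stages in study order: load (or simulate) genotypes;
#' SNP-by-SNP homozygosity association with BH FDR; overall homozygosity
#' comparison; ROH calling and burden tests (Student t, population-adjusted
#' GLM, permutation of regressor residuals); pooling into common ROH
#' regions with carrier association, region homozygosity t-tests and the
#' FDR non-inferiority comparison against single-SNP allelic p-values;
#' inbreeding coefficients (F I/II/III, F_ROH), group tests and
#' consanguinity correlations.  Per-stage TSVs and a text report are
#' written to `out_dir`; the run is deterministic under the config seeds.
#'
#' @param config list with entries:
#'   `simulate` (arguments to [simulationConfig()]) or `input`
#'   (`ped`, `map`, optional `sidecar` paths);
#'   optional `roh` (arguments to [rohParams()]);
#'   optional `pooling` (`min_overlap_snps`, `min_carriers`);
#'   optional `stats` (`n_mc`, `n_perm`, `seed`, `m_total`);
#'   optional `centromeres` (BED-like TSV path: chrom, start, end).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results.
#' @export
runPipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) write.table(d, file.path(out_dir, name),
                                       quote = FALSE, sep = "\t",
                                       row.names = FALSE)
  stats_cfg <- config$stats %||% list()
  n_mc <- stats_cfg$n_mc %||% 2000L
  n_perm <- stats_cfg$n_perm %||% 500L
  seed <- stats_cfg$seed %||% 1L

  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulationConfig, config$simulate)
    sim <- simulateCohort(sim_cfg)
    x <- sim$data
    writeTruthRecord(sim$truth, file.path(out_dir, "truth.json"))
  } else if (!is.null(config$input)) {
    x <- readPedMap(config$input$ped, config$input$map,
                    sidecar_path = config$input$sidecar)
  } else stop("config needs either 'simulate' or 'input'; run the simulate ",
              "stage or point 'input' at PED/MAP files")

  centromeres <- NULL
  if (!is.null(config$centromeres)) {
    cen <- read.table(config$centromeres, header = FALSE)
    centromeres <- GRanges(as.character(cen[[1L]]),
                           IRanges(cen[[2L]], cen[[3L]]))
  }

  # stage: SNP association
  assoc <- snpAssociation(x, m_total = stats_cfg$m_total %||% NULL)
  tsv(assoc[order(assoc$p), ], "snp_association.tsv")
  overall <- overallHomozygosityTest(x)

  # stage: ROH calling and burden
  params <- do.call(rohParams, config$roh %||% list())
  segments <- callROHs(x, params)
  seg_df <- data.frame(sample_id = mcols(segments)$sample_id,
                       chrom = as.character(seqnames(segments)),
                       start_bp = start(segments), end_bp = end(segments),
                       n_snps = mcols(segments)$n_snps,
                       length_kb = mcols(segments)$length_kb)
  tsv(seg_df, "roh_segments.tsv")
  cd <- as.data.frame(sampleInfo(x))
  burden <- burdenPerSample(segments, cd$sample_id)
  tsv(burden, "roh_burden.tsv")
  burden_tests <- burdenGroupTests(burden, cd)
  tsv(burden_tests, "burden_tests.tsv")
  lv <- .groupLevels(cd$group)
  glm_res <- glmBurden(burden$n_roh, factor(cd$group, levels = lv),
                       cd$population)
  perm_res <- permutationRegressorResiduals(
    burden$n_roh, factor(cd$group, levels = lv), cd$population,
    n_perm = n_perm, seed = seed)

  # stage: pooling and common ROHs
  pool_cfg <- config$pooling %||% list()
  pools <- poolROHs(segments, x,
                    min_overlap_snps = pool_cfg$min_overlap_snps %||% 75L,
                    centromeres = centromeres)
  common <- selectCommonROHs(pools,
                             min_carriers = pool_cfg$min_carriers %||% 5L)
  n1 <- sum(cd$group == lv[1L]); n2 <- sum(cd$group == lv[2L])
  allelic <- allelicAssociation(x)
  rr <- variantInfo(x)
  vchr <- as.character(seqnames(rr)); vpos <- start(rr)
  if (nrow(common)) {
    extra <- lapply(seq_len(nrow(common)), function(r) {
      ca <- carrierAssociation(common$carriers_1[r], common$carriers_2[r],
                               n1, n2, n_mc = n_mc, seed = seed + r)
      ph <- regionHomozygosityTest(x, common$chrom[r],
                                   common$consensus_start_bp[r],
                                   common$consensus_end_bp[r])
      j <- which(vchr == common$chrom[r] &
                   vpos >= common$consensus_start_bp[r] &
                   vpos <= common$consensus_end_bp[r])
      fdr <- fdrNoninferiority(assoc$p[j], allelic$p[j])
      data.frame(chi2 = ca$chi2, p_mc = ca$p_mc, p_fisher = ca$p_fisher,
                 p_hom = ph$p, p_fdr_diff = fdr$p)
    })
    common_out <- cbind(common[, setdiff(names(common), "members")],
                        do.call(rbind, extra))
  } else {
    common_out <- common[, setdiff(names(common), "members")]
  }
  tsv(common_out, "common_rohs.tsv")

  # stage: inbreeding
  inb <- inbreedingCoeffs(x)
  f_roh <- fROH(segments, cd$sample_id,
                l_auto = sum(vapply(split(vpos, vchr), max, numeric(1))))
  inb$F_ROH <- f_roh[inb$sample_id]
  tsv(inb, "inbreeding.tsv")
  inb_tests <- inbreedingGroupTests(
    inb[, c("F_I", "F_II", "F_III", "F_ROH")],
    factor(cd$group, levels = lv))
  tsv(inb_tests, "inbreeding_tests.tsv")
  cons <- consanguinityCorrelations(burden, inb$F_II, inb$F_ROH)

  report <- c(
    sprintf("rohsurv pipeline report (seed %d)", seed),
    sprintf("samples: %d (%s=%d, %s=%d); variants: %d",
            ncol(x), lv[1L], n1, lv[2L], n2, nrow(x)),
    sprintf("overall homozygosity: %.4f vs %.4f (one-sided p = %.3g)",
            overall$mean_1, overall$mean_2, overall$p),
    sprintf("top SNP: %s chi2 = %.2f p = %.3g q = %.2f",
            assoc$variant_id[which.min(assoc$p)],
            max(assoc$chi2, na.rm = TRUE), min(assoc$p, na.rm = TRUE),
            assoc$q[which.min(assoc$p)]),
    sprintf("ROH segments: %d; mean per person %.2f vs %.2f (t p = %.3g)",
            length(segments),
            mean(burden$n_roh[cd$group == lv[1L]]),
            mean(burden$n_roh[cd$group == lv[2L]]),
            burden_tests$p[burden_tests$stratum == "overall" &
                             burden_tests$metric == "n_roh"]),
    sprintf("GLM group p = %.3g; permutation p = %.3g",
            glm_res$group_p, perm_res$p_perm),
    sprintf("pools: %d; common ROHs: %d", nrow(pools), nrow(common)),
    if (nrow(common)) sprintf(
      "best common ROH: chr%s:%d-%d carriers %d/%d (MC p = %.3g)",
      common_out$chrom[which.min(common_out$p_mc)],
      common_out$consensus_start_bp[which.min(common_out$p_mc)],
      common_out$consensus_end_bp[which.min(common_out$p_mc)],
      common_out$carriers_1[which.min(common_out$p_mc)],
      common_out$carriers_2[which.min(common_out$p_mc)],
      min(common_out$p_mc))
    else "common ROHs: none",
    sprintf("mean F_II %.4f vs %.4f (t p = %.3g); mean F_ROH %.4f vs %.4f",
            inb_tests$mean_1[inb_tests$measure == "F_II"],
            inb_tests$mean_2[inb_tests$measure == "F_II"],
            inb_tests$p_t[inb_tests$measure == "F_II"],
            inb_tests$mean_1[inb_tests$measure == "F_ROH"],
            inb_tests$mean_2[inb_tests$measure == "F_ROH"]))
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(data = x, assoc = assoc, overall = overall,
                 segments = segments, burden = burden,
                 burden_tests = burden_tests, glm = glm_res,
                 permutation = perm_res, pools = pools,
                 common_rohs = common_out, inbreeding = inb,
                 inbreeding_tests = inb_tests, correlations = cons))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
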