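#' Run the full admixture-mapping pipeline
#'
#' End-to-end orchestration: obtain a cohort (simulated from
#' `config$sim`, or loaded from files), apply marker QC, construct the
#' analysis phenotypes, summarize ancestry, estimate the effective number
#' of tests and the significance threshold, scan diastolic BP, MAP and
#' log10 systolic BP, extract significant regions, fine-map them with
#' delta-filtered SNP association, test mediation by conditional scans,
#' and run the stratified meta-analysis for every Bonferroni-passing SNP.
#' All stage outputs are written under `outDir` with provenance headers;
#' the run is deterministic given the config (and its seed).
#'
#' @param config an [admixConfig()].
#' @param outDir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param input optional `AdmixtureExperiment` to analyze instead of
#'   simulating.
#' @param phenotypes phenotype columns to scan.
#' @return a list (class `pipelineReport`) with per-stage summaries:
#'   marker/individual counts, Meff and alpha, the scans, regions, regional
#'   results, conditional verdicts and meta results.
#' @export
runPipeline <- function(config = admixConfig(), outDir = NULL,
                        input = NULL,
                        phenotypes = c("dbp_adj", "map", "log10_sbp")) {
  stopifnot(inherits(config, "admixConfig"))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- function(f) if (is.null(outDir)) NULL else file.path(outDir, f)
  seed <- config$seed
  report <- list(seed = seed, config_hash = rlang::hash(unclass(config)))

  x <- if (is.null(input)) {
    config$sim$seed <- seed
    simulateAdmixedCohort(config$sim)
  } else input
  report$n_individuals <- ncol(x)
  report$n_markers_in <- nrow(x)
  if (!is.null(outDir)) {
    writeGenotypes(x, out("genotypes.vcf"), seed, config)
    writeLocalAncestry(x, out("ancestry.tsv"), seed, config)
    writeCohort(cohort(x), out("cohort.tsv"), seed, config)
  }

  qc <- qcFilter(x, config)
  x <- qc$experiment
  report$qc <- as.list(qc$report@counts)
  report$n_markers_qc <- nrow(x)

  x <- preparePhenotypes(x)
  report$normality <- S4Vectors::metadata(x)$normality
  if (!is.null(outDir)) writeCohort(cohort(x), out("phenotypes.tsv"),
                                    seed, config)

  G <- globalAncestry(x)
  report$global_ancestry <- list(mean = attr(G, "mean"), sd = attr(G, "sd"))
  report$switch_points_mean <- mean(switchPoints(x))
  report$ancestry_correlations <- lapply(
    stats::setNames(phenotypes, phenotypes),
    function(ph) ancestryPhenotypeCorrelation(
      as.numeric(G), cohort(x)[[ph]]))

  mres <- effectiveTests(x, config$fwer)
  report$meff <- meff(mres)
  report$alpha <- sigThreshold(mres)
  if (!is.null(outDir))
    jsonlite::write_json(
      list(meff = meff(mres), fwer = config$fwer,
           alpha = sigThreshold(mres), seed = seed),
      out("meff.json"), auto_unbox = TRUE, digits = NA)

  report$scans <- list()
  report$regions <- list()
  report$regional <- list()
  report$conditional <- list()
  report$meta <- list()
  for (ph in phenotypes) {
    scan <- admixtureScan(x, ph, alpha = sigThreshold(mres))
    if (!is.null(outDir))
      writeScanResults(scan, out(sprintf("scan_%s.tsv", ph)), seed, config)
    regions <- peakRegions(scan, sigThreshold(mres),
                           dropScale = config$drop_scale)
    report$scans[[ph]] <- scan
    report$regions[[ph]] <- regions
    if (!length(regions)) next

    reg <- regionalAssociation(x, regions, ph, config$delta_cutoff,
                               config$n_pcs, config$fwer)
    report$regional[[ph]] <- reg
    hits <- as.data.frame(reg@stats)
    hits <- hits$id[hits$pass_bonferroni]
    if (length(hits)) {
      cond <- conditionalScan(x, ph, snps = hits, regions = regions,
                              alpha = sigThreshold(mres))
      report$conditional[[ph]] <- cond
      if (!is.null(outDir))
        writeScanResults(cond, out(sprintf("conditional_%s.tsv", ph)),
                         seed, config)
      report$meta[[ph]] <- lapply(
        stats::setNames(hits, hits),
        function(id) tryCatch(
          stratifiedMeta(x, id, ph, config$min_stratum_n),
          error = function(e) conditionMessage(e)))
    }
  }

  if (!is.null(outDir)) {
    summary <- list(
      seed = seed, config_hash = report$config_hash,
      n_individuals = report$n_individuals,
      n_markers_in = report$n_markers_in,
      n_markers_qc = report$n_markers_qc,
      meff = report$meff, alpha = report$alpha,
      n_regions = vapply(report$regions, length, 0L),
      regional_hits = lapply(report$regional, function(r)
        as.data.frame(r@stats)$id[as.data.frame(r@stats)$pass_bonferroni]),
      verdicts = lapply(report$conditional, function(cc)
        as.data.frame(mediation(cc))[, c("region", "verdict")]))
    jsonlite::write_json(summary, out("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  class(report) <- "pipelineReport"
  report
}

#' @export
print.pipelineReport <- function(x, ...) {
  cat("admixscan pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  %d individuals, %d -> %d markers after QC\n",
              x$n_individuals, x$n_markers_in, x$n_markers_qc))
  cat(sprintf("  Meff = %.2f, alpha = %.3g\n", x$meff, x$alpha))
  for (ph in names(x$regions))
    cat(sprintf("  %s: %d significant region(s)\n", ph,
                length(x$regions[[ph]])))
  invisible(x)
}
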