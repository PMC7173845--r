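#' AdmixtureExperiment: genotypes and local ancestry over an admixed cohort
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with rows = markers
#' (a `GRanges` carrying marker metadata) and columns = individuals
#' (`colData` carrying the phenotype/covariate table). Two assays are
#' recognised:
#'
#' * `dosage` — alt-allele count per individual in \{0, 1, 2, NA\};
#' * `ancestry` — diploid local African ancestry proportion in
#'   \{0, 0.5, 1\} (African allele count / 2). Missing local ancestry is not
#'   allowed: the ancestry scan needs a call at every tested locus, so
#'   upstream local-ancestry inference must be complete.
#'
#' Marker metadata columns (on `rowRanges`): `id`, `ref`, `alt`, `f_eur`
#' and `f_afr` (alt-allele frequencies in the European and African reference
#' populations), `depth` (mean sequencing depth, used to break LD-pruning
#' ties) and `cM` (genetic-map position in centimorgans; stored per
#' chromosome).
#'
#' Cohort columns (on `colData`): `age` (years), `sex` (`"female"` /
#' `"male"`), `bmi` (kg/m^2), `on_bp_meds` (logical), `dbp_raw`, `sbp_raw`
#' (mmHg). [preparePhenotypes()] adds `dbp_adj`, `sbp_adj`, `map` and
#' `log10_sbp`.
#'
#' @section Validity:
#' Positions are non-decreasing within each chromosome (the constructor
#' sorts); ancestry values are restricted to \{0, 0.5, 1\}; dosages to
#' \{0, 1, 2, NA\}; reference frequencies lie in \[0, 1\]; `dbp_raw <
#' sbp_raw` for every individual.
#'
#' @aliases AdmixtureExperiment-class
#' @exportClass AdmixtureExperiment
setClass("AdmixtureExperiment",
         contains = "RangedSummarizedExperiment")

.validAdmixtureExperiment <- function(object) {
  msg <- character()
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    bychr <- split(GenomicRanges::start(rr),
                   as.character(GenomicRanges::seqnames(rr)))
    if (any(vapply(bychr, is.unsorted, logical(1))))
      msg <- c(msg, "marker positions must be sorted within chromosome")
    mc <- S4Vectors::mcols(rr)
    for (fcol in c("f_eur", "f_afr")) {
      if (fcol %in% names(mc)) {
        f <- mc[[fcol]]
        if (any(!is.na(f) & (f < 0 | f > 1)))
          msg <- c(msg, sprintf("%s outside [0, 1]", fcol))
      }
    }
  }
  anames <- SummarizedExperiment::assayNames(object)
  if ("ancestry" %in% anames) {
    L <- SummarizedExperiment::assay(object, "ancestry")
    if (anyNA(L))
      msg <- c(msg, "missing local ancestry is not allowed")
    else if (!all(L %in% c(0, 0.5, 1)))
      msg <- c(msg, "ancestry values must be in {0, 0.5, 1}")
  }
  if ("dosage" %in% anames) {
    g <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(g) & !(g %in% 0:2)
    if (any(bad))
      msg <- c(msg, "dosages must be in {0, 1, 2, NA}")
  }
  cd <- SummarizedExperiment::colData(object)
  if (all(c("dbp_raw", "sbp_raw") %in% names(cd))) {
    if (any(cd$dbp_raw >= cd$sbp_raw))
      msg <- c(msg, "dbp_raw must be < sbp_raw for every individual")
  }
  if (length(msg)) msg else TRUE
}

setValidity("AdmixtureExperiment", .validAdmixtureExperiment)

#' ScanResult: per-marker admixture-mapping statistics
#'
#' Holds the output of [admixtureScan()]: one row per tested marker with the
#' coefficient of (G - L) (`beta2`, mmHg per unit excess-global ancestry),
#' its standard error, two-sided p-value, LOD score and the number of
#' individuals used. Markers whose (G - L) predictor is degenerate carry
#' `NA` statistics and are counted in the show method rather than dropped.
#'
#' @slot stats `DataFrame` with columns `chrom`, `pos`, `id`, `beta2`, `se`,
#'   `p`, `lod`, `n_used`.
#' @slot phenotype name of the phenotype column scanned.
#' @slot covariates covariate column names used in the model.
#' @slot alpha significance level attached to the scan (may be `NA` until a
#'   threshold is chosen).
#' @slot conditioned ids of SNPs conditioned on (empty for a plain scan).
#' @aliases ScanResult-class
#' @exportClass ScanResult
setClass("ScanResult",
         representation(stats = "DataFrame",
                        phenotype = "character",
                        covariates = "character",
                        alpha = "numeric",
                        conditioned = "character"))

setValidity("ScanResult", function(object) {
  st <- object@stats
  need <- c("chrom", "pos", "id", "beta2", "se", "p", "lod", "n_used")
  if (!all(need %in% names(st)))
    return(paste("stats must have columns:", paste(need, collapse = ", ")))
  p <- st$p
  if (any(!is.na(p) & (p <= 0 | p > 1))) return("p-values must be in (0, 1]")
  if (any(!is.na(st$lod) & st$lod < 0)) return("LOD must be >= 0")
  TRUE
})

#' ConditionalScanResult: a scan adjusted for candidate SNP genotypes
#'
#' Extends [ScanResult-class] with a mediation table comparing each prior
#' peak's p-value before and after conditioning, and a verdict:
#' `fully_explained` (conditional p >= 0.05), `partially_explained`
#' (alpha <= p < 0.05) or `unexplained` (p < alpha).
#'
#' @slot mediation `DataFrame` with columns `region`, `peak_id`, `p_before`,
#'   `p_after`, `verdict`.
#' @aliases ConditionalScanResult-class
#' @exportClass ConditionalScanResult
setClass("ConditionalScanResult",
         contains = "ScanResult",
         representation(mediation = "DataFrame"))

#' MeffResult: effective number of tests and significance threshold
#'
#' Effective-sample-size matrix (individuals x chromosomes) of the
#' local-ancestry series, per-individual totals, their mean (the effective
#' number of tests Meff) and the family-wise threshold `alpha = fwer / Meff`.
#'
#' @slot ess matrix of per-individual, per-chromosome effective sizes.
#' @slot perIndividual per-individual sums over chromosomes.
#' @slot meff mean of the per-individual totals.
#' @slot fwer nominal family-wise error rate.
#' @slot alpha `fwer / meff`.
#' @slot negLog10Alpha `-log10(alpha)` rounded to 2 decimals for display.
#' @aliases MeffResult-class
#' @exportClass MeffResult
setClass("MeffResult",
         representation(ess = "matrix",
                        perIndividual = "numeric",
                        meff = "numeric",
                        fwer = "numeric",
                        alpha = "numeric",
                        negLog10Alpha = "numeric"))

setValidity("MeffResult", function(object) {
  if (object@meff <= 0) return("meff must be > 0")
  if (abs(object@alpha - object@fwer / object@meff) >
      1e-12 * object@alpha) return("alpha must equal fwer / meff")
  TRUE
})

#' QCReport: marker-level quality-control flags and removal counts
#'
#' One row per input marker with logical flags `fail_hwe`, `fail_maf`,
#' `fail_callrate`, `monomorphic` (all recorded even when a marker fails
#' several rules), plus the thresholds applied and summary counts. A marker
#' failing multiple rules is removed once.
#'
#' @slot flags `DataFrame` of per-marker flags, rownames = marker ids.
#' @slot counts named integer vector of removals per rule plus
#'   `removed_total` and `retained`.
#' @slot thresholds list with `hwe_p_min`, `maf_min`, `callrate_min`.
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
         representation(flags = "DataFrame",
                        counts = "integer",
                        thresholds = "list"))

#' RegionalResult: delta-filtered SNP association within significant regions
#'
#' Fine-mapping output of [regionalAssociation()]: per-SNP genotype effects
#' with PC adjustment, restricted to ancestry-differentiated SNPs
#' (delta > cutoff) inside admixture-mapping significant regions, with a
#' phenotype-level Bonferroni flag (the test count `mTested` spans all
#' regions scanned for that phenotype).
#'
#' @slot stats `DataFrame` with columns `chrom`, `pos`, `id`, `region`,
#'   `delta`, `beta`, `se`, `p`, `pass_bonferroni`.
#' @slot phenotype phenotype column name.
#' @slot mTested number of delta-selected SNPs tested for this phenotype.
#' @slot threshold Bonferroni threshold `fwer / mTested`.
#' @aliases RegionalResult-class
#' @exportClass RegionalResult
setClass("RegionalResult",
         representation(stats = "DataFrame",
                        phenotype = "character",
                        mTested = "integer",
                        threshold = "numeric"))

#' MetaResult: local-ancestry stratified genotypic test, DL-pooled
#'
#' Genotype association within each local-ancestry stratum (L = 0, 0.5, 1 at
#' the SNP), combined by DerSimonian-Laird random-effects meta-analysis.
#' Stratification replaces ancestry adjustment, so by construction the
#' per-stratum tests cannot be confounded by local ancestry.
#'
#' @slot strata `DataFrame` with per-stratum `stratum`, `n`, `beta`, `se`
#'   (usable strata only).
#' @slot excluded names of strata dropped for small n or constant dosage.
#' @slot Q Cochran heterogeneity statistic.
#' @slot tau2 DerSimonian-Laird between-stratum variance (>= 0).
#' @slot beta pooled random-effects estimate.
#' @slot se pooled standard error.
#' @slot p two-sided normal p-value of the pooled estimate.
#' @aliases MetaResult-class
#' @exportClass MetaResult
setClass("MetaResult",
         representation(strata = "DataFrame",
                        excluded = "character",
                        Q = "numeric",
                        tau2 = "numeric",
                        beta = "numeric",
                        se = "numeric",
                        p = "numeric"))

setValidity("MetaResult", function(object) {
  if (object@tau2 < 0) return("tau2 must be >= 0")
  TRUE
})
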