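#' Construct an AdmixtureExperiment
#'
#' Assembles marker metadata, optional dosage and local-ancestry assays and a
#' cohort table into a validated [AdmixtureExperiment-class]. Markers are
#' sorted by (chromosome, position); assays are reordered accordingly.
#' Assays are oriented markers x individuals (the SummarizedExperiment
#' convention of features in rows).
#'
#' @param markers `GRanges` of marker positions (width-1 ranges) with
#'   metadata columns `id` and optionally `ref`, `alt`, `f_eur`, `f_afr`,
#'   `depth`, `cM`. If `cM` is absent it is derived from position at
#'   1 cM/Mb.
#' @param dosage optional markers x individuals matrix of alt-allele counts
#'   in \{0, 1, 2, NA\}.
#' @param ancestry optional markers x individuals matrix of diploid local
#'   African ancestry proportions in \{0, 0.5, 1\}.
#' @param cohort optional `data.frame`/`DataFrame` of per-individual
#'   phenotypes and covariates, rownames (or column `individual_id`) =
#'   individual ids.
#' @return An `AdmixtureExperiment`.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                              id = c("m1", "m2"))
#' L <- matrix(c(0, 0.5, 1, 0.5), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("i1", "i2")))
#' AdmixtureExperiment(markers = gr, ancestry = L)
#' @export
AdmixtureExperiment <- function(markers, dosage = NULL, ancestry = NULL,
                                cohort = NULL) {
  stopifnot(is(markers, "GRanges"))
  if (is.null(S4Vectors::mcols(markers)$id))
    S4Vectors::mcols(markers)$id <- paste0("m", seq_along(markers))
  if (is.null(S4Vectors::mcols(markers)$cM))
    S4Vectors::mcols(markers)$cM <- GenomicRanges::start(markers) / 1e6
  names(markers) <- S4Vectors::mcols(markers)$id
  if (anyDuplicated(names(markers)))
    stop("duplicate marker ids")

  assays <- list()
  if (!is.null(dosage)) assays$dosage <- as.matrix(dosage)
  if (!is.null(ancestry)) assays$ancestry <- as.matrix(ancestry)
  if (!length(assays))
    stop("at least one of 'dosage' or 'ancestry' is required")

  ids <- Reduce(function(a, b) {
    if (is.null(a)) b else {
      if (!is.null(b) && !identical(a, b))
        stop("assays disagree on individual ids/order")
      a
    }
  }, lapply(assays, colnames), NULL)
  if (is.null(ids))
    ids <- paste0("ind", seq_len(ncol(assays[[1]])))
  assays <- lapply(assays, function(a) { colnames(a) <- ids; a })
  if (anyDuplicated(ids)) stop("duplicate individual ids")

  if (is.null(cohort)) {
    cd <- S4Vectors::DataFrame(row.names = ids)
  } else {
    cd <- S4Vectors::DataFrame(cohort)
    if ("individual_id" %in% names(cd)) {
      rownames(cd) <- cd$individual_id
      cd$individual_id <- NULL
    }
    if (!all(ids %in% rownames(cd)))
      stop("cohort table is missing individuals: ",
           paste(setdiff(ids, rownames(cd)), collapse = ", "))
    cd <- cd[ids, , drop = FALSE]
  }

  ord <- order(as.factor(GenomicRanges::seqnames(markers)),
               GenomicRanges::start(markers))
  markers <- markers[ord]
  assays <- lapply(assays, function(a) {
    rownames(a) <- NULL
    a <- a[ord, , drop = FALSE]
    rownames(a) <- names(markers)
    a
  })

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = markers, colData = cd)
  new("AdmixtureExperiment", se)
}

#' @describeIn AdmixtureExperiment alt-allele dosage matrix
#'   (markers x individuals).
#' @param x an `AdmixtureExperiment`.
#' @export
setMethod("dosage", "AdmixtureExperiment", function(x) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(x))
    stop("object has no 'dosage' assay")
  SummarizedExperiment::assay(x, "dosage")
})

#' @describeIn AdmixtureExperiment diploid local African ancestry matrix
#'   (markers x individuals).
#' @export
setMethod("ancestry", "AdmixtureExperiment", function(x) {
  if (!"ancestry" %in% SummarizedExperiment::assayNames(x))
    stop("object has no 'ancestry' assay")
  SummarizedExperiment::assay(x, "ancestry")
})

#' @describeIn AdmixtureExperiment marker `GRanges` with metadata.
#' @export
setMethod("markerInfo", "AdmixtureExperiment", function(x)
  SummarizedExperiment::rowRanges(x))

#' @describeIn AdmixtureExperiment cohort table as a `data.frame`.
#' @export
setMethod("cohort", "AdmixtureExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Ancestral allele-frequency differential of each marker
#'
#' delta = |f_afr - f_eur| per marker; high-delta SNPs are
#' ancestry-informative (see [deltaStatistic()]).
#'
#' @param x an `AdmixtureExperiment` whose markers carry `f_eur`, `f_afr`.
#' @return named numeric vector of deltas.
#' @export
markerDelta <- function(x) {
  mc <- S4Vectors::mcols(markerInfo(x))
  if (!all(c("f_eur", "f_afr") %in% names(mc)))
    stop("markers carry no reference allele frequencies")
  stats::setNames(abs(mc$f_afr - mc$f_eur), mc$id)
}

setMethod("show", "AdmixtureExperiment", function(object) {
  cat("AdmixtureExperiment:", nrow(object), "markers x",
      ncol(object), "individuals\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  chr <- as.character(GenomicRanges::seqnames(markerInfo(object)))
  cat("  chromosomes:", length(unique(chr)), "\n")
  cd <- names(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  cohort columns:", paste(cd, collapse = ", "), "\n")
})

#' @describeIn ScanResult scan statistics as a `data.frame`.
#' @param x a `ScanResult`.
#' @export
setMethod("scanStats", "ScanResult", function(x) as.data.frame(x@stats))

#' @describeIn ScanResult significance level attached to the scan.
#' @export
setMethod("sigThreshold", "ScanResult", function(x) x@alpha)

setMethod("show", "ScanResult", function(object) {
  st <- object@stats
  ok <- !is.na(st$p)
  cat("ScanResult:", nrow(st), "markers, phenotype", object@phenotype, "\n")
  if (length(object@conditioned))
    cat("  conditioned on:", paste(object@conditioned, collapse = ", "), "\n")
  if (any(!ok)) cat("  degenerate markers (NA stats):", sum(!ok), "\n")
  if (any(ok)) {
    i <- which.min(st$p)
    cat(sprintf("  top: %s (%s:%d)  beta2 = %.3g  p = %.3g\n",
                st$id[i], st$chrom[i], st$pos[i], st$beta2[i], st$p[i]))
  }
  if (!is.na(object@alpha))
    cat(sprintf("  alpha = %.3g; significant markers: %d\n", object@alpha,
                sum(ok & st$p < object@alpha)))
})

#' @describeIn ConditionalScanResult per-peak mediation table
#'   (`p_before`, `p_after`, `verdict`).
#' @param x a `ConditionalScanResult`.
#' @export
setMethod("mediation", "ConditionalScanResult", function(x)
  as.data.frame(x@mediation))

setMethod("show", "ConditionalScanResult", function(object) {
  callNextMethod()
  m <- object@mediation
  if (nrow(m))
    for (i in seq_len(nrow(m)))
      cat(sprintf("  %s: p %.3g -> %.3g (%s)\n", m$region[i],
                  m$p_before[i], m$p_after[i], m$verdict[i]))
})

#' @describeIn MeffResult the effective number of tests (mean over
#'   individuals of per-individual chromosome-summed effective sizes).
#' @param x a `MeffResult`.
#' @export
setMethod("meff", "MeffResult", function(x) x@meff)

#' @describeIn MeffResult the family-wise threshold `fwer / meff`.
#' @export
setMethod("sigThreshold", "MeffResult", function(x) x@alpha)

setMethod("show", "MeffResult", function(object) {
  cat(sprintf(
    "MeffResult: Meff = %.2f over %d individuals x %d chromosomes\n",
    object@meff, nrow(object@ess), ncol(object@ess)))
  cat(sprintf("  alpha = %.4g / %.2f = %.3g (-log10 = %.2f)\n",
              object@fwer, object@meff, object@alpha, object@negLog10Alpha))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", nrow(object@flags), "markers in\n")
  for (nm in names(object@counts))
    cat(sprintf("  %s: %d\n", nm, object@counts[[nm]]))
})

setMethod("show", "RegionalResult", function(object) {
  cat("RegionalResult:", nrow(object@stats), "delta-selected SNPs,",
      "phenotype", object@phenotype, "\n")
  cat(sprintf("  Bonferroni: %.4g / %d = %.3g; passing: %d\n",
              object@threshold * object@mTested, object@mTested,
              object@threshold, sum(object@stats$pass_bonferroni)))
})

setMethod("show", "MetaResult", function(object) {
  cat("MetaResult:", nrow(object@strata), "ancestry strata\n")
  cat(sprintf("  Q = %.3g, tau2 = %.3g\n", object@Q, object@tau2))
  cat(sprintf("  pooled beta = %.3g (SE %.3g), p = %.3g\n",
              object@beta, object@se, object@p))
  if (length(object@excluded))
    cat("  excluded strata:", paste(object@excluded, collapse = ", "), "\n")
})
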