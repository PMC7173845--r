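#' Global ancestry from local ancestry
#'
#' An individual's global African ancestry G is the average of their
#' diploid local ancestry across every marker in the panel (the exome-wide
#' average in an exome design).
#'
#' @param x an `AdmixtureExperiment` with an `ancestry` assay (no missing
#'   values), or a markers x individuals matrix.
#' @return named numeric vector of per-individual G in \[0, 1\], with the
#'   cohort mean and SD in attributes `mean` and `sd`.
#' @export
setMethod("globalAncestry", "AdmixtureExperiment", function(x)
  globalAncestry(ancestry(x)))

#' @rdname globalAncestry-AdmixtureExperiment-method
#' @export
setMethod("globalAncestry", "matrix", function(x) {
  if (!nrow(x)) stop("zero markers")
  if (anyNA(x)) stop("missing local ancestry")
  G <- colMeans(x)
  attr(G, "mean") <- mean(G)
  attr(G, "sd") <- stats::sd(G)
  G
})

#' Ancestry switch points per individual
#'
#' Counts, per individual, the adjacent within-chromosome marker pairs at
#' which the diploid local ancestry value changes. Chromosome boundaries
#' are never counted. Markers must be sorted by (chromosome, position) —
#' the `AdmixtureExperiment` constructor guarantees this.
#'
#' @param x an `AdmixtureExperiment` with an `ancestry` assay.
#' @return named integer vector of per-individual switch counts.
#' @export
setMethod("switchPoints", "AdmixtureExperiment", function(x) {
  L <- ancestry(x)
  gr <- markerInfo(x)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bychr <- split(GenomicRanges::start(gr), chrom)
  if (any(vapply(bychr, is.unsorted, logical(1))))
    stop("markers are not sorted within chromosome")
  total <- integer(ncol(L))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    if (length(idx) < 2) next
    total <- total +
      colSums(L[idx[-1], , drop = FALSE] !=
                L[idx[-length(idx)], , drop = FALSE])
  }
  stats::setNames(as.integer(total), colnames(L))
})

#' Ancestral allele-frequency differential (delta)
#'
#' `delta = |f_afr - f_eur|`, the absolute difference of a SNP's alt-allele
#' frequency between the African and European reference populations.
#' High-delta SNPs are ancestry-informative and are the fine-mapping
#' candidates inside admixture-mapping significant regions. The absolute
#' value makes delta symmetric in the two populations and independent of
#' allele labeling; it is bounded in \[0, 1\].
#'
#' @param f_eur,f_afr alt-allele frequencies in \[0, 1\] (vectorized).
#' @return delta in \[0, 1\].
#' @examples
#' deltaStatistic(0.34, 0.85)  # 0.51
#' @export
deltaStatistic <- function(f_eur, f_afr) {
  .assertProb(f_eur, "f_eur")
  .assertProb(f_afr, "f_afr")
  abs(f_afr - f_eur)
}

#' Correlation between global ancestry and a phenotype
#'
#' Pearson correlation of per-individual global African ancestry with a
#' phenotype, with the two-sided p-value from the t distribution on n - 2
#' degrees of freedom.
#'
#' @param G numeric vector of global ancestry proportions.
#' @param phenotype numeric vector, same length, n >= 3.
#' @return list with `r`, `p` and `n`.
#' @export
ancestryPhenotypeCorrelation <- function(G, phenotype) {
  if (length(G) != length(phenotype)) stop("lengths differ")
  ok <- stats::complete.cases(G, phenotype)
  G <- G[ok]; phenotype <- phenotype[ok]
  if (length(G) < 3) stop("need n >= 3")
  if (stats::sd(G) == 0 || stats::sd(phenotype) == 0)
    stop("constant input")
  ct <- stats::cor.test(G, phenotype)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(G))
}
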