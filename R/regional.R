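# Regional fine-mapping inside admixture-mapping significant regions:
# SNPs with a large ancestral allele-frequency differential are tested for
# genotype association with PC adjustment, Bonferroni-corrected at the
# phenotype level, and probed for ancestry confounding by local-ancestry
# stratified tests pooled with DerSimonian-Laird random effects.

#' Select ancestry-differentiated SNPs within a region
#'
#' Markers lying inside the region (1-based inclusive) whose delta
#' statistic `|f_afr - f_eur|` is strictly greater than the cutoff. SNPs
#' that drive an ancestry association must differ in frequency between the
#' ancestral populations, so only these are informative fine-mapping
#' candidates.
#'
#' @param x an `AdmixtureExperiment` whose markers carry `f_eur`, `f_afr`.
#' @param region a length-1 `GRanges` (as produced by [peakRegions()]).
#' @param deltaCutoff strict lower bound on delta.
#' @return character vector of selected marker ids (empty, with a warning,
#'   when the region holds no qualifying marker).
#' @export
selectDeltaSnps <- function(x, region, deltaCutoff = 0.4) {
  stopifnot(is(region, "GRanges"), length(region) == 1)
  gr <- markerInfo(x)
  inside <- IRanges::overlapsAny(gr, region)
  delta <- markerDelta(x)
  sel <- inside & !is.na(delta) & delta > deltaCutoff
  if (!any(sel))
    warning("no markers with delta > ", deltaCutoff, " in region")
  S4Vectors::mcols(gr)$id[sel]
}

#' Principal components of the genotype matrix
#'
#' PCs of the column-standardized dosage matrix (individuals as
#' observations): monomorphic markers are dropped, missing dosages are
#' filled with the marker mean before standardization, and components are
#' ordered by decreasing variance explained. Used to adjust the SNP model
#' for population structure.
#'
#' @param x an `AdmixtureExperiment` with a `dosage` assay.
#' @param k number of components (0 gives an empty matrix).
#' @return individuals x k matrix of PC scores (columns `PC1..PCk`).
#' @export
computePCs <- function(x, k = 10L) {
  dos <- dosage(x)
  n <- ncol(dos)
  if (k == 0) return(matrix(numeric(0), n, 0,
                            dimnames = list(colnames(dos), NULL)))
  mu <- rowMeans(dos, na.rm = TRUE)
  filled <- dos
  filled[is.na(filled)] <- mu[row(filled)[is.na(filled)]]
  sdv <- apply(filled, 1, stats::sd)
  keep <- !is.na(sdv) & sdv > 0
  if (sum(keep) < k) stop("fewer polymorphic markers than requested PCs")
  M <- scale(t(filled[keep, , drop = FALSE]))  # individuals x markers
  if (n <= k) stop("need more than k individuals")
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  if (ncol(pc$x) < k) stop("requested k exceeds achievable rank")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(dos)
  scores
}

#' Single-SNP genotype association
#'
#' OLS of the phenotype on allele dosage with age, age^2, sex, BMI and the
#' supplied principal components as covariates; beta is the effect per alt
#' allele (mmHg on the untransformed phenotypes). Individuals with missing
#' dosage are dropped listwise.
#'
#' @param phenotype numeric vector.
#' @param dosg dosage vector in \{0, 1, 2, NA\}, non-constant on the
#'   analyzed individuals.
#' @param covariates data.frame with `age`, `sex`, `bmi`.
#' @param pcs optional individuals x k PC score matrix.
#' @return list with `beta`, `se`, `p`, `n`.
#' @export
snpAssociation <- function(phenotype, dosg, covariates, pcs = NULL) {
  Z <- .covariateDesign(covariates)
  if (!is.null(pcs) && ncol(pcs)) Z <- cbind(Z, pcs)
  use <- stats::complete.cases(cbind(phenotype, dosg, Z))
  y <- phenotype[use]; d <- dosg[use]; Z <- Z[use, , drop = FALSE]
  if (length(unique(d)) < 2) stop("monomorphic dosage")
  fit <- .olsFit(y, cbind(Z, dosage = d), "dosage")
  list(beta = fit$beta, se = fit$se, p = fit$p, n = fit$n)
}

#' Regional association with delta filter, PCs and Bonferroni correction
#'
#' For each significant region, tests every SNP with delta > cutoff using
#' [snpAssociation()]. The Bonferroni threshold uses the total number of
#' delta-selected SNPs across all supplied regions (the per-phenotype test
#' count), not a per-region count.
#'
#' @param x an `AdmixtureExperiment` with `dosage` (post-QC) and phenotype
#'   columns.
#' @param regions `GRanges` of significant regions.
#' @param phenotype phenotype column name.
#' @param deltaCutoff strict delta cutoff.
#' @param nPcs number of principal components.
#' @param fwer family-wise error rate for the Bonferroni flag.
#' @return a [RegionalResult-class].
#' @export
regionalAssociation <- function(x, regions, phenotype = "dbp_adj",
                                deltaCutoff = 0.4, nPcs = 10L,
                                fwer = 0.05) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!phenotype %in% names(cd))
    stop("no phenotype column '", phenotype, "'")
  y <- cd[[phenotype]]
  pcs <- computePCs(x, nPcs)
  dos <- dosage(x)
  delta <- markerDelta(x)

  rows <- list()
  for (i in seq_along(regions)) {
    ids <- suppressWarnings(selectDeltaSnps(x, regions[i], deltaCutoff))
    for (id in ids) {
      res <- tryCatch(
        snpAssociation(y, dos[id, ], cd, pcs),
        error = function(e) list(beta = NA_real_, se = NA_real_,
                                 p = NA_real_, n = NA_integer_))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions[i])),
        pos = GenomicRanges::start(markerInfo(x))[
          match(id, S4Vectors::mcols(markerInfo(x))$id)],
        id = id,
        region = sprintf("%s:%d-%d",
                         as.character(GenomicRanges::seqnames(regions[i])),
                         GenomicRanges::start(regions[i]),
                         GenomicRanges::end(regions[i])),
        delta = unname(delta[id]),
        beta = res$beta, se = res$se, p = res$p)
    }
  }
  if (!length(rows)) {
    st <- S4Vectors::DataFrame(chrom = character(0), pos = integer(0),
                               id = character(0), region = character(0),
                               delta = numeric(0), beta = numeric(0),
                               se = numeric(0), p = numeric(0),
                               pass_bonferroni = logical(0))
    return(new("RegionalResult", stats = st, phenotype = phenotype,
               mTested = 0L, threshold = fwer))
  }
  df <- do.call(rbind, rows)
  m <- nrow(df)
  thr <- fwer / m
  df$pass_bonferroni <- !is.na(df$p) & df$p < thr
  new("RegionalResult", stats = S4Vectors::DataFrame(df),
      phenotype = phenotype, mTested = as.integer(m), threshold = thr)
}

#' Bonferroni flags at a phenotype-level test count
#'
#' `pass <=> p < fwer / mTested`, where `mTested` counts all
#' delta-selected SNPs tested for the phenotype across its significant
#' regions.
#'
#' @param p vector of p-values.
#' @param mTested number of tests (>= 1).
#' @param fwer family-wise error rate.
#' @return logical vector of pass flags, with the threshold in
#'   `attr(, "threshold")`.
#' @examples
#' bonferroniFlag(9.57e-4, 21)  # TRUE: 9.57e-4 < 0.05/21 = 2.38e-3
#' @export
bonferroniFlag <- function(p, mTested, fwer = 0.05) {
  if (mTested < 1) stop("mTested must be >= 1")
  out <- !is.na(p) & p < fwer / mTested
  attr(out, "threshold") <- fwer / mTested
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Given per-stratum estimates and standard errors: fixed-effect weights
#' `w_i = 1 / SE_i^2`, heterogeneity `Q = sum w_i (b_i - b_FE)^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effect
#' weights `w*_i = 1 / (SE_i^2 + tau2)`, pooled
#' `b = sum w* b / sum w*` with `SE = (sum w*)^(-1/2)` and a two-sided
#' normal p-value.
#'
#' @param beta,se numeric vectors of per-stratum estimates and SEs
#'   (length >= 2).
#' @return list with `Q`, `tau2`, `beta`, `se`, `p`.
#' @examples
#' dlPool(c(1, 3), c(1, 1))  # Q = 2, tau2 = 1, beta = 2, se = 1
#' @export
dlPool <- function(beta, se) {
  k <- length(beta)
  if (k < 2 || length(se) != k) stop("need >= 2 strata")
  if (any(se <= 0)) stop("se must be > 0")
  w <- 1 / se^2
  bFE <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bFE)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- sqrt(1 / sum(ws))
  list(Q = Q, tau2 = tau2, beta = b, se = s,
       p = 2 * stats::pnorm(-abs(b / s)))
}

#' Local-ancestry stratified genotypic test with random-effects pooling
#'
#' Splits the cohort by diploid local ancestry at the SNP (L = 0, 0.5, 1),
#' fits the genotype model within each stratum (covariates age, age^2,
#' sex, BMI — no PCs, since stratification itself removes local-ancestry
#' confounding), and pools the per-stratum effects with
#' DerSimonian-Laird random-effects meta-analysis. Strata with fewer than
#' `minStratumN` individuals or constant dosage are excluded and recorded;
#' fewer than two usable strata is an error (the SNP is not assessable this
#' way).
#'
#' @param x an `AdmixtureExperiment` with `dosage` and `ancestry` assays
#'   and phenotype columns.
#' @param snp marker id.
#' @param phenotype phenotype column name.
#' @param minStratumN minimum stratum size.
#' @param adjustCovariates fit age/age^2/sex/BMI within strata (`FALSE`
#'   for intercept-plus-dosage fits).
#' @return a [MetaResult-class].
#' @export
stratifiedMeta <- function(x, snp, phenotype = "dbp_adj",
                           minStratumN = 30L, adjustCovariates = TRUE) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!phenotype %in% names(cd))
    stop("no phenotype column '", phenotype, "'")
  dos <- dosage(x)
  L <- ancestry(x)
  if (!snp %in% rownames(dos)) stop("unknown SNP: ", snp)
  d <- dos[snp, ]
  la <- L[snp, ]
  y <- cd[[phenotype]]

  fits <- list(); excluded <- character()
  for (lev in c(0, 0.5, 1)) {
    nm <- sprintf("L=%g", lev)
    sel <- which(la == lev & !is.na(d) & !is.na(y))
    if (length(sel) < minStratumN) {
      excluded <- c(excluded, nm); next
    }
    if (length(unique(d[sel])) < 2) {
      excluded <- c(excluded, nm); next
    }
    fit <- tryCatch({
      if (adjustCovariates)
        snpAssociation(y[sel], d[sel], cd[sel, , drop = FALSE])
      else {
        f <- .olsFit(y[sel], cbind(`(Intercept)` = 1, dosage = d[sel]),
                     "dosage")
        list(beta = f$beta, se = f$se, p = f$p, n = f$n)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) { excluded <- c(excluded, nm); next }
    fits[[nm]] <- fit
  }
  if (length(fits) < 2)
    stop("fewer than 2 usable ancestry strata; SNP not assessable")
  strata <- S4Vectors::DataFrame(
    stratum = names(fits),
    n = vapply(fits, `[[`, 0, "n"),
    beta = vapply(fits, `[[`, 0, "beta"),
    se = vapply(fits, `[[`, 0, "se"))
  pool <- dlPool(strata$beta, strata$se)
  new("MetaResult", strata = strata, excluded = excluded,
      Q = pool$Q, tau2 = pool$tau2, beta = pool$beta, se = pool$se,
      p = pool$p)
}
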