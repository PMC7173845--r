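# Admixture-mapping scan: per-locus OLS of a blood-pressure phenotype on
# global ancestry G, the excess term (G - L), and age, age^2, sex, BMI.
# beta2, the coefficient of (G - L), measures the local response after the
# global ancestral effect carried by every locus; note its sign is opposite
# to the effect of *local* African ancestry itself.

# OLS fit with rank checking; returns the named coefficient's statistics
.olsFit <- function(y, X, target) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- length(y)
  df <- n - ncol(X)
  if (df < 2) stop("too few observations for the model")
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot),
                               drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  j <- match(target, colnames(X))
  list(beta = unname(beta[j]), se = unname(se[j]), p = unname(p[j]),
       n = n, df = df, coefficients = beta)
}

# covariate design shared by the ancestry and SNP models: intercept, age,
# age^2 (constructed internally), sex (female = 0, male = 1), BMI
.covariateDesign <- function(covariates) {
  need <- c("age", "sex", "bmi")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariates: ",
                         paste(miss, collapse = ", "))
  sex <- covariates$sex
  sexnum <- if (is.numeric(sex)) sex else as.numeric(sex == "male")
  cbind(`(Intercept)` = 1, age = covariates$age, age2 = covariates$age^2,
        sex = sexnum, bmi = covariates$bmi)
}

#' Fit the admixture-mapping model at one locus
#'
#' OLS of `phenotype ~ G + (G - L) + age + age^2 + sex + BMI`
#' (age-squared is constructed internally). Returns the coefficient of
#' (G - L), its standard error and the two-sided t-test p-value.
#'
#' @param phenotype numeric vector (mmHg, or log10 mmHg for systolic BP).
#' @param G per-individual global African ancestry.
#' @param L diploid local African ancestry at the locus, in \{0, 0.5, 1\}.
#' @param covariates data.frame with `age`, `sex`, `bmi`.
#' @param conditionDosages optional matrix (individuals x SNPs) of
#'   conditioning genotypes added as covariates.
#' @return list with `beta2`, `se`, `p`, `n`.
#' @export
fitAdmixtureModel <- function(phenotype, G, L, covariates,
                              conditionDosages = NULL) {
  gl <- G - L
  if (stats::sd(gl) == 0)
    stop("degenerate design: G - L is constant (local equals global ",
         "ancestry for every individual)")
  Z <- cbind(.covariateDesign(covariates), G = G)
  if (!is.null(conditionDosages)) {
    cd <- as.matrix(conditionDosages)
    if (is.null(colnames(cd))) colnames(cd) <- paste0("snp", seq_len(ncol(cd)))
    Z <- cbind(Z, cd)
  }
  X <- cbind(Z, GminusL = gl)
  fit <- .olsFit(phenotype, X, "GminusL")
  list(beta2 = fit$beta, se = fit$se, p = fit$p, n = fit$n)
}

#' LOD score from a Wald statistic
#'
#' `LOD = (beta / se)^2 / (2 ln 10)`, the chi-squared Wald statistic on the
#' log10 scale. For 1-df tests this is asymptotically consistent with
#' -log10(p) and is the scale on which significant regions are delimited by
#' a one-unit drop from the peak.
#'
#' @param beta2,se coefficient and standard error (vectorized; `se > 0`).
#' @return LOD score(s), >= 0.
#' @export
lodFromWald <- function(beta2, se) {
  if (any(!is.na(se) & se <= 0)) stop("se must be > 0")
  (beta2 / se)^2 / (2 * log(10))
}

#' Genome-wide admixture-mapping scan
#'
#' Fits the admixture-mapping model at every marker of the ancestry assay.
#' Global ancestry is computed once as the exome-wide average of local
#' ancestry. The per-marker fits share one residualization of the common
#' covariates (Frisch-Waugh-Lovell), which is algebraically identical to
#' refitting the full model at each marker. Markers with a degenerate
#' (G - L) predictor get `NA` statistics and are counted in a warning, not
#' silently dropped.
#'
#' @param x an `AdmixtureExperiment` with an `ancestry` assay and phenotype
#'   columns (run [preparePhenotypes()] first).
#' @param phenotype name of the phenotype column to scan (e.g. `"dbp_adj"`,
#'   `"map"`, `"log10_sbp"`).
#' @param conditionOn optional conditioning SNPs: marker ids present in the
#'   `dosage` assay, or an individuals x SNPs dosage matrix. Individuals
#'   with missing conditioning dosage are dropped listwise.
#' @param alpha significance level to attach to the result (`NA` to leave
#'   unset).
#' @return a [ScanResult-class] (a [ConditionalScanResult-class] carrying a
#'   mediation table is returned by [conditionalScan()]).
#' @export
admixtureScan <- function(x, phenotype = "dbp_adj", conditionOn = NULL,
                          alpha = NA_real_) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!phenotype %in% names(cd))
    stop("no phenotype column '", phenotype,
         "'; run preparePhenotypes() first")
  L <- ancestry(x)
  if (!ncol(L)) stop("no individuals")
  G <- as.numeric(globalAncestry(L))

  cond <- NULL
  condIds <- character()
  if (!is.null(conditionOn) && length(conditionOn)) {
    if (is.character(conditionOn)) {
      condIds <- conditionOn
      dos <- dosage(x)
      miss <- setdiff(condIds, rownames(dos))
      if (length(miss)) stop("conditioning SNPs not found: ",
                             paste(miss, collapse = ", "))
      cond <- t(dos[condIds, , drop = FALSE])
    } else {
      cond <- as.matrix(conditionOn)
      condIds <- colnames(cond)
      if (is.null(condIds)) condIds <- paste0("snp", seq_len(ncol(cond)))
      colnames(cond) <- condIds
    }
  }

  y <- cd[[phenotype]]
  Z <- .covariateDesign(cd)
  if (stats::sd(G) > 0) Z <- cbind(Z, G = G)
  else warning("global ancestry is constant; dropped from the model")
  if (!is.null(cond)) Z <- cbind(Z, cond)
  use <- stats::complete.cases(cbind(y, Z))
  if (!any(use)) stop("zero usable individuals")
  y <- y[use]; Z <- Z[use, , drop = FALSE]
  Lu <- L[, use, drop = FALSE]
  Gu <- G[use]
  n <- length(y)

  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("covariates are rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  ry <- qr.resid(qz, y)
  # (G - L) per marker, residualized on the covariates in one pass
  X <- matrix(Gu, n, nrow(Lu)) - t(Lu)
  RX <- qr.resid(qz, X)
  sxx <- colSums(RX^2)
  sxy <- colSums(RX * ry)
  syy <- sum(ry^2)
  df <- n - ncol(Z) - 1L
  if (df < 2) stop("too few individuals for the model")
  degenerate <- sxx < n * 1e-12
  beta <- ifelse(degenerate, NA_real_, sxy / sxx)
  sigma2 <- pmax(syy - beta * sxy, 0) / df
  se <- ifelse(degenerate, NA_real_, sqrt(sigma2 / sxx))
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  p <- pmax(p, .Machine$double.xmin)
  if (any(degenerate))
    warning(sum(degenerate), " marker(s) with degenerate (G - L); ",
            "statistics set to NA")

  gr <- markerInfo(x)
  st <- S4Vectors::DataFrame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    id = S4Vectors::mcols(gr)$id,
    beta2 = beta, se = se, p = p,
    lod = ifelse(degenerate, NA_real_, lodFromWald(beta, se)),
    n_used = rep(n, length(gr)))
  new("ScanResult",
      stats = st, phenotype = phenotype,
      covariates = c("age", "age2", "sex", "bmi", "G", condIds),
      alpha = alpha, conditioned = condIds)
}

#' Significant regions by one-unit LOD drop
#'
#' Identifies, per chromosome, each significant peak (a local maximum of
#' the score with `p < alpha`) and extends it left and right to the furthest contiguous
#' markers whose score is within `drop` of the peak (score = LOD by
#' default, or -log10 p). Overlapping spans from multiple peaks are merged,
#' keeping the best peak. Region bounds are the first/last qualifying
#' marker positions (1-based inclusive) — no interpolation, since exome
#' markers are sparse.
#'
#' @param scan a [ScanResult-class].
#' @param alpha significance level (e.g. `sigThreshold(effectiveTests(x))`).
#' @param drop score drop delimiting the region (1 approximates a 95%
#'   confidence interval).
#' @param dropScale `"lod"` or `"mlog10p"`.
#' @return `GRanges` of regions with peak statistics in `mcols`; empty when
#'   nothing is significant.
#' @export
peakRegions <- function(scan, alpha, drop = 1,
                        dropScale = c("lod", "mlog10p")) {
  dropScale <- match.arg(dropScale)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  st <- as.data.frame(scan@stats)
  empty <- GenomicRanges::GRanges()
  spans <- list()
  for (chr in unique(st$chrom)) {
    cs <- st[st$chrom == chr & !is.na(st$p), , drop = FALSE]
    if (!nrow(cs)) next
    score <- if (dropScale == "lod") cs$lod else -log10(cs$p)
    sig <- cs$p < alpha
    m <- nrow(cs)
    localmax <- sig & score >= c(-Inf, score[-m]) &
      score >= c(score[-1], -Inf)
    claimed <- rep(FALSE, m)
    for (peak in intersect(order(-score), which(localmax))) {
      if (claimed[peak]) next
      lo <- peak
      while (lo > 1 && score[lo - 1] >= score[peak] - drop) lo <- lo - 1
      hi <- peak
      while (hi < nrow(cs) && score[hi + 1] >= score[peak] - drop)
        hi <- hi + 1
      claimed[lo:hi] <- TRUE
      spans[[length(spans) + 1]] <- data.frame(
        chrom = chr, start = cs$pos[lo], end = cs$pos[hi],
        peak_id = cs$id[peak], peak_pos = cs$pos[peak],
        peak_beta2 = cs$beta2[peak], peak_se = cs$se[peak],
        peak_p = cs$p[peak], peak_lod = cs$lod[peak],
        n_markers = hi - lo + 1)
    }
  }
  if (!length(spans)) return(empty)
  sp <- do.call(rbind, spans)
  gr <- GenomicRanges::GRanges(sp$chrom,
                               IRanges::IRanges(sp$start, sp$end))
  S4Vectors::mcols(gr) <- sp[, -(1:3)]
  # merge overlapping spans, keeping the best (smallest peak p) peak
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(red, gr)
  keep <- vapply(seq_along(red), function(i) {
    js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    js[which.min(S4Vectors::mcols(gr)$peak_p[js])]
  }, integer(1))
  S4Vectors::mcols(red) <- S4Vectors::mcols(gr)[keep, , drop = FALSE]
  sort(red)
}

#' Conditional admixture mapping
#'
#' Re-runs the ancestry scan with candidate SNP genotypes as covariates and
#' reports, for each previously significant region, the peak p-value before
#' and after conditioning with a verdict: `fully_explained` (conditional
#' p >= 0.05 — the ancestry signal is accounted for by the SNPs),
#' `partially_explained` (`alpha <= p < 0.05`) or `unexplained`
#' (`p < alpha`).
#'
#' @param x an `AdmixtureExperiment` with `ancestry` and `dosage` assays.
#' @param phenotype phenotype column name.
#' @param snps conditioning SNP ids (or an individuals x SNPs dosage
#'   matrix); an empty set reproduces the unconditional scan.
#' @param regions `GRanges` from [peakRegions()]; computed internally from
#'   the unconditional scan when `NULL`.
#' @param alpha significance level used for the verdicts (and for deriving
#'   `regions` when needed).
#' @return a [ConditionalScanResult-class].
#' @export
conditionalScan <- function(x, phenotype = "dbp_adj", snps = character(),
                            regions = NULL, alpha = 0.05 / 1) {
  if (is.null(regions)) {
    base <- admixtureScan(x, phenotype, alpha = alpha)
    regions <- peakRegions(base, alpha)
  }
  scan <- admixtureScan(x, phenotype, conditionOn = snps, alpha = alpha)
  st <- as.data.frame(scan@stats)
  med <- S4Vectors::DataFrame(
    region = character(0), peak_id = character(0),
    p_before = numeric(0), p_after = numeric(0), verdict = character(0))
  if (length(regions)) {
    mc <- S4Vectors::mcols(regions)
    p_after <- st$p[match(mc$peak_id, st$id)]
    verdict <- ifelse(p_after >= 0.05, "fully_explained",
                      ifelse(p_after >= alpha, "partially_explained",
                             "unexplained"))
    med <- S4Vectors::DataFrame(
      region = sprintf("%s:%d-%d",
                       as.character(GenomicRanges::seqnames(regions)),
                       GenomicRanges::start(regions),
                       GenomicRanges::end(regions)),
      peak_id = mc$peak_id, p_before = mc$peak_p, p_after = p_after,
      verdict = verdict)
  }
  out <- new("ConditionalScanResult", stats = scan@stats,
             phenotype = scan@phenotype, covariates = scan@covariates,
             alpha = alpha, conditioned = scan@conditioned,
             mediation = med)
  out
}
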