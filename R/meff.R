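# Effective number of tests from the autocorrelation of local ancestry.
#
# For each individual and chromosome the local-ancestry series along the
# marker grid is an autocorrelated sequence; its effective sample size is
# n * var(x) / s(0), where s(0) is the spectral density at frequency zero
# of an AR(p) model fitted by Yule-Walker with p chosen by AIC. The
# Levinson-Durbin recursion is run batched across individuals (columns)
# so a whole chromosome is processed with vector operations.

# autocovariances (biased, /n) of demeaned series in columns of X
.acovLags <- function(X, lagmax) {
  m <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  out <- matrix(0, lagmax + 1, ncol(X))
  for (k in 0:lagmax)
    out[k + 1, ] <- colSums(Xc[seq_len(m - k), , drop = FALSE] *
                              Xc[seq_len(m - k) + k, , drop = FALSE]) / m
  out
}

# batched Yule-Walker/AIC fit; returns s(0), selected order and innovation
# variance per column. Columns with zero variance get s0 = NA.
.ywSpectrum0Batch <- function(acov, n) {
  k <- ncol(acov)
  pmax <- nrow(acov) - 1L
  v <- acov[1, ]                       # innovation variance, order 0
  zero <- v <= 0
  vsafe <- ifelse(zero, 1, v)
  aic <- matrix(Inf, pmax + 1, k)
  aic[1, ] <- n * log(vsafe)
  sumphi <- matrix(0, pmax + 1, k)
  vmat <- matrix(NA_real_, pmax + 1, k)
  vmat[1, ] <- vsafe
  phi <- matrix(0, max(pmax, 1), k)
  for (p in seq_len(pmax)) {
    num <- acov[p + 1, ]
    if (p > 1)
      num <- num - colSums(phi[seq_len(p - 1), , drop = FALSE] *
                             acov[p:2, , drop = FALSE])
    kp <- num / vsafe
    kp <- pmin(pmax(kp, -0.999999999), 0.999999999)
    phiNew <- phi
    phiNew[p, ] <- kp
    if (p > 1) {
      j <- seq_len(p - 1)
      phiNew[j, ] <- phi[j, , drop = FALSE] -
        rep(kp, each = p - 1) * phi[rev(j), , drop = FALSE]
    }
    phi <- phiNew
    vsafe <- pmax(vsafe * (1 - kp^2), 1e-300)
    vmat[p + 1, ] <- vsafe
    aic[p + 1, ] <- n * log(vsafe) + 2 * p
    sumphi[p + 1, ] <- colSums(phi[seq_len(p), , drop = FALSE])
  }
  best <- apply(aic, 2, which.min)     # ties resolve to the smaller order
  pick <- cbind(best, seq_len(k))
  # degrees-of-freedom correction of the innovation variance, as in the
  # standard AR fitting routine (var.pred); order = best - 1
  vpred <- vmat[pick] * n / pmax(n - best, 1)
  s0 <- vpred / (1 - sumphi[pick])^2
  s0[zero] <- NA_real_
  list(s0 = s0, order = best - 1L, sumphi = sumphi[pick],
       innovVar = vmat[pick])
}

#' Spectral density at frequency zero of an AR model
#'
#' Fits AR(p) models by Yule-Walker for p = 0..floor(10 log10(n)), selects
#' the order minimizing AIC = n log(sigma2_p) + 2p (ties towards smaller p)
#' and returns s(0) = sigma2 / (1 - sum(phi))^2.
#'
#' @param x numeric series, n >= 10, non-constant.
#' @return s(0), a positive scalar.
#' @export
arSpectrum0 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need n >= 10")
  if (stats::sd(x) == 0) stop("constant vector")
  pmax <- min(floor(10 * log10(n)), n - 2L)
  fit <- .ywSpectrum0Batch(.acovLags(matrix(x, ncol = 1), pmax), n)
  if (fit$sumphi >= 1)
    stop("selected AR model is non-stationary (sum of coefficients >= 1)")
  fit$s0
}

#' Effective sample size of an autocorrelated series
#'
#' `ESS = n var(x) / s(0)` with s(0) from [arSpectrum0()], clamped to
#' \[1, n\]. ESS is invariant to affine rescaling of the series, so the
#' coding of local ancestry (\{0, 0.5, 1\} versus \{0, 1, 2\}) does not
#' matter.
#'
#' @param x numeric series, n >= 10, non-constant.
#' @return effective sample size in \[1, n\].
#' @export
effectiveSize <- function(x) {
  n <- length(x)
  s0 <- arSpectrum0(x)
  min(max(n * stats::var(x) / s0, 1), n)
}

#' Effective number of tests of an admixture scan
#'
#' For every individual and chromosome, the effective sample size of the
#' local-ancestry series along the marker grid; the per-individual
#' chromosome ESS values are summed, and Meff is the mean of these totals
#' across individuals. A chromosome on which an individual's ancestry is
#' constant contributes 1 effective test. The family-wise threshold is
#' `alpha = fwer / Meff`.
#'
#' @param x an `AdmixtureExperiment` with an `ancestry` assay.
#' @param fwer nominal family-wise error rate.
#' @return a [MeffResult-class].
#' @export
effectiveTests <- function(x, fwer = 0.05) {
  L <- ancestry(x)
  chrom <- as.character(GenomicRanges::seqnames(markerInfo(x)))
  chrs <- unique(chrom)
  nind <- ncol(L)
  ess <- matrix(NA_real_, nind, length(chrs),
                dimnames = list(colnames(L), chrs))
  for (ci in seq_along(chrs)) {
    idx <- which(chrom == chrs[ci])
    m <- length(idx)
    if (m < 2) { ess[, ci] <- 1; next }
    X <- L[idx, , drop = FALSE]
    pmax <- max(1L, min(floor(10 * log10(m)), m - 2L))
    fit <- .ywSpectrum0Batch(.acovLags(X, pmax), m)
    v <- apply(X, 2, stats::var)
    e <- m * v / fit$s0
    e[is.na(fit$s0) | !is.finite(e)] <- 1   # constant-ancestry chromosome
    ess[, ci] <- pmin(pmax(e, 1), m)
  }
  perInd <- rowSums(ess)
  mv <- mean(perInd)
  if (all(ess == 1))
    warning("ancestry constant everywhere; Meff equals chromosome count")
  th <- significanceThreshold(mv, fwer)
  new("MeffResult", ess = ess, perIndividual = perInd, meff = mv,
      fwer = fwer, alpha = th$alpha, negLog10Alpha = th$negLog10Alpha)
}

#' Family-wise significance threshold from an effective test count
#'
#' `alpha = fwer / meff`, the Bonferroni bound at the effective number of
#' tests, with `-log10(alpha)` rounded to 2 decimals for display.
#'
#' @param meff effective number of tests, >= 1.
#' @param fwer family-wise error rate.
#' @return list with `alpha` and `negLog10Alpha`.
#' @examples
#' significanceThreshold(66.84)  # alpha 7.48e-04, -log10 3.13
#' @export
significanceThreshold <- function(meff, fwer = 0.05) {
  if (!is.finite(meff) || meff < 1) stop("meff must be >= 1")
  .assertProb(fwer, "fwer")
  alpha <- fwer / meff
  list(alpha = alpha, negLog10Alpha = round(-log10(alpha), 2))
}
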