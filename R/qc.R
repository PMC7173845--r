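#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions for a biallelic
#' marker. Conditional on the observed allele counts, every heterozygote
#' count with the right parity has probability
#' `P(nAa) = n! nA! na! 2^nAa / (nAA! nAa! naa! (2n)!)`;
#' the p-value is the sum over all configurations whose probability does not
#' exceed the observed one (no mid-p correction). Probabilities are compared
#' with a relative tolerance of 1e-9 so that exactly tied configurations
#' computed in floating point are included.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return the exact p-value, in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)  # 1/3
#' hweExactTest(5, 0, 0)  # monomorphic: 1
#' @export
hweExactTest <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(h) up to a constant shared by all configurations
  h <- hets
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pobs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

# per-marker genotype counts and summaries from a dosage matrix
.markerCounts <- function(dos) {
  n0 <- rowSums(dos == 0, na.rm = TRUE)
  n1 <- rowSums(dos == 1, na.rm = TRUE)
  n2 <- rowSums(dos == 2, na.rm = TRUE)
  nonmiss <- n0 + n1 + n2
  af <- ifelse(nonmiss > 0, (n1 + 2 * n2) / (2 * nonmiss), NA)
  list(n0 = n0, n1 = n1, n2 = n2, nonmiss = nonmiss, af = af,
       callrate = nonmiss / ncol(dos),
       maf = pmin(af, 1 - af))
}

#' Marker-level quality control
#'
#' Removes markers that are monomorphic, have call rate strictly below
#' `callrate_min`, minor allele frequency strictly below `maf_min`
#' (computed on non-missing calls), or a Hardy-Weinberg exact-test p-value
#' strictly below `hwe_p_min`. All flags are recorded per marker even when
#' a marker fails several rules, and the final marker set does not depend
#' on any rule ordering (the union of failures is removed).
#'
#' @param x an `AdmixtureExperiment` with a `dosage` assay.
#' @param config an [admixConfig()] holding the thresholds.
#' @return list with `experiment` (the filtered `AdmixtureExperiment`) and
#'   `report` (a [QCReport-class]).
#' @export
qcFilter <- function(x, config = admixConfig()) {
  dos <- dosage(x)
  if (!nrow(dos)) stop("empty genotype matrix")
  cs <- .markerCounts(dos)
  hwe_p <- vapply(seq_len(nrow(dos)), function(i) {
    if (cs$nonmiss[i] == 0) return(NA_real_)
    hweExactTest(cs$n0[i], cs$n1[i], cs$n2[i])
  }, numeric(1))
  mono <- cs$nonmiss == 0 |
    (cs$n0 == cs$nonmiss) | (cs$n1 == cs$nonmiss) | (cs$n2 == cs$nonmiss)
  flags <- S4Vectors::DataFrame(
    fail_hwe = !is.na(hwe_p) & hwe_p < config$hwe_p_min,
    fail_maf = !is.na(cs$maf) & cs$maf < config$maf_min,
    fail_callrate = cs$callrate < config$callrate_min,
    monomorphic = mono,
    hwe_p = hwe_p, maf = cs$maf, callrate = cs$callrate,
    row.names = rownames(dos))
  fail <- flags$fail_hwe | flags$fail_maf | flags$fail_callrate |
    flags$monomorphic
  counts <- c(fail_hwe = sum(flags$fail_hwe),
              fail_maf = sum(flags$fail_maf),
              fail_callrate = sum(flags$fail_callrate),
              monomorphic = sum(flags$monomorphic),
              removed_total = sum(fail),
              retained = sum(!fail))
  thr <- config[c("hwe_p_min", "maf_min", "callrate_min")]
  # read-level genotype filters (GQ, GQ/DP) need read data and are an
  # upstream step; recorded here so the report is explicit about it
  thr$read_level_filters <- "not applied (no read data)"
  report <- new("QCReport", flags = flags, counts = as.integer(counts),
                thresholds = thr)
  names(report@counts) <- names(counts)
  list(experiment = x[!fail, ], report = report)
}

#' LD pruning with depth-aware tie-breaking
#'
#' Sliding-window genotype LD pruning: within each window of `window`
#' markers (advancing by `step`, never crossing a chromosome boundary), as
#' long as any pair of retained markers has squared Pearson dosage
#' correlation above `r2_max`, the member of the worst pair with the lower
#' mean sequencing depth is removed (depth ties keep the lower-position
#' marker). The output is deterministic and contains no within-window pair
#' exceeding `r2_max`.
#'
#' @param x an `AdmixtureExperiment` with a `dosage` assay and a `depth`
#'   marker column.
#' @param window,step window size and step, in markers.
#' @param r2_max maximum tolerated squared correlation.
#' @return character vector of retained marker ids, with the removed ids in
#'   `attr(, "removed")`.
#' @export
ldPrune <- function(x, window = 200L, step = 20L, r2_max = 0.1) {
  if (window < step) stop("window must be >= step")
  dos <- dosage(x)
  gr <- markerInfo(x)
  depth <- S4Vectors::mcols(gr)$depth
  if (is.null(depth)) stop("markers carry no 'depth' metadata")
  pos <- GenomicRanges::start(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- rep(TRUE, nrow(dos))
  sdv <- apply(dos, 1, stats::sd, na.rm = TRUE)

  for (chr in unique(chrom)) {
    cidx <- which(chrom == chr)
    m <- length(cidx)
    for (start in seq(1L, max(1L, m), by = step)) {
      win <- cidx[start:min(start + window - 1L, m)]
      repeat {
        act <- win[keep[win] & !is.na(sdv[win]) & sdv[win] > 0]
        if (length(act) < 2) break
        r2 <- suppressWarnings(
          stats::cor(t(dos[act, , drop = FALSE]),
                     use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        if (max(r2) <= r2_max) break
        ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- act[ij[1]]; b <- act[ij[2]]
        drop <- if (depth[a] < depth[b]) a
          else if (depth[b] < depth[a]) b
          else if (pos[a] > pos[b]) a else b
        keep[drop] <- FALSE
      }
      if (start + window - 1L >= m) break
    }
  }
  ids <- S4Vectors::mcols(gr)$id
  out <- ids[keep]
  attr(out, "removed") <- ids[!keep]
  out
}
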