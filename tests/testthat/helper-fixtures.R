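# fixtures and independent oracles shared across test files

# small hand-specified experiment with both assays
toyExperiment <- function() {
  gr <- GenomicRanges::GRanges(
    rep(c("1", "2"), c(3, 2)),
    IRanges::IRanges(c(100, 200, 300, 150, 250), width = 1),
    id = paste0("m", 1:5),
    ref = "A", alt = "G",
    f_eur = c(0.34, 0.03, 0.18, 0.5, 0.5),
    f_afr = c(0.85, 0.68, 0.79, 0.5, 0.5),
    depth = c(30, 20, 25, 40, 10))
  dos <- matrix(c(0, 1, 2, 1, 0,
                  1, 1, 0, 2, 1,
                  2, 0, 1, 0, 2,
                  0, 2, 1, 1, 1), nrow = 5,
                dimnames = list(paste0("m", 1:5), paste0("i", 1:4)))
  L <- matrix(c(0, 0.5, 0.5, 1, 1,
                0, 0, 0.5, 0.5, 1,
                1, 1, 1, 0, 0,
                0.5, 0.5, 0.5, 0.5, 0.5), nrow = 5,
              dimnames = dimnames(dos))
  coh <- data.frame(individual_id = paste0("i", 1:4),
                    age = c(50, 55, 60, 48),
                    sex = c("female", "male", "female", "female"),
                    bmi = c(28, 32, 35, 30),
                    on_bp_meds = c(TRUE, FALSE, TRUE, FALSE),
                    dbp_raw = c(72, 80, 68, 75),
                    sbp_raw = c(120, 135, 118, 128))
  AdmixtureExperiment(markers = gr, dosage = dos, ancestry = L,
                      cohort = coh)
}

# brute-force normal-equations OLS used as the independent regression oracle
olsOracle <- function(y, X, target) {
  XtX <- solve(crossprod(X))
  beta <- XtX %*% crossprod(X, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  se <- sqrt(diag(XtX) * sum(res^2) / df)
  j <- match(target, colnames(X))
  list(beta = beta[j], se = se[j],
       p = 2 * pt(-abs(beta[j] / se[j]), df))
}

# direct enumeration oracle for the HWE exact test: probability of each
# heterozygote configuration from the closed-form conditional distribution
hweOracle <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  n <- n_AA + n_Aa + n_aa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(k)
    exp(lfactorial(n) - lfactorial((nA - k) / 2) - lfactorial(k) -
          lfactorial((na - k) / 2) + k * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)),
    numeric(1))
  pobs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

# one-chromosome cohort with an injected local-ancestry effect at marker 20
causalCohort <- function(seed, beta2, n = 484, spacingCM = 4,
                         lengthM = 1.6) {
  p <- simParams(nIndividuals = n, chromosomes = c(`1` = lengthM),
                 markerSpacingCM = spacingCM, causalLocus = 20,
                 effects = list(beta2 = beta2), seed = seed)
  preparePhenotypes(simulateAdmixedCohort(p, genotypes = FALSE))
}

# cohort whose ancestry signal is entirely mediated by a strong
# ancestry-differentiated causal SNP at marker 20
mediatedCohort <- function(seed, betaSnp = 6, fEur = 0.05, fAfr = 0.95) {
  p <- simParams(nIndividuals = 484, chromosomes = c(`1` = 1.6),
                 markerSpacingCM = 4, causalSnp = 20,
                 effects = list(beta2 = 0, betaSnp = betaSnp), seed = seed)
  sim <- simulateAncestry(p)
  m <- length(sim$markers)
  freqs <- data.frame(f_eur = rep(0.5, m), f_afr = rep(0.5, m))
  freqs[20, ] <- c(fEur, fAfr)
  geno <- simulateGenotypes(sim, p, freqs = freqs)
  ph <- simulatePhenotypes(sim, geno, p)
  preparePhenotypes(AdmixtureExperiment(markers = geno$markers,
                                        dosage = geno$dosage,
                                        ancestry = sim$L, cohort = ph))
}

# ScanResult built directly from a LOD profile (p-values to match)
scanFromLod <- function(lod, sig, chrom = "1") {
  p <- ifelse(sig, 1e-6, 0.5)
  st <- S4Vectors::DataFrame(
    chrom = chrom, pos = seq_along(lod) * 1000L,
    id = paste0("m", seq_along(lod)),
    beta2 = 1, se = 1, p = p, lod = lod,
    n_used = 100L)
  new("ScanResult", stats = st, phenotype = "dbp_adj",
      covariates = character(), alpha = NA_real_,
      conditioned = character())
}
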