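test_that("ancestry simulation is deterministic and respects limits", {
  p <- simParams(nIndividuals = 12, chromosomes = c(`1` = 0.3), seed = 3)
  a1 <- simulateAncestry(p)
  a2 <- simulateAncestry(p)
  expect_identical(a1$L, a2$L)
  expect_identical(a1$q, a2$q)
  expect_true(all(a1$L %in% c(0, 0.5, 1)))

  # vanishing map distances: haplotypes constant along the chromosome
  p0 <- simParams(nIndividuals = 20, chromosomes = c(`1` = 1e-7),
                  markerSpacingCM = 1e-6, seed = 4)
  a0 <- simulateAncestry(p0)
  expect_gt(length(a0$markers), 3)
  x0 <- AdmixtureExperiment(markers = a0$markers, ancestry = a0$L)
  expect_identical(unname(switchPoints(x0)), rep(0L, 20))

  expect_error(simulateAncestry(simParams(chromosomes = numeric(0))),
               "empty")
})

test_that("haploid switch counts match the Markov transition oracle", {
  # expected switches per haplotype: sum over intervals of
  # 2 q (1-q) (1 - exp(-g d))
  p <- simParams(nIndividuals = 50, g = 6,
                 chromosomes = stats::setNames(rep(7, 5), 1:5),  # 35 M total
                 markerSpacingCM = 0.1,
                 ancestryBetaMean = 0.8, ancestryBetaSD = 0, seed = 21)
  a <- simulateAncestry(p)
  chrom <- as.character(GenomicRanges::seqnames(a$markers))
  cm <- S4Vectors::mcols(a$markers)$cM
  expected <- 0; observed <- 0
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    d <- diff(cm[idx]) / 100
    expected <- expected + sum(2 * 0.8 * 0.2 * (1 - exp(-6 * d)))
    observed <- observed +
      mean(c(colSums(abs(diff(a$hap1[idx, ]))),
             colSums(abs(diff(a$hap2[idx, ])))))
  }
  expect_lt(abs(observed - expected) / expected, 0.1)
})

test_that("switch counts increase with generations since admixture", {
  counts <- vapply(c(2, 6, 20), function(g) {
    p <- simParams(nIndividuals = 30, g = g, chromosomes = c(`1` = 2),
                   markerSpacingCM = 0.5, seed = 8)
    a <- simulateAncestry(p)
    x <- AdmixtureExperiment(markers = a$markers, ancestry = a$L)
    mean(switchPoints(x))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("global ancestry matches the Beta prior across replicates", {
  gm <- vapply(1:5, function(s) {
    p <- simParams(nIndividuals = 100, chromosomes = c(`1` = 1),
                   seed = 100 + s)
    attr(globalAncestry(simulateAncestry(p)$L), "mean")
  }, numeric(1))
  se <- 0.128 / sqrt(5 * 100)
  expect_lt(abs(mean(gm) - 0.767), 3 * se + 0.01)
})

test_that("genotypes follow ancestry-conditional allele frequencies", {
  p <- simParams(nIndividuals = 50, chromosomes = c(`1` = 0.1), seed = 6)
  a <- simulateAncestry(p)
  m <- length(a$markers)

  fixed <- simulateGenotypes(a, p, freqs = data.frame(
    f_eur = rep(1, m), f_afr = rep(1, m)))
  expect_true(all(fixed$dosage == 2))

  perfect <- simulateGenotypes(a, p, freqs = data.frame(
    f_eur = rep(0, m), f_afr = rep(1, m)))
  expect_equal(unname(perfect$dosage + 0), unname(2 * a$L))

  # binomial sampling: empirical alt frequency within 3 SE of 0.85
  p2 <- simParams(nIndividuals = 2000, chromosomes = c(`1` = 0.015),
                  seed = 7)
  a2 <- simulateAncestry(p2)
  m2 <- length(a2$markers)
  g2 <- simulateGenotypes(a2, p2, freqs = data.frame(
    f_eur = rep(0.85, m2), f_afr = rep(0.85, m2)))
  fhat <- mean(g2$dosage) / 2
  expect_lt(abs(fhat - 0.85),
            3 * sqrt(0.85 * 0.15 / (2 * 2000 * m2)))

  expect_error(simulateGenotypes(a, p, freqs = data.frame(
    f_eur = rep(1.2, m), f_afr = rep(0.5, m))), "\\[0, 1\\]")
})

test_that("phenotypes reduce to the intercept without effects or noise", {
  p <- simParams(nIndividuals = 25, chromosomes = c(`1` = 0.1),
                 effects = list(beta0 = 70, beta1 = 0, beta2 = 0,
                                betaSnp = 0, betaAge = 0, betaAge2 = 0,
                                betaSex = 0, betaBmi = 0),
                 noiseSd = 1e-9, medRate = 0, seed = 10)
  a <- simulateAncestry(p)
  ph <- simulatePhenotypes(a, NULL, p)
  expect_equal(ph$dbp_raw, rep(70, 25), tolerance = 1e-6)
  expect_false(any(ph$on_bp_meds))
  expect_true(all(ph$sbp_raw > ph$dbp_raw))

  ph2 <- simulatePhenotypes(a, NULL, p)
  expect_identical(ph, ph2)

  p$causalLocus <- 10000
  expect_error(simulatePhenotypes(a, NULL, p), "out of range")
})

test_that("medication rate and phenotype moments track the defaults", {
  p <- simParams(nIndividuals = 800, chromosomes = c(`1` = 0.5), seed = 12)
  x <- simulateAdmixedCohort(p, genotypes = FALSE)
  coh <- cohort(x)
  expect_lt(abs(mean(coh$on_bp_meds) - 0.45), 0.06)
  dbp_true <- coh$dbp_raw + 5 * coh$on_bp_meds
  sbp_true <- coh$sbp_raw + 10 * coh$on_bp_meds
  expect_lt(abs(mean(dbp_true) - 73), 2.5)
  expect_lt(abs(sd(dbp_true) - 9), 2)
  expect_lt(abs(mean(sbp_true) - 125), 3.5)
  expect_lt(abs(mean(coh$sex == "female") - 0.74), 0.06)
})
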