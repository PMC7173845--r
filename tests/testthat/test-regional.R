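test_that("delta selection respects region bounds and the strict cutoff", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200, 300, 400),
                                                     width = 1),
                               id = paste0("s", 1:4),
                               f_eur = c(0.34, 0.10, 0.30, 0.03),
                               f_afr = c(0.85, 0.50, 0.70, 0.68))
  L <- matrix(0.5, 4, 3, dimnames = list(paste0("s", 1:4),
                                         paste0("i", 1:3)))
  x <- AdmixtureExperiment(markers = gr, ancestry = L)
  region <- GenomicRanges::GRanges("1", IRanges::IRanges(100, 300))
  sel <- selectDeltaSnps(x, region, 0.4)
  expect_identical(sel, "s1")          # s2 delta 0.4 exactly: excluded
  expect_false("s4" %in% sel)          # delta 0.65 but outside region
  empty <- GenomicRanges::GRanges("1", IRanges::IRanges(900, 950))
  expect_warning(out <- selectDeltaSnps(x, empty), "no markers")
  expect_length(out, 0)
})

test_that("principal components separate ancestral clusters", {
  set.seed(31)
  n1 <- 50; n2 <- 50; m <- 150
  f1 <- runif(m, 0.05, 0.95)
  f2 <- pmin(0.99, pmax(0.01, f1 + sample(c(-0.4, 0.4), m, TRUE)))
  dos <- cbind(matrix(rbinom(m * n1, 2, f1), m),
               matrix(rbinom(m * n2, 2, f2), m))
  dimnames(dos) <- list(paste0("m", 1:m), paste0("i", 1:(n1 + n2)))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:m * 10, width = 1),
                               id = rownames(dos))
  x <- AdmixtureExperiment(markers = gr, dosage = dos)
  pc <- computePCs(x, 10)
  lbl <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pc[, 1], lbl)), 0.9)
  # orthogonality
  cp <- crossprod(pc)
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)
  expect_identical(ncol(computePCs(x, 0)), 0L)
  expect_error(computePCs(x, 1000), "rank|markers")
})

test_that("SNP association recovers a noiseless effect and matches OLS", {
  set.seed(32)
  n <- 100
  d <- rbinom(n, 2, 0.4)
  cov <- data.frame(age = runif(n, 45, 65),
                    sex = sample(c("female", "male"), n, TRUE),
                    bmi = rnorm(n, 32, 6))
  y <- 70 - 2.42 * d + 0.1 * cov$age + 0.5 * (cov$sex == "male") +
    0.02 * cov$bmi
  fit <- snpAssociation(y, d, cov)
  expect_lt(abs(fit$beta - (-2.42)), 1e-8)

  yn <- y + rnorm(n, 0, 3)
  fit2 <- snpAssociation(yn, d, cov)
  X <- cbind(`(Intercept)` = 1, age = cov$age, age2 = cov$age^2,
             sex = as.numeric(cov$sex == "male"), bmi = cov$bmi,
             dosage = d)
  orc <- olsOracle(yn, X, "dosage")
  expect_lt(abs(fit2$beta - orc$beta), 1e-10)
  expect_lt(abs(fit2$se - orc$se), 1e-10)
  expect_error(snpAssociation(y, rep(1, n), cov), "monomorphic")
})

test_that("SNP association is calibrated under a permuted null", {
  set.seed(33)
  n <- 200
  cov <- data.frame(age = runif(n, 45, 65),
                    sex = sample(c("female", "male"), n, TRUE),
                    bmi = rnorm(n, 32, 6))
  y <- rnorm(n, 73, 9)
  hits <- vapply(1:400, function(r) {
    d <- rbinom(n, 2, 0.3)
    snpAssociation(y, d, cov)$p < 0.05
  }, logical(1))
  ci <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(hits) - 0.05), ci + 0.01)
})

test_that("bonferroni flags reproduce the phenotype-level thresholds", {
  f1 <- bonferroniFlag(9.57e-4, 21)
  expect_true(f1)
  expect_equal(attr(f1, "threshold"), 0.05 / 21)
  expect_true(bonferroniFlag(3.37e-3, 14))
  expect_false(bonferroniFlag(4e-3, 14))
  expect_equal(attr(bonferroniFlag(0.01, 1), "threshold"), 0.05)
})

test_that("DerSimonian-Laird pooling matches the hand calculation", {
  out <- dlPool(c(1, 3), c(1, 1))
  expect_equal(out$Q, 2)
  expect_equal(out$tau2, 1)
  expect_equal(out$beta, 2)
  expect_equal(out$se, 1)
  # homogeneous strata: tau2 = 0, pooled = common value
  same <- dlPool(c(1.5, 1.5, 1.5), c(0.5, 0.5, 0.5))
  expect_equal(same$tau2, 0)
  expect_equal(same$beta, 1.5)
  expect_error(dlPool(1, 1), "strata")
  # pooled estimate lies within the stratum range
  set.seed(34)
  for (r in 1:20) {
    b <- rnorm(4); s <- runif(4, 0.3, 2)
    p <- dlPool(b, s)
    expect_gte(p$beta, min(b))
    expect_lte(p$beta, max(b))
  }
})

test_that("DerSimonian-Laird pooling matches metafor", {
  skip_if_not_installed("metafor")
  set.seed(35)
  for (r in 1:10) {
    b <- rnorm(5); s <- runif(5, 0.3, 2)
    mine <- dlPool(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
  }
})

test_that("stratified meta recovers a homogeneous SNP effect", {
  est <- vapply(1:60, function(r) {
    p <- simParams(nIndividuals = 400, chromosomes = c(`1` = 0.05),
                   causalSnp = 5, deltaFrac = 1,
                   effects = list(betaSnp = -2.42), seed = 400 + r)
    x <- preparePhenotypes(simulateAdmixedCohort(p))
    id <- rownames(dosage(x))[5]
    out <- tryCatch(stratifiedMeta(x, id, "dbp_adj", minStratumN = 30),
                    error = function(e) NULL)
    if (is.null(out)) NA_real_ else out@beta
  }, numeric(1))
  est <- est[!is.na(est)]
  expect_gt(length(est), 30)
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-2.42)), 2 * mcse + 0.05)
})

test_that("stratified meta requires two usable strata", {
  p <- simParams(nIndividuals = 60, chromosomes = c(`1` = 0.05),
                 ancestryBetaMean = 0.98, ancestryBetaSD = 0, seed = 36)
  x <- preparePhenotypes(simulateAdmixedCohort(p))
  id <- rownames(dosage(x))[1]
  expect_error(stratifiedMeta(x, id, "dbp_adj", minStratumN = 30),
               "strata")
})

test_that("regional association combines delta filter, PCs and flags", {
  p <- simParams(nIndividuals = 200, chromosomes = c(`1` = 0.3),
                 deltaFrac = 0.5, causalSnp = 10,
                 effects = list(betaSnp = -4), seed = 37)
  x <- preparePhenotypes(simulateAdmixedCohort(p))
  gr <- markerInfo(x)
  region <- GenomicRanges::GRanges("1", IRanges::IRanges(
    1, max(GenomicRanges::start(gr))))
  res <- regionalAssociation(x, region, "dbp_adj", deltaCutoff = 0.4,
                             nPcs = 5)
  st <- as.data.frame(res@stats)
  expect_true(all(st$delta > 0.4))
  expect_equal(res@threshold, 0.05 / res@mTested)
  expect_identical(st$pass_bonferroni, !is.na(st$p) & st$p < res@threshold)
})
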