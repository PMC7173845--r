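test_that("noiseless construction recovers the locus effect exactly", {
  set.seed(24)
  n <- 120
  G <- rbeta(n, 7.6, 2.3)
  L <- pmin(pmax(round(2 * G + sample(c(-1, 0, 1), n, TRUE)) / 2, 0), 1)
  cov <- data.frame(age = runif(n, 45, 65),
                    sex = sample(c("female", "male"), n, TRUE),
                    bmi = rnorm(n, 32, 5))
  y <- 60 + 8 * G + 5.28 * (G - L) + 0.05 * cov$age +
    1 * (cov$sex == "male") + 0.05 * cov$bmi
  fit <- fitAdmixtureModel(y, G, L, cov)
  expect_lt(abs(fit$beta2 - 5.28), 1e-8)
  expect_lt(fit$p, 1e-12)
  expect_error(fitAdmixtureModel(y, G, G, cov), "degenerate")
})

test_that("rank-deficient covariates are reported by name", {
  set.seed(25)
  n <- 50
  G <- runif(n); L <- rbinom(n, 2, 0.5) / 2
  cov <- data.frame(age = runif(n, 45, 65), sex = "female",
                    bmi = rnorm(n, 30, 4))
  y <- rnorm(n)
  # sex is constant, collinear with the intercept
  expect_error(fitAdmixtureModel(y, G, L, cov), "sex")
})

test_that("scan equals per-marker OLS and the normal-equations oracle", {
  p <- simParams(nIndividuals = 50, chromosomes = c(`1` = 0.2), seed = 26)
  x <- preparePhenotypes(simulateAdmixedCohort(p, genotypes = FALSE))
  s <- scanStats(admixtureScan(x, "dbp_adj"))
  coh <- cohort(x)
  G <- as.numeric(globalAncestry(x))
  L <- ancestry(x)
  for (i in c(1, 10, 25, nrow(s))) {
    X <- cbind(`(Intercept)` = 1, age = coh$age, age2 = coh$age^2,
               sex = as.numeric(coh$sex == "male"), bmi = coh$bmi,
               G = G, GminusL = G - L[i, ])
    if (qr(X)$rank < ncol(X)) next
    orc <- olsOracle(coh$dbp_adj, X, "GminusL")
    expect_lt(abs(s$beta2[i] - orc$beta), 1e-10)
    expect_lt(abs(s$se[i] - orc$se), 1e-10)
    expect_lt(abs(s$p[i] - orc$p), 1e-10)
  }
})

test_that("scan p-values are invariant to affine covariate rescaling", {
  p <- simParams(nIndividuals = 60, chromosomes = c(`1` = 0.15), seed = 27)
  x <- preparePhenotypes(simulateAdmixedCohort(p, genotypes = FALSE))
  s1 <- scanStats(admixtureScan(x, "dbp_adj"))
  cd <- SummarizedExperiment::colData(x)
  cd$age <- (cd$age - 50) / 10
  cd$bmi <- cd$bmi * 3 + 1
  SummarizedExperiment::colData(x) <- cd
  s2 <- scanStats(admixtureScan(x, "dbp_adj"))
  expect_equal(s2$p, s1$p, tolerance = 1e-8)
})

test_that("constant-ancestry cohorts yield a degenerate scan with warning", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:10 * 100, width = 1),
                               id = paste0("m", 1:10))
  L <- matrix(1, 10, 30, dimnames = list(paste0("m", 1:10),
                                         paste0("i", 1:30)))
  set.seed(28)
  coh <- data.frame(individual_id = paste0("i", 1:30),
                    age = runif(30, 45, 65),
                    sex = sample(c("female", "male"), 30, TRUE),
                    bmi = rnorm(30, 30, 4),
                    on_bp_meds = FALSE,
                    dbp_raw = rnorm(30, 73, 9), sbp_raw = rnorm(30, 125, 5))
  coh$sbp_raw <- pmax(coh$sbp_raw, coh$dbp_raw + 20)
  x <- preparePhenotypes(AdmixtureExperiment(markers = gr, ancestry = L,
                                             cohort = coh))
  w <- capture_warnings(s <- admixtureScan(x, "dbp_adj"))
  expect_match(w, "degenerate", all = FALSE)
  expect_match(w, "constant", all = FALSE)  # G also constant here
  expect_true(all(is.na(scanStats(s)$p)))
})

test_that("LOD is the squared Wald statistic over 2 ln 10", {
  expect_equal(lodFromWald(2, 1), 4 / (2 * log(10)))
  expect_equal(lodFromWald(2, 1), 0.8686, tolerance = 1e-4)
  expect_equal(lodFromWald(0, 2), 0)
  expect_equal(lodFromWald(-3, 1.5), lodFromWald(3, 1.5))
  expect_error(lodFromWald(1, 0), "se")
})

test_that("peak regions follow the one-unit drop rule", {
  lod <- c(0.2, 1.0, 3.5, 2.8, 2.6, 1.9, 0.3)
  scan <- scanFromLod(lod, sig = seq_along(lod) == 3)
  reg <- peakRegions(scan, alpha = 1e-3)
  expect_length(reg, 1)
  expect_equal(GenomicRanges::start(reg), 3000)
  expect_equal(GenomicRanges::end(reg), 5000)
  expect_equal(S4Vectors::mcols(reg)$peak_id, "m3")

  none <- peakRegions(scanFromLod(lod, sig = rep(FALSE, 7)), alpha = 1e-3)
  expect_length(none, 0)

  two <- scanFromLod(c(4, 1, 0.5, 1, 5, 1), sig = c(TRUE, rep(FALSE, 3),
                                                    TRUE, FALSE))
  regs <- peakRegions(two, alpha = 1e-3)
  expect_length(regs, 2)
  expect_setequal(S4Vectors::mcols(regs)$peak_id, c("m1", "m5"))
  expect_error(peakRegions(two, alpha = 2), "alpha")
})

test_that("empty conditioning reproduces the plain scan", {
  p <- simParams(nIndividuals = 40, chromosomes = c(`1` = 0.15), seed = 29)
  x <- preparePhenotypes(simulateAdmixedCohort(p))
  plain <- admixtureScan(x, "dbp_adj", alpha = 0.01)
  cond <- conditionalScan(x, "dbp_adj", snps = character(),
                          regions = GenomicRanges::GRanges(), alpha = 0.01)
  expect_identical(scanStats(cond), scanStats(plain))
})

test_that("conditioning on a collinear vector errors", {
  p <- simParams(nIndividuals = 40, chromosomes = c(`1` = 0.15), seed = 30)
  x <- preparePhenotypes(simulateAdmixedCohort(p))
  coh <- cohort(x)
  collin <- matrix(as.numeric(coh$sex == "male"), ncol = 1,
                   dimnames = list(NULL, "copy_of_sex"))
  expect_error(admixtureScan(x, "dbp_adj", conditionOn = collin),
               "collinear")
})

test_that("conditional verdicts classify mediation strength", {
  x <- mediatedCohort(301)
  s <- admixtureScan(x, "dbp_adj")
  st <- scanStats(s)
  alpha <- 7.5e-4
  regions <- peakRegions(s, alpha)
  expect_gte(length(regions), 1)
  cond <- conditionalScan(x, "dbp_adj", snps = st$id[20],
                          regions = regions, alpha = alpha)
  med <- mediation(cond)
  expect_true(all(med$verdict %in%
                    c("fully_explained", "partially_explained",
                      "unexplained")))
  expect_true(all(med$p_after >= med$p_before | med$p_after < 0.05))
})
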